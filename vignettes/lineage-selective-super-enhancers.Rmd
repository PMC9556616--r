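---
title: "Lineage-selective super enhancers and core regulatory circuitry: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lineage-selective super enhancers and core regulatory circuitry: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The biological setting

Human mesenchymal stromal cells (hMSCs) can differentiate into
adipocytes or osteoblasts, and the balance between these two fates is
relevant to both osteoporosis and obesity.  Super enhancers (SEs) —
clusters of enhancers with exceptionally high activity signal — are
strong candidates for the regulatory elements that lock in one fate or
the other.  `secircuit` implements a complete analysis of this system
from called peaks and quantified signal: it identifies SEs per cell
type from H3K27ac ChIP-seq, calls the subset that is *selective* for
the adipocyte or osteoblast lineage, assigns those SEs their target
genes with an activity-by-contact (ABC) score, assembles the core
regulatory circuitry (CRC) of SE-regulated transcription factors, and
scores trait-associated variants inside SE functional regions for
allele-specific TF-binding changes.

The package expects the data shape of a three-cell-type differentiation
experiment: H3K27ac peaks and coverage for hMSCs, adipocytes and
osteoblasts with two replicates each, per-cell-type accessibility
(DNase) peaks and coverage, an FPKM expression table, and optionally
PWMs, k-mer binding weights and a GWAS summary table.

# Enhancer landscape

Peaks from all six samples are merged into a consensus set
(`merge_peaks`; intervals that overlap or touch end-to-start are
unioned).  Peaks lying completely inside a promoter window — 2 kb on
each side of any annotated TSS of protein-coding or lncRNA genes
(`read_tss`, per-transcript records) — are removed; peaks that only
partially overlap a promoter window are kept
(`exclude_promoter_peaks`).  The remaining enhancers are stitched:
consecutive peaks on one chromosome closer than 12.5 kb form one
stitched enhancer (`stitch_enhancers`).  The comparator is strict
(`<`), with `<=` available via the `comparator` argument for users who
prefer the alternative convention.

Per-sample signal of a stitched enhancer is the sum over its
constituent peaks of coverage × overlapped bp, normalized per million
within the quantified region set (`quantify_signal`).  Normalization
makes signals comparable across samples while leaving ranks and
fold-change structure intact; raw sums are retained as an attribute.
Inter-peak gaps are deliberately excluded from quantification (they
contribute noise, not enhancer signal); `quantify_signal` on a plain
interval table quantifies full spans when that is wanted.

# Super-enhancer calling

Within each sample, stitched enhancers are ranked by signal (rank 1 =
strongest; ties resolve by genomic position so output is reproducible).
The classical hockey-stick cutoff is applied per sample
(`inflection_cutoff`): signals are sorted ascending, index and signal
are scaled to the unit square, and the cutoff is the tangency point of
a slope-1 line with the rank curve.  We locate it as the *rightmost
maximizer of x − y*, the point furthest below the unit diagonal.  On a
convex curve this is exactly the first point whose discrete slope
crosses 1 (for signals proportional to the squared index the cutoff
falls at the curve midpoint, which the test suite checks in closed
form), but unlike a left-to-right slope scan it is immune to isolated
steep steps among near-zero signals, which on noisy data can otherwise
place the cutoff at the very bottom of the curve and call everything an
SE.  A linear ramp has x − y constant; the rightmost-tie rule then
yields a primary count of 0, and an all-equal vector warns.

The consensus SE number `N` is the mean of the per-sample primary
counts, rounded half away from zero (`consensus_se_number`).  An
enhancer is an SE for a cell type iff its mean rank over that cell
type's replicates is at or above the consensus number — numerically
`mean_rank <= N` (`call_cell_type_ses`).

# Differential test and lineage-selective SEs

Counts on stitched enhancers (adipocyte vs osteoblast, replicates
pooled within group) are compared with a conditional exact test
(`diff_enhancer_test`): with pooled counts `a` and `b` and group
library sizes `L_A`, `L_B`, the region total `n = a + b` is fixed and
`a` is tested against `Binomial(n, L_A / (L_A + L_B))`, two-sided by
the minimum-likelihood rule (the `stats::binom.test` definition; our
implementation finds the opposite-tail boundary by binary search on the
unimodal pmf, and the tests verify equality with `binom.test` on a
dense grid).  Fold change is computed on library-normalized counts with
a 0.5-count pseudocount per group so zeros stay finite, and
Benjamini–Hochberg FDR is applied across regions.  This replaces a
negative-binomial wrapper deliberately: at two replicates per group a
fully specified, deterministic exact test is preferable, and externally
computed p-values can be substituted upstream of the selective call if
a dispersion-aware test is wanted.

Exact-test p-values are discrete: at low counts the spacing of
attainable p-values is about `2 * sqrt(2 / (pi * n))`, which makes the
test conservative rather than miscalibrated.  The test suite therefore
checks null calibration (KS against uniform, and the p < 0.05 rate
against its exact binomial confidence interval) at deep counts
(Poisson mean 20,000 per sample over 20,000 regions), where the null
distribution is effectively continuous; at shallow counts conservatism
is expected and harmless for an FDR gate.

A stitched enhancer is **adipocyte-selective** iff all of: mean rank in
adipocytes `<= N`; mean rank in osteoblasts `> N`; differential FDR
`<= 0.1`; and fold change adipocyte/osteoblast `>= 1.5`
(`call_lineage_selective_ses`).  Osteoblast-selective calls mirror the
criterion, so the two sets are disjoint by construction.  The combined
rank + signal criterion avoids the false positives that a naive
set-difference of SE lists produces near the SE/TE boundary.

# ABC target assignment

Functional regions of a selective SE are the accessibility peaks of its
own lineage clipped to the SE interval; fragments under 50 bp are
dropped as unquantifiable (`define_functional_regions`).  For a gene
`G` and element `E`, the ABC score is

    ABC(E, G) = A_E * C_EG / sum over candidates E' of A_E' * C_E'G

with activity `A = sqrt(dnase * h3k27ac)` and contact
`C = max(distance, d_min)^(-gamma)`; distance is element midpoint to
TSS.  Without chromatin-contact data the power law with `gamma = 1`
and a 5 kb floor is the standard fallback, and both are configurable.
The candidate set of a gene is every element within 5 Mb of its TSS
*plus the gene's own promoter element* (TSS ± 250 bp, quantified like
any other element): without promoter competition the normalization is
meaningless for genes with no nearby enhancer.  Elements and promoters
must share one per-million normalization per track; `run_pipeline`
quantifies them in a single call per track for exactly that reason
(scores are invariant to common rescaling, not to per-set rescaling).
A gene is a credible target of an SE iff some functional region links
to it with score strictly above 0.02, and SE-level targets are the
union over the SE's functional regions (`assign_se_targets`).

Target-set expression is contrasted between cell types with a
two-sided Wilcoxon rank-sum test on per-gene mean FPKM
(`expression_contrast`); a fully tied null returns p = 1.

# Motif scanning and the CRC

PWMs receive a 1e-3 pseudocount per cell and are scanned on both
strands with log2 odds scores against a zero-order background
(`scan_pwm`).  P-values are exact: scores are discretized at 1e-3 bits
and the full null score distribution is built by dynamic-programming
convolution across motif positions, so the `p < 1e-4` hit rule is a
reproducible hard threshold rather than an approximation.  The tests
verify the DP against complete enumeration of all sequences up to
motif length 8.  Windows containing N are skipped.

A TF regulates a gene if at least two motif hits with `p < 1e-4` occur
in the functional regions of the SEs targeting that gene (pooled
across regions by default; `per_region = TRUE` requires both hits in
one region), or if a merged ChIP peak set for the TF overlaps those
regions by at least 1 bp (`tf_target_pairs`).  With neither evidence
source the pair is "untestable", which is deliberately distinct from
"rejected".  The CRC is then the set of SE-regulated TFs in which
every TF binds the SE of every TF in the set *including its own*:
maximal cliques (exact enumeration; node counts here are small) of the
mutual-edge graph restricted to TFs with a self-loop (`build_crc`).

# GWAS variants in functional regions

Genome-wide-significant variants (`p <= 5e-8`, inclusive) are
intersected with functional regions by a half-open point-in-interval
test.  Enrichment is a two-sided Fisher exact test on
{significant, not} × {in region, not}, with the odds ratio reported as
the plain cross-product ratio and a Woolf logit 95% CI (0.5 added to
all cells only when a cell is zero).  The background here is all
variants in the supplied summary panel; an interval-matched control
background can be substituted by subsetting the panel before the call
— the 2×2 design itself does not dictate the choice, so it is left
explicit.

Allele effects on TF binding use a k-mer weight model (default
k = 11): each allele's score sums the weights of the k k-mers covering
the variant base in a 2k−1 window, looking up the larger of a k-mer's
and its reverse complement's weight (gkm-style weight lists are
strand-collapsed; absent k-mers weigh 0).  `delta = alt − ref`; an
allele is "bound" iff its score exceeds `tau` (default 0, the natural
margin for SVM-derived weights), and only variants whose bound status
changes are interpreted.  Indels are reported "unsupported" — window
algebra is ill-defined under length changes.  The directional filter
keeps a variant iff `sign(beta) = sign(delta) * sign(corr)`, where
`corr` is the TF→target expression-correlation sign; this encodes the
working assumption that the target gene promotes the trait in its own
lineage, and that assumption is recorded in every verdict rather than
silently applied.

# The synthetic-data generator

`simulate_dataset` emits a complete dataset of exactly the
three-cell-type, two-replicate shape above, with every planted feature
recorded in a truth manifest.  Defaults (changeable via `sim_config`)
describe the study conditions the package is validated under:

* genome: 3 chromosomes × 10 Mb; 180 enhancer loci of 2–3 constituent
  peaks placed on a jittered grid at least 25 kb apart;
* signal tiers: locus-level lognormal signal with SE-tier scale 50 and
  typical-enhancer scale 5 (sdlog 0.25), 15% of non-selective loci in
  the SE tier; replicate noise multiplicative lognormal with CV 0.2;
* selectivity: 7% of loci per lineage, with a guaranteed minimum fold
  of 3 between the differentiated lineages.  Adipocyte-selective loci
  are planted *de novo* (near-zero progenitor signal) and
  osteoblast-selective loci *inherited* (SE-level progenitor signal),
  mirroring the asymmetry observed in real hMSC differentiation;
* counts: Poisson with mean 8 per signal unit, emitted as a per-region
  table so the differential test is exercised independently of
  coverage summation;
* expression: FPKM = base × (1 + α · normalized element activity) with
  α = 2, multiplicative noise CV 0.2 — target genes track their
  element's activity, decoys do not;
* ABC geometry: each selective locus gets one target gene 20–80 kb
  away; selective loci sit ≥ ~0.8 Mb apart and decoy genes ≥ 0.7 Mb
  from selective loci.  These spacings follow from the score algebra:
  with element/promoter activity amplitudes 50 and 40, a planted link
  at ≤ 80 kb scores far above 0.02 while any non-parent element beyond
  ~0.5 Mb scores below it, so planted links are the only
  super-threshold links by construction rather than by tuning;
* CRC: 3 TFs among the osteoblast-lineage targets; near-deterministic
  PWMs (consensus probability 0.85, length 10) with two consensus
  sites per directed TF pair embedded in the target SE's functional
  regions (`plant_motif_sites`);
* GWAS: 2,000 variants, 25% placed inside functional regions;
  significance rate 0.2 inside vs 0.05 outside (a planted 4× design);
  8 causal variants receive k-mer models built so that exactly one
  allele is bound, with GWAS effect signs planted consistent with the
  directional rule except for a labeled inconsistent minority (25%).

The generator is deterministic given the seed (byte-identical files on
re-run).  What it does **not** emulate: mapping artifacts and blacklist
regions, input/control subtraction, overdispersion beyond lognormal ×
Poisson, LD structure among variants, correlated motif background, or
genuine 3D contact variation (contact is the analytic power law).
Passing recovery tests therefore demonstrate correctness of the
pipeline's logic under its stated model, not robustness to every
real-data pathology.

# Numerical choices and degenerate inputs

* Coordinates are 0-based half-open everywhere internally; GTF and
  GWAS positions convert at the parse boundary only.  Chromosome names
  are taken verbatim.
* Rank ties break by genomic position; the inflection degenerate cases
  are defined above; `N` rounding is half away from zero.
* PWM score discretization is 1e-3 bits (configurable); the DP tail is
  exact for the discretized score.
* The motif-enrichment background rate is floored at
  1/(n_background + 1) so an empty background cannot produce p = 0.
* Fisher enrichment refuses tables with a zero margin (the test is
  undefined) rather than silently returning 1.
* `delta_kmer_score` requires windows of length exactly 2k−1 centered
  on a single-base difference; anything else is an error or an
  "unsupported" verdict, never a silent guess.

# Problem sizes used by the test suite

The packaged tests run the full pipeline at the default generator
conditions over 10 seeds for selective-SE, ABC, CRC and
directional-filter recovery; 50 random interval sets of 500 intervals
against brute-force oracles; complete enumeration for motif-p and
Fisher oracles (all 4^L sequences for L ≤ 8; all 2×2 tables with
margins ≤ 30); 20,000 regions for the null calibration; and 20 seeds
each for GWAS enrichment power and size.  `scripts/acceptance.R`
re-runs the pipeline from scratch on three simulated replicates and
writes the headline quantities as JSON.

# Known limitations

* The differential test ignores replicate-level overdispersion by
  design; with more replicates a dispersion-aware test is preferable
  (external p-values can be injected).
* ABC without contact data is a distance prior, not a measurement.
* The directional filter's trait-sign assumption is heuristic and is
  carried in the output for the user to audit.
* The CRC clique enumeration is exact but intended for the small TF
  sets this analysis yields (≈ 10 nodes).
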