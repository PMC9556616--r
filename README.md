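# secircuit

Lineage-selective super-enhancer discovery and core regulatory
circuitry inference for differentiating cell populations.

## What problem this solves

Mesenchymal stromal cells choose between adipocyte and osteoblast
fates, and that choice is steered by super enhancers (SEs): stitched
clusters of enhancers with exceptionally high H3K27ac signal.
`secircuit` is for computational biologists who have *called peaks and
signal* (not raw reads) from such a system — three cell types, two
replicates each — and want the full downstream analysis:

1. **Consensus landscape** — merge peaks across samples, drop peaks
   fully inside promoter windows (TSS ± 2 kb), stitch the rest
   (< 12.5 kb gaps) and quantify per-sample signal.
2. **SE calling** — rank stitched enhancers per sample, cut each rank
   curve at the hockey-stick inflection (the slope-1 tangency on the
   unit-scaled curve), average the per-sample primary counts into a
   consensus SE number `N`, and call an enhancer an SE for a cell type
   iff its mean replicate rank is `<= N`.
3. **Lineage-selective SEs** — a combined criterion: SE-level rank in
   one lineage, non-SE rank in the other, differential signal at
   FDR ≤ 0.1 (pooled two-sided exact binomial test conditioned on
   region totals) with fold change ≥ 1.5.
4. **Target genes** — activity-by-contact scoring over the SEs'
   accessible functional regions,
   `ABC(E,G) = A_E C_EG / Σ_E' A_E' C_E'G` with
   `A = sqrt(DNase × H3K27ac)` and `C = max(d, 5 kb)^(-1)`;
   genes with a score > 0.02 are credible targets.
5. **Core regulatory circuitry** — exact-p-value PWM scanning
   (dynamic-programming null distribution; hits at p < 1e-4, ≥ 2 hits
   per TF–gene pair, or ≥ 1 bp ChIP-peak overlap), then maximal
   cliques of SE-regulated TFs in which every TF binds every member's
   SE including its own.
6. **GWAS variants** — Fisher enrichment of genome-wide-significant
   variants (p ≤ 5e-8) in SE functional regions, allele-specific
   binding scores from k-mer (gkm-style) weight models
   (`delta = alt − ref` over the 2k−1 variant window), and a
   directional-consistency filter
   `sign(beta) = sign(delta) × sign(TF→target correlation)`.

A deterministic synthetic-data generator (`simulate_dataset`) emits a
complete dataset of exactly this shape with planted ground truth —
selective loci, element→gene links, a TF clique with embedded motif
sites, and causal variants — so the whole pipeline is testable end to
end without any downloads.

## Worked example

```r
library(secircuit)

ds  <- simulate_dataset(sim_config(seed = 1))
ds
#> sim_dataset: 180 loci (adipocyte=13, none=154, osteoblast=13), 70 genes,
#>   2000 variants, CRC of 3 TFs (seed 1)

res <- run_pipeline(ds)
res
#> se_pipeline_result: 180 stitched enhancers, N = 42
#> selective SEs: adipocyte=13, none=154, osteoblast=13
#> recovery: adipo P=1.00 R=1.00 | osteo P=1.00 R=1.00

res$ranked
#> ranked_enhancer_table: 180 enhancers, 6 samples, N = 42
#> primary SE counts: 42, 41, 41, 41, 41, 43

res$crc
#> crc_graph: 3 TFs, 9 edges, 1 CRC(s)
#>   CRC 1: TF1, TF2, TF3

e <- res$gwas$osteoblast$enrichment
sprintf("OR = %.2f (95%% CI %.2f-%.2f), p = %.2e",
        e$odds_ratio, e$ci_lower, e$ci_upper, e$p_value)
#> "OR = 3.69 (95% CI 2.60-5.24), p = 8.11e-12"
```

Reading that output: the six samples each yield ~41–43 primary SEs, so
the consensus SE number is `N = 42`; 13 adipocyte- and 13
osteoblast-selective SEs are called, matching the planted truth with
perfect precision and recall (`recovery`); the planted three-TF clique
is recovered as a fully connected CRC with self-loops; and the planted
4× enrichment of significant GWAS variants inside osteoblast-selective
functional regions comes back as a Fisher odds ratio of 3.7.

The same run works from disk: `write_dataset(ds, dir)` then
`run_pipeline(read_dataset(dir))`.  A thin command-line front end with
`simulate` and `run-all` subcommands is installed at
`system.file("cli", "se-circuit", package = "secircuit")`; all other
stages are the exported functions (`merge_peaks`, `stitch_enhancers`,
`diff_enhancer_test`, `call_lineage_selective_ses`, `abc_score_links`,
`scan_pwm`, `build_crc`, `fisher_enrichment`, `delta_kmer_score`, ...).

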