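# Synthetic dataset generator: a complete three-cell-type, two-replicate
# H3K27ac + DNase + RNA-seq shaped dataset with planted lineage-selective
# super enhancers, element-gene links, a TF core regulatory circuitry,
# embedded motif sites, a GWAS panel with planted functional-region
# enrichment, and k-mer binding models for causal variants.  Fully
# deterministic given the seed; a truth manifest records every planted
# feature for end-to-end recovery tests.

CELL_TYPES <- c("hMSC", "adipocyte", "osteoblast")

#' Simulation configuration
#'
#' Defaults describe the study conditions the generator emulates: three
#' cell types (multipotent stromal cells and their adipocyte and
#' osteoblast progeny), two replicates each, heavy-tailed enhancer
#' signals in which a small super-enhancer tier separates from typical
#' enhancers, adipocyte-selective loci established de novo (near-zero
#' progenitor signal) and osteoblast-selective loci inherited from the
#' progenitor state.
#'
#' @param seed integer master seed; every random draw derives from it.
#' @param n_chroms,chrom_length genome shape (bp).
#' @param n_enhancer_loci total enhancer loci to place (>= 25 kb apart).
#' @param n_genes gene budget (planted target genes plus decoys).
#' @param frac_selective_adipo,frac_selective_osteo fractions of loci
#'   planted as lineage-selective.
#' @param selective_fold minimum planted signal fold between the two
#'   differentiated lineages at selective loci (> 1.5).
#' @param se_signal_scale,te_signal_scale lognormal location scales of
#'   the super-enhancer-tier and typical-enhancer-tier signal.
#' @param frac_se_tier fraction of non-selective loci in the SE tier.
#' @param signal_sdlog lognormal shape of locus-level signal.
#' @param noise_cv replicate coefficient of variation (multiplicative).
#' @param count_depth expected counts per signal unit for the emitted
#'   per-region count table.
#' @param dnase_scale,promoter_scale accessibility amplitudes at
#'   functional regions and promoters.
#' @param n_tfs_in_crc planted CRC size; \code{crc_lineage} its lineage.
#' @param motif_length PWM length for the planted TF motifs.
#' @param n_variants GWAS panel size.
#' @param frac_variants_in_regions fraction of panel variants placed
#'   inside functional regions (the panel is enhancer-focused).
#' @param frac_significant_in_functional significance rate of in-region
#'   variants; \code{background_sig_rate} the outside rate.
#' @param n_causal_variants planted causal variants with k-mer models.
#' @param frac_inconsistent fraction of causal variants whose GWAS
#'   effect sign is planted opposite to the binding-change direction.
#' @param kmer_k k-mer length of the binding models.
#' @param expression_alpha effect size linking element activity to
#'   target-gene FPKM.
#' @param gc_content background GC of generated sequence.
#' @return a \code{sim_config} list, validated.
#' @export
sim_config <- function(seed = 1L,
                       n_chroms = 3L, chrom_length = 1e7,
                       n_enhancer_loci = 180L, n_genes = 80L,
                       frac_selective_adipo = 0.07,
                       frac_selective_osteo = 0.07,
                       selective_fold = 3.0,
                       se_signal_scale = 50, te_signal_scale = 5,
                       frac_se_tier = 0.15, signal_sdlog = 0.25,
                       noise_cv = 0.2, count_depth = 8,
                       dnase_scale = 50, promoter_scale = 40,
                       n_tfs_in_crc = 3L, crc_lineage = "osteoblast",
                       motif_length = 10L,
                       n_variants = 2000L,
                       frac_variants_in_regions = 0.25,
                       frac_significant_in_functional = 0.2,
                       background_sig_rate = 0.05,
                       n_causal_variants = 8L,
                       frac_inconsistent = 0.25,
                       kmer_k = 11L,
                       expression_alpha = 2.0,
                       gc_content = 0.41) {
  cfg <- as.list(environment())
  fracs <- c(frac_selective_adipo, frac_selective_osteo, frac_se_tier,
             frac_variants_in_regions, frac_significant_in_functional,
             background_sig_rate, frac_inconsistent)
  stopifnot(all(fracs >= 0 & fracs <= 1), selective_fold > 1.5,
            n_chroms >= 1, kmer_k >= 1, motif_length >= 4,
            crc_lineage %in% c("adipocyte", "osteoblast"))
  margin <- 2e5
  per_chrom <- ceiling(n_enhancer_loci / n_chroms)
  spacing <- floor((chrom_length - 2 * margin) / per_chrom)
  if (spacing < 55000) {
    stop("infeasible placement: too many enhancer loci for the genome size")
  }
  cfg$margin <- margin
  cfg$spacing <- spacing
  structure(cfg, class = "sim_config")
}

# --- internal placement helpers ---------------------------------------

.place_loci <- function(cfg) {
  per_chrom <- ceiling(cfg$n_enhancer_loci / cfg$n_chroms)
  loci <- list()
  idx <- 0L
  for (ch in seq_len(cfg$n_chroms)) {
    n_here <- min(per_chrom, cfg$n_enhancer_loci - (ch - 1L) * per_chrom)
    if (n_here <= 0) break
    for (i in seq_len(n_here)) {
      idx <- idx + 1L
      center <- cfg$margin + (i - 1) * cfg$spacing +
        round(runif(1, -15000, 15000))
      n_peaks <- sample(2:3, 1)
      widths <- round(runif(n_peaks, 800, 2000))
      gaps <- round(runif(n_peaks, 500, 3000))  # < stitch distance
      starts <- center + cumsum(c(0, widths[-n_peaks] + gaps[-n_peaks]))
      loci[[idx]] <- data.frame(
        locus_id = sprintf("locus_%04d", idx),
        chrom = paste0("chr", ch), chrom_index = ch, grid_index = i,
        start = starts[1], end = starts[n_peaks] + widths[n_peaks],
        peak_starts = I(list(starts)), peak_widths = I(list(widths)),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, loci)
}

.assign_selective <- function(cfg, loci) {
  k_sel <- ceiling(8e5 / cfg$spacing)  # keeps selective loci well apart
  cand <- which(loci$grid_index > 1 &
                ave(loci$grid_index, loci$chrom_index,
                    FUN = function(g) (g - 2) %% k_sel) == 0)
  n_adipo <- round(cfg$frac_selective_adipo * nrow(loci))
  n_osteo <- round(cfg$frac_selective_osteo * nrow(loci))
  if (n_adipo + n_osteo > length(cand)) {
    stop("infeasible placement: too many selective loci for the genome size")
  }
  cand <- sample(cand)
  label <- rep("none", nrow(loci))
  if (n_adipo > 0) label[cand[seq_len(n_adipo)]] <- "adipocyte"
  if (n_osteo > 0) label[cand[n_adipo + seq_len(n_osteo)]] <- "osteoblast"
  label
}

# per-locus, per-cell-type mean signal (before replicate noise)
.locus_signals <- function(cfg, loci, selective) {
  n <- nrow(loci)
  eps <- function(k = n) rlnorm(k, 0, cfg$signal_sdlog)
  B <- matrix(0, n, 3, dimnames = list(loci$locus_id, CELL_TYPES))
  se_tier <- selective == "none" &
    (runif(n) < cfg$frac_se_tier)
  base <- ifelse(se_tier, cfg$se_signal_scale, cfg$te_signal_scale) * eps()
  for (ct in CELL_TYPES) B[, ct] <- base
  ai <- which(selective == "adipocyte")
  if (length(ai) > 0) {
    own <- cfg$se_signal_scale * eps(length(ai))
    B[ai, "adipocyte"] <- own
    B[ai, "osteoblast"] <- pmin(cfg$te_signal_scale * eps(length(ai)),
                                own / cfg$selective_fold)
    # de novo: near-absent signal in the progenitor
    B[ai, "hMSC"] <- 0.3 * cfg$te_signal_scale * eps(length(ai))
  }
  oi <- which(selective == "osteoblast")
  if (length(oi) > 0) {
    own <- cfg$se_signal_scale * eps(length(oi))
    B[oi, "osteoblast"] <- own
    B[oi, "adipocyte"] <- pmin(cfg$te_signal_scale * eps(length(oi)),
                               own / cfg$selective_fold)
    # inherited: already SE-level in the progenitor
    B[oi, "hMSC"] <- own * .ln_noise(length(oi), 0.15)
  }
  list(B = B, se_tier = se_tier)
}

.place_genes <- function(cfg, loci, selective) {
  sel_idx <- which(selective != "none")
  genes <- list()
  gi <- 0L
  occupied <- data.frame(chrom = loci$chrom, pos = (loci$start + loci$end) / 2)
  too_close <- function(chrom, pos, min_locus = 15000) {
    any(loci$chrom == chrom & pos > loci$start - min_locus &
        pos < loci$end + min_locus)
  }
  gene_positions <- data.frame(chrom = character(), pos = numeric())
  add_gene <- function(chrom, tss, gtype, name, target_of) {
    gi <<- gi + 1L
    genes[[gi]] <<- data.frame(
      gene_id = sprintf("G%04d", gi), gene_name = name,
      gene_type = gtype, chrom = chrom, tss = as.integer(tss),
      strand = sample(c("+", "-"), 1), target_of = target_of,
      stringsAsFactors = FALSE)
    gene_positions <<- rbind(gene_positions,
                             data.frame(chrom = chrom, pos = tss))
  }
  # one true target gene near each selective locus
  n_crc_assigned <- 0L
  for (li in sel_idx) {
    for (attempt in 1:50) {
      off <- sample(c(-1, 1), 1) * round(runif(1, 20000, 80000))
      tss <- (loci$start[li] + loci$end[li]) / 2 + off
      if (tss > 5000 && tss < cfg$chrom_length - 5000 &&
          !too_close(loci$chrom[li], tss)) break
    }
    is_crc <- selective[li] == cfg$crc_lineage &&
      n_crc_assigned < cfg$n_tfs_in_crc
    if (is_crc) n_crc_assigned <- n_crc_assigned + 1L
    name <- if (is_crc) sprintf("TF%d", n_crc_assigned) else
      sprintf("TG_%s", loci$locus_id[li])
    gtype <- if (!is_crc && runif(1) < 0.1) "lncRNA" else "protein_coding"
    add_gene(loci$chrom[li], tss, gtype, name, loci$locus_id[li])
  }
  # decoy genes: far from all selective loci so planted links dominate
  sel_centers <- data.frame(chrom = loci$chrom[sel_idx],
                            pos = (loci$start[sel_idx] + loci$end[sel_idx]) / 2)
  n_decoy <- max(0L, cfg$n_genes - length(sel_idx))
  tries <- 0L
  while (n_decoy > 0 && tries < n_decoy * 60) {
    tries <- tries + 1L
    chrom <- paste0("chr", sample(cfg$n_chroms, 1))
    tss <- round(runif(1, 5000, cfg$chrom_length - 5000))
    near_sel <- any(sel_centers$chrom == chrom &
                    abs(sel_centers$pos - tss) < 7e5)
    near_gene <- any(gene_positions$chrom == chrom &
                     abs(gene_positions$pos - tss) < 10000)
    if (near_sel || near_gene || too_close(chrom, tss)) next
    gtype <- sample(c("protein_coding", "lncRNA", "miRNA"), 1,
                    prob = c(0.8, 0.1, 0.1))
    add_gene(chrom, tss, gtype, sprintf("DECOY%d", gi + 1L), NA_character_)
    n_decoy <- n_decoy - 1L
  }
  do.call(rbind, genes)
}

# functional regions: accessible sub-intervals inside the first one or
# two constituent peaks of each selective locus
.place_functional_regions <- function(cfg, loci, selective) {
  sel_idx <- which(selective != "none")
  out <- list()
  ri <- 0L
  for (li in sel_idx) {
    starts <- loci$peak_starts[[li]]
    widths <- loci$peak_widths[[li]]
    n_fr <- sample(1:2, 1)
    for (j in seq_len(n_fr)) {
      w <- round(runif(1, 450, 700))
      pk_w <- widths[j]
      w <- min(w, pk_w - 100)
      s <- starts[j] + round(runif(1, 50, pk_w - w - 50))
      ri <- ri + 1L
      out[[ri]] <- data.frame(
        region_id = sprintf("truth_fr_%03d", ri),
        locus_id = loci$locus_id[li], lineage = selective[li],
        chrom = loci$chrom[li], start = s, end = s + w,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(region_id = character(), locus_id = character(),
                      lineage = character(), chrom = character(),
                      start = integer(), end = integer(),
                      stringsAsFactors = FALSE)
  }
  out
}

#' Embed motif sites realizing a TF adjacency into region sequences
#'
#' For every edge u -> v of the adjacency (self edges included),
#' \code{n_sites} copies of u's consensus sequence are written into the
#' functional-region sequences mapped to v, at non-overlapping offsets.
#' The consensus of the near-deterministic planted PWMs scores far
#' above the p < 1e-4 scan threshold by construction.
#'
#' @param sequences named character vector of region sequences.
#' @param pwms named list of \code{pwm} objects (names are TFs).
#' @param crc_adjacency data frame \code{from}, \code{to} over TF names.
#' @param target_regions named list: TF name -> region ids whose SE
#'   targets that TF.
#' @param n_sites sites per (edge, target) (default 2).
#' @return list with \code{sequences} (modified) and \code{sites}
#'   (data frame region, tf, offset).
#' @export
plant_motif_sites <- function(sequences, pwms, crc_adjacency,
                              target_regions, n_sites = 2) {
  consensus <- vapply(pwms, function(p) {
    paste(DNA_BASES[apply(p$mat, 1, which.max)], collapse = "")
  }, character(1))
  occupied <- lapply(sequences, function(s) integer(0))
  sites <- list()
  si <- 0L
  if (!is.null(crc_adjacency) && nrow(crc_adjacency) > 0) {
    for (e in seq_len(nrow(crc_adjacency))) {
      u <- crc_adjacency$from[e]
      v <- crc_adjacency$to[e]
      regs <- target_regions[[v]]
      if (length(regs) == 0) stop("no target regions for TF ", v)
      motif <- consensus[[u]]
      w <- nchar(motif)
      for (s_i in seq_len(n_sites)) {
        reg <- regs[((s_i - 1L) %% length(regs)) + 1L]
        L <- nchar(sequences[[reg]])
        if (w > L) stop("motif longer than region ", reg)
        for (attempt in 1:200) {
          off <- sample.int(L - w + 1L, 1) - 1L  # 0-based
          span <- (off + 1L):(off + w)
          if (!any(span %in% occupied[[reg]])) break
        }
        occupied[[reg]] <- c(occupied[[reg]], span)
        substr(sequences[[reg]], off + 1L, off + w) <- motif
        si <- si + 1L
        sites[[si]] <- data.frame(region = reg, tf = u, offset = off,
                                  stringsAsFactors = FALSE)
      }
    }
  }
  list(sequences = sequences,
       sites = if (si > 0) do.call(rbind, sites) else
         data.frame(region = character(), tf = character(),
                    offset = integer(), stringsAsFactors = FALSE),
       occupied = occupied)
}

#' Generate a GWAS summary panel with planted functional-region enrichment
#'
#' A fraction of the panel is placed inside the supplied functional
#' regions, the rest uniformly outside; inside variants reach genome-wide
#' significance (p <= 5e-8) at rate
#' \code{frac_significant_in_functional}, outside at
#' \code{background_sig_rate}.
#'
#' @param functional_regions interval data frame.
#' @param cfg a \code{\link{sim_config}} (fields \code{n_variants},
#'   \code{frac_variants_in_regions},
#'   \code{frac_significant_in_functional},
#'   \code{background_sig_rate}, genome shape).
#' @return data frame of variants with truth columns
#'   \code{truth_in_region} and \code{truth_significant}.
#' @export
plant_gwas_panel <- function(functional_regions, cfg) {
  n <- cfg$n_variants
  fr <- functional_regions
  n_in <- if (nrow(fr) > 0) round(n * cfg$frac_variants_in_regions) else 0L
  n_out <- n - n_in
  widths <- fr$end - fr$start
  pick_in <- if (n_in > 0) {
    sample(nrow(fr), n_in, replace = TRUE, prob = widths)
  } else {
    integer(0)
  }
  pos_in <- fr$start[pick_in] +
    floor(runif(n_in) * widths[pick_in])
  chrom_in <- fr$chrom[pick_in]
  chrom_out <- paste0("chr", sample(cfg$n_chroms, n_out, replace = TRUE))
  pos_out <- integer(n_out)
  for (i in seq_len(n_out)) {
    repeat {
      p <- round(runif(1, 1000, cfg$chrom_length - 1000))
      inside <- any(fr$chrom == chrom_out[i] & p >= fr$start & p < fr$end)
      if (!inside) break
    }
    pos_out[i] <- p
  }
  in_region <- c(rep(TRUE, n_in), rep(FALSE, n_out))
  chrom <- c(chrom_in, chrom_out)
  pos <- as.integer(c(pos_in, pos_out))
  sig_rate <- ifelse(in_region, cfg$frac_significant_in_functional,
                     cfg$background_sig_rate)
  significant <- runif(n) < sig_rate
  pvalue <- ifelse(significant,
                   10^runif(n, -25, log10(5e-8)),
                   10^runif(n, -6, 0))
  alleles <- t(vapply(seq_len(n), function(i) sample(DNA_BASES, 2),
                      character(2)))
  ord <- order(chrom, pos)
  data.frame(variant_id = sprintf("var_%05d", seq_len(n)),
             chrom = chrom, pos = pos,
             ref_allele = alleles[, 1], alt_allele = alleles[, 2],
             beta = rnorm(n, 0, 0.05),
             pvalue = pvalue,
             truth_in_region = in_region,
             truth_significant = significant,
             stringsAsFactors = FALSE)[ord, ]
}

# causal variants: pick significant in-region variants, give them k-mer
# weight models with a guaranteed bound-status change, and set the GWAS
# effect sign consistent (or deliberately inconsistent) with the
# directional rule
.plant_causal_variants <- function(cfg, gwas, fr, fr_seqs, occupied,
                                   crc_tfs) {
  k <- cfg$kmer_k
  cand <- which(gwas$truth_in_region & gwas$truth_significant)
  n_causal <- if (length(crc_tfs) > 0) {
    min(cfg$n_causal_variants, length(cand))
  } else {
    0L
  }
  weights <- list()
  causal <- list()
  ci <- 0L
  for (i in seq_len(n_causal)) {
    vi <- cand[i]
    # locate the region and a usable offset away from planted sites
    ri <- which(fr$chrom == gwas$chrom[vi] & gwas$pos[vi] >= fr$start &
                gwas$pos[vi] < fr$end)[1]
    reg <- fr$region_id[ri]
    L <- fr$end[ri] - fr$start[ri]
    ok_off <- NULL
    for (attempt in 1:100) {
      off <- sample(seq.int(k, L - k), 1)  # 0-based variant offset
      span <- (off - k + 2L):(off + k)     # 1-based window span
      if (!any(span %in% occupied[[reg]])) { ok_off <- off; break }
    }
    if (is.null(ok_off)) next
    off <- ok_off
    seq_r <- fr_seqs[[reg]]
    ref_base <- substr(seq_r, off + 1L, off + 1L)
    alt_base <- sample(setdiff(DNA_BASES, ref_base), 1)
    win_ref <- substr(seq_r, off - k + 2L, off + k)
    win_alt <- win_ref
    substr(win_alt, k, k) <- alt_base
    tf <- crc_tfs[((i - 1L) %% length(crc_tfs)) + 1L]
    gain <- i %% 2 == 1  # alternate gain/loss of binding
    starts <- seq_len(k)
    ref_kmers <- substring(win_ref, starts, starts + k - 1L)
    alt_kmers <- substring(win_alt, starts, starts + k - 1L)
    w_new <- c(setNames(rep(if (gain) -0.2 else 0.3, k), ref_kmers),
               setNames(rep(if (gain) 0.3 else -0.2, k), alt_kmers))
    w_tf <- c(weights[[tf]], w_new)
    w_tf <- w_tf[!duplicated(names(w_tf))]
    eff <- delta_kmer_score(win_ref, win_alt, w_tf, tau = 0, tf_name = tf)
    if (eff$status_change == "none" || sign(eff$delta) == 0) next
    weights[[tf]] <- w_tf
    corr_sign <- sample(c(-1, 1), 1)
    consistent <- (i %% 4) != 0  # a labeled minority is inconsistent
    beta_sign <- sign(eff$delta) * corr_sign * (if (consistent) 1 else -1)
    ci <- ci + 1L
    causal[[ci]] <- data.frame(
      variant_id = gwas$variant_id[vi], region_id = reg, tf = tf,
      offset_in_region = off, ref_window = win_ref, alt_window = win_alt,
      ref_allele = ref_base, alt_allele = alt_base,
      delta = eff$delta, status_change = eff$status_change,
      correlation_sign = corr_sign,
      beta = beta_sign * (abs(rnorm(1, 0.08, 0.02)) + 0.01),
      label = if (consistent) "consistent" else "inconsistent",
      stringsAsFactors = FALSE)
  }
  causal <- if (ci > 0) do.call(rbind, causal) else NULL
  # push planted alleles and effects back into the panel
  if (!is.null(causal)) {
    m <- match(causal$variant_id, gwas$variant_id)
    gwas$ref_allele[m] <- causal$ref_allele
    gwas$alt_allele[m] <- causal$alt_allele
    gwas$beta[m] <- causal$beta
  }
  list(gwas = gwas, causal = causal, kmer_weights = weights)
}

#' Generate a complete synthetic dataset with planted ground truth
#'
#' Emits, in memory, everything the pipeline consumes -- per-sample
#' H3K27ac peak calls and coverage, per-cell-type accessibility peaks
#' and coverage, a per-region count table, a gene annotation, an FPKM
#' expression table, PWMs, functional-region sequences, k-mer weight
#' models and a GWAS summary panel -- together with a truth manifest of
#' every planted feature.  Deterministic given \code{cfg$seed}.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @return object of class \code{sim_dataset}; see the fields set below
#'   and \code{\link{write_dataset}}.
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  loci <- .place_loci(cfg)
  selective <- .assign_selective(cfg, loci)
  sig <- .locus_signals(cfg, loci, selective)
  genes <- .place_genes(cfg, loci, selective)
  fr <- .place_functional_regions(cfg, loci, selective)

  samples <- data.frame(
    sample = paste0(rep(CELL_TYPES, each = 2), "_rep", 1:2),
    cell_type = rep(CELL_TYPES, each = 2),
    replicate = rep(1:2, 3), stringsAsFactors = FALSE)

  n_loci <- nrow(loci)
  rep_noise <- matrix(.ln_noise(n_loci * 6, cfg$noise_cv), n_loci, 6,
                      dimnames = list(loci$locus_id, samples$sample))
  S <- sig$B[, samples$cell_type] * rep_noise  # per-sample peak signal
  colnames(S) <- samples$sample

  active_genes <- genes[genes$gene_type != "miRNA", , drop = FALSE]
  peak_min <- 2
  peaks <- list()
  coverage <- list()
  for (j in seq_len(6)) {
    sm <- samples$sample[j]
    rows <- list()
    cov_rows <- list()
    for (li in seq_len(n_loci)) {
      starts <- loci$peak_starts[[li]]
      widths <- loci$peak_widths[[li]]
      cov_rows[[li]] <- data.frame(chrom = loci$chrom[li], start = starts,
                                   end = starts + widths,
                                   signal = S[li, j])
      if (S[li, j] < peak_min) next
      jit_s <- starts + round(runif(length(starts), -50, 50))
      jit_e <- starts + widths + round(runif(length(starts), -50, 50))
      rows[[li]] <- data.frame(chrom = loci$chrom[li], start = jit_s,
                               end = jit_e,
                               name = sprintf("%s_pk%d", loci$locus_id[li],
                                              seq_along(starts)),
                               signal = S[li, j])
    }
    prom_sig <- cfg$promoter_scale * .ln_noise(nrow(active_genes), cfg$noise_cv)
    prom <- data.frame(chrom = active_genes$chrom,
                       start = active_genes$tss - 400L,
                       end = active_genes$tss + 400L,
                       name = paste0("prom_", active_genes$gene_id),
                       signal = prom_sig)
    peaks[[sm]] <- .sort_intervals(rbind(do.call(rbind, rows), prom))
    coverage[[sm]] <- .sort_intervals(
      rbind(do.call(rbind, cov_rows),
            prom[, c("chrom", "start", "end", "signal")]))
  }

  counts <- matrix(rpois(n_loci * 6, as.vector(S) * cfg$count_depth),
                   n_loci, 6, dimnames = dimnames(S))

  # accessibility: own-lineage functional regions + promoters + background
  dnase_peaks <- list()
  dnase_cov <- list()
  n_bg_sites <- 30
  bg_sites <- data.frame(
    chrom = paste0("chr", sample(cfg$n_chroms, n_bg_sites, replace = TRUE)),
    start = round(runif(n_bg_sites, 1e4, cfg$chrom_length - 1e4)))
  bg_sites$end <- bg_sites$start + 400L
  sel_centers <- (loci$start + loci$end) / 2
  keep_bg <- vapply(seq_len(n_bg_sites), function(i) {
    !any(loci$chrom == bg_sites$chrom[i] & selective != "none" &
         abs(sel_centers - bg_sites$start[i]) < 25000)
  }, logical(1))
  bg_sites <- bg_sites[keep_bg, , drop = FALSE]
  for (ct in CELL_TYPES) {
    fr_ct <- fr[fr$lineage == ct, c("chrom", "start", "end"), drop = FALSE]
    prom <- data.frame(chrom = active_genes$chrom,
                       start = active_genes$tss - 250L,
                       end = active_genes$tss + 250L)
    parts <- list(cbind(prom, signal = cfg$promoter_scale),
                  cbind(bg_sites, signal = 10))
    if (nrow(fr_ct) > 0) {
      parts <- c(list(cbind(fr_ct, signal = cfg$dnase_scale)), parts)
    }
    pk <- do.call(rbind, parts)
    pk <- .sort_intervals(pk)
    pk$name <- sprintf("dnase_%s_%04d", ct, seq_len(nrow(pk)))
    dnase_peaks[[ct]] <- pk
    dnase_cov[[ct]] <- pk[, c("chrom", "start", "end", "signal")]
  }

  # expression: targets track their element's activity in each cell type
  act_norm <- matrix(0, nrow(genes), 3,
                     dimnames = list(genes$gene_id, CELL_TYPES))
  tgt <- !is.na(genes$target_of)
  act_norm[tgt, ] <- sig$B[genes$target_of[tgt], ] / cfg$se_signal_scale
  base_expr <- rlnorm(nrow(genes), log(10), 0.4)
  fpkm <- matrix(0, nrow(genes), 6,
                 dimnames = list(genes$gene_id, samples$sample))
  for (j in seq_len(6)) {
    mu <- base_expr * (1 + cfg$expression_alpha *
                         act_norm[, samples$cell_type[j]])
    fpkm[, j] <- mu * .ln_noise(nrow(genes), cfg$noise_cv)
  }

  # PWMs and motif planting for the CRC clique
  crc_tfs <- genes$gene_name[grepl("^TF\\d+$", genes$gene_name)]
  pwms <- list()
  for (tf in crc_tfs) {
    cons <- sample(DNA_BASES, cfg$motif_length, replace = TRUE)
    m <- matrix(0.05, cfg$motif_length, 4, dimnames = list(NULL, DNA_BASES))
    m[cbind(seq_len(cfg$motif_length), match(cons, DNA_BASES))] <- 0.85
    pwms[[tf]] <- make_pwm(m, tf_name = tf)
  }
  fr_seqs <- setNames(
    vapply(fr$end - fr$start, .random_dna, character(1), gc = cfg$gc_content),
    fr$region_id)
  crc_gene_ids <- genes$gene_id[match(crc_tfs, genes$gene_name)]
  crc_loci <- genes$target_of[match(crc_tfs, genes$gene_name)]
  target_regions <- setNames(
    lapply(crc_loci, function(l) fr$region_id[fr$locus_id == l]), crc_tfs)
  adjacency <- if (length(crc_tfs) > 0) {
    expand.grid(from = crc_tfs, to = crc_tfs, stringsAsFactors = FALSE)
  } else {
    data.frame(from = character(), to = character())
  }
  planted <- plant_motif_sites(fr_seqs, pwms, adjacency, target_regions)
  fr_seqs <- planted$sequences

  gwas <- plant_gwas_panel(fr, cfg)
  causal <- .plant_causal_variants(cfg, gwas, fr, fr_seqs,
                                   planted$occupied, crc_tfs)

  truth <- list(
    loci = cbind(loci[, c("locus_id", "chrom", "start", "end")],
                 selective = selective, se_tier = sig$se_tier),
    signals = sig$B,
    links = data.frame(locus_id = genes$target_of[tgt],
                       gene_id = genes$gene_id[tgt],
                       gene_name = genes$gene_name[tgt],
                       stringsAsFactors = FALSE),
    crc = list(tfs = crc_tfs, gene_ids = crc_gene_ids,
               adjacency = adjacency),
    functional_regions = fr,
    motif_sites = planted$sites,
    causal_variants = causal$causal)

  structure(list(config = cfg, samples = samples,
                 peaks = peaks, coverage = coverage, counts = counts,
                 dnase_peaks = dnase_peaks, dnase_coverage = dnase_cov,
                 genes = genes, expression = fpkm,
                 pwms = pwms, region_sequences = fr_seqs,
                 kmer_weights = causal$kmer_weights,
                 gwas = causal$gwas, truth = truth),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  sel <- table(x$truth$loci$selective)
  cat(sprintf(paste0("sim_dataset: %d loci (%s), %d genes, %d variants, ",
                     "CRC of %d TFs (seed %d)\n"),
              nrow(x$truth$loci),
              paste(names(sel), sel, sep = "=", collapse = ", "),
              nrow(x$genes), nrow(x$gwas), length(x$truth$crc$tfs),
              x$config$seed))
  invisible(x)
}

# GTF attribute block for one row
.gtf_attrs <- function(g, transcript = FALSE) {
  a <- sprintf('gene_id "%s"; gene_name "%s"; gene_type "%s";',
               g$gene_id, g$gene_name, g$gene_type)
  if (transcript) a <- paste0(a, sprintf(' transcript_id "%s.t1";', g$gene_id))
  a
}

#' Write a simulated dataset to plain-text files
#'
#' Produces the on-disk dataset shape the pipeline reads: broadPeak and
#' bedGraph per H3K27ac sample, narrowPeak and bedGraph per cell type
#' for accessibility, a GTF annotation, an FPKM table, MEME-style PWMs,
#' a FASTA of functional-region sequences, k-mer weight and GWAS
#' summary TSVs, a sample sheet, and the truth manifest as JSON.
#'
#' @param ds a \code{sim_dataset}.
#' @param dir output directory (created).
#' @return \code{dir}, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (sm in names(ds$peaks)) {
    write_intervals(ds$peaks[[sm]],
                    file.path(dir, paste0("h3k27ac_", sm, ".broadPeak")),
                    "broadpeak")
    write_intervals(ds$coverage[[sm]],
                    file.path(dir, paste0("h3k27ac_", sm, ".bedGraph")),
                    "bedgraph")
  }
  for (ct in names(ds$dnase_peaks)) {
    write_intervals(ds$dnase_peaks[[ct]],
                    file.path(dir, paste0("dnase_", ct, ".narrowPeak")),
                    "narrowpeak")
    write_intervals(ds$dnase_coverage[[ct]],
                    file.path(dir, paste0("dnase_", ct, ".bedGraph")),
                    "bedgraph")
  }
  g <- ds$genes
  span <- ifelse(g$strand == "+", 1L, -1L)
  gstart <- ifelse(g$strand == "+", g$tss, g$tss - 4999L)
  gtf <- c(
    sprintf("%s\tsim\tgene\t%d\t%d\t.\t%s\t.\t%s",
            g$chrom, gstart + 1L, gstart + 5000L, g$strand,
            vapply(seq_len(nrow(g)), function(i) .gtf_attrs(g[i, ]),
                   character(1))),
    sprintf("%s\tsim\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
            g$chrom, gstart + 1L, gstart + 5000L, g$strand,
            vapply(seq_len(nrow(g)), function(i) .gtf_attrs(g[i, ], TRUE),
                   character(1))))
  writeLines(gtf, file.path(dir, "annotation.gtf"))
  expr <- data.frame(gene_id = rownames(ds$expression),
                     ds$expression, check.names = FALSE)
  write.table(expr, file.path(dir, "expression.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  cnt <- data.frame(locus_id = rownames(ds$counts),
                    ds$truth$loci[, c("chrom", "start", "end")],
                    ds$counts, check.names = FALSE)
  write.table(cnt, file.path(dir, "counts.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(ds$samples, file.path(dir, "samples.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (length(ds$pwms) > 0) {
    write_pwms(lapply(ds$pwms, `[[`, "mat"), file.path(dir, "pwms.meme"))
  }
  fa <- character(0)
  for (nm in names(ds$region_sequences)) {
    fa <- c(fa, paste0(">", nm), ds$region_sequences[[nm]])
  }
  writeLines(fa, file.path(dir, "functional_regions.fa"))
  if (length(ds$kmer_weights) > 0) {
    kw <- do.call(rbind, lapply(names(ds$kmer_weights), function(tf) {
      data.frame(tf = tf, kmer = names(ds$kmer_weights[[tf]]),
                 weight = as.numeric(ds$kmer_weights[[tf]]))
    }))
    write.table(kw, file.path(dir, "kmer_weights.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  gw <- ds$gwas
  names(gw)[names(gw) == "pos"] <- "pos0"
  gw$pos <- gw$pos0 + 1L  # GWAS summaries are 1-based on disk
  write.table(gw[, c("variant_id", "chrom", "pos", "ref_allele",
                     "alt_allele", "beta", "pvalue")],
              file.path(dir, "gwas_summary.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  truth <- ds$truth
  truth$signals <- as.data.frame(truth$signals)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
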