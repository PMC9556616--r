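# Super-enhancer calling: per-sample ROSE-style ranking, hockey-stick
# inflection cutoff, consensus SE number, per-cell-type SE sets, the
# pooled exact-binomial differential test, and the combined
# rank/FDR/fold criterion for lineage-selective SEs.

#' Rank stitched enhancers within each sample
#'
#' Rank 1 is the highest signal.  Ties are broken deterministically by
#' row position (rows are expected in (chrom, start) order), so output
#' is reproducible.
#'
#' @param signal matrix enhancers x samples of non-negative signals.
#' @return integer matrix of the same shape; each column is a
#'   permutation of 1..M.
#' @export
rank_enhancers <- function(signal) {
  signal <- as.matrix(signal)
  stopifnot(all(signal >= 0))
  apply(signal, 2, function(s) {
    ord <- order(-s, seq_along(s))
    r <- integer(length(s))
    r[ord] <- seq_along(s)
    r
  })
}

#' Hockey-stick inflection cutoff on a signal vector
#'
#' ROSE-style geometric cutoff: signals are sorted ascending, index and
#' signal are each scaled to [0, 1], and the cutoff is the point where
#' a line of slope 1 is tangent to the rank curve.  It is located as
#' the rightmost maximizer of x - y, i.e. the point furthest below the
#' unit diagonal, where the discrete slope crosses 1; on a convex curve
#' this equals the first left-to-right slope-1 crossing, and it is
#' robust to local slope noise in the flat left tail.  The primary SE
#' count is the number of enhancers strictly right of the cutoff point.
#'
#' A linear ramp (x - y constant) resolves to the rightmost point and
#' hence count 0; an all-equal vector additionally warns.
#'
#' @param signals numeric vector of enhancer signals (need >= 3 distinct
#'   values for a meaningful curve).
#' @return list with \code{count} (primary SE count) and
#'   \code{cutoff_signal} (signal at the cutoff point, NA if degenerate).
#' @export
inflection_cutoff <- function(signals) {
  stopifnot(is.numeric(signals), length(signals) >= 2, all(signals >= 0))
  m <- length(signals)
  s <- sort(signals)
  rng <- s[m] - s[1]
  if (rng == 0) {
    warning("inflection_cutoff: all signals equal; returning count 0")
    return(list(count = 0L, cutoff_signal = NA_real_))
  }
  if (length(unique(s)) < 3) {
    warning("inflection_cutoff: fewer than 3 distinct signal values")
  }
  x <- (seq_len(m) - 1) / (m - 1)
  y <- (s - s[1]) / rng
  gap <- x - y
  # rightmost tangency point; tolerance breaks float ties (linear ramp)
  i0 <- max(which(gap >= max(gap) - 1e-9))
  list(count = as.integer(m - i0), cutoff_signal = s[i0])
}

#' Consensus SE number across samples
#'
#' Arithmetic mean of the per-sample primary SE counts, rounded to the
#' nearest integer (half away from zero).
#'
#' @param primary_counts integer vector of per-sample counts.
#' @return integer consensus SE number N.
#' @export
consensus_se_number <- function(primary_counts) {
  stopifnot(length(primary_counts) >= 1, all(primary_counts >= 0))
  as.integer(.round_half_away(mean(primary_counts)))
}

#' Build the ranked enhancer table
#'
#' Couples per-sample signals and ranks with per-cell-type mean ranks
#' and the consensus SE number, the working object for SE and
#' selective-SE calling.
#'
#' @param signal matrix enhancers x samples (normalized signal).
#' @param samples data frame with columns \code{sample} and
#'   \code{cell_type}, one row per signal column.
#' @param se_number optional consensus SE number; computed from the
#'   per-sample hockey-stick cutoffs when NULL.
#' @return object of class \code{ranked_enhancer_table}: list with
#'   \code{signal}, \code{rank}, \code{mean_rank} (enhancers x cell
#'   types), \code{samples}, \code{primary_counts}, \code{N}.
#' @export
ranked_enhancer_table <- function(signal, samples, se_number = NULL) {
  signal <- as.matrix(signal)
  stopifnot(ncol(signal) == nrow(samples),
            all(colnames(signal) == samples$sample))
  rank_mat <- rank_enhancers(signal)
  cts <- unique(samples$cell_type)
  mean_rank <- sapply(cts, function(ct) {
    cols <- which(samples$cell_type == ct)
    rowMeans(rank_mat[, cols, drop = FALSE])
  })
  mean_rank <- matrix(mean_rank, nrow = nrow(signal),
                      dimnames = list(rownames(signal), cts))
  primary <- vapply(seq_len(ncol(signal)),
                    function(j) inflection_cutoff(signal[, j])$count,
                    integer(1))
  N <- if (is.null(se_number)) consensus_se_number(primary) else
    as.integer(se_number)
  structure(list(signal = signal, rank = rank_mat, mean_rank = mean_rank,
                 samples = samples, primary_counts = primary, N = N),
            class = "ranked_enhancer_table")
}

#' @export
print.ranked_enhancer_table <- function(x, ...) {
  cat(sprintf("ranked_enhancer_table: %d enhancers, %d samples, N = %d\n",
              nrow(x$signal), ncol(x$signal), x$N))
  cat("primary SE counts:", paste(x$primary_counts, collapse = ", "), "\n")
  invisible(x)
}

#' Call per-cell-type SE sets from a ranked table
#'
#' An enhancer is an SE for a cell type iff its mean rank over that
#' cell type's replicates is at or above the consensus SE number, i.e.
#' numerically \code{mean_rank <= N}.
#'
#' @param ranked a \code{ranked_enhancer_table}.
#' @param N consensus SE number (defaults to the table's).
#' @return list with \code{is_se} (logical matrix enhancers x cell
#'   types) and \code{union} (logical vector, SE in any cell type).
#' @export
call_cell_type_ses <- function(ranked, N = ranked$N) {
  is_se <- ranked$mean_rank <= N
  list(is_se = is_se, union = rowSums(is_se) > 0)
}

# Two-sided exact binomial p ("minlike": sum of all outcome
# probabilities not exceeding the observed one, the stats::binom.test
# definition, with the same 1 + 1e-7 tolerance).  The opposite-tail
# boundary is located by binary search on the unimodal pmf, so the cost
# is O(log n) and large counts stay cheap.
.binom_two_sided <- function(a, n, pi0) {
  if (n == 0) return(1)
  thr <- dbinom(a, n, pi0) * (1 + 1e-7)
  mode <- floor((n + 1) * pi0)
  if (dbinom(a, n, pi0) >= dbinom(mode, n, pi0) / (1 + 1e-7)) return(1)
  if (a < mode) {
    # smallest j in [mode, n] with dbinom(j) <= thr (pmf non-increasing)
    if (dbinom(n, n, pi0) > thr) return(pbinom(a, n, pi0))
    lo <- mode; hi <- n
    while (lo < hi) {
      mid <- (lo + hi) %/% 2
      if (dbinom(mid, n, pi0) <= thr) hi <- mid else lo <- mid + 1
    }
    pbinom(a, n, pi0) + pbinom(lo - 1, n, pi0, lower.tail = FALSE)
  } else {
    # largest j in [0, mode] with dbinom(j) <= thr (pmf non-decreasing)
    if (dbinom(0, n, pi0) > thr) {
      return(pbinom(a - 1, n, pi0, lower.tail = FALSE))
    }
    lo <- 0; hi <- mode
    while (lo < hi) {
      mid <- (lo + hi + 1) %/% 2
      if (dbinom(mid, n, pi0) <= thr) lo <- mid else hi <- mid - 1
    }
    pbinom(a - 1, n, pi0, lower.tail = FALSE) + pbinom(lo, n, pi0)
  }
}

#' Differential enhancer test between two sample groups
#'
#' Counts are pooled within groups per region; each region's pooled
#' count for group A is tested against the effective-library
#' probability pi = L_A / (L_A + L_B) with a two-sided exact binomial
#' test conditioned on the region total.  The log2 fold change is
#' computed on library-normalized counts with a 0.5-count pseudocount
#' per group, and Benjamini-Hochberg FDR is applied across regions.
#'
#' @param counts matrix regions x samples of non-negative counts.
#' @param group_a,group_b column names (or indices) of the two groups.
#' @return data frame per region: \code{id}, \code{count_a},
#'   \code{count_b}, \code{log2fc} (A over B), \code{pvalue},
#'   \code{fdr}.
#' @export
diff_enhancer_test <- function(counts, group_a, group_b) {
  counts <- as.matrix(counts)
  stopifnot(all(counts >= 0))
  a <- rowSums(counts[, group_a, drop = FALSE])
  b <- rowSums(counts[, group_b, drop = FALSE])
  L_a <- sum(a)
  L_b <- sum(b)
  if (L_a == 0 || L_b == 0) stop("zero total library in a group")
  pi0 <- L_a / (L_a + L_b)
  n <- a + b
  pvals <- vapply(seq_along(a), function(i) {
    .binom_two_sided(round(a[i]), round(n[i]), pi0)
  }, numeric(1))
  pvals <- pmin(pvals, 1)
  log2fc <- log2(((a + 0.5) / L_a) / ((b + 0.5) / L_b))
  data.frame(id = if (!is.null(rownames(counts))) rownames(counts) else
                  as.character(seq_along(a)),
             count_a = a, count_b = b, log2fc = log2fc,
             pvalue = pvals, fdr = p.adjust(pvals, method = "BH"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Call lineage-selective super enhancers
#'
#' The combined criterion: an enhancer is selective for lineage A iff
#' its mean rank in A is at or above the consensus SE number
#' (\code{<= N}), its mean rank in the other lineage is below
#' (\code{> N}), the differential test passes \code{fdr <= fdr_max},
#' and the normalized-signal fold change A over B is at least
#' \code{min_fold}.  The B-selective criterion is the mirror image, so
#' the two selective sets are disjoint by construction.
#'
#' @param ranked a \code{ranked_enhancer_table}.
#' @param diff result of \code{\link{diff_enhancer_test}} with group A
#'   = \code{lineage_a} and group B = \code{lineage_b} (row order must
#'   match the ranked table).
#' @param lineage_a,lineage_b the two cell-type names being contrasted
#'   (defaults \code{"adipocyte"}, \code{"osteoblast"}).
#' @param N consensus SE number (defaults to the table's).
#' @param fdr_max FDR gate (default 0.1).
#' @param min_fold minimum fold change (default 1.5).
#' @return data frame per enhancer: mean ranks, \code{log2fc},
#'   \code{fold}, \code{fdr}, logical criterion columns and
#'   \code{selective} in \{\code{lineage_a}, \code{lineage_b},
#'   \code{"none"}\}.
#' @export
call_lineage_selective_ses <- function(ranked, diff,
                                       lineage_a = "adipocyte",
                                       lineage_b = "osteoblast",
                                       N = ranked$N, fdr_max = 0.1,
                                       min_fold = 1.5) {
  stopifnot(nrow(diff) == nrow(ranked$mean_rank),
            all(c(lineage_a, lineage_b) %in% colnames(ranked$mean_rank)))
  r_a <- ranked$mean_rank[, lineage_a]
  r_b <- ranked$mean_rank[, lineage_b]
  fold_a <- 2^diff$log2fc        # A over B on normalized counts
  fold_b <- 2^(-diff$log2fc)
  sig <- diff$fdr <= fdr_max
  sel_a <- (r_a <= N) & (r_b > N) & sig & (fold_a >= min_fold)
  sel_b <- (r_b <= N) & (r_a > N) & sig & (fold_b >= min_fold)
  stopifnot(!any(sel_a & sel_b))  # mirror criteria cannot both hold
  data.frame(id = diff$id,
             mean_rank_a = r_a, mean_rank_b = r_b,
             log2fc = diff$log2fc,
             fold = pmax(fold_a, fold_b),
             fdr = diff$fdr,
             rank_criterion_a = (r_a <= N) & (r_b > N),
             rank_criterion_b = (r_b <= N) & (r_a > N),
             fdr_pass = sig,
             selective = ifelse(sel_a, lineage_a,
                                ifelse(sel_b, lineage_b, "none")),
             stringsAsFactors = FALSE, row.names = NULL)
}
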