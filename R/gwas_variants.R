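# GWAS variant integration: overlap of genome-wide-significant variants
# with SE functional regions, Fisher enrichment, allele-specific k-mer
# binding scores, and the directional-consistency filter.

#' Flag GWAS variants by significance and functional-region membership
#'
#' Point-in-interval test on the 0-based position against half-open
#' regions; significance uses the conventional genome-wide threshold
#' inclusively (p <= p_gw).
#'
#' @param variants GWAS variant data frame (see
#'   \code{\link{read_gwas_summary}}).
#' @param regions functional-region intervals.
#' @param p_gw genome-wide significance threshold (default 5e-8).
#' @return the variants with logical columns \code{significant} and
#'   \code{in_region} appended.
#' @export
overlap_significant_variants <- function(variants, regions, p_gw = 5e-8) {
  variants$significant <- variants$pvalue <= p_gw
  if (nrow(regions) == 0 || nrow(variants) == 0) {
    variants$in_region <- rep(FALSE, nrow(variants))
    return(variants)
  }
  pts <- data.frame(chrom = variants$chrom, start = variants$pos,
                    end = variants$pos + 1L)
  ov <- GenomicRanges::findOverlaps(.as_granges(pts), .as_granges(regions))
  variants$in_region <- seq_len(nrow(variants)) %in% S4Vectors::queryHits(ov)
  variants
}

#' Fisher enrichment of significant variants in functional regions
#'
#' Two-sided Fisher exact test on the 2x2 table {significant, not} x
#' {in region, not} (exact hypergeometric two-sided p: the sum of
#' table probabilities not exceeding the observed one).  The odds
#' ratio is the cross-product ad/bc; the 95% CI is Woolf's logit
#' interval, with 0.5 added to every cell only when some cell is zero.
#'
#' @param flags data frame with logical \code{significant} and
#'   \code{in_region} (from
#'   \code{\link{overlap_significant_variants}}), or a 2x2 count matrix
#'   (rows: significant yes/no; columns: in-region yes/no).
#' @return list with \code{table} (2x2), \code{odds_ratio},
#'   \code{p_value}, \code{ci_lower}, \code{ci_upper}.
#' @export
fisher_enrichment <- function(flags) {
  if (is.matrix(flags)) {
    stopifnot(all(dim(flags) == 2), all(flags >= 0))
    a <- flags[1, 1]; b <- flags[1, 2]; c_ <- flags[2, 1]; d <- flags[2, 2]
  } else {
    a <- sum(flags$significant & flags$in_region)
    b <- sum(flags$significant & !flags$in_region)
    c_ <- sum(!flags$significant & flags$in_region)
    d <- sum(!flags$significant & !flags$in_region)
  }
  tab <- matrix(c(a, b, c_, d), nrow = 2, byrow = TRUE,
                dimnames = list(c("significant", "not_significant"),
                                c("in_region", "outside")))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("fisher_enrichment: a table margin is zero; test undefined")
  }
  p <- fisher.test(tab, alternative = "two.sided")$p.value
  or <- (a * d) / (b * c_)
  cells <- c(a, b, c_, d)
  if (any(cells == 0)) cells <- cells + 0.5
  log_or_ci <- log((cells[1] * cells[4]) / (cells[2] * cells[3]))
  se <- sqrt(sum(1 / cells))
  z <- qnorm(0.975)
  list(table = tab, odds_ratio = or, p_value = p,
       ci_lower = exp(log_or_ci - z * se),
       ci_upper = exp(log_or_ci + z * se))
}

# weight of one k-mer under a strand-collapsed table: max over the
# entries present among {kmer, revcomp(kmer)}; 0 when neither is present
.kmer_weight <- function(kmers, weights) {
  w1 <- weights[kmers]
  w2 <- weights[revcomp(kmers)]
  w1[is.na(w1)] <- -Inf
  w2[is.na(w2)] <- -Inf
  out <- pmax(w1, w2)
  out[!is.finite(out)] <- 0
  unname(out)
}

# sum of the k k-mer weights covering the center base of a (2k-1)-mer
.window_score <- function(window, k, weights) {
  starts <- seq_len(k)
  kmers <- substring(window, starts, starts + k - 1L)
  sum(.kmer_weight(kmers, weights))
}

#' Allele-specific binding score from a k-mer weight model
#'
#' Each allele's score is the sum of weights of the k contiguous
#' k-mers covering the variant base in a window of length 2k-1
#' centered on it; k-mer lookup takes the larger of the k-mer's and
#' its reverse complement's weight (absent k-mers weigh 0).  The
#' binding status of an allele is "bound" iff its score exceeds
#' \code{tau}; a status change is recorded when exactly one allele is
#' bound.  SNVs only: windows of unequal length or a multi-base
#' difference give verdict "unsupported".
#'
#' @param ref_window,alt_window sequences of length 2k-1 centered on
#'   the variant base for the reference and alternate allele.
#' @param weights named numeric k-mer weight vector (names of length k).
#' @param tau bound/unbound threshold on the window score (default 0).
#' @param tf_name TF label carried into the result.
#' @return list with \code{tf}, \code{ref_score}, \code{alt_score},
#'   \code{delta} (alt minus ref), \code{status_change} in
#'   \{"unbound>bound", "bound>unbound", "none"\}, \code{ref_bound},
#'   \code{alt_bound}, \code{supported}.
#' @export
delta_kmer_score <- function(ref_window, alt_window, weights, tau = 0,
                             tf_name = NA_character_) {
  k <- unique(nchar(names(weights)))
  stopifnot(length(k) == 1, k >= 1)
  L <- 2L * k - 1L
  if (nchar(ref_window) != L || nchar(alt_window) != L) {
    if (nchar(ref_window) != nchar(alt_window)) {
      return(list(tf = tf_name, ref_score = NA_real_, alt_score = NA_real_,
                  delta = NA_real_, status_change = "unsupported",
                  ref_bound = NA, alt_bound = NA, supported = FALSE))
    }
    stop(sprintf("windows must have length 2k-1 = %d, got %d", L,
                 nchar(ref_window)))
  }
  ref_window <- toupper(ref_window)
  alt_window <- toupper(alt_window)
  diff_pos <- which(strsplit(ref_window, "")[[1]] !=
                    strsplit(alt_window, "")[[1]])
  if (length(diff_pos) > 1 || (length(diff_pos) == 1 && diff_pos != k)) {
    return(list(tf = tf_name, ref_score = NA_real_, alt_score = NA_real_,
                delta = NA_real_, status_change = "unsupported",
                ref_bound = NA, alt_bound = NA, supported = FALSE))
  }
  ref_score <- .window_score(ref_window, k, weights)
  alt_score <- .window_score(alt_window, k, weights)
  ref_bound <- ref_score > tau
  alt_bound <- alt_score > tau
  status <- if (!ref_bound && alt_bound) "unbound>bound" else
    if (ref_bound && !alt_bound) "bound>unbound" else "none"
  list(tf = tf_name, ref_score = ref_score, alt_score = alt_score,
       delta = alt_score - ref_score, status_change = status,
       ref_bound = ref_bound, alt_bound = alt_bound, supported = TRUE)
}

#' Directional-consistency filter for variant binding effects
#'
#' A variant effect is kept iff the sign of the GWAS effect of the alt
#' allele equals the product of the binding-change sign (delta) and
#' the TF-to-target expression-correlation sign, under the working
#' assumption that the target gene promotes the trait in its lineage
#' (recorded in the output).  Effects with no status change, a zero
#' sign, or unsupported scores are "untestable".
#'
#' @param effect result of \code{\link{delta_kmer_score}}.
#' @param beta signed GWAS effect of the alt allele.
#' @param correlation_sign +1 or -1: sign of the TF-target expression
#'   correlation.
#' @return list with \code{verdict} ("keep", "drop", "untestable"),
#'   the three signs, and \code{assumption}.
#' @export
directional_filter <- function(effect, beta, correlation_sign) {
  assumption <- "target gene assumed trait-promoting in its lineage"
  signs <- list(beta_sign = sign(beta), delta_sign = sign(effect$delta),
                correlation_sign = sign(correlation_sign))
  if (!isTRUE(effect$supported) || effect$status_change == "none" ||
      any(vapply(signs, function(s) is.na(s) || s == 0, logical(1)))) {
    return(c(list(verdict = "untestable"), signs,
             list(assumption = assumption)))
  }
  keep <- signs$beta_sign == signs$delta_sign * signs$correlation_sign
  c(list(verdict = if (keep) "keep" else "drop"), signs,
    list(assumption = assumption))
}
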