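# Shared helpers: coordinate conversion, sequence utilities, validation.

DNA_BASES <- c("A", "C", "G", "T")

#' Convert a 0-based half-open interval data frame to GRanges
#'
#' Internal bridge to the Bioconductor interval machinery.  GRanges is
#' 1-based closed, so start is shifted by one.
#'
#' @param df data frame with columns chrom, start, end.
#' @return A GRanges object in the same row order.
#' @keywords internal
#' @noRd
.as_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
}

# GRanges -> 0-based half-open data frame
.from_granges <- function(gr) {
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
}

# sort by (chrom, start, end); stable
.sort_intervals <- function(df) {
  df[order(df$chrom, df$start, df$end), , drop = FALSE]
}

.check_intervals <- function(df, what = "intervals") {
  stopifnot(is.data.frame(df), all(c("chrom", "start", "end") %in% names(df)))
  bad <- which(df$start < 0 | df$start >= df$end)
  if (length(bad) > 0) {
    stop(sprintf("invalid %s: start >= end or start < 0 at row(s) %s",
                 what, paste(utils::head(bad, 5), collapse = ", ")))
  }
  invisible(df)
}

#' Reverse complement of DNA strings
#'
#' @param x character vector of sequences over A/C/G/T/N.
#' @return character vector of reverse complements.
#' @export
#' @examples
#' revcomp("ACGTT")
revcomp <- function(x) {
  comp <- chartr("ACGTNacgtn", "TGCANtgcan", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

# deterministic per-stage seed derived from a master seed; kept < 2^31
.derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset) %% 2147483647)
}

# round half away from zero
.round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# random DNA with given GC content
.random_dna <- function(n, gc = 0.41) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(DNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}

# multiplicative lognormal noise with mean 1 and coefficient of variation cv
.ln_noise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  s2 <- log(1 + cv^2)
  rlnorm(n, meanlog = -s2 / 2, sdlog = sqrt(s2))
}
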