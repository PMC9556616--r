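# Consensus enhancer landscape: merge peaks across samples, remove
# promoter-contained peaks, stitch the remainder into enhancer units and
# quantify per-sample signal on them.

#' Merge peak sets across samples into a consensus peak set
#'
#' Returns the connected components of the interval-overlap graph over
#' all input peaks: the union of overlapping intervals, with
#' end-to-start touching intervals (gap 0 in half-open coordinates)
#' also merged.  Output is sorted and pairwise disjoint.
#'
#' @param peak_lists a list of interval data frames (or a single data
#'   frame) with \code{chrom}, \code{start}, \code{end}.
#' @return data frame \code{chrom}, \code{start}, \code{end},
#'   \code{name} with consensus intervals.
#' @export
merge_peaks <- function(peak_lists) {
  if (is.data.frame(peak_lists)) peak_lists <- list(peak_lists)
  all_df <- do.call(rbind, lapply(peak_lists, function(d) {
    d[, c("chrom", "start", "end"), drop = FALSE]
  }))
  if (is.null(all_df) || nrow(all_df) == 0) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), name = character(),
                      stringsAsFactors = FALSE))
  }
  .check_intervals(all_df, "peaks")
  merged <- GenomicRanges::reduce(.as_granges(all_df))  # min.gapwidth = 1:
  # merges overlap and 0-gap adjacency, exactly the consensus contract
  out <- .sort_intervals(.from_granges(merged))
  rownames(out) <- NULL
  out$name <- sprintf("consensus_%05d", seq_len(nrow(out)))
  out
}

#' Partition consensus peaks into enhancer and promoter peaks
#'
#' A peak is promoter-assigned iff it lies completely within
#' \code{[tss - w, tss + w)} of at least one TSS record; peaks that
#' only partially overlap a promoter window are retained as enhancers.
#'
#' @param consensus sorted, disjoint consensus peaks (see
#'   \code{\link{merge_peaks}}).
#' @param tss_records TSS records from \code{\link{read_tss}}.
#' @param promoter_window half-width of the promoter window in bp
#'   (default 2000).
#' @return list with elements \code{enhancers} and \code{promoters},
#'   both interval data frames partitioning \code{consensus}.
#' @export
exclude_promoter_peaks <- function(consensus, tss_records,
                                   promoter_window = 2000) {
  stopifnot(promoter_window > 0)
  if (nrow(consensus) == 0 || nrow(tss_records) == 0) {
    return(list(enhancers = consensus, promoters = consensus[0, , drop = FALSE]))
  }
  win <- data.frame(
    chrom = tss_records$chrom,
    start = pmax(0L, tss_records$tss_position - as.integer(promoter_window)),
    end = tss_records$tss_position + as.integer(promoter_window)
  )
  hits <- GenomicRanges::findOverlaps(.as_granges(consensus),
                                      .as_granges(win), type = "within")
  is_prom <- seq_len(nrow(consensus)) %in% S4Vectors::queryHits(hits)
  list(enhancers = consensus[!is_prom, , drop = FALSE],
       promoters = consensus[is_prom, , drop = FALSE])
}

#' Stitch enhancer peaks into enhancer units
#'
#' Consecutive peaks on one chromosome fall in the same stitched unit
#' iff the gap between them (next start minus previous end) is below
#' \code{stitch_distance}; the comparator is strict by default and can
#' be relaxed to \code{"<="}.  The stitched interval spans the first
#' constituent start to the last constituent end.
#'
#' @param enhancer_peaks disjoint, sorted peaks.
#' @param stitch_distance stitching gap threshold in bp (default 12500).
#' @param comparator \code{"<"} (default) or \code{"<="} applied to the
#'   gap versus \code{stitch_distance}.
#' @return object of class \code{stitched_enhancers}: a list with
#'   \code{units} (id, chrom, start, end, n_peaks) and
#'   \code{constituents} (unit_id plus the peak coordinates).
#' @export
stitch_enhancers <- function(enhancer_peaks, stitch_distance = 12500,
                             comparator = c("<", "<=")) {
  comparator <- match.arg(comparator)
  stopifnot(stitch_distance > 0)
  peaks <- .sort_intervals(enhancer_peaks)
  if (nrow(peaks) == 0) {
    units <- data.frame(id = character(), chrom = character(),
                        start = integer(), end = integer(),
                        n_peaks = integer(), stringsAsFactors = FALSE)
    return(structure(list(units = units,
                          constituents = cbind(unit_id = character(0), peaks)),
                     class = "stitched_enhancers"))
  }
  # reduce() merges ranges whose 0-based gap is < min.gapwidth
  gapw <- if (comparator == "<") stitch_distance else stitch_distance + 1
  merged <- GenomicRanges::reduce(.as_granges(peaks), min.gapwidth = gapw)
  units <- .sort_intervals(.from_granges(merged))
  rownames(units) <- NULL
  units$id <- sprintf("stitched_%05d", seq_len(nrow(units)))
  ov <- GenomicRanges::findOverlaps(.as_granges(peaks), .as_granges(units),
                                    type = "within")
  stopifnot(length(ov) == nrow(peaks))  # every peak in exactly one unit
  constituents <- peaks
  constituents$unit_id <- units$id[S4Vectors::subjectHits(ov)]
  units$n_peaks <- as.integer(table(factor(constituents$unit_id,
                                           levels = units$id)))
  structure(list(units = units[, c("id", "chrom", "start", "end", "n_peaks")],
                 constituents = constituents),
            class = "stitched_enhancers")
}

#' @export
print.stitched_enhancers <- function(x, ...) {
  cat(sprintf("stitched_enhancers: %d units from %d peaks\n",
              nrow(x$units), nrow(x$constituents)))
  invisible(x)
}

# sum of coverage * overlapped bp of `regions` against one bedGraph track
.coverage_sum <- function(regions, track) {
  if (nrow(track) == 0 || nrow(regions) == 0) return(numeric(nrow(regions)))
  gr_r <- .as_granges(regions)
  gr_t <- .as_granges(track)
  ov <- GenomicRanges::findOverlaps(gr_r, gr_t)
  if (length(ov) == 0) return(numeric(nrow(regions)))
  qi <- S4Vectors::queryHits(ov)
  si <- S4Vectors::subjectHits(ov)
  w <- IRanges::width(IRanges::pintersect(IRanges::ranges(gr_r)[qi],
                                          IRanges::ranges(gr_t)[si]))
  contrib <- w * track$signal[si]
  out <- numeric(nrow(regions))
  agg <- tapply(contrib, qi, sum)
  out[as.integer(names(agg))] <- as.numeric(agg)
  out
}

#' Quantify per-sample signal on stitched enhancers (or any regions)
#'
#' Raw signal of a unit in a sample is the sum over its constituent
#' peaks of coverage times overlapped base pairs.  Normalized signal
#' divides by the sample's total raw signal over all units and
#' multiplies by 1e6 (per-million within the quantified region set), so
#' it is invariant to rescaling the coverage track.
#'
#' @param stitched a \code{stitched_enhancers} object, or a plain
#'   interval data frame with an \code{id} column (quantified over the
#'   full intervals).
#' @param coverage named list (one element per sample) of bedGraph-style
#'   data frames (\code{chrom}, \code{start}, \code{end},
#'   \code{signal}).
#' @param normalize per-million normalize (default TRUE).
#' @return matrix units x samples of signals; the raw (unnormalized)
#'   matrix is attached as attribute \code{"raw"}.
#' @export
quantify_signal <- function(stitched, coverage, normalize = TRUE) {
  if (inherits(stitched, "stitched_enhancers")) {
    ids <- stitched$units$id
    regions <- stitched$constituents
    region_unit <- regions$unit_id
  } else {
    stopifnot(is.data.frame(stitched), "id" %in% names(stitched))
    ids <- stitched$id
    regions <- stitched
    region_unit <- stitched$id
  }
  stopifnot(is.list(coverage), !is.null(names(coverage)))
  raw <- sapply(coverage, function(track) {
    per_region <- .coverage_sum(regions, track)
    as.numeric(tapply(per_region, factor(region_unit, levels = ids), sum))
  })
  raw <- matrix(raw, nrow = length(ids),
                dimnames = list(ids, names(coverage)))
  raw[is.na(raw)] <- 0
  if (!normalize) return(raw)
  totals <- colSums(raw)
  norm <- sweep(raw, 2, ifelse(totals > 0, totals, 1), "/") * 1e6
  attr(norm, "raw") <- raw
  norm
}
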