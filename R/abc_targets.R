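# Activity-by-contact target assignment: functional regions inside
# selective SEs, element-gene link scoring with a distance power-law
# contact, target calling at a score threshold, and expression
# contrasts of target-gene sets.

#' Define functional regions of selective super enhancers
#'
#' Functional regions are accessibility (DNase) peaks intersected with
#' and clipped to the SE interval; fragments shorter than
#' \code{min_width} bp after clipping are dropped.
#'
#' @param ses interval data frame of selective SEs with an \code{id}
#'   column.
#' @param accessibility_peaks interval data frame of accessibility
#'   peaks for the SE lineage.
#' @param min_width minimum clipped width in bp (default 50).
#' @return data frame \code{region_id}, \code{se_id}, \code{chrom},
#'   \code{start}, \code{end}.  SEs with no accessible sub-region emit
#'   nothing (a message reports how many).
#' @export
define_functional_regions <- function(ses, accessibility_peaks,
                                      min_width = 50) {
  stopifnot("id" %in% names(ses))
  if (nrow(ses) == 0 || is.null(accessibility_peaks) ||
      nrow(accessibility_peaks) == 0) {
    if (nrow(ses) > 0) {
      stop("accessibility peaks missing for functional-region definition")
    }
    return(data.frame(region_id = character(), se_id = character(),
                      chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  gr_se <- .as_granges(ses)
  gr_ac <- .as_granges(accessibility_peaks)
  # disjoint chromosome vocabularies are a legitimate no-overlap case
  ov <- suppressWarnings(GenomicRanges::findOverlaps(gr_ac, gr_se))
  qi <- S4Vectors::queryHits(ov)
  si <- S4Vectors::subjectHits(ov)
  start <- pmax(accessibility_peaks$start[qi], ses$start[si])
  end <- pmin(accessibility_peaks$end[qi], ses$end[si])
  keep <- (end - start) >= min_width
  out <- data.frame(se_id = ses$id[si][keep],
                    chrom = ses$chrom[si][keep],
                    start = start[keep], end = end[keep],
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  # ids derive from the parent SE so regions from different calls never
  # collide
  ord <- stats::ave(seq_len(nrow(out)), out$se_id, FUN = seq_along)
  out <- cbind(region_id = sprintf("%s_fr%02d", out$se_id, ord), out)
  n_empty <- sum(!(ses$id %in% out$se_id))
  if (n_empty > 0) {
    message(sprintf("define_functional_regions: %d SE(s) without accessible sub-regions",
                    n_empty))
  }
  out
}

#' Score element-to-gene links with the activity-by-contact model
#'
#' Activity is the geometric mean of accessibility and H3K27ac signal;
#' contact is a distance power law with exponent \code{gamma} and a
#' floor at \code{d_min} bp.  For each gene, the candidate set is all
#' elements within \code{window} bp of its TSS plus the gene's own
#' promoter element (TSS +/- \code{promoter_halfwidth}), and scores are
#' normalized so they sum to one over the candidate set.
#'
#' @param elements data frame with \code{region_id}, \code{chrom},
#'   \code{start}, \code{end}, \code{dnase_signal},
#'   \code{h3k27ac_signal} (functional regions, quantified in the
#'   cell type being scored).
#' @param tss_records TSS records (one row per gene is used: the first
#'   TSS per \code{gene_id}).
#' @param promoter_signals optional data frame \code{gene_id},
#'   \code{dnase_signal}, \code{h3k27ac_signal} for promoter elements;
#'   promoters default to zero activity when absent.
#' @param gamma contact power-law exponent (> 0, default 1).
#' @param window candidate window around the TSS in bp (default 5e6).
#' @param d_min contact distance floor in bp (default 5000).
#' @param promoter_halfwidth promoter element half-width (default 250).
#' @return data frame of links: \code{element_id}, \code{gene_id},
#'   \code{distance}, \code{activity}, \code{contact},
#'   \code{abc_score}, \code{is_promoter}.  Genes whose candidate set
#'   has zero total activity get no links.
#' @export
abc_score_links <- function(elements, tss_records, promoter_signals = NULL,
                            gamma = 1.0, window = 5e6, d_min = 5000,
                            promoter_halfwidth = 250) {
  if (gamma <= 0) stop("gamma must be > 0")
  genes <- tss_records[!duplicated(tss_records$gene_id), , drop = FALSE]
  el <- elements
  el$midpoint <- (el$start + el$end) / 2
  el$activity <- sqrt(el$dnase_signal * el$h3k27ac_signal)
  prom_act <- setNames(rep(0, nrow(genes)), genes$gene_id)
  if (!is.null(promoter_signals)) {
    idx <- match(genes$gene_id, promoter_signals$gene_id)
    ok <- !is.na(idx)
    prom_act[ok] <- sqrt(promoter_signals$dnase_signal[idx[ok]] *
                         promoter_signals$h3k27ac_signal[idx[ok]])
  }
  links <- vector("list", nrow(genes))
  for (g in seq_len(nrow(genes))) {
    tss <- genes$tss_position[g]
    cand <- which(el$chrom == genes$chrom[g] &
                  abs(el$midpoint - tss) <= window)
    d_el <- abs(el$midpoint[cand] - tss)
    # the gene's own promoter element always competes in the denominator
    ids <- c(el$region_id[cand], paste0("promoter_", genes$gene_id[g]))
    act <- c(el$activity[cand], prom_act[g])
    dist <- c(d_el, promoter_halfwidth / 2)
    is_prom <- c(rep(FALSE, length(cand)), TRUE)
    contact <- pmax(dist, d_min)^(-gamma)
    ac <- act * contact
    denom <- sum(ac)
    if (denom <= 0) next
    links[[g]] <- data.frame(element_id = ids,
                             gene_id = genes$gene_id[g],
                             distance = dist, activity = act,
                             contact = contact, abc_score = ac / denom,
                             is_promoter = is_prom,
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, links)
  if (is.null(out)) {
    out <- data.frame(element_id = character(), gene_id = character(),
                      distance = numeric(), activity = numeric(),
                      contact = numeric(), abc_score = numeric(),
                      is_promoter = logical(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Assign target genes to super enhancers from ABC links
#'
#' A gene is a target of an SE iff some functional region of that SE
#' links to it with an ABC score strictly above \code{threshold}; the
#' SE's target set is the union over its functional regions.
#'
#' @param links output of \code{\link{abc_score_links}}.
#' @param regions functional regions (maps \code{region_id} to
#'   \code{se_id}).
#' @param threshold ABC score cut (strict >, default 0.02).
#' @return data frame \code{se_id}, \code{gene_id}, \code{max_score}.
#' @export
assign_se_targets <- function(links, regions, threshold = 0.02) {
  hits <- links[!links$is_promoter & links$abc_score > threshold, , drop = FALSE]
  if (nrow(hits) == 0) {
    return(data.frame(se_id = character(), gene_id = character(),
                      max_score = numeric(), stringsAsFactors = FALSE))
  }
  hits$se_id <- regions$se_id[match(hits$element_id, regions$region_id)]
  agg <- stats::aggregate(abc_score ~ se_id + gene_id, data = hits, FUN = max)
  names(agg)[names(agg) == "abc_score"] <- "max_score"
  agg <- agg[order(agg$se_id, agg$gene_id), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Expression contrast of a target-gene set between two cell types
#'
#' Two-sided Wilcoxon rank-sum test with genes as units, comparing
#' per-gene mean FPKM (over replicates) between two cell types.
#'
#' @param genes character vector of gene ids (>= 2).
#' @param expression genes x samples FPKM matrix.
#' @param sample_map data frame \code{sample}, \code{cell_type}.
#' @param cell_type_a,cell_type_b cell types to contrast (A vs B).
#' @return list with \code{p_value}, \code{median_shift} (median A
#'   minus median B), \code{n_genes}.
#' @export
expression_contrast <- function(genes, expression, sample_map,
                                cell_type_a, cell_type_b) {
  genes <- intersect(genes, rownames(expression))
  if (length(genes) < 2) stop("need >= 2 genes with expression data")
  mean_ct <- function(ct) {
    cols <- sample_map$sample[sample_map$cell_type == ct]
    rowMeans(expression[genes, cols, drop = FALSE])
  }
  x <- mean_ct(cell_type_a)
  y <- mean_ct(cell_type_b)
  wt <- suppressWarnings(wilcox.test(x, y, alternative = "two.sided",
                                     exact = FALSE, correct = TRUE))
  p <- wt$p.value
  if (is.na(p)) p <- 1  # fully tied groups carry no evidence
  list(p_value = p, median_shift = median(x) - median(y),
       n_genes = length(genes))
}
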