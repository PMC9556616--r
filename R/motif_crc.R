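# PWM scanning with exact tail p-values by dynamic programming over a
# discretized score distribution, motif enrichment against sampled
# background sequence, TF-target pair calling (motif rule / ChIP-overlap
# rule), and core regulatory circuitry clique inference.

#' Construct a PWM object
#'
#' Probabilities receive a pseudocount per cell and are re-normalized,
#' so all log-odds are finite.
#'
#' @param matrix positions x 4 matrix of base probabilities (columns
#'   A, C, G, T).
#' @param tf_name TF name.
#' @param background length-4 background base probabilities (default
#'   uniform).
#' @param pseudocount added to every cell before renormalization
#'   (default 1e-3).
#' @return object of class \code{pwm}: list with \code{tf},
#'   \code{mat}, \code{bg}, \code{score} (log2 odds matrix).
#' @export
make_pwm <- function(matrix, tf_name = "TF", background = rep(0.25, 4),
                     pseudocount = 1e-3) {
  matrix <- as.matrix(matrix)
  stopifnot(ncol(matrix) == 4, all(matrix >= 0),
            length(background) == 4, all(background > 0))
  m <- matrix + pseudocount
  m <- m / rowSums(m)
  bg <- background / sum(background)
  stopifnot(all(abs(rowSums(m) - 1) < 1e-6))
  colnames(m) <- DNA_BASES
  structure(list(tf = tf_name, mat = m, bg = bg,
                 score = sweep(log2(m), 2, log2(bg), "-")),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("pwm: %s, %d positions, max score %.2f bits\n",
              x$tf, nrow(x$mat), sum(apply(x$score, 1, max))))
  invisible(x)
}

# Discretized integer score matrix and the exact background tail
# distribution of the total score, by per-position convolution.
# Returns list(int_score: w x 4 integer matrix, tail: function mapping
# integer total score -> P(S >= s) under the zero-order background).
.pwm_score_dp <- function(pwm, granularity = 1e-3) {
  D <- round(pwm$score / granularity)
  w <- nrow(D)
  # convolve the per-position score distributions one position at a time
  pmf <- 1
  cur_lo <- 0
  for (i in seq_len(w)) {
    d <- D[i, ]
    new_lo <- cur_lo + min(d)
    new_hi <- cur_lo + length(pmf) - 1 + max(d)
    new <- numeric(new_hi - new_lo + 1)
    for (b in 1:4) {
      off <- d[b] - min(d) + 1
      idx <- off:(off + length(pmf) - 1)
      new[idx] <- new[idx] + pmf * pwm$bg[b]
    }
    pmf <- new
    cur_lo <- new_lo
  }
  tail_p <- rev(cumsum(rev(pmf)))
  list(int_score = D, lo = cur_lo, hi = cur_lo + length(pmf) - 1,
       granularity = granularity,
       tail = function(s) {
         s <- pmax(pmin(s, cur_lo + length(pmf) - 1), cur_lo)
         tail_p[s - cur_lo + 1]
       })
}

# integer score at every valid offset of a single strand; NA where the
# window contains a non-ACGT base
.scan_strand <- function(seq_int, D) {
  w <- nrow(D)
  L <- length(seq_int)
  if (L < w) return(numeric(0))
  n_off <- L - w + 1
  sc <- numeric(n_off)
  ok <- rep(TRUE, n_off)
  for (j in seq_len(w)) {
    base <- seq_int[j:(j + n_off - 1)]
    valid <- !is.na(base)
    ok <- ok & valid
    sc[valid] <- sc[valid] + D[j, base[valid]]
  }
  sc[!ok] <- NA_real_
  sc
}

.encode_dna <- function(sequence) {
  v <- match(strsplit(toupper(sequence), "", fixed = TRUE)[[1]], DNA_BASES)
  v  # NA for N and other characters
}

#' Scan a sequence with a PWM, reporting exact p-values
#'
#' Both strands are scanned.  The score at an offset is the summed
#' log2 odds of the window; its p-value is the exact tail probability
#' of that score under the zero-order background, computed by dynamic
#' programming on the integer-discretized score distribution.  Windows
#' containing N are skipped.  Hits with p-value strictly below
#' \code{p_threshold} are returned sorted by offset.
#'
#' @param sequence string over A/C/G/T/N.
#' @param pwm a \code{\link{make_pwm}} object.
#' @param p_threshold hit threshold on the exact p-value (default 1e-4).
#' @param granularity score discretization step in bits (default 1e-3).
#' @param dp optional precomputed result of the internal DP (reused
#'   across sequences for speed).
#' @return data frame \code{tf}, \code{offset} (0-based, on the
#'   forward strand), \code{strand}, \code{score} (bits),
#'   \code{p_value}.
#' @export
scan_pwm <- function(sequence, pwm, p_threshold = 1e-4,
                     granularity = 1e-3, dp = NULL) {
  stopifnot(inherits(pwm, "pwm"))
  if (is.null(dp)) dp <- .pwm_score_dp(pwm, granularity)
  w <- nrow(dp$int_score)
  fwd <- .encode_dna(sequence)
  empty <- data.frame(tf = character(), offset = integer(),
                      strand = character(), score = numeric(),
                      p_value = numeric(), stringsAsFactors = FALSE)
  if (length(fwd) < w) return(empty)
  rev_int <- rev(5L - fwd)  # complement within 1..4 then reverse
  res <- list()
  for (strand in c("+", "-")) {
    sc <- .scan_strand(if (strand == "+") fwd else rev_int, dp$int_score)
    valid <- which(!is.na(sc))
    if (length(valid) == 0) next
    pv <- dp$tail(sc[valid])
    hit <- pv < p_threshold
    if (!any(hit)) next
    off_local <- valid[hit] - 1L            # 0-based on scanned strand
    offset <- if (strand == "+") off_local else
      length(fwd) - w - off_local           # map back to forward coords
    res[[strand]] <- data.frame(tf = pwm$tf, offset = offset,
                                strand = strand,
                                score = sc[valid][hit] * dp$granularity,
                                p_value = pv[hit],
                                stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  if (is.null(out)) return(empty)
  out <- out[order(out$offset, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Motif enrichment of a PWM set in foreground regions
#'
#' Compares the fraction of foreground sequences carrying at least one
#' hit against the same fraction in random background sequences
#' (length-matched, fixed GC), with a one-sided binomial test per TF
#' and BH correction across TFs.  The background rate is floored at
#' 1/(n_background + 1) so a zero background never yields p = 0.
#'
#' @param foreground_seqs character vector of region sequences.
#' @param pwms list of \code{pwm} objects.
#' @param n_background_per_fg background draws per foreground region
#'   (default 10).
#' @param gc background GC content; default matches the foreground.
#' @param p_threshold hit threshold passed to \code{\link{scan_pwm}}.
#' @return data frame per TF: hit fractions, \code{p_value}, \code{q_value}.
#' @export
motif_enrichment <- function(foreground_seqs, pwms,
                             n_background_per_fg = 10, gc = NULL,
                             p_threshold = 1e-4) {
  if (length(foreground_seqs) == 0) stop("empty foreground")
  if (is.null(gc)) {
    ch <- strsplit(paste(foreground_seqs, collapse = ""), "")[[1]]
    gc <- mean(ch %in% c("G", "C"))
  }
  n_fg <- length(foreground_seqs)
  n_bg <- n_fg * n_background_per_fg
  lens <- nchar(foreground_seqs)
  bg_seqs <- vapply(sample(lens, n_bg, replace = TRUE),
                    .random_dna, character(1), gc = gc)
  res <- lapply(pwms, function(p) {
    dp <- .pwm_score_dp(p)
    has_hit <- function(s) nrow(scan_pwm(s, p, p_threshold, dp = dp)) > 0
    k_fg <- sum(vapply(foreground_seqs, has_hit, logical(1)))
    k_bg <- sum(vapply(bg_seqs, has_hit, logical(1)))
    rate <- max(k_bg / n_bg, 1 / (n_bg + 1))
    pv <- binom.test(k_fg, n_fg, rate, alternative = "greater")$p.value
    data.frame(tf = p$tf, fg_fraction = k_fg / n_fg,
               bg_fraction = k_bg / n_bg, p_value = pv,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q_value <- p.adjust(out$p_value, method = "BH")
  rownames(out) <- NULL
  out[order(out$p_value), , drop = FALSE]
}

#' Decide whether a TF regulates a gene through SE functional regions
#'
#' Rule 1 (motif): at least \code{min_hits} motif hits with exact
#' p-value below \code{p_threshold}, counted across all functional
#' regions targeting the gene (both strands; one count per
#' offset/strand), or per region when \code{per_region} is TRUE.
#' Rule 2 (ChIP): at least 1 bp overlap between the TF's merged ChIP
#' peaks and any of the functional regions.  The pair is accepted if
#' either available rule holds; with no evidence source it is
#' "untestable".
#'
#' @param pwm \code{pwm} object for the TF, or NULL.
#' @param region_seqs named character vector: sequences of the
#'   functional regions of SEs targeting the gene.
#' @param regions interval data frame of those regions (needed for
#'   rule 2).
#' @param chip_peaks merged ChIP peak data frame for the TF, or NULL.
#' @param p_threshold,min_hits rule-1 parameters (defaults 1e-4, 2).
#' @param per_region require \code{min_hits} within a single region.
#' @return list with \code{verdict} ("accepted", "rejected",
#'   "untestable"), \code{n_motif_hits}, \code{chip_overlap},
#'   \code{rule}.
#' @export
tf_target_pairs <- function(pwm = NULL, region_seqs = character(),
                            regions = NULL, chip_peaks = NULL,
                            p_threshold = 1e-4, min_hits = 2,
                            per_region = FALSE) {
  has_motif_evidence <- !is.null(pwm) && length(region_seqs) > 0
  has_chip_evidence <- !is.null(chip_peaks) && !is.null(regions) &&
    nrow(regions) > 0
  if (!has_motif_evidence && !has_chip_evidence) {
    return(list(verdict = "untestable", n_motif_hits = NA_integer_,
                chip_overlap = NA, rule = NA_character_))
  }
  n_hits <- 0L
  rule1 <- FALSE
  if (has_motif_evidence) {
    dp <- .pwm_score_dp(pwm)
    per_region_hits <- vapply(region_seqs, function(s) {
      nrow(scan_pwm(s, pwm, p_threshold, dp = dp))
    }, integer(1))
    n_hits <- sum(per_region_hits)
    rule1 <- if (per_region) any(per_region_hits >= min_hits) else
      n_hits >= min_hits
  }
  chip_overlap <- FALSE
  if (has_chip_evidence) {
    ov <- GenomicRanges::findOverlaps(.as_granges(regions),
                                      .as_granges(chip_peaks))
    chip_overlap <- length(ov) > 0
  }
  verdict <- if (rule1 || chip_overlap) "accepted" else "rejected"
  list(verdict = verdict, n_motif_hits = n_hits,
       chip_overlap = chip_overlap,
       rule = if (rule1) "motif" else if (chip_overlap) "chip" else NA_character_)
}

#' Build the core regulatory circuitry graph and its cliques
#'
#' Nodes are the SE-regulated TFs; a directed edge u -> v records an
#' accepted (u, SE-targeting-v) pair.  CRCs are the maximal node
#' subsets in which every ordered pair (including each TF with itself)
#' has an edge: maximal cliques of the mutual-edge graph restricted to
#' TFs with a self-loop, enumerated exactly.
#'
#' @param tfs character vector of SE-regulated TFs (the node set).
#' @param edges data frame with columns \code{from}, \code{to} of
#'   accepted TF -> TF-gene pairs.
#' @return object of class \code{crc_graph}: list with \code{tfs},
#'   \code{edges}, \code{crcs} (list of character vectors, largest
#'   first, ties by name).
#' @export
build_crc <- function(tfs, edges) {
  tfs <- sort(unique(tfs))
  edges <- unique(edges[edges$from %in% tfs & edges$to %in% tfs,
                        c("from", "to"), drop = FALSE])
  has_edge <- function(u, v) any(edges$from == u & edges$to == v)
  selfloop <- tfs[vapply(tfs, function(u) has_edge(u, u), logical(1))]
  crcs <- list()
  if (length(selfloop) > 0) {
    # undirected mutual graph over self-loop TFs
    g <- igraph::make_empty_graph(n = length(selfloop), directed = FALSE)
    igraph::V(g)$name <- selfloop
    pairs <- if (length(selfloop) > 1) utils::combn(selfloop, 2) else
      matrix(character(0), nrow = 2)
    for (k in seq_len(ncol(pairs))) {
      u <- pairs[1, k]; v <- pairs[2, k]
      if (has_edge(u, v) && has_edge(v, u)) {
        g <- igraph::add_edges(g, c(u, v))
      }
    }
    cl <- igraph::max_cliques(g)
    crcs <- lapply(cl, function(x) sort(igraph::V(g)$name[x]))
    ord <- order(-lengths(crcs), vapply(crcs, `[`, character(1), 1))
    crcs <- crcs[ord]
  }
  structure(list(tfs = tfs, edges = edges, crcs = crcs),
            class = "crc_graph")
}

#' @export
print.crc_graph <- function(x, ...) {
  cat(sprintf("crc_graph: %d TFs, %d edges, %d CRC(s)\n",
              length(x$tfs), nrow(x$edges), length(x$crcs)))
  for (i in seq_along(x$crcs)) {
    cat(sprintf("  CRC %d: %s\n", i, paste(x$crcs[[i]], collapse = ", ")))
  }
  invisible(x)
}
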