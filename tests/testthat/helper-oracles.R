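# Shared fixtures and independent oracles used across test files.

# quick interval data frame
iv <- function(chrom, start, end, name = NA_character_, signal = NA_real_) {
  n <- length(start)
  data.frame(chrom = rep_len(chrom, n), start = as.integer(start),
             end = as.integer(end), name = rep_len(name, n),
             signal = rep_len(signal, n), stringsAsFactors = FALSE)
}

# random interval set on a couple of chromosomes
random_intervals <- function(n, max_pos = 1e5, max_width = 2000,
                             chroms = c("chr1", "chr2")) {
  start <- sample.int(max_pos, n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start, end = start + sample.int(max_width, n, TRUE),
             stringsAsFactors = FALSE)
}

# Independent interval-union / stitching oracle: connect two intervals
# when their gap (max start - min end, negative on overlap) is strictly
# below `link_gap`, take connected components of that graph, and span
# each component.  link_gap = 1 reproduces "overlap or touch" (gap <= 0),
# i.e. the consensus-merge contract.
oracle_components <- function(df, link_gap = 1) {
  n <- nrow(df)
  if (n == 0) return(df[, c("chrom", "start", "end")])
  same <- outer(df$chrom, df$chrom, "==")
  gap <- pmax(outer(df$start, df$start, pmax) - outer(df$end, df$end, pmin), 0)
  overlap <- outer(df$start, df$start, pmax) < outer(df$end, df$end, pmin)
  linked <- same & (overlap | gap < link_gap)
  g <- igraph::graph_from_adjacency_matrix(linked, mode = "undirected")
  comp <- igraph::components(g)$membership
  out <- do.call(rbind, lapply(split(seq_len(n), comp), function(idx) {
    data.frame(chrom = df$chrom[idx[1]], start = min(df$start[idx]),
               end = max(df$end[idx]), stringsAsFactors = FALSE)
  }))
  out[order(out$chrom, out$start, out$end), , drop = FALSE]
}

# brute-force promoter containment oracle over all peak x TSS pairs
oracle_promoter_contained <- function(peaks, tss, w) {
  vapply(seq_len(nrow(peaks)), function(i) {
    any(tss$chrom == peaks$chrom[i] &
        peaks$start[i] >= pmax(0, tss$tss_position - w) &
        peaks$end[i] <= tss$tss_position + w)
  }, logical(1))
}

# two-sided Fisher p by direct hypergeometric summation on table
# [[a, b], [c, d]] (rows: significant yes/no, cols: in-region yes/no)
oracle_fisher_p <- function(a, b, c_, d) {
  k <- a + c_            # in-region total
  m <- a + b             # significant total
  n <- c_ + d
  x_all <- max(0, k - n):min(k, m)
  pr <- dhyper(x_all, m, n, k)
  sum(pr[pr <= dhyper(a, m, n, k) * (1 + 1e-7)])
}

# enumerate every length-L sequence, score it against the discretized
# PWM and return the exact tail probability function (uniform background)
oracle_pwm_tail <- function(pwm, granularity = 1e-3) {
  D <- round(pwm$score / granularity)
  L <- nrow(D)
  grid <- as.matrix(expand.grid(rep(list(1:4), L)))
  sc <- numeric(nrow(grid))
  for (j in seq_len(L)) sc <- sc + D[j, grid[, j]]
  prob <- rep(1 / 4^L, nrow(grid))
  function(s) sum(prob[sc >= s])
}

# small, fast simulation for tests that only need the dataset's shape
small_config <- function(seed = 1, ...) {
  sim_config(seed = seed, n_chroms = 2, chrom_length = 6e6,
             n_enhancer_loci = 60, n_genes = 30, n_variants = 400, ...)
}

# cache pipeline runs at the default study conditions; several test
# files interrogate the same runs
.run_cache <- new.env(parent = emptyenv())
cached_default_run <- function(seed) {
  key <- as.character(seed)
  if (is.null(.run_cache[[key]])) {
    ds <- simulate_dataset(sim_config(seed = seed))
    .run_cache[[key]] <- suppressMessages(run_pipeline(ds))
  }
  .run_cache[[key]]
}
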