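# PWM construction, exact-p scanning, enrichment, TF-target rules and
# CRC clique inference.

random_pwm <- function(w, tf = "TF", conc = 1) {
  m <- matrix(rgamma(w * 4, conc), w, 4)
  make_pwm(m / rowSums(m), tf_name = tf)
}

test_that("PWM rows are pseudocounted probability vectors", {
  p <- make_pwm(matrix(c(1, 0, 0, 0), 1, 4), "t")
  expect_equal(rowSums(p$mat), 1, tolerance = 1e-9)
  expect_true(all(p$mat > 0))
  expect_true(all(is.finite(p$score)))
})

test_that("a single-position PWM gives the enumerable exact p-value", {
  p <- make_pwm(matrix(c(1, 0, 0, 0), 1, 4), "t")
  hits <- scan_pwm("A", p, p_threshold = 0.3)
  # top score is achieved only by A under a uniform background: p = 1/4
  fwd <- hits[hits$strand == "+", ]
  expect_equal(nrow(fwd), 1)
  expect_equal(fwd$p_value, 0.25)
})

test_that("DP tail probabilities equal brute-force enumeration", {
  set.seed(17)
  for (w in c(2, 4, 6)) {
    p <- random_pwm(w)
    dp <- secircuit:::.pwm_score_dp(p)
    tail_fn <- oracle_pwm_tail(p)
    for (s in unique(round(seq(dp$lo, dp$hi, length.out = 25)))) {
      expect_equal(dp$tail(s), tail_fn(s), tolerance = 1e-12)
    }
  }
})

test_that("reverse-complementing the sequence flips strands only", {
  set.seed(23)
  p <- random_pwm(6, conc = 0.3)
  seqs <- vapply(1:10, function(i) secircuit:::.random_dna(200), character(1))
  for (s in seqs) {
    h1 <- scan_pwm(s, p, p_threshold = 0.05)
    h2 <- scan_pwm(revcomp(s), p, p_threshold = 0.05)
    expect_equal(nrow(h1), nrow(h2))
    if (nrow(h1) > 0) {
      # a + hit at offset o maps to a - hit at L - w - o
      L <- nchar(s)
      mapped <- data.frame(offset = L - 6 - h2$offset,
                           strand = ifelse(h2$strand == "+", "-", "+"),
                           score = h2$score)
      mapped <- mapped[order(mapped$offset, mapped$strand), ]
      orig <- h1[order(h1$offset, h1$strand), c("offset", "strand", "score")]
      expect_equal(orig, mapped, ignore_attr = TRUE)
    }
  }
})

test_that("windows containing N are skipped and short sequences are empty", {
  p <- random_pwm(5)
  expect_equal(nrow(scan_pwm("ACG", p)), 0)
  h <- scan_pwm("ACGTNACGTA", p, p_threshold = 1)
  # offsets 0..5 exist per strand but windows covering the N (0..4) drop:
  # only offset 5 remains on each strand
  expect_true(all(h$offset == 5))
})

test_that("hit counts are monotone in the p-value threshold", {
  set.seed(29)
  p <- random_pwm(6, conc = 0.3)
  s <- secircuit:::.random_dna(3000)
  counts <- vapply(c(1e-2, 1e-3, 1e-4), function(thr) {
    nrow(scan_pwm(s, p, p_threshold = thr))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("null scan hit rate matches the threshold expectation", {
  set.seed(41)
  w <- 8
  p <- random_pwm(w, conc = 0.5)
  thr <- 1e-3
  L <- 300
  n_regions <- 400
  hits <- vapply(seq_len(n_regions), function(i) {
    nrow(scan_pwm(secircuit:::.random_dna(L), p, p_threshold = thr))
  }, numeric(1))
  # discrete scores make P(p < thr) <= thr; stay within 3 SE of the
  # upper bound and require a strictly positive rate
  expected <- 2 * (L - w + 1) * thr
  se3 <- 3 * sqrt(expected / n_regions)
  expect_lt(mean(hits), expected + se3)
  expect_gt(mean(hits), 0)
})

test_that("motif enrichment flags planted motifs and floors the background", {
  set.seed(53)
  tfs <- lapply(1:2, function(i) random_pwm(8, tf = paste0("TF", i),
                                            conc = 0.05))
  names(tfs) <- c("TF1", "TF2")
  cons <- vapply(tfs, function(p) {
    paste(c("A", "C", "G", "T")[apply(p$mat, 1, which.max)], collapse = "")
  }, character(1))
  fg <- vapply(1:25, function(i) {
    s <- secircuit:::.random_dna(150)
    substr(s, 30, 37) <- cons[["TF1"]]   # plant TF1 only
    s
  }, character(1))
  res <- motif_enrichment(fg, tfs, n_background_per_fg = 10)
  expect_equal(res$tf[1], "TF1")
  expect_lt(res$q_value[res$tf == "TF1"], 0.05)
  expect_gte(min(res$bg_fraction + res$p_value), 0)  # defined everywhere
  expect_error(motif_enrichment(character(0), tfs), "empty")
})

test_that("TF-target verdicts follow the two evidence rules", {
  set.seed(61)
  p <- random_pwm(8, conc = 0.05)
  cons <- paste(c("A", "C", "G", "T")[apply(p$mat, 1, which.max)],
                collapse = "")
  s2 <- secircuit:::.random_dna(200)
  substr(s2, 10, 17) <- cons
  substr(s2, 100, 107) <- cons
  expect_equal(tf_target_pairs(p, c(r1 = s2))$verdict, "accepted")
  s1 <- secircuit:::.random_dna(200)
  substr(s1, 10, 17) <- cons
  v1 <- tf_target_pairs(p, c(r1 = s1))
  expect_equal(v1$verdict, "rejected")     # one hit only, no ChIP
  expect_equal(v1$n_motif_hits, 1L)
  # two single-hit regions pool across regions by default ...
  expect_equal(tf_target_pairs(p, c(r1 = s1, r2 = s1))$verdict, "accepted")
  # ... but not when per_region is requested
  expect_equal(tf_target_pairs(p, c(r1 = s1, r2 = s1),
                               per_region = TRUE)$verdict, "rejected")
  # rule 2: a 1-bp ChIP overlap rescues a motif-free pair
  regions <- data.frame(region_id = "r", se_id = "se", chrom = "chr1",
                        start = 100L, end = 200L)
  chip <- iv("chr1", 199, 300)
  v2 <- tf_target_pairs(NULL, character(0), regions, chip)
  expect_equal(v2$verdict, "accepted")
  expect_equal(v2$rule, "chip")
  chip_out <- iv("chr1", 200, 300)
  expect_equal(tf_target_pairs(NULL, character(0), regions,
                               chip_out)$verdict, "rejected")
  expect_equal(tf_target_pairs()$verdict, "untestable")
})

test_that("CRC cliques require every edge including self-loops", {
  tfs <- c("A", "B", "C", "D")
  full <- expand.grid(from = c("A", "B", "C"), to = c("A", "B", "C"),
                      stringsAsFactors = FALSE)
  crc <- build_crc(tfs, full)
  expect_equal(crc$crcs[[1]], c("A", "B", "C"))
  # dropping one self-loop drops that TF from the clique
  no_self <- full[!(full$from == "C" & full$to == "C"), ]
  crc2 <- build_crc(tfs, no_self)
  expect_equal(crc2$crcs[[1]], c("A", "B"))
  # dropping one direction of a pair also breaks the clique
  no_dir <- full[!(full$from == "A" & full$to == "B"), ]
  crc3 <- build_crc(tfs, no_dir)
  expect_false(any(vapply(crc3$crcs, function(x) {
    all(c("A", "B") %in% x)
  }, logical(1))))
  # node order does not matter
  crc4 <- build_crc(rev(tfs), full[sample(nrow(full)), ])
  expect_equal(crc4$crcs, crc$crcs)
})
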