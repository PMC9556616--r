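# Variant overlap, Fisher enrichment, k-mer allele scores and the
# directional filter.

variants_df <- function(pos, p, chrom = "chr1", beta = 0.1) {
  data.frame(variant_id = sprintf("v%d", seq_along(pos)), chrom = chrom,
             pos = as.integer(pos), ref_allele = "A", alt_allele = "G",
             beta = beta, pvalue = p, stringsAsFactors = FALSE)
}

test_that("variant overlap uses half-open intervals and inclusive 5e-8", {
  regions <- iv("chr1", 100, 200)
  v <- variants_df(c(100, 150, 200, 99), c(1e-9, 5e-8, 1e-10, 0.5))
  out <- overlap_significant_variants(v, regions)
  expect_equal(out$in_region, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(out$significant, c(TRUE, TRUE, TRUE, FALSE))
})

test_that("Fisher enrichment reproduces the closed-form odds ratio", {
  flags <- data.frame(
    significant = rep(c(TRUE, TRUE, FALSE, FALSE), c(5, 95, 10, 890)),
    in_region = rep(c(TRUE, FALSE, TRUE, FALSE), c(5, 95, 10, 890)))
  res <- fisher_enrichment(flags)
  expect_equal(res$odds_ratio, (5 * 890) / (95 * 10))
  expect_equal(res$p_value, oracle_fisher_p(5, 95, 10, 890),
               tolerance = 1e-9)
  expect_true(res$ci_lower < res$odds_ratio & res$odds_ratio < res$ci_upper)
  # swapping the two classifications inverts the OR, keeps the p
  flags2 <- flags
  flags2$significant <- flags$in_region
  flags2$in_region <- flags$significant
  res2 <- fisher_enrichment(flags2)
  expect_equal(res2$p_value, res$p_value, tolerance = 1e-12)
  expect_equal(res2$odds_ratio, res$odds_ratio)
  # row swap inverts the OR
  flags3 <- flags
  flags3$significant <- !flags$significant
  res3 <- fisher_enrichment(flags3)
  expect_equal(res3$odds_ratio, 1 / res$odds_ratio, tolerance = 1e-12)
  expect_equal(res3$p_value, res$p_value, tolerance = 1e-12)
  # zero margin is an error
  flags0 <- data.frame(significant = c(TRUE, TRUE),
                       in_region = c(TRUE, FALSE))
  expect_error(fisher_enrichment(flags0), "margin")
})

test_that("independent null tables give odds ratios near one", {
  set.seed(3)
  ors <- replicate(50, {
    flags <- data.frame(significant = runif(800) < 0.2,
                        in_region = runif(800) < 0.3)
    fisher_enrichment(flags)$odds_ratio
  })
  expect_lt(abs(mean(log(ors))), 0.1)
})

test_that("delta score reproduces the hand-enumerated 2-mer case", {
  w <- c(AA = 1, AC = -1)
  eff <- delta_kmer_score("AAA", "ACA", w)
  # ref: AA + AA = 2; alt: AC (present) + CA (absent both strands) = -1
  expect_equal(eff$ref_score, 2)
  expect_equal(eff$alt_score, -1)
  expect_equal(eff$delta, -3)
  expect_equal(eff$status_change, "bound>unbound")
})

test_that("degenerate and unsupported variants are handled", {
  w <- c(AA = 1)
  same <- delta_kmer_score("AAA", "AAA", w)
  expect_equal(same$delta, 0)
  expect_equal(same$status_change, "none")
  indel <- delta_kmer_score("AAA", "AAAA", w)
  expect_equal(indel$status_change, "unsupported")
  off_center <- delta_kmer_score("AAA", "CAA", w)  # difference not centered
  expect_equal(off_center$status_change, "unsupported")
  expect_error(delta_kmer_score("AAAA", "AAGA", w), "2k-1")
})

test_that("delta is antisymmetric and linear over canonical weights", {
  set.seed(19)
  k <- 4
  for (rep in 1:50) {
    win_ref <- secircuit:::.random_dna(2 * k - 1)
    alt <- sample(setdiff(c("A", "C", "G", "T"),
                          substr(win_ref, k, k)), 1)
    win_alt <- win_ref
    substr(win_alt, k, k) <- alt
    starts <- seq_len(k)
    kmers <- unique(c(substring(win_ref, starts, starts + k - 1),
                      substring(win_alt, starts, starts + k - 1)))
    canon <- unique(pmin(kmers, revcomp(kmers)))
    w1 <- setNames(rnorm(length(canon)), canon)
    w2 <- setNames(rnorm(length(canon)), canon)
    d1 <- delta_kmer_score(win_ref, win_alt, w1)$delta
    # allele swap negates
    expect_equal(delta_kmer_score(win_alt, win_ref, w1)$delta, -d1)
    # linearity over a shared canonical support
    d2 <- delta_kmer_score(win_ref, win_alt, w2)$delta
    d12 <- delta_kmer_score(win_ref, win_alt, w1 + w2)$delta
    expect_equal(d12, d1 + d2, tolerance = 1e-9)
    expect_equal(delta_kmer_score(win_ref, win_alt, 3 * w1)$delta, 3 * d1,
                 tolerance = 1e-9)
    # exactly k covering k-mers contribute per allele
    ones <- setNames(rep(1, length(canon)), canon)
    expect_equal(delta_kmer_score(win_ref, win_alt, ones)$ref_score, k)
  }
})

test_that("the directional filter multiplies the three signs", {
  up <- list(delta = 2, status_change = "unbound>bound", supported = TRUE)
  expect_equal(directional_filter(up, beta = 0.3, 1)$verdict, "keep")
  expect_equal(directional_filter(up, beta = 0.3, -1)$verdict, "drop")
  expect_equal(directional_filter(up, beta = -0.3, -1)$verdict, "keep")
  # disrupted binding of a repressor with a positive trait effect is kept
  down <- list(delta = -1.4, status_change = "bound>unbound",
               supported = TRUE)
  expect_equal(directional_filter(down, beta = 0.2, -1)$verdict, "keep")
  expect_equal(directional_filter(down, beta = 0.2, 1)$verdict, "drop")
  # zero signs or no status change are untestable
  none <- list(delta = 0.5, status_change = "none", supported = TRUE)
  expect_equal(directional_filter(none, 0.2, 1)$verdict, "untestable")
  expect_equal(directional_filter(up, 0, 1)$verdict, "untestable")
})

test_that("a null GWAS panel shows no systematic enrichment", {
  fr <- iv("chr1", seq(1e5, 1e6, 1e5), seq(1e5, 1e6, 1e5) + 600)
  cfg <- small_config(seed = 1,
                      frac_significant_in_functional = 0.05,
                      background_sig_rate = 0.05)
  set.seed(99)
  log_ors <- replicate(20, {
    panel <- plant_gwas_panel(fr, cfg)
    flags <- overlap_significant_variants(panel, fr)
    log(fisher_enrichment(flags)$odds_ratio)
  })
  expect_lt(abs(mean(log_ors)), 0.25)
})
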