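# Functional regions, activity-by-contact scoring, target assignment and
# expression contrasts.

test_that("functional regions are accessibility peaks clipped to the SE", {
  ses <- data.frame(id = "se1", chrom = "chr1", start = 500L, end = 5000L)
  acc <- iv("chr1", c(1000, 400, 4990, 8000), c(1600, 700, 5600, 9000))
  fr <- suppressMessages(define_functional_regions(ses, acc))
  # inside peak kept, straddling peak clipped, 10-bp fragment dropped,
  # outside peak ignored
  expect_equal(fr$start, c(500L, 1000L))
  expect_equal(fr$end, c(700L, 1600L))
  expect_true(all(fr$se_id == "se1"))
  expect_message(
    define_functional_regions(
      data.frame(id = "se2", chrom = "chr2", start = 0L, end = 100L), acc),
    "without accessible")
  expect_error(define_functional_regions(ses, NULL), "missing")
})

test_that("ABC scores follow the gamma = 1 distance algebra", {
  tss <- data.frame(gene_id = "g", gene_name = "g",
                    gene_type = "protein_coding", chrom = "chr1",
                    tss_position = 1000000L, strand = "+")
  el <- data.frame(region_id = c("e1", "e2"), chrom = "chr1",
                   start = c(1000000L + 20000L - 250L,
                             1000000L + 40000L - 250L),
                   end = c(1000000L + 20000L + 250L,
                           1000000L + 40000L + 250L),
                   dnase_signal = 4, h3k27ac_signal = 9)
  # equal activities at distances d and 2d with a zero-activity promoter
  links <- abc_score_links(el, tss)
  got <- links$abc_score[match(c("e1", "e2"), links$element_id)]
  expect_equal(got, c(2 / 3, 1 / 3), tolerance = 1e-12)
  # single candidate element normalizes to 1
  links1 <- abc_score_links(el[1, ], tss)
  expect_equal(links1$abc_score[links1$element_id == "e1"], 1.0)
  expect_error(abc_score_links(el, tss, gamma = -1), "gamma")
})

test_that("per-gene ABC scores always sum to one", {
  set.seed(13)
  for (rep in 1:20) {
    n_el <- sample(2:30, 1)
    pos <- sort(sample.int(4e6, n_el))
    el <- data.frame(region_id = sprintf("e%02d", seq_len(n_el)),
                     chrom = "chr1", start = pos, end = pos + 500L,
                     dnase_signal = runif(n_el, 0, 50),
                     h3k27ac_signal = runif(n_el, 0, 50))
    tss <- data.frame(gene_id = sprintf("g%d", 1:3), gene_name = "x",
                      gene_type = "protein_coding", chrom = "chr1",
                      tss_position = sample.int(4e6, 3), strand = "+")
    prom <- data.frame(gene_id = tss$gene_id,
                       dnase_signal = runif(3, 1, 20),
                       h3k27ac_signal = runif(3, 1, 20))
    links <- abc_score_links(el, tss, prom)
    sums <- tapply(links$abc_score, links$gene_id, sum)
    expect_true(all(abs(sums - 1) < 1e-9))
    expect_true(all(links$abc_score >= 0 & links$abc_score <= 1))
    # rescaling every activity leaves scores unchanged
    el2 <- el
    el2$dnase_signal <- el$dnase_signal * 3.7
    el2$h3k27ac_signal <- el$h3k27ac_signal * 3.7
    prom2 <- prom
    prom2$dnase_signal <- prom$dnase_signal * 3.7
    prom2$h3k27ac_signal <- prom$h3k27ac_signal * 3.7
    links2 <- abc_score_links(el2, tss, prom2)
    expect_equal(links2$abc_score, links$abc_score, tolerance = 1e-12)
  }
})

test_that("with equal activities the score decays beyond the distance floor", {
  tss <- data.frame(gene_id = "g", gene_name = "g",
                    gene_type = "protein_coding", chrom = "chr1",
                    tss_position = 0L, strand = "+")
  d <- c(2000, 4000, 6000, 2e4, 1e5, 1e6)
  el <- data.frame(region_id = sprintf("e%d", seq_along(d)), chrom = "chr1",
                   start = as.integer(d - 50), end = as.integer(d + 50),
                   dnase_signal = 4, h3k27ac_signal = 4)
  links <- abc_score_links(el, tss)
  sc <- links$abc_score[match(sprintf("e%d", seq_along(d)), links$element_id)]
  expect_equal(sc[1], sc[2])              # both under the 5 kb floor
  expect_true(all(diff(sc[3:6]) < 0))     # strictly decreasing beyond it
})

test_that("target assignment is strict at the threshold and unions regions", {
  regions <- data.frame(region_id = c("r1", "r2"), se_id = "se1",
                        chrom = "chr1", start = c(0L, 1000L),
                        end = c(500L, 1500L))
  links <- data.frame(element_id = c("r1", "r1", "r2", "r2"),
                      gene_id = c("g1", "g2", "g1", "g3"),
                      distance = 1, activity = 1, contact = 1,
                      abc_score = c(0.5, 0.020, 0.021, 0.4),
                      is_promoter = FALSE)
  t <- assign_se_targets(links, regions)
  expect_equal(sort(unique(t$gene_id)), c("g1", "g3"))  # 0.020 excluded
  expect_equal(nrow(t[t$gene_id == "g1", ]), 1)          # union, not double
  expect_equal(t$max_score[t$gene_id == "g1"], 0.5)
})

test_that("expression contrast behaves at the null and rejects n = 1", {
  sm <- data.frame(sample = c("a1", "a2", "o1", "o2"),
                   cell_type = rep(c("adipocyte", "osteoblast"), each = 2))
  ex <- matrix(rep(c(5, 5, 5, 5), each = 10), 10, 4,
               dimnames = list(sprintf("g%d", 1:10), sm$sample))
  res <- expression_contrast(rownames(ex), ex, sm, "adipocyte", "osteoblast")
  expect_equal(res$median_shift, 0)
  # the normal approximation with continuity correction sits just
  # below 1 on an all-tied null
  expect_gt(res$p_value, 0.9)
  expect_error(expression_contrast("g1", ex, sm, "adipocyte", "osteoblast"),
               ">= 2 genes")
  # a strong planted shift is detected
  ex2 <- ex
  ex2[, c("a1", "a2")] <- ex2[, c("a1", "a2")] * rep(runif(10, 2.5, 3.5), 2)
  res2 <- expression_contrast(rownames(ex2), ex2, sm, "adipocyte",
                              "osteoblast")
  expect_lt(res2$p_value, 0.01)
  expect_gt(res2$median_shift, 0)
})
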