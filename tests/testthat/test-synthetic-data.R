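# The generator: determinism, manifest/file consistency, planted
# patterns and the planting helpers.

test_that("identical config and seed give byte-identical datasets", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_dataset(simulate_dataset(small_config(seed = 4)), d1)
  write_dataset(simulate_dataset(small_config(seed = 4)), d2)
  f1 <- sort(list.files(d1))
  expect_equal(f1, sort(list.files(d2)))
  for (f in f1) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  # a different seed changes the data
  d3 <- withr::local_tempdir()
  write_dataset(simulate_dataset(small_config(seed = 5)), d3)
  expect_false(identical(readLines(file.path(d1, "gwas_summary.tsv")),
                         readLines(file.path(d3, "gwas_summary.tsv"))))
})

test_that("zero selective fractions plant no selective loci", {
  ds <- simulate_dataset(small_config(seed = 2, frac_selective_adipo = 0,
                                      frac_selective_osteo = 0,
                                      n_tfs_in_crc = 0L,
                                      n_causal_variants = 0L))
  expect_equal(sum(ds$truth$loci$selective != "none"), 0)
  expect_equal(nrow(ds$truth$links), 0)
})

test_that("infeasible placements are rejected at configuration", {
  expect_error(sim_config(n_enhancer_loci = 5000, chrom_length = 1e6),
               "infeasible")
  expect_error(simulate_dataset(sim_config(n_enhancer_loci = 178,
                                           frac_selective_adipo = 0.45,
                                           frac_selective_osteo = 0.45)),
               "infeasible")
})

test_that("the manifest is consistent with the emitted files", {
  ds <- simulate_dataset(small_config(seed = 6))
  loci <- ds$truth$loci
  # every planted locus interval is covered by peaks of at least one
  # sample (within the boundary jitter)
  all_peaks <- do.call(rbind, ds$peaks)
  for (i in seq_len(nrow(loci))) {
    hit <- any(all_peaks$chrom == loci$chrom[i] &
               all_peaks$start < loci$end[i] &
               all_peaks$end > loci$start[i])
    expect_true(hit, label = loci$locus_id[i])
  }
  # every true link's element is within 5 Mb of its gene's TSS
  links <- ds$truth$links
  g <- ds$genes[match(links$gene_id, ds$genes$gene_id), ]
  l <- loci[match(links$locus_id, loci$locus_id), ]
  expect_true(all(g$chrom == l$chrom))
  expect_true(all(abs((l$start + l$end) / 2 - g$tss) <= 5e6))
  # functional regions sit inside their parent locus
  fr <- ds$truth$functional_regions
  l2 <- loci[match(fr$locus_id, loci$locus_id), ]
  expect_true(all(fr$start >= l2$start & fr$end <= l2$end))
  # selective signals respect the planted minimum fold
  sel <- which(loci$selective != "none")
  own <- loci$selective[sel]
  other <- ifelse(own == "adipocyte", "osteoblast", "adipocyte")
  B <- ds$truth$signals
  folds <- B[cbind(loci$locus_id[sel], own)] /
    B[cbind(loci$locus_id[sel], other)]
  expect_true(all(folds >= ds$config$selective_fold))
})

test_that("planted motif sites realize the full adjacency at scan level", {
  ds <- simulate_dataset(small_config(seed = 8))
  crc <- ds$truth$crc
  fr <- ds$truth$functional_regions
  expect_equal(nrow(crc$adjacency), length(crc$tfs)^2)
  for (e in seq_len(nrow(crc$adjacency))) {
    u <- crc$adjacency$from[e]
    v <- crc$adjacency$to[e]
    locus_v <- ds$truth$links$locus_id[ds$truth$links$gene_name == v]
    regs <- fr$region_id[fr$locus_id == locus_v]
    hits <- sum(vapply(regs, function(r) {
      nrow(scan_pwm(ds$region_sequences[[r]], ds$pwms[[u]], 1e-4))
    }, numeric(1)))
    expect_gte(hits, 2)
  }
})

test_that("empty adjacency plants nothing and leaves background rates", {
  seqs <- setNames(vapply(1:30, function(i) secircuit:::.random_dna(400),
                          character(1)), sprintf("r%02d", 1:30))
  p <- make_pwm(matrix(c(rep(c(0.85, 0.05, 0.05, 0.05), 8)), 8, 4,
                       byrow = TRUE), "TFX")
  out <- plant_motif_sites(seqs, list(TFX = p),
                           data.frame(from = character(),
                                      to = character()),
                           list())
  expect_identical(out$sequences, seqs)
  expect_equal(nrow(out$sites), 0)
  # hit rate on unplanted sequence is binomial-background small
  hits <- sum(vapply(seqs, function(s) nrow(scan_pwm(s, p, 1e-3)),
                     numeric(1)))
  n_windows <- 2 * sum(nchar(seqs) - 8 + 1)
  expect_lt(hits, n_windows * 1e-3 + 3 * sqrt(n_windows * 1e-3) + 3)
})

test_that("causal variants are planted with verifiable binding changes", {
  ds <- simulate_dataset(small_config(seed = 9))
  cv <- ds$truth$causal_variants
  expect_gt(nrow(cv), 0)
  for (i in seq_len(nrow(cv))) {
    eff <- delta_kmer_score(cv$ref_window[i], cv$alt_window[i],
                            ds$kmer_weights[[cv$tf[i]]])
    expect_equal(eff$delta, cv$delta[i])
    expect_true(eff$status_change %in% c("unbound>bound", "bound>unbound"))
    # the panel carries the planted alleles and effect sizes
    gw <- ds$gwas[ds$gwas$variant_id == cv$variant_id[i], ]
    expect_equal(gw$beta, cv$beta[i])
    expect_equal(gw$alt_allele, cv$alt_allele[i])
  }
  # labels split into consistent and a planted-inconsistent minority
  expect_true(all(cv$label %in% c("consistent", "inconsistent")))
  expect_gt(sum(cv$label == "consistent"), 0)
})

test_that("significant variants are denser inside functional regions", {
  ds <- simulate_dataset(small_config(seed = 10))
  gw <- ds$gwas
  rate_in <- mean(gw$pvalue[gw$truth_in_region] <= 5e-8)
  rate_out <- mean(gw$pvalue[!gw$truth_in_region] <= 5e-8)
  expect_gt(rate_in, rate_out)
  expect_true(all(gw$pvalue[gw$truth_significant] <= 5e-8))
  expect_true(all(gw$pvalue[!gw$truth_significant] > 5e-8))
})
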