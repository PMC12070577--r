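test_that("the read generator is deterministic and respects invariants", {
  cfg <- sim_config(n_genes = 50, n_mito_genes = 3, seed = 21)
  a <- simulate_polya_reads(cfg)
  b <- simulate_polya_reads(cfg)
  expect_identical(a$reads, b$reads)
  expect_identical(a$truth, b$truth)

  r <- a$reads
  expect_true(all(r$polya_length >= 1))
  expect_true(all(r$read_length >= 1))
  expect_false(anyDuplicated(paste(r$sample_id, r$read_id)) > 0)
  expect_true(all(nzchar(r$batch)) && all(nzchar(r$condition)))
  expect_setequal(unique(r$condition), c("bacterial", "viral"))
})

test_that("truth tables track injected differential polyadenylation", {
  cfg0 <- sim_config(n_genes = 30, dp_genes = NULL, seed = 4)
  expect_equal(sum(simulate_polya_reads(cfg0)$truth$is_dp), 0)

  dp <- tibble::tibble(gene_id = c("GENE0001", "GENE0007"),
                       delta_log2 = c(1, -0.8))
  cfg1 <- sim_config(n_genes = 30, dp_genes = dp, seed = 4)
  tr <- simulate_polya_reads(cfg1)$truth
  expect_setequal(tr$gene_id[tr$is_dp], dp$gene_id)
  expect_equal(unname(tr$true_median_viral[tr$gene_id == "GENE0001"] /
                        tr$true_median_bacterial[tr$gene_id == "GENE0001"]), 2)

  bad <- sim_config(n_genes = 30,
                    dp_genes = tibble::tibble(gene_id = "GENE9999",
                                              delta_log2 = 1),
                    seed = 4)
  expect_error(simulate_polya_reads(bad), class = "polyatails_config_error")
})

test_that("per-gene median tails are calibrated to the 83 nt target", {
  cfg <- sim_config(n_genes = 2000, n_mito_genes = 0,
                    reads_per_gene_mean = 50, seed = 31)
  sim <- simulate_polya_reads(cfg)
  med <- summarize_gene_polya(sim$reads)
  expect_equal(mean(med$median_polya), 83, tolerance = 3 / 83)
})

test_that("noiseless perfectly correlated platforms agree exactly", {
  cfg <- sim_config(n_genes = 200, platform_corr_target = 1,
                    length_bias_coeff = 0, gc_bias_coeff = 0, seed = 5)
  cm <- simulate_count_matrices(cfg, poisson = FALSE)
  r <- correlate_samples(cm$a, cm$b, scale = "raw")
  expect_true(all(abs(r$r - 1) < 1e-12))
})

test_that("a null length-bias configuration shows no length trend", {
  slopes_p <- vapply(1:20, function(i) {
    cfg <- sim_config(n_genes = 800, length_bias_coeff = 0, seed = 1000 + i)
    cm <- simulate_count_matrices(cfg)
    cpm <- compute_tpm(cm$a, length_normalize = FALSE)
    bias_regression(cpm, cm$truth, "log10_length")$p_value
  }, numeric(1))
  expect_gte(mean(slopes_p > 0.05), 0.9)
})

test_that("isoform counts follow the configured proportions", {
  # no DTU: both conditions share the truth proportions
  cfg0 <- sim_config(n_genes = 20, dtu_genes = NULL, seed = 6)
  tr0 <- simulate_isoform_counts(cfg0)$truth
  expect_identical(tr0$prop_bacterial, tr0$prop_viral)

  # near-infinite precision: per-sample proportions concentrate
  cfg1 <- sim_config(n_genes = 10, dm_precision = 1e6,
                     iso_total_mean = 2000, seed = 7)
  iso1 <- simulate_isoform_counts(cfg1)
  m <- as.matrix(iso1$counts[, -1])
  rownames(m) <- iso1$counts$feature_id
  g1 <- m[1:3, ]
  props <- sweep(g1, 2, colSums(g1), "/")
  expect_lt(max(abs(props - iso1$truth$prop_bacterial[[1]])), 0.05)

  # configured proportion difference is recovered on average
  dtu <- tibble::tibble(gene_id = "GENE0001",
                        prop_bacterial = list(c(0.8, 0.1, 0.1)),
                        prop_viral = list(c(0.1, 0.8, 0.1)))
  cfg2 <- sim_config(n_genes = 5, dtu_genes = dtu, iso_total_mean = 500,
                     dm_precision = 50, seed = 8)
  iso2 <- simulate_isoform_counts(cfg2)
  m2 <- as.matrix(iso2$counts[, -1])
  rownames(m2) <- iso2$counts$feature_id
  t1 <- m2["GENE0001.t1", ]
  tot <- colSums(m2[1:3, ])
  p1 <- t1 / tot
  cond <- iso2$metadata$condition[match(colnames(m2),
                                        iso2$metadata$sample_id)]
  diff <- mean(p1[cond == "bacterial"]) - mean(p1[cond == "viral"])
  expect_equal(diff, 0.7, tolerance = 0.05 / 0.7)
})
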