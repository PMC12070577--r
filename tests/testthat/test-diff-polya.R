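test_that("single-batch fits reduce to the pooled two-sample t-test", {
  set.seed(41)
  for (i in 1:25) {
    nb <- sample(8:20, 1); nv <- sample(8:20, 1)
    tails_b <- 2^rnorm(nb, 6, 0.5)
    tails_v <- 2^rnorm(nv, 6.4, 0.5)
    reads <- dplyr::bind_rows(
      make_reads(tails_b, rep("bacterial", nb), sample_id = "S1",
                 batch = "b1"),
      make_reads(tails_v, rep("viral", nv), sample_id = "S2", batch = "b1")
    )
    fit <- fit_gene_lmm(reads, min_reads = 5)
    ref <- oracle_pooled_t(log2(tails_b), log2(tails_v))
    expect_equal(fit$method, "ols")
    expect_equal(fit$log2fc, ref$estimate, tolerance = 1e-10)
    expect_equal(fit$se, ref$se, tolerance = 1e-10)
    expect_equal(fit$df, ref$df)
    expect_equal(fit$p_value, ref$p, tolerance = 1e-10)
  }
})

test_that("an exact twofold tail shift yields log2FC of exactly one", {
  base <- c(40, 50, 60, 70, 80, 90, 100, 110, 120, 130)
  reads <- dplyr::bind_rows(
    make_reads(base, rep("bacterial", 10), sample_id = "S1", batch = "b1"),
    make_reads(2 * base, rep("viral", 10), sample_id = "S2", batch = "b1")
  )
  fit <- fit_gene_lmm(reads, min_reads = 5)
  expect_equal(fit$log2fc, 1, tolerance = 1e-12)
  expect_gt(fit$se, 0)
})

test_that("degenerate inputs are refused with informative conditions", {
  few <- make_reads(c(50, 60), c("bacterial", "viral"))
  expect_error(fit_gene_lmm(few, min_reads = 10),
               class = "polyatails_skip_gene")
  flat <- dplyr::bind_rows(
    make_reads(rep(64, 10), rep("bacterial", 10), sample_id = "S1",
               batch = "b1"),
    make_reads(rep(128, 10), rep("viral", 10), sample_id = "S2", batch = "b1")
  )
  # lm warns about the perfect within-group fit before our error fires
  suppressWarnings(
    expect_error(fit_gene_lmm(flat, min_reads = 5),
                 class = "polyatails_fit_error")
  )
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.04, 0.03, 0.005)),
               c(0.02, 0.04, 0.04, 0.02))
  expect_equal(bh_adjust(0.037), 0.037)
  expect_equal(bh_adjust(rep(0.2, 6)), rep(0.2, 6))
  set.seed(42)
  for (i in 1:300) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-14)
  }
})

test_that("DPG calling applies the dual cutoff with the viral-positive sign", {
  cfg <- sim_config(
    n_genes = 40, n_mito_genes = 0, reads_per_gene_mean = 400,
    dp_genes = tibble::tibble(gene_id = c("GENE0001", "GENE0002"),
                              delta_log2 = c(1.2, -1.2)),
    seed = 51
  )
  sim <- simulate_polya_reads(cfg)
  dp <- dp_test(sim$reads, min_reads = 5)
  expect_gt(dp$log2fc[dp$gene_id == "GENE0001"], 0) # longer in viral
  expect_lt(dp$log2fc[dp$gene_id == "GENE0002"], 0)
  expect_true(all(dp$p_adj >= dp$p_value))
  expect_true(all(dp$is_dpg == (dp$p_adj < 0.05 & abs(dp$log2fc) >= 0.5)))

  dp_inf <- dp_test(sim$reads, lfc_threshold = Inf, min_reads = 5)
  expect_equal(sum(dp_inf$is_dpg), 0)

  expect_error(dp_test(sim$reads, min_reads = 1e6),
               class = "polyatails_config_error")
})

test_that("genes with too few reads are skipped with a record", {
  cfg <- sim_config(n_genes = 10, n_mito_genes = 0,
                    reads_per_gene_mean = 60, seed = 52)
  sim <- simulate_polya_reads(cfg)
  few <- sim$reads[sim$reads$gene_id != "GENE0001" |
                     sim$reads$condition == "viral", ]
  dp <- dp_test(few, min_reads = 5)
  expect_true("GENE0001" %in% attr(dp, "skipped"))
  expect_false("GENE0001" %in% dp$gene_id)
})

test_that("bootstrap robustness is deterministic and seed-driven", {
  cfg <- sim_config(
    n_genes = 6, n_mito_genes = 0, reads_per_gene_mean = 240,
    dp_genes = tibble::tibble(gene_id = "GENE0001", delta_log2 = 1.5),
    seed = 53
  )
  sim <- simulate_polya_reads(cfg)
  r1 <- bootstrap_robustness(sim$reads, c("GENE0001", "GENE0002"),
                             n_boot = 10, seed = 99, min_reads = 3)
  r2 <- bootstrap_robustness(sim$reads, c("GENE0001", "GENE0002"),
                             n_boot = 10, seed = 99, min_reads = 3)
  expect_identical(r1, r2)
  expect_true(all(r1$robust_fraction >= 0 & r1$robust_fraction <= 1))
  expect_true(all(r1$n_replicates_used == 10))
  # the strong gene resists resampling, the unshifted gene does not
  expect_gt(r1$robust_fraction[1], r1$robust_fraction[2])
})
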