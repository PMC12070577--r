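counts_2x2 <- function(vals) {
  abundance_table(matrix(vals, 2, dimnames = list(c("g1", "g2"),
                                                  c("s1", "s2"))),
                  unit = "counts", level = "gene")
}

test_that("TPM follows the rate formula and CPM skips lengths", {
  ab <- abundance_table(matrix(c(30, 10), 2,
                               dimnames = list(c("g1", "g2"), "s1")),
                        unit = "counts", level = "gene")
  lens <- c(g1 = 300, g2 = 100)
  tpm <- compute_tpm(ab, lens, length_normalize = TRUE)
  expect_equal(as.numeric(as.matrix(tpm[, -1])), c(500000, 500000))
  cpm <- compute_tpm(ab, length_normalize = FALSE)
  expect_equal(as.numeric(as.matrix(cpm[, -1])), c(750000, 250000))

  eq <- abundance_table(matrix(rep(7, 4), 4,
                               dimnames = list(paste0("g", 1:4), "s1")),
                        unit = "counts", level = "gene")
  tpm_eq <- compute_tpm(eq, setNames(rep(100, 4), paste0("g", 1:4)))
  expect_true(all(as.matrix(tpm_eq[, -1]) == 1e6 / 4))

  zero <- counts_2x2(c(0, 0, 5, 5))
  expect_error(compute_tpm(zero, length_normalize = FALSE), "s1",
               class = "polyatails_config_error")
})

test_that("TPM columns always sum to one million", {
  set.seed(11)
  m <- matrix(rpois(200, 40), 20,
              dimnames = list(sprintf("g%02d", 1:20), sprintf("s%02d", 1:10)))
  ab <- abundance_table(m, unit = "counts", level = "gene")
  tpm <- compute_tpm(ab, setNames(rexp(20, 1 / 1000) + 100, rownames(m)))
  expect_equal(colSums(as.matrix(tpm[, -1])), rep(1e6, 10),
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("sample correlations are exact on identity and scale-invariant", {
  set.seed(2)
  m <- matrix(rpois(60, 30), 20,
              dimnames = list(sprintf("g%02d", 1:20), c("s1", "s2", "s3")))
  a <- abundance_table(m, unit = "counts", level = "gene")
  expect_true(all(correlate_samples(a, a)$r == 1))
  b <- abundance_table(2 * m, unit = "counts", level = "gene")
  expect_true(all(abs(correlate_samples(a, b, scale = "raw")$r - 1) < 1e-12))

  small <- counts_2x2(c(1, 2, 3, 4))
  expect_error(correlate_samples(small, small),
               class = "polyatails_config_error")
})

test_that("feature correlations drop unusable features and match brute force", {
  set.seed(3)
  m <- matrix(rpois(120, 50), 12,
              dimnames = list(sprintf("g%02d", 1:12), sprintf("s%02d", 1:10)))
  m[1, ] <- 7 # constant across samples
  m[2, ] <- 0 # below any positive threshold
  a <- abundance_table(m, unit = "counts", level = "gene")
  b <- abundance_table(m + matrix(rpois(120, 5), 12), unit = "counts",
                       level = "gene")
  res <- correlate_features(a, b, min_expression = 1)
  exc <- attr(res, "excluded")
  expect_true("g01" %in% exc$feature_id[exc$reason == "zero variance"])
  expect_true("g02" %in% exc$feature_id[exc$reason == "below min_expression"])
  expect_false(any(c("g01", "g02") %in% res$feature_id))

  empty <- correlate_features(a, b, min_expression = 1e9)
  expect_equal(nrow(empty), 0)

  # sweep counts equal a brute-force recount
  sweep_res <- correlation_sweep(a, b, thresholds = c(0, 10, 40))
  for (k in seq_len(nrow(sweep_res))) {
    thr <- sweep_res$threshold[k]
    keep <- rowMeans(m) >= thr & rowMeans(as.matrix(b[, -1])) >= thr
    la <- log2(m[keep, , drop = FALSE] + 1)
    lb <- log2(as.matrix(b[, -1])[keep, , drop = FALSE] + 1)
    ok <- apply(la, 1, sd) > 0 & apply(lb, 1, sd) > 0
    rs <- sapply(which(ok), function(i) cor(la[i, ], lb[i, ]))
    expect_equal(sweep_res$n_features[k], sum(ok))
    expect_equal(sweep_res$n_high_r[k], sum(rs >= 0.8))
  }
})

test_that("Fisher-z comparison matches the closed form", {
  eq <- fisher_z_test(0.6, 50, 0.6, 50)
  expect_equal(eq$z, 0)
  expect_equal(eq$p_value, 1)

  res <- fisher_z_test(0.9, 100, 0.8, 100)
  z_ref <- (atanh(0.9) - atanh(0.8)) / sqrt(2 / 97)
  expect_equal(res$z, z_ref, tolerance = 1e-12)
  expect_equal(res$z, 2.602, tolerance = 1e-3)
  expect_equal(res$p_value, 0.0093, tolerance = 1e-2)

  swapped <- fisher_z_test(0.8, 100, 0.9, 100)
  expect_equal(swapped$z, -res$z)
  expect_equal(swapped$p_value, res$p_value)

  expect_error(fisher_z_test(1, 50, 0.5, 50),
               class = "polyatails_config_error")
})

test_that("Jensen-Shannon divergence has its defining properties", {
  expect_equal(jensen_shannon_divergence(c(0.2, 0.8), c(0.2, 0.8)), 0)
  expect_equal(jensen_shannon_divergence(c(1, 0), c(0, 1)), 1)
  expect_equal(jensen_shannon_divergence(c(1, 0), c(0.5, 0.5)), 0.3113,
               tolerance = 1e-4)
  set.seed(4)
  for (i in 1:200) {
    p <- rgamma(5, 1); q <- rgamma(5, 1)
    j <- jensen_shannon_divergence(p, q)
    expect_equal(j, jensen_shannon_divergence(q, p))
    expect_gte(j, 0)
    expect_lte(j, 1)
    expect_lt(abs(j - oracle_jsd(p, q)), 1e-12)
  }
  expect_error(jensen_shannon_divergence(c(0, 0), c(1, 0)),
               class = "polyatails_config_error")
})

test_that("bias regression reports consistent statistics", {
  set.seed(5)
  gm <- tibble::tibble(gene_id = sprintf("g%02d", 1:30),
                       union_exon_length = round(exp(rnorm(30, 7, 1))),
                       gc_fraction = runif(30, 0.3, 0.7))
  m <- matrix(rpois(60, 100), 30, dimnames = list(gm$gene_id, c("s1", "s2")))
  ab <- abundance_table(m, unit = "counts", level = "gene")
  tpm <- compute_tpm(ab, length_normalize = FALSE)
  res <- bias_regression(tpm, gm, "gc_fraction")
  expect_equal(res$r_squared, res$pearson_r^2, tolerance = 1e-12)

  gm$gc_fraction <- 0.5
  expect_error(bias_regression(tpm, gm, "gc_fraction"), "zero-variance",
               class = "polyatails_config_error")
})

test_that("sign of an injected platform length bias is recovered", {
  signs <- vapply(1:20, function(i) {
    cfg <- sim_config(n_genes = 800, length_bias_coeff = -0.5, seed = 300 + i)
    cm <- simulate_count_matrices(cfg)
    cpm <- compute_tpm(cm$a, length_normalize = FALSE)
    sign(bias_regression(cpm, cm$truth, "log10_length")$slope)
  }, numeric(1))
  expect_gte(mean(signs == -1), 0.95)
})
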