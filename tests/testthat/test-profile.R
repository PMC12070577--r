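test_that("gene summaries report medians and condition partitions", {
  reads <- dplyr::bind_rows(
    make_reads(c(40, 50, 60), rep("bacterial", 3), gene_id = "geneA"),
    make_reads(c(80, 90), rep("viral", 2), gene_id = "geneA"),
    make_reads(100, "viral", gene_id = "geneB")
  )
  s <- summarize_gene_polya(reads)
  a <- s[s$gene_id == "geneA", ]
  expect_equal(a$median_polya, median(c(40, 50, 60, 80, 90)))
  expect_equal(a$median_bacterial, 50)
  expect_equal(a$n_bacterial + a$n_viral, a$n_reads)
  expect_true(all(s$n_bacterial + s$n_viral == s$n_reads))

  s2 <- summarize_gene_polya(reads, min_reads = 2)
  expect_false("geneB" %in% s2$gene_id)

  none <- make_reads(NA_real_, "viral")
  expect_error(summarize_gene_polya(none), class = "polyatails_config_error")
})

test_that("tail fractions count exceedances among usable reads", {
  expect_equal(tail_fraction(make_reads(rep(45, 10), rep("viral", 10))), 0)
  reads <- make_reads(c(rep(400, 5), rep(100, 5)), rep("viral", 10))
  expect_equal(tail_fraction(reads), 0.5)
  # missing tails are not part of the denominator
  reads$polya_length[1] <- NA
  expect_equal(tail_fraction(reads), 4 / 9)
})

test_that("compartment stratification is exhaustive and disjoint", {
  gm <- tibble::tibble(gene_id = c("geneA", "geneM"),
                       is_mitochondrial = c(FALSE, TRUE))
  reads <- dplyr::bind_rows(
    make_reads(rep(45, 50), rep("viral", 50), gene_id = "geneM"),
    make_reads(c(60, 70, 80, 90), rep("bacterial", 4), gene_id = "geneA")
  )
  strat <- stratify_compartment(reads, gm)
  expect_equal(strat$n[strat$compartment == "mitochondrial"], 50L)
  expect_equal(strat$mode[strat$compartment == "mitochondrial"], 45)
  expect_equal(strat$frac_gt_70[strat$compartment == "mitochondrial"], 0)
  expect_equal(sum(strat$n), nrow(reads))

  no_mito <- stratify_compartment(reads,
                                  gm[!gm$is_mitochondrial, , drop = FALSE])
  expect_true(no_mito$empty[no_mito$compartment == "mitochondrial"])
})

test_that("simulated compartments land at their configured centres", {
  cfg <- sim_config(n_genes = 1500, n_mito_genes = 13,
                    reads_per_gene_mean = 120, seed = 17)
  sim <- simulate_polya_reads(cfg)
  strat <- stratify_compartment(sim$reads, sim$gene_models)
  expect_equal(strat$mode[strat$compartment == "mitochondrial"], 45,
               tolerance = 3 / 45)
  expect_lt(strat$frac_gt_70[strat$compartment == "mitochondrial"], 0.01)
  # Analytic density peak of the nuclear lognormal mixture:
  # exp(mu*ln2 - sigma_ln^2) with sigma^2 the total log2 variance.
  s2 <- cfg$nuclear_tail_log2_median_sd^2 + cfg$read_noise_sd^2 +
    cfg$batch_sd^2
  peak <- exp(cfg$nuclear_tail_log2_median_mean * log(2) - s2 * log(2)^2)
  expect_equal(strat$mode[strat$compartment == "nuclear"], peak,
               tolerance = 12 / peak)
})

test_that("per-gene medians track the simulator truth closely", {
  cfg <- sim_config(n_genes = 300, n_mito_genes = 0,
                    reads_per_gene_mean = 2400,
                    read_noise_sd = 0.1, batch_sd = 0, seed = 23)
  sim <- simulate_polya_reads(cfg)
  s <- summarize_gene_polya(sim$reads)
  tr <- sim$truth
  overall_med <- (tr$true_median_bacterial[match(s$gene_id, tr$gene_id)])
  frac_close <- mean(abs(s$median_polya - overall_med) <= 2)
  expect_gte(frac_close, 0.95)
})

test_that("gene ranking is deterministic, tie-stable and order-invariant", {
  s <- tibble::tibble(gene_id = c("gene1", "gene2", "gene3"),
                      median_polya = c(10, 20, 30))
  r <- rank_genes(s)
  expect_equal(r$gene_id, c("gene3", "gene2", "gene1"))
  expect_true(all(diff(r$score) <= 0))

  tied <- tibble::tibble(gene_id = c("geneB", "geneA"),
                         median_polya = c(15, 15))
  expect_equal(rank_genes(tied)$gene_id, c("geneA", "geneB"))

  perm <- s[c(2, 3, 1), ]
  expect_identical(rank_genes(perm), r)
})
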