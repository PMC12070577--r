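make_tx_counts <- function(m, genes_per = 2) {
  abundance_table(m, unit = "counts", level = "transcript")
}

test_that("the expression filter reproduces its definition on a toy matrix", {
  # gene A passes everything; gene B fails the gene-total rule
  a1 <- rep(20, 12); a2 <- rep(15, 12)
  b1 <- rep(2, 12); b2 <- rep(3, 12)
  m <- rbind(A.t1 = a1, A.t2 = a2, B.t1 = b1, B.t2 = b2)
  colnames(m) <- sprintf("S%02d", 1:12)
  t2g <- tibble::tibble(transcript_id = rownames(m),
                        gene_id = rep(c("A", "B"), each = 2))
  kept <- filter_counts(make_tx_counts(m), t2g)
  expect_setequal(kept$feature_id, c("A.t1", "A.t2"))
  expect_setequal(kept$feature_id,
                  oracle_filter(m, rep(c("A", "B"), each = 2), 12, 4, 10, 10))

  zeros <- m * 0
  expect_warning(empty <- filter_counts(make_tx_counts(zeros), t2g),
                 "no transcript")
  expect_equal(nrow(empty), 0)

  # thresholds of zero only remove single-transcript genes
  m2 <- rbind(m, C.t1 = rep(50, 12))
  t2g2 <- dplyr::bind_rows(t2g, tibble::tibble(transcript_id = "C.t1",
                                               gene_id = "C"))
  loose <- filter_counts(make_tx_counts(m2), t2g2,
                         min_samps_gene_expr = 0, min_samps_feature_expr = 0,
                         min_gene_expr = 0, min_feature_expr = 0)
  expect_setequal(loose$feature_id, rownames(m))

  expect_error(filter_counts(make_tx_counts(m),
                             t2g[t2g$transcript_id != "A.t1", ]),
               class = "polyatails_format_error")
})

test_that("the filter agrees with brute force on random matrices", {
  set.seed(71)
  for (i in 1:30) {
    n_genes <- sample(3:8, 1)
    k <- sample(2:4, 1)
    n_s <- 12
    gene_of <- rep(sprintf("G%d", 1:n_genes), each = k)
    m <- matrix(rnbinom(n_genes * k * n_s, mu = 12, size = 1),
                n_genes * k, n_s)
    rownames(m) <- sprintf("%s.t%d", gene_of, rep(1:k, n_genes))
    colnames(m) <- sprintf("S%02d", 1:n_s)
    t2g <- tibble::tibble(transcript_id = rownames(m), gene_id = gene_of)
    got <- suppressWarnings(
      filter_counts(make_tx_counts(m), t2g,
                    min_samps_gene_expr = 9, min_samps_feature_expr = 4,
                    min_gene_expr = 10, min_feature_expr = 10))
    expect_setequal(got$feature_id,
                    oracle_filter(m, gene_of, 9, 4, 10, 10))
  }
})

test_that("identical conditions give a null likelihood ratio", {
  x <- matrix(rep(c(30, 10, 5), 12), 3, 12)
  rownames(x) <- paste0("t", 1:3)
  res <- dm_gene_test(x, rep(c("bacterial", "viral"), each = 6))
  expect_lt(res$lr_stat, 1e-4)
  expect_gt(res$p_gene, 0.999)
  expect_equal(res$df, 2L)
})

test_that("the DM test approaches the multinomial LRT at huge precision", {
  set.seed(72)
  cond <- rep(c("bacterial", "viral"), each = 6)
  p_b <- c(0.6, 0.3, 0.1); p_v <- c(0.3, 0.5, 0.2)
  x <- sapply(seq_along(cond), function(j) {
    rmultinom(1, 400, if (cond[j] == "bacterial") p_b else p_v)
  })
  rownames(x) <- paste0("t", 1:3)
  dm <- dm_gene_test(x, cond, precision = 1e6)
  ref <- oracle_multinomial_lrt(x, cond)
  expect_equal(dm$lr_stat, ref, tolerance = 0.01)
})

test_that("per-transcript tests collapse consistently", {
  set.seed(73)
  cond <- rep(c("bacterial", "viral"), each = 6)
  # K = 2: both transcript tests equal the gene test
  x2 <- sapply(seq_along(cond), function(j) {
    rmultinom(1, 200, if (cond[j] == "bacterial") c(0.7, 0.3) else c(0.4, 0.6))
  })
  rownames(x2) <- c("tA", "tB")
  g <- dm_gene_test(x2, cond)
  t2 <- dm_transcript_tests(x2, cond)
  expect_equal(t2$p_tx, rep(g$p_gene, 2), tolerance = 1e-6)

  # permuting transcript order permutes outputs
  x3 <- rbind(x2, tC = rpois(12, 40))
  t3 <- dm_transcript_tests(x3, cond)
  t3p <- dm_transcript_tests(x3[c(3, 1, 2), ], cond)
  expect_equal(t3p$p_tx[match(t3$transcript_id, t3p$transcript_id)],
               t3$p_tx, tolerance = 1e-8)
})

test_that("stage-wise adjustment follows the screen-confirm rule", {
  gene <- tibble::tibble(gene_id = "G1", p_gene = 0.001)
  tx <- tibble::tibble(gene_id = "G1", transcript_id = c("t1", "t2"),
                       p_tx = c(0.01, 0.5))
  sw <- stagewise_adjust(gene, tx, alpha_ofdr = 0.05)
  expect_true(all(sw$screened))
  expect_equal(sw$stagewise_adj_p, c(0.01, 0.5)) # m = R = 1, Shaffer at K=2

  gene2 <- tibble::tibble(gene_id = c("G1", "G2"), p_gene = c(0.6, 0.9))
  tx2 <- tibble::tibble(gene_id = c("G1", "G2"),
                        transcript_id = c("t1", "t2"),
                        p_tx = c(0.001, 0.002))
  sw2 <- stagewise_adjust(gene2, tx2)
  expect_false(any(sw2$screened))
  expect_true(all(is.na(sw2$stagewise_adj_p)))

  expect_error(
    stagewise_adjust(gene, tibble::tibble(gene_id = "GX",
                                          transcript_id = "t",
                                          p_tx = 0.1)),
    class = "polyatails_config_error"
  )

  expect_true(all(sw$stagewise_adj_p >= sw$p_tx))
})

test_that("the full DTU path detects an injected proportion swap", {
  dtu_genes <- tibble::tibble(
    gene_id = sprintf("GENE%04d", 1:3),
    prop_bacterial = rep(list(c(0.7, 0.2, 0.1)), 3),
    prop_viral = rep(list(c(0.15, 0.2, 0.65)), 3)
  )
  cfg <- sim_config(n_genes = 30, dtu_genes = dtu_genes,
                    iso_total_mean = 400, dm_precision = 80, seed = 74)
  iso <- simulate_isoform_counts(cfg)
  res <- dtu_test(iso$counts, iso$tx2gene, iso$metadata,
                  min_samps_gene_expr = 12, min_samps_feature_expr = 4,
                  min_gene_expr = 10, min_feature_expr = 10)
  hits <- res$gene$gene_id[res$gene$screened]
  expect_true(all(dtu_genes$gene_id %in% hits))
  expect_true(all(res$gene$lr_stat >= 0))
  g <- glance(res)
  expect_equal(g$n_genes_tested, res$n_genes_tested)
})
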