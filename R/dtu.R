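# Dirichlet-multinomial log-likelihood (multinomial coefficient dropped) for
# a K x S count matrix with column totals n_j, concentration alpha = lambda*pi.
dm_loglik <- function(counts, pi, lambda) {
  alpha <- lambda * pi
  n_j <- colSums(counts)
  sum(lgamma(lambda) - lgamma(n_j + lambda)) +
    sum(lgamma(counts + alpha) - lgamma(alpha))
}

softmax0 <- function(theta) {
  e <- exp(c(0, theta) - max(0, theta))
  e / sum(e)
}

# Maximize the DM likelihood for one proportion vector shared by the given
# columns; lambda profiled jointly (or held at `fixed_lambda`). Returns
# list(pi, lambda, loglik, conv).
dm_fit_group <- function(counts, init_pi = NULL, init_loglambda = log(30),
                         fixed_lambda = NULL) {
  k <- nrow(counts)
  if (is.null(init_pi)) {
    init_pi <- (rowSums(counts) + 0.5) / sum(rowSums(counts) + 0.5)
  }
  theta0 <- pmin(pmax(log(init_pi[-1] / init_pi[1]), -20), 20)
  if (is.null(fixed_lambda)) {
    par0 <- c(theta0, init_loglambda)
    nll <- function(par) {
      pi <- softmax0(par[seq_len(k - 1)])
      -dm_loglik(counts, pi, exp(par[k]))
    }
    fit <- optim(par0, nll, method = "L-BFGS-B",
                 lower = c(rep(-30, k - 1), -10),
                 upper = c(rep(30, k - 1), 30),
                 control = list(maxit = 500))
    list(pi = softmax0(fit$par[seq_len(k - 1)]), lambda = exp(fit$par[k]),
         loglik = -fit$value, conv = fit$convergence == 0)
  } else {
    nll <- function(par) -dm_loglik(counts, softmax0(par), fixed_lambda)
    fit <- optim(theta0, nll, method = "L-BFGS-B",
                 lower = rep(-30, k - 1), upper = rep(30, k - 1),
                 control = list(maxit = 500))
    list(pi = softmax0(fit$par), lambda = fixed_lambda,
         loglik = -fit$value, conv = fit$convergence == 0)
  }
}

#' Dirichlet-multinomial gene-level test of differential transcript usage
#'
#' Likelihood-ratio test comparing a null Dirichlet-multinomial with one
#' proportion vector for all samples against an alternative with one vector
#' per condition. A common precision is profiled by maximum likelihood under
#' the null and held fixed for both hypotheses, so the likelihood ratio
#' compares proportions only and is referred to a chi-squared distribution
#' with K - 1 degrees of freedom (K transcripts).
#'
#' @param gene_counts Integer matrix, transcripts x samples, for one gene.
#' @param conditions Character vector (length = samples) of
#'   `"bacterial"`/`"viral"` labels.
#' @param precision `NULL` (default) estimates the precision by maximum
#'   likelihood; a fixed value evaluates the test at that precision (as
#'   precision grows the statistic converges to the multinomial LRT).
#' @return One-row tibble: `lr_stat`, `df`, `p_gene`, `converged`.
#' @export
dm_gene_test <- function(gene_counts, conditions, precision = NULL) {
  gene_counts <- as.matrix(gene_counts)
  conditions <- condition_factor(conditions)
  if (length(conditions) != ncol(gene_counts)) {
    stop_polyatails("conditions length must match sample columns.",
                    "polyatails_config_error")
  }
  if (nlevels(droplevels(conditions)) < 2) {
    stop_polyatails("both conditions must be represented.",
                    "polyatails_config_error")
  }
  zero <- rowSums(gene_counts) == 0
  if (any(zero)) {
    rlang::warn(sprintf("dropping %d all-zero transcript(s).", sum(zero)))
    gene_counts <- gene_counts[!zero, , drop = FALSE]
  }
  k <- nrow(gene_counts)
  if (k < 2) {
    stop_polyatails("gene needs at least 2 expressed transcripts.",
                    "polyatails_config_error")
  }
  # Common precision: profiled by maximum likelihood under the null (one
  # proportion vector), then held fixed for both hypotheses, so the LRT
  # compares proportions only (df = K - 1).
  null_fit <- dm_fit_group(gene_counts, fixed_lambda = precision)
  lambda_hat <- null_fit$lambda
  ll0 <- null_fit$loglik
  cond_b <- conditions == "bacterial"
  fit_b <- dm_fit_group(gene_counts[, cond_b, drop = FALSE],
                        init_pi = null_fit$pi, fixed_lambda = lambda_hat)
  fit_v <- dm_fit_group(gene_counts[, !cond_b, drop = FALSE],
                        init_pi = null_fit$pi, fixed_lambda = lambda_hat)
  # The fixed-precision alternative nests the null, so ll1 >= ll0.
  ll1 <- max(fit_b$loglik + fit_v$loglik, ll0)
  conv <- null_fit$conv && fit_b$conv && fit_v$conv
  lr <- max(0, 2 * (ll1 - ll0))
  tibble(
    lr_stat = lr,
    df = k - 1L,
    p_gene = if (conv) pchisq(lr, df = k - 1, lower.tail = FALSE) else NA_real_,
    converged = conv
  )
}

#' Per-transcript Dirichlet-multinomial tests
#'
#' Each transcript is tested against the aggregate of the gene's other
#' transcripts (a K = 2 collapse of the gene matrix), giving a one-degree-
#' of-freedom test per transcript.
#'
#' @inheritParams dm_gene_test
#' @return A tibble with `transcript_id`, `lr_stat`, `p_tx`, `converged`.
#' @export
dm_transcript_tests <- function(gene_counts, conditions) {
  gene_counts <- as.matrix(gene_counts)
  if (is.null(rownames(gene_counts))) {
    rownames(gene_counts) <- paste0("tx", seq_len(nrow(gene_counts)))
  }
  purrr::map_dfr(seq_len(nrow(gene_counts)), function(i) {
    collapsed <- rbind(this = gene_counts[i, ],
                       rest = colSums(gene_counts[-i, , drop = FALSE]))
    res <- dm_gene_test(collapsed, conditions)
    tibble(transcript_id = rownames(gene_counts)[i],
           lr_stat = res$lr_stat, p_tx = res$p_gene,
           converged = res$converged)
  })
}

#' DRIMSeq-style expression filter for transcript counts
#'
#' Keeps a transcript when at least `min_samps_feature_expr` samples have at
#' least `min_feature_expr` of it; keeps a gene when at least
#' `min_samps_gene_expr` samples have a gene total of at least
#' `min_gene_expr`; genes retaining fewer than two transcripts are dropped.
#'
#' @param x Transcript-level [abundance_table()] of counts.
#' @param tx2gene Tibble mapping `transcript_id` to `gene_id`.
#' @param min_samps_gene_expr,min_samps_feature_expr Sample-count thresholds
#'   (defaults 12 and 4).
#' @param min_gene_expr,min_feature_expr Expression thresholds (defaults 10
#'   and 10).
#' @return A filtered transcript-level [abundance_table()].
#' @export
filter_counts <- function(x, tx2gene,
                          min_samps_gene_expr = 12,
                          min_samps_feature_expr = 4,
                          min_gene_expr = 10,
                          min_feature_expr = 10) {
  stopifnot(inherits(x, "abundance_tbl"))
  m <- ab_matrix(x)
  gidx <- match(rownames(m), tx2gene$transcript_id)
  if (any(is.na(gidx))) {
    stop_polyatails(
      sprintf("transcript(s) without gene mapping: %s",
              paste(utils::head(rownames(m)[is.na(gidx)], 3), collapse = ", ")),
      "polyatails_format_error"
    )
  }
  gene_of <- tx2gene$gene_id[gidx]
  gene_tot <- rowsum(m, gene_of)
  gene_ok_names <- rownames(gene_tot)[
    rowSums(gene_tot >= min_gene_expr) >= min_samps_gene_expr]
  tx_ok <- rowSums(m >= min_feature_expr) >= min_samps_feature_expr
  keep <- tx_ok & gene_of %in% gene_ok_names
  surviving_gene <- gene_of[keep]
  multi <- names(which(table(surviving_gene) >= 2))
  keep <- keep & gene_of %in% multi
  if (!any(keep)) {
    rlang::warn("no transcript survives the expression filter.")
  }
  out <- m[keep, , drop = FALSE]
  abundance_table(out, unit = ab_unit(x), level = "transcript")
}

# Holm step-down with Shaffer's improvement for the sum-to-one constraint:
# a single changed transcript is impossible, so the step-i multiplier is
# max(K - i, 1) instead of K - i + 1; at K = 2 no correction is applied.
holm_shaffer <- function(p) {
  k <- length(p)
  if (k == 1) return(pmin(1, p))
  o <- order(p)
  mult <- pmax(k - seq_len(k), 1)
  adj <- cummax(pmin(1, p[o] * mult))
  out <- numeric(k)
  out[o] <- adj
  out
}

#' Stage-wise adjustment of DTU results
#'
#' Two-stage testing controlling the overall FDR: stage one screens genes by
#' BH-adjusting the gene-level p-values at `alpha_ofdr`; stage two confirms
#' transcripts within each screened gene, adjusting the transcript p-values
#' by Holm with Shaffer's improvement (no correction at two transcripts) and
#' scaling by `m/R` (genes tested over genes screened) so the confirmation
#' stage inherits the screening multiplicity.
#'
#' @param gene_results Tibble with `gene_id`, `p_gene` (one row per gene).
#' @param tx_results Tibble with `gene_id`, `transcript_id`, `p_tx`.
#' @param alpha_ofdr Target overall FDR (default 0.05).
#' @return A tibble with `gene_id`, `p_gene`, `p_gene_adj`, `screened`,
#'   `transcript_id`, `p_tx`, `stagewise_adj_p` (NA for unscreened genes).
#' @export
stagewise_adjust <- function(gene_results, tx_results, alpha_ofdr = 0.05) {
  orphan <- setdiff(tx_results$gene_id, gene_results$gene_id)
  if (length(orphan) > 0) {
    stop_polyatails("transcript rows reference genes absent from gene_results.",
                    "polyatails_config_error")
  }
  m <- sum(!is.na(gene_results$p_gene))
  gene_results$p_gene_adj <- NA_real_
  ok <- !is.na(gene_results$p_gene)
  gene_results$p_gene_adj[ok] <- bh_adjust(gene_results$p_gene[ok])
  gene_results$screened <- !is.na(gene_results$p_gene_adj) &
    gene_results$p_gene_adj < alpha_ofdr
  r <- sum(gene_results$screened)

  out <- dplyr::left_join(
    tx_results,
    gene_results[, c("gene_id", "p_gene", "p_gene_adj", "screened")],
    by = "gene_id"
  )
  out$stagewise_adj_p <- NA_real_
  if (r > 0) {
    for (g in gene_results$gene_id[gene_results$screened]) {
      idx <- which(out$gene_id == g & !is.na(out$p_tx))
      out$stagewise_adj_p[idx] <-
        pmin(1, holm_shaffer(out$p_tx[idx]) * m / r)
    }
  }
  dplyr::select(out, "gene_id", "p_gene", "p_gene_adj", "screened",
                "transcript_id", "p_tx", "stagewise_adj_p")
}

#' Differential transcript usage analysis
#'
#' End-to-end DTU: expression filtering, per-gene Dirichlet-multinomial
#' likelihood-ratio tests, per-transcript tests, and stage-wise adjustment.
#' Fractional counts (TPM-scaled quantifier outputs) are rounded to integers
#' with a warning, since the Dirichlet-multinomial likelihood needs counts.
#'
#' @inheritParams filter_counts
#' @param metadata Sample metadata tibble (`sample_id`, `batch`,
#'   `condition`).
#' @param alpha_ofdr Target overall FDR for stage-wise testing.
#' @param filter Apply [filter_counts()] first (default TRUE)?
#' @param ... Filter thresholds passed to [filter_counts()].
#' @return A list of class `dtu_result`: `gene` (per-gene tibble with
#'   `lr_stat`, `df`, `p_gene`, `p_gene_adj`, `screened`), `transcript`
#'   (stage-wise transcript tibble), `n_genes_tested`, `n_genes_screened`.
#' @export
dtu_test <- function(x, tx2gene, metadata, alpha_ofdr = 0.05,
                     filter = TRUE, ...) {
  stopifnot(inherits(x, "abundance_tbl"))
  m <- ab_matrix(x)
  if (any(m != round(m))) {
    rlang::warn("fractional counts rounded to integers for the DM likelihood.")
    m <- round(m)
    x <- abundance_table(m, unit = ab_unit(x), level = "transcript")
  }
  if (filter) x <- filter_counts(x, tx2gene, ...)
  m <- ab_matrix(x)
  samps <- colnames(m)
  cond <- metadata$condition[match(samps, metadata$sample_id)]
  if (any(is.na(cond))) {
    stop_polyatails("metadata lacks some samples in the count matrix.",
                    "polyatails_config_error")
  }
  gene_of <- tx2gene$gene_id[match(rownames(m), tx2gene$transcript_id)]
  genes <- unique(gene_of)

  gene_rows <- vector("list", length(genes))
  tx_rows <- vector("list", length(genes))
  for (i in seq_along(genes)) {
    gm <- m[gene_of == genes[i], , drop = FALSE]
    gres <- dm_gene_test(gm, cond)
    gres$gene_id <- genes[i]
    gene_rows[[i]] <- gres
    tres <- dm_transcript_tests(gm, cond)
    tres$gene_id <- genes[i]
    tx_rows[[i]] <- tres
  }
  gene_tbl <- dplyr::bind_rows(gene_rows) |>
    dplyr::select("gene_id", dplyr::everything())
  tx_tbl <- dplyr::bind_rows(tx_rows) |>
    dplyr::select("gene_id", "transcript_id", "lr_stat", "p_tx", "converged")

  sw <- stagewise_adjust(gene_tbl[, c("gene_id", "p_gene")],
                         tx_tbl[, c("gene_id", "transcript_id", "p_tx")],
                         alpha_ofdr = alpha_ofdr)
  gene_tbl <- dplyr::left_join(
    gene_tbl,
    dplyr::distinct(sw[, c("gene_id", "p_gene_adj", "screened")]),
    by = "gene_id"
  )
  out <- list(
    gene = gene_tbl,
    transcript = sw,
    n_genes_tested = nrow(gene_tbl),
    n_genes_screened = sum(gene_tbl$screened),
    alpha_ofdr = alpha_ofdr
  )
  class(out) <- "dtu_result"
  out
}

#' @export
print.dtu_result <- function(x, ...) {
  cat(sprintf(
    "DTU analysis: %d genes tested, %d screened (OFDR %.3g), %d confirmed transcript(s)\n",
    x$n_genes_tested, x$n_genes_screened, x$alpha_ofdr,
    sum(x$transcript$stagewise_adj_p < x$alpha_ofdr, na.rm = TRUE)
  ))
  invisible(x)
}
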