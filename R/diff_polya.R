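#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment (monotone, capped at 1, order-preserving relative
#' to input positions); a thin wrapper over `stats::p.adjust(method = "BH")`
#' so that every module adjusts identically.
#'
#' @param p Numeric vector of p-values.
#' @return Adjusted p-values in input order.
#' @export
bh_adjust <- function(p) {
  p.adjust(p, method = "BH")
}

#' Per-gene linear mixed model for differential polyadenylation
#'
#' Fits `log2(polya_length) ~ condition + (1 | batch)` by REML for one gene's
#' reads: the condition fixed effect (viral minus bacterial) is the log2
#' fold-change of tail length, tested with Satterthwaite denominator degrees
#' of freedom. With a single batch, or when the batch variance estimate hits
#' the zero boundary (singular fit), the model reduces to ordinary least
#' squares on the fixed effect with residual degrees of freedom — which for
#' a two-level factor is exactly the pooled-variance two-sample t-test — and
#' the result is flagged `method = "ols"`.
#'
#' @param gene_reads Read-record tibble for a single gene.
#' @param min_reads Minimum usable reads required in each condition.
#' @return One-row tibble: `log2fc`, `se`, `df`, `p_value`, `n_bacterial`,
#'   `n_viral`, `method` (`"lmm"` or `"ols"`).
#' @export
fit_gene_lmm <- function(gene_reads, min_reads = 10) {
  validate_reads(gene_reads)
  usable <- usable_polya(gene_reads)
  usable$condition <- condition_factor(usable$condition)
  n_b <- sum(usable$condition == "bacterial")
  n_v <- sum(usable$condition == "viral")
  if (n_b < min_reads || n_v < min_reads) {
    stop_polyatails(
      sprintf("gene has < %d usable reads in a condition (bacterial %d, viral %d).",
              min_reads, n_b, n_v),
      "polyatails_skip_gene"
    )
  }
  y <- log2(usable$polya_length)
  dat <- data.frame(y = y, condition = usable$condition,
                    batch = factor(usable$batch))

  fit_ols <- function() {
    fit <- lm(y ~ condition, data = dat)
    sm <- summary(fit)
    if (sm$sigma < 1e-10) {
      stop_polyatails("zero residual variance.", "polyatails_fit_error")
    }
    co <- sm$coefficients["conditionviral", ]
    tibble(log2fc = unname(co[1]), se = unname(co[2]),
           df = fit$df.residual, p_value = unname(co[4]),
           n_bacterial = n_b, n_viral = n_v, method = "ols")
  }

  if (nlevels(droplevels(dat$batch)) < 2) {
    return(fit_ols())
  }
  ctl <- lme4::lmerControl(
    check.conv.singular = lme4::.makeCC(action = "ignore", tol = 1e-4),
    calc.derivs = FALSE
  )
  fit <- tryCatch(
    suppressMessages(suppressWarnings(
      lmerTest::lmer(y ~ condition + (1 | batch), data = dat, REML = TRUE,
                     control = ctl)
    )),
    error = function(e) NULL
  )
  if (is.null(fit) || lme4::isSingular(fit, tol = 1e-4)) {
    return(fit_ols())
  }
  co <- coef(summary(fit))["conditionviral", ]
  tibble(log2fc = unname(co["Estimate"]), se = unname(co["Std. Error"]),
         df = unname(co["df"]), p_value = unname(co["Pr(>|t|)"]),
         n_bacterial = n_b, n_viral = n_v, method = "lmm")
}

#' Differential polyadenylation across all genes
#'
#' Fits the per-gene mixed model for every gene with enough usable reads in
#' both conditions, adjusts p-values across fitted genes with
#' Benjamini-Hochberg, and calls differentially polyadenylated genes (DPGs)
#' with the dual cutoff `p_adj < alpha` and `|log2FC| >= lfc_threshold`.
#'
#' @param reads Read-record tibble with gene assignments.
#' @param alpha BH-adjusted significance cutoff (default 0.05).
#' @param lfc_threshold Absolute log2 fold-change cutoff (default 0.5).
#' @param min_reads Minimum usable reads per condition per gene (default 10).
#' @return A tibble of class `dp_result`, one row per fitted gene:
#'   `gene_id`, `log2fc`, `se`, `df`, `p_value`, `p_adj`, `n_bacterial`,
#'   `n_viral`, `method`, `is_dpg`, `robust_fraction` (NA until
#'   [bootstrap_robustness()]), `is_robust`. Genes skipped for insufficient
#'   reads are in the `skipped` attribute.
#' @export
dp_test <- function(reads, alpha = 0.05, lfc_threshold = 0.5, min_reads = 10) {
  validate_reads(reads, require_gene = TRUE)
  reads <- dplyr::filter(reads, !is.na(.data$gene_id))
  by_gene <- split(reads, reads$gene_id)
  skipped <- character(0)
  rows <- vector("list", length(by_gene))
  for (i in seq_along(by_gene)) {
    res <- tryCatch(
      fit_gene_lmm(by_gene[[i]], min_reads = min_reads),
      polyatails_skip_gene = function(e) NULL,
      polyatails_fit_error = function(e) NULL
    )
    if (is.null(res)) {
      skipped <- c(skipped, names(by_gene)[i])
    } else {
      res$gene_id <- names(by_gene)[i]
      rows[[i]] <- res
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    stop_polyatails("no gene could be fitted.", "polyatails_config_error")
  }
  out$p_adj <- bh_adjust(out$p_value)
  out$is_dpg <- out$p_adj < alpha & abs(out$log2fc) >= lfc_threshold
  out$robust_fraction <- NA_real_
  out$is_robust <- NA
  out <- dplyr::select(out, "gene_id", dplyr::everything())
  attr(out, "skipped") <- skipped
  attr(out, "alpha") <- alpha
  attr(out, "lfc_threshold") <- lfc_threshold
  class(out) <- c("dp_result", class(tibble::tibble()))
  out
}

#' Bootstrap robustness of DPG calls
#'
#' For each candidate gene, reads are resampled with replacement `n_boot`
#' times — by default within each (gene, sample) stratum, preserving the
#' per-sample read depth and the batch/condition design — the mixed model is
#' refitted, and p-values are BH-adjusted across candidates within each
#' replicate. `robust_fraction` is the fraction of replicates in which the
#' gene stays significant (`p_adj < alpha`); a gene is robust when that
#' fraction reaches `robust_quantile`.
#'
#' @param reads Read-record tibble with gene assignments.
#' @param candidates Character vector of candidate gene ids (typically the
#'   DPGs of [dp_test()]), or a `dp_result` (its DPGs are used).
#' @param n_boot Number of bootstrap replicates (default 100).
#' @param seed Integer seed; results are deterministic given it.
#' @param alpha Significance cutoff applied to replicate-level adjusted
#'   p-values.
#' @param robust_quantile Robustness threshold on `robust_fraction`
#'   (default 0.95).
#' @param min_reads Per-condition read floor passed to the refits.
#' @param stratify `TRUE` (default) resamples within each sample; `FALSE`
#'   pools a gene's reads before resampling.
#' @return A tibble with `gene_id`, `robust_fraction`, `is_robust`,
#'   `n_replicates_used`.
#' @export
bootstrap_robustness <- function(reads, candidates, n_boot = 100, seed = 1L,
                                 alpha = 0.05, robust_quantile = 0.95,
                                 min_reads = 10, stratify = TRUE) {
  if (inherits(candidates, "dp_result")) {
    candidates <- candidates$gene_id[candidates$is_dpg]
  }
  if (length(candidates) == 0) {
    stop_polyatails("no candidate genes supplied.", "polyatails_config_error")
  }
  if (n_boot < 2) {
    stop_polyatails("n_boot must be at least 2.", "polyatails_config_error")
  }
  validate_reads(reads, require_gene = TRUE)
  reads <- dplyr::filter(reads, .data$gene_id %in% candidates)
  by_gene <- split(reads, factor(reads$gene_id, levels = candidates))

  ok <- matrix(FALSE, n_boot, length(candidates),
               dimnames = list(NULL, candidates))
  used <- matrix(FALSE, n_boot, length(candidates),
                 dimnames = list(NULL, candidates))
  withr::with_seed(new_seed_stream(seed, 404L), {
    for (b in seq_len(n_boot)) {
      pvals <- rep(NA_real_, length(candidates))
      for (gi in seq_along(candidates)) {
        g_reads <- by_gene[[gi]]
        if (nrow(g_reads) == 0) next
        idx <- if (stratify) {
          unlist(lapply(split(seq_len(nrow(g_reads)), g_reads$sample_id),
                        function(ix) ix[sample.int(length(ix),
                                                   replace = TRUE)]),
                 use.names = FALSE)
        } else {
          sample.int(nrow(g_reads), replace = TRUE)
        }
        boot <- g_reads[idx, ]
        res <- tryCatch(
          fit_gene_lmm(boot, min_reads = min_reads),
          polyatails_skip_gene = function(e) NULL,
          polyatails_fit_error = function(e) NULL
        )
        used[b, gi] <- TRUE
        if (!is.null(res)) pvals[gi] <- res$p_value
      }
      padj <- rep(NA_real_, length(pvals))
      padj[!is.na(pvals)] <- bh_adjust(pvals[!is.na(pvals)])
      ok[b, ] <- !is.na(padj) & padj < alpha
    }
  })
  frac <- colSums(ok) / pmax(colSums(used), 1)
  tibble(
    gene_id = candidates,
    robust_fraction = unname(frac),
    is_robust = unname(frac >= robust_quantile),
    n_replicates_used = unname(colSums(used))
  )
}
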