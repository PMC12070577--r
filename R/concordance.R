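#' Compute TPM (or CPM-style) values from counts
#'
#' With `length_normalize = TRUE` each count is first divided by its feature
#' length (a rate), then rates are scaled to sum to one million per sample —
#' transcripts per million. With `length_normalize = FALSE` the counts are
#' scaled directly (counts per million), the behaviour of long-read "TPM"
#' outputs that skip length normalization.
#'
#' @param x An [abundance_table()] of counts.
#' @param lengths Named numeric vector of feature lengths (nt), or a gene
#'   model tibble with `gene_id`/`transcript_id` and `union_exon_length`.
#'   Required when `length_normalize = TRUE`.
#' @param length_normalize Divide by feature length before scaling?
#' @return An [abundance_table()] with unit `"TPM"`; every sample column sums
#'   to 1e6.
#' @export
compute_tpm <- function(x, lengths = NULL, length_normalize = TRUE) {
  stopifnot(inherits(x, "abundance_tbl"))
  m <- ab_matrix(x)
  if (length_normalize) {
    if (is.null(lengths)) {
      stop_polyatails("lengths are required for length normalization.",
                      "polyatails_config_error")
    }
    if (is.data.frame(lengths)) {
      idcol <- intersect(c("gene_id", "transcript_id", "feature_id"),
                         names(lengths))[1]
      lengths <- setNames(lengths$union_exon_length, lengths[[idcol]])
    }
    lens <- lengths[rownames(m)]
    if (any(is.na(lens) | lens < 1)) {
      stop_polyatails("missing or invalid length for some features.",
                      "polyatails_config_error")
    }
    m <- m / lens
  }
  tot <- colSums(m)
  if (any(tot == 0)) {
    stop_polyatails(
      sprintf("sample '%s' has zero total abundance.",
              colnames(m)[which(tot == 0)[1]]),
      "polyatails_config_error"
    )
  }
  out <- sweep(m, 2, tot, "/") * 1e6
  abundance_table(out, unit = "TPM", level = ab_level(x),
                  length_normalized = length_normalize)
}

# Intersect two abundance tables on shared features and samples.
intersect_abundance <- function(a, b) {
  feats <- intersect(a$feature_id, b$feature_id)
  samps <- intersect(ab_samples(a), ab_samples(b))
  ma <- ab_matrix(a)[feats, samps, drop = FALSE]
  mb <- ab_matrix(b)[feats, samps, drop = FALSE]
  list(a = ma, b = mb, features = feats, samples = samps)
}

#' Per-sample Pearson correlation between two platforms
#'
#' For every shared sample, the Pearson correlation of the two matrices'
#' abundances over the intersection of feature ids. The default scale applies
#' log2(x + 1) first; `scale = "raw"` correlates untransformed values.
#'
#' @param a,b [abundance_table()]s sharing sample ids.
#' @param scale `"log1p"` (log2(x+1), default) or `"raw"`.
#' @return A tibble with `sample_id`, `r`, `n` (feature pairs used), `scale`.
#' @export
correlate_samples <- function(a, b, scale = c("log1p", "raw")) {
  scale <- match.arg(scale)
  xs <- intersect_abundance(a, b)
  if (length(xs$features) < 3) {
    stop_polyatails("fewer than 3 shared features.", "polyatails_config_error")
  }
  if (length(xs$samples) == 0) {
    stop_polyatails("no shared samples.", "polyatails_config_error")
  }
  ma <- xs$a; mb <- xs$b
  if (scale == "log1p") { ma <- log2(ma + 1); mb <- log2(mb + 1) }
  tibble(
    sample_id = xs$samples,
    r = vapply(seq_along(xs$samples),
               function(j) cor(ma[, j], mb[, j]), numeric(1)),
    n = length(xs$features),
    scale = scale
  )
}

#' Per-feature Pearson correlation across samples
#'
#' For every shared feature whose mean abundance is at least `min_expression`
#' in both matrices, the Pearson correlation of its per-sample abundances.
#' Features with zero variance in either matrix are excluded and reported
#' with a reason.
#'
#' @inheritParams correlate_samples
#' @param min_expression Minimum mean abundance (both matrices) for a feature
#'   to be correlated.
#' @return A tibble with `feature_id`, `r`, `n`, `scale`, plus the excluded
#'   features in attribute `excluded` (tibble `feature_id`, `reason`).
#' @export
correlate_features <- function(a, b, min_expression = 0,
                               scale = c("log1p", "raw")) {
  scale <- match.arg(scale)
  xs <- intersect_abundance(a, b)
  if (length(xs$samples) < 3) {
    stop_polyatails("fewer than 3 shared samples.", "polyatails_config_error")
  }
  keep <- rowMeans(xs$a) >= min_expression & rowMeans(xs$b) >= min_expression
  ma <- xs$a[keep, , drop = FALSE]
  mb <- xs$b[keep, , drop = FALSE]
  if (scale == "log1p") { ma <- log2(ma + 1); mb <- log2(mb + 1) }
  zero_var <- matrixStats_rowSds(ma) == 0 | matrixStats_rowSds(mb) == 0
  excluded <- tibble(
    feature_id = c(xs$features[!keep], rownames(ma)[zero_var]),
    reason = c(rep("below min_expression", sum(!keep)),
               rep("zero variance", sum(zero_var)))
  )
  ma <- ma[!zero_var, , drop = FALSE]
  mb <- mb[!zero_var, , drop = FALSE]
  out <- tibble(
    feature_id = rownames(ma),
    r = if (nrow(ma) > 0) {
      vapply(seq_len(nrow(ma)), function(i) cor(ma[i, ], mb[i, ]), numeric(1))
    } else numeric(0),
    n = length(xs$samples),
    scale = scale
  )
  attr(out, "excluded") <- excluded
  out
}

matrixStats_rowSds <- function(m) {
  if (nrow(m) == 0) return(numeric(0))
  apply(m, 1, sd)
}

#' Expression-filter sweep of highly correlated features
#'
#' For each expression threshold, counts the features that survive the filter
#' and, of those, how many correlate at `r >= r_threshold` across samples.
#'
#' @inheritParams correlate_features
#' @param thresholds Numeric vector of `min_expression` values to sweep.
#' @param r_threshold Correlation defining "highly correlated" (default 0.8).
#' @return A tibble with `threshold`, `n_features`, `n_high_r`.
#' @export
correlation_sweep <- function(a, b, thresholds, r_threshold = 0.8,
                              scale = c("log1p", "raw")) {
  scale <- match.arg(scale)
  purrr::map_dfr(thresholds, function(thr) {
    res <- correlate_features(a, b, min_expression = thr, scale = scale)
    tibble(threshold = thr, n_features = nrow(res),
           n_high_r = sum(res$r >= r_threshold))
  })
}

#' Fisher-z test comparing two Pearson correlations
#'
#' Transforms both correlations with atanh and compares them with a
#' two-sided z-test: `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) +
#' 1/(n2-3))`.
#'
#' @param r1,r2 Pearson correlations, strictly inside (-1, 1).
#' @param n1,n2 Numbers of pairs behind each correlation (> 3).
#' @return A tibble with `z` and `p_value` (two-sided).
#' @export
fisher_z_test <- function(r1, n1, r2, n2) {
  if (any(abs(c(r1, r2)) >= 1)) {
    stop_polyatails("|r| = 1: Fisher transform diverges.",
                    "polyatails_config_error")
  }
  if (n1 <= 3 || n2 <= 3) {
    stop_polyatails("sample sizes must exceed 3.", "polyatails_config_error")
  }
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  tibble(z = z, p_value = 2 * pnorm(-abs(z)))
}

#' Jensen-Shannon divergence between two probability vectors
#'
#' `JSD(p, q) = KL(p || m)/2 + KL(q || m)/2` with `m = (p + q)/2`, using the
#' convention `0 * log 0 = 0`. Inputs are renormalized to sum to 1. In base 2
#' the value lies in `[0, 1]`, is symmetric, and is 0 iff `p == q`.
#'
#' @param p,q Non-negative vectors of equal length (not both all zero).
#' @param base Logarithm base (default 2).
#' @return A single numeric divergence.
#' @export
jensen_shannon_divergence <- function(p, q, base = 2) {
  if (length(p) != length(q)) {
    stop_polyatails("p and q must have equal length.", "polyatails_config_error")
  }
  if (any(p < 0) || any(q < 0) || sum(p) == 0 || sum(q) == 0) {
    stop_polyatails("p and q must be non-negative and not all zero.",
                    "polyatails_config_error")
  }
  p <- p / sum(p)
  q <- q / sum(q)
  m <- (p + q) / 2
  kl <- function(x, y) {
    i <- x > 0
    sum(x[i] * (log(x[i], base = base) - log(y[i], base = base)))
  }
  kl(p, m) / 2 + kl(q, m) / 2
}

#' Per-sample JSD between two platforms
#'
#' Each sample's abundances over the shared features are normalized to a
#' probability vector per platform, and the Jensen-Shannon divergence of the
#' two vectors is reported.
#'
#' @inheritParams correlate_samples
#' @param base Logarithm base (default 2).
#' @return A tibble with `sample_id`, `jsd`.
#' @export
jsd_samples <- function(a, b, base = 2) {
  xs <- intersect_abundance(a, b)
  tibble(
    sample_id = xs$samples,
    jsd = vapply(seq_along(xs$samples), function(j) {
      jensen_shannon_divergence(xs$a[, j], xs$b[, j], base = base)
    }, numeric(1))
  )
}

#' Length/GC bias regression
#'
#' Ordinary least squares of per-gene mean log2(TPM + 1) on a covariate
#' (log10 gene length or GC fraction), the diagnostic for residual length or
#' GC bias in a quantification.
#'
#' @param x An [abundance_table()] (typically TPM).
#' @param gene_models Gene model tibble with `gene_id`, `union_exon_length`,
#'   `gc_fraction`.
#' @param covariate `"log10_length"` or `"gc_fraction"`.
#' @return A tibble with `covariate`, `slope`, `pearson_r`, `r_squared`,
#'   `p_value`, `n`.
#' @export
bias_regression <- function(x, gene_models,
                            covariate = c("log10_length", "gc_fraction")) {
  covariate <- match.arg(covariate)
  stopifnot(inherits(x, "abundance_tbl"))
  m <- ab_matrix(x)
  idx <- match(rownames(m), gene_models$gene_id)
  ok <- !is.na(idx)
  cov_val <- switch(
    covariate,
    log10_length = log10(gene_models$union_exon_length[idx[ok]]),
    gc_fraction = gene_models$gc_fraction[idx[ok]]
  )
  y <- rowMeans(log2(m[ok, , drop = FALSE] + 1))
  keep <- is.finite(cov_val) & is.finite(y)
  cov_val <- cov_val[keep]; y <- y[keep]
  if (length(y) < 3) {
    stop_polyatails("fewer than 3 genes with covariate values.",
                    "polyatails_config_error")
  }
  if (sd(cov_val) == 0) {
    stop_polyatails("zero-variance covariate.", "polyatails_config_error")
  }
  if (sd(y) == 0) {
    # perfectly flat expression (e.g. after exact length normalization):
    # no trend by definition
    return(tibble(covariate = covariate, slope = 0, pearson_r = 0,
                  r_squared = 0, p_value = 1, n = length(y)))
  }
  fit <- lm(y ~ cov_val)
  sm <- summary(fit)
  r <- cor(cov_val, y)
  tibble(
    covariate = covariate,
    slope = unname(coef(fit)[2]),
    pearson_r = r,
    r_squared = r^2,
    p_value = sm$coefficients[2, 4],
    n = length(y)
  )
}
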