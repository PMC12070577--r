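#' Per-gene poly(A) tail summaries
#'
#' Summarises usable reads (non-missing poly(A) estimate) per gene: read
#' counts overall and per condition, median tail, per-condition median tails
#' and the mean log2 tail (the mixed model's response scale).
#'
#' @param reads Read-record tibble with gene assignments.
#' @param min_reads Minimum usable reads for a gene to be reported.
#' @param exclude_mito Drop mitochondrial genes (requires `gene_models`)?
#' @param gene_models Optional gene-model tibble with `gene_id`,
#'   `is_mitochondrial`.
#' @return A tibble with one row per gene: `gene_id`, `n_reads`,
#'   `n_bacterial`, `n_viral`, `median_polya`, `mean_log2_polya`,
#'   `median_bacterial`, `median_viral`.
#' @export
summarize_gene_polya <- function(reads, min_reads = 1, exclude_mito = FALSE,
                                 gene_models = NULL) {
  validate_reads(reads, require_gene = TRUE)
  usable <- usable_polya(dplyr::filter(reads, !is.na(.data$gene_id)))
  if (nrow(usable) == 0) {
    stop_polyatails("no usable reads with gene assignments.",
                    "polyatails_config_error")
  }
  if (exclude_mito) {
    if (is.null(gene_models)) {
      stop_polyatails("gene_models required to exclude mitochondrial genes.",
                      "polyatails_config_error")
    }
    mito <- gene_models$gene_id[gene_models$is_mitochondrial]
    usable <- dplyr::filter(usable, !.data$gene_id %in% mito)
  }
  med_or_na <- function(x) if (length(x) == 0) NA_real_ else median(x)
  usable |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      n_reads = dplyr::n(),
      n_bacterial = sum(.data$condition == "bacterial"),
      n_viral = sum(.data$condition == "viral"),
      median_polya = median(.data$polya_length),
      mean_log2_polya = mean(log2(.data$polya_length)),
      median_bacterial = med_or_na(.data$polya_length[.data$condition == "bacterial"]),
      median_viral = med_or_na(.data$polya_length[.data$condition == "viral"])
    ) |>
    dplyr::filter(.data$n_reads >= min_reads) |>
    dplyr::arrange(.data$gene_id)
}

#' Fraction of tails exceeding a threshold
#'
#' @param reads Read-record tibble.
#' @param threshold_nt Tail-length threshold in nt (default 350, the
#'   long-tail landmark for blood mRNA).
#' @return Fraction of usable reads with `polya_length > threshold_nt`.
#' @export
tail_fraction <- function(reads, threshold_nt = 350) {
  validate_reads(reads)
  usable <- usable_polya(reads)
  if (nrow(usable) == 0) {
    stop_polyatails("no usable reads.", "polyatails_config_error")
  }
  mean(usable$polya_length > threshold_nt)
}

# Mode of a 1-nt histogram smoothed with a +/- 2 nt moving average.
histogram_mode <- function(x) {
  if (length(x) == 0) return(NA_real_)
  xi <- round(x)
  rng <- range(xi)
  breaks <- seq(rng[1], rng[2])
  counts <- tabulate(xi - rng[1] + 1L, nbins = length(breaks))
  if (length(counts) >= 5) {
    sm <- stats::filter(counts, rep(1 / 5, 5), sides = 2)
    sm[is.na(sm)] <- counts[is.na(sm)]
  } else {
    sm <- counts
  }
  breaks[which.max(sm)]
}

#' Mitochondrial vs nuclear tail-length stratification
#'
#' Splits usable reads by compartment and summarises each: read count, mode
#' (smoothed 1-nt histogram), median, and the fractions of tails exceeding
#' 70 nt and 350 nt.
#'
#' @param reads Read-record tibble with gene assignments.
#' @param gene_models Gene models with `gene_id`, `is_mitochondrial`.
#' @return A tibble with one row per compartment (`mitochondrial`,
#'   `nuclear`): `n`, `mode`, `median`, `frac_gt_70`, `frac_gt_350`,
#'   `empty` flag.
#' @export
stratify_compartment <- function(reads, gene_models) {
  validate_reads(reads, require_gene = TRUE)
  usable <- usable_polya(dplyr::filter(reads, !is.na(.data$gene_id)))
  mito_genes <- gene_models$gene_id[gene_models$is_mitochondrial]
  summarise_part <- function(x, label) {
    if (nrow(x) == 0) {
      return(tibble(compartment = label, n = 0L, mode = NA_real_,
                    median = NA_real_, frac_gt_70 = NA_real_,
                    frac_gt_350 = NA_real_, empty = TRUE))
    }
    tibble(
      compartment = label,
      n = nrow(x),
      mode = histogram_mode(x$polya_length),
      median = median(x$polya_length),
      frac_gt_70 = mean(x$polya_length > 70),
      frac_gt_350 = mean(x$polya_length > 350),
      empty = FALSE
    )
  }
  known <- dplyr::filter(usable, .data$gene_id %in% gene_models$gene_id)
  dplyr::bind_rows(
    summarise_part(dplyr::filter(known, .data$gene_id %in% mito_genes),
                   "mitochondrial"),
    summarise_part(dplyr::filter(known, !.data$gene_id %in% mito_genes),
                   "nuclear")
  )
}

#' Rank genes by median poly(A) tail length
#'
#' Orders genes from longest to shortest median tail; ties break by
#' lexicographic gene id, so the ranking is deterministic and invariant to
#' input order.
#'
#' @param summaries Output of [summarize_gene_polya()] (needs `gene_id`,
#'   `median_polya`).
#' @return A tibble with `gene_id`, `score` (median tail, non-increasing).
#' @export
rank_genes <- function(summaries) {
  if (anyDuplicated(summaries$gene_id)) {
    stop_polyatails("duplicate gene ids in summaries.", "polyatails_format_error")
  }
  summaries |>
    dplyr::select("gene_id", score = "median_polya") |>
    dplyr::arrange(dplyr::desc(.data$score), .data$gene_id)
}
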