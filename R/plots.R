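#' Poly(A) tail-length distributions by compartment
#'
#' Density of tail lengths split into mitochondrial and nuclear reads — the
#' standard first look at a direct RNA-seq tail profile (narrow mito mode
#' near 45 nt against a broad nuclear distribution peaking near 80 nt).
#'
#' @param reads Read-record tibble with gene assignments.
#' @param gene_models Gene models with `is_mitochondrial`.
#' @param max_nt Truncate the x axis (default 300 nt).
#' @return A ggplot object.
#' @export
plot_polya_distribution <- function(reads, gene_models, max_nt = 300) {
  usable <- usable_polya(dplyr::filter(reads, !is.na(.data$gene_id)))
  mito <- gene_models$gene_id[gene_models$is_mitochondrial]
  usable$compartment <- ifelse(usable$gene_id %in% mito,
                               "mitochondrial", "nuclear")
  ggplot2::ggplot(usable,
                  ggplot2::aes(x = .data$polya_length,
                               fill = .data$compartment)) +
    ggplot2::geom_density(alpha = 0.5) +
    ggplot2::coord_cartesian(xlim = c(0, max_nt)) +
    ggplot2::labs(x = "poly(A) tail length (nt)", y = "density",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Volcano plot of differential polyadenylation
#'
#' @param object A `dp_result` from [dp_test()].
#' @param ... Unused.
#' @return A ggplot object: log2 fold-change against -log10 adjusted p, DPGs
#'   highlighted.
#' @export
autoplot.dp_result <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$log2fc,
                                  y = -log10(.data$p_adj),
                                  colour = .data$is_dpg)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = -log10(attr(object, "alpha")),
                        linetype = 2) +
    ggplot2::geom_vline(xintercept = c(-1, 1) * attr(object, "lfc_threshold"),
                        linetype = 2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 fold-change (viral - bacterial)",
                  y = "-log10 adjusted p", colour = "DPG") +
    ggplot2::theme_minimal()
}

#' Raincloud-style read-level tails for one gene
#'
#' Per-condition distribution of raw read tails for a candidate gene: half
#' density plus jittered reads, the display used to review DPG calls.
#'
#' @param reads Read-record tibble.
#' @param gene Gene id to display.
#' @return A ggplot object.
#' @export
plot_gene_raincloud <- function(reads, gene) {
  d <- usable_polya(dplyr::filter(reads, .data$gene_id == gene))
  if (nrow(d) == 0) {
    stop_polyatails(sprintf("no usable reads for gene '%s'.", gene),
                    "polyatails_config_error")
  }
  ggplot2::ggplot(d, ggplot2::aes(x = .data$condition,
                                  y = .data$polya_length,
                                  colour = .data$condition)) +
    ggplot2::geom_violin(alpha = 0.3, ggplot2::aes(fill = .data$condition)) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.5, size = 0.8) +
    ggplot2::scale_y_continuous(trans = "log2") +
    ggplot2::labs(title = gene, x = NULL, y = "poly(A) tail length (nt)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Enrichment summary plot
#'
#' @param object A `gsea_result` from [gsea_preranked()].
#' @param ... Unused.
#' @return A ggplot object: NES per set, coloured by FDR significance.
#' @export
autoplot.gsea_result <- function(object, ...) {
  d <- tidy(object)
  d$significant <- d$fdr_q < 0.05
  ggplot2::ggplot(d, ggplot2::aes(x = .data$nes,
                                  y = stats::reorder(.data$set_id, .data$nes),
                                  fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey70",
                                          `TRUE` = "firebrick")) +
    ggplot2::labs(x = "normalized enrichment score", y = NULL,
                  fill = "FDR q < 0.05") +
    ggplot2::theme_minimal()
}

#' Running-sum plot for one gene set
#'
#' @param object A `gsea_result`.
#' @param set_id Which set to display.
#' @return A ggplot object of the running enrichment sum over the ranking.
#' @export
plot_running_sum <- function(object, set_id) {
  rs <- attr(object, "running_sums")[[set_id]]
  if (is.null(rs)) {
    stop_polyatails(sprintf("no running sum stored for set '%s'.", set_id),
                    "polyatails_config_error")
  }
  d <- tibble(rank = seq_along(rs), running_sum = rs)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$rank, y = .data$running_sum)) +
    ggplot2::geom_line(colour = "firebrick") +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(title = set_id, x = "rank (longest to shortest tail)",
                  y = "running enrichment sum") +
    ggplot2::theme_minimal()
}

#' Estimated transcript proportions for one gene
#'
#' Per-sample observed transcript proportions by condition, the display used
#' to inspect differential transcript usage.
#'
#' @param x Transcript-level [abundance_table()] of counts.
#' @param tx2gene Tibble mapping `transcript_id` to `gene_id`.
#' @param metadata Sample metadata tibble.
#' @param gene Gene id to display.
#' @return A ggplot object.
#' @export
plot_dtu_proportions <- function(x, tx2gene, metadata, gene) {
  m <- ab_matrix(x)
  txs <- tx2gene$transcript_id[tx2gene$gene_id == gene]
  gm <- m[rownames(m) %in% txs, , drop = FALSE]
  if (nrow(gm) == 0) {
    stop_polyatails(sprintf("no transcripts for gene '%s'.", gene),
                    "polyatails_config_error")
  }
  props <- sweep(gm, 2, pmax(colSums(gm), 1), "/")
  d <- tibble::as_tibble(props, rownames = "transcript_id") |>
    tidyr::pivot_longer(-"transcript_id", names_to = "sample_id",
                        values_to = "proportion") |>
    dplyr::left_join(metadata, by = "sample_id")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$transcript_id,
                                  y = .data$proportion,
                                  colour = .data$condition)) +
    ggplot2::geom_boxplot(outlier.shape = NA,
                          position = ggplot2::position_dodge(0.7)) +
    ggplot2::geom_point(position =
                          ggplot2::position_jitterdodge(jitter.width = 0.1,
                                                        dodge.width = 0.7),
                        alpha = 0.7) +
    ggplot2::labs(title = gene, x = NULL, y = "transcript proportion") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
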