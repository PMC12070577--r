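#' Tidy a differential polyadenylation result
#' @param x A `dp_result` from [dp_test()].
#' @param ... Unused.
#' @return The per-gene result tibble.
#' @export
tidy.dp_result <- function(x, ...) {
  tibble::as_tibble(unclass(x)[names(x)])
}

#' One-row summary of a differential polyadenylation result
#' @inheritParams tidy.dp_result
#' @export
glance.dp_result <- function(x, ...) {
  tibble(
    n_genes = nrow(x),
    n_dpg = sum(x$is_dpg),
    n_up = sum(x$is_dpg & x$log2fc > 0),
    n_down = sum(x$is_dpg & x$log2fc < 0),
    n_robust = sum(x$is_robust, na.rm = TRUE),
    alpha = attr(x, "alpha"),
    lfc_threshold = attr(x, "lfc_threshold")
  )
}

#' Tidy a GSEA result
#' @param x A `gsea_result` from [gsea_preranked()].
#' @param ... Unused.
#' @export
tidy.gsea_result <- function(x, ...) {
  out <- tibble::as_tibble(unclass(x)[names(x)])
  out$leading_edge_size <- vapply(out$leading_edge, length, 1L)
  out
}

#' One-row summary of a GSEA result
#' @inheritParams tidy.gsea_result
#' @export
glance.gsea_result <- function(x, ...) {
  tibble(
    n_sets = nrow(x),
    n_significant = sum(x$fdr_q < 0.05, na.rm = TRUE),
    n_perm = attr(x, "n_perm") %||% NA_integer_
  )
}

#' Tidy a DTU result
#' @param x A `dtu_result` from [dtu_test()].
#' @param ... Unused.
#' @return The stage-wise transcript-level tibble.
#' @export
tidy.dtu_result <- function(x, ...) {
  x$transcript
}

#' One-row summary of a DTU result
#' @inheritParams tidy.dtu_result
#' @export
glance.dtu_result <- function(x, ...) {
  tibble(
    n_genes_tested = x$n_genes_tested,
    n_genes_screened = x$n_genes_screened,
    n_transcripts_confirmed =
      sum(x$transcript$stagewise_adj_p < x$alpha_ofdr, na.rm = TRUE),
    alpha_ofdr = x$alpha_ofdr
  )
}
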