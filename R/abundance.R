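#' Construct an abundance table
#'
#' The package's container for feature-by-sample abundances is a tibble whose
#' first column is `feature_id` and whose remaining columns are one numeric
#' column per sample, carrying `unit` (counts / CPM / TPM), `level`
#' (gene / transcript) and `length_normalized` metadata as attributes.
#'
#' @param values A numeric matrix (features x samples) with rownames as feature
#'   ids and colnames as sample ids, or a data frame with a `feature_id` first
#'   column.
#' @param unit One of `"counts"`, `"CPM"`, `"TPM"`.
#' @param level One of `"gene"`, `"transcript"`.
#' @param length_normalized Logical; whether values were length-normalized.
#' @return A tibble of class `abundance_tbl`.
#' @examples
#' m <- matrix(1:4, 2, dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' abundance_table(m, unit = "counts", level = "gene")
#' @export
abundance_table <- function(values, unit = c("counts", "CPM", "TPM"),
                            level = c("gene", "transcript"),
                            length_normalized = FALSE) {
  unit <- match.arg(unit)
  level <- match.arg(level)
  if (is.matrix(values)) {
    if (is.null(colnames(values)) ||
        (nrow(values) > 0 && is.null(rownames(values)))) {
      stop_polyatails("abundance matrix needs feature rownames and sample colnames.",
                      "polyatails_format_error")
    }
    if (nrow(values) == 0) {
      tb <- tibble::as_tibble(matrix(numeric(0), 0, ncol(values),
                                     dimnames = list(NULL, colnames(values))))
      tb <- tibble::add_column(tb, feature_id = character(0), .before = 1)
    } else {
      tb <- tibble::as_tibble(values, rownames = "feature_id")
    }
  } else {
    tb <- tibble::as_tibble(values)
    if (names(tb)[1] != "feature_id") names(tb)[1] <- "feature_id"
    tb$feature_id <- as.character(tb$feature_id)
  }
  if (anyDuplicated(tb$feature_id)) {
    stop_polyatails("duplicate feature ids in abundance table.",
                    "polyatails_format_error")
  }
  if (anyDuplicated(names(tb))) {
    stop_polyatails("duplicate sample ids in abundance table.",
                    "polyatails_format_error")
  }
  vals <- as.matrix(tb[, -1, drop = FALSE])
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop_polyatails("abundance values must be finite and non-negative.",
                    "polyatails_format_error")
  }
  structure(
    tb,
    unit = unit, level = level, length_normalized = length_normalized,
    class = c("abundance_tbl", class(tibble::tibble()))
  )
}

ab_unit <- function(x) attr(x, "unit", exact = TRUE) %||% "counts"
ab_level <- function(x) attr(x, "level", exact = TRUE) %||% "gene"
ab_samples <- function(x) setdiff(names(x), "feature_id")

# Numeric matrix view (features x samples) with feature_id rownames.
ab_matrix <- function(x) {
  m <- as.matrix(x[, ab_samples(x), drop = FALSE])
  rownames(m) <- x$feature_id
  m
}

#' @export
print.abundance_tbl <- function(x, ...) {
  cat(sprintf("# Abundance table: %d features x %d samples [%s, %s level%s]\n",
              nrow(x), length(ab_samples(x)), ab_unit(x), ab_level(x),
              if (isTRUE(attr(x, "length_normalized"))) ", length-normalized" else ""))
  NextMethod()
}
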