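# Internal helpers shared across modules.

# Stop with a classed condition so callers/tests can match on class.
stop_polyatails <- function(msg, class) {
  rlang::abort(msg, class = c(class, "polyatails_error"))
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    stop_polyatails(
      sprintf("`%s` must be a single number in [%s, %s].", name, lower, upper),
      "polyatails_config_error"
    )
  }
  invisible(x)
}

# The canonical two-level condition coding used throughout: "bacterial" is the
# reference level, so fixed effects read as viral - bacterial.
condition_factor <- function(x) {
  bad <- setdiff(unique(as.character(x)), c("bacterial", "viral"))
  if (length(bad) > 0) {
    stop_polyatails(
      sprintf("condition labels must be 'bacterial' or 'viral'; found: %s",
              paste(bad, collapse = ", ")),
      "polyatails_config_error"
    )
  }
  factor(as.character(x), levels = c("bacterial", "viral"))
}

# Validate a reads tibble (the ReadRecord collection).
validate_reads <- function(reads, require_gene = FALSE) {
  needed <- c("read_id", "sample_id", "batch", "condition",
              "read_length", "polya_length")
  missing_cols <- setdiff(needed, names(reads))
  if (length(missing_cols) > 0) {
    stop_polyatails(
      sprintf("reads table lacks column(s): %s",
              paste(missing_cols, collapse = ", ")),
      "polyatails_format_error"
    )
  }
  if (require_gene && !"gene_id" %in% names(reads)) {
    stop_polyatails("reads table lacks a gene_id column.",
                    "polyatails_format_error")
  }
  invisible(reads)
}

# Usable reads: those with a defined poly(A) estimate (>= 1 nt, non-missing).
usable_polya <- function(reads) {
  dplyr::filter(reads, !is.na(.data$polya_length) & .data$polya_length >= 1)
}

new_seed_stream <- function(seed, offset) {
  # Derive stage-specific seeds that stay well inside 32-bit integer range.
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483647)
}
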