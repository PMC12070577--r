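# Independent reference implementations used as oracles. These deliberately
# use the plainest possible formulations (explicit loops, textbook formulas)
# and never call the package functions they check.

# Benjamini-Hochberg step-up, literal definition.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- Inf
  for (i in m:1) {
    prev <- min(prev, p[o[i]] * m / i)
    adj[o[i]] <- min(1, prev)
  }
  adj
}

# Weighted KS running sum by explicit walk over the ranking.
oracle_es <- function(scores, is_hit, w = 1) {
  n <- length(scores)
  nr <- sum(abs(scores[is_hit])^w)
  nh <- sum(is_hit)
  run <- 0
  best <- 0
  runs <- numeric(n)
  for (i in seq_len(n)) {
    if (is_hit[i]) {
      run <- run + (if (nr > 0) abs(scores[i])^w / nr else 1 / nh)
    } else {
      run <- run - 1 / (n - nh)
    }
    runs[i] <- run
    if (abs(run) > abs(best)) best <- run
  }
  list(es = best, running = runs)
}

# Jensen-Shannon divergence by direct KL summation.
oracle_jsd <- function(p, q, base = 2) {
  p <- p / sum(p)
  q <- q / sum(q)
  m <- (p + q) / 2
  s <- 0
  for (i in seq_along(p)) {
    if (p[i] > 0) s <- s + 0.5 * p[i] * log(p[i] / m[i], base = base)
    if (q[i] > 0) s <- s + 0.5 * q[i] * log(q[i] / m[i], base = base)
  }
  s
}

# Textbook pooled-variance two-sample t-test on log2 values.
oracle_pooled_t <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  se <- sqrt(sp2 * (1 / nx + 1 / ny))
  est <- mean(y) - mean(x)
  tt <- est / se
  list(estimate = est, se = se, df = nx + ny - 2,
       p = 2 * pt(-abs(tt), df = nx + ny - 2))
}

# Multinomial likelihood-ratio statistic for shared vs per-condition
# proportions (the precision -> infinity limit of the DM test).
oracle_multinomial_lrt <- function(counts, conditions) {
  ll <- function(m) {
    tot <- rowSums(m) # per-transcript totals across samples of a group
    p <- tot / sum(tot)
    sum(tot[tot > 0] * log(p[tot > 0]))
  }
  g1 <- counts[, conditions == unique(conditions)[1], drop = FALSE]
  g2 <- counts[, conditions != unique(conditions)[1], drop = FALSE]
  2 * (ll(g1) + ll(g2) - ll(counts))
}

# Brute-force DRIMSeq-style filter.
oracle_filter <- function(m, gene_of, msg, msf, mge, mfe) {
  keep <- logical(nrow(m))
  for (i in seq_len(nrow(m))) {
    g <- gene_of[i]
    gene_tot <- colSums(m[gene_of == g, , drop = FALSE])
    gene_ok <- sum(gene_tot >= mge) >= msg
    tx_ok <- sum(m[i, ] >= mfe) >= msf
    keep[i] <- gene_ok && tx_ok
  }
  for (g in unique(gene_of)) {
    idx <- gene_of == g
    if (sum(keep & idx) < 2) keep[idx] <- FALSE
  }
  rownames(m)[keep]
}

# Deterministic small read-record builder.
make_reads <- function(polya, condition, sample_id = NULL, batch = NULL,
                       gene_id = "geneA") {
  n <- length(polya)
  if (is.null(sample_id)) sample_id <- ifelse(condition == "viral", "S2", "S1")
  if (is.null(batch)) batch <- sample_id
  tibble::tibble(
    read_id = sprintf("r%04d", seq_len(n)),
    sample_id = sample_id,
    batch = batch,
    condition = condition,
    gene_id = gene_id,
    read_length = 500L,
    polya_length = polya
  )
}
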