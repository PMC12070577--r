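# Core running-sum evaluation from sorted hit positions.
# pos: sorted ranks of the set members in the ranking; w: |score|^exponent at
# those ranks; N: ranking length. Returns es and peak index without
# materializing the full N-length running sum.
es_from_hits <- function(pos, w, N) {
  nh <- length(pos)
  nr <- sum(w)
  cw <- if (nr > 0) cumsum(w) / nr else cumsum(rep(1 / nh, nh))
  miss_dec <- if (N > nh) (pos - seq_len(nh)) / (N - nh) else rep(0, nh)
  val_at <- cw - miss_dec
  val_before <- c(0, cw[-nh]) - miss_dec
  i_max <- which.max(val_at)
  i_min <- which.min(val_before)
  # On an exact |deviation| tie, keep the extremum reached first along the
  # ranking (the walk-order convention).
  pos_max <- pos[i_max]
  pos_min <- pos[i_min] - 1L
  take_pos <- val_at[i_max] > -val_before[i_min] ||
    (val_at[i_max] == -val_before[i_min] && pos_max <= pos_min)
  if (take_pos) {
    list(es = val_at[i_max], peak_index = pos_max)
  } else {
    list(es = val_before[i_min], peak_index = pos_min)
  }
}

#' Weighted running-sum enrichment score
#'
#' The classic weighted Kolmogorov-Smirnov statistic over a ranked gene
#' list: walking down the ranking, set members ("hits") increment the
#' running sum by `|score|^w / sum_hits |score|^w` and non-members decrement
#' it by `1/(N - N_hits)`; the enrichment score is the signed maximal
#' deviation from zero.
#'
#' @param ranked A ranked gene list ([rank_genes()]): tibble with `gene_id`,
#'   `score`, scores non-increasing.
#' @param gene_set Character vector of member gene ids.
#' @param weight_exponent Weight on |score| (default 1; 0 gives the
#'   unweighted KS statistic).
#' @return A list with `es`, `running_sum` (length-N numeric), `peak_index`.
#' @export
enrichment_score <- function(ranked, gene_set, weight_exponent = 1) {
  n <- nrow(ranked)
  hit <- ranked$gene_id %in% gene_set
  nh <- sum(hit)
  if (nh == 0) {
    stop_polyatails("empty overlap between gene set and ranking.",
                    "polyatails_config_error")
  }
  w <- abs(ranked$score)^weight_exponent
  nr <- sum(w[hit])
  incr <- numeric(n)
  incr[hit] <- if (nr > 0) w[hit] / nr else 1 / nh
  if (n > nh) incr[!hit] <- -1 / (n - nh)
  running <- cumsum(incr)
  core <- es_from_hits(which(hit), w[hit], n)
  list(es = core$es, running_sum = running, peak_index = core$peak_index)
}

#' Leading-edge subset of a gene set
#'
#' Members driving the enrichment signal: for a positive enrichment score,
#' the set members at ranks up to the running-sum peak; for a negative
#' score, the members from the peak onwards.
#'
#' @inheritParams enrichment_score
#' @param peak_index Rank of the running-sum extremum.
#' @param es The enrichment score (its sign selects the side).
#' @return Character vector of leading-edge gene ids, in ranking order.
#' @export
leading_edge <- function(ranked, gene_set, peak_index, es) {
  hit_ranks <- which(ranked$gene_id %in% gene_set)
  if (length(hit_ranks) == 0) {
    stop_polyatails("empty overlap between gene set and ranking.",
                    "polyatails_config_error")
  }
  keep <- if (es >= 0) hit_ranks <= peak_index else hit_ranks >= peak_index
  ranked$gene_id[hit_ranks[keep]]
}

#' Pre-ranked gene-set enrichment analysis
#'
#' Computes the weighted enrichment score of each set against the ranking,
#' builds a permutation null by gene-label permutation (equivalently, random
#' placement of the set on the ranking), and reports the add-one permutation
#' p-value against the same-sign half of the null (so a null set is
#' uniformly calibrated), the normalized enrichment score (ES divided by the mean |null
#' ES| of matching sign), and an FDR q-value from same-sign pooling of
#' normalized null scores across sets.
#'
#' @inheritParams enrichment_score
#' @param sets Gene-set tibble ([read_gmt()]): `set_id`, `description`,
#'   `genes` list column.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed; results are deterministic given it.
#' @param min_size,max_size Bounds on the number of set members present in
#'   the ranking; sets outside the bounds are dropped.
#' @return A tibble of class `gsea_result`: `set_id`, `set_size_used`, `es`,
#'   `nes`, `p_perm`, `fdr_q`, `leading_edge` (list column). Running sums
#'   are in the `running_sums` attribute.
#' @export
gsea_preranked <- function(ranked, sets, n_perm = 1000, seed = 1L,
                           min_size = 10, max_size = 500,
                           weight_exponent = 1) {
  n <- nrow(ranked)
  w_all <- abs(ranked$score)^weight_exponent
  sizes <- vapply(sets$genes, function(g) sum(ranked$gene_id %in% g), 1L)
  keep <- sizes >= min_size & sizes <= max_size
  if (!any(keep)) {
    rlang::warn("all gene sets filtered out by size bounds.")
    out <- tibble(set_id = character(0), set_size_used = integer(0),
                  es = numeric(0), nes = numeric(0), p_perm = numeric(0),
                  fdr_q = numeric(0), leading_edge = list())
    class(out) <- c("gsea_result", class(tibble::tibble()))
    return(out)
  }
  sets <- sets[keep, ]
  # Deterministic processing order regardless of how sets were supplied.
  sets <- sets[order(sets$set_id), ]
  sizes <- vapply(sets$genes, function(g) sum(ranked$gene_id %in% g), 1L)

  obs <- lapply(sets$genes, function(g) enrichment_score(ranked, g,
                                                         weight_exponent))
  es_obs <- vapply(obs, `[[`, numeric(1), "es")

  # Shared permutation null per distinct set size.
  uniq_sizes <- sort(unique(sizes))
  null_by_size <- withr::with_seed(new_seed_stream(seed, 505L), {
    setNames(lapply(uniq_sizes, function(k) {
      vapply(seq_len(n_perm), function(b) {
        pos <- sort(sample.int(n, k))
        es_from_hits(pos, w_all[pos], n)$es
      }, numeric(1))
    }), as.character(uniq_sizes))
  })

  pos_mean <- vapply(null_by_size, function(e) {
    if (any(e >= 0)) mean(e[e >= 0]) else NA_real_
  }, numeric(1))
  neg_mean <- vapply(null_by_size, function(e) {
    if (any(e < 0)) mean(abs(e[e < 0])) else NA_real_
  }, numeric(1))

  p_perm <- nes <- numeric(length(es_obs))
  nes_null_pool <- list()
  for (i in seq_along(es_obs)) {
    key <- as.character(sizes[i])
    e_null <- null_by_size[[key]]
    if (es_obs[i] >= 0) {
      same <- e_null[e_null >= 0]
      p_perm[i] <- (1 + sum(same >= es_obs[i])) / (length(same) + 1)
      nes[i] <- es_obs[i] / pos_mean[key]
    } else {
      same <- e_null[e_null < 0]
      p_perm[i] <- (1 + sum(abs(same) >= abs(es_obs[i]))) / (length(same) + 1)
      nes[i] <- -abs(es_obs[i]) / neg_mean[key]
    }
    nes_null_pool[[i]] <- c(
      if (!is.na(pos_mean[key])) e_null[e_null >= 0] / pos_mean[key],
      if (!is.na(neg_mean[key])) -abs(e_null[e_null < 0]) / neg_mean[key]
    )
  }
  pool <- unlist(nes_null_pool)

  fdr_q <- vapply(seq_along(nes), function(i) {
    if (is.na(nes[i])) return(NA_real_)
    if (nes[i] >= 0) {
      denom_null <- sum(pool >= 0)
      num <- if (denom_null > 0) sum(pool >= nes[i]) / denom_null else NA_real_
      obs_denom <- sum(nes >= 0)
      obs_frac <- sum(nes >= nes[i]) / obs_denom
    } else {
      denom_null <- sum(pool < 0)
      num <- if (denom_null > 0) sum(pool <= nes[i]) / denom_null else NA_real_
      obs_denom <- sum(nes < 0)
      obs_frac <- sum(nes <= nes[i]) / obs_denom
    }
    min(1, num / obs_frac)
  }, numeric(1))

  le <- lapply(seq_along(es_obs), function(i) {
    leading_edge(ranked, sets$genes[[i]], obs[[i]]$peak_index, es_obs[i])
  })

  out <- tibble(
    set_id = sets$set_id,
    set_size_used = sizes,
    es = es_obs,
    nes = nes,
    p_perm = p_perm,
    fdr_q = fdr_q,
    leading_edge = le
  )
  attr(out, "running_sums") <- setNames(lapply(obs, `[[`, "running_sum"),
                                        sets$set_id)
  attr(out, "n_perm") <- n_perm
  class(out) <- c("gsea_result", class(tibble::tibble()))
  out
}
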