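#' Simulation configuration
#'
#' Defines a truth-known synthetic dataset emulating whole-blood Nanopore
#' direct RNA-seq of a two-condition cohort (default 6 bacterial + 6 viral
#' samples, each its own library batch). Nuclear genes draw per-gene baseline
#' median tails log2-normally, calibrated so the cohort mean of per-gene
#' median tails is ~83 nt with typical medians spanning roughly 26-147 nt;
#' mitochondrial tails follow a narrow truncated normal centred at 45 nt.
#' Read-level log2 tails add a per-batch random intercept and read noise,
#' which is exactly the generative model the differential-polyadenylation
#' mixed model assumes.
#'
#' @param n_genes Number of nuclear genes.
#' @param n_mito_genes Number of mitochondrial genes.
#' @param samples Tibble with columns `sample_id`, `batch`, `condition`;
#'   default 12 samples (6 bacterial, 6 viral), one batch per sample.
#' @param reads_per_gene_mean Expected total reads per gene across all
#'   samples (split evenly across samples; per-sample counts are negative
#'   binomial).
#' @param reads_per_gene_dispersion Negative-binomial size parameter of the
#'   per-sample read counts.
#' @param nuclear_tail_log2_median_mean,nuclear_tail_log2_median_sd Mean and
#'   sd of the per-gene baseline log2 median tail. The default mean is
#'   `log2(83) - nuclear_tail_log2_median_sd^2 * log(2) / 2` so that the
#'   expectation of the per-gene median tail (2^mu, lognormal) is 83 nt.
#' @param mito_tail_center,mito_tail_sd Centre (nt) and sd of the truncated
#'   normal (lower bound 10 nt) mitochondrial tail regime.
#' @param read_noise_sd Read-level noise sd on the log2 scale.
#' @param batch_sd Batch random-intercept sd on the log2 scale.
#' @param dp_genes Tibble with columns `gene_id`, `delta_log2`: genes given a
#'   viral-minus-bacterial shift in log2 tail length.
#' @param platform_corr_target Target Pearson correlation, across genes, of
#'   the two platforms' log expected abundances, in (0, 1].
#' @param length_bias_coeff,gc_bias_coeff Platform-A log-abundance shift per
#'   log10(gene length) and per unit (GC - 0.5).
#' @param abundance_log_mean,abundance_log_sd Natural-log mean/sd of the
#'   per-gene expected abundance shared by the platforms.
#' @param n_transcripts_per_gene Transcripts per gene for isoform simulation.
#' @param iso_total_mean,iso_total_dispersion Negative-binomial mean/size of
#'   per-gene per-sample isoform count totals.
#' @param dtu_genes Tibble with columns `gene_id`, `prop_bacterial`,
#'   `prop_viral` (list columns of proportion vectors summing to 1).
#' @param dm_precision Dirichlet-multinomial precision (> 0); larger means
#'   proportions closer to the condition target.
#' @param seed Integer seed; every generator is deterministic given it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 1000,
                       n_mito_genes = 13,
                       samples = default_samples(),
                       reads_per_gene_mean = 50,
                       reads_per_gene_dispersion = 10,
                       nuclear_tail_log2_median_sd = 0.55,
                       nuclear_tail_log2_median_mean =
                         log2(83) - nuclear_tail_log2_median_sd^2 * log(2) / 2,
                       mito_tail_center = 45,
                       mito_tail_sd = 8,
                       read_noise_sd = 0.5,
                       batch_sd = 0.2,
                       dp_genes = NULL,
                       platform_corr_target = 0.9,
                       length_bias_coeff = 0,
                       gc_bias_coeff = 0,
                       abundance_log_mean = log(250),
                       abundance_log_sd = 1.3,
                       n_transcripts_per_gene = 3,
                       iso_total_mean = 300,
                       iso_total_dispersion = 10,
                       dtu_genes = NULL,
                       dm_precision = 50,
                       seed = 1L) {
  assert_scalar_number(n_genes, "n_genes", lower = 1)
  assert_scalar_number(n_mito_genes, "n_mito_genes", lower = 0)
  assert_scalar_number(reads_per_gene_mean, "reads_per_gene_mean", lower = 1)
  assert_scalar_number(reads_per_gene_dispersion, "reads_per_gene_dispersion",
                       lower = 1e-6)
  assert_scalar_number(read_noise_sd, "read_noise_sd", lower = 0)
  assert_scalar_number(batch_sd, "batch_sd", lower = 0)
  assert_scalar_number(platform_corr_target, "platform_corr_target",
                       lower = 1e-12, upper = 1)
  assert_scalar_number(dm_precision, "dm_precision", lower = 1e-12)
  assert_scalar_number(seed, "seed")
  samples <- tibble::as_tibble(samples)
  stopifnot(all(c("sample_id", "batch", "condition") %in% names(samples)))
  samples$condition <- as.character(condition_factor(samples$condition))
  if (length(unique(samples$condition)) < 2) {
    stop_polyatails("samples must include both conditions.",
                    "polyatails_config_error")
  }
  cfg <- list(
    n_genes = as.integer(n_genes), n_mito_genes = as.integer(n_mito_genes),
    samples = samples,
    reads_per_gene_mean = reads_per_gene_mean,
    reads_per_gene_dispersion = reads_per_gene_dispersion,
    nuclear_tail_log2_median_mean = nuclear_tail_log2_median_mean,
    nuclear_tail_log2_median_sd = nuclear_tail_log2_median_sd,
    mito_tail_center = mito_tail_center, mito_tail_sd = mito_tail_sd,
    read_noise_sd = read_noise_sd, batch_sd = batch_sd,
    dp_genes = dp_genes,
    platform_corr_target = platform_corr_target,
    length_bias_coeff = length_bias_coeff, gc_bias_coeff = gc_bias_coeff,
    abundance_log_mean = abundance_log_mean, abundance_log_sd = abundance_log_sd,
    n_transcripts_per_gene = as.integer(n_transcripts_per_gene),
    iso_total_mean = iso_total_mean, iso_total_dispersion = iso_total_dispersion,
    dtu_genes = dtu_genes, dm_precision = dm_precision,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  cfg
}

#' Default 12-sample two-condition design
#'
#' Six bacterial and six viral samples; each sample is its own library batch
#' (per-patient libraries), the free structure the batch random effect
#' absorbs.
#' @return A tibble with `sample_id`, `batch`, `condition`.
#' @export
default_samples <- function() {
  tibble(
    sample_id = sprintf("S%02d", 1:12),
    batch = sprintf("S%02d", 1:12),
    condition = rep(c("bacterial", "viral"), each = 6)
  )
}

sim_gene_ids <- function(cfg) {
  nuc <- sprintf("GENE%04d", seq_len(cfg$n_genes))
  mito <- if (cfg$n_mito_genes > 0) sprintf("MT-G%02d", seq_len(cfg$n_mito_genes)) else character(0)
  list(nuclear = nuc, mito = mito)
}

# Truncated normal (lower bound only) by inverse-CDF.
rtruncnorm_lower <- function(n, mean, sd, lower) {
  p0 <- pnorm(lower, mean, sd)
  qnorm(runif(n, p0, 1), mean, sd)
}

#' Simulate read-level poly(A) tail data
#'
#' For nuclear gene g the log2 tail of each read is
#' `mu_g + delta_g * 1[viral] + b_batch + eps`, with `b_batch ~ N(0,
#' batch_sd^2)` and `eps ~ N(0, read_noise_sd^2)`; mitochondrial reads come
#' from a truncated normal centred at `mito_tail_center`. Deterministic given
#' `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A list with `reads` (read-record tibble), `truth` (per-gene true
#'   median tails per condition, injected deltas, compartment), `gene_models`
#'   (gene length/GC/mitochondrial flags usable by downstream modules) and
#'   `metadata` (the sample sidecar).
#' @export
simulate_polya_reads <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  ids <- sim_gene_ids(config)
  dp <- config$dp_genes
  if (!is.null(dp)) {
    bad <- setdiff(dp$gene_id, ids$nuclear)
    if (length(bad) > 0) {
      stop_polyatails(
        sprintf("dp_genes not among simulated nuclear genes: %s",
                paste(utils::head(bad, 3), collapse = ", ")),
        "polyatails_config_error"
      )
    }
  }
  withr::with_seed(new_seed_stream(config$seed, 101L), {
    smp <- config$samples
    n_s <- nrow(smp)
    batches <- unique(smp$batch)
    # Per-gene batch intercepts: a library batch perturbs each gene's tail
    # estimates independently, which is exactly the random effect the
    # per-gene mixed model assumes (and keeps genes independent).
    b_eff <- matrix(rnorm(config$n_genes * length(batches), 0, config$batch_sd),
                    nrow = config$n_genes,
                    dimnames = list(NULL, batches))

    mu <- rnorm(config$n_genes, config$nuclear_tail_log2_median_mean,
                config$nuclear_tail_log2_median_sd)
    names(mu) <- ids$nuclear
    delta <- setNames(rep(0, config$n_genes), ids$nuclear)
    if (!is.null(dp)) delta[dp$gene_id] <- dp$delta_log2

    all_genes <- c(ids$nuclear, ids$mito)
    n_g <- length(all_genes)
    per_sample_mean <- config$reads_per_gene_mean / n_s

    # counts[g, s]
    counts <- matrix(
      rnbinom(n_g * n_s, mu = per_sample_mean,
              size = config$reads_per_gene_dispersion),
      nrow = n_g
    )
    gene_idx <- rep(rep(seq_len(n_g), n_s), times = as.vector(counts))
    samp_idx <- rep(rep(seq_len(n_s), each = n_g), times = as.vector(counts))
    n_reads <- length(gene_idx)

    is_mito <- gene_idx > config$n_genes
    tail <- numeric(n_reads)
    if (any(!is_mito)) {
      g <- gene_idx[!is_mito]
      s <- samp_idx[!is_mito]
      y <- mu[g] + delta[g] * (smp$condition[s] == "viral") +
        b_eff[cbind(g, match(smp$batch[s], batches))] +
        rnorm(sum(!is_mito), 0, config$read_noise_sd)
      tail[!is_mito] <- pmax(2^y, 1)
    }
    if (any(is_mito)) {
      tail[is_mito] <- pmax(
        rtruncnorm_lower(sum(is_mito), config$mito_tail_center,
                         config$mito_tail_sd, lower = 10), 1)
    }
    read_length <- pmax(as.integer(round(exp(rnorm(n_reads, log(971), 0.5)))), 50L)

    reads <- tibble(
      read_id = sprintf("read%07d", seq_len(n_reads)),
      sample_id = smp$sample_id[samp_idx],
      batch = smp$batch[samp_idx],
      condition = smp$condition[samp_idx],
      gene_id = all_genes[gene_idx],
      read_length = read_length,
      polya_length = tail
    )

    truth <- tibble(
      gene_id = all_genes,
      is_mitochondrial = c(rep(FALSE, config$n_genes),
                           rep(TRUE, config$n_mito_genes)),
      true_median_bacterial = c(2^mu, rep(config$mito_tail_center,
                                          config$n_mito_genes)),
      true_median_viral = c(2^(mu + delta), rep(config$mito_tail_center,
                                                config$n_mito_genes)),
      delta_log2 = c(delta, rep(0, config$n_mito_genes)),
      is_dp = c(delta != 0, rep(FALSE, config$n_mito_genes))
    )

    gene_models <- tibble(
      gene_id = all_genes,
      chromosome = c(rep("chr1", config$n_genes),
                     rep("chrM", config$n_mito_genes)),
      transcript_ids = lapply(all_genes, function(g) paste0(g, ".t1")),
      union_exon_length = as.integer(round(exp(rnorm(n_g, log(1500), 0.8)))),
      gc_fraction = stats::rbeta(n_g, 20, 20),
      is_mitochondrial = truth$is_mitochondrial
    )

    list(reads = reads, truth = truth, gene_models = gene_models,
         metadata = smp)
  })
}

#' Simulate paired two-platform count matrices
#'
#' Per gene, the two platforms' log expected abundances are bivariate normal
#' with correlation `platform_corr_target` (shared gene signal plus
#' platform-specific noise); platform A is additionally shifted by
#' `length_bias_coeff * log10(length)` and `gc_bias_coeff * (gc - 0.5)`, and
#' counts are Poisson around the exponentiated means.
#'
#' @param config A [sim_config()].
#' @param gene_models Optional gene-model tibble (defaults to freshly
#'   simulated lengths/GC).
#' @param poisson Draw Poisson counts around the exponentiated means
#'   (default); `FALSE` returns the noiseless expected abundances, useful
#'   for exact-identity checks.
#' @return List with `a` and `b` ([abundance_table()]s of counts), `truth`
#'   (per-gene expected log abundances, length, GC) and `metadata`.
#' @export
simulate_count_matrices <- function(config, gene_models = NULL,
                                    poisson = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(new_seed_stream(config$seed, 202L), {
    smp <- config$samples
    n_s <- nrow(smp)
    n_g <- config$n_genes
    genes <- sprintf("GENE%04d", seq_len(n_g))
    if (is.null(gene_models)) {
      gene_models <- tibble(
        gene_id = genes,
        union_exon_length = as.integer(round(exp(rnorm(n_g, log(1500), 0.8)))),
        gc_fraction = stats::rbeta(n_g, 20, 20)
      )
    }
    lens <- gene_models$union_exon_length[match(genes, gene_models$gene_id)]
    gc <- gene_models$gc_fraction[match(genes, gene_models$gene_id)]

    rho <- config$platform_corr_target
    tau2 <- config$abundance_log_sd^2
    noise_var <- tau2 * (1 - rho) / rho
    m_g <- rnorm(n_g, config$abundance_log_mean, sqrt(tau2))
    bias_a <- config$length_bias_coeff * log10(lens) +
      config$gc_bias_coeff * (gc - 0.5)

    draw <- function(biased) {
      mat <- matrix(0, n_g, n_s, dimnames = list(genes, smp$sample_id))
      for (s in seq_len(n_s)) {
        logmu <- m_g + rnorm(n_g, 0, sqrt(noise_var)) +
          if (biased) bias_a else 0
        mat[, s] <- if (poisson) rpois(n_g, exp(logmu)) else exp(logmu)
      }
      mat
    }
    a <- draw(biased = TRUE)
    b <- draw(biased = FALSE)

    truth <- tibble(
      gene_id = genes,
      log_abundance = m_g,
      union_exon_length = lens,
      gc_fraction = gc
    )
    list(
      a = abundance_table(a, unit = "counts", level = "gene"),
      b = abundance_table(b, unit = "counts", level = "gene"),
      truth = truth, metadata = smp
    )
  })
}

# One Dirichlet draw per row of alpha (matrix rows = draws).
rdirichlet_rows <- function(alpha) {
  g <- matrix(rgamma(length(alpha), shape = alpha, rate = 1),
              nrow = nrow(alpha))
  g / rowSums(g)
}

#' Simulate transcript-level isoform counts
#'
#' Per gene and sample, transcript counts are Dirichlet-multinomial: the
#' sample's proportion vector is Dirichlet around the condition's target
#' proportions with precision `dm_precision`, and counts are multinomial
#' given a negative-binomial total. DTU genes use distinct per-condition
#' proportion vectors; all other genes share one vector across conditions.
#'
#' @param config A [sim_config()].
#' @return List with `counts` (transcript-level [abundance_table()]),
#'   `tx2gene` (tibble `transcript_id`, `gene_id`), `truth` (per-gene
#'   condition proportion vectors and DTU flag) and `metadata`.
#' @export
simulate_isoform_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  dtu <- config$dtu_genes
  withr::with_seed(new_seed_stream(config$seed, 303L), {
    smp <- config$samples
    n_s <- nrow(smp)
    n_g <- config$n_genes
    k <- config$n_transcripts_per_gene
    genes <- sprintf("GENE%04d", seq_len(n_g))
    if (!is.null(dtu)) {
      bad <- setdiff(dtu$gene_id, genes)
      if (length(bad) > 0) {
        stop_polyatails("dtu_genes not among simulated genes.",
                        "polyatails_config_error")
      }
    }

    base_prop <- rdirichlet_rows(matrix(5, n_g, k))
    prop_bact <- base_prop
    prop_viral <- base_prop
    is_dtu <- rep(FALSE, n_g)
    if (!is.null(dtu)) {
      for (i in seq_len(nrow(dtu))) {
        gi <- match(dtu$gene_id[i], genes)
        pb <- dtu$prop_bacterial[[i]]
        pv <- dtu$prop_viral[[i]]
        if (length(pb) != k || length(pv) != k ||
            abs(sum(pb) - 1) > 1e-8 || abs(sum(pv) - 1) > 1e-8) {
          stop_polyatails("dtu proportion vectors must have length k and sum to 1.",
                          "polyatails_config_error")
        }
        prop_bact[gi, ] <- pb
        prop_viral[gi, ] <- pv
        is_dtu[gi] <- TRUE
      }
    }

    tx_ids <- as.vector(t(outer(genes, seq_len(k),
                                function(g, j) sprintf("%s.t%d", g, j))))
    counts <- matrix(0L, n_g * k, n_s,
                     dimnames = list(tx_ids, smp$sample_id))
    viral <- smp$condition == "viral"
    for (s in seq_len(n_s)) {
      totals <- rnbinom(n_g, mu = config$iso_total_mean,
                        size = config$iso_total_dispersion)
      target <- if (viral[s]) prop_viral else prop_bact
      p <- rdirichlet_rows(target * config$dm_precision)
      for (g in seq_len(n_g)) {
        if (totals[g] > 0) {
          counts[((g - 1) * k + 1):(g * k), s] <-
            as.integer(rmultinom(1, totals[g], p[g, ]))
        }
      }
    }

    truth <- tibble(
      gene_id = genes,
      prop_bacterial = lapply(seq_len(n_g), function(g) prop_bact[g, ]),
      prop_viral = lapply(seq_len(n_g), function(g) prop_viral[g, ]),
      is_dtu = is_dtu
    )
    list(
      counts = abundance_table(counts, unit = "counts", level = "transcript"),
      tx2gene = tibble(transcript_id = tx_ids, gene_id = rep(genes, each = k)),
      truth = truth, metadata = smp
    )
  })
}
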