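#' Simulation configuration for paired expression data
#'
#' Defines a paired bulk + single-cell dataset with a planted TF-target
#' regulatory structure. Each TF has a latent log-activity drawn per bulk
#' sample and per cell; its targets track that activity with slope
#' `effect_slope` on the log scale, while decoy genes are independent of
#' every TF. Bulk values are log-normal around the gene's log-mean;
#' single-cell values are negative-binomial counts with Bernoulli dropout,
#' emulating the sparse, zero-inflated counts of scRNA-Seq.
#'
#' The defaults describe the strong-signal regime used throughout the
#' package's own evaluation: 40 TFs x 5 targets plus 200 decoys (440
#' genes, 400 labeled pairs), 200 bulk samples and 500 cells, slope 2,
#' bulk noise sd 0.2 on the natural-log scale, negative-binomial size 2
#' and 30\% dropout.
#'
#' @param n_tfs Number of transcription factors.
#' @param targets_per_tf Regulated targets per TF.
#' @param n_decoys Unregulated genes used as negative-pair partners.
#' @param n_bulk_samples Number of bulk samples.
#' @param n_cells Number of single cells.
#' @param effect_slope Regulatory strength on the log scale; 0 removes
#'   the planted signal entirely.
#' @param bulk_noise_sd Log-scale Gaussian noise sd of bulk values.
#' @param sc_dispersion Negative-binomial size parameter (inverse
#'   dispersion) of single-cell counts; smaller is noisier.
#' @param dropout_rate Probability that a single-cell count is zeroed.
#' @param baseline_log_mean,baseline_log_sd Mean and sd of the latent
#'   log-activity (natural-log scale).
#' @param seed Integer seed; identical config + seed gives bit-identical
#'   output.
#' @return A `SimulationConfig` list.
#' @export
simulation_config <- function(n_tfs = 40, targets_per_tf = 5, n_decoys = 200,
                              n_bulk_samples = 200, n_cells = 500,
                              effect_slope = 2, bulk_noise_sd = 0.2,
                              sc_dispersion = 2, dropout_rate = 0.3,
                              baseline_log_mean = 3, baseline_log_sd = 1,
                              seed = 1L) {
  cfg <- list(n_tfs = as.integer(n_tfs), targets_per_tf = as.integer(targets_per_tf),
              n_decoys = as.integer(n_decoys),
              n_bulk_samples = as.integer(n_bulk_samples),
              n_cells = as.integer(n_cells), effect_slope = effect_slope,
              bulk_noise_sd = bulk_noise_sd, sc_dispersion = sc_dispersion,
              dropout_rate = dropout_rate, baseline_log_mean = baseline_log_mean,
              baseline_log_sd = baseline_log_sd, seed = as.integer(seed))
  stopifnot(cfg$n_tfs >= 1, cfg$targets_per_tf >= 1, cfg$n_decoys >= 0,
            cfg$n_bulk_samples >= 1, cfg$n_cells >= 1,
            cfg$bulk_noise_sd >= 0, cfg$sc_dispersion > 0,
            cfg$dropout_rate >= 0, cfg$dropout_rate <= 1,
            cfg$baseline_log_sd >= 0)
  class(cfg) <- "SimulationConfig"
  cfg
}

#' Simulate a paired bulk + single-cell dataset with planted regulation
#'
#' Generates an expression dataset in which every TF's targets co-vary
#' with the TF across both bulk samples and single cells, and decoy genes
#' are independent, then emits one positive label per (TF, own target)
#' pair and an equal number of (TF, decoy) negative pairs sampled without
#' replacement.
#'
#' @param config A [simulation_config()].
#' @return A list with `bulk` and `sc` (`ExpressionMatrix` objects, raw
#'   state) and `pairs` (a `GenePairLabelSet` data frame with columns
#'   `tf_id`, `target_id`, `label`).
#' @export
simulate_paired_dataset <- function(config = simulation_config()) {
  stopifnot(inherits(config, "SimulationConfig"))
  n_pos <- config$n_tfs * config$targets_per_tf
  if (config$n_tfs * config$n_decoys < n_pos)
    stop(sprintf("need %d negative (TF, decoy) pairs but only %d are available",
                 n_pos, config$n_tfs * config$n_decoys))
  set.seed(config$seed)

  tf_ids <- sprintf("TF%03d", seq_len(config$n_tfs))
  tg_ids <- as.vector(vapply(seq_len(config$n_tfs), function(i)
    sprintf("TG%03d_%02d", i, seq_len(config$targets_per_tf)),
    character(config$targets_per_tf)))
  dc_ids <- if (config$n_decoys > 0) sprintf("DC%04d", seq_len(config$n_decoys)) else character()
  genes <- c(tf_ids, tg_ids, dc_ids)
  owner <- rep(seq_len(config$n_tfs), each = config$targets_per_tf)

  mu0 <- config$baseline_log_mean

  sim_modality <- function(n_units, unit_prefix, single_cell) {
    # latent activity per TF per unit
    act <- matrix(stats::rnorm(config$n_tfs * n_units, mu0, config$baseline_log_sd),
                  nrow = config$n_tfs)
    logmean <- matrix(0, nrow = length(genes), ncol = n_units,
                      dimnames = list(genes, sprintf("%s%04d", unit_prefix, seq_len(n_units))))
    logmean[tf_ids, ] <- act
    logmean[tg_ids, ] <- mu0 + config$effect_slope * (act[owner, , drop = FALSE] - mu0)
    if (length(dc_ids)) {
      # decoys follow the same marginal law as targets — an independent
      # "phantom TF" latent scaled by the same slope — so positives and
      # negatives differ only in their joint structure with the TF, and
      # at slope 0 planted pairs are exchangeable with decoy pairs
      phantom <- matrix(stats::rnorm(length(dc_ids) * n_units, mu0,
                                     config$baseline_log_sd),
                        nrow = length(dc_ids))
      logmean[dc_ids, ] <- mu0 + config$effect_slope * (phantom - mu0)
    }
    if (single_cell) {
      counts <- matrix(stats::rnbinom(length(logmean), mu = exp(logmean),
                                      size = config$sc_dispersion),
                       nrow = nrow(logmean), dimnames = dimnames(logmean))
      if (config$dropout_rate > 0) {
        drop <- matrix(stats::runif(length(counts)) < config$dropout_rate,
                       nrow = nrow(counts))
        counts[drop] <- 0
      }
      counts
    } else {
      exp(logmean + matrix(stats::rnorm(length(logmean), 0, config$bulk_noise_sd),
                           nrow = nrow(logmean)))
    }
  }

  bulk_v <- sim_modality(config$n_bulk_samples, "S", single_cell = FALSE)
  sc_v <- sim_modality(config$n_cells, "C", single_cell = TRUE)

  positives <- data.frame(tf_id = tf_ids[owner], target_id = tg_ids,
                          label = 1L, stringsAsFactors = FALSE)
  # negatives: uniform sample without replacement from TF x decoy
  all_neg <- expand.grid(tf_id = tf_ids, target_id = dc_ids,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  take <- sample.int(nrow(all_neg), n_pos)
  negatives <- all_neg[take, , drop = FALSE]
  negatives$label <- 0L
  pairs <- rbind(positives, negatives)
  rownames(pairs) <- NULL
  pairs <- gene_pair_label_set(pairs, provenance = "simulated")

  list(bulk = expression_matrix(bulk_v, modality = "bulk"),
       sc = expression_matrix(sc_v, modality = "single_cell"),
       pairs = pairs)
}

#' Per-pair rank-correlation summary of a simulated dataset
#'
#' Computes the Spearman correlation of every labeled pair in each
#' modality and the group means by label — a quick check that planted
#' pairs co-vary more strongly than decoy pairs.
#'
#' @param bulk,sc `ExpressionMatrix` objects.
#' @param pairs A `GenePairLabelSet`.
#' @return A list with `per_pair` (data frame: tf_id, target_id, label,
#'   cor_bulk, cor_sc) and `group_means` (data frame of mean absolute
#'   correlations by label).
#' @export
summarize_simulation <- function(bulk, sc, pairs) {
  if (nrow(pairs) == 0) {
    empty <- data.frame(tf_id = character(), target_id = character(),
                        label = integer(), cor_bulk = numeric(),
                        cor_sc = numeric(), stringsAsFactors = FALSE)
    return(list(per_pair = empty,
                group_means = data.frame(label = integer(),
                                         mean_abs_cor_bulk = numeric(),
                                         mean_abs_cor_sc = numeric())))
  }
  pair_cor <- function(em, tf, tg) {
    suppressWarnings(stats::cor(em$values[tf, ], em$values[tg, ],
                                method = "spearman"))
  }
  cor_bulk <- mapply(pair_cor, list(bulk), pairs$tf_id, pairs$target_id)
  cor_sc <- mapply(pair_cor, list(sc), pairs$tf_id, pairs$target_id)
  per_pair <- data.frame(tf_id = pairs$tf_id, target_id = pairs$target_id,
                         label = pairs$label, cor_bulk = cor_bulk,
                         cor_sc = cor_sc, stringsAsFactors = FALSE)
  gm <- do.call(rbind, lapply(split(per_pair, per_pair$label), function(d)
    data.frame(label = d$label[1],
               mean_abs_cor_bulk = mean(abs(d$cor_bulk), na.rm = TRUE),
               mean_abs_cor_sc = mean(abs(d$cor_sc), na.rm = TRUE))))
  rownames(gm) <- NULL
  list(per_pair = per_pair, group_means = gm)
}
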