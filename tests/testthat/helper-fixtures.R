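# Shared fixtures: everything is generated in code at test time.

# small named expression matrix with reproducible values
toy_matrix <- function(genes = c("g1", "g2", "g3"), samples = c("s1", "s2"),
                       seed = 1, modality = "bulk") {
  set.seed(seed)
  v <- matrix(round(stats::runif(length(genes) * length(samples), 0, 100), 3),
              nrow = length(genes), dimnames = list(genes, samples))
  expression_matrix(v, modality = modality)
}

write_tsv_lines <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

# a tiny simulated dataset shared across tests (cheap: ~1 s)
tiny_sim <- function(seed = 7, effect_slope = 2) {
  simulate_paired_dataset(simulation_config(
    n_tfs = 8, targets_per_tf = 3, n_decoys = 40,
    n_bulk_samples = 60, n_cells = 120,
    effect_slope = effect_slope, seed = seed))
}

# small-model config for fast classifier tests (full layer inventory,
# reduced widths and 8-bin images -> 16x8 stacked input)
tiny_model_config <- function(input_shape = c(16L, 8L), max_epochs = 5L,
                              seed = 3L, ...) {
  model_config(input_shape = input_shape,
               conv_filters = c(8L, 8L, 16L, 16L, 16L, 16L),
               dense_widths = c(32L, 16L),
               max_epochs = max_epochs, early_stop_patience = 3L,
               seed = seed, ...)
}

tiny_hist_config <- function(...) histogram_config(bins = 8L, ...)

# brute-force 2D histogram oracle: explicit double loop over samples
histogram2d_oracle <- function(x, y, bins, x_range, y_range) {
  counts <- matrix(0, bins, bins)
  ex <- seq(x_range[1], x_range[2], length.out = bins + 1)
  ey <- seq(y_range[1], y_range[2], length.out = bins + 1)
  bin1 <- function(v, e) {
    for (i in seq_len(length(e) - 1)) {
      hi <- e[i + 1]
      if ((v >= e[i] && v < hi) || (i == length(e) - 1 && v == hi)) return(i)
    }
    NA_integer_
  }
  for (s in seq_along(x)) {
    bx <- bin1(x[s], ex)
    by <- bin1(y[s], ey)
    if (!is.na(bx) && !is.na(by)) counts[bx, by] <- counts[bx, by] + 1
  }
  counts
}

# exhaustive concordant-pair AUROC oracle
auroc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + if (p > n) 1 else if (p == n) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# exact hypergeometric upper tail by enumerating all draws of size n
hyper_tail_oracle <- function(k, K, N, n) {
  # P(X >= k), X = overlap of a uniform n-subset with a fixed K-subset
  total <- choose(N, n)
  sum(vapply(k:min(n, K), function(i)
    choose(K, i) * choose(N - K, n - i), numeric(1))) / total
}
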