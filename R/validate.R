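#' Reference network constructor
#'
#' An experimentally derived TF -> target network (ChIP binding,
#' perturbation DE sets, Y1H promoter binding, DAP-seq target lists)
#' consumed as gene-level edges.
#'
#' @param df Data frame with columns `tf_id`, `target_id` and optionally
#'   `source`.
#' @param source Source tag used when `df` lacks a `source` column.
#' @return The data frame with class `ReferenceNetwork`.
#' @export
reference_network <- function(df, source = "other") {
  stopifnot(is.data.frame(df), all(c("tf_id", "target_id") %in% names(df)))
  df$tf_id <- as.character(df$tf_id)
  df$target_id <- as.character(df$target_id)
  if (is.null(df$source)) df$source <- source
  df <- df[!duplicated(paste(df$tf_id, df$target_id, sep = "\r")), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("ReferenceNetwork", "data.frame")
  df
}

#' Read a reference network TSV (`tf_id  target_id  [source]`)
#' @param path Path to the TSV; a header line and `#` comments are
#'   optional.
#' @return A `ReferenceNetwork`.
#' @export
read_reference_tsv <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (grepl("tf_id", lines[1], fixed = TRUE)) lines <- lines[-1]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  df <- data.frame(tf_id = vapply(parts, `[[`, "", 1),
                   target_id = vapply(parts, `[[`, "", 2),
                   stringsAsFactors = FALSE)
  if (all(lengths(parts) >= 3)) df$source <- vapply(parts, `[[`, "", 3)
  reference_network(df)
}

.target_sets <- function(net) {
  split(net$target_id, net$tf_id)
}

#' Overlap between a predicted and a reference network
#'
#' The overlap is the number of (tf, target) edges present in both
#' networks. The comparable edge count — the reference edges whose TF is
#' predicted at all — is the denominator used for overlap percentages.
#'
#' @param predicted An `EdgeList`.
#' @param reference A `ReferenceNetwork`.
#' @return A list with `observed`, `comparable_edge_count` and
#'   `overlap_pct` (100 * observed / comparable).
#' @export
count_overlap <- function(predicted, reference) {
  pred_key <- paste(predicted$tf_id, predicted$target_id, sep = "\r")
  ref_key <- paste(reference$tf_id, reference$target_id, sep = "\r")
  observed <- sum(ref_key %in% pred_key)
  comparable <- sum(reference$tf_id %in% unique(predicted$tf_id))
  list(observed = observed, comparable_edge_count = comparable,
       overlap_pct = if (comparable > 0) 100 * observed / comparable else NA_real_)
}

#' Fold enrichment of an observed overlap over its null expectation
#'
#' @param observed Observed overlap count.
#' @param expected Null-expected overlap (permutation mean).
#' @return `observed / expected`; `Inf` (flagged, not an error) when
#'   `expected` is 0. Summaries report it to 2 decimals.
#' @export
fold_enrichment <- function(observed, expected) {
  if (expected < 0) stop("'expected' must be non-negative")
  if (expected == 0) return(Inf)
  observed / expected
}

#' Permutation-null expected overlap between networks
#'
#' Each permutation rewires the predicted network by replacing every
#' TF's target set with a uniform sample of equal size drawn without
#' replacement from the gene universe — a degree-preserving null. The
#' expected overlap is the mean across permutations; the empirical
#' p-value is the fraction of permutations whose overlap strictly
#' exceeds the observed one, displayed as `< 1/n` when that count is 0.
#'
#' @param predicted An `EdgeList`.
#' @param reference A `ReferenceNetwork`.
#' @param universe Character vector of candidate target genes; must
#'   contain every predicted target.
#' @param n_permutations Number of permutations (default 10000).
#' @param seed Integer seed.
#' @return An `OverlapEnrichmentResult` list: `observed`, `expected`,
#'   `range`, `fold_enrichment`, `empirical_p`, `p_display`,
#'   `n_permutations`, `seed`.
#' @export
permutation_expected_overlap <- function(predicted, reference, universe,
                                         n_permutations = 10000L, seed = 1L) {
  stopifnot(inherits(predicted, "EdgeList"))
  missing <- setdiff(unique(predicted$target_id), universe)
  if (length(missing))
    stop("universe lacks predicted target(s): ",
         paste(utils::head(missing, 5), collapse = ", "))
  obs <- count_overlap(predicted, reference)$observed
  degrees <- table(predicted$tf_id)
  ref_sets <- .target_sets(reference)
  N <- length(universe)
  if (any(degrees > N)) stop("a TF's out-degree exceeds the universe size")
  # per TF: indicator over the universe of membership in its reference set
  tf_ids <- names(degrees)
  indicators <- lapply(tf_ids, function(tf) universe %in% ref_sets[[tf]])
  d <- as.integer(degrees)
  set.seed(seed)
  perm_overlap <- integer(n_permutations)
  for (b in seq_len(n_permutations)) {
    tot <- 0L
    for (i in seq_along(tf_ids)) {
      tot <- tot + sum(indicators[[i]][sample.int(N, d[i])])
    }
    perm_overlap[b] <- tot
  }
  expected <- mean(perm_overlap)
  n_greater <- sum(perm_overlap > obs)
  structure(list(observed = obs, expected = expected,
                 range = range(perm_overlap),
                 fold_enrichment = fold_enrichment(obs, expected),
                 empirical_p = n_greater / n_permutations,
                 p_display = if (n_greater == 0)
                   sprintf("< %g", 1 / n_permutations)
                 else sprintf("%g", n_greater / n_permutations),
                 n_permutations = n_permutations, seed = seed),
            class = "OverlapEnrichmentResult")
}

#' @export
print.OverlapEnrichmentResult <- function(x, ...) {
  cat(sprintf(
    "overlap %d (expected %.1f, range %d-%d), fold enrichment %.2f, p %s (%d permutations)\n",
    x$observed, x$expected, x$range[1], x$range[2], x$fold_enrichment,
    x$p_display, x$n_permutations))
  invisible(x)
}

#' Upper-tail hypergeometric overlap test
#'
#' Probability of drawing at least the observed overlap: `P(X >= k)` for
#' X hypergeometric with population `|universe|`, `|reference_targets|`
#' successes and `|predicted_targets|` draws,
#' `k = |intersection|`.
#'
#' @param predicted_targets,reference_targets Character vectors (sets),
#'   both subsets of `universe`.
#' @param universe Character vector of the candidate gene universe.
#' @return The upper-tail p-value.
#' @export
hypergeometric_target_overlap <- function(predicted_targets, reference_targets,
                                          universe) {
  predicted_targets <- unique(predicted_targets)
  reference_targets <- unique(reference_targets)
  universe <- unique(universe)
  if (length(setdiff(predicted_targets, universe)) ||
      length(setdiff(reference_targets, universe)))
    stop("both target sets must be subsets of the universe")
  k <- length(intersect(predicted_targets, reference_targets))
  stats::phyper(k - 1, length(reference_targets),
                length(universe) - length(reference_targets),
                length(predicted_targets), lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment (`q_(i) = min_{j >= i} p_(j) * m / j`, capped
#' at 1), returned in input order.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted q-values in input order.
#' @export
bh_adjust <- function(p_values) {
  if (!length(p_values)) return(numeric(0))
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Per-TF hypergeometric target-set overlap table
#'
#' For every TF present in both networks, tests whether its predicted
#' target set overlaps its reference target set more than expected by
#' chance, with BH adjustment across the table.
#'
#' @param predicted An `EdgeList`.
#' @param reference A `ReferenceNetwork`.
#' @param universe Candidate gene universe.
#' @param q_cutoff Significance cutoff on the adjusted value (default
#'   0.05).
#' @return A list with `table` (tf_id, k, n_predicted, n_reference,
#'   n_universe, p, q, significant), `n_reference_tfs`, `n_shared_tfs`,
#'   `shared_pct`, `n_significant`, `significant_pct` (of shared TFs).
#' @export
per_tf_enrichment_table <- function(predicted, reference, universe,
                                    q_cutoff = 0.05) {
  pred_sets <- .target_sets(predicted)
  ref_sets <- .target_sets(reference)
  ref_tfs <- names(ref_sets)
  shared <- intersect(ref_tfs, names(pred_sets))
  if (!length(shared)) {
    tab <- data.frame(tf_id = character(), k = integer(),
                      n_predicted = integer(), n_reference = integer(),
                      n_universe = integer(), p = numeric(), q = numeric(),
                      significant = logical(), stringsAsFactors = FALSE)
  } else {
    rows <- lapply(shared, function(tf) {
      ps <- intersect(unique(pred_sets[[tf]]), universe)
      rs <- intersect(unique(ref_sets[[tf]]), universe)
      data.frame(tf_id = tf, k = length(intersect(ps, rs)),
                 n_predicted = length(ps), n_reference = length(rs),
                 n_universe = length(unique(universe)),
                 p = hypergeometric_target_overlap(ps, rs, universe),
                 stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    tab$q <- bh_adjust(tab$p)
    tab$significant <- tab$q < q_cutoff
  }
  list(table = tab,
       n_reference_tfs = length(ref_tfs),
       n_shared_tfs = length(shared),
       shared_pct = if (length(ref_tfs)) 100 * length(shared) / length(ref_tfs) else NA_real_,
       n_significant = sum(tab$significant),
       significant_pct = if (length(ref_tfs)) 100 * sum(tab$significant) / length(ref_tfs) else NA_real_)
}
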