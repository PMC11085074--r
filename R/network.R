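#' Score all TF x candidate pairs with a trained classifier
#'
#' Streams over the TF x candidate grid in chunks (so genome-scale scans
#' never hold the full image corpus in memory), skipping self-pairs, and
#' returns every scored edge.
#'
#' @param model A trained `PairClassifier`.
#' @param tf_ids TF gene ids (must be present in both matrices).
#' @param candidate_ids Candidate target gene ids.
#' @param bulk,sc Aligned `ExpressionMatrix` objects.
#' @param hist_config The [histogram_config()] the model was trained
#'   under.
#' @param chunk_size Pairs scored per chunk (default 1000).
#' @return An `EdgeList` data frame with columns `tf_id`, `target_id`,
#'   `score`.
#' @export
scan_all_pairs <- function(model, tf_ids, candidate_ids, bulk, sc,
                           hist_config = histogram_config(),
                           chunk_size = 1000L) {
  grid <- expand.grid(target_id = candidate_ids, tf_id = tf_ids,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[grid$tf_id != grid$target_id, c("tf_id", "target_id")]
  rownames(grid) <- NULL
  n <- nrow(grid)
  scores <- numeric(n)
  for (s in seq(1, n, by = chunk_size)) {
    e <- min(s + chunk_size - 1, n)
    imgs <- lapply(s:e, function(i)
      make_pair_image(bulk, sc, grid$tf_id[i], grid$target_id[i], hist_config))
    scores[s:e] <- predict_scores(model, imgs)
  }
  grid$score <- scores
  edge_list(grid)
}

#' Edge list constructor / validator
#'
#' @param df Data frame with columns `tf_id`, `target_id`, `score`.
#' @return The validated data frame with class `EdgeList` (no duplicate
#'   pairs, no self-edges, scores in `[0, 1]`).
#' @export
edge_list <- function(df) {
  stopifnot(is.data.frame(df),
            all(c("tf_id", "target_id", "score") %in% names(df)))
  df$tf_id <- as.character(df$tf_id)
  df$target_id <- as.character(df$target_id)
  if (any(df$tf_id == df$target_id)) stop("self-edges are not allowed")
  if (anyDuplicated(paste(df$tf_id, df$target_id, sep = "\r")))
    stop("duplicate (tf_id, target_id) edges")
  if (any(df$score < 0 | df$score > 1)) stop("scores must lie in [0, 1]")
  class(df) <- c("EdgeList", "data.frame")
  df
}

#' Retain the top-scoring fraction of edges
#'
#' Keeps the `ceiling(fraction * N)` highest-scoring edges. Ties at the
#' retention boundary are broken by (tf_id, target_id) lexicographic
#' order so the result is exactly reproducible, and the minimum retained
#' score is reported as the implied probability cutoff.
#'
#' @param edges An `EdgeList`.
#' @param fraction Fraction to retain, in (0, 1] (default 0.10).
#' @return A list with `edges` (retained `EdgeList`) and `cutoff` (the
#'   minimum retained score).
#' @export
threshold_top_fraction <- function(edges, fraction = 0.10) {
  stopifnot(inherits(edges, "EdgeList"))
  if (nrow(edges) == 0) stop("empty edge list")
  if (fraction <= 0 || fraction > 1) stop("'fraction' must be in (0, 1]")
  n_keep <- ceiling(fraction * nrow(edges))
  ord <- order(-edges$score, edges$tf_id, edges$target_id)
  kept <- edges[ord[seq_len(n_keep)], , drop = FALSE]
  rownames(kept) <- NULL
  list(edges = edge_list(kept), cutoff = min(kept$score))
}

#' Retain edges above a score cutoff
#'
#' Strict inequality: an edge is kept only when `score > cutoff`.
#'
#' @param edges An `EdgeList`.
#' @param cutoff Score cutoff in `[0, 1]` (default 0.5).
#' @return The filtered `EdgeList`.
#' @export
threshold_by_score <- function(edges, cutoff = 0.5) {
  stopifnot(inherits(edges, "EdgeList"))
  if (cutoff < 0 || cutoff > 1) stop("'cutoff' must be in [0, 1]")
  out <- edges[edges$score > cutoff, , drop = FALSE]
  rownames(out) <- NULL
  edge_list(out)
}

#' Distribution of the number of predicted TFs per target
#'
#' @param edges A non-empty `EdgeList`.
#' @return A list with `per_target` (data frame: target_id, n_tfs) and
#'   `binned` (data frame: bin in 1-100 / 101-1000 / >1000, n_targets,
#'   percentage; percentages sum to 100 over targets with at least one
#'   regulator).
#' @export
target_degree_distribution <- function(edges) {
  stopifnot(inherits(edges, "EdgeList"))
  if (nrow(edges) == 0) stop("empty edge list")
  tab <- table(edges$target_id)
  per_target <- data.frame(target_id = names(tab), n_tfs = as.integer(tab),
                           stringsAsFactors = FALSE)
  bins <- cut(per_target$n_tfs, breaks = c(0, 100, 1000, Inf),
              labels = c("1-100", "101-1000", ">1000"))
  counts <- table(bins)
  binned <- data.frame(bin = names(counts), n_targets = as.integer(counts),
                       percentage = 100 * as.integer(counts) / nrow(per_target),
                       stringsAsFactors = FALSE)
  list(per_target = per_target, binned = binned)
}

#' Per-TF and per-family interaction summary
#'
#' @param edges A non-empty `EdgeList`.
#' @param family_map Optional data frame with columns `tf_id`, `family`;
#'   rows naming TFs absent from the edge list are ignored with a
#'   warning.
#' @return A list with `per_tf` (tf_id, n_targets), `mean_targets`
#'   (total edges / TFs with >= 1 edge), `median_targets`, and
#'   `per_family` when a map is supplied (family, n_members,
#'   mean_targets, median_targets).
#' @export
tf_summary <- function(edges, family_map = NULL) {
  stopifnot(inherits(edges, "EdgeList"))
  if (nrow(edges) == 0) stop("empty edge list")
  tab <- table(edges$tf_id)
  per_tf <- data.frame(tf_id = names(tab), n_targets = as.integer(tab),
                       stringsAsFactors = FALSE)
  out <- list(per_tf = per_tf,
              mean_targets = nrow(edges) / nrow(per_tf),
              median_targets = stats::median(per_tf$n_targets))
  if (!is.null(family_map)) {
    stopifnot(all(c("tf_id", "family") %in% names(family_map)))
    unknown <- setdiff(family_map$tf_id, per_tf$tf_id)
    if (length(unknown))
      warning(length(unknown), " family-map TF(s) absent from the edge list; ignored")
    fm <- merge(per_tf, family_map, by = "tf_id")
    out$per_family <- do.call(rbind, lapply(split(fm, fm$family), function(d)
      data.frame(family = d$family[1], n_members = nrow(d),
                 mean_targets = mean(d$n_targets),
                 median_targets = stats::median(d$n_targets),
                 stringsAsFactors = FALSE)))
    rownames(out$per_family) <- NULL
  }
  out
}

#' Write an edge list TSV
#'
#' Tab-separated `tf_id  target_id  score` preceded by a `#`-prefixed
#' header block recording provenance metadata.
#'
#' @param edges An `EdgeList`.
#' @param path Output path.
#' @param metadata Named character vector written as `# key: value`
#'   header lines.
#' @return `path`, invisibly.
#' @export
write_edges_tsv <- function(edges, path, metadata = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(metadata))
    writeLines(sprintf("# %s: %s", k, metadata[[k]]), con)
  writeLines("tf_id\ttarget_id\tscore", con)
  writeLines(sprintf("%s\t%s\t%s", edges$tf_id, edges$target_id,
                     format(edges$score, digits = 17, trim = TRUE)), con)
  invisible(path)
}

#' Read an edge list TSV written by [write_edges_tsv()]
#' @param path Path to the TSV.
#' @return An `EdgeList`.
#' @export
read_edges_tsv <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  stopifnot(length(lines) >= 1, lines[1] == "tf_id\ttarget_id\tscore")
  if (length(lines) == 1)
    return(edge_list(data.frame(tf_id = character(), target_id = character(),
                                score = numeric(), stringsAsFactors = FALSE)))
  parts <- strsplit(lines[-1], "\t", fixed = TRUE)
  edge_list(data.frame(tf_id = vapply(parts, `[[`, "", 1),
                       target_id = vapply(parts, `[[`, "", 2),
                       score = as.numeric(vapply(parts, `[[`, "", 3)),
                       stringsAsFactors = FALSE))
}
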