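#' Histogram featurization configuration
#'
#' Controls how a gene pair's joint expression is turned into the 2D
#' histogram image the classifier consumes.
#'
#' @param bins Bins per axis (default 32, giving 32 x 32 blocks and a
#'   64 x 32 stacked image).
#' @param count_transform `"log10_1p"` (default) applies log10(1 + count)
#'   entrywise after binning, compressing the dynamic-range gap between a
#'   few hundred bulk samples and thousands of cells; `"raw"` keeps
#'   counts, so each block sums to its modality's sample count.
#' @param combine `"stacked"` (default; bulk block on top of the
#'   single-cell block, shape 2*bins x bins), `"bulk_only"` or
#'   `"sc_only"` (shape bins x bins).
#' @return A `HistogramConfig` list.
#' @export
histogram_config <- function(bins = 32L, count_transform = c("log10_1p", "raw"),
                             combine = c("stacked", "bulk_only", "sc_only")) {
  bins <- as.integer(bins)
  if (bins < 2) stop("'bins' must be >= 2")
  cfg <- list(bins = bins, count_transform = match.arg(count_transform),
              range_policy = "per_gene_min_max", combine = match.arg(combine))
  class(cfg) <- "HistogramConfig"
  cfg
}

#' 2D histogram with equal-width bins
#'
#' Bins the paired observations (x_i, y_i) on an equal-width grid. Bins
#' are half-open `[e_i, e_{i+1})` with the final bin closed on the right,
#' so when all values lie within range the counts sum to the number of
#' observations. A degenerate range (lo == hi, e.g. a constant gene) is
#' widened to `[lo, lo + 1]` with a warning.
#'
#' @param x,y Numeric vectors of equal length >= 1.
#' @param bins Number of bins per axis.
#' @param x_range,y_range Length-2 `c(lo, hi)` ranges.
#' @return A `bins x bins` count matrix; entry `[i, j]` counts
#'   observations with x in x-bin i and y in y-bin j.
#' @export
histogram2d <- function(x, y, bins, x_range = range(x), y_range = range(y)) {
  if (length(x) != length(y))
    stop(sprintf("length mismatch: |x| = %d, |y| = %d", length(x), length(y)))
  if (length(x) < 1) stop("need at least one observation")
  bins <- as.integer(bins)
  if (bins < 1) stop("'bins' must be >= 1")
  fix_range <- function(r, axis) {
    if (r[1] > r[2]) stop("invalid ", axis, " range")
    if (r[1] == r[2]) {
      warning(sprintf("degenerate %s range [%g, %g] widened to [%g, %g]",
                      axis, r[1], r[2], r[1], r[1] + 1))
      r[2] <- r[1] + 1
    }
    r
  }
  x_range <- fix_range(x_range, "x")
  y_range <- fix_range(y_range, "y")
  bin_of <- function(v, r) {
    edges <- seq(r[1], r[2], length.out = bins + 1)
    idx <- findInterval(v, edges, rightmost.closed = TRUE)
    idx[v < r[1] | v > r[2]] <- NA_integer_ # out of range: not counted
    idx
  }
  bx <- bin_of(x, x_range)
  by <- bin_of(y, y_range)
  keep <- !is.na(bx) & !is.na(by)
  counts <- matrix(0, bins, bins)
  if (any(keep)) {
    tab <- table(factor(bx[keep], levels = seq_len(bins)),
                 factor(by[keep], levels = seq_len(bins)))
    counts <- matrix(as.numeric(tab), bins, bins)
  }
  counts
}

#' Build the pair image for one (TF, target) pair
#'
#' Extracts the TF's and the target's expression vectors from each
#' requested modality, bins them into a `bins x bins` joint histogram
#' (TF on the first axis, target on the second) using each gene's
#' per-modality min/max as the range, applies the count transform, and —
#' in stacked mode — concatenates the bulk block above the single-cell
#' block into a `2*bins x bins` image.
#'
#' @param bulk,sc `ExpressionMatrix` objects (either may be NULL when the
#'   config does not use that modality).
#' @param tf_id,target_id Gene identifiers.
#' @param config A [histogram_config()].
#' @param label Optional 0/1 label carried on the image.
#' @return A `PairImage` list with fields `tf_id`, `target_id`, `tensor`,
#'   `label`.
#' @export
make_pair_image <- function(bulk, sc, tf_id, target_id,
                            config = histogram_config(), label = NULL) {
  stopifnot(inherits(config, "HistogramConfig"))
  block <- function(em, modality) {
    if (is.null(em)) stop("modality '", modality, "' requested but matrix is NULL")
    for (g in c(tf_id, target_id))
      if (!g %in% rownames(em$values))
        stop(sprintf("gene '%s' not present in the %s matrix", g, modality))
    x <- em$values[tf_id, ]
    y <- em$values[target_id, ]
    h <- histogram2d(x, y, config$bins, range(x), range(y))
    if (config$count_transform == "log10_1p") log10(1 + h) else h
  }
  tensor <- switch(config$combine,
    bulk_only = block(bulk, "bulk"),
    sc_only = block(sc, "single-cell"),
    stacked = rbind(block(bulk, "bulk"), block(sc, "single-cell")))
  structure(list(tf_id = tf_id, target_id = target_id, tensor = tensor,
                 label = if (is.null(label)) NA_integer_ else as.integer(label)),
            class = "PairImage")
}

#' Build the image corpus for a labeled pair set
#'
#' One image per pair, in input order. Pairs referencing a gene absent
#' from the aligned matrices are skipped with a warning and counted.
#' Images are generated in chunks so peak memory is bounded by
#' `chunk_size`, not corpus size.
#'
#' @param pairs A `GenePairLabelSet`.
#' @param bulk,sc `ExpressionMatrix` objects.
#' @param config A [histogram_config()].
#' @param chunk_size Pairs per generation chunk (default 1000).
#' @return A list with `images` (list of `PairImage`), `labels` (integer
#'   vector aligned with `images`) and `n_skipped`.
#' @export
build_image_corpus <- function(pairs, bulk, sc, config = histogram_config(),
                               chunk_size = 1000L) {
  need_bulk <- config$combine != "sc_only"
  need_sc <- config$combine != "bulk_only"
  known <- function(g) {
    (!need_bulk || g %in% rownames(bulk$values)) &&
      (!need_sc || g %in% rownames(sc$values))
  }
  ok <- vapply(seq_len(nrow(pairs)), function(i)
    known(pairs$tf_id[i]) && known(pairs$target_id[i]), logical(1))
  n_skipped <- sum(!ok)
  if (n_skipped > 0)
    warning(n_skipped, " pair(s) reference genes absent from the matrices; skipped")
  kept <- pairs[ok, , drop = FALSE]
  images <- vector("list", nrow(kept))
  starts <- seq(1L, max(1L, nrow(kept)), by = chunk_size)
  for (s in starts) {
    e <- min(s + chunk_size - 1L, nrow(kept))
    if (e < s) break
    for (i in s:e)
      images[[i]] <- make_pair_image(bulk, sc, kept$tf_id[i], kept$target_id[i],
                                     config, label = kept$label[i])
  }
  list(images = images, labels = as.integer(kept$label), n_skipped = n_skipped)
}
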