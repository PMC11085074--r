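#' Labeled TF-target pair set
#'
#' Validates a data frame of (tf_id, target_id, label) records, the
#' gold-standard currency of the classifier: label 1 means the TF
#' regulates the target, 0 means no interaction.
#'
#' @param df Data frame with columns `tf_id`, `target_id`, `label`.
#' @param tf_list Optional character vector of allowed TF ids.
#' @param provenance Free-text tag recording where the set came from.
#' @return The validated data frame with class `GenePairLabelSet`.
#' @export
gene_pair_label_set <- function(df, tf_list = NULL, provenance = "unspecified") {
  stopifnot(is.data.frame(df), all(c("tf_id", "target_id", "label") %in% names(df)))
  df$tf_id <- as.character(df$tf_id)
  df$target_id <- as.character(df$target_id)
  df$label <- as.integer(df$label)
  if (anyNA(df$label) || !all(df$label %in% c(0L, 1L)))
    stop("labels must be 0 or 1")
  key <- paste(df$tf_id, df$target_id, sep = "\r")
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    lines <- which(key == d)
    stop(sprintf("duplicated pair (%s, %s) at records %s",
                 df$tf_id[lines[1]], df$target_id[lines[1]],
                 paste(lines, collapse = ", ")))
  }
  if (!is.null(tf_list)) {
    bad <- setdiff(unique(df$tf_id), tf_list)
    if (length(bad))
      stop("tf_id not in the declared TF list: ", paste(utils::head(bad, 5), collapse = ", "))
  }
  attr(df, "provenance") <- provenance
  class(df) <- c("GenePairLabelSet", "data.frame")
  df
}

#' Read a labeled pair TSV
#'
#' Expects tab-separated columns `tf_id`, `target_id`, `label`; a header
#' line is optional and `#`-prefixed comment lines are ignored.
#'
#' @param path Path to the TSV.
#' @param tf_list Optional allowed TF ids.
#' @return A `GenePairLabelSet`.
#' @export
read_pairs_tsv <- function(path, tf_list = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("no pair records in ", path)
  has_header <- grepl("tf_id", lines[1], fixed = TRUE)
  body <- if (has_header) lines[-1] else lines
  parts <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 3))
    stop("expected 3 tab-separated fields, got ", nf[nf != 3][1],
         " at line ", which(nf != 3)[1])
  df <- data.frame(tf_id = vapply(parts, `[[`, "", 1),
                   target_id = vapply(parts, `[[`, "", 2),
                   label_raw = vapply(parts, `[[`, "", 3),
                   stringsAsFactors = FALSE)
  bad <- which(!df$label_raw %in% c("0", "1"))
  if (length(bad))
    stop(sprintf("label '%s' at line %d is not 0/1", df$label_raw[bad[1]], bad[1]))
  df$label <- as.integer(df$label_raw)
  df$label_raw <- NULL
  gene_pair_label_set(df, tf_list = tf_list, provenance = path)
}

#' Write a labeled pair TSV
#' @param pairs A `GenePairLabelSet`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pairs_tsv <- function(pairs, path) {
  utils::write.table(pairs[, c("tf_id", "target_id", "label")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Sample negative (non-interacting) pairs
#'
#' Adds `ceiling(ratio * n_positives)` pairs drawn uniformly without
#' replacement from `tf_ids x gene_universe` minus the positive pairs and
#' self-pairs, labeled 0. How gold standards obtain negatives is rarely
#' stated; uniform sampling is the field's convention, and any true but
#' unknown edges among the negatives are accepted label noise.
#'
#' @param positives A `GenePairLabelSet` of label-1 records.
#' @param tf_ids TFs eligible as sources.
#' @param gene_universe Genes eligible as targets.
#' @param ratio Negatives per positive (default 1).
#' @param seed Integer seed.
#' @return A `GenePairLabelSet` of positives plus sampled negatives.
#' @export
sample_negatives <- function(positives, tf_ids, gene_universe, ratio = 1.0, seed = 1L) {
  stopifnot(inherits(positives, "GenePairLabelSet"))
  n_neg <- ceiling(ratio * nrow(positives))
  if (n_neg == 0) return(positives)
  cand <- expand.grid(tf_id = tf_ids, target_id = gene_universe,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cand <- cand[cand$tf_id != cand$target_id, , drop = FALSE]
  pos_key <- paste(positives$tf_id, positives$target_id, sep = "\r")
  cand <- cand[!paste(cand$tf_id, cand$target_id, sep = "\r") %in% pos_key, , drop = FALSE]
  if (nrow(cand) < n_neg)
    stop(sprintf("requested %d negatives but only %d candidate pairs exist",
                 n_neg, nrow(cand)))
  set.seed(seed)
  neg <- cand[sample.int(nrow(cand), n_neg), , drop = FALSE]
  neg$label <- 0L
  out <- rbind(as.data.frame(positives)[, c("tf_id", "target_id", "label")], neg)
  rownames(out) <- NULL
  gene_pair_label_set(out, provenance = attr(positives, "provenance"))
}

#' Split a pair set into train and test
#'
#' @param pairs A `GenePairLabelSet`.
#' @param train_fraction Fraction assigned to training (default 0.7).
#' @param seed Integer seed.
#' @param stratified Preserve per-class proportions (default TRUE).
#' @return A list with `train` and `test` `GenePairLabelSet`s; together
#'   they partition the input.
#' @export
split_train_test <- function(pairs, train_fraction = 0.7, seed = 1L,
                             stratified = TRUE) {
  stopifnot(inherits(pairs, "GenePairLabelSet"),
            train_fraction > 0, train_fraction < 1, nrow(pairs) >= 2)
  set.seed(seed)
  n <- nrow(pairs)
  if (stratified) {
    if (length(unique(pairs$label)) < 2)
      stop("stratified split requires both classes present")
    by_class <- split(seq_len(n), pairs$label)
    sizes <- lengths(by_class)
    # largest-remainder allocation: per-class counts sum to round(f * n)
    total <- max(1L, min(n - 1L, round(train_fraction * n)))
    base <- pmin(sizes - 1L, pmax(1L, floor(train_fraction * sizes)))
    short <- total - sum(base)
    if (short > 0) {
      ord <- order(train_fraction * sizes - floor(train_fraction * sizes),
                   decreasing = TRUE)
      for (i in ord) {
        if (short == 0) break
        if (base[i] < sizes[i] - 1L) { base[i] <- base[i] + 1L; short <- short - 1L }
      }
    }
    train_idx <- unlist(mapply(function(idx, k) idx[sample.int(length(idx), k)],
                               by_class, base, SIMPLIFY = FALSE), use.names = FALSE)
  } else {
    k <- max(1L, min(n - 1L, round(train_fraction * n)))
    train_idx <- sample.int(n, k)
  }
  subset_set <- function(idx) {
    out <- as.data.frame(pairs)[idx, , drop = FALSE]
    rownames(out) <- NULL
    gene_pair_label_set(out, provenance = attr(pairs, "provenance"))
  }
  list(train = subset_set(sort(train_idx)),
       test = subset_set(setdiff(seq_len(n), train_idx)))
}

#' Repeated k-fold partitions
#'
#' For each repeat the set is shuffled once and sliced into k contiguous
#' folds whose sizes differ by at most one; each fold in turn is the test
#' set. Repeats use a seed sequence derived from `seed` so shuffles
#' differ across repeats but the whole schedule is reproducible.
#'
#' @param pairs A `GenePairLabelSet`.
#' @param k Number of folds (default 10).
#' @param repeats Number of repeats (default 20).
#' @param seed Integer seed.
#' @return A list of length `k * repeats`; each element has `repeat_id`,
#'   `fold`, `train_idx`, `test_idx` (row indices into `pairs`).
#' @export
kfold_partitions <- function(pairs, k = 10L, repeats = 20L, seed = 1L) {
  n <- nrow(pairs)
  if (k > n) stop(sprintf("k = %d exceeds the number of pairs (%d)", k, n))
  set.seed(seed)
  repeat_seeds <- sample.int(.Machine$integer.max - 1L, repeats)
  out <- vector("list", k * repeats)
  pos <- 1L
  bounds <- floor(seq(0, n, length.out = k + 1))
  for (r in seq_len(repeats)) {
    set.seed(repeat_seeds[r])
    perm <- sample.int(n)
    for (f in seq_len(k)) {
      test_idx <- sort(perm[(bounds[f] + 1):bounds[f + 1]])
      out[[pos]] <- list(repeat_id = r, fold = f,
                         train_idx = setdiff(seq_len(n), test_idx),
                         test_idx = test_idx)
      pos <- pos + 1L
    }
  }
  out
}
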