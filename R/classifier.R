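#' Convolutional pair-image classifier configuration
#'
#' The architecture is six 3x3 convolutional layers (rectifier
#' activations) with 2x2 max pooling after layers 2, 4 and 6, a flatten,
#' two hidden dense layers and a single sigmoid output unit, trained with
#' binary cross-entropy and Adam. Filter counts, dense widths, learning
#' rate and batch size follow the minimal conventional configuration for
#' this layer inventory and are all exposed here.
#'
#' @param input_shape `c(rows, cols)` of the pair image: `c(64, 32)` for
#'   stacked bulk + single-cell images at 32 bins, `c(32, 32)` for a
#'   single modality.
#' @param conv_filters Exactly six filter counts.
#' @param kernel_size Convolution kernel size (3; fixed).
#' @param pool_after Indices of the three conv layers followed by
#'   pooling.
#' @param pool_size Pooling window (2; fixed).
#' @param dense_widths Exactly two hidden dense widths.
#' @param learning_rate Adam learning rate.
#' @param batch_size Mini-batch size.
#' @param max_epochs Epoch cap.
#' @param early_stop_patience Stop when validation AUROC has not improved
#'   for this many epochs; the best-epoch weights are restored.
#' @param validation_fraction Fraction of the training pairs held out for
#'   early stopping (0 disables it).
#' @param seed Integer seed covering initialization, shuffling and the
#'   validation split; training is fully deterministic given the seed.
#' @return A `ModelConfig` list.
#' @export
model_config <- function(input_shape = c(64L, 32L),
                         conv_filters = c(32L, 32L, 64L, 64L, 128L, 128L),
                         kernel_size = 3L, pool_after = c(2L, 4L, 6L),
                         pool_size = 2L, dense_widths = c(128L, 64L),
                         learning_rate = 1e-3, batch_size = 32L,
                         max_epochs = 50L, early_stop_patience = 5L,
                         validation_fraction = 0.1, seed = 1L) {
  if (kernel_size != 3L) stop("only 3x3 kernels are supported")
  if (pool_size != 2L) stop("only 2x2 pooling is supported")
  cfg <- list(input_shape = as.integer(input_shape),
              conv_filters = as.integer(conv_filters),
              kernel_size = 3L, pool_after = as.integer(pool_after),
              pool_size = 2L, dense_widths = as.integer(dense_widths),
              activation = "relu", loss = "binary_crossentropy",
              optimizer = "adam", learning_rate = learning_rate,
              batch_size = as.integer(batch_size),
              max_epochs = as.integer(max_epochs),
              early_stop_patience = as.integer(early_stop_patience),
              validation_fraction = validation_fraction,
              seed = as.integer(seed))
  class(cfg) <- "ModelConfig"
  cfg
}

#' Build an untrained pair-image classifier
#'
#' Validates the architecture against the input shape (each pooling stage
#' halves both spatial dimensions, which must stay at least 1) and
#' initializes parameters with seeded He-normal draws.
#'
#' @param config A [model_config()].
#' @return An untrained `PairClassifier`.
#' @export
build_model <- function(config = model_config()) {
  stopifnot(inherits(config, "ModelConfig"))
  plan <- .model_plan(config$input_shape, config$conv_filters,
                      config$pool_after, config$dense_widths)
  params <- .init_params(plan, config$seed)
  structure(list(config = config, plan = plan, params = params,
                 input_center = 0, input_scale = 1,
                 trained = FALSE, history = NULL),
            class = "PairClassifier")
}

#' @export
print.PairClassifier <- function(x, ...) {
  cat(sprintf(
    "PairClassifier: input %dx%d, conv filters [%s], dense [%s], %s\n",
    x$config$input_shape[1], x$config$input_shape[2],
    paste(x$config$conv_filters, collapse = ","),
    paste(x$config$dense_widths, collapse = ","),
    if (x$trained) sprintf("trained (%d epochs)", nrow(x$history)) else "untrained"))
  invisible(x)
}

# stack PairImage tensors into the (N*HW) x 1 activation layout
.stack_images <- function(images, input_shape) {
  HW <- prod(input_shape)
  for (im in images) {
    if (!identical(dim(im$tensor), as.integer(input_shape)))
      stop(sprintf("image shape %dx%d does not match model input %dx%d",
                   dim(im$tensor)[1], dim(im$tensor)[2],
                   input_shape[1], input_shape[2]))
  }
  matrix(vapply(images, function(im) as.vector(im$tensor), numeric(HW)),
         nrow = HW)
}

#' Train the classifier on labeled pair images
#'
#' Mini-batch Adam on binary cross-entropy. A stratified fraction of the
#' input is held out as a validation set; training stops when validation
#' AUROC has not improved for `early_stop_patience` epochs (or at
#' `max_epochs`) and the best-epoch weights are kept. Fully seeded, so
#' identical data and config reproduce identical parameters.
#'
#' @param model A `PairClassifier` from [build_model()].
#' @param images List of `PairImage`s (or the result of
#'   [build_image_corpus()]).
#' @param labels 0/1 integer vector; defaults to the labels carried on
#'   the images.
#' @param quiet Suppress the per-epoch log line.
#' @return The trained `PairClassifier` with a `history` data frame
#'   (epoch, train_loss, val_auroc).
#' @export
train_model <- function(model, images, labels = NULL, quiet = FALSE) {
  stopifnot(inherits(model, "PairClassifier"))
  if (is.list(images) && !is.null(images$images)) {
    if (is.null(labels)) labels <- images$labels
    images <- images$images
  }
  if (is.null(labels)) labels <- vapply(images, function(im) im$label, integer(1))
  labels <- as.integer(labels)
  if (length(labels) != length(images)) stop("one label per image is required")
  if (anyNA(labels) || length(unique(labels)) < 2)
    stop("training requires both classes present with no missing labels")
  cfg <- model$config
  plan <- model$plan
  set.seed(cfg$seed)
  model$params <- .init_params(plan, cfg$seed) # fresh seeded start per call

  Tmat <- .stack_images(images, cfg$input_shape) # HW x N
  model$input_center <- mean(Tmat)
  model$input_scale <- stats::sd(Tmat)
  if (!is.finite(model$input_scale) || model$input_scale == 0)
    model$input_scale <- 1
  Tmat <- (Tmat - model$input_center) / model$input_scale

  n <- length(images)
  val_idx <- integer(0)
  if (cfg$validation_fraction > 0 && n >= 10) {
    val_idx <- unlist(lapply(split(seq_len(n), labels), function(idx)
      idx[sample.int(length(idx), max(1L, round(cfg$validation_fraction * length(idx))))]),
      use.names = FALSE)
  }
  tr_idx <- setdiff(seq_len(n), val_idx)
  HW <- prod(cfg$input_shape)

  geom_cache <- list()
  get_geom <- function(N) {
    key <- as.character(N)
    if (is.null(geom_cache[[key]]))
      geom_cache[[key]] <<- .make_geom(plan, N)
    geom_cache[[key]]
  }

  refs <- .param_refs(model$params)
  opt <- .adam_init(model$params, refs)
  best <- list(auroc = -Inf, params = model$params, epoch = 0L)
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_auroc = numeric())
  stall <- 0L

  for (epoch in seq_len(cfg$max_epochs)) {
    perm <- tr_idx[sample.int(length(tr_idx))]
    losses <- numeric(0)
    for (s in seq(1, length(perm), by = cfg$batch_size)) {
      bidx <- perm[s:min(s + cfg$batch_size - 1, length(perm))]
      N <- length(bidx)
      X <- matrix(Tmat[, bidx], ncol = 1)
      y <- labels[bidx]
      geom <- get_geom(N)
      fw <- .forward(model$params, plan, geom, X, N, with_cache = TRUE)
      eps <- 1e-12
      losses <- c(losses, -mean(y * log(fw$p + eps) + (1 - y) * log(1 - fw$p + eps)))
      grads <- .backward(model$params, plan, geom, fw, y, N)
      stepped <- .adam_step(model$params, grads, opt, refs, cfg$learning_rate)
      model$params <- stepped$params
      opt <- stepped$state
    }
    val_auroc <- NA_real_
    if (length(val_idx)) {
      vp <- .predict_matrix(model, Tmat[, val_idx, drop = FALSE], standardized = TRUE)
      val_auroc <- auroc(vp, labels[val_idx])
    }
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = mean(losses),
                                         val_auroc = val_auroc))
    if (!quiet)
      message(sprintf("epoch %3d  loss %.4f  val_auroc %s", epoch, mean(losses),
                      ifelse(is.na(val_auroc), "NA", sprintf("%.4f", val_auroc))))
    if (length(val_idx)) {
      if (val_auroc > best$auroc + 1e-6) {
        best <- list(auroc = val_auroc, params = model$params, epoch = epoch)
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= cfg$early_stop_patience) break
      }
    }
  }
  if (length(val_idx) && is.finite(best$auroc)) model$params <- best$params
  model$trained <- TRUE
  model$history <- history
  model
}

# score standardized HW x N column matrix in chunks
.predict_matrix <- function(model, Tmat, standardized = FALSE, chunk = 256L) {
  if (!standardized)
    Tmat <- (Tmat - model$input_center) / model$input_scale
  n <- ncol(Tmat)
  if (n == 0) return(numeric(0))
  out <- numeric(n)
  for (s in seq(1, n, by = chunk)) {
    e <- min(s + chunk - 1, n)
    N <- e - s + 1
    geom <- .make_geom(model$plan, N)
    X <- matrix(Tmat[, s:e], ncol = 1)
    out[s:e] <- .forward(model$params, model$plan, geom, X, N)$p
  }
  out
}

#' Score pair images
#'
#' @param model A trained `PairClassifier`.
#' @param images List of `PairImage`s (or a [build_image_corpus()]
#'   result).
#' @return Numeric vector of scores in `[0, 1]`, one per image in input
#'   order; values near 1 indicate a likely TF-target interaction.
#' @export
predict_scores <- function(model, images) {
  stopifnot(inherits(model, "PairClassifier"))
  if (is.list(images) && !is.null(images$images)) images <- images$images
  if (!length(images)) return(numeric(0))
  Tmat <- .stack_images(images, model$config$input_shape)
  .predict_matrix(model, Tmat)
}

#' Confusion counts at a score threshold
#'
#' A pair is called positive when its score is strictly greater than the
#' threshold. TP are called interactions present in the gold standard,
#' FP called but absent, FN missed but present, TN neither.
#'
#' @param scores Numeric scores.
#' @param labels 0/1 labels, same length.
#' @param threshold Decision threshold (default 0.5).
#' @return A `ConfusionCounts` list with `TP`, `FP`, `TN`, `FN`.
#' @export
confusion_at_threshold <- function(scores, labels, threshold = 0.5) {
  if (length(scores) != length(labels))
    stop(sprintf("length mismatch: %d scores vs %d labels",
                 length(scores), length(labels)))
  pred <- scores > threshold
  structure(list(TP = sum(pred & labels == 1), FP = sum(pred & labels == 0),
                 TN = sum(!pred & labels == 0), FN = sum(!pred & labels == 1)),
            class = "ConfusionCounts")
}

#' Classification metrics from confusion counts
#'
#' TPR = TP / (TP + FN), FPR = FP / (FP + TN),
#' precision = TP / (TP + FP), recall = TP / (TP + FN),
#' F1 = 2 * precision * recall / (precision + recall).
#' Any 0/0 ratio is reported as `NA` (flagged undefined), never an error;
#' recall always equals TPR.
#'
#' @param counts A `ConfusionCounts`.
#' @return A data frame row with columns `tpr`, `fpr`, `precision`,
#'   `recall`, `f1`.
#' @export
compute_metrics <- function(counts) {
  stopifnot(inherits(counts, "ConfusionCounts"))
  rat <- function(num, den) if (den == 0) NA_real_ else num / den
  tpr <- rat(counts$TP, counts$TP + counts$FN)
  fpr <- rat(counts$FP, counts$FP + counts$TN)
  precision <- rat(counts$TP, counts$TP + counts$FP)
  recall <- tpr
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0)
    NA_real_ else 2 * precision * recall / (precision + recall)
  data.frame(tpr = tpr, fpr = fpr, precision = precision, recall = recall,
             f1 = f1)
}

#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a random positive
#' outscores a random negative, with ties counted one half — identical to
#' the trapezoidal area under the TPR/FPR curve.
#'
#' @param scores Numeric scores.
#' @param labels 0/1 labels with both classes present.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  if (length(scores) != length(labels)) stop("scores and labels differ in length")
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) stop("auroc requires both classes present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Repeated k-fold cross-validation of the pair classifier
#'
#' Builds the image corpus once, then trains a fresh seeded model on each
#' of the `k * repeats` train partitions and scores the held-out fold.
#'
#' @param pairs A `GenePairLabelSet`.
#' @param bulk,sc Aligned `ExpressionMatrix` objects.
#' @param hist_config A [histogram_config()].
#' @param mod_config A [model_config()].
#' @param k Folds (default 10).
#' @param repeats Repeats (default 20).
#' @param seed Seed for the fold schedule; per-partition model seeds are
#'   derived from it.
#' @param quiet Suppress per-epoch logs.
#' @return A list with `per_partition` (data frame: repeat_id, fold,
#'   auroc), `mean_auroc` and `sd_auroc`.
#' @export
cross_validate_pairs <- function(pairs, bulk, sc,
                                 hist_config = histogram_config(),
                                 mod_config = model_config(),
                                 k = 10L, repeats = 20L, seed = 1L,
                                 quiet = TRUE) {
  corpus <- build_image_corpus(pairs, bulk, sc, hist_config)
  parts <- kfold_partitions(pairs, k = k, repeats = repeats, seed = seed)
  res <- lapply(seq_along(parts), function(i) {
    p <- parts[[i]]
    cfg <- mod_config
    cfg$seed <- mod_config$seed + i
    m <- build_model(cfg)
    m <- train_model(m, corpus$images[p$train_idx],
                     corpus$labels[p$train_idx], quiet = quiet)
    sc_test <- predict_scores(m, corpus$images[p$test_idx])
    data.frame(repeat_id = p$repeat_id, fold = p$fold,
               auroc = auroc(sc_test, corpus$labels[p$test_idx]))
  })
  per_partition <- do.call(rbind, res)
  list(per_partition = per_partition,
       mean_auroc = mean(per_partition$auroc),
       sd_auroc = stats::sd(per_partition$auroc))
}
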