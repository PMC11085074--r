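test_that("confusion counts follow the strict-> threshold rule", {
  cm <- confusion_at_threshold(c(0.9, 0.1), c(1, 0), 0.5)
  expect_equal(unclass(cm)[c("TP", "FP", "TN", "FN")],
               list(TP = 1L, FP = 0L, TN = 1L, FN = 0L))

  # all scores below threshold -> nothing called positive
  cm2 <- confusion_at_threshold(c(0.1, 0.2, 0.3), c(1, 0, 1), 0.5)
  expect_equal(cm2$TP + cm2$FP, 0)

  # a score exactly at the threshold is counted negative
  cm3 <- confusion_at_threshold(c(0.5, 0.6), c(1, 1), 0.5)
  expect_equal(cm3$TP, 1)
  expect_equal(cm3$FN, 1)

  expect_error(confusion_at_threshold(1:3 / 10, c(0, 1)), "length mismatch")
})

test_that("metric formulas match hand-computed confusion counts", {
  cm <- structure(list(TP = 3, FP = 1, TN = 5, FN = 1),
                  class = "ConfusionCounts")
  m <- compute_metrics(cm)
  expect_equal(m$tpr, 0.75)
  expect_equal(m$fpr, 1 / 6)
  expect_equal(m$precision, 0.75)
  expect_equal(m$recall, 0.75)
  expect_equal(m$f1, 0.75)
  expect_identical(m$recall, m$tpr)

  # 0/0 cases are flagged undefined, never an error
  none <- structure(list(TP = 0, FP = 0, TN = 4, FN = 0),
                    class = "ConfusionCounts")
  m0 <- compute_metrics(none)
  expect_true(is.na(m0$precision))
  expect_true(is.na(m0$recall))
  expect_true(is.na(m0$f1))
  expect_equal(m0$fpr, 0)

  perfect <- structure(list(TP = 5, FP = 0, TN = 5, FN = 0),
                       class = "ConfusionCounts")
  mp <- compute_metrics(perfect)
  expect_equal(c(mp$tpr, mp$fpr, mp$f1), c(1, 0, 1))
})

test_that("recall equals tpr for arbitrary confusion counts", {
  set.seed(3)
  for (i in 1:20) {
    cm <- structure(as.list(setNames(sample(0:20, 4, TRUE),
                                     c("TP", "FP", "TN", "FN"))),
                    class = "ConfusionCounts")
    m <- compute_metrics(cm)
    expect_identical(m$recall, m$tpr)
  }
})

test_that("auroc matches rank intuition and handles ties", {
  expect_equal(auroc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  # 3 of 4 (pos, neg) pairs concordant, none tied
  expect_equal(auroc(c(0.1, 0.2, 0.3, 0.4), c(0, 1, 0, 1)), 0.75)
  expect_equal(auroc(rep(0.5, 10), rep(c(0, 1), 5)), 0.5)
  expect_error(auroc(1:3 / 10, c(1, 1, 1)), "both classes")
})

test_that("auroc equals the exhaustive concordant-pair oracle", {
  set.seed(11)
  for (i in 1:200) {
    n <- sample(4:50, 1)
    labels <- c(0, 1, sample(0:1, n - 2, TRUE)) # both classes guaranteed
    scores <- round(runif(n), sample(1:3, 1))   # coarse rounding forces ties
    expect_equal(auroc(scores, labels), auroc_oracle(scores, labels))
  }
})

test_that("auroc is antisymmetric under score negation", {
  set.seed(12)
  for (i in 1:20) {
    n <- 30
    labels <- c(0, 1, sample(0:1, n - 2, TRUE))
    scores <- round(runif(n), 2)
    expect_equal(auroc(scores, labels) + auroc(1 - scores, labels), 1)
  }
})

test_that("model building validates architecture feasibility", {
  m <- build_model(model_config(input_shape = c(64L, 32L)))
  expect_equal(m$plan$out_shape, c(8L, 4L)) # three halvings
  m32 <- build_model(model_config(input_shape = c(32L, 32L)))
  expect_equal(m32$plan$out_shape, c(4L, 4L))

  expect_error(build_model(model_config(input_shape = c(4L, 4L))), "pool")
  expect_error(model_config(kernel_size = 5), "3x3")
  expect_error(build_model(model_config(conv_filters = c(8, 8, 8))), "6 conv")
})

test_that("training reduces the loss and is reproducible under a seed", {
  sim <- tiny_sim()
  corpus <- build_image_corpus(sim$pairs, sim$bulk, sim$sc, tiny_hist_config())
  cfg <- tiny_model_config(max_epochs = 4)
  m1 <- train_model(build_model(cfg), corpus, quiet = TRUE)
  expect_lt(utils::tail(m1$history$train_loss, 1), m1$history$train_loss[1])

  # identical seed reproduces training to BLAS reduction order (threaded
  # GEMM may reassociate sums at ~1e-16); everything upstream of the
  # matrix products is bit-exact
  m2 <- train_model(build_model(cfg), corpus, quiet = TRUE)
  expect_equal(m1$params, m2$params, tolerance = 1e-10)
  expect_equal(predict_scores(m1, corpus), predict_scores(m2, corpus),
               tolerance = 1e-10)

  onecls <- corpus
  onecls$labels <- rep(1L, length(onecls$labels))
  expect_error(train_model(build_model(cfg), onecls$images, onecls$labels),
               "both classes")
})

test_that("prediction is pure, ordered, in range, and shape-checked", {
  sim <- tiny_sim()
  corpus <- build_image_corpus(sim$pairs[c(1:6, 25:30), ], sim$bulk, sim$sc,
                               tiny_hist_config())
  m <- train_model(build_model(tiny_model_config(max_epochs = 2)),
                   corpus, quiet = TRUE)
  s <- predict_scores(m, corpus)
  expect_length(s, 12)
  expect_true(all(s >= 0 & s <= 1))

  # duplicated image scores identically; empty input gives empty output
  dup <- predict_scores(m, corpus$images[c(1, 1)])
  expect_equal(dup[1], dup[2])
  expect_length(predict_scores(m, list()), 0)

  wrong <- make_pair_image(sim$bulk, sim$sc, "TF001", "TG001_01",
                           histogram_config(bins = 16))
  expect_error(predict_scores(m, list(wrong)), "does not match")
})

test_that("with zero effect slope the trained classifier scores at chance", {
  # no planted signal at all: positives are statistically identical to
  # decoy pairs, so held-out AUROC against the true labels is ~0.5
  # (~500 evaluation pairs; binomial se ~0.026)
  sim <- simulate_paired_dataset(simulation_config(
    n_tfs = 60, targets_per_tf = 6, n_decoys = 360, effect_slope = 0,
    seed = 31))
  al <- align_gene_universe(log_transform(sim$bulk), log_transform(sim$sc))
  sp <- split_train_test(sim$pairs, 0.3, seed = 32)
  hc <- histogram_config(bins = 32)
  tr <- build_image_corpus(sp$train, al$bulk, al$sc, hc)
  te <- build_image_corpus(sp$test, al$bulk, al$sc, hc)
  m <- train_model(build_model(model_config(max_epochs = 4,
                                            early_stop_patience = 3,
                                            seed = 33)), tr, quiet = TRUE)
  a <- auroc(predict_scores(m, te), te$labels)
  expect_gte(length(te$labels), 500)
  expect_gte(a, 0.42)
  expect_lte(a, 0.58)
})

test_that("cross-validation aggregates per-partition AUROCs", {
  sim <- tiny_sim()
  res <- cross_validate_pairs(sim$pairs, sim$bulk, sim$sc,
                              tiny_hist_config(),
                              tiny_model_config(max_epochs = 3),
                              k = 2, repeats = 1, seed = 4)
  expect_equal(nrow(res$per_partition), 2)
  expect_true(all(res$per_partition$auroc >= 0 & res$per_partition$auroc <= 1))
  expect_equal(res$mean_auroc, mean(res$per_partition$auroc))
})
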