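ref_net <- function(tf, tg, source = "ChIP") {
  reference_network(data.frame(tf_id = tf, target_id = tg,
                               stringsAsFactors = FALSE), source = source)
}

pred_net <- function(tf, tg, score = 0.9) {
  edge_list(data.frame(tf_id = tf, target_id = tg, score = score,
                       stringsAsFactors = FALSE))
}

test_that("network overlap counts shared edges and comparable denominators", {
  p <- pred_net(rep("t1", 3), c("a", "b", "c"))
  expect_equal(count_overlap(p, ref_net(rep("t1", 3), c("a", "b", "c")))$observed, 3)
  expect_equal(count_overlap(p, ref_net("t9", "z"))$observed, 0)

  # reference edges from unpredicted TFs are excluded from the denominator
  r <- ref_net(c("t1", "t1", "t9"), c("a", "x", "y"))
  ov <- count_overlap(p, r)
  expect_equal(ov$observed, 1)
  expect_equal(ov$comparable_edge_count, 2)
  expect_equal(ov$overlap_pct, 50)
})

test_that("fold enrichment is the observed/expected ratio with flagged division by zero", {
  expect_equal(round(fold_enrichment(1245, 687), 2), 1.81)
  expect_equal(round(fold_enrichment(586, 194), 2), 3.02)
  expect_equal(fold_enrichment(7, 7), 1)
  expect_equal(fold_enrichment(3, 0), Inf)
  expect_error(fold_enrichment(3, -1), "non-negative")
})

test_that("permutation null preserves degrees and matches the closed form", {
  # closed form for degree-preserving uniform resampling:
  # E[overlap] = sum_tf d_tf * r_tf / N
  set.seed(31)
  universe <- sprintf("g%03d", 1:60)
  tfs <- paste0("t", 1:5)
  pred <- do.call(rbind, lapply(tfs, function(tf) {
    d <- sample(5:20, 1)
    data.frame(tf_id = tf, target_id = sample(universe, d), score = 0.9)
  }))
  pred <- edge_list(pred)
  ref <- do.call(rbind, lapply(tfs, function(tf) {
    r <- sample(5:25, 1)
    data.frame(tf_id = tf, target_id = sample(universe, r))
  }))
  ref <- reference_network(ref)

  res <- permutation_expected_overlap(pred, ref, universe,
                                      n_permutations = 10000, seed = 1)
  d <- table(pred$tf_id)
  r <- table(ref$tf_id)
  closed <- sum(as.numeric(d[tfs]) * as.numeric(r[tfs])) / length(universe)
  expect_equal(res$expected, closed, tolerance = 0.02)
  expect_gte(res$expected, res$range[1])
  expect_lte(res$expected, res$range[2])
  expect_equal(res$fold_enrichment, res$observed / res$expected)

  # deterministic under the seed
  res2 <- permutation_expected_overlap(pred, ref, universe,
                                       n_permutations = 10000, seed = 1)
  expect_identical(unclass(res), unclass(res2))
})

test_that("saturated prediction makes every permutation hit the observed overlap", {
  universe <- paste0("g", 1:10)
  pred <- pred_net(rep(c("t1", "t2"), each = 10), rep(universe, 2))
  ref <- ref_net(c("t1", "t1", "t2"), c("g1", "g2", "g5"))
  res <- permutation_expected_overlap(pred, ref, universe,
                                      n_permutations = 200, seed = 3)
  expect_equal(res$observed, 3)
  expect_equal(res$expected, 3)
  expect_equal(res$range, c(3, 3))
  expect_equal(res$fold_enrichment, 1)
  expect_equal(res$empirical_p, 0) # strictly-greater count is zero
  expect_match(res$p_display, "^< ")
})

test_that("hypergeometric upper tail matches hand computation and enumeration", {
  # |U|=10, |pred|=4, |ref|=5, overlap 4: P(X>=4) = C(5,4)C(5,0)/C(10,4)
  u <- paste0("g", 1:10)
  p <- hypergeometric_target_overlap(u[1:4], u[1:5], u)
  expect_equal(p, 5 / 210, tolerance = 1e-12)

  # no overlap in a huge universe: tail from 0 includes everything
  big <- paste0("g", 1:1000)
  expect_equal(hypergeometric_target_overlap(big[1:3], big[998:1000], big), 1,
               tolerance = 1e-6)

  # predicted = universe forces complete overlap, p = 1
  expect_equal(hypergeometric_target_overlap(u, u[1:5], u), 1)

  expect_error(hypergeometric_target_overlap(c("zz"), u[1:2], u), "subsets")

  # random instances vs subset-enumeration oracle, universes <= 12
  set.seed(17)
  for (i in 1:50) {
    N <- sample(4:12, 1)
    uni <- paste0("x", 1:N)
    n <- sample(1:N, 1)
    K <- sample(1:N, 1)
    predicted <- sample(uni, n)
    reference <- sample(uni, K)
    k <- length(intersect(predicted, reference))
    expect_equal(hypergeometric_target_overlap(predicted, reference, uni),
                 hyper_tail_oracle(k, K, N, n), tolerance = 1e-12)
  }
})

test_that("BH adjustment reproduces the step-up computation", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  # monotone on sorted input; permutation-equivariant
  set.seed(5)
  p <- sort(runif(20))
  q <- bh_adjust(p)
  expect_true(all(diff(q) >= 0))
  perm <- sample(20)
  expect_equal(bh_adjust(p[perm]), q[perm])
})

test_that("per-TF enrichment table covers shared TFs and summarizes fractions", {
  universe <- paste0("g", 1:40)
  pred <- pred_net(rep(c("t1", "t2"), each = 10),
                   c(universe[1:10], universe[11:20]))
  ref <- reference_network(data.frame(
    tf_id = c(rep("t1", 8), rep("t3", 2)),
    target_id = c(universe[1:8], universe[30:31])))
  res <- per_tf_enrichment_table(pred, ref, universe)
  # t3 predicted nowhere: excluded from the table, counted in totals
  expect_equal(res$table$tf_id, "t1")
  expect_equal(res$n_reference_tfs, 2)
  expect_equal(res$n_shared_tfs, 1)
  expect_equal(res$shared_pct, 50)
  # t1's 8/8 reference targets recovered out of 10 predicted: highly enriched
  expect_equal(res$table$k, 8)
  expect_lt(res$table$q, 0.05)
  expect_equal(res$n_significant, 1)

  empty <- per_tf_enrichment_table(pred_net("zz", "g1"), ref, universe)
  expect_equal(nrow(empty$table), 0)
  expect_equal(empty$n_significant, 0)
})
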