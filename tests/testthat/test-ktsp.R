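test_that("greedy disjoint selection skips overlapping pairs", {
  scores <- tibble::tibble(
    feature_i = c("A", "A", "D"), feature_j = c("B", "C", "E"),
    p1 = 1, p2 = 0, score = c(0.9, 0.8, 0.7), rank_score = 0
  )
  sel <- select_disjoint_pairs(scores, 2)
  expect_equal(sel$feature_i, c("A", "D"))
  expect_equal(sel$feature_j, c("B", "E"))
  expect_warning(select_disjoint_pairs(scores, 3), "only 2 disjoint pairs")
  expect_equal(nrow(select_disjoint_pairs(scores, 1)), 1L)
})

test_that("greedy selection is disjoint, starts at the top pair, and never beats the exhaustive optimum", {
  for (seed in 1:6) {
    d <- random_data(n = 10, p = sample(5:8, 1), seed = 100 + seed)
    tab <- score_pairs(d, "class")
    sel <- select_disjoint_pairs(tab, 2)
    feats <- c(sel$feature_i, sel$feature_j)
    expect_equal(anyDuplicated(feats), 0L)
    expect_equal(sel[1, ], tab[1, ])
    best <- oracle_best_disjoint(tab, 2)
    expect_lte(sum(sel$score), best + 1e-12)
    # greedy keeps the top pair, so it is within one pair-score of optimal
    expect_gte(sum(sel$score), tab$score[1])
  }
})

test_that("the variance-normalized criterion matches a hand computation", {
  # pairs (A,B), (C,D); per-sample ordering counts: class 1 -> 2,1,1;
  # class 2 -> 0,1,1; scores 1/3 each
  X <- rbind(
    c(1, 2, 1, 2), c(2, 1, 1, 2), c(1, 2, 2, 1),
    c(2, 1, 2, 1), c(1, 2, 2, 1), c(2, 1, 1, 2)
  )
  d <- make_data(X, cls = c(1, 1, 1, 2, 2, 2), feats = c("A", "B", "C", "D"))
  pairs <- tibble::tibble(feature_i = c("A", "C"), feature_j = c("B", "D"))
  tau <- ktsp_tau(d, "class", pairs)
  expect_equal(tau, (2 / 3) / sqrt(var(c(2, 1, 1)) + var(c(0, 1, 1))))
  expect_equal(tau, sqrt(2 / 3))
})

test_that("tau matches the brute-force oracle on random matrices", {
  for (seed in 1:5) {
    d <- random_data(n = sample(6:12, 1), p = 6, seed = 200 + seed)
    tab <- score_pairs(d, "class")
    sel <- select_disjoint_pairs(tab, 3)
    pairs_idx <- tibble::tibble(
      i = match(sel$feature_i, paste0("f", 1:6)),
      j = match(sel$feature_j, paste0("f", 1:6))
    )
    X <- as.matrix(d[, paste0("f", 1:6)])
    for (k in seq_len(nrow(sel))) {
      expect_equal(
        suppressWarnings(ktsp_tau(d, "class", sel[seq_len(k), ])),
        oracle_tau(X, d$class, pairs_idx[seq_len(k), ])
      )
    }
  }
})

test_that("a perfectly separating single pair yields the infinite sentinel", {
  d <- toy_perfect()
  expect_warning(
    tau <- ktsp_tau(d, "class", tibble::tibble(feature_i = "A", feature_j = "B")),
    "zero within-class variance"
  )
  expect_identical(tau, Inf)
})

test_that("tau is invariant to positive rescaling of the features", {
  d <- random_data(10, 6, seed = 31)
  pairs <- tibble::tibble(feature_i = c("f1", "f3"), feature_j = c("f2", "f4"))
  d_scaled <- d
  d_scaled[paste0("f", 1:6)] <- d[paste0("f", 1:6)] * 7.3
  expect_equal(ktsp_tau(d, "class", pairs), ktsp_tau(d_scaled, "class", pairs))
})

test_that("fit_ktsp picks the planted number of pairs and k_grid = 1 reduces to TSP", {
  hits <- 0
  for (seed in 1:10) {
    d <- withr::with_seed(300 + seed, planted_pairs_data())
    fit <- fit_ktsp(d, "class", k_grid = 1:3)
    if (fit$k_star == 2) hits <- hits + 1
  }
  expect_gte(hits, 7)

  d <- random_data(14, 6, seed = 41)
  k1 <- fit_ktsp(d, "class", k_grid = 1)
  t1 <- fit_tsp(d, "class")
  expect_equal(k1$k_star, 1L)
  expect_equal(k1$pairs$feature_i[1], t1$pair$feature_i)
  expect_equal(k1$pairs$feature_j[1], t1$pair$feature_j)
  expect_equal(predict(k1, d), predict(t1, d))
})

test_that("fit_ktsp validates the feature budget and keeps disjoint pairs", {
  d <- random_data(10, 3, seed = 51)
  expect_error(fit_ktsp(d, "class", k_grid = 2:3), "too few features")
  d6 <- random_data(20, 6, seed = 52)
  fit <- fit_ktsp(d6, "class", k_grid = 2:3)
  feats <- c(fit$pairs$feature_i, fit$pairs$feature_j)
  expect_equal(anyDuplicated(feats), 0L)
  expect_true(fit$k_star %in% 2:3)
  expect_equal(fit$tau$tau[fit$tau$k == fit$k_star], max(fit$tau$tau))
  # numerator identity: tau * sqrt(denominator variance) = summed scores
  expect_equal(sum(fit$pairs$score[seq_len(fit$k_star)]),
               glance(fit)$total_score)
})

test_that("majority voting follows the documented tie rule", {
  lev <- c("1", "2")
  model <- structure(
    list(
      pairs = tibble::tibble(
        feature_i = c("A", "C", "E"), feature_j = c("B", "D", "F"),
        p1 = c(0, 0, 0), p2 = c(1, 1, 1),
        score = c(0.9, 0.8, 0.7), rank_score = 0,
        vote_lt = "2", vote_ge = "1"
      ),
      k_star = 3L, tau = tibble::tibble(k = 3, tau = 1),
      levels = lev, class_counts = c(5L, 5L)
    ),
    class = "ktsp"
  )
  # votes (2,2,1) -> class 2 by strict majority
  test3 <- tibble::tibble(A = 0, B = 1, C = 0, D = 1, E = 1, F = 0)
  expect_equal(as.character(predict(model, test3)), "2")
  # two pairs voting (2,1): the top-scoring pair decides
  test_tie <- tibble::tibble(A = 0, B = 1, C = 1, D = 0, E = 0, F = 0)
  expect_equal(as.character(predict(model, test_tie, k = 2)), "2")
  test_tie2 <- tibble::tibble(A = 1, B = 0, C = 0, D = 1, E = 0, F = 0)
  expect_equal(as.character(predict(model, test_tie2, k = 2)), "1")
})

test_that("the whole K-TSP fit is invariant to per-sample monotone transforms", {
  d <- random_data(16, 6, seed = 61)
  f_raw <- fit_ktsp(d, "class", k_grid = 1:3)
  d_exp <- d
  d_exp[paste0("f", 1:6)] <- exp(d[paste0("f", 1:6)])
  f_exp <- fit_ktsp(d_exp, "class", k_grid = 1:3)
  expect_equal(f_raw$k_star, f_exp$k_star)
  expect_equal(f_raw$pairs, f_exp$pairs)
  expect_equal(f_raw$tau, f_exp$tau)
  expect_equal(predict(f_raw, d), predict(f_exp, d_exp))
})
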