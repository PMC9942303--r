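test_that("confusion metrics match hand-computed values", {
  # TP=3, FP=1, TN=5, FN=1 with positive class "2"
  truth <- c(rep("2", 4), rep("1", 6))
  pred <- c("2", "2", "2", "1", "2", rep("1", 5))
  m <- confusion_metrics(truth, pred, positive = "2")
  expect_equal(m$tp, 3); expect_equal(m$fp, 1)
  expect_equal(m$tn, 5); expect_equal(m$fn, 1)
  expect_equal(m$sensitivity, 0.75)
  expect_equal(m$specificity, 5 / 6)
  expect_equal(m$ppv, 0.75)
  expect_equal(m$npv, 5 / 6)
  expect_equal(m$overall_accuracy, 0.8)
  expect_equal(m$balanced_accuracy, (0.75 + 5 / 6) / 2)
})

test_that("perfect prediction yields all six measures equal to one", {
  truth <- rep(c(1, 2), 5)
  m <- confusion_metrics(truth, truth)
  expect_equal(unlist(m[c("overall_accuracy", "sensitivity", "specificity",
                          "balanced_accuracy", "ppv", "npv")], use.names = FALSE),
               rep(1, 6))
})

test_that("an all-negative predictor on 20% positive data shows the degenerate profile", {
  truth <- c(rep(2, 4), rep(1, 16))
  pred <- rep(1, 20)
  m <- confusion_metrics(truth, pred, positive = 2)
  expect_equal(m$overall_accuracy, 0.8)
  expect_equal(m$sensitivity, 0)
  expect_equal(m$specificity, 1)
  expect_equal(m$balanced_accuracy, 0.5)
  expect_true(is.na(m$ppv))   # undefined, not zero: no positive predictions
  expect_equal(m$npv, 0.8)
})

test_that("metric inputs are validated", {
  expect_error(confusion_metrics(1:3, 1:2), "same length")
  expect_error(confusion_metrics(c(1, 1, 1, 1), c(1, 1, 1, 1)), "2 classes")
  expect_error(confusion_metrics(c(1, 2), c(1, 3)), "outside the truth label set")
  expect_error(confusion_metrics(c(1, 2), c(1, 2), positive = "x"), "not one of")
})

test_that("every sample lands in exactly one test fold and folds are stratified", {
  cls <- rep(1:2, times = c(40, 10))
  withr::with_seed(5, {
    fid <- covtsp:::assign_folds(cls, 5, stratified = TRUE)
  })
  expect_equal(sort(unique(fid)), 1:5)
  expect_equal(length(fid), 50)
  for (f in 1:5) {
    expect_equal(sum(fid == f & cls == 1), 8)
    expect_equal(sum(fid == f & cls == 2), 2)
  }
})

test_that("repeated CV is reproducible and averages metrics across folds", {
  sim <- simulate_study1(n = 120, seed = 2)
  run <- function() repeated_cv(sim, "Y", features = c("X1", "X2", "X3", "X4"),
                                iterations = 3, folds = 4, seed = 11)
  cv1 <- run(); cv2 <- run()
  expect_identical(cv1$metrics, cv2$metrics)
  expect_identical(cv1$selected, cv2$selected)
  expect_equal(nrow(cv1$metrics), 3L)
  expect_equal(cv1$metrics$iteration, 1:3)
  # balanced accuracy column respects its identity with sensitivity/specificity
  # fold-wise, so the fold average of the mean equals the mean of the averages
  expect_equal(cv1$metrics$balanced_accuracy,
               (cv1$metrics$sensitivity + cv1$metrics$specificity) / 2,
               tolerance = 1e-12)
})

test_that("per-fold residualized CV shifts selection to outcome-driven features", {
  sim <- simulate_study1(n = 200, seed = 21)
  involves <- function(sel, feats) {
    sel$feature_i %in% feats | sel$feature_j %in% feats
  }
  cv <- repeated_cv(sim, "Y", features = c("X1", "X2", "X3", "X4"),
                    covariates = "Z", residualize_mode = "per_fold",
                    iterations = 10, folds = 5, seed = 22)
  # after residualizing, the selected pair carries outcome-driven signal
  # (X3 and/or X4); the purely covariate-driven pair (X1, X2) disappears
  expect_gte(mean(involves(cv$selected, c("X3", "X4"))), 0.9)
  expect_lte(mean(cv$selected$feature_i == "X1" & cv$selected$feature_j == "X2"), 0.1)
  # the raw analysis instead leans on the covariate-driven features
  cv_raw <- repeated_cv(sim, "Y", features = c("X1", "X2", "X3", "X4"),
                        iterations = 10, folds = 5, seed = 22)
  expect_gte(mean(involves(cv_raw$selected, c("X1", "X2"))), 0.5)
})

test_that("unstratified folds that lose a class raise the suggested-fix error", {
  d <- make_data(matrix(rnorm(12), 6, 2), cls = c(1, rep(2, 5)))
  expect_error(
    # earlier folds can fit on near-degenerate 4-sample splits (warnings ok);
    # the fold that loses class 1 from training must error
    suppressWarnings(
      repeated_cv(d, "class", iterations = 5, folds = 3, stratified = FALSE,
                  seed = 3)
    ),
    "stratified"
  )
})

test_that("tidy/glance/plug-in interfaces work", {
  sim <- simulate_study1(n = 100, seed = 4)
  cv <- repeated_cv(sim, "Y", features = c("X1", "X2", "X3", "X4"),
                    iterations = 2, folds = 3, seed = 5)
  td <- tidy(cv)
  expect_setequal(unique(td$metric),
                  c("overall_accuracy", "sensitivity", "specificity",
                    "balanced_accuracy", "ppv", "npv"))
  expect_equal(nrow(td), 2 * 6)
  expect_equal(ncol(glance(cv)), 7)

  # plug-in contract: a majority-class dummy classifier
  dummy_fit <- function(train, label_col, feats) {
    names(which.max(table(train[[label_col]])))
  }
  dummy_pred <- function(model, test) rep(model, nrow(test))
  cv_dummy <- repeated_cv(sim, "Y", features = c("X1", "X2", "X3", "X4"),
                          iterations = 2, folds = 3, seed = 6,
                          fit_fun = dummy_fit, predict_fun = dummy_pred)
  # one-class predictions give sensitivity/specificity {0,1} per fold,
  # hence balanced accuracy exactly 0.5
  expect_equal(cv_dummy$metrics$balanced_accuracy, rep(0.5, 2))
})
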