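#' Fit a top-scoring pair (TSP) classifier
#'
#' Selects the feature pair with the maximal discriminant score (ties broken
#' by the secondary rank score, then by feature position) and records the vote
#' orientation: if on the training data
#' \eqn{P(X_i < X_j \mid C=1) < P(X_i < X_j \mid C=2)}, observing
#' \eqn{X_i < X_j} in a test profile predicts class 2, otherwise class 1; the
#' opposite ordering (\eqn{X_i \ge X_j}, ties included) predicts the other
#' class. The rule is parameter free: prediction depends only on which of the
#' two features is larger in the test profile.
#'
#' @inheritParams score_pairs
#' @return An object of class `"tsp"`: a list with the selected `pair`
#'   (one-row tibble as from [score_pairs()]), the `orientation` (class
#'   predicted when `X_i < X_j` is observed, on the original label coding),
#'   the class `levels`, per-class training counts and the full fit call.
#'   Supports [predict()][predict.tsp], [tidy()], [glance()] and
#'   [autoplot()][autoplot.tsp].
#'
#' @examples
#' sim <- simulate_study1(seed = 7)
#' fit <- fit_tsp(sim, labels = "Y", features = c("X1", "X2", "X3", "X4"))
#' fit
#' table(predict(fit, sim), sim$Y)
#' @export
fit_tsp <- function(data, labels, features = NULL, id_col = "sample_id") {
  lab <- normalize_classes(resolve_labels(data, labels))
  check_both_classes(lab$cls)
  tab <- score_pairs(data, labels, features, id_col)
  if (max(tab$score) == 0) {
    warn("all pair scores are zero; returning the rank-score tie-break winner")
  }
  top <- tab[1, ]
  structure(
    list(
      pair = top,
      orientation = if (top$p1 < top$p2) lab$levels[2] else lab$levels[1],
      levels = lab$levels,
      class_counts = c(sum(lab$cls == 1L), sum(lab$cls == 2L)),
      scores = tab
    ),
    class = "tsp"
  )
}

#' Predict with a fitted TSP classifier
#'
#' @param object A `"tsp"` model from [fit_tsp()].
#' @param newdata Data frame containing both model features (matched by
#'   column name, so column order is irrelevant).
#' @param ... Unused.
#' @return A factor of predicted classes, one per row of `newdata`, with the
#'   training class levels. A tie `X_i == X_j` follows the `X_i >= X_j` branch
#'   of the rule.
#' @export
predict.tsp <- function(object, newdata, ...) {
  fi <- object$pair$feature_i; fj <- object$pair$feature_j
  missing <- setdiff(c(fi, fj), names(newdata))
  if (length(missing) > 0) {
    abort(paste0("model feature(s) missing from newdata: ",
                 paste(missing, collapse = ", ")))
  }
  lt <- newdata[[fi]] < newdata[[fj]]
  other <- setdiff(object$levels, object$orientation)
  factor(ifelse(lt, object$orientation, other), levels = object$levels)
}

#' @export
print.tsp <- function(x, ...) {
  cat("Top-scoring pair classifier\n")
  cat(sprintf("  pair: (%s, %s)   score: %.3f   rank score: %.3f\n",
              x$pair$feature_i, x$pair$feature_j, x$pair$score, x$pair$rank_score))
  cat(sprintf("  P(%s < %s | C=1) = %.3f ; P(. | C=2) = %.3f\n",
              x$pair$feature_i, x$pair$feature_j, x$pair$p1, x$pair$p2))
  cat(sprintf("  rule: %s < %s -> class %s, otherwise class %s\n",
              x$pair$feature_i, x$pair$feature_j, x$orientation,
              setdiff(x$levels, x$orientation)))
  invisible(x)
}

#' @describeIn fit_tsp One row per (here: the single) selected pair, with the
#'   class each ordering votes for.
#' @param x A `"tsp"` model.
#' @param ... Unused.
#' @export
tidy.tsp <- function(x, ...) {
  dplyr::mutate(x$pair,
                vote_lt = x$orientation,
                vote_ge = setdiff(x$levels, x$orientation))
}

#' @describeIn fit_tsp One-row model summary (score, training class counts,
#'   training balanced accuracy implied by the score on tie-free data).
#' @export
glance.tsp <- function(x, ...) {
  tibble::tibble(
    score = x$pair$score,
    rank_score = x$pair$rank_score,
    n_class1 = x$class_counts[1],
    n_class2 = x$class_counts[2],
    train_balanced_accuracy = (1 + x$pair$score) / 2
  )
}

#' Scatter plot of a fitted TSP pair with its decision boundary
#'
#' @param object A `"tsp"` model.
#' @param data The data frame to plot (training or test), containing the two
#'   model features and the label column used below.
#' @param labels Label column name or vector, as in [fit_tsp()].
#' @param ... Unused.
#' @return A ggplot: feature j against feature i, points colored by class,
#'   with the `X_i = X_j` decision boundary overlaid.
#' @export
autoplot.tsp <- function(object, data, labels, ...) {
  fi <- object$pair$feature_i; fj <- object$pair$feature_j
  df <- tibble::tibble(
    x = data[[fi]], y = data[[fj]],
    class = factor(resolve_labels(data, labels), levels = object$levels)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, color = .data$class)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::labs(x = fi, y = fj, color = "class",
                  title = sprintf("TSP pair (%s, %s), score %.2f",
                                  fi, fj, object$pair$score)) +
    ggplot2::theme_minimal()
}
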