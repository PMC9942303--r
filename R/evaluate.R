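#' Confusion-matrix accuracy measures
#'
#' Computes the six accuracy measures from a confusion matrix: overall
#' accuracy, sensitivity (correct among true positives), specificity (correct
#' among true negatives), balanced accuracy (their mean — preferred under
#' class imbalance), positive predictive value and negative predictive value.
#' PPV is `NA` (undefined, not zero) when no positive predictions are made —
#' the degenerate regime of a classifier that never predicts the positive
#' class; NPV likewise when no negative predictions are made.
#'
#' @param truth Vector of true two-level class labels.
#' @param predicted Vector of predicted labels, same length and label set.
#' @param positive The positive class for sensitivity/PPV. Default: the
#'   second class level (the larger label value).
#' @param levels Optional character vector of the two class labels, needed
#'   when `truth` may contain only one of them (e.g. a small held-out fold);
#'   by default the levels are inferred from `truth`.
#' @return A one-row tibble: `tp`, `fp`, `tn`, `fn`, `overall_accuracy`,
#'   `sensitivity`, `specificity`, `balanced_accuracy`, `ppv`, `npv`,
#'   `positive_class`.
#' @examples
#' confusion_metrics(c(1, 1, 2, 2, 2), c(1, 2, 2, 2, 1), positive = 2)
#' @export
confusion_metrics <- function(truth, predicted, positive = NULL, levels = NULL) {
  if (length(truth) != length(predicted)) {
    abort("`truth` and `predicted` must have the same length")
  }
  if (length(truth) == 0) abort("empty inputs")
  if (is.null(levels)) {
    lab <- normalize_classes(truth)
  } else {
    if (length(levels) != 2) abort("`levels` must name exactly 2 classes")
    lab <- list(levels = as.character(levels))
    if (!all(as.character(truth) %in% lab$levels)) {
      abort("`truth` contains labels outside `levels`")
    }
  }
  pred <- as.character(predicted)
  bad <- setdiff(unique(pred), lab$levels)
  if (length(bad) > 0) {
    abort(paste0("predicted labels outside the truth label set: ",
                 paste(bad, collapse = ", ")))
  }
  positive <- if (is.null(positive)) lab$levels[2] else as.character(positive)
  if (!positive %in% lab$levels) abort("`positive` is not one of the class labels")
  tr_pos <- as.character(truth) == positive
  pr_pos <- pred == positive
  tp <- sum(tr_pos & pr_pos); fp <- sum(!tr_pos & pr_pos)
  tn <- sum(!tr_pos & !pr_pos); fn <- sum(tr_pos & !pr_pos)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  tibble::tibble(
    tp = tp, fp = fp, tn = tn, fn = fn,
    overall_accuracy = (tp + tn) / length(truth),
    sensitivity = sens,
    specificity = spec,
    balanced_accuracy = if (is.na(sens) || is.na(spec)) NA_real_ else (sens + spec) / 2,
    ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
    positive_class = positive
  )
}

#' Repeated stratified cross-validation of TSP-type classifiers
#'
#' Runs `iterations` independent rounds of `folds`-fold cross-validation,
#' re-randomizing the fold partition each round. Within a round every fold is
#' held out once; the model is fitted on the remaining folds (so it may select
#' different pairs in every fit) and evaluated on the held-out fold with
#' [confusion_metrics()]. Each round's report is the across-fold average of
#' every measure; folds where PPV (or NPV) is undefined are excluded from that
#' measure's average, with the count of such folds reported.
#'
#' Covariate adjustment is controlled by `residualize_mode`:
#' \describe{
#'   \item{`"none"`}{raw features.}
#'   \item{`"per_fold"`}{the residualizer is fitted on the training folds only
#'     and applied to both training and test folds — no information leaks
#'     from the held-out samples (the default when covariates are given).}
#'   \item{`"global"`}{the whole dataset is residualized once before
#'     partitioning, reproducing a whole-dataset preprocessing workflow.}
#' }
#'
#' @inheritParams score_pairs
#' @param covariates Covariate columns (character vector) for residualizing,
#'   or `NULL` for none.
#' @param method `"tsp"` or `"ktsp"`, ignored when `fit_fun` is supplied.
#' @param residualize_mode `"none"`, `"per_fold"` or `"global"`.
#' @param iterations Number of CV rounds (default 100).
#' @param folds Number of folds (default 5).
#' @param k_grid Passed to [fit_ktsp()] when `method = "ktsp"`.
#' @param stratified Stratify fold assignment by class (default `TRUE`; with
#'   imbalanced classes unstratified folds can lose a class entirely).
#' @param positive Positive class for the metrics; default the second level.
#' @param seed Optional integer seed; the full procedure is reproducible.
#' @param fit_fun,predict_fun Optional plug-in classifier:
#'   `fit_fun(train_data, label_col, features)` returning a model and
#'   `predict_fun(model, test_data)` returning labels. Lets external learners
#'   be evaluated under the identical protocol (any probability cutoff is the
#'   plug-in's responsibility).
#' @return An object of class `"tsp_cv"`: `$metrics` (one row per iteration
#'   with the six fold-averaged measures plus undefined-fold counts),
#'   `$selected` (features selected per iteration and fold) and `$settings`.
#'   Supports [tidy()], [glance()] and [autoplot()][autoplot.tsp_cv].
#' @examples
#' sim <- simulate_study1(seed = 3)
#' cv <- repeated_cv(sim, "Y", features = c("X1", "X2", "X3", "X4"),
#'                   covariates = "Z", residualize_mode = "per_fold",
#'                   iterations = 2, folds = 5, seed = 9)
#' glance(cv)
#' @export
repeated_cv <- function(data, labels, features = NULL, covariates = NULL,
                        method = c("tsp", "ktsp"),
                        residualize_mode = c("none", "per_fold", "global"),
                        iterations = 100, folds = 5, k_grid = 2:10,
                        stratified = TRUE, positive = NULL, seed = NULL,
                        fit_fun = NULL, predict_fun = NULL,
                        id_col = "sample_id") {
  method <- match.arg(method)
  residualize_mode <- match.arg(residualize_mode)
  if (folds < 2) abort("`folds` must be at least 2")
  if (residualize_mode != "none" && is.null(covariates)) {
    abort("`covariates` are required for residualized modes")
  }
  if (xor(is.null(fit_fun), is.null(predict_fun))) {
    abort("supply both `fit_fun` and `predict_fun`, or neither")
  }
  data <- tibble::as_tibble(data)
  label_col <- if (is.character(labels) && length(labels) == 1 &&
                   labels %in% names(data)) {
    labels
  } else {
    data$.class <- resolve_labels(data, labels)
    ".class"
  }
  lab <- normalize_classes(data[[label_col]])
  check_both_classes(lab$cls)
  feats <- resolve_features(data, features,
                            exclude = c(label_col, covariates, "posterior"),
                            id_col = id_col)
  positive <- if (is.null(positive)) lab$levels[2] else as.character(positive)

  fit1 <- fit_fun %||% switch(method,
    tsp = function(train, label_col, feats) fit_tsp(train, label_col, feats, id_col),
    ktsp = function(train, label_col, feats) {
      fit_ktsp(train, label_col, feats, k_grid = k_grid, id_col = id_col)
    })
  pred1 <- predict_fun %||% function(model, test) predict(model, test)

  run <- function() {
    if (residualize_mode == "global") {
      data <- residualize(data, covariates, feats, id_col)
    }
    n <- nrow(data)
    one_iteration <- function(it) {
      fold_id <- assign_folds(lab$cls, folds, stratified)
      fold_out <- lapply(seq_len(folds), function(f) {
        train <- data[fold_id != f, ]
        test <- data[fold_id == f, ]
        if (length(unique(train[[label_col]])) < 2) {
          abort(paste0("a training partition lost one class entirely; ",
                       "use stratified = TRUE"))
        }
        if (residualize_mode == "per_fold") {
          rz <- fit_residualizer(train, covariates, feats, id_col)
          train <- predict(rz, train)
          test <- predict(rz, test)
        }
        model <- fit1(train, label_col, feats)
        m <- confusion_metrics(test[[label_col]], pred1(model, test), positive,
                               levels = lab$levels)
        list(metrics = m, selected = selected_features(model, it, f))
      })
      ms <- dplyr::bind_rows(purrr::map(fold_out, "metrics"))
      avg <- function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
      list(
        metrics = tibble::tibble(
          iteration = it,
          overall_accuracy = avg(ms$overall_accuracy),
          sensitivity = avg(ms$sensitivity),
          specificity = avg(ms$specificity),
          balanced_accuracy = avg(ms$balanced_accuracy),
          ppv = avg(ms$ppv),
          npv = avg(ms$npv),
          ppv_undefined_folds = sum(is.na(ms$ppv)),
          npv_undefined_folds = sum(is.na(ms$npv))
        ),
        selected = dplyr::bind_rows(purrr::map(fold_out, "selected"))
      )
    }
    out <- lapply(seq_len(iterations), one_iteration)
    list(metrics = dplyr::bind_rows(purrr::map(out, "metrics")),
         selected = dplyr::bind_rows(purrr::map(out, "selected")))
  }
  res <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  structure(
    list(
      metrics = res$metrics,
      selected = res$selected,
      settings = list(method = method, residualize_mode = residualize_mode,
                      iterations = iterations, folds = folds,
                      stratified = stratified, k_grid = k_grid,
                      positive = positive, seed = seed, features = feats)
    ),
    class = "tsp_cv"
  )
}

# Random fold assignment; stratified keeps class proportions near-equal
# across folds so every fold sees both classes.
#' @noRd
assign_folds <- function(cls, folds, stratified) {
  n <- length(cls)
  fold_id <- integer(n)
  if (stratified) {
    for (c in unique(cls)) {
      idx <- which(cls == c)
      fold_id[idx] <- sample(rep(seq_len(folds), length.out = length(idx)))
    }
  } else {
    fold_id <- sample(rep(seq_len(folds), length.out = n))
  }
  fold_id
}

#' @noRd
selected_features <- function(model, iteration, fold) {
  pairs <- if (inherits(model, "tsp")) {
    model$pair
  } else if (inherits(model, "ktsp")) {
    model$pairs[seq_len(model$k_star), ]
  } else {
    return(NULL)
  }
  tibble::tibble(
    iteration = iteration, fold = fold,
    rank = seq_len(nrow(pairs)),
    feature_i = pairs$feature_i, feature_j = pairs$feature_j
  )
}

#' @export
print.tsp_cv <- function(x, ...) {
  s <- x$settings
  cat(sprintf("Repeated %d-fold CV, %d iterations (%s%s)\n",
              s$folds, s$iterations, s$method,
              if (s$residualize_mode == "none") "" else
                paste0(", residualized ", s$residualize_mode)))
  print(glance(x))
  invisible(x)
}

#' @describeIn repeated_cv Long format: one row per iteration and measure.
#' @param x A `"tsp_cv"` object.
#' @export
tidy.tsp_cv <- function(x, ...) {
  tidyr::pivot_longer(
    dplyr::select(x$metrics, -"ppv_undefined_folds", -"npv_undefined_folds"),
    -"iteration", names_to = "metric", values_to = "value"
  )
}

#' @describeIn repeated_cv One row of across-iteration medians per measure.
#' @export
glance.tsp_cv <- function(x, ...) {
  m <- x$metrics
  tibble::tibble(
    overall_accuracy = median(m$overall_accuracy, na.rm = TRUE),
    sensitivity = median(m$sensitivity, na.rm = TRUE),
    specificity = median(m$specificity, na.rm = TRUE),
    balanced_accuracy = median(m$balanced_accuracy, na.rm = TRUE),
    ppv = median(m$ppv, na.rm = TRUE),
    npv = median(m$npv, na.rm = TRUE),
    iterations = nrow(m)
  )
}

#' Box plots of cross-validated accuracy measures
#'
#' @param object A `"tsp_cv"` object from [repeated_cv()].
#' @param ... Unused.
#' @return A ggplot with one box per measure over the CV iterations.
#' @export
autoplot.tsp_cv <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "cross-validated value") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
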