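#' Greedy selection of disjoint top-scoring pairs
#'
#' Walks the deterministically ordered score table (descending score, then
#' descending rank score, then feature position) and keeps every pair sharing
#' no feature with an already-kept pair, until `k_max` pairs are selected or
#' the table is exhausted. The first selected pair is always the TSP top pair.
#' Greedy selection is the conventional construction for the K-TSP pair set;
#' it does not always attain the exact maximum-total-score disjoint set, which
#' is a weighted-matching problem.
#'
#' @param scores A score table from [score_pairs()] (columns `feature_i`,
#'   `feature_j`, `score`, `rank_score`), already in its deterministic order.
#' @param k_max Maximum number of pairs to select.
#' @return A tibble of at most `k_max` rows of `scores`, in selection order.
#'   If fewer than `k_max` disjoint pairs exist a warning is raised.
#' @export
select_disjoint_pairs <- function(scores, k_max) {
  if (k_max < 1) abort("`k_max` must be at least 1")
  used <- character(0)
  keep <- integer(0)
  for (r in seq_len(nrow(scores))) {
    fi <- scores$feature_i[r]; fj <- scores$feature_j[r]
    if (!(fi %in% used) && !(fj %in% used)) {
      keep <- c(keep, r)
      used <- c(used, fi, fj)
      if (length(keep) == k_max) break
    }
  }
  if (length(keep) < k_max) {
    warn(sprintf("only %d disjoint pairs available (requested %d)",
                 length(keep), k_max))
  }
  scores[keep, ]
}

#' Variance-normalized K-TSP criterion
#'
#' For a set of disjoint pairs, the criterion is the sum of the pair scores
#' divided by the square root of the summed within-class sample variances of
#' the per-sample ordering count \eqn{\sum_r I(X_{i_r} < X_{j_r})}:
#' \deqn{\hat\tau = \frac{\sum_r \hat s_{i_r j_r}}
#'   {\sqrt{\widehat{Var}(\sum_r I(X_{i_r} < X_{j_r}) \mid C=1) +
#'          \widehat{Var}(\cdot \mid C=2)}}.}
#' Variances use the unbiased (\eqn{n_c - 1}) denominator. Indicators are
#' evaluated in the stored `(feature_i, feature_j)` order of each pair. If both
#' within-class variances are zero (e.g. a single perfectly separating pair)
#' the criterion is `Inf`, with a warning, and is treated as maximal when
#' choosing the number of pairs.
#'
#' @inheritParams pair_score
#' @param pairs A tibble with columns `feature_i`, `feature_j` (disjoint pairs).
#' @return A single non-negative number (possibly `Inf`).
#' @export
ktsp_tau <- function(data, labels, pairs, id_col = "sample_id") {
  if (nrow(pairs) < 1) abort("`pairs` must contain at least one pair")
  lab <- normalize_classes(resolve_labels(data, labels))
  check_both_classes(lab$cls)
  ind <- vapply(seq_len(nrow(pairs)), function(r) {
    as.numeric(data[[pairs$feature_i[r]]] < data[[pairs$feature_j[r]]])
  }, numeric(nrow(data)))
  ind <- matrix(ind, nrow = nrow(data))
  s <- vapply(seq_len(nrow(pairs)), function(r) {
    abs(mean(ind[lab$cls == 1L, r]) - mean(ind[lab$cls == 2L, r]))
  }, numeric(1))
  if (min(table(lab$cls)) < 2) {
    abort("each class needs at least 2 samples for the within-class variances")
  }
  counts <- rowSums(ind)
  v <- var(counts[lab$cls == 1L]) + var(counts[lab$cls == 2L])
  if (v == 0) {
    warn("zero within-class variance of the ordering count; tau is Inf")
    return(Inf)
  }
  sum(s) / sqrt(v)
}

#' Fit a K-TSP classifier
#'
#' Selects disjoint top-scoring pairs greedily (nested: the pair set for each
#' `k` is the first `k` greedily selected pairs), evaluates the
#' variance-normalized criterion [ktsp_tau()] for every `k` in `k_grid`, and
#' keeps `k_star`, the `k` with maximal criterion (ties toward smaller `k`).
#' Test samples are classified by majority vote of the `k_star` pair rules,
#' each oriented as in [fit_tsp()]; a vote tie is decided by the top-scoring
#' pair.
#'
#' @inheritParams score_pairs
#' @param k_grid Candidate numbers of pairs (default `2:10`).
#' @return An object of class `"ktsp"`: selected `pairs` (in selection order,
#'   with per-pair vote orientation), `k_star`, the `tau` table over `k_grid`,
#'   class levels and counts. Supports [predict()][predict.ktsp], [tidy()]
#'   and [glance()].
#'
#' @examples
#' sim <- simulate_study1(seed = 7)
#' fit <- fit_ktsp(sim, "Y", features = c("X1", "X2", "X3", "X4"), k_grid = 1:2)
#' fit$k_star
#' @export
fit_ktsp <- function(data, labels, features = NULL, k_grid = 2:10,
                     id_col = "sample_id") {
  k_grid <- sort(unique(as.integer(k_grid)))
  if (any(k_grid < 1)) abort("`k_grid` values must be positive")
  lab <- normalize_classes(resolve_labels(data, labels))
  check_both_classes(lab$cls)
  exclude <- if (is.character(labels) && length(labels) == 1) labels else character()
  feats <- resolve_features(data, features, exclude = exclude, id_col = id_col)
  if (length(feats) < 2 * min(k_grid)) {
    abort(sprintf("too few features (%d) for the smallest k in k_grid (%d)",
                  length(feats), min(k_grid)))
  }
  tab <- score_pairs(data, labels, feats, id_col)
  sel <- withCallingHandlers(
    select_disjoint_pairs(tab, max(k_grid)),
    warning = function(w) invokeRestart("muffleWarning")
  )
  ks <- k_grid[k_grid <= nrow(sel)]
  tau <- vapply(ks, function(k) {
    suppressWarnings(ktsp_tau(data, labels, sel[seq_len(k), ], id_col))
  }, numeric(1))
  k_star <- ks[which.max(tau)]
  pairs <- dplyr::mutate(
    sel,
    vote_lt = ifelse(sel$p1 < sel$p2, lab$levels[2], lab$levels[1]),
    vote_ge = ifelse(sel$p1 < sel$p2, lab$levels[1], lab$levels[2])
  )
  structure(
    list(
      pairs = pairs,
      k_star = k_star,
      tau = tibble::tibble(k = ks, tau = tau),
      levels = lab$levels,
      class_counts = c(sum(lab$cls == 1L), sum(lab$cls == 2L)),
      scores = tab
    ),
    class = "ktsp"
  )
}

#' Predict with a fitted K-TSP classifier
#'
#' @param object A `"ktsp"` model from [fit_ktsp()].
#' @param newdata Data frame containing all model features (matched by name).
#' @param k Number of pairs to vote with; defaults to the model's `k_star`.
#' @param ... Unused.
#' @return A factor of predicted classes with the training levels. Each pair
#'   votes per its orientation; the majority wins; a tie is broken by the
#'   highest-scoring pair's vote.
#' @export
predict.ktsp <- function(object, newdata, k = object$k_star, ...) {
  pairs <- object$pairs[seq_len(k), ]
  missing <- setdiff(unique(c(pairs$feature_i, pairs$feature_j)), names(newdata))
  if (length(missing) > 0) {
    abort(paste0("model feature(s) missing from newdata: ",
                 paste(missing, collapse = ", ")))
  }
  votes2 <- matrix(0L, nrow = nrow(newdata), ncol = k)
  for (r in seq_len(k)) {
    lt <- newdata[[pairs$feature_i[r]]] < newdata[[pairs$feature_j[r]]]
    vote <- ifelse(lt, pairs$vote_lt[r], pairs$vote_ge[r])
    votes2[, r] <- as.integer(vote == object$levels[2])
  }
  n2 <- rowSums(votes2)
  pred <- ifelse(n2 > k / 2, object$levels[2],
                 ifelse(n2 < k / 2, object$levels[1],
                        ifelse(votes2[, 1] == 1L, object$levels[2], object$levels[1])))
  factor(pred, levels = object$levels)
}

#' @export
print.ktsp <- function(x, ...) {
  cat(sprintf("K-TSP classifier: k* = %d of grid {%s}\n",
              x$k_star, paste(x$tau$k, collapse = ",")))
  print(dplyr::select(x$pairs[seq_len(x$k_star), ],
                      "feature_i", "feature_j", "score", "vote_lt"))
  invisible(x)
}

#' @describeIn fit_ktsp Selected pairs (one row each, selection order) with
#'   scores and vote orientation; `all_pairs = TRUE` includes greedy pairs
#'   beyond `k_star`.
#' @param x A `"ktsp"` model.
#' @param all_pairs Include pairs beyond `k_star`?
#' @param ... Unused.
#' @export
tidy.ktsp <- function(x, all_pairs = FALSE, ...) {
  n <- if (all_pairs) nrow(x$pairs) else x$k_star
  dplyr::mutate(x$pairs[seq_len(n), ], rank = dplyr::row_number(),
                .before = 1)
}

#' @describeIn fit_ktsp One-row summary: `k_star`, its criterion value, the
#'   summed score of the selected pairs and training class counts.
#' @export
glance.ktsp <- function(x, ...) {
  tibble::tibble(
    k_star = x$k_star,
    tau = x$tau$tau[x$tau$k == x$k_star],
    total_score = sum(x$pairs$score[seq_len(x$k_star)]),
    n_class1 = x$class_counts[1],
    n_class2 = x$class_counts[2]
  )
}
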