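#' Discriminant score of a single feature pair
#'
#' The pair score of features \eqn{(i, j)} is the absolute difference between
#' the two class-conditional proportions of the ordering \eqn{X_i < X_j}:
#' \deqn{\hat s_{ij} = | P(X_i < X_j \mid C = 1) - P(X_i < X_j \mid C = 2) |,}
#' with the proportions estimated from the sample. A score of 1 means the
#' ordering separates the classes perfectly; 0 means no discrimination. The
#' comparison is strict: a tie \eqn{X_i = X_j} does not count as
#' \eqn{X_i < X_j}. Because only within-profile orderings enter, the score is
#' invariant to any strictly increasing transform applied to a sample's
#' profile, e.g. log transformation or sample-wise normalization.
#'
#' @param data A data frame with one row per sample. A `sample_id` column (or
#'   the column named by `id_col`) is used for sample identifiers when present;
#'   all other columns referenced by `i`/`j` must be numeric.
#' @param labels Name of the column of `data` holding the two-level class
#'   label, or a vector with one label per row. The first factor level (or the
#'   smaller value) is class 1, the other class 2.
#' @param i,j Feature columns (names or positions). Must differ.
#' @param id_col Name of the sample-identifier column. Default `"sample_id"`.
#'
#' @return A one-row tibble with columns `feature_i`, `feature_j`, `p1`, `p2`
#'   (the class-conditional ordering proportions), `score` and `rank_score`
#'   (the secondary tie-break statistic, see [secondary_rank_score()]).
#'
#' @examples
#' d <- tibble::tibble(
#'   sample_id = paste0("s", 1:4),
#'   A = c(0, 0, 3, 5), B = c(1, 2, 1, 2),
#'   class = c(1, 1, 2, 2)
#' )
#' pair_score(d, "class", "A", "B")
#' @seealso [score_pairs()] for all pairs at once, [fit_tsp()] for the
#'   classifier built on the top-scoring pair.
#' @export
pair_score <- function(data, labels, i, j, id_col = "sample_id") {
  lab <- normalize_classes(resolve_labels(data, labels))
  check_both_classes(lab$cls)
  exclude <- if (is.character(labels) && length(labels) == 1) labels else character()
  feats <- resolve_features(data, exclude = exclude, id_col = id_col)
  ij <- resolve_pair(feats, i, j)
  X <- feature_matrix(data, feats, id_col)
  R <- profile_ranks(X)
  score_one_pair(X, R, lab$cls, ij[1], ij[2], feats)
}

#' @noRd
resolve_pair <- function(feats, i, j) {
  to_idx <- function(f) {
    if (is.numeric(f)) {
      if (f < 1 || f > length(feats)) abort("feature index out of range")
      as.integer(f)
    } else {
      k <- match(as.character(f), feats)
      if (is.na(k)) abort(sprintf("feature '%s' not found", f))
      k
    }
  }
  ii <- to_idx(i); jj <- to_idx(j)
  if (ii == jj) abort("invalid pair: i and j must be different features")
  c(ii, jj)
}

#' @noRd
score_one_pair <- function(X, R, cls, ii, jj, feats) {
  lt <- X[, ii] < X[, jj]
  p1 <- mean(lt[cls == 1L])
  p2 <- mean(lt[cls == 2L])
  dR <- R[, ii] - R[, jj]
  rs <- abs(mean(dR[cls == 1L]) - mean(dR[cls == 2L]))
  tibble::tibble(
    feature_i = feats[ii], feature_j = feats[jj],
    p1 = p1, p2 = p2, score = abs(p1 - p2), rank_score = rs
  )
}

#' Secondary rank score of a feature pair
#'
#' Tie-break statistic used when several pairs reach the same discriminant
#' score: the absolute between-class difference of the mean within-sample rank
#' difference of the two features,
#' \deqn{| \bar{(R_i - R_j)}_{C=1} - \bar{(R_i - R_j)}_{C=2} |,}
#' where \eqn{R} holds within-profile ranks (average rank on ties). Larger
#' values indicate a wider, more consistent rank separation. The exact
#' tie-break statistic is a convention of this package (the literature uses
#' several variants); residual ties are broken lexicographically by feature
#' position, making the top-pair selection deterministic.
#'
#' @inheritParams pair_score
#' @return A single non-negative number.
#' @export
secondary_rank_score <- function(data, labels, i, j, id_col = "sample_id") {
  pair_score(data, labels, i, j, id_col = id_col)$rank_score
}

#' Score all feature pairs
#'
#' Computes the discriminant score and secondary rank score for every
#' unordered feature pair, returning a deterministically ordered table:
#' descending score, then descending rank score, then feature position.
#'
#' @inheritParams pair_score
#' @param features Character vector (or positions) of feature columns to
#'   score. Default: every numeric column except the id and label columns.
#'
#' @return A tibble with `choose(p, 2)` rows and columns `feature_i`,
#'   `feature_j`, `p1`, `p2`, `score`, `rank_score`, ordered as described.
#'   `feature_i`/`feature_j` follow the column order of `features`.
#'
#' @examples
#' set.seed(1)
#' d <- tibble::tibble(
#'   sample_id = paste0("s", 1:20),
#'   A = rnorm(20), B = rnorm(20), C = rnorm(20),
#'   class = rep(1:2, each = 10)
#' )
#' score_pairs(d, "class")
#' @export
score_pairs <- function(data, labels, features = NULL, id_col = "sample_id") {
  lab <- normalize_classes(resolve_labels(data, labels))
  check_both_classes(lab$cls)
  exclude <- if (is.character(labels) && length(labels) == 1) labels else character()
  feats <- resolve_features(data, features, exclude = exclude, id_col = id_col)
  if (length(feats) < 2) abort("need at least 2 features to score pairs")
  X <- feature_matrix(data, feats, id_col)
  score_table(X, lab$cls, feats)
}

# All-pairs engine. Accumulates, per class, the count matrix
# C[i, j] = #{samples k in class : X[k, i] < X[k, j]} from within-sample rank
# comparisons (O(N p^2) time, O(p^2) memory).
#' @noRd
score_table <- function(X, cls, feats) {
  p <- ncol(X)
  n1 <- sum(cls == 1L); n2 <- sum(cls == 2L)
  R <- profile_ranks(X)
  count_lt <- function(rows) {
    cnt <- matrix(0, p, p)
    for (k in rows) {
      r <- R[k, ]
      cnt <- cnt + outer(r, r, "<")
    }
    cnt
  }
  P1 <- count_lt(which(cls == 1L)) / n1
  P2 <- count_lt(which(cls == 2L)) / n2
  m1 <- colMeans(R[cls == 1L, , drop = FALSE])
  m2 <- colMeans(R[cls == 2L, , drop = FALSE])
  d1 <- outer(m1, m1, "-"); d2 <- outer(m2, m2, "-")
  RS <- abs(d1 - d2)
  idx <- which(upper.tri(P1), arr.ind = TRUE)
  out <- tibble::tibble(
    feature_i = feats[idx[, 1]], feature_j = feats[idx[, 2]],
    p1 = P1[idx], p2 = P2[idx],
    score = abs(P1[idx] - P2[idx]), rank_score = RS[idx],
    .i = idx[, 1], .j = idx[, 2]
  )
  out <- dplyr::arrange(out, dplyr::desc(.data$score),
                        dplyr::desc(.data$rank_score), .data$.i, .data$.j)
  dplyr::select(out, -".i", -".j")
}
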