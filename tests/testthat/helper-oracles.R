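# Independent brute-force oracles and small fixture builders. The oracles use
# explicit double loops over samples and pairs and never call package
# internals, so they can certify the vectorized implementations.

# Build an analysis tibble from a plain matrix and a class vector.
make_data <- function(X, cls, feats = paste0("f", seq_len(ncol(X)))) {
  colnames(X) <- feats
  tibble::as_tibble(as.data.frame(X)) |>
    dplyr::mutate(sample_id = paste0("s", dplyr::row_number()), .before = 1) |>
    dplyr::mutate(class = cls)
}

# Proportion-difference score by explicit counting (strict inequality).
oracle_pair_score <- function(X, cls, i, j) {
  n1 <- 0; c1 <- 0; n2 <- 0; c2 <- 0
  for (k in seq_len(nrow(X))) {
    if (cls[k] == sort(unique(cls))[1]) {
      n1 <- n1 + 1
      if (X[k, i] < X[k, j]) c1 <- c1 + 1
    } else {
      n2 <- n2 + 1
      if (X[k, i] < X[k, j]) c2 <- c2 + 1
    }
  }
  list(p1 = c1 / n1, p2 = c2 / n2, score = abs(c1 / n1 - c2 / n2))
}

# Secondary rank score by explicit per-sample ranking.
oracle_rank_score <- function(X, cls, i, j) {
  lev <- sort(unique(cls))
  d <- numeric(nrow(X))
  for (k in seq_len(nrow(X))) {
    r <- rank(X[k, ], ties.method = "average")
    d[k] <- r[i] - r[j]
  }
  abs(mean(d[cls == lev[1]]) - mean(d[cls == lev[2]]))
}

# Variance-normalized criterion by explicit indicator sums.
oracle_tau <- function(X, cls, pairs) {
  lev <- sort(unique(cls))
  s_sum <- 0
  counts <- numeric(nrow(X))
  for (r in seq_len(nrow(pairs))) {
    o <- oracle_pair_score(X, cls, pairs$i[r], pairs$j[r])
    s_sum <- s_sum + o$score
    for (k in seq_len(nrow(X))) {
      counts[k] <- counts[k] + as.numeric(X[k, pairs$i[r]] < X[k, pairs$j[r]])
    }
  }
  v <- var(counts[cls == lev[1]]) + var(counts[cls == lev[2]])
  if (v == 0) Inf else s_sum / sqrt(v)
}

# Exhaustive maximum total score over all sets of m disjoint pairs.
oracle_best_disjoint <- function(score_tbl, m) {
  pairs <- score_tbl[, c("feature_i", "feature_j", "score")]
  best <- -Inf
  pick <- function(start, chosen, used, total) {
    if (length(chosen) == m) {
      best <<- max(best, total)
      return()
    }
    if (start > nrow(pairs)) return()
    for (r in start:nrow(pairs)) {
      fi <- pairs$feature_i[r]; fj <- pairs$feature_j[r]
      if (!(fi %in% used) && !(fj %in% used)) {
        pick(r + 1, c(chosen, r), c(used, fi, fj), total + pairs$score[r])
      }
    }
  }
  pick(1, integer(0), character(0), 0)
  best
}

# Fixtures from hand-worked examples ------------------------------------------

# Perfect separation on the (A, B) ordering: score 1, rank score 2.
toy_perfect <- function() {
  make_data(rbind(c(0, 1), c(0, 2), c(3, 1), c(5, 2)),
            cls = c(1, 1, 2, 2), feats = c("A", "B"))
}

# Counted by hand: p1 = 2/3, p2 = 1/3, score 1/3.
toy_third <- function() {
  make_data(rbind(c(1, 2), c(2, 1), c(0, 3), c(4, 1), c(1, 4), c(5, 0)),
            cls = c(1, 1, 1, 2, 2, 2), feats = c("A", "B"))
}

# Two planted pairs (A,B) and (C,D) whose orderings flip between classes with
# noise, plus two uninformative features E, F.
planted_pairs_data <- function(n_per_class = 40, flip_prob = 0.15) {
  n <- 2 * n_per_class
  cls <- rep(1:2, each = n_per_class)
  gen_pair <- function() {
    a <- rnorm(n)
    sign <- ifelse(cls == 1, 1, -1)
    sign <- sign * ifelse(runif(n) < flip_prob, -1, 1)
    b <- a + sign + rnorm(n, sd = 0.1)
    cbind(a, b)
  }
  X <- cbind(gen_pair(), gen_pair(), rnorm(n), rnorm(n))
  make_data(X, cls, feats = c("A", "B", "C", "D", "E", "F"))
}

random_data <- function(n, p, seed = NULL) {
  stopifnot(n >= 4)
  run <- function() {
    # at least two samples per class so within-class variances exist
    cls <- sample(c(1, 1, 2, 2, sample(1:2, n - 4, replace = TRUE)))
    make_data(matrix(rnorm(n * p), n, p), cls)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
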