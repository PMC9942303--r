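# Simulation generators: two designed studies contrasting a feature pair whose
# class separation is inherited from a binary covariate with a pair driven by
# the outcome itself.

# Means/variances of the two bivariate-normal feature pairs.
SIM_PARAMS <- list(
  x12 = list(m0 = c(0, 5), m1 = c(5, 0), v = 2),    # conditional on Z
  x34 = list(m0 = c(0, 2.5), m1 = c(2.5, 0), v = 3) # conditional on class
)

#' @noRd
log_dbvn <- function(x, y, m, v, rho) {
  rho <- pmin(pmax(rho, -1 + 1e-12), 1 - 1e-12)
  dx <- x - m[1]; dy <- y - m[2]
  q <- (dx^2 - 2 * rho * dx * dy + dy^2) / (v * (1 - rho^2))
  -q / 2 - log(2 * pi * v * sqrt(1 - rho^2))
}

# Draw n points from a bivariate normal with common variance v and correlation
# rho, via the Cholesky-style construction; exact (degenerate) at |rho| = 1.
#' @noRd
draw_bvn <- function(n, m, v, rho) {
  a <- rnorm(n); b <- rnorm(n)
  cbind(m[1] + sqrt(v) * a,
        m[2] + sqrt(v) * (rho * a + sqrt(pmax(0, 1 - rho^2)) * b))
}

#' Posterior probability of the outcome given the outcome-driven pair
#'
#' Bayes posterior \eqn{P(Y=1 \mid X_3, X_4, Z)} under the simulation model:
#' \eqn{(X_3, X_4)} is bivariate normal with mean \eqn{(2.5, 0)} under
#' \eqn{Y=1} and \eqn{(0, 2.5)} under \eqn{Y=0} (variance 3, correlation
#' `rho`), independent of \eqn{Z} given \eqn{Y}, and the prior is
#' \eqn{P(Y=1 \mid Z) = |Z - 0.05|} (0.95 for \eqn{Z=1}, 0.05 for
#' \eqn{Z=0}). Computed in log space, so it remains stable as
#' \eqn{|\rho| \to 1} where the two densities degenerate.
#'
#' @param x3,x4 Numeric vectors of feature values.
#' @param z Binary covariate values (0/1), recycled to the feature length.
#' @param rho Correlation of the \eqn{(X_3, X_4)} pair, in `[-1, 1]`.
#' @return Posterior probabilities in `[0, 1]`.
#' @examples
#' posterior_prob_y(2.5, 0, z = 1)   # strong evidence and prior: near 1
#' posterior_prob_y(1.25, 1.25, z = 0)  # equidistant from both means: prior 0.05
#' @export
posterior_prob_y <- function(x3, x4, z, rho = 0) {
  if (any(abs(rho) > 1)) abort("`rho` must lie in [-1, 1]")
  pi_z <- abs(z - 0.05)
  l1 <- log_dbvn(x3, x4, SIM_PARAMS$x34$m1, SIM_PARAMS$x34$v, rho)
  l0 <- log_dbvn(x3, x4, SIM_PARAMS$x34$m0, SIM_PARAMS$x34$v, rho)
  # sigmoid of the log posterior odds
  1 / (1 + exp(l0 - l1 + log1p(-pi_z) - log(pi_z)))
}

#' Simulate a covariate-confounded two-pair dataset (study 1)
#'
#' Generates `n` samples with four features and one binary covariate:
#' \itemize{
#'   \item \eqn{Z \sim} Bernoulli(0.5), the "clinical" covariate;
#'   \item \eqn{(X_1, X_2) \mid Z} bivariate normal, means \eqn{(0, 5)} /
#'     \eqn{(5, 0)} for \eqn{Z = 0 / 1}, variance 2, correlation `rho` —
#'     the covariate-driven pair;
#'   \item a balanced latent class \eqn{Y_0 \sim} Bernoulli(0.5), and
#'     \eqn{(X_3, X_4) \mid Y_0} bivariate normal, means \eqn{(0, 2.5)} /
#'     \eqn{(2.5, 0)}, variance 3, correlation `rho` — the outcome-driven
#'     pair, generated independently of \eqn{Z};
#'   \item the outcome \eqn{Y \sim} Bernoulli drawn from the Bayes posterior
#'     [posterior_prob_y()], which combines the \eqn{(X_3, X_4)} evidence
#'     with the covariate prior \eqn{P(Y=1 \mid Z) = |Z - 0.05|}.
#' }
#' So \eqn{(X_1, X_2)} predicts \eqn{Y} only through \eqn{Z}, while
#' \eqn{(X_3, X_4)} carries direct outcome signal: residualizing on \eqn{Z}
#' should collapse the former pair's discriminant score and approximately
#' preserve the latter's.
#'
#' @param n Number of samples (default 200).
#' @param rho Within-pair correlation, shared by both pairs (default 0;
#'   study 2 varies it over a grid).
#' @param seed Optional integer seed (the global RNG state is preserved).
#' @return A tibble with columns `sample_id`, `X1`–`X4`, `Z`, `Y` (0/1
#'   integer) and `posterior` (the Bernoulli probability used to draw `Y`).
#' @examples
#' sim <- simulate_study1(seed = 1)
#' mean(sim$Y)  # close to 0.5
#' @export
simulate_study1 <- function(n = 200, rho = 0, seed = NULL) {
  run <- function() {
    z <- rbinom(n, 1, 0.5)
    y0 <- rbinom(n, 1, 0.5)
    x12 <- matrix(NA_real_, n, 2)
    x12[z == 0, ] <- draw_bvn(sum(z == 0), SIM_PARAMS$x12$m0, SIM_PARAMS$x12$v, rho)
    x12[z == 1, ] <- draw_bvn(sum(z == 1), SIM_PARAMS$x12$m1, SIM_PARAMS$x12$v, rho)
    x34 <- matrix(NA_real_, n, 2)
    x34[y0 == 0, ] <- draw_bvn(sum(y0 == 0), SIM_PARAMS$x34$m0, SIM_PARAMS$x34$v, rho)
    x34[y0 == 1, ] <- draw_bvn(sum(y0 == 1), SIM_PARAMS$x34$m1, SIM_PARAMS$x34$v, rho)
    post <- posterior_prob_y(x34[, 1], x34[, 2], z, rho)
    y <- rbinom(n, 1, post)
    tibble::tibble(
      sample_id = sprintf("s%03d", seq_len(n)),
      X1 = x12[, 1], X2 = x12[, 2], X3 = x34[, 1], X4 = x34[, 2],
      Z = z, Y = y, posterior = post
    )
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Pair scores across a correlation grid (study 2)
#'
#' For each correlation value in `rho`, simulates one dataset (or
#' `replicates` datasets) with [simulate_study1()] and records the
#' discriminant score of both feature pairs, raw and after residualizing on
#' the covariate `Z`. The grid default follows the design: \eqn{\rho} from
#' \eqn{-1} to \eqn{1} in steps of 0.01, one dataset per value.
#'
#' @param n Samples per dataset (default 200).
#' @param rho Numeric vector of correlation values (default
#'   `seq(-1, 1, by = 0.01)`).
#' @param replicates Datasets per grid value (default 1; more gives smoother
#'   score curves).
#' @param seed Optional integer seed.
#' @return A tibble of class `"tsp_sim2"` with columns `rho`, `replicate`,
#'   `pair` (`"X1,X2"` or `"X3,X4"`), `variant` (`"raw"` or
#'   `"residualized"`) and `score`. Plot with [autoplot()][autoplot.tsp_sim2].
#' @export
simulate_study2 <- function(n = 200, rho = seq(-1, 1, by = 0.01),
                            replicates = 1, seed = NULL) {
  if (any(abs(rho) > 1)) abort("`rho` values must lie in [-1, 1]")
  run <- function() {
    grid <- tidyr::expand_grid(rho = rho, replicate = seq_len(replicates))
    purrr::pmap_dfr(grid, function(rho, replicate) {
      sim <- simulate_study1(n = n, rho = rho)
      # guard against an (astronomically unlikely) single-class outcome draw
      tries <- 0
      while (length(unique(sim$Y)) < 2 && tries < 100) {
        sim <- simulate_study1(n = n, rho = rho)
        tries <- tries + 1
      }
      res <- residualize(sim, covariates = "Z",
                         features = c("X1", "X2", "X3", "X4"))
      tibble::tibble(
        rho = rho, replicate = replicate,
        pair = rep(c("X1,X2", "X3,X4"), 2),
        variant = rep(c("raw", "residualized"), each = 2),
        score = c(
          pair_score(sim, "Y", "X1", "X2")$score,
          pair_score(sim, "Y", "X3", "X4")$score,
          pair_score(res, "Y", "X1", "X2")$score,
          pair_score(res, "Y", "X3", "X4")$score
        )
      )
    })
  }
  out <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  class(out) <- c("tsp_sim2", class(out))
  out
}

#' Plot pair scores against the correlation grid
#'
#' @param object A `"tsp_sim2"` table from [simulate_study2()].
#' @param ... Unused.
#' @return A ggplot: score vs correlation, one panel per feature pair, raw
#'   and residualized variants overlaid.
#' @export
autoplot.tsp_sim2 <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$rho, y = .data$score,
                                       color = .data$variant)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_smooth(se = FALSE, method = "loess", formula = y ~ x) +
    ggplot2::facet_wrap(~pair) +
    ggplot2::labs(x = "within-pair correlation ρ",
                  y = "pair discriminant score") +
    ggplot2::theme_minimal()
}
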