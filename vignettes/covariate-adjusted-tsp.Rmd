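---
title: "Covariate-adjusted top-scoring pairs: model, conventions and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Covariate-adjusted top-scoring pairs: model, conventions and simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(covtsp)
```

## The classification model

The top-scoring pair (TSP) classifier works on a samples × features table of
continuous measurements (e.g. metabolite ion abundances) with a two-level
class label. For an ordered feature pair $(i, j)$ the discriminant score is
the absolute difference of the class-conditional probabilities of the
within-profile ordering:

$$\hat s_{ij} = \bigl| \hat P(X_i < X_j \mid C = 1) - \hat P(X_i < X_j \mid C = 2) \bigr|,$$

with the probabilities estimated as sample proportions. $\hat s_{ij} = 1$ is
perfect separation by the ordering; $0$ is no discrimination. Because only
within-sample orderings enter, every score — and therefore the fitted
classifier — is invariant to strictly increasing transforms applied to a
sample's profile. This makes the method robust to monotone normalization
choices (log transforms, per-sample scaling), an important property for
abundance data whose preprocessing pipelines vary between laboratories.

TSP fits the arg-max pair and classifies a test sample from the observed
ordering of those two features: if on the training data
$\hat P(X_i < X_j \mid C=1) < \hat P(X_i < X_j \mid C=2)$, then observing
$X_i < X_j$ predicts class 2 and $X_i \ge X_j$ predicts class 1; in the
opposite training configuration the predictions swap.

K-TSP fits $k$ feature-disjoint pairs and takes a majority vote. The number
of pairs $k^\*$ is chosen from a grid (default $2,\dots,10$) by maximizing a
variance-normalized criterion in the spirit of an analysis-of-variance
$F$-ratio: the summed scores of the $k$ pairs (between-class separation of
the ensemble) divided by the square root of the summed within-class sample
variances of the per-sample vote count $\sum_r \mathbf 1[X_{i_r} < X_{j_r}]$.
A pair set that separates the classes widely *and* votes consistently within
each class scores high.

## Covariate adjustment by residualizing

Clinical cohorts come with risk factors $Z$ (age, BMI, blood pressure,
established biomarkers…) already known to predict the outcome. An
unadjusted pair search happily selects features that merely proxy those
covariates. The adjustment implemented here regresses every feature on the
covariates by ordinary least squares with an intercept and replaces the
feature values by the residuals $e_{ik} = X_{ik} - \hat X_{ik}$ before the
pair search. On the fitting data OLS residuals are exactly orthogonal to —
hence uncorrelated with — every covariate column, so the selected pairs
cannot be driven by a linear covariate effect. The residualizer is a fitted
object: its coefficients can be applied to new samples (held-out folds, new
cohorts) without refitting.

Conventions worth knowing:

* Categorical covariates with more than two levels must be pre-encoded as
  0/1 indicator columns by the caller. Automatic encoding would silently
  pick reference levels; an explicit design matrix is auditable.
* A rank-deficient design (collinear covariates) is an error naming the
  collinear columns, not a silent drop.
* Residualizing is linear. If feature–covariate relationships are strongly
  nonlinear or heteroscedastic, linear residuals remove only the linear
  part; the residualizer interface would admit richer backends, but none is
  provided here.

In cross-validation (`repeated_cv()`) the default residualized mode is
`per_fold`: the residualizer is fitted on the training folds and applied to
the held-out fold, so the test samples contribute nothing to the adjustment.
A `global` mode residualizes the full table once before partitioning, which
matches the common "preprocess, then cross-validate" workflow; it leaks a
small amount of information and is provided for comparability, not as the
default.

## Numerical conventions

* **Ties in values.** The score uses the strict comparison $X_i < X_j$; a
  tie counts against it (it is an $X_i \ge X_j$ observation). With
  continuous abundance data exact ties are rare; with heavily rounded data
  the strict rule systematically favors the "$\ge$" branch, which is the
  documented behavior rather than a hidden coin flip.
* **Ties in scores.** Pairs with equal scores are ordered by a secondary
  rank score: the absolute between-class difference of the mean
  within-sample rank difference of the two features, with average ranks on
  ties. This statistic is one of several used in the pair-classifier
  literature; it is adopted here as a convention and documented as such.
  Residual ties fall back to feature position, making every fit
  deterministic and reproducible across row permutations of the input.
* **Disjoint pair selection.** The $k$ disjoint pairs are selected greedily
  down the ordered score table. The exact maximizer of the summed score
  over disjoint pair sets is a maximum-weight matching problem; greedy is
  the established construction for this classifier family, is deterministic
  given the score ordering, and its prefix property means the pair sets for
  successive $k$ are nested — the whole $k$ grid costs one pass. The test
  suite compares greedy selections against exhaustive enumeration on small
  instances.
* **Degenerate criterion.** If both within-class vote-count variances are
  zero (e.g. a single perfectly separating pair), the selection criterion is
  reported as `Inf` with a warning and treated as maximal; ties in the
  criterion resolve toward smaller $k$ (the more parsimonious model).
* **Vote ties.** For even $k$ a majority vote can tie; the vote of the
  top-scoring pair decides. This is deterministic and leans on the most
  reliable pair.
* **Undefined measures.** PPV is undefined — reported as `NA`, never 0 —
  when a fold receives no positive predictions (the characteristic failure
  of imbalanced-data baselines that always predict the majority class), and
  likewise NPV with no negative predictions. Cross-validation averages skip
  undefined folds and report how many were skipped.

## What the simulation generators emulate

The two built-in studies create the cleanest possible contrast between a
*covariate-driven* and an *outcome-driven* feature pair.

**Study 1** (`simulate_study1()`, defaults: $N = 200$, correlation $\rho = 0$):

* a binary covariate $Z \sim \mathrm{Bernoulli}(0.5)$ — a prevalent risk
  factor;
* $(X_1, X_2) \mid Z$ bivariate normal with means $(0, 5)$ under $Z = 0$ and
  $(5, 0)$ under $Z = 1$, variance 2: the ordering $X_1 < X_2$ flips with
  $Z$, so the pair is a pure covariate readout;
* a balanced latent class $Y_0 \sim \mathrm{Bernoulli}(0.5)$ and
  $(X_3, X_4) \mid Y_0$ bivariate normal with means $(0, 2.5)$ /
  $(2.5, 0)$, variance 3, generated independently of $Z$: direct disease
  signal with substantial overlap;
* the outcome $Y$ drawn from the Bayes posterior
  $P(Y = 1 \mid X_3, X_4, Z) \propto \phi_1(X_3, X_4)\,\pi(Z)$ with prior
  $\pi(Z) = |Z - 0.05|$, i.e. 0.95 when the risk factor is present and 0.05
  when absent.

Two points of this design deserve explanation. First, the latent class that
shapes $(X_3, X_4)$ is balanced and independent of $Z$: the posterior
formula treats $(X_3, X_4)$ as conditionally independent of $Z$ given $Y$,
and generating them from a $Z$-dependent class would contradict that
assumption — it would push essentially all of the outcome's randomness into
$Z$ and make the covariate-driven pair a near-perfect classifier, erasing
the contrast the study exists to show. Second, the final outcome is a fresh
Bernoulli draw from the posterior rather than the latent class itself, so
$Y$ blends covariate risk with feature evidence exactly as the posterior
prescribes, and the per-sample posterior is returned for calibration checks
(the test suite verifies that outcomes are calibrated against it, and that
class-conditional feature moments match the stated normals).

Under this design, residualizing on $Z$ collapses the $(X_1, X_2)$ score
(its class separation *is* the covariate effect) while approximately
preserving the $(X_3, X_4)$ score. Replicate medians at $N = 200$ are about
0.59 (raw) vs 0.04 (residualized) for $(X_1, X_2)$ and 0.38 vs 0.38 for
$(X_3, X_4)$; single draws scatter around these with a spread of roughly
±0.05–0.07, which is why the acceptance checks compare replicate medians
within a ±0.10 band rather than single draws.

**Study 2** (`simulate_study2()`) repeats study 1 over a grid of within-pair
correlations $\rho$ from $-1$ to $1$ in steps of 0.01 (covariances $2\rho$
and $3\rho$ respectively), one dataset per grid value by default. As $\rho$
grows, $(X_3, X_4)$ becomes a sharper discriminator (the difference
$X_3 - X_4$ concentrates), the posterior polarizes toward the latent class,
and the outcome decouples from $Z$ — so the *raw* $(X_1, X_2)$ score
declines with increasing $\rho$ while the residualized $(X_1, X_2)$ score
stays in the sampling-noise band (below 0.2 for essentially all grid
points). The grid endpoints $|\rho| = 1$ are handled exactly: draws use the
degenerate linear construction, and the posterior is evaluated in log space
so the density ratio stays finite on the support lines.

What the generators do **not** emulate: high-dimensional feature tables
(only four features), mass-spectrometry artifacts (missingness,
batch effects, heteroscedastic noise), correlated covariate sets, or class
imbalance. Passing the simulation-based tests therefore demonstrates the
mechanics and the covariate-adjustment behavior of the estimators, not
their operating characteristics on real metabolomics cohorts.

## Parameters that matter

| Parameter | Where | Default | Meaning |
|---|---|---|---|
| `k_grid` | `fit_ktsp()` | `2:10` | candidate numbers of disjoint pairs; `k_star` maximizes the criterion, ties to smaller `k` |
| `residualize_mode` | `repeated_cv()` | `none` / `per_fold` with covariates | fold-safe vs whole-dataset adjustment |
| `iterations`, `folds` | `repeated_cv()` | 100, 5 | CV rounds × folds; each round re-randomizes the partition |
| `stratified` | `repeated_cv()` | `TRUE` | class-stratified folds; with imbalanced data unstratified folds can lose a class (then an error suggests stratifying) |
| `positive` | metrics | second class level | class treated as "positive" for sensitivity/PPV |
| `n`, `rho`, `seed` | simulators | 200, 0, none | sample size, within-pair correlation, reproducibility |

## Problem sizes and runtime

The examples and the test suite run at deliberately small scale: simulated
datasets of $N = 200$ with 4 features, score-table oracles at $N \le 12$,
$p \le 6$ (where exhaustive double-loop counting is feasible), 200
replicates for distributional checks, and 20×5-fold cross-validation for
calibration checks. The scoring engine materializes $p \times p$ count
matrices, so a full score table for $p$ in the low thousands (millions of
pairs) remains comfortably in memory; the cross-validation harness refits
the full pipeline per fold and scales linearly in `iterations × folds`.

## Known limitations

* Two classes only; multi-class orderings are out of scope.
* Hard classification: TSP votes carry no calibrated probabilities, so
  there is no ROC/AUC machinery here.
* Linear residualization only (see above).
* Greedy disjoint selection can in principle miss the optimal pair set;
  the first (top) pair is always included, bounding the loss.
* The secondary rank score is a tie-break convention; alternative
  conventions can pick a different—equally top-scoring—pair.
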