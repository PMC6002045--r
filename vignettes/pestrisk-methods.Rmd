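---
title: "Methods: presence-only suitability modelling and risk overlay"
author: "pestrisk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: presence-only suitability modelling and risk overlay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pestrisk)
```

## The problem

A pest insect and its host crop each occupy a climatic niche. With only
*presence* records (no absences) and gridded bioclimatic layers, we want
to (i) map each species' climatic suitability, (ii) decide which candidate
model to trust, (iii) binarize suitability into interpretable classes, and
(iv) overlay the two maps to grade pest risk inside the area where the
host finds optimal growing conditions — now and under a warmed future
climate. This vignette documents the models, conventions and numerical
choices the package makes, and what its tests do and do not demonstrate.

## The maximum-entropy model

Presence-background modelling treats the landscape's unmasked grid cells
(a background sample of them) as the support of a probability density and
asks for the density of *relative* habitat use. The package fits the Gibbs
form

$$ q_\lambda(x) = \frac{\exp(\lambda \cdot f(x))}{Z_\lambda},
   \qquad Z_\lambda = \sum_{x \in \text{background}} \exp(\lambda \cdot f(x)), $$

by maximizing the L1-penalized presence log-likelihood

$$ \frac{1}{m} \sum_{i=1}^m \lambda \cdot f(x_i) \;-\; \log Z_\lambda
   \;-\; \sum_j \beta_j |\lambda_j|. $$

This is the standard convex reformulation of the classic maximum-entropy
objective: maximizing entropy subject to moment constraints on the
features is the dual of this penalized likelihood. The problem is concave,
so the optimum is unique up to features' linear dependences.

### Features

Covariates are first rescaled to $u = (x - \min)/(\max - \min)$ using
*training* bounds (presences plus background). All feature classes are
defined on $u$:

* L: $u$; Q: $u^2$; P: $u_i u_j$ for distinct pairs;
* T: step features $1[u > k]$ at equispaced knots $k = i/(K+1)$;
* H: forward hinges $\max(0, u-k)/(1-k)$ and mirrored reverse hinges
  $\max(0, k-u)/k$, at $K$ equispaced knots per direction (default 20).

Defining Q and P on the rescaled value (rather than squaring the raw
covariate and rescaling afterwards) spans the same function space but
makes every feature — and hence the fitted suitability surface — exactly
invariant under positive affine rescaling of a covariate (changing
temperature units, say). The test suite asserts this invariance at 1e-6.

### Penalties

$\beta_j = \mathrm{RM} \cdot c(\mathrm{class}_j) \cdot s_j/\sqrt{m}$, with
$s_j$ the presence-sample standard deviation of feature $j$ (floored at
$0.5/\sqrt{m}$ so presence-constant features are not unpenalized) and a
per-class schedule interpolated on the presence count $m \in [10, 100]$:
linear/quadratic 1.0 → 0.05, threshold 2.0 → 1.0, product 0.2, hinge 0.5.
These follow the published default schedules of the classic software era
and are config-overridable; the regularization multiplier RM scales all of
them globally.

### Optimization

Cyclic coordinate descent with per-coordinate Newton steps and soft
thresholding, safeguarded by a halving line search so the penalized
objective is non-decreasing (a property test asserts this). Each pass
starts from a fresh full gradient; only coordinates violating the KKT
conditions are updated, and each pass ends with a joint Newton step over
the active set — where the L1 objective is smooth — with backtracking,
which breaks the first-order zigzag between correlated hinge features
(typical fits converge in tens of passes). Convergence is declared when
the maximum KKT violation falls below 1e-6 (pass cap 50,000). Failure to
converge raises an error with diagnostics rather
than returning a silently unconverged model. The fit is deterministic
given its inputs. On small instances the coefficients agree with an
independent box-constrained L-BFGS-B maximizer of the same objective
(split $\lambda = a - b$, $a, b \ge 0$) to 1e-3, and a single-binary-feature
instance reproduces the closed-form moment condition $\lambda = \ln 4$.

Complete presence/background separation makes the penalized likelihood
unbounded; this is a degenerate input (presences outside the background's
covariate envelope), not a solver failure, and surfaces as a convergence
error.

### Output transforms and clamping

Raw output is $q_\lambda$ (sums to 1 over the training background). The
default logistic index is $e^H q/(1 + e^H q)$ with $H$ the entropy of the
fitted background distribution — the convention that makes a "typical"
presence score about 0.5; cloglog is available by flag. When projecting
onto a new climate, three extrapolation modes exist: `none`, `clamp`
(covariates truncated to training bounds), and `fade` (default): the
clamped logistic output minus the absolute difference between clamped and
unclamped linear predictors rescaled into [0, 1] over the projection
cells, floored at 0. The exact fade formula of the original software is
unpublished; this linear-predictor-difference fade is documented as the
package's own definition. Inside the training envelope all three modes
agree exactly, which is tested. Per-cell counts of out-of-range variables
are returned as clamp diagnostics.

### Importance measures

*Percent contribution* credits each coordinate-descent objective gain to
the feature's source variable (product features split credit evenly);
this is path-dependent, as in the original software, and is reported
alongside the path-free *permutation importance* (drop in training AUC
when one variable is permuted across presence + background rows, averaged
over seeded permutations, normalized to 100), which is the primary metric.
The *jackknife* refits each variable alone and excluded (2k + 1 fits) and
reports unpenalized training gain relative to the uniform model. Response
curves sweep one variable over its training range with the others held at
their presence means.

## Data-preparation conventions

* **Thinning.** The strict ">10 km" contract is enforced exactly: every
  retained pair is more than 10 km apart (haversine, R = 6371 km). The
  algorithm deletes the point with the most neighbours within the limit
  (ties uniform at random) until clean, repeated over randomized restarts,
  keeping the largest survivor set — mirroring the "retain as many
  localities as possible" behaviour of established thinning tools. On up
  to 12 points it stays within one of the brute-force optimum across 100
  seeded trials.
* **Bias surface.** Gaussian kernel density of occurrences over great-circle
  distances, normalized over unmasked cells. The bandwidth is not a
  published value; the default (200 km) is a declared constant chosen to
  be a few grid cells wide at 2.5-arc-min scale, and is config-exposed.
* **Background.** Cells drawn with replacement proportional to the bias
  surface, points at cell centres; 50,000 for a full-scale run. Whether
  the original analyses restricted background geographically is unknown;
  sampling here spans all unmasked cells by default.
* **Variable screening.** Pearson r over all unmasked cells by default
  (the larger sample; an occurrence-cell option exists). |r| >= 0.75
  excludes; the survivor of each correlated group is decided by an
  explicit priority list (default shortlist bio1, bio2, bio7, bio12,
  bio14, bio15, then numeric order), making the otherwise
  judgement-based choice auditable.

## Evaluation and selection

Folds partition presences only (sizes differ by ≤1); the full background
is reused per fold since no background-splitting rule is standard. AUC is
the rank-sum (Mann–Whitney) estimator with ties counted 0.5 — identical
to the trapezoidal ROC area, which a property test verifies to 1e-12.
Omission rates use the lower empirical quantile with no interpolation:
the 10% threshold is the ceiling(0.1 m)-th training order statistic, the
0% threshold the training minimum, and omission counts test presences
*strictly below* the threshold. Under iid continuous scores the 10% OR
is calibrated to 0.10 (asserted at ±0.01 with n = 10,000), and OR0 is
exactly 0 whenever the test set is a subset of the training set.

Candidates are the Cartesian product of feature-class sets and RM values
(defaults: LQPH, LQPTH, LQH, LQP, LH, LQPT × 1.0, 1.5, 2.0), all under
shared folds, ranked by OR10 ascending, then OR0 ascending, then AUC
descending, with a stable sort. Ascending raw OR10 is used rather than
distance from the nominal 0.10 — indistinguishable on published tables,
where all OR10 values exceed 0.10.

## Thresholding, classes, overlay

The MTSPS threshold maximizes test sensitivity plus specificity over
midpoints of adjacent distinct pooled scores, ties toward the smallest
maximizer; it is computed on the best candidate's pooled held-out fold
predictions against the background scores, since "test sensitivity"
implies held-out presences. The interval [t, 1] is split into three
equal-width bins — low, medium, high (half-open below, closed at 1);
published analyses never state their interior cut points, so a symmetric
parameter-free default is declared and made overridable. Future slices
reuse the current-climate threshold and bounds so area comparisons are
like-for-like. "Optimal" host cells are those of medium or high host
suitability; inside that mask the pest class maps directly to no/low/
medium/high risk, outside it cells are excluded from all percentages.

Areas default to geodesic cell areas
$(c\,\pi/180\,R)^2 \cos\phi$, $R = 6371$ km (summing to the sphere's
surface within 0.5% on a global grid); planar pixel counting is available
because published percentage statistics do not state their area
computation. Change statistics are plain percent changes of per-class
areas, reported as extensions (positive) or shortenings (negative).

## The synthetic generator

`makeClimate()` builds layers as low-order spatial trends plus seeded,
smoothed Gaussian noise: temperature spanning −10…32 °C — about the span
of global annual-mean-temperature layers — with a superlinear latitudinal
profile so warm cells are rare relative to cold ones, as in area-weighted
global land climates; precipitation (0–3000 mm, longitudinal trend so the
two are not collinear); and generic standardized noise layers. With the
default warm-adapted niche this yields a true-suitability discriminability
(AUC of the truth surface against uniform background) of about 0.9,
comparable to what well-fit global niche models report on real data — a
deliberate calibration, since a markedly narrower temperature span makes
high discrimination impossible for any estimator. The truth surface is

$$ s(x) = \exp\!\big(-(T - T_{opt})^2 / 2\sigma^2\big) \cdot
          \frac{h}{h + P}, $$

unimodal in temperature and strictly decreasing in precipitation. Default
truth parameters — optimum 23.8 °C, σ = 3.8 °C — mirror the empirical
occurrence-temperature mean and spread of a globally distributed
warm-adapted whitefly pest; the host preset uses 20.1 ± 4.3 °C. The
precipitation half-saturation (1000 mm pest, 1500 mm host) is a generator
choice on the order of global mean annual precipitation over land.
Presences are drawn proportional to truth (optionally × bias) with a
small uniform jitter inside the sampled cell, so thinning is exercised by
realistic near-duplicate coordinates.

What the generator does *not* emulate: the covariance structure of real
bioclimatic layers (19 mutually correlated variables), coastline masks,
spatially clumped survey effort, or GCM-specific future anomalies. Tests
passing on generator output therefore demonstrate correctness of the
algorithms and recoverability of a known niche under the stated noise —
not predictive skill on real species data.

## Problem sizes and defaults in the tests

The suite runs the full pipeline on a 32 × 32 grid (200 presences, 2,000
background points, 3 candidate feature sets, 3 folds, 5 hinge knots) and
parameter-recovery experiments on 40 × 40 grids (500 presences, 2,000
background, LQ features, 10 seeds) — sizes chosen so each experiment
completes in seconds while leaving the statistical behaviour (AUC > 0.85
held-out, temperature optimum recovered within ±1 °C in ≥9/10 seeds)
comfortably testable. Full-scale defaults (50,000 background points,
10 folds, 20 knots, 18 candidates) remain the package defaults for real
runs.

## Known limitations

* No reprojection or resampling: input rasters must already align, and
  only geographic lat/lon grids are supported.
* Percent contribution is path-dependent by construction; use permutation
  importance for comparisons across fits.
* The four-class cut points and the fade formula are package conventions
  (documented above), not published standards; both are overridable.
* Categorical covariates are not supported (the motivating analyses use
  none).
* TIFF output stores values rescaled to the grid's range with a JSON
  sidecar; round-trips are exact to ~1 part in 2³⁰ of the value range,
  which is ample for climate layers but not bit-exact.
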