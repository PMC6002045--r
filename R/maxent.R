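# The maximum-entropy presence-background model, fitted as L1-penalized
# maximum likelihood of a Gibbs distribution q_lambda(x) ∝ exp(lambda·f(x))
# over the background cells:
#
#   maximize (1/m) sum_presences lambda·f(x_i) - log Z_lambda
#            - sum_j beta_j |lambda_j|
#
# with Z_lambda = sum_background exp(lambda·f(x)). This is the standard
# convex reformulation of the classic MaxEnt objective; it is solved by
# cyclic coordinate descent with per-coordinate Newton steps, soft
# thresholding, and a halving line search that keeps the penalized
# objective non-decreasing.

logSumExp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Low-level penalized maximum-entropy solver
#'
#' Maximizes the penalized presence log-likelihood of the Gibbs distribution
#' over background rows, for an already-built feature matrix. Most users
#' want \code{\link{fitMaxent}}; this entry point exists for working at the
#' feature level.
#'
#' @param presX presence rows of the feature matrix.
#' @param bgX background rows of the feature matrix.
#' @param betas per-feature L1 penalties (non-negative).
#' @param tol KKT/gradient tolerance (default 1e-6).
#' @param maxit maximum coordinate-descent passes.
#' @param varOf optional per-feature list of source variables, used to
#'   credit objective gain per variable along the optimization path.
#' @return list with \code{lambda}, \code{logZ}, \code{entropy},
#'   \code{objective} (penalized, final), \code{trace} (per-pass penalized
#'   objective), \code{credits} (per-variable gain credit), \code{kkt}
#'   (final max violation), \code{iterations}
#' @export
maxentSolve <- function(presX, bgX, betas, tol = 1e-6, maxit = 50000L,
                        varOf = NULL) {
  presX <- as.matrix(presX); bgX <- as.matrix(bgX)
  J <- ncol(presX)
  stopifnot(ncol(bgX) == J, length(betas) == J, all(betas >= 0))
  if (nrow(presX) < 2L || nrow(bgX) < 2L)
    stop("need at least 2 presence and 2 background rows")
  pbar <- colMeans(presX)
  lambda <- numeric(J)
  eta <- numeric(nrow(bgX))
  lZ <- logSumExp(eta)
  obj <- function(lam, lz) sum(pbar * lam) - lz - sum(betas * abs(lam))
  cur <- obj(lambda, lZ)
  if (!is.finite(cur)) stop("non-finite objective at initialization")
  trace <- cur
  credits <- if (is.null(varOf)) NULL else
    stats::setNames(numeric(length(unique(unlist(varOf)))),
                    unique(unlist(varOf)))
  kkt <- Inf
  it <- 0L
  while (it < maxit) {
    it <- it + 1L
    q <- exp(eta - lZ)
    # screening: fresh full gradient, then cyclic updates over the
    # coordinates whose KKT conditions are violated
    g_all <- pbar - as.vector(crossprod(bgX, q))
    viol <- ifelse(lambda == 0, pmax(abs(g_all) - betas, 0),
                   abs(g_all - betas * sign(lambda)))
    kkt <- max(viol)
    if (kkt <= tol) break
    for (j in which(viol > tol / 2)) {
      fj <- bgX[, j]
      mu <- sum(q * fj)
      g <- pbar[j] - mu
      h <- max(sum(q * fj * fj) - mu * mu, 1e-12)
      z <- lambda[j] + g / h
      target <- sign(z) * max(abs(z) - betas[j] / h, 0)
      d <- target - lambda[j]
      if (d == 0) next
      # halving line search on the penalized objective
      for (step in 0:30) {
        newl <- lambda[j] + d
        lZnew <- logSumExp(eta + d * fj)
        delta <- pbar[j] * d - (lZnew - lZ) -
          betas[j] * (abs(newl) - abs(lambda[j]))
        if (is.finite(delta) && delta >= 0) break
        d <- d / 2
      }
      if (!is.finite(delta) || delta < 0) next
      eta <- eta + d * fj
      lambda[j] <- lambda[j] + d
      lZ <- lZnew
      q <- exp(eta - lZ)
      cur <- cur + delta
      if (!is.null(credits) && delta > 0) {
        vs <- varOf[[j]]
        credits[vs] <- credits[vs] + delta / length(vs)
      }
    }
    # second-order acceleration: on the current active set the penalized
    # objective is smooth (fixed signs), so a joint Newton step with
    # backtracking breaks the zigzag between correlated features
    active <- which(lambda != 0)
    if (length(active) >= 2L && length(active) <= 200L) {
      q <- exp(eta - lZ)
      Fa <- bgX[, active, drop = FALSE]
      mu <- as.vector(crossprod(Fa, q))
      H <- crossprod(Fa, Fa * q) - tcrossprod(mu)
      diag(H) <- diag(H) + 1e-10
      ga <- pbar[active] - mu - betas[active] * sign(lambda[active])
      d <- tryCatch(solve(H, ga), error = function(e) NULL)
      if (!is.null(d) && all(is.finite(d)) && any(d != 0)) {
        step <- 1
        for (k in 0:25) {
          lam_try <- lambda
          lam_try[active] <- lambda[active] + step * d
          eta_try <- eta + as.vector(Fa %*% (step * d))
          lZ_try <- logSumExp(eta_try)
          new_obj <- obj(lam_try, lZ_try)
          if (is.finite(new_obj) && new_obj > cur + 1e-15) break
          step <- step / 2
        }
        if (is.finite(new_obj) && new_obj > cur + 1e-15) {
          if (!is.null(credits)) {
            gain <- new_obj - cur
            contrib <- abs(step * d)
            contrib <- if (sum(contrib) > 0) contrib / sum(contrib)
                       else rep(1 / length(d), length(d))
            for (ii in seq_along(active)) {
              vs <- varOf[[active[ii]]]
              credits[vs] <- credits[vs] + gain * contrib[ii] / length(vs)
            }
          }
          lambda <- lam_try
          eta <- eta_try
          lZ <- lZ_try
          cur <- new_obj
        }
      }
    }
    cur <- obj(lambda, lZ)
    trace <- c(trace, cur)
  }
  if (kkt > tol && it >= maxit)
    stop("maxent fit failed to converge within ", maxit,
         " passes (max KKT violation ", signif(kkt, 3), ", objective ",
         signif(cur, 6), ")")
  q <- exp(eta - lZ)
  list(lambda = lambda, logZ = lZ, entropy = -sum(q * log(q)),
       objective = cur, trace = trace, credits = credits, kkt = kkt,
       iterations = it)
}

#' Fit a maximum-entropy suitability model
#'
#' Expands presence and background covariates into features (see
#' \code{\link{buildFeatures}}), sets per-feature L1 penalties
#' \eqn{\beta_j = rm \cdot c(class_j) \cdot s_j / \sqrt{m}} (with \eqn{s_j}
#' the presence-sample standard deviation of feature j, floored at
#' \eqn{0.5/\sqrt{m}}, and \eqn{c} the per-class default schedule), and
#' maximizes the penalized Gibbs likelihood over the background. The fit is
#' deterministic given its inputs.
#'
#' @param presenceValues matrix of covariates at presence points (rows x
#'   named variables, raw scale).
#' @param backgroundValues matrix of covariates at background points.
#' @param config a \code{\link{makeFeatureConfig}}.
#' @param transform default output transform for predictions.
#' @param tol,maxit solver controls (see \code{\link{maxentSolve}}).
#' @return a \linkS4class{MaxentModel}
#' @export
fitMaxent <- function(presenceValues, backgroundValues,
                      config = makeFeatureConfig(),
                      transform = c("logistic", "cloglog", "raw"),
                      tol = 1e-6, maxit = 50000L) {
  transform <- match.arg(transform)
  presenceValues <- as.matrix(presenceValues)
  backgroundValues <- as.matrix(backgroundValues)
  if (is.null(colnames(presenceValues)))
    colnames(presenceValues) <- paste0("v", seq_len(ncol(presenceValues)))
  if (is.null(colnames(backgroundValues)))
    colnames(backgroundValues) <- paste0("v", seq_len(ncol(backgroundValues)))
  if (!identical(sort(colnames(presenceValues)),
                 sort(colnames(backgroundValues))))
    stop("presence and background covariates must share variable names")
  m <- nrow(presenceValues)
  # training bounds span presence + background rows, so presence features
  # stay inside [0,1] and clamping is defined on the full training envelope
  comb <- buildFeatures(
    rbind(presenceValues,
          backgroundValues[, colnames(presenceValues), drop = FALSE]),
    config)
  tr <- buildFeatures(backgroundValues[, comb$bounds$var, drop = FALSE],
                      config, bounds = comb$bounds)
  presF <- buildFeatures(presenceValues[, comb$bounds$var, drop = FALSE],
                         config, bounds = comb$bounds)
  s <- apply(presF$X, 2, sd)
  s <- pmax(s, 0.5 / sqrt(m))
  cclass <- vapply(tr$defs$class, classPenalty, numeric(1), m = m)
  betas <- config$rm * cclass * s / sqrt(m)
  varOf <- lapply(seq_len(nrow(tr$defs)), function(i) {
    v <- c(tr$defs$var1[i], tr$defs$var2[i])
    v[!is.na(v)]
  })
  fit <- maxentSolve(presF$X, tr$X, betas, tol = tol, maxit = maxit,
                     varOf = varOf)
  contrib <- fit$credits
  contrib <- if (sum(contrib) > 0) 100 * contrib / sum(contrib)
             else stats::setNames(rep(0, length(contrib)), names(contrib))
  pmeans <- colMeans(presenceValues[, tr$bounds$var, drop = FALSE])
  new("MaxentModel",
      featureTable = tr$defs, lambdas = fit$lambda, betas = betas,
      varBounds = tr$bounds, logZ = fit$logZ, entropyH = fit$entropy,
      rm = config$rm, classes = config$classes, transform = transform,
      presenceMeans = pmeans,
      gain = sum(colMeans(presF$X) * fit$lambda) - fit$logZ +
        log(nrow(tr$X)),
      contributions = contrib,
      nBackground = nrow(backgroundValues),
      convergence = list(iterations = fit$iterations, kkt = fit$kkt,
                         trace = fit$trace))
}

# Linear predictor eta = lambda . f(x) for raw covariate rows.
modelEta <- function(model, values, clamp = FALSE) {
  fb <- buildFeatures(values, configOf(model), bounds = model@varBounds,
                      clamp = clamp)
  as.vector(fb$X %*% model@lambdas)
}

configOf <- function(model) {
  defs <- model@featureTable
  nT <- if (any(defs$class == "T"))
    sum(defs$class == "T" & defs$var1 == defs$var1[defs$class == "T"][1])
  else 20L
  nH <- if (any(defs$class == "H"))
    sum(defs$class == "H" & defs$dir == "fwd" &
        defs$var1 == defs$var1[defs$class == "H"][1])
  else 20L
  makeFeatureConfig(model@classes, model@rm, nHingeKnots = nH,
                    nThresholdKnots = nT)
}

# Output transform from linear predictor (training logZ and entropy).
applyTransform <- function(eta, model, transform) {
  raw <- exp(eta - model@logZ)
  switch(transform,
    raw = raw,
    logistic = {
      r <- exp(model@entropyH) * raw
      r / (1 + r)
    },
    cloglog = 1 - exp(-exp(model@entropyH) * raw))
}

#' Score covariate rows with a fitted model
#'
#' @param model a \linkS4class{MaxentModel}
#' @param values covariate matrix (raw scale).
#' @param transform output transform (default: the model's).
#' @param clamp truncate covariates to the training bounds first.
#' @return numeric vector of suitability scores
#' @export
scoreValues <- function(model, values, transform = model@transform,
                        clamp = TRUE) {
  applyTransform(modelEta(model, values, clamp = clamp), model, transform)
}

#' Project a fitted model onto a grid stack
#'
#' Evaluates the model at every unmasked cell of the stack. Extrapolation
#' beyond the training range is controlled by \code{clamp}: \code{"none"}
#' evaluates features as-is; \code{"clamp"} truncates every covariate to its
#' training bounds first; \code{"fade"} additionally subtracts from the
#' clamped logistic output the absolute difference between the clamped and
#' unclamped linear predictors rescaled into [0,1], floored at 0, so
#' predictions fade where clamping bites. Cells inside the training envelope
#' are identical under all three modes.
#'
#' @param model a \linkS4class{MaxentModel}
#' @param stack a \linkS4class{GridStack} supplying every model variable.
#' @param clamp extrapolation mode: \code{"fade"}, \code{"clamp"},
#'   \code{"none"}.
#' @param transform output transform (default: the model's).
#' @return a \linkS4class{SuitabilityGrid}
#' @export
predictSuitability <- function(model, stack,
                               clamp = c("fade", "clamp", "none"),
                               transform = model@transform) {
  clamp <- match.arg(clamp)
  stopifnot(is(model, "MaxentModel"), is(stack, "GridStack"))
  missing_vars <- setdiff(model@varBounds$var, names(stack@layers))
  if (length(missing_vars))
    stop("stack lacks model variable(s): ",
         paste(missing_vars, collapse = ", "))
  vals <- stackValues(stack)
  cells <- attr(vals, "cells")
  vals <- vals[, model@varBounds$var, drop = FALSE]
  # per-cell count of variables outside the training range
  nout <- integer(nrow(vals))
  for (v in model@varBounds$var) {
    b <- model@varBounds[model@varBounds$var == v, ]
    nout <- nout + as.integer(vals[, v] < b$min | vals[, v] > b$max)
  }
  out <- switch(clamp,
    none = applyTransform(modelEta(model, vals, clamp = FALSE), model,
                          transform),
    clamp = applyTransform(modelEta(model, vals, clamp = TRUE), model,
                           transform),
    fade = {
      eta_u <- modelEta(model, vals, clamp = FALSE)
      eta_c <- modelEta(model, vals, clamp = TRUE)
      d <- abs(eta_u - eta_c)
      if (max(d) > 0) d <- d / max(d)
      pmax(applyTransform(eta_c, model, "logistic") - d, 0)
    })
  ref <- stack@layers[[1L]]
  vm <- matrix(NA_real_, nrow(ref@values), ncol(ref@values))
  vm[cells] <- out
  cm <- matrix(NA_integer_, nrow(ref@values), ncol(ref@values))
  cm[cells] <- nout
  tr_used <- if (clamp == "fade") "logistic" else transform
  new("SuitabilityGrid", name = "suitability", values = vm,
      origin = ref@origin, cellSize = ref@cellSize, units = "suitability",
      transform = tr_used, clampCounts = cm)
}
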