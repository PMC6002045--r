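# Feature expansion for the maximum-entropy model. Covariates are first
# rescaled to [0,1] with their training bounds; every feature class is then
# defined on the rescaled value u, which makes the whole basis exactly
# invariant under positive affine rescaling of a covariate:
#   L: u           Q: u^2          P: u_i * u_j (distinct pairs)
#   T: 1[u > k]    H: forward max(0, u-k)/(1-k), reverse max(0, k-u)/k

#' Feature configuration for a maximum-entropy fit
#'
#' @param classes feature classes as a string or character vector, subset of
#'   L (linear), Q (quadratic), P (product), T (threshold), H (hinge);
#'   e.g. \code{"LQPH"}.
#' @param rm regularization multiplier (> 0); larger values give sparser,
#'   smoother models.
#' @param nHingeKnots hinge knots per variable per direction (default 20).
#' @param nThresholdKnots threshold knots per variable (default 20).
#' @return a \code{FeatureConfig} list
#' @export
makeFeatureConfig <- function(classes = "LQPH", rm = 1.0,
                              nHingeKnots = 20L, nThresholdKnots = 20L) {
  cl <- toupper(unlist(strsplit(paste(classes, collapse = ""), "")))
  bad <- setdiff(cl, c("L", "Q", "P", "T", "H"))
  if (length(bad)) stop("unknown feature class(es): ",
                        paste(bad, collapse = ", "))
  if (!length(cl)) stop("feature classes must be non-empty")
  if (!is.numeric(rm) || rm <= 0) stop("rm must be positive")
  structure(list(classes = unique(cl), rm = rm,
                 nHingeKnots = as.integer(nHingeKnots),
                 nThresholdKnots = as.integer(nThresholdKnots)),
            class = "FeatureConfig")
}

# Feature definition table for a set of variables under a config.
featureDefs <- function(vars, config) {
  defs <- list()
  add <- function(class, var1, var2 = NA_character_, knot = NA_real_,
                  dir = NA_character_) {
    defs[[length(defs) + 1L]] <<- data.frame(
      class = class, var1 = var1, var2 = var2, knot = knot, dir = dir,
      stringsAsFactors = FALSE)
  }
  if ("L" %in% config$classes) for (v in vars) add("L", v)
  if ("Q" %in% config$classes) for (v in vars) add("Q", v)
  if ("P" %in% config$classes && length(vars) >= 2L) {
    for (i in seq_len(length(vars) - 1L))
      for (j in seq(i + 1L, length(vars)))
        add("P", vars[i], vars[j])
  }
  if ("T" %in% config$classes) {
    knots <- seq_len(config$nThresholdKnots) / (config$nThresholdKnots + 1)
    for (v in vars) for (k in knots) add("T", v, knot = k)
  }
  if ("H" %in% config$classes) {
    fwd <- (seq_len(config$nHingeKnots) - 1) / config$nHingeKnots
    rev_ <- seq_len(config$nHingeKnots) / config$nHingeKnots
    for (v in vars) {
      for (k in fwd) add("H", v, knot = k, dir = "fwd")
      for (k in rev_) add("H", v, knot = k, dir = "rev")
    }
  }
  do.call(rbind, defs)
}

featureLabels <- function(defs) {
  lab <- character(nrow(defs))
  for (i in seq_len(nrow(defs))) {
    lab[i] <- switch(defs$class[i],
      L = defs$var1[i],
      Q = paste0(defs$var1[i], "^2"),
      P = paste0(defs$var1[i], "*", defs$var2[i]),
      T = sprintf("(%s>%.4g)", defs$var1[i], defs$knot[i]),
      H = sprintf("h%s(%s,%.4g)", ifelse(defs$dir[i] == "fwd", "", "'"),
                  defs$var1[i], defs$knot[i]))
  }
  lab
}

# Rescale raw covariates to [0,1] with (training) bounds; optionally
# truncating to the bounds first (clamping).
scaleCovariates <- function(values, bounds, clamp = FALSE) {
  U <- values
  for (v in colnames(values)) {
    b <- bounds[bounds$var == v, ]
    x <- values[, v]
    if (clamp) x <- pmin(pmax(x, b$min), b$max)
    U[, v] <- (x - b$min) / (b$max - b$min)
  }
  U
}

# Evaluate features on a rescaled covariate matrix U (cells x variables).
evalFeatures <- function(U, defs) {
  n <- nrow(U)
  X <- matrix(0, n, nrow(defs))
  for (i in seq_len(nrow(defs))) {
    u <- U[, defs$var1[i]]
    X[, i] <- switch(defs$class[i],
      L = u,
      Q = u * u,
      P = u * U[, defs$var2[i]],
      T = as.numeric(u > defs$knot[i]),
      H = if (defs$dir[i] == "fwd") pmax(0, u - defs$knot[i]) / (1 - defs$knot[i])
          else pmax(0, defs$knot[i] - u) / defs$knot[i])
  }
  colnames(X) <- featureLabels(defs)
  X
}

#' Expand covariates into model features
#'
#' Builds the feature matrix for a covariate matrix under a
#' \code{\link{makeFeatureConfig}}. When \code{bounds} is \code{NULL}
#' (training) the per-variable min/max are computed from \code{values} and
#' recorded; variables constant over the training data have no usable
#' features (threshold and hinge knots collapse) and are dropped with a
#' warning.
#'
#' @param values numeric matrix, rows = points/cells, named columns =
#'   variables (raw covariate scale).
#' @param config a \code{FeatureConfig}.
#' @param bounds optional data.frame (var, min, max) of training bounds for
#'   projection; when supplied, no variables are dropped.
#' @param clamp truncate covariates to the bounds before expansion.
#' @return list with \code{X} (points x features), \code{defs} (feature
#'   definition table), \code{bounds} (per-variable training min/max)
#' @export
buildFeatures <- function(values, config, bounds = NULL, clamp = FALSE) {
  values <- as.matrix(values)
  if (is.null(colnames(values)))
    colnames(values) <- paste0("v", seq_len(ncol(values)))
  if (any(!is.finite(values))) stop("covariates must be finite")
  if (is.null(bounds)) {
    mins <- apply(values, 2, min)
    maxs <- apply(values, 2, max)
    const <- maxs == mins
    if (any(const)) {
      warning("dropping constant variable(s): ",
              paste(colnames(values)[const], collapse = ", "))
      values <- values[, !const, drop = FALSE]
      mins <- mins[!const]; maxs <- maxs[!const]
      if (!ncol(values)) stop("no non-constant variables left")
    }
    bounds <- data.frame(var = colnames(values), min = unname(mins),
                         max = unname(maxs), stringsAsFactors = FALSE)
  }
  vars <- bounds$var
  missing_vars <- setdiff(vars, colnames(values))
  if (length(missing_vars))
    stop("covariate matrix lacks variable(s): ",
         paste(missing_vars, collapse = ", "))
  U <- scaleCovariates(values[, vars, drop = FALSE], bounds, clamp = clamp)
  defs <- featureDefs(vars, config)
  list(X = evalFeatures(U, defs), defs = defs, bounds = bounds)
}

# Per-class default penalty coefficient c(class), interpolated on the
# presence count m. Linear/quadratic relax from 1.0 at m = 10 to 0.05 at
# m = 100; threshold from 2.0 to 1.0; product 0.2 and hinge 0.5 constant.
classPenalty <- function(class, m) {
  interp <- function(y10, y100)
    approx(c(10, 100), c(y10, y100), xout = min(max(m, 10), 100))$y
  switch(class,
    L = interp(1.0, 0.05),
    Q = interp(1.0, 0.05),
    P = 0.2,
    T = interp(2.0, 1.0),
    H = 0.5,
    stop("unknown feature class: ", class))
}
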