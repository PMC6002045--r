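# Variable importance: path-based percent contribution, permutation
# importance, the jackknife of single-variable and leave-one-out fits, and
# response curves.

#' Variable contribution and permutation importance
#'
#' Percent contribution is the share of the cumulative penalized-gain
#' increase credited, during each coordinate-descent pass, to the variable
#' whose feature changed (product features split credit between their two
#' variables); it is path-dependent and reported as stored in the fitted
#' model. Permutation importance is path-free and is the primary metric:
#' the drop in training AUC when one variable's values are permuted jointly
#' across presence and background rows, averaged over \code{nPerm} seeded
#' permutations and normalized to sum 100.
#'
#' @param model a \linkS4class{MaxentModel}
#' @param presenceValues,backgroundValues training covariate matrices.
#' @param nPerm permutations per variable (default 5).
#' @param seed RNG seed.
#' @return data.frame: variable, percent_contribution, permutation_importance
#' @export
variableImportance <- function(model, presenceValues, backgroundValues,
                               nPerm = 5L, seed = 1L) {
  presenceValues <- as.matrix(presenceValues)
  backgroundValues <- as.matrix(backgroundValues)
  vars <- model@varBounds$var
  m <- nrow(presenceValues)
  all_vals <- rbind(presenceValues[, vars, drop = FALSE],
                    backgroundValues[, vars, drop = FALSE])
  eta <- modelEta(model, all_vals, clamp = FALSE)
  auc0 <- aucScore(eta[seq_len(m)], eta[-seq_len(m)])
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  drops <- vapply(vars, function(v) {
    mean(vapply(seq_len(nPerm), function(k) {
      perm <- all_vals
      perm[, v] <- perm[sample(nrow(perm)), v]
      e <- modelEta(model, perm, clamp = FALSE)
      auc0 - aucScore(e[seq_len(m)], e[-seq_len(m)])
    }, numeric(1)))
  }, numeric(1))
  drops <- pmax(drops, 0)
  perm_imp <- if (sum(drops) > 0) 100 * drops / sum(drops)
              else rep(0, length(drops))
  contrib <- model@contributions[vars]
  contrib[is.na(contrib)] <- 0
  data.frame(variable = vars,
             percent_contribution = unname(contrib),
             permutation_importance = unname(perm_imp),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Jackknife of variable contribution
#'
#' Fits, for k candidate variables, each variable alone, each variable
#' excluded, and the full model (2k + 1 fits). Reports unpenalized training
#' gain relative to the uniform background model and, for single-variable
#' models, training AUC.
#'
#' @param presenceValues,backgroundValues training covariate matrices with
#'   at least two named variables.
#' @param config a \code{\link{makeFeatureConfig}}.
#' @param tol,maxit solver controls passed to \code{\link{fitMaxent}}.
#' @return list with \code{table} (variable, gain_with_only, gain_without,
#'   auc_with_only) and \code{full_gain}
#' @export
jackknifeVariables <- function(presenceValues, backgroundValues,
                               config = makeFeatureConfig(),
                               tol = 1e-6, maxit = 50000L) {
  presenceValues <- as.matrix(presenceValues)
  backgroundValues <- as.matrix(backgroundValues)
  vars <- colnames(presenceValues)
  if (length(vars) < 2L) stop("jackknife needs at least 2 variables")
  fit1 <- function(v) {
    tryCatch(
      fitMaxent(presenceValues[, v, drop = FALSE],
                backgroundValues[, v, drop = FALSE], config,
                tol = tol, maxit = maxit),
      error = function(e) stop("jackknife sub-model {",
                               paste(v, collapse = ","), "} failed: ",
                               conditionMessage(e)))
  }
  full <- fit1(vars)
  rows <- lapply(vars, function(v) {
    only <- fit1(v)
    without <- fit1(setdiff(vars, v))
    eta_p <- modelEta(only, presenceValues[, v, drop = FALSE])
    eta_b <- modelEta(only, backgroundValues[, v, drop = FALSE])
    data.frame(variable = v,
               gain_with_only = only@gain,
               gain_without = without@gain,
               auc_with_only = aucScore(eta_p, eta_b),
               stringsAsFactors = FALSE)
  })
  list(table = do.call(rbind, rows), full_gain = full@gain)
}

#' Response curve of one variable
#'
#' Sweeps a variable across its training range at \code{nPoints} equally
#' spaced values while holding every other variable at its presence-sample
#' mean, and returns the model's logistic output at each point.
#'
#' @param model a \linkS4class{MaxentModel}
#' @param variable variable name.
#' @param nPoints number of sweep points (default 100).
#' @return data.frame with \code{value} and \code{suitability}
#' @export
responseCurve <- function(model, variable, nPoints = 100L) {
  b <- model@varBounds[model@varBounds$var == variable, ]
  if (!nrow(b)) stop("model does not use variable '", variable, "'")
  sweep_vals <- seq(b$min, b$max, length.out = nPoints)
  vals <- matrix(rep(model@presenceMeans, each = nPoints),
                 nrow = nPoints,
                 dimnames = list(NULL, names(model@presenceMeans)))
  vals[, variable] <- sweep_vals
  data.frame(value = sweep_vals,
             suitability = scoreValues(model, vals, transform = "logistic",
                                       clamp = TRUE))
}

#' Serialize a fitted model to a plain-text lambdas-style file
#'
#' Header lines carry the transform, entropy, log-partition constant and
#' regularization multiplier; each following line is one feature with its
#' coefficient, penalty, and the source variable bounds.
#'
#' @param model a \linkS4class{MaxentModel}
#' @param path output path.
#' @export
writeMaxentModel <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# maxent model"),
    paste0("transform=", model@transform),
    paste0("entropy=", format(model@entropyH, digits = 17)),
    paste0("logZ=", format(model@logZ, digits = 17)),
    paste0("rm=", format(model@rm, digits = 17)),
    paste0("classes=", paste(model@classes, collapse = "")),
    paste0("gain=", format(model@gain, digits = 17)),
    "feature\tlambda\tbeta"), con)
  lab <- featureLabels(model@featureTable)
  for (i in seq_along(model@lambdas))
    writeLines(paste(lab[i], format(model@lambdas[i], digits = 17),
                     format(model@betas[i], digits = 17), sep = "\t"), con)
  writeLines("variable\tmin\tmax", con)
  for (i in seq_len(nrow(model@varBounds)))
    writeLines(paste(model@varBounds$var[i],
                     format(model@varBounds$min[i], digits = 17),
                     format(model@varBounds$max[i], digits = 17),
                     sep = "\t"), con)
  invisible(path)
}
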