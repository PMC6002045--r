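#' @import methods
#' @importFrom stats approx cor optim quantile rnorm runif sd var
#' @importFrom utils read.csv write.csv
NULL

#' ClimateGrid: a single gridded environmental variable
#'
#' A regular lat/lon raster holding one environmental variable (for example a
#' bioclimatic layer such as annual mean temperature, "bio1"). Cells are
#' addressed row-major from the upper-left corner; a point falls in the cell
#' whose half-open interval \code{[edge, edge + cellSize)} contains it.
#' Nodata cells are stored as \code{NA} in \code{values}.
#'
#' @slot name variable label, e.g. \code{"bio1"}.
#' @slot values numeric matrix of cell values; \code{NA} marks nodata.
#' @slot origin numeric of length 2: (lon, lat) of the grid's upper-left
#'   corner, in decimal degrees.
#' @slot cellSize cell edge length in degrees (square cells).
#' @slot units free-text units ("degC", "mm", "index", ...).
#'
#' @examples
#' g <- ClimateGrid("bio1", matrix(rnorm(12), 3, 4), origin = c(0, 10),
#'                  cellSize = 0.5, units = "degC")
#' gridValues(g)[1, 1]
#' @export ClimateGrid
#' @exportClass ClimateGrid
setClass("ClimateGrid",
  representation(
    name = "character",
    values = "matrix",
    origin = "numeric",
    cellSize = "numeric",
    units = "character"
  ),
  prototype(name = "layer", origin = c(0, 0), cellSize = 1, units = "")
)

setValidity("ClimateGrid", function(object) {
  msg <- character()
  if (length(object@cellSize) != 1L || !is.finite(object@cellSize) ||
      object@cellSize <= 0)
    msg <- c(msg, "cellSize must be a single positive number")
  if (length(object@origin) != 2L || any(!is.finite(object@origin)))
    msg <- c(msg, "origin must be finite (lon, lat)")
  if (!is.numeric(object@values))
    msg <- c(msg, "values must be a numeric matrix")
  else {
    v <- object@values[!is.na(object@values)]
    if (any(!is.finite(v)))
      msg <- c(msg, "all unmasked values must be finite")
  }
  if (length(msg)) msg else TRUE
})

ClimateGrid <- function(name, values, origin, cellSize, units = "") {
  new("ClimateGrid", name = as.character(name),
      values = values, origin = as.numeric(origin),
      cellSize = as.numeric(cellSize), units = as.character(units))
}

#' GridStack: aligned raster layers for one time slice
#'
#' A named collection of \linkS4class{ClimateGrid} layers sharing origin,
#' cell size, shape, and nodata mask; the covariate space of a suitability
#' model for one time slice (e.g. "current", "2050", "2070"). Build with
#' \code{\link{alignStack}}, which unions the member masks and refuses
#' mismatched georeferences.
#'
#' @slot layers named list of \linkS4class{ClimateGrid} objects.
#' @slot sliceLabel time-slice tag.
#' @export
setClass("GridStack",
  representation(layers = "list", sliceLabel = "character"),
  prototype(sliceLabel = "current")
)

setValidity("GridStack", function(object) {
  if (length(object@layers) < 1L)
    return("a GridStack needs at least one layer")
  if (!all(vapply(object@layers, is, logical(1), "ClimateGrid")))
    return("all layers must be ClimateGrid objects")
  ref <- object@layers[[1L]]
  for (g in object@layers) {
    if (!identical(dim(g@values), dim(ref@values)))
      return("layers differ in shape")
    if (!isTRUE(all.equal(g@origin, ref@origin)) ||
        !isTRUE(all.equal(g@cellSize, ref@cellSize)))
      return("layers differ in georeference (origin/cellSize)")
    if (!identical(is.na(g@values), is.na(ref@values)))
      return("layers differ in nodata mask")
  }
  if (is.null(names(object@layers)) || anyDuplicated(names(object@layers)))
    return("layers must be uniquely named")
  TRUE
})

#' OccurrenceSet: presence coordinates for one species
#'
#' @slot species species label.
#' @slot points two-column matrix (lon, lat) in decimal degrees, WGS84
#'   assumed; exact duplicates are collapsed at construction.
#' @slot provenance free-text source tag.
#' @export OccurrenceSet
#' @exportClass OccurrenceSet
setClass("OccurrenceSet",
  representation(species = "character", points = "matrix",
                 provenance = "character"),
  prototype(species = "", provenance = "")
)

setValidity("OccurrenceSet", function(object) {
  p <- object@points
  if (ncol(p) != 2L) return("points must have two columns (lon, lat)")
  if (nrow(p)) {
    if (any(!is.finite(p))) return("coordinates must be finite")
    if (any(p[, 1] < -180 | p[, 1] > 180))
      return("longitude out of [-180, 180]")
    if (any(p[, 2] < -90 | p[, 2] > 90))
      return("latitude out of [-90, 90]")
    if (anyDuplicated(p)) return("duplicate coordinates present")
  }
  TRUE
})

OccurrenceSet <- function(species, points, provenance = "") {
  points <- as.matrix(points)
  if (nrow(points)) points <- points[!duplicated(points), , drop = FALSE]
  dimnames(points) <- list(NULL, c("lon", "lat"))
  new("OccurrenceSet", species = as.character(species), points = points,
      provenance = as.character(provenance))
}

#' BackgroundSet: weighted background sample
#'
#' Background (pseudo-absence) points drawn from unmasked cells of a
#' \linkS4class{GridStack}, with the per-point selection density and RNG seed
#' recorded for reproducibility.
#'
#' @slot points two-column matrix (lon, lat) of cell centres.
#' @slot weights selection density of each drawn point.
#' @slot seed integer RNG seed used for the draw.
#' @export
setClass("BackgroundSet",
  representation(points = "matrix", weights = "numeric", seed = "integer")
)

#' MaxentModel: a fitted maximum-entropy suitability model
#'
#' Holds the feature definitions, L1-penalized coefficients, per-variable
#' training bounds (used for feature rescaling and clamping), the per-feature
#' penalties, the log partition constant over the training background, the
#' entropy of the fitted raw distribution (used by the logistic output
#' transform), and bookkeeping needed by response curves and importance
#' measures. Created by \code{\link{fitMaxent}}.
#'
#' @slot featureTable data.frame describing each feature (class, source
#'   variable(s), knot, direction).
#' @slot lambdas per-feature coefficients.
#' @slot betas per-feature L1 penalties.
#' @slot varBounds data.frame of per-variable training min/max.
#' @slot logZ log partition constant over the training background.
#' @slot entropyH entropy of the fitted raw distribution over background.
#' @slot rm regularization multiplier used.
#' @slot classes feature classes used (subset of L, Q, P, T, H).
#' @slot transform default output transform ("logistic", "cloglog", "raw").
#' @slot presenceMeans per-variable presence-sample means (raw covariate
#'   scale), used to hold variables fixed in response curves.
#' @slot gain unpenalized training gain over the uniform background model.
#' @slot contributions per-variable percent contribution accumulated along
#'   the optimization path (sums to 100).
#' @slot nBackground number of background points used in the fit.
#' @slot convergence list with iterations, final max KKT violation, and the
#'   objective trace.
#' @export
setClass("MaxentModel",
  representation(
    featureTable = "data.frame",
    lambdas = "numeric",
    betas = "numeric",
    varBounds = "data.frame",
    logZ = "numeric",
    entropyH = "numeric",
    rm = "numeric",
    classes = "character",
    transform = "character",
    presenceMeans = "numeric",
    gain = "numeric",
    contributions = "numeric",
    nBackground = "integer",
    convergence = "list"
  )
)

setValidity("MaxentModel", function(object) {
  if (length(object@lambdas) != nrow(object@featureTable))
    return("one lambda per feature required")
  if (any(!is.finite(object@lambdas)))
    return("lambdas must be finite")
  TRUE
})

#' SuitabilityGrid: model output on a grid
#'
#' A \linkS4class{ClimateGrid} whose values are habitat suitability. For the
#' logistic and cloglog transforms values lie in [0, 1] (0 unsuitable, 1
#' optimal); for "raw" they are cell probabilities summing to 1 over the
#' projection cells' training normalizer.
#'
#' @slot transform output transform tag.
#' @slot clampCounts integer matrix: per cell, how many model variables fell
#'   outside their training range (extrapolation diagnostics).
#' @export
setClass("SuitabilityGrid", contains = "ClimateGrid",
  representation(transform = "character", clampCounts = "matrix"),
  prototype(transform = "logistic")
)

setValidity("SuitabilityGrid", function(object) {
  v <- object@values[!is.na(object@values)]
  if (object@transform %in% c("logistic", "cloglog") &&
      length(v) && (min(v) < 0 || max(v) > 1))
    return("logistic/cloglog suitability must lie in [0, 1]")
  TRUE
})

#' ClassGrid: suitability classified into four classes
#'
#' Integer-coded suitability classes: 0 unsuitable, 1 low, 2 medium, 3 high.
#' Produced by \code{\link{classifySuitability}} from a threshold t (usually
#' the maximum test sensitivity plus specificity threshold) with the interval
#' [t, 1] split into three equal-width bins.
#'
#' @slot threshold the suitability threshold used.
#' @slot classBounds the two interior cut points between low/medium/high.
#' @export
setClass("ClassGrid", contains = "ClimateGrid",
  representation(threshold = "numeric", classBounds = "numeric")
)

setValidity("ClassGrid", function(object) {
  v <- object@values[!is.na(object@values)]
  if (length(v) && !all(v %in% 0:3))
    return("class codes must be 0 (unsuitable), 1 (low), 2 (medium), 3 (high)")
  if (length(object@threshold) == 1L &&
      (object@threshold <= 0 || object@threshold >= 1))
    return("threshold must lie in (0, 1)")
  TRUE
})

#' RiskMap: pest risk classes over the optimal-host mask
#'
#' Integer-coded overlay of pest suitability classes restricted to cells where
#' the host crop finds optimal (medium or high) conditions: 0 outside-optimal,
#' 1 no risk, 2 low, 3 medium, 4 high risk.
#'
#' @slot pestSlice time-slice label of the pest classification.
#' @slot hostSlice time-slice label of the host classification.
#' @export
setClass("RiskMap", contains = "ClimateGrid",
  representation(pestSlice = "character", hostSlice = "character")
)

setValidity("RiskMap", function(object) {
  v <- object@values[!is.na(object@values)]
  if (length(v) && !all(v %in% 0:4))
    return("risk codes must be in 0:4")
  TRUE
})

#' Risk class code table
#'
#' Named integer codes used in \linkS4class{RiskMap} values.
#' @export
riskLevels <- c(outside_optimal = 0L, no_risk = 1L, low_risk = 2L,
                medium_risk = 3L, high_risk = 4L)

#' Suitability class code table
#'
#' Named integer codes used in \linkS4class{ClassGrid} values.
#' @export
suitabilityLevels <- c(unsuitable = 0L, low = 1L, medium = 2L, high = 3L)
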