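# Accessors and show methods. Slot access from user code should go through
# these, not @.

#' @rdname accessors
#' @param x a pestrisk object
#' @export
setGeneric("gridValues", function(x) standardGeneric("gridValues"))
#' @rdname accessors
#' @export
setGeneric("gridMask", function(x) standardGeneric("gridMask"))
#' @rdname accessors
#' @export
setGeneric("gridOrigin", function(x) standardGeneric("gridOrigin"))
#' @rdname accessors
#' @export
setGeneric("cellSize", function(x) standardGeneric("cellSize"))
#' @rdname accessors
#' @export
setGeneric("layerNames", function(x) standardGeneric("layerNames"))
#' @rdname accessors
#' @export
setGeneric("sliceLabel", function(x) standardGeneric("sliceLabel"))
#' @rdname accessors
#' @export
setGeneric("occPoints", function(x) standardGeneric("occPoints"))
#' @rdname accessors
#' @export
setGeneric("speciesName", function(x) standardGeneric("speciesName"))

#' Accessors for pestrisk classes
#'
#' \code{gridValues} returns the value matrix (\code{NA} = nodata);
#' \code{gridMask} a logical matrix, \code{TRUE} where masked;
#' \code{gridOrigin} the (lon, lat) of the upper-left corner;
#' \code{cellSize} the cell edge in degrees; \code{layerNames} and
#' \code{sliceLabel} describe a \linkS4class{GridStack}; \code{occPoints}
#' and \code{speciesName} describe an \linkS4class{OccurrenceSet}.
#'
#' @name accessors
#' @rdname accessors
#' @export
setMethod("gridValues", "ClimateGrid", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("gridMask", "ClimateGrid", function(x) is.na(x@values))
#' @rdname accessors
#' @export
setMethod("gridOrigin", "ClimateGrid", function(x) x@origin)
#' @rdname accessors
#' @export
setMethod("cellSize", "ClimateGrid", function(x) x@cellSize)
#' @rdname accessors
#' @export
setMethod("layerNames", "GridStack", function(x) names(x@layers))
#' @rdname accessors
#' @export
setMethod("sliceLabel", "GridStack", function(x) x@sliceLabel)
#' @rdname accessors
#' @export
setMethod("occPoints", "OccurrenceSet", function(x) x@points)
#' @rdname accessors
#' @export
setMethod("occPoints", "BackgroundSet", function(x) x@points)
#' @rdname accessors
#' @export
setMethod("speciesName", "OccurrenceSet", function(x) x@species)

#' Extract a layer from a GridStack
#'
#' @param x a \linkS4class{GridStack}
#' @param name layer name
#' @return a \linkS4class{ClimateGrid}
#' @export
getLayer <- function(x, name) {
  stopifnot(is(x, "GridStack"))
  if (!name %in% names(x@layers))
    stop("no layer named '", name, "' in stack (",
         paste(names(x@layers), collapse = ", "), ")")
  x@layers[[name]]
}

#' Number of occurrences
#' @param x an \linkS4class{OccurrenceSet}
#' @export
nOccurrences <- function(x) nrow(x@points)

#' Fitted coefficients of a MaxentModel
#' @param object a \linkS4class{MaxentModel}
#' @return named numeric vector of per-feature coefficients
#' @export
lambdas <- function(object) {
  stopifnot(is(object, "MaxentModel"))
  stats::setNames(object@lambdas, featureLabels(object@featureTable))
}

#' Entropy of the fitted raw distribution
#' @param object a \linkS4class{MaxentModel}
#' @export
modelEntropy <- function(object) object@entropyH

#' Unpenalized training gain over the uniform model
#' @param object a \linkS4class{MaxentModel}
#' @export
trainingGain <- function(object) object@gain

setMethod("show", "ClimateGrid", function(object) {
  d <- dim(object@values)
  cat("ClimateGrid '", object@name, "': ", d[1], " x ", d[2],
      " cells of ", object@cellSize, " deg, origin (",
      object@origin[1], ", ", object@origin[2], ")",
      if (nzchar(object@units)) paste0(" [", object@units, "]"), "\n",
      sep = "")
  n_masked <- sum(is.na(object@values))
  cat("  ", n_masked, " masked / ", prod(d), " cells\n", sep = "")
})

setMethod("show", "GridStack", function(object) {
  cat("GridStack (slice '", object@sliceLabel, "') with ",
      length(object@layers), " layers: ",
      paste(names(object@layers), collapse = ", "), "\n", sep = "")
})

setMethod("show", "OccurrenceSet", function(object) {
  cat("OccurrenceSet: ", nrow(object@points), " records of '",
      object@species, "'", sep = "")
  if (nzchar(object@provenance)) cat(" (", object@provenance, ")", sep = "")
  cat("\n")
})

setMethod("show", "BackgroundSet", function(object) {
  cat("BackgroundSet: ", nrow(object@points), " points (seed ",
      object@seed, ")\n", sep = "")
})

setMethod("show", "MaxentModel", function(object) {
  nz <- sum(object@lambdas != 0)
  cat("MaxentModel: classes {", paste(object@classes, collapse = ""),
      "}, RM ", object@rm, ", ", length(object@lambdas), " features (",
      nz, " active)\n", sep = "")
  cat("  training gain ", round(object@gain, 4), ", entropy ",
      round(object@entropyH, 4), ", transform '", object@transform,
      "'\n", sep = "")
})

setMethod("show", "SuitabilityGrid", function(object) {
  v <- object@values[!is.na(object@values)]
  cat("SuitabilityGrid (", object@transform, "): ",
      paste(dim(object@values), collapse = " x "), " cells, range [",
      round(min(v), 4), ", ", round(max(v), 4), "]\n", sep = "")
})

setMethod("show", "ClassGrid", function(object) {
  v <- object@values[!is.na(object@values)]
  tab <- table(factor(v, levels = 0:3, labels = names(suitabilityLevels)))
  cat("ClassGrid (threshold ", round(object@threshold, 4), "):\n", sep = "")
  print(tab)
})

setMethod("show", "RiskMap", function(object) {
  v <- object@values[!is.na(object@values)]
  tab <- table(factor(v, levels = 0:4, labels = names(riskLevels)))
  cat("RiskMap (pest '", object@pestSlice, "' on host '",
      object@hostSlice, "'):\n", sep = "")
  print(tab)
})
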