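# Thresholding suitability into classes, the optimal-host mask, the pest
# risk overlay, and area/change summaries between time slices.

#' Maximum test sensitivity plus specificity threshold
#'
#' Scans candidate thresholds at the midpoints of adjacent distinct pooled
#' scores and returns the one maximizing sensitivity (fraction of presences
#' scoring >= t) plus specificity (fraction of background scoring < t).
#' Ties break toward the smallest maximizing threshold.
#'
#' @param presenceScores held-out presence scores of the selected model.
#' @param backgroundScores background scores of the selected model.
#' @return the threshold t
#' @export
mtspsThreshold <- function(presenceScores, backgroundScores) {
  if (!length(presenceScores) || !length(backgroundScores))
    stop("empty score vector")
  pooled <- sort(unique(c(presenceScores, backgroundScores)))
  if (length(pooled) < 2L)
    stop("degenerate scores: all pooled values identical, no threshold exists")
  cand <- (pooled[-1] + pooled[-length(pooled)]) / 2
  ss <- vapply(cand, function(t)
    mean(presenceScores >= t) + mean(backgroundScores < t), numeric(1))
  cand[which.max(ss)]  # which.max takes the first, i.e. smallest, maximizer
}

#' Classify suitability into four classes
#'
#' Values below the threshold t are unsuitable; the interval [t, 1] is split
#' into three equal-width bins, half-open below and closed at 1, giving low,
#' medium, and high suitability.
#'
#' @param suit a \linkS4class{SuitabilityGrid} (logistic/cloglog scale).
#' @param threshold t in (0, 1), typically from \code{\link{mtspsThreshold}}.
#' @param classBounds optional explicit interior cut points (length 2)
#'   overriding the equal-width default.
#' @return a \linkS4class{ClassGrid}
#' @export
classifySuitability <- function(suit, threshold, classBounds = NULL) {
  stopifnot(is(suit, "ClimateGrid"))
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must lie in (0, 1)")
  if (is.null(classBounds)) {
    w <- (1 - threshold) / 3
    classBounds <- c(threshold + w, threshold + 2 * w)
  }
  stopifnot(length(classBounds) == 2L)
  v <- suit@values
  cls <- matrix(NA_real_, nrow(v), ncol(v))
  ok <- !is.na(v)
  cls[ok] <- ifelse(v[ok] < threshold, 0,
              ifelse(v[ok] < classBounds[1], 1,
               ifelse(v[ok] < classBounds[2], 2, 3)))
  new("ClassGrid", name = paste0(suit@name, "_class"), values = cls,
      origin = suit@origin, cellSize = suit@cellSize, units = "class",
      threshold = threshold, classBounds = classBounds)
}

#' Optimal-host mask
#'
#' TRUE where the host crop's suitability class is medium or high — the
#' "optimal conditions" cells over which pest risk is assessed.
#'
#' @param hostClasses a \linkS4class{ClassGrid} for the host.
#' @return logical matrix (NA where masked)
#' @export
optimalMask <- function(hostClasses) {
  stopifnot(is(hostClasses, "ClassGrid"))
  m <- hostClasses@values >= suitabilityLevels[["medium"]]
  m
}

#' Overlay pest suitability classes on the optimal-host mask
#'
#' Cells outside the mask are coded outside_optimal; inside the mask the
#' pest class maps directly to a risk level (unsuitable -> no_risk, low ->
#' low_risk, medium -> medium_risk, high -> high_risk). Purely cellwise.
#'
#' @param pestClasses a \linkS4class{ClassGrid} for the pest.
#' @param hostMask logical matrix from \code{\link{optimalMask}}.
#' @param pestSlice,hostSlice time-slice labels (bookkeeping).
#' @return a \linkS4class{RiskMap}
#' @export
riskOverlay <- function(pestClasses, hostMask, pestSlice = "current",
                        hostSlice = "current") {
  stopifnot(is(pestClasses, "ClassGrid"))
  if (!identical(dim(hostMask), dim(pestClasses@values)))
    stop("misaligned grids: host mask shape differs from pest classes")
  v <- pestClasses@values
  risk <- matrix(NA_real_, nrow(v), ncol(v))
  ok <- !is.na(v) & !is.na(hostMask)
  risk[ok] <- ifelse(hostMask[ok], v[ok] + 1, riskLevels[["outside_optimal"]])
  new("RiskMap", name = "risk", values = risk, origin = pestClasses@origin,
      cellSize = pestClasses@cellSize, units = "risk",
      pestSlice = pestSlice, hostSlice = hostSlice)
}

#' Per-class risk areas
#'
#' Areas in km^2 (geodesic, latitude-weighted cell areas; or planar pixel
#' counts) per risk class, and each class as a percent of the total
#' optimal-host area.
#'
#' @param risk a \linkS4class{RiskMap}
#' @param method \code{"geodesic"} (default) or \code{"planar"}; see
#'   \code{\link{cellAreas}}.
#' @return data.frame: class, area_km2, percent_of_optimal
#' @export
areaSummary <- function(risk, method = c("geodesic", "planar")) {
  method <- match.arg(method)
  stopifnot(is(risk, "RiskMap"))
  areas <- cellAreas(risk, method)
  v <- risk@values
  classes <- names(riskLevels)[-1]  # inside the optimal mask
  inside <- !is.na(v) & v != riskLevels[["outside_optimal"]]
  total <- sum(areas[inside])
  if (total == 0) stop("risk map has no optimal-host cells")
  out <- do.call(rbind, lapply(classes, function(cl) {
    sel <- !is.na(v) & v == riskLevels[[cl]]
    a <- sum(areas[sel])
    data.frame(class = cl, area_km2 = a,
               percent_of_optimal = 100 * a / total,
               stringsAsFactors = FALSE)
  }))
  out
}

#' Percent change of class areas between two time slices
#'
#' change% = (future - current) / current * 100 per class; positive values
#' are extensions, negative values shortenings. Classes with zero current
#' area have undefined change and are flagged NA.
#'
#' @param current,future data.frames from \code{\link{areaSummary}} (or any
#'   with columns class and area_km2) over the same class set.
#' @return data.frame: class, current_km2, future_km2, change_percent,
#'   direction
#' @export
changeStats <- function(current, future) {
  if (!setequal(current$class, future$class))
    stop("current and future summaries cover different classes")
  future <- future[match(current$class, future$class), ]
  chg <- ifelse(current$area_km2 > 0,
                (future$area_km2 - current$area_km2) / current$area_km2 * 100,
                NA_real_)
  data.frame(class = current$class,
             current_km2 = current$area_km2,
             future_km2 = future$area_km2,
             change_percent = chg,
             direction = ifelse(is.na(chg), "undefined",
                          ifelse(chg > 0, "extension",
                           ifelse(chg < 0, "shortening", "unchanged"))),
             stringsAsFactors = FALSE)
}
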