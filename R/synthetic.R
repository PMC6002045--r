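# Synthetic inputs with the statistical structure the analysis assumes:
# smooth climate fields, a known true suitability surface (unimodal in
# temperature, decreasing in precipitation), biased presence samples, and a
# warmed future slice. The generator's truth is the recovery target for
# end-to-end tests; it deliberately uses only two active variables plus
# generic noise layers so importance measures have known expected winners.

# Separable Gaussian smoothing with reflective padding.
smooth2d <- function(m, sigma = 3) {
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-0.5 * ((-half:half) / sigma)^2)
  k <- k / sum(k)
  pad_filter <- function(x) {
    n <- length(x)
    xp <- c(rev(x[seq_len(half)]), x, rev(x[n - seq_len(half) + 1L]))
    as.numeric(stats::filter(xp, k, sides = 2))[half + seq_len(n)]
  }
  m <- apply(m, 2, pad_filter)
  t(apply(m, 1, pad_filter))
}

rescaleTo <- function(m, lo, hi) {
  r <- range(m)
  if (r[2] == r[1]) return(matrix(lo, nrow(m), ncol(m)))
  (m - r[1]) / (r[2] - r[1]) * (hi - lo) + lo
}

#' Generate a synthetic climate stack
#'
#' Each layer is a low-order spatial trend plus seeded, smoothed Gaussian
#' noise. The first layer ("bio1") is temperature in degrees C spanning
#' -10 to 32 (about the span of global annual-mean-temperature layers)
#' with a cold-skewed latitudinal profile, warmest at the equatorward
#' (bottom) edge; the second ("bio12") is precipitation in mm with range
#' 0-3000 (mostly longitudinal trend + noise, so it is not collinear with
#' temperature); remaining layers are generic standardized indices.
#' Deterministic per seed.
#'
#' @param nrow,ncol grid size (>= 10 x 10).
#' @param nVars number of layers (>= 2).
#' @param seed RNG seed.
#' @param origin (lon, lat) of the upper-left corner.
#' @param cellSize cell size in degrees.
#' @param sliceLabel time-slice tag.
#' @return a \linkS4class{GridStack}
#' @export
makeClimate <- function(nrow = 40L, ncol = 40L, nVars = 4L, seed = 1L,
                        origin = c(-10, 25), cellSize = 0.25,
                        sliceLabel = "current") {
  stopifnot(nrow >= 10L, ncol >= 10L, nVars >= 2L)
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  latnorm <- matrix(rep(seq(0, 1, length.out = nrow), ncol), nrow, ncol)
  lonnorm <- matrix(rep(seq(0, 1, length.out = ncol), each = nrow),
                    nrow, ncol)
  noise <- function(amp) amp * smooth2d(matrix(rnorm(nrow * ncol),
                                               nrow, ncol), sigma = 3)
  # temperature: warmer toward the equatorward (bottom) edge, with a
  # superlinear profile so warm cells are rare relative to cold ones, as
  # in area-weighted global land climates
  temp <- rescaleTo(latnorm^1.5 + noise(0.6), -10, 32)
  precip <- rescaleTo(0.7 * lonnorm + noise(0.8), 0, 3000)
  layers <- list(
    ClimateGrid("bio1", temp, origin, cellSize, "degC"),
    ClimateGrid("bio12", precip, origin, cellSize, "mm"))
  if (nVars > 2L) for (i in seq_len(nVars - 2L)) {
    g <- noise(1)
    g <- (g - mean(g)) / sd(g)
    layers[[2L + i]] <- ClimateGrid(paste0("noise", i), g, origin, cellSize,
                                    "index")
  }
  alignStack(layers, sliceLabel)
}

#' Perturb a climate stack into a future slice
#'
#' Temperature layers (units "degC") are shifted by \code{deltaTemp};
#' precipitation layers (units "mm") are multiplied by \code{precipScale};
#' everything else is unchanged.
#'
#' @param stack a \linkS4class{GridStack}
#' @param deltaTemp warming in degrees C.
#' @param precipScale multiplicative precipitation factor.
#' @param sliceLabel label for the new slice.
#' @return a \linkS4class{GridStack}
#' @export
makeFuture <- function(stack, deltaTemp = 2, precipScale = 1,
                       sliceLabel = "future") {
  layers <- lapply(stack@layers, function(g) {
    if (g@units == "degC") g@values <- g@values + deltaTemp
    else if (g@units == "mm") g@values <- g@values * precipScale
    g
  })
  names(layers) <- names(stack@layers)
  new("GridStack", layers = layers, sliceLabel = sliceLabel)
}

#' Truth parameters for the synthetic suitability surface
#'
#' Defaults describe a warm-adapted pest niche: optimum 23.8 degrees C with
#' SD 3.8 (the empirical occurrence-temperature mean and spread of a
#' globally distributed whitefly pest), precipitation half-saturation 1000
#' mm so suitability falls with rainfall.
#'
#' @param tempOptimum optimal temperature, degrees C.
#' @param tempSd Gaussian niche breadth, degrees C.
#' @param precipHalfsat precipitation at which suitability halves, mm.
#' @param biasStrength weight of the sampling-bias surface (0 = unbiased).
#' @param nPresence presence sample size.
#' @param seed RNG seed.
#' @return a \code{TruthParams} list
#' @export
makeTruthParams <- function(tempOptimum = 23.8, tempSd = 3.8,
                            precipHalfsat = 1000, biasStrength = 0,
                            nPresence = 500L, seed = 1L) {
  stopifnot(tempSd > 0, nPresence >= 1, precipHalfsat > 0, biasStrength >= 0)
  structure(list(tempOptimum = tempOptimum, tempSd = tempSd,
                 precipHalfsat = precipHalfsat, biasStrength = biasStrength,
                 nPresence = as.integer(nPresence), seed = as.integer(seed)),
            class = "TruthParams")
}

#' True suitability surface of the generator
#'
#' \deqn{s(x) = \exp(-(T - T_{opt})^2 / (2\sigma^2)) \cdot
#'   h / (h + P)}
#' with T the temperature layer, P the precipitation layer, and h the
#' precipitation half-saturation: unimodal in temperature, strictly
#' decreasing in precipitation, values in (0, 1].
#'
#' @param stack a \linkS4class{GridStack} with temperature ("degC") and
#'   precipitation ("mm") layers.
#' @param params a \code{\link{makeTruthParams}}.
#' @return a \linkS4class{SuitabilityGrid}
#' @export
trueSuitability <- function(stack, params = makeTruthParams()) {
  units <- vapply(stack@layers, function(g) g@units, character(1))
  ti <- which(units == "degC")[1]
  pi_ <- which(units == "mm")[1]
  if (is.na(ti) || is.na(pi_))
    stop("stack needs a temperature (degC) and a precipitation (mm) layer")
  T_ <- stack@layers[[ti]]@values
  P <- stack@layers[[pi_]]@values
  s <- exp(-(T_ - params$tempOptimum)^2 / (2 * params$tempSd^2)) *
    params$precipHalfsat / (params$precipHalfsat + P)
  ref <- stack@layers[[1L]]
  new("SuitabilityGrid", name = "truth", values = s, origin = ref@origin,
      cellSize = ref@cellSize, units = "suitability",
      transform = "logistic", clampCounts = matrix(0L, nrow(s), ncol(s)))
}

#' Sample presence records from a truth surface
#'
#' Cells are drawn with replacement with probability proportional to truth
#' (times an optional bias surface); each point is placed at the sampled
#' cell's centre with a small uniform jitter inside the cell, avoiding
#' exact coordinate duplicates. Deterministic per seed.
#'
#' @param truth a \linkS4class{SuitabilityGrid} (e.g. from
#'   \code{\link{trueSuitability}}).
#' @param bias optional \linkS4class{ClimateGrid} of sampling effort.
#' @param n number of presences.
#' @param seed RNG seed.
#' @param species species label for the result.
#' @return an \linkS4class{OccurrenceSet}
#' @export
samplePresences <- function(truth, bias = NULL, n = 500L, seed = 1L,
                            species = "synthetic") {
  stopifnot(n >= 1)
  unmasked <- which(!is.na(truth@values))
  w <- truth@values[unmasked]
  if (!is.null(bias)) w <- w * bias@values[unmasked]
  if (all(w == 0)) stop("all-zero sampling weights")
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  picks <- sample(seq_along(unmasked), n, replace = TRUE, prob = w)
  centers <- cellCenters(truth)[unmasked[picks], , drop = FALSE]
  jitter_amt <- truth@cellSize * 0.49
  pts <- centers + cbind(runif(n, -jitter_amt, jitter_amt),
                         runif(n, -jitter_amt, jitter_amt))
  OccurrenceSet(species, pts, provenance = paste0("synthetic seed=", seed))
}

#' Write a truth manifest
#'
#' JSON record of the generator parameters and seed, for recovery tests.
#'
#' @param params a \code{TruthParams}.
#' @param path output path.
#' @export
writeTruthManifest <- function(params, path) {
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
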