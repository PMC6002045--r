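# Occurrence ingestion, spatial thinning, the kernel-density sampling-bias
# surface, and weighted background sampling.

#' Load presence records from CSV
#'
#' Reads rows for one species, collapses exact duplicate coordinates, and
#' drops rows with out-of-range or non-numeric coordinates (with a message
#' reporting how many were rejected).
#'
#' @param path CSV file with species, longitude, latitude columns.
#' @param species species label to select.
#' @param cols names of the species/longitude/latitude columns.
#' @return an \linkS4class{OccurrenceSet}
#' @export
loadOccurrences <- function(path, species,
                            cols = c(species = "species",
                                     lon = "longitude", lat = "latitude")) {
  df <- read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  missing_cols <- setdiff(unname(cols), names(df))
  if (length(missing_cols))
    stop("occurrence CSV is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  df <- df[df[[cols[["species"]]]] == species, , drop = FALSE]
  if (!nrow(df)) {
    warning("no records for species '", species, "' in ", path)
    return(OccurrenceSet(species, matrix(numeric(0), 0, 2), provenance = path))
  }
  lon <- suppressWarnings(as.numeric(df[[cols[["lon"]]]]))
  lat <- suppressWarnings(as.numeric(df[[cols[["lat"]]]]))
  ok <- is.finite(lon) & is.finite(lat) &
    lon >= -180 & lon <= 180 & lat >= -90 & lat <= 90
  n_bad <- sum(!ok)
  if (n_bad)
    message(n_bad, " row(s) with invalid coordinates rejected for '",
            species, "'")
  OccurrenceSet(species, cbind(lon[ok], lat[ok]), provenance = path)
}

#' Write an occurrence set to CSV
#'
#' The first line is a \code{#}-prefixed provenance comment.
#'
#' @param occ an \linkS4class{OccurrenceSet}
#' @param path output CSV path.
#' @export
writeOccurrences <- function(occ, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# species=", occ@species, " n=", nrow(occ@points),
                    " provenance=", occ@provenance), con)
  df <- data.frame(species = occ@species,
                   longitude = occ@points[, 1], latitude = occ@points[, 2])
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Great-circle distance in km
#'
#' Haversine distance on a sphere of radius 6371 km.
#'
#' @param p,q numeric (lon, lat) pairs in degrees, or two-column matrices.
#' @return distance(s) in km
#' @export
haversineKm <- function(p, q) {
  geosphere::distHaversine(p, q, r = EARTH_RADIUS_KM * 1000) / 1000
}

# Full pairwise great-circle distance matrix in km on the R = 6371 km
# sphere (distm has no radius argument, so rescale from WGS84).
pairwiseKm <- function(pts) {
  geosphere::distm(pts, fun = geosphere::distHaversine) / 1000 *
    (EARTH_RADIUS_KM / 6378.137)
}

#' Spatially thin presence records
#'
#' Enforces a minimum pairwise great-circle distance: the returned set has
#' every pair strictly more than \code{minDistKm} apart. Each repetition
#' greedily deletes the point with the most neighbours within
#' \code{minDistKm} (ties broken uniformly at random) until no violating
#' pair remains; the largest retained set over \code{reps} randomized
#' repetitions is returned. Deterministic under a fixed seed. This mirrors
#' the behaviour of established thinning tools that aim to keep as many
#' localities as possible.
#'
#' @param occ an \linkS4class{OccurrenceSet}
#' @param minDistKm minimum separation in km (default 10, so that retained
#'   points are >10 km apart and at most one per ~5 km grid cell).
#' @param reps number of randomized repetitions (default 10).
#' @param seed RNG seed.
#' @return a thinned \linkS4class{OccurrenceSet}
#' @export
thinOccurrences <- function(occ, minDistKm = 10, reps = 10, seed = 1L) {
  stopifnot(minDistKm > 0, reps >= 1)
  pts <- occ@points
  n <- nrow(pts)
  if (n <= 1L) return(occ)
  dmat <- pairwiseKm(pts)
  viol <- dmat <= minDistKm & !diag(TRUE, n)
  best <- NULL
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  for (r in seq_len(reps)) {
    keep <- rep(TRUE, n)
    deg <- rowSums(viol)
    while (any(deg[keep] > 0)) {
      mx <- max(deg[keep])
      cand <- which(keep & deg == mx)
      drop <- if (length(cand) == 1L) cand else sample(cand, 1L)
      keep[drop] <- FALSE
      deg <- deg - viol[, drop]
      deg[drop] <- 0
    }
    if (is.null(best) || sum(keep) > sum(best)) best <- keep
  }
  OccurrenceSet(occ@species, pts[best, , drop = FALSE],
                provenance = paste0(occ@provenance,
                                    " | thinned >", minDistKm, " km"))
}

#' Kernel-density sampling-bias surface
#'
#' Gaussian-kernel density of the occurrence points evaluated at the
#' unmasked cell centres of a template grid, normalized to sum to 1 over
#' unmasked cells. Strictly positive everywhere (the kernel has unbounded
#' support), so weighted background sampling can reach every unmasked cell.
#' Distances are great-circle km; the bandwidth is the kernel's standard
#' deviation.
#'
#' @param occ an \linkS4class{OccurrenceSet} with at least one record.
#' @param template a \linkS4class{ClimateGrid} supplying geometry and mask.
#' @param bandwidthKm Gaussian bandwidth in km (default 200).
#' @return a \linkS4class{ClimateGrid} of normalized densities
#' @export
biasSurface <- function(occ, template, bandwidthKm = 200) {
  stopifnot(bandwidthKm > 0)
  if (nrow(occ@points) == 0L) stop("empty occurrence set")
  centers <- cellCenters(template)
  unmasked <- which(!is.na(template@values))
  cc <- centers[unmasked, , drop = FALSE]
  dens <- numeric(length(unmasked))
  for (i in seq_len(nrow(occ@points))) {
    d <- haversineKm(occ@points[i, ], cc)
    dens <- dens + exp(-0.5 * (d / bandwidthKm)^2)
  }
  dens <- dens / sum(dens)
  vals <- matrix(NA_real_, nrow(template@values), ncol(template@values))
  vals[unmasked] <- dens
  ClimateGrid("bias", vals, template@origin, template@cellSize, "density")
}

#' Draw weighted background points
#'
#' Samples \code{n} unmasked cells with replacement, with probability
#' proportional to a bias surface, and places points at cell centres.
#' Deterministic under a fixed seed.
#'
#' @param stack a \linkS4class{GridStack}
#' @param bias a \linkS4class{ClimateGrid} aligned with the stack (e.g. from
#'   \code{\link{biasSurface}}); \code{NULL} for uniform sampling.
#' @param n number of points (50,000 for a full-scale run).
#' @param seed RNG seed, recorded in the result.
#' @return a \linkS4class{BackgroundSet}
#' @export
sampleBackground <- function(stack, bias = NULL, n = 50000, seed = 1L) {
  stopifnot(n >= 1)
  ref <- stack@layers[[1L]]
  unmasked <- which(!is.na(ref@values))
  if (!length(unmasked)) stop("all cells masked; cannot sample background")
  if (is.null(bias)) {
    w <- rep(1, length(unmasked))
  } else {
    if (!identical(dim(bias@values), dim(ref@values)) ||
        !isTRUE(all.equal(bias@origin, ref@origin)) ||
        !isTRUE(all.equal(bias@cellSize, ref@cellSize)))
      stop("bias surface is not aligned with the stack")
    w <- bias@values[unmasked]
    if (any(is.na(w)))
      stop("bias surface masks cells that are unmasked in the stack")
  }
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  picks <- sample(seq_along(unmasked), n, replace = TRUE, prob = w)
  centers <- cellCenters(ref)
  pts <- centers[unmasked[picks], , drop = FALSE]
  new("BackgroundSet", points = pts, weights = w[picks] / sum(w),
      seed = as.integer(seed))
}
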