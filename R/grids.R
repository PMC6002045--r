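# Raster data model: readers/writers, stack alignment, cell geometry and
# latitude-aware cell areas. Inputs must already share georeference; nothing
# here resamples or reprojects.

EARTH_RADIUS_KM <- 6371

#' Read a gridded variable from disk
#'
#' Supports two plain formats: ESRI ASCII grids (\code{format = "ascii"}),
#' parsed directly, and TIFF (\code{format = "tiff"}) written by
#' \code{\link{writeGrid}} (grayscale + mask channel with a \code{.aux.json}
#' sidecar holding georeference, value scaling, and units). Nodata cells
#' become \code{NA}.
#'
#' @param path file path.
#' @param format \code{"ascii"} or \code{"tiff"}.
#' @param name layer name; defaults to the file stem.
#' @param units units string attached to the returned grid.
#' @return a \linkS4class{ClimateGrid}
#' @export
readGrid <- function(path, format = c("ascii", "tiff"), name = NULL,
                     units = "") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file does not exist: ", path)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  if (format == "ascii") readAsciiGrid(path, name, units)
  else readTiffGrid(path, name, units)
}

readAsciiGrid <- function(path, name, units) {
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  i <- 1L
  repeat {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    key <- tolower(parts[1])
    if (key %in% c("ncols", "nrows", "xllcorner", "yllcorner", "xllcenter",
                   "yllcenter", "cellsize", "dx", "dy", "nodata_value")) {
      hdr[[key]] <- as.numeric(parts[2])
      i <- i + 1L
    } else break
  }
  for (k in c("ncols", "nrows", "cellsize"))
    if (is.null(hdr[[k]]))
      stop("ASCII grid header missing required field: ", k)
  if (!is.null(hdr$dx) && !is.null(hdr$dy) && hdr$dx != hdr$dy)
    stop("non-square cells: dx (", hdr$dx, ") != dy (", hdr$dy, ")")
  nodata <- if (is.null(hdr$nodata_value)) -9999 else hdr$nodata_value
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  nc <- hdr$ncols; nr <- hdr$nrows
  if (length(vals) != nr * nc)
    stop("ASCII grid body has ", length(vals), " values, expected ", nr * nc)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA_real_
  xll <- if (!is.null(hdr$xllcorner)) hdr$xllcorner
         else hdr$xllcenter - hdr$cellsize / 2
  yll <- if (!is.null(hdr$yllcorner)) hdr$yllcorner
         else hdr$yllcenter - hdr$cellsize / 2
  origin <- c(xll, yll + nr * hdr$cellsize)  # upper-left corner
  ClimateGrid(name, m, origin, hdr$cellsize, units)
}

readTiffGrid <- function(path, name, units) {
  aux_path <- paste0(path, ".aux.json")
  if (!file.exists(aux_path))
    stop("missing sidecar for tiff grid: ", aux_path)
  aux <- jsonlite::read_json(aux_path, simplifyVector = TRUE)
  # the mask channel is stored as a second sample; libtiff flags it as an
  # extra (non-colour) sample, which is expected
  a <- withCallingHandlers(
    tiff::readTIFF(path),
    warning = function(w) {
      if (grepl("ExtraSamples", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  if (length(dim(a)) != 3L || dim(a)[3] != 2L)
    stop("tiff grid must have two channels (values, mask): ", path)
  vals <- a[, , 1]
  mask <- a[, , 2] < 0.5
  rng <- aux$value_range
  m <- vals * (rng[2] - rng[1]) + rng[1]
  m[mask] <- NA_real_
  g <- ClimateGrid(name, m, as.numeric(aux$origin), as.numeric(aux$cell_size),
                   if (nzchar(units)) units else as.character(aux$units))
  g
}

#' Write a gridded variable to disk
#'
#' ESRI ASCII grids are written with a \code{NODATA_value} of -9999 and full
#' double precision. TIFF output is a two-channel (values, mask) 32-bit
#' image of [0,1]-rescaled values plus a \code{.aux.json} sidecar with the
#' georeference and value range; round-tripping is value-preserving to about
#' one part in 2^32 of the value range.
#'
#' @param grid a \linkS4class{ClimateGrid}
#' @param path output path.
#' @param format \code{"ascii"} or \code{"tiff"}.
#' @return \code{path}, invisibly.
#' @export
writeGrid <- function(grid, path, format = c("ascii", "tiff")) {
  format <- match.arg(format)
  stopifnot(is(grid, "ClimateGrid"))
  if (format == "ascii") writeAsciiGrid(grid, path) else writeTiffGrid(grid, path)
  invisible(path)
}

writeAsciiGrid <- function(grid, path) {
  m <- grid@values
  nr <- nrow(m); nc <- ncol(m)
  nodata <- -9999
  if (any(!is.na(m) & m == nodata))
    stop("grid contains the nodata sentinel ", nodata, " as a real value")
  yll <- grid@origin[2] - nr * grid@cellSize
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", format(nc)),
    paste("nrows", format(nr)),
    paste("xllcorner", format(grid@origin[1], digits = 15)),
    paste("yllcorner", format(yll, digits = 15)),
    paste("cellsize", format(grid@cellSize, digits = 15)),
    paste("NODATA_value", nodata)
  ), con)
  m[is.na(m)] <- nodata
  body <- apply(m, 1, function(r)
    paste(format(r, digits = 17, trim = TRUE, scientific = FALSE),
          collapse = " "))
  writeLines(body, con)
}

writeTiffGrid <- function(grid, path) {
  m <- grid@values
  mask <- is.na(m)
  v <- m
  rng <- if (all(mask)) c(0, 1) else range(m, na.rm = TRUE)
  if (rng[2] == rng[1]) rng[2] <- rng[1] + 1
  v <- (v - rng[1]) / (rng[2] - rng[1])
  v[mask] <- 0
  a <- array(c(v, as.numeric(!mask)), dim = c(nrow(m), ncol(m), 2))
  tiff::writeTIFF(a, path, bits.per.sample = 32L, compression = "none")
  jsonlite::write_json(
    list(origin = grid@origin, cell_size = grid@cellSize,
         value_range = rng, units = grid@units, name = grid@name),
    paste0(path, ".aux.json"), auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Align grids into a stack for one time slice
#'
#' The stack's shared nodata mask is the union of the member masks. Grids
#' with mismatched shape, origin, or cell size are rejected: the pipeline
#' never resamples, inputs must already align.
#'
#' @param grids list of \linkS4class{ClimateGrid} objects (named or using
#'   each grid's own name).
#' @param sliceLabel time-slice tag ("current", "2050", ...).
#' @return a \linkS4class{GridStack}
#' @export
alignStack <- function(grids, sliceLabel = "current") {
  if (is(grids, "ClimateGrid")) grids <- list(grids)
  if (length(grids) < 1L) stop("need at least one grid")
  ref <- grids[[1L]]
  for (g in grids) {
    if (!identical(dim(g@values), dim(ref@values)))
      stop("alignment error: shape mismatch (", paste(dim(g@values),
           collapse = "x"), " vs ", paste(dim(ref@values), collapse = "x"),
           ") for layer '", g@name, "'")
    if (!isTRUE(all.equal(g@cellSize, ref@cellSize)))
      stop("alignment error: cell_size mismatch (", g@cellSize, " vs ",
           ref@cellSize, ") for layer '", g@name, "'")
    if (!isTRUE(all.equal(g@origin, ref@origin, tolerance = 1e-9)))
      stop("alignment error: origin mismatch for layer '", g@name, "'")
  }
  shared_mask <- Reduce(`|`, lapply(grids, function(g) is.na(g@values)))
  layers <- lapply(grids, function(g) {
    g@values[shared_mask] <- NA_real_
    g
  })
  nm <- names(grids)
  if (is.null(nm) || any(!nzchar(nm)))
    nm <- vapply(layers, function(g) g@name, character(1))
  names(layers) <- nm
  new("GridStack", layers = layers, sliceLabel = sliceLabel)
}

#' Latitude-aware cell area
#'
#' Spherical-Earth area of one grid cell in a given row:
#' \eqn{(c \pi/180 \cdot R)^2 \cos(\phi)} with \eqn{c} the cell size in
#' degrees, \eqn{R} = 6371 km, and \eqn{\phi} the latitude of the row
#' centre. Constant within a row.
#'
#' @param grid a \linkS4class{ClimateGrid}
#' @param rowIndex 1-based row index from the top.
#' @return cell area in km^2
#' @export
cellAreaKm2 <- function(grid, rowIndex) {
  nr <- nrow(grid@values)
  if (any(rowIndex < 1L | rowIndex > nr))
    stop("row index out of range 1..", nr)
  lat <- grid@origin[2] - (rowIndex - 0.5) * grid@cellSize
  (grid@cellSize * pi / 180 * EARTH_RADIUS_KM)^2 * cos(lat * pi / 180)
}

#' Per-cell area matrix
#'
#' @param grid a \linkS4class{ClimateGrid}
#' @param method \code{"geodesic"} (default, latitude-weighted spherical
#'   areas) or \code{"planar"} (every cell counts 1, i.e. pixel counting).
#' @return matrix of cell areas, same shape as the grid
#' @export
cellAreas <- function(grid, method = c("geodesic", "planar")) {
  method <- match.arg(method)
  d <- dim(grid@values)
  if (method == "planar") return(matrix(1, d[1], d[2]))
  matrix(rep(cellAreaKm2(grid, seq_len(d[1])), d[2]), d[1], d[2])
}

# (lon, lat) of every cell centre, row-major from the upper-left.
cellCenters <- function(grid) {
  d <- dim(grid@values)
  lon <- grid@origin[1] + (seq_len(d[2]) - 0.5) * grid@cellSize
  lat <- grid@origin[2] - (seq_len(d[1]) - 0.5) * grid@cellSize
  cbind(lon = rep(lon, each = d[1]), lat = rep(lat, times = d[2]))
}

# Map points (lon, lat) to linear cell indices (column-major, matching R
# matrix indexing); points under half-open cell intervals [edge, edge+size).
# Returns NA for points off the grid.
pointToCell <- function(grid, pts) {
  pts <- matrix(as.numeric(pts), ncol = 2)
  d <- dim(grid@values)
  col <- floor((pts[, 1] - grid@origin[1]) / grid@cellSize) + 1L
  row <- floor((grid@origin[2] - pts[, 2]) / grid@cellSize) + 1L
  # a point exactly on the top/left boundary belongs to the first cell;
  # the bottom/right edge is outside under the half-open convention, except
  # we accept lat == southern edge into the last row for closed-domain use
  ok <- col >= 1L & col <= d[2] & row >= 1L & row <= d[1]
  idx <- ifelse(ok, (col - 1L) * d[1] + row, NA_integer_)
  as.integer(idx)
}

# Values of all layers at given linear cell indices (default: all unmasked
# cells). Returns a matrix cells x variables plus the cell indices used.
stackValues <- function(stack, cells = NULL) {
  ref <- stack@layers[[1L]]
  if (is.null(cells)) cells <- which(!is.na(ref@values))
  m <- vapply(stack@layers, function(g) g@values[cells],
              numeric(length(cells)))
  if (length(cells) == 1L) m <- matrix(m, nrow = 1,
                                       dimnames = list(NULL, names(stack@layers)))
  attr(m, "cells") <- cells
  m
}
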