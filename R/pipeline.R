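# Orchestration: run the full analysis (thin -> select variables ->
# background -> candidate grid -> rank -> best-model fit -> threshold ->
# classify -> overlay -> summarize) from one declarative config, with a
# machine-readable reproducibility log.

pipelineDefaults <- function() {
  list(
    seed = 1L,
    thin_km = 10,
    thin_reps = 10,
    correlation_cutoff = 0.75,
    use_bias = TRUE,
    background_n = 50000L,
    bias_bandwidth_km = 200,
    folds = 10L,
    clamp = "fade",
    feature_sets = c("LQPH", "LQPTH", "LQH", "LQP", "LH", "LQPT"),
    rms = c(1.0, 1.5, 2.0),
    hinge_knots = 20L,
    threshold_knots = 20L,
    area_method = "geodesic",
    transform = "logistic",
    tol = 1e-6,
    maxit = 50000L
  )
}

#' Read a pipeline run configuration
#'
#' Loads a YAML config and fills unset keys with the package defaults
#' (10 km thinning, |r| cutoff 0.75, 50,000 background points, 10 folds,
#' feature sets LQPH/LQPTH/LQH/LQP/LH/LQPT with RM 1.0/1.5/2.0,
#' fade-by-clamping). Paths are resolved relative to the config file.
#'
#' @param path YAML file.
#' @return a named config list
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  defs <- pipelineDefaults()
  for (k in names(defs)) if (is.null(cfg[[k]])) cfg[[k]] <- defs[[k]]
  cfg$.base <- dirname(normalizePath(path))
  cfg
}

resolvePath <- function(cfg, p) {
  if (grepl("^/", p) || is.null(cfg$.base)) p else file.path(cfg$.base, p)
}

readSlice <- function(cfg, sliceName) {
  paths <- cfg$slices[[sliceName]]$rasters
  if (is.null(paths)) stop("stage read_rasters: no rasters for slice '",
                           sliceName, "'")
  grids <- lapply(paths, function(p) {
    p <- resolvePath(cfg, p)
    if (!file.exists(p)) stop("stage read_rasters: missing raster path: ", p)
    fmt <- if (grepl("\\.tiff?$", p)) "tiff" else "ascii"
    readGrid(p, fmt)
  })
  alignStack(grids, sliceName)
}

subsetStack <- function(stack, vars) {
  alignStack(stack@layers[vars], sliceLabel = stack@sliceLabel)
}

# covariates at occurrence points; points on masked cells are dropped
valuesAtPoints <- function(stack, pts) {
  ref <- stack@layers[[1L]]
  cells <- pointToCell(ref, pts)
  ok <- !is.na(cells) & !is.na(ref@values[cells])
  if (any(!ok))
    message(sum(!ok), " point(s) on masked or off-grid cells dropped")
  stackValues(stack, cells[ok])
}

#' Run the full risk-mapping pipeline
#'
#' Executes every stage for the pest and host species, then the overlay and
#' change statistics for each future slice, writing all artifacts (thinned
#' occurrences, correlation matrix, ranked candidate table, best-model
#' lambdas file, suitability and class rasters, risk maps, area and change
#' summaries) plus \code{run_log.json} with the seeds, thresholds, retained
#' variables and ranked table needed to re-execute the run. Identical
#' config + seeds give byte-identical CSV outputs.
#'
#' @param config a config list from \code{\link{readRunConfig}} (or a path
#'   to the YAML file).
#' @return the output directory, invisibly
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- readRunConfig(config)
  cfg <- config
  out_dir <- resolvePath(cfg, cfg$output_dir %||% "run_output")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- list(seed = cfg$seed, defaults = cfg[setdiff(names(pipelineDefaults()),
                                                      "tol")])
  slices <- names(cfg$slices)
  if (!"current" %in% slices)
    stop("stage read_rasters: config must define a 'current' slice")
  stacks <- lapply(slices, function(s) readSlice(cfg, s))
  names(stacks) <- slices

  # variable screening on the current slice
  corr <- correlationMatrix(stacks$current)
  writeCorrelationMatrix(corr, file.path(out_dir, "correlation_matrix.csv"))
  retained <- selectVariables(corr, bioPriority(corr$variables),
                              cutoff = cfg$correlation_cutoff)
  log$retained_variables <- retained
  stacks <- lapply(stacks, subsetStack, vars = retained)

  species_results <- list()
  for (sp in names(cfg$species)) {
    spc <- cfg$species[[sp]]
    occ <- loadOccurrences(resolvePath(cfg, spc$occurrences),
                           spc$name %||% sp)
    thinned <- thinOccurrences(occ, minDistKm = cfg$thin_km,
                               reps = cfg$thin_reps, seed = cfg$seed)
    writeOccurrences(thinned, file.path(out_dir,
                                        paste0(sp, "_thinned.csv")))
    bias <- if (isTRUE(cfg$use_bias))
      biasSurface(thinned, stacks$current@layers[[1L]],
                  bandwidthKm = cfg$bias_bandwidth_km)
    bg <- sampleBackground(stacks$current, bias, n = cfg$background_n,
                           seed = cfg$seed + 1L)
    pres_vals <- valuesAtPoints(stacks$current, thinned@points)
    bg_vals <- stackValues(stacks$current,
                           pointToCell(stacks$current@layers[[1L]],
                                       bg@points))
    folds <- makeFolds(nrow(pres_vals), k = cfg$folds, seed = cfg$seed + 2L)
    records <- runCandidateGrid(pres_vals, bg_vals,
                                featureSets = cfg$feature_sets,
                                rms = cfg$rms, folds = folds,
                                nHingeKnots = cfg$hinge_knots,
                                nThresholdKnots = cfg$threshold_knots,
                                tol = cfg$tol, maxit = cfg$maxit)
    ranked <- rankModels(records)
    writeEvaluationRecords(ranked, file.path(out_dir,
                                             paste0(sp, "_candidates.csv")))
    best <- ranked[1L, ]
    best_cfg <- makeFeatureConfig(best$features, best$rm,
                                  cfg$hinge_knots, cfg$threshold_knots)
    model <- fitMaxent(pres_vals, bg_vals, best_cfg,
                       transform = cfg$transform,
                       tol = cfg$tol, maxit = cfg$maxit)
    writeMaxentModel(model, file.path(out_dir, paste0(sp, "_model.lambdas")))
    sc <- attr(records, "scores")[[paste0(best$features, "_",
                                          format(best$rm))]]
    thr <- mtspsThreshold(sc$test, sc$background)
    suits <- lapply(stacks, function(st)
      predictSuitability(model, st, clamp = cfg$clamp))
    for (s in slices)
      writeGrid(suits[[s]], file.path(out_dir,
                                      paste0(sp, "_suitability_", s, ".asc")))
    classes <- lapply(suits, classifySuitability, threshold = thr)
    for (s in slices)
      writeGrid(classes[[s]], file.path(out_dir,
                                        paste0(sp, "_classes_", s, ".asc")))
    species_results[[sp]] <- list(model = model, threshold = thr,
                                  classes = classes,
                                  best = list(features = best$features,
                                              rm = best$rm),
                                  n_thinned = nOccurrences(thinned),
                                  n_raw = nOccurrences(occ))
    log$species[[sp]] <- list(best_features = best$features,
                              best_rm = best$rm, mtsps_threshold = thr,
                              n_raw = nOccurrences(occ),
                              n_thinned = nOccurrences(thinned))
  }

  pest <- cfg$overlay$pest %||% names(cfg$species)[1]
  host <- cfg$overlay$host %||% names(cfg$species)[2]
  summaries <- list()
  for (s in slices) {
    mask <- optimalMask(species_results[[host]]$classes[[s]])
    risk <- riskOverlay(species_results[[pest]]$classes[[s]], mask,
                        pestSlice = s, hostSlice = s)
    writeGrid(risk, file.path(out_dir, paste0("risk_", s, ".asc")))
    summaries[[s]] <- areaSummary(risk, method = cfg$area_method)
    summ <- cbind(slice = s, summaries[[s]])
    write.csv(summ, file.path(out_dir, paste0("area_summary_", s, ".csv")),
              row.names = FALSE)
  }
  for (s in setdiff(slices, "current")) {
    ch <- changeStats(summaries$current, summaries[[s]])
    write.csv(ch, file.path(out_dir, paste0("change_current_to_", s, ".csv")),
              row.names = FALSE)
    log$change[[s]] <- stats::setNames(as.list(ch$change_percent), ch$class)
  }
  log$area_summaries <- lapply(summaries, function(x)
    stats::setNames(as.list(x$percent_of_optimal), x$class))
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(out_dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a synthetic quick-start run
#'
#' Generates a small fully synthetic study (32 x 32 climate grid with four
#' layers, a warmed "2050" slice, 200 pest and 200 host presences drawn
#' from known truth surfaces) into \code{dir}, together with a pipeline
#' config using 3 candidate feature sets, 3 folds, and 2,000 background
#' points, and a truth manifest. Returns the config path, ready for
#' \code{\link{runPipeline}}.
#'
#' @param dir output directory.
#' @param seed RNG seed driving every generator draw.
#' @return path to the written config YAML
#' @export
syntheticQuickStart <- function(dir, seed = 1L) {
  current <- makeClimate(32L, 32L, nVars = 4L, seed = seed)
  future <- makeFuture(current, deltaTemp = 2, precipScale = 0.9,
                       sliceLabel = "2050")
  for (s in list(current, future)) {
    d <- file.path(dir, "rasters", s@sliceLabel)
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(s@layers))
      writeGrid(s@layers[[nm]], file.path(d, paste0(nm, ".asc")))
  }
  pest_truth <- makeTruthParams(tempOptimum = 23.8, tempSd = 3.8,
                                precipHalfsat = 1000, nPresence = 200L,
                                seed = seed)
  host_truth <- makeTruthParams(tempOptimum = 20.1, tempSd = 4.3,
                                precipHalfsat = 1500, nPresence = 200L,
                                seed = seed + 1L)
  occ_path <- file.path(dir, "occurrences.csv")
  rows <- list()
  for (sp in c("pest", "host")) {
    par <- if (sp == "pest") pest_truth else host_truth
    occ <- samplePresences(trueSuitability(current, par), n = par$nPresence,
                           seed = par$seed, species = sp)
    rows[[sp]] <- data.frame(species = sp,
                             longitude = occ@points[, 1],
                             latitude = occ@points[, 2])
    writeTruthManifest(par, file.path(dir, paste0(sp, "_truth.json")))
  }
  write.csv(do.call(rbind, rows), occ_path, row.names = FALSE)
  cfg <- list(
    output_dir = "output",
    seed = as.integer(seed),
    thin_km = 10, thin_reps = 5,
    background_n = 2000L,
    use_bias = FALSE,  # quick-start presences carry no sampling bias
    folds = 3L,
    feature_sets = c("LQ", "LQH", "LQP"),
    rms = 1.0,
    hinge_knots = 5L,
    bias_bandwidth_km = 200,
    species = list(
      pest = list(name = "pest", occurrences = "occurrences.csv"),
      host = list(name = "host", occurrences = "occurrences.csv")),
    overlay = list(pest = "pest", host = "host"),
    slices = list(
      current = list(rasters = as.list(file.path("rasters", "current",
        paste0(names(current@layers), ".asc")))),
      "2050" = list(rasters = as.list(file.path("rasters", "2050",
        paste0(names(current@layers), ".asc"))))))
  cfg_path <- file.path(dir, "config.yaml")
  yaml::write_yaml(cfg, cfg_path)
  cfg_path
}
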