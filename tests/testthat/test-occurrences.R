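# Occurrence ingestion, thinning, bias surface, background sampling.

write_occ_csv <- function(rows) {
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  write.csv(rows, path, row.names = FALSE)
  path
}

test_that("loadOccurrences deduplicates and rejects invalid rows", {
  path <- write_occ_csv(data.frame(
    species = rep("pest", 4),
    longitude = c(10, 10, 12, 13),
    latitude = c(5, 5, 95, 6)))
  expect_message(occ <- loadOccurrences(path, "pest"), "rejected")
  expect_equal(nOccurrences(occ), 2L)  # dup collapsed, lat 95 dropped
  expect_equal(speciesName(occ), "pest")

  path2 <- write_occ_csv(data.frame(species = "other",
                                    longitude = 1, latitude = 1))
  expect_warning(empty <- loadOccurrences(path2, "pest"), "no records")
  expect_equal(nOccurrences(empty), 0L)

  path3 <- write_occ_csv(data.frame(sp = "pest", x = 1, y = 2))
  expect_error(loadOccurrences(path3, "pest"), "missing column")
})

test_that("haversine distance matches the closed form", {
  expect_equal(haversineKm(c(10, 20), c(10, 20)), 0)
  # 1 degree of arc at the equator = R * pi/180
  expect_equal(haversineKm(c(0, 0), c(1, 0)), 6371 * pi / 180,
               tolerance = 1e-6)
  expect_equal(haversineKm(c(0, 0), c(1, 0)), 111.19, tolerance = 1e-3)
  # two 90-degree arcs are equal
  expect_equal(haversineKm(c(0, 0), c(0, 90)), haversineKm(c(0, 0), c(90, 0)),
               tolerance = 1e-9)
})

test_that("thinning enforces the strict pairwise distance contract", {
  one <- OccurrenceSet("s", cbind(0, 0))
  expect_equal(nOccurrences(thinOccurrences(one, 10)), 1L)

  # two points ~5 km apart -> exactly one survives
  two <- OccurrenceSet("s", rbind(c(0, 0), c(0, 0.045)))
  expect_equal(nOccurrences(thinOccurrences(two, 10, seed = 3)), 1L)

  # five collinear points at 0, 6, 12, 18, 24 km along a meridian: the
  # optimum keeps {0, 12, 24}
  km_per_deg <- 6371 * pi / 180
  lat <- c(0, 6, 12, 18, 24) / km_per_deg
  five <- OccurrenceSet("s", cbind(0, lat))
  thinned <- thinOccurrences(five, 10, reps = 20, seed = 1)
  expect_equal(nOccurrences(thinned), 3L)
  expect_equal(sort(occPoints(thinned)[, 2]), lat[c(1, 3, 5)],
               tolerance = 1e-12)
})

test_that("thinning output is always valid and near brute-force optimal", {
  for (s in 1:25) {
    set.seed(s + 500)
    n <- sample(5:12, 1)
    pts <- cbind(runif(n, 0, 0.5), runif(n, 0, 0.5))  # ~0-55 km extent
    occ <- OccurrenceSet("s", pts)
    th <- thinOccurrences(occ, 10, reps = 10, seed = s)
    kept <- occPoints(th)
    if (nrow(kept) > 1) {
      d <- oracle_dist_matrix(kept)
      expect_gt(min(d[upper.tri(d)]), 10)
    }
    opt <- brute_force_thin_size(pts, 10)
    expect_gte(nrow(kept), opt - 1L)
  }
})

test_that("thinning is deterministic under a fixed seed", {
  set.seed(9)
  occ <- OccurrenceSet("s", cbind(runif(30, 0, 1), runif(30, 0, 1)))
  a <- thinOccurrences(occ, 20, reps = 5, seed = 11)
  b <- thinOccurrences(occ, 20, reps = 5, seed = 11)
  expect_identical(occPoints(a), occPoints(b))
})

test_that("bias surface is a normalized, positive, distance-decaying density", {
  tmpl <- flat_grid(9, 9, 1, origin = c(0, 9), cell = 1)
  occ <- OccurrenceSet("s", cbind(4.5, 4.5))  # centre cell
  b <- biasSurface(occ, tmpl, bandwidthKm = 150)
  v <- gridValues(b)
  expect_equal(sum(v), 1, tolerance = 1e-9)
  expect_true(all(v > 0))
  expect_equal(which.max(v), pestrisk:::pointToCell(tmpl, c(4.5, 4.5)))
  # density decays with distance from the occurrence cell
  centers <- pestrisk:::cellCenters(tmpl)
  d <- haversineKm(c(4.5, 4.5), centers)
  expect_lt(suppressWarnings(cor(d, as.vector(v), method = "spearman")), -0.99)
})

test_that("two mirrored occurrences give a mirror-symmetric bias field", {
  tmpl <- flat_grid(7, 9, 1, origin = c(0, 7), cell = 1)
  occ <- OccurrenceSet("s", rbind(c(2.5, 3.5), c(6.5, 3.5)))
  v <- gridValues(biasSurface(occ, tmpl, bandwidthKm = 200))
  expect_equal(v, v[, ncol(v):1], tolerance = 1e-9)
})

test_that("background sampling respects mask, bias, and seed", {
  m <- matrix(1, 10, 10)
  m[1:5, 1:5] <- NA
  g <- ClimateGrid("t", m, origin = c(0, 10), cellSize = 1)
  st <- alignStack(list(g))
  bg <- sampleBackground(st, NULL, n = 2000, seed = 5)
  expect_equal(nrow(occPoints(bg)), 2000L)
  cells <- pestrisk:::pointToCell(g, occPoints(bg))
  expect_true(all(!is.na(gridValues(g)[cells])))  # masked never sampled
  bg2 <- sampleBackground(st, NULL, n = 2000, seed = 5)
  expect_identical(occPoints(bg), occPoints(bg2))

  # uniform bias over 100 unmasked cells: chi-square GoF below the 0.999
  # quantile
  g2 <- flat_grid(10, 10, 1, origin = c(0, 10))
  st2 <- alignStack(list(g2))
  bgu <- sampleBackground(st2, NULL, n = 1000, seed = 7)
  counts <- tabulate(pestrisk:::pointToCell(g2, occPoints(bgu)), 100)
  chisq <- sum((counts - 10)^2 / 10)
  expect_lt(chisq, qchisq(0.999, df = 99))

  g_all_masked <- ClimateGrid("t", matrix(NA_real_, 3, 3) + NA,
                              origin = c(0, 3), cellSize = 1)
  expect_error(sampleBackground(alignStack(list(g_all_masked)), NULL, 10),
               "masked")
})
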