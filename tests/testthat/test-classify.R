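# MTSPS thresholding, classification, overlay, areas, change statistics.

test_that("MTSPS matches the hand example and the separable tie rule", {
  expect_equal(mtspsThreshold(c(0.8, 0.7, 0.3), c(0.2, 0.4, 0.6)), 0.65)
  # separable scores: smallest midpoint in the gap
  t <- mtspsThreshold(c(0.8, 0.9), c(0.1, 0.2, 0.4))
  expect_equal(t, (0.4 + 0.8) / 2)
  expect_error(mtspsThreshold(rep(0.5, 4), rep(0.5, 3)), "degenerate")
})

test_that("MTSPS equals exhaustive threshold search on random instances", {
  set.seed(61)
  for (i in 1:100) {
    pres <- round(runif(sample(3:20, 1)), 2)
    bg <- round(runif(sample(3:40, 1)), 2)
    if (length(unique(c(pres, bg))) < 2) next
    expect_equal(mtspsThreshold(pres, bg), exhaustive_mtsps(pres, bg),
                 tolerance = 1e-12)
  }
})

suit_grid <- function(vals) {
  m <- matrix(vals, 1)
  new("SuitabilityGrid", name = "s", values = m, origin = c(0, 1),
      cellSize = 1, units = "suitability", transform = "logistic",
      clampCounts = matrix(0L, 1, length(vals)))
}

test_that("four-class split uses equal-width bins above the threshold", {
  s <- suit_grid(c(0.1, 0.4, 0.5, 0.75, 0.85, 1.0))
  cg <- classifySuitability(s, 0.4)
  # bins: [0.4, 0.6) low, [0.6, 0.8) medium, [0.8, 1] high
  expect_equal(as.vector(gridValues(cg)), c(0, 1, 1, 2, 3, 3))
  expect_equal(cg@classBounds, c(0.6, 0.8))
  expect_error(classifySuitability(s, 1.2), "threshold")
})

test_that("classification is monotone in suitability", {
  set.seed(71)
  v <- sort(runif(50))
  cls <- gridValues(classifySuitability(suit_grid(v), 0.3))
  expect_true(all(diff(as.vector(cls)) >= 0))
})

test_that("optimal mask and overlay follow the class rules", {
  host <- classifySuitability(suit_grid(c(0.1, 0.5, 0.7, 0.9)), 0.4)
  mask <- optimalMask(host)                    # classes 0,1,2,3
  expect_equal(as.vector(mask), c(FALSE, FALSE, TRUE, TRUE))

  pest <- classifySuitability(suit_grid(c(0.9, 0.9, 0.1, 0.9)), 0.4)
  risk <- riskOverlay(pest, mask)
  expect_equal(as.vector(gridValues(risk)),
               c(riskLevels[["outside_optimal"]],
                 riskLevels[["outside_optimal"]],
                 riskLevels[["no_risk"]],
                 riskLevels[["high_risk"]]))
  expect_error(riskOverlay(pest, mask[, 1:2, drop = FALSE]), "misaligned")
})

test_that("overlay is cellwise: permuting cells permutes the output", {
  set.seed(81)
  v <- runif(30)
  perm <- sample(30)
  pest1 <- classifySuitability(suit_grid(v), 0.3)
  pest2 <- classifySuitability(suit_grid(v[perm]), 0.3)
  hostm <- rep(c(TRUE, FALSE), 15)
  r1 <- gridValues(riskOverlay(pest1, matrix(hostm, 1)))
  r2 <- gridValues(riskOverlay(pest2, matrix(hostm[perm], 1)))
  expect_equal(as.vector(r2), as.vector(r1)[perm])
})

test_that("area summary mirrors the toy high-risk percentage", {
  # 25 cells near the equator: 20 optimal, of which 1 high risk; 5 outside
  codes <- c(rep(1, 13), rep(2, 4), rep(3, 2), 4, rep(0, 5))
  rm_ <- new("RiskMap", name = "r", values = matrix(codes, 5, 5),
             origin = c(0, 0.05), cellSize = 0.01, units = "risk",
             pestSlice = "current", hostSlice = "current")
  summ <- areaSummary(rm_, "planar")
  expect_equal(summ$percent_of_optimal[summ$class == "high_risk"], 5)
  expect_equal(sum(summ$percent_of_optimal), 100, tolerance = 0.01)
  # geodesic areas at near-equator cells give the same percentages
  summ_g <- areaSummary(rm_, "geodesic")
  expect_equal(summ_g$percent_of_optimal, summ$percent_of_optimal,
               tolerance = 0.01)
})

test_that("change statistics report extension and shortening percentages", {
  cur <- data.frame(class = c("high_risk", "low_risk", "no_risk"),
                    area_km2 = c(100, 100, 0))
  fut <- data.frame(class = c("high_risk", "low_risk", "no_risk"),
                    area_km2 = c(280, 33, 10))
  ch <- changeStats(cur, fut)
  expect_equal(ch$change_percent[ch$class == "high_risk"], 180)
  expect_equal(ch$change_percent[ch$class == "low_risk"], -67)
  expect_equal(ch$direction[ch$class == "high_risk"], "extension")
  expect_equal(ch$direction[ch$class == "low_risk"], "shortening")
  expect_true(is.na(ch$change_percent[ch$class == "no_risk"]))
  expect_equal(ch$direction[ch$class == "no_risk"], "undefined")
  ch0 <- changeStats(cur[1:2, ], cur[1:2, ])
  expect_true(all(ch0$change_percent == 0))
})

test_that("a noiseless truth yields the analytically derived risk map", {
  # suitability is a known function of cell index; threshold fixed at 0.5
  v <- seq(0.02, 1, length.out = 50)
  pest <- classifySuitability(suit_grid(v), 0.5)
  host <- classifySuitability(suit_grid(rev(v)), 0.5)
  risk <- riskOverlay(pest, optimalMask(host))
  # analytic derivation, cell by cell
  cls <- function(x) ifelse(x < 0.5, 0, pmin(floor((x - 0.5) / (1 / 6)) + 1, 3))
  expected <- ifelse(cls(rev(v)) >= 2, cls(v) + 1, 0)
  expect_equal(as.vector(gridValues(risk)), expected)
})
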