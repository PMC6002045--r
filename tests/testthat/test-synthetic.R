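# The synthetic climate/truth/presence generator.

test_that("climate generation is seeded and respects layer contracts", {
  a <- makeClimate(12, 15, 4, seed = 5)
  b <- makeClimate(12, 15, 4, seed = 5)
  expect_equal(lapply(a@layers, gridValues), lapply(b@layers, gridValues))
  c_ <- makeClimate(12, 15, 4, seed = 6)
  expect_false(identical(gridValues(getLayer(a, "bio1")),
                         gridValues(getLayer(c_, "bio1"))))
  temp <- gridValues(getLayer(a, "bio1"))
  expect_gte(min(temp), -10)
  expect_lte(max(temp), 40)
  expect_gte(min(gridValues(getLayer(a, "bio12"))), 0)
  expect_equal(layerNames(a), c("bio1", "bio12", "noise1", "noise2"))
})

test_that("future perturbation shifts temperature and scales precipitation", {
  st <- makeClimate(12, 12, 3, seed = 7)
  same <- makeFuture(st, deltaTemp = 0, precipScale = 1)
  expect_equal(lapply(same@layers, gridValues), lapply(st@layers, gridValues))
  warm <- makeFuture(st, deltaTemp = 2, precipScale = 0.5, sliceLabel = "2050")
  expect_equal(mean(gridValues(getLayer(warm, "bio1"))),
               mean(gridValues(getLayer(st, "bio1"))) + 2, tolerance = 1e-12)
  expect_equal(sum(gridValues(getLayer(warm, "bio12"))),
               sum(gridValues(getLayer(st, "bio12"))) / 2, tolerance = 1e-9)
  expect_equal(gridValues(getLayer(warm, "noise1")),
               gridValues(getLayer(st, "noise1")))
  expect_equal(sliceLabel(warm), "2050")
})

test_that("the truth surface follows its stated closed form", {
  tg <- ClimateGrid("bio1", matrix(c(23.8, 23.8 + 3.8, 23.8 - 3.8, 10), 2),
                    c(0, 2), 1, "degC")
  pg <- ClimateGrid("bio12", matrix(c(0, 0, 0, 1000), 2), c(0, 2), 1, "mm")
  st <- alignStack(list(tg, pg))
  s <- gridValues(trueSuitability(st, makeTruthParams(
    tempOptimum = 23.8, tempSd = 3.8, precipHalfsat = 1000)))
  expect_equal(s[1, 1], 1)                       # optimum, zero rain
  expect_equal(s[2, 1], exp(-0.5), tolerance = 1e-12)
  expect_equal(s[1, 2], exp(-0.5), tolerance = 1e-12)
  # halving precipitation term at P = halfsat
  expect_equal(s[2, 2], exp(-(10 - 23.8)^2 / (2 * 3.8^2)) * 0.5,
               tolerance = 1e-12)
  # strictly decreasing in P at fixed T
  pg2 <- ClimateGrid("bio12", matrix(c(0, 100, 200, 300), 2), c(0, 2), 1, "mm")
  tg2 <- ClimateGrid("bio1", matrix(20, 2, 2), c(0, 2), 1, "degC")
  s2 <- gridValues(trueSuitability(alignStack(list(tg2, pg2))))
  expect_true(all(diff(as.vector(s2)) < 0))
})

test_that("presence sampling follows the truth weights and the seed", {
  st <- makeClimate(10, 10, 2, seed = 11)
  truth <- trueSuitability(st)
  v <- gridValues(truth) * 0
  v[5, 5] <- 1
  spike <- new("SuitabilityGrid", name = "t", values = v,
               origin = truth@origin, cellSize = truth@cellSize,
               units = "suitability", transform = "logistic",
               clampCounts = matrix(0L, 10, 10))
  occ <- samplePresences(spike, n = 25, seed = 12)
  cells <- pestrisk:::pointToCell(getLayer(st, "bio1"), occPoints(occ))
  expect_true(all(cells == pestrisk:::pointToCell(
    getLayer(st, "bio1"), pestrisk:::cellCenters(spike)[(5 - 1) * 10 + 5, ,
                                                        drop = FALSE])))
  occ2 <- samplePresences(spike, n = 25, seed = 12)
  expect_identical(occPoints(occ), occPoints(occ2))

  # uniform truth: per-cell counts consistent with a uniform multinomial
  vu <- gridValues(truth) * 0 + 1
  unif <- new("SuitabilityGrid", name = "t", values = vu,
              origin = truth@origin, cellSize = truth@cellSize,
              units = "suitability", transform = "logistic",
              clampCounts = matrix(0L, 10, 10))
  occu <- samplePresences(unif, n = 10000, seed = 13)
  counts <- tabulate(pestrisk:::pointToCell(getLayer(st, "bio1"),
                                            occPoints(occu)), 100)
  chisq <- sum((counts - 100)^2 / 100)
  expect_lt(chisq, qchisq(0.999, df = 99))
})

test_that("warming raises mean suitability for a warm-adapted niche", {
  # the 23.8 degC optimum sits far above the domain mean temperature, so a
  # +2 degC shift moves most cells toward the optimum
  for (s in 1:10) {
    st <- makeClimate(40, 40, 2, seed = 900 + s)
    par <- makeTruthParams(tempOptimum = 23.8)
    cur <- mean(gridValues(trueSuitability(st, par)))
    fut <- mean(gridValues(trueSuitability(makeFuture(st, 2), par)))
    expect_gt(fut, cur)
  }
  # and a fitted model's projection moves the same way in most seeds
  hits <- 0L
  for (s in 1:5) {
    st <- makeClimate(30, 30, 2, seed = 950 + s)
    truth <- trueSuitability(st, makeTruthParams(tempOptimum = 23.8))
    occ <- samplePresences(truth, n = 300, seed = 960 + s)
    bg <- sampleBackground(st, NULL, n = 1000, seed = 970 + s)
    pv <- pestrisk:::valuesAtPoints(st, occPoints(occ))
    bv <- pestrisk:::stackValues(
      st, pestrisk:::pointToCell(getLayer(st, "bio1"), occPoints(bg)))
    m <- fitMaxent(pv, bv, makeFeatureConfig("LQ", 1.0))
    cur <- mean(gridValues(predictSuitability(m, st)), na.rm = TRUE)
    fut <- mean(gridValues(predictSuitability(m, makeFuture(st, 2))),
                na.rm = TRUE)
    if (fut > cur) hits <- hits + 1L
  }
  expect_gte(hits, 4L)
})
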