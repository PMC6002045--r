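# The penalized maximum-entropy fit: closed forms, oracle equivalence,
# invariances, prediction contracts, importance, jackknife, response curves.

test_that("single binary feature recovers the moment-condition closed form", {
  presX <- matrix(c(rep(1, 8), rep(0, 2)), ncol = 1)
  bgX <- matrix(c(rep(1, 50), rep(0, 50)), ncol = 1)
  fit <- maxentSolve(presX, bgX, betas = 0)
  # 50 e^l / (50 e^l + 50) = 0.8  =>  l = ln 4
  expect_equal(fit$lambda, log(4), tolerance = 1e-6)
  # raw probabilities over background sum to 1
  q <- exp(as.vector(bgX %*% fit$lambda) - fit$logZ)
  expect_equal(sum(q), 1, tolerance = 1e-9)
})

test_that("coefficients match an independent L-BFGS-B maximizer", {
  for (s in 1:8) {
    inst <- random_maxent_instance(s)
    fit <- maxentSolve(inst$presX, inst$bgX, inst$betas)
    oracle <- lbfgs_maxent(inst$presX, inst$bgX, inst$betas)
    expect_lt(max(abs(fit$lambda - oracle)), 1e-3)
  }
})

test_that("the penalized objective is non-decreasing across passes", {
  for (s in 1:5) {
    inst <- random_maxent_instance(s + 100)
    fit <- maxentSolve(inst$presX, inst$bgX, inst$betas)
    expect_true(all(diff(fit$trace) >= -1e-10))
  }
})

test_that("increasing RM never increases the number of active coefficients", {
  sep <- separable_instance(40, 150, seed = 5)
  set.seed(6)
  pres <- cbind(sep$pres, z = rnorm(nrow(sep$pres)))
  bg <- cbind(sep$bg, z = rnorm(nrow(sep$bg)))
  nnz <- vapply(c(0.5, 1, 2, 4), function(rm) {
    m <- fitMaxent(pres, bg, makeFeatureConfig("LQ", rm))
    sum(lambdas(m) != 0)
  }, numeric(1))
  expect_true(all(diff(nnz) <= 0))
})

test_that("a pure-noise covariate is shrunk and scores near-random AUC", {
  set.seed(8)
  bg <- cbind(noise = rnorm(300))
  pres <- cbind(noise = rnorm(80))
  m <- fitMaxent(pres, bg, makeFeatureConfig("LQ", 1.0))
  expect_lt(max(abs(lambdas(m))), 0.5)
  auc <- aucScore(scoreValues(m, pres), scoreValues(m, bg))
  expect_lt(abs(auc - 0.5), 0.1)
})

test_that("fitted suitability is invariant under affine covariate rescaling", {
  sep <- separable_instance(30, 120, seed = 9)
  m1 <- fitMaxent(sep$pres, sep$bg, makeFeatureConfig("LQ", 1.0))
  pres2 <- sep$pres; bg2 <- sep$bg
  pres2[, "x"] <- 10 * pres2[, "x"] + 5
  bg2[, "x"] <- 10 * bg2[, "x"] + 5
  m2 <- fitMaxent(pres2, bg2, makeFeatureConfig("LQ", 1.0))
  expect_equal(scoreValues(m1, sep$bg), scoreValues(m2, bg2),
               tolerance = 1e-6)
})

test_that("projection contracts: range, normalization, clamp-mode agreement", {
  st <- makeClimate(20, 20, 3, seed = 11)
  truth <- trueSuitability(st, makeTruthParams(nPresence = 100))
  occ <- samplePresences(truth, n = 100, seed = 12)
  bg <- sampleBackground(st, NULL, n = 500, seed = 13)
  pv <- pestrisk:::valuesAtPoints(st, occPoints(occ))
  bv <- pestrisk:::stackValues(
    st, pestrisk:::pointToCell(getLayer(st, "bio1"), occPoints(bg)))
  m <- fitMaxent(pv, bv, makeFeatureConfig("LQ", 1.0))

  suit <- predictSuitability(m, st, clamp = "none")
  v <- gridValues(suit)
  expect_true(all(v[!is.na(v)] >= 0 & v[!is.na(v)] <= 1))

  # raw scores over the training background sum to 1
  raw_bg <- scoreValues(m, bv, transform = "raw", clamp = FALSE)
  expect_equal(sum(raw_bg), 1, tolerance = 1e-6)

  # cells inside the training envelope are identical under all three
  # clamp modes (cells never drawn into training can fall outside it)
  p_none <- predictSuitability(m, st, clamp = "none")
  p_clamp <- predictSuitability(m, st, clamp = "clamp")
  p_fade <- predictSuitability(m, st, clamp = "fade")
  inside <- p_none@clampCounts == 0 & !is.na(gridValues(p_none))
  expect_gt(sum(inside, na.rm = TRUE), 300)
  expect_equal(gridValues(p_none)[inside], gridValues(p_clamp)[inside],
               tolerance = 1e-12)
  expect_equal(gridValues(p_none)[inside], gridValues(p_fade)[inside],
               tolerance = 1e-12)

  # a warmed slice pushes cells outside the envelope; fade only lowers
  fut <- makeFuture(st, deltaTemp = 10, sliceLabel = "hot")
  f_clamp <- gridValues(predictSuitability(m, fut, clamp = "clamp"))
  f_fade <- gridValues(predictSuitability(m, fut, clamp = "fade"))
  expect_true(all(f_fade[!is.na(f_fade)] <= f_clamp[!is.na(f_clamp)] + 1e-12))
  expect_error(predictSuitability(m, alignStack(list(getLayer(st, "bio12"))),
                                  clamp = "none"), "lacks")
})

test_that("importance metrics identify the constructed signal variable", {
  st <- makeClimate(25, 25, 4, seed = 21)
  truth <- trueSuitability(st, makeTruthParams(nPresence = 200))
  occ <- samplePresences(truth, n = 200, seed = 22)
  bg <- sampleBackground(st, NULL, n = 800, seed = 23)
  pv <- pestrisk:::valuesAtPoints(st, occPoints(occ))
  bv <- pestrisk:::stackValues(
    st, pestrisk:::pointToCell(getLayer(st, "bio1"), occPoints(bg)))
  m <- fitMaxent(pv, bv, makeFeatureConfig("LQ", 1.0))
  imp <- variableImportance(m, pv, bv, nPerm = 3, seed = 31)
  expect_equal(sum(imp$percent_contribution), 100, tolerance = 0.1)
  expect_equal(sum(imp$permutation_importance), 100, tolerance = 0.1)
  noise_imp <- imp$permutation_importance[grepl("noise", imp$variable)]
  bio1_imp <- imp$permutation_importance[imp$variable == "bio1"]
  expect_true(all(bio1_imp > noise_imp))
})

test_that("single-variable model concentrates both importance measures", {
  sep <- separable_instance(25, 100, seed = 41)
  m <- fitMaxent(sep$pres[, "x", drop = FALSE], sep$bg[, "x", drop = FALSE],
                 makeFeatureConfig("LQ", 1.0))
  imp <- variableImportance(m, sep$pres[, "x", drop = FALSE],
                            sep$bg[, "x", drop = FALSE], nPerm = 2)
  expect_equal(imp$percent_contribution, 100, tolerance = 1e-9)
  expect_equal(imp$permutation_importance, 100, tolerance = 1e-9)
})

test_that("jackknife reports 2k+1 fits with redundancy and nesting behaviour", {
  set.seed(51)
  n_bg <- 150; n_pr <- 40
  bg <- cbind(a = runif(n_bg), b = runif(n_bg))
  w <- exp(3 * bg[, "a"])
  pres <- bg[sample(n_bg, n_pr, replace = TRUE, prob = w), ]
  # duplicate variable: excluding one copy barely changes the gain
  bg_dup <- cbind(bg, a2 = bg[, "a"])
  pres_dup <- cbind(pres, a2 = pres[, "a"])
  jk <- jackknifeVariables(pres_dup, bg_dup, makeFeatureConfig("L", 1.0))
  expect_equal(nrow(jk$table), 3L)  # 3 with-only + 3 without + full = 7 fits
  gw <- jk$table$gain_without[jk$table$variable == "a"]
  expect_lt(abs(gw - jk$full_gain), 1e-3)
  # nested-model monotonicity under the shared regularization path
  expect_true(all(jk$table$gain_with_only <= jk$full_gain + 1e-6))
  expect_true(all(jk$table$auc_with_only >= 0 & jk$table$auc_with_only <= 1))
})

test_that("response curves are bounded, peak near the truth, and flat for
           unused variables", {
  st <- makeClimate(30, 30, 3, seed = 61)
  truth <- trueSuitability(st, makeTruthParams(nPresence = 300))
  occ <- samplePresences(truth, n = 300, seed = 62)
  bg <- sampleBackground(st, NULL, n = 1000, seed = 63)
  pv <- pestrisk:::valuesAtPoints(st, occPoints(occ))
  bv <- pestrisk:::stackValues(
    st, pestrisk:::pointToCell(getLayer(st, "bio1"), occPoints(bg)))
  m <- fitMaxent(pv, bv, makeFeatureConfig("LQ", 1.0))
  rc <- responseCurve(m, "bio1", 200)
  expect_true(all(rc$suitability >= 0 & rc$suitability <= 1))
  expect_lt(abs(rc$value[which.max(rc$suitability)] - 23.8), 2.5)
  expect_error(responseCurve(m, "bio99"), "does not use")

  # a variable whose coefficients are all zero yields a flat curve
  m0 <- m
  keep <- m0@featureTable$var1 == "bio1"
  m0@lambdas[!keep] <- 0
  rc0 <- responseCurve(m0, "noise1", 50)
  expect_lt(diff(range(rc0$suitability)), 1e-12)
})

test_that("model serialization writes a complete plain-text lambdas file", {
  sep <- separable_instance(20, 80, seed = 71)
  m <- fitMaxent(sep$pres, sep$bg, makeFeatureConfig("LQ", 1.5))
  path <- withr::local_tempfile(fileext = ".lambdas")
  writeMaxentModel(m, path)
  txt <- readLines(path)
  expect_true(any(grepl("^transform=logistic", txt)))
  expect_true(any(grepl("^rm=1.5", txt)))
  expect_equal(sum(grepl("\t", txt)) - 2L,  # minus two header rows
               length(m@lambdas) + nrow(m@varBounds))
})
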