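test_that("median-effect fit recovers exact parameters from noiseless data", {
  fit <- fitMedianEffect(c(0.25, 0.5, 1, 2, 4), c(0.2, 1/3, 0.5, 2/3, 0.8))
  expect_equal(slope(fit), 1, tolerance = 1e-10)
  expect_equal(dm(fit), 1, tolerance = 1e-10)
  expect_equal(fit@r, 1, tolerance = 1e-10)
  expect_identical(fitStatus(fit), "ok")

  # three collinear points on the linearized scale: slope 2, Dm 1
  fit2 <- fitMedianEffect(c(0.5, 1, 2), c(0.2, 0.5, 0.8))
  expect_equal(slope(fit2), 2, tolerance = 1e-10)
  expect_equal(dm(fit2), 1, tolerance = 1e-10)

  # random-parameter round trips through the noiseless simulator
  set.seed(11)
  for (i in 1:20) {
    m <- runif(1, 0.5, 3); Dm <- exp(runif(1, -2, 2))
    doses <- Dm * 2^seq(-2, 2)
    tab <- simulateSingleAgent(m, Dm, doses, simConfig(noiseSd = 0))
    refit <- fitMedianEffect(tab$dose, tab$fa)
    expect_equal(slope(refit), m, tolerance = 1e-6)
    expect_equal(dm(refit), Dm, tolerance = 1e-6)
  }
})

test_that("degenerate and non-monotone curves are handled explicitly", {
  expect_error(fitMedianEffect(c(1, 2, 4), rep(0.5, 3)), "zero variance")
  expect_error(fitMedianEffect(c(1, 2), c(0.3, 0.6)), "at least 3")
  expect_error(fitMedianEffect(c(-1, 1, 2), c(0.2, 0.5, 0.8)), "positive")
  expect_warning(
    fit <- fitMedianEffect(c(0.5, 1, 2), c(0.8, 0.5, 0.2)),
    "non-monotone")
  expect_identical(fitStatus(fit), "non-monotone")
  expect_error(doseForEffect(fit, 0.5), "status")
})

test_that("dose_for_effect inverts the median-effect equation", {
  expect_equal(doseForEffect(meFit(1, 1), 0.5), 1)
  expect_equal(doseForEffect(meFit(1, 2), 0.8), 8)   # 2 * (0.8/0.2)^1
  expect_equal(doseForEffect(meFit(2, 1), 0.8), 2)   # (4)^(1/2)
  expect_error(doseForEffect(meFit(1, 1), 1), "inside")
  expect_error(doseForEffect(meFit(1, 1), 0), "inside")
})

test_that("combination index satisfies sham identity, worked value, and dose linearity", {
  f11 <- meFit(1, 1)
  expect_equal(combinationIndex(f11, f11, 0.5, 0.5, 0.5), 1)
  # DxA = 2, DxB = 4 at fa = 2/3 -> CI = 0.5/2 + 1/4 = 0.5
  expect_equal(combinationIndex(f11, meFit(1, 2), 0.5, 1.0, 2/3), 0.5)
  # doubling both doses at fixed fa doubles CI
  set.seed(3)
  for (i in 1:10) {
    fa <- runif(1, 0.05, 0.95)
    fA <- meFit(runif(1, 0.5, 3), exp(runif(1, -1, 1)))
    fB <- meFit(runif(1, 0.5, 3), exp(runif(1, -1, 1)))
    dA <- runif(1, 0.1, 2); dB <- runif(1, 0.1, 2)
    expect_equal(combinationIndex(fA, fB, 2 * dA, 2 * dB, fa),
                 2 * combinationIndex(fA, fB, dA, dB, fa))
  }
})

test_that("sham combinations give CI = 1 at the fa produced by the total dose", {
  set.seed(7)
  for (i in 1:25) {
    fit <- meFit(runif(1, 0.5, 3), exp(runif(1, -2, 2)))
    D <- exp(runif(1, -2, 2))
    x <- runif(1, 0.01, 0.99) * D
    fa <- oracle_fa(D, fit@m, fit@Dm)
    expect_equal(combinationIndex(fit, fit, x, D - x, fa), 1,
                 tolerance = 1e-9)
  }
})

test_that("classify_ci is a step function with breakpoints at 0.83 and 1.2", {
  expect_identical(classifyCI(0.5), "synergism")
  expect_identical(classifyCI(0.83), "additive")   # boundary is additive
  expect_identical(classifyCI(1.2), "additive")    # boundary is additive
  expect_identical(classifyCI(1.5), "antagonism")
  expect_error(classifyCI(0), "positive")
  # exactly two breakpoints over a fine grid
  grid <- seq(0.01, 2, by = 1e-3)
  cls <- classifyCI(grid)
  changes <- which(cls[-1] != cls[-length(cls)])
  expect_length(changes, 2L)
  expect_lt(abs(grid[changes[1] + 1] - 0.83), 2e-3)
  expect_lt(abs(grid[changes[2] + 1] - 1.2), 2e-3)
  # monotone step classes in order
  expect_identical(unique(cls), c("synergism", "additive", "antagonism"))
})

test_that("combination summaries take the median over valid points and classify it", {
  pts <- data.frame(dose_a = 1:5, dose_b = 1:5, fa = seq(0.2, 0.8, len = 5),
                    ci = c(0.4, 0.5, 0.6, 0.9, 1.1))
  rec <- summarizeCombination(pts, "OVCAR8", "olaparib", "epi01")
  expect_equal(medianCI(rec), 0.6)
  expect_identical(synergyClass(rec), "synergism")

  one <- summarizeCombination(
    data.frame(dose_a = 1, dose_b = 1, fa = 0.5, ci = 1.0))
  expect_equal(medianCI(one), 1.0)
  expect_identical(synergyClass(one), "additive")

  # mean summary available behind the flag
  recM <- summarizeCombination(pts, center = "mean")
  expect_equal(medianCI(recM), mean(pts$ci))

  # zero valid points -> summary-failure, not an error
  expect_warning(
    bad <- summarizeCombination(
      data.frame(dose_a = 1, dose_b = 1, fa = 0.5, ci = NA_real_)),
    "summary-failure")
  expect_identical(bad@status, "summary-failure")
})

test_that("scoreScreen runs the long-format pipeline and recovers a planted alpha", {
  fitA <- meFit(1.2, 1); fitB <- meFit(0.9, 2)
  design <- constantRatioDesign(fitA, fitB)
  cmb <- simulateCombination(fitA, fitB, design, alpha = 0.5,
                             simConfig(noiseSd = 0))
  sa <- rbind(
    cbind(simulateSingleAgent(1.2, 1, 2^seq(-2, 2), simConfig(noiseSd = 0),
                              drug = "A"), cell_line = "L1"),
    cbind(simulateSingleAgent(0.9, 2, 2 * 2^seq(-2, 2), simConfig(noiseSd = 0),
                              drug = "B"), cell_line = "L1"))
  combos <- data.frame(cell_line = "L1", drug_a = "A", dose_a = cmb$dose_a,
                       drug_b = "B", dose_b = cmb$dose_b, fa = cmb$fa)
  res <- scoreScreen(sa, combos)
  expect_equal(res$table$median_ci, 0.5, tolerance = 1e-6)
  expect_identical(res$table$synergy_class, "synergism")
})
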