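test_that("single-agent simulation matches the median-effect closed form", {
  tab <- simulateSingleAgent(1, 1, c(0.25, 0.5, 1, 2, 4),
                             simConfig(noiseSd = 0))
  expect_equal(tab$fa, c(0.2, 1/3, 0.5, 2/3, 0.8), tolerance = 1e-12)
  # fa at D = Dm is 0.5 for any slope
  for (m in c(0.5, 1, 2, 4))
    expect_equal(simulateSingleAgent(m, 1, c(0.5, 1, 2),
                                     simConfig(noiseSd = 0))$fa[2], 0.5)
  expect_error(simulateSingleAgent(1, -1, c(1, 2, 3), simConfig()),
               "'Dm'.*-1")
  expect_error(simulateSingleAgent(1, 1, c(-1, 2, 3), simConfig()),
               "'doses'.*-1")
  expect_error(simulateSingleAgent(1, 1, c(1, 1, 1), simConfig()),
               "distinct")
})

test_that("simulation is seed-reproducible and respects bounds", {
  cfg <- simConfig(seed = 42, noiseSd = 0.3, nReplicates = 4)
  a <- simulateSingleAgent(1.5, 3, 3 * 2^seq(-2, 2), cfg)
  b <- simulateSingleAgent(1.5, 3, 3 * 2^seq(-2, 2), cfg)
  expect_identical(a, b)
  expect_true(all(a$fa >= 0 & a$fa <= 1))
  c <- simulateSingleAgent(1.5, 3, 3 * 2^seq(-2, 2),
                           simConfig(seed = 43, noiseSd = 0.3, nReplicates = 4))
  expect_false(identical(a$fa, c$fa))

  # noisy refit still lands near the truth
  tab <- simulateSingleAgent(1.5, 3, 3 * 2^seq(-2, 2),
                             simConfig(seed = 5, noiseSd = 0.02, nReplicates = 3))
  agg <- aggregate(fa ~ dose, tab, mean)
  refit <- fitMedianEffect(agg$dose, agg$fa)
  expect_equal(slope(refit), 1.5, tolerance = 0.15)
  expect_equal(dm(refit), 3, tolerance = 0.15 * 3)
})

test_that("combination simulation plants the requested true CI", {
  f11 <- meFit(1, 1)
  # sham pair at total dose Dm with alpha = 1 sits exactly at fa = 0.5
  sham <- simulateCombination(f11, f11, cbind(0.5, 0.5), alpha = 1,
                              simConfig(noiseSd = 0))
  expect_equal(sham$fa, 0.5, tolerance = 1e-9)

  # analytic worked case: 0.5*(1-fa)/fa + 1.0*(1-fa)/(2 fa) = 0.5 -> fa = 2/3
  w <- simulateCombination(f11, meFit(1, 2), cbind(0.5, 1.0), alpha = 0.5,
                           simConfig(noiseSd = 0))
  expect_equal(w$fa, 2/3, tolerance = 1e-9)

  # noiseless CI recovery equals alpha at every point, for random pairs
  set.seed(19)
  for (alpha in c(0.5, 1, 1.5)) {
    fA <- meFit(runif(1, 0.8, 2), exp(runif(1, -1, 1)))
    fB <- meFit(runif(1, 0.8, 2), exp(runif(1, -1, 1)))
    d <- constantRatioDesign(fA, fB)
    sim <- simulateCombination(fA, fB, d, alpha, simConfig(noiseSd = 0))
    ci <- combinationIndex(fA, fB, sim$dose_a, sim$dose_b, sim$fa)
    expect_equal(ci, rep(alpha, 5), tolerance = 1e-6)
  }
  expect_error(simulateCombination(f11, f11, cbind(0.5, 0.5), alpha = -1,
                                   simConfig()), "'alpha'")
})

test_that("pan-cancer cohort simulation plants shifts, hazards, and exclusion cases", {
  sim <- simulatePanCancerCohort(
    c("g1", "g2"), nCancers = 4, delta = c(g1 = 2, g2 = 0), beta = 0,
    nTumor = 20, nNormal = c(10, 10, 10, 2), cfg = simConfig(seed = 2))
  cohort <- sim$cohort
  expect_s4_class(cohort, "ExpressionCohort")
  cd <- SummarizedExperiment::colData(cohort)
  expect_true(all(cd$sample_type %in% c("tumor", "normal")))
  # the short-normal cancer is excluded by the meta step
  meta <- deMeta(cohort)
  expect_identical(nrow(excludedUnits(meta)), 1L)
  expect_identical(meta@results$n_units, c(3L, 3L))
  expect_identical(unname(chosenDirection(meta)["g1"]), "up")
  # survival times positive, events binary
  expect_true(all(sim$survival$time > 0))
  expect_true(all(sim$survival$event %in% 0:1))
  # reproducibility
  sim2 <- simulatePanCancerCohort(
    c("g1", "g2"), nCancers = 4, delta = c(g1 = 2, g2 = 0), beta = 0,
    nTumor = 20, nNormal = c(10, 10, 10, 2), cfg = simConfig(seed = 2))
  expect_identical(SummarizedExperiment::assay(cohort),
                   SummarizedExperiment::assay(sim2$cohort))
  expect_identical(sim$survival, sim2$survival)
})

test_that("censoring rate of simulated survival is near its target", {
  sim <- simulatePanCancerCohort("g", nCancers = 5, beta = 0, nTumor = 5,
                                 nNormal = 3, nSurv = 400,
                                 censorRate = 0.3, cfg = simConfig(seed = 8))
  expect_equal(mean(sim$survival$event == 0), 0.3, tolerance = 0.05)
})

test_that("siRNA screen simulation plants drivers and validates input", {
  # noiseless: the single driver is the extreme point on both axes
  scr <- simulateSirnaScreen(paste0("g", 1:13), drivers = "g5",
                             cfg = simConfig(noiseSd = 0))
  inp <- scr$inputs
  fe <- log2(inp$expr_PRMT1i) - log2(inp$expr_control)
  expect_identical(inp$gene[which.min(fe)], "g5")
  expect_identical(inp$gene[which.min(inp$ic50_knockdown / inp$ic50_control)],
                   "g5")
  expect_error(simulateSirnaScreen("only1"), "at least 2")
  expect_error(simulateSirnaScreen(c("a", "b"), drivers = "zzz"), "subset")

  # identical genes (no driver, no noise) -> degenerate min-max is flagged
  flat <- simulateSirnaScreen(c("a", "b", "c"), cfg = simConfig(noiseSd = 0))
  expect_warning(impactScore(flat$inputs), "degenerate")
})
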