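test_that("one-sided DE test is antisymmetric with complementary sides", {
  set.seed(41)
  tumor <- rnorm(20, 1); normal <- rnorm(10)
  a <- oneSidedDeTest(tumor, normal)
  b <- oneSidedDeTest(normal, tumor)
  expect_equal(a$p_up, b$p_down, tolerance = 1e-12)
  expect_equal(a$p_down, b$p_up, tolerance = 1e-12)
  expect_equal(a$p_up + a$p_down, 1, tolerance = 1e-12)
  # planted +3 SD shift is overwhelmingly significant upward
  big <- oneSidedDeTest(rnorm(20, 3), rnorm(10))
  expect_lt(big$p_up, 1e-4)
  # symmetric null-ish data sits near 0.5
  sym <- oneSidedDeTest(c(-1, 0, 1), c(-1, 0, 1))
  expect_equal(sym$p_up, 0.5)
  # degenerate zero-variance inputs
  expect_equal(oneSidedDeTest(c(1, 1, 1), c(1, 1, 1))$p_up, 0.5)
  shifted <- oneSidedDeTest(c(2, 2, 2), c(1, 1, 1))
  expect_lt(shifted$p_up, 1e-200)
  expect_equal(shifted$p_down, 1)
})

test_that("paired DE test uses the pair differences", {
  set.seed(42)
  n <- 12
  base <- rnorm(n)
  tumor <- base + 0.5 + rnorm(n, sd = 0.1)
  normal <- base
  pair <- oneSidedDeTest(tumor, normal, paired = TRUE)
  unpair <- oneSidedDeTest(tumor, normal, paired = FALSE)
  expect_lt(pair$p_up, unpair$p_up)  # pairing removes the shared baseline
  ref <- t.test(tumor, normal, paired = TRUE, alternative = "greater")
  expect_equal(pair$p_up, ref$p.value, tolerance = 1e-12)
})

test_that("Fisher combination matches the closed-form chi-square oracle", {
  expect_equal(fisherCombine(0.05), 0.05, tolerance = 1e-15)  # k = 1 identity
  expect_equal(fisherCombine(c(1, 1, 1)), 1)
  # worked pair: X = -2(ln 0.01 + ln 0.04) = 15.6481...
  X <- -2 * (log(0.01) + log(0.04))
  expect_equal(X, 15.64809, tolerance = 1e-5)
  expect_equal(fisherCombine(c(0.01, 0.04)), oracle_chisq_upper_even(X, 2),
               tolerance = 1e-15)
  set.seed(43)
  for (i in 1:200) {
    k <- sample(1:10, 1)
    p <- runif(k)
    expect_equal(fisherCombine(p),
                 oracle_chisq_upper_even(-2 * sum(log(p)), k),
                 tolerance = 1e-12)
  }
  # monotone: decreasing any one p-value decreases the meta-p
  p <- c(0.2, 0.5, 0.9)
  for (j in 1:3) {
    q <- p; q[j] <- p[j] / 2
    expect_lt(fisherCombine(q), fisherCombine(p))
  }
  expect_error(fisherCombine(numeric(0)), "at least one")
  expect_error(fisherCombine(c(0.5, 1.2)), "in \\(0, 1\\]")
})

test_that("directional meta picks the more significant side with a signed z", {
  up <- directionalMeta(rep(0.01, 5), rep(0.99, 5))
  expect_identical(unname(chosenDirection(up)), "up")
  expect_gt(unname(metaZ(up)), 0)
  dn <- directionalMeta(rep(0.99, 5), rep(0.01, 5))
  expect_identical(unname(chosenDirection(dn)), "down")
  expect_equal(unname(metaZ(dn)), -unname(metaZ(up)), tolerance = 1e-12)
  # meta_z = 0 exactly when the chosen meta-p = 0.5
  half <- directionalMeta(0.5, 0.5)
  expect_identical(unname(metaZ(half)), 0)
  expect_true(half@results$tie)
  expect_identical(unname(chosenDirection(half)), "up")  # tie rule
})

test_that("Cox z matches the hand-rolled partial-likelihood oracle", {
  # 5-subject worked dataset, no ties, all events
  time <- c(2, 5, 7, 9, 12)
  event <- rep(1L, 5)
  x <- c(1.2, -0.5, 0.3, -1.1, 0.8)
  or <- oracle_cox_z(time, event, x)
  cx <- coxSurvivalZ(time, event, x, standardize = FALSE, minN = 5L,
                     minEvents = 3L)
  expect_identical(cx$status, "ok")
  expect_equal(cx$z, or$z, tolerance = 1e-6)
  expect_equal(cx$p_risky, pnorm(or$z, lower.tail = FALSE), tolerance = 1e-6)
  expect_equal(cx$p_risky + cx$p_protective, 1, tolerance = 1e-12)
})

test_that("Cox fitting rejects tiny strata and null covariates behave", {
  small <- coxSurvivalZ(1:5, rep(1, 5), rnorm(5))
  expect_match(small$status, "fewer than 10")
  few <- coxSurvivalZ(1:20, c(rep(0, 18), 1, 1), rnorm(20))
  expect_match(few$status, "fewer than 3 events")
  # permuted covariate: z near zero on average
  set.seed(44)
  zs <- replicate(30, {
    t <- rexp(80); e <- rbinom(80, 1, 0.8)
    coxSurvivalZ(t, e, rnorm(80))$z
  })
  expect_lt(abs(mean(zs)), 0.5)
})

test_that("survival meta recovers a planted risky gene", {
  sim <- simulatePanCancerCohort("g", nCancers = 6, beta = 0.5, nTumor = 5,
                                 nNormal = 3, nSurv = 150,
                                 cfg = simConfig(seed = 46))
  res <- survivalMeta(sim$survival)
  expect_identical(unname(chosenDirection(res)), "risky")
  expect_gt(unname(metaZ(res)), 0)
})

test_that("signature scoring is the mean z-score with sane edge cases", {
  set.seed(47)
  m <- matrix(rnorm(5 * 30), 5, 30,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:30)))
  one <- signatureScore(m, "g2")
  expect_equal(as.numeric(one), as.numeric(scale(m["g2", ])),
               tolerance = 1e-12)
  # two perfectly anticorrelated genes cancel
  m2 <- rbind(a = m[1, ], b = -m[1, ])
  expect_equal(as.numeric(signatureScore(m2, c("a", "b"))), rep(0, 30),
               tolerance = 1e-12)
  expect_warning(expect_null(signatureScore(m, c("nope", "nada"))),
                 "no gene")
  # planted co-expressed module is recovered
  driver <- rnorm(50)
  mod <- t(vapply(1:6, function(i) driver + rnorm(50, sd = 0.3),
                  numeric(50)))
  rownames(mod) <- paste0("mod", 1:6)
  noise <- matrix(rnorm(4 * 50), 4, 50, dimnames = list(paste0("n", 1:4), NULL))
  sc <- signatureScore(rbind(mod, noise), rownames(mod))
  expect_gt(cor(mod["mod1", ], sc), 0.7)
})

test_that("hallmark correlation ranking maps p-values onto [0, 1]", {
  set.seed(48)
  driver <- rnorm(60)
  expr <- rbind(
    GENE = driver,
    t(vapply(1:4, function(i) driver * 0.8 + rnorm(60, sd = 0.5), numeric(60))),
    matrix(rnorm(6 * 60), 6, 60))
  rownames(expr) <- c("GENE", paste0("mod", 1:4), paste0("rand", 1:6))
  sigs <- list(linked = paste0("mod", 1:4),
               random = paste0("rand", 1:3),
               other = paste0("rand", 4:6))
  rk <- hallmarkCorrelationRank(expr, "GENE", sigs)
  expect_setequal(rk$rank01, c(1, 0.5, 0))
  expect_identical(rk$signature[rk$rank01 == 1], "linked")
  # K = 2 endpoints
  rk2 <- hallmarkCorrelationRank(expr, "GENE", sigs[1:2])
  expect_setequal(rk2$rank01, c(1, 0))
  # constant signature score is assigned p = 1
  expr2 <- rbind(expr, flat1 = rep(3, 60), flat2 = rep(5, 60))
  rk3 <- hallmarkCorrelationRank(expr2, "GENE",
                                 c(sigs, list(flat = c("flat1", "flat2"))))
  expect_equal(rk3$p[rk3$signature == "flat"], 1)
})

test_that("dependency summaries weight cancer types equally", {
  eff <- data.frame(gene = "G", cell_line = c("l1", "l2"),
                    cancer_type = "OV", effect = c(-1, -0.5))
  ds <- dependencySummary(eff)
  expect_equal(ds$byType$mean_effect, -0.75)
  expect_equal(ds$overall$overall_effect, -0.75)
  # unbalanced panel: two types with means -1 and 0 -> overall -0.5
  eff2 <- data.frame(gene = "G",
                     cell_line = paste0("l", 1:7),
                     cancer_type = c(rep("OV", 6), "BRCA"),
                     effect = c(rep(-1, 6), 0))
  expect_equal(dependencySummary(eff2)$overall$overall_effect, -0.5)
  # translation equivariance
  eff3 <- eff2; eff3$effect <- eff3$effect + 2
  expect_equal(dependencySummary(eff3)$overall$overall_effect, 1.5)
})

test_that("enrichment test equals the hypergeometric oracle with BH control", {
  res <- enrichmentTest(10, 100, 50, 10000)
  expect_equal(res$p, oracle_hypergeom_upper(10, 100, 50, 10000),
               tolerance = 1e-12)
  expect_gt(res$odds_ratio, 1)
  # proportional hits: no enrichment signal
  null <- enrichmentTest(5, 1000, 50, 10000)
  expect_gt(null$p, 0.3)
  # identical tests: BH leaves q = p
  fam <- enrichmentTest(rep(10, 4), 100, 50, 10000)
  expect_equal(fam$q, fam$p)
  expect_error(enrichmentTest(60, 100, 50, 10000), "margins")
})
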