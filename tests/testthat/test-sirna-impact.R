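test_that("fold-change primitives match their formulas", {
  expect_equal(expressionFoldChange(100, 100), 0)
  expect_equal(expressionFoldChange(200, 100), 1)
  expect_equal(expressionFoldChange(25, 100), -2)
  expect_error(expressionFoldChange(-1, 100), "positive")

  expect_equal(ic50FoldChange(1, 1), 1)
  expect_equal(ic50FoldChange(0.25, 1), 0.25)
  expect_equal(ic50FoldChange(1.2, 1), 1.2)
  expect_error(ic50FoldChange(0, 1), "positive")

  expect_equal(minmaxScale(c(0.25, 1.0, 1.2)),
               c(0, (1 - 0.25) / (1.2 - 0.25), 1))
  v <- runif(10)
  expect_equal(minmaxScale(v)[which.min(v)], 0)
  expect_equal(minmaxScale(v)[which.max(v)], 1)
  expect_warning(flat <- minmaxScale(c(2, 2, 2)), "degenerate")
  expect_equal(flat, rep(0.5, 3))
  expect_error(minmaxScale(1), "at least 2")
})

test_that("impact score reproduces the hand-computed three-gene panel", {
  # A: Fexp sum -2, FIC50 0.25; B: 0, 1.0; C: +1, 1.2
  inputs <- data.frame(
    gene = c("A", "B", "C"),
    expr_t1 = c(100 * 2^-1, 100, 100 * 2^0.5),
    expr_t2 = c(100 * 2^-1, 100, 100 * 2^0.5),
    expr_control = 100,
    ic50_knockdown = c(0.25, 1.0, 1.2),
    ic50_control = 1)
  res <- impactScore(inputs)
  expect_equal(res$sum_fexp, c(-2, 0, 1))
  expect_equal(res$fic50_scaled, c(0, 0.75 / 0.95, 1))
  expect_equal(res$score_literal, c(0, 0, 1))
  expect_equal(res$impact_corrected, c(1 * 2, (1 - 0.75 / 0.95) * 0, 0 * -1))
  expect_identical(res$gene[res$rank_corrected == 1L], "A")
  # literal ranking puts the most negative score first; all >= 0 here, so
  # the tie at 0 resolves by row order and C (score 1) is last
  expect_identical(res$gene[res$rank_literal == 3L], "C")
  expect_identical(attr(res, "variant"), "corrected")
})

test_that("literal variant equals the one-liner oracle on random panels", {
  set.seed(31)
  for (i in 1:20) {
    n <- sample(5:15, 1)
    tmat <- matrix(exp(rnorm(n * 2)), n, 2)
    ctrl <- exp(rnorm(n))
    ic50k <- exp(rnorm(n)); ic50c <- exp(rnorm(1))
    inputs <- data.frame(gene = paste0("g", 1:n),
                         expr_t1 = tmat[, 1], expr_t2 = tmat[, 2],
                         expr_control = ctrl, ic50_knockdown = ic50k,
                         ic50_control = ic50c)
    res <- impactScore(inputs, variant = "literal")
    expect_equal(res$score_literal,
                 oracle_impact_literal(tmat, ctrl, ic50k, ic50c),
                 tolerance = 1e-12)
  }
})

test_that("corrected impact is monotone in sensitization and repression", {
  base <- data.frame(gene = c("a", "b", "c", "d"),
                     expr_t1 = c(25, 50, 100, 100),
                     expr_control = 100,
                     ic50_knockdown = c(0.25, 0.5, 1, 1.2),
                     ic50_control = 1)
  res <- impactScore(base)
  # gene with Fexp sum 0 has corrected impact 0 regardless of FIC50
  expect_equal(res$impact_corrected[res$gene == "c"], 0)
  # lower FIC50 (same repression) cannot lower the impact
  expect_gte(res$impact_corrected[1], res$impact_corrected[2])
  # stronger repression (same FIC50 scale position) ranks a first
  expect_identical(res$gene[res$rank_corrected == 1L], "a")
})

test_that("genes with missing inputs are flagged, not silently dropped", {
  inputs <- data.frame(gene = c("a", "b", "c"),
                       expr_t1 = c(50, NA, 100),
                       expr_control = 100,
                       ic50_knockdown = c(0.5, 1, 1.2),
                       ic50_control = 1)
  expect_warning(res <- impactScore(inputs), "excluded")
  expect_identical(res$status, c("ok", "excluded", "ok"))
  expect_identical(nrow(res), 3L)
  expect_true(is.na(res$rank[2]))
})

test_that("the planted driver is top-ranked under the corrected variant", {
  hits <- 0L
  for (s in 1:40) {
    scr <- simulateSirnaScreen(paste0("g", 1:13), drivers = "g7",
                               cfg = simConfig(seed = s, noiseSd = 0.1))
    res <- impactScore(scr$inputs)
    hits <- hits + (res$gene[res$rank == 1L] == "g7")
  }
  expect_gte(hits / 40, 0.95)
})
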