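#' Simulate a single-agent dose-response table
#'
#' Generates fractions affected from the median-effect model
#' \eqn{fa(D) = (D/Dm)^m / (1 + (D/Dm)^m)}, adds Gaussian noise with
#' standard deviation `cfg@noiseSd` on the fa scale, and clips to `[0, 1]`.
#' With `noiseSd = 0` the curves are exactly the model values, so a refit
#' with [fitMedianEffect()] recovers `(m, Dm)` to numerical precision.
#'
#' @param m positive median-effect slope of the planted curve.
#' @param Dm positive median-effect dose (IC50) of the planted curve.
#' @param doses positive dose vector with at least 3 distinct values.
#' @param cfg a [SimConfig-class]; the seed fixes the noise stream.
#' @param drug label written into the table.
#' @return `data.frame` with columns `drug`, `dose`, `replicate`, `fa`,
#'   `viability` (= 1 - fa).
#' @examples
#' simulateSingleAgent(1, 1, c(0.25, 0.5, 1, 2, 4), simConfig(noiseSd = 0))
#' @export
simulateSingleAgent <- function(m, Dm, doses, cfg = simConfig(),
                                drug = "drug") {
  .stopIfNotPositive(m, "m")
  .stopIfNotPositive(Dm, "Dm")
  .stopIfNotPositive(doses, "doses")
  if (length(unique(doses)) < 3L)
    stop("need at least 3 distinct doses, got ", length(unique(doses)))
  stopifnot(is(cfg, "SimConfig"))
  fa0 <- (doses / Dm)^m / (1 + (doses / Dm)^m)
  out <- withr::with_seed(.childSeed(cfg@seed, paste0("single:", drug)), {
    do.call(rbind, lapply(seq_len(cfg@nReplicates), function(rep) {
      fa <- .clip(fa0 + rnorm(length(doses), sd = cfg@noiseSd), 0, 1)
      data.frame(drug = drug, dose = doses, replicate = rep, fa = fa,
                 viability = 1 - fa, stringsAsFactors = FALSE)
    }))
  })
  rownames(out) <- NULL
  out
}

# fa solving dA/DxA(fa) + dB/DxB(fa) = alpha by bracketed root finding.
# The left side is strictly decreasing in fa (each Dx increases with fa),
# so the root in (eps, 1-eps) is unique when it exists.
.faForAlpha <- function(fitA, fitB, dA, dB, alpha, eps = 1e-12) {
  f <- function(fa)
    dA / doseForEffect(fitA, fa) + dB / doseForEffect(fitB, fa) - alpha
  lo <- eps; hi <- 1 - eps
  if (f(lo) < 0 || f(hi) > 0)
    stop("unattainable effect: no fa in (0,1) satisfies the planted CI ",
         alpha, " at doses (", dA, ", ", dB, ")")
  uniroot(f, c(lo, hi), tol = 1e-12)$root
}

#' Simulate a drug-pair combination surface with a planted true CI
#'
#' Inverts the combination-index definition: for each dose pair
#' `(dA, dB)` the noiseless fraction affected is the unique root of
#' \deqn{d_A / D_{x,A}(fa) + d_B / D_{x,B}(fa) = \alpha,}
#' found by bracketed bisection-style root finding on `fa` in (0, 1), so the
#' true CI at every point equals `alpha` by construction. `alpha < 1` plants
#' synergy, `alpha = 1` a Loewe-additive surface, `alpha > 1` antagonism.
#' Noise is then added on the fa scale and clipped to `[0, 1]`.
#'
#' @param fitA,fitB successful [MedianEffectFit-class] objects defining the
#'   single-agent curves.
#' @param dosePairs two-column matrix or `data.frame` of positive doses
#'   `(dA, dB)`.
#' @param alpha positive planted interaction level (the true CI).
#' @param cfg a [SimConfig-class].
#' @param label tag used to split the seed stream per combination.
#' @return `data.frame` with columns `dose_a`, `dose_b`, `replicate`, `fa`;
#'   attribute `"alpha"` stores the planted truth.
#' @examples
#' fit <- fitMedianEffect(c(0.25, 0.5, 1, 2, 4), c(0.2, 1/3, 0.5, 2/3, 0.8))
#' simulateCombination(fit, fit, cbind(0.5, 0.5), alpha = 1, simConfig())
#' @export
simulateCombination <- function(fitA, fitB, dosePairs, alpha,
                                cfg = simConfig(), label = "pair") {
  .stopIfNotPositive(alpha, "alpha")
  dosePairs <- as.matrix(dosePairs)
  if (ncol(dosePairs) != 2L) stop("'dosePairs' must have two columns")
  .stopIfNotPositive(as.numeric(dosePairs), "dosePairs")
  stopifnot(is(cfg, "SimConfig"))
  fa0 <- vapply(seq_len(nrow(dosePairs)), function(i)
    .faForAlpha(fitA, fitB, dosePairs[i, 1L], dosePairs[i, 2L], alpha),
    numeric(1))
  out <- withr::with_seed(.childSeed(cfg@seed, paste0("combo:", label)), {
    do.call(rbind, lapply(seq_len(cfg@nReplicates), function(rep) {
      fa <- .clip(fa0 + rnorm(length(fa0), sd = cfg@noiseSd), 0, 1)
      data.frame(dose_a = dosePairs[, 1L], dose_b = dosePairs[, 2L],
                 replicate = rep, fa = fa)
    }))
  })
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  out
}

#' Five-point constant-ratio dose design anchored at the IC50s
#'
#' The screen's design: serially constant twofold dilutions of the pair,
#' centred at half of each agent's fitted IC50, i.e. dose pairs
#' \eqn{(Dm_A/2, Dm_B/2) \cdot 2^j} for `j = -2, ..., 2` by default.
#'
#' @param fitA,fitB successful [MedianEffectFit-class] objects.
#' @param nPoints odd number of points (default 5).
#' @param foldStep dilution factor between consecutive points (default 2).
#' @return Two-column matrix of dose pairs.
#' @export
constantRatioDesign <- function(fitA, fitB, nPoints = 5L, foldStep = 2) {
  stopifnot(fitA@status == "ok", fitB@status == "ok", nPoints >= 3L)
  j <- seq_len(nPoints) - (nPoints + 1L) / 2
  cbind(dose_a = fitA@Dm / 2 * foldStep^j, dose_b = fitB@Dm / 2 * foldStep^j)
}

#' Simulate a pan-cancer expression cohort with linked survival tables
#'
#' Log2 expression is a cancer-specific per-gene baseline plus a planted
#' tumor shift `delta` (log2 units) on tumor samples plus Gaussian noise.
#' Survival times are exponential with hazard proportional to
#' `exp(beta * z)` where `z` is the gene's standardized expression in the
#' survival cohort; censoring is uniform administrative censoring tuned to
#' the requested rate (independent of the event process).
#'
#' Some cancers may be generated with fewer than three normals (via the
#' `nNormal` vector) to exercise the meta-analysis exclusion rule.
#'
#' @param genes character vector of gene names.
#' @param nCancers number of cancer types.
#' @param delta named (or scalar) planted tumor-vs-normal log2 shift per
#'   gene.
#' @param beta named (or scalar) planted log-hazard coefficient per gene on
#'   the standardized-expression scale.
#' @param nTumor,nNormal tumor/normal sample counts per cancer (scalars or
#'   length-`nCancers` vectors; `nNormal` may contain values below 3).
#' @param nSurv survival-cohort size per cancer (default `nTumor`).
#' @param exprSd residual SD of log2 expression (default 1).
#' @param censorRate target administrative censoring fraction (default 0.3).
#' @param cfg a [SimConfig-class].
#' @return list with `cohort` ([ExpressionCohort-class]), `survival`
#'   (long `data.frame`: `gene`, `cancer_type`, `time`, `event`, `expr`)
#'   and `truth` (the planted `delta` and `beta`).
#' @examples
#' sim <- simulatePanCancerCohort(c("PRMT1", "PRMT5"), nCancers = 3,
#'                                delta = c(PRMT1 = 2, PRMT5 = 0),
#'                                beta = 0, nTumor = 10, nNormal = 5)
#' sim$cohort
#' @export
simulatePanCancerCohort <- function(genes, nCancers = 10L, delta = 0,
                                    beta = 0, nTumor = 20L, nNormal = 10L,
                                    nSurv = NULL, exprSd = 1,
                                    censorRate = 0.3, cfg = simConfig()) {
  stopifnot(is(cfg, "SimConfig"), length(genes) >= 1L, nCancers >= 1L)
  delta <- .perGene(delta, genes, "delta")
  beta <- .perGene(beta, genes, "beta")
  nTumor <- rep_len(as.integer(nTumor), nCancers)
  nNormal <- rep_len(as.integer(nNormal), nCancers)
  if (any(nNormal < 0L)) stop("'nNormal' must be non-negative")
  if (is.null(nSurv)) nSurv <- nTumor else nSurv <- rep_len(as.integer(nSurv), nCancers)
  cancers <- sprintf("cancer%02d", seq_len(nCancers))

  withr::with_seed(.childSeed(cfg@seed, "cohort"), {
    mats <- list(); ct <- character(0); st <- character(0)
    for (ci in seq_len(nCancers)) {
      n <- nTumor[ci] + nNormal[ci]
      base <- rnorm(length(genes), mean = 8, sd = 1)  # cancer-specific baseline
      tumorFlag <- rep(c(1, 0), c(nTumor[ci], nNormal[ci]))
      mat <- base + outer(delta, tumorFlag) +
        matrix(rnorm(length(genes) * n, sd = exprSd), length(genes), n)
      mats[[ci]] <- mat
      ct <- c(ct, rep(cancers[ci], n))
      st <- c(st, rep(c("tumor", "normal"), c(nTumor[ci], nNormal[ci])))
    }
    expr <- do.call(cbind, mats)
    dimnames(expr) <- list(genes, sprintf("s%04d", seq_len(ncol(expr))))
    cohort <- ExpressionCohort(expr, ct, st)

    # administrative uniform censoring on (0, tau): for unit-rate exponential
    # events the censored fraction is (1 - exp(-tau))/tau; tau = 3.2 gives
    # roughly 30%. Scale tau for other target rates by root finding.
    tau <- if (censorRate <= 0) Inf else
      uniroot(function(t) (1 - exp(-t)) / t - censorRate, c(1e-6, 1e3))$root
    surv <- list()
    for (ci in seq_len(nCancers)) {
      ns <- nSurv[ci]
      if (ns < 1L) next
      for (g in genes) {
        x <- rnorm(ns, mean = 8, sd = exprSd)
        z <- as.numeric(scale(x))
        tEvent <- rexp(ns, rate = exp(beta[g] * z))
        tCens <- if (is.finite(tau)) runif(ns, 0, tau) else rep(Inf, ns)
        surv[[length(surv) + 1L]] <- data.frame(
          gene = g, cancer_type = cancers[ci],
          time = 365 * pmin(tEvent, tCens),   # day-scale times
          event = as.integer(tEvent <= tCens), expr = x,
          stringsAsFactors = FALSE)
      }
    }
    list(cohort = cohort,
         survival = if (length(surv)) do.call(rbind, surv) else
           data.frame(gene = character(), cancer_type = character(),
                      time = numeric(), event = integer(), expr = numeric()),
         truth = list(delta = delta, beta = beta))
  })
}

.perGene <- function(x, genes, what) {
  if (length(x) == 1L && is.null(names(x))) return(setNames(rep(x, length(genes)), genes))
  if (is.null(names(x)) && length(x) == length(genes)) return(setNames(x, genes))
  if (!all(genes %in% names(x)))
    stop("'", what, "' must be a scalar or named per gene")
  x[genes]
}

#' Simulate an siRNA sensitization screen with planted drivers
#'
#' Emulates the inputs of the impact-score analysis: per-gene expression
#' fold changes under each treatment (RNA-seq style) and the PARP-inhibitor
#' IC50 after knocking the gene down versus control transfection. Planted
#' driver genes receive a strongly negative expression fold change under
#' every treatment and an IC50 fold change below 1 (knockdown sensitizes);
#' non-drivers sit at fold change ~0 / IC50 ratio ~1. Noise is Gaussian on
#' the log2 scale of both quantities with SD `cfg@noiseSd`.
#'
#' @param genes >= 2 candidate gene names.
#' @param drivers subset of `genes` planted as repressed sensitizers.
#' @param treatments treatment labels (default two inhibitor arms).
#' @param driverFexp planted log2 expression fold change for drivers
#'   (default -2).
#' @param driverFIC50 planted IC50 fold change for drivers (default 0.25).
#' @param controlExpr,controlIC50 control-condition expression level and
#'   IC50 (arbitrary positive units).
#' @param cfg a [SimConfig-class].
#' @return list with `inputs` (`data.frame`: `gene`, one `expr_<treatment>`
#'   column per treatment, `expr_control`, `ic50_knockdown`,
#'   `ic50_control`) and `truth` (planted drivers and effect sizes).
#' @examples
#' simulateSirnaScreen(paste0("g", 1:13), drivers = "g1",
#'                     cfg = simConfig(noiseSd = 0.1))$inputs
#' @export
simulateSirnaScreen <- function(genes, drivers = character(0),
                                treatments = c("PRMT1i", "PRMT5i"),
                                driverFexp = -2, driverFIC50 = 0.25,
                                controlExpr = 100, controlIC50 = 1,
                                cfg = simConfig()) {
  if (length(genes) < 2L)
    stop("need at least 2 candidate genes for min-max scaling, got ",
         length(genes))
  if (!all(drivers %in% genes)) stop("'drivers' must be a subset of 'genes'")
  stopifnot(is(cfg, "SimConfig"))
  isDriver <- genes %in% drivers
  withr::with_seed(.childSeed(cfg@seed, "sirna"), {
    inputs <- data.frame(gene = genes, stringsAsFactors = FALSE)
    for (t in treatments) {
      fexp <- ifelse(isDriver, driverFexp, 0) +
        rnorm(length(genes), sd = cfg@noiseSd)
      inputs[[paste0("expr_", t)]] <- controlExpr * 2^fexp
    }
    inputs$expr_control <- rep(controlExpr, length(genes))
    lfic <- log2(ifelse(isDriver, driverFIC50, 1)) +
      rnorm(length(genes), sd = cfg@noiseSd)
    inputs$ic50_knockdown <- controlIC50 * 2^lfic
    inputs$ic50_control <- rep(controlIC50, length(genes))
    list(inputs = inputs,
         truth = list(drivers = drivers, driverFexp = driverFexp,
                      driverFIC50 = driverFIC50))
  })
}
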