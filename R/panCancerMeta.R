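#' One-sided differential-expression test for one cancer type
#'
#' Welch unequal-variance t-test of tumor versus normal expression, returning
#' both one-sided p-values: `p_up` for up-regulation in tumor and `p_down`
#' for down-regulation. The two sides satisfy `p_up + p_down = 1` up to the
#' point mass at `t = 0`. With pair linkage (`paired = TRUE`, protein-style
#' cohorts) the paired t-test on tumor - normal differences is used
#' instead. Degenerate input with zero variance in both groups returns
#' `p_up = p_down = 0.5` when the means are equal; with unequal means the
#' shift is treated as infinitely significant (p floored at 1e-300 on the
#' shifted side).
#'
#' @param tumor,normal numeric expression vectors (log2 scale). For the
#'   paired test they must have equal length and matched order.
#' @param paired use the paired one-sided t-test.
#' @return list with `statistic` (t), `p_up`, `p_down`.
#' @examples
#' oneSidedDeTest(rnorm(20, 1), rnorm(10))
#' @export
oneSidedDeTest <- function(tumor, normal, paired = FALSE) {
  if (paired && length(tumor) != length(normal))
    stop("paired test needs equal-length matched vectors")
  minN <- if (paired) 2L else 2L
  if (length(tumor) < minN || length(normal) < 2L)
    stop("too few samples for a t-test")
  tt <- tryCatch(
    t.test(tumor, normal, alternative = "greater", paired = paired,
           var.equal = FALSE),
    error = function(e) NULL)
  if (is.null(tt)) {  # constant data
    d <- mean(tumor) - mean(normal)
    if (d == 0) return(list(statistic = 0, p_up = 0.5, p_down = 0.5))
    if (d > 0) return(list(statistic = Inf, p_up = .P_FLOOR, p_down = 1))
    return(list(statistic = -Inf, p_up = 1, p_down = .P_FLOOR))
  }
  tstat <- unname(tt$statistic)
  df <- unname(tt$parameter)
  list(statistic = tstat,
       p_up = max(pt(tstat, df, lower.tail = FALSE), .P_FLOOR),
       p_down = max(pt(tstat, df, lower.tail = TRUE), .P_FLOOR))
}

#' Fisher's combined probability test
#'
#' Combines k independent p-values via
#' \eqn{X = -2 \sum_i \ln p_i \sim \chi^2_{2k}} under the global null; the
#' returned meta-p is the upper-tail probability of that chi-square. For a
#' single p-value the combination is the identity. Inputs are floored at
#' 1e-300 before taking logs.
#'
#' @param pvals numeric vector of p-values in (0, 1], length >= 1.
#' @return The combined meta-p value.
#' @examples
#' fisherCombine(c(0.01, 0.04))
#' @export
fisherCombine <- function(pvals) {
  if (length(pvals) < 1L) stop("need at least one p-value to combine")
  if (any(!is.finite(pvals) | pvals <= 0 | pvals > 1))
    stop("p-values must lie in (0, 1]")
  pvals <- pmax(pvals, .P_FLOOR)
  if (length(pvals) == 1L) return(pvals)  # single-study identity, exact
  X <- -2 * sum(log(pvals))
  pchisq(X, df = 2 * length(pvals), lower.tail = FALSE)
}

# shared core: combine two direction-wise p-value vectors for one gene
.directionalCombine <- function(pFirst, pSecond, directions) {
  mpFirst <- fisherCombine(pFirst)
  mpSecond <- fisherCombine(pSecond)
  tie <- mpFirst == mpSecond
  first <- mpFirst <= mpSecond   # deterministic: first direction wins ties
  chosen <- if (first) directions[1L] else directions[2L]
  mp <- if (first) mpFirst else mpSecond
  z <- -qnorm(pmax(mp, .P_FLOOR))  # upper-tail quantile; exactly 0 at p = 0.5
  if (!first) z <- -z
  list(meta_p_first = mpFirst, meta_p_second = mpSecond, direction = chosen,
       meta_z = z, tie = tie, n_units = length(pFirst))
}

#' Directional Fisher meta-analysis across cancer types
#'
#' Combines per-cancer one-sided p-values separately for each direction via
#' [fisherCombine()], reports the direction with the smaller meta-p, and
#' transforms it to a signed meta-z: `qnorm(meta_p, lower.tail = FALSE)`,
#' negated when the chosen direction is the second (down/protective) label.
#' `meta_z` is therefore 0 exactly when the chosen meta-p is 0.5, and
#' positive for the first (up/risky) direction. Ties between directions are
#' resolved toward the first label and flagged.
#'
#' @param pFirst,pSecond per-cancer one-sided p-values for the first and
#'   second direction (equal length >= 1).
#' @param directions the two direction labels.
#' @param gene label written into the result.
#' @return A [MetaResult-class] with a single-gene `results` table.
#' @examples
#' directionalMeta(rep(0.01, 5), rep(0.99, 5))
#' @export
directionalMeta <- function(pFirst, pSecond, directions = c("up", "down"),
                            gene = "gene") {
  if (length(pFirst) != length(pSecond) || length(pFirst) < 1L)
    stop("need equal-length, non-empty per-cancer p-value vectors")
  cmb <- .directionalCombine(pFirst, pSecond, directions)
  res <- data.frame(gene = gene, direction = cmb$direction,
                    meta_z = cmb$meta_z, n_units = cmb$n_units,
                    tie = cmb$tie, stringsAsFactors = FALSE)
  res[[paste0("meta_p_", directions[1L])]] <- cmb$meta_p_first
  res[[paste0("meta_p_", directions[2L])]] <- cmb$meta_p_second
  pu <- data.frame(gene = gene, unit = seq_along(pFirst),
                   stringsAsFactors = FALSE)
  pu[[paste0("p_", directions[1L])]] <- pFirst
  pu[[paste0("p_", directions[2L])]] <- pSecond
  new("MetaResult", results = res, perUnit = pu, directions = directions,
      excluded = data.frame(unit = character(), reason = character()))
}

#' Pan-cancer differential-expression meta-analysis
#'
#' For every gene of an [ExpressionCohort-class], runs the one-sided
#' tumor-versus-normal test per cancer type (excluding cancers with fewer
#' than `minNormal` normal samples, default 3, which mirrors the inclusion
#' rule of the source cohorts), combines each direction across cancers via
#' Fisher's method, and reports the more significant direction with its
#' signed meta-z. With `paired = TRUE`, cancers are tested with the paired
#' t-test using the cohort's `pair_id` linkage.
#'
#' @param cohort an [ExpressionCohort-class].
#' @param genes genes to analyse (default all rows).
#' @param minNormal minimum normal-sample count for a cancer to enter the
#'   meta-analysis.
#' @param paired use paired tests (requires `pair_id` in `colData`).
#' @return A [MetaResult-class] with directions `up`/`down`; excluded
#'   cancers are listed in `excludedUnits()`.
#' @examples
#' sim <- simulatePanCancerCohort("PRMT5", nCancers = 4, delta = 2,
#'                                nTumor = 15, nNormal = 8)
#' deMeta(sim$cohort)
#' @export
deMeta <- function(cohort, genes = NULL, minNormal = 3L, paired = FALSE) {
  stopifnot(is(cohort, "ExpressionCohort"))
  expr <- SummarizedExperiment::assay(cohort, "log2expr")
  cd <- SummarizedExperiment::colData(cohort)
  if (is.null(genes)) genes <- rownames(expr)
  cancers <- unique(as.character(cd$cancer_type))
  excluded <- data.frame(unit = character(), reason = character(),
                         stringsAsFactors = FALSE)
  useCancers <- character(0)
  for (cc in cancers) {
    nn <- sum(cd$cancer_type == cc & cd$sample_type == "normal")
    nt <- sum(cd$cancer_type == cc & cd$sample_type == "tumor")
    if (nn < minNormal || nt < 2L) {
      excluded <- rbind(excluded, data.frame(
        unit = cc, reason = sprintf("%d normal / %d tumor samples", nn, nt),
        stringsAsFactors = FALSE))
    } else useCancers <- c(useCancers, cc)
  }
  if (!length(useCancers))
    stop("no cancer type passes the inclusion rule (minNormal = ", minNormal, ")")

  resRows <- list(); puRows <- list()
  for (g in genes) {
    pUp <- pDown <- numeric(0)
    for (cc in useCancers) {
      tumorIdx <- which(cd$cancer_type == cc & cd$sample_type == "tumor")
      normalIdx <- which(cd$cancer_type == cc & cd$sample_type == "normal")
      if (paired) {
        if (!"pair_id" %in% names(cd)) stop("paired = TRUE needs 'pair_id'")
        pid <- intersect(na.omit(cd$pair_id[tumorIdx]),
                         na.omit(cd$pair_id[normalIdx]))
        tumorIdx <- tumorIdx[match(pid, cd$pair_id[tumorIdx])]
        normalIdx <- normalIdx[match(pid, cd$pair_id[normalIdx])]
      }
      tst <- oneSidedDeTest(expr[g, tumorIdx], expr[g, normalIdx],
                            paired = paired)
      pUp <- c(pUp, tst$p_up); pDown <- c(pDown, tst$p_down)
      puRows[[length(puRows) + 1L]] <- data.frame(
        gene = g, unit = cc, p_up = tst$p_up, p_down = tst$p_down,
        statistic = tst$statistic, stringsAsFactors = FALSE)
    }
    cmb <- .directionalCombine(pUp, pDown, c("up", "down"))
    resRows[[length(resRows) + 1L]] <- data.frame(
      gene = g, direction = cmb$direction, meta_z = cmb$meta_z,
      n_units = cmb$n_units, tie = cmb$tie, meta_p_up = cmb$meta_p_first,
      meta_p_down = cmb$meta_p_second, stringsAsFactors = FALSE)
  }
  new("MetaResult", results = do.call(rbind, resRows),
      perUnit = do.call(rbind, puRows), directions = c("up", "down"),
      excluded = excluded)
}

#' Cox proportional-hazards z-statistic for one cancer type
#'
#' Fits `Surv(time, event) ~ covariate` by partial likelihood (Efron tie
#' handling) and returns the Wald z (coefficient over standard error)
#' together with directional p-values: `p_risky` is the upper-tail normal
#' probability (high expression associated with poor outcome),
#' `p_protective` the lower tail. The expression covariate is z-scored
#' within the stratum by default, so hazard ratios are per-SD.
#'
#' @param time positive follow-up times.
#' @param event 0/1 event indicators.
#' @param covariate numeric expression covariate.
#' @param standardize z-score the covariate before fitting (default TRUE).
#' @param minN,minEvents minimum samples (10) and events (3); smaller
#'   strata are rejected so callers can skip them with a warning.
#' @return list with `z`, `p_risky`, `p_protective`, `n`, `n_events`,
#'   `status` (`"ok"` or a failure reason).
#' @examples
#' s <- simulatePanCancerCohort("g", nCancers = 1, beta = 0.5, nTumor = 100)
#' with(s$survival, coxSurvivalZ(time, event, expr))
#' @export
coxSurvivalZ <- function(time, event, covariate, standardize = TRUE,
                         minN = 10L, minEvents = 3L) {
  n <- length(time)
  fail <- function(reason)
    list(z = NA_real_, p_risky = NA_real_, p_protective = NA_real_,
         n = n, n_events = sum(event), status = reason)
  if (n < minN) return(fail(sprintf("fewer than %d samples", minN)))
  if (sum(event) < minEvents)
    return(fail(sprintf("fewer than %d events", minEvents)))
  if (any(time <= 0)) stop("survival times must be positive")
  if (!all(event %in% c(0, 1))) stop("'event' must be 0/1")
  x <- if (standardize) as.numeric(scale(covariate)) else covariate
  if (!all(is.finite(x)) || sd(covariate) == 0)
    return(fail("constant covariate"))
  fit <- tryCatch(
    withCallingHandlers(
      survival::coxph(survival::Surv(time, event) ~ x, ties = "efron"),
      warning = function(w) {
        if (grepl("converge|infinite|beta may be", conditionMessage(w)))
          stop(conditionMessage(w)) else invokeRestart("muffleWarning")
      }),
    error = function(e) NULL)
  if (is.null(fit)) return(fail("non-convergence or separation"))
  sm <- summary(fit)$coefficients
  z <- unname(sm[1L, "z"])
  if (!is.finite(z)) return(fail("non-finite z"))
  list(z = z,
       p_risky = max(pnorm(z, lower.tail = FALSE), .P_FLOOR),
       p_protective = max(pnorm(z, lower.tail = TRUE), .P_FLOOR),
       n = n, n_events = sum(event), status = "ok")
}

#' Pan-cancer survival meta-analysis
#'
#' Per gene and cancer type, fits the Cox model of [coxSurvivalZ()]; the
#' per-cancer directional p-values (risky/protective) are then combined by
#' Fisher's method per direction and the more significant direction is
#' reported with its signed meta-z (positive = risky, i.e. high expression
#' associated with poor outcome). Strata that are too small or fail to
#' converge are excluded with a logged reason.
#'
#' @param survTable `data.frame` with columns `gene`, `cancer_type`,
#'   `time`, `event`, `expr` (one row per sample per gene, as produced by
#'   [simulatePanCancerCohort()]).
#' @param minN,minEvents stratum-size thresholds passed to [coxSurvivalZ()].
#' @return A [MetaResult-class] with directions `risky`/`protective`.
#' @export
survivalMeta <- function(survTable, minN = 10L, minEvents = 3L) {
  need <- c("gene", "cancer_type", "time", "event", "expr")
  if (!all(need %in% names(survTable)))
    stop("'survTable' needs columns ", paste(need, collapse = ", "))
  resRows <- list(); puRows <- list()
  excluded <- data.frame(unit = character(), reason = character(),
                         stringsAsFactors = FALSE)
  for (g in unique(survTable$gene)) {
    sub <- survTable[survTable$gene == g, ]
    pR <- pP <- numeric(0)
    for (cc in unique(sub$cancer_type)) {
      s <- sub[sub$cancer_type == cc, ]
      cx <- coxSurvivalZ(s$time, s$event, s$expr, minN = minN,
                         minEvents = minEvents)
      if (cx$status != "ok") {
        excluded <- rbind(excluded, data.frame(
          unit = paste(g, cc, sep = ":"), reason = cx$status,
          stringsAsFactors = FALSE))
        next
      }
      pR <- c(pR, cx$p_risky); pP <- c(pP, cx$p_protective)
      puRows[[length(puRows) + 1L]] <- data.frame(
        gene = g, unit = cc, p_risky = cx$p_risky,
        p_protective = cx$p_protective, statistic = cx$z,
        stringsAsFactors = FALSE)
    }
    if (!length(pR)) {
      warning("no usable stratum for gene ", g, "; skipped")
      next
    }
    cmb <- .directionalCombine(pR, pP, c("risky", "protective"))
    resRows[[length(resRows) + 1L]] <- data.frame(
      gene = g, direction = cmb$direction, meta_z = cmb$meta_z,
      n_units = cmb$n_units, tie = cmb$tie,
      meta_p_risky = cmb$meta_p_first, meta_p_protective = cmb$meta_p_second,
      stringsAsFactors = FALSE)
  }
  if (!length(resRows)) stop("no gene had any usable stratum")
  new("MetaResult", results = do.call(rbind, resRows),
      perUnit = do.call(rbind, puRows),
      directions = c("risky", "protective"), excluded = excluded)
}

#' Mean z-score signature score per sample
#'
#' Scores a gene set on every sample as the mean of the member genes'
#' z-scored log2 expression (each gene standardized across samples within
#' the cohort). This is a deliberate simple-convention scorer; sample-rank
#' methods (ssGSEA/GSVA) are out of scope and the convention is recorded in
#' the returned attribute.
#'
#' @param x an [ExpressionCohort-class] or a gene-by-sample numeric matrix.
#' @param geneSet character vector of gene names; genes absent from the
#'   matrix are ignored, an empty intersection returns `NULL` with a
#'   warning so callers can skip the signature.
#' @return Named per-sample score vector (attribute `"n_genes"` gives the
#'   member count used), or `NULL`.
#' @export
signatureScore <- function(x, geneSet) {
  expr <- if (is(x, "ExpressionCohort"))
    SummarizedExperiment::assay(x, "log2expr") else as.matrix(x)
  genes <- intersect(geneSet, rownames(expr))
  if (!length(genes)) {
    warning("signature has no gene in the expression matrix; skipped")
    return(NULL)
  }
  z <- t(apply(expr[genes, , drop = FALSE], 1L, function(v) {
    s <- sd(v)
    if (s == 0) rep(0, length(v)) else (v - mean(v)) / s
  }))
  out <- colMeans(z)
  attr(out, "n_genes") <- length(genes)
  out
}

#' Correlation ranking of a gene against scored signatures
#'
#' Correlates one gene's expression with each signature's per-sample score
#' (Pearson by default, Spearman behind a flag), then ranks the signatures
#' 0-1 by p-value: `rank01 = (K - rank)/(K - 1)` with rank 1 = smallest p,
#' so 1 marks the most significant signature and 0 the least; tied p-values
#' share the mean rank. A constant score vector gets `p = 1`.
#'
#' @param x an [ExpressionCohort-class] or gene-by-sample matrix.
#' @param gene the gene to correlate.
#' @param signatures named list of gene sets (K >= 2 must produce a score).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return `data.frame` with columns `signature`, `r`, `p`, `rank01`.
#' @export
hallmarkCorrelationRank <- function(x, gene, signatures,
                                    method = c("pearson", "spearman")) {
  method <- match.arg(method)
  expr <- if (is(x, "ExpressionCohort"))
    SummarizedExperiment::assay(x, "log2expr") else as.matrix(x)
  if (!gene %in% rownames(expr)) stop("gene '", gene, "' not in matrix")
  g <- expr[gene, ]
  rows <- list()
  for (nm in names(signatures)) {
    sc <- signatureScore(expr, signatures[[nm]])
    if (is.null(sc)) next
    if (sd(sc) == 0) {
      rows[[nm]] <- data.frame(signature = nm, r = NA_real_, p = 1,
                               stringsAsFactors = FALSE)
    } else {
      ct <- cor.test(g, sc, method = method, exact = FALSE)
      rows[[nm]] <- data.frame(signature = nm, r = unname(ct$estimate),
                               p = ct$p.value, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) < 2L)
    stop("need at least 2 scoreable signatures")
  K <- nrow(out)
  out$rank01 <- (K - rank(out$p, ties.method = "average")) / (K - 1)
  rownames(out) <- NULL
  out
}

#' Summarize dependency (gene-effect) scores by cancer type
#'
#' Averages CRISPR gene-effect scores within each cancer type, then takes
#' the overall summary as the unweighted mean of the type means so each
#' cancer type counts once regardless of how many cell lines it
#' contributes. Lower effect scores indicate stronger dependence of cancer
#' cells on the gene.
#'
#' @param effects `data.frame` with columns `gene`, `cell_line`,
#'   `cancer_type`, `effect`.
#' @return list with `byType` (`gene`, `cancer_type`, `mean_effect`,
#'   `n_lines`) and `overall` (`gene`, `overall_effect`, `n_types`).
#' @examples
#' eff <- data.frame(gene = "PRMT5", cell_line = c("a", "b", "c"),
#'                   cancer_type = c("OV", "OV", "BRCA"),
#'                   effect = c(-1, -1, 0))
#' dependencySummary(eff)$overall   # type means -1 and 0 -> overall -0.5
#' @export
dependencySummary <- function(effects) {
  need <- c("gene", "cell_line", "cancer_type", "effect")
  if (!all(need %in% names(effects)))
    stop("'effects' needs columns ", paste(need, collapse = ", "))
  if (!nrow(effects)) stop("empty effect table")
  byType <- stats::aggregate(effect ~ gene + cancer_type, data = effects,
                             FUN = mean)
  names(byType)[names(byType) == "effect"] <- "mean_effect"
  cnt <- stats::aggregate(cell_line ~ gene + cancer_type, data = effects,
                          FUN = length)
  byType$n_lines <- cnt$cell_line[match(
    paste(byType$gene, byType$cancer_type),
    paste(cnt$gene, cnt$cancer_type))]
  overall <- stats::aggregate(mean_effect ~ gene, data = byType, FUN = mean)
  names(overall)[names(overall) == "mean_effect"] <- "overall_effect"
  nt <- stats::aggregate(cancer_type ~ gene, data = byType, FUN = length)
  overall$n_types <- nt$cancer_type[match(overall$gene, nt$gene)]
  list(byType = byType, overall = overall)
}

#' Gene-set enrichment by Fisher's exact test with FDR control
#'
#' One-sided (enrichment-direction) Fisher's exact test on the 2x2 table
#' of hit/set membership, vectorized over a family of tests, with
#' Benjamini-Hochberg q-values across the family.
#'
#' @param kInSetHits hits inside the set (vector over tests).
#' @param nHits total hits.
#' @param KSet set size.
#' @param NUniverse universe size.
#' @return `data.frame` with `odds_ratio` (conditional MLE), `p`
#'   (one-sided), `q` (BH across the supplied family).
#' @examples
#' enrichmentTest(10, 100, 50, 10000)
#' @export
enrichmentTest <- function(kInSetHits, nHits, KSet, NUniverse) {
  m <- max(length(kInSetHits), length(nHits), length(KSet), length(NUniverse))
  k <- rep_len(kInSetHits, m); n <- rep_len(nHits, m)
  K <- rep_len(KSet, m); N <- rep_len(NUniverse, m)
  bad <- k > pmin(n, K) | n > N | K > N | k < 0 | pmin(n, K, N) < 0 |
    (n - k) > (N - K)
  if (any(bad))
    stop("inconsistent 2x2 margins in test(s) ",
         paste(which(bad), collapse = ", "))
  p <- or <- numeric(m)
  for (i in seq_len(m)) {
    tab <- matrix(c(k[i], n[i] - k[i], K[i] - k[i],
                    N[i] - K[i] - n[i] + k[i]), nrow = 2L)
    ft <- fisher.test(tab, alternative = "greater")
    p[i] <- ft$p.value
    or[i] <- unname(ft$estimate)
  }
  data.frame(odds_ratio = or, p = p, q = p.adjust(p, method = "BH"))
}
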