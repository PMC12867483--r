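#' Fit the median-effect equation to a single-agent dose-response curve
#'
#' Fits the median-effect model \eqn{fa/fu = (D/Dm)^m} (with
#' \eqn{fu = 1 - fa}) by ordinary least squares on the linearized scale
#' \eqn{\log(fa/(1 - fa)) = m \log D - m \log Dm}. This is the computation
#' combination-index software performs for each agent before any CI
#' arithmetic; `Dm` is recovered as `exp(-intercept/m)` and equals the IC50.
#'
#' Fractions affected are clipped into `[1e-6, 1 - 1e-6]` before the
#' linearization (clipped, not dropped); the number of clipped points is
#' recorded on the fit. An estimated slope `m <= 0` marks the curve
#' non-monotone: the record is kept with `fitStatus(fit) == "non-monotone"`
#' and a warning, so a screen over many drugs can continue.
#'
#' @param doses positive dose vector (>= 3 distinct doses).
#' @param fa fractions affected in `(0, 1)` (raw values outside are clipped).
#' @param drug optional label stored on the fit.
#'
#' @return A [MedianEffectFit-class] with slope `m`, median-effect dose
#'   `Dm`, linear correlation `r`, and point counts.
#' @examples
#' fitMedianEffect(c(0.25, 0.5, 1, 2, 4), c(0.2, 1/3, 0.5, 2/3, 0.8))
#' @seealso [doseForEffect()], [combinationIndex()]
#' @export
fitMedianEffect <- function(doses, fa, drug = NA_character_) {
  .stopIfNotPositive(doses, "doses")
  if (length(doses) != length(fa))
    stop("'doses' and 'fa' must have equal length")
  keep <- is.finite(fa)
  doses <- doses[keep]; fa <- fa[keep]
  nClipped <- sum(fa <= .FA_EPS | fa >= 1 - .FA_EPS)
  fa <- .clip(fa, .FA_EPS, 1 - .FA_EPS)
  if (length(doses) < 3L)
    stop("median-effect fit needs at least 3 usable points, got ",
         length(doses))
  x <- log(doses)
  y <- log(fa / (1 - fa))
  if (sd(y) == 0 || sd(x) == 0)
    stop("median-effect fit failed: zero variance in ",
         if (sd(y) == 0) "response (all fa identical)" else "doses")
  ls <- lm(y ~ x)
  m <- unname(coef(ls)[2L])
  b <- unname(coef(ls)[1L])
  r <- cor(x, y)
  if (m <= 0) {
    warning("non-monotone dose-response (estimated m = ",
            signif(m, 3), ") for drug '", drug, "'")
    return(new("MedianEffectFit", drug = as.character(drug), m = m,
               Dm = NA_real_, r = r, nPoints = length(doses),
               nClipped = as.integer(nClipped), status = "non-monotone"))
  }
  new("MedianEffectFit", drug = as.character(drug), m = m,
      Dm = exp(-b / m), r = r, nPoints = length(doses),
      nClipped = as.integer(nClipped), status = "ok")
}

#' Dose of a single agent producing a given effect
#'
#' Inverts the median-effect equation:
#' \deqn{D_x = Dm \cdot (fa / (1 - fa))^{1/m}.}
#'
#' @param fit a successful [MedianEffectFit-class].
#' @param fa effect level(s) strictly inside (0, 1).
#' @return Positive dose(s) `Dx` in the fit's concentration units.
#' @examples
#' fit <- fitMedianEffect(c(0.25, 0.5, 1, 2, 4), c(0.2, 1/3, 0.5, 2/3, 0.8))
#' doseForEffect(fit, 0.5)   # the IC50, i.e. Dm
#' doseForEffect(fit, 0.8)
#' @export
doseForEffect <- function(fit, fa) {
  stopifnot(is(fit, "MedianEffectFit"))
  if (fit@status != "ok")
    stop("cannot invert a fit with status '", fit@status, "'")
  if (any(!is.finite(fa) | fa <= 0 | fa >= 1))
    stop("'fa' must lie strictly inside (0, 1)")
  fit@Dm * (fa / (1 - fa))^(1 / fit@m)
}

#' Combination index at an observed effect level
#'
#' The two-term (mutually exclusive) Chou-Talalay combination index at a
#' common fraction affected:
#' \deqn{CI = d_A / D_{x,A}(fa) + d_B / D_{x,B}(fa),}
#' where \eqn{D_{x}} is each agent's single-dose equivalent from
#' [doseForEffect()]. `CI = 1` is Loewe additivity; the three-term
#' mutually-nonexclusive variant is intentionally not provided.
#'
#' @param fitA,fitB successful [MedianEffectFit-class] objects for the two
#'   agents.
#' @param dA,dB doses of A and B actually applied (vectors allowed).
#' @param fa the observed fraction(s) affected of the combination, in (0, 1).
#' @return Positive CI value(s).
#' @examples
#' fit <- fitMedianEffect(c(0.25, 0.5, 1, 2, 4), c(0.2, 1/3, 0.5, 2/3, 0.8))
#' combinationIndex(fit, fit, 0.5, 0.5, fa = 0.5)  # sham combination: CI = 1
#' @export
combinationIndex <- function(fitA, fitB, dA, dB, fa) {
  .stopIfNotPositive(dA, "dA")
  .stopIfNotPositive(dB, "dB")
  dA / doseForEffect(fitA, fa) + dB / doseForEffect(fitB, fa)
}

#' Classify a combination index into synergy classes
#'
#' Step classification at the screen's printed thresholds: CI < 0.83 is
#' synergism, CI in the closed interval \[0.83, 1.2\] is additive, and
#' CI > 1.2 is antagonism. Both boundaries belong to "additive".
#'
#' @param ci positive CI value(s).
#' @return Character vector over `{"synergism", "additive", "antagonism"}`.
#' @examples
#' classifyCI(c(0.5, 0.83, 1.0, 1.2, 1.5))
#' @export
classifyCI <- function(ci) {
  .stopIfNotPositive(ci, "ci")
  ifelse(ci < 0.83, "synergism", ifelse(ci <= 1.2, "additive", "antagonism"))
}

#' Summarize a drug-pair combination into a record
#'
#' Computes the per-combination central CI over the dose points whose
#' fraction affected lies strictly inside (0, 1) and carries a finite
#' positive CI, then classifies it with [classifyCI()]. The median is the
#' default central summary; the mean is available behind `center = "mean"`.
#' With zero valid points the record is returned with status
#' `"summary-failure"` (a warning, not an error) so a screen over many
#' combinations continues.
#'
#' @param points `data.frame` with columns `dose_a`, `dose_b`, `fa`, `ci`.
#' @param cellLine,drugA,drugB labels stored on the record.
#' @param center `"median"` (default) or `"mean"`.
#' @return A [CombinationRecord-class].
#' @examples
#' pts <- data.frame(dose_a = 1:5, dose_b = 1:5, fa = seq(0.2, 0.8, len = 5),
#'                   ci = c(0.4, 0.5, 0.6, 0.9, 1.1))
#' summarizeCombination(pts, "OVCAR8", "olaparib", "drugX")
#' @export
summarizeCombination <- function(points, cellLine = NA_character_,
                                 drugA = NA_character_, drugB = NA_character_,
                                 center = c("median", "mean")) {
  center <- match.arg(center)
  if (!all(c("dose_a", "dose_b", "fa", "ci") %in% names(points)))
    stop("'points' needs columns dose_a, dose_b, fa, ci")
  valid <- is.finite(points$ci) & points$ci > 0 &
    is.finite(points$fa) & points$fa > 0 & points$fa < 1
  if (!any(valid)) {
    warning("no valid CI points for ", drugA, " + ", drugB, " in ", cellLine,
            "; recording summary-failure")
    return(new("CombinationRecord", cellLine = as.character(cellLine),
               drugA = as.character(drugA), drugB = as.character(drugB),
               points = points, medianCI = NA_real_,
               synergyClass = NA_character_, status = "summary-failure"))
  }
  ci <- points$ci[valid]
  mci <- if (center == "median") median(ci) else mean(ci)
  new("CombinationRecord", cellLine = as.character(cellLine),
      drugA = as.character(drugA), drugB = as.character(drugB),
      points = points, medianCI = mci, synergyClass = classifyCI(mci),
      status = "ok")
}

#' Score a combination screen from long-format plate tables
#'
#' Convenience wrapper over the whole CI pipeline: fits each single agent
#' from the single-agent table, then for each (cell line, drug pair)
#' computes the fraction affected at every dose pair (averaging replicates),
#' the per-point CI, and the summarized [CombinationRecord-class].
#'
#' @param singleAgent `data.frame` with columns `cell_line`, `drug`, `dose`,
#'   `fa` (or `viability` plus a `control` column, converted via
#'   [fractionAffected()]).
#' @param combinations `data.frame` with columns `cell_line`, `drug_a`,
#'   `dose_a`, `drug_b`, `dose_b`, `fa`.
#' @param center passed to [summarizeCombination()].
#' @return A list with `fits` (named list of [MedianEffectFit-class] per
#'   cell line/drug), `records` (list of [CombinationRecord-class]) and
#'   `table` (one summary row per combination, with a `status` column).
#' @export
scoreScreen <- function(singleAgent, combinations, center = "median") {
  need <- c("cell_line", "drug", "dose", "fa")
  if (!all(need %in% names(singleAgent)))
    stop("'singleAgent' needs columns ", paste(need, collapse = ", "))
  fits <- list()
  for (key in unique(paste(singleAgent$cell_line, singleAgent$drug, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1L]]
    sub <- singleAgent[singleAgent$cell_line == parts[1L] &
                         singleAgent$drug == parts[2L], ]
    agg <- stats::aggregate(fa ~ dose, data = sub, FUN = mean)
    fits[[key]] <- tryCatch(
      fitMedianEffect(agg$dose, agg$fa, drug = parts[2L]),
      error = function(e) {
        warning("fit failed for ", parts[2L], " in ", parts[1L], ": ",
                conditionMessage(e))
        new("MedianEffectFit", drug = parts[2L], status = "failed")
      })
  }
  records <- list()
  rows <- list()
  combos <- unique(combinations[, c("cell_line", "drug_a", "drug_b")])
  for (i in seq_len(nrow(combos))) {
    cl <- combos$cell_line[i]; da <- combos$drug_a[i]; db <- combos$drug_b[i]
    sub <- combinations[combinations$cell_line == cl &
                          combinations$drug_a == da &
                          combinations$drug_b == db, ]
    agg <- stats::aggregate(fa ~ dose_a + dose_b, data = sub, FUN = mean)
    fitA <- fits[[paste(cl, da, sep = "\r")]]
    fitB <- fits[[paste(cl, db, sep = "\r")]]
    okFits <- !is.null(fitA) && !is.null(fitB) &&
      fitA@status == "ok" && fitB@status == "ok"
    fa <- .clip(agg$fa, .FA_EPS, 1 - .FA_EPS)
    ci <- if (okFits)
      combinationIndex(fitA, fitB, agg$dose_a, agg$dose_b, fa)
    else rep(NA_real_, nrow(agg))
    pts <- data.frame(dose_a = agg$dose_a, dose_b = agg$dose_b,
                      fa = fa, ci = ci)
    rec <- summarizeCombination(pts, cl, da, db, center = center)
    records[[length(records) + 1L]] <- rec
    rows[[length(rows) + 1L]] <- data.frame(
      cell_line = cl, drug_a = da, drug_b = db,
      n_points = nrow(pts), median_ci = rec@medianCI,
      synergy_class = rec@synergyClass, status = rec@status,
      stringsAsFactors = FALSE)
  }
  list(fits = fits, records = records, table = do.call(rbind, rows))
}
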