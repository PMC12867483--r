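#' Expression fold change (log2) of a gene under treatment
#'
#' \deqn{Fexp(t)_g = \log_2(exp(t)_g) - \log_2(expC_g)}
#'
#' @param expTreat,expControl strictly positive linear-scale expression
#'   under treatment and control (vectors allowed).
#' @return Log2 fold change(s).
#' @examples
#' expressionFoldChange(25, 100)  # -2
#' @export
expressionFoldChange <- function(expTreat, expControl) {
  .stopIfNotPositive(expTreat, "expTreat")
  .stopIfNotPositive(expControl, "expControl")
  log2(expTreat) - log2(expControl)
}

#' IC50 fold change after gene knockdown
#'
#' \deqn{FIC50(k)_g = IC50(k)_g / IC50C}
#' A value below 1 means knocking the gene down sensitized the cell line to
#' the PARP inhibitor.
#'
#' @param ic50Knockdown,ic50Control strictly positive IC50s under gene
#'   knockdown and control transfection.
#' @return Positive fold change(s).
#' @examples
#' ic50FoldChange(0.25, 1)  # 0.25: strong sensitization
#' @export
ic50FoldChange <- function(ic50Knockdown, ic50Control) {
  .stopIfNotPositive(ic50Knockdown, "ic50Knockdown")
  .stopIfNotPositive(ic50Control, "ic50Control")
  ic50Knockdown / ic50Control
}

#' Min-max feature scaling of IC50 fold changes
#'
#' \deqn{F' = (F - F_{min}) / (F_{max} - F_{min})}
#' across the screened panel, so the strongest sensitizer maps to 0 and the
#' least to 1. A constant input is degenerate: every value is set to 0.5
#' with a warning.
#'
#' @param values numeric vector of fold changes (>= 2 values).
#' @return Values scaled into `[0, 1]`.
#' @examples
#' minmaxScale(c(0.25, 1.0, 1.2))
#' @export
minmaxScale <- function(values) {
  if (length(values) < 2L)
    stop("min-max scaling needs at least 2 values, got ", length(values))
  if (any(!is.finite(values))) stop("'values' must be finite")
  rng <- range(values)
  if (diff(rng) == 0) {
    warning("degenerate min-max scaling: all values equal (", rng[1L],
            "); returning 0.5")
    return(rep(0.5, length(values)))
  }
  (values - rng[1L]) / diff(rng)
}

#' Impact score of an siRNA sensitization screen
#'
#' Combines PRMT-inhibitor-induced transcriptional repression with
#' siRNA-knockdown PARP-inhibitor sensitization into one per-gene score.
#' Two variants are computed:
#'
#' * **literal** — exactly the published arithmetic:
#'   \eqn{Score_g = F'IC50(k)_g \cdot \sum_t Fexp(t)_g}, with min-max-scaled
#'   IC50 fold change \eqn{F'} and the sum over all treatments present;
#'   ranked by most negative score first. Note that under this arithmetic
#'   the panel's strongest sensitizer has \eqn{F' = 0} and hence score 0.
#' * **corrected** — replaces \eqn{F'} with \eqn{1 - F'} (so the strongest
#'   sensitizer scores 1) and ranks by \eqn{(1 - F') \cdot (-\sum_t Fexp)}
#'   descending, so strong repression combined with strong sensitization
#'   ranks first. This is the default ranking.
#'
#' Both scores and ranks are always reported side by side; `variant` only
#' selects which rank is copied into the `rank` column. Genes with missing
#' treatment or IC50 values are flagged (`status = "excluded"`) and left out
#' of the scaling and ranking rather than silently dropped.
#'
#' @param inputs `data.frame` with columns `gene`, one `expr_<treatment>`
#'   column per treatment, `expr_control`, `ic50_knockdown`,
#'   `ic50_control` (see [simulateSirnaScreen()] for the layout).
#' @param variant `"corrected"` (default) or `"literal"`.
#' @return `data.frame` with per-treatment `fexp_*` columns, `sum_fexp`,
#'   `fic50`, `fic50_scaled`, `score_literal`, `rank_literal`,
#'   `impact_corrected`, `rank_corrected`, `rank` (the chosen variant's)
#'   and `status`; attribute `"variant"` records the choice.
#' @examples
#' scr <- simulateSirnaScreen(paste0("g", 1:13), drivers = "g1",
#'                            cfg = simConfig(noiseSd = 0.1))
#' head(impactScore(scr$inputs))
#' @export
impactScore <- function(inputs, variant = c("corrected", "literal")) {
  variant <- match.arg(variant)
  exprCols <- setdiff(grep("^expr_", names(inputs), value = TRUE),
                      "expr_control")
  need <- c("gene", "expr_control", "ic50_knockdown", "ic50_control")
  if (!all(need %in% names(inputs)) || length(exprCols) == 0L)
    stop("'inputs' needs columns gene, expr_<treatment>..., expr_control, ",
         "ic50_knockdown, ic50_control")
  if (nrow(inputs) < 2L) stop("impact scoring needs at least 2 genes")

  num <- as.matrix(inputs[, c(exprCols, "expr_control", "ic50_knockdown",
                              "ic50_control")])
  ok <- apply(is.finite(num) & num > 0, 1L, all)
  if (!all(ok))
    warning(sum(!ok), " gene(s) with missing/nonpositive values excluded: ",
            paste(utils::head(inputs$gene[!ok], 5), collapse = ", "))
  if (sum(ok) < 2L) stop("fewer than 2 complete genes; cannot scale")

  out <- data.frame(gene = inputs$gene, stringsAsFactors = FALSE)
  for (ec in exprCols) {
    fe <- rep(NA_real_, nrow(inputs))
    fe[ok] <- expressionFoldChange(inputs[[ec]][ok], inputs$expr_control[ok])
    out[[sub("^expr_", "fexp_", ec)]] <- fe
  }
  out$sum_fexp <- rowSums(out[, sub("^expr_", "fexp_", exprCols), drop = FALSE])
  out$fic50 <- NA_real_
  out$fic50[ok] <- ic50FoldChange(inputs$ic50_knockdown[ok],
                                  inputs$ic50_control[ok])
  out$fic50_scaled <- NA_real_
  out$fic50_scaled[ok] <- minmaxScale(out$fic50[ok])

  out$score_literal <- out$fic50_scaled * out$sum_fexp
  out$impact_corrected <- (1 - out$fic50_scaled) * (-out$sum_fexp)
  out$rank_literal <- NA_integer_
  out$rank_literal[ok] <- rank(out$score_literal[ok], ties.method = "first")
  out$rank_corrected <- NA_integer_
  out$rank_corrected[ok] <- rank(-out$impact_corrected[ok], ties.method = "first")
  out$rank <- if (variant == "corrected") out$rank_corrected else out$rank_literal
  out$status <- ifelse(ok, "ok", "excluded")
  attr(out, "variant") <- variant
  out
}
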