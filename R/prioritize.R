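#' Normalize a screening feature to the favorable [0, 1] scale
#'
#' Min-max scaling after orienting the feature so that 1 is always the most
#' favorable value: for `direction = "lower_better"` (e.g. median CI,
#' single-agent IC50, dependency effect score) the minimum maps to 1; for
#' `"higher_better"` (e.g. tumor up-regulation meta-z, genomic-alteration
#' recurrence) the maximum maps to 1. Missing values are imputed at 0
#' (least favorable) with a warning, so inhibitors lacking a feature stay in
#' the ranked panel instead of being dropped. If all finite values are equal
#' the feature is uninformative: every value maps to 0.5 and a warning flags
#' the degeneracy.
#'
#' @param values numeric feature vector (>= 2 finite values unless
#'   degenerate).
#' @param direction `"lower_better"` or `"higher_better"`.
#' @return Numeric vector in `[0, 1]`, 1 = most favorable.
#' @examples
#' normalizeFeature(c(0.5, 1.0, 1.5), "lower_better")  # 1, 0.5, 0
#' @export
normalizeFeature <- function(values,
                             direction = c("lower_better", "higher_better")) {
  direction <- match.arg(direction)
  fin <- is.finite(values)
  if (!any(fin)) stop("no finite feature values")
  v <- values[fin]
  rng <- range(v)
  if (diff(rng) == 0) {
    warning("degenerate feature: all values equal (", rng[1L],
            "); mapping to 0.5")
    out <- rep(0.5, length(values))
  } else {
    scaled <- (values - rng[1L]) / diff(rng)
    out <- if (direction == "lower_better") 1 - scaled else scaled
  }
  if (any(!fin)) {
    warning(sum(!fin), " missing feature value(s) imputed as least favorable (0)")
    out[!fin] <- 0
  }
  out
}

#' Five-feature clinical priority score
#'
#' Weighted sum of five normalized features collected per inhibitor:
#' combination CI across screened lines, single-agent efficacy, cancer
#' dependency of the target gene, tumor expression dysregulation, and
#' genomic-alteration recurrence. Each feature must already be oriented to
#' the favorable `[0, 1]` scale (see [normalizeFeature()]); the score is
#' then in `[0, 1]`. Weights default to equal (0.2 each) and must be
#' non-negative and sum to 1.
#'
#' @param features numeric matrix or `data.frame` of normalized features,
#'   one row per inhibitor, five columns.
#' @param weights numeric length-5 non-negative weight vector summing to 1.
#' @return Numeric score per inhibitor (named if `features` has row names).
#' @examples
#' f <- matrix(1, 1, 5)
#' priorityScore(f)  # 1
#' @export
priorityScore <- function(features, weights = rep(0.2, 5)) {
  features <- as.matrix(features)
  if (ncol(features) != 5L)
    stop("'features' must have exactly five columns, got ", ncol(features))
  if (length(weights) != 5L || any(!is.finite(weights)) || any(weights < 0))
    stop("'weights' must be five non-negative finite numbers")
  if (abs(sum(weights) - 1) > 1e-9)
    stop("'weights' must sum to 1 (got ", sum(weights), ")")
  if (any(features < -1e-9 | features > 1 + 1e-9, na.rm = TRUE))
    stop("'features' must be normalized to [0, 1] first")
  drop(features %*% weights)
}

#' Rank a scored inhibitor panel
#'
#' Stable descending sort by score; ties are broken lexicographically by
#' inhibitor label so the ranking is deterministic.
#'
#' @param scores named numeric vector of priority scores.
#' @return `data.frame` with columns `inhibitor`, `score`, `rank`.
#' @examples
#' rankPanel(c(B = 0.5, A = 0.9))
#' @export
rankPanel <- function(scores) {
  if (length(scores) < 1L) stop("need at least one scored inhibitor")
  if (is.null(names(scores)))
    names(scores) <- sprintf("inhibitor%02d", seq_along(scores))
  ord <- order(-scores, names(scores))
  data.frame(inhibitor = names(scores)[ord], score = unname(scores[ord]),
             rank = seq_along(scores), stringsAsFactors = FALSE)
}

#' Normalize, score and rank a raw feature table
#'
#' One-call wrapper around [normalizeFeature()], [priorityScore()] and
#' [rankPanel()] with the screen's fixed feature orientations:
#' `median_ci`, `single_agent` and `dependency` are lower-better (a lower
#' dependency effect score means stronger cancer-cell reliance on the
#' target), `expr_meta_z` and `genomic_alteration` are higher-better.
#'
#' @param features `data.frame` with columns `inhibitor`, `median_ci`,
#'   `single_agent`, `dependency`, `expr_meta_z`, `genomic_alteration`
#'   (raw, unnormalized; `NA` allowed and imputed least-favorable).
#' @param weights passed to [priorityScore()].
#' @return `data.frame`: one row per inhibitor, the normalized features
#'   (columns prefixed `norm_`), `score` and `rank`, ordered by rank. The
#'   applied weights and orientations are attached as attributes so reports
#'   can record them.
#' @export
prioritizePanel <- function(features, weights = rep(0.2, 5)) {
  cols <- c("median_ci", "single_agent", "dependency", "expr_meta_z",
            "genomic_alteration")
  orient <- c(median_ci = "lower_better", single_agent = "lower_better",
              dependency = "lower_better", expr_meta_z = "higher_better",
              genomic_alteration = "higher_better")
  if (!all(c("inhibitor", cols) %in% names(features)))
    stop("'features' needs columns inhibitor, ", paste(cols, collapse = ", "))
  norm <- vapply(cols, function(cn)
    normalizeFeature(features[[cn]], orient[[cn]]), numeric(nrow(features)))
  norm <- matrix(norm, nrow = nrow(features),
                 dimnames = list(features$inhibitor, paste0("norm_", cols)))
  score <- priorityScore(norm, weights)
  ranked <- rankPanel(setNames(score, features$inhibitor))
  out <- cbind(ranked,
               as.data.frame(norm)[match(ranked$inhibitor, features$inhibitor), ,
                                   drop = FALSE])
  rownames(out) <- NULL
  attr(out, "weights") <- setNames(weights, cols)
  attr(out, "orientation") <- orient
  out
}
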