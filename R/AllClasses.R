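#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData
#' @importFrom S4Vectors DataFrame
#' @importFrom stats coef cor lm median na.omit p.adjust pchisq pnorm pt qnorm
#'   rbinom rexp rnorm runif sd setNames uniroot fisher.test t.test cor.test
NULL

#' Simulation configuration
#'
#' Holds the reproducibility and noise settings shared by every synthetic-data
#' generator in the package. Identical configurations yield bit-identical
#' outputs; `noiseSd = 0` yields deterministic noiseless data.
#'
#' @slot seed integer seed; all randomness inside a generator is derived from
#'   it (hierarchically split per dataset, so adding a dataset does not
#'   perturb the others).
#' @slot noiseSd non-negative standard deviation of the additive Gaussian
#'   noise on the fraction-affected (viability) scale.
#' @slot nReplicates positive number of technical replicates per condition.
#'
#' @seealso [simConfig()]
#' @export
setClass("SimConfig",
  representation(seed = "integer", noiseSd = "numeric", nReplicates = "integer"),
  prototype(seed = 1L, noiseSd = 0, nReplicates = 1L)
)

setValidity("SimConfig", function(object) {
  msg <- NULL
  if (length(object@seed) != 1L || is.na(object@seed))
    msg <- c(msg, "'seed' must be a single non-missing integer")
  if (length(object@noiseSd) != 1L || is.na(object@noiseSd) || object@noiseSd < 0)
    msg <- c(msg, "'noiseSd' must be a single non-negative number")
  if (length(object@nReplicates) != 1L || is.na(object@nReplicates) ||
      object@nReplicates < 1L)
    msg <- c(msg, "'nReplicates' must be a positive integer")
  if (is.null(msg)) TRUE else msg
})

#' Construct a simulation configuration
#'
#' @param seed integer seed for the generator.
#' @param noiseSd non-negative Gaussian noise standard deviation on the
#'   fraction-affected scale.
#' @param nReplicates positive integer number of replicates.
#'
#' @return A [SimConfig-class] object.
#' @examples
#' simConfig(seed = 7, noiseSd = 0.02, nReplicates = 3)
#' @export
simConfig <- function(seed = 1L, noiseSd = 0, nReplicates = 1L) {
  new("SimConfig", seed = as.integer(seed), noiseSd = as.numeric(noiseSd),
      nReplicates = as.integer(nReplicates))
}

#' Median-effect fit for a single agent
#'
#' Result of fitting the median-effect equation
#' \deqn{fa/fu = (D/Dm)^m, \quad fu = 1 - fa}
#' to a dose-response curve via the linearization
#' \eqn{\log(fa/(1-fa)) = m \log D - m \log Dm}. `Dm` is the median-effect
#' dose (the IC50: `fa = 0.5` at `D = Dm`) and `m` the sigmoidicity slope.
#'
#' @slot drug label of the fitted agent.
#' @slot m median-effect slope (dimensionless).
#' @slot Dm median-effect dose, in the drug's concentration units.
#' @slot r correlation coefficient of the linearized fit, in \[-1, 1\].
#' @slot nPoints number of dose-response points used.
#' @slot nClipped number of points whose fraction affected was clipped into
#'   `[1e-6, 1 - 1e-6]` before linearization.
#' @slot status `"ok"`, `"non-monotone"` (estimated `m <= 0`, record kept
#'   with a warning) or `"failed"`.
#'
#' @seealso [fitMedianEffect()], [doseForEffect()], [combinationIndex()]
#' @export
setClass("MedianEffectFit",
  representation(drug = "character", m = "numeric", Dm = "numeric",
                 r = "numeric", nPoints = "integer", nClipped = "integer",
                 status = "character"),
  prototype(drug = NA_character_, m = NA_real_, Dm = NA_real_, r = NA_real_,
            nPoints = 0L, nClipped = 0L, status = "failed")
)

setValidity("MedianEffectFit", function(object) {
  msg <- NULL
  if (!object@status %in% c("ok", "non-monotone", "failed"))
    msg <- c(msg, "'status' must be one of 'ok', 'non-monotone', 'failed'")
  if (object@status == "ok") {
    if (!is.finite(object@Dm) || object@Dm <= 0)
      msg <- c(msg, "'Dm' must be positive for a successful fit")
    if (object@nPoints < 3L)
      msg <- c(msg, "a successful fit needs at least 3 points")
    if (is.finite(object@r) && abs(object@r) > 1 + 1e-12)
      msg <- c(msg, "'r' must lie in [-1, 1]")
  }
  if (is.null(msg)) TRUE else msg
})

#' Summary of one drug-pair combination
#'
#' Per-dose-point combination indices for one drug pair in one cell line,
#' together with the median CI and the synergy call at the screen's
#' thresholds (CI < 0.83 synergism, 0.83-1.2 additive, > 1.2 antagonism).
#'
#' @slot cellLine,drugA,drugB labels.
#' @slot points `data.frame` with columns `dose_a`, `dose_b`, `fa`, `ci`.
#' @slot medianCI central CI across points with `fa` strictly inside (0, 1);
#'   the median by default, the mean if requested at summary time.
#' @slot synergyClass `"synergism"`, `"additive"` or `"antagonism"`.
#' @slot status `"ok"` or `"summary-failure"` (no valid points).
#'
#' @seealso [summarizeCombination()], [classifyCI()]
#' @export
setClass("CombinationRecord",
  representation(cellLine = "character", drugA = "character",
                 drugB = "character", points = "data.frame",
                 medianCI = "numeric", synergyClass = "character",
                 status = "character"),
  prototype(cellLine = NA_character_, drugA = NA_character_,
            drugB = NA_character_, points = data.frame(),
            medianCI = NA_real_, synergyClass = NA_character_, status = "ok")
)

setValidity("CombinationRecord", function(object) {
  msg <- NULL
  if (!object@status %in% c("ok", "summary-failure"))
    msg <- c(msg, "'status' must be 'ok' or 'summary-failure'")
  if (object@status == "ok") {
    if (!all(c("dose_a", "dose_b", "fa", "ci") %in% names(object@points)))
      msg <- c(msg, "'points' needs columns dose_a, dose_b, fa, ci")
    if (!is.finite(object@medianCI) || object@medianCI <= 0)
      msg <- c(msg, "'medianCI' must be positive")
    if (!object@synergyClass %in% c("synergism", "additive", "antagonism"))
      msg <- c(msg, "invalid 'synergyClass'")
  }
  if (is.null(msg)) TRUE else msg
})

#' Directional meta-analysis result
#'
#' Per-gene result of a two-direction Fisher combined-probability
#' meta-analysis across cancer types: per-direction meta-p values, the
#' chosen (more significant) direction, and the signed meta-z
#' (`qnorm(meta_p, lower.tail = FALSE)`, negated for the second direction).
#'
#' @slot results `data.frame` with one row per gene: `gene`,
#'   `meta_p_<dir1>`, `meta_p_<dir2>`, `direction`, `meta_z`,
#'   `n_units`, `tie`.
#' @slot perUnit long `data.frame` of the per-cancer inputs (`gene`, `unit`,
#'   one p-value column per direction, plus any per-unit statistic).
#' @slot directions the two direction labels, e.g. `c("up", "down")` or
#'   `c("risky", "protective")`; the first is positive on the meta-z scale.
#' @slot excluded `data.frame` (`unit`, `reason`) of strata excluded from
#'   the combination (too few normals, Cox failures, ...).
#'
#' @seealso [directionalMeta()], [deMeta()], [survivalMeta()]
#' @export
setClass("MetaResult",
  representation(results = "data.frame", perUnit = "data.frame",
                 directions = "character", excluded = "data.frame"),
  prototype(results = data.frame(), perUnit = data.frame(),
            directions = c("up", "down"),
            excluded = data.frame(unit = character(), reason = character()))
)

setValidity("MetaResult", function(object) {
  msg <- NULL
  if (length(object@directions) != 2L)
    msg <- c(msg, "'directions' must have exactly two labels")
  if (nrow(object@results) &&
      !all(c("gene", "direction", "meta_z") %in% names(object@results)))
    msg <- c(msg, "'results' needs columns gene, direction, meta_z")
  if (is.null(msg)) TRUE else msg
})

#' Multi-source gene catalog
#'
#' Named source gene lists plus sets assembled from them by explicit,
#' recorded rules: \eqn{\ge k}-of-\eqn{n} voting and provenance-tracked
#' unions. Gene identifiers are compared after uppercasing and whitespace
#' stripping.
#'
#' @slot sources named list of character vectors (case-normalized, unique).
#' @slot sets named list of character vectors, the assembled sets.
#' @slot rules named list; for each assembled set, a record of the rule
#'   (`"vote"` or `"union"`), its inputs, and `k` where applicable.
#'
#' @seealso [geneCatalog()], [voteAssemble()], [unionAssemble()],
#'   [buildBRCAnessCatalog()]
#' @export
setClass("GeneCatalog",
  representation(sources = "list", sets = "list", rules = "list"),
  prototype(sources = list(), sets = list(), rules = list())
)

setValidity("GeneCatalog", function(object) {
  msg <- NULL
  if (length(object@sources) && is.null(names(object@sources)))
    msg <- c(msg, "'sources' must be a named list")
  if (length(object@sets) && is.null(names(object@sets)))
    msg <- c(msg, "'sets' must be a named list")
  if (!identical(sort(names(object@sets)), sort(names(object@rules))))
    msg <- c(msg, "every assembled set must record its rule")
  for (s in object@sets)
    if (anyDuplicated(s)) msg <- c(msg, "assembled sets must not contain duplicates")
  if (is.null(msg)) TRUE else msg
})

#' Pan-cancer expression cohort
#'
#' A [SummarizedExperiment::SummarizedExperiment] carrying a gene-by-sample
#' `log2expr` assay with per-sample `cancer_type` and `sample_type`
#' (`"tumor"`/`"normal"`) annotation; optional `pair_id` links tumor samples
#' to their matched normals for paired (protein-style) analyses.
#'
#' @seealso [ExpressionCohort()], [deMeta()], [signatureScore()]
#' @export
setClass("ExpressionCohort", contains = "SummarizedExperiment")

setValidity("ExpressionCohort", function(object) {
  msg <- NULL
  if (!"log2expr" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'log2expr' is required")
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("cancer_type", "sample_type") %in% names(cd)))
    msg <- c(msg, "colData must contain 'cancer_type' and 'sample_type'")
  else if (!all(cd$sample_type %in% c("tumor", "normal")))
    msg <- c(msg, "'sample_type' must be 'tumor' or 'normal'")
  if (is.null(msg)) TRUE else msg
})

#' Construct an expression cohort
#'
#' @param log2expr numeric gene-by-sample matrix of log2 expression, with
#'   gene row names.
#' @param cancerType character vector, one cancer-type label per sample.
#' @param sampleType character vector of `"tumor"`/`"normal"` flags.
#' @param pairId optional vector linking matched tumor/normal samples
#'   (`NA` for unpaired samples).
#'
#' @return An [ExpressionCohort-class].
#' @examples
#' m <- matrix(rnorm(20), 2, 10, dimnames = list(c("PRMT1", "PRMT5"), NULL))
#' ExpressionCohort(m, rep("BRCA", 10), rep(c("tumor", "normal"), each = 5))
#' @export
ExpressionCohort <- function(log2expr, cancerType, sampleType, pairId = NULL) {
  log2expr <- as.matrix(log2expr)
  if (is.null(rownames(log2expr)))
    stop("'log2expr' must have gene row names")
  cd <- S4Vectors::DataFrame(cancer_type = as.character(cancerType),
                             sample_type = as.character(sampleType))
  if (!is.null(pairId)) cd$pair_id <- pairId
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(log2expr = log2expr), colData = cd)
  new("ExpressionCohort", se)
}
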