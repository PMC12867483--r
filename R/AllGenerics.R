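#' Accessors for fitted and derived objects
#'
#' Small accessor generics so downstream code never touches slots directly:
#' `slope()` and `dm()` read the median-effect parameters of a
#' [MedianEffectFit-class] (`dm()` is the IC50), `fitStatus()` its status;
#' `medianCI()` and `synergyClass()` read the summary of a
#' [CombinationRecord-class]; `metaZ()`, `chosenDirection()` and
#' `excludedUnits()` read a [MetaResult-class]; `catalogSources()` and
#' `catalogSet()` read a [GeneCatalog-class].
#'
#' @param object the object to read from.
#' @param name for `catalogSet()`, the assembled set to extract.
#' @return The corresponding slot contents; for [MetaResult-class]
#'   accessors, named per-gene vectors.
#' @name accessors
#' @examples
#' fit <- fitMedianEffect(c(0.25, 0.5, 1, 2, 4), c(0.2, 1/3, 0.5, 2/3, 0.8))
#' slope(fit)
#' dm(fit)
NULL

#' @rdname accessors
#' @export
setGeneric("slope", function(object) standardGeneric("slope"))
#' @rdname accessors
#' @export
setGeneric("dm", function(object) standardGeneric("dm"))
#' @rdname accessors
#' @export
setGeneric("fitStatus", function(object) standardGeneric("fitStatus"))
#' @rdname accessors
#' @export
setGeneric("medianCI", function(object) standardGeneric("medianCI"))
#' @rdname accessors
#' @export
setGeneric("synergyClass", function(object) standardGeneric("synergyClass"))
#' @rdname accessors
#' @export
setGeneric("metaZ", function(object) standardGeneric("metaZ"))
#' @rdname accessors
#' @export
setGeneric("chosenDirection", function(object) standardGeneric("chosenDirection"))
#' @rdname accessors
#' @export
setGeneric("excludedUnits", function(object) standardGeneric("excludedUnits"))
#' @rdname accessors
#' @export
setGeneric("catalogSources", function(object) standardGeneric("catalogSources"))
#' @rdname accessors
#' @export
setGeneric("catalogSet", function(object, name) standardGeneric("catalogSet"))

#' @rdname accessors
#' @export
setMethod("slope", "MedianEffectFit", function(object) object@m)
#' @rdname accessors
#' @export
setMethod("dm", "MedianEffectFit", function(object) object@Dm)
#' @rdname accessors
#' @export
setMethod("fitStatus", "MedianEffectFit", function(object) object@status)
#' @rdname accessors
#' @export
setMethod("medianCI", "CombinationRecord", function(object) object@medianCI)
#' @rdname accessors
#' @export
setMethod("synergyClass", "CombinationRecord", function(object) object@synergyClass)

#' @rdname accessors
#' @export
setMethod("metaZ", "MetaResult", function(object)
  setNames(object@results$meta_z, object@results$gene))
#' @rdname accessors
#' @export
setMethod("chosenDirection", "MetaResult", function(object)
  setNames(object@results$direction, object@results$gene))
#' @rdname accessors
#' @export
setMethod("excludedUnits", "MetaResult", function(object) object@excluded)

#' @rdname accessors
#' @export
setMethod("catalogSources", "GeneCatalog", function(object) object@sources)
#' @rdname accessors
#' @export
setMethod("catalogSet", "GeneCatalog", function(object, name) {
  if (!name %in% names(object@sets))
    stop("no assembled set named '", name, "'")
  object@sets[[name]]
})

setMethod("show", "MedianEffectFit", function(object) {
  cat("MedianEffectFit (", object@status, ")\n", sep = "")
  cat("  drug: ", object@drug, "\n", sep = "")
  cat(sprintf("  m = %.4g, Dm = %.4g, r = %.4f\n", object@m, object@Dm, object@r))
  cat(sprintf("  points: %d (%d clipped)\n", object@nPoints, object@nClipped))
})

setMethod("show", "CombinationRecord", function(object) {
  cat("CombinationRecord (", object@status, ")\n", sep = "")
  cat("  ", object@drugA, " + ", object@drugB, " in ", object@cellLine, "\n",
      sep = "")
  if (object@status == "ok")
    cat(sprintf("  median CI = %.3f (%s), %d points\n", object@medianCI,
                object@synergyClass, nrow(object@points)))
})

setMethod("show", "MetaResult", function(object) {
  cat("MetaResult: ", nrow(object@results), " gene(s), directions ",
      paste(object@directions, collapse = "/"), "\n", sep = "")
  if (nrow(object@results)) {
    print(utils::head(object@results, 5))
    if (nrow(object@results) > 5) cat("  ...\n")
  }
  if (nrow(object@excluded))
    cat("  excluded units:", nrow(object@excluded), "\n")
})

setMethod("show", "GeneCatalog", function(object) {
  cat("GeneCatalog with", length(object@sources), "source(s) and",
      length(object@sets), "assembled set(s)\n")
  for (nm in names(object@sets))
    cat(sprintf("  %s: %d genes (%s)\n", nm, length(object@sets[[nm]]),
                object@rules[[nm]]$rule))
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf("SimConfig(seed = %d, noiseSd = %g, nReplicates = %d)\n",
              object@seed, object@noiseSd, object@nReplicates))
})
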