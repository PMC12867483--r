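# gene identifiers are compared after uppercasing and whitespace stripping;
# alias (synonym) resolution is intentionally out of scope.
.normalizeGenes <- function(x) {
  x <- toupper(trimws(as.character(x)))
  unique(x[nzchar(x)])
}

#' Construct a gene catalog from source lists
#'
#' @param sources named list of character gene vectors; identifiers are
#'   uppercased, whitespace-stripped and de-duplicated.
#' @return A [GeneCatalog-class] with no assembled sets yet.
#' @examples
#' geneCatalog(list(db1 = c("brca1", "RAD51"), db2 = "BRCA1"))
#' @export
geneCatalog <- function(sources) {
  if (!length(sources) || is.null(names(sources)) || any(!nzchar(names(sources))))
    stop("'sources' must be a non-empty named list of gene vectors")
  new("GeneCatalog", sources = lapply(sources, .normalizeGenes),
      sets = list(), rules = list())
}

#' Assemble a gene set by at-least-k-of-n voting
#'
#' Returns the genes present in at least `k` of the `n` supplied source
#' lists. `k = 1` is the plain union, `k = n` the intersection; the result
#' shrinks monotonically as `k` grows. If the source lists share no genes
#' at all, a note is emitted since that often signals an identifier-scheme
#' mismatch rather than true disjointness.
#'
#' @param sources a [GeneCatalog-class] (votes over its sources) or a list
#'   of character gene vectors.
#' @param k minimum number of supporting sources, `1 <= k <= n`.
#' @return Sorted character vector of genes.
#' @examples
#' voteAssemble(list(c("a", "b"), c("b", "c"), "c"), k = 2)  # "B" "C"
#' @export
voteAssemble <- function(sources, k) {
  if (is(sources, "GeneCatalog")) sources <- sources@sources
  if (!is.list(sources) || !length(sources))
    stop("'sources' must be a non-empty list of gene vectors")
  n <- length(sources)
  if (length(k) != 1L || is.na(k) || k < 1L || k > n)
    stop("'k' must satisfy 1 <= k <= ", n, " (got ", k, ")")
  lists <- lapply(sources, .normalizeGenes)
  counts <- table(unlist(lists, use.names = FALSE))
  if (n > 1L && max(counts) == 1L)
    message("note: the sources share no genes; check identifier schemes")
  sort(names(counts)[counts >= k])
}

#' Union of two gene sets with per-gene provenance
#'
#' De-duplicated union recording, for every gene, whether it came from the
#' first set only, the second only, or both.
#'
#' @param setA,setB character gene vectors.
#' @param nameA,nameB labels used in the provenance column.
#' @return `data.frame` with columns `gene` and `provenance`
#'   (`"<nameA>-only"`, `"<nameB>-only"`, `"both"`), sorted by gene.
#' @examples
#' unionAssemble(c("b", "c"), c("c", "d"))
#' @export
unionAssemble <- function(setA, setB, nameA = "A", nameB = "B") {
  a <- .normalizeGenes(setA); b <- .normalizeGenes(setB)
  genes <- sort(union(a, b))
  prov <- ifelse(genes %in% a & genes %in% b, "both",
                 ifelse(genes %in% a, paste0(nameA, "-only"),
                        paste0(nameB, "-only")))
  data.frame(gene = genes, provenance = prov, stringsAsFactors = FALSE)
}

#' Add an assembled set to a catalog
#'
#' `addVoteSet()` assembles by [voteAssemble()] over named sources;
#' `addUnionSet()` takes the provenance-tracked union of two existing
#' sets or sources. Every assembled set records its rule.
#'
#' @param catalog a [GeneCatalog-class].
#' @param name name of the new assembled set.
#' @param sourceNames names of sources (for voting) or of sets/sources
#'   (for the union; assembled sets are looked up first).
#' @param k voting threshold.
#' @return The updated [GeneCatalog-class].
#' @export
addVoteSet <- function(catalog, name, sourceNames, k) {
  stopifnot(is(catalog, "GeneCatalog"))
  if (!all(sourceNames %in% names(catalog@sources)))
    stop("unknown source(s): ",
         paste(setdiff(sourceNames, names(catalog@sources)), collapse = ", "))
  genes <- voteAssemble(catalog@sources[sourceNames], k)
  catalog@sets[[name]] <- genes
  catalog@rules[[name]] <- list(rule = "vote", k = k, sources = sourceNames)
  validObject(catalog)
  catalog
}

.lookupSet <- function(catalog, nm) {
  if (nm %in% names(catalog@sets)) return(catalog@sets[[nm]])
  if (nm %in% names(catalog@sources)) return(catalog@sources[[nm]])
  stop("unknown set or source '", nm, "'")
}

#' @rdname addVoteSet
#' @export
addUnionSet <- function(catalog, name, sourceNames) {
  stopifnot(is(catalog, "GeneCatalog"), length(sourceNames) == 2L)
  u <- unionAssemble(.lookupSet(catalog, sourceNames[1L]),
                     .lookupSet(catalog, sourceNames[2L]),
                     nameA = sourceNames[1L], nameB = sourceNames[2L])
  catalog@sets[[name]] <- u$gene
  catalog@rules[[name]] <- list(rule = "union", sources = sourceNames,
                                provenance = u)
  validObject(catalog)
  catalog
}

#' Assemble a BRCAness gene catalog
#'
#' The catalog's assembly rules: (1) homologous-recombination/Fanconi-anemia
#' (HR/FA) pathway genes are the genes annotated by at least two of three
#' independent pathway databases; (2) PARP-inhibitor-sensitivity genes are
#' the union of a published review list and a manual literature-search
#' list; (3) the BRCAness set is the union of (1) and (2). All rules and
#' provenance are recorded on the returned catalog.
#'
#' @param hrSources named list of exactly three HR/FA database gene lists.
#' @param reviewList,literatureList the two PARPi-sensitivity gene lists.
#' @return A [GeneCatalog-class] with assembled sets `HR_FA`,
#'   `PARPi_sensitivity` and `BRCAness`.
#' @export
buildBRCAnessCatalog <- function(hrSources, reviewList, literatureList) {
  if (length(hrSources) != 3L)
    stop("'hrSources' must contain exactly three database lists")
  cat <- geneCatalog(c(hrSources,
                       list(review = reviewList, literature = literatureList)))
  cat <- addVoteSet(cat, "HR_FA", names(hrSources), k = 2L)
  cat <- addUnionSet(cat, "PARPi_sensitivity", c("review", "literature"))
  cat <- addUnionSet(cat, "BRCAness", c("HR_FA", "PARPi_sensitivity"))
  cat
}

#' Read and write gene-set files
#'
#' `readGeneList()` reads a one-gene-per-line text file; `readGmt()` reads
#' a GMT file into a named list of gene sets; `writeGmt()` writes one;
#' `writeCatalog()` writes a catalog's assembled sets as GMT plus a
#' provenance CSV (which set(s) and rule produced each gene).
#'
#' @param path file path (for `writeCatalog()`, an output directory).
#' @param sets named list of character gene vectors.
#' @param description per-set description column of the GMT (recycled).
#' @param catalog a [GeneCatalog-class].
#' @return `readGeneList()` a character vector; `readGmt()` a named list;
#'   the writers return their output path(s) invisibly.
#' @name geneSetIO
NULL

#' @rdname geneSetIO
#' @export
readGeneList <- function(path) .normalizeGenes(readLines(path, warn = FALSE))

#' @rdname geneSetIO
#' @export
readGmt <- function(path) lapply(fgsea::gmtPathways(path), .normalizeGenes)

#' @rdname geneSetIO
#' @export
writeGmt <- function(sets, path, description = "na") {
  if (is.null(names(sets))) stop("'sets' must be named")
  description <- rep_len(description, length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], description[i], sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname geneSetIO
#' @export
writeCatalog <- function(catalog, path) {
  stopifnot(is(catalog, "GeneCatalog"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  gmt <- file.path(path, "catalog.gmt")
  writeGmt(catalog@sets, gmt,
           description = vapply(catalog@rules, function(r) r$rule, character(1)))
  prov <- do.call(rbind, lapply(names(catalog@sets), function(nm) {
    r <- catalog@rules[[nm]]
    data.frame(set = nm, gene = catalog@sets[[nm]], rule = r$rule,
               rule_sources = paste(r$sources, collapse = "|"),
               stringsAsFactors = FALSE)
  }))
  csv <- file.path(path, "catalog_provenance.csv")
  utils::write.csv(prov, csv, row.names = FALSE)
  invisible(c(gmt, csv))
}
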