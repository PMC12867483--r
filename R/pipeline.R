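#' Default configuration for the end-to-end demo screen
#'
#' @param seed global seed; every simulated dataset derives its own stream
#'   from it.
#' @param nInhibitors panel size (default 20).
#' @param cellLines cell-line labels (default two).
#' @param noiseSd viability-scale noise SD (default 0.02).
#' @param nSynergists,nAntagonists how many inhibitors are planted as
#'   synergistic (true CI 0.5) and antagonistic (true CI 1.5); the rest are
#'   Loewe-additive (true CI 1).
#' @param weights priority-score weights (five values summing to 1).
#' @return A named list understood by [runDemo()].
#' @export
demoConfig <- function(seed = 1L, nInhibitors = 20L,
                       cellLines = c("OVCAR8", "MDA-MB-231"),
                       noiseSd = 0.02, nSynergists = 5L, nAntagonists = 3L,
                       weights = rep(0.2, 5)) {
  list(seed = as.integer(seed), nInhibitors = as.integer(nInhibitors),
       cellLines = cellLines, noiseSd = noiseSd,
       nSynergists = as.integer(nSynergists),
       nAntagonists = as.integer(nAntagonists), weights = weights)
}

.validateDemoConfig <- function(cfg) {
  need <- c("seed", "nInhibitors", "cellLines", "noiseSd", "nSynergists",
            "nAntagonists", "weights")
  missing <- setdiff(need, names(cfg))
  bad <- character(0)
  if (length(missing)) bad <- c(bad, paste("missing:", paste(missing, collapse = ", ")))
  if ("nInhibitors" %in% names(cfg) &&
      (!is.numeric(cfg$nInhibitors) || cfg$nInhibitors < 1))
    bad <- c(bad, "nInhibitors: need at least one inhibitor")
  if (all(c("nSynergists", "nAntagonists", "nInhibitors") %in% names(cfg)) &&
      is.numeric(cfg$nInhibitors) && cfg$nInhibitors >= 1 &&
      cfg$nSynergists + cfg$nAntagonists > cfg$nInhibitors)
    bad <- c(bad, "nSynergists + nAntagonists exceeds nInhibitors")
  if ("noiseSd" %in% names(cfg) && (!is.numeric(cfg$noiseSd) || cfg$noiseSd < 0))
    bad <- c(bad, "noiseSd: must be non-negative")
  if ("weights" %in% names(cfg) &&
      (length(cfg$weights) != 5L || abs(sum(cfg$weights) - 1) > 1e-9))
    bad <- c(bad, "weights: need five values summing to 1")
  if (length(bad))
    stop("invalid demo config - ", paste(bad, collapse = "; "), call. = FALSE)
  invisible(cfg)
}

#' Run the end-to-end demo pipeline
#'
#' Simulates a combination screen of a PARP-inhibitor anchor against a
#' panel of epigenetic inhibitors across cell lines (a subset planted as
#' true synergists with CI 0.5 and a subset as antagonists with CI 1.5),
#' fits every single agent, scores each combination's CI, classifies
#' synergy, derives the five priority features (median CI across lines,
#' fitted single-agent IC50, target dependency, pan-cancer expression
#' meta-z from a simulated cohort, genomic-alteration recurrence — the
#' last three planted in favour of the synergists' targets), ranks the
#' panel, and writes everything to `outDir` as CSV plus a JSON run
#' manifest (config snapshot, seeds, output digests, package version,
#' collected warnings).
#'
#' The config is validated before anything is written; a malformed config
#' raises a schema error naming the offending keys and leaves no partial
#' outputs.
#'
#' @param outDir output directory (created; must be empty or absent).
#' @param config a list from [demoConfig()].
#' @return Invisibly, a list with the ranking table, the combination
#'   summary table, the planted truth, and the manifest path.
#' @export
runDemo <- function(outDir, config = demoConfig()) {
  .validateDemoConfig(config)
  warnings <- character(0)
  wh <- function(w) {
    warnings <<- c(warnings, conditionMessage(w))
    invokeRestart("muffleWarning")
  }

  nI <- config$nInhibitors
  inhibitors <- sprintf("epi%02d", seq_len(nI))
  targets <- sprintf("TGT%02d", seq_len(nI))
  alphaClass <- rep("additive", nI)
  if (config$nSynergists) alphaClass[seq_len(config$nSynergists)] <- "synergist"
  if (config$nAntagonists)
    alphaClass[nI - seq_len(config$nAntagonists) + 1L] <- "antagonist"
  alphas <- c(synergist = 0.5, additive = 1.0, antagonist = 1.5)[alphaClass]
  truth <- data.frame(inhibitor = inhibitors, target = targets,
                      planted_class = alphaClass, true_ci = unname(alphas),
                      stringsAsFactors = FALSE)

  result <- withCallingHandlers({
    doses5 <- function(ic50) ic50 / 2 * 2^(-2:2)
    fitRows <- list(); comboRows <- list()
    withr::with_seed(.childSeed(config$seed, "drug-params"), {
      # per cell line: anchor PARPi params then one per inhibitor
      params <- list()
      for (cl in config$cellLines)
        params[[cl]] <- list(
          anchor = c(m = runif(1, 0.8, 2), Dm = exp(runif(1, -1, 1))),
          panel = cbind(m = runif(nI, 0.8, 2), Dm = exp(runif(nI, -1, 1))))
    })
    for (cl in config$cellLines) {
      cfgSA <- simConfig(seed = .childSeed(config$seed, paste0("sa:", cl)),
                         noiseSd = config$noiseSd, nReplicates = 3L)
      pA <- params[[cl]]$anchor
      saA <- simulateSingleAgent(pA["m"], pA["Dm"], doses5(pA["Dm"]), cfgSA,
                                 drug = "PARPi")
      aggA <- stats::aggregate(fa ~ dose, saA, mean)
      fitA <- fitMedianEffect(aggA$dose, aggA$fa, drug = "PARPi")
      fitRows[[paste(cl, "PARPi")]] <- data.frame(
        cell_line = cl, drug = "PARPi", m = fitA@m, Dm = fitA@Dm, r = fitA@r,
        status = fitA@status, stringsAsFactors = FALSE)
      for (i in seq_len(nI)) {
        pB <- params[[cl]]$panel[i, ]
        saB <- simulateSingleAgent(pB["m"], pB["Dm"], doses5(pB["Dm"]),
                                   cfgSA, drug = inhibitors[i])
        aggB <- stats::aggregate(fa ~ dose, saB, mean)
        fitB <- fitMedianEffect(aggB$dose, aggB$fa, drug = inhibitors[i])
        fitRows[[paste(cl, inhibitors[i])]] <- data.frame(
          cell_line = cl, drug = inhibitors[i], m = fitB@m, Dm = fitB@Dm,
          r = fitB@r, status = fitB@status, stringsAsFactors = FALSE)
        design <- constantRatioDesign(fitA, fitB)
        cmb <- simulateCombination(
          fitA, fitB, design, alphas[i],
          simConfig(seed = .childSeed(config$seed, paste0("cmb:", cl, ":", i)),
                    noiseSd = config$noiseSd, nReplicates = 3L),
          label = paste(cl, inhibitors[i]))
        agg <- stats::aggregate(fa ~ dose_a + dose_b, cmb, mean)
        fa <- .clip(agg$fa, .FA_EPS, 1 - .FA_EPS)
        ci <- combinationIndex(fitA, fitB, agg$dose_a, agg$dose_b, fa)
        rec <- summarizeCombination(
          data.frame(dose_a = agg$dose_a, dose_b = agg$dose_b, fa = fa, ci = ci),
          cl, "PARPi", inhibitors[i])
        comboRows[[paste(cl, inhibitors[i])]] <- data.frame(
          cell_line = cl, drug_a = "PARPi", drug_b = inhibitors[i],
          median_ci = rec@medianCI, synergy_class = rec@synergyClass,
          status = rec@status, stringsAsFactors = FALSE)
      }
    }
    fits <- do.call(rbind, fitRows)
    combos <- do.call(rbind, comboRows)

    # five priority features; expression dysregulation from a simulated
    # pan-cancer cohort with tumor up-shift planted on synergist targets
    medCI <- vapply(inhibitors, function(d)
      median(combos$median_ci[combos$drug_b == d], na.rm = TRUE), numeric(1))
    singleAgent <- vapply(inhibitors, function(d)
      mean(fits$Dm[fits$drug == d], na.rm = TRUE), numeric(1))
    delta <- setNames(ifelse(alphaClass == "synergist", 2, 0), targets)
    cohortSim <- simulatePanCancerCohort(
      targets, nCancers = 8L, delta = delta, beta = 0, nTumor = 15L,
      nNormal = 8L, nSurv = 0L,
      cfg = simConfig(seed = .childSeed(config$seed, "cohort")))
    meta <- deMeta(cohortSim$cohort)
    exprZ <- metaZ(meta)[targets]
    withr::with_seed(.childSeed(config$seed, "dep-genomic"), {
      dependency <- ifelse(alphaClass == "synergist", -1, 0) + rnorm(nI, sd = 0.1)
      genomic <- ifelse(alphaClass == "synergist", 1, 0) + runif(nI, 0, 0.2)
    })
    features <- data.frame(inhibitor = inhibitors, target = targets,
                           median_ci = unname(medCI),
                           single_agent = unname(singleAgent),
                           dependency = dependency,
                           expr_meta_z = unname(exprZ),
                           genomic_alteration = genomic,
                           stringsAsFactors = FALSE)
    ranking <- prioritizePanel(features, weights = config$weights)
    list(fits = fits, combos = combos, features = features, ranking = ranking)
  }, warning = wh)

  if (dir.exists(outDir) && length(dir(outDir)))
    stop("'outDir' exists and is not empty: ", outDir)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  files <- c(single_agent_fits = "single_agent_fits.csv",
             combination_records = "combination_records.csv",
             features = "features.csv", ranking = "ranking.csv",
             planted_truth = "planted_truth.csv")
  utils::write.csv(result$fits, file.path(outDir, files[1]), row.names = FALSE)
  utils::write.csv(result$combos, file.path(outDir, files[2]), row.names = FALSE)
  utils::write.csv(result$features, file.path(outDir, files[3]), row.names = FALSE)
  utils::write.csv(result$ranking, file.path(outDir, files[4]), row.names = FALSE)
  utils::write.csv(truth, file.path(outDir, files[5]), row.names = FALSE)

  manifest <- list(
    package = "SynergyScreen",
    version = as.character(utils::packageVersion("SynergyScreen")),
    config = config,
    weights = as.numeric(config$weights),
    outputs = as.list(setNames(
      unname(tools::md5sum(file.path(outDir, files))), files)),
    warnings = warnings)
  manifestPath <- file.path(outDir, "manifest.json")
  jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(ranking = result$ranking, combinations = result$combos,
                 features = result$features, truth = truth,
                 manifest = manifestPath))
}
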