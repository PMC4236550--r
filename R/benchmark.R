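#' Run the full filtering / masking / imputation / scoring benchmark
#'
#' Executes the complete evaluation chain on a synthetic dataset: simulate
#' an LD-structured panel and corrupted study genotypes; compute per-SNP
#' quality and the HQ SNP set; build one nested mask plan restricted to
#' the HQ SNPs (genotype holes or entire SNPs); then, for every filter
#' scenario and masking level, restrict the data to the scenario's SNPs,
#' apply the mask, impute the overlap (lowest-level) cells, score them
#' against the stored truth with `epsilon = 0`, and dichotomise at the
#' cutoff. Scenarios are compared per level with paired McNemar tests
#' against the best scenario ([scenarioTable()]). Fully reproducible from
#' the master seed in `cfg`.
#'
#' Scenario filtering keeps the full SNP index space and blanks the
#' excluded SNPs' calls, so map distances (and hence the decay of
#' flanking information in the LS imputer) reflect the true SNP spacing.
#'
#' @param cfg a [simConfig()].
#' @param scenarios list of [FilterScenario-class] objects (default: the
#'   five main built-ins ALL, LQ, NQ, BQ, HQ).
#' @param levels masking percentages.
#' @param imputer an [imputerSpec()], or a function
#'   `f(gmMasked, targets, panel)` returning a [PosteriorSet-class]
#'   (useful for injecting a custom or oracle imputer).
#' @param mode `"holes"` (mask individual genotypes) or `"snps"` (mask
#'   entire SNPs; requires a reference-using imputer).
#' @param measure score used for dichotomisation (`"hellinger"` or
#'   `"sen"`).
#' @param cutoff well-imputed cutoff (defaults: 0.6 for Hellinger, 0.95
#'   for SEN).
#' @param adjust,familySize,alpha passed to [scenarioTable()];
#'   `familySize` defaults to the number of scenarios.
#' @return List of class `"BenchmarkResult"`: `table` (the
#'   [scenarioTable()] report), `pcts`, `flags`, `cellScores` (per
#'   scenario x level), `snpScores`, `plan`, `quality`, `hqSnps`, `data`.
#' @export
runBenchmark <- function(cfg, scenarios = builtinScenarios()[c("ALL", "LQ", "NQ", "BQ", "HQ")],
                         levels = c(10, 20, 50), imputer = imputerSpec(),
                         mode = c("holes", "snps"),
                         measure = c("hellinger", "sen"), cutoff = NULL,
                         adjust = "holm", familySize = NULL, alpha = 0.05) {
  mode <- match.arg(mode)
  measure <- match.arg(measure)
  if (is.null(cutoff)) cutoff <- if (measure == "hellinger") 0.6 else 0.95
  if (is(scenarios, "FilterScenario")) scenarios <- list(scenarios)
  names(scenarios) <- vapply(scenarios, function(s) s@name, "")
  if (is.null(familySize)) familySize <- length(scenarios)

  ds <- simulateDataset(cfg)
  gm <- ds$gm
  quality <- snpQuality(gm)
  hq <- applyScenario(gm, quality, builtinScenarios()[["HQ"]])
  if (length(hq) < 2)
    stop("benchmark aborted at QC stage: fewer than 2 HQ SNPs")

  plan <- if (mode == "holes")
    makeNestedGenotypeMasks(gm, hq, levels, seed = .childSeed(cfg$seed, 4L))
  else
    makeNestedSnpMasks(gm, hq, levels, seed = .childSeed(cfg$seed, 4L))
  overlap <- overlapUnits(plan)
  overlapTruth <- maskTruth(plan, plan@levels[1])

  imputeFun <- if (is.function(imputer)) imputer else {
    switch(imputer$kind,
      freq_null = function(gmMasked, targets, panel)
        imputeFreqNull(gmMasked, targets,
                       panel = if (imputer$useReference) panel else NULL),
      haplotype_ls = function(gmMasked, targets, panel)
        imputeHaplotypeLS(gmMasked, targets,
                          panel = if (imputer$useReference) panel else NULL,
                          spec = imputer))
  }

  snpCounts <- integer(length(scenarios))
  names(snpCounts) <- names(scenarios)
  flagsByLevel <- stats::setNames(
    replicate(length(levels), list(), simplify = FALSE),
    as.character(levels))
  pcts <- matrix(NA_real_, length(scenarios), length(levels),
                 dimnames = list(names(scenarios), as.character(levels)))
  cellScores <- list()
  snpScores <- list()

  for (sName in names(scenarios)) {
    idx <- applyScenario(gm, quality, scenarios[[sName]])
    snpCounts[sName] <- length(idx)
    gmScen <- gm
    excluded <- setdiff(seq_len(nSnps(gm)), idx)
    if (length(excluded))
      gmScen@calls[, excluded] <- NA_integer_
    for (lev in levels) {
      tag <- paste0(sName, "@", lev)
      gmMasked <- tryCatch(applyMask(gmScen, plan, lev),
        error = function(e) stop("masking stage (", tag, "): ",
                                 conditionMessage(e)))
      post <- tryCatch(imputeFun(gmMasked, overlap, ds$panel),
        error = function(e) stop("imputation stage (", tag, "): ",
                                 conditionMessage(e)))
      st <- tryCatch(scoreCells(overlap, overlapTruth, post, epsilon = 0),
        error = function(e) stop("scoring stage (", tag, "): ",
                                 conditionMessage(e)))
      d <- dichotomize(st, measure, cutoff)
      flagsByLevel[[as.character(lev)]][[sName]] <- d$flags
      pcts[sName, as.character(lev)] <- d$pct
      cellScores[[tag]] <- st
      snpScores[[tag]] <- aggregateScores(st, posteriors = post)
    }
  }

  tab <- scenarioTable(flagsByLevel, snpCounts = snpCounts,
                       familySize = familySize, adjust = adjust,
                       alpha = alpha)
  structure(list(table = tab, pcts = pcts, flags = flagsByLevel,
                 cellScores = cellScores, snpScores = snpScores,
                 plan = plan, quality = quality, hqSnps = hq,
                 snpCounts = snpCounts, data = ds,
                 measure = measure, cutoff = cutoff),
            class = "BenchmarkResult")
}

#' @export
print.BenchmarkResult <- function(x, ...) {
  cat("Benchmark (", x$plan@mode, "; ", x$measure, " >= ", x$cutoff,
      "; overlap units = ", nrow(overlapUnits(x$plan)), "):\n", sep = "")
  cat(formatScenarioTable(x$table), sep = "\n")
  cat("legend: '+' best per column, '*' significantly inferior to best\n")
  invisible(x)
}
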