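#' @rdname nSamples
#' @aliases nSamples,GenotypeMatrix-method
#' @export
setMethod("nSamples", "GenotypeMatrix", function(object) length(object@samples))

#' @rdname nSamples
#' @export
setMethod("nSamples", "PosteriorSet", function(object) length(object@samples))

#' @rdname nSnps
#' @aliases nSnps,GenotypeMatrix-method
#' @export
setMethod("nSnps", "GenotypeMatrix", function(object) nrow(object@snps))

#' @rdname nSnps
#' @export
setMethod("nSnps", "PosteriorSet", function(object) length(object@snpIds))

#' @rdname nSnps
#' @export
setMethod("nSnps", "HaplotypePanel", function(object) nrow(object@snps))

#' @rdname sampleIds
#' @export
setMethod("sampleIds", "GenotypeMatrix", function(object) object@samples)

#' @rdname sampleIds
#' @export
setMethod("sampleIds", "PosteriorSet", function(object) object@samples)

#' @rdname snpInfo
#' @export
setMethod("snpInfo", "GenotypeMatrix", function(object) object@snps)

#' @rdname snpInfo
#' @export
setMethod("snpInfo", "HaplotypePanel", function(object) object@snps)

#' @rdname genotypeCalls
#' @export
setMethod("genotypeCalls", "GenotypeMatrix", function(object) object@calls)

#' @rdname posteriorArray
#' @export
setMethod("posteriorArray", "PosteriorSet", function(object) object@probs)

#' @rdname haplotypeAlleles
#' @export
setMethod("haplotypeAlleles", "HaplotypePanel", function(object) object@haplotypes)

#' @rdname maskLevels
#' @export
setMethod("maskLevels", "MaskPlan", function(object) object@levels)

.levelIndex <- function(plan, level) {
  k <- match(level, plan@levels)
  if (is.na(k))
    stop("level ", level, " is not one of the plan's levels (",
         paste(plan@levels, collapse = ", "), ")")
  k
}

#' @rdname maskedCells
#' @export
setMethod("maskedCells", "MaskPlan", function(object, level) {
  if (missing(level)) level <- max(object@levels)
  k <- .levelIndex(object, level)
  object@cells[seq_len(object@nPerLevel[k]), , drop = FALSE]
})

#' @rdname maskedSnps
#' @export
setMethod("maskedSnps", "MaskPlan", function(object, level) {
  if (missing(level)) level <- max(object@levels)
  if (object@mode != "entire_snps")
    stop("maskedSnps applies only to entire-SNP plans")
  k <- .levelIndex(object, level)
  object@snpOrder[seq_len(object@nSnpPerLevel[k])]
})

#' @rdname maskTruth
#' @export
setMethod("maskTruth", "MaskPlan", function(object, level) {
  if (missing(level)) level <- max(object@levels)
  k <- .levelIndex(object, level)
  object@truth[seq_len(object@nPerLevel[k])]
})

#' @rdname overlapUnits
#' @export
setMethod("overlapUnits", "MaskPlan", function(object) {
  maskedCells(object, object@levels[1])
})

#' @rdname scoreFrame
#' @export
setMethod("scoreFrame", "ScoreTable", function(object) object@table)

#' @rdname scoreLevel
#' @export
setMethod("scoreLevel", "ScoreTable", function(object) object@level)

#' @export
setMethod("show", "GenotypeMatrix", function(object) {
  cl <- object@calls
  cat("GenotypeMatrix:", nSamples(object), "samples x", nSnps(object), "SNPs\n")
  if (length(cl))
    cat("  missing calls:", sum(is.na(cl)),
        sprintf("(%.1f%%)\n", 100 * mean(is.na(cl))))
})

#' @export
setMethod("show", "PosteriorSet", function(object) {
  emitted <- sum(!is.na(object@probs[, , 1, drop = FALSE]))
  cat("PosteriorSet:", nSamples(object), "samples x", nSnps(object),
      "SNPs;", emitted, "emitted cells\n")
})

#' @export
setMethod("show", "HaplotypePanel", function(object) {
  cat("HaplotypePanel:", nrow(object@haplotypes), "haplotypes x",
      nSnps(object), "SNPs\n")
})

#' @export
setMethod("show", "FilterScenario", function(object) {
  thr <- c(
    if (!is.na(object@mafMin)) paste0("MAF >= ", object@mafMin),
    if (!is.na(object@crMin)) paste0("CR >= ", object@crMin),
    if (!is.na(object@hweMin)) paste0("p(HWE) >= ", format(object@hweMin)))
  if (object@composite != "") thr <- c(thr, paste0("composite: ", object@composite))
  cat("FilterScenario '", object@name, "': ",
      paste(thr, collapse = ", "), "\n", sep = "")
})

#' @export
setMethod("show", "MaskPlan", function(object) {
  cat("MaskPlan (", object@mode, "): levels ",
      paste0(object@levels, "%", collapse = ", "),
      "; ", paste(object@nPerLevel, collapse = "/"), " cells; seed ",
      object@seed, "\n", sep = "")
})

#' @export
setMethod("show", "ScoreTable", function(object) {
  cat("ScoreTable (", object@level, " level): ", nrow(object@table),
      " rows\n", sep = "")
})
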