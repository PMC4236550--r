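#' @import methods
NULL

.MISSING_OK <- function(x) is.na(x)

.checkSnpMeta <- function(snps) {
  need <- c("snp_id", "chrom", "position", "allele_major", "allele_minor")
  if (!is.data.frame(snps)) return("'snps' must be a data.frame")
  miss <- setdiff(need, names(snps))
  if (length(miss)) return(paste0("snps lacks column(s): ", paste(miss, collapse = ", ")))
  msgs <- character()
  if (anyNA(snps$snp_id) || any(!nzchar(snps$snp_id)))
    msgs <- c(msgs, "snp_id must be non-empty")
  if (anyDuplicated(snps$snp_id))
    msgs <- c(msgs, "snp_id must be unique")
  if (any(snps$position < 0, na.rm = TRUE))
    msgs <- c(msgs, "positions must be non-negative")
  if (any(snps$allele_major == snps$allele_minor, na.rm = TRUE))
    msgs <- c(msgs, "allele_major and allele_minor must differ")
  msgs
}

#' Hard-call genotype matrix with SNP metadata
#'
#' Individuals-by-SNPs hard-call genotypes coded 0 (homozygous major allele),
#' 1 (heterozygous), 2 (homozygous minor allele); missing calls are `NA`.
#' SNP metadata rows (`snp_id`, `chrom`, `position`, `allele_major`,
#' `allele_minor`) align with the columns of the call matrix.
#'
#' @slot calls integer matrix (samples x SNPs) with values in \{0, 1, 2, NA\}.
#' @slot snps data.frame of per-SNP metadata.
#' @slot samples character vector of unique sample identifiers.
#'
#' @seealso [readPlinkPed()], [genotypesFromPanel()]
#' @export
setClass("GenotypeMatrix",
  representation(calls = "matrix", snps = "data.frame", samples = "character"))

setValidity("GenotypeMatrix", function(object) {
  msgs <- character()
  cl <- object@calls
  if (!is.numeric(cl) && !is.integer(cl)) msgs <- c(msgs, "calls must be numeric")
  if (nrow(cl) != length(object@samples))
    msgs <- c(msgs, "nrow(calls) must equal length(samples)")
  if (ncol(cl) != nrow(object@snps))
    msgs <- c(msgs, "ncol(calls) must equal nrow(snps)")
  if (anyDuplicated(object@samples))
    msgs <- c(msgs, "sample identifiers must be unique")
  bad <- !(is.na(cl) | cl == 0 | cl == 1 | cl == 2)
  if (any(bad)) msgs <- c(msgs, "non-missing calls must be in {0, 1, 2}")
  msgs <- c(msgs, .checkSnpMeta(object@snps))
  if (length(msgs)) msgs else TRUE
})

#' Construct a GenotypeMatrix
#'
#' @param calls integer matrix of genotype codes (samples x SNPs), `NA` for
#'   missing.
#' @param snps data.frame with columns `snp_id`, `chrom`, `position`,
#'   `allele_major`, `allele_minor`.
#' @param samples character vector of sample identifiers; defaults to the
#'   rownames of `calls`.
#' @return A [GenotypeMatrix-class] object.
#' @examples
#' gm <- GenotypeMatrix(
#'   calls = matrix(c(0L, 1L, 2L, NA), 2, 2),
#'   snps = data.frame(snp_id = c("rs1", "rs2"), chrom = "22",
#'                     position = c(100L, 200L),
#'                     allele_major = "A", allele_minor = "B"),
#'   samples = c("s1", "s2"))
#' nSnps(gm)
#' @export
GenotypeMatrix <- function(calls, snps, samples = rownames(calls)) {
  if (is.null(samples)) samples <- paste0("sample", seq_len(nrow(calls)))
  storage.mode(calls) <- "integer"
  dimnames(calls) <- list(samples, snps$snp_id)
  new("GenotypeMatrix", calls = calls, snps = as.data.frame(snps),
      samples = as.character(samples))
}

#' Posterior genotype probabilities from an imputer
#'
#' A trinomial probability triplet per (sample, SNP) cell, stored as an
#' n_samples x n_snps x 3 array over genotype codes (0, 1, 2). Cells the
#' imputer did not emit are all-`NA`.
#'
#' @slot probs numeric array (samples x SNPs x 3).
#' @slot samples character vector of sample identifiers.
#' @slot snpIds character vector of SNP identifiers.
#' @export
setClass("PosteriorSet",
  representation(probs = "array", samples = "character", snpIds = "character"))

setValidity("PosteriorSet", function(object) {
  msgs <- character()
  d <- dim(object@probs)
  if (length(d) != 3 || d[3] != 3)
    return("probs must be a samples x snps x 3 array")
  if (d[1] != length(object@samples)) msgs <- c(msgs, "dim 1 must match samples")
  if (d[2] != length(object@snpIds)) msgs <- c(msgs, "dim 2 must match snpIds")
  p <- matrix(object@probs, ncol = 3)
  emitted <- !is.na(p[, 1])
  if (any(is.na(p[emitted, ])))
    msgs <- c(msgs, "cells must be fully specified or fully NA")
  if (any(emitted)) {
    pe <- p[emitted, , drop = FALSE]
    if (any(pe < -1e-9)) msgs <- c(msgs, "posterior probabilities must be non-negative")
    if (any(abs(rowSums(pe) - 1) > 1e-6))
      msgs <- c(msgs, "posterior triplets must sum to 1 within 1e-6")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a PosteriorSet
#'
#' @param probs numeric array (samples x SNPs x 3) of genotype posterior
#'   probabilities; non-emitted cells all-`NA`.
#' @param samples,snpIds identifiers for the first two array dimensions.
#' @return A [PosteriorSet-class] object.
#' @export
PosteriorSet <- function(probs, samples, snpIds) {
  new("PosteriorSet", probs = probs, samples = as.character(samples),
      snpIds = as.character(snpIds))
}

#' Phased reference haplotype panel
#'
#' Haplotypes-by-SNPs allele matrix coded 0/1. By package convention allele
#' code 1 corresponds to `allele_minor` of the SNP metadata (the rarer allele
#' in the panel) and 0 to `allele_major`; genotype code alignment between a
#' panel and a [GenotypeMatrix-class] is resolved through these labels.
#'
#' @slot haplotypes integer matrix (haplotypes x SNPs) of 0/1 alleles.
#' @slot snps data.frame of per-SNP metadata (see [GenotypeMatrix-class]).
#' @export
setClass("HaplotypePanel",
  representation(haplotypes = "matrix", snps = "data.frame"))

setValidity("HaplotypePanel", function(object) {
  msgs <- character()
  h <- object@haplotypes
  if (ncol(h) != nrow(object@snps))
    msgs <- c(msgs, "ncol(haplotypes) must equal nrow(snps)")
  if (any(!(h == 0 | h == 1)))
    msgs <- c(msgs, "haplotype alleles must be 0 or 1")
  msgs <- c(msgs, .checkSnpMeta(object@snps))
  if (length(msgs)) msgs else TRUE
})

#' Construct a HaplotypePanel
#'
#' @param haplotypes integer matrix (haplotypes x SNPs) of 0/1 alleles.
#' @param snps data.frame of per-SNP metadata.
#' @return A [HaplotypePanel-class] object.
#' @export
HaplotypePanel <- function(haplotypes, snps) {
  storage.mode(haplotypes) <- "integer"
  new("HaplotypePanel", haplotypes = haplotypes, snps = as.data.frame(snps))
}

#' Named pre-imputation SNP filter scenario
#'
#' A combination of minor-allele-frequency, call-rate and Hardy-Weinberg
#' p-value thresholds (all inclusive, `>=`), or one of the composite rules
#' `"ALL"` (no filtering) and `"BQ"` (SNPs failing the NQ criteria united
#' with SNPs passing the HQ criteria). Unset thresholds are `NA`.
#'
#' @slot name scenario name.
#' @slot mafMin,crMin,hweMin numeric thresholds or `NA` when unset.
#' @slot composite `""`, `"ALL"` or `"BQ"`.
#' @seealso [builtinScenarios()], [applyScenario()]
#' @export
setClass("FilterScenario",
  representation(name = "character", mafMin = "numeric", crMin = "numeric",
                 hweMin = "numeric", composite = "character"))

setValidity("FilterScenario", function(object) {
  msgs <- character()
  if (!nzchar(object@name)) msgs <- c(msgs, "scenario name must be non-empty")
  if (!object@composite %in% c("", "ALL", "BQ"))
    msgs <- c(msgs, "composite must be '', 'ALL' or 'BQ'")
  if (object@composite == "" &&
      is.na(object@mafMin) && is.na(object@crMin) && is.na(object@hweMin))
    msgs <- c(msgs, "at least one threshold (or a composite rule) must be set")
  if (!is.na(object@mafMin) && (object@mafMin < 0 || object@mafMin > 0.5))
    msgs <- c(msgs, "mafMin must lie in [0, 0.5]")
  if (!is.na(object@crMin) && (object@crMin < 0 || object@crMin > 1))
    msgs <- c(msgs, "crMin must lie in [0, 1]")
  if (!is.na(object@hweMin) && (object@hweMin < 0 || object@hweMin > 1))
    msgs <- c(msgs, "hweMin must lie in [0, 1]")
  if (length(msgs)) msgs else TRUE
})

#' Construct a FilterScenario
#'
#' @param name scenario name.
#' @param mafMin,crMin,hweMin inclusive thresholds; `NA` leaves a criterion
#'   unset.
#' @param composite `""` for a plain threshold scenario, `"ALL"` or `"BQ"`
#'   for the composite rules.
#' @return A [FilterScenario-class] object.
#' @examples
#' FilterScenario("HQ", mafMin = 0.1, crMin = 1, hweMin = 1e-2)
#' @export
FilterScenario <- function(name, mafMin = NA_real_, crMin = NA_real_,
                           hweMin = NA_real_, composite = "") {
  new("FilterScenario", name = as.character(name), mafMin = as.numeric(mafMin),
      crMin = as.numeric(crMin), hweMin = as.numeric(hweMin),
      composite = composite)
}

#' Nested masking plan with stored truth
#'
#' Seeded plan of nested masked units restricted to a designated
#' high-quality SNP set. Units masked at a lower percentage level are, by
#' construction, a subset of those masked at every higher level: the plan
#' stores one permutation of eligible units and per-level prefix lengths.
#'
#' For `mode = "genotype_holes"` the units are individual (sample, SNP)
#' cells; for `mode = "entire_snps"` whole SNPs are masked and `cells`
#' expands them to all sample cells (truth may be `NA` where the original
#' call was missing).
#'
#' @slot mode `"genotype_holes"` or `"entire_snps"`.
#' @slot levels strictly increasing masking percentages.
#' @slot cells integer matrix (columns `sample`, `snp`) of maskable cells in
#'   masking order; level k masks the first `nPerLevel[k]` rows.
#' @slot nPerLevel integer vector of per-level cell counts.
#' @slot snpOrder for `entire_snps`: masked SNP indices in masking order.
#' @slot nSnpPerLevel for `entire_snps`: per-level SNP counts.
#' @slot truth integer vector of original genotype calls aligned to `cells`.
#' @slot hqSnps the eligible SNP index set.
#' @slot seed the seed the plan was drawn with.
#' @seealso [makeNestedGenotypeMasks()], [makeNestedSnpMasks()], [applyMask()]
#' @export
setClass("MaskPlan",
  representation(mode = "character", levels = "numeric", cells = "matrix",
                 nPerLevel = "integer", snpOrder = "integer",
                 nSnpPerLevel = "integer", truth = "integer",
                 hqSnps = "integer", seed = "integer"))

setValidity("MaskPlan", function(object) {
  msgs <- character()
  if (!object@mode %in% c("genotype_holes", "entire_snps"))
    msgs <- c(msgs, "mode must be 'genotype_holes' or 'entire_snps'")
  if (length(object@levels) < 1 || is.unsorted(object@levels, strictly = TRUE))
    msgs <- c(msgs, "levels must be strictly increasing")
  if (any(object@levels <= 0 | object@levels > 100))
    msgs <- c(msgs, "levels must lie in (0, 100]")
  if (length(object@nPerLevel) != length(object@levels))
    msgs <- c(msgs, "one cell count per level required")
  if (is.unsorted(object@nPerLevel))
    msgs <- c(msgs, "per-level cell counts must be non-decreasing")
  if (length(object@nPerLevel) && max(object@nPerLevel) > nrow(object@cells))
    msgs <- c(msgs, "per-level counts exceed available cells")
  if (ncol(object@cells) != 2)
    msgs <- c(msgs, "cells must have two columns (sample, snp)")
  if (length(object@truth) != nrow(object@cells))
    msgs <- c(msgs, "truth must align with cells")
  if (nrow(object@cells) && !all(object@cells[, 2] %in% object@hqSnps))
    msgs <- c(msgs, "masked units must be drawn from the designated HQ SNP set")
  if (object@mode == "genotype_holes" && anyNA(object@truth))
    msgs <- c(msgs, "truth must be recorded for every masked genotype hole")
  if (length(msgs)) msgs else TRUE
})

#' Table of imputation quality scores
#'
#' A thin container around a data.frame of per-cell scores (columns
#' `sample`, `snp_id`, `true_g`, `hellinger`, `sen`, `best_guess`,
#' `concordant`) or per-SNP aggregates (`snp_id`, `mean_hellinger`,
#' `mean_sen`, `rsq`, `info`, `n_cells`).
#'
#' @slot table the score data.frame.
#' @slot level `"cell"` or `"snp"`.
#' @seealso [scoreCells()], [aggregateScores()], [writeScoreTable()]
#' @export
setClass("ScoreTable", representation(table = "data.frame", level = "character"))

setValidity("ScoreTable", function(object) {
  if (!object@level %in% c("cell", "snp"))
    return("level must be 'cell' or 'snp'")
  TRUE
})

#' Construct a ScoreTable
#'
#' @param table score data.frame.
#' @param level `"cell"` or `"snp"`.
#' @return A [ScoreTable-class] object.
#' @export
ScoreTable <- function(table, level = c("cell", "snp")) {
  new("ScoreTable", table = as.data.frame(table), level = match.arg(level))
}
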