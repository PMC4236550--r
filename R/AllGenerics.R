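#' Number of samples
#'
#' @param object a [GenotypeMatrix-class] or [PosteriorSet-class].
#' @return Integer count.
#' @export
setGeneric("nSamples", function(object) standardGeneric("nSamples"))

#' Number of SNPs
#'
#' @param object a [GenotypeMatrix-class], [PosteriorSet-class] or
#'   [HaplotypePanel-class].
#' @return Integer count.
#' @export
setGeneric("nSnps", function(object) standardGeneric("nSnps"))

#' Sample identifiers
#'
#' @inheritParams nSamples
#' @return Character vector.
#' @export
setGeneric("sampleIds", function(object) standardGeneric("sampleIds"))

#' SNP metadata
#'
#' @inheritParams nSnps
#' @return data.frame with columns `snp_id`, `chrom`, `position`,
#'   `allele_major`, `allele_minor`.
#' @export
setGeneric("snpInfo", function(object) standardGeneric("snpInfo"))

#' Genotype call matrix
#'
#' @param object a [GenotypeMatrix-class].
#' @return Integer matrix (samples x SNPs) of codes in \{0, 1, 2, NA\}.
#' @export
setGeneric("genotypeCalls", function(object) standardGeneric("genotypeCalls"))

#' Posterior probability array
#'
#' @param object a [PosteriorSet-class].
#' @return Numeric array (samples x SNPs x 3).
#' @export
setGeneric("posteriorArray", function(object) standardGeneric("posteriorArray"))

#' Haplotype allele matrix
#'
#' @param object a [HaplotypePanel-class].
#' @return Integer matrix (haplotypes x SNPs) of 0/1 alleles.
#' @export
setGeneric("haplotypeAlleles", function(object) standardGeneric("haplotypeAlleles"))

#' Masking percentage levels of a plan
#'
#' @param object a [MaskPlan-class].
#' @return Numeric vector of strictly increasing percentages.
#' @export
setGeneric("maskLevels", function(object) standardGeneric("maskLevels"))

#' Masked cells of a plan at one level
#'
#' @param object a [MaskPlan-class].
#' @param level one of the plan's percentage levels; defaults to the highest.
#' @return Integer matrix with columns `sample` and `snp`.
#' @export
setGeneric("maskedCells", function(object, level) standardGeneric("maskedCells"))

#' Masked SNP indices of an entire-SNP plan at one level
#'
#' @inheritParams maskedCells
#' @return Integer vector of SNP indices.
#' @export
setGeneric("maskedSnps", function(object, level) standardGeneric("maskedSnps"))

#' Stored truth for the masked cells at one level
#'
#' @inheritParams maskedCells
#' @return Integer vector of original genotype calls aligned to
#'   `maskedCells(object, level)`.
#' @export
setGeneric("maskTruth", function(object, level) standardGeneric("maskTruth"))

#' Overlap evaluation units of a mask plan
#'
#' The lowest-level masked set — the common subset of every level and hence
#' the evaluation universe for cross-level and cross-scenario comparisons.
#'
#' @param object a [MaskPlan-class].
#' @return Integer matrix of (sample, snp) cells.
#' @export
setGeneric("overlapUnits", function(object) standardGeneric("overlapUnits"))

#' Underlying data.frame of a score table
#'
#' @param object a [ScoreTable-class].
#' @return data.frame.
#' @export
setGeneric("scoreFrame", function(object) standardGeneric("scoreFrame"))

#' Aggregation level of a score table
#'
#' @param object a [ScoreTable-class].
#' @return `"cell"` or `"snp"`.
#' @export
setGeneric("scoreLevel", function(object) standardGeneric("scoreLevel"))
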