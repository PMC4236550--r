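.checkLevels <- function(levels) {
  if (length(levels) < 1 || is.unsorted(levels, strictly = TRUE) ||
      any(levels <= 0 | levels > 100))
    stop("levels must be strictly increasing percentages in (0, 100]")
  as.numeric(levels)
}

#' Nested random masking of individual genotypes (hole filling design)
#'
#' Draws, for each masking percentage, a uniformly random set of
#' non-missing genotype cells within the designated high-quality SNP
#' columns, of size `round-half-up(level% x eligible cells)`. A single
#' permutation of the eligible cells is drawn (seeded) and levels take
#' nested prefixes, so the masked set at a lower level is contained in the
#' set at every higher level by construction. Original calls are stored as
#' truth before masking.
#'
#' @param gm a [GenotypeMatrix-class].
#' @param hqSnps integer indices of the eligible (high-quality) SNPs.
#' @param levels strictly increasing masking percentages, e.g.
#'   `c(10, 20, 50)`.
#' @param seed integer seed; the same seed reproduces the plan exactly.
#' @return A [MaskPlan-class] with `mode = "genotype_holes"`.
#' @export
makeNestedGenotypeMasks <- function(gm, hqSnps, levels = c(10, 20, 50), seed) {
  stopifnot(is(gm, "GenotypeMatrix"))
  levels <- .checkLevels(levels)
  hqSnps <- sort(unique(as.integer(hqSnps)))
  if (!length(hqSnps)) stop("hqSnps must be non-empty")
  if (any(hqSnps < 1 | hqSnps > nSnps(gm)))
    stop("hqSnps out of range")
  sub <- gm@calls[, hqSnps, drop = FALSE]
  elig <- which(!is.na(sub), arr.ind = TRUE)
  nElig <- nrow(elig)
  if (!nElig) stop("no eligible (non-missing) cells in the HQ SNP columns")
  counts <- .roundHalfUp(levels / 100 * nElig)
  if (any(counts > nElig))
    stop("masking level exceeds the number of eligible cells")
  perm <- .withSeed(seed, sample.int(nElig))
  cells <- cbind(sample = elig[perm, 1], snp = hqSnps[elig[perm, 2]])
  truth <- gm@calls[cells]
  new("MaskPlan", mode = "genotype_holes", levels = levels, cells = cells,
      nPerLevel = as.integer(counts), snpOrder = integer(0),
      nSnpPerLevel = integer(0), truth = as.integer(truth),
      hqSnps = hqSnps, seed = as.integer(seed))
}

#' Nested random masking of whole SNPs (entire-SNP imputation design)
#'
#' Masks `round-half-up(level% x |hqSnps|)` whole SNPs per level, nested
#' across levels via prefixes of one seeded permutation of the eligible
#' SNPs. Truth stores the full genotype column of every masked SNP
#' (possibly `NA` where the original call was missing).
#'
#' @inheritParams makeNestedGenotypeMasks
#' @return A [MaskPlan-class] with `mode = "entire_snps"`.
#' @export
makeNestedSnpMasks <- function(gm, hqSnps, levels = c(10, 20, 50), seed) {
  stopifnot(is(gm, "GenotypeMatrix"))
  levels <- .checkLevels(levels)
  hqSnps <- sort(unique(as.integer(hqSnps)))
  if (!length(hqSnps)) stop("hqSnps must be non-empty")
  if (any(hqSnps < 1 | hqSnps > nSnps(gm)))
    stop("hqSnps out of range")
  nHq <- length(hqSnps)
  nSnpPerLevel <- .roundHalfUp(levels / 100 * nHq)
  if (any(nSnpPerLevel > nHq))
    stop("masking level exceeds the number of eligible SNPs")
  snpOrder <- hqSnps[.withSeed(seed, sample.int(nHq))]
  nSamp <- nSamples(gm)
  cells <- cbind(sample = rep(seq_len(nSamp), times = nHq),
                 snp = rep(snpOrder, each = nSamp))
  truth <- gm@calls[cells]
  new("MaskPlan", mode = "entire_snps", levels = levels, cells = cells,
      nPerLevel = as.integer(nSnpPerLevel * nSamp),
      snpOrder = as.integer(snpOrder),
      nSnpPerLevel = as.integer(nSnpPerLevel),
      truth = as.integer(truth), hqSnps = hqSnps, seed = as.integer(seed))
}

#' Apply a mask plan at one level
#'
#' Returns a copy of the genotype matrix with every unit masked at the
#' requested level set to missing; the input object is unchanged and the
#' original calls remain retrievable via [maskTruth()].
#'
#' @param gm the [GenotypeMatrix-class] the plan was built from.
#' @param plan a [MaskPlan-class].
#' @param level one of `maskLevels(plan)`.
#' @return A masked [GenotypeMatrix-class].
#' @export
applyMask <- function(gm, plan, level) {
  stopifnot(is(gm, "GenotypeMatrix"), is(plan, "MaskPlan"))
  cells <- maskedCells(plan, level)
  calls <- gm@calls
  calls[cells] <- NA_integer_
  GenotypeMatrix(calls, gm@snps, gm@samples)
}
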