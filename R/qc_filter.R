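#' Minor allele frequency of a SNP
#'
#' Computed from non-missing calls only: the code-2 allele frequency is the
#' genotype dose sum divided by twice the number of non-missing calls, and
#' the result is folded to `min(f, 1 - f)` so the returned value is always
#' the frequency of the rarer allele, in `[0, 0.5]`.
#'
#' @param gm a [GenotypeMatrix-class].
#' @param snpIndex SNP column index (or vector of indices).
#' @return Numeric vector of folded minor allele frequencies.
#' @examples
#' gm <- GenotypeMatrix(matrix(c(0L, 0L, 1L, 2L, NA), 5, 1),
#'   snps = data.frame(snp_id = "rs1", chrom = "22", position = 1L,
#'                     allele_major = "A", allele_minor = "B"))
#' computeMaf(gm, 1)  # 3/8
#' @export
computeMaf <- function(gm, snpIndex = seq_len(nSnps(gm))) {
  stopifnot(is(gm, "GenotypeMatrix"))
  vapply(snpIndex, function(j) {
    g <- gm@calls[, j]
    g <- g[!is.na(g)]
    if (!length(g))
      stop("MAF undefined: all calls missing at SNP index ", j)
    f <- sum(g) / (2 * length(g))
    min(f, 1 - f)
  }, numeric(1))
}

#' Call rate of a SNP
#'
#' Fraction of samples with a non-missing genotype.
#'
#' @inheritParams computeMaf
#' @return Numeric vector of call rates in `[0, 1]`.
#' @export
computeCallRate <- function(gm, snpIndex = seq_len(nSnps(gm))) {
  stopifnot(is(gm, "GenotypeMatrix"))
  if (nSamples(gm) == 0) stop("call rate undefined for 0 samples")
  vapply(snpIndex, function(j) mean(!is.na(gm@calls[, j])), numeric(1))
}

# exact conditional distribution of the heterozygote count given allele
# counts, built by the standard recurrence anchored at the modal count
.hweHetDist <- function(nHet, nRare, n) {
  hets <- seq(nRare %% 2, min(nRare, 2 * n - nRare), by = 2)
  probs <- numeric(length(hets))
  # start near the mode for numerical stability
  mid <- round(nRare * (2 * n - nRare) / (2 * n))
  if (mid %% 2 != nRare %% 2) mid <- mid + 1
  mid <- min(max(mid, min(hets)), max(hets))
  i0 <- match(mid, hets)
  probs[i0] <- 1
  # downward: P(h-2)/P(h) = h (h-1) / (4 * nAA(h-2+2?)...) use ratio
  if (i0 > 1) for (i in (i0 - 1):1) {
    h <- hets[i] + 2
    homR <- (nRare - h) / 2
    homC <- n - h - homR
    probs[i] <- probs[i + 1] * h * (h - 1) / (4 * (homR + 1) * (homC + 1))
  }
  if (i0 < length(hets)) for (i in (i0 + 1):length(hets)) {
    h <- hets[i]
    homR <- (nRare - h) / 2
    homC <- n - h - homR
    probs[i] <- probs[i - 1] * 4 * (homR + 1) * (homC + 1) / (h * (h - 1))
  }
  probs <- probs / sum(probs)
  list(hets = hets, probs = probs)
}

#' Exact Hardy-Weinberg equilibrium test p-value
#'
#' Two-sided exact conditional test of Hardy-Weinberg genotype proportions
#' given the allele counts (the Wigginton-style test used by PLINK): the
#' p-value sums the conditional probabilities of every heterozygote count
#' (with the observed allele counts and matching parity) whose probability
#' does not exceed that of the observed count. Monomorphic tables return 1.
#'
#' An asymptotic one-degree-of-freedom chi-square alternative is available
#' via `method = "asymptotic"`.
#'
#' @param nHomMajor,nHet,nHomMinor genotype counts (vectors are recycled to
#'   common length).
#' @param method `"exact"` (default) or `"asymptotic"`.
#' @return Numeric vector of p-values in `[0, 1]`.
#' @examples
#' hweExactP(1, 0, 1)   # 1/3
#' hweExactP(25, 50, 25)
#' @export
hweExactP <- function(nHomMajor, nHet, nHomMinor,
                      method = c("exact", "asymptotic")) {
  method <- match.arg(method)
  n <- length(nHomMajor)
  stopifnot(length(nHet) == n, length(nHomMinor) == n)
  mapply(function(aa, ab, bb) {
    if (anyNA(c(aa, ab, bb)) || aa < 0 || ab < 0 || bb < 0)
      stop("genotype counts must be non-negative")
    tot <- aa + ab + bb
    if (tot == 0) stop("HWE test undefined for an empty table")
    nRare <- 2 * min(aa, bb) + ab
    if (nRare == 0 || nRare == 2 * tot) return(1)
    if (method == "asymptotic") {
      p <- (2 * aa + ab) / (2 * tot)
      expd <- tot * c(p^2, 2 * p * (1 - p), (1 - p)^2)
      stat <- sum((c(aa, ab, bb) - expd)^2 / expd)
      return(stats::pchisq(stat, df = 1, lower.tail = FALSE))
    }
    d <- .hweHetDist(ab, nRare, tot)
    pObs <- d$probs[match(ab, d$hets)]
    min(1, sum(d$probs[d$probs <= pObs * (1 + 1e-7)]))
  }, nHomMajor, nHet, nHomMinor)
}

#' Per-SNP quality statistics
#'
#' MAF, call rate and exact HWE p-value for every SNP. SNPs with no
#' non-missing calls get `maf = NA`, `call_rate = 0`, `hwe_p = NA`;
#' monomorphic SNPs get `hwe_p = 1` (and their folded `maf` is 0, so they
#' are governed by the MAF criterion).
#'
#' @param gm a [GenotypeMatrix-class].
#' @param hweMethod passed to [hweExactP()].
#' @return data.frame with columns `snp_id`, `maf`, `call_rate`, `hwe_p`.
#' @export
snpQuality <- function(gm, hweMethod = c("exact", "asymptotic")) {
  hweMethod <- match.arg(hweMethod)
  stopifnot(is(gm, "GenotypeMatrix"))
  cl <- gm@calls
  m <- nSnps(gm)
  maf <- rep(NA_real_, m); cr <- numeric(m); hwe <- rep(NA_real_, m)
  for (j in seq_len(m)) {
    g <- cl[, j]
    cr[j] <- mean(!is.na(g))
    g <- g[!is.na(g)]
    if (!length(g)) next
    f <- sum(g) / (2 * length(g))
    maf[j] <- min(f, 1 - f)
    hwe[j] <- hweExactP(sum(g == 0), sum(g == 1), sum(g == 2),
                        method = hweMethod)
  }
  data.frame(snp_id = gm@snps$snp_id, maf = maf, call_rate = cr,
             hwe_p = hwe, stringsAsFactors = FALSE)
}

# threshold comparison with NA treated as fail; call-rate thresholds get a
# 1e-12 slack so CR = 1 means "exactly complete" without float brittleness
.passes <- function(quality, mafMin, crMin, hweMin) {
  ok <- rep(TRUE, nrow(quality))
  if (!is.na(mafMin)) ok <- ok & !is.na(quality$maf) & quality$maf >= mafMin
  if (!is.na(crMin)) ok <- ok & quality$call_rate >= crMin - 1e-12
  if (!is.na(hweMin)) ok <- ok & !is.na(quality$hwe_p) & quality$hwe_p >= hweMin
  ok
}

#' Apply a filter scenario to a SNP set
#'
#' Returns the indices of SNPs passing all set thresholds (inclusive
#' `>=`; a call-rate threshold of 1 means exactly complete). The composite
#' `"ALL"` returns every SNP; `"BQ"` returns the union of SNPs failing the
#' NQ criteria and SNPs passing the HQ criteria.
#'
#' @param gm a [GenotypeMatrix-class].
#' @param quality per-SNP quality table from [snpQuality()], aligned with
#'   the SNPs of `gm`.
#' @param scenario a [FilterScenario-class].
#' @return Sorted integer vector of passing SNP indices.
#' @export
applyScenario <- function(gm, quality, scenario) {
  stopifnot(is(gm, "GenotypeMatrix"), is(scenario, "FilterScenario"))
  if (nrow(quality) != nSnps(gm))
    stop("quality table must align with the SNPs of gm")
  if (scenario@composite == "ALL") return(seq_len(nSnps(gm)))
  if (scenario@composite == "BQ") {
    failNQ <- !.passes(quality, 0.01, 0.95, 1e-6)
    passHQ <- .passes(quality, 0.1, 1, 1e-2)
    return(which(failNQ | passHQ))
  }
  if (scenario@composite != "")
    stop("unknown composite scenario tag: ", scenario@composite)
  which(.passes(quality, scenario@mafMin, scenario@crMin, scenario@hweMin))
}

#' The sixteen built-in pre-imputation filter scenarios
#'
#' The named filter scenarios of the benchmark design: three basic quality
#' tiers (HQ: MAF >= 0.1, CR = 1, p(HWE) >= 1e-2; NQ: MAF >= 0.01,
#' CR >= 0.95, p(HWE) >= 1e-6; LQ: MAF >= 0.005, CR >= 0.5,
#' p(HWE) >= 1e-12), their single- and two-criterion variants, the
#' bad-quality composite BQ (SNPs failing NQ united with SNPs passing HQ)
#' and the unfiltered ALL.
#'
#' @return Named list of 16 [FilterScenario-class] objects.
#' @examples
#' names(builtinScenarios())
#' @export
builtinScenarios <- function() {
  s <- list(
    FilterScenario("HQ", 0.1, 1, 1e-2),
    FilterScenario("NQ", 0.01, 0.95, 1e-6),
    FilterScenario("LQ", 0.005, 0.5, 1e-12),
    FilterScenario("NQ.MAF", mafMin = 0.01),
    FilterScenario("NQ.HWE", hweMin = 1e-6),
    FilterScenario("NQ.CAR", crMin = 0.95),
    FilterScenario("HQ.MAF", mafMin = 0.1),
    FilterScenario("HQ.HWE", hweMin = 1e-2),
    FilterScenario("HQ.CAR", crMin = 1),
    FilterScenario("NQ.MAF.HWE", mafMin = 0.01, hweMin = 1e-6),
    FilterScenario("HQ.MAF.HWE", mafMin = 0.1, hweMin = 1e-2),
    FilterScenario("LQ.MAF", mafMin = 0.005),
    FilterScenario("LQ.HWE", hweMin = 1e-12),
    FilterScenario("LQ.MAF.HWE", mafMin = 0.005, hweMin = 1e-12),
    FilterScenario("BQ", composite = "BQ"),
    FilterScenario("ALL", composite = "ALL"))
  names(s) <- vapply(s, function(x) x@name, "")
  s
}
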