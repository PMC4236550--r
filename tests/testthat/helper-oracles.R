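# Independent oracles and fixture builders shared across test files.

# Exact HWE p-value by direct enumeration: probability of every heterozygote
# count with the observed allele counts computed from the closed-form
# conditional distribution (log-factorials), two-sided by cumulative
# probability inclusion. Independent of the package's recurrence.
hweEnumOracle <- function(nHomMajor, nHet, nHomMinor) {
  n <- nHomMajor + nHet + nHomMinor
  nRare <- 2 * min(nHomMajor, nHomMinor) + nHet
  if (nRare == 0 || nRare == 2 * n) return(1)
  hets <- seq(nRare %% 2, min(nRare, 2 * n - nRare), by = 2)
  logp <- vapply(hets, function(h) {
    homR <- (nRare - h) / 2
    homC <- n - h - homR
    lfactorial(n) - lfactorial(h) - lfactorial(homR) - lfactorial(homC) +
      h * log(2) + lfactorial(nRare) + lfactorial(2 * n - nRare) -
      lfactorial(2 * n)
  }, numeric(1))
  probs <- exp(logp - max(logp))
  probs <- probs / sum(probs)
  pObs <- probs[match(nHet, hets)]
  min(1, sum(probs[probs <= pObs * (1 + 1e-7)]))
}

# Exact two-sided McNemar p-value by full binomial enumeration of the
# discordant-pair split.
mcnemarEnumOracle <- function(b, cc) {
  n <- b + cc
  if (n == 0) return(1)
  pmf <- vapply(0:n, function(k) choose(n, k) * 0.5^n, numeric(1))
  lo <- sum(pmf[0:min(b, cc) + 1])
  min(1, 2 * lo)
}

# small deterministic genotype matrix fixture
makeTinyGm <- function(calls, ids = NULL) {
  calls <- as.matrix(calls)
  m <- ncol(calls)
  if (is.null(ids)) ids <- sprintf("rs%d", seq_len(m))
  GenotypeMatrix(calls,
    snps = data.frame(snp_id = ids, chrom = "22",
                      position = seq_len(m) * 100L,
                      allele_major = "A", allele_minor = "G",
                      stringsAsFactors = FALSE),
    samples = sprintf("ind%d", seq_len(nrow(calls))))
}

# PosteriorSet from a list of (sample, snp) -> triplet entries
makePosteriors <- function(nSamp, snpIds, entries) {
  probs <- array(NA_real_, c(nSamp, length(snpIds), 3))
  for (e in entries) probs[e[[1]], e[[2]], ] <- e[[3]]
  PosteriorSet(probs, samples = sprintf("ind%d", seq_len(nSamp)),
               snpIds = snpIds)
}

# uniform simplex grid with the given step (includes the boundary)
simplexGrid <- function(step) {
  k <- round(1 / step)
  g <- expand.grid(i = 0:k, j = 0:k)
  g <- g[g$i + g$j <= k, ]
  cbind(g$i, g$j, k - g$i - g$j) / k
}
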