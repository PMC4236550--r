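#' Configuration for the synthetic benchmark data generator
#'
#' Collects the parameters of the founder-mosaic haplotype simulator and
#' the genotype corruption model. Defaults are the package's standard
#' desk-scale benchmark conditions (documented in the methods vignette):
#' an LD-structured panel of 120 haplotypes over 200 SNPs built from 16
#' founders, 60 diploid individuals, a 1% genotyping error rate, per-SNP
#' missingness uniform on 0-5%, and 8% of SNPs each perturbed towards low
#' MAF and towards Hardy-Weinberg violation so that the built-in filter
#' scenarios stratify the SNP set non-trivially.
#'
#' @param nFounders number of founder haplotypes.
#' @param nHap number of panel haplotypes built as founder mosaics.
#' @param nSnp number of SNPs.
#' @param nInd number of diploid study individuals.
#' @param switchRate per-SNP probability of switching founder when copying
#'   (mosaic segment length is geometric with this rate; larger values
#'   mean weaker LD).
#' @param mutationRate per-allele flip probability on copied haplotypes.
#' @param epsilon genotyping error probability of the corruption model.
#' @param missingRateRange per-SNP missingness rate interval (uniform).
#' @param lowMafFrac fraction of SNPs perturbed to low minor allele
#'   frequency (rare-allele downsampling).
#' @param hweViolationFrac fraction of SNPs perturbed to violate
#'   Hardy-Weinberg proportions (heterozygote depletion).
#' @param seed master seed; all stages derive child seeds from it.
#' @return A validated list of class `"SimConfig"`.
#' @export
simConfig <- function(nFounders = 16, nHap = 120, nSnp = 200, nInd = 60,
                      switchRate = 0.08, mutationRate = 0.005,
                      epsilon = 0.01, missingRateRange = c(0, 0.05),
                      lowMafFrac = 0.08, hweViolationFrac = 0.08,
                      seed = 1L) {
  cfg <- list(nFounders = as.integer(nFounders), nHap = as.integer(nHap),
              nSnp = as.integer(nSnp), nInd = as.integer(nInd),
              switchRate = switchRate, mutationRate = mutationRate,
              epsilon = epsilon, missingRateRange = as.numeric(missingRateRange),
              lowMafFrac = lowMafFrac, hweViolationFrac = hweViolationFrac,
              seed = as.integer(seed))
  with(cfg, {
    if (nFounders < 1 || nHap < 2 || nSnp < 1 || nInd < 0)
      stop("counts must be positive")
    if (nFounders > nHap) stop("nFounders must not exceed nHap")
    rates <- c(switchRate, mutationRate, epsilon, missingRateRange,
               lowMafFrac, hweViolationFrac)
    if (any(rates < 0 | rates > 1)) stop("all rates must lie in [0, 1]")
    if (epsilon > 0.5) stop("epsilon must lie in [0, 0.5]")
    if (length(missingRateRange) != 2 || diff(missingRateRange) < 0)
      stop("missingRateRange must be an interval (lo, hi)")
  })
  structure(cfg, class = "SimConfig")
}

#' Specification of a built-in stand-in imputer
#'
#' @param kind `"haplotype_ls"` (windowed Li-Stephens-style haplotype
#'   copying) or `"freq_null"` (allele-frequency HWE posterior, ignoring
#'   LD — a null baseline).
#' @param window number of flanking observed SNPs used on each side of the
#'   target.
#' @param lsTheta copying mismatch (per-allele miscopy) parameter.
#' @param lsRho copying switch parameter; flanking information decays as
#'   `(1 - lsRho)^distance` with map-index distance.
#' @param useReference use the external reference panel (required for
#'   entire-SNP imputation; without it the other individuals'
#'   pseudo-phased haplotypes form the panel).
#' @return A validated list of class `"ImputerSpec"`.
#' @export
imputerSpec <- function(kind = c("haplotype_ls", "freq_null"), window = 10,
                        lsTheta = 0.01, lsRho = 0.05, useReference = TRUE) {
  kind <- match.arg(kind)
  if (window < 1) stop("window must be >= 1")
  if (lsTheta <= 0 || lsTheta >= 0.5) stop("lsTheta must lie in (0, 0.5)")
  if (lsRho < 0 || lsRho >= 1) stop("lsRho must lie in [0, 1)")
  structure(list(kind = kind, window = as.integer(window), lsTheta = lsTheta,
                 lsRho = lsRho, useReference = isTRUE(useReference)),
            class = "ImputerSpec")
}

#' Simulate an LD-structured haplotype panel
#'
#' Founder haplotypes are drawn with per-SNP minor-allele frequencies
#' uniform on `[0.05, 0.5]`; panel haplotypes are built as founder
#' mosaics with geometric segment lengths (switch probability
#' `switchRate` per SNP) and per-allele flips (`mutationRate`). Adjacent
#' SNPs are therefore positively correlated in expectation, more strongly
#' for smaller switch rates. Columns are flipped where needed so that
#' allele code 1 is the rarer allele in the panel.
#'
#' @param cfg a [simConfig()] object.
#' @return A [HaplotypePanel-class].
#' @export
simulatePanel <- function(cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  .withSeed(.childSeed(cfg$seed, 1L), {
    m <- cfg$nSnp
    freq <- stats::runif(m, 0.05, 0.5)
    founders <- matrix(stats::rbinom(cfg$nFounders * m, 1, rep(freq, each = cfg$nFounders)),
                       nrow = cfg$nFounders)
    hap <- matrix(0L, cfg$nHap, m)
    for (h in seq_len(cfg$nHap)) {
      src <- sample.int(cfg$nFounders, 1)
      switches <- stats::runif(m) < cfg$switchRate
      row <- integer(m)
      for (j in seq_len(m)) {
        if (switches[j]) src <- sample.int(cfg$nFounders, 1)
        row[j] <- founders[src, j]
      }
      hap[h, ] <- row
    }
    if (cfg$mutationRate > 0) {
      flip <- matrix(stats::runif(cfg$nHap * m) < cfg$mutationRate, cfg$nHap, m)
      hap[flip] <- 1L - hap[flip]
    }
    major <- rep("A", m); minor <- rep("B", m)
    f1 <- colMeans(hap)
    swap <- f1 > 0.5
    hap[, swap] <- 1L - hap[, swap, drop = FALSE]
    major[swap] <- "B"; minor[swap] <- "A"
    snps <- data.frame(
      snp_id = sprintf("snp%05d", seq_len(m)), chrom = "22",
      position = seq_len(m) * 1000L,
      allele_major = major, allele_minor = minor, stringsAsFactors = FALSE)
    HaplotypePanel(hap, snps)
  })
}

#' Form diploid genotypes by pairing panel haplotypes
#'
#' Draws `2 * nInd` haplotypes from the panel (without replacement when
#' possible, otherwise with replacement if `replace = TRUE`), pairs them,
#' and codes each genotype as the allele-1 dose. Columns where the
#' sampled code-2 allele frequency exceeds 0.5 are folded (codes flipped,
#' allele labels swapped) so that code 2 counts the sample's minor allele.
#'
#' @param panel a [HaplotypePanel-class].
#' @param nInd number of individuals to form.
#' @param seed integer seed.
#' @param replace sample haplotypes with replacement.
#' @param fold fold genotype codes to the sample's minor allele.
#' @return A [GenotypeMatrix-class].
#' @export
genotypesFromPanel <- function(panel, nInd, seed, replace = FALSE,
                               fold = TRUE) {
  stopifnot(is(panel, "HaplotypePanel"))
  nInd <- as.integer(nInd)
  H <- nrow(panel@haplotypes)
  if (!replace && 2 * nInd > H)
    stop("panel has fewer than 2 * nInd haplotypes; set replace = TRUE")
  snps <- panel@snps
  if (nInd == 0)
    return(GenotypeMatrix(matrix(NA_integer_, 0, nrow(snps)), snps,
                          samples = character(0)))
  .withSeed(.childSeed(seed, 0L), {
    pick <- sample.int(H, 2 * nInd, replace = replace)
    h1 <- panel@haplotypes[pick[seq_len(nInd)], , drop = FALSE]
    h2 <- panel@haplotypes[pick[nInd + seq_len(nInd)], , drop = FALSE]
    calls <- h1 + h2
    if (fold) {
      f <- colMeans(calls) / 2
      swap <- which(f > 0.5)
      if (length(swap)) {
        calls[, swap] <- 2L - calls[, swap, drop = FALSE]
        tmp <- snps$allele_major[swap]
        snps$allele_major[swap] <- snps$allele_minor[swap]
        snps$allele_minor[swap] <- tmp
      }
    }
    GenotypeMatrix(calls, snps,
                   samples = sprintf("ind%04d", seq_len(nInd)))
  })
}

#' Corrupt genotypes with error, missingness and low-quality SNP strata
#'
#' Emulates imperfect array genotyping: every call is replaced by a draw
#' from its error-model distribution ([trueGenotypeDistribution()] with
#' the configured `epsilon`); per-SNP missingness rates are drawn
#' uniformly from `missingRateRange`; and designated SNP fractions are
#' perturbed to low minor allele frequency (each minor allele copy kept
#' with probability targeting MAF ~ 0.006) or towards Hardy-Weinberg
#' violation (80% of heterozygotes resolved to a random homozygote), so
#' that the built-in filter scenarios stratify the SNPs non-trivially.
#'
#' @param gm a [GenotypeMatrix-class] of true genotypes.
#' @param cfg a [simConfig()] object.
#' @return A corrupted [GenotypeMatrix-class].
#' @export
corruptGenotypes <- function(gm, cfg) {
  stopifnot(is(gm, "GenotypeMatrix"), inherits(cfg, "SimConfig"))
  calls <- gm@calls
  n <- nrow(calls); m <- ncol(calls)
  .withSeed(.childSeed(cfg$seed, 3L), {
    if (cfg$epsilon > 0 && length(calls)) {
      # per-allele error: each of the two allele calls flips independently
      u1 <- matrix(stats::runif(n * m) < cfg$epsilon, n, m)
      u2 <- matrix(stats::runif(n * m) < cfg$epsilon, n, m)
      a1 <- (calls >= 1L) + 0L  # first allele: 1 for g in {1,2}
      a2 <- (calls == 2L) + 0L
      a1[u1] <- 1L - a1[u1]
      a2[u2] <- 1L - a2[u2]
      newCalls <- a1 + a2
      newCalls[is.na(calls)] <- NA_integer_
      calls <- newCalls
    }
    lo <- cfg$missingRateRange[1]; hi <- cfg$missingRateRange[2]
    if (hi > 0 && length(calls)) {
      rates <- stats::runif(m, lo, hi)
      drop <- matrix(stats::runif(n * m), n, m) <
        matrix(rates, n, m, byrow = TRUE)
      calls[drop] <- NA_integer_
    }
    nLow <- .roundHalfUp(cfg$lowMafFrac * m)
    nHwe <- .roundHalfUp(cfg$hweViolationFrac * m)
    perturb <- sample.int(m, min(m, nLow + nHwe))
    lowIdx <- perturb[seq_len(min(nLow, length(perturb)))]
    hweIdx <- setdiff(perturb, lowIdx)
    for (j in lowIdx) {
      g <- calls[, j]
      f <- mean(g, na.rm = TRUE) / 2
      if (is.nan(f) || f <= 0) next
      keep <- min(1, 0.006 / f)
      het <- which(!is.na(g) & g == 1L)
      hom <- which(!is.na(g) & g == 2L)
      g[het] <- ifelse(stats::runif(length(het)) < keep, 1L, 0L)
      k1 <- stats::runif(length(hom)) < keep
      k2 <- stats::runif(length(hom)) < keep
      g[hom] <- as.integer(k1) + as.integer(k2)
      calls[, j] <- g
    }
    for (j in hweIdx) {
      g <- calls[, j]
      het <- which(!is.na(g) & g == 1L)
      resolve <- het[stats::runif(length(het)) < 0.8]
      g[resolve] <- ifelse(stats::runif(length(resolve)) < 0.5, 0L, 2L)
      calls[, j] <- g
    }
  })
  GenotypeMatrix(calls, gm@snps, gm@samples)
}

#' Simulate a full benchmark dataset
#'
#' Runs the generator chain with child seeds derived from the master
#' seed: haplotype panel, true genotypes, corrupted study genotypes.
#'
#' @param cfg a [simConfig()] object.
#' @return List with elements `panel` ([HaplotypePanel-class]),
#'   `gmTrue` and `gm` ([GenotypeMatrix-class]).
#' @export
simulateDataset <- function(cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  panel <- simulatePanel(cfg)
  gmTrue <- genotypesFromPanel(panel, cfg$nInd, seed = .childSeed(cfg$seed, 2L))
  gm <- corruptGenotypes(gmTrue, cfg)
  list(panel = panel, gmTrue = gmTrue, gm = gm)
}

# align a panel's allele coding to a GenotypeMatrix's codes by allele labels:
# returns the haplotype matrix with columns flipped where the gm's minor
# allele is the panel's major allele
.alignPanel <- function(gm, panel) {
  gs <- gm@snps; ps <- panel@snps
  if (nrow(gs) != nrow(ps) || !all(gs$snp_id == ps$snp_id))
    stop("panel SNPs must match the genotype matrix SNPs")
  hap <- panel@haplotypes
  flip <- gs$allele_minor == ps$allele_major & gs$allele_major == ps$allele_minor
  same <- gs$allele_minor == ps$allele_minor & gs$allele_major == ps$allele_major
  if (any(!(flip | same)))
    stop("allele labels of panel and genotypes do not match at ",
         sum(!(flip | same)), " SNP(s)")
  if (any(flip)) hap[, flip] <- 1L - hap[, flip, drop = FALSE]
  hap
}

# deterministic naive phasing of a genotype matrix into 2n pseudo-haplotypes.
# Homozygotes are unambiguous; at heterozygous sites the minor allele is
# chained greedily: it stays on the same pseudo-haplotype as the previous
# het when the two SNPs' genotype covariance (composite LD) is positive,
# and switches otherwise. Missing calls contribute the major allele.
.pseudoPhase <- function(gm) {
  calls <- gm@calls
  n <- nrow(calls); m <- ncol(calls)
  covCache <- new.env(parent = emptyenv())
  pairCov <- function(j1, j2) {
    key <- paste0(j1, "_", j2)
    v <- covCache[[key]]
    if (is.null(v)) {
      v <- tryCatch(
        stats::cov(calls[, j1], calls[, j2], use = "pairwise.complete.obs"),
        warning = function(w) 0)
      if (is.na(v)) v <- 0
      covCache[[key]] <- v
    }
    v
  }
  h <- matrix(0L, 2 * n, m)
  for (i in seq_len(n)) {
    g <- calls[i, ]
    g[is.na(g)] <- 0L
    a1 <- as.integer(g == 2L)
    a2 <- a1
    het <- which(g == 1L)
    if (length(het)) {
      side <- 1L
      a1[het[1]] <- 1L
      for (k in seq_along(het)[-1]) {
        if (pairCov(het[k - 1], het[k]) < 0) side <- 3L - side
        if (side == 1L) a1[het[k]] <- 1L else a2[het[k]] <- 1L
      }
    }
    h[2 * i - 1, ] <- a1
    h[2 * i, ] <- a2
  }
  h
}

#' Frequency-only null imputer
#'
#' Posterior at every target cell equals the Hardy-Weinberg triplet
#' `((1-q)^2, 2q(1-q), q^2)` at the SNP's observed code-2 allele
#' frequency `q`, ignoring linkage disequilibrium entirely. For SNPs with
#' no observed calls the frequency is taken from the reference panel when
#' supplied; otherwise the cell is skipped with a warning.
#'
#' @param gmMasked the masked [GenotypeMatrix-class].
#' @param targets integer matrix of (sample, snp) target cells.
#' @param panel optional [HaplotypePanel-class] supplying frequencies for
#'   fully masked SNPs.
#' @return A [PosteriorSet-class].
#' @export
imputeFreqNull <- function(gmMasked, targets, panel = NULL) {
  stopifnot(is(gmMasked, "GenotypeMatrix"))
  targets <- as.matrix(targets)
  probs <- array(NA_real_, c(nSamples(gmMasked), nSnps(gmMasked), 3))
  alignedHap <- if (!is.null(panel)) .alignPanel(gmMasked, panel) else NULL
  skipped <- 0L
  for (j in unique(targets[, 2])) {
    g <- gmMasked@calls[, j]
    g <- g[!is.na(g)]
    q <- if (length(g)) sum(g) / (2 * length(g)) else if (!is.null(alignedHap))
      mean(alignedHap[, j]) else NA_real_
    if (is.na(q)) { skipped <- skipped + 1L; next }
    tri <- c((1 - q)^2, 2 * q * (1 - q), q^2)
    rows <- targets[targets[, 2] == j, 1]
    probs[cbind(rep(rows, each = 3), j,
                rep(1:3, times = length(rows)))] <-
      rep(tri, times = length(rows))
  }
  if (skipped)
    warning(skipped, " target SNP(s) skipped: no estimable allele frequency")
  PosteriorSet(probs, samples = gmMasked@samples,
               snpIds = gmMasked@snps$snp_id)
}

# genotype emission log-probabilities given a haplotype-pair dose, under
# per-allele miscopy rate theta: columns d = 0,1,2, rows g = 0,1,2
.lsEmissionLog <- function(theta) {
  log(cbind(trueGenotypeDistribution(0, theta),
            trueGenotypeDistribution(1, theta),
            trueGenotypeDistribution(2, theta)))
}

# posterior for one cell by haplotype-pair copying over a window.
# hap: H x m aligned allele matrix; obsIdx/obsG: the individual's observed
# SNPs and genotypes; j: target SNP index.
.lsCellPosterior <- function(hap, obsIdx, obsG, j, window, theta, rho) {
  emis <- .lsEmissionLog(theta)
  left <- obsIdx[obsIdx < j]
  right <- obsIdx[obsIdx > j]
  sel <- c(utils::tail(left, window), utils::head(right, window))
  at <- hap[, j]
  H <- nrow(hap)
  if (!length(sel)) {
    W <- matrix(1, H, H)
  } else {
    g <- obsG[match(sel, obsIdx)]
    decay <- (1 - rho)^abs(sel - j)
    # log P(g | d) weighted by decay, split by dose class:
    # d = a1 + a2 is bilinear in the two allele vectors
    e0 <- decay * emis[cbind(g + 1L, 1L)]
    e1 <- decay * emis[cbind(g + 1L, 2L)]
    e2 <- decay * emis[cbind(g + 1L, 3L)]
    A <- hap[, sel, drop = FALSE]
    B <- 1L - A
    L <- B %*% (e0 * t(B)) + A %*% (e1 * t(B)) + B %*% (e1 * t(A)) +
      A %*% (e2 * t(A))
    W <- exp(L - max(L))
  }
  v1 <- at; v0 <- 1 - at
  pd <- c(as.numeric(v0 %*% W %*% v0),
          as.numeric(v1 %*% W %*% v0 + v0 %*% W %*% v1),
          as.numeric(v1 %*% W %*% v1))
  pd <- pd / sum(pd)
  # smooth through the miscopy error at the target allele pair
  post <- as.numeric(exp(emis) %*% pd)
  post / sum(post)
}

#' Windowed Li-Stephens-style haplotype-copying imputer
#'
#' For each target cell, candidate haplotype pairs from the copy panel are
#' weighted by their copying likelihood against the individual's observed
#' flanking genotypes within a window: per-allele miscopies cost `lsTheta`
#' and the contribution of a flanking SNP decays as
#' `(1 - lsRho)^distance` (map-index distance), standing in for copying
#' switches. The posterior genotype at the target is the pair-weighted
#' dose distribution smoothed through the miscopy error. With a reference
#' panel the panel haplotypes are copied; without one
#' (`useReference = FALSE`) the other individuals' deterministically
#' pseudo-phased haplotypes form the panel (so entire-SNP imputation,
#' where no individual is typed at the target, requires a reference).
#'
#' @param gmMasked the masked [GenotypeMatrix-class].
#' @param targets integer matrix of (sample, snp) target cells.
#' @param panel a [HaplotypePanel-class], or `NULL` for the no-reference
#'   mode.
#' @param spec an [imputerSpec()].
#' @return A [PosteriorSet-class] with posteriors on the probability
#'   simplex at every target cell.
#' @export
imputeHaplotypeLS <- function(gmMasked, targets, panel = NULL,
                              spec = imputerSpec()) {
  stopifnot(is(gmMasked, "GenotypeMatrix"), inherits(spec, "ImputerSpec"))
  targets <- as.matrix(targets)
  useRef <- !is.null(panel) && spec$useReference
  if (!useRef) {
    untypedTargets <- unique(targets[, 2])
    fullyMissing <- untypedTargets[vapply(untypedTargets, function(j)
      all(is.na(gmMasked@calls[, j])), logical(1))]
    if (length(fullyMissing))
      stop("entire-SNP imputation requires a reference panel (",
           length(fullyMissing), " target SNP(s) untyped in all individuals)")
  }
  hap <- if (useRef) .alignPanel(gmMasked, panel) else .pseudoPhase(gmMasked)
  probs <- array(NA_real_, c(nSamples(gmMasked), nSnps(gmMasked), 3))
  calls <- gmMasked@calls
  ord <- order(targets[, 1], targets[, 2])
  targets <- targets[ord, , drop = FALSE]
  lastSample <- -1L
  obsIdx <- integer(0); obsG <- integer(0)
  for (r in seq_len(nrow(targets))) {
    i <- targets[r, 1]; j <- targets[r, 2]
    if (i != lastSample) {
      obsIdx <- which(!is.na(calls[i, ]))
      obsG <- calls[i, obsIdx]
      lastSample <- i
    }
    hapUse <- if (useRef) hap else hap[-c(2 * i - 1, 2 * i), , drop = FALSE]
    probs[i, j, ] <- .lsCellPosterior(hapUse, obsIdx, obsG, j, spec$window,
                                      spec$lsTheta, spec$lsRho)
  }
  PosteriorSet(probs, samples = gmMasked@samples,
               snpIds = gmMasked@snps$snp_id)
}
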