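test_that("panel simulation respects shape, seed determinism and the degenerate mosaic limit", {
  cfg <- simConfig(nFounders = 2, nHap = 4, nSnp = 10, nInd = 2, seed = 5)
  panel <- simulatePanel(cfg)
  expect_equal(dim(haplotypeAlleles(panel)), c(4L, 10L))
  expect_true(all(haplotypeAlleles(panel) %in% 0:1))
  expect_identical(haplotypeAlleles(simulatePanel(cfg)),
                   haplotypeAlleles(panel))
  # no switching, no mutation: every haplotype equals a founder row pattern
  cfg0 <- simConfig(nFounders = 3, nHap = 12, nSnp = 40, nInd = 4,
                    switchRate = 0, mutationRate = 0, seed = 9)
  hap <- haplotypeAlleles(simulatePanel(cfg0))
  expect_lte(nrow(unique(hap)), 3)
  # panel convention: allele 1 is never the more frequent allele
  expect_true(all(colMeans(hap) <= 0.5 + 1e-12))
  expect_error(simConfig(nFounders = 10, nHap = 4), "exceed")
})

test_that("adjacent-SNP LD weakens as the mosaic switch rate grows", {
  meanAdjR2 <- function(switchRate, seed) {
    cfg <- simConfig(nFounders = 8, nHap = 60, nSnp = 60, nInd = 2,
                     switchRate = switchRate, mutationRate = 0, seed = seed)
    h <- haplotypeAlleles(simulatePanel(cfg))
    keep <- apply(h, 2, sd) > 0
    h <- h[, keep, drop = FALSE]
    r <- diag(cor(h[, -ncol(h)], h[, -1]))
    mean(r^2, na.rm = TRUE)
  }
  lo <- vapply(1:25, function(s) meanAdjR2(0.02, s), numeric(1))
  hi <- vapply(1:25, function(s) meanAdjR2(0.5, s), numeric(1))
  expect_gt(mean(lo), mean(hi))
  expect_lt(binom.test(sum(lo > hi), 25, alternative = "greater")$p.value, 0.05)
})

test_that("genotype formation pairs haplotypes and preserves allele frequency", {
  cfg <- simConfig(nFounders = 2, nHap = 2, nSnp = 5, nInd = 1, seed = 1)
  panel <- HaplotypePanel(rbind(rep(0L, 5), rep(1L, 5)),
                          snpInfo(simulatePanel(cfg)))
  gm <- genotypesFromPanel(panel, 1, seed = 3, fold = FALSE)
  expect_true(all(genotypeCalls(gm) == 1L))  # complementary pair -> all het
  expect_equal(nSamples(genotypesFromPanel(panel, 0, seed = 1)), 0)
  expect_error(genotypesFromPanel(panel, 5, seed = 1), "fewer than")
  # frequency preservation over seeds (binomial tolerance)
  cfgF <- simConfig(nFounders = 10, nHap = 200, nSnp = 30, nInd = 50, seed = 2)
  panelF <- simulatePanel(cfgF)
  pf <- colMeans(haplotypeAlleles(panelF))
  gf <- rowMeans(vapply(1:10, function(s) {
    g <- genotypesFromPanel(panelF, 50, seed = s, fold = FALSE)
    colMeans(genotypeCalls(g)) / 2
  }, numeric(30)))
  expect_true(all(abs(gf - pf) < 4 * sqrt(pf * (1 - pf) / (2 * 50 * 10)) + 0.02))
})

test_that("corruption is the identity when disabled and random at epsilon = 0.5", {
  cfg0 <- simConfig(nFounders = 6, nHap = 40, nSnp = 30, nInd = 20,
                    epsilon = 0, missingRateRange = c(0, 0),
                    lowMafFrac = 0, hweViolationFrac = 0, seed = 3)
  ds <- simulateDataset(cfg0)
  expect_identical(genotypeCalls(ds$gm), genotypeCalls(ds$gmTrue))
  # epsilon = 0.5: both allele reads are coin flips, so concordance drops
  # to the error-model expectation sum(P(g|g)) averaged over genotypes
  cfgR <- simConfig(nFounders = 6, nHap = 100, nSnp = 50, nInd = 40,
                    epsilon = 0.5, missingRateRange = c(0, 0),
                    lowMafFrac = 0, hweViolationFrac = 0, seed = 3)
  conc <- vapply(1:10, function(s) {
    cfgS <- simConfig(nFounders = 6, nHap = 100, nSnp = 50, nInd = 40,
                      epsilon = 0.5, missingRateRange = c(0, 0),
                      lowMafFrac = 0, hweViolationFrac = 0, seed = s)
    d <- simulateDataset(cfgS)
    mean(genotypeCalls(d$gm) == genotypeCalls(d$gmTrue))
  }, numeric(1))
  truthG <- genotypeCalls(simulateDataset(cfgR)$gmTrue)
  expChance <- mean(vapply(as.vector(truthG), function(g)
    trueGenotypeDistribution(g, 0.5)[g + 1], numeric(1)))
  expect_equal(mean(conc), expChance, tolerance = 0.05)
})

test_that("corruption draws match the error-model branch frequencies in Monte-Carlo", {
  # one SNP column fixed at each genotype, many individuals
  eps <- 0.2
  n <- 30000
  for (g in 0:2) {
    gm <- makeTinyGm(matrix(as.integer(g), n, 1))
    cfg <- simConfig(nFounders = 2, nHap = 4, nSnp = 1, nInd = n,
                     epsilon = eps, missingRateRange = c(0, 0),
                     lowMafFrac = 0, hweViolationFrac = 0, seed = 77 + g)
    out <- genotypeCalls(corruptGenotypes(gm, cfg))
    obs <- tabulate(out + 1L, 3)
    expected <- trueGenotypeDistribution(g, eps) * n
    gof <- sum((obs - expected)^2 / expected)
    expect_gt(pchisq(gof, df = 2, lower.tail = FALSE), 0.01)
  }
})

test_that("quality perturbation strata are detectable by the QC filters", {
  cfg <- simConfig(nFounders = 10, nHap = 200, nSnp = 100, nInd = 100,
                   epsilon = 0, missingRateRange = c(0, 0),
                   lowMafFrac = 0.2, hweViolationFrac = 0.2, seed = 19)
  ds <- simulateDataset(cfg)
  q <- snpQuality(ds$gm)
  # ~20% of SNPs pushed to low MAF (fail the 1% criterion)
  expect_equal(mean(q$maf < 0.01, na.rm = TRUE), 0.2, tolerance = 0.35)
  # ~20% pushed out of HWE at large n
  expect_equal(mean(q$hwe_p < 1e-2, na.rm = TRUE), 0.2, tolerance = 0.35)
  # and the scenarios stratify non-trivially
  sc <- builtinScenarios()
  sizes <- vapply(sc[c("HQ", "NQ", "LQ", "ALL")], function(s)
    length(applyScenario(ds$gm, q, s)), numeric(1))
  expect_true(sizes[["HQ"]] < sizes[["NQ"]])
  expect_true(sizes[["NQ"]] <= sizes[["LQ"]])
  expect_true(sizes[["LQ"]] <= sizes[["ALL"]])
})

test_that("the frequency-null imputer emits HWE posteriors with near-zero rsq", {
  gm <- makeTinyGm(cbind(rep(c(0L, 1L, 2L), times = c(25, 50, 25)),
                         rep(0L, 100)))
  targets <- cbind(1:100, 1)
  ps <- imputeFreqNull(gm, targets)
  expect_equal(posteriorArray(ps)[1, 1, ], c(0.25, 0.5, 0.25))
  # all cells identical; dose variance zero
  doses <- expectedDose(cbind(posteriorArray(ps)[, 1, 1],
                              posteriorArray(ps)[, 1, 2],
                              posteriorArray(ps)[, 1, 3]))
  expect_equal(machRsq(doses), 0)
  # q = 0 -> point mass on the major homozygote
  ps2 <- imputeFreqNull(gm, cbind(1:3, 2))
  expect_equal(posteriorArray(ps2)[1, 2, ], c(1, 0, 0))
  # untyped SNP without panel frequency -> warning and skip
  gmNa <- makeTinyGm(matrix(NA_integer_, 5, 1))
  expect_warning(imputeFreqNull(gmNa, cbind(1:2, 1)), "skipped")
})

test_that("the LS imputer collapses to the panel genotype as mismatch vanishes", {
  # panel with a unique matching haplotype pair for the target individual
  hap <- rbind(c(0L, 0L, 0L, 0L, 0L),
               c(1L, 1L, 1L, 1L, 1L),
               c(0L, 1L, 0L, 1L, 0L),
               c(1L, 0L, 1L, 0L, 1L))
  snps <- data.frame(snp_id = sprintf("rs%d", 1:5), chrom = "22",
                     position = (1:5) * 100L, allele_major = "A",
                     allele_minor = "G", stringsAsFactors = FALSE)
  panel <- HaplotypePanel(hap, snps)
  # individual carries haplotypes 1+2 -> het everywhere; mask the middle SNP
  gm <- GenotypeMatrix(matrix(c(1L, 1L, NA, 1L, 1L), 1, 5), snps, "i1")
  ps <- imputeHaplotypeLS(gm, cbind(1, 3), panel,
                          imputerSpec(window = 2, lsTheta = 1e-4))
  post <- posteriorArray(ps)[1, 3, ]
  expect_gt(post[2], 0.99)  # het forced by the consistent pairs
  expect_equal(sum(post), 1, tolerance = 1e-9)
})

test_that("on an LD-free panel the LS posterior approaches the HWE triplet", {
  set.seed(41)
  m <- 21
  q <- 0.3
  hap <- matrix(rbinom(400 * m, 1, q), 400, m)
  snps <- data.frame(snp_id = sprintf("rs%d", 1:m), chrom = "1",
                     position = (1:m) * 10L, allele_major = "A",
                     allele_minor = "G", stringsAsFactors = FALSE)
  panel <- HaplotypePanel(hap, snps)
  gm <- GenotypeMatrix(matrix(c(rep(0L, 10), NA, rep(0L, 10)), 1, m), snps, "i1")
  ps <- imputeHaplotypeLS(gm, cbind(1, 11), panel, imputerSpec(window = 5))
  qPanel <- mean(hap[, 11])
  hwe <- c((1 - qPanel)^2, 2 * qPanel * (1 - qPanel), qPanel^2)
  expect_lt(max(abs(posteriorArray(ps)[1, 11, ] - hwe)), 0.08)
})

test_that("every emitted posterior lies on the simplex and is sample-order invariant", {
  cfg <- simConfig(nFounders = 8, nHap = 50, nSnp = 50, nInd = 20, seed = 23)
  ds <- simulateDataset(cfg)
  q <- snpQuality(ds$gm)
  hq <- applyScenario(ds$gm, q, builtinScenarios()[["HQ"]])
  plan <- makeNestedGenotypeMasks(ds$gm, hq, 20, seed = 2)
  gmM <- applyMask(ds$gm, plan, 20)
  ov <- overlapUnits(plan)
  for (ps in list(imputeHaplotypeLS(gmM, ov, ds$panel, imputerSpec(window = 4)),
                  imputeFreqNull(gmM, ov))) {
    p <- posteriorArray(ps)
    tri <- matrix(p, ncol = 3)
    tri <- tri[!is.na(tri[, 1]), , drop = FALSE]
    expect_equal(nrow(tri), nrow(ov))
    expect_true(all(tri >= -1e-9))
    expect_true(all(abs(rowSums(tri) - 1) <= 1e-9))
  }
  # permuting samples permutes the posteriors identically
  perm <- c(5:1, 6:20)
  gmP <- GenotypeMatrix(genotypeCalls(gmM)[perm, ], snpInfo(gmM),
                        sampleIds(gmM)[perm])
  ovP <- ov
  ovP[, 1] <- order(perm)[ov[, 1]]  # new row index of each original sample
  psA <- imputeHaplotypeLS(gmM, ov, ds$panel, imputerSpec(window = 4))
  psB <- imputeHaplotypeLS(gmP, ovP, ds$panel, imputerSpec(window = 4))
  for (r in seq_len(nrow(ov)))
    expect_equal(posteriorArray(psB)[ovP[r, 1], ovP[r, 2], ],
                 posteriorArray(psA)[ov[r, 1], ov[r, 2], ])
})

test_that("entire-SNP imputation without a reference panel is refused", {
  gm <- makeTinyGm(cbind(c(0L, 1L), c(NA_integer_, NA_integer_)))
  expect_error(
    imputeHaplotypeLS(gm, cbind(1:2, 2), panel = NULL,
                      spec = imputerSpec(useReference = FALSE)),
    "requires a reference panel")
})

test_that("the LS imputer beats the frequency-null baseline on LD-structured data", {
  cfg <- simConfig(seed = 42)
  ds <- simulateDataset(cfg)
  q <- snpQuality(ds$gm)
  hq <- applyScenario(ds$gm, q, builtinScenarios()[["HQ"]])
  plan <- makeNestedGenotypeMasks(ds$gm, hq, 10, seed = 7)
  ov <- overlapUnits(plan)
  tr <- maskTruth(plan, 10)
  gmM <- applyMask(ds$gm, plan, 10)
  meanH <- function(ps) mean(scoreFrame(scoreCells(ov, tr, ps))$hellinger)
  hNull <- meanH(imputeFreqNull(gmM, ov))
  hLs <- meanH(imputeHaplotypeLS(gmM, ov, NULL, imputerSpec(useReference = FALSE)))
  hLsRef <- meanH(imputeHaplotypeLS(gmM, ov, ds$panel, imputerSpec()))
  expect_gt(hLs, hNull)
  expect_gt(hLsRef, hLs)
})
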