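test_that("the genotyping-error distribution follows the piecewise error model", {
  expect_equal(trueGenotypeDistribution(0, 0), c(1, 0, 0))
  expect_equal(trueGenotypeDistribution(2, 0), c(0, 0, 1))
  expect_equal(trueGenotypeDistribution(1, 0.1), c(0.09, 0.82, 0.09))
  e <- 0.3
  expect_equal(trueGenotypeDistribution(0, e),
               c((1 - e)^2, 2 * e * (1 - e), e^2))
  # all branches sum to 1 analytically
  for (g in 0:2) for (e in c(0, 0.05, 0.25, 0.5))
    expect_equal(sum(trueGenotypeDistribution(g, e)), 1)
  expect_error(trueGenotypeDistribution(NA, 0), "genotype code")
  expect_error(trueGenotypeDistribution(1, 0.6), "epsilon")
})

test_that("Bhattacharyya and Hellinger behave at identity, orthogonality and the worked example", {
  expect_equal(bhattacharyya(c(1, 0, 0), c(1, 0, 0)), 1)
  expect_equal(bhattacharyya(c(1, 0, 0), c(0, 1, 0)), 0)
  expect_equal(bhattacharyya(c(1, 0, 0), c(0.81, 0.18, 0.01)), 0.9)
  expect_equal(hellingerScore(c(1, 0, 0), c(0.7056, 0.2944, 0)), 0.6)
  expect_error(bhattacharyya(c(1, 0, -0.1), c(1, 0, 0)), "negative|sum")
})

test_that("Hellinger and SEN are symmetric, bounded and maximal at identity", {
  grid <- simplexGrid(0.1)
  set.seed(4)
  idx <- cbind(sample(nrow(grid), 200, TRUE), sample(nrow(grid), 200, TRUE))
  h12 <- hellingerScore(grid[idx[, 1], ], grid[idx[, 2], ])
  h21 <- hellingerScore(grid[idx[, 2], ], grid[idx[, 1], ])
  expect_equal(h12, h21)
  expect_true(all(h12 >= -1e-12 & h12 <= 1 + 1e-12))
  expect_equal(hellingerScore(grid, grid), rep(1, nrow(grid)))
  d <- expectedDose(grid)
  expect_equal(senScore(d, d), rep(1, nrow(grid)))
  expect_equal(senScore(d, 2 - d), 1 - (2 * d - 2)^2 / 4)
})

test_that("expected dose and SEN match their closed forms", {
  expect_equal(expectedDose(c(1, 0, 0)), 0)
  expect_equal(expectedDose(c(0, 0, 1)), 2)
  expect_equal(expectedDose(c(0.25, 0.5, 0.25)), 1)
  expect_equal(senScore(0, 0.4), 0.96)
  expect_equal(senScore(2, 0), 0)
  expect_error(senScore(2.1, 0), "\\[0, 2\\]")
})

test_that("with zero error the Hellinger score reduces to 1 - sqrt(1 - sqrt(p_true))", {
  grid <- simplexGrid(0.05)
  for (g in 0:2) {
    f1 <- trueGenotypeDistribution(g, 0)
    general <- hellingerScore(matrix(f1, nrow(grid), 3, byrow = TRUE), grid)
    closed <- 1 - sqrt(1 - sqrt(grid[, g + 1]))
    expect_equal(general, closed, tolerance = 1e-12)
  }
})

test_that("a SEN score of at least 0.95 pins down the true hard call at zero error", {
  # |m_obs - m_imp| < 0.5 whenever SEN >= 0.95, so rounding the imputed
  # dose recovers the integer truth
  grid <- simplexGrid(0.02)
  d <- expectedDose(grid)
  for (g in 0:2) {
    s <- senScore(g, d)
    keep <- s >= 0.95
    expect_true(all(abs(d[keep] - g) < 0.5))
    expect_true(all(round(d[keep]) == g))
  }
})

test_that("Hellinger >= 0.6 at zero error implies posterior of the truth >= 0.7056", {
  grid <- simplexGrid(0.01)
  h <- hellingerScore(matrix(c(1, 0, 0), nrow(grid), 3, byrow = TRUE), grid)
  expect_equal(min(grid[h >= 0.6, 1]), 0.71, tolerance = 0.011)
  expect_true(min(grid[h >= 0.6, 1]) >= 0.84^2)
  # algebraic bound: H = 0.6 <=> sqrt(p) = 1 - 0.4^2
  expect_equal(1 - sqrt(1 - sqrt(0.84^2)), 0.6)
})

test_that("scoreCells scores each cell and flags concordance with tie-break to the smaller code", {
  posts <- makePosteriors(2, c("rs1", "rs2"), list(
    list(1, 1, c(1, 0, 0)),
    list(1, 2, c(1 / 3, 1 / 3, 1 / 3)),
    list(2, 1, c(0.5, 0.5, 0))))
  cells <- rbind(c(1, 1), c(1, 2), c(2, 1))
  st <- scoreFrame(scoreCells(cells, c(0L, 0L, 1L), posts, epsilon = 0))
  expect_equal(st$hellinger[1], 1)
  expect_equal(st$sen[1], 1)
  expect_true(st$concordant[1])
  expect_equal(st$hellinger[2], 1 - sqrt(1 - sqrt(1 / 3)))
  expect_equal(st$sen[2], 0.75)
  expect_equal(st$best_guess[3], 0)  # tie -> smaller code
  expect_false(st$concordant[3])
  # coverage error for missing posteriors
  expect_error(scoreCells(rbind(c(2, 2)), 1L, posts), "no posterior")
})

test_that("a perfect imputer yields all-ones scores", {
  truth <- c(0L, 1L, 2L)
  posts <- makePosteriors(3, "rs1", lapply(1:3, function(i)
    list(i, 1, trueGenotypeDistribution(truth[i], 0))))
  st <- scoreFrame(scoreCells(cbind(1:3, 1), truth, posts))
  expect_equal(st$hellinger, rep(1, 3))
  expect_equal(st$sen, rep(1, 3))
  expect_true(all(st$concordant))
})

test_that("machRsq hits its closed-form limits and is invariant to allele relabelling", {
  expect_equal(machRsq(rep(1, 10)), 0)           # constant doses
  expect_equal(machRsq(rep(0.4, 5)), 0)
  doses <- rep(c(0, 1, 2), times = c(25, 50, 25))
  expect_equal(machRsq(doses), 1)                # exact-HWE hard calls
  expect_equal(machRsq(doses, denom = "pq"), 2)  # literal printed denominator
  set.seed(6)
  d <- runif(50, 0, 2)
  expect_equal(machRsq(d), machRsq(2 - d))
  expect_error(machRsq(1), "at least 2")
  expect_error(machRsq(c(0, 1), p = 1.2), "\\(0, 1\\)")
})

test_that("imputeInfo hits its closed-form limits", {
  hard <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(1, 0, 0))
  expect_equal(imputeInfo(hard), 1)
  for (theta in c(0.2, 0.5)) {
    hwe <- matrix(c((1 - theta)^2, 2 * theta * (1 - theta), theta^2),
                  10, 3, byrow = TRUE)
    expect_equal(imputeInfo(hwe), 0, tolerance = 1e-12)
  }
  unif <- matrix(1 / 3, 6, 3)
  expect_equal(imputeInfo(unif), -1 / 3)
  expect_equal(imputeInfo(unif, clamp = TRUE), 0)
  mono <- matrix(c(1, 0, 0), 4, 3, byrow = TRUE)
  expect_equal(imputeInfo(mono), 1)  # monomorphic convention
})

test_that("aggregation averages per SNP and the global mean is the weighted per-SNP mean", {
  posts <- makePosteriors(3, c("rs1", "rs2"), list(
    list(1, 1, c(1, 0, 0)), list(2, 1, c(0.7056, 0.2944, 0)),
    list(3, 1, c(1, 0, 0)), list(1, 2, c(0, 1, 0))))
  cells <- rbind(c(1, 1), c(2, 1), c(3, 1), c(1, 2))
  st <- scoreCells(cells, c(0L, 0L, 0L, 1L), posts)
  bySnp <- scoreFrame(aggregateScores(st, posteriors = posts))
  expect_equal(bySnp$mean_hellinger[bySnp$snp_id == "rs1"], mean(c(1, 0.6, 1)))
  expect_equal(bySnp$n_cells, c(3L, 1L))
  glob <- scoreFrame(aggregateScores(st, bySnp = FALSE))
  expect_equal(glob$mean_hellinger,
               weighted.mean(bySnp$mean_hellinger, bySnp$n_cells))
  # single-cell group: mean equals the cell
  expect_equal(bySnp$mean_sen[bySnp$snp_id == "rs2"],
               scoreFrame(st)$sen[4])
})

test_that("dichotomisation uses an inclusive cutoff and reports the flagged percentage", {
  d <- dichotomize(c(0.59, 0.60, 0.61), cutoff = 0.6)
  expect_equal(d$flags, c(FALSE, TRUE, TRUE))
  expect_equal(d$pct, 200 / 3)
  expect_equal(dichotomize(c(1, 1, 1), cutoff = 0.95)$pct, 100)
  expect_equal(dichotomize(c(0.29, 0.31), cutoff = 0.3)$pct, 50)
  st <- ScoreTable(data.frame(hellinger = c(0.7, 0.5)), "cell")
  expect_equal(dichotomize(st, "hellinger", 0.6)$pct, 50)
  expect_error(dichotomize(st, "info", 0.3), "not present")
})
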