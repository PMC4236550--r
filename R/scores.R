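#' True-genotype trinomial distribution under a genotyping error model
#'
#' The distribution of the underlying true genotype given an observed
#' hard call `g` and a per-allele genotyping error probability `epsilon`:
#' each of the two allele calls is wrong independently with probability
#' `epsilon`, giving
#' \deqn{((1-\epsilon)^2,\; 2\epsilon(1-\epsilon),\; \epsilon^2)}{( (1-e)^2, 2e(1-e), e^2 )}
#' for `g = 0`, \eqn{(\epsilon(1-\epsilon), (1-\epsilon)^2+\epsilon^2,
#' \epsilon(1-\epsilon))} for `g = 1`, and the mirror of the first branch
#' for `g = 2`. `epsilon = 0` yields a point mass on the observed call.
#'
#' @param g genotype code in \{0, 1, 2\}.
#' @param epsilon genotyping error probability in `[0, 0.5]`.
#' @return Numeric probability triplet over genotype codes (0, 1, 2).
#' @examples
#' trueGenotypeDistribution(1, 0.1)  # (0.09, 0.82, 0.09)
#' @export
trueGenotypeDistribution <- function(g, epsilon = 0) {
  if (length(g) != 1 || is.na(g) || !(g %in% c(0, 1, 2)))
    stop("g must be a single genotype code in {0, 1, 2}")
  if (is.na(epsilon) || epsilon < 0 || epsilon > 0.5)
    stop("epsilon must lie in [0, 0.5]")
  e <- epsilon
  switch(as.character(g),
    "0" = c((1 - e)^2, 2 * e * (1 - e), e^2),
    "1" = c(e * (1 - e), (1 - e)^2 + e^2, e * (1 - e)),
    "2" = c(e^2, 2 * e * (1 - e), (1 - e)^2))
}

#' Bhattacharyya coefficient of two trinomial distributions
#'
#' \eqn{B = \sum_i \sqrt{f_{1i} f_{2i}}}, the overlap of the two
#' distributions, in `[0, 1]`.
#'
#' @param f1,f2 probability triplets (length-3 vectors) or n x 3 matrices
#'   of triplets, compared row-wise.
#' @return Numeric vector of coefficients in `[0, 1]`.
#' @export
bhattacharyya <- function(f1, f2) {
  f1 <- .asTripletMatrix(f1); f2 <- .asTripletMatrix(f2)
  if (nrow(f1) != nrow(f2)) stop("f1 and f2 must have matching rows")
  b <- rowSums(sqrt(pmax(f1, 0) * pmax(f2, 0)))
  b <- pmin(pmax(b, 0), 1)
  # snap sub-1e-12 rounding residue so coinciding distributions score 1 exactly
  b[1 - b < 1e-12] <- 1
  b
}

#' Hellinger score of two trinomial distributions
#'
#' One minus the Hellinger distance: \eqn{H = 1 - \sqrt{1 - B}} with `B`
#' the [bhattacharyya()] coefficient. Equals 1 iff the distributions
#' coincide and 0 iff their supports are disjoint (perpendicular
#' probability vectors).
#'
#' @inheritParams bhattacharyya
#' @return Numeric vector of scores in `[0, 1]`.
#' @examples
#' hellingerScore(c(1, 0, 0), c(0.7056, 0.2944, 0))  # 0.6
#' @export
hellingerScore <- function(f1, f2) {
  b <- bhattacharyya(f1, f2)
  1 - sqrt(1 - b)
}

#' Expected allele dose of a genotype distribution
#'
#' \eqn{0 f_1 + 1 f_2 + 2 f_3}: the expected count of the minor
#' (code-2) allele, in `[0, 2]`.
#'
#' @param f probability triplet or n x 3 matrix of triplets.
#' @return Numeric vector of doses.
#' @export
expectedDose <- function(f) {
  f <- .asTripletMatrix(f)
  as.numeric(f[, 2] + 2 * f[, 3])
}

#' Scaled Euclidean Norm (SEN) score of two allele doses
#'
#' \eqn{S = 1 - (m_{obs} - m_{imp})^2 / 4}, in `[0, 1]`: 1 iff the doses
#' agree, 0 iff they differ by the maximum of 2.
#'
#' @param mObs,mImp expected allele doses in `[0, 2]` (vectorised).
#' @return Numeric vector of SEN scores.
#' @examples
#' senScore(0, 0.4)  # 0.96
#' @export
senScore <- function(mObs, mImp) {
  if (any(is.na(mObs)) || any(is.na(mImp)) ||
      any(mObs < 0 | mObs > 2) || any(mImp < 0 | mImp > 2))
    stop("doses must lie in [0, 2]")
  1 - (mObs - mImp)^2 / 4
}

.posteriorAtCells <- function(posteriors, cells) {
  p <- posteriors@probs
  n <- nrow(cells)
  out <- matrix(NA_real_, n, 3)
  for (k in 1:3) out[, k] <- p[cbind(cells[, 1], cells[, 2], k)]
  out
}

#' Score imputed posteriors against masked truth, cell by cell
#'
#' For every masked cell the true-genotype distribution (from the stored
#' hard call and `epsilon`) is compared with the imputed posterior:
#' Hellinger score, SEN score (via expected doses), the best-guess
#' genotype (argmax of the posterior, ties broken toward the smaller
#' code) and its concordance with the truth.
#'
#' @param cells integer matrix of (sample, snp) indices, e.g.
#'   [overlapUnits()] of a mask plan.
#' @param truth integer vector of true genotype calls aligned to `cells`;
#'   cells with `NA` truth are dropped with a warning.
#' @param posteriors a [PosteriorSet-class] covering every truth cell.
#' @param epsilon genotyping error probability for the true distribution
#'   (default 0: masked high-quality genotypes are taken as exact).
#' @return A cell-level [ScoreTable-class].
#' @export
scoreCells <- function(cells, truth, posteriors, epsilon = 0) {
  stopifnot(is(posteriors, "PosteriorSet"))
  cells <- as.matrix(cells)
  if (nrow(cells) != length(truth))
    stop("truth must align with cells")
  keep <- !is.na(truth)
  if (!all(keep)) {
    warning(sum(!keep), " cell(s) with missing truth dropped from scoring")
    cells <- cells[keep, , drop = FALSE]
    truth <- truth[keep]
  }
  if (!nrow(cells)) stop("no scorable cells")
  post <- .posteriorAtCells(posteriors, cells)
  bad <- which(is.na(post[, 1]))
  if (length(bad))
    stop("no posterior emitted for ", length(bad), " truth cell(s), e.g. (",
         paste(cells[bad[1], ], collapse = ", "), ")")
  post <- .asTripletMatrix(post, what = "posterior triplet")
  f1 <- t(vapply(truth, trueGenotypeDistribution, numeric(3),
                 epsilon = epsilon))
  hell <- hellingerScore(f1, post)
  sen <- senScore(expectedDose(f1), expectedDose(post))
  # argmax of the posterior; ties broken toward the smaller genotype code
  best <- max.col(post, ties.method = "first") - 1L
  df <- data.frame(
    sample = posteriors@samples[cells[, 1]],
    snp_id = posteriors@snpIds[cells[, 2]],
    sample_index = cells[, 1], snp_index = cells[, 2],
    true_g = truth, hellinger = hell, sen = sen,
    best_guess = best, concordant = best == truth,
    stringsAsFactors = FALSE)
  ScoreTable(df, level = "cell")
}

#' MaCH-style rsq imputation certainty measure
#'
#' The ratio of the empirically observed variance of the imputed allele
#' dosage (population variance, divided by n) to the dosage variance
#' expected under Hardy-Weinberg equilibrium. The default denominator is
#' `2p(1-p)` — the dosage variance at allele frequency `p`, under which
#' confident HWE-consistent hard calls score 1; `denom = "pq"` uses the
#' binomial variance `p(1-p)` instead. `p` is estimated as half the mean
#' dose unless supplied. A monomorphic estimate (`p` = 0 or 1) returns 0
#' by convention; the value tends to 0 as imputation certainty vanishes.
#'
#' @param doses numeric vector (length >= 2) of per-sample expected doses.
#' @param p optional allele frequency in (0, 1); estimated from `doses`
#'   when `NULL`.
#' @param denom `"hwe2pq"` (default, `2p(1-p)`) or `"pq"`.
#' @return A single rsq value (>= 0).
#' @export
machRsq <- function(doses, p = NULL, denom = c("hwe2pq", "pq")) {
  denom <- match.arg(denom)
  if (length(doses) < 2) stop("machRsq requires at least 2 doses")
  if (anyNA(doses)) stop("doses must be complete")
  if (!is.null(p) && (p <= 0 || p >= 1))
    stop("supplied allele frequency must lie in (0, 1)")
  if (is.null(p)) p <- mean(doses) / 2
  if (p <= 0 || p >= 1) return(0)
  vEmp <- mean((doses - mean(doses))^2)
  vExp <- if (denom == "hwe2pq") 2 * p * (1 - p) else p * (1 - p)
  vEmp / vExp
}

#' IMPUTE-style info imputation certainty measure
#'
#' The standard IMPUTE2 information measure for one SNP: with per-sample
#' posterior dose moments \eqn{e_i = p_{i2} + 2 p_{i3}} and
#' \eqn{f_i = p_{i2} + 4 p_{i3}} and estimated allele frequency
#' \eqn{\hat\theta = \sum_i e_i / (2N)},
#' \deqn{\mathrm{info} = 1 - \frac{\sum_i (f_i - e_i^2)}
#'   {2N\,\hat\theta(1-\hat\theta)}.}
#' Hard-call posteriors give 1; posteriors equal to the HWE triplet give
#' 0; a monomorphic \eqn{\hat\theta} returns 1 by convention. Raw values
#' below 0 are reported as computed unless `clamp = TRUE`.
#'
#' @param posteriors n x 3 matrix of posterior triplets at one SNP (or a
#'   single triplet).
#' @param clamp clamp negative values to 0 for parity with common tooling.
#' @return A single info value (<= 1).
#' @export
imputeInfo <- function(posteriors, clamp = FALSE) {
  p <- .asTripletMatrix(posteriors, what = "posterior triplet")
  if (!nrow(p)) stop("imputeInfo requires at least one posterior")
  n <- nrow(p)
  e <- p[, 2] + 2 * p[, 3]
  f <- p[, 2] + 4 * p[, 3]
  theta <- sum(e) / (2 * n)
  if (theta <= 0 || theta >= 1) return(1)
  info <- 1 - sum(f - e^2) / (2 * n * theta * (1 - theta))
  if (clamp) info <- max(0, info)
  info
}

#' Aggregate cell scores per SNP or analysis-wide
#'
#' Arithmetic means of the Hellinger and SEN scores over the scored cells
#' of each SNP (or over all cells when `bySnp = FALSE`), with the cell
#' count recorded. When the posteriors are supplied, the SNP-wise
#' [machRsq()] and [imputeInfo()] certainty measures are computed from the
#' posterior triplets of the scored cells; otherwise they are `NA`.
#'
#' @param cellScores a cell-level [ScoreTable-class] from [scoreCells()].
#' @param posteriors optional [PosteriorSet-class] for rsq/info.
#' @param bySnp aggregate per SNP (`TRUE`) or analysis-wide (`FALSE`).
#' @return A SNP-level [ScoreTable-class] (or a single-row table with
#'   `snp_id = "(all)"`).
#' @export
aggregateScores <- function(cellScores, posteriors = NULL, bySnp = TRUE) {
  stopifnot(is(cellScores, "ScoreTable"), scoreLevel(cellScores) == "cell")
  df <- cellScores@table
  if (!nrow(df)) stop("no cells to aggregate")
  groups <- if (bySnp) split(seq_len(nrow(df)), df$snp_id) else
    list("(all)" = seq_len(nrow(df)))
  rows <- lapply(names(groups), function(id) {
    idx <- groups[[id]]
    rsq <- info <- NA_real_
    if (!is.null(posteriors) && length(idx) >= 1) {
      cells <- cbind(df$sample_index[idx], df$snp_index[idx])
      post <- .posteriorAtCells(posteriors, cells)
      if (!anyNA(post)) {
        info <- imputeInfo(post)
        rsq <- if (length(idx) >= 2) machRsq(expectedDose(post)) else NA_real_
      }
    }
    data.frame(snp_id = id,
               mean_hellinger = mean(df$hellinger[idx]),
               mean_sen = mean(df$sen[idx]),
               rsq = rsq, info = info, n_cells = length(idx),
               stringsAsFactors = FALSE)
  })
  ScoreTable(do.call(rbind, rows), level = "snp")
}

#' Dichotomise scores at a well-imputed cutoff
#'
#' Flags each scored unit as well imputed when its value of the chosen
#' measure is at least the cutoff (inclusive), and reports the flagged
#' percentage — the "percentage of masked genotypes imputed with a score
#' above the cutoff" statistic. Conventional cutoffs: 0.6 (Hellinger),
#' 0.95 (SEN), 0.3 (rsq and info).
#'
#' @param scores a [ScoreTable-class] (cell level for `hellinger`/`sen`,
#'   SNP level for any measure) or a plain numeric vector.
#' @param measure one of `"hellinger"`, `"sen"`, `"rsq"`, `"info"`
#'   (ignored for a numeric vector).
#' @param cutoff inclusive threshold.
#' @return List with `flags` (logical vector) and `pct` (percentage of
#'   `TRUE` flags, 0-100).
#' @examples
#' dichotomize(c(0.59, 0.60, 0.61), cutoff = 0.6)$pct  # 66.7
#' @export
dichotomize <- function(scores, measure = c("hellinger", "sen", "rsq", "info"),
                        cutoff) {
  if (is.numeric(scores)) {
    vals <- scores
  } else {
    stopifnot(is(scores, "ScoreTable"))
    measure <- match.arg(measure)
    df <- scores@table
    col <- if (scoreLevel(scores) == "snp" && measure %in% c("hellinger", "sen"))
      paste0("mean_", measure) else measure
    if (!col %in% names(df))
      stop("measure '", measure, "' not present in this score table")
    vals <- df[[col]]
  }
  if (anyNA(vals)) {
    warning(sum(is.na(vals)), " unit(s) with missing score excluded")
    vals <- vals[!is.na(vals)]
  }
  flags <- vals >= cutoff
  list(flags = flags, pct = 100 * mean(flags))
}
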