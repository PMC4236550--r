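#' McNemar test on paired well-imputed flags
#'
#' Paired test of marginal homogeneity on the discordant pairs of two
#' aligned boolean vectors (e.g. well-imputed flags of two filter
#' scenarios over the same overlap units). The continuity-corrected
#' variant uses \eqn{\chi^2 = (|b - c| - 1)^2 / (b + c)} with one degree
#' of freedom; the exact variant doubles the smaller binomial(b + c, 1/2)
#' tail, capped at 1. `variant = "auto"` selects the exact test when
#' b + c < 25. With no discordant pairs the p-value is 1 and a warning
#' flag is set.
#'
#' @param flagsA,flagsB logical vectors of equal length, aligned to the
#'   same evaluation units.
#' @param variant `"auto"`, `"cc"` (continuity-corrected chi-square) or
#'   `"exact"`.
#' @return List with `statistic` (chi-square, `NA` for exact), `p.value`,
#'   discordant counts `b` (B-only) and `c` (A-only), `method`, and
#'   `degenerate` (`TRUE` when there were no discordant pairs).
#' @examples
#' a <- rep(c(TRUE, FALSE, FALSE, TRUE), c(60, 20, 15, 5))
#' b <- rep(c(TRUE, FALSE, TRUE, FALSE), c(60, 20, 15, 5))
#' mcnemarTest(a, b, variant = "cc")  # 15 vs 5 discordant: chi-square 4.05
#' @export
mcnemarTest <- function(flagsA, flagsB, variant = c("auto", "cc", "exact")) {
  variant <- match.arg(variant)
  if (length(flagsA) != length(flagsB))
    stop("flagsA and flagsB must be aligned (equal length)")
  if (anyNA(flagsA) || anyNA(flagsB)) stop("flags must be complete")
  b <- sum(!flagsA & flagsB)
  cc <- sum(flagsA & !flagsB)
  n <- b + cc
  if (variant == "auto") variant <- if (n < 25) "exact" else "cc"
  if (n == 0) {
    warning("no discordant pairs; p = 1")
    return(list(statistic = NA_real_, p.value = 1, b = b, c = cc,
                method = paste0("mcnemar_", variant), degenerate = TRUE))
  }
  if (variant == "cc") {
    stat <- (abs(b - cc) - 1)^2 / n
    p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  } else {
    stat <- NA_real_
    p <- min(1, 2 * stats::pbinom(min(b, cc), n, 0.5))
  }
  list(statistic = stat, p.value = p, b = b, c = cc,
       method = paste0("mcnemar_", variant), degenerate = FALSE)
}

#' Bonferroni-Holm step-down adjustment
#'
#' Sorts the raw p-values ascending, multiplies the i-th by
#' `n - i + 1`, enforces monotonicity along the sorted order, caps at 1
#' and restores the original order. The family size `n` may exceed the
#' number of p-values supplied (tests planned but not all carried out).
#'
#' @param p numeric vector of raw p-values in `[0, 1]`.
#' @param n adjustment family size, at least `length(p)`.
#' @return Adjusted p-values in the original order.
#' @examples
#' holmAdjust(c(0.01, 0.04))  # 0.02, 0.04
#' @export
holmAdjust <- function(p, n = length(p)) {
  if (!length(p)) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  if (n < length(p)) stop("family size n must be at least length(p)")
  o <- order(p)
  mult <- n - seq_along(p) + 1
  adj <- pmin(1, cummax(p[o] * mult))
  adj[order(o)]
}

#' Bonferroni adjustment
#'
#' `min(1, n * p)` elementwise, with family size `n`.
#'
#' @inheritParams holmAdjust
#' @return Adjusted p-values.
#' @export
bonferroniAdjust <- function(p, n = length(p)) {
  if (!length(p)) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  if (n < length(p)) stop("family size n must be at least length(p)")
  pmin(1, n * p)
}

#' Compare scenarios against the best one on paired flags
#'
#' For one masking level: computes the well-imputed percentage of each
#' scenario, designates the scenario with the maximum percentage as best,
#' tests every other scenario against it with a paired [mcnemarTest()] on
#' the shared evaluation units, and adjusts the p-values over the stated
#' family size. A scenario is "equally well suitable" when its adjusted
#' p-value is >= alpha (not significantly inferior to the best).
#'
#' @param flagsByScenario named list of logical vectors, all aligned to
#'   the same overlap units.
#' @param familySize adjustment family size N (default: number of
#'   scenarios).
#' @param adjust `"holm"` or `"bonferroni"`.
#' @param variant passed to [mcnemarTest()].
#' @param alpha significance level for the inferiority marker.
#' @return data.frame with one row per scenario: `scenario`, `pct`,
#'   `best` (logical), `b`, `c`, `statistic`, `p_raw`, `p_adj`,
#'   `inferior` (significantly inferior to best).
#' @export
compareToBest <- function(flagsByScenario, familySize = length(flagsByScenario),
                          adjust = c("holm", "bonferroni"),
                          variant = "auto", alpha = 0.05) {
  adjust <- match.arg(adjust)
  if (is.null(names(flagsByScenario)) || any(!nzchar(names(flagsByScenario))))
    stop("flagsByScenario must be a named list")
  lens <- lengths(flagsByScenario)
  if (length(unique(lens)) != 1)
    stop("all flag vectors must be aligned to the same units")
  pcts <- vapply(flagsByScenario, function(f) 100 * mean(f), numeric(1))
  bestIdx <- which.max(pcts)
  others <- setdiff(seq_along(pcts), bestIdx)
  tests <- lapply(others, function(i)
    mcnemarTest(flagsByScenario[[i]], flagsByScenario[[bestIdx]],
                variant = variant))
  pRaw <- vapply(tests, `[[`, numeric(1), "p.value")
  pAdj <- if (adjust == "holm") holmAdjust(pRaw, n = familySize) else
    bonferroniAdjust(pRaw, n = familySize)
  out <- data.frame(
    scenario = names(pcts), pct = unname(pcts),
    best = seq_along(pcts) == bestIdx,
    b = NA_real_, c = NA_real_, statistic = NA_real_,
    p_raw = NA_real_, p_adj = NA_real_, inferior = FALSE,
    stringsAsFactors = FALSE)
  out$b[others] <- vapply(tests, `[[`, numeric(1), "b")
  out$c[others] <- vapply(tests, `[[`, numeric(1), "c")
  out$statistic[others] <- vapply(tests, `[[`, numeric(1), "statistic")
  out$p_raw[others] <- pRaw
  out$p_adj[others] <- pAdj
  out$inferior[others] <- pAdj < alpha & pcts[others] < pcts[bestIdx]
  out
}

#' Scenario-by-level report table of well-imputed percentages
#'
#' Builds the benchmark report layout: one row per filter scenario (with
#' its SNP count), one column group per missingness level carrying the
#' well-imputed percentage and a marker — `"+"` for the best scenario of
#' the column, `"*"` for scenarios significantly inferior to it (adjusted
#' p < alpha). Markers follow the package's own legend.
#'
#' @param flagsByLevel named list (one element per masking level, named by
#'   the level) of named lists of logical flag vectors per scenario, all
#'   aligned to the same overlap units.
#' @param snpCounts optional named vector of per-scenario SNP counts.
#' @param familySize,adjust,variant,alpha passed to [compareToBest()].
#' @return data.frame with columns `scenario`, `n_snps`, then per level
#'   `pct_<level>` (numeric) and `mark_<level>` (character).
#' @export
scenarioTable <- function(flagsByLevel, snpCounts = NULL,
                          familySize = NULL, adjust = c("holm", "bonferroni"),
                          variant = "auto", alpha = 0.05) {
  adjust <- match.arg(adjust)
  if (!length(flagsByLevel)) stop("empty results: no levels to report")
  scens <- names(flagsByLevel[[1]])
  if (is.null(scens)) stop("empty results: scenarios must be named")
  if (is.null(familySize)) familySize <- length(scens)
  out <- data.frame(scenario = scens, stringsAsFactors = FALSE)
  out$n_snps <- if (is.null(snpCounts)) NA_integer_ else
    as.integer(snpCounts[scens])
  for (lev in names(flagsByLevel)) {
    cmp <- compareToBest(flagsByLevel[[lev]], familySize = familySize,
                         adjust = adjust, variant = variant, alpha = alpha)
    cmp <- cmp[match(scens, cmp$scenario), ]
    out[[paste0("pct_", lev)]] <- cmp$pct
    mark <- ifelse(cmp$best, "+", ifelse(cmp$inferior, "*", ""))
    out[[paste0("mark_", lev)]] <- mark
  }
  out
}

#' Render a scenario table as aligned text
#'
#' @param tab a data.frame from [scenarioTable()].
#' @return Character vector of report lines.
#' @export
formatScenarioTable <- function(tab) {
  levs <- sub("^pct_", "", grep("^pct_", names(tab), value = TRUE))
  cells <- cbind(
    scenario = format(c("scenario", tab$scenario)),
    n_snps = format(c("n_snps", tab$n_snps)),
    vapply(levs, function(l) {
      format(c(paste0(l, "%"),
               paste0(sprintf("%.2f", tab[[paste0("pct_", l)]]),
                      tab[[paste0("mark_", l)]])))
    }, character(nrow(tab) + 1)))
  apply(cells, 1, paste, collapse = "  ")
}
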