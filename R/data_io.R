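#' Read a PLINK text ped/map file pair
#'
#' Parses biallelic genotypes from PLINK's text format into a
#' [GenotypeMatrix-class]. Allele pairs are converted to 0/1/2 codes
#' relative to a per-SNP major/minor assignment computed from the observed
#' allele counts (the more frequent allele is major; frequency ties are
#' broken by lexicographic allele order). Pairs containing the allele
#' symbol `"0"` are treated as missing.
#'
#' @param pedPath path to the .ped file (6 leading columns, then two
#'   allele columns per SNP).
#' @param mapPath path to the .map file (3 or 4 whitespace-separated
#'   columns: chromosome, SNP id, optional genetic distance, position).
#' @return A [GenotypeMatrix-class].
#' @examples
#' ped <- tempfile(fileext = ".ped"); map <- tempfile(fileext = ".map")
#' writeLines(c("f1 i1 0 0 0 -9 A A", "f2 i2 0 0 0 -9 A G"), ped)
#' writeLines("22 rs1 0 100", map)
#' genotypeCalls(readPlinkPed(ped, map))
#' @export
readPlinkPed <- function(pedPath, mapPath) {
  if (!file.exists(pedPath)) stop("ped file not found: ", pedPath)
  if (!file.exists(mapPath)) stop("map file not found: ", mapPath)
  mapLines <- readLines(mapPath)
  mapLines <- mapLines[nzchar(trimws(mapLines))]
  mapTok <- strsplit(trimws(mapLines), "[ \t]+")
  nc <- lengths(mapTok)
  if (length(mapTok) && !all(nc %in% c(3L, 4L)))
    stop("malformed map line ", which(!nc %in% c(3L, 4L))[1],
         ": expected 3 or 4 fields")
  snps <- data.frame(
    snp_id = vapply(mapTok, `[`, "", 2),
    chrom = vapply(mapTok, `[`, "", 1),
    position = as.integer(vapply(mapTok, function(x) x[length(x)], "")),
    stringsAsFactors = FALSE)
  nSnp <- nrow(snps)

  pedLines <- readLines(pedPath)
  pedLines <- pedLines[nzchar(trimws(pedLines))]
  nInd <- length(pedLines)
  a1 <- matrix("0", nInd, nSnp)
  a2 <- matrix("0", nInd, nSnp)
  ids <- character(nInd)
  for (i in seq_len(nInd)) {
    tok <- strsplit(trimws(pedLines[i]), "[ \t]+")[[1]]
    if (length(tok) != 6 + 2 * nSnp)
      stop("malformed ped line ", i, ": expected ", 6 + 2 * nSnp,
           " fields, found ", length(tok))
    ids[i] <- tok[2]
    if (nSnp) {
      al <- tok[-(1:6)]
      a1[i, ] <- al[seq(1, 2 * nSnp, by = 2)]
      a2[i, ] <- al[seq(2, 2 * nSnp, by = 2)]
    }
  }
  if (anyDuplicated(ids)) ids <- make.unique(ids, sep = "_")

  calls <- matrix(NA_integer_, nInd, nSnp)
  major <- character(nSnp)
  minor <- character(nSnp)
  for (j in seq_len(nSnp)) {
    half <- a1[, j] == "0" | a2[, j] == "0"
    obs <- c(a1[!half, j], a2[!half, j])
    alleles <- sort(unique(obs))
    if (length(alleles) > 2)
      stop("more than 2 alleles at SNP '", snps$snp_id[j], "': ",
           paste(alleles, collapse = ", "))
    if (length(alleles) == 0) {
      major[j] <- "N"; minor[j] <- "."
      next
    }
    counts <- table(factor(obs, levels = alleles))
    # major = more frequent; ties broken by lexicographic order (alleles sorted)
    ord <- order(-as.integer(counts), alleles)
    major[j] <- alleles[ord[1]]
    minor[j] <- if (length(alleles) == 2) alleles[ord[2]] else
      if (major[j] == "N") "." else "N"
    calls[, j] <- (a1[, j] == minor[j]) + (a2[, j] == minor[j])
    calls[half, j] <- NA_integer_
  }
  snps$allele_major <- major
  snps$allele_minor <- minor
  GenotypeMatrix(calls, snps, samples = ids)
}

#' Write a GenotypeMatrix as PLINK text ped/map
#'
#' Inverse of [readPlinkPed()]: re-reading the written pair reproduces the
#' genotype codes exactly for matrices whose major/minor labelling is
#' consistent with the observed allele counts (as produced by the readers
#' and the simulator). Missing calls are written as `"0 0"`.
#'
#' @param gm a [GenotypeMatrix-class].
#' @param pedPath,mapPath output paths.
#' @return Invisibly, `NULL`.
#' @export
writePlinkPed <- function(gm, pedPath, mapPath) {
  stopifnot(is(gm, "GenotypeMatrix"))
  snps <- gm@snps
  mapLines <- sprintf("%s\t%s\t0\t%d", snps$chrom, snps$snp_id, snps$position)
  tryCatch(writeLines(mapLines, mapPath),
           error = function(e) stop("cannot write map file: ", conditionMessage(e)))
  cl <- gm@calls
  pairFor <- function(g, j) {
    M <- snps$allele_major[j]; m <- snps$allele_minor[j]
    out <- rep("0 0", length(g))
    out[!is.na(g) & g == 0L] <- paste(M, M)
    out[!is.na(g) & g == 1L] <- paste(M, m)
    out[!is.na(g) & g == 2L] <- paste(m, m)
    out
  }
  geno <- vapply(seq_len(ncol(cl)), function(j) pairFor(cl[, j], j),
                 character(nrow(cl)))
  if (nrow(cl) == 1) geno <- matrix(geno, nrow = 1)
  lead <- sprintf("%s %s 0 0 0 -9", gm@samples, gm@samples)
  body <- if (ncol(cl)) apply(geno, 1, paste, collapse = " ") else
    character(nrow(cl))
  lines <- if (ncol(cl)) paste(lead, body) else lead
  tryCatch(writeLines(lines, pedPath),
           error = function(e) stop("cannot write ped file: ", conditionMessage(e)))
  invisible(NULL)
}

#' Read IMPUTE2 .gen posterior probabilities
#'
#' Each data row carries five leading fields (chromosome/chunk id, SNP id,
#' position, first allele, second allele) followed by three probabilities
#' per sample, in genotype order (0, 1, 2) relative to the file's allele
#' pair mapped onto major/minor. Triplets whose stored sum deviates from 1
#' by at most 0.02 (three-decimal rounding in real files) are silently
#' renormalised; larger deviations are a format error.
#'
#' @param genPath path to the .gen file.
#' @param samples character vector of sample identifiers, in file column
#'   order.
#' @return A [PosteriorSet-class].
#' @export
readImpute2Gen <- function(genPath, samples) {
  if (!file.exists(genPath)) stop("gen file not found: ", genPath)
  lines <- readLines(genPath)
  lines <- lines[nzchar(trimws(lines))]
  nSamp <- length(samples)
  nSnp <- length(lines)
  probs <- array(NA_real_, c(nSamp, nSnp, 3))
  snpIds <- character(nSnp)
  for (r in seq_len(nSnp)) {
    tok <- strsplit(trimws(lines[r]), "[ \t]+")[[1]]
    if (length(tok) != 5 + 3 * nSamp)
      stop("gen row ", r, ": expected ", 5 + 3 * nSamp, " fields, found ",
           length(tok))
    snpIds[r] <- tok[2]
    p <- suppressWarnings(as.numeric(tok[-(1:5)]))
    if (anyNA(p)) stop("gen row ", r, ": non-numeric probability field")
    p <- matrix(p, ncol = 3, byrow = TRUE)
    s <- rowSums(p)
    if (any(abs(s - 1) > 0.02))
      stop("gen row ", r, ": probability triplet sum deviates from 1 by more than 0.02")
    probs[, r, ] <- p / s
  }
  PosteriorSet(probs, samples = samples, snpIds = snpIds)
}

#' Read a MaCH-style two-probability posterior file
#'
#' Reads the package's documented MaCH-style dialect: one line per
#' individual consisting of a sample identifier followed by two stored
#' probabilities per SNP (for genotype codes 0 and 1); the third
#' probability is implied as `1 - p0 - p1`. Implied values in
#' `[-1e-6, 0)` are clamped to 0 (rounding noise); anything below that is a
#' format error.
#'
#' @param path path to the posterior file.
#' @param snpIds SNP identifiers, in file column order.
#' @return A [PosteriorSet-class].
#' @export
readMachPosteriors <- function(path, snpIds) {
  if (!file.exists(path)) stop("posterior file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  nSnp <- length(snpIds)
  nSamp <- length(lines)
  probs <- array(NA_real_, c(nSamp, nSnp, 3))
  ids <- character(nSamp)
  for (i in seq_len(nSamp)) {
    tok <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (length(tok) != 1 + 2 * nSnp)
      stop("posterior line ", i, ": expected ", 1 + 2 * nSnp,
           " fields, found ", length(tok))
    ids[i] <- tok[1]
    p <- suppressWarnings(as.numeric(tok[-1]))
    if (anyNA(p)) stop("posterior line ", i, ": non-numeric probability")
    p0 <- p[seq(1, 2 * nSnp, by = 2)]
    p1 <- p[seq(2, 2 * nSnp, by = 2)]
    p2 <- 1 - p0 - p1
    if (any(p2 < -1e-6))
      stop("posterior line ", i, ": stored probabilities sum to more than 1")
    p2[p2 < 0] <- 0
    probs[i, , ] <- cbind(p0, p1, p2)
  }
  PosteriorSet(probs, samples = ids, snpIds = snpIds)
}

#' Import genotypes from a VCF with GT fields
#'
#' Optional import path for biallelic VCF records with hard GT calls,
#' backed by the vcfR package. Genotype codes are folded so that code 2
#' counts the rarer (minor) allele.
#'
#' @param vcfPath path to an (uncompressed or gzipped) VCF.
#' @return A [GenotypeMatrix-class].
#' @export
readVcfGenotypes <- function(vcfPath) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("readVcfGenotypes requires the 'vcfR' package")
  v <- vcfR::read.vcfR(vcfPath, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  fix <- matrix(fix, ncol = ncol(vcfR::getFIX(v)),
                dimnames = list(NULL, colnames(vcfR::getFIX(v))))
  alt <- fix[, "ALT"]
  if (any(grepl(",", alt)))
    stop("multi-allelic VCF records are not supported")
  gt <- vcfR::extract.gt(v, element = "GT")
  nAlt <- matrix(NA_integer_, nrow = ncol(gt), ncol = nrow(gt))
  for (j in seq_len(nrow(gt))) {
    g <- gt[j, ]
    al <- strsplit(gsub("\\|", "/", g), "/")
    nAlt[, j] <- vapply(al, function(a) {
      if (length(a) != 2 || any(a == ".") || anyNA(a)) return(NA_integer_)
      sum(as.integer(a))
    }, integer(1))
  }
  ref <- fix[, "REF"]
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <-
    paste0(fix[, "CHROM"], ":", fix[, "POS"])[is.na(ids) | ids == "."]
  calls <- nAlt
  major <- ref; minor <- alt
  for (j in seq_len(ncol(calls))) {
    f <- mean(calls[, j], na.rm = TRUE) / 2
    if (!is.nan(f) && (f > 0.5 ||
        (f == 0.5 && alt[j] < ref[j]))) {  # fold; tie -> lexicographic major
      calls[, j] <- 2L - calls[, j]
      major[j] <- alt[j]; minor[j] <- ref[j]
    }
  }
  snps <- data.frame(snp_id = ids, chrom = fix[, "CHROM"],
                     position = as.integer(fix[, "POS"]),
                     allele_major = major, allele_minor = minor,
                     stringsAsFactors = FALSE)
  GenotypeMatrix(calls, snps, samples = colnames(gt))
}

#' Write a score table as TSV
#'
#' Tab-separated output with a header row; floating point values are
#' rendered with 6 significant digits.
#'
#' @param table a [ScoreTable-class] or plain data.frame.
#' @param path output path.
#' @return Invisibly, `NULL`.
#' @export
writeScoreTable <- function(table, path) {
  df <- if (is(table, "ScoreTable")) table@table else as.data.frame(table)
  out <- df
  for (nm in names(out)) {
    if (is.double(out[[nm]])) out[[nm]] <- signif(out[[nm]], 6)
  }
  tryCatch(
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE),
    error = function(e) stop("cannot write score table: ", conditionMessage(e)))
  invisible(NULL)
}

#' Read a TSV score table written by [writeScoreTable()]
#'
#' @param path input path.
#' @param level `"cell"` or `"snp"`.
#' @return A [ScoreTable-class].
#' @export
readScoreTable <- function(path, level = c("cell", "snp")) {
  level <- match.arg(level)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  ScoreTable(df, level = level)
}
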