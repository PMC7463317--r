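#' Read a Genepop genotype file
#'
#' Parses the classic Genepop dialect: a title line, one locus name per line
#' (or a single comma-separated line), \code{POP} separators, and individual
#' lines of the form \code{"id , g1 g2 ..."} where each genotype is a pair of
#' concatenated 2- or 3-digit allele codes. All-zero allele codes denote a
#' missing allele; a call with any missing allele is treated as missing.
#' Allele codes are mapped to the first/second allele by ascending numeric
#' code; loci showing more than two distinct non-zero codes are rejected.
#'
#' @param path path to a Genepop text file.
#' @return a \code{\link{SnpGenotypes}} object whose collection boundaries
#'   match the POP blocks. Collections are labelled by the first individual
#'   id in each block when ids look like site codes, otherwise POP1, POP2...
#' @export
readGenepop <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\\s+$", "", lines)
  if (length(lines) < 2L)
    stop("Genepop parse error at line 1: file too short for a header")
  # title line is lines[1]; locus names until first POP
  popIdx <- grep("^\\s*pop\\s*$", lines, ignore.case = TRUE)
  if (!length(popIdx) || popIdx[1] < 3L)
    stop("Genepop parse error: no POP separator after the locus-name header")
  locusLines <- lines[2:(popIdx[1] - 1L)]
  loci <- unlist(strsplit(paste(locusLines, collapse = ","), ","))
  loci <- trimws(loci)
  loci <- loci[nzchar(loci)]
  if (!length(loci))
    stop("Genepop parse error at line 2: no locus names found")
  L <- length(loci)

  ids <- character(0); coll <- character(0)
  a1 <- list(); a2 <- list()   # per-individual allele code vectors
  popNo <- 0L
  for (k in seq_along(popIdx)) {
    popNo <- popNo + 1L
    from <- popIdx[k] + 1L
    to <- if (k < length(popIdx)) popIdx[k + 1L] - 1L else length(lines)
    if (to < from) next
    for (ln in from:to) {
      txt <- lines[ln]
      if (!nzchar(trimws(txt))) next
      parts <- strsplit(txt, ",")[[1]]
      if (length(parts) < 2L)
        stop(sprintf("Genepop parse error at line %d: expected 'id , genotypes'", ln))
      id <- trimws(parts[1])
      gts <- strsplit(trimws(paste(parts[-1], collapse = " ")), "\\s+")[[1]]
      gts <- gts[nzchar(gts)]
      if (length(gts) != L)
        stop(sprintf(
          "Genepop parse error at line %d: individual '%s' has %d genotypes, expected %d",
          ln, id, length(gts), L))
      w <- nchar(gts)
      if (any(w != w[1]) || !(w[1] %in% c(4L, 6L)))
        stop(sprintf("Genepop parse error at line %d: genotype codes must be 4 or 6 digits", ln))
      half <- w[1] / 2L
      ids <- c(ids, id)
      coll <- c(coll, paste0("POP", popNo))
      a1[[length(a1) + 1L]] <- as.integer(substr(gts, 1L, half))
      a2[[length(a2) + 1L]] <- as.integer(substr(gts, half + 1L, w[1]))
    }
  }
  n <- length(ids)
  A1 <- do.call(rbind, a1); A2 <- do.call(rbind, a2)
  if (is.null(A1)) { A1 <- matrix(integer(0), 0, L); A2 <- A1 }

  calls <- matrix(NA_integer_, n, L, dimnames = list(make.unique(ids), loci))
  alle1 <- character(L); alle2 <- character(L)
  for (l in seq_len(L)) {
    x1 <- A1[, l]; x2 <- A2[, l]
    codes <- sort(unique(c(x1[x1 > 0L], x2[x2 > 0L])))
    if (length(codes) > 2L)
      stop(sprintf("biallelic violation at locus '%s': %d distinct allele codes (%s)",
                   loci[l], length(codes), paste(codes, collapse = ", ")))
    if (length(codes) == 0L) codes <- c(1L, 2L)
    if (length(codes) == 1L) codes <- c(codes, NA_integer_)
    second <- codes[2]
    ok <- x1 > 0L & x2 > 0L
    dos <- (x1 == second) + (x2 == second)
    dos[!ok] <- NA_integer_
    calls[, l] <- as.integer(dos)
    alle1[l] <- as.character(codes[1]); alle2[l] <- as.character(second)
  }
  lociDf <- data.frame(locus_id = loci, allele1 = alle1, allele2 = alle2,
                       stringsAsFactors = FALSE)
  SnpGenotypes(calls, collection = coll, loci = lociDf)
}

#' Write a Genepop genotype file
#'
#' Emits 3-digit allele codes (first allele \code{001}, second \code{002},
#' missing \code{000000}) with one POP block per collection in input order.
#' The emitted file re-reads (via \code{\link{readGenepop}}) to an identical
#' calls matrix.
#'
#' @param gm a \code{\link{SnpGenotypes}} object.
#' @param path output file path.
#' @param title optional title line.
#' @return invisibly, \code{path}.
#' @export
writeGenepop <- function(gm, path, title = "panelpop genotype export") {
  stopifnot(is(gm, "SnpGenotypes"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(title, con)
  writeLines(lociNames(gm), con)
  calls <- genotypeCalls(gm)
  code <- c("001001", "001002", "002002")
  for (pop in levels(collections(gm))) {
    writeLines("POP", con)
    idx <- which(collections(gm) == pop)
    for (i in idx) {
      g <- calls[i, ]
      s <- ifelse(is.na(g), "000000", code[g + 1L])
      writeLines(paste0(rownames(calls)[i], " ,  ", paste(s, collapse = " ")), con)
    }
  }
  invisible(path)
}

#' Read/write a delimited genotype table
#'
#' The table format is one row per individual with columns \code{id},
#' \code{collection}, then one column per locus holding \code{0}, \code{1},
#' \code{2} or \code{NA}. The round trip through
#' \code{writeGenotypeTable} / \code{readGenotypeTable} is lossless.
#'
#' @param path file path.
#' @param sep field separator (default tab).
#' @return \code{readGenotypeTable}: a \code{\link{SnpGenotypes}} object.
#' @export
readGenotypeTable <- function(path, sep = "\t") {
  df <- read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                   check.names = FALSE)
  if (!all(c("id", "collection") %in% names(df)[1:2]))
    stop("genotype table must start with 'id' and 'collection' columns")
  lociCols <- names(df)[-(1:2)]
  calls <- as.matrix(df[, lociCols, drop = FALSE])
  bad <- calls[!is.na(calls)]
  if (length(bad) && !all(bad %in% c(0, 1, 2))) {
    culprit <- unique(bad[!bad %in% c(0, 1, 2)])
    stop("invalid genotype cell value(s): ", paste(head(culprit, 5), collapse = ", "))
  }
  storage.mode(calls) <- "integer"
  rownames(calls) <- make.unique(as.character(df$id))
  SnpGenotypes(calls, collection = df$collection)
}

#' @rdname readGenotypeTable
#' @param gm a \code{\link{SnpGenotypes}} object.
#' @export
writeGenotypeTable <- function(gm, path, sep = "\t") {
  stopifnot(is(gm, "SnpGenotypes"))
  df <- data.frame(id = individualNames(gm),
                   collection = as.character(collections(gm)),
                   genotypeCalls(gm), check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read collection (sampling-site) metadata
#'
#' Delimited file with at least a \code{code} column; typical columns are
#' \code{region}, \code{year}, \code{month}, \code{site}, \code{latitude},
#' \code{longitude}, \code{ripe}.
#'
#' @param path file path.
#' @param sep field separator.
#' @return a data.frame, validated for unique codes and coordinate ranges.
#' @export
readCollectionMetadata <- function(path, sep = "\t") {
  df <- read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE)
  if (!"code" %in% names(df)) stop("metadata must have a 'code' column")
  if (anyDuplicated(df$code)) stop("collection codes must be unique")
  if ("latitude" %in% names(df) && any(abs(df$latitude) > 90, na.rm = TRUE))
    stop("latitude out of [-90, 90]")
  if ("longitude" %in% names(df) && any(abs(df$longitude) > 180, na.rm = TRUE))
    stop("longitude out of [-180, 180]")
  df
}

#' Per-individual and per-locus missingness summary
#'
#' @param gm a \code{\link{SnpGenotypes}} object.
#' @return a list with \code{perIndividual} and \code{perLocus} missing-call
#'   fractions and \code{fractionBelow10pct}, the share of individuals with
#'   strictly less than 10\% missing calls.
#' @export
missingnessSummary <- function(gm) {
  calls <- genotypeCalls(gm)
  perInd <- rowMeans(is.na(calls))
  perLoc <- colMeans(is.na(calls))
  list(perIndividual = perInd, perLocus = perLoc,
       fractionBelow10pct = if (length(perInd)) mean(perInd < 0.10) else NA_real_)
}

#' Purge individuals by missing-genotype fraction
#'
#' Removes individuals whose missing-call fraction strictly exceeds
#' \code{maxMissingFraction} (the default 0.30 removes ">30\% missing";
#' an individual at exactly the threshold is retained). Idempotent and
#' order-preserving.
#'
#' @param gm a \code{\link{SnpGenotypes}} object.
#' @param maxMissingFraction maximum tolerated missing fraction in [0, 1].
#' @return the filtered \code{SnpGenotypes}; the per-individual missingness
#'   of the input is attached as attribute \code{"missingness"}.
#' @export
filterIndividualsByMissingness <- function(gm, maxMissingFraction = 0.30) {
  stopifnot(maxMissingFraction >= 0, maxMissingFraction <= 1)
  miss <- rowMeans(is.na(genotypeCalls(gm)))
  keep <- miss <= maxMissingFraction
  out <- gm[keep, ]
  attr(out, "missingness") <- miss
  out
}

#' Filter candidate RAD loci for an assayable single-SNP panel
#'
#' Retains candidates carrying exactly one diallelic SNP, positioned within
#' \code{positionRange} (inclusive) of the trimmed read, with a minor-allele
#' count of at least \code{minMinorCount} over the discovery haplotypes
#' (two per discovery individual).
#'
#' @param candidates a list; each element a list with \code{locus_id},
#'   \code{snp_positions} (integer vector of SNP offsets within the read),
#'   \code{flank_length}, and \code{discovery_genotypes} (dosage vector over
#'   the discovery individuals for the single SNP, when present).
#' @param positionRange inclusive position bounds, default \code{c(41, 95)}.
#' @param minMinorCount minimum minor-allele count, default 2.
#' @return the retained sub-list. Candidates lacking discovery genotypes are
#'   skipped with a warning.
#' @export
selectAssayableSnps <- function(candidates, positionRange = c(41L, 95L),
                                minMinorCount = 2L) {
  keep <- logical(length(candidates))
  for (i in seq_along(candidates)) {
    cand <- candidates[[i]]
    if (length(cand$snp_positions) != 1L) next
    pos <- cand$snp_positions[1]
    if (!is.null(cand$flank_length) && pos > cand$flank_length) next
    if (pos < positionRange[1] || pos > positionRange[2]) next
    if (is.null(cand$discovery_genotypes)) {
      warning("candidate '", cand$locus_id,
              "' lacks discovery genotypes; skipped")
      next
    }
    g <- cand$discovery_genotypes[!is.na(cand$discovery_genotypes)]
    nHap <- 2L * length(g)
    mac <- min(sum(g), nHap - sum(g))
    if (mac >= minMinorCount) keep[i] <- TRUE
  }
  candidates[keep]
}

#' Per-group allele frequencies of the second allele
#'
#' @param gm a \code{\link{SnpGenotypes}} object.
#' @param grouping factor over individuals (default: collection membership);
#'   \code{NA} entries exclude an individual.
#' @return a list of matrices (groups x loci): \code{freq}, the frequency of
#'   the second allele (dosage sum / (2 x non-missing count), \code{NA} where
#'   a group has no non-missing calls), and \code{n}, the number of
#'   non-missing gene copies.
#' @export
alleleFrequencies <- function(gm, grouping = collections(gm)) {
  grouping <- as.factor(grouping)
  if (length(grouping) != nIndividuals(gm))
    stop("grouping must have one entry per individual")
  grouping <- droplevels(grouping)
  if (any(table(grouping) == 0L) || nlevels(grouping) == 0L)
    stop("empty group in grouping")
  calls <- genotypeCalls(gm)
  groups <- levels(grouping)
  L <- ncol(calls)
  freq <- matrix(NA_real_, length(groups), L, dimnames = list(groups, colnames(calls)))
  ncop <- matrix(0L, length(groups), L, dimnames = dimnames(freq))
  for (g in seq_along(groups)) {
    sub <- calls[which(grouping == groups[g]), , drop = FALSE]
    nn <- colSums(!is.na(sub))
    ds <- colSums(sub, na.rm = TRUE)
    f <- ifelse(nn > 0L, ds / (2 * nn), NA_real_)
    freq[g, ] <- f
    ncop[g, ] <- as.integer(2L * nn)
  }
  list(freq = freq, n = ncop)
}
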