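#' @useDynLib panelpop, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @importFrom stats sd var quantile rbinom rbeta runif rnorm rgamma lm coef
#'   pchisq p.adjust setNames complete.cases prcomp predict median cor
#' @importFrom utils combn read.table write.table head
NULL

#' SnpGenotypes: a panel of biallelic SNP genotypes
#'
#' Central container for a biallelic SNP genotype panel: an individuals x
#' loci matrix of allele-dosage calls (0 = homozygous first allele,
#' 1 = heterozygous, 2 = homozygous second allele, \code{NA} = missing),
#' a collection (sampling-site) membership factor, per-locus metadata and
#' optional per-collection metadata (region, coordinates, sampling time).
#'
#' @slot calls integer matrix, individuals in rows (rownames = individual
#'   identifiers), loci in columns (colnames = locus identifiers); values in
#'   \{0, 1, 2, NA\}.
#' @slot collection factor of length \code{nrow(calls)} giving each
#'   individual's collection code.
#' @slot loci data.frame with one row per locus; always carries
#'   \code{locus_id}, \code{allele1}, \code{allele2} and a
#'   \code{monomorphic} flag, optionally \code{flank_length},
#'   \code{snp_position} and discovery minor-allele counts.
#' @slot collectionData data.frame of per-collection metadata keyed by
#'   \code{code} (may have zero rows); typical columns are \code{region},
#'   \code{latitude}, \code{longitude}, \code{year}, \code{month},
#'   \code{ripe}.
#'
#' @seealso \code{\link{SnpGenotypes}} (constructor),
#'   \code{\link{readGenepop}}, \code{\link{generateDataset}}
#' @name SnpGenotypes-class
#' @rdname SnpGenotypes-class
#' @exportClass SnpGenotypes
setClass("SnpGenotypes",
  representation(
    calls = "matrix",
    collection = "factor",
    loci = "data.frame",
    collectionData = "data.frame"
  )
)

setValidity("SnpGenotypes", function(object) {
  msgs <- character(0)
  cl <- object@calls
  if (!is.numeric(cl) && !is.integer(cl))
    msgs <- c(msgs, "calls must be a numeric/integer matrix")
  bad <- cl[!is.na(cl)]
  if (length(bad) && !all(bad %in% c(0L, 1L, 2L)))
    msgs <- c(msgs, "genotype calls must be 0, 1, 2 or NA")
  if (length(object@collection) != nrow(cl))
    msgs <- c(msgs, "collection factor length must equal number of individuals")
  if (nrow(object@loci) != ncol(cl))
    msgs <- c(msgs, "loci metadata rows must equal number of loci")
  if (anyNA(object@collection))
    msgs <- c(msgs, "every individual must belong to exactly one collection")
  cd <- object@collectionData
  if (nrow(cd)) {
    if (!"code" %in% names(cd))
      msgs <- c(msgs, "collectionData must have a 'code' column")
    else if (anyDuplicated(cd$code))
      msgs <- c(msgs, "collection codes must be unique within a dataset")
    if ("latitude" %in% names(cd) &&
        any(!is.na(cd$latitude) & abs(cd$latitude) > 90))
      msgs <- c(msgs, "latitude must lie in [-90, 90]")
    if ("longitude" %in% names(cd) &&
        any(!is.na(cd$longitude) & abs(cd$longitude) > 180))
      msgs <- c(msgs, "longitude must lie in [-180, 180]")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a SnpGenotypes object
#'
#' @param calls integer matrix of dosage calls (individuals x loci) with
#'   values in \{0, 1, 2, NA\}; rownames are individual ids (generated when
#'   absent), colnames are locus ids.
#' @param collection character or factor of collection codes, one per
#'   individual.
#' @param loci optional per-locus metadata data.frame; a minimal one is
#'   built when omitted.
#' @param collectionData optional per-collection metadata data.frame with a
#'   \code{code} column.
#' @return a validated \code{SnpGenotypes} object.
#' @examples
#' gm <- SnpGenotypes(matrix(c(0L, 1L, 2L, NA), 2, 2,
#'                           dimnames = list(c("a", "b"), c("L1", "L2"))),
#'                    collection = c("P1", "P1"))
#' nIndividuals(gm)
#' @export
SnpGenotypes <- function(calls, collection, loci = NULL, collectionData = NULL) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (is.null(rownames(calls)) && nrow(calls) > 0)
    rownames(calls) <- paste0("ind", seq_len(nrow(calls)))
  if (is.null(colnames(calls)) && ncol(calls) > 0)
    colnames(calls) <- paste0("L", seq_len(ncol(calls)))
  if (!is.factor(collection))
    collection <- factor(collection, levels = unique(as.character(collection)))
  collection <- droplevels(collection)
  if (is.null(loci)) {
    loci <- data.frame(
      locus_id = colnames(calls),
      allele1 = "A", allele2 = "C",
      stringsAsFactors = FALSE
    )
  }
  if (!"monomorphic" %in% names(loci)) {
    loci$monomorphic <- apply(calls, 2, function(g) {
      g <- g[!is.na(g)]
      length(g) == 0L || all(g == g[1L] & g != 1L)
    })
  }
  if (is.null(collectionData))
    collectionData <- data.frame(code = levels(collection),
                                 stringsAsFactors = FALSE)
  new("SnpGenotypes", calls = calls, collection = collection,
      loci = loci, collectionData = collectionData)
}

#' @describeIn SnpGenotypes-class number of individuals
#' @param x,object a \code{SnpGenotypes} object
#' @export
nIndividuals <- function(x) nrow(x@calls)

#' @describeIn SnpGenotypes-class number of loci
#' @export
nLoci <- function(x) ncol(x@calls)

#' @describeIn SnpGenotypes-class dosage-call matrix (individuals x loci)
#' @export
genotypeCalls <- function(x) x@calls

#' @describeIn SnpGenotypes-class collection membership factor
#' @export
collections <- function(x) x@collection

#' @describeIn SnpGenotypes-class per-locus metadata data.frame
#' @export
lociInfo <- function(x) x@loci

#' @describeIn SnpGenotypes-class per-collection metadata data.frame
#' @export
collectionInfo <- function(x) x@collectionData

#' @describeIn SnpGenotypes-class locus identifiers
#' @export
lociNames <- function(x) colnames(x@calls)

#' @describeIn SnpGenotypes-class individual identifiers
#' @export
individualNames <- function(x) rownames(x@calls)

setMethod("show", "SnpGenotypes", function(object) {
  cl <- object@calls
  miss <- if (length(cl)) mean(is.na(cl)) else 0
  cat("SnpGenotypes:", nrow(cl), "individuals x", ncol(cl), "loci in",
      nlevels(object@collection), "collections\n")
  cat(sprintf("  missing calls: %.2f%%; monomorphic loci: %d\n",
              100 * miss, sum(object@loci$monomorphic)))
  invisible(object)
})

#' Subset a SnpGenotypes object
#'
#' \code{x[i, j]} keeps individuals \code{i} and loci \code{j}; collection
#' and locus metadata follow the subset, and collection levels with no
#' remaining individuals are dropped.
#'
#' @param x a \code{SnpGenotypes} object
#' @param i,j individual and locus indices (integer, logical or character)
#' @param ... ignored
#' @param drop ignored (kept for generic compatibility)
#' @export
setMethod("[", "SnpGenotypes", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x@calls))
  if (missing(j)) j <- seq_len(ncol(x@calls))
  if (is.character(j)) j <- match(j, colnames(x@calls))
  calls <- x@calls[i, j, drop = FALSE]
  coll <- droplevels(x@collection[i])
  loci <- x@loci[j, , drop = FALSE]
  cd <- x@collectionData
  if (nrow(cd) && "code" %in% names(cd))
    cd <- cd[cd$code %in% levels(coll), , drop = FALSE]
  new("SnpGenotypes", calls = calls, collection = coll,
      loci = loci, collectionData = cd)
})

# internal: dosage matrix restricted to one collection
.collCalls <- function(x, collection) {
  stopifnot(collection %in% levels(x@collection))
  x@calls[x@collection == collection, , drop = FALSE]
}
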