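#' Simulate in-silico F1 hybrids between two parental pools
#'
#' Parental allele frequencies are estimated from randomly selected subsets
#' of the two pools; each hybrid then receives, independently at each
#' locus, one gamete drawn from pool A's frequencies and one from pool B's
#' (the HYBRIDLAB gamete rule). Loci entirely missing in a pool yield
#' missing hybrid calls at that locus.
#'
#' @param gm a \code{\link{SnpGenotypes}} object holding both pools.
#' @param poolA,poolB index vectors or collection codes defining the
#'   (disjoint) parental pools.
#' @param nPerPool individuals drawn from each pool to estimate parental
#'   frequencies (default 150, capped at pool size).
#' @param nHybrids number of simulated F1 individuals (default 150).
#' @param seed RNG seed.
#' @return a list: \code{hybrids} (a \code{\link{SnpGenotypes}} with one
#'   collection "F1"), \code{parentalFreqA}, \code{parentalFreqB},
#'   \code{selectedA}, \code{selectedB} (row indices used).
#' @export
simulateF1Hybrids <- function(gm, poolA, poolB, nPerPool = 150,
                              nHybrids = 150, seed = 1L) {
  idx <- .resolveGroups(gm, poolA, poolB)
  if (!length(idx$a) || !length(idx$b)) stop("empty parental pool")
  set.seed(seed)
  nA <- min(nPerPool, length(idx$a)); nB <- min(nPerPool, length(idx$b))
  selA <- sample(idx$a, nA); selB <- sample(idx$b, nB)
  calls <- genotypeCalls(gm)
  fr <- function(sel) {
    sub <- calls[sel, , drop = FALSE]
    nn <- colSums(!is.na(sub))
    ifelse(nn > 0, colSums(sub, na.rm = TRUE) / (2 * nn), NA_real_)
  }
  fA <- fr(selA); fB <- fr(selB)
  L <- nLoci(gm)
  H <- matrix(NA_integer_, nHybrids, L,
              dimnames = list(sprintf("F1_%03d", seq_len(nHybrids)),
                              lociNames(gm)))
  ok <- !is.na(fA) & !is.na(fB)
  for (i in seq_len(nHybrids))
    H[i, ok] <- rbinom(sum(ok), 1, fA[ok]) + rbinom(sum(ok), 1, fB[ok])
  list(hybrids = SnpGenotypes(H, collection = rep("F1", nHybrids),
                              loci = lociInfo(gm)),
       parentalFreqA = fA, parentalFreqB = fB,
       selectedA = selA, selectedB = selB)
}

#' Classify individuals as admixed or pure by credible-interval overlap
#'
#' An individual is "admixed" if its 90\% credible intervals for ancestry
#' in the two focal clusters overlap; otherwise it is pure toward the
#' cluster with the higher posterior-mean q. Widening both intervals can
#' only move individuals toward "admixed", never away.
#'
#' @param run an \code{"admixtureRun"} (from
#'   \code{\link{runAdmixtureMcmc}}) containing credible intervals.
#' @param focal integer pair of cluster indices.
#' @param individuals optional subset (indices or names).
#' @return a list: \code{status} per individual ("admixed", "pure-A",
#'   "pure-B"), \code{overlap} logical, \code{fractionAdmixed}, and
#'   \code{byGroup} (fraction admixed per collection when labels exist).
#' @export
classifyByCiOverlap <- function(run, focal = c(1L, 2L), individuals = NULL) {
  stopifnot(length(focal) == 2)
  if (focal[1] == focal[2]) stop("focal clusters must differ")
  Q <- run$Q; lo <- run$Qlower; hi <- run$Qupper
  if (is.null(individuals)) individuals <- seq_len(nrow(Q))
  if (is.character(individuals)) individuals <- match(individuals, rownames(Q))
  a <- focal[1]; b <- focal[2]
  ov <- hi[individuals, a] >= lo[individuals, b] &
        hi[individuals, b] >= lo[individuals, a]
  status <- ifelse(ov, "admixed",
                   ifelse(Q[individuals, a] > Q[individuals, b],
                          "pure-A", "pure-B"))
  out <- list(status = status, overlap = ov, fractionAdmixed = mean(ov))
  if (!is.null(run$collection)) {
    grp <- droplevels(as.factor(run$collection[individuals]))
    out$byGroup <- tapply(ov, grp, mean)
  }
  out
}

#' Baseline assignment of individuals (leave-one-out)
#'
#' Probability of each query individual's multilocus genotype under each
#' baseline group, from the baseline's posterior-predictive allele
#' frequencies with a symmetric Dirichlet prior (lambda per allele,
#' default 1/2 for biallelic data; the Rannala-Mountain convention).
#' Genotype probabilities use the sequential-sampling (compound
#' Dirichlet-multinomial) form, so a homozygote a/a contributes
#' (x_a + lambda)(x_a + 1 + lambda) / ((N + 2 lambda)(N + 1 + 2 lambda))
#' and a heterozygote twice the analogous cross-product, with x the
#' baseline allele count and N the baseline total at the locus. When a
#' query belongs to a baseline its own two alleles are removed from that
#' baseline's counts first (leave-one-out). Log-probabilities are summed
#' over typed loci and normalised across baselines.
#'
#' @param gm a \code{\link{SnpGenotypes}} holding the baselines (and the
#'   queries, if internal).
#' @param baselines named list of index vectors, or a factor over
#'   individuals (NA = not in any baseline); collection codes also work.
#' @param queries index vector (or names) of individuals to assign.
#' @param lambda Dirichlet prior mass per allele.
#' @return a list of class \code{"assignmentResult"}: \code{probabilities}
#'   (queries x baselines, rows sum to 1), \code{topGroup},
#'   \code{leaveOneOut} (logical per query).
#' @export
assignIndividuals <- function(gm, baselines, queries, lambda = 0.5) {
  calls <- genotypeCalls(gm)
  coll <- collections(gm)
  if (is.factor(baselines) || is.character(baselines) &&
      all(baselines %in% levels(coll))) {
    if (is.character(baselines)) {
      bl <- lapply(baselines, function(cc) which(coll == cc))
      names(bl) <- baselines
    } else {
      bl <- lapply(levels(droplevels(baselines)), function(g)
        which(baselines == g))
      names(bl) <- levels(droplevels(baselines))
    }
    baselines <- bl
  }
  if (length(baselines) < 2L) stop("need at least two baselines")
  if (is.character(queries)) queries <- match(queries, rownames(calls))
  L <- ncol(calls)
  # per-baseline allele-2 counts and totals per locus
  x2 <- matrix(vapply(baselines, function(ix)
    colSums(calls[ix, , drop = FALSE], na.rm = TRUE), numeric(L)), nrow = L)
  nTot <- matrix(vapply(baselines, function(ix)
    2 * colSums(!is.na(calls[ix, , drop = FALSE])), numeric(L)), nrow = L)
  B <- length(baselines)
  logp <- matrix(0, length(queries), B,
                 dimnames = list(rownames(calls)[queries], names(baselines)))
  loo <- logical(length(queries))
  twoLam <- 2 * lambda
  for (qi in seq_along(queries)) {
    q <- queries[qi]
    g <- calls[q, ]
    typed <- !is.na(g)
    for (b in seq_len(B)) {
      xb <- x2[, b]; nb <- nTot[, b]
      if (q %in% baselines[[b]]) {
        xb <- xb - ifelse(typed, g, 0)
        nb <- nb - ifelse(typed, 2, 0)
        loo[qi] <- TRUE
      }
      x1 <- nb - xb
      lp <- numeric(L)
      hom2 <- typed & g == 2L; hom1 <- typed & g == 0L; het <- typed & g == 1L
      lp[hom2] <- log(xb[hom2] + lambda) + log(xb[hom2] + 1 + lambda)
      lp[hom1] <- log(x1[hom1] + lambda) + log(x1[hom1] + 1 + lambda)
      lp[het] <- log(2) + log(xb[het] + lambda) + log(x1[het] + lambda)
      denom <- numeric(L)
      denom[typed] <- log(nb[typed] + twoLam) + log(nb[typed] + 1 + twoLam)
      logp[qi, b] <- sum(lp[typed] - denom[typed])
    }
    if (!any(typed)) warning("query ", rownames(calls)[q],
                             " has no typed loci; uniform assignment")
  }
  pr <- exp(logp - apply(logp, 1, max))
  pr <- pr / rowSums(pr)
  structure(list(probabilities = pr,
                 topGroup = colnames(pr)[max.col(pr, ties.method = "first")],
                 leaveOneOut = loo),
            class = "assignmentResult")
}
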