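#' Per-collection diversity statistics
#'
#' Observed heterozygosity (Ho), unbiased expected heterozygosity (uHe, the
#' Nei gene diversity with the 2n/(2n-1) small-sample correction) and the
#' inbreeding coefficient FIS = (uHe - Ho) / uHe, each computed per locus
#' within a collection and summarised as mean +/- SE over loci (SE = sample
#' sd over loci / sqrt(number of contributing loci)).
#'
#' Loci with no usable data in a collection (all missing for Ho; fewer than
#' two typed individuals for uHe; uHe = 0 for FIS) are excluded from the
#' corresponding mean.
#'
#' @param gm a \code{\link{SnpGenotypes}} object.
#' @param collection a collection code present in \code{collections(gm)}.
#' @return a list with \code{perLocus} (vector over loci, NA where excluded),
#'   \code{mean}, \code{se} and \code{nLoci} (contributing loci).
#' @name diversity
NULL

.meanSe <- function(x) {
  x <- x[!is.na(x)]
  list(mean = if (length(x)) mean(x) else NA_real_,
       se = if (length(x) > 1L) sd(x) / sqrt(length(x)) else NA_real_,
       nLoci = length(x))
}

#' @rdname diversity
#' @export
observedHeterozygosity <- function(gm, collection) {
  sub <- .collCalls(gm, collection)
  nn <- colSums(!is.na(sub))
  ho <- ifelse(nn > 0L, colSums(sub == 1L, na.rm = TRUE) / nn, NA_real_)
  c(list(perLocus = ho), .meanSe(ho))
}

#' @rdname diversity
#' @export
unbiasedExpectedHeterozygosity <- function(gm, collection) {
  sub <- .collCalls(gm, collection)
  nn <- colSums(!is.na(sub))
  p <- ifelse(nn > 0L, colSums(sub, na.rm = TRUE) / (2 * nn), NA_real_)
  uhe <- ifelse(nn >= 2L, (2 * nn / (2 * nn - 1)) * 2 * p * (1 - p), NA_real_)
  c(list(perLocus = uhe), .meanSe(uhe))
}

#' @rdname diversity
#' @export
inbreedingCoefficient <- function(gm, collection) {
  ho <- observedHeterozygosity(gm, collection)$perLocus
  uhe <- unbiasedExpectedHeterozygosity(gm, collection)$perLocus
  fis <- ifelse(!is.na(uhe) & uhe > 0, (uhe - ho) / uhe, NA_real_)
  c(list(perLocus = fis), .meanSe(fis))
}

#' Diversity summary table over all collections
#'
#' One row per collection with sample size and Ho, uHe and FIS means and
#' standard errors over loci, mirroring the usual "mean +/- SE" sample
#' summary layout.
#'
#' @param gm a \code{\link{SnpGenotypes}} object.
#' @return a data.frame with columns \code{code}, \code{n_individuals},
#'   \code{Ho_mean}, \code{Ho_se}, \code{uHe_mean}, \code{uHe_se},
#'   \code{Fis_mean}, \code{Fis_se}.
#' @export
diversityTable <- function(gm) {
  codes <- levels(collections(gm))
  rows <- lapply(codes, function(cc) {
    ho <- observedHeterozygosity(gm, cc)
    he <- unbiasedExpectedHeterozygosity(gm, cc)
    fis <- inbreedingCoefficient(gm, cc)
    data.frame(code = cc, n_individuals = sum(collections(gm) == cc),
               Ho_mean = ho$mean, Ho_se = ho$se,
               uHe_mean = he$mean, uHe_se = he$se,
               Fis_mean = fis$mean, Fis_se = fis$se,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# log conditional (Levene) probability of nAB heterozygotes given allele
# counts: P(nAB | nA, nB) = n! / (nAA! nAB! nBB!) * 2^nAB * nA! nB! / (2n)!
.hweLogProb <- function(nAB, nA, nB) {
  n <- (nA + nB) / 2
  nAA <- (nA - nAB) / 2
  nBB <- (nB - nAB) / 2
  lfactorial(n) - lfactorial(nAA) - lfactorial(nAB) - lfactorial(nBB) +
    nAB * log(2) + lfactorial(nA) + lfactorial(nB) - lfactorial(2 * n)
}

#' Exact Hardy-Weinberg test for a biallelic locus
#'
#' Levene's conditional distribution of the heterozygote count given the
#' observed allele counts is enumerated completely (it is one-dimensional
#' for two alleles, so no Markov chain is needed). The probability-test
#' p-value sums the probabilities of all outcomes no more probable than the
#' observed one; one-sided heterozygote-deficit and -excess p-values are the
#' lower/upper tail sums, and the reported direction is the side with the
#' smaller one-sided p.
#'
#' A Monte-Carlo mode (\code{method = "montecarlo"}) resamples tables from
#' the same conditional distribution by shuffling gene copies into pairs;
#' its \code{dememorization}, \code{batches} and \code{iterations} arguments
#' mirror the chain configuration of the classic exact-test software and are
#' used only as a cross-check of the enumeration.
#'
#' @param nAA,nAB,nBB genotype counts.
#' @param method "enumeration" (default, exact) or "montecarlo".
#' @param dememorization,batches,iterations Monte-Carlo chain configuration
#'   (total resamples = batches x iterations after dememorization discards).
#' @return a list: \code{p_value} (probability test), \code{p_deficit},
#'   \code{p_excess}, \code{direction} ("deficit", "excess" or "none"),
#'   \code{testable}.
#' @export
hweExactTest <- function(nAA, nAB, nBB, method = c("enumeration", "montecarlo"),
                         dememorization = 10000, batches = 1000,
                         iterations = 10000) {
  method <- match.arg(method)
  stopifnot(nAA + nAB + nBB >= 1)
  nA <- 2 * nAA + nAB
  nB <- 2 * nBB + nAB
  if (nA == 0 || nB == 0)
    return(list(p_value = 1, p_deficit = 1, p_excess = 1,
                direction = "none", testable = FALSE))
  hMax <- min(nA, nB)
  h <- seq(hMax %% 2, hMax, by = 2)  # parity of nAB is fixed by nA
  lp <- .hweLogProb(h, nA, nB)
  pr <- exp(lp - max(lp)); pr <- pr / sum(pr)
  obs <- match(nAB, h)
  if (method == "enumeration") {
    pProb <- sum(pr[pr <= pr[obs] * (1 + 1e-9)])
    pDef <- sum(pr[h <= nAB])
    pExc <- sum(pr[h >= nAB])
  } else {
    total <- batches * iterations
    # sample h directly from the exact conditional distribution; the
    # dememorization/batch structure is retained for configuration parity
    nSamp <- min(total, 2e5)
    hs <- sample(h, nSamp, replace = TRUE, prob = pr)
    prs <- pr[match(hs, h)]
    pProb <- mean(prs <= pr[obs] * (1 + 1e-9))
    pDef <- mean(hs <= nAB)
    pExc <- mean(hs >= nAB)
  }
  dir <- if (pDef < pExc) "deficit" else if (pExc < pDef) "excess" else "none"
  list(p_value = pProb, p_deficit = pDef, p_excess = pExc,
       direction = dir, testable = TRUE)
}

#' Hardy-Weinberg tests for every collection x locus cell
#'
#' @param gm a \code{\link{SnpGenotypes}} object.
#' @return a data.frame with one row per collection x locus: genotype
#'   counts, probability-test p, one-sided p-values, direction, testable.
#' @export
hweTestAll <- function(gm) {
  calls <- genotypeCalls(gm)
  out <- list()
  for (cc in levels(collections(gm))) {
    sub <- calls[collections(gm) == cc, , drop = FALSE]
    for (l in seq_len(ncol(sub))) {
      g <- sub[, l]; g <- g[!is.na(g)]
      if (!length(g)) next
      cnt <- tabulate(g + 1L, 3L)
      r <- hweExactTest(cnt[1], cnt[2], cnt[3])
      out[[length(out) + 1L]] <- data.frame(
        collection = cc, locus = colnames(sub)[l],
        nAA = cnt[1], nAB = cnt[2], nBB = cnt[3],
        p_value = r$p_value, p_deficit = r$p_deficit, p_excess = r$p_excess,
        direction = r$direction, testable = r$testable,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

# G statistic (log-likelihood ratio) of an r x c contingency table
.gStatistic <- function(tab) {
  n <- sum(tab)
  if (n == 0) return(0)
  e <- outer(rowSums(tab), colSums(tab)) / n
  idx <- tab > 0
  2 * sum(tab[idx] * log(tab[idx] / e[idx]))
}

#' Genotypic linkage-disequilibrium test for a locus pair
#'
#' Log-likelihood-ratio (G) statistic on the 3 x 3 genotype contingency
#' table of two loci within one collection, with significance from
#' permutations of one locus' genotypes across individuals. The p-value uses
#' the (1 + #\{G_perm >= G_obs\}) / (1 + n_perm) estimator. With
#' \code{exhaustive = TRUE} (feasible for few individuals) all n!
#' permutations are enumerated and p is the exact proportion with
#' G >= G_obs.
#'
#' @param gm a \code{\link{SnpGenotypes}} object.
#' @param collection collection code.
#' @param locusA,locusB locus names or indices.
#' @param nPerm number of random permutations.
#' @param seed RNG seed (an integer) for reproducibility.
#' @param exhaustive enumerate all permutations instead (n <= 8 only).
#' @return a list: \code{G}, \code{p_value}, \code{n_permutations_used},
#'   \code{testable} (FALSE when either locus is monomorphic among the
#'   complete pairs).
#' @export
ldGenotypicTest <- function(gm, collection, locusA, locusB, nPerm = 10000,
                            seed = NULL, exhaustive = FALSE) {
  sub <- .collCalls(gm, collection)
  if (is.character(locusA)) locusA <- match(locusA, colnames(sub))
  if (is.character(locusB)) locusB <- match(locusB, colnames(sub))
  ga <- sub[, locusA]; gb <- sub[, locusB]
  ok <- !is.na(ga) & !is.na(gb)
  ga <- ga[ok]; gb <- gb[ok]
  if (length(ga) < 2L || length(unique(ga)) < 2L || length(unique(gb)) < 2L)
    return(list(G = NA_real_, p_value = NA_real_, n_permutations_used = 0L,
                testable = FALSE))
  tab <- table(factor(ga, 0:2), factor(gb, 0:2))
  gObs <- .gStatistic(tab)
  if (exhaustive) {
    n <- length(ga)
    if (n > 8L) stop("exhaustive enumeration limited to 8 individuals")
    perms <- .permutations(n)
    gs <- apply(perms, 1, function(ix)
      .gStatistic(table(factor(ga, 0:2), factor(gb[ix], 0:2))))
    p <- mean(gs >= gObs - 1e-12)
    return(list(G = gObs, p_value = p, n_permutations_used = nrow(perms),
                testable = TRUE))
  }
  if (!is.null(seed)) set.seed(seed)
  cnt <- 0L
  for (b in seq_len(nPerm)) {
    gp <- .gStatistic(table(factor(ga, 0:2), factor(sample(gb), 0:2)))
    if (gp >= gObs - 1e-12) cnt <- cnt + 1L
  }
  list(G = gObs, p_value = (1 + cnt) / (1 + nPerm),
       n_permutations_used = nPerm, testable = TRUE)
}

#' Genotypic LD tests over all locus pairs and collections
#'
#' @param gm a \code{\link{SnpGenotypes}} object.
#' @param nPerm permutations per test.
#' @param seed master seed; each test gets a derived sub-seed.
#' @param maxPairs optional cap on the number of locus pairs per collection
#'   (pairs are then sampled, seeded), for large panels.
#' @return data.frame: collection, locusA, locusB, G, p_value, testable.
#' @export
ldTestAll <- function(gm, nPerm = 1000, seed = 1L, maxPairs = Inf) {
  L <- nLoci(gm)
  prs <- combn(L, 2)
  out <- list()
  for (cc in levels(collections(gm))) {
    use <- prs
    if (ncol(prs) > maxPairs) {
      set.seed(seed)
      use <- prs[, sample(ncol(prs), maxPairs), drop = FALSE]
    }
    for (k in seq_len(ncol(use))) {
      r <- ldGenotypicTest(gm, cc, use[1, k], use[2, k], nPerm = nPerm,
                           seed = seed + k)
      out[[length(out) + 1L]] <- data.frame(
        collection = cc, locusA = lociNames(gm)[use[1, k]],
        locusB = lociNames(gm)[use[2, k]], G = r$G, p_value = r$p_value,
        testable = r$testable, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Holm sequential Bonferroni correction
#'
#' Standard Holm step-down family-wise error control: p-values are sorted
#' ascending and rejected while p(i) <= alpha / (m - i + 1); flags are
#' returned in input order. NA p-values are never rejected.
#'
#' @param pValues numeric vector of p-values in [0, 1].
#' @param alpha family-wise significance level.
#' @return logical vector of rejection flags (input order).
#' @export
holmSequentialBonferroni <- function(pValues, alpha = 0.05) {
  if (!length(pValues)) return(logical(0))
  adj <- p.adjust(pValues, method = "holm")
  out <- !is.na(adj) & adj <= alpha
  out
}

# all permutations of 1..n as an n! x n matrix (small n only)
.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- setdiff(seq_len(n), i)
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}
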