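# simulate per-locus (He, FST) under the symmetric island-model null:
# ancestral p ~ U(0.02, 0.98); per-group frequency ~ Balding-Nichols around
# p with drift targetFst; genotype counts multinomial Hardy-Weinberg with
# the observed group sizes. Returns data.frame(he, fst).
.fdistNull <- function(nIter, targetFst, groupSizes) {
  p <- runif(nIter, 0.02, 0.98)
  J <- length(groupSizes)
  nMat <- pMat <- hMat <- matrix(NA_real_, J, nIter)
  for (j in seq_len(J)) {
    f <- .bnDraw(p, rep(targetFst, nIter))
    nj <- groupSizes[j]
    nAA <- rbinom(nIter, nj, (1 - f)^2)
    pr <- ifelse((1 - f)^2 < 1, 2 * f * (1 - f) / (1 - (1 - f)^2), 0)
    nAB <- rbinom(nIter, nj - nAA, pmin(pr, 1))
    nBB <- nj - nAA - nAB
    nMat[j, ] <- nj
    pMat[j, ] <- (nAB + 2 * nBB) / (2 * nj)
    hMat[j, ] <- nAB / nj
  }
  fst <- vapply(seq_len(nIter), function(l) {
    cc <- .wcComponentsLocus(nMat[, l], pMat[, l], hMat[, l])
    s <- sum(cc)
    if (is.na(s) || s == 0) NA_real_ else cc["a"] / s
  }, numeric(1))
  totN <- sum(groupSizes)
  pooled <- colSums(pMat * groupSizes) / totN
  he <- 2 * pooled * (1 - pooled)
  ok <- !is.na(fst) & he > 1e-4
  data.frame(he = he[ok], fst = fst[ok])
}

# observed per-locus (He, FST) under a grouping
.observedLocusStats <- function(gm, grouping) {
  grouping <- droplevels(as.factor(grouping))
  calls <- genotypeCalls(gm)[!is.na(grouping), , drop = FALSE]
  grouping <- droplevels(grouping[!is.na(grouping)])
  sm <- .groupSummaries(calls, grouping)
  th <- .thetaFromSummaries(sm)
  nTot <- colSums(sm$n)
  pooled <- colSums(sm$n * sm$p) / nTot
  data.frame(locus = colnames(calls), he = 2 * pooled * (1 - pooled),
             fst = th$perLocusTheta, stringsAsFactors = FALSE)
}

# bin-wise empirical envelope with isotonic (monotone in He) smoothing
.envelopeQuantiles <- function(null, obsHe, conf, nBins = 20) {
  qs <- c((1 - conf) / 2, 1 - (1 - conf) / 2)
  br <- quantile(null$he, probs = seq(0, 1, length.out = nBins + 1))
  br[1] <- -Inf; br[length(br)] <- Inf
  bin <- cut(null$he, br, labels = FALSE)
  lo <- tapply(null$fst, bin, quantile, probs = qs[1], na.rm = TRUE)
  hi <- tapply(null$fst, bin, quantile, probs = qs[2], na.rm = TRUE)
  mid <- tapply(null$he, bin, median)
  ord <- order(mid)
  loS <- stats::isoreg(mid[ord], lo[ord])$yf
  hiS <- stats::isoreg(mid[ord], hi[ord])$yf
  obsBin <- cut(obsHe, br, labels = FALSE)
  # map each observed locus to its bin's smoothed quantiles
  pos <- match(obsBin, as.integer(names(mid)[ord]))
  list(lower = loS[pos], upper = hiS[pos])
}

#' FDist-style FST outlier scan
#'
#' Simulation-envelope outlier detection in the spirit of the
#' Beaumont-Nichols FDist procedure: a neutral joint distribution of
#' (heterozygosity, FST) is simulated under a symmetric island model with a
#' "forced" target mean FST estimated from the data by iterative trimming
#' (loci outside a provisional envelope are excluded and the neutral mean
#' re-estimated; two refinement passes). The null generator draws per-group
#' allele frequencies from the Balding-Nichols distribution calibrated to
#' the target FST and samples genotypes with the observed group sizes.
#' Empirical quantiles at the configured confidence are computed in 20
#' equal-count heterozygosity bins with monotone smoothing; loci above the
#' upper quantile are flagged as candidates for directional selection,
#' below the lower quantile for balancing selection.
#'
#' @param gm a \code{\link{SnpGenotypes}} object (>= 10 loci).
#' @param grouping factor over individuals (default collections).
#' @param nIterations simulated null loci.
#' @param confidence envelope confidence (default 0.95, i.e. significance
#'   0.05 two-sided).
#' @param seed RNG seed.
#' @param refinePasses trimming passes for the target mean FST.
#' @return list of class \code{"fdistScan"}: \code{perLocus} (locus, he,
#'   fst, lower, upper, flagged_directional, flagged_balancing),
#'   \code{targetFst}, \code{settings}.
#' @export
fdistScan <- function(gm, grouping = collections(gm), nIterations = 100000,
                      confidence = 0.95, seed = 1L, refinePasses = 2L) {
  if (nLoci(gm) < 10L) stop("outlier envelope unreliable below 10 loci; refusing")
  set.seed(seed)
  obs <- .observedLocusStats(gm, grouping)
  grouping <- droplevels(as.factor(grouping))
  sizes <- as.integer(table(grouping[!is.na(grouping)]))
  keep <- rep(TRUE, nrow(obs))
  target <- NA_real_
  for (pass in seq_len(refinePasses)) {
    target <- max(mean(obs$fst[keep], na.rm = TRUE), 1e-4)
    nullSm <- .fdistNull(max(2000, nIterations %/% 10), target, sizes)
    env <- .envelopeQuantiles(nullSm, obs$he, confidence)
    keep <- !is.na(obs$fst) & obs$fst <= env$upper & obs$fst >= env$lower
    if (!any(keep)) { keep <- rep(TRUE, nrow(obs)); break }
  }
  target <- max(mean(obs$fst[keep], na.rm = TRUE), 1e-4)
  null <- .fdistNull(nIterations, target, sizes)
  env <- .envelopeQuantiles(null, obs$he, confidence)
  perLocus <- data.frame(
    locus = obs$locus, he = obs$he, fst = obs$fst,
    lower = env$lower, upper = env$upper,
    flagged_directional = !is.na(obs$fst) & obs$fst > env$upper,
    flagged_balancing = !is.na(obs$fst) & obs$fst < env$lower,
    stringsAsFactors = FALSE)
  structure(list(perLocus = perLocus, targetFst = target,
                 settings = list(n_iterations = nIterations,
                                 confidence = confidence,
                                 n_groups = length(sizes), seed = seed)),
            class = "fdistScan")
}

# beta-binomial log-likelihood matrix for the F-model:
# ll[i,j] = log BetaBinom(x_ij | N_ij, p_i * lam_ij, (1-p_i) * lam_ij)
# with lam_ij = exp(-(alpha_i + beta_j)) (so FST_ij = logistic(alpha_i+beta_j))
.fmodelLL <- function(p, alphaEff, beta, x, N) {
  lam <- exp(-outer(alphaEff, beta, "+"))
  a <- p * lam; b <- (1 - p) * lam
  lbeta(a + x, b + (N - x)) - lbeta(a, b)
}

#' Bayesian F-model outlier scan (reversible-jump MCMC)
#'
#' Hierarchical Bayesian outlier detection in the style of the
#' Beaumont-Balding / BayeScan F-model: the locus-by-population FST is
#' decomposed on the logistic scale as alpha_i (locus effect) + beta_j
#' (population effect); allele counts are beta-binomial (the
#' multinomial-Dirichlet likelihood with per-population frequencies
#' integrated out under the Balding-Nichols prior). A per-locus indicator
#' switches alpha_i on/off by reversible jump, with configurable prior odds
#' for neutrality. The posterior probability of selection at a locus is its
#' indicator's posterior inclusion frequency; loci exceeding
#' \code{posteriorThreshold} are flagged, and the log10 Bayes factor is
#' reported alongside.
#'
#' @param gm a \code{\link{SnpGenotypes}} object.
#' @param grouping factor over individuals (default collections).
#' @param sampleSize retained posterior samples.
#' @param thinning iterations between retained samples.
#' @param burnIn discarded initial iterations.
#' @param priorOdds prior odds for neutrality (P(neutral)/P(selected)).
#' @param posteriorThreshold flagging threshold on the posterior
#'   probability of selection.
#' @param seed RNG seed.
#' @return list of class \code{"bayesFModel"}: \code{perLocus} (locus,
#'   posterior_prob_selection, alpha_mean, log10_bayes_factor, q_value,
#'   flagged), \code{settings}, \code{acceptance}.
#' @export
bayesFModelScan <- function(gm, grouping = collections(gm), sampleSize = 10000,
                            thinning = 50, burnIn = 50000, priorOdds = 10,
                            posteriorThreshold = 0.99, seed = 1L) {
  grouping <- droplevels(as.factor(grouping))
  af <- alleleFrequencies(gm, grouping)
  N <- af$n                       # groups x loci gene copies
  x <- round(af$freq * N); x[is.na(x)] <- 0; N[is.na(af$freq)] <- 0
  x <- t(x); N <- t(N)            # loci x groups
  L <- nrow(x); J <- ncol(x)
  if (J < 2L) stop("need at least two groups")
  set.seed(seed)
  nIter <- burnIn + sampleSize * thinning
  pIncl <- 1 / (1 + priorOdds)
  # state
  p <- pmin(pmax(rowSums(x) / pmax(rowSums(N), 1), 0.01), 0.99)
  alpha <- rep(0, L); delta <- rep(0L, L)
  beta <- rep(-2, J)
  ll <- .fmodelLL(p, alpha * delta, beta, x, N)
  sdP <- 0.05; sdA <- 0.6; sdB <- 0.25
  acc <- c(p = 0, alpha = 0, beta = 0, jump = 0)
  keepEvery <- thinning
  sDelta <- matrix(0L, sampleSize, L); sAlpha <- matrix(0, sampleSize, L)
  kept <- 0L
  for (it in seq_len(nIter)) {
    # ancestral frequencies p_i: reflected random walk, vectorised over loci
    pProp <- p + rnorm(L, 0, sdP)
    pProp <- ifelse(pProp < 0, -pProp, pProp)
    pProp <- ifelse(pProp > 1, 2 - pProp, pProp)
    pProp <- pmin(pmax(pProp, 1e-4), 1 - 1e-4)
    llProp <- .fmodelLL(pProp, alpha * delta, beta, x, N)
    accRow <- log(runif(L)) < rowSums(llProp) - rowSums(ll)
    p[accRow] <- pProp[accRow]; ll[accRow, ] <- llProp[accRow, ]
    acc["p"] <- acc["p"] + mean(accRow)
    # locus effects alpha_i (included loci only)
    inc <- delta == 1L
    if (any(inc)) {
      aProp <- alpha
      aProp[inc] <- alpha[inc] + rnorm(sum(inc), 0, sdA)
      llProp <- .fmodelLL(p, aProp * delta, beta, x, N)
      lr <- rowSums(llProp) - rowSums(ll) +
        stats::dnorm(aProp, 0, 1, log = TRUE) - stats::dnorm(alpha, 0, 1, log = TRUE)
      accRow <- inc & (log(runif(L)) < lr)
      alpha[accRow] <- aProp[accRow]; ll[accRow, ] <- llProp[accRow, ]
      acc["alpha"] <- acc["alpha"] + mean(accRow[inc])
    }
    # population effects beta_j: sequential scan (columns interact only
    # through their own column of ll)
    bProp <- beta + rnorm(J, 0, sdB)
    for (j in seq_len(J)) {
      bTry <- beta; bTry[j] <- bProp[j]
      llj <- .fmodelLL(p, alpha * delta, bTry[j], x[, j, drop = FALSE],
                       N[, j, drop = FALSE])
      lr <- sum(llj) - sum(ll[, j]) +
        stats::dnorm(bProp[j], -1, 1.8, log = TRUE) -
        stats::dnorm(beta[j], -1, 1.8, log = TRUE)
      if (log(runif(1)) < lr) {
        beta[j] <- bProp[j]; ll[, j] <- llj
        acc["beta"] <- acc["beta"] + 1 / J
      }
    }
    # reversible jump on the inclusion indicators, proposal q(alpha) = prior
    dProp <- delta
    aNew <- ifelse(delta == 1L, 0, rnorm(L, 0, 1))
    aEffProp <- ifelse(delta == 1L, 0, aNew)
    llProp <- .fmodelLL(p, aEffProp, beta, x, N)
    lr <- rowSums(llProp) - rowSums(ll) +
      ifelse(delta == 1L, log(priorOdds), -log(priorOdds))
    accRow <- log(runif(L)) < lr
    if (any(accRow)) {
      togOn <- accRow & delta == 0L
      togOff <- accRow & delta == 1L
      delta[togOn] <- 1L; alpha[togOn] <- aNew[togOn]
      delta[togOff] <- 0L; alpha[togOff] <- 0
      ll[accRow, ] <- llProp[accRow, ]
    }
    acc["jump"] <- acc["jump"] + mean(accRow)
    if (it > burnIn && (it - burnIn) %% keepEvery == 0L) {
      kept <- kept + 1L
      sDelta[kept, ] <- delta
      sAlpha[kept, ] <- alpha * delta
    }
  }
  postProb <- colMeans(sDelta[seq_len(kept), , drop = FALSE])
  alphaMean <- colMeans(sAlpha[seq_len(kept), , drop = FALSE])
  pp <- pmin(pmax(postProb, 1 / (kept + 1)), 1 - 1 / (kept + 1))
  log10BF <- log10(pp / (1 - pp)) + log10(priorOdds)
  # q-value: mean posterior error probability among loci at least as extreme
  pep <- 1 - postProb
  ord <- order(pep)
  qv <- numeric(L)
  qv[ord] <- cumsum(pep[ord]) / seq_len(L)
  res <- data.frame(locus = lociNames(gm),
                    posterior_prob_selection = postProb,
                    alpha_mean = alphaMean, log10_bayes_factor = log10BF,
                    q_value = qv,
                    flagged = postProb > posteriorThreshold,
                    stringsAsFactors = FALSE)
  if (mean(acc["alpha"] / nIter) < 0.05 && any(delta == 1L))
    warning("low alpha acceptance rate; consider raising sampleSize")
  structure(list(perLocus = res,
                 settings = list(sample_size = sampleSize, thinning = thinning,
                                 burn_in = burnIn, prior_odds = priorOdds,
                                 threshold = posteriorThreshold, seed = seed),
                 acceptance = acc / nIter),
            class = "bayesFModel")
}

#' Two-method outlier consensus
#'
#' Retains only loci flagged by both detection procedures (the conservative
#' consensus rule used to minimise false positives).
#'
#' @param a,b character vectors of flagged locus names (or scan result
#'   objects from \code{\link{fdistScan}} / \code{\link{bayesFModelScan}},
#'   whose directional/flagged sets are extracted).
#' @param scope free-text label for the analysis scope.
#' @return list of class \code{"consensusOutliers"}: \code{methodA},
#'   \code{methodB}, \code{consensus}, \code{scope}.
#' @export
consensusOutliers <- function(a, b, scope = "all") {
  getSet <- function(z) {
    if (inherits(z, "fdistScan")) z$perLocus$locus[z$perLocus$flagged_directional]
    else if (inherits(z, "bayesFModel")) z$perLocus$locus[z$perLocus$flagged]
    else as.character(z)
  }
  sa <- getSet(a); sb <- getSet(b)
  structure(list(methodA = sa, methodB = sb,
                 consensus = intersect(sa, sb), scope = scope),
            class = "consensusOutliers")
}

#' Balanced pairwise-region outlier scans
#'
#' For every pair of regions, all individuals of each region are pooled into
#' a single sample from which equal-size random subsets are drawn (the
#' subset size is kept identical on the two sides to avoid uneven-sample
#' bias), both outlier scans are run on the two-group design, and their
#' consensus is taken.
#'
#' @param gm a \code{\link{SnpGenotypes}} object.
#' @param regions factor over individuals giving region labels.
#' @param nPerSide subset size per region (default: smallest region size).
#' @param seed RNG seed.
#' @param fdistIterations,bayesSampleSize,bayesThinning,bayesBurnIn scan
#'   configuration passed through.
#' @return list: \code{perPair} (named list of
#'   \code{\link{consensusOutliers}}), \code{union} (all consensus loci).
#' @export
pairwiseRegionScan <- function(gm, regions, nPerSide = NULL, seed = 1L,
                               fdistIterations = 20000,
                               bayesSampleSize = 1000, bayesThinning = 2,
                               bayesBurnIn = 1000) {
  regions <- droplevels(as.factor(regions))
  sizes <- table(regions)
  if (is.null(nPerSide)) nPerSide <- min(sizes)
  small <- names(sizes)[sizes < nPerSide]
  if (length(small))
    stop("region(s) too small for nPerSide = ", nPerSide, ": ",
         paste(small, collapse = ", "))
  prs <- combn(levels(regions), 2)
  out <- list()
  set.seed(seed)
  for (k in seq_len(ncol(prs))) {
    ra <- prs[1, k]; rb <- prs[2, k]
    ia <- sample(which(regions == ra), nPerSide)
    ib <- sample(which(regions == rb), nPerSide)
    sub <- gm[c(ia, ib), ]
    grp <- rep(c(ra, rb), each = nPerSide)
    fd <- fdistScan(sub, grp, nIterations = fdistIterations,
                    seed = seed + 101 * k)
    bs <- bayesFModelScan(sub, grp, sampleSize = bayesSampleSize,
                          thinning = bayesThinning, burnIn = bayesBurnIn,
                          seed = seed + 211 * k)
    out[[paste(ra, rb, sep = "-")]] <-
      consensusOutliers(fd, bs, scope = paste("regions", ra, "vs", rb))
  }
  list(perPair = out,
       union = sort(unique(unlist(lapply(out, `[[`, "consensus")))))
}
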