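#' Simulation configuration for synthetic SNP panels
#'
#' Describes a hierarchical Balding-Nichols genotype simulation: loci draw
#' an ancestral frequency, each genetic cluster drifts around it with a
#' cluster drift parameter F (Beta(p(1-F)/F, (1-p)(1-F)/F)), and each
#' collection drifts around its cluster with a small within-cluster F.
#' Designated admixture-zone collections hold a mixture of F1 hybrids
#' (between two parental clusters) and pure individuals.
#'
#' @param nClusters number of genetic clusters.
#' @param clusterFst per-cluster Balding-Nichols drift F (recycled to
#'   \code{nClusters}); pairwise FST between clusters is approximately the
#'   mean of their two F values.
#' @param withinClusterFst drift of collections around their cluster.
#' @param nCollectionsPerCluster integer vector (recycled).
#' @param nIndividualsPerCollection individuals per collection.
#' @param nLoci number of biallelic loci.
#' @param outlierLoci number of loci with elevated divergence.
#' @param outlierMultiplier factor applied to cluster F at outlier loci
#'   (capped so F stays below 0.95).
#' @param admixtureZone \code{NULL}, or a list with \code{nCollections},
#'   \code{parents} (two cluster indices), \code{fractionF1}, and
#'   \code{fractionPureA} / \code{fractionPureB} (the pure remainder is
#'   split evenly when omitted).
#' @param missingRate per-call missing probability.
#' @param ancestralFreqRange uniform sampling range for ancestral
#'   frequencies, within (0, 1).
#' @param seed integer RNG seed.
#' @return a validated config list of class \code{"simConfig"}.
#' @export
simConfig <- function(nClusters = 3, clusterFst = 0.10,
                      withinClusterFst = 0.005,
                      nCollectionsPerCluster = 2,
                      nIndividualsPerCollection = 50,
                      nLoci = 91, outlierLoci = 0, outlierMultiplier = 5,
                      admixtureZone = NULL, missingRate = 0,
                      ancestralFreqRange = c(0.05, 0.95), seed = 1L) {
  clusterFst <- rep_len(clusterFst, nClusters)
  nCollectionsPerCluster <- rep_len(as.integer(nCollectionsPerCluster), nClusters)
  stopifnot(all(clusterFst >= 0), all(clusterFst < 1),
            withinClusterFst >= 0, withinClusterFst < 1,
            missingRate >= 0, missingRate <= 1,
            outlierLoci >= 0, outlierLoci <= nLoci,
            ancestralFreqRange[1] > 0, ancestralFreqRange[2] < 1,
            ancestralFreqRange[1] <= ancestralFreqRange[2])
  if (!is.null(admixtureZone)) {
    az <- admixtureZone
    stopifnot(length(az$parents) == 2, all(az$parents %in% seq_len(nClusters)),
              az$fractionF1 >= 0, az$fractionF1 <= 1)
    if (is.null(az$fractionPureA)) az$fractionPureA <- (1 - az$fractionF1) / 2
    if (is.null(az$fractionPureB)) az$fractionPureB <-
        1 - az$fractionF1 - az$fractionPureA
    stopifnot(abs(az$fractionF1 + az$fractionPureA + az$fractionPureB - 1) < 1e-9)
    if (is.null(az$nCollections)) az$nCollections <- 1L
    admixtureZone <- az
  }
  structure(list(
    nClusters = nClusters, clusterFst = clusterFst,
    withinClusterFst = withinClusterFst,
    nCollectionsPerCluster = nCollectionsPerCluster,
    nIndividualsPerCollection = nIndividualsPerCollection,
    nLoci = nLoci, outlierLoci = outlierLoci,
    outlierMultiplier = outlierMultiplier,
    admixtureZone = admixtureZone, missingRate = missingRate,
    ancestralFreqRange = ancestralFreqRange, seed = as.integer(seed)
  ), class = "simConfig")
}

#' The "sprat-like" study preset
#'
#' Encodes the geometry the package's acceptance studies exercise: three
#' genetic clusters (fjord-like, Atlantic-like and Baltic-like; drift
#' parameters 0.05/0.12/0.25 giving between-cluster FST roughly 0.09-0.19
#' and near-zero within-cluster differentiation), 40 collections (15/14/8
#' per cluster plus 3 transition-zone collections between clusters 2 and 3
#' holding 73% F1-like admixed and 27% pure individuals), 91 biallelic loci
#' of which 9 (~10\%) carry 5x elevated cluster divergence, about 60
#' individuals per collection (~2,400 total), and a 5\% per-call missing
#' rate (which leaves about 98\% of individuals with <10\% missing calls).
#'
#' @param seed RNG seed.
#' @param nIndividualsPerCollection override for scaled runs.
#' @param nCollectionsPerCluster override (length-3 integer).
#' @return a \code{\link{simConfig}}.
#' @export
spratPreset <- function(seed = 1L, nIndividualsPerCollection = 60,
                        nCollectionsPerCluster = c(15L, 14L, 8L)) {
  simConfig(
    nClusters = 3, clusterFst = c(0.05, 0.12, 0.25),
    withinClusterFst = 0.005,
    nCollectionsPerCluster = nCollectionsPerCluster,
    nIndividualsPerCollection = nIndividualsPerCollection,
    nLoci = 91, outlierLoci = 9, outlierMultiplier = 5,
    admixtureZone = list(nCollections = 3L, parents = c(2L, 3L),
                         fractionF1 = 0.73),
    missingRate = 0.05, ancestralFreqRange = c(0.05, 0.95), seed = seed)
}

# Balding-Nichols draw: frequency around p with drift F (F = 0 copies p)
.bnDraw <- function(p, F) {
  out <- p
  pos <- F > 0
  if (any(pos)) {
    lam <- (1 - F[pos]) / F[pos]
    out[pos] <- rbeta(sum(pos), p[pos] * lam, (1 - p[pos]) * lam)
  }
  pmin(pmax(out, 1e-6), 1 - 1e-6)
}

#' Sample the allele-frequency hierarchy
#'
#' Draws ancestral, per-cluster and per-collection frequencies of the second
#' allele under the Balding-Nichols hierarchy described in
#' \code{\link{simConfig}}. Outlier loci use cluster drift
#' \code{min(F * outlierMultiplier, 0.95)}.
#'
#' @param config a \code{\link{simConfig}}.
#' @return list: \code{ancestral} (length nLoci), \code{cluster}
#'   (nClusters x nLoci), \code{collection} (collections x nLoci, with a
#'   \code{cluster} attribute mapping rows to clusters), \code{outlier}
#'   (logical per locus).
#' @export
sampleFrequencies <- function(config) {
  stopifnot(inherits(config, "simConfig"))
  set.seed(config$seed)
  L <- config$nLoci
  anc <- runif(L, config$ancestralFreqRange[1], config$ancestralFreqRange[2])
  outlier <- rep(FALSE, L)
  if (config$outlierLoci > 0)
    outlier[sample.int(L, config$outlierLoci)] <- TRUE
  K <- config$nClusters
  clF <- config$clusterFst
  clFreq <- matrix(NA_real_, K, L)
  for (k in seq_len(K))
    clFreq[k, ] <- .bnDraw(anc, rep(clF[k], L))
  # outlier loci emulate divergent local adaptation: one cluster is driven
  # toward the opposite allele-frequency extreme, with the Balding-Nichols
  # variance inflated by the configured multiplier (pure variance inflation
  # co-fixes all clusters too often to yield divergent loci)
  selCluster <- rep(NA_integer_, L)
  if (any(outlier)) {
    for (l in which(outlier)) {
      sel <- sample.int(K, 1)
      target <- if (anc[l] < 0.5) 0.9 else 0.1
      fOut <- min(clF[sel] * config$outlierMultiplier, 0.95)
      clFreq[sel, l] <- .bnDraw(target, fOut)
      selCluster[l] <- sel
    }
  }
  nColl <- config$nCollectionsPerCluster
  collFreq <- matrix(NA_real_, sum(nColl), L)
  collCluster <- integer(sum(nColl))
  r <- 0L
  for (k in seq_len(K)) for (j in seq_len(nColl[k])) {
    r <- r + 1L
    collFreq[r, ] <- .bnDraw(clFreq[k, ], rep(config$withinClusterFst, L))
    collCluster[r] <- k
  }
  attr(collFreq, "cluster") <- collCluster
  list(ancestral = anc, cluster = clFreq, collection = collFreq,
       outlier = outlier, outlierCluster = selCluster)
}

#' Generate a synthetic genotype dataset with truth tables
#'
#' Pure individuals draw both gene copies binomially from their collection's
#' allele frequencies; F1 individuals in admixture-zone collections draw one
#' copy from each parental cluster's frequencies; missing calls are masked
#' uniformly at random at \code{missingRate}. Fully reproducible given the
#' config seed.
#'
#' @param config a \code{\link{simConfig}}.
#' @return a list: \code{genotypes} (a \code{\link{SnpGenotypes}}) and
#'   \code{truth} (list with per-individual \code{cluster} (0 for hybrids),
#'   \code{class} ("pure"/"F1"), \code{q} (true ancestry, individuals x
#'   clusters), and the \code{\link{sampleFrequencies}} output).
#' @export
generateDataset <- function(config) {
  stopifnot(inherits(config, "simConfig"))
  fr <- sampleFrequencies(config)   # also sets the seed
  L <- config$nLoci
  K <- config$nClusters
  nPer <- config$nIndividualsPerCollection
  collCluster <- attr(fr$collection, "cluster")
  nStd <- nrow(fr$collection)
  az <- config$admixtureZone
  nAz <- if (is.null(az)) 0L else az$nCollections
  nColl <- nStd + nAz
  n <- nColl * nPer
  calls <- matrix(NA_integer_, n, L)
  collLab <- character(n)
  cls <- integer(n); klass <- character(n)
  qTrue <- matrix(0, n, K)
  row <- 0L
  for (cIdx in seq_len(nStd)) {
    f <- fr$collection[cIdx, ]
    for (i in seq_len(nPer)) {
      row <- row + 1L
      calls[row, ] <- rbinom(L, 2, f)
      collLab[row] <- sprintf("C%02d", cIdx)
      cls[row] <- collCluster[cIdx]; klass[row] <- "pure"
      qTrue[row, collCluster[cIdx]] <- 1
    }
  }
  if (nAz > 0L) {
    pa <- az$parents[1]; pb <- az$parents[2]
    fA <- fr$cluster[pa, ]; fB <- fr$cluster[pb, ]
    for (z in seq_len(nAz)) {
      nF1 <- round(az$fractionF1 * nPer)
      nPa <- round(az$fractionPureA * nPer)
      nPb <- nPer - nF1 - nPa
      types <- sample(rep(c("F1", "pureA", "pureB"), c(nF1, nPa, nPb)))
      for (i in seq_len(nPer)) {
        row <- row + 1L
        collLab[row] <- sprintf("AZ%d", z)
        if (types[i] == "F1") {
          calls[row, ] <- rbinom(L, 1, fA) + rbinom(L, 1, fB)
          cls[row] <- 0L; klass[row] <- "F1"
          qTrue[row, pa] <- 0.5; qTrue[row, pb] <- 0.5
        } else {
          par <- if (types[i] == "pureA") pa else pb
          calls[row, ] <- rbinom(L, 2, fr$cluster[par, ])
          cls[row] <- par; klass[row] <- "pure"
          qTrue[row, par] <- 1
        }
      }
    }
  }
  if (config$missingRate > 0) {
    mask <- runif(length(calls)) < config$missingRate
    calls[mask] <- NA_integer_
  }
  rownames(calls) <- sprintf("%s_i%03d", collLab, stats::ave(
    seq_len(n), collLab, FUN = seq_along))
  colnames(calls) <- sprintf("Ssp%03d", 200 + seq_len(L))
  gm <- SnpGenotypes(calls, collection = collLab)
  truth <- list(cluster = cls, class = klass, q = qTrue, frequencies = fr,
                outlier = fr$outlier, config = config)
  list(genotypes = gm, truth = truth)
}

#' Recovery metrics against simulation truth
#'
#' Compares estimates with generator truth: RMSE of ancestry proportions
#' after the best cluster-label permutation, bias of a realized FST
#' estimate, precision/recall of outlier flags, and a K-selection hit
#' indicator.
#'
#' @param estimates list with any of \code{q} (individuals x K),
#'   \code{fst} (scalar), \code{outlierFlags} (logical per locus),
#'   \code{chosenK} (integer).
#' @param truth list with the matching \code{q}, \code{fst},
#'   \code{outlier}, \code{K} entries.
#' @return list of computed metrics (\code{qRmse}, \code{qPermutation},
#'   \code{fstBias}, \code{precision}, \code{recall}, \code{kHit}).
#' @export
truthMetrics <- function(estimates, truth) {
  out <- list()
  if (!is.null(estimates$q)) {
    Qe <- estimates$q; Qt <- truth$q
    if (!all(dim(Qe) == dim(Qt))) stop("q dimension mismatch")
    K <- ncol(Qe)
    perms <- .permutations(K)
    best <- Inf; bestPerm <- seq_len(K)
    for (i in seq_len(nrow(perms))) {
      rmse <- sqrt(mean((Qe[, perms[i, ]] - Qt)^2))
      if (rmse < best) { best <- rmse; bestPerm <- perms[i, ] }
    }
    out$qRmse <- best; out$qPermutation <- bestPerm
  }
  if (!is.null(estimates$fst) && !is.null(truth$fst))
    out$fstBias <- estimates$fst - truth$fst
  if (!is.null(estimates$outlierFlags) && !is.null(truth$outlier)) {
    fl <- estimates$outlierFlags; tr <- truth$outlier
    if (length(fl) != length(tr)) stop("outlier flag length mismatch")
    tp <- sum(fl & tr)
    out$precision <- if (sum(fl)) tp / sum(fl) else NA_real_
    out$recall <- if (sum(tr)) tp / sum(tr) else NA_real_
  }
  if (!is.null(estimates$chosenK) && !is.null(truth$K))
    out$kHit <- estimates$chosenK == truth$K
  out
}
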