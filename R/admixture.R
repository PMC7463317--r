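#' Bayesian admixture clustering (Gibbs sampler)
#'
#' Runs the admixture model with correlated allele frequencies and no
#' location prior: each individual's genome is a mixture over K clusters
#' with proportions q (Dirichlet(alpha) prior); cluster allele frequencies
#' are Beta-distributed around a per-locus ancestral frequency with
#' per-cluster drift parameters F_k (Balding-Nichols form). Allele-copy
#' origins, q rows and cluster frequencies are Gibbs-updated; ancestral
#' frequencies, F_k and alpha move by random-walk Metropolis. The model
#' evidence estimate for K selection is
#' L = mean(lnL) - var(lnL)/2 over the retained post-burn-in sweeps, and q
#' posterior means carry equal-tailed 90\% credible intervals from thinned
#' retained sweeps.
#'
#' Chain-length defaults follow the heavy "paper" profile (1e5 burn-in,
#' 1e6 sweeps, 10 replicates); scaled-down chains for routine work are
#' available through \code{profile = "test"} in \code{\link{runPipeline}}
#' or by setting the arguments directly.
#'
#' @param gm a \code{\link{SnpGenotypes}} object.
#' @param K number of clusters (>= 1).
#' @param burnIn discarded sweeps.
#' @param length post-burn-in sweeps.
#' @param replicates independent chains.
#' @param seed master seed; replicate r uses seed + r - 1.
#' @param thin sweeps between retained q samples (credible intervals).
#' @param ciLevel credible-interval mass (default 0.90).
#' @param fPrior Beta prior shape for the drift parameters (defaults give
#'   mean 0.01).
#' @param alphaMax upper bound of the uniform prior on alpha.
#' @return list of per-replicate results, each of class
#'   \code{"admixtureRun"} with elements \code{K}, \code{Q}, \code{Qlower},
#'   \code{Qupper}, \code{P}, \code{Fk}, \code{alpha}, \code{L},
#'   \code{lnL}, \code{settings}.
#' @export
runAdmixtureMcmc <- function(gm, K, burnIn = 100000, length = 1000000,
                             replicates = 10, seed = 1L, thin = 50,
                             ciLevel = 0.90, fPrior = c(1, 99),
                             alphaMax = 10) {
  stopifnot(K >= 1)
  if (K > nIndividuals(gm)) stop("K exceeds the number of individuals")
  G <- genotypeCalls(gm)
  out <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    set.seed(seed + r - 1L)
    raw <- admixture_gibbs_cpp(G, as.integer(K), as.integer(burnIn),
                               as.integer(length), as.integer(thin),
                               1.0, 0.01, 0.025, 0.2, 0.02,
                               fPrior[1], fPrior[2], alphaMax)
    if (any(!is.finite(raw$lnL)))
      stop("non-finite likelihood encountered; aborting (K=", K,
           ", replicate ", r, ")")
    n <- nrow(G)
    kept <- raw$nKept
    qs <- array(raw$qSamples[seq_len(kept * n * K)], dim = c(K, n, kept))
    Q <- apply(qs, c(2, 1), mean)
    aL <- (1 - ciLevel) / 2
    Qlo <- apply(qs, c(2, 1), quantile, probs = aL, names = FALSE)
    Qhi <- apply(qs, c(2, 1), quantile, probs = 1 - aL, names = FALSE)
    rownames(Q) <- rownames(Qlo) <- rownames(Qhi) <- rownames(G)
    lnL <- raw$lnL
    out[[r]] <- structure(list(
      K = K, Q = Q, Qlower = Qlo, Qupper = Qhi,
      P = raw$pMean, Fk = colMeans(raw$fSamples[seq_len(kept), , drop = FALSE]),
      alpha = mean(raw$alphaSamples[seq_len(kept)]),
      L = mean(lnL) - var(lnL) / 2, lnL = lnL,
      collection = collections(gm),
      settings = list(burn_in = burnIn, length = length, thin = thin,
                      ci_level = ciLevel, seed = seed + r - 1L)),
      class = "admixtureRun")
  }
  out
}

# G' similarity between two Q matrices (higher = more similar)
.gPrimeSimilarity <- function(Qa, Qb) {
  1 - norm(Qa - Qb, type = "F") / sqrt(2 * nrow(Qa))
}

#' Align replicate admixture runs (label switching)
#'
#' Cluster labels are arbitrary per run; alignment finds per-run label
#' permutations maximising the average pairwise G' similarity
#' (normalised Frobenius agreement between permuted Q matrices). When the
#' joint permutation space is small the search is exhaustive (run 1 fixed);
#' otherwise runs are aligned sequentially to the running mean and refined
#' iteratively until stable (the greedy fallback also covers K > 8). The
#' consensus Q is the mean of the aligned runs.
#'
#' @param runs list of \code{"admixtureRun"} objects (or plain Q matrices)
#'   sharing K and individuals.
#' @param maxJoint exhaustive-search budget on the joint permutation count.
#' @return list: \code{consensusQ}, \code{permutations} (list per run),
#'   \code{alignedQ}, \code{meanSimilarity}.
#' @export
alignRuns <- function(runs, maxJoint = 20000) {
  Qs <- lapply(runs, function(r) if (is.list(r)) r$Q else r)
  K <- ncol(Qs[[1]])
  if (!all(vapply(Qs, ncol, 1L) == K) ||
      !all(vapply(Qs, nrow, 1L) == nrow(Qs[[1]])))
    stop("all runs must share K and individuals")
  R <- length(Qs)
  if (R == 1L)
    return(list(consensusQ = Qs[[1]], permutations = list(seq_len(K)),
                alignedQ = Qs, meanSimilarity = 1))
  perms <- .permutations(K)
  nP <- nrow(perms)
  exhaustive <- K <= 8 && nP^(R - 1) <= maxJoint
  if (exhaustive) {
    grid <- as.matrix(expand.grid(rep(list(seq_len(nP)), R - 1L)))
    best <- -Inf; bestAssign <- rep(1L, R - 1L)
    for (g in seq_len(nrow(grid))) {
      aligned <- c(Qs[1], lapply(seq_len(R - 1L), function(j)
        Qs[[j + 1L]][, perms[grid[g, j], ], drop = FALSE]))
      sim <- 0; cnt <- 0
      for (i in seq_len(R - 1L)) for (j in (i + 1L):R) {
        sim <- sim + .gPrimeSimilarity(aligned[[i]], aligned[[j]]); cnt <- cnt + 1
      }
      sim <- sim / cnt
      if (sim > best) { best <- sim; bestAssign <- grid[g, ] }
    }
    permList <- c(list(seq_len(K)),
                  lapply(seq_len(R - 1L), function(j) perms[bestAssign[j], ]))
  } else {
    permList <- rep(list(seq_len(K)), R)
    repeat {
      changed <- FALSE
      for (r in seq_len(R)) {
        others <- setdiff(seq_len(R), r)
        ref <- Reduce(`+`, lapply(others, function(o)
          Qs[[o]][, permList[[o]], drop = FALSE])) / length(others)
        sims <- apply(perms, 1, function(pp)
          .gPrimeSimilarity(ref, Qs[[r]][, pp, drop = FALSE]))
        bestP <- which.max(sims)
        if (!identical(perms[bestP, ], permList[[r]])) {
          permList[[r]] <- perms[bestP, ]; changed <- TRUE
        }
      }
      if (!changed) break
    }
  }
  aligned <- lapply(seq_len(R), function(r)
    Qs[[r]][, permList[[r]], drop = FALSE])
  sims <- c()
  for (i in seq_len(R - 1L)) for (j in (i + 1L):R)
    sims <- c(sims, .gPrimeSimilarity(aligned[[i]], aligned[[j]]))
  list(consensusQ = Reduce(`+`, aligned) / R, permutations = permList,
       alignedQ = aligned, meanSimilarity = mean(sims))
}

#' Evanno's delta-K statistic
#'
#' Second-order rate of change of the model-evidence estimate across K,
#' normalised by its replicate standard deviation:
#' deltaK(K) = mean over replicates of |L(K+1) - 2 L(K) + L(K-1)| divided
#' by sd(L(K)) across replicates. Defined only for interior K; undefined
#' (NA) where sd(L(K)) is zero.
#'
#' @param L a replicates x K matrix of evidence estimates (columns named by
#'   K, or assumed to be 1..ncol).
#' @return list: \code{deltaK} (named vector over interior K),
#'   \code{chosenK} (argmax, NA when all undefined), \code{meanL},
#'   \code{sdL}.
#' @export
evannoDeltaK <- function(L) {
  L <- as.matrix(L)
  Ks <- as.integer(if (is.null(colnames(L))) seq_len(ncol(L)) else colnames(L))
  if (ncol(L) < 3L) stop("need at least 3 consecutive K values")
  meanL <- colMeans(L); sdL <- apply(L, 2, sd)
  dk <- rep(NA_real_, ncol(L) - 2L)
  names(dk) <- Ks[-c(1L, length(Ks))]
  for (j in 2:(ncol(L) - 1L)) {
    second <- L[, j + 1L] - 2 * L[, j] + L[, j - 1L]
    if (!is.na(sdL[j]) && sdL[j] > 0)
      dk[j - 1L] <- mean(abs(second)) / sdL[j]
  }
  chosen <- if (all(is.na(dk))) NA_integer_ else
    as.integer(names(dk)[which.max(dk)])
  list(deltaK = dk, chosenK = chosen, meanL = meanL, sdL = sdL)
}

#' Puechmaille-style cluster-number estimators
#'
#' For each replicate run, each predefined collection's mean and median
#' membership per cluster is computed; a cluster counts as "real" in a run
#' if at least one collection's statistic exceeds \code{threshold}.
#' Per-run counts based on the mean give the "Mean" family, on the median
#' the "Med" family; the median of per-run counts across runs gives the
#' "Med-" prefix and the maximum the "Max-" prefix, yielding MedMed,
#' MedMean, MaxMed and MaxMean.
#'
#' @param runs list of \code{"admixtureRun"} objects (one K), or plain Q
#'   matrices if \code{collection} is supplied.
#' @param collection factor of collection labels per individual (taken from
#'   the runs when absent).
#' @param threshold membership threshold (default 0.5).
#' @return named integer vector c(MedMed, MedMean, MaxMed, MaxMean).
#' @export
puechmailleEstimators <- function(runs, collection = NULL, threshold = 0.5) {
  if (is.null(collection)) {
    if (!is.list(runs[[1]]) || is.null(runs[[1]]$collection))
      stop("collection labels are required")
    collection <- runs[[1]]$collection
  }
  collection <- as.factor(collection)
  perRunMed <- perRunMean <- integer(length(runs))
  for (r in seq_along(runs)) {
    Q <- if (is.list(runs[[r]])) runs[[r]]$Q else runs[[r]]
    if (nrow(Q) != length(collection)) stop("collection labels are required")
    mMean <- apply(Q, 2, function(col) tapply(col, collection, mean))
    mMed <- apply(Q, 2, function(col) tapply(col, collection, median))
    mMean <- matrix(mMean, ncol = ncol(Q)); mMed <- matrix(mMed, ncol = ncol(Q))
    perRunMean[r] <- sum(apply(mMean, 2, max) > threshold)
    perRunMed[r] <- sum(apply(mMed, 2, max) > threshold)
  }
  c(MedMed = as.integer(median(perRunMed)),
    MedMean = as.integer(median(perRunMean)),
    MaxMed = max(perRunMed), MaxMean = max(perRunMean))
}

#' K-selection report over a grid of K
#'
#' Runs replicate admixture chains for each K in \code{kRange}, collects
#' the evidence estimates, computes Evanno's delta-K and the four
#' Puechmaille-style statistics, and reports the chosen K per criterion
#' (for the Puechmaille family, the chosen K is the maximum statistic value
#' over the grid — the plateau height — as the statistics count supported
#' clusters).
#'
#' @param gm a \code{\link{SnpGenotypes}} object.
#' @param kRange integer vector of K values (consecutive for delta-K).
#' @param replicates chains per K.
#' @param burnIn,length,seed,thin passed to \code{\link{runAdmixtureMcmc}}.
#' @param threshold Puechmaille membership threshold.
#' @return list of class \code{"kSelection"}: \code{evidence} (replicates x
#'   K matrix), \code{evanno}, \code{puechmaille} (4 x K matrix),
#'   \code{chosenK} (named vector), \code{runs} (list by K).
#' @export
kSelectionReport <- function(gm, kRange = 1:5, replicates = 3, burnIn = 500,
                             length = 2000, seed = 1L, thin = 10,
                             threshold = 0.5) {
  nK <- base::length(kRange)   # `length` here is the chain length
  runsByK <- list()
  ev <- matrix(NA_real_, replicates, nK, dimnames = list(NULL, kRange))
  pm <- matrix(NA_integer_, 4, nK,
               dimnames = list(c("MedMed", "MedMean", "MaxMed", "MaxMean"),
                               kRange))
  for (j in seq_along(kRange)) {
    K <- kRange[j]
    runs <- runAdmixtureMcmc(gm, K, burnIn = burnIn, length = length,
                             replicates = replicates,
                             seed = seed + 1000L * j, thin = thin)
    runsByK[[as.character(K)]] <- runs
    ev[, j] <- vapply(runs, `[[`, numeric(1), "L")
    al <- if (K > 1) alignRuns(runs) else NULL
    pm[, j] <- puechmailleEstimators(
      if (is.null(al)) runs else lapply(al$alignedQ, identity),
      collection = collections(gm), threshold = threshold)
  }
  evo <- if (nK >= 3) evannoDeltaK(ev) else NULL
  chosen <- c(deltaK = if (is.null(evo)) NA_integer_ else evo$chosenK,
              apply(pm, 1, max))
  structure(list(evidence = ev, evanno = evo, puechmaille = pm,
                 chosenK = chosen, runs = runsByK),
            class = "kSelection")
}
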