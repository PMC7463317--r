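# per-locus Weir-Cockerham variance components from per-group summaries:
# ni = individuals typed, pi = second-allele frequency, hi = observed het
# frequency, per group (rows = loci handled by the callers).
.wcComponentsLocus <- function(ni, pi, hi) {
  use <- ni > 0 & !is.na(pi)
  ni <- ni[use]; pi <- pi[use]; hi <- hi[use]
  r <- length(ni)
  if (r < 2L) return(c(a = NA_real_, b = NA_real_, c = NA_real_))
  nbar <- mean(ni)
  if (nbar <= 1) return(c(a = NA_real_, b = NA_real_, c = NA_real_))
  nc <- (sum(ni) - sum(ni^2) / sum(ni)) / (r - 1)
  if (nc <= 0) return(c(a = NA_real_, b = NA_real_, c = NA_real_))
  pbar <- sum(ni * pi) / sum(ni)
  s2 <- sum(ni * (pi - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(ni * hi) / sum(ni)
  a <- (nbar / nc) *
    (s2 - (1 / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
  c(a = a, b = b, c = hbar / 2)
}

# group summaries for a dosage matrix under a grouping factor:
# lists of (groups x loci) matrices n, p, h
.groupSummaries <- function(calls, grouping) {
  grouping <- droplevels(as.factor(grouping))
  gl <- levels(grouping)
  L <- ncol(calls)
  n <- p <- h <- matrix(NA_real_, length(gl), L)
  for (g in seq_along(gl)) {
    sub <- calls[which(grouping == gl[g]), , drop = FALSE]
    nn <- colSums(!is.na(sub))
    n[g, ] <- nn
    p[g, ] <- ifelse(nn > 0, colSums(sub, na.rm = TRUE) / (2 * nn), NA_real_)
    h[g, ] <- ifelse(nn > 0, colSums(sub == 1L, na.rm = TRUE) / nn, NA_real_)
  }
  list(n = n, p = p, h = h, groups = gl)
}

.thetaFromSummaries <- function(sm) {
  L <- ncol(sm$n)
  comp <- matrix(NA_real_, L, 3, dimnames = list(NULL, c("a", "b", "c")))
  for (l in seq_len(L))
    comp[l, ] <- .wcComponentsLocus(sm$n[, l], sm$p[, l], sm$h[, l])
  denom <- rowSums(comp)
  ok <- !is.na(denom)
  theta <- sum(comp[ok, "a"]) / sum(denom[ok])
  perLocus <- ifelse(!is.na(denom) & abs(denom) > 0, comp[, "a"] / denom, NA_real_)
  list(theta = theta, components = comp, perLocusTheta = perLocus)
}

#' Weir-Cockerham theta (FST)
#'
#' Method-of-moments multilocus FST from the Weir-Cockerham (1984) variance
#' components: per locus, \code{a} (among populations), \code{b} (among
#' individuals within populations) and \code{c} (within individuals) are
#' estimated from per-group sample sizes, allele frequencies and observed
#' heterozygote frequencies; the multilocus estimate is the ratio of sums
#' theta = sum(a) / sum(a + b + c) over loci with a defined denominator.
#' Negative per-locus values are retained, not truncated. Per-locus sample
#' sizes reflect missing data; loci typed in fewer than two groups are
#' dropped.
#'
#' @param gm a \code{\link{SnpGenotypes}} object.
#' @param grouping factor over individuals (default: collections);
#'   \code{NA} excludes an individual.
#' @return a list: \code{theta} (multilocus), \code{components} (loci x
#'   \{a, b, c\}), \code{perLocusTheta}.
#' @export
wcTheta <- function(gm, grouping = collections(gm)) {
  grouping <- as.factor(grouping)
  keep <- !is.na(grouping)
  calls <- genotypeCalls(gm)[keep, , drop = FALSE]
  grouping <- droplevels(grouping[keep])
  if (nlevels(grouping) < 2L) stop("theta requires at least two groups")
  sm <- .groupSummaries(calls, grouping)
  if (any(apply(sm$n, 1, max) < 2))
    stop("a group has fewer than 2 typed individuals at every locus")
  .thetaFromSummaries(sm)
}

#' Permutation test for pairwise theta
#'
#' Individuals are permuted between the two groups preserving group sizes;
#' p = (1 + #\{theta_perm >= theta_obs\}) / (1 + nPerm). With
#' \code{exhaustive = TRUE} all distinct relabelings are enumerated and p is
#' the exact proportion (which includes the observed labeling).
#'
#' @param gm a \code{\link{SnpGenotypes}} object.
#' @param groupA,groupB index vectors (or collection codes) defining the two
#'   groups.
#' @param nPerm number of permutations.
#' @param seed RNG seed.
#' @param exhaustive enumerate all relabelings (small groups only).
#' @return list: \code{theta}, \code{p_value}, \code{n_permutations_used}.
#' @export
fstPermutationTest <- function(gm, groupA, groupB, nPerm = 10000, seed = NULL,
                               exhaustive = FALSE) {
  idx <- .resolveGroups(gm, groupA, groupB)
  calls <- genotypeCalls(gm)[c(idx$a, idx$b), , drop = FALSE]
  nA <- length(idx$a)
  n <- nrow(calls)
  lab0 <- rep(c("A", "B"), c(nA, n - nA))
  obs <- .thetaFromSummaries(.groupSummaries(calls, lab0))$theta
  if (exhaustive) {
    sel <- combn(n, nA)
    th <- apply(sel, 2, function(ix) {
      lab <- rep("B", n); lab[ix] <- "A"
      .thetaFromSummaries(.groupSummaries(calls, lab))$theta
    })
    return(list(theta = obs, p_value = mean(th >= obs - 1e-12),
                n_permutations_used = ncol(sel)))
  }
  if (!is.null(seed)) set.seed(seed)
  cnt <- 0L
  for (b in seq_len(nPerm)) {
    ix <- sample.int(n, nA)
    lab <- rep("B", n); lab[ix] <- "A"
    th <- .thetaFromSummaries(.groupSummaries(calls, lab))$theta
    if (!is.na(th) && th >= obs - 1e-12) cnt <- cnt + 1L
  }
  list(theta = obs, p_value = (1 + cnt) / (1 + nPerm),
       n_permutations_used = nPerm)
}

.resolveGroups <- function(gm, groupA, groupB) {
  coll <- collections(gm)
  asIdx <- function(g) {
    if (is.character(g) && all(g %in% levels(coll))) which(coll %in% g)
    else if (is.logical(g)) which(g)
    else as.integer(g)
  }
  a <- asIdx(groupA); b <- asIdx(groupB)
  if (length(intersect(a, b))) stop("groups must be disjoint")
  list(a = a, b = b)
}

#' Pairwise FST matrix with permutation significance
#'
#' Computes Weir-Cockerham theta and its permutation p-value for every pair
#' of collections, applies the Holm correction jointly across all pairwise
#' tests, and exports the usual lower-triangle theta / upper-triangle p
#' layout.
#'
#' @param gm a \code{\link{SnpGenotypes}} object.
#' @param nPerm permutations per pair.
#' @param seed master seed (each pair uses a derived sub-seed).
#' @return a list: \code{table} (long format: pair, theta, p_value,
#'   significant_after_holm), \code{matrix} (lower theta / upper p),
#'   \code{thetaMatrix}, \code{pMatrix} (both symmetric).
#' @export
pairwiseFstMatrix <- function(gm, nPerm = 10000, seed = 1L) {
  codes <- levels(collections(gm))
  if (length(codes) < 2L) stop("need at least two collections")
  prs <- combn(length(codes), 2)
  rows <- vector("list", ncol(prs))
  for (k in seq_len(ncol(prs))) {
    a <- codes[prs[1, k]]; b <- codes[prs[2, k]]
    r <- fstPermutationTest(gm, a, b, nPerm = nPerm, seed = seed + k)
    rows[[k]] <- data.frame(collectionA = a, collectionB = b,
                            theta = r$theta, p_value = r$p_value,
                            stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  tab$significant_after_holm <- holmSequentialBonferroni(tab$p_value)
  k <- length(codes)
  thM <- pM <- matrix(NA_real_, k, k, dimnames = list(codes, codes))
  mix <- matrix(NA_real_, k, k, dimnames = list(codes, codes))
  for (i in seq_len(nrow(tab))) {
    ia <- match(tab$collectionA[i], codes); ib <- match(tab$collectionB[i], codes)
    thM[ia, ib] <- thM[ib, ia] <- tab$theta[i]
    pM[ia, ib] <- pM[ib, ia] <- tab$p_value[i]
    mix[max(ia, ib), min(ia, ib)] <- tab$theta[i]
    mix[min(ia, ib), max(ia, ib)] <- tab$p_value[i]
  }
  list(table = tab, matrix = mix, thetaMatrix = thM, pMatrix = pM)
}

#' Linearized FST
#'
#' The monotone transform theta / (1 - theta) used for isolation-by-distance
#' regression; negative theta maps below zero.
#'
#' @param theta FST estimate(s), each < 1.
#' @return theta / (1 - theta).
#' @export
linearizeFst <- function(theta) {
  if (any(!is.na(theta) & theta >= 1)) stop("linearized FST undefined at theta = 1")
  theta / (1 - theta)
}

#' Isolation-by-distance regression
#'
#' Ordinary least squares of linearized genetic distance FST/(1-FST) on
#' geographic (waterway) distance, with R-squared and the two-sided slope
#' test.
#'
#' @param linearizedFst numeric vector of FST/(1-FST) values.
#' @param distanceKm matching distances in km.
#' @return a list: \code{slope} (per km), \code{intercept},
#'   \code{r_squared}, \code{p_value}, \code{points} (data.frame).
#' @export
ibdRegression <- function(linearizedFst, distanceKm) {
  ok <- !is.na(linearizedFst) & !is.na(distanceKm)
  y <- linearizedFst[ok]; x <- distanceKm[ok]
  if (length(y) < 3L) stop("need at least 3 points")
  if (sd(x) == 0) stop("zero distance variance")
  fit <- lm(y ~ x)
  sm <- suppressWarnings(summary(fit))  # collinear inputs are legitimate
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = sm$r.squared, p_value = sm$coefficients[2, 4],
       points = data.frame(distance_km = x, linearized_fst = y))
}

#' Great-circle distances between collections (fallback)
#'
#' Haversine great-circle distance from collection coordinates. This is a
#' clearly labelled fallback for when true shortest-waterway distances are
#' unavailable; over-water path distances should be supplied as a distance
#' matrix whenever possible.
#'
#' @param metadata data.frame with \code{code}, \code{latitude},
#'   \code{longitude}.
#' @return symmetric distance matrix in km, dimnames = codes.
#' @export
greatCircleDistances <- function(metadata) {
  stopifnot(all(c("code", "latitude", "longitude") %in% names(metadata)))
  pts <- as.matrix(metadata[, c("longitude", "latitude")])
  k <- nrow(pts)
  d <- matrix(0, k, k, dimnames = list(metadata$code, metadata$code))
  for (i in seq_len(k))
    d[i, ] <- geosphere::distHaversine(pts[i, ], pts) / 1000
  d
}
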