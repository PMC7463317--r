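# fallback LDA with a ridge-regularized within-group scatter, for inputs
# where groups are internally (near-)constant and MASS::lda refuses
.ridgeLda <- function(X, groups) {
  mu <- colMeans(X)
  p <- ncol(X)
  W <- B <- matrix(0, p, p)
  for (g in levels(groups)) {
    Xi <- X[groups == g, , drop = FALSE]
    mi <- colMeans(Xi)
    if (nrow(Xi) > 1) W <- W + crossprod(sweep(Xi, 2, mi))
    B <- B + nrow(Xi) * tcrossprod(mi - mu)
  }
  W <- W / max(1, nrow(X) - nlevels(groups))
  eps <- 1e-8 * (mean(diag(W)) + mean(diag(B)) / nrow(X) + 1e-12)
  ei <- eigen(solve(W + diag(eps, p), B))
  nd <- min(nlevels(groups) - 1L, p)
  list(scaling = Re(ei$vectors[, seq_len(nd), drop = FALSE]),
       svd = sqrt(pmax(Re(ei$values[seq_len(nd)]), 0)))
}

#' Discriminant analysis of principal components (DAPC)
#'
#' Allele dosages are centred (missing calls imputed with the locus mean),
#' reduced by PCA, and the retained principal components are fed to a
#' linear discriminant analysis on the predefined group labels. Reported
#' per-axis percentages are shares of the discriminant (between-group)
#' variance; per-locus loading contributions are obtained by rotating the
#' discriminant coefficients back through the PCA rotation.
#'
#' @param gm a \code{\link{SnpGenotypes}} object.
#' @param groups factor over individuals (default collections).
#' @param retainedPcs integer count of PCs to retain, or a variance target
#'   in (0, 1); the default keeps the smallest count explaining >= 90\% of
#'   total variance, capped at n/3. If the within-group scatter is singular
#'   the PC count is reduced automatically with a message.
#' @return list of class \code{"dapcResult"}: \code{coordinates}
#'   (individuals x axes), \code{percentVariance}, \code{loadings}
#'   (loci x axes squared contributions, columns sum to 1),
#'   \code{retainedPcs}, \code{groups}, \code{groupCentroids}.
#' @export
dapc <- function(gm, groups = collections(gm), retainedPcs = 0.90) {
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) < 2L) stop("need at least two groups")
  X <- genotypeCalls(gm)
  storage.mode(X) <- "double"
  mu <- colMeans(X, na.rm = TRUE)
  for (l in seq_len(ncol(X))) X[is.na(X[, l]), l] <- mu[l]
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  varShare <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
  nMax <- max(1L, min(floor(nrow(X) / 3), sum(pc$sdev^2 > 1e-10)))
  nPc <- if (retainedPcs < 1) min(which(varShare >= retainedPcs)) else
    as.integer(retainedPcs)
  nPc <- max(1L, min(nPc, nMax, nrow(X) - nlevels(groups)))
  scores <- pc$x[, seq_len(nPc), drop = FALSE]
  fit <- NULL
  repeat {
    fit <- tryCatch(
      suppressWarnings(MASS::lda(scores[, seq_len(nPc), drop = FALSE], groups)),
      error = function(e) NULL)
    if (!is.null(fit) || nPc == 1L) break
    nPc <- nPc - 1L
    message("reducing retained PCs to ", nPc, " (singular within-group scatter)")
  }
  if (is.null(fit)) {
    # degenerate within-group scatter (e.g. groups internally constant):
    # regularized discriminant eigenanalysis
    fit <- .ridgeLda(scores[, seq_len(nPc), drop = FALSE], groups)
  }
  sc <- scores[, seq_len(nPc), drop = FALSE]
  ld <- sc %*% fit$scaling
  pctVar <- 100 * fit$svd^2 / sum(fit$svd^2)
  # rotate discriminant coefficients back to locus space
  lociLoad <- pc$rotation[, seq_len(nPc), drop = FALSE] %*% fit$scaling
  contr <- sweep(lociLoad^2, 2, colSums(lociLoad^2), "/")
  centro <- apply(ld, 2, function(a) tapply(a, groups, mean))
  structure(list(coordinates = ld, percentVariance = pctVar,
                 loadings = contr, retainedPcs = nPc, groups = groups,
                 groupCentroids = centro),
            class = "dapcResult")
}
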