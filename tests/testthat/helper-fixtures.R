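# small in-code fixtures shared across test files

# a tiny deterministic matrix: 4 individuals, 2 collections, 3 loci
tinyGm <- function() {
  calls <- matrix(c(0L, 1L, 2L,
                    1L, 1L, 0L,
                    2L, 0L, NA,
                    2L, 2L, 1L),
                  nrow = 4, byrow = TRUE,
                  dimnames = list(paste0("i", 1:4), paste0("L", 1:3)))
  SnpGenotypes(calls, collection = c("P1", "P1", "P2", "P2"))
}

# random valid genotype matrix for round-trip properties
randomGm <- function(n = 12, L = 6, nColl = 3, missRate = 0.1, seed = 1) {
  set.seed(seed)
  calls <- matrix(sample(0:2, n * L, replace = TRUE), n, L,
                  dimnames = list(sprintf("ind%02d", 1:n), sprintf("loc%d", 1:L)))
  calls[runif(n * L) < missRate] <- NA
  storage.mode(calls) <- "integer"
  SnpGenotypes(calls, collection = sort(rep_len(paste0("C", 1:nColl), n)))
}

# independent Weir-Cockerham oracle via the allele-indicator ANOVA route
# (sums of squares / mean squares), coded separately from the package's
# variance-component formulas
oracleWcTheta <- function(calls, grouping) {
  grouping <- as.factor(grouping)
  L <- ncol(calls)
  A <- B <- C <- rep(NA_real_, L)
  for (l in seq_len(L)) {
    g <- calls[, l]
    ok <- !is.na(g)
    gr <- droplevels(grouping[ok]); g <- g[ok]
    ni <- as.vector(table(gr))
    if (length(ni) < 2 || sum(ni) < 2) next
    r <- length(ni)
    ybarInd <- g / 2                       # per-individual allele-2 share
    ybarPop <- tapply(ybarInd, gr, mean)
    nTot <- sum(ni)
    ybarAll <- sum(ni * ybarPop) / nTot
    SSG <- sum(ifelse(g == 1, 0.5, 0))
    SSI <- 2 * sum((ybarInd - ybarPop[gr])^2)
    SSP <- 2 * sum(ni * (ybarPop - ybarAll)^2)
    MSG <- SSG / nTot
    MSI <- SSI / (nTot - r)
    MSP <- SSP / (r - 1)
    nc <- (nTot - sum(ni^2) / nTot) / (r - 1)
    if (nTot - r <= 0 || nc <= 0) next
    C[l] <- MSG
    B[l] <- (MSI - MSG) / 2
    A[l] <- (MSP - MSI) / (2 * nc)
  }
  ok <- !is.na(A)
  sum(A[ok]) / sum(A[ok] + B[ok] + C[ok])
}

# independent exact HWE (Levene) enumeration oracle using plain factorials
oracleHweP <- function(nAA, nAB, nBB) {
  nA <- 2 * nAA + nAB; nB <- 2 * nBB + nAB; n <- nAA + nAB + nBB
  hs <- seq(nA %% 2, min(nA, nB), by = 2)
  pr <- sapply(hs, function(h) {
    naa <- (nA - h) / 2; nbb <- (nB - h) / 2
    exp(lgamma(n + 1) - lgamma(naa + 1) - lgamma(h + 1) - lgamma(nbb + 1) +
          h * log(2) + lgamma(nA + 1) + lgamma(nB + 1) - lgamma(2 * n + 1))
  })
  pr <- pr / sum(pr)
  pObs <- pr[match(nAB, hs)]
  list(p = sum(pr[pr <= pObs * (1 + 1e-9)]), probs = pr, hs = hs)
}

# independent G statistic for a genotype pair table
oracleG <- function(ga, gb) {
  tab <- table(factor(ga, 0:2), factor(gb, 0:2))
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  idx <- tab > 0
  2 * sum(tab[idx] * log(tab[idx] / e[idx]))
}

# all permutations of 1..n (independent of the package internal)
oraclePerms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- oraclePerms(n - 1)
  out <- NULL
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  out
}
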