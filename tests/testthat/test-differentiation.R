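test_that("theta is 1 for groups fixed for opposite alleles", {
  calls <- rbind(matrix(0L, 10, 5), matrix(2L, 10, 5))
  gm <- SnpGenotypes(calls, rep(c("A", "B"), each = 10))
  expect_equal(wcTheta(gm)$theta, 1, tolerance = 1e-12)
})

test_that("theta matches the independent ANOVA oracle to 1e-12", {
  set.seed(17)
  for (i in 1:8) {
    n <- 3 * sample(2:4, 1)
    calls <- matrix(sample(0:2, n * 4, replace = TRUE), n, 4)
    if (i > 4) calls[sample(length(calls), 3)] <- NA
    storage.mode(calls) <- "integer"
    grp <- rep(paste0("G", 1:3), each = n / 3)
    gm <- SnpGenotypes(calls, grp)
    got <- tryCatch(wcTheta(gm)$theta, error = function(e) NA)
    ora <- oracleWcTheta(calls, grp)
    if (!is.na(got)) expect_equal(got, ora, tolerance = 1e-12)
  }
})

test_that("theta is near zero for panmictic groups and split duplicates", {
  set.seed(23)
  p <- runif(91, 0.1, 0.9)
  calls <- sapply(p, function(pp) rbinom(400, 2, pp))
  gm <- SnpGenotypes(calls, rep(c("A", "B"), each = 200))
  expect_lt(abs(wcTheta(gm)$theta), 0.005)
  # same individuals split arbitrarily into two groups
  gm2 <- SnpGenotypes(calls, sample(rep(c("X", "Y"), 200)))
  expect_lt(abs(wcTheta(gm2)$theta), 0.005)
})

test_that("theta is invariant to locus order and allele relabeling", {
  gm <- randomGm(n = 30, L = 8, nColl = 3, seed = 5)
  th <- wcTheta(gm)$theta
  perm <- sample(8)
  expect_equal(wcTheta(gm[, perm])$theta, th, tolerance = 1e-12)
  calls <- genotypeCalls(gm)
  calls[, 1:3] <- 2L - calls[, 1:3]
  expect_equal(wcTheta(SnpGenotypes(calls, collections(gm)))$theta, th,
               tolerance = 1e-12)
})

test_that("theta errors when a group is essentially untyped", {
  calls <- rbind(matrix(0L, 5, 2), matrix(NA_integer_, 2, 2))
  calls[6, 1] <- 1L  # one typed individual only in group B
  gm <- SnpGenotypes(calls, rep(c("A", "B"), c(5, 2)))
  expect_error(wcTheta(gm), "fewer than 2 typed")
})

test_that("permutation p matches exhaustive enumeration on tiny groups", {
  set.seed(41)
  calls <- matrix(sample(0:2, 12, replace = TRUE), 6, 2)
  storage.mode(calls) <- "integer"
  gm <- SnpGenotypes(calls, rep(c("A", "B"), each = 3))
  r <- fstPermutationTest(gm, "A", "B", exhaustive = TRUE)
  sel <- combn(6, 3)
  ths <- apply(sel, 2, function(ix) {
    grp <- rep("B", 6); grp[ix] <- "A"
    oracleWcTheta(calls, grp)
  })
  expect_equal(r$n_permutations_used, 20)
  expect_equal(r$p_value, mean(ths >= r$theta - 1e-12), tolerance = 1e-12)
})

test_that("fixed differences give the smallest attainable p", {
  calls <- rbind(matrix(0L, 6, 4), matrix(2L, 6, 4))
  gm <- SnpGenotypes(calls, rep(c("A", "B"), each = 6))
  r <- fstPermutationTest(gm, "A", "B", nPerm = 99, seed = 1)
  expect_equal(r$p_value, 1 / 100)
})

test_that("pairwise FST matrix is symmetric with joint Holm flags", {
  cfg <- simConfig(nClusters = 3, clusterFst = c(0.02, 0.1, 0.2),
                   nCollectionsPerCluster = 1,
                   nIndividualsPerCollection = 40, nLoci = 40, seed = 3)
  gm <- generateDataset(cfg)$genotypes
  pw <- pairwiseFstMatrix(gm, nPerm = 199, seed = 7)
  expect_equal(pw$thetaMatrix, t(pw$thetaMatrix))
  expect_equal(pw$pMatrix, t(pw$pMatrix))
  expect_equal(nrow(pw$table), 3L)
  # mixed layout: lower triangle theta, upper triangle p, full precision
  codes <- rownames(pw$matrix)
  for (k in seq_len(nrow(pw$table))) {
    i <- match(pw$table$collectionA[k], codes)
    j <- match(pw$table$collectionB[k], codes)
    expect_equal(pw$matrix[max(i, j), min(i, j)], pw$table$theta[k])
    expect_equal(pw$matrix[min(i, j), max(i, j)], pw$table$p_value[k])
  }
  expect_true(all(pw$table$significant_after_holm ==
                  holmSequentialBonferroni(pw$table$p_value)))
})

test_that("linearized FST transforms correctly and rejects theta = 1", {
  expect_equal(linearizeFst(0), 0)
  expect_equal(linearizeFst(0.5), 1)
  expect_equal(linearizeFst(0.217), 0.217 / 0.783, tolerance = 1e-12)
  expect_lt(linearizeFst(-0.01), 0)
  expect_error(linearizeFst(1), "undefined")
})

test_that("IBD regression recovers structure and handles degenerate input", {
  # collinear points
  r <- ibdRegression(0.002 * (1:10), seq(100, 1000, by = 100))
  expect_equal(r$r_squared, 1, tolerance = 1e-12)
  expect_equal(r$slope, 2e-5, tolerance = 1e-12)
  expect_error(ibdRegression(c(1, 2, 3), c(5, 5, 5)), "zero distance")
  expect_error(ibdRegression(c(1, 2), c(1, 2)), "at least 3")
  # zero-slope truth: 95% CI covers 0 in >= 90% of 500 replicates
  set.seed(13)
  cover <- replicate(500, {
    x <- runif(37, 0, 2000)
    y <- rnorm(37, 0.1, 0.03)
    ibdRegression(y, x)$p_value >= 0.05
  })
  expect_gte(mean(cover), 0.90)
  # linear truth with noise: slope within 2 SE
  set.seed(14)
  x <- runif(37, 0, 2000)
  y <- 0.01 + 2e-4 * x + rnorm(37, 0, 0.05)
  fit <- ibdRegression(y, x)
  sm <- summary(lm(y ~ x))
  expect_lt(abs(fit$slope - 2e-4), 2 * sm$coefficients[2, 2])
})

test_that("great-circle fallback distances are symmetric and plausible", {
  md <- data.frame(code = c("N", "S"), latitude = c(60, 59),
                   longitude = c(5, 5))
  d <- greatCircleDistances(md)
  expect_equal(d["N", "S"], d["S", "N"])
  expect_equal(unname(d["N", "S"]), 111.2, tolerance = 0.01)
})
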