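test_that("consensus is the intersection and respects scope labels", {
  a <- c("L1", "L2", "L3"); b <- c("L4", "L5")
  expect_length(consensusOutliers(a, b)$consensus, 0)
  expect_equal(consensusOutliers(a, a, scope = "x")$consensus, a)
  expect_equal(consensusOutliers(a, a, scope = "x")$scope, "x")
  expect_true(all(consensusOutliers(a, c("L2", "L9"))$consensus %in% a))
})

test_that("FDist scan refuses tiny panels and calibrates on neutral data", {
  gm <- randomGm(n = 20, L = 5, nColl = 2, seed = 1)
  expect_error(fdistScan(gm), "refusing")
  fracs <- sapply(1:5, function(rep) {
    cfg <- simConfig(nClusters = 3, clusterFst = 0.1,
                     nCollectionsPerCluster = 1,
                     nIndividualsPerCollection = 50, nLoci = 91,
                     ancestralFreqRange = c(0.15, 0.85), seed = 700 + rep)
    d <- generateDataset(cfg)
    fd <- fdistScan(d$genotypes, nIterations = 10000, seed = rep)
    mean(fd$perLocus$flagged_directional | fd$perLocus$flagged_balancing,
         na.rm = TRUE)
  })
  expect_gte(mean(fracs), 0.02)
  expect_lte(mean(fracs), 0.08)
})

test_that("FDist envelope is monotone in heterozygosity and flags match it", {
  cfg <- simConfig(nClusters = 2, clusterFst = 0.1,
                   nCollectionsPerCluster = 1,
                   nIndividualsPerCollection = 60, nLoci = 91,
                   outlierLoci = 5, seed = 19)
  d <- generateDataset(cfg)
  fd <- fdistScan(d$genotypes, nIterations = 10000, seed = 2)
  pl <- fd$perLocus[order(fd$perLocus$he), ]
  ok <- !is.na(pl$upper)
  expect_true(all(diff(pl$upper[ok]) >= -1e-12))
  expect_equal(pl$flagged_directional,
               !is.na(pl$fst) & pl$fst > pl$upper)
})

test_that("FDist recovers inflated loci on the 5x background-0.1 design", {
  hits <- sapply(1:5, function(rep) {
    cfg <- simConfig(nClusters = 3, clusterFst = 0.1,
                     nCollectionsPerCluster = 1,
                     nIndividualsPerCollection = 50, nLoci = 91,
                     outlierLoci = 5, outlierMultiplier = 5, seed = 800 + rep)
    d <- generateDataset(cfg)
    fd <- fdistScan(d$genotypes, nIterations = 10000, seed = rep)
    sum(fd$perLocus$flagged_directional[d$truth$outlier])
  })
  expect_gte(mean(hits >= 4), 0.5)  # majority of replicates flag >= 4 of 5
})

test_that("Bayesian F-model scan is quiet on neutral data, loud on outliers", {
  cfg <- simConfig(nClusters = 3, clusterFst = 0.1,
                   nCollectionsPerCluster = 1,
                   nIndividualsPerCollection = 50, nLoci = 91, seed = 55)
  d <- generateDataset(cfg)
  bs <- bayesFModelScan(d$genotypes, sampleSize = 400, thinning = 2,
                        burnIn = 600, seed = 4)
  expect_true(all(bs$perLocus$posterior_prob_selection >= 0 &
                  bs$perLocus$posterior_prob_selection <= 1))
  expect_lte(sum(bs$perLocus$flagged), 2)
  # strong outliers across many groups are decisively flagged
  cfg2 <- simConfig(nClusters = 2, clusterFst = 0.1,
                    nCollectionsPerCluster = 5,
                    nIndividualsPerCollection = 40, nLoci = 91,
                    outlierLoci = 5, outlierMultiplier = 10, seed = 56)
  d2 <- generateDataset(cfg2)
  bs2 <- bayesFModelScan(d2$genotypes, sampleSize = 500, thinning = 2,
                         burnIn = 800, seed = 5)
  expect_gte(sum(bs2$perLocus$flagged & d2$truth$outlier), 3)
})

test_that("Bayesian scan flags are invariant to allele relabeling", {
  cfg <- simConfig(nClusters = 2, clusterFst = 0.12,
                   nCollectionsPerCluster = 1,
                   nIndividualsPerCollection = 80, nLoci = 60,
                   outlierLoci = 4, outlierMultiplier = 8, seed = 57)
  d <- generateDataset(cfg)
  bs1 <- bayesFModelScan(d$genotypes, sampleSize = 400, thinning = 2,
                         burnIn = 800, seed = 6)
  calls <- genotypeCalls(d$genotypes)
  calls[, 1:30] <- 2L - calls[, 1:30]
  gm2 <- SnpGenotypes(calls, collections(d$genotypes))
  bs2 <- bayesFModelScan(gm2, sampleSize = 400, thinning = 2,
                         burnIn = 800, seed = 6)
  expect_equal(bs1$perLocus$flagged, bs2$perLocus$flagged)
})

test_that("pairwise region scan enforces balanced subsets", {
  gm <- randomGm(n = 30, L = 12, nColl = 2, seed = 2)
  regions <- collections(gm)
  expect_error(pairwiseRegionScan(gm, regions, nPerSide = 100), "too small")
  cfg <- simConfig(nClusters = 2, clusterFst = 0.002,
                   nCollectionsPerCluster = 1,
                   nIndividualsPerCollection = 60, nLoci = 91, seed = 60)
  d <- generateDataset(cfg)
  pr <- pairwiseRegionScan(d$genotypes, collections(d$genotypes),
                           nPerSide = 50, seed = 3,
                           fdistIterations = 8000, bayesSampleSize = 300,
                           bayesThinning = 2, bayesBurnIn = 500)
  # near-identical regions: consensus essentially empty
  expect_lte(length(pr$union), 2)
})
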