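test_that("Genepop files are transcribed to correct dosage calls", {
  f <- withr::local_tempfile(fileext = ".gen")
  writeLines(c("two pops, two loci",
               "LocA", "LocB",
               "POP",
               "a1 ,  0101 0102",
               "a2 ,  0102 0202",
               "POP",
               "b1 ,  0202 0101",
               "b2 ,  0000 0102"), f)
  gm <- readGenepop(f)
  expect_equal(nIndividuals(gm), 4L)
  expect_equal(lociNames(gm), c("LocA", "LocB"))
  expect_equal(unname(genotypeCalls(gm)[, "LocA"]), c(0L, 1L, 2L, NA))
  expect_equal(unname(genotypeCalls(gm)[, "LocB"]), c(1L, 2L, 0L, 1L))
  expect_equal(nlevels(collections(gm)), 2L)
  expect_equal(as.vector(table(collections(gm))), c(2L, 2L))
})

test_that("Genepop reader rejects loci with more than two allele codes", {
  f <- withr::local_tempfile(fileext = ".gen")
  writeLines(c("bad locus", "LocA", "POP",
               "x1 ,  0101", "x2 ,  0102", "x3 ,  0103"), f)
  expect_error(readGenepop(f), "biallelic violation.*LocA")
})

test_that("Genepop reader names the offending line on malformed input", {
  f <- withr::local_tempfile(fileext = ".gen")
  writeLines(c("title", "LocA", "LocB", "POP",
               "x1 ,  0101"), f)  # one genotype, two loci expected
  expect_error(readGenepop(f), "line 5")
  f2 <- withr::local_tempfile(fileext = ".gen")
  writeLines(c("title only"), f2)
  expect_error(readGenepop(f2), "parse error")
})

test_that("write/read round trips are lossless for both formats", {
  for (seed in 1:4) {
    gm <- randomGm(n = 10 + seed, L = 5, nColl = 2 + seed %% 2, seed = seed)
    fg <- withr::local_tempfile(fileext = ".gen")
    writeGenepop(gm, fg)
    back <- readGenepop(fg)
    expect_equal(unname(genotypeCalls(back)), unname(genotypeCalls(gm)))
    expect_equal(as.integer(collections(back)), as.integer(collections(gm)))
    ft <- withr::local_tempfile(fileext = ".tsv")
    writeGenotypeTable(gm, ft)
    back2 <- readGenotypeTable(ft)
    expect_equal(unname(genotypeCalls(back2)), unname(genotypeCalls(gm)))
    expect_equal(as.character(collections(back2)), as.character(collections(gm)))
  }
  # byte stability on second write
  gm <- randomGm(n = 30, L = 8, nColl = 5, seed = 9)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  writeGenepop(gm, f1)
  writeGenepop(readGenepop(f1), f2)
  expect_identical(readLines(f2)[-1], readLines(f1)[-1])  # title aside
})

test_that("empty and single-individual Genepop exports follow the dialect", {
  gm0 <- SnpGenotypes(matrix(integer(0), 0, 2,
                             dimnames = list(NULL, c("A", "B"))),
                      collection = character(0))
  f <- withr::local_tempfile()
  writeGenepop(gm0, f)
  expect_equal(readLines(f), c("panelpop genotype export", "A", "B"))
  gm1 <- SnpGenotypes(matrix(1L, 1, 1, dimnames = list("id", "L1")), "P")
  writeGenepop(gm1, f)
  expect_equal(readLines(f)[4], "id ,  001002")
})

test_that("genotype-table reader rejects invalid cells", {
  f <- withr::local_tempfile()
  writeLines(c("id\tcollection\tL1", "a\tP1\t3"), f)
  expect_error(readGenotypeTable(f), "invalid genotype cell")
})

test_that("missingness filter applies the strict >30% rule", {
  set.seed(2)
  calls <- matrix(sample(0:2, 3 * 91, replace = TRUE), 3, 91)
  calls[1, 1:28] <- NA   # 30.8% -> removed
  calls[2, 1:27] <- NA   # 29.7% -> kept
  storage.mode(calls) <- "integer"
  gm <- SnpGenotypes(calls, collection = rep("P", 3))
  out <- filterIndividualsByMissingness(gm)
  expect_equal(nIndividuals(out), 2L)
  expect_equal(individualNames(out), individualNames(gm)[2:3])
  # complete matrix is untouched; the filter is idempotent, order-preserving
  gm2 <- randomGm(missRate = 0, seed = 3)
  expect_equal(genotypeCalls(filterIndividualsByMissingness(gm2)),
               genotypeCalls(gm2))
  once <- filterIndividualsByMissingness(gm)
  twice <- filterIndividualsByMissingness(once)
  expect_equal(genotypeCalls(twice), genotypeCalls(once))
})

test_that("missingness summary reports fractions and the <10% share", {
  gm <- randomGm(n = 10, L = 10, missRate = 0, seed = 5)
  s <- missingnessSummary(gm)
  expect_true(all(s$perIndividual == 0) && all(s$perLocus == 0))
  expect_equal(s$fractionBelow10pct, 1.0)
  calls <- genotypeCalls(gm)
  calls[1, 1:2] <- NA
  gm2 <- SnpGenotypes(calls, collections(gm))
  s2 <- missingnessSummary(gm2)
  expect_equal(unname(s2$perIndividual[1]), 0.2)
  expect_equal(s2$fractionBelow10pct, 0.9)
})

test_that("assayable-SNP selection matches an independent predicate", {
  set.seed(11)
  cands <- lapply(1:20, function(i) {
    nSnp <- sample(0:3, 1, prob = c(.1, .5, .25, .15))
    list(locus_id = paste0("cand", i),
         snp_positions = if (nSnp) sample(1:135, nSnp) else integer(0),
         flank_length = 135L,
         discovery_genotypes = sample(0:2, 8, replace = TRUE))
  })
  got <- vapply(selectAssayableSnps(cands), `[[`, "", "locus_id")
  wanted <- vapply(cands, function(cc) {
    ok <- length(cc$snp_positions) == 1 &&
      cc$snp_positions >= 41 && cc$snp_positions <= 95 &&
      min(sum(cc$discovery_genotypes), 16 - sum(cc$discovery_genotypes)) >= 2
    if (ok) cc$locus_id else NA_character_
  }, "")
  expect_equal(got, wanted[!is.na(wanted)])
  # position boundary: 40 rejected, 41 retained; 2 SNPs rejected
  mk <- function(pos, n = 1) list(locus_id = "x", snp_positions = rep(pos, n),
                                  flank_length = 135L,
                                  discovery_genotypes = c(1, 1, 0, 0, 0, 0, 0, 0))
  expect_length(selectAssayableSnps(list(mk(40))), 0)
  expect_length(selectAssayableSnps(list(mk(41))), 1)
  expect_length(selectAssayableSnps(list(mk(60, n = 2))), 0)
  noDisc <- list(list(locus_id = "y", snp_positions = 50, flank_length = 135L))
  expect_warning(out <- selectAssayableSnps(noDisc), "discovery genotypes")
  expect_length(out, 0)
})

test_that("allele frequencies use gene copies and flag undefined groups", {
  calls <- matrix(c(0L, 1L, NA, NA), 2, 2,
                  dimnames = list(c("a", "b"), c("L1", "L2")))
  gm <- SnpGenotypes(calls, collection = c("G", "G"))
  af <- alleleFrequencies(gm)
  expect_equal(unname(af$freq["G", "L1"]), 0.25)
  expect_equal(unname(af$n["G", "L1"]), 4L)
  expect_true(is.na(af$freq["G", "L2"]))
  expect_error(alleleFrequencies(gm, factor(c(NA, NA))), "empty group")
  # generator truth: frequencies within 3 binomial SE
  cfg <- simConfig(nClusters = 3, clusterFst = 0.1,
                   nCollectionsPerCluster = 1,
                   nIndividualsPerCollection = 100, nLoci = 50, seed = 42)
  d <- generateDataset(cfg)
  af2 <- alleleFrequencies(d$genotypes)
  truthF <- d$truth$frequencies$collection
  se <- sqrt(truthF * (1 - truthF) / 200)
  dev <- abs(af2$freq - truthF) / pmax(se, 1e-6)
  expect_lt(mean(dev > 3), 0.02)
})

test_that("SnpGenotypes validity and subsetting behave", {
  expect_error(SnpGenotypes(matrix(5L, 1, 1), "A"), "0, 1, 2 or NA")
  expect_error(SnpGenotypes(matrix(1L, 2, 1), "A"), "collection factor length")
  gm <- tinyGm()
  sub <- gm[collections(gm) == "P1", "L2"]
  expect_equal(nIndividuals(sub), 2L)
  expect_equal(lociNames(sub), "L2")
  expect_equal(nlevels(collections(sub)), 1L)
  md <- data.frame(code = c("P1", "P1"), latitude = 0, longitude = 0)
  expect_error(SnpGenotypes(genotypeCalls(gm), collections(gm),
                            collectionData = md), "unique")
})
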