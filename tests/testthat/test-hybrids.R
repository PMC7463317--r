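test_that("F1 gamete rule forces heterozygosity between fixed pools", {
  calls <- rbind(matrix(0L, 20, 10), matrix(2L, 20, 10))
  gm <- SnpGenotypes(calls, rep(c("A", "B"), each = 20))
  sim <- simulateF1Hybrids(gm, "A", "B", nPerPool = 20, nHybrids = 25, seed = 1)
  expect_true(all(genotypeCalls(sim$hybrids) == 1L))
})

test_that("F1 genotype frequencies match the exact expectation at p = 0.5", {
  set.seed(2)
  calls <- rbind(sapply(rep(0.5, 10), function(p) rbinom(400, 2, p)),
                 sapply(rep(0.5, 10), function(p) rbinom(400, 2, p)))
  gm <- SnpGenotypes(calls, rep(c("A", "B"), each = 400))
  sim <- simulateF1Hybrids(gm, "A", "B", nPerPool = 400, nHybrids = 5000,
                           seed = 3)
  h <- genotypeCalls(sim$hybrids)
  fr <- table(factor(h, 0:2)) / length(h)
  # binomial error at n = 50,000 calls: 4 SE ~ 0.008
  expect_equal(unname(fr[["0"]]), 0.25, tolerance = 0.012)
  expect_equal(unname(fr[["1"]]), 0.50, tolerance = 0.012)
  # expected per-locus heterozygosity pA(1-pB) + pB(1-pA) within 3 SE
  pA <- sim$parentalFreqA; pB <- sim$parentalFreqB
  expHet <- pA * (1 - pB) + pB * (1 - pA)
  obsHet <- colMeans(h == 1L)
  se <- sqrt(expHet * (1 - expHet) / 5000)
  expect_true(all(abs(obsHet - expHet) < 3.5 * se))
})

test_that("loci missing in one pool yield missing hybrid calls", {
  calls <- rbind(matrix(0L, 5, 2), matrix(2L, 5, 2))
  calls[1:5, 2] <- NA
  gm <- SnpGenotypes(calls, rep(c("A", "B"), each = 5))
  sim <- simulateF1Hybrids(gm, "A", "B", nPerPool = 5, nHybrids = 4, seed = 1)
  expect_true(all(is.na(genotypeCalls(sim$hybrids)[, 2])))
  expect_true(all(!is.na(genotypeCalls(sim$hybrids)[, 1])))
})

test_that("credible-interval overlap classification is correct and monotone", {
  fakeRun <- function(q, lo, hi) {
    structure(list(Q = q, Qlower = lo, Qupper = hi, K = 2,
                   collection = factor(rep("Z", nrow(q)))),
              class = "admixtureRun")
  }
  q <- rbind(c(0.5, 0.5), c(0.95, 0.05))
  lo <- rbind(c(0.4, 0.4), c(0.9, 0.0))
  hi <- rbind(c(0.6, 0.6), c(1.0, 0.1))
  r <- classifyByCiOverlap(fakeRun(q, lo, hi), c(1, 2))
  expect_equal(r$status, c("admixed", "pure-A"))
  expect_equal(r$fractionAdmixed, 0.5)
  # widening both intervals never flips admixed -> pure
  lo2 <- lo - 0.05; hi2 <- hi + 0.05
  r2 <- classifyByCiOverlap(fakeRun(q, lo2, hi2), c(1, 2))
  expect_true(all(!(r$status == "admixed" & r2$status != "admixed")))
  expect_error(classifyByCiOverlap(fakeRun(q, lo, hi), c(1, 1)), "differ")
})

test_that("assignment is symmetric for identical baselines", {
  set.seed(9)
  base <- matrix(sample(0:2, 25 * 20, replace = TRUE), 25, 20)
  calls <- rbind(base, base, sample(0:2, 20, TRUE))
  storage.mode(calls) <- "integer"
  gm <- SnpGenotypes(calls, c(rep(c("A", "B"), each = 25), "Q"))
  r <- assignIndividuals(gm, c("A", "B"), queries = 51)
  expect_equal(unname(r$probabilities[1, ]), c(0.5, 0.5), tolerance = 1e-12)
})

test_that("assignment matches a hand-computed posterior-predictive oracle", {
  # one locus; baseline A: counts x2 = 3 of N = 8; baseline B: x2 = 6 of 8
  callsA <- c(0L, 1L, 2L, 0L)   # dosage sum 3, 4 individuals
  callsB <- c(2L, 2L, 1L, 1L)   # dosage sum 6
  gm <- SnpGenotypes(matrix(c(callsA, callsB, 2L), ncol = 1),
                     c(rep("A", 4), rep("B", 4), "Q"))
  r <- assignIndividuals(gm, c("A", "B"), queries = 9, lambda = 0.5)
  num <- function(x2, N) (x2 + 0.5) * (x2 + 1.5) / ((N + 1) * (N + 2))
  pA <- num(3, 8); pB <- num(6, 8)
  expect_equal(unname(r$probabilities[1, "A"]), pA / (pA + pB),
               tolerance = 1e-12)
})

test_that("strong multilocus signal assigns with near certainty", {
  set.seed(10)
  nA <- sapply(rep(0.9, 50), function(p) rbinom(60, 2, p))
  nB <- sapply(rep(0.1, 50), function(p) rbinom(60, 2, p))
  q <- matrix(rep(2L, 50), 1)
  gm <- SnpGenotypes(rbind(nA, nB, q), c(rep(c("A", "B"), each = 60), "Q"))
  r <- assignIndividuals(gm, c("A", "B"), queries = 121)
  expect_gt(r$probabilities[1, "A"], 0.999)
  expect_equal(r$topGroup, "A")
})

test_that("assignment is invariant to locus order; leave-one-out shrinks self-assignment", {
  gm <- randomGm(n = 40, L = 12, nColl = 2, missRate = 0, seed = 15)
  r1 <- assignIndividuals(gm, levels(collections(gm)), queries = 1:5)
  perm <- sample(12)
  r2 <- assignIndividuals(gm[, perm], levels(collections(gm)), queries = 1:5)
  expect_equal(r1$probabilities, r2$probabilities, tolerance = 1e-12)
  expect_true(all(r1$leaveOneOut))
  # compare with the query excluded from its baseline (no LOO correction)
  for (q in 1:3) {
    own <- as.character(collections(gm)[q])
    rLoo <- assignIndividuals(gm, levels(collections(gm)), queries = q)
    keep <- setdiff(seq_len(40), q)
    gm2 <- SnpGenotypes(rbind(genotypeCalls(gm)[keep, ], genotypeCalls(gm)[q, , drop = FALSE]),
                        c(as.character(collections(gm))[keep], "QRY"))
    rExt <- assignIndividuals(gm2, levels(collections(gm)), queries = 40)
    expect_equal(unname(rLoo$probabilities[1, own]),
                 unname(rExt$probabilities[1, own]), tolerance = 1e-12)
  }
})

test_that("all-missing queries fall back to uniform assignment", {
  gm <- randomGm(n = 20, L = 5, nColl = 2, missRate = 0, seed = 16)
  calls <- rbind(genotypeCalls(gm), matrix(NA_integer_, 1, 5))
  gm2 <- SnpGenotypes(calls, c(as.character(collections(gm)), "C1"))
  expect_warning(r <- assignIndividuals(gm2, c("C1", "C2"), queries = 21),
                 "no typed loci")
  expect_equal(unname(r$probabilities[1, ]), c(0.5, 0.5))
})
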