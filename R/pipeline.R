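#' Pipeline configuration
#'
#' Assembles the configuration for \code{\link{runPipeline}}: input data
#' (a \code{\link{SnpGenotypes}} or a path), optional metadata and distance
#' matrix, stage toggles, a chain-length profile and a master seed.
#'
#' The \code{"paper"} profile uses the heavy settings of the original
#' study design (1e5/1e6 x 10 admixture chains for K = 1..10, 1e5 FDist
#' iterations, 1e4 permutations, BayeScan-style 1e4 samples thinned by 50);
#' the \code{"test"} profile scales every stochastic stage down roughly
#' 100-fold for routine desk-scale runs.
#'
#' @param genotypes a \code{\link{SnpGenotypes}} or a path to a Genepop
#'   (.gen/.txt Genepop dialect) or genotype-table file.
#' @param metadata optional collection metadata data.frame or path.
#' @param distances optional distance matrix (km) or path to a delimited
#'   matrix with collection codes as header row/column.
#' @param stages character vector of stages to run, a subset of
#'   \code{c("filter", "diversity", "hwe", "ld", "fst", "outliers",
#'   "structure", "dapc", "hybrids", "assignment", "ibd")}.
#' @param profile "test" or "paper".
#' @param seed master seed; every stochastic stage derives its own.
#' @param outDir output directory (created); \code{NULL} = no files.
#' @param kRange K grid for the structure stage.
#' @param ibdReference collection code for the IBD reference (default the
#'   first collection).
#' @param hybridPools list(poolA =, poolB =) of collection codes for the
#'   hybrid-zone diagnostic (stage skipped when NULL).
#' @param maxLdPairs cap on LD pairs per collection in the test profile.
#' @return a list of class \code{"pipelineConfig"}.
#' @export
pipelineConfig <- function(genotypes, metadata = NULL, distances = NULL,
                           stages = c("filter", "diversity", "hwe", "fst",
                                      "outliers", "structure", "dapc", "ibd"),
                           profile = c("test", "paper"), seed = 1L,
                           outDir = NULL, kRange = 1:4,
                           ibdReference = NULL, hybridPools = NULL,
                           maxLdPairs = 50) {
  profile <- match.arg(profile)
  if (is.character(genotypes)) {
    genotypes <- if (grepl("\\.gen$", genotypes)) readGenepop(genotypes)
                 else readGenotypeTable(genotypes)
  }
  stopifnot(is(genotypes, "SnpGenotypes"))
  if (is.character(metadata)) metadata <- readCollectionMetadata(metadata)
  if (is.character(distances)) {
    distances <- as.matrix(read.table(distances, header = TRUE,
                                      row.names = 1, check.names = FALSE))
  }
  structure(list(genotypes = genotypes, metadata = metadata,
                 distances = distances, stages = stages, profile = profile,
                 seed = as.integer(seed), outDir = outDir, kRange = kRange,
                 ibdReference = ibdReference, hybridPools = hybridPools,
                 maxLdPairs = maxLdPairs),
            class = "pipelineConfig")
}

.profileSettings <- function(profile) {
  if (profile == "paper")
    list(nPerm = 10000, fdistIter = 100000, bayesSample = 10000,
         bayesThin = 50, bayesBurn = 50000, admixBurn = 100000,
         admixLen = 1000000, admixReps = 10, ldPerm = 10000)
  else
    list(nPerm = 300, fdistIter = 20000, bayesSample = 600,
         bayesThin = 2, bayesBurn = 800, admixBurn = 500,
         admixLen = 2000, admixReps = 3, ldPerm = 200)
}

#' Run the full analysis pipeline
#'
#' Executes the configured stages in order: individual-missingness filter,
#' diversity table, HWE (and optionally LD) tests with Holm correction,
#' pairwise FST matrix with permutation significance, dual outlier scan
#' with consensus, admixture clustering with K selection, DAPC, the
#' hybrid-zone diagnostic (F1 simulation + CI-overlap classification +
#' assignment), and isolation-by-distance regression. Every stochastic
#' stage is seeded deterministically from the master seed; a manifest
#' records settings, seeds and per-stage timings. Stage outputs are
#' written as delimited tables under \code{outDir} when configured, and
#' partial failure leaves completed outputs intact.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @return a list of class \code{"pipelineReport"}: one element per
#'   executed stage plus \code{manifest}.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "pipelineConfig"))
  st <- .profileSettings(config$profile)
  gm <- config$genotypes
  res <- list()
  manifest <- list(profile = config$profile, seed = config$seed,
                   settings = st, stages = config$stages,
                   timings = list(),
                   package_version = as.character(utils::packageVersion("panelpop")))
  tic <- function() proc.time()[["elapsed"]]
  saveTab <- function(df, name) {
    if (!is.null(config$outDir)) {
      dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
      write.table(df, file.path(config$outDir, paste0(name, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  has <- function(s) s %in% config$stages

  if (has("filter")) {
    t0 <- tic()
    gm <- filterIndividualsByMissingness(gm)
    res$filter <- missingnessSummary(gm)
    manifest$timings$filter <- tic() - t0
  }
  if (has("diversity")) {
    t0 <- tic()
    res$diversity <- diversityTable(gm)
    saveTab(res$diversity, "diversity")
    manifest$timings$diversity <- tic() - t0
  }
  if (has("hwe")) {
    t0 <- tic()
    hw <- hweTestAll(gm)
    hw$significant <- !is.na(hw$p_value) & hw$p_value < 0.05
    hw$significant_after_holm <- holmSequentialBonferroni(hw$p_value)
    res$hwe <- hw
    saveTab(hw, "hwe")
    manifest$timings$hwe <- tic() - t0
  }
  if (has("ld")) {
    t0 <- tic()
    ld <- ldTestAll(gm, nPerm = st$ldPerm, seed = config$seed + 11L,
                    maxPairs = if (config$profile == "test")
                      config$maxLdPairs else Inf)
    ld$significant_after_holm <- holmSequentialBonferroni(ld$p_value)
    res$ld <- ld
    saveTab(ld, "ld")
    manifest$timings$ld <- tic() - t0
  }
  if (has("fst")) {
    t0 <- tic()
    res$fst <- pairwiseFstMatrix(gm, nPerm = st$nPerm,
                                 seed = config$seed + 23L)
    saveTab(res$fst$table, "pairwise_fst")
    manifest$timings$fst <- tic() - t0
  }
  if (has("outliers")) {
    t0 <- tic()
    fd <- fdistScan(gm, nIterations = st$fdistIter,
                    seed = config$seed + 31L)
    bs <- bayesFModelScan(gm, sampleSize = st$bayesSample,
                          thinning = st$bayesThin, burnIn = st$bayesBurn,
                          seed = config$seed + 37L)
    res$outliers <- list(fdist = fd, bayes = bs,
                         consensus = consensusOutliers(fd, bs,
                                                       scope = "all collections"))
    saveTab(fd$perLocus, "fdist")
    saveTab(bs$perLocus, "bayes_fmodel")
    manifest$timings$outliers <- tic() - t0
  }
  if (has("structure")) {
    t0 <- tic()
    res$structure <- kSelectionReport(
      gm, kRange = config$kRange, replicates = st$admixReps,
      burnIn = st$admixBurn, length = st$admixLen,
      seed = config$seed + 41L)
    manifest$timings$structure <- tic() - t0
  }
  if (has("dapc")) {
    t0 <- tic()
    res$dapc <- dapc(gm)
    manifest$timings$dapc <- tic() - t0
  }
  if (has("hybrids") && !is.null(config$hybridPools)) {
    t0 <- tic()
    hp <- config$hybridPools
    sim <- simulateF1Hybrids(gm, hp$poolA, hp$poolB,
                             seed = config$seed + 53L)
    res$hybrids <- sim
    manifest$timings$hybrids <- tic() - t0
  }
  if (has("assignment")) {
    t0 <- tic()
    res$assignment <- assignIndividuals(
      gm, baselines = levels(collections(gm)),
      queries = seq_len(nIndividuals(gm)))
    manifest$timings$assignment <- tic() - t0
  }
  if (has("ibd") && !is.null(config$distances)) {
    t0 <- tic()
    ref <- if (is.null(config$ibdReference)) levels(collections(gm))[1]
           else config$ibdReference
    fstRes <- if (!is.null(res$fst)) res$fst else
      pairwiseFstMatrix(gm, nPerm = st$nPerm, seed = config$seed + 23L)
    others <- setdiff(levels(collections(gm)), ref)
    others <- intersect(others, colnames(config$distances))
    th <- fstRes$thetaMatrix[ref, others]
    dd <- config$distances[ref, others]
    res$ibd <- ibdRegression(linearizeFst(th), dd)
    manifest$timings$ibd <- tic() - t0
  }
  res$manifest <- manifest
  structure(res, class = "pipelineReport")
}
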