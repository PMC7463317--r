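#' @export
print.fdistScan <- function(x, ...) {
  pl <- x$perLocus
  cat("FDist-style outlier scan:", nrow(pl), "loci,",
      x$settings$n_groups, "groups\n")
  cat(sprintf("  target (neutral) FST: %.4f; %d directional, %d balancing candidates\n",
              x$targetFst, sum(pl$flagged_directional, na.rm = TRUE),
              sum(pl$flagged_balancing, na.rm = TRUE)))
  invisible(x)
}

#' @export
print.bayesFModel <- function(x, ...) {
  pl <- x$perLocus
  cat("Bayesian F-model outlier scan:", nrow(pl), "loci\n")
  cat(sprintf("  %d loci with posterior probability of selection > %.2f\n",
              sum(pl$flagged), x$settings$threshold))
  invisible(x)
}

#' @export
print.consensusOutliers <- function(x, ...) {
  cat("Outlier consensus (", x$scope, "): ", length(x$consensus),
      " loci flagged by both methods\n", sep = "")
  if (length(x$consensus)) cat(" ", paste(x$consensus, collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.admixtureRun <- function(x, ...) {
  cat("Admixture run: K =", x$K, "|", nrow(x$Q), "individuals | L =",
      format(x$L, digits = 6), "\n")
  cat(sprintf("  alpha = %.3f; drift F = %s\n", x$alpha,
              paste(sprintf("%.3f", x$Fk), collapse = ", ")))
  invisible(x)
}

#' @export
print.kSelection <- function(x, ...) {
  cat("K selection over K =", paste(colnames(x$evidence), collapse = ", "), "\n")
  if (!is.null(x$evanno))
    cat("  delta-K:", paste(sprintf("%s=%.1f", names(x$evanno$deltaK),
                                    x$evanno$deltaK), collapse = "  "), "\n")
  cat("  chosen K:", paste(sprintf("%s=%s", names(x$chosenK), x$chosenK),
                           collapse = "  "), "\n")
  invisible(x)
}

#' @export
print.dapcResult <- function(x, ...) {
  cat("DAPC:", x$retainedPcs, "retained PCs,", ncol(x$coordinates),
      "discriminant axes\n")
  cat("  percent discriminant variance:",
      paste(sprintf("%.1f", x$percentVariance), collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.assignmentResult <- function(x, ...) {
  cat("Baseline assignment of", nrow(x$probabilities), "individuals to",
      ncol(x$probabilities), "baselines\n")
  print(head(round(x$probabilities, 3)))
  invisible(x)
}

#' @export
print.pipelineReport <- function(x, ...) {
  stages <- setdiff(names(x), "manifest")
  cat("Pipeline report (profile:", x$manifest$profile, "| seed:",
      x$manifest$seed, ")\n")
  cat("  stages run:", paste(stages, collapse = ", "), "\n")
  invisible(x)
}
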