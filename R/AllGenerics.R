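# Accessor generics and show methods. Slots are never reached into by
# user code; these are the supported surface.

#' @rdname DetectionFrequency-class
#' @param x,object a \linkS4class{DetectionFrequency}
#' @export
setGeneric("freqCounts", function(x) standardGeneric("freqCounts"))

#' @rdname DetectionFrequency-class
#' @export
setMethod("freqCounts", "DetectionFrequency", function(x) x@counts)

#' @rdname DetectionFrequency-class
#' @export
setGeneric("surveyData", function(x) standardGeneric("surveyData"))

#' @rdname DetectionFrequency-class
#' @export
setMethod("surveyData", "DetectionFrequency", function(x) x@surveys)

#' @rdname DetectionFrequency-class
#' @export
setGeneric("speciesCodes", function(x) standardGeneric("speciesCodes"))

#' @rdname DetectionFrequency-class
#' @export
setMethod("speciesCodes", "DetectionFrequency", function(x) x@species)

#' @rdname DetectionFrequency-class
#' @export
setGeneric("nSurveys", function(x) standardGeneric("nSurveys"))

#' @rdname DetectionFrequency-class
#' @export
setMethod("nSurveys", "DetectionFrequency", function(x) dim(x@counts)[1L])

#' @rdname DetectionFrequency-class
#' @export
setGeneric("nIntervals", function(x) standardGeneric("nIntervals"))

#' @rdname DetectionFrequency-class
#' @export
setMethod("nIntervals", "DetectionFrequency", function(x) dim(x@counts)[3L])

#' Total detected individuals per survey and species
#'
#' Sums the detection-frequency cells over j, giving the number of
#' distinct individuals recorded (D_ik). This is the lower bound on the
#' latent abundance N_ik.
#'
#' @param x a \linkS4class{DetectionFrequency}
#' @return integer matrix, surveys x species.
#' @export
setGeneric("totalDetections", function(x) standardGeneric("totalDetections"))

#' @rdname totalDetections
#' @export
setMethod("totalDetections", "DetectionFrequency", function(x) {
  out <- apply(x@counts, c(1L, 2L), sum)
  dimnames(out) <- list(NULL, x@species)
  out
})

setMethod("show", "DetectionFrequency", function(object) {
  d <- dim(object@counts)
  cat("DetectionFrequency:", d[1L], "surveys x", d[2L], "species x J =",
      d[3L], "intervals\n")
  tot <- sum(object@counts)
  cat("  ", tot, "observed individuals;",
      sum(apply(object@counts, 2L, sum) > 0), "species with detections\n")
  covs <- setdiff(names(object@surveys),
                  c("survey_id", "location", "date"))
  if (length(covs))
    cat("  survey covariates:", paste(covs, collapse = ", "), "\n")
})

#' @rdname CovariateScores-class
#' @param x,object a \linkS4class{CovariateScores}
#' @export
setGeneric("pcScores", function(x) standardGeneric("pcScores"))

#' @rdname CovariateScores-class
#' @export
setMethod("pcScores", "CovariateScores", function(x) x@scores)

#' @rdname CovariateScores-class
#' @export
setGeneric("pcLoadings", function(x) standardGeneric("pcLoadings"))

#' @rdname CovariateScores-class
#' @export
setMethod("pcLoadings", "CovariateScores", function(x) x@loadings)

#' @rdname CovariateScores-class
#' @export
setGeneric("varianceExplained",
           function(x) standardGeneric("varianceExplained"))

#' @rdname CovariateScores-class
#' @export
setMethod("varianceExplained", "CovariateScores",
          function(x) x@varianceExplained)

setMethod("show", "CovariateScores", function(object) {
  k <- ncol(object@scores)
  cum <- sum(object@varianceExplained[seq_len(k)])
  cat("CovariateScores:", nrow(object@scores), "sites,", k,
      "retained components\n")
  cat(sprintf("  cumulative variance explained: %.1f%%\n", 100 * cum))
})

#' @rdname NMixFit-class
#' @param object an \linkS4class{NMixFit}
#' @export
setMethod("coef", "NMixFit", function(object) {
  c(stats::setNames(object@beta,
                    paste0("beta_", colnames(object@X))),
    stats::setNames(object@alpha,
                    paste0("alpha_", colnames(object@W))))
})

#' @rdname NMixFit-class
#' @param ... unused
#' @export
setMethod("logLik", "NMixFit", function(object, ...) {
  structure(object@logLik, df = object@nParams,
            nobs = object@nSurveys, class = "logLik")
})

#' @rdname NMixFit-class
#' @export
setGeneric("BIC")

#' @rdname NMixFit-class
#' @export
setMethod("BIC", "NMixFit", function(object, ...) object@bic)

#' @rdname NMixFit-class
#' @export
setGeneric("isConverged", function(x) standardGeneric("isConverged"))

#' @rdname NMixFit-class
#' @param x an object with a convergence flag
#' @export
setMethod("isConverged", "NMixFit", function(x) x@converged)

#' @rdname CommunityPosterior-class
#' @export
setMethod("isConverged", "CommunityPosterior", function(x) x@converged)

setMethod("show", "NMixFit", function(object) {
  cat("NMixFit for species", object@species, "\n")
  cat("  abundance terms:",
      if (length(object@abundanceTerms))
        paste(object@abundanceTerms, collapse = " + ") else "(intercept only)",
      "\n")
  cat("  detection terms:",
      if (length(object@detectionTerms))
        paste(object@detectionTerms, collapse = " + ") else "(intercept only)",
      "\n")
  cat(sprintf("  logLik %.3f on %d surveys; %d parameters; BIC %.3f\n",
              object@logLik, object@nSurveys, object@nParams, object@bic))
  if (!object@converged) cat("  WARNING: optimizer did not converge\n")
  if (object@boundary) cat("  NOTE: fit at the lambda -> 0 boundary\n")
})

setMethod("show", "NMixSelection", function(object) {
  cat("NMixSelection over", nrow(object@table), "candidate models\n")
  show(object@best)
  if (length(object@excluded))
    cat("  excluded (non-converged):", length(object@excluded), "models\n")
})

#' @rdname NMixSelection-class
#' @param x an \linkS4class{NMixSelection}
#' @export
setGeneric("bestModel", function(x) standardGeneric("bestModel"))

#' @rdname NMixSelection-class
#' @export
setMethod("bestModel", "NMixSelection", function(x) x@best)

#' @rdname NMixSelection-class
#' @export
setGeneric("selectionTable", function(x) standardGeneric("selectionTable"))

#' @rdname NMixSelection-class
#' @export
setMethod("selectionTable", "NMixSelection", function(x) x@table)

setMethod("show", "NMixGOF", function(object) {
  cat(sprintf(paste0("Parametric-bootstrap goodness of fit: X2 = %.3f, ",
                     "p = %.4f (%d replicates)\n"),
              object@statObserved, object@pValue, length(object@statNull)))
  cat("  overdispersed at level", object@level, ":",
      object@overdispersed, "\n")
})

#' @rdname NMixGOF-class
#' @param x an \linkS4class{NMixGOF}
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))

#' @rdname NMixGOF-class
#' @export
setMethod("pValue", "NMixGOF", function(x) x@pValue)

#' @rdname NMixGOF-class
#' @export
setGeneric("isOverdispersed", function(x) standardGeneric("isOverdispersed"))

#' @rdname NMixGOF-class
#' @export
setMethod("isOverdispersed", "NMixGOF", function(x) x@overdispersed)

#' @rdname CommunityPosterior-class
#' @param x,object a \linkS4class{CommunityPosterior}
#' @export
setGeneric("sigmaDraws", function(x) standardGeneric("sigmaDraws"))

#' @rdname CommunityPosterior-class
#' @export
setMethod("sigmaDraws", "CommunityPosterior", function(x) x@Sigma)

#' @rdname CommunityPosterior-class
#' @export
setGeneric("betaDraws", function(x) standardGeneric("betaDraws"))

#' @rdname CommunityPosterior-class
#' @export
setMethod("betaDraws", "CommunityPosterior", function(x) x@beta)

#' @rdname CommunityPosterior-class
#' @export
setGeneric("alphaDraws", function(x) standardGeneric("alphaDraws"))

#' @rdname CommunityPosterior-class
#' @export
setMethod("alphaDraws", "CommunityPosterior", function(x) x@alpha)

#' @rdname CommunityPosterior-class
#' @export
setGeneric("mcmcDiagnostics", function(x) standardGeneric("mcmcDiagnostics"))

#' @rdname CommunityPosterior-class
#' @export
setMethod("mcmcDiagnostics", "CommunityPosterior", function(x) x@diagnostics)

setMethod("show", "CommunityPosterior", function(object) {
  K <- length(object@species)
  cat("CommunityPosterior:", K, "species,", dim(object@Sigma)[3L],
      "stored draws,", length(unique(object@chain)), "chains\n")
  cat("  species:", paste(object@species, collapse = ", "), "\n")
  cat("  converged (all split-Rhat <= 1.1):", object@converged, "\n")
})

setMethod("show", "SyntheticDataset", function(object) {
  cfg <- object@config
  cat("SyntheticDataset: I =", cfg$I, "surveys, K =", cfg$K,
      "species, J =", cfg$J, "intervals\n")
  cat("  true N total:", sum(object@truth$N), "; observed individuals:",
      nrow(object@records), "\n")
})

setMethod("show", "PipelineReport", function(object) {
  d <- object@dispositions
  cat("PipelineReport:", nrow(d), "species\n")
  if (nrow(d)) print(table(d$disposition))
  if (nrow(object@correlations)) {
    cat("  joint-model correlation pairs:", nrow(object@correlations), "\n")
  } else {
    cat("  no species advanced to the multispecies model\n")
  }
})

#' @rdname PipelineReport-class
#' @param x a \linkS4class{PipelineReport}
#' @export
setGeneric("dispositions", function(x) standardGeneric("dispositions"))

#' @rdname PipelineReport-class
#' @export
setMethod("dispositions", "PipelineReport", function(x) x@dispositions)

#' @rdname PipelineReport-class
#' @export
setGeneric("correlationTable", function(x) standardGeneric("correlationTable"))

#' @rdname PipelineReport-class
#' @export
setMethod("correlationTable", "PipelineReport", function(x) x@correlations)
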