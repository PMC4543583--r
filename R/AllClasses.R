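#' @import methods
NULL

#' Detection-frequency data for a community point-count survey
#'
#' Container for the sufficient summary of individual capture histories:
#' \code{counts[i, k, j]} holds the number of individuals of species
#' \code{k} detected in exactly \code{j} of the \code{J} observation
#' intervals of survey \code{i}. The unobservable \code{j = 0} cell
#' (individuals present but never detected) is absent by construction.
#'
#' @slot counts integer array, surveys x species x J.
#' @slot surveys data.frame of survey metadata and covariates, one row
#'   per survey (row order matches the first array dimension).
#' @slot species character vector of species codes (second dimension).
#' @export
setClass("DetectionFrequency",
  representation(
    counts  = "array",
    surveys = "data.frame",
    species = "character"
  )
)

setValidity("DetectionFrequency", function(object) {
  cnt <- object@counts
  if (length(dim(cnt)) != 3L)
    return("'counts' must be a 3-d array (survey x species x frequency)")
  if (any(cnt < 0) || any(cnt != round(cnt)))
    return("'counts' must contain non-negative integers")
  if (nrow(object@surveys) != dim(cnt)[1L])
    return("nrow(surveys) must equal dim(counts)[1]")
  if (length(object@species) != dim(cnt)[2L])
    return("length(species) must equal dim(counts)[2]")
  if (anyDuplicated(object@species))
    return("species codes must be unique")
  TRUE
})

#' Principal-component covariate scores
#'
#' Scores, loadings and variance proportions from a PCA of site
#' measurements on the correlation scale (each input column centred and
#' scaled to unit variance before eigendecomposition).
#'
#' @slot scores numeric matrix, sites x retained components.
#' @slot loadings numeric matrix, variables x all components.
#' @slot varianceExplained numeric vector over all components,
#'   non-increasing, summing to 1.
#' @slot center,scale numeric vectors used to standardize the inputs.
#' @export
setClass("CovariateScores",
  representation(
    scores            = "matrix",
    loadings          = "matrix",
    varianceExplained = "numeric",
    center            = "numeric",
    scale             = "numeric"
  )
)

setValidity("CovariateScores", function(object) {
  ve <- object@varianceExplained
  if (any(ve < -1e-8) || any(ve > 1 + 1e-8))
    return("varianceExplained entries must lie in [0, 1]")
  if (abs(sum(ve) - 1) > 1e-6)
    return("varianceExplained must sum to 1 over all components")
  if (is.unsorted(rev(ve), strictly = FALSE))
    return("varianceExplained must be non-increasing")
  TRUE
})

#' Maximum-likelihood fit of a single-species N-mixture model
#'
#' Result of fitting the Poisson N-mixture model with a log-linear
#' abundance predictor and a logit-linear per-interval detection
#' probability to one species' detection frequencies.
#'
#' @slot species species code.
#' @slot abundanceTerms,detectionTerms covariate names entering the
#'   abundance (log) and detection (logit) linear predictors.
#' @slot beta,alpha fitted coefficient vectors (intercept first).
#' @slot logLik maximized log-likelihood.
#' @slot nParams,nSurveys parameter and survey counts.
#' @slot bic Bayesian information criterion,
#'   \code{-2 logLik + nParams log(nSurveys)}.
#' @slot converged,boundary logical flags; \code{boundary} marks fits
#'   driven to the \code{lambda -> 0} edge (e.g. all-zero data).
#' @slot gradNorm max-norm of the log-likelihood gradient at the optimum.
#' @slot X,W design matrices used (abundance, detection).
#' @slot Y integer matrix, surveys x J, of detection frequencies.
#' @export
setClass("NMixFit",
  representation(
    species        = "character",
    abundanceTerms = "character",
    detectionTerms = "character",
    beta           = "numeric",
    alpha          = "numeric",
    logLik         = "numeric",
    nParams        = "integer",
    nSurveys       = "integer",
    bic            = "numeric",
    converged      = "logical",
    boundary       = "logical",
    gradNorm       = "numeric",
    X              = "matrix",
    W              = "matrix",
    Y              = "matrix"
  )
)

setValidity("NMixFit", function(object) {
  expected <- -2 * object@logLik + object@nParams * log(object@nSurveys)
  if (is.finite(object@bic) && abs(object@bic - expected) > 1e-6)
    return("bic inconsistent with -2 logLik + nParams log(nSurveys)")
  TRUE
})

#' Best-subset model selection result
#'
#' @slot best the selected \linkS4class{NMixFit}.
#' @slot table data.frame of every candidate model (terms, nParams,
#'   logLik, bic, converged) ordered by BIC.
#' @slot excluded character descriptions of candidates dropped for
#'   non-convergence.
#' @export
setClass("NMixSelection",
  representation(
    best     = "NMixFit",
    table    = "data.frame",
    excluded = "character"
  )
)

#' Parametric-bootstrap goodness-of-fit result
#'
#' @slot statObserved observed Pearson fit statistic.
#' @slot statNull bootstrap replicates of the statistic under the fitted
#'   Poisson N-mixture model.
#' @slot pValue upper-tail bootstrap probability.
#' @slot overdispersed logical, \code{pValue < level}.
#' @slot level significance level used for the flag.
#' @export
setClass("NMixGOF",
  representation(
    statObserved  = "numeric",
    statNull      = "numeric",
    pValue        = "numeric",
    overdispersed = "logical",
    level         = "numeric"
  )
)

setValidity("NMixGOF", function(object) {
  if (object@pValue < 0 || object@pValue > 1)
    return("pValue must lie in [0, 1]")
  if (!identical(object@overdispersed, object@pValue < object@level))
    return("overdispersed flag must equal pValue < level")
  TRUE
})

#' Posterior samples from the multispecies N-mixture model
#'
#' MCMC draws from the K-species Poisson-lognormal N-mixture model.
#' Coefficient draws are stored per species; the abundance covariance
#' matrix Sigma is stored as a K x K x nDraws array with every stored
#' draw positive definite.
#'
#' @slot species species codes (order fixes the Sigma indexing).
#' @slot beta,alpha lists (one element per species) of draw matrices,
#'   nDraws x nCoef.
#' @slot Sigma numeric array K x K x nDraws.
#' @slot chain integer vector assigning each stored draw to a chain.
#' @slot diagnostics data.frame of split-Rhat and effective sample size
#'   per monitored scalar.
#' @slot converged logical; FALSE when any split-Rhat exceeds 1.1.
#' @slot config the sampler configuration list (chains, iterations,
#'   burn-in, thinning, seed, proposal scales).
#' @export
setClass("CommunityPosterior",
  representation(
    species     = "character",
    beta        = "list",
    alpha       = "list",
    Sigma       = "array",
    chain       = "integer",
    diagnostics = "data.frame",
    converged   = "logical",
    config      = "list"
  )
)

setValidity("CommunityPosterior", function(object) {
  d <- dim(object@Sigma)
  if (length(d) != 3L || d[1L] != d[2L])
    return("Sigma must be a K x K x nDraws array")
  if (d[1L] != length(object@species))
    return("Sigma dimension must match number of species")
  if (length(object@chain) != d[3L])
    return("chain index length must equal the number of stored draws")
  TRUE
})

#' Synthetic community survey dataset
#'
#' Output of the generative simulator: the latent truth (parameters,
#' residuals and abundances), the observed individual capture records
#' (individuals with at least one detection), and the derived
#' detection-frequency table.
#'
#' @slot truth list of true parameters and latent states (beta, alpha,
#'   Sigma, epsilon, lambda, p, N).
#' @slot records data.frame of observed individual capture histories.
#' @slot freq the \linkS4class{DetectionFrequency} built from the
#'   observed layer.
#' @slot surveys survey covariate table used for both submodels.
#' @slot config the simulation configuration (I, K, J, terms, seed).
#' @export
setClass("SyntheticDataset",
  representation(
    truth   = "list",
    records = "data.frame",
    freq    = "DetectionFrequency",
    surveys = "data.frame",
    config  = "list"
  )
)

#' Two-step pipeline report
#'
#' @slot dispositions data.frame with one row per species: disposition
#'   (single_adequate / multispecies / unfittable_sparse), selected
#'   terms, GOF p-value.
#' @slot correlations correlation summary table from the joint fit
#'   (empty when no species advance).
#' @slot posterior the \linkS4class{CommunityPosterior} or NULL.
#' @slot metadata run metadata: seed, configuration, package version,
#'   config hash.
#' @export
setClass("PipelineReport",
  representation(
    dispositions = "data.frame",
    correlations = "data.frame",
    posterior    = "ANY",
    metadata     = "list"
  )
)

setValidity("PipelineReport", function(object) {
  d <- object@dispositions
  if (nrow(d) && anyDuplicated(d$species))
    return("each species must appear exactly once in dispositions")
  ok <- c("single_adequate", "multispecies", "unfittable_sparse")
  if (nrow(d) && !all(d$disposition %in% ok))
    return("unknown disposition label")
  TRUE
})
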