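## Generative simulator for community capture-history surveys. Draws the
## full model forward: correlated lognormal residuals, Poisson latent
## abundances, then a J-interval Bernoulli capture history for every
## individual; individuals never detected are dropped from the observed
## layer but retained in the truth.

.defaultCovariateNames <- c("LPC1", "LPC2", paste0("VPC", 1:6))

#' Simulate a community point-count survey dataset
#'
#' Generates survey covariates (standard-normal PC-like scores, a
#' uniform day-of-year over a 52-day season, and a uniform time-of-day
#' block, emulating the standardized and roughly orthogonal structure
#' of PCA covariates), then draws the full generative chain:
#' \code{eps_i ~ MVN(0, Sigma)}, \code{N_ik ~ Poisson(exp(mu_ik +
#' eps_ik))} with \code{mu_ik = x_ik' beta_k}, and for each of the
#' \code{N_ik} individuals a length-J capture history of independent
#' Bernoulli(\code{p_ik}) detections with \code{logit(p_ik) = w_ik'
#' alpha_k}. Individuals with all-zero histories exist in the truth but
#' not in the observed records.
#'
#' @param I,K,J surveys, species and intervals per survey.
#' @param beta list (length K) of abundance coefficient vectors aligned
#'   to intercept + \code{abundanceTerms[[k]]}; a single vector is
#'   recycled across species.
#' @param alpha detection coefficient vectors, same conventions.
#' @param Sigma K x K positive-definite residual covariance (default
#'   zero matrix: pure Poisson, no extra-Poisson variation).
#' @param abundanceTerms,detectionTerms per-species covariate names
#'   (vector recycled, or list by position).
#' @param covariates optional survey covariate data.frame to use
#'   instead of generating one (must contain the named terms).
#' @param speciesNames codes for the simulated species.
#' @param dayRange integer day-of-year window for survey dates.
#' @param seed RNG seed.
#' @return a \linkS4class{SyntheticDataset}.
#' @export
simulateCommunity <- function(I, K, J = 4,
                              beta = list(c(0.5)), alpha = list(c(0)),
                              Sigma = matrix(0, K, K),
                              abundanceTerms = character(0),
                              detectionTerms = character(0),
                              covariates = NULL,
                              speciesNames = sprintf("SP%02d", seq_len(K)),
                              dayRange = c(141L, 192L), seed = 1) {
  stopifnot(I >= 1, K >= 1, J >= 1)
  if (is.null(Sigma)) Sigma <- matrix(0, K, K)
  Sigma <- as.matrix(Sigma)
  if (!isTRUE(all.equal(Sigma, t(Sigma), tolerance = 1e-10)))
    stop("Sigma must be symmetric")
  zeroSigma <- all(Sigma == 0)
  if (!zeroSigma &&
      min(eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values) <= 0)
    stop("Sigma must be positive definite (or all zero for pure Poisson)")
  asList <- function(x) if (is.list(x)) rep_len(x, K) else rep(list(x), K)
  beta <- asList(beta); alpha <- asList(alpha)
  aTerms <- if (is.list(abundanceTerms)) rep_len(abundanceTerms, K)
            else rep(list(abundanceTerms), K)
  dTerms <- if (is.list(detectionTerms)) rep_len(detectionTerms, K)
            else rep(list(detectionTerms), K)

  set.seed(seed)
  if (is.null(covariates)) {
    covariates <- as.data.frame(
      matrix(stats::rnorm(I * length(.defaultCovariateNames)), I,
             dimnames = list(NULL, .defaultCovariateNames)))
    covariates$day_of_year <- sample(seq(dayRange[1L], dayRange[2L]), I,
                                     replace = TRUE)
    covariates$time_block <- sample(c("early", "middle", "late"), I,
                                    replace = TRUE)
  }
  surveys <- data.frame(survey_id = seq_len(I),
                        location = sprintf("L%04d", seq_len(I)),
                        date = as.character(
                          as.Date(covariates$day_of_year %||% 150L,
                                  origin = "1983-12-31")),
                        stringsAsFactors = FALSE)
  surveys <- cbind(surveys, covariates)

  X <- lapply(aTerms, function(tt) .designMatrix(surveys, tt))
  W <- lapply(dTerms, function(tt) .designMatrix(surveys, tt))
  for (k in seq_len(K)) {
    if (length(beta[[k]]) != ncol(X[[k]]))
      stop("beta[[", k, "]] must have length ", ncol(X[[k]]),
           " (intercept + abundance terms)")
    if (length(alpha[[k]]) != ncol(W[[k]]))
      stop("alpha[[", k, "]] must have length ", ncol(W[[k]]))
  }
  mu <- vapply(seq_len(K), function(k) drop(X[[k]] %*% beta[[k]]),
               numeric(I))
  P <- vapply(seq_len(K), function(k)
    stats::plogis(drop(W[[k]] %*% alpha[[k]])), numeric(I))
  mu <- matrix(mu, I, K); P <- matrix(P, I, K)

  eps <- if (zeroSigma) matrix(0, I, K)
         else MASS::mvrnorm(I, rep(0, K), Sigma)
  eps <- matrix(eps, I, K)
  lambda <- exp(mu + eps)
  N <- matrix(stats::rpois(I * K, lambda), I, K)

  counts <- array(0L, c(I, K, J),
                  dimnames = list(NULL, speciesNames, NULL))
  recs <- vector("list", K)
  for (k in seq_len(K)) {
    nTot <- sum(N[, k])
    if (nTot == 0) next
    si <- rep.int(seq_len(I), N[, k])
    prob <- P[si, k]
    hist <- matrix(stats::rbinom(nTot * J, 1L, prob), nTot, J)
    det <- rowSums(hist)
    keep <- det >= 1L
    counts[, k, ] <- as.matrix(
      table(factor(si[keep], levels = seq_len(I)),
            factor(det[keep], levels = seq_len(J))))
    if (any(keep)) {
      rk <- data.frame(survey_id = si[keep],
                       species = speciesNames[k],
                       stringsAsFactors = FALSE)
      hk <- hist[keep, , drop = FALSE]
      colnames(hk) <- paste0("int", seq_len(J))
      recs[[k]] <- cbind(rk, as.data.frame(hk))
    }
  }
  records <- if (length(Filter(Negate(is.null), recs)))
    do.call(rbind, Filter(Negate(is.null), recs))
  else
    data.frame(survey_id = integer(0), species = character(0))
  rownames(records) <- NULL
  if (nrow(records)) {
    records <- cbind(records[, c("survey_id", "species")],
                     location = surveys$location[records$survey_id],
                     date = surveys$date[records$survey_id],
                     records[, grep("^int", names(records)), drop = FALSE])
  }

  freq <- new("DetectionFrequency", counts = counts, surveys = surveys,
              species = speciesNames)
  truth <- list(beta = beta, alpha = alpha, Sigma = Sigma, eps = eps,
                mu = mu, p = P, lambda = lambda, N = N,
                abundanceTerms = aTerms, detectionTerms = dTerms)
  new("SyntheticDataset", truth = truth, records = records, freq = freq,
      surveys = surveys,
      config = list(I = I, K = K, J = J, seed = seed,
                    species = speciesNames))
}

#' Write a synthetic dataset as survey data files
#'
#' Emits the delimited-file layout accepted by
#' \code{\link{readSurveyFiles}}: \code{observations.csv} (one row per
#' observed individual with its interval capture history),
#' \code{habitat.csv} (per-location covariates), \code{species.csv}
#' (species code list), plus \code{surveys.csv} (survey-level metadata,
#' needed so surveys with zero detections are representable) and a
#' versioned \code{truth.json} with the generating parameters. Files
#' are byte-identical across runs for a fixed simulation seed.
#'
#' @param dataset a \linkS4class{SyntheticDataset}.
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of file paths.
#' @export
writeFixture <- function(dataset, dir) {
  stopifnot(is(dataset, "SyntheticDataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  surveys <- dataset@surveys
  J <- dataset@config$J
  covCols <- setdiff(names(surveys),
                     c("survey_id", "location", "date", "day_of_year",
                       "time_block"))
  paths <- c(observations = file.path(dir, "observations.csv"),
             habitat = file.path(dir, "habitat.csv"),
             species = file.path(dir, "species.csv"),
             surveys = file.path(dir, "surveys.csv"),
             truth = file.path(dir, "truth.json"))
  obs <- dataset@records
  if (!nrow(obs)) {
    obs <- data.frame(location = character(0), date = character(0),
                      species = character(0))
    for (j in seq_len(J)) obs[[paste0("int", j)]] <- integer(0)
  } else {
    obs <- obs[, c("location", "date", "species",
                   paste0("int", seq_len(J)))]
  }
  utils::write.csv(obs, paths["observations"], row.names = FALSE)
  utils::write.csv(surveys[, c("location", covCols)], paths["habitat"],
                   row.names = FALSE)
  utils::write.csv(
    data.frame(species_code = dataset@config$species,
               common_name = dataset@config$species),
    paths["species"], row.names = FALSE)
  utils::write.csv(
    surveys[, c("location", "date", "day_of_year", "time_block")],
    paths["surveys"], row.names = FALSE)
  truth <- dataset@truth
  jsonlite::write_json(
    list(format_version = 1L,
         config = dataset@config[c("I", "K", "J", "seed", "species")],
         beta = truth$beta, alpha = truth$alpha,
         Sigma = truth$Sigma, N = truth$N),
    paths["truth"], digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
  invisible(paths)
}
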