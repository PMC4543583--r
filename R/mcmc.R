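## Multispecies Poisson-lognormal N-mixture sampler.
##
## Latent layer per survey i: eps_i ~ MVN(0, Sigma) (K-variate,
## unrestricted covariance), N_ik ~ Poisson(exp(mu_ik + eps_ik)) with
## mu_ik = x_ik' beta_k. Observation layer: the detection-frequency
## vector Y_ik is multinomial over capture-history frequencies with
## binomial cell probabilities driven by logit(p_ik) = w_ik' alpha_k.
## The sampler sweeps: discrete Metropolis on N, componentwise
## Metropolis (or prior Gibbs) on eps, block random-walk Metropolis on
## beta_k and alpha_k, and a conjugate inverse-Wishart Gibbs draw for
## Sigma.

.xlogy <- function(x, ly) ifelse(x == 0, 0, x * ly)

## multinomial capture-history term for latent count n given total
## detections D and log pi_0; the 0 * -Inf case (n = D, p = 1) is 0.
.latentCountTerm <- function(n, D, logPi0) {
  lgamma(n + 1) - lgamma(n - D + 1) + .xlogy(n - D, logPi0)
}

.lmvgamma <- function(K, a) {
  K * (K - 1) / 4 * log(pi) + sum(lgamma(a + (1 - seq_len(K)) / 2))
}

.logDetPD <- function(M) 2 * sum(log(diag(chol(M))))

## log inverse-Wishart density (up to nothing: fully normalized)
.ldInvWishart <- function(Sigma, nu, S) {
  K <- ncol(Sigma)
  0.5 * nu * .logDetPD(S) - 0.5 * nu * K * log(2) - .lmvgamma(K, nu / 2) -
    0.5 * (nu + K + 1) * .logDetPD(Sigma) -
    0.5 * sum(diag(S %*% chol2inv(chol(Sigma))))
}

#' Joint log-density of the multispecies N-mixture model
#'
#' Evaluates the full joint density of latent abundances, lognormal
#' residuals and observed detection frequencies: the multinomial
#' observation terms conditional on N, the Poisson abundance terms, the
#' multivariate-normal residual terms, and (optionally) the priors on
#' coefficients and on the covariance matrix. Returns \code{-Inf} for
#' impossible states (any \code{N_ik} below the observed total
#' detections).
#'
#' @param N integer matrix I x K of latent abundances.
#' @param eps numeric matrix I x K of lognormal residuals.
#' @param beta,alpha lists (length K) of coefficient vectors.
#' @param Sigma K x K positive-definite residual covariance.
#' @param Y integer array I x K x J of detection frequencies.
#' @param X,W lists (length K) of design matrices.
#' @param priors list with \code{coefSD}, \code{nu0}, \code{S0}.
#' @param includePriors add prior terms (default TRUE).
#' @param components return the named component breakdown instead of
#'   the scalar total.
#' @return scalar log-density, or a named list when
#'   \code{components = TRUE}.
#' @export
communityLogDensity <- function(N, eps, beta, alpha, Sigma, Y, X, W,
                                priors = list(coefSD = 10,
                                              nu0 = ncol(N) + 1,
                                              S0 = diag(ncol(N))),
                                includePriors = TRUE, components = FALSE) {
  I <- nrow(N); K <- ncol(N); J <- dim(Y)[3L]
  D <- apply(Y, c(1L, 2L), sum)
  if (any(N < D)) return(if (components) list(total = -Inf) else -Inf)
  mu <- vapply(seq_len(K), function(k) drop(X[[k]] %*% beta[[k]]),
               numeric(I))
  P <- vapply(seq_len(K), function(k)
    stats::plogis(drop(W[[k]] %*% alpha[[k]])), numeric(I))
  mu <- matrix(mu, I, K); P <- matrix(P, I, K)

  obs <- sum(lgamma(N + 1) - lgamma(N - D + 1) +
               .xlogy(N - D, J * log1p(-P)))
  for (j in seq_len(J)) {
    logPij <- lchoose(J, j) + j * log(P) + (J - j) * log1p(-P)
    obs <- obs + sum(.xlogy(Y[, , j], logPij) - lgamma(Y[, , j] + 1))
  }
  pois <- sum(stats::dpois(N, exp(mu + eps), log = TRUE))
  mvn <- sum(mvtnorm::dmvnorm(eps, sigma = Sigma, log = TRUE))
  prior <- 0
  if (includePriors) {
    prior <- sum(vapply(seq_len(K), function(k)
      sum(stats::dnorm(c(beta[[k]], alpha[[k]]), 0, priors$coefSD,
                       log = TRUE)), numeric(1))) +
      .ldInvWishart(Sigma, priors$nu0, priors$S0)
  }
  total <- obs + pois + mvn + prior
  if (components)
    list(observation = obs, poisson = pois, normal = mvn, prior = prior,
         total = total)
  else total
}

#' Metropolis update of the latent abundances
#'
#' One sweep of the discrete random-walk Metropolis step on every
#' \code{N_ik}: a symmetric proposal of -2, -1, +1 or +2, truncated at
#' the observed total detections \code{D_ik} (proposals below it are
#' rejected). Vectorized over all cells; satisfies detailed balance with
#' respect to the joint density.
#'
#' @param N current I x K latent abundance matrix.
#' @param D I x K matrix of observed total detections.
#' @param lambda I x K matrix of Poisson means \code{exp(mu + eps)}.
#' @param logPi0 I x K matrix of \code{J log(1 - p_ik)}, the
#'   log-probability of an all-zero capture history.
#' @return list with the updated \code{N} and the acceptance count.
#' @export
updateLatentN <- function(N, D, lambda, logPi0) {
  step <- sample(c(-2L, -1L, 1L, 2L), length(N), replace = TRUE)
  prop <- N + step
  v <- which(prop >= D)
  propLd <- rep(-Inf, length(N))
  propLd[v] <- stats::dpois(prop[v], lambda[v], log = TRUE) +
    .latentCountTerm(prop[v], D[v], logPi0[v])
  curLd <- stats::dpois(N, lambda, log = TRUE) +
    .latentCountTerm(N, D, logPi0)
  ## an impossible current state (can only arise from initialization)
  ## accepts any possible proposal; impossible proposals are rejected
  acc <- propLd > -Inf &
    (curLd == -Inf | log(stats::runif(length(N))) < propLd - curLd)
  N[acc] <- prop[acc]
  list(N = N, accepted = sum(acc))
}

#' Update the lognormal residual matrix
#'
#' Componentwise update of \code{eps_ik}, vectorized over surveys. The
#' target is the product of the Poisson abundance terms and the
#' conditional normal \code{eps_ik | eps_i,-k} implied by
#' \code{MVN(0, Sigma)}. With \code{useData = FALSE} the Poisson terms
#' are dropped and the conditional normal is drawn exactly (a Gibbs
#' step), so the stationary distribution is exactly
#' \code{MVN(0, Sigma)} — the prior-recovery contract.
#'
#' @param eps current I x K residual matrix.
#' @param N I x K latent abundances (ignored when
#'   \code{useData = FALSE}).
#' @param mu I x K matrix of abundance linear predictors.
#' @param Sigma K x K residual covariance.
#' @param scales length-K vector of proposal standard deviations.
#' @param useData include the Poisson data terms (default TRUE).
#' @return list with updated \code{eps} and per-species acceptance
#'   counts.
#' @export
updateResiduals <- function(eps, N, mu, Sigma, scales = rep(0.5, ncol(eps)),
                            useData = TRUE) {
  K <- ncol(eps); I <- nrow(eps)
  Omega <- chol2inv(chol(Sigma))
  accepted <- integer(K)
  for (k in seq_len(K)) {
    v <- 1 / Omega[k, k]
    m <- if (K > 1)
      -v * drop(eps[, -k, drop = FALSE] %*% Omega[-k, k]) else rep(0, I)
    if (!useData) {
      eps[, k] <- stats::rnorm(I, m, sqrt(v))
      accepted[k] <- I
      next
    }
    cur <- eps[, k]
    prop <- cur + scales[k] * stats::rnorm(I)
    logR <- N[, k] * (prop - cur) -
      exp(mu[, k]) * (exp(prop) - exp(cur)) +
      stats::dnorm(prop, m, sqrt(v), log = TRUE) -
      stats::dnorm(cur, m, sqrt(v), log = TRUE)
    acc <- log(stats::runif(I)) < logR
    eps[acc, k] <- prop[acc]
    accepted[k] <- sum(acc)
  }
  list(eps = eps, accepted = accepted)
}

#' Gibbs update of the residual covariance matrix
#'
#' Conjugate draw of Sigma given the residual matrix: with an
#' inverse-Wishart(\code{nu0}, \code{S0}) prior the full conditional is
#' inverse-Wishart(\code{nu0 + I}, \code{S0 + eps' eps}).
#'
#' @param eps I x K residual matrix (I = 0 rows draws from the prior).
#' @param nu0 prior degrees of freedom (> K - 1).
#' @param S0 prior scale matrix (positive definite).
#' @return a K x K positive-definite draw.
#' @export
updateCovariance <- function(eps, nu0, S0) {
  K <- ncol(S0)
  if (nu0 <= K - 1) stop("inverse-Wishart prior requires nu0 > K - 1")
  Sn <- S0 + crossprod(eps)
  if (any(!is.finite(Sn))) stop("non-finite scale matrix")
  ev <- eigen(Sn, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("scale matrix is not positive definite")
  Wdraw <- stats::rWishart(1L, df = nu0 + nrow(eps),
                           Sigma = chol2inv(chol(Sn)))[, , 1L]
  Sigma <- chol2inv(chol(Wdraw))
  (Sigma + t(Sigma)) / 2
}

#' Random-walk Metropolis update of the regression coefficients
#'
#' Updates each species' abundance coefficient block \code{beta_k}
#' (target: Poisson terms for \code{N_k} given \code{eps_k}, plus the
#' normal prior) and detection coefficient block \code{alpha_k}
#' (target: binomial likelihood of the total detection events in
#' \code{J N_ik} interval trials, plus the prior) with joint
#' random-walk proposals.
#'
#' @param beta,alpha lists (length K) of current coefficient vectors.
#' @param N I x K latent abundances.
#' @param eps I x K residuals.
#' @param S I x K matrix of total detection events
#'   (\code{sum_j j Y_ikj}).
#' @param X,W design-matrix lists.
#' @param J number of intervals.
#' @param scalesBeta,scalesAlpha length-K proposal scales.
#' @param coefSD prior standard deviation of every coefficient.
#' @return list with updated \code{beta}, \code{alpha} and per-block
#'   acceptance indicators.
#' @export
updateCoefficients <- function(beta, alpha, N, eps, S, X, W, J,
                               scalesBeta, scalesAlpha, coefSD = 10) {
  K <- length(beta)
  accB <- logical(K); accA <- logical(K)
  for (k in seq_len(K)) {
    ## beta_k block: sum_i [N log lambda - lambda], lambda = exp(Xb + eps)
    cur <- beta[[k]]
    prop <- cur + scalesBeta[k] * stats::rnorm(length(cur))
    etaC <- drop(X[[k]] %*% cur); etaP <- drop(X[[k]] %*% prop)
    logR <- sum(N[, k] * (etaP - etaC) -
                  exp(eps[, k]) * (exp(etaP) - exp(etaC))) +
      sum(stats::dnorm(prop, 0, coefSD, log = TRUE) -
            stats::dnorm(cur, 0, coefSD, log = TRUE))
    if (is.finite(logR) && log(stats::runif(1)) < logR) {
      beta[[k]] <- prop; accB[k] <- TRUE
    }
    ## alpha_k block: binomial with S_ik successes in J N_ik trials
    cur <- alpha[[k]]
    prop <- cur + scalesAlpha[k] * stats::rnorm(length(cur))
    pC <- stats::plogis(drop(W[[k]] %*% cur))
    pP <- stats::plogis(drop(W[[k]] %*% prop))
    pC <- pmin(pmax(pC, 1e-12), 1 - 1e-12)
    pP <- pmin(pmax(pP, 1e-12), 1 - 1e-12)
    logR <- sum(S[, k] * (log(pP) - log(pC)) +
                  (J * N[, k] - S[, k]) * (log1p(-pP) - log1p(-pC))) +
      sum(stats::dnorm(prop, 0, coefSD, log = TRUE) -
            stats::dnorm(cur, 0, coefSD, log = TRUE))
    if (is.finite(logR) && log(stats::runif(1)) < logR) {
      alpha[[k]] <- prop; accA[k] <- TRUE
    }
  }
  list(beta = beta, alpha = alpha, accBeta = accB, accAlpha = accA)
}

#' Sampler configuration for the multispecies model
#'
#' Defaults follow common practice for this model class: 3 chains of
#' 50,000 iterations with 20,000 burn-in and thinning by 10, proposal
#' scales adapted toward 20-45\% acceptance during burn-in only (frozen
#' afterwards), weakly informative Normal(0, 10^2) coefficient priors
#' and an inverse-Wishart(K + 1, I_K) prior on Sigma. All entries are
#' overridable; analyses in the package's own tests use shorter chains.
#'
#' @param nChains number of chains (>= 2 for split-Rhat).
#' @param nIter iterations per chain (including burn-in).
#' @param burnin burn-in iterations discarded per chain.
#' @param thin thinning interval for stored draws.
#' @param seed master seed; per-chain seeds are spawned from it.
#' @param adaptInterval iterations between proposal-scale adaptations.
#' @param coefSD prior SD of regression coefficients.
#' @param nu0,S0 inverse-Wishart prior (defaults K + 1 and identity,
#'   resolved at run time).
#' @param storeN store latent-abundance draws (memory heavy).
#' @return a named list.
#' @export
mcmcControl <- function(nChains = 3, nIter = 50000, burnin = 20000,
                        thin = 10, seed = 1, adaptInterval = 50,
                        coefSD = 10, nu0 = NULL, S0 = NULL,
                        storeN = FALSE) {
  stopifnot(nChains >= 1, nIter > burnin, thin >= 1)
  list(nChains = nChains, nIter = nIter, burnin = burnin, thin = thin,
       seed = seed, adaptInterval = adaptInterval, coefSD = coefSD,
       nu0 = nu0, S0 = S0, storeN = storeN)
}

#' Fit the multispecies N-mixture model by MCMC
#'
#' Runs the full sampler for K species jointly: latent abundances,
#' correlated lognormal residuals with unrestricted covariance Sigma,
#' and species-specific abundance/detection coefficient blocks. Each
#' species may carry its own covariate sets (as selected in the
#' single-species step). Chains are initialized at \code{N = D + 1},
#' \code{eps = 0}, single-species maximum-likelihood coefficients and
#' \code{Sigma = I}; split-Rhat and effective sample sizes are attached
#' and the result is flagged non-converged (but returned) if any
#' split-Rhat exceeds 1.1. Given the same configuration and seed the
#' draws are bit-reproducible.
#'
#' @param freq a \linkS4class{DetectionFrequency}.
#' @param speciesSet character vector of species codes to model jointly.
#' @param abundanceTerms,detectionTerms either a character vector used
#'   for every species or a named list (by species code) of per-species
#'   term vectors.
#' @param control a list from \code{\link{mcmcControl}}.
#' @return a \linkS4class{CommunityPosterior}.
#' @export
runCommunityMCMC <- function(freq, speciesSet,
                             abundanceTerms = character(0),
                             detectionTerms = character(0),
                             control = mcmcControl()) {
  stopifnot(is(freq, "DetectionFrequency"))
  K <- length(speciesSet)
  kIdx <- match(speciesSet, speciesCodes(freq))
  if (anyNA(kIdx)) stop("species not present in the data: ",
                        paste(speciesSet[is.na(kIdx)], collapse = ", "))
  J <- nIntervals(freq)
  I <- nSurveys(freq)
  Y <- freqCounts(freq)[, kIdx, , drop = FALSE]
  surveys <- surveyData(freq)
  termsFor <- function(terms, sp)
    if (is.list(terms)) terms[[sp]] %||% character(0) else terms
  X <- lapply(speciesSet, function(sp)
    .designMatrix(surveys, termsFor(abundanceTerms, sp)))
  W <- lapply(speciesSet, function(sp)
    .designMatrix(surveys, termsFor(detectionTerms, sp)))
  D <- apply(Y, c(1L, 2L), sum)
  S <- apply(sweep(Y, 3L, seq_len(J), "*"), c(1L, 2L), sum)
  nu0 <- control$nu0 %||% (K + 1)
  S0 <- control$S0 %||% diag(K)

  ## initialize at single-species MLEs
  beta0 <- vector("list", K); alpha0 <- vector("list", K)
  for (k in seq_len(K)) {
    f <- fitNMix(freq, speciesSet[k], termsFor(abundanceTerms, speciesSet[k]),
                 termsFor(detectionTerms, speciesSet[k]), nStarts = 1)
    b <- unname(f@beta); a <- unname(f@alpha)
    b[!is.finite(b)] <- -2
    beta0[[k]] <- b; alpha0[[k]] <- a
  }

  set.seed(control$seed)
  chainSeeds <- sample.int(.Machine$integer.max, control$nChains)
  nStore <- floor((control$nIter - control$burnin) / control$thin)
  chains <- vector("list", control$nChains)

  for (ch in seq_len(control$nChains)) {
    set.seed(chainSeeds[ch])
    N <- D + 1L
    eps <- matrix(0, I, K)
    beta <- beta0; alpha <- alpha0
    Sigma <- diag(K)
    sEps <- rep(0.5, K); sBeta <- rep(0.1, K); sAlpha <- rep(0.2, K)
    accEps <- integer(K); accB <- integer(K); accA <- integer(K); nAd <- 0L
    drawsB <- lapply(X, function(x) matrix(NA_real_, nStore, ncol(x)))
    drawsA <- lapply(W, function(w) matrix(NA_real_, nStore, ncol(w)))
    drawsS <- array(NA_real_, c(K, K, nStore))
    drawsN <- if (control$storeN) array(NA_integer_, c(I, K, nStore))
    s <- 0L
    for (it in seq_len(control$nIter)) {
      mu <- vapply(seq_len(K), function(k) drop(X[[k]] %*% beta[[k]]),
                   numeric(I))
      mu <- matrix(mu, I, K)
      P <- vapply(seq_len(K), function(k)
        stats::plogis(drop(W[[k]] %*% alpha[[k]])), numeric(I))
      P <- matrix(pmin(pmax(P, 1e-12), 1 - 1e-12), I, K)
      lambda <- exp(mu + eps)
      upN <- updateLatentN(N, D, lambda, J * log1p(-P))
      N <- upN$N
      upE <- updateResiduals(eps, N, mu, Sigma, sEps)
      eps <- upE$eps
      accEps <- accEps + upE$accepted
      upC <- updateCoefficients(beta, alpha, N, eps, S, X, W, J,
                                sBeta, sAlpha, control$coefSD)
      beta <- upC$beta; alpha <- upC$alpha
      accB <- accB + upC$accBeta; accA <- accA + upC$accAlpha
      Sigma <- updateCovariance(eps, nu0, S0)
      nAd <- nAd + 1L
      if (it <= control$burnin && it %% control$adaptInterval == 0L) {
        tune <- function(scale, rate) {
          scale * exp(ifelse(rate < 0.20, -0.25,
                             ifelse(rate > 0.45, 0.25, 0)))
        }
        sEps <- tune(sEps, accEps / (nAd * I))
        sBeta <- tune(sBeta, accB / nAd)
        sAlpha <- tune(sAlpha, accA / nAd)
        accEps[] <- 0L; accB[] <- 0L; accA[] <- 0L; nAd <- 0L
      }
      if (it > control$burnin &&
          (it - control$burnin) %% control$thin == 0L) {
        s <- s + 1L
        for (k in seq_len(K)) {
          drawsB[[k]][s, ] <- beta[[k]]
          drawsA[[k]][s, ] <- alpha[[k]]
        }
        drawsS[, , s] <- Sigma
        if (control$storeN) drawsN[, , s] <- N
      }
    }
    chains[[ch]] <- list(beta = drawsB, alpha = drawsA, Sigma = drawsS,
                         N = drawsN)
  }

  ## stack chains
  betaAll <- lapply(seq_len(K), function(k)
    do.call(rbind, lapply(chains, function(cc) cc$beta[[k]])))
  alphaAll <- lapply(seq_len(K), function(k)
    do.call(rbind, lapply(chains, function(cc) cc$alpha[[k]])))
  SigmaAll <- array(NA_real_, c(K, K, nStore * control$nChains))
  for (ch in seq_len(control$nChains))
    SigmaAll[, , (ch - 1L) * nStore + seq_len(nStore)] <-
      chains[[ch]]$Sigma
  chainIdx <- rep(seq_len(control$nChains), each = nStore)
  for (k in seq_len(K)) {
    colnames(betaAll[[k]]) <- colnames(X[[k]])
    colnames(alphaAll[[k]]) <- colnames(W[[k]])
  }
  names(betaAll) <- names(alphaAll) <- speciesSet

  diag_df <- .posteriorDiagnostics(betaAll, alphaAll, SigmaAll, chainIdx,
                                   speciesSet)
  converged <- all(is.na(diag_df$rhat) | diag_df$rhat <= 1.1)

  new("CommunityPosterior", species = speciesSet, beta = betaAll,
      alpha = alphaAll, Sigma = SigmaAll, chain = as.integer(chainIdx),
      diagnostics = diag_df, converged = converged,
      config = c(control, list(nu0 = nu0, S0 = S0)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Split-Rhat convergence diagnostic
#'
#' Potential scale reduction factor computed on chains split in half,
#' the standard guard against within-chain trends.
#'
#' @param draws numeric matrix, iterations x chains.
#' @return scalar Rhat (1 for constant draws).
#' @export
splitRhat <- function(draws) {
  draws <- as.matrix(draws)
  n <- nrow(draws)
  half <- floor(n / 2)
  if (half < 2) return(NA_real_)
  seqs <- do.call(cbind, lapply(seq_len(ncol(draws)), function(j)
    cbind(draws[seq_len(half), j], draws[half + seq_len(half), j])))
  m <- ncol(seqs)
  means <- colMeans(seqs)
  vars <- apply(seqs, 2L, stats::var)
  Wv <- mean(vars)
  Bv <- half * stats::var(means)
  if (Wv == 0) return(1)
  sqrt(((half - 1) / half * Wv + Bv / half) / Wv)
}

.posteriorDiagnostics <- function(betaAll, alphaAll, SigmaAll, chainIdx,
                                  speciesSet) {
  K <- length(speciesSet)
  scalars <- list()
  for (k in seq_len(K)) {
    for (j in seq_len(ncol(betaAll[[k]])))
      scalars[[paste0("beta[", speciesSet[k], ",",
                      colnames(betaAll[[k]])[j], "]")]] <- betaAll[[k]][, j]
    for (j in seq_len(ncol(alphaAll[[k]])))
      scalars[[paste0("alpha[", speciesSet[k], ",",
                      colnames(alphaAll[[k]])[j], "]")]] <- alphaAll[[k]][, j]
  }
  for (k in seq_len(K)) {
    scalars[[paste0("sigma2[", speciesSet[k], "]")]] <- SigmaAll[k, k, ]
    if (k < K) for (l in (k + 1):K)
      scalars[[paste0("rho[", speciesSet[k], ",", speciesSet[l], "]")]] <-
        SigmaAll[k, l, ] / sqrt(SigmaAll[k, k, ] * SigmaAll[l, l, ])
  }
  chains <- sort(unique(chainIdx))
  out <- lapply(names(scalars), function(nm) {
    x <- scalars[[nm]]
    mat <- vapply(chains, function(ch) x[chainIdx == ch],
                  numeric(sum(chainIdx == chains[1L])))
    ess <- sum(vapply(seq_len(ncol(mat)), function(j)
      as.numeric(coda::effectiveSize(mat[, j])), numeric(1)))
    data.frame(parameter = nm, mean = mean(x),
               rhat = if (length(chains) > 1) splitRhat(mat) else NA_real_,
               ess = ess, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Monte Carlo standard error by non-overlapping batch means
#'
#' @param x numeric vector of (possibly autocorrelated) draws.
#' @param batchSize batch length; default \code{floor(sqrt(length(x)))}.
#' @return scalar MCSE (0 for constant draws).
#' @export
mcseBatchMeans <- function(x, batchSize = floor(sqrt(length(x)))) {
  n <- length(x)
  if (n < 4 || batchSize < 1) return(NA_real_)
  nb <- floor(n / batchSize)
  if (nb < 2) return(NA_real_)
  bm <- vapply(seq_len(nb), function(b)
    mean(x[(b - 1L) * batchSize + seq_len(batchSize)]), numeric(1))
  stats::sd(bm) / sqrt(nb)
}

#' Posterior summary of between-species abundance correlations
#'
#' Summarizes the posterior draws of each pairwise correlation
#' \code{rho_kl} implied by the Sigma draws: posterior mean, Monte Carlo
#' standard error by batch means, equal-tailed credible interval, and a
#' significance flag set when the interval excludes zero (the Bayesian
#' reading of a two-sided test at \code{1 - level}).
#'
#' @param post a \linkS4class{CommunityPosterior}.
#' @param level credible level (default 0.95).
#' @return data.frame with one row per unordered species pair.
#' @export
summarizeCorrelations <- function(post, level = 0.95) {
  stopifnot(is(post, "CommunityPosterior"))
  K <- length(post@species)
  a <- (1 - level) / 2
  rows <- list()
  if (K < 2)
    return(data.frame(species_k = character(0), species_l = character(0),
                      mean = numeric(0), mcse = numeric(0),
                      lower = numeric(0), upper = numeric(0),
                      significant = logical(0)))
  for (k in seq_len(K - 1)) {
    for (l in (k + 1):K) {
      rho <- post@Sigma[k, l, ] /
        sqrt(post@Sigma[k, k, ] * post@Sigma[l, l, ])
      qs <- unname(stats::quantile(rho, c(a, 1 - a)))
      mc <- if (stats::sd(rho) == 0) 0 else mcseBatchMeans(rho)
      rows[[length(rows) + 1L]] <- data.frame(
        species_k = post@species[k], species_l = post@species[l],
        mean = mean(rho), mcse = mc, lower = qs[1L], upper = qs[2L],
        significant = qs[1L] > 0 | qs[2L] < 0,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
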