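#' Binomial cell probability of a capture-history frequency
#'
#' Probability that one individual with per-interval detection
#' probability \code{p} is detected in exactly \code{j} of the \code{J}
#' intervals of a survey: \code{choose(J, j) p^j (1 - p)^(J - j)}.
#' The \code{j = 0} cell is the unobservable class of individuals that
#' are present but never detected.
#'
#' @param p per-interval detection probability in [0, 1] (vectorized).
#' @param J number of observation intervals (>= 1).
#' @param j detection frequency, 0 <= j <= J.
#' @return numeric probability (recycled over the longest argument).
#' @examples
#' cellProbability(0.5, 4, 2)   # 0.375
#' cellProbability(0.3, 4, 0)   # 0.2401
#' @export
cellProbability <- function(p, J, j) {
  if (any(j > J) || any(j < 0))
    stop("detection frequency j must satisfy 0 <= j <= J")
  if (any(p < 0 | p > 1)) stop("p must lie in [0, 1]")
  stats::dbinom(j, size = J, prob = p)
}

## Direct-summation likelihood: marginalize the latent abundance n over
## n = D, D+1, ... with the multinomial capture-history term, truncating
## when the tail is negligible. Kept as an exported cross-check for the
## closed-form thinning route; the two must agree to numerical precision.
.surveyLogLikSum <- function(Y, lambda, p, J, tol = 1e-12) {
  D <- sum(Y)
  if (lambda == 0) return(if (D == 0) 0 else -Inf)
  pij <- cellProbability(p, J, 0:J)
  if (any(Y > 0 & pij[-1L] == 0)) return(-Inf)
  ## constant multinomial factor over the observed cells
  logConst <- sum(Y[Y > 0] * log(pij[-1L][Y > 0])) - sum(lgamma(Y + 1))
  nMax <- D + max(200, ceiling(lambda + 10 * sqrt(lambda)))
  logTerm <- function(n) {
    stats::dpois(n, lambda, log = TRUE) +
      lgamma(n + 1) - lgamma(n - D + 1) +
      (n - D) * log(pij[1L])
  }
  n <- D:nMax
  lt <- logTerm(n)
  m <- max(lt)
  s <- sum(exp(lt - m))
  ## extend until the next term is < tol of the running sum
  repeat {
    nMax <- nMax + 1L
    t1 <- exp(logTerm(nMax) - m)
    if (!is.finite(t1) || t1 < tol * s) break
    s <- s + t1
  }
  logConst + m + log(s)
}

## Poisson-thinning closed form: marginally the frequency cells
## Y_1, ..., Y_J are independent Poisson(lambda * pi_j), the j = 0 cell
## having been integrated out.
.surveyLogLikThin <- function(Y, lambda, p, J) {
  if (lambda == 0) return(if (sum(Y) == 0) 0 else -Inf)
  pij <- cellProbability(p, J, seq_len(J))
  sum(stats::dpois(Y, lambda * pij, log = TRUE))
}

#' Marginal log-likelihood of one survey's detection frequencies
#'
#' Log-probability of the observed frequency vector \code{Y} =
#' (Y_1, ..., Y_J) for one species in one survey under the Poisson
#' N-mixture model: the latent number present is Poisson(\code{lambda})
#' and, conditional on it, the capture-history frequencies are
#' multinomial with binomial cell probabilities. Two routes are
#' provided and agree to numerical precision: \code{"thinning"} uses the
#' closed form in which the observed cells are independent
#' Poisson(\code{lambda * pi_j}) after the never-detected class is
#' marginalized; \code{"sum"} truncates the explicit sum over the latent
#' abundance.
#'
#' @param Y non-negative integer vector of length \code{J}.
#' @param lambda expected abundance (>= 0).
#' @param p per-interval detection probability.
#' @param J number of intervals; defaults to \code{length(Y)}.
#' @param method \code{"thinning"} (default, closed form) or
#'   \code{"sum"} (truncated enumeration).
#' @return scalar log-probability.
#' @examples
#' surveyLogLik(c(0, 0, 0, 0), lambda = 1, p = 0.5)  # -0.9375
#' @export
surveyLogLik <- function(Y, lambda, p, J = length(Y),
                         method = c("thinning", "sum")) {
  method <- match.arg(method)
  if (any(Y != round(Y)) || any(Y < 0))
    stop("Y must contain non-negative integers")
  if (length(Y) != J) stop("length(Y) must equal J")
  if (lambda < 0) stop("lambda must be non-negative")
  if (method == "thinning") .surveyLogLikThin(Y, lambda, p, J)
  else .surveyLogLikSum(Y, lambda, p, J)
}

#' Marginal moments of the multivariate Poisson-lognormal abundance
#'
#' Closed-form mean, variance and cross-species covariance of latent
#' abundances under the Poisson-lognormal mixture: with
#' \code{tau = exp(mu + sigma2/2)},
#' \code{E(N) = tau},
#' \code{Var(N) = tau + tau^2 (exp(sigma2) - 1)} and
#' \code{Cov(N_k, N_l) = tau_k tau_l (exp(rho sigma_k sigma_l) - 1)}.
#' At \code{sigma2 = 0} the Poisson degenerate case is recovered:
#' mean = variance = \code{exp(mu)} and zero covariance.
#'
#' @param mu_k,mu_l linear predictors (log scale) of the two species.
#' @param sigma2_k,sigma2_l lognormal residual variances (>= 0).
#' @param rho residual correlation in [-1, 1].
#' @return list with \code{mean_k}, \code{var_k}, \code{mean_l},
#'   \code{var_l} and \code{cov_kl}.
#' @examples
#' marginalMoments(0, 0, sigma2_k = 0, sigma2_l = 0, rho = 0)
#' @export
marginalMoments <- function(mu_k, mu_l = mu_k, sigma2_k, sigma2_l = sigma2_k,
                            rho = 0) {
  if (sigma2_k < 0 || sigma2_l < 0) stop("sigma2 must be non-negative")
  if (abs(rho) > 1) stop("rho must lie in [-1, 1]")
  tauK <- exp(mu_k + sigma2_k / 2)
  tauL <- exp(mu_l + sigma2_l / 2)
  list(
    mean_k = tauK,
    var_k  = tauK + tauK^2 * (exp(sigma2_k) - 1),
    mean_l = tauL,
    var_l  = tauL + tauL^2 * (exp(sigma2_l) - 1),
    cov_kl = tauK * tauL * (exp(rho * sqrt(sigma2_k * sigma2_l)) - 1)
  )
}
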