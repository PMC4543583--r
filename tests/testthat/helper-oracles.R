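# Independent oracles used across test files. These are deliberately
# written from the model definition, not by calling the package's own
# computational paths.

# Direct-enumeration log-likelihood of one survey's detection
# frequencies: sum the Poisson prior over the latent count n against
# the multinomial capture-history term (stats::dmultinom), including
# the unobservable zero-detections cell.
oracleSurveyLogLik <- function(Y, lambda, p, J, nExtra = 400) {
  D <- sum(Y)
  if (lambda == 0) return(if (D == 0) 0 else -Inf)
  pij <- dbinom(0:J, J, p)
  pr <- sum(vapply(D:(D + nExtra), function(n)
    dpois(n, lambda) * dmultinom(c(n - D, Y), n, pij), numeric(1)))
  log(pr)
}

# Conditional pmf of the latent count N given observed frequencies,
# by enumeration: p(n) proportional to Poisson(n; lambda) *
# Multinomial(Y, n - D | n).
oracleLatentPosterior <- function(Y, lambda, p, J, nMax) {
  D <- sum(Y)
  pij <- dbinom(0:J, J, p)
  n <- D:nMax
  w <- vapply(n, function(nn)
    dpois(nn, lambda) * dmultinom(c(nn - D, Y), nn, pij), numeric(1))
  list(n = n, pmf = w / sum(w))
}

# Joint log-density of a tiny community instance, coded independently
# of the package: explicit dmultinom / dpois / dmvnorm sums.
oracleJointLogDensity <- function(N, eps, beta, alpha, Sigma, Y, X, W) {
  I <- nrow(N); K <- ncol(N); J <- dim(Y)[3]
  total <- 0
  for (i in seq_len(I)) {
    for (k in seq_len(K)) {
      mu <- sum(X[[k]][i, ] * beta[[k]])
      p <- plogis(sum(W[[k]][i, ] * alpha[[k]]))
      pij <- dbinom(0:J, J, p)
      yk <- Y[i, k, ]
      D <- sum(yk)
      if (N[i, k] < D) return(-Inf)
      total <- total +
        log(dmultinom(c(N[i, k] - D, yk), N[i, k], pij)) +
        dpois(N[i, k], exp(mu + eps[i, k]), log = TRUE)
    }
    total <- total + mvtnorm::dmvnorm(eps[i, ], sigma = Sigma, log = TRUE)
  }
  total
}

# Small community datasets reused across files.
makePoissonDataset <- function(I = 200, seed = 1, K = 1, betaInt = 1.0,
                               alphaInt = 0) {
  simulateCommunity(I = I, K = K, J = 4, beta = list(betaInt),
                    alpha = list(alphaInt), seed = seed)
}
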