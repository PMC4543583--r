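# The multispecies Poisson-lognormal sampler: joint density, individual
# update kernels, posterior summaries and diagnostics.

makeTinyInstance <- function(I = 4, K = 2, J = 3, seed = 51) {
  set.seed(seed)
  X <- replicate(K, cbind(1, rnorm(I)), simplify = FALSE)
  W <- replicate(K, matrix(1, I, 1), simplify = FALSE)
  beta <- replicate(K, c(0.4, 0.3), simplify = FALSE)
  alpha <- replicate(K, 0.1, simplify = FALSE)
  Sigma <- matrix(c(1, 0.4, 0.4, 0.8), 2)[seq_len(K), seq_len(K),
                                          drop = FALSE]
  eps <- matrix(rnorm(I * K, 0, 0.5), I, K)
  Y <- array(rpois(I * K * J, 0.6), c(I, K, J))
  D <- apply(Y, c(1, 2), sum)
  N <- D + matrix(rpois(I * K, 2), I, K)
  list(X = X, W = W, beta = beta, alpha = alpha, Sigma = Sigma,
       eps = eps, Y = Y, D = D, N = N, J = J)
}

test_that("joint log-density matches an independently coded evaluator", {
  for (seed in c(51, 52, 53)) {
    z <- makeTinyInstance(seed = seed)
    got <- communityLogDensity(z$N, z$eps, z$beta, z$alpha, z$Sigma,
                               z$Y, z$X, z$W, includePriors = FALSE)
    want <- oracleJointLogDensity(z$N, z$eps, z$beta, z$alpha, z$Sigma,
                                  z$Y, z$X, z$W)
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("impossible latent states have zero density", {
  z <- makeTinyInstance()
  N <- z$N
  N[1, 1] <- z$D[1, 1] - 1L
  expect_identical(
    communityLogDensity(N, z$eps, z$beta, z$alpha, z$Sigma, z$Y, z$X, z$W),
    -Inf)
})

test_that("the multivariate-normal term at zero residuals is -(K/2) log(2 pi) per survey", {
  z <- makeTinyInstance()
  K <- 2; I <- 4
  comps <- communityLogDensity(z$N, matrix(0, I, K), z$beta, z$alpha,
                               diag(K), z$Y, z$X, z$W,
                               includePriors = FALSE, components = TRUE)
  expect_equal(comps$normal, -I * K / 2 * log(2 * pi), tolerance = 1e-12)
})

test_that("marginalizing the latent count reproduces the single-species likelihood", {
  # K = 1, sigma2 -> 0 (eps = 0): summing the joint over N must give the
  # marginal survey likelihood, up to the normal and prior terms
  set.seed(61)
  J <- 4; Y1 <- c(1, 1, 0, 0)
  beta <- list(0.4); alpha <- list(-0.2)
  X <- list(matrix(1, 1, 1)); W <- list(matrix(1, 1, 1))
  lam <- exp(0.4); p <- plogis(-0.2)
  terms <- vapply(2:250, function(n) {
    comps <- communityLogDensity(matrix(n, 1, 1), matrix(0, 1, 1), beta,
                                 alpha, matrix(1e-4, 1, 1),
                                 array(Y1, c(1, 1, J)), X, W,
                                 includePriors = FALSE, components = TRUE)
    comps$observation + comps$poisson
  }, numeric(1))
  marg <- log(sum(exp(terms)))
  expect_equal(marg, surveyLogLik(Y1, lam, p, J), tolerance = 1e-8)
})

test_that("latent-count proposals below the observed total are always rejected", {
  set.seed(71)
  D <- matrix(3L, 10, 2)
  N <- D
  lambda <- matrix(0.5, 10, 2)   # strong pull downward
  logPi0 <- matrix(log(0.3), 10, 2)
  for (s in 1:200) {
    N <- updateLatentN(N, D, lambda, logPi0)$N
    expect_true(all(N >= D))
  }
})

test_that("perfect detection pins the latent count at the observed total", {
  set.seed(72)
  D <- matrix(2L, 5, 1)
  N <- D + 1L                    # one step from the only possible state
  lambda <- matrix(3, 5, 1)
  logPi0 <- matrix(-Inf, 5, 1)   # p = 1: zero-history class impossible
  for (s in 1:400) N <- updateLatentN(N, D, lambda, logPi0)$N
  expect_equal(N, D)
  # once at D it never leaves
  for (s in 1:100) N <- updateLatentN(N, D, lambda, logPi0)$N
  expect_equal(N, D)
})

test_that("the latent-count chain matches the enumerated conditional", {
  set.seed(73)
  Y1 <- c(2, 1, 0, 0); J <- 4; lambda <- 6; p <- 0.3
  D <- matrix(sum(Y1), 1, 1)
  logPi0 <- matrix(J * log(1 - p), 1, 1)
  lam <- matrix(lambda, 1, 1)
  N <- D + 1L
  draws <- integer(30000)
  for (s in seq_along(draws)) {
    N <- updateLatentN(N, D, lam, logPi0)$N
    draws[s] <- N[1, 1]
  }
  draws <- draws[-(1:2000)]
  oracle <- oracleLatentPosterior(Y1, lambda, p, J, nMax = 60)
  empCdf <- cumsum(tabulate(draws + 1L, 61)[oracle$n + 1L]) / length(draws)
  expect_lt(max(abs(empCdf - cumsum(oracle$pmf))), 0.02)
})

test_that("prior-only residual updates reproduce the multivariate normal", {
  set.seed(81)
  Sigma <- matrix(c(1, 0.8, 0.8, 1), 2)
  eps <- matrix(0, 4000, 2)
  for (s in 1:30)
    eps <- updateResiduals(eps, N = NULL, mu = NULL, Sigma,
                           useData = FALSE)$eps
  expect_equal(cor(eps[, 1], eps[, 2]), 0.8, tolerance = 0.03)
  expect_equal(sd(eps[, 1]), 1, tolerance = 0.05)
  # diagonal Sigma: species residuals uncorrelated
  eps2 <- matrix(0, 4000, 2)
  for (s in 1:30)
    eps2 <- updateResiduals(eps2, NULL, NULL, diag(2),
                            useData = FALSE)$eps
  expect_lt(abs(cor(eps2[, 1], eps2[, 2])), 0.05)
})

test_that("conditional mean of one residual given the other follows the bivariate normal", {
  # eps_1 | eps_2 = 1 with rho = 0.5, sigma1 = sigma2: mean 0.5
  set.seed(82)
  Sigma <- matrix(c(1, 0.5, 0.5, 1), 2)
  I <- 5000
  eps <- cbind(rep(0, I), rep(1, I))
  draws <- numeric(40)
  for (s in 1:40) {
    eps <- updateResiduals(eps, NULL, NULL, Sigma, useData = FALSE)$eps
    eps[, 2] <- 1                      # hold the conditioning value
    draws[s] <- mean(eps[, 1])
  }
  expect_equal(mean(draws[-(1:5)]), 0.5, tolerance = 0.02)
})

test_that("the covariance step is the conjugate inverse-Wishart draw", {
  set.seed(91)
  K <- 2; nu0 <- K + 1; S0 <- diag(K)
  # all-zero residuals: posterior is IW(nu0 + I, S0) with analytic mean
  I <- 40
  eps0 <- matrix(0, I, K)
  m <- Reduce(`+`, lapply(1:3000, function(s)
    updateCovariance(eps0, nu0, S0))) / 3000
  expect_equal(m, S0 / (nu0 + I - K - 1), tolerance = 0.02,
               ignore_attr = TRUE)
  # no data rows: a draw from the prior (finite mean needs nu0 > K + 1)
  nu0b <- K + 3
  mPrior <- Reduce(`+`, lapply(1:3000, function(s)
    updateCovariance(matrix(0, 0, K), nu0b, S0))) / 3000
  expect_equal(mPrior, S0 / (nu0b - K - 1), tolerance = 0.05,
               ignore_attr = TRUE)
  # concentration: residuals with empirical covariance pinned to a known
  # Sigma* at I = 2000; the posterior mean must sit within 10% of it
  SigStar <- matrix(c(1, -0.6, -0.6, 1.5), 2)
  epsBig <- MASS::mvrnorm(2000, c(0, 0), SigStar, empirical = TRUE)
  mBig <- Reduce(`+`, lapply(1:300, function(s)
    updateCovariance(epsBig, nu0, S0))) / 300
  expect_true(all(abs(mBig - SigStar) / pmax(abs(SigStar), 0.5) < 0.1))
  expect_error(updateCovariance(eps0, nu0 = 0.5, S0), "nu0")
})

test_that("zero proposal scales leave the coefficient chain at its state", {
  z <- makeTinyInstance()
  S <- apply(sweep(z$Y, 3, seq_len(z$J), "*"), c(1, 2), sum)
  set.seed(1)
  up <- updateCoefficients(z$beta, z$alpha, z$N, z$eps, S, z$X, z$W, z$J,
                           scalesBeta = c(0, 0), scalesAlpha = c(0, 0))
  expect_equal(up$beta, z$beta)
  expect_equal(up$alpha, z$alpha)
})

test_that("the full sampler is reproducible and recovers a single-species lognormal", {
  ds <- simulateCommunity(I = 300, K = 1, J = 4, beta = list(1.2),
                          alpha = list(0.5), Sigma = matrix(0.8, 1, 1),
                          seed = 101)
  ctrl <- mcmcControl(nChains = 2, nIter = 1500, burnin = 600, thin = 3,
                      seed = 9)
  post1 <- runCommunityMCMC(ds@freq, "SP01", control = ctrl)
  post2 <- runCommunityMCMC(ds@freq, "SP01", control = ctrl)
  expect_identical(sigmaDraws(post1), sigmaDraws(post2))
  expect_identical(betaDraws(post1), betaDraws(post2))
  # sigma^2 posterior concentrates near the generating value 0.8
  s2 <- sigmaDraws(post1)[1, 1, ]
  ci <- quantile(s2, c(0.025, 0.975))
  expect_gt(0.8, ci[1] - 0.25)
  expect_lt(0.8, ci[2] + 0.25)
  expect_lt(abs(mean(s2) - 0.8), 0.35)
  # intercept posteriors cover the truth loosely (3 posterior SDs)
  b <- betaDraws(post1)[["SP01"]][, 1]
  expect_lt(abs(mean(b) - 1.2), 3 * sd(b) + 0.1)
  a <- alphaDraws(post1)[["SP01"]][, 1]
  expect_lt(abs(mean(a) - 0.5), 3 * sd(a) + 0.1)
})

test_that("every stored covariance draw is positive definite", {
  ds <- simulateCommunity(I = 120, K = 2, J = 4, beta = list(0.8),
                          alpha = list(0),
                          Sigma = matrix(c(1, 0.5, 0.5, 1), 2), seed = 111)
  post <- runCommunityMCMC(ds@freq, speciesCodes(ds@freq),
                           control = mcmcControl(nChains = 2, nIter = 600,
                                                 burnin = 200, thin = 2,
                                                 seed = 5))
  S <- sigmaDraws(post)
  minEig <- apply(S, 3, function(m)
    min(eigen(m, symmetric = TRUE, only.values = TRUE)$values))
  expect_true(all(minEig > 0))
  expect_true(all(is.finite(S)))
})

test_that("relabelling species permutes the correlation summaries identically", {
  ds <- simulateCommunity(I = 150, K = 3, J = 4, beta = list(1.0),
                          alpha = list(0),
                          Sigma = diag(3) * 0.7 + 0.2, seed = 121)
  post <- runCommunityMCMC(ds@freq, speciesCodes(ds@freq),
                           control = mcmcControl(nChains = 2, nIter = 500,
                                                 burnin = 200, thin = 2,
                                                 seed = 7))
  perm <- c(3L, 1L, 2L)
  permuted <- new("CommunityPosterior",
                  species = post@species[perm],
                  beta = betaDraws(post)[perm],
                  alpha = alphaDraws(post)[perm],
                  Sigma = sigmaDraws(post)[perm, perm, , drop = FALSE],
                  chain = post@chain, diagnostics = post@diagnostics,
                  converged = post@converged, config = post@config)
  a <- summarizeCorrelations(post)
  b <- summarizeCorrelations(permuted)
  key <- function(d) paste(pmin(d$species_k, d$species_l),
                           pmax(d$species_k, d$species_l))
  b <- b[match(key(a), key(b)), ]
  expect_equal(a$mean, b$mean)
  expect_equal(a$significant, b$significant)
})

test_that("batch-means MCSE and interval summaries behave as advertised", {
  set.seed(131)
  x <- rnorm(10000, 0.5, 0.1)
  expect_equal(mcseBatchMeans(x), 0.001, tolerance = 0.35)
  # constant draws: zero MCSE, degenerate interval, flag by sign
  mkPost <- function(rhoDraws) {
    n <- length(rhoDraws)
    Sig <- array(0, c(2, 2, n))
    Sig[1, 1, ] <- 1; Sig[2, 2, ] <- 1
    Sig[1, 2, ] <- Sig[2, 1, ] <- rhoDraws
    new("CommunityPosterior", species = c("A", "B"),
        beta = list(A = matrix(0, n, 1), B = matrix(0, n, 1)),
        alpha = list(A = matrix(0, n, 1), B = matrix(0, n, 1)),
        Sigma = Sig, chain = rep(1L, n),
        diagnostics = data.frame(), converged = TRUE, config = list())
  }
  const <- summarizeCorrelations(mkPost(rep(0.4, 500)))
  expect_equal(const$mcse, 0)
  expect_equal(const$lower, 0.4)
  expect_equal(const$upper, 0.4)
  expect_true(const$significant)
  sym <- summarizeCorrelations(mkPost(seq(-0.5, 0.5, length.out = 1000)))
  expect_false(sym$significant)
})

test_that("split-Rhat flags disagreeing chains and passes identical ones", {
  set.seed(141)
  good <- cbind(rnorm(500), rnorm(500))
  expect_lt(splitRhat(good), 1.05)
  bad <- cbind(rnorm(500), rnorm(500) + 3)
  expect_gt(splitRhat(bad), 1.5)
})
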