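# Survey-level marginal likelihood and the Poisson-lognormal moment
# identities.

test_that("capture-history cell probabilities are binomial masses", {
  expect_equal(cellProbability(0.5, 4, 2), 0.375)       # 6/16
  expect_equal(cellProbability(0, 4, 1), 0)
  expect_equal(cellProbability(0.3, 4, 0), 0.7^4)       # 0.2401
  expect_equal(sum(cellProbability(0.37, 5, 0:5)), 1)
  expect_error(cellProbability(0.5, 4, 5), "j must")
  expect_error(cellProbability(1.2, 4, 1), "p must")
})

test_that("all-zero surveys have the Poisson-thinning closed form", {
  # P(no birds detected) = exp(-lambda * (1 - (1-p)^J))
  expect_equal(surveyLogLik(c(0, 0, 0, 0), lambda = 1, p = 0.5), -0.9375)
  expect_equal(surveyLogLik(rep(0, 3), lambda = 2.5, p = 0.2, J = 3),
               -2.5 * (1 - 0.8^3))
  # impossible data at lambda = 0
  expect_identical(surveyLogLik(c(1, 0, 0, 0), lambda = 0, p = 0.5), -Inf)
  expect_identical(surveyLogLik(c(0, 0, 0, 0), lambda = 0, p = 0.5), 0)
  expect_error(surveyLogLik(c(0.5, 0, 0, 0), 1, 0.5), "integers")
})

test_that("thinning route, truncated sum and enumeration oracle agree", {
  set.seed(11)
  for (r in 1:200) {
    J <- sample(1:5, 1)
    Y <- rpois(J, 0.8)
    lambda <- runif(1, 0, 8)
    p <- runif(1, 0.02, 0.98)
    thin <- surveyLogLik(Y, lambda, p, J)
    tsum <- surveyLogLik(Y, lambda, p, J, method = "sum")
    expect_equal(thin, tsum, tolerance = 1e-10)
    expect_equal(thin, oracleSurveyLogLik(Y, lambda, p, J),
                 tolerance = 1e-8)
  }
})

test_that("probabilities over bounded frequency vectors sum correctly", {
  # enumerate every Y in {0..6}^J with total <= 6; the probability mass
  # equals P(total detected <= 6), total detected ~ Poisson(lambda pdet)
  J <- 3; lambda <- 1.3; p <- 0.4
  grid <- expand.grid(rep(list(0:6), J))
  keep <- rowSums(grid) <= 6
  tot <- sum(apply(grid[keep, ], 1, function(y)
    exp(surveyLogLik(as.numeric(y), lambda, p, J))))
  pdet <- 1 - (1 - p)^J
  expect_equal(tot, ppois(6, lambda * pdet), tolerance = 1e-10)
})

test_that("Poisson-lognormal moment identities hold in closed form", {
  # no extra-Poisson variation: mean = variance = exp(mu), zero cov
  m0 <- marginalMoments(0.7, 0.7, 0, 0, 0.9)
  expect_equal(m0$mean_k, exp(0.7))
  expect_equal(m0$var_k, exp(0.7))
  expect_equal(m0$cov_kl, 0)
  # mu = 0, sigma2 = ln 2: tau = sqrt(2), var = sqrt(2) + 2
  m1 <- marginalMoments(0, 0, log(2), log(2), 1)
  expect_equal(m1$mean_k, sqrt(2))
  expect_equal(m1$var_k, sqrt(2) + 2, tolerance = 1e-12)
  expect_equal(m1$cov_kl, 2, tolerance = 1e-12)
  expect_error(marginalMoments(0, 0, -1, 1, 0), "non-negative")
  expect_error(marginalMoments(0, 0, 1, 1, 1.5), "rho")
})

test_that("moment formulas match direct Monte Carlo of the mixture", {
  set.seed(12)
  n <- 5e5
  s2 <- log(2)
  eps <- rnorm(n, 0, sqrt(s2))
  N <- rpois(n, exp(eps))
  m <- marginalMoments(0, 0, s2, s2, 1)
  expect_equal(mean(N), m$mean_k, tolerance = 0.02)
  expect_equal(var(N), m$var_k, tolerance = 0.05)
  # perfectly correlated residuals: cov = tau^2 (exp(s2) - 1) = 2
  N2 <- rpois(n, exp(eps))
  expect_equal(cov(N, N2), m$cov_kl, tolerance = 0.08)
})
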