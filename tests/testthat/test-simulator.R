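# The generative simulator: observed-layer thinning, determinism and
# fixture writing.

test_that("perfect detection exposes every individual", {
  ds <- simulateCommunity(I = 150, K = 2, J = 4, beta = list(1.0),
                          alpha = list(20), seed = 61)  # p ~ 1
  expect_equal(unname(totalDetections(ds@freq)), ds@truth$N)
  # all observed individuals detected in all J intervals
  expect_equal(sum(freqCounts(ds@freq)[, , 1:3]), 0L)
})

test_that("observed individuals per cell follow binomial thinning of N", {
  p <- plogis(-0.5)
  ds <- simulateCommunity(I = 4000, K = 1, J = 4, beta = list(1.0),
                          alpha = list(-0.5), seed = 62)
  pdet <- 1 - (1 - p)^4
  nTrue <- sum(ds@truth$N)
  nObs <- sum(totalDetections(ds@freq))
  se <- sqrt(nTrue * pdet * (1 - pdet))
  expect_lt(abs(nObs - nTrue * pdet), 4 * se)
  # and the frequency table agrees with recounting the records
  freq2 <- buildFrequencyTable(ds@records, ds@surveys,
                               speciesCodes(ds@freq), J = 4)
  expect_equal(unname(freqCounts(freq2)), unname(freqCounts(ds@freq)))
})

test_that("simulated abundances match the mixture moments at one design point", {
  mu <- 0.5; s2 <- 0.6; rho <- -0.5
  Sigma <- matrix(c(s2, rho * s2, rho * s2, s2), 2)
  ds <- simulateCommunity(I = 8000, K = 2, J = 4, beta = list(mu),
                          alpha = list(0), Sigma = Sigma, seed = 63)
  N <- ds@truth$N
  m <- marginalMoments(mu, mu, s2, s2, rho)
  seMean <- sd(N[, 1]) / sqrt(nrow(N))
  expect_lt(abs(mean(N[, 1]) - m$mean_k), 3 * seMean)
  v <- N[, 1] - mean(N[, 1])
  seVar <- sd(v^2) / sqrt(nrow(N))
  expect_lt(abs(var(N[, 1]) - m$var_k), 3 * seVar)
  cp <- (N[, 1] - mean(N[, 1])) * (N[, 2] - mean(N[, 2]))
  seCov <- sd(cp) / sqrt(nrow(N))
  expect_lt(abs(cov(N[, 1], N[, 2]) - m$cov_kl), 3 * seCov)
})

test_that("a fixed seed reproduces the dataset and its fixture files exactly", {
  ds1 <- simulateCommunity(I = 40, K = 2, J = 4, beta = list(0.7),
                           alpha = list(0), seed = 64)
  ds2 <- simulateCommunity(I = 40, K = 2, J = 4, beta = list(0.7),
                           alpha = list(0), seed = 64)
  expect_identical(ds1@truth$N, ds2@truth$N)
  expect_identical(ds1@records, ds2@records)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- writeFixture(ds1, d1); p2 <- writeFixture(ds2, d2)
  for (f in names(p1))
    expect_identical(readLines(p1[[f]]), readLines(p2[[f]]))
})

test_that("an empty community writes an observations file with header only", {
  ds <- simulateCommunity(I = 15, K = 1, J = 4, beta = list(-Inf),
                          alpha = list(0), seed = 65)
  expect_equal(sum(ds@truth$N), 0L)
  d <- withr::local_tempdir()
  p <- writeFixture(ds, d)
  expect_length(readLines(p[["observations"]]), 1L)
})

test_that("invalid covariance matrices are rejected", {
  badSym <- matrix(c(1, 0.5, 0.2, 1), 2)
  expect_error(simulateCommunity(I = 5, K = 2, beta = list(0),
                                 alpha = list(0), Sigma = badSym),
               "symmetric")
  badPD <- matrix(c(1, 2, 2, 1), 2)
  expect_error(simulateCommunity(I = 5, K = 2, beta = list(0),
                                 alpha = list(0), Sigma = badPD),
               "positive definite")
})

test_that("truth serialization is versioned and consistent with the dataset", {
  ds <- simulateCommunity(I = 12, K = 2, J = 4, beta = list(0.5),
                          alpha = list(0), seed = 66)
  d <- withr::local_tempdir()
  p <- writeFixture(ds, d)
  truth <- jsonlite::read_json(p[["truth"]], simplifyVector = TRUE)
  expect_equal(truth$format_version, 1L)
  expect_equal(truth$config$I, 12L)
  expect_equal(unname(as.matrix(truth$N)), unname(ds@truth$N))
})
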