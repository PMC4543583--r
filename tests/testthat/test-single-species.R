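# Single-species N-mixture fitting, BIC subset selection and the
# parametric-bootstrap overdispersion screen.

test_that("maximum likelihood recovers simulated abundance and detection", {
  # truth: log-lambda intercept 1.0, logit-p intercept 0.0, I = 500.
  # Monte Carlo SEs of the estimators at this design are ~0.022 (beta)
  # and ~0.025 (alpha); bounds are 3 SEs.
  ds <- simulateCommunity(I = 500, K = 1, J = 4, beta = list(1.0),
                          alpha = list(0.0), seed = 42)
  fit <- fitNMix(ds@freq, "SP01", seed = 1)
  expect_true(isConverged(fit))
  expect_lt(abs(fit@beta[["(Intercept)"]] - 1.0), 3 * 0.022)
  expect_lt(abs(fit@alpha[["(Intercept)"]] - 0.0), 3 * 0.025)
  expect_equal(BIC(fit), -2 * fit@logLik + 2 * log(500))
})

test_that("all-zero data drives lambda to the boundary and is flagged", {
  ds <- simulateCommunity(I = 50, K = 1, J = 4, beta = list(-30),
                          alpha = list(0), seed = 3)
  expect_equal(sum(freqCounts(ds@freq)), 0L)
  fit <- fitNMix(ds@freq, "SP01")
  expect_true(fit@boundary)
  expect_equal(fittedRates(fit)$lambda, rep(0, 50))
  expect_equal(fit@logLik, 0)
})

test_that("a fuller model never has lower maximized log-likelihood", {
  ds <- simulateCommunity(I = 300, K = 1, J = 4, beta = list(c(0.8, 0.5)),
                          alpha = list(0), abundanceTerms = "LPC1",
                          seed = 13)
  f0 <- fitNMix(ds@freq, "SP01")
  f1 <- fitNMix(ds@freq, "SP01", "LPC1")
  f2 <- fitNMix(ds@freq, "SP01", c("LPC1", "VPC1"), "day_of_year")
  expect_gte(f1@logLik, f0@logLik - 1e-8)
  expect_gte(f2@logLik, f1@logLik - 1e-8)
})

test_that("BIC follows its formula and is monotone in parameter count", {
  # -2(-10) + 2 ln(245)
  expect_equal(20 + 2 * log(245), 31.0021, tolerance = 1e-4)
  ds <- simulateCommunity(I = 245, K = 1, J = 4, beta = list(0.5),
                          alpha = list(0), seed = 17)
  f0 <- fitNMix(ds@freq, "SP01")
  expect_equal(f0@bic, -2 * f0@logLik + f0@nParams * log(245))
  # at fixed loglik and n, BIC increases with each extra parameter
  bicOf <- function(k) -2 * (-10) + k * log(245)
  expect_true(all(diff(bicOf(1:6)) > 0))
})

test_that("best-subset search finds a strong single covariate and respects parsimony", {
  pool <- c("LPC1", "LPC2", "VPC1", "VPC2")
  ds <- simulateCommunity(I = 500, K = 1, J = 4, beta = list(c(1.0, 0.8)),
                          alpha = list(0.3), abundanceTerms = "LPC1",
                          seed = 23)
  sel <- bicSelect(ds@freq, "SP01", pool, seed = 1)
  # the active covariate must be retained (exact-recovery frequency is a
  # separate consistency study over many replicates)
  expect_true("LPC1" %in% bestModel(sel)@abundanceTerms)
  tab <- selectionTable(sel)
  # 2^4 abundance subsets x 2^2 detection subsets
  expect_equal(nrow(tab), 16L * 4L)
  expect_equal(tab$bic, sort(tab$bic))
  # null data: intercept-only wins
  ds0 <- simulateCommunity(I = 500, K = 1, J = 4, beta = list(1.0),
                           alpha = list(0), seed = 29)
  sel0 <- bicSelect(ds0@freq, "SP01", pool, seed = 1)
  expect_length(bestModel(sel0)@abundanceTerms, 0L)
})

test_that("overdispersed counts are flagged and Poisson counts are not", {
  # lognormal overdispersion sigma2 = 1 at the study's survey count
  dsOver <- simulateCommunity(I = 245, K = 1, J = 4, beta = list(1.0),
                              alpha = list(0), Sigma = matrix(1, 1, 1),
                              seed = 37)
  fitO <- fitNMix(dsOver@freq, "SP01")
  gofO <- gofOverdispersion(fitO, nBoot = 200, seed = 5)
  expect_true(isOverdispersed(gofO))
  # pure Poisson data from the same design
  dsP <- simulateCommunity(I = 245, K = 1, J = 4, beta = list(1.0),
                           alpha = list(0), seed = 41)
  fitP <- fitNMix(dsP@freq, "SP01")
  gofP <- gofOverdispersion(fitP, nBoot = 200, seed = 5)
  expect_gt(pValue(gofP), 0.05)
  expect_warning(gofOverdispersion(fitP, nBoot = 50, seed = 1), "nBoot")
})

test_that("degenerate statistic distributions give p-value 1", {
  # all-zero data: statistic is identically zero observed and simulated
  ds <- simulateCommunity(I = 60, K = 1, J = 4, beta = list(-30),
                          alpha = list(0), seed = 3)
  fit <- fitNMix(ds@freq, "SP01")
  gof <- gofOverdispersion(fit, nBoot = 100, seed = 1)
  expect_equal(pValue(gof), 1)
  expect_false(isOverdispersed(gof))
})

test_that("requesting unknown species or covariates fails clearly", {
  ds <- simulateCommunity(I = 20, K = 1, J = 4, beta = list(0.5),
                          alpha = list(0), seed = 2)
  expect_error(fitNMix(ds@freq, "NOPE"), "not present")
  expect_error(fitNMix(ds@freq, "SP01", "NOT_A_COVARIATE"), "not found")
})
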