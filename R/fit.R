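## Design construction shared by the ML and MCMC fitters. time_block is
## a single selectable unit expanding to two indicators (middle, late;
## early is the reference); day_of_year is centred and scaled to unit
## variance for sampler/optimizer conditioning.
.designMatrix <- function(surveys, terms) {
  I <- nrow(surveys)
  X <- matrix(1, I, 1L, dimnames = list(NULL, "(Intercept)"))
  for (tm in terms) {
    if (tm == "time_block") {
      tb <- surveys$time_block
      if (is.null(tb)) stop("surveys table has no 'time_block' column")
      tb <- factor(tb, levels = c("early", "middle", "late"))
      X <- cbind(X, time_block_middle = as.numeric(tb == "middle"),
                 time_block_late = as.numeric(tb == "late"))
    } else if (tm == "day_of_year") {
      d <- surveys$day_of_year
      if (is.null(d)) stop("surveys table has no 'day_of_year' column")
      s <- stats::sd(d)
      X <- cbind(X, day_of_year = if (s > 0) (d - mean(d)) / s else d * 0)
    } else {
      v <- surveys[[tm]]
      if (is.null(v))
        stop("covariate '", tm, "' not found in the surveys table")
      if (!is.numeric(v))
        stop("covariate '", tm, "' must be numeric")
      X <- cbind(X, stats::setNames(data.frame(v), tm)[[1L]])
      colnames(X)[ncol(X)] <- tm
    }
  }
  if (qr(X)$rank < ncol(X))
    stop("design matrix is rank deficient for terms: ",
         paste(terms, collapse = ", "))
  X
}

## Negative log-likelihood and analytic gradient of the marginal
## Poisson-product likelihood over all surveys of one species.
## The likelihood collapses onto per-survey sufficient statistics:
## D_i (individuals detected) and S_i (total detection events), since
## sum_j pi_ij = 1 - (1-p)^J and sum_j j pi_ij = J p. This keeps every
## evaluation O(I) with no I x J temporaries.
.nmixObjective <- function(Y, X, W, J) {
  jSeq <- seq_len(J)
  D <- rowSums(Y)
  S <- drop(Y %*% jSeq)
  constY <- sum(Y %*% lchoose(J, jSeq)) - sum(lgamma(Y + 1))
  pA <- ncol(X)
  pD <- ncol(W)
  pieces <- function(theta) {
    eta <- drop(X %*% theta[seq_len(pA)])
    lambda <- exp(eta)
    p <- stats::plogis(drop(W %*% theta[pA + seq_len(pD)]))
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    q <- (1 - p)^J
    list(eta = eta, lambda = lambda, p = p, q = q)
  }
  nll <- function(theta) {
    pc <- pieces(theta)
    -(sum(D * pc$eta) + constY +
        sum(S * log(pc$p) + (J * D - S) * log1p(-pc$p)) -
        sum(pc$lambda * (1 - pc$q)))
  }
  grad <- function(theta) {
    pc <- pieces(theta)
    gBeta <- -drop(crossprod(X, D - pc$lambda * (1 - pc$q)))
    gAlpha <- -drop(crossprod(W, S - J * pc$p * D -
                                pc$lambda * J * pc$p * pc$q))
    c(gBeta, gAlpha)
  }
  list(nll = nll, grad = grad, pA = pA, pD = pD)
}

.newNMixFit <- function(species, abundanceTerms, detectionTerms, beta, alpha,
                        logLik, nSurveys, converged, boundary, gradNorm,
                        X, W, Y) {
  nParams <- length(beta) + length(alpha)
  new("NMixFit", species = species,
      abundanceTerms = as.character(abundanceTerms),
      detectionTerms = as.character(detectionTerms),
      beta = stats::setNames(beta, colnames(X)),
      alpha = stats::setNames(alpha, colnames(W)),
      logLik = logLik, nParams = as.integer(nParams),
      nSurveys = as.integer(nSurveys),
      bic = -2 * logLik + nParams * log(nSurveys),
      converged = converged, boundary = boundary, gradNorm = gradNorm,
      X = X, W = W, Y = Y)
}

#' Fit a single-species Poisson N-mixture model by maximum likelihood
#'
#' Maximizes the marginal likelihood of one species' detection
#' frequencies over all surveys, with a log-linear model for expected
#' abundance and a logit-linear model for the per-interval detection
#' probability. The marginal likelihood is the product over surveys of
#' independent Poisson cells (the Poisson-thinning factorization of the
#' latent-abundance mixture), maximized by quasi-Newton iteration with
#' analytic gradients from a moment-based start plus random restarts.
#'
#' @param freq a \linkS4class{DetectionFrequency}.
#' @param species species code to fit (must be in
#'   \code{speciesCodes(freq)}).
#' @param abundanceTerms character vector of covariate names (columns of
#'   \code{surveyData(freq)}) entering the log-abundance predictor;
#'   empty for intercept only.
#' @param detectionTerms subset of \code{c("day_of_year", "time_block")}
#'   (or other numeric survey columns) entering the logit-detection
#'   predictor.
#' @param nStarts number of optimizer starts (1 deterministic
#'   moment-based start plus \code{nStarts - 1} random perturbations).
#' @param start optional full start vector (overrides the moment start).
#' @param seed optional seed for the random restarts.
#' @return an \linkS4class{NMixFit}.
#' @export
fitNMix <- function(freq, species, abundanceTerms = character(0),
                    detectionTerms = character(0), nStarts = 5,
                    start = NULL, seed = NULL) {
  stopifnot(is(freq, "DetectionFrequency"))
  k <- match(species, speciesCodes(freq))
  if (is.na(k)) stop("species '", species, "' not present in the data")
  Y <- freqCounts(freq)[, k, , drop = TRUE]
  if (is.null(dim(Y))) Y <- matrix(Y, nrow = nSurveys(freq))
  J <- nIntervals(freq)
  surveys <- surveyData(freq)
  X <- .designMatrix(surveys, abundanceTerms)
  W <- .designMatrix(surveys, detectionTerms)
  I <- nrow(Y)

  if (sum(Y) == 0) {
    ## likelihood is maximized in the limit lambda -> 0; sup logLik = 0
    beta <- c(-Inf, rep(0, ncol(X) - 1L))
    alpha <- rep(0, ncol(W))
    return(.newNMixFit(species, abundanceTerms, detectionTerms, beta, alpha,
                       logLik = 0, nSurveys = I, converged = TRUE,
                       boundary = TRUE, gradNorm = 0, X = X, W = W, Y = Y))
  }

  obj <- .nmixObjective(Y, X, W, J)
  D <- rowSums(Y)
  p0 <- 0.3
  lam0 <- mean(D) / (1 - (1 - p0)^J)
  momentStart <- c(log(lam0 + 1e-3), rep(0, obj$pA - 1L),
                   stats::qlogis(p0), rep(0, obj$pD - 1L))
  if (!is.null(start)) momentStart <- start

  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  starts <- c(list(momentStart),
              lapply(seq_len(max(0L, nStarts - 1L)), function(s)
                momentStart + stats::rnorm(length(momentStart), 0, 0.5)))

  best <- NULL
  for (st in starts) {
    opt <- try(stats::optim(st, obj$nll, obj$grad, method = "BFGS",
                            control = list(maxit = 1000, reltol = 1e-14)),
               silent = TRUE)
    if (inherits(opt, "try-error")) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best))
    stop("all optimizer starts failed for species '", species, "'")

  gradNorm <- max(abs(obj$grad(best$par)))
  converged <- best$convergence == 0 &&
    gradNorm < 1e-6 * max(1, abs(best$value))
  beta <- best$par[seq_len(obj$pA)]
  boundary <- beta[1L] < -20   # lambda at intercept effectively zero
  .newNMixFit(species, abundanceTerms, detectionTerms,
              beta, best$par[obj$pA + seq_len(obj$pD)],
              logLik = -best$value, nSurveys = I, converged = converged,
              boundary = boundary, gradNorm = gradNorm, X = X, W = W, Y = Y)
}

#' Fitted abundance and detection for an N-mixture fit
#'
#' @param fit an \linkS4class{NMixFit}.
#' @return list with per-survey \code{lambda} (expected abundance) and
#'   \code{p} (per-interval detection probability).
#' @export
fittedRates <- function(fit) {
  stopifnot(is(fit, "NMixFit"))
  list(lambda = exp(drop(fit@X %*% fit@beta)),
       p = stats::plogis(drop(fit@W %*% fit@alpha)))
}

.termLabel <- function(terms)
  if (length(terms)) paste(sort(terms), collapse = "+") else "1"

.powerset <- function(items) {
  out <- list(character(0))
  for (it in items) out <- c(out, lapply(out, c, it))
  out
}

#' Best-subset covariate selection by BIC
#'
#' Exhaustively fits every subset of the candidate abundance terms
#' crossed with every subset of the candidate detection terms (the
#' \code{time_block} indicator pair is selected as one unit) and returns
#' the model minimizing BIC, with ties broken by fewer parameters and
#' then by lexicographic term order. Candidates whose optimizer fails to
#' converge are excluded from the comparison and reported. Search fits
#' use a single warm start from the intercept-only fit; the winning
#' model is refit with the full multi-start protocol.
#'
#' @inheritParams fitNMix
#' @param candidateAbundanceTerms character vector of candidate
#'   abundance covariates (e.g. the eight PC scores).
#' @param candidateDetectionTerms candidate detection covariates.
#' @param nStartsFinal starts for the refit of the selected model.
#' @return an \linkS4class{NMixSelection}.
#' @export
bicSelect <- function(freq, species,
                      candidateAbundanceTerms,
                      candidateDetectionTerms = c("day_of_year", "time_block"),
                      nStartsFinal = 5, seed = NULL) {
  aSets <- .powerset(candidateAbundanceTerms)
  dSets <- .powerset(candidateDetectionTerms)
  k <- match(species, speciesCodes(freq))
  if (is.na(k)) stop("species '", species, "' not present in the data")
  Y <- freqCounts(freq)[, k, , drop = TRUE]
  if (is.null(dim(Y))) Y <- matrix(Y, nrow = nSurveys(freq))
  J <- nIntervals(freq)
  surveys <- surveyData(freq)
  I <- nrow(Y)
  allZero <- sum(Y) == 0
  ## shared design columns, built once; submodels subset columns
  Xfull <- .designMatrix(surveys, candidateAbundanceTerms)
  rows <- vector("list", length(aSets) * length(dSets))
  aLab <- character(length(rows)); dLab <- character(length(rows))
  aList <- vector("list", length(rows)); dList <- vector("list", length(rows))
  ri <- 0L
  for (dT in dSets) {
    Wsub <- .designMatrix(surveys, dT)
    ## anchor fit: all candidate abundance terms with this detection set;
    ## submodels warm-start from its coefficients restricted to their terms
    objFull <- .nmixObjective(Y, Xfull, Wsub, J)
    stFull <- c(log(mean(rowSums(Y)) / (1 - 0.7^J) + 1e-3),
                rep(0, ncol(Xfull) - 1L), rep(0, ncol(Wsub)))
    fullPar <- if (allZero) stFull else
      stats::optim(stFull, objFull$nll, objFull$grad, method = "BFGS",
                   control = list(maxit = 1000, reltol = 1e-12))$par
    fB <- stats::setNames(fullPar[seq_len(ncol(Xfull))], colnames(Xfull))
    fA <- fullPar[ncol(Xfull) + seq_len(ncol(Wsub))]
    if (!all(is.finite(fB))) fB[!is.finite(fB)] <- -2
    for (aT in aSets) {
      ri <- ri + 1L
      aLab[ri] <- .termLabel(aT); dLab[ri] <- .termLabel(dT)
      aList[[ri]] <- aT; dList[[ri]] <- dT
      lab <- paste0("N~", aLab[ri], " | p~", dLab[ri])
      Xsub <- Xfull[, c("(Intercept)", aT), drop = FALSE]
      nPar <- ncol(Xsub) + ncol(Wsub)
      if (allZero) {
        rows[[ri]] <- data.frame(
          model = lab, abundance = aLab[ri], detection = dLab[ri],
          nParams = nPar, logLik = 0, bic = nPar * log(I),
          converged = TRUE, stringsAsFactors = FALSE)
        next
      }
      obj <- .nmixObjective(Y, Xsub, Wsub, J)
      st <- c(fB[c("(Intercept)", aT)], fA)
      opt <- stats::optim(st, obj$nll, obj$grad, method = "BFGS",
                          control = list(maxit = 1000, reltol = 1e-12))
      conv <- opt$convergence == 0 &&
        max(abs(obj$grad(opt$par))) < 1e-6 * max(1, abs(opt$value))
      rows[[ri]] <- data.frame(
        model = lab, abundance = aLab[ri], detection = dLab[ri],
        nParams = nPar, logLik = -opt$value,
        bic = 2 * opt$value + nPar * log(I),
        converged = conv, stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  excluded <- tab$model[!tab$converged]
  if (all(!tab$converged))
    stop("no candidate model converged for species '", species, "'")
  keep <- which(tab$converged)
  ord <- keep[order(tab$bic[keep], tab$nParams[keep], tab$model[keep])]
  bestIdx <- ord[1L]
  ## refit the winner through the full multi-start protocol
  bestFit <- fitNMix(freq, species, aList[[bestIdx]], dList[[bestIdx]],
                     nStarts = nStartsFinal, seed = seed)
  tab <- tab[order(tab$bic, tab$nParams, tab$model), , drop = FALSE]
  new("NMixSelection", best = bestFit, table = tab, excluded = excluded)
}

## Pearson fit statistic: pooled frequency cells (j = 1..J summed over
## surveys) plus counts of surveys by total detections (0, 1, 2, 3+),
## with expectations from the fitted marginal Poisson model.
.gofStatistic <- function(Y, lambda, p, J) {
  jSeq <- seq_len(J)
  Pi <- vapply(jSeq, function(j) stats::dbinom(j, J, p),
               numeric(length(p)))
  Pi <- matrix(Pi, length(p), J)
  M <- lambda * Pi
  oCell <- colSums(Y)
  eCell <- colSums(M)
  rate <- lambda * (1 - (1 - p)^J)      # Poisson rate of total detections
  D <- rowSums(Y)
  oTot <- c(sum(D == 0), sum(D == 1), sum(D == 2), sum(D >= 3))
  eTot <- c(sum(stats::dpois(0, rate)), sum(stats::dpois(1, rate)),
            sum(stats::dpois(2, rate)), sum(1 - stats::ppois(2, rate)))
  O <- c(oCell, oTot)
  E <- c(eCell, eTot)
  keep <- E > 1e-10
  sum((O[keep] - E[keep])^2 / E[keep])
}

#' Parametric-bootstrap screen for overdispersion
#'
#' Goodness-of-fit test of a fitted single-species Poisson N-mixture
#' model. The fit statistic is a Pearson chi-square comparing observed
#' and expected counts in the pooled detection-frequency cells
#' (j = 1..J) and in the survey-total categories (0, 1, 2, 3+ birds
#' detected). Its null distribution is obtained by simulating
#' \code{nBoot} datasets from the fitted model, refitting, and
#' recomputing the statistic; the p-value is the upper-tail bootstrap
#' probability \code{(1 + #(T* >= T)) / (1 + nBoot)}. A small p-value
#' indicates extra-Poisson variation, the trigger for advancing a
#' species to the multispecies model.
#'
#' @param fit a converged \linkS4class{NMixFit}.
#' @param nBoot number of bootstrap replicates (warned below 100).
#' @param seed RNG seed for the bootstrap.
#' @param level significance level for the overdispersion flag.
#' @param refit refit the model to each replicate (default TRUE; FALSE
#'   gives a conservative test using the original estimates).
#' @return an \linkS4class{NMixGOF}.
#' @export
gofOverdispersion <- function(fit, nBoot = 200, seed = NULL, level = 0.05,
                              refit = TRUE) {
  stopifnot(is(fit, "NMixFit"))
  if (!fit@converged) stop("goodness of fit requires a converged fit")
  if (nBoot < 100) warning("nBoot < 100 gives a coarse bootstrap p-value")
  if (!is.null(seed)) set.seed(seed)
  J <- ncol(fit@Y)
  rates <- fittedRates(fit)
  lambda <- rates$lambda
  p <- rates$p
  jSeq <- seq_len(J)
  Pi <- matrix(vapply(jSeq, function(j) stats::dbinom(j, J, p),
                      numeric(length(p))), length(p), J)
  M <- lambda * Pi
  obs <- .gofStatistic(fit@Y, lambda, p, J)
  parHat <- c(fit@beta, fit@alpha)
  statNull <- vapply(seq_len(nBoot), function(b) {
    Yb <- matrix(stats::rpois(length(M), M), nrow(M), ncol(M))
    if (refit) {
      fb <- .refitTo(fit, Yb, parHat)
      rb <- list(lambda = exp(drop(fit@X %*% fb$beta)),
                 p = stats::plogis(drop(fit@W %*% fb$alpha)))
      .gofStatistic(Yb, rb$lambda, rb$p, J)
    } else {
      .gofStatistic(Yb, lambda, p, J)
    }
  }, numeric(1))
  pv <- (1 + sum(statNull >= obs)) / (1 + nBoot)
  new("NMixGOF", statObserved = obs, statNull = statNull, pValue = pv,
      overdispersed = pv < level, level = level)
}

## fast refit used inside the bootstrap: warm start at the original MLE
.refitTo <- function(fit, Yb, parHat) {
  if (sum(Yb) == 0)
    return(list(beta = c(-Inf, rep(0, ncol(fit@X) - 1L)),
                alpha = rep(0, ncol(fit@W))))
  obj <- .nmixObjective(Yb, fit@X, fit@W, ncol(Yb))
  st <- parHat
  if (!all(is.finite(st))) st[!is.finite(st)] <- -2
  opt <- stats::optim(st, obj$nll, obj$grad, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  list(beta = opt$par[seq_len(obj$pA)],
       alpha = opt$par[obj$pA + seq_len(obj$pD)])
}
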