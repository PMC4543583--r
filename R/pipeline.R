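#' Configuration for the two-step analysis pipeline
#'
#' Bundles everything reproducibility-relevant: data sources, covariate
#' construction, the GOF screen, the sparse-species rule and the MCMC
#' settings. Supply either the file paths of the survey data layout or
#' a \linkS4class{SyntheticDataset}.
#'
#' @param observationsPath,habitatPath,speciesPath,surveysPath data file
#'   paths (see \code{\link{readSurveyFiles}}).
#' @param dataset optional \linkS4class{SyntheticDataset} used directly
#'   instead of files.
#' @param J intervals per survey.
#' @param landscapeCols,vegetationCols habitat measurement columns to
#'   summarize by PCA; when NULL, numeric habitat columns are used as
#'   abundance covariates directly (the simulator already emits
#'   PC-like scores).
#' @param nLandscapePC,nVegetationPC retained components.
#' @param candidateDetectionTerms detection covariate pool.
#' @param gofNBoot,gofLevel bootstrap size and level of the
#'   overdispersion screen.
#' @param sparseMaxPerSurvey,sparseMinPropSurveys the sparse-species
#'   rule: an overdispersed species is unfittable when its maximum
#'   per-survey count is <= \code{sparseMaxPerSurvey} and it was
#'   detected in fewer than \code{sparseMinPropSurveys} of surveys.
#' @param mcmc an \code{\link{mcmcControl}} list for the joint fit.
#' @param seed master seed for selection refits and the GOF bootstrap.
#' @return a named list.
#' @export
pipelineConfig <- function(observationsPath = NULL, habitatPath = NULL,
                           speciesPath = NULL, surveysPath = NULL,
                           dataset = NULL, J = 4,
                           landscapeCols = NULL, vegetationCols = NULL,
                           nLandscapePC = 2, nVegetationPC = 6,
                           candidateDetectionTerms = c("day_of_year",
                                                       "time_block"),
                           gofNBoot = 200, gofLevel = 0.05,
                           sparseMaxPerSurvey = 1,
                           sparseMinPropSurveys = 0.05,
                           mcmc = mcmcControl(), seed = 1) {
  list(observationsPath = observationsPath, habitatPath = habitatPath,
       speciesPath = speciesPath, surveysPath = surveysPath,
       dataset = dataset, J = J, landscapeCols = landscapeCols,
       vegetationCols = vegetationCols, nLandscapePC = nLandscapePC,
       nVegetationPC = nVegetationPC,
       candidateDetectionTerms = candidateDetectionTerms,
       gofNBoot = gofNBoot, gofLevel = gofLevel,
       sparseMaxPerSurvey = sparseMaxPerSurvey,
       sparseMinPropSurveys = sparseMinPropSurveys,
       mcmc = mcmc, seed = seed)
}

## sparse-species rule: overdispersed but effectively unfittable — never
## more than maxPerSurvey individuals in any survey and detected in
## fewer than minPropSurveys of surveys
.sparseRule <- function(dsp, maxPerSurvey, minPropSurveys) {
  max(dsp) <= maxPerSurvey && mean(dsp > 0) < minPropSurveys
}

.configHash <- function(x) {
  x$dataset <- NULL
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}

#' Run the two-step community analysis pipeline
#'
#' Executes the full procedure: (1) ingest the survey data and build
#' PCA-based abundance covariates; (2) per species, best-subset BIC
#' selection of a single-species Poisson N-mixture model followed by
#' the parametric-bootstrap overdispersion screen; (3) species that are
#' overdispersed and not sparse (see the sparse rule in
#' \code{\link{pipelineConfig}}) enter one joint multispecies
#' Poisson-lognormal fit, carrying their selected covariates; (4) a
#' report with per-species dispositions and the posterior correlation
#' table is assembled. When no species is overdispersed the report
#' completes with an empty correlation table, since the multispecies
#' model cannot be fitted to counts that lack overdispersion.
#'
#' @param config a list from \code{\link{pipelineConfig}}.
#' @return a \linkS4class{PipelineReport}.
#' @export
runPipeline <- function(config) {
  ## --- step 0: validate inputs before any compute
  if (is.null(config$dataset)) {
    paths <- c(config$observationsPath, config$habitatPath,
               config$speciesPath)
    if (length(paths) < 3 || any(!vapply(paths, file.exists, logical(1))))
      stop("pipeline config error: data paths missing or nonexistent")
  }

  ## --- step 1: ingest + covariate construction
  if (!is.null(config$dataset)) {
    ds <- config$dataset
    stopifnot(is(ds, "SyntheticDataset"))
    freq <- ds@freq
  } else {
    raw <- readSurveyFiles(config$observationsPath, config$habitatPath,
                           config$speciesPath, config$surveysPath)
    surveys <- raw$surveys
    if (!is.null(config$landscapeCols)) {
      lp <- pcaScores(surveys[, config$landscapeCols, drop = FALSE],
                      config$nLandscapePC)
      sc <- pcScores(lp)
      colnames(sc) <- paste0("LPC", seq_len(ncol(sc)))
      surveys <- cbind(surveys, sc)
    }
    if (!is.null(config$vegetationCols)) {
      vp <- pcaScores(surveys[, config$vegetationCols, drop = FALSE],
                      config$nVegetationPC)
      sc <- pcScores(vp)
      colnames(sc) <- paste0("VPC", seq_len(ncol(sc)))
      surveys <- cbind(surveys, sc)
    }
    freq <- buildFrequencyTable(raw$records, surveys,
                                raw$species$species_code, config$J)
  }
  surveys <- surveyData(freq)
  candA <- intersect(c("LPC1", "LPC2", paste0("VPC", 1:6)),
                     names(surveys))
  if (!length(candA))
    candA <- setdiff(names(surveys)[vapply(surveys, is.numeric,
                                           logical(1))],
                     c("survey_id", "day_of_year"))
  candD <- intersect(config$candidateDetectionTerms, names(surveys))

  ## --- step 2: per-species selection + overdispersion screen
  species <- speciesCodes(freq)
  D <- totalDetections(freq)
  rows <- list(); selections <- list(); gofs <- list()
  for (sp in species) {
    sel <- bicSelect(freq, sp, candA, candD, seed = config$seed)
    fit <- bestModel(sel)
    gof <- gofOverdispersion(fit, nBoot = config$gofNBoot,
                             seed = config$seed + match(sp, species),
                             level = config$gofLevel)
    dsp <- D[, sp]
    sparse <- .sparseRule(dsp, config$sparseMaxPerSurvey,
                          config$sparseMinPropSurveys)
    disposition <- if (!isOverdispersed(gof)) "single_adequate"
                   else if (sparse) "unfittable_sparse"
                   else "multispecies"
    rows[[sp]] <- data.frame(
      species = sp, disposition = disposition,
      abundance_terms = .termLabel(fit@abundanceTerms),
      detection_terms = .termLabel(fit@detectionTerms),
      bic = fit@bic, gof_p = pValue(gof),
      max_per_survey = max(dsp), prop_surveys_detected = mean(dsp > 0),
      stringsAsFactors = FALSE)
    selections[[sp]] <- sel; gofs[[sp]] <- gof
  }
  dispositions <- do.call(rbind, rows)
  rownames(dispositions) <- NULL

  ## --- step 3: one joint multispecies fit for the advancing set
  advance <- dispositions$species[dispositions$disposition ==
                                    "multispecies"]
  posterior <- NULL
  correlations <- data.frame()
  note <- NULL
  if (length(advance)) {
    aTerms <- lapply(selections[advance], function(s) {
      tm <- bestModel(s)@abundanceTerms
      tm
    })
    dTerms <- lapply(selections[advance], function(s)
      bestModel(s)@detectionTerms)
    names(aTerms) <- names(dTerms) <- advance
    posterior <- runCommunityMCMC(freq, advance, aTerms, dTerms,
                                  control = config$mcmc)
    correlations <- summarizeCorrelations(posterior)
  } else {
    note <- paste("no species advanced: the multispecies N-mixture model",
                  "cannot be fitted to counts that lack overdispersion")
  }

  metadata <- list(seed = config$seed,
                   config_hash = .configHash(config),
                   package_version = as.character(
                     utils::packageVersion("commNmix")),
                   n_surveys = nSurveys(freq),
                   n_species = length(species),
                   advanced = advance, note = note)
  report <- new("PipelineReport", dispositions = dispositions,
                correlations = correlations, posterior = posterior,
                metadata = metadata)
  report@metadata$report_hash <- reportHash(report)
  report
}

#' Deterministic hash of a pipeline report's tabular content
#'
#' MD5 over the serialized dispositions and correlation tables; equal
#' configs and seeds yield equal hashes.
#'
#' @param report a \linkS4class{PipelineReport}.
#' @return character MD5 hash.
#' @export
reportHash <- function(report) {
  stopifnot(is(report, "PipelineReport"))
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(list(report@dispositions, report@correlations), f,
          version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}

#' Format a correlation summary as a lower-triangle table
#'
#' Publication-shaped view of \code{\link{summarizeCorrelations}}
#' output: species x species lower triangle with the posterior mean
#' correlation (an asterisk marks intervals excluding zero) over the
#' Monte Carlo standard error in parentheses.
#'
#' @param correlations data.frame from
#'   \code{\link{summarizeCorrelations}}.
#' @return character matrix (empty for fewer than two species).
#' @export
formatCorrelationTable <- function(correlations) {
  if (!nrow(correlations)) return(matrix(character(0), 0, 0))
  sp <- unique(c(correlations$species_k, correlations$species_l))
  K <- length(sp)
  out <- matrix("", K, K, dimnames = list(sp, sp))
  for (r in seq_len(nrow(correlations))) {
    k <- match(correlations$species_k[r], sp)
    l <- match(correlations$species_l[r], sp)
    lo <- max(k, l); hi <- min(k, l)
    out[lo, hi] <- sprintf("%.2f%s (%.3f)", correlations$mean[r],
                           if (correlations$significant[r]) "*" else "",
                           correlations$mcse[r])
  }
  out
}

#' Write a pipeline report to disk
#'
#' Emits \code{dispositions.csv}, \code{correlations.csv}, the
#' formatted lower-triangle \code{correlation_table.csv} and a
#' \code{report.json} with the run metadata.
#'
#' @param report a \linkS4class{PipelineReport}.
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
writePipelineReport <- function(report, dir) {
  stopifnot(is(report, "PipelineReport"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(report@dispositions,
                   file.path(dir, "dispositions.csv"), row.names = FALSE)
  utils::write.csv(report@correlations,
                   file.path(dir, "correlations.csv"), row.names = FALSE)
  ft <- formatCorrelationTable(report@correlations)
  if (length(ft))
    utils::write.csv(as.data.frame(ft),
                     file.path(dir, "correlation_table.csv"))
  jsonlite::write_json(report@metadata, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
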