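#' Column schema for the three survey data files
#'
#' The survey data layout is three comma-delimited files with header
#' rows — individual observations, per-location habitat measurements,
#' and the species code list — whose exact column names vary between
#' datasets; this mapping names them once so every reader agrees.
#'
#' @param location,date,time,species column names in the observations
#'   file (\code{time} is optional when a surveys file provides
#'   \code{time_block}).
#' @param intervals column names of the per-interval detection
#'   indicators, in interval order.
#' @param speciesCode species-code column in the species file.
#' @param habitatLocation location column in the habitat file.
#' @return a named list.
#' @export
surveySchema <- function(location = "location", date = "date",
                         time = "time", species = "species",
                         intervals = paste0("int", 1:4),
                         speciesCode = "species_code",
                         habitatLocation = "location") {
  list(location = location, date = date, time = time, species = species,
       intervals = intervals, speciesCode = speciesCode,
       habitatLocation = habitatLocation)
}

.requireColumns <- function(df, cols, file) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop("schema error: missing column(s) ",
         paste(sQuote(missing), collapse = ", "), " in ", file, " file")
}

#' Read the three-file community survey layout
#'
#' Reads the observations, habitat and species files, checks them
#' against the column schema, and returns individual capture records
#' together with a survey table (one row per location x date) carrying
#' day-of-year, time-of-day block and the per-location habitat
#' measurements. Observation rows whose interval indicators are missing
#' belong to surveys conducted before interval-level recording; those
#' surveys are retained but flagged unusable for the capture-history
#' likelihood.
#'
#' @param observationsPath,habitatPath,speciesPath CSV file paths.
#' @param surveysPath optional CSV of survey-level metadata (location,
#'   date, day_of_year, time_block); needed to represent surveys with
#'   zero detections. When absent, surveys are derived from the
#'   observations.
#' @param schema a list from \code{\link{surveySchema}}.
#' @return list with \code{records} (one row per individual, with
#'   survey_id and intN history columns), \code{surveys},
#'   \code{species}, \code{habitat}, and \code{unusableSurveys}
#'   (survey_ids lacking interval histories).
#' @export
readSurveyFiles <- function(observationsPath, habitatPath, speciesPath,
                            surveysPath = NULL, schema = surveySchema()) {
  for (p in c(observationsPath, habitatPath, speciesPath))
    if (!file.exists(p)) stop("file not found: ", p)
  obs <- utils::read.csv(observationsPath, stringsAsFactors = FALSE)
  hab <- utils::read.csv(habitatPath, stringsAsFactors = FALSE)
  spp <- utils::read.csv(speciesPath, stringsAsFactors = FALSE)
  .requireColumns(obs, c(schema$location, schema$date, schema$species,
                         schema$intervals), "observations")
  .requireColumns(hab, schema$habitatLocation, "habitat")
  .requireColumns(spp, schema$speciesCode, "species")

  codes <- spp[[schema$speciesCode]]
  bad <- setdiff(unique(obs[[schema$species]]), codes)
  if (length(bad))
    stop("referential-integrity error: species code(s) ",
         paste(sQuote(bad), collapse = ", "),
         " absent from the species table")

  if (!is.null(surveysPath)) {
    sv <- utils::read.csv(surveysPath, stringsAsFactors = FALSE)
    .requireColumns(sv, c("location", "date"), "surveys")
  } else {
    sv <- unique(data.frame(location = obs[[schema$location]],
                            date = obs[[schema$date]],
                            stringsAsFactors = FALSE))
    sv <- sv[order(sv$location, sv$date), , drop = FALSE]
  }
  sv$survey_id <- seq_len(nrow(sv))
  if (is.null(sv$day_of_year))
    sv$day_of_year <- as.integer(strftime(as.Date(sv$date), "%j"))
  if (is.null(sv$time_block) && schema$time %in% names(obs)) {
    tm <- obs[!duplicated(paste(obs[[schema$location]], obs[[schema$date]])),
              c(schema$location, schema$date, schema$time)]
    key <- paste(sv$location, sv$date)
    sv$time_block <- as.character(
      timeBlock(tm[[schema$time]][match(key, paste(tm[[schema$location]],
                                                   tm[[schema$date]]))]))
  }

  ## join habitat covariates onto surveys by location
  habIdx <- match(sv$location, hab[[schema$habitatLocation]])
  if (anyNA(habIdx))
    stop("referential-integrity error: location(s) ",
         paste(sQuote(unique(sv$location[is.na(habIdx)])), collapse = ", "),
         " absent from the habitat table")
  habCovs <- hab[habIdx, setdiff(names(hab), schema$habitatLocation),
                 drop = FALSE]
  rownames(habCovs) <- NULL
  surveys <- cbind(sv[, c("survey_id", "location", "date", "day_of_year",
                          intersect("time_block", names(sv)))],
                   habCovs)

  records <- data.frame(
    survey_id = match(paste(obs[[schema$location]], obs[[schema$date]]),
                      paste(sv$location, sv$date)),
    location = obs[[schema$location]], date = obs[[schema$date]],
    species = obs[[schema$species]], stringsAsFactors = FALSE)
  hist <- as.matrix(obs[, schema$intervals, drop = FALSE])
  colnames(hist) <- paste0("int", seq_along(schema$intervals))
  records <- cbind(records, as.data.frame(hist))
  if (anyNA(records$survey_id))
    stop("observation rows reference surveys absent from the surveys file")

  unusable <- sort(unique(records$survey_id[rowSums(is.na(hist)) > 0]))
  if (length(unusable))
    message(length(unusable),
            " survey(s) lack interval-level capture histories; ",
            "flagged unusable for the capture-history likelihood")
  list(records = records, surveys = surveys,
       species = spp, habitat = hab, unusableSurveys = unusable)
}

#' Tabulate detection frequencies from individual capture records
#'
#' Builds the sufficient summary Y_ikj: the number of individuals of
#' species k whose capture history in survey i sums to exactly j
#' detections, for j = 1..J. Surveys with no records of a species get
#' an all-zero row (a legal observation); records with all-zero
#' histories are an error, since undetected individuals cannot be
#' recorded. Records from surveys flagged unusable (missing interval
#' indicators) are excluded.
#'
#' @param records data.frame from \code{\link{readSurveyFiles}} (or the
#'   simulator) with survey_id, species and intN columns.
#' @param surveys survey table (one row per survey, with covariates).
#' @param species character vector of species codes defining the
#'   species axis (order preserved).
#' @param J number of intervals.
#' @return a \linkS4class{DetectionFrequency}.
#' @export
buildFrequencyTable <- function(records, surveys, species, J = 4) {
  I <- nrow(surveys)
  intCols <- paste0("int", seq_len(J))
  counts <- array(0L, c(I, length(species), J),
                  dimnames = list(NULL, species, NULL))
  if (nrow(records)) {
    .requireColumns(records, c("survey_id", "species", intCols), "records")
    hist <- as.matrix(records[, intCols, drop = FALSE])
    usable <- rowSums(is.na(hist)) == 0
    hist <- hist[usable, , drop = FALSE]
    recs <- records[usable, , drop = FALSE]
    if (nrow(recs)) {
      if (any(!hist %in% c(0L, 1L)))
        stop("interval indicators must be 0/1")
      d <- rowSums(hist)
      if (any(d == 0))
        stop("data error: record(s) with all-zero capture history ",
             "(undetected individuals cannot appear)")
      bad <- setdiff(unique(recs$species), species)
      if (length(bad))
        stop("records contain species absent from the species axis: ",
             paste(sQuote(bad), collapse = ", "))
      for (k in seq_along(species)) {
        sel <- recs$species == species[k]
        if (!any(sel)) next
        counts[, k, ] <- as.matrix(
          table(factor(recs$survey_id[sel], levels = seq_len(I)),
                factor(d[sel], levels = seq_len(J))))
      }
    }
  }
  freq <- new("DetectionFrequency", counts = counts, surveys = surveys,
              species = as.character(species))
  ## ingest invariant: per-cell totals equal the number of usable records
  stopifnot(sum(freq@counts) ==
              if (nrow(records))
                sum(rowSums(is.na(as.matrix(
                  records[, intCols, drop = FALSE]))) == 0)
              else 0L)
  freq
}

#' Write a detection-frequency table as tidy CSV
#'
#' One row per (survey, species, frequency) cell:
#' \code{survey_id, species_code, j, count}.
#'
#' @param freq a \linkS4class{DetectionFrequency}.
#' @param path output CSV path.
#' @export
writeFrequencyTable <- function(freq, path) {
  stopifnot(is(freq, "DetectionFrequency"))
  cnt <- freqCounts(freq)
  d <- dim(cnt)
  out <- data.frame(
    survey_id = rep(seq_len(d[1L]), times = d[2L] * d[3L]),
    species_code = rep(rep(speciesCodes(freq), each = d[1L]),
                       times = d[3L]),
    j = rep(seq_len(d[3L]), each = d[1L] * d[2L]),
    count = as.vector(cnt))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Principal-component scores of site measurements
#'
#' PCA on the correlation matrix: each measurement column is centred
#' and scaled to unit variance before eigendecomposition, so scores are
#' invariant to affine rescaling of any input column. Each component is
#' oriented so that its largest-magnitude loading is positive, a
#' deterministic sign convention across linear-algebra backends.
#' Missing values are refused rather than imputed.
#'
#' @param measurements numeric matrix or data.frame, sites x variables.
#' @param nComponents number of leading components to retain as scores.
#' @return a \linkS4class{CovariateScores}; \code{varianceExplained}
#'   covers all components (eigenvalues over their total).
#' @export
pcaScores <- function(measurements, nComponents) {
  X <- as.matrix(measurements)
  if (!is.numeric(X)) stop("measurements must be numeric")
  if (nrow(X) < 2) stop("PCA requires at least 2 sites")
  if (anyNA(X))
    stop("missing values in measurements; imputation is refused")
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0))
    stop("degenerate covariate: constant column(s) ",
         paste(sQuote(colnames(X)[sds == 0]), collapse = ", "))
  if (nComponents < 1 || nComponents > ncol(X))
    stop("nComponents must be between 1 and ncol(measurements)")
  Z <- scale(X)
  e <- eigen(stats::cor(X), symmetric = TRUE)
  load <- e$vectors
  for (j in seq_len(ncol(load))) {
    lead <- which.max(abs(load[, j]))
    if (load[lead, j] < 0) load[, j] <- -load[, j]
  }
  dimnames(load) <- list(colnames(X), paste0("PC", seq_len(ncol(load))))
  scores <- Z %*% load[, seq_len(nComponents), drop = FALSE]
  ve <- pmax(e$values, 0)
  ve <- ve / sum(ve)
  new("CovariateScores", scores = scores, loadings = load,
      varianceExplained = ve,
      center = attr(Z, "scaled:center"), scale = attr(Z, "scaled:scale"))
}

#' Assign survey clock times to time-of-day blocks
#'
#' Bins survey start times into early (5:30-7:00), middle (7:00-8:30)
#' and late (8:30-10:00) blocks. Boundary times belong to the later
#' block (half-open intervals keep the bins disjoint); times outside
#' the 5:30-10:00 survey window are an error.
#'
#' @param clockTime character "HH:MM" strings or numeric decimal hours.
#' @return factor with levels early, middle, late.
#' @examples
#' timeBlock(c("6:00", "7:00", "8:30"))
#' @export
timeBlock <- function(clockTime) {
  if (is.character(clockTime)) {
    parts <- strsplit(clockTime, ":", fixed = TRUE)
    hours <- vapply(parts, function(x) {
      if (length(x) != 2L || anyNA(suppressWarnings(as.numeric(x))))
        stop("cannot parse clock time: ", paste(x, collapse = ":"))
      as.numeric(x[1L]) + as.numeric(x[2L]) / 60
    }, numeric(1))
  } else {
    hours <- as.numeric(clockTime)
  }
  if (anyNA(hours) || any(hours < 5.5 - 1e-9) || any(hours > 10 + 1e-9))
    stop("range error: survey times must lie within 5:30-10:00")
  out <- ifelse(hours < 7, "early", ifelse(hours < 8.5, "middle", "late"))
  factor(out, levels = c("early", "middle", "late"))
}
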