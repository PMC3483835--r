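#' @include AllClasses.R AllGenerics.R scenario.R measurement.R estimation.R
NULL

# ---- delimited-text interchange --------------------------------------------
# comma-separated with explicit headers throughout; no binary formats.

.TC_HEADER <- c("time_h", "mrna", "protein_total", "protein_labeled",
                "protein_unlabeled")

#' Read and write trajectories, measurements and bias grids as delimited text
#'
#' Time courses use the header
#' \code{time_h,mrna,protein_total,protein_labeled,protein_unlabeled};
#' measurement sets use \code{time_h,replicate,signal}; bias grids are written
#' as a matrix with mRNA half-lives as row names and protein half-lives as
#' column headers.
#'
#' @param tc,ms,grid object to write.
#' @param path file path.
#' @return Readers return the corresponding S4 object; writers return the
#'   path invisibly.
#' @name turnover-io
NULL

#' @rdname turnover-io
#' @export
writeTimeCourse <- function(tc, path) {
  utils::write.csv(as.data.frame(tc), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname turnover-io
#' @export
readTimeCourse <- function(path) {
  df <- utils::read.csv(path)
  if (!identical(names(df), .TC_HEADER))
    stop("'", path, "': expected header ", paste(.TC_HEADER, collapse = ","))
  TimeCourse(times = df$time_h, mrna = df$mrna,
             proteinTotal = df$protein_total,
             proteinLabeled = df$protein_labeled,
             proteinUnlabeled = df$protein_unlabeled)
}

#' @rdname turnover-io
#' @export
writeMeasurementSet <- function(ms, path) {
  utils::write.csv(as.data.frame(ms), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname turnover-io
#' @export
readMeasurementSet <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  need <- c("time_h", "replicate", "signal")
  if (!all(need %in% names(df)))
    stop("'", path, "': expected columns ", paste(need, collapse = ","))
  tnum <- suppressWarnings(as.numeric(df$time_h))
  rnum <- suppressWarnings(as.integer(df$replicate))
  snum <- suppressWarnings(as.numeric(df$signal))
  bad <- which(is.na(tnum) | is.na(rnum) | is.na(snum))
  if (length(bad))
    stop("'", path, "': malformed rows at line(s) ",
         paste(bad + 1L, collapse = ", "))  # +1 for the header line
  MeasurementSet(time = tnum, replicate = rnum, signal = snum)
}

#' @rdname turnover-io
#' @export
writeBiasGrid <- function(grid, path) {
  m <- grid@ratios
  dimnames(m) <- list(grid@mrnaHalfLives, grid@proteinHalfLives)
  utils::write.csv(data.frame(mrna_half_life_h = rownames(m), m,
                              check.names = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- configuration ---------------------------------------------------------

#' Read a turnover parameter set from a flat key-value config
#'
#' Keys: \code{mrna_copies}, \code{translation_rate_per_h},
#' \code{mrna_half_life_h}, \code{protein_half_life_h},
#' \code{doubling_time_h} (a number, or \code{none}/\code{non-dividing}).
#'
#' @param x path to a YAML file, or an already-parsed named list.
#' @return A [TurnoverParams-class].
#' @export
readTurnoverParams <- function(x) {
  cfg <- if (is.character(x)) yaml::read_yaml(x) else x
  need <- c("mrna_copies", "translation_rate_per_h", "mrna_half_life_h",
            "protein_half_life_h")
  miss <- setdiff(need, names(cfg))
  if (length(miss))
    stop("parameter config missing key(s): ", paste(miss, collapse = ", "))
  dt <- cfg$doubling_time_h
  if (is.null(dt)) dt <- "non-dividing"
  TurnoverParams(mrnaCopies = cfg$mrna_copies,
                 translationRate = cfg$translation_rate_per_h,
                 mrnaHalfLife = cfg$mrna_half_life_h,
                 proteinHalfLife = cfg$protein_half_life_h,
                 doublingTime = dt)
}

#' Read a scenario from a structured config
#'
#' Expects a list with \code{sampling_times_h} and either \code{preset} (one
#' of the [scenarioPreset()] names, with optional \code{options}) or
#' \code{perturbations}, a list of \code{{onset_h, kind, magnitude}} entries.
#'
#' @param x path to a YAML file, or an already-parsed list.
#' @return A [Scenario-class].
#' @export
readScenario <- function(x) {
  cfg <- if (is.character(x)) yaml::read_yaml(x) else x
  times <- as.numeric(unlist(cfg$sampling_times_h))
  if (!is.null(cfg$preset)) {
    opts <- cfg$options
    return(scenarioPreset(cfg$preset, samplingTimes = times,
      residualFraction = if (is.null(opts$residual_fraction)) 0.2
                         else opts$residual_fraction,
      synthesisMultiplier = opts$synthesis_multiplier,
      degradationMultiplier = if (is.null(opts$degradation_multiplier)) 0
                              else opts$degradation_multiplier,
      transcriptionMultiplier = if (is.null(opts$transcription_multiplier)) 1
                                else opts$transcription_multiplier))
  }
  perts <- do.call(rbind, lapply(cfg$perturbations, function(p)
    Perturbation(p$kind, magnitude = if (is.null(p$magnitude)) NA_real_
                                     else p$magnitude,
                 onset = p$onset_h)))
  Scenario(perturbations = perts, samplingTimes = times)
}

#' Run a configured simulation, writing trajectory and measurements
#'
#' The whole-pipeline front end: reads a run configuration (turnover
#' parameters, a scenario or preset reference, an optional noise model, output
#' paths and a seed), simulates, optionally samples noisy replicate
#' measurements, writes the delimited-text outputs and logs the derived rate
#' constants. A seed is mandatory whenever a noise block is present, so runs
#' are reproducible end to end.
#'
#' @param config path to a YAML run configuration, or a parsed list with
#'   blocks \code{params}, \code{scenario}, optional \code{noise}
#'   (\code{cv}, \code{replicates}, \code{detection_floor}), optional
#'   \code{outputs} (\code{timecourse}, \code{measurements}) and \code{seed}.
#' @param quiet suppress the log messages.
#' @return Invisibly, \code{list(timeCourse=, measurements=)} (the latter
#'   \code{NULL} without a noise block).
#' @export
runSimulate <- function(config, quiet = FALSE) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  params <- readTurnoverParams(cfg$params)
  scenario <- readScenario(cfg$scenario)
  rc <- rateConstants(params)
  if (!quiet) {
    message(sprintf("proteoturn %s: simulate",
      as.character(utils::packageVersion("proteoturn"))))
    message(sprintf(
      "  params: M=%g, R=%g/h, tm=%g h, tp=%g h, doubling=%s",
      params@mrnaCopies, params@translationRate, params@mrnaHalfLife,
      params@proteinHalfLife,
      if (is.finite(params@doublingTime))
        paste0(params@doublingTime, " h") else "non-dividing"))
    message(sprintf(
      "  rates /h: kM=%.6g, D=%.6g, V=%.6g, kP=%.6g", rc@kM, rc@D, rc@V,
      rc@kP))
  }
  tc <- simulateScenario(scenario, params)

  ms <- NULL
  if (!is.null(cfg$noise)) {
    if (is.null(cfg$seed))
      stop("'seed' is mandatory when a noise block is present")
    nm <- NoiseModel(
      cv = if (is.null(cfg$noise$cv)) 0.10 else cfg$noise$cv,
      replicates = if (is.null(cfg$noise$replicates)) 3L
                   else cfg$noise$replicates,
      seed = cfg$seed,
      detectionFloor = if (is.null(cfg$noise$detection_floor)) 0
                       else cfg$noise$detection_floor)
    ms <- sampleMeasurements(tc, "total", nm)
  }

  outs <- cfg$outputs
  writeOne <- function(obj, path, writer) {
    if (is.null(path)) return()
    ok <- tryCatch({ writer(obj, path); TRUE },
                   error = function(e) {
                     stop("failed to write '", path, "': ",
                          conditionMessage(e), call. = FALSE)
                   })
    if (!quiet && ok) message("  wrote ", path)
  }
  writeOne(tc, outs$timecourse, writeTimeCourse)
  if (!is.null(ms)) writeOne(ms, outs$measurements, writeMeasurementSet)
  invisible(list(timeCourse = tc, measurements = ms))
}

#' Fit a half-life to a measurement table on disk
#'
#' Reads a delimited measurement table (\code{time_h,replicate,signal}), fits
#' the requested estimator and prints the estimate with its concept label.
#'
#' @param input path to the measurement table.
#' @param method,concept passed to [fitHalfLife()].
#' @param out optional path; when given, a one-row summary table
#'   (\code{half_life_h,rate_per_h,stderr_h,method,concept}) is written.
#' @param quiet suppress printing.
#' @return The [HalfLifeEstimate-class], invisibly.
#' @export
runFit <- function(input, method = "nonlinear_1exp", concept = "apparent",
                   out = NULL, quiet = FALSE) {
  ms <- readMeasurementSet(input)
  est <- fitHalfLife(ms, method = method, concept = concept)
  if (!quiet) show(est)
  if (!is.null(out)) {
    utils::write.csv(data.frame(half_life_h = est@halfLife,
                                rate_per_h = est@rate,
                                stderr_h = est@stderr,
                                method = est@method, concept = est@concept),
                     out, row.names = FALSE, quote = FALSE)
    if (!quiet) message("  wrote ", out)
  }
  invisible(est)
}
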