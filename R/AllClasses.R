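#' @import methods
NULL

# Distinguished doubling-time value for non-dividing (quiescent) cells.
# Internally Inf, so that V = ln(2)/doublingTime is exactly 0.
.NON_DIVIDING <- Inf

#' Turnover parameters for one protein
#'
#' The five quantities that define the proteostatic state of a single protein
#' species in the deterministic turnover model: mRNA copy number per cell,
#' translation rate per mRNA, mRNA half-life, protein (degradation-only)
#' half-life and the cell doubling time. Growth dilution enters as a
#' first-order loss on protein with rate \eqn{V = \ln 2 / t_{double}};
#' non-dividing cells have \eqn{V = 0}.
#'
#' @slot mrnaCopies mRNA copy number per cell (dimensionless count, > 0).
#' @slot translationRate proteins synthesised per mRNA per hour (>= 0).
#' @slot mrnaHalfLife effective mRNA half-life in hours (> 0). Treated as the
#'   chemical-plus-dilution decay actually measured in mRNA decay experiments;
#'   no additional dilution term is applied to mRNA.
#' @slot proteinHalfLife degradation-only protein half-life in hours (> 0);
#'   defines \eqn{D = \ln 2 / t_{1/2}}.
#' @slot doublingTime cell doubling time in hours, or \code{Inf} for
#'   non-dividing cells.
#'
#' @seealso [TurnoverParams()] for the user constructor, [rateConstants()],
#'   [steadyState()].
#' @export
setClass("TurnoverParams",
  representation(
    mrnaCopies      = "numeric",
    translationRate = "numeric",
    mrnaHalfLife    = "numeric",
    proteinHalfLife = "numeric",
    doublingTime    = "numeric"
  )
)

setValidity("TurnoverParams", function(object) {
  msgs <- character(0)
  chkPos <- function(x, nm) {
    if (length(x) != 1L || !is.finite(x) || x <= 0)
      sprintf("'%s' must be a single finite value > 0 (got %s)", nm,
              paste(format(x), collapse = ","))
    else character(0)
  }
  msgs <- c(msgs, chkPos(object@mrnaCopies, "mrnaCopies"))
  if (length(object@translationRate) != 1L ||
      is.na(object@translationRate) ||
      object@translationRate < 0 ||
      (!is.finite(object@translationRate)))
    msgs <- c(msgs, "'translationRate' must be a single finite value >= 0")
  msgs <- c(msgs, chkPos(object@mrnaHalfLife, "mrnaHalfLife"))
  msgs <- c(msgs, chkPos(object@proteinHalfLife, "proteinHalfLife"))
  dt <- object@doublingTime
  if (length(dt) != 1L || is.na(dt) || dt <= 0)
    msgs <- c(msgs, "'doublingTime' must be > 0 hours or Inf (non-dividing)")
  if (length(msgs)) msgs else TRUE
})

#' Construct a turnover parameter set
#'
#' @param mrnaCopies mRNA copies per cell.
#' @param translationRate proteins per mRNA per hour.
#' @param mrnaHalfLife mRNA half-life, hours.
#' @param proteinHalfLife degradation-only protein half-life, hours.
#' @param doublingTime cell doubling time in hours, or \code{"non-dividing"}
#'   (equivalently \code{Inf} or \code{NA}) for quiescent cells.
#' @return A [TurnoverParams-class] object.
#' @examples
#' tp <- TurnoverParams(mrnaCopies = 10, translationRate = 2,
#'                      mrnaHalfLife = 0.5, proteinHalfLife = 1,
#'                      doublingTime = "non-dividing")
#' steadyState(tp)
#' @export
TurnoverParams <- function(mrnaCopies, translationRate, mrnaHalfLife,
                           proteinHalfLife, doublingTime = "non-dividing") {
  if (is.character(doublingTime)) {
    if (!identical(tolower(doublingTime), "non-dividing") &&
        !identical(tolower(doublingTime), "none"))
      stop("'doublingTime' must be a positive number of hours or \"non-dividing\"")
    doublingTime <- .NON_DIVIDING
  }
  if (length(doublingTime) == 1L && is.na(doublingTime))
    doublingTime <- .NON_DIVIDING
  new("TurnoverParams",
      mrnaCopies = as.numeric(mrnaCopies),
      translationRate = as.numeric(translationRate),
      mrnaHalfLife = as.numeric(mrnaHalfLife),
      proteinHalfLife = as.numeric(proteinHalfLife),
      doublingTime = as.numeric(doublingTime))
}

#' First-order rate constants derived from a turnover parameter set
#'
#' @slot kM mRNA decay rate constant, per hour.
#' @slot D protein degradation rate constant, per hour.
#' @slot V growth-dilution rate constant, per hour (0 when non-dividing).
#' @slot kP effective protein removal rate constant, \code{D + V}, per hour.
#' @seealso [rateConstants()]
#' @export
setClass("RateConstants",
  representation(kM = "numeric", D = "numeric", V = "numeric", kP = "numeric"))

setValidity("RateConstants", function(object) {
  msgs <- character(0)
  if (object@kM <= 0) msgs <- c(msgs, "kM must be > 0")
  if (object@D < 0 || object@V < 0) msgs <- c(msgs, "D and V must be >= 0")
  if (abs(object@kP - (object@D + object@V)) >
      1e-12 * max(1, object@kP))
    msgs <- c(msgs, "kP must equal D + V")
  if (length(msgs)) msgs else TRUE
})

#' An experimental scenario: timed perturbations plus sampling times
#'
#' A scenario is an ordered list of instantaneous multiplier steps applied to
#' the turnover system, together with the times at which the trajectory is
#' sampled. Perturbation kinds:
#' \describe{
#'   \item{synthesis_multiplier}{scales the translation rate R from the onset
#'     on (0 = total synthesis block, e.g. cycloheximide).}
#'   \item{transcription_multiplier}{scales mRNA production from the onset on;
#'     mRNA relaxes exponentially (rate \eqn{k_M}) to the new steady level
#'     (0 = Tet-off shutoff; a residual fraction models siRNA knockdown;
#'     values > 1 model transcriptional upregulation side effects of
#'     degradation inhibitors).}
#'   \item{degradation_multiplier}{scales the degradation rate constant D
#'     (not the dilution term V); 0 = complete degradation block.}
#'   \item{label_switch}{from the onset on, all new synthesis enters the
#'     labelled (heavy) pool; at most one per scenario.}
#' }
#'
#' @slot perturbations data.frame with columns \code{onset} (hours),
#'   \code{kind}, \code{magnitude}; sorted by onset.
#' @slot samplingTimes sorted non-negative sampling times, hours.
#' @slot initialCondition numeric of length 0 (start from steady state, the
#'   default) or a named vector \code{c(mrna=, protein=)}.
#' @export
setClass("Scenario",
  representation(
    perturbations    = "data.frame",
    samplingTimes    = "numeric",
    initialCondition = "numeric"
  )
)

.PERT_KINDS <- c("synthesis_multiplier", "transcription_multiplier",
                 "degradation_multiplier", "label_switch")

setValidity("Scenario", function(object) {
  msgs <- character(0)
  p <- object@perturbations
  if (!all(c("onset", "kind", "magnitude") %in% names(p)))
    return("perturbations must have columns onset, kind, magnitude")
  if (nrow(p)) {
    if (!all(p$kind %in% .PERT_KINDS))
      msgs <- c(msgs, paste0("unknown perturbation kind(s): ",
                             paste(setdiff(p$kind, .PERT_KINDS), collapse = ", ")))
    if (any(!is.finite(p$onset)) || any(p$onset < 0))
      msgs <- c(msgs, "perturbation onsets must be finite and >= 0")
    if (is.unsorted(p$onset))
      msgs <- c(msgs, "perturbation onsets must be sorted")
    nonlab <- p$kind != "label_switch"
    if (any(!is.finite(p$magnitude[nonlab])) || any(p$magnitude[nonlab] < 0))
      msgs <- c(msgs, "perturbation magnitudes must be finite and >= 0")
    if (sum(p$kind == "label_switch") > 1L)
      msgs <- c(msgs, "at most one label_switch per scenario")
  }
  st <- object@samplingTimes
  if (length(st)) {
    if (any(!is.finite(st)) || any(st < 0))
      msgs <- c(msgs, "samplingTimes must be finite and >= 0")
    if (is.unsorted(st)) msgs <- c(msgs, "samplingTimes must be sorted")
  }
  ic <- object@initialCondition
  if (length(ic) && (length(ic) != 2L ||
                     !all(c("mrna", "protein") %in% names(ic)) ||
                     any(ic < 0)))
    msgs <- c(msgs, "initialCondition must be empty or c(mrna=, protein=) >= 0")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn Scenario-class Construct a single perturbation (one-row
#'   data.frame suitable for binding into a scenario).
#' @param onset time of the step, hours.
#' @param kind one of \code{"synthesis_multiplier"},
#'   \code{"transcription_multiplier"}, \code{"degradation_multiplier"},
#'   \code{"label_switch"}.
#' @param magnitude dimensionless multiplier (ignored for
#'   \code{label_switch}).
#' @export
Perturbation <- function(kind, magnitude = NA_real_, onset = 0) {
  kind <- match.arg(kind, .PERT_KINDS)
  if (kind == "label_switch") magnitude <- NA_real_
  data.frame(onset = as.numeric(onset), kind = kind,
             magnitude = as.numeric(magnitude), stringsAsFactors = FALSE)
}

#' @describeIn Scenario-class Construct a scenario from perturbations and
#'   sampling times.
#' @param perturbations a data.frame as produced by (rbinding)
#'   [Perturbation()] rows, or \code{NULL} for an unperturbed scenario.
#' @param samplingTimes sampling times, hours (sorted internally).
#' @param initialCondition \code{NULL} (steady state) or
#'   \code{c(mrna=, protein=)}.
#' @export
Scenario <- function(perturbations = NULL, samplingTimes = numeric(0),
                     initialCondition = NULL) {
  if (is.null(perturbations))
    perturbations <- data.frame(onset = numeric(0), kind = character(0),
                                magnitude = numeric(0),
                                stringsAsFactors = FALSE)
  perturbations <- perturbations[order(perturbations$onset), , drop = FALSE]
  rownames(perturbations) <- NULL
  new("Scenario",
      perturbations = perturbations,
      samplingTimes = sort(as.numeric(samplingTimes)),
      initialCondition = if (is.null(initialCondition)) numeric(0)
                         else initialCondition)
}

#' Simulated trajectory of mRNA and protein pools
#'
#' Holds the noiseless trajectory of a turnover simulation: mRNA copies and
#' the total, labelled and unlabelled protein pools at each sampled time.
#' Label conservation (\code{proteinTotal == proteinLabeled +
#' proteinUnlabeled}) is enforced by the validity method.
#'
#' @slot times sampling times, hours.
#' @slot mrna mRNA copies per cell.
#' @slot proteinTotal total protein molecules per cell.
#' @slot proteinLabeled labelled (heavy / pulse-labelled) protein molecules;
#'   all zero when the scenario has no label.
#' @slot proteinUnlabeled unlabelled (light / pre-existing) protein molecules.
#' @export
setClass("TimeCourse",
  representation(
    times            = "numeric",
    mrna             = "numeric",
    proteinTotal     = "numeric",
    proteinLabeled   = "numeric",
    proteinUnlabeled = "numeric"
  )
)

setValidity("TimeCourse", function(object) {
  n <- length(object@times)
  msgs <- character(0)
  if (length(object@mrna) != n || length(object@proteinTotal) != n ||
      length(object@proteinLabeled) != n ||
      length(object@proteinUnlabeled) != n)
    return("all trajectory slots must have the same length as 'times'")
  if (n == 0L) return(TRUE)
  if (any(!is.finite(object@times))) msgs <- c(msgs, "times must be finite")
  neg <- function(x) any(x < -1e-12 * max(1, max(abs(x))))
  if (neg(object@mrna) || neg(object@proteinTotal) ||
      neg(object@proteinLabeled) || neg(object@proteinUnlabeled))
    msgs <- c(msgs, "trajectory quantities must be non-negative")
  tot <- object@proteinLabeled + object@proteinUnlabeled
  scale <- pmax(object@proteinTotal, 1e-300)
  if (max(abs(tot - object@proteinTotal) / scale) > 1e-9)
    msgs <- c(msgs, "label conservation violated: labeled + unlabeled != total")
  if (length(msgs)) msgs else TRUE
})

TimeCourse <- function(times, mrna, proteinTotal,
                       proteinLabeled = rep(0, length(times)),
                       proteinUnlabeled = proteinTotal - proteinLabeled) {
  new("TimeCourse", times = as.numeric(times), mrna = as.numeric(mrna),
      proteinTotal = as.numeric(proteinTotal),
      proteinLabeled = as.numeric(proteinLabeled),
      proteinUnlabeled = as.numeric(proteinUnlabeled))
}

#' Replicate measurement noise model
#'
#' Multiplicative lognormal noise (mean 1, spread set by the coefficient of
#' variation) applied independently per replicate and time point, emulating
#' densitometry of immunoblots or scintillation counting. Signals below the
#' detection floor are censored to the floor.
#'
#' @slot cv coefficient of variation of the multiplicative noise (>= 0).
#' @slot replicates number of replicates (>= 1).
#' @slot seed integer RNG seed; identical seeds give identical measurements.
#' @slot detectionFloor relative-signal censoring floor (>= 0; 0 disables).
#' @export
setClass("NoiseModel",
  representation(cv = "numeric", replicates = "integer", seed = "integer",
                 detectionFloor = "numeric"))

setValidity("NoiseModel", function(object) {
  msgs <- character(0)
  if (object@cv < 0 || !is.finite(object@cv)) msgs <- c(msgs, "cv must be >= 0")
  if (object@replicates < 1L) msgs <- c(msgs, "replicates must be >= 1")
  if (object@detectionFloor < 0) msgs <- c(msgs, "detectionFloor must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn NoiseModel-class Constructor.
#' @param cv coefficient of variation, default 0.10.
#' @param replicates replicate count, default 3.
#' @param seed integer seed.
#' @param detectionFloor censoring floor on the relative signal, default 0.
#' @export
NoiseModel <- function(cv = 0.10, replicates = 3L, seed = 1L,
                       detectionFloor = 0) {
  new("NoiseModel", cv = as.numeric(cv), replicates = as.integer(replicates),
      seed = as.integer(seed), detectionFloor = as.numeric(detectionFloor))
}

#' A set of replicated, normalised measurements of a decay channel
#'
#' Long-format container: one row per (time, replicate) observation. Signals
#' are normalised to the mean signal at the first sampling time
#' (\code{"t0-mean"} normalisation), mirroring the percent-of-initial
#' convention of chase experiments.
#'
#' @slot time observation times, hours (one entry per observation).
#' @slot replicate replicate index per observation.
#' @slot signal normalised relative signal per observation.
#' @slot normalization normalisation rule; currently \code{"t0-mean"}.
#' @export
setClass("MeasurementSet",
  representation(time = "numeric", replicate = "integer", signal = "numeric",
                 normalization = "character"))

setValidity("MeasurementSet", function(object) {
  n <- length(object@time)
  msgs <- character(0)
  if (length(object@replicate) != n || length(object@signal) != n)
    return("time, replicate and signal must have equal length")
  if (n) {
    if (any(object@signal < 0)) msgs <- c(msgs, "signals must be >= 0")
    reps <- table(object@time)
    if (length(unique(as.integer(reps))) > 1L)
      msgs <- c(msgs, "same replicate count required at every time")
  }
  if (!identical(object@normalization, "t0-mean"))
    msgs <- c(msgs, "normalization must be \"t0-mean\"")
  if (length(msgs)) msgs else TRUE
})

MeasurementSet <- function(time, replicate, signal,
                           normalization = "t0-mean") {
  new("MeasurementSet", time = as.numeric(time),
      replicate = as.integer(replicate), signal = as.numeric(signal),
      normalization = normalization)
}

#' A fitted protein half-life with its interpretation
#'
#' Records not only the fitted value but \emph{which} half-life concept it
#' estimates: \code{degradation_only} (\eqn{\ln 2 / D}),
#' \code{effective_removal} (\eqn{\ln 2 / (D+V)}, including growth dilution)
#' or \code{apparent} (read off an observed decline that may be confounded by
#' upstream processes such as mRNA decay).
#'
#' @slot halfLife fitted half-life, hours.
#' @slot rate fitted first-order rate, per hour (\code{log(2)/halfLife}).
#' @slot concept one of \code{"degradation_only"}, \code{"effective_removal"},
#'   \code{"apparent"}.
#' @slot stderr standard error of the half-life, hours (\code{NA} for the
#'   model-free t50 estimator).
#' @slot method one of \code{"log_linear"}, \code{"nonlinear_1exp"},
#'   \code{"t50_interpolated"}.
#' @export
setClass("HalfLifeEstimate",
  representation(halfLife = "numeric", rate = "numeric", concept = "character",
                 stderr = "numeric", method = "character"))

.HL_CONCEPTS <- c("degradation_only", "effective_removal", "apparent")
.HL_METHODS  <- c("log_linear", "nonlinear_1exp", "t50_interpolated")

setValidity("HalfLifeEstimate", function(object) {
  msgs <- character(0)
  if (!is.finite(object@halfLife) || object@halfLife <= 0)
    msgs <- c(msgs, "halfLife must be finite and > 0")
  if (abs(object@halfLife - log(2) / object@rate) >
      1e-9 * object@halfLife)
    msgs <- c(msgs, "halfLife must equal log(2)/rate")
  if (!object@concept %in% .HL_CONCEPTS)
    msgs <- c(msgs, "unknown half-life concept")
  if (!object@method %in% .HL_METHODS)
    msgs <- c(msgs, "unknown fitting method")
  if (length(msgs)) msgs else TRUE
})

HalfLifeEstimate <- function(halfLife, concept, method, stderr = NA_real_) {
  new("HalfLifeEstimate", halfLife = as.numeric(halfLife),
      rate = log(2) / as.numeric(halfLife), concept = concept,
      stderr = as.numeric(stderr), method = method)
}

#' Apparent-over-true half-life bias grid for shutoff designs
#'
#' For a grid of mRNA and protein half-lives, the ratio of the apparent
#' half-life (model-free t50 of the simulated decline) to the true effective
#' removal half-life \eqn{\ln 2/(D+V)}. For transcriptional-shutoff designs
#' the ratio is always >= 1 and approaches 1 only when mRNA decay is much
#' faster than protein removal.
#'
#' @slot mrnaHalfLives grid of mRNA half-lives, hours (rows).
#' @slot proteinHalfLives grid of protein half-lives, hours (columns).
#' @slot ratios matrix of apparent/true ratios, rows = mRNA half-lives.
#' @slot design the shutoff design simulated (\code{"tet_off"} or
#'   \code{"sirna_knockdown"}).
#' @export
setClass("BiasGrid",
  representation(mrnaHalfLives = "numeric", proteinHalfLives = "numeric",
                 ratios = "matrix", design = "character"))

setValidity("BiasGrid", function(object) {
  msgs <- character(0)
  if (!identical(dim(object@ratios),
                 c(length(object@mrnaHalfLives),
                   length(object@proteinHalfLives))))
    msgs <- c(msgs, "ratio matrix dimensions inconsistent with grids")
  if (any(object@ratios < 1 - 1e-9))
    msgs <- c(msgs, "shutoff apparent/true ratios must be >= 1")
  if (length(msgs)) msgs else TRUE
})

#' Evidence-grading report for a declared experimental design
#'
#' Produced by [appraise()]: the checklist rules matched by the declared set
#' of design ticks, the conclusion and compulsory controls of each, and an
#' overall evidence grade taken from the most specific matched rule.
#'
#' @slot ticks the declared tick ids (subset of 1..10).
#' @slot matchedRules data.frame of matched rules (id, label, pattern,
#'   conclusion, grade, most specific first).
#' @slot overallGrade grade of the most specific matched rule.
#' @slot conclusion conclusion string of the most specific matched rule.
#' @slot requiredControls deduplicated compulsory control statements, in rule
#'   order.
#' @slot unmatchedTicks ticks not covered by the most specific matched rule.
#' @export
setClass("AppraisalReport",
  representation(ticks = "integer", matchedRules = "data.frame",
                 overallGrade = "character", conclusion = "character",
                 requiredControls = "character", unmatchedTicks = "integer"))

.GRADES <- c("good_evidence", "good_approach", "partial",
             "not_good_approach", "insufficient")
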