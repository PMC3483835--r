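#' @include AllClasses.R AllGenerics.R
NULL

# ---- deterministic turnover model ------------------------------------------
#
# dM/dt = T - kM * M          (T: transcription rate; at baseline T = kM*M0)
# dP/dt = R * M - (D + V) * P
#
# All rates per hour; half-life <-> rate conversions via ln(2). Dilution by
# growth (V) is a first-order loss applied to protein only; the user-supplied
# mRNA half-life is the effective (chemical + dilution) decay.

# relative tolerance below which the two-exponential solution switches to its
# degenerate (kM == kP) limit; kept tiny because the expm1 formulation is
# stable well past it
.DEGENERACY_TOL <- 1e-9

#' Derive first-order rate constants
#'
#' Converts the half-life parameterisation into rate constants:
#' \eqn{k_M = \ln 2 / t_{1/2,mRNA}}, \eqn{D = \ln 2 / t_{1/2,protein}},
#' \eqn{V = \ln 2 / t_{double}} (0 when non-dividing) and the effective
#' protein removal rate \eqn{k_P = D + V}.
#'
#' @param params a [TurnoverParams-class] object.
#' @return A [RateConstants-class] object.
#' @examples
#' rateConstants(TurnoverParams(10, 2, 0.5, 1, 24))
#' @rdname rateConstants
#' @export
setMethod("rateConstants", "TurnoverParams", function(params) {
  validObject(params)
  kM <- log(2) / params@mrnaHalfLife
  D  <- log(2) / params@proteinHalfLife
  V  <- if (is.finite(params@doublingTime)) log(2) / params@doublingTime else 0
  new("RateConstants", kM = kM, D = D, V = V, kP = D + V)
})

#' Steady-state protein abundance
#'
#' The steady-state protein level \eqn{P_0 = M R / (D + V)}: the abundance at
#' which synthesis (\eqn{M R}) balances removal by degradation plus growth
#' dilution. Simulating from this level with no perturbation yields a flat
#' trajectory.
#'
#' @param params a [TurnoverParams-class] object.
#' @return Protein molecules per cell (numeric scalar).
#' @examples
#' steadyState(TurnoverParams(10, 2, 0.5, 1))   # 20 / ln(2)
#' @rdname steadyState
#' @export
setMethod("steadyState", "TurnoverParams", function(params) {
  rc <- rateConstants(params)
  if (rc@kP <= 0)
    stop("no removal process: D + V must be > 0 for a finite steady state")
  params@mrnaCopies * params@translationRate / rc@kP
})

# phi1(k, tau) = (1 - exp(-k tau)) / k, the integral of exp(-k s) over
# [0, tau]; continuous limit tau at k = 0. Scalar rate, vectorised over tau.
.phi1 <- function(k, tau) {
  if (k == 0) return(tau)
  -expm1(-k * tau) / k
}

# phi2(kM, kP, tau) = (exp(-kM tau) - exp(-kP tau)) / (kP - kM), the response
# of a pool with removal kP to an input decaying at kM; limit tau*exp(-k tau)
# when kM == kP. Written via expm1 so the near-degenerate case is stable.
# Scalar rates, vectorised over tau.
.phi2 <- function(kM, kP, tau) {
  d <- kP - kM
  if (d == 0) return(tau * exp(-kP * tau))
  out <- numeric(length(tau))
  big <- d * tau > 500   # expm1 would overflow; the two terms are far apart
  out[big] <- (exp(-kM * tau[big]) - exp(-kP * tau[big])) / d
  out[!big] <- exp(-kP * tau[!big]) * expm1(d * tau[!big]) / d
  out
}

.checkTimes <- function(t) {
  if (any(!is.finite(t)) || any(t < 0))
    stop("times must be finite and >= 0")
  invisible(t)
}

#' Relative protein decay under a total protein-synthesis block
#'
#' Closed-form trajectory for a chase with a translation inhibitor
#' (cycloheximide, emetine, anisomycin): synthesis stops instantaneously at
#' t = 0 from steady state and pre-existing protein decays as
#' \eqn{P(t)/P_0 = e^{-k_P t}} with the effective removal rate
#' \eqn{k_P = D + V}.
#'
#' @param params a [TurnoverParams-class] object.
#' @param t time(s) since the block, hours (vectorised).
#' @return \eqn{P(t)/P_0}, dimensionless in (0, 1].
#' @export
solveSynthesisBlock <- function(params, t) {
  .checkTimes(t)
  rc <- rateConstants(params)
  exp(-rc@kP * t)
}

#' Relative protein decay after transcriptional shutoff
#'
#' Closed-form trajectory for a Tet-off style experiment: transcription stops
#' at t = 0 from steady state, mRNA decays as \eqn{M_0 e^{-k_M t}}, and the
#' protein follows the two-exponential solution
#' \deqn{P(t)/P_0 = \frac{k_P e^{-k_M t} - k_M e^{-k_P t}}{k_P - k_M},}
#' which degenerates to \eqn{(1 + k t) e^{-k t}} when \eqn{k_M = k_P}. Because
#' mRNA must decay before protein loss becomes visible, the apparent half-life
#' of this decline always exceeds the true effective half-life
#' \eqn{\ln 2 / k_P} unless \eqn{k_M \gg k_P}.
#'
#' @inheritParams solveSynthesisBlock
#' @return \eqn{P(t)/P_0}, dimensionless in (0, 1].
#' @export
solveTranscriptionShutoff <- function(params, t) {
  .checkTimes(t)
  rc <- rateConstants(params)
  # P/P0 = exp(-kP t) + kP * phi2(kM, kP, t): decay of the initial pool plus
  # the response to the decaying synthesis input. Algebraically identical to
  # the two-exponential quotient, but stable through the degeneracy.
  exp(-rc@kP * t) + rc@kP * .phi2(rc@kM, rc@kP, t)
}

#' High-accuracy numeric reference integration of the turnover ODE
#'
#' Direct numeric solution of the turnover system under piecewise-constant
#' synthesis/transcription/degradation multipliers, used as the independent
#' oracle for every closed-form and piecewise-analytic solution in the
#' package. Integration is performed segment-by-segment between perturbation
#' breakpoints with \code{deSolve::ode} (lsoda, relative tolerance 1e-10), so
#' multiplier steps never straddle an integrator step.
#'
#' @param params a [TurnoverParams-class] object.
#' @param perturbations a data.frame of perturbation rows (see
#'   [Perturbation()]); may be \code{NULL}.
#' @param times sorted, non-negative output times (hours).
#' @param initialCondition \code{NULL} to start from steady state, or
#'   \code{c(mrna=, protein=)}.
#' @param labelActiveAtStart logical; when \code{TRUE} all synthesis is
#'   routed to the labelled pool from t = 0 (before any
#'   \code{label_switch} perturbation fires).
#' @param labelOffAt optional time at which labelling stops (synthesis
#'   reverts to the unlabelled pool), for pulse-style protocols.
#' @return A [TimeCourse-class] object.
#' @export
integrateReference <- function(params, perturbations = NULL, times,
                               initialCondition = NULL,
                               labelActiveAtStart = FALSE,
                               labelOffAt = NULL) {
  if (is.unsorted(times)) stop("output times must be sorted")
  .checkTimes(times)
  rc <- rateConstants(params)
  M0 <- params@mrnaCopies
  T0 <- rc@kM * M0
  R0 <- params@translationRate

  if (is.null(perturbations))
    perturbations <- data.frame(onset = numeric(0), kind = character(0),
                                magnitude = numeric(0))
  if (nrow(perturbations) &&
      any(perturbations$onset > max(times, 0)) )
    stop("perturbation breakpoint outside the simulated range")

  if (is.null(initialCondition)) {
    P0 <- M0 * R0 / rc@kP
    state <- c(M = M0, U = P0, L = 0)
  } else {
    state <- c(M = unname(initialCondition["mrna"]),
               U = unname(initialCondition["protein"]), L = 0)
  }

  events <- perturbations
  if (!is.null(labelOffAt))
    events <- rbind(events, data.frame(onset = labelOffAt,
                                       kind = "label_off", magnitude = NA_real_))
  events <- events[order(events$onset), , drop = FALSE]

  mult <- list(s = 1, c = 1, g = 1, label = isTRUE(labelActiveAtStart))
  breakpoints <- unique(c(0, events$onset, times))
  breakpoints <- sort(breakpoints[breakpoints <= max(times, 0)])

  deriv <- function(t, y, parms) {
    dM <- parms$c * T0 - rc@kM * y[1]
    synth <- parms$s * R0 * y[1]
    kP <- parms$g * rc@D + rc@V
    dU <- (if (parms$label) 0 else synth) - kP * y[2]
    dL <- (if (parms$label) synth else 0) - kP * y[3]
    list(c(dM, dU, dL))
  }

  out <- matrix(NA_real_, nrow = length(times), ncol = 3,
                dimnames = list(NULL, c("M", "U", "L")))
  tcur <- 0
  applyEvents <- function(mult, tt) {
    hit <- events$onset == tt
    for (i in which(hit)) {
      kind <- events$kind[i]
      if (kind == "synthesis_multiplier") mult$s <- events$magnitude[i]
      else if (kind == "transcription_multiplier") mult$c <- events$magnitude[i]
      else if (kind == "degradation_multiplier") mult$g <- events$magnitude[i]
      else if (kind == "label_switch") mult$label <- TRUE
      else if (kind == "label_off") mult$label <- FALSE
    }
    mult
  }
  mult <- applyEvents(mult, 0)
  out[times == 0, ] <- rep(state, each = sum(times == 0))

  segEnds <- breakpoints[breakpoints > 0]
  for (tend in segEnds) {
    sol <- deSolve::ode(y = state, times = c(tcur, tend), func = deriv,
                        parms = mult, method = "lsoda",
                        rtol = 1e-10, atol = 1e-12)
    state <- sol[nrow(sol), 2:4]
    tcur <- tend
    out[times == tend, ] <- rep(state, each = sum(times == tend))
    mult <- applyEvents(mult, tend)
  }
  TimeCourse(times = times, mrna = out[, "M"],
             proteinTotal = out[, "U"] + out[, "L"],
             proteinLabeled = pmax(out[, "L"], 0),
             proteinUnlabeled = pmax(out[, "U"], 0))
}
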