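#' @include AllClasses.R AllGenerics.R kinetics.R
NULL

# ---- piecewise-analytic propagation ----------------------------------------
#
# Within any interval where the multipliers are constant the system is linear
# with constant coefficients, so it admits the exact segment solution
#   M(tau) = Minf + (Ms - Minf) exp(-kM tau),          Minf = c * M0
#   P(tau) = Ps exp(-k tau)
#            + R' [ Minf phi1(k, tau) + (Ms - Minf) phi2(kM, k, tau) ]
# with phi1, phi2 the stable kernels from kinetics.R. Perturbations are
# instantaneous multiplier steps, so trajectories are propagated exactly from
# breakpoint to breakpoint with continuity of state.

.poolStep <- function(Ps, synthOn, Rp, Ms, Minf, kM, k, tau) {
  Ps * exp(-k * tau) +
    (if (synthOn) Rp * (Minf * .phi1(k, tau) + (Ms - Minf) * .phi2(kM, k, tau))
     else 0)
}

# internal engine shared by simulateScenario, pulseChase and silacSwitch.
# labelOffAt: time at which synthesis reverts to the unlabelled pool.
# labeledDegMult: extra degradation multiplier applied to the labelled pool
# only (newly synthesised protein may be degraded at a different rate).
.propagate <- function(params, perturbations, times,
                       initialCondition = NULL,
                       labelActiveAtStart = FALSE, labelOffAt = NULL,
                       labeledDegMult = 1) {
  .checkTimes(times)
  rc <- rateConstants(params)
  M0 <- params@mrnaCopies
  R0 <- params@translationRate

  events <- perturbations
  if (!is.null(labelOffAt))
    events <- rbind(events,
                    data.frame(onset = labelOffAt, kind = "label_off",
                               magnitude = NA_real_))
  events <- events[order(events$onset), , drop = FALSE]

  if (is.null(initialCondition)) {
    M <- M0
    U <- M0 * R0 / rc@kP
  } else {
    M <- unname(initialCondition["mrna"])
    U <- unname(initialCondition["protein"])
  }
  L <- 0
  if (labelActiveAtStart) { L <- 0 }  # labelled pool always starts empty

  mult <- list(s = 1, c = 1, g = 1, label = isTRUE(labelActiveAtStart))
  applyEvents <- function(mult, tt) {
    for (i in which(events$onset == tt)) {
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

  tmax <- if (length(times)) max(times) else 0
  bps <- sort(unique(c(0, events$onset[events$onset > 0 &
                                         events$onset <= tmax])))
  nseg <- length(bps)
  segStart <- bps
  segM <- segU <- segL <- numeric(nseg)
  segMult <- vector("list", nseg)

  for (i in seq_len(nseg)) {
    if (i > 1L) {
      # advance state across the previous segment
      tau <- segStart[i] - segStart[i - 1L]
      st <- .segAdvance(segM[i - 1L], segU[i - 1L], segL[i - 1L],
                        segMult[[i - 1L]], tau, M0, R0, rc, labeledDegMult)
      M <- st[1]; U <- st[2]; L <- st[3]
      mult <- applyEvents(segMult[[i - 1L]], segStart[i])
    }
    segM[i] <- M; segU[i] <- U; segL[i] <- L
    segMult[[i]] <- mult
  }

  idx <- findInterval(times, segStart)
  idx[idx < 1L] <- 1L
  outM <- outU <- outL <- numeric(length(times))
  for (j in seq_along(times)) {
    i <- idx[j]
    tau <- times[j] - segStart[i]
    st <- .segAdvance(segM[i], segU[i], segL[i], segMult[[i]], tau,
                      M0, R0, rc, labeledDegMult)
    outM[j] <- st[1]; outU[j] <- st[2]; outL[j] <- st[3]
  }
  TimeCourse(times = times, mrna = outM, proteinTotal = outU + outL,
             proteinLabeled = outL, proteinUnlabeled = outU)
}

.segAdvance <- function(M, U, L, mult, tau, M0, R0, rc, labeledDegMult) {
  if (tau == 0) return(c(M, U, L))
  Minf <- mult$c * M0
  Rp <- mult$s * R0
  kU <- mult$g * rc@D + rc@V
  kL <- mult$g * labeledDegMult * rc@D + rc@V
  Mnew <- Minf + (M - Minf) * exp(-rc@kM * tau)
  Unew <- .poolStep(U, !mult$label, Rp, M, Minf, rc@kM, kU, tau)
  Lnew <- .poolStep(L, mult$label, Rp, M, Minf, rc@kM, kL, tau)
  c(Mnew, Unew, Lnew)
}

#' Simulate a scenario
#'
#' Propagates the turnover system through the ordered perturbations of a
#' scenario and returns the trajectory at the scenario's sampling times.
#' Propagation is piecewise-analytic (exact per segment), so results agree
#' with [integrateReference()] to the integrator's tolerance with no step-size
#' artefacts.
#'
#' @param scenario a [Scenario-class].
#' @param params a [TurnoverParams-class].
#' @return A [TimeCourse-class].
#' @examples
#' tp <- TurnoverParams(10, 2, 0.5, 2)
#' sc <- scenarioPreset("chx_chase", samplingTimes = seq(0, 8, by = 0.5))
#' simulateScenario(sc, tp)
#' @export
simulateScenario <- function(scenario, params) {
  validObject(scenario)
  validObject(params)
  p <- scenario@perturbations
  hasLabel <- any(p$kind == "label_switch")
  explicitIC <- length(scenario@initialCondition) > 0L
  if (hasLabel && explicitIC)
    stop("unsupported combination: label_switch with an explicit ",
         "non-steady initial condition (pre-existing pool is undefined)")
  .propagate(params, p, scenario@samplingTimes,
             initialCondition = if (explicitIC) scenario@initialCondition
                                else NULL)
}

#' Canonical experimental-design presets
#'
#' Returns the scenario corresponding to a named standard design for
#' measuring protein degradation:
#' \describe{
#'   \item{chx_chase}{total protein-synthesis block at the onset
#'     (cycloheximide chase); decay is the pure exponential \eqn{e^{-k_P t}}.}
#'   \item{tet_off}{transcriptional shutoff; decline is rate-limited by mRNA
#'     decay whenever the mRNA half-life is not much shorter than the protein
#'     half-life.}
#'   \item{sirna_knockdown}{transcription reduced to a residual fraction
#'     \code{residualFraction} (mRNA relaxes to that fraction of its steady
#'     level), optionally combined with a translation multiplier on the
#'     remaining mRNA, since RNA interference acts through mRNA decay and/or
#'     translational inhibition.}
#'   \item{degradation_inhibitor}{degradation rate scaled by
#'     \code{degradationMultiplier} (default 0, complete block), optionally
#'     with a transcriptional side effect (\code{transcriptionMultiplier}),
#'     as degradation inhibitors can upregulate transcription.}
#'   \item{chx_plus_inhibitor}{synthesis block combined with a degradation
#'     multiplier.}
#' }
#'
#' @param name design name (see above).
#' @param samplingTimes sampling times of the returned scenario, hours.
#' @param residualFraction residual transcription under siRNA (default 0.2).
#' @param synthesisMultiplier optional translation multiplier for
#'   \code{sirna_knockdown} (default \code{NULL}: none).
#' @param degradationMultiplier degradation-rate multiplier for the inhibitor
#'   designs (default 0).
#' @param transcriptionMultiplier transcriptional side-effect multiplier for
#'   \code{degradation_inhibitor} (default 1: no side effect).
#' @param onset time at which the design's perturbations fire, hours.
#' @return A [Scenario-class].
#' @export
scenarioPreset <- function(name, samplingTimes = numeric(0),
                           residualFraction = 0.2,
                           synthesisMultiplier = NULL,
                           degradationMultiplier = 0,
                           transcriptionMultiplier = 1,
                           onset = 0) {
  name <- match.arg(name, c("chx_chase", "tet_off", "sirna_knockdown",
                            "degradation_inhibitor", "chx_plus_inhibitor"))
  chkMult <- function(x, nm) {
    if (!is.null(x) && (!is.finite(x) || x < 0))
      stop(sprintf("'%s' must be a finite multiplier >= 0", nm))
  }
  chkMult(residualFraction, "residualFraction")
  chkMult(synthesisMultiplier, "synthesisMultiplier")
  chkMult(degradationMultiplier, "degradationMultiplier")
  chkMult(transcriptionMultiplier, "transcriptionMultiplier")

  p <- switch(name,
    chx_chase = Perturbation("synthesis_multiplier", 0, onset),
    tet_off = Perturbation("transcription_multiplier", 0, onset),
    sirna_knockdown = {
      p <- Perturbation("transcription_multiplier", residualFraction, onset)
      if (!is.null(synthesisMultiplier))
        p <- rbind(p, Perturbation("synthesis_multiplier",
                                   synthesisMultiplier, onset))
      p
    },
    degradation_inhibitor = {
      p <- Perturbation("degradation_multiplier", degradationMultiplier, onset)
      if (transcriptionMultiplier != 1)
        p <- rbind(p, Perturbation("transcription_multiplier",
                                   transcriptionMultiplier, onset))
      p
    },
    chx_plus_inhibitor = rbind(
      Perturbation("synthesis_multiplier", 0, onset),
      Perturbation("degradation_multiplier", degradationMultiplier, onset))
  )
  Scenario(perturbations = p, samplingTimes = samplingTimes)
}

#' Simulate a pulse-chase experiment
#'
#' Labels all protein synthesised during a pulse of the given duration (the
#' system otherwise at steady state), then follows the labelled pool through
#' a chase. During the chase the labelled pool receives no synthesis, so an
#' unperturbed chase decays as \eqn{e^{-k_P t}}; chase-scenario perturbations
#' (e.g. degradation inhibitors added at the start of the chase) apply during
#' the chase only. Times in the returned trajectory are measured from the
#' start of the chase.
#'
#' @param params a [TurnoverParams-class].
#' @param pulseDuration labelling pulse length, hours (> 0).
#' @param chaseScenario a [Scenario-class] whose perturbations (onsets
#'   relative to the chase start) and sampling times define the chase;
#'   must not contain a \code{label_switch}.
#' @param labeledDegradationMultiplier optional multiplier applied to the
#'   degradation rate of the labelled (newly synthesised) pool only, default
#'   1 (newly synthesised protein kinetically identical to pre-existing).
#' @return A [TimeCourse-class]; \code{proteinLabeled} is the pulse-labelled
#'   pool.
#' @export
pulseChase <- function(params, pulseDuration, chaseScenario = Scenario(),
                       labeledDegradationMultiplier = 1) {
  if (!is.finite(pulseDuration) || pulseDuration <= 0)
    stop("'pulseDuration' must be > 0 hours")
  validObject(chaseScenario)
  p <- chaseScenario@perturbations
  if (any(p$kind == "label_switch"))
    stop("label_switch inside the chase scenario: labels are set by the pulse")
  # internal clock starts at the pulse; shift chase onsets/times accordingly
  if (nrow(p)) p$onset <- p$onset + pulseDuration
  tc <- .propagate(params, p,
                   times = chaseScenario@samplingTimes + pulseDuration,
                   labelActiveAtStart = TRUE, labelOffAt = pulseDuration,
                   labeledDegMult = labeledDegradationMultiplier)
  TimeCourse(times = tc@times - pulseDuration, mrna = tc@mrna,
             proteinTotal = tc@proteinTotal,
             proteinLabeled = tc@proteinLabeled,
             proteinUnlabeled = tc@proteinUnlabeled)
}

#' Simulate a SILAC medium-switch experiment
#'
#' From steady state, all synthesis from t = 0 is isotopically heavy
#' (labelled) while growth and degradation continue unchanged. The
#' pre-existing light pool decays as \eqn{P_0 e^{-k_P t}}, the heavy pool
#' accumulates as \eqn{P_0 (1 - e^{-k_P t})}, and the total stays constant at
#' \eqn{P_0}: the heavy/light ratio reads out the effective removal rate
#' \eqn{k_P = D + V} under fully unperturbed, steady-state conditions.
#'
#' @param params a [TurnoverParams-class].
#' @param times sampling times since the medium switch, hours.
#' @return A [TimeCourse-class]; \code{proteinLabeled} is the heavy pool,
#'   \code{proteinUnlabeled} the light pool.
#' @export
silacSwitch <- function(params, times) {
  .propagate(params, data.frame(onset = numeric(0), kind = character(0),
                                magnitude = numeric(0)),
             times = times, labelActiveAtStart = TRUE)
}

#' Predict the fold change under a degradation inhibitor
#'
#' Computes \eqn{P(t)/P_0} after simultaneously scaling the degradation rate
#' and (optionally) transcription at t = 0 from steady state, and decomposes
#' the observed fold change into the part achievable by the degradation block
#' alone (transcription unchanged) and the residual factor that must come
#' from increased synthesis. With degradation fully blocked and transcription
#' unchanged, accumulation is bounded by the synthesis flux: a long-lived
#' protein (\eqn{t_{1/2}} tens of hours) can only gain
#' \eqn{1 + D t} fold in a few hours, so a several-fold rise over such a
#' window cannot arise from the degradation block and is attributed to
#' increased synthesis.
#'
#' @param params a [TurnoverParams-class].
#' @param degradationMultiplier multiplier on D (0 = complete block).
#' @param transcriptionMultiplier multiplier on transcription (1 = unchanged).
#' @param t treatment duration(s), hours (vectorised).
#' @return A list with components \code{foldChange} (observed
#'   \eqn{P(t)/P_0}), \code{degradationComponent} (fold change with
#'   transcription unchanged) and \code{synthesisComponent}
#'   (\code{foldChange / degradationComponent}), each vectorised over
#'   \code{t}.
#' @examples
#' tp <- TurnoverParams(10, 2, 0.5, 40)   # 40 h half-life protein
#' predictFoldChange(tp, 0, 1, 8)$foldChange   # 1 + 8*log(2)/40
#' @export
predictFoldChange <- function(params, degradationMultiplier,
                              transcriptionMultiplier, t) {
  if (!is.finite(degradationMultiplier) || degradationMultiplier < 0 ||
      !is.finite(transcriptionMultiplier) || transcriptionMultiplier < 0)
    stop("multipliers must be finite and >= 0")
  .checkTimes(t)
  P0 <- steadyState(params)
  run <- function(cmult) {
    p <- rbind(Perturbation("degradation_multiplier", degradationMultiplier),
               if (cmult != 1)
                 Perturbation("transcription_multiplier", cmult))
    proteinTotal(.propagate(params, p, times = t)) / P0
  }
  fold <- run(transcriptionMultiplier)
  degOnly <- run(1)
  list(foldChange = fold, degradationComponent = degOnly,
       synthesisComponent = fold / degOnly)
}
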