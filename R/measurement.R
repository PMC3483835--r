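#' @include AllClasses.R AllGenerics.R
NULL

#' Sample noisy replicate measurements from a trajectory
#'
#' Converts a noiseless trajectory into immunoblot/pulse-chase-like replicate
#' measurements. Each observation is the true channel value multiplied by an
#' independent lognormal factor with mean exactly 1 and coefficient of
#' variation \code{cv} (densitometry noise is multiplicative and positive),
#' censored at the detection floor, then normalised to the mean signal at the
#' first sampling time. Sampling is fully determined by the seed in the noise
#' model.
#'
#' Channels: \code{"total"} (total protein), \code{"labeled"} (pulse-labelled
#' or heavy pool) and \code{"heavy_fraction"}
#' (\code{proteinLabeled / proteinTotal}, the SILAC readout).
#'
#' @param tc a [TimeCourse-class].
#' @param channel which trajectory channel to measure.
#' @param noise a [NoiseModel-class].
#' @return A [MeasurementSet-class] with
#'   \code{replicates * length(times)} observations.
#' @export
sampleMeasurements <- function(tc, channel = c("total", "labeled",
                                               "heavy_fraction"),
                               noise = NoiseModel()) {
  channel <- match.arg(channel)
  validObject(noise)
  if (length(tc@times) == 0L) stop("empty time course")
  truth <- switch(channel,
    total = tc@proteinTotal,
    labeled = {
      if (all(tc@proteinLabeled == 0))
        stop("channel 'labeled' absent: trajectory has no labelled pool")
      tc@proteinLabeled
    },
    heavy_fraction = {
      if (all(tc@proteinLabeled == 0))
        stop("channel 'heavy_fraction' absent: trajectory has no labelled pool")
      tc@proteinLabeled / tc@proteinTotal
    })

  n <- length(truth)
  reps <- noise@replicates
  if (noise@cv > 0) {
    # lognormal with mean exactly 1: sdlog^2 = log(1 + cv^2)
    sdl <- sqrt(log1p(noise@cv^2))
    fac <- withr::with_seed(noise@seed,
      stats::rlnorm(n * reps, meanlog = -sdl^2 / 2, sdlog = sdl))
  } else {
    fac <- rep(1, n * reps)
  }
  obs <- rep(truth, times = reps) * fac
  time <- rep(tc@times, times = reps)
  replicate <- rep(seq_len(reps), each = n)
  ms <- normalizeT0(MeasurementSet(time = time, replicate = replicate,
                                   signal = obs))
  # the detection floor is a relative signal, so censoring applies on the
  # normalised (percent-of-initial) scale
  if (noise@detectionFloor > 0)
    ms <- MeasurementSet(time = ms@time, replicate = ms@replicate,
                         signal = pmax(ms@signal, noise@detectionFloor))
  ms
}

#' Normalise a measurement set to its initial mean signal
#'
#' Divides every signal by the mean signal at the earliest sampling time
#' (percent-of-initial convention). Idempotent up to floating point:
#' normalising an already-normalised set rescales by a factor of 1.
#'
#' @param ms a [MeasurementSet-class].
#' @return The normalised [MeasurementSet-class].
#' @export
normalizeT0 <- function(ms) {
  t0 <- min(ms@time)
  m0 <- mean(ms@signal[ms@time == t0])
  if (m0 <= 0) stop("cannot normalise: mean signal at t0 is not positive")
  MeasurementSet(time = ms@time, replicate = ms@replicate,
                 signal = ms@signal / m0)
}
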