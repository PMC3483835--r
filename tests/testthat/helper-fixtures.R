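# shared fixtures: seeded random parameter sets and small independent oracles

# random but reproducible turnover parameter sets: half-lives log-uniform in
# [0.1, 100] h, doubling times half non-dividing / half uniform in [12, 72] h
randomTurnoverParams <- function(n, seed = 42L) {
  withr::with_seed(seed, lapply(seq_len(n), function(i) {
    TurnoverParams(
      mrnaCopies = stats::runif(1, 1, 100),
      translationRate = exp(stats::runif(1, log(0.1), log(10))),
      mrnaHalfLife = exp(stats::runif(1, log(0.1), log(100))),
      proteinHalfLife = exp(stats::runif(1, log(0.1), log(100))),
      doublingTime = if (stats::runif(1) < 0.5) "non-dividing"
                     else stats::runif(1, 12, 72))
  }))
}

effHalfLife <- function(tp) log(2) / rateConstants(tp)@kP

# max deviation relative to the trajectory scale (initial abundance)
relDev <- function(a, b, scale = max(abs(b))) max(abs(a - b)) / scale

# independent bisection oracle for the 50% crossing of the equal-half-lives
# transcription-shutoff decline (1 + ln2 * tau) * exp(-ln2 * tau) = 0.5,
# tau in units of the (effective) half-life
shutoffT50EqualOracle <- function() {
  stats::uniroot(function(x) (1 + log(2) * x) * exp(-log(2) * x) - 0.5,
                 c(1, 5), tol = 1e-12)$root
}
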