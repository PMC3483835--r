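test_that("half-life to rate-constant conversions use ln 2 in hours", {
  rc <- rateConstants(TurnoverParams(10, 2, 0.5, 1))
  expect_equal(rc@D, log(2), tolerance = 1e-12)
  expect_equal(rc@kP, log(2), tolerance = 1e-12)   # non-dividing: V = 0
  expect_equal(rc@V, 0)
  expect_equal(rc@kM, log(2) / 0.5, tolerance = 1e-12)

  rc24 <- rateConstants(TurnoverParams(10, 2, 0.5, 1, doublingTime = 24))
  expect_equal(rc24@V, log(2) / 24, tolerance = 1e-12)
  expect_equal(rc24@kP, log(2) + log(2) / 24, tolerance = 1e-12)
  expect_equal(rc24@kP, rc24@D + rc24@V)
})

test_that("invalid parameters are rejected with the offending field named", {
  expect_error(TurnoverParams(10, 2, -1, 1), "mrnaHalfLife")
  expect_error(TurnoverParams(10, 2, 0.5, 0), "proteinHalfLife")
  expect_error(TurnoverParams(0, 2, 0.5, 1), "mrnaCopies")
  expect_error(TurnoverParams(10, -2, 0.5, 1), "translationRate")
  expect_error(TurnoverParams(10, 2, 0.5, 1, doublingTime = -24),
               "doublingTime")
  # non-dividing spellings all accepted
  expect_equal(rateConstants(TurnoverParams(10, 2, 0.5, 1, "none"))@V, 0)
  expect_equal(rateConstants(TurnoverParams(10, 2, 0.5, 1, Inf))@V, 0)
})

test_that("steady state is M*R/(D+V) and the fixed point of the dynamics", {
  # frozen expected values previously confirmed by integrating the ODE from
  # an empty protein pool to convergence
  expect_equal(steadyState(TurnoverParams(10, 2, 0.5, 1)),
               28.8539, tolerance = 1e-4)
  expect_equal(steadyState(TurnoverParams(10, 2, 0.5, 1, 24)),
               27.69974, tolerance = 1e-4)
  expect_equal(steadyState(TurnoverParams(10, 0, 0.5, 1)), 0)

  # convergence to P0 from a perturbed initial condition
  tp <- TurnoverParams(10, 2, 0.5, 1, 24)
  tc <- integrateReference(tp, times = c(0, 40),
                           initialCondition = c(mrna = 10, protein = 0))
  expect_equal(proteinTotal(tc)[2], steadyState(tp), tolerance = 1e-8)
})

test_that("synthesis-block decay is the pure effective-removal exponential", {
  tp <- TurnoverParams(10, 2, 0.5, 40)
  expect_equal(solveSynthesisBlock(tp, 0), 1)
  expect_equal(solveSynthesisBlock(tp, 40), 0.5, tolerance = 1e-12)
  expect_equal(solveSynthesisBlock(tp, 8), exp(-8 * log(2) / 40),
               tolerance = 1e-12)
  expect_equal(solveSynthesisBlock(tp, 8), 0.8706, tolerance = 1e-4)
  expect_error(solveSynthesisBlock(tp, -1), "times")
})

test_that("transcription-shutoff solution matches its closed forms", {
  # degenerate limit (equal half-lives): (1 + k t) exp(-k t)
  tpd <- TurnoverParams(10, 2, 1, 1)
  expect_equal(solveTranscriptionShutoff(tpd, 0), 1)
  expect_equal(solveTranscriptionShutoff(tpd, 1),
               (1 + log(2)) * exp(-log(2)), tolerance = 1e-12)
  expect_equal(solveTranscriptionShutoff(tpd, 1), 0.8466, tolerance = 1e-4)
  # fast mRNA decay: protein decline tracks its own half-life
  tps <- TurnoverParams(10, 2, 0.1, 10)
  expect_equal(solveTranscriptionShutoff(tps, 10), 0.505, tolerance = 1e-3)
  expect_error(solveTranscriptionShutoff(tps, c(1, -2)), "times")
})

test_that("closed forms agree with the numeric reference integrator", {
  for (tp in randomTurnoverParams(25, seed = 101L)) {
    th <- effHalfLife(tp)
    P0 <- steadyState(tp)
    times <- c(0, 0.25, 1, 2.5) * th

    blk <- integrateReference(tp,
      data.frame(onset = 0, kind = "synthesis_multiplier", magnitude = 0),
      times = times)
    expect_lt(relDev(proteinTotal(blk) / P0, solveSynthesisBlock(tp, times),
                     scale = 1), 1e-6)

    off <- integrateReference(tp,
      data.frame(onset = 0, kind = "transcription_multiplier", magnitude = 0),
      times = times)
    expect_lt(relDev(proteinTotal(off) / P0,
                     solveTranscriptionShutoff(tp, times), scale = 1), 1e-6)
  }
})

test_that("unperturbed trajectories stay at steady state", {
  for (tp in randomTurnoverParams(10, seed = 7L)) {
    times <- seq(0, 10 * effHalfLife(tp), length.out = 21)
    tc <- integrateReference(tp, times = times)
    expect_lt(relDev(proteinTotal(tc), rep(steadyState(tp), 21)), 1e-8)
  }
})

test_that("shutoff solution is continuous across the degeneracy", {
  kP <- log(2)  # tp = 1 h, non-dividing
  t <- c(0.3, 1, 2.7, 6)
  ref <- solveTranscriptionShutoff(TurnoverParams(10, 2, 1, 1), t)
  for (eps in c(-1e-7, 1e-7, -1e-10, 1e-10)) {
    tmEps <- log(2) / (kP * (1 + eps))
    near <- solveTranscriptionShutoff(TurnoverParams(10, 2, tmEps, 1), t)
    expect_lt(max(abs(near - ref)), 1e-6)
  }
})

test_that("shutoff limits: fast mRNA decay gives a chase, slow gives a plateau", {
  tp <- function(tm) TurnoverParams(10, 2, tm, 5)
  t <- c(1, 5, 10)
  # kM -> infinity: shutoff converges to the synthesis-block exponential
  expect_equal(solveTranscriptionShutoff(tp(1e-4), t),
               solveSynthesisBlock(tp(1e-4), t), tolerance = 1e-3)
  # kM -> 0: protein barely moves on any finite horizon
  expect_equal(solveTranscriptionShutoff(tp(1e6), t), rep(1, 3),
               tolerance = 1e-4)
})

test_that("reference integrator validates its inputs", {
  tp <- TurnoverParams(10, 2, 0.5, 1)
  expect_error(integrateReference(tp, times = c(2, 1)), "sorted")
  expect_error(integrateReference(tp,
    data.frame(onset = 50, kind = "synthesis_multiplier", magnitude = 0),
    times = c(0, 1)), "breakpoint")
})
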