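test_that("empty scenarios and canonical presets reduce to the closed forms", {
  tp <- TurnoverParams(10, 2, 0.5, 2)
  P0 <- steadyState(tp)

  flat <- simulateScenario(Scenario(samplingTimes = c(0, 5, 20)), tp)
  expect_equal(proteinTotal(flat), rep(P0, 3), tolerance = 1e-12)

  chx <- simulateScenario(
    scenarioPreset("chx_chase", samplingTimes = c(0, 1, 2, 6)), tp)
  expect_equal(proteinTotal(chx) / P0,
               solveSynthesisBlock(tp, c(0, 1, 2, 6)), tolerance = 1e-12)
  expect_equal(proteinTotal(chx)[3] / P0, 0.5, tolerance = 1e-12)

  tpd <- TurnoverParams(10, 2, 1, 1)
  tet <- simulateScenario(scenarioPreset("tet_off", samplingTimes = c(0, 1)),
                          tpd)
  expect_equal(proteinTotal(tet)[2] / steadyState(tpd), 0.8466,
               tolerance = 1e-4)
  expect_equal(proteinTotal(tet) / steadyState(tpd),
               solveTranscriptionShutoff(tpd, c(0, 1)), tolerance = 1e-10)
})

test_that("siRNA knockdown relaxes protein to the residual fraction", {
  tp <- TurnoverParams(10, 2, 0.05, 5)   # mRNA much faster than protein
  sc <- scenarioPreset("sirna_knockdown", samplingTimes = c(0, 200),
                       residualFraction = 0.2)
  rel <- proteinTotal(simulateScenario(sc, tp)) / steadyState(tp)
  expect_equal(rel[2], 0.2, tolerance = 1e-6)
  # the residual fraction rescales the steady state (Eq 2 scaling)
  sc5 <- scenarioPreset("sirna_knockdown", samplingTimes = 200,
                        residualFraction = 0.45)
  expect_equal(proteinTotal(simulateScenario(sc5, tp)) / steadyState(tp),
               0.45, tolerance = 1e-6)
})

test_that("a complete degradation block accumulates linearly at rate D*P0", {
  tp <- TurnoverParams(10, 2, 0.5, 40)   # non-dividing
  P0 <- steadyState(tp)
  D <- rateConstants(tp)@D
  sc <- scenarioPreset("degradation_inhibitor", samplingTimes = c(0, 2, 4, 8),
                       degradationMultiplier = 0, transcriptionMultiplier = 1)
  got <- proteinTotal(simulateScenario(sc, tp)) / P0
  expect_equal(got, 1 + D * c(0, 2, 4, 8), tolerance = 1e-10)
})

test_that("scenario composition is segment-consistent", {
  tp <- TurnoverParams(20, 1.5, 0.8, 6, 30)
  full <- simulateScenario(Scenario(
    rbind(Perturbation("synthesis_multiplier", 0.3, onset = 0),
          Perturbation("degradation_multiplier", 2, onset = 3)),
    samplingTimes = c(3, 5, 9)), tp)

  # state reached under the first segment ...
  atSwitch <- simulateScenario(Scenario(
    Perturbation("synthesis_multiplier", 0.3, onset = 0),
    samplingTimes = 3), tp)
  # ... restarted explicitly with both multipliers active
  resumed <- simulateScenario(Scenario(
    rbind(Perturbation("synthesis_multiplier", 0.3, onset = 0),
          Perturbation("degradation_multiplier", 2, onset = 0)),
    samplingTimes = c(2, 6),
    initialCondition = c(mrna = mrna(atSwitch), protein = proteinTotal(atSwitch))),
    tp)
  expect_equal(proteinTotal(resumed), proteinTotal(full)[2:3],
               tolerance = 1e-8)
  expect_equal(mrna(resumed), mrna(full)[2:3], tolerance = 1e-8)
})

test_that("preset trajectories agree with the numeric reference integrator", {
  presets <- list(
    function(t) scenarioPreset("chx_chase", samplingTimes = t),
    function(t) scenarioPreset("tet_off", samplingTimes = t),
    function(t) scenarioPreset("sirna_knockdown", samplingTimes = t),
    function(t) scenarioPreset("degradation_inhibitor", samplingTimes = t,
                               transcriptionMultiplier = 2),
    function(t) scenarioPreset("chx_plus_inhibitor", samplingTimes = t,
                               degradationMultiplier = 0.1))
  for (tp in randomTurnoverParams(10, seed = 202L)) {
    th <- effHalfLife(tp)
    P0 <- steadyState(tp)
    times <- c(0, 0.5, 1.5, 3) * th
    for (mk in presets) {
      sc <- mk(times)
      sim <- simulateScenario(sc, tp)
      ref <- integrateReference(tp, sc@perturbations, times)
      expect_lt(relDev(proteinTotal(sim), proteinTotal(ref),
                       scale = max(P0, proteinTotal(ref))), 1e-6)
      expect_lt(relDev(mrna(sim), mrna(ref), scale = tp@mrnaCopies), 1e-6)
    }
  }
})

test_that("pulse-chase labels accumulate during the pulse and chase out at kP", {
  tp <- TurnoverParams(10, 2, 0.5, 2)   # non-dividing, tp = 2 h
  P0 <- steadyState(tp)
  pc <- pulseChase(tp, 0.5, Scenario(samplingTimes = c(0, 2, 4)))
  # labelled pool at chase start: integral of synthesis against removal
  expect_equal(proteinLabeled(pc)[1] / P0, 1 - exp(-0.5 * log(2) / 2),
               tolerance = 1e-10)
  expect_equal(proteinLabeled(pc)[1] / P0, 0.1591, tolerance = 1e-4)
  # unperturbed chase: labelled fraction halves every protein half-life
  expect_equal(proteinLabeled(pc)[2] / proteinLabeled(pc)[1], 0.5,
               tolerance = 1e-10)
  expect_equal(proteinLabeled(pc)[3] / proteinLabeled(pc)[1], 0.25,
               tolerance = 1e-10)

  # degradation blocked during the chase: labelled pool is frozen
  frozen <- pulseChase(tp, 0.5, scenarioPreset("degradation_inhibitor",
    samplingTimes = c(0, 2, 4), degradationMultiplier = 0))
  expect_equal(proteinLabeled(frozen),
               rep(proteinLabeled(frozen)[1], 3), tolerance = 1e-10)

  expect_error(pulseChase(tp, 0, Scenario(samplingTimes = 1)),
               "pulseDuration")
  expect_error(pulseChase(tp, 0.5,
    Scenario(Perturbation("label_switch"), samplingTimes = 1)),
    "label_switch")
})

test_that("label conservation holds at every sampled time", {
  for (tp in randomTurnoverParams(8, seed = 303L)) {
    th <- effHalfLife(tp)
    pc <- pulseChase(tp, 0.3 * th,
                     Scenario(samplingTimes = seq(0, 3 * th, length.out = 9)))
    expect_lt(max(abs(proteinLabeled(pc) + proteinUnlabeled(pc) -
                        proteinTotal(pc))) / max(proteinTotal(pc)), 1e-9)
  }
})

test_that("SILAC switch: heavy rises, light falls, total invariant at P0", {
  tp <- TurnoverParams(10, 2, 0.5, 40, doublingTime = 24)
  P0 <- steadyState(tp)
  kP <- rateConstants(tp)@kP
  times <- c(0, 8, log(2) / kP, 50)
  s <- silacSwitch(tp, times)
  hf <- proteinLabeled(s) / proteinTotal(s)
  expect_equal(hf[1], 0)
  expect_equal(hf[2], 1 - exp(-8 * kP), tolerance = 1e-10)
  expect_equal(hf[2], 0.3090, tolerance = 1e-3)     # kP = ln2/40 + ln2/24
  expect_equal(hf[3], 0.5, tolerance = 1e-10)       # one effective half-life
  expect_equal(proteinUnlabeled(s) / P0, exp(-kP * times), tolerance = 1e-10)
  expect_lt(relDev(proteinTotal(s), rep(P0, 4)), 1e-8)
  expect_error(silacSwitch(tp, c(-1, 2)), "times")
})

test_that("label switch with an explicit initial condition is rejected", {
  tp <- TurnoverParams(10, 2, 0.5, 2)
  sc <- Scenario(Perturbation("label_switch"), samplingTimes = c(0, 1),
                 initialCondition = c(mrna = 5, protein = 3))
  expect_error(simulateScenario(sc, tp), "unsupported combination")
})

test_that("fold-change prediction decomposes degradation and synthesis", {
  tp40 <- TurnoverParams(10, 2, 0.5, 40)
  # full degradation block, transcription unchanged, 8 h
  f <- predictFoldChange(tp40, 0, 1, 8)
  expect_equal(f$foldChange, 1 + 8 * log(2) / 40, tolerance = 1e-10)
  expect_equal(f$synthesisComponent, 1, tolerance = 1e-10)

  # no perturbation at all: identity at any time
  id <- predictFoldChange(tp40, 1, 1, c(1, 8, 24))
  expect_equal(id$foldChange, rep(1, 3), tolerance = 1e-10)

  # doubling transcription with fast mRNA: fold approaches 2 (Eq 2 scaling)
  tpf <- TurnoverParams(10, 2, 0.05, 5)
  f2 <- predictFoldChange(tpf, 1, 2, 200)
  expect_equal(f2$foldChange, 2, tolerance = 1e-6)
  expect_equal(f2$degradationComponent, 1, tolerance = 1e-10)
  expect_equal(f2$synthesisComponent, 2, tolerance = 1e-6)
})
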