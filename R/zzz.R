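#' proteoturn: simulation and critical appraisal of protein degradation experiments
#'
#' Deterministic model of cellular protein turnover
#' (\eqn{dP/dt = M(t) R - P(t)(D + V)}) with piecewise-analytic simulation of
#' the standard degradation-measurement designs, replicate measurement noise,
#' half-life estimators that expose the mRNA-decay confound of shutoff
#' designs, and a checklist-based evidence-grading engine.
#'
#' @keywords internal
"_PACKAGE"
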