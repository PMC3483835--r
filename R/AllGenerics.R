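#' @include AllClasses.R
NULL

#' @rdname rateConstants
#' @export
setGeneric("rateConstants", function(params) standardGeneric("rateConstants"))

#' @rdname steadyState
#' @export
setGeneric("steadyState", function(params) standardGeneric("steadyState"))

#' Accessors
#'
#' Small accessor generics for the package's S4 containers; use these rather
#' than reaching into slots.
#'
#' @param object an object of the documented class.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("sampleTimes", function(object) standardGeneric("sampleTimes"))
#' @rdname accessors
#' @export
setGeneric("mrna", function(object) standardGeneric("mrna"))
#' @rdname accessors
#' @export
setGeneric("proteinTotal", function(object) standardGeneric("proteinTotal"))
#' @rdname accessors
#' @export
setGeneric("proteinLabeled", function(object) standardGeneric("proteinLabeled"))
#' @rdname accessors
#' @export
setGeneric("proteinUnlabeled",
           function(object) standardGeneric("proteinUnlabeled"))
#' @rdname accessors
#' @export
setGeneric("halfLife", function(object) standardGeneric("halfLife"))
#' @rdname accessors
#' @export
setGeneric("decayRate", function(object) standardGeneric("decayRate"))
#' @rdname accessors
#' @export
setGeneric("concept", function(object) standardGeneric("concept"))
#' @rdname accessors
#' @export
setGeneric("stdError", function(object) standardGeneric("stdError"))
#' @rdname accessors
#' @export
setGeneric("fitMethod", function(object) standardGeneric("fitMethod"))
#' @rdname accessors
#' @export
setGeneric("overallGrade", function(object) standardGeneric("overallGrade"))
#' @rdname accessors
#' @export
setGeneric("conclusion", function(object) standardGeneric("conclusion"))
#' @rdname accessors
#' @export
setGeneric("requiredControlsOf",
           function(object) standardGeneric("requiredControlsOf"))
#' @rdname accessors
#' @export
setGeneric("matchedRules", function(object) standardGeneric("matchedRules"))
#' @rdname accessors
#' @export
setGeneric("biasRatios", function(object) standardGeneric("biasRatios"))

setMethod("sampleTimes", "TimeCourse", function(object) object@times)
setMethod("mrna", "TimeCourse", function(object) object@mrna)
setMethod("proteinTotal", "TimeCourse", function(object) object@proteinTotal)
setMethod("proteinLabeled", "TimeCourse",
          function(object) object@proteinLabeled)
setMethod("proteinUnlabeled", "TimeCourse",
          function(object) object@proteinUnlabeled)
setMethod("sampleTimes", "MeasurementSet", function(object) object@time)

setMethod("halfLife", "HalfLifeEstimate", function(object) object@halfLife)
setMethod("decayRate", "HalfLifeEstimate", function(object) object@rate)
setMethod("concept", "HalfLifeEstimate", function(object) object@concept)
setMethod("stdError", "HalfLifeEstimate", function(object) object@stderr)
setMethod("fitMethod", "HalfLifeEstimate", function(object) object@method)

setMethod("overallGrade", "AppraisalReport",
          function(object) object@overallGrade)
setMethod("conclusion", "AppraisalReport", function(object) object@conclusion)
setMethod("requiredControlsOf", "AppraisalReport",
          function(object) object@requiredControls)
setMethod("matchedRules", "AppraisalReport",
          function(object) object@matchedRules)

setMethod("biasRatios", "BiasGrid", function(object) object@ratios)

#' @describeIn TimeCourse-class Coerce to a data.frame with the canonical
#'   column names \code{time_h, mrna, protein_total, protein_labeled,
#'   protein_unlabeled}.
#' @param x a \code{TimeCourse}.
#' @param ... ignored.
#' @export
as.data.frame.TimeCourse <- function(x, ...) {
  data.frame(time_h = x@times, mrna = x@mrna, protein_total = x@proteinTotal,
             protein_labeled = x@proteinLabeled,
             protein_unlabeled = x@proteinUnlabeled)
}
setMethod("as.data.frame", "TimeCourse", as.data.frame.TimeCourse)

#' @describeIn MeasurementSet-class Coerce to a long data.frame
#'   (\code{time_h, replicate, signal}).
#' @param x a \code{MeasurementSet}.
#' @param ... ignored.
#' @export
as.data.frame.MeasurementSet <- function(x, ...) {
  data.frame(time_h = x@time, replicate = x@replicate, signal = x@signal)
}
setMethod("as.data.frame", "MeasurementSet", as.data.frame.MeasurementSet)

setMethod("show", "TurnoverParams", function(object) {
  rc <- rateConstants(object)
  cat("TurnoverParams\n",
      sprintf("  mRNA copies/cell:       %g\n", object@mrnaCopies),
      sprintf("  translation rate:       %g /mRNA/h\n", object@translationRate),
      sprintf("  mRNA half-life:         %g h  (kM = %.4g /h)\n",
              object@mrnaHalfLife, rc@kM),
      sprintf("  protein half-life (D):  %g h  (D = %.4g /h)\n",
              object@proteinHalfLife, rc@D),
      if (is.finite(object@doublingTime))
        sprintf("  doubling time:          %g h  (V = %.4g /h)\n",
                object@doublingTime, rc@V)
      else "  doubling time:          non-dividing (V = 0)\n",
      sprintf("  effective removal:      kP = %.4g /h (t1/2,eff = %.4g h)\n",
              rc@kP, log(2) / rc@kP),
      sep = "")
})

setMethod("show", "RateConstants", function(object) {
  cat(sprintf(
    "RateConstants: kM = %.6g, D = %.6g, V = %.6g, kP = %.6g (per hour)\n",
    object@kM, object@D, object@V, object@kP))
})

setMethod("show", "Scenario", function(object) {
  cat("Scenario with", nrow(object@perturbations), "perturbation(s) and",
      length(object@samplingTimes), "sampling time(s)\n")
  if (nrow(object@perturbations)) print(object@perturbations)
})

setMethod("show", "TimeCourse", function(object) {
  cat("TimeCourse:", length(object@times), "time points")
  if (length(object@times))
    cat(sprintf(" over [%g, %g] h", min(object@times), max(object@times)))
  cat("\n")
  df <- as.data.frame(object)
  print(utils::head(df, 6))
  if (nrow(df) > 6) cat("  ...", nrow(df) - 6, "more rows\n")
})

setMethod("show", "HalfLifeEstimate", function(object) {
  cat(sprintf("HalfLifeEstimate (%s, %s): %.4g h (rate %.4g /h%s)\n",
              object@concept, object@method, object@halfLife, object@rate,
              if (is.na(object@stderr)) ""
              else sprintf(", se %.3g h", object@stderr)))
})

setMethod("show", "BiasGrid", function(object) {
  cat(sprintf("BiasGrid (%s): %d mRNA x %d protein half-lives\n",
              object@design, length(object@mrnaHalfLives),
              length(object@proteinHalfLives)))
  m <- object@ratios
  dimnames(m) <- list(paste0("tm=", signif(object@mrnaHalfLives, 3)),
                      paste0("tp=", signif(object@proteinHalfLives, 3)))
  print(signif(m, 4))
})

setMethod("show", "AppraisalReport", function(object) {
  cat("AppraisalReport for ticks {",
      paste(object@ticks, collapse = ", "), "}\n", sep = "")
  cat("  Grade:     ", object@overallGrade, "\n", sep = "")
  cat("  Conclusion:", object@conclusion, "\n")
  if (length(object@requiredControls)) {
    cat("  Compulsory controls / caveats:\n")
    for (ctrl in object@requiredControls) cat("   -", ctrl, "\n")
  } else cat("  No compulsory controls.\n")
  if (length(object@unmatchedTicks))
    cat("  Ticks outside the most specific rule: ",
        paste(object@unmatchedTicks, collapse = ", "), "\n", sep = "")
})
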