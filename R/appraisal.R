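#' @include AllClasses.R AllGenerics.R
NULL

# rules are shipped as a versioned JSON data file and cached per session
.appraisalEnv <- new.env(parent = emptyenv())

.loadRules <- function() {
  if (!is.null(.appraisalEnv$rules)) return(.appraisalEnv$rules)
  path <- system.file("extdata", "appraisal_rules.json",
                      package = "proteoturn", mustWork = TRUE)
  .appraisalEnv$rules <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  .appraisalEnv$rules
}

#' The design checklist table
#'
#' The ten checklist items (design ticks) used by [appraise()], each with its
#' single-item conclusion and evidence grade.
#'
#' @return data.frame with columns \code{id}, \code{label}, \code{conclusion},
#'   \code{grade}.
#' @export
checklistTable <- function() {
  t1 <- .loadRules()$table1
  data.frame(id = vapply(t1, function(x) x$id, numeric(1)),
             label = vapply(t1, function(x) x$label, character(1)),
             conclusion = vapply(t1, function(x) x$conclusion, character(1)),
             grade = vapply(t1, function(x) x$grade, character(1)),
             stringsAsFactors = FALSE)
}

# a rule pattern is a list of alternative groups; it matches when every group
# has at least one ticked member. Pattern size (specificity) = group count.
.ruleMatches <- function(pattern, ticks) {
  all(vapply(pattern, function(g) any(unlist(g) %in% ticks), logical(1)))
}

.ruleCovers <- function(pattern, ticks) {
  intersect(ticks, unlist(pattern))
}

#' Appraise a declared protein-degradation study design
#'
#' Deterministic evidence grading of an experimental design declared as a set
#' of checklist ticks (see [checklistTable()]): 1 untagged / 2 tagged protein;
#' 3 steady-state / 4 kinetic readout; 5 protein synthesis inhibitor; 6
#' radioactive pulse-chase; 7 inhibitors of protein degradation; 8 Tet-on/off
#' or RNA interference; 9 steady-state SILAC-MS; 10 SILAC-MS upon stimulus or
#' stress. The tick set is matched against the twelve combination rules of
#' the checklist (each written for "1 or 2" plus a design signature); the
#' \emph{most specific} matching rule (largest pattern; a superset pattern
#' always outranks its subsets) supplies the overall grade and headline
#' conclusion, and the compulsory controls of every matched rule are
#' aggregated in rule order. Tick sets matching no combination rule fall back
#' to the per-item conclusions, graded worst-case.
#'
#' @param ticks integer vector of tick ids (non-empty subset of 1..10).
#'   Ticks 1 and 2 are mutually exclusive; declaring both proceeds with a
#'   warning.
#' @return An [AppraisalReport-class].
#' @examples
#' appraise(c(1, 9))     # steady-state SILAC of an untagged protein
#' appraise(c(1, 4, 8))  # Tet-off / RNAi kinetic experiment
#' @export
appraise <- function(ticks) {
  ticks <- unique(as.integer(ticks))
  if (!length(ticks)) stop("empty tick set: declare at least one design tick")
  if (any(is.na(ticks)) || any(ticks < 1L) || any(ticks > 10L))
    stop("tick ids must be integers in 1..10")
  ticks <- sort(ticks)
  if (all(c(1L, 2L) %in% ticks))
    warning("ticks 1 (untagged) and 2 (tagged) are mutually exclusive; ",
            "matching proceeds with their union")

  ruleSpec <- .loadRules()
  gradeLabels <- unlist(ruleSpec$grade_labels)

  matched <- Filter(function(r) .ruleMatches(r$pattern, ticks), ruleSpec$rules)
  t1 <- checklistTable()
  tickedRows <- t1[t1$id %in% ticks, , drop = FALSE]

  ruleDf <- if (length(matched)) {
    data.frame(
      id = vapply(matched, function(r) r$id, character(1)),
      type = "combination",
      label = vapply(matched, function(r) r$label, character(1)),
      pattern = vapply(matched, function(r)
        paste(vapply(r$pattern, function(g)
          paste(unlist(g), collapse = "|"), character(1)), collapse = "+"),
        character(1)),
      patternSize = vapply(matched, function(r) length(r$pattern), numeric(1)),
      conclusion = vapply(matched, function(r) r$conclusion, character(1)),
      grade = vapply(matched, function(r) r$grade, character(1)),
      stringsAsFactors = FALSE)
  } else {
    data.frame(id = character(0), type = character(0), label = character(0),
               pattern = character(0), patternSize = numeric(0),
               conclusion = character(0), grade = character(0),
               stringsAsFactors = FALSE)
  }
  rowDf <- data.frame(
    id = paste0("T", tickedRows$id), type = "table1",
    label = tickedRows$label, pattern = as.character(tickedRows$id),
    patternSize = 1, conclusion = tickedRows$conclusion,
    grade = tickedRows$grade, stringsAsFactors = FALSE)

  if (nrow(ruleDf)) {
    # most specific first; ties keep rule-file order (stable sort)
    ruleDf <- ruleDf[order(-ruleDf$patternSize), , drop = FALSE]
    top <- ruleDf[1L, ]
    overall <- top$grade
    concl <- paste0(gradeLabels[[overall]], ": ", top$conclusion)
    topRule <- matched[[which(vapply(matched, function(r) r$id,
                                     character(1)) == top$id)]]
    unmatched <- setdiff(ticks, .ruleCovers(topRule$pattern, ticks))
    controls <- unique(unlist(lapply(matched, function(r)
      r$required_controls), use.names = FALSE))
    if (is.null(controls)) controls <- character(0)
  } else {
    # fallback: per-item conclusions only, graded worst-case
    overall <- .GRADES[max(match(rowDf$grade, .GRADES))]
    concl <- paste0(gradeLabels[[overall]], ": ",
                    paste(paste0(rowDf$label, " - ", rowDf$conclusion),
                          collapse = "; "))
    unmatched <- integer(0)
    controls <- character(0)
  }

  new("AppraisalReport", ticks = ticks,
      matchedRules = rbind(ruleDf, rowDf),
      overallGrade = overall, conclusion = concl,
      requiredControls = as.character(controls),
      unmatchedTicks = as.integer(unmatched))
}

#' Compulsory controls for a declared design
#'
#' Convenience view of [appraise()]: the deduplicated compulsory control
#' experiments and caveats of every checklist rule matched by the tick set,
#' in rule order.
#'
#' @inheritParams appraise
#' @return character vector of control statements (may be empty).
#' @examples
#' requiredControls(c(1, 3, 7))
#' @export
requiredControls <- function(ticks) {
  requiredControlsOf(appraise(ticks))
}
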