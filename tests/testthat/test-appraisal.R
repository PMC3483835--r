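# exact single-item conclusions of the design checklist
TABLE1 <- data.frame(
  id = 1:10,
  conclusion = c(
    "Good approach",
    "Not a good approach",
    "Partial evidence",
    "Partial evidence",
    "Partial evidence for pre-existing proteins in the cell",
    "Partial evidence for newly synthesized proteins",
    "Partial evidence",
    "Partial evidence",
    "Good evidence",
    "Partial evidence"),
  stringsAsFactors = FALSE)

# the twelve tick-combination rules: a representative tick set and the exact
# conclusion each must produce
RULES <- list(
  list(ticks = 1, id = "R1",
       concl = "Studying the degradation of untagged proteins is the best approach."),
  list(ticks = 2, id = "R2",
       concl = "Using tagged proteins is not a very good approach."),
  list(ticks = c(1, 3, 7), id = "R3",
       concl = "The changes in the protein levels cannot be attributed to changes in protein degradation rate."),
  list(ticks = c(2, 4, 5), id = "R4",
       concl = "The changes in protein levels may be attributed to protein degradation of pre-existing protein in the cell."),
  list(ticks = c(1, 4, 5, 7), id = "R5",
       concl = "The changes in protein levels may be attributed to protein degradation of pre-existing proteins in the cell."),
  list(ticks = c(1, 4, 8), id = "R6",
       concl = "The decrease in protein levels cannot be attributed exclusively to protein degradation."),
  list(ticks = c(2, 4, 7, 8), id = "R7",
       concl = "The changes in protein levels cannot be attributed exclusively to protein degradation."),
  list(ticks = c(1, 6), id = "R8",
       concl = "The decrease in the levels of the labelled protein can be attributed to degradation of the newly synthesised protein."),
  list(ticks = c(1, 6, 7), id = "R9",
       concl = "The changes in the levels of the labelled protein can be attributed to degradation of the newly synthesised protein."),
  list(ticks = c(2, 5, 6, 7), id = "R10",
       concl = "The changes in the levels of the labelled protein can be attributed to degradation of the newly synthesised protein and can be compared with the degradation rate of pre-existing protein in the cell."),
  list(ticks = c(1, 9), id = "R11",
       concl = "The calculated changes in the levels of the labelled protein can be attributed to protein degradation under steady-state conditions."),
  list(ticks = c(2, 10), id = "R12",
       concl = "The calculated changes in the levels of the labelled protein cannot be attributed to protein degradation exclusively."))

test_that("the checklist table carries the exact single-item conclusions", {
  tab <- checklistTable()
  expect_identical(tab$id, as.numeric(1:10))
  expect_identical(tab$conclusion, TABLE1$conclusion)
  # ticked single rows surface their exact conclusion in every report
  for (i in c(2, 5, 6, 9)) {
    mr <- matchedRules(appraise(i))
    expect_true(TABLE1$conclusion[i] %in%
                  mr$conclusion[mr$type == "table1"])
  }
})

test_that("each combination rule is matched most specifically with its conclusion", {
  for (r in RULES) {
    rep <- appraise(r$ticks)
    mr <- matchedRules(rep)
    comb <- mr[mr$type == "combination", ]
    expect_identical(comb$id[1], r$id)     # most specific first
    expect_identical(comb$conclusion[1], r$concl)
    expect_true(grepl(r$concl, conclusion(rep), fixed = TRUE))
  }
})

test_that("evidence grades follow the rule conclusions", {
  r19 <- appraise(c(1, 9))
  expect_identical(overallGrade(r19), "good_evidence")
  expect_true(grepl("Good evidence", conclusion(r19), fixed = TRUE))

  r2 <- appraise(2)
  expect_identical(overallGrade(r2), "not_good_approach")
  expect_true(grepl("Not a good approach", conclusion(r2), fixed = TRUE))

  expect_identical(overallGrade(appraise(1)), "good_approach")
  expect_identical(overallGrade(appraise(c(1, 4, 5))), "partial")
  expect_identical(overallGrade(appraise(c(1, 4, 8))), "insufficient")
})

test_that("compulsory controls aggregate across matched rules", {
  c137 <- requiredControls(c(1, 3, 7))
  expect_true(any(grepl("measure the amounts of mRNA", c137, fixed = TRUE)))

  c148 <- requiredControls(c(1, 4, 8))
  expect_true(any(grepl("measure the decay (time-course) of the mRNA", c148,
                        fixed = TRUE)))

  c16 <- requiredControls(c(1, 6))
  expect_true(any(grepl("may not be identical to the rate of the degradation",
                        c16, fixed = TRUE)))

  expect_length(requiredControls(c(1, 9)), 0)
})

test_that("invalid and conflicting tick sets are handled as specified", {
  expect_error(appraise(integer(0)), "empty")
  expect_error(appraise(c(1, 11)), "1..10")
  expect_error(appraise(0), "1..10")
  expect_warning(appraise(c(1, 2, 6)), "mutually exclusive")
})

test_that("appraisal is total, deterministic and specificity-ordered", {
  withr::with_seed(99L, {
    for (i in 1:60) {
      ticks <- sample(1:10, sample(1:5, 1))
      if (all(c(1, 2) %in% ticks)) ticks <- setdiff(ticks, 2)
      a <- appraise(ticks)
      b <- appraise(ticks)
      expect_s4_class(a, "AppraisalReport")
      expect_identical(conclusion(a), conclusion(b))
      expect_identical(requiredControlsOf(a), requiredControlsOf(b))
      mr <- matchedRules(a)
      comb <- mr[mr$type == "combination", ]
      if (nrow(comb) > 1)   # superset patterns outrank their subsets
        expect_true(all(diff(comb$patternSize) <= 0))
    }
  })
  # sets with no base tick still yield a (fallback) report
  fb <- appraise(c(3, 7))
  expect_s4_class(fb, "AppraisalReport")
  expect_identical(overallGrade(fb), "partial")
})
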