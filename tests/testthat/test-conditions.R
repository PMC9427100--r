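test_that("feasibility: 85% enrollment boundary and termination reasons", {
  recs <- bind_records(
    completed_record("NCT1", 200, 170),   # exactly 85%: passes
    completed_record("NCT2", 200, 169),   # below 85%: fails
    trial_record("NCT3", status = "terminated", termination_reason = "accrual",
                 expected_enrollment = 100L, actual_enrollment = 95L),
    trial_record("NCT4", status = "terminated",
                 termination_reason = "scientific_futility",
                 expected_enrollment = 100L, actual_enrollment = 40L)
  )
  v <- assess_feasibility(recs, ASSESS_DATE)
  expect_identical(v$passed, c(TRUE, FALSE, FALSE, TRUE))
  expect_identical(v$reason,
                   c("adequate_enrollment", "under_enrolled",
                     "nonscientific_termination", "scientific_termination"))
})

test_that("feasibility: ongoing trials fail once past the doubled window", {
  rec <- trial_record("NCT1", status = "recruiting",
                      start_date = as.Date("2009-01-01"),
                      planned_primary_completion_date = as.Date("2010-01-01"))
  # doubled-window deadline is 2011-01-01
  v <- assess_feasibility(rec, as.Date("2011-06-01"))
  expect_false(v$passed)
  expect_identical(v$reason, "overdue")
  # unknown status is treated as ongoing
  vu <- assess_feasibility(
    trial_record("NCT2", status = "unknown",
                 start_date = as.Date("2009-01-01"),
                 planned_primary_completion_date = as.Date("2010-01-01")),
    as.Date("2011-06-01"))
  expect_identical(vu$reason, "overdue")
  # an indeterminate trial reaching this stage is a state error
  expect_error(assess_feasibility(rec, as.Date("2010-06-01")),
               "indeterminate")
  expect_error(
    assess_feasibility(completed_record("NCT3", 100, NA), ASSESS_DATE),
    "missing actual enrollment")
})

test_that("feasibility is monotone in actual enrollment for completed trials", {
  expected <- 173L
  passed <- vapply(seq(0L, 2L * expected, by = 1L), function(a) {
    assess_feasibility(completed_record("NCT1", expected, a),
                       ASSESS_DATE)$passed
  }, NA)
  expect_true(all(diff(passed) >= 0))  # pass never flips back to fail
  expect_equal(min(which(passed)) - 1L, ceiling(0.85 * expected))
})

test_that("reporting passes via registry deposition or publication", {
  recs <- bind_records(
    trial_record("NCT1", registry_results_posted = TRUE,
                 primary_outcome_publication_date = as.Date(NA)),
    trial_record("NCT2", registry_results_posted = FALSE,
                 primary_outcome_publication_date = as.Date("2012-03-01")),
    trial_record("NCT3", registry_results_posted = TRUE,
                 primary_outcome_publication_date = as.Date("2012-03-01")),
    trial_record("NCT4", registry_results_posted = FALSE,
                 primary_outcome_publication_date = as.Date(NA))
  )
  v <- assess_reporting(recs)
  expect_identical(v$passed, c(TRUE, TRUE, TRUE, FALSE))
  expect_identical(v$reason,
                   c("registry_only", "publication_only", "both",
                     "unreported"))
})

test_that("importance follows the SR -> CPG -> UpToDate hierarchy", {
  recs <- bind_records(
    trial_record("NCT1",
                 citation_evidence = citation_evidence("other_sr", FALSE,
                                                       TRUE)),
    trial_record("NCT2",
                 citation_evidence = citation_evidence("cpg", TRUE, TRUE)),
    trial_record("NCT3", citation_evidence = citation_evidence()),
    trial_record("NCT4",
                 citation_evidence = citation_evidence("uptodate", TRUE,
                                                       TRUE)),
    trial_record("NCT5",  # cited but not for its results
                 citation_evidence = citation_evidence("cochrane_sr", TRUE,
                                                       FALSE))
  )
  v <- assess_importance(recs)
  expect_identical(v$passed, c(FALSE, TRUE, FALSE, TRUE, FALSE))
  expect_identical(v$reason, c("uncited", "cpg", "uncited", "uptodate",
                               "uncited"))
})

test_that("importance reports the highest satisfying tier regardless of extra evidence", {
  top <- citation_evidence("ahrq_sr", TRUE, TRUE)
  lower <- citation_evidence(c("cpg", "uptodate"), c(TRUE, TRUE),
                             c(TRUE, TRUE))
  with_top <- trial_record("NCT1", citation_evidence = top)
  with_both <- trial_record("NCT1",
                            citation_evidence = rbind(lower, top))
  expect_identical(assess_importance(with_top)$reason, "sr")
  # adding lower-tier evidence never changes a higher-tier pass
  expect_identical(assess_importance(with_both)$reason, "sr")
})

test_that("risk-of-bias aggregation requires a strict low majority and no highs", {
  all_low <- stats::setNames(rep("low", 7), letters[1:7])
  expect_true(aggregate_rob(all_low))
  expect_true(aggregate_rob(c(rep("low", 4), rep("unclear", 3))))
  expect_false(aggregate_rob(c(rep("low", 3), rep("unclear", 4))))
  # even split is a fail: strict majority required
  expect_false(aggregate_rob(c(rep("low", 3), rep("unclear", 3))))
  one_high <- all_low; one_high["c"] <- "high"
  expect_false(aggregate_rob(one_high))
  expect_error(aggregate_rob(character(0)), "empty")
})

test_that("risk-of-bias aggregation ignores element order and names", {
  set.seed(31)
  for (rep in 1:50) {
    m <- sample(3:9, 1)
    e <- stats::setNames(sample(c("low", "unclear", "high"), m, TRUE),
                         paste0("e", seq_len(m)))
    base <- aggregate_rob(e)
    expect_identical(aggregate_rob(sample(e)), base)
    renamed <- stats::setNames(e, paste0("x", seq_len(m)))
    expect_identical(aggregate_rob(renamed), base)
  }
})

test_that("design condition fails without a locatable risk-of-bias assessment", {
  recs <- bind_records(
    informative_record("NCT1"),
    trial_record("NCT2",
                 rob_assessment = rob_assessment(c(a = "low", b = "high"))),
    trial_record("NCT3")  # no assessment
  )
  v <- assess_design(recs)
  expect_identical(v$passed, c(TRUE, FALSE, FALSE))
  expect_identical(v$reason, c("low_rob", "elevated_rob", "missing_rob"))
})
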