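test_that("registry dates parse across the three dialects", {
  expect_equal(parse_registry_date("2009-06-15"), as.Date("2009-06-15"))
  # month-precision dates resolve to the first of the month
  expect_equal(parse_registry_date("June 2010"), as.Date("2010-06-01"))
  expect_equal(parse_registry_date("Jun 2010"), as.Date("2010-06-01"))
  expect_equal(parse_registry_date("2010-06"), as.Date("2010-06-01"))
  expect_true(is.na(parse_registry_date("")))
  expect_error(parse_registry_date("sometime 2010"), "unparseable")
  expect_error(parse_registry_date("15/06/2009"), "unparseable")
})

test_that("record invariants are detected and valid records pass", {
  ok <- trial_record("NCT00000001")
  expect_identical(validate_record(ok), character(0))

  # completed trial cannot carry a termination reason
  bad1 <- trial_record("NCT00000002", termination_reason = "accrual")
  expect_true("termination_reason_mismatch" %in% validate_record(bad1))
  # terminated trial must carry one
  bad2 <- trial_record("NCT00000003", status = "terminated")
  expect_true("termination_reason_mismatch" %in% validate_record(bad2))

  bad3 <- trial_record("NCT00000004",
                       planned_primary_completion_date = as.Date("2009-01-01"))
  expect_true("completion_not_after_start" %in% validate_record(bad3))

  bad4 <- trial_record("NCT00000005", expected_enrollment = 0L)
  expect_true("nonpositive_expected_enrollment" %in% validate_record(bad4))

  # Cochrane/AHRQ/UpToDate citations are high quality by definition
  bad5 <- trial_record("NCT00000006",
                       citation_evidence = citation_evidence("cochrane_sr",
                                                             FALSE, TRUE))
  expect_true("citation_quality_flag" %in% validate_record(bad5))
})

test_that("validation is total over enum-valid status/termination grids", {
  for (st in c("completed", "terminated", "active_not_recruiting", "unknown",
               "recruiting")) {
    for (tr in c("none", "accrual", "scientific_futility")) {
      rec <- trial_record("NCT00000001", status = st, termination_reason = tr)
      expect_no_error(validate_record(rec))
    }
  }
})

test_that("read/write round-trips preserve records in both formats", {
  recs <- bind_records(
    informative_record("NCT00000001"),
    trial_record("NCT00000002", status = "terminated",
                 termination_reason = "accrual",
                 registry_results_posted = FALSE,
                 primary_outcome_publication_date = as.Date(NA)),
    trial_record("NCT00000003", actual_enrollment = NA_integer_,
                 status = "unknown", registry_results_posted = FALSE,
                 primary_outcome_publication_date = as.Date(NA),
                 rob_assessment = rob_assessment(c(a = "low", b = "unclear")))
  )
  for (fmt in c("csv", "json")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_trial_records(recs, path, fmt)
    back <- read_trial_records(path, fmt)
    expect_equal(as.data.frame(back), as.data.frame(recs))
  }
})

test_that("reading maps fields and rejects schema violations", {
  recs <- trial_record("NCT00000010", status = "terminated",
                       termination_reason = "accrual")
  path <- withr::local_tempfile(fileext = ".csv")
  write_trial_records(recs, path, "csv")
  back <- read_trial_records(path, "csv")
  expect_identical(back$status, "terminated")
  expect_identical(back$termination_reason, "accrual")

  # month-precision date in a file resolves deterministically
  txt <- readLines(path)
  txt[2] <- sub("2009-06-15", "June 2010", txt[2])
  txt[2] <- sub("2011-06-15", "2012-06-15", txt[2])
  writeLines(txt, path)
  expect_equal(read_trial_records(path, "csv")$start_date,
               as.Date("2010-06-01"))

  # an empty mandatory cell is a schema error naming record and field
  write_trial_records(recs, path, "csv")
  txt <- readLines(path)
  txt[2] <- sub("\"true\",\"true\"", "\"\",\"true\"", txt[2], fixed = TRUE)
  writeLines(txt, path)
  expect_error(read_trial_records(path, "csv"), "randomized")
  expect_error(read_trial_records(path, "csv"), "NCT00000010")

  # invariant violations abort the read, naming the record
  bad <- trial_record("NCT00000011", termination_reason = "accrual")
  write_trial_records(bad, path, "csv")
  expect_error(read_trial_records(path, "csv"),
               "termination_reason_mismatch")
})
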