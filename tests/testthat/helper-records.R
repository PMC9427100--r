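# Shared builders for small test cohorts.

ASSESS_DATE <- as.Date("2021-10-06")

# completed trial with given planned/actual enrollment
completed_record <- function(id, expected, actual, ...) {
  trial_record(id, expected_enrollment = as.integer(expected),
               actual_enrollment = as.integer(actual), ...)
}

# fully informative one-row record (passes all four conditions)
informative_record <- function(id = "NCT00000001", ...) {
  trial_record(
    id,
    citation_evidence = citation_evidence("cochrane_sr", TRUE, TRUE),
    rob_assessment = rob_assessment(
      stats::setNames(rep("low", 7),
                      c("sequence_generation", "allocation_concealment",
                        "blinding_participants_personnel",
                        "blinding_outcome_assessment",
                        "incomplete_outcome_data", "selective_reporting",
                        "other")),
      "extracted_from_sr"),
    ...
  )
}

bind_records <- function(...) do.call(rbind, list(...))
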