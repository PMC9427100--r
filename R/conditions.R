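# The four informativeness condition assessors. Each returns a verdict table
# with one row per input record: registry_id, condition, assessed, passed,
# reason. Assessors are independent of gating; sequential gating lives in
# classify_trials().

ti_verdict <- function(ids, condition, passed, reason) {
  tibble::tibble(registry_id = ids, condition = condition, assessed = TRUE,
                 passed = passed, reason = reason)
}

#' Assess the feasibility condition
#'
#' A trial demonstrates feasibility when it achieved adequate enrollment in a
#' timely fashion:
#' * completed trials pass when final enrollment reached at least `threshold`
#'   (default 85%) of the enrollment planned in the final pre-start
#'   registration record — exactly 85% passes, since only enrollment *below*
#'   the threshold reflects a substantial loss of power;
#' * terminated trials pass only when termination was for a scientific reason
#'   (accumulated evidence of early efficacy, futility, or toxicity),
#'   irrespective of enrollment attained;
#' * ongoing trials (including unknown status) fail as overdue once the
#'   assessment date has surpassed twice the planned start-to-primary-
#'   completion window. An ongoing trial still inside that window is
#'   indeterminate and should have been excluded at screening; reaching this
#'   assessor is a state error.
#'
#' @param records Trial-record tibble (already screened).
#' @param assessment_date Date at which feasibility is judged.
#' @param threshold Minimum attained fraction of planned enrollment
#'   (default 0.85).
#' @param window_multiplier Multiplier on the planned window for the overdue
#'   rule (default 2).
#' @return Verdict tibble with reasons `adequate_enrollment`,
#'   `under_enrolled`, `scientific_termination`, `nonscientific_termination`,
#'   or `overdue`.
#' @export
assess_feasibility <- function(records, assessment_date, threshold = 0.85,
                               window_multiplier = 2) {
  assessment_date <- as.Date(assessment_date)
  completed <- records$status == "completed"
  if (any(completed & is.na(records$actual_enrollment))) {
    bad <- records$registry_id[completed & is.na(records$actual_enrollment)]
    stop("completed trials missing actual enrollment: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  ongoing <- records$status %in% ti_ongoing_statuses
  deadline <- ti_overdue_deadline(records$start_date,
                                  records$planned_primary_completion_date,
                                  window_multiplier)
  if (any(ongoing & assessment_date <= deadline)) {
    bad <- records$registry_id[ongoing & assessment_date <= deadline]
    stop("indeterminate trials reached feasibility assessment ",
         "(should have been screened out): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  passed <- logical(nrow(records))
  reason <- character(nrow(records))
  enrolled_ok <- records$actual_enrollment >=
    threshold * records$expected_enrollment
  passed[completed] <- enrolled_ok[completed]
  reason[completed] <- ifelse(enrolled_ok[completed], "adequate_enrollment",
                              "under_enrolled")
  term <- records$status == "terminated"
  sci <- records$termination_reason %in% ti_scientific_termination
  passed[term] <- sci[term]
  reason[term] <- ifelse(sci[term], "scientific_termination",
                         "nonscientific_termination")
  passed[ongoing] <- FALSE
  reason[ongoing] <- "overdue"
  ti_verdict(records$registry_id, "feasibility", passed, reason)
}

#' Assess the reporting condition
#'
#' A trial fulfills reporting when its primary outcome results are publicly
#' available, either deposited on the registry or in a journal publication
#' (the earliest published report is the one carried downstream).
#'
#' @param records Trial-record tibble.
#' @return Verdict tibble with reasons `registry_only`, `publication_only`,
#'   `both`, or `unreported`.
#' @export
assess_reporting <- function(records) {
  posted <- records$registry_results_posted
  published <- !is.na(records$primary_outcome_publication_date)
  passed <- posted | published
  reason <- ifelse(posted & published, "both",
            ifelse(posted, "registry_only",
            ifelse(published, "publication_only", "unreported")))
  ti_verdict(records$registry_id, "reporting", passed, reason)
}

#' Assess the importance condition
#'
#' A trial fulfills importance when its results are cited in a high-quality
#' clinical synthesizing document, checked hierarchically: (1) a high-quality
#' systematic review (Cochrane, AHRQ, or another SR judged high quality),
#' (2) a high-quality clinical practice guideline, (3) an UpToDate review
#' article. The reason records the highest satisfying tier.
#'
#' @param records Trial-record tibble.
#' @return Verdict tibble with reasons `sr`, `cpg`, `uptodate`, or `uncited`.
#' @export
assess_importance <- function(records) {
  tier <- vapply(records$citation_evidence, function(ce) {
    if (is.null(ce) || nrow(ce) == 0) return("uncited")
    cited <- ce[ce$cites_trial_results, , drop = FALSE]
    sr <- cited$doc_type %in% c("cochrane_sr", "ahrq_sr") |
      (cited$doc_type == "other_sr" & cited$high_quality)
    if (any(sr)) return("sr")
    if (any(cited$doc_type == "cpg" & cited$high_quality)) return("cpg")
    if (any(cited$doc_type == "uptodate")) return("uptodate")
    "uncited"
  }, "")
  ti_verdict(records$registry_id, "importance", tier != "uncited", tier)
}

#' Aggregate risk-of-bias element judgments
#'
#' A trial is not at elevated risk of bias when all elements are low risk, or
#' a strict majority are low with the remaining minority unclear; any single
#' high-risk element fails. With an even element count and exactly as many
#' low as unclear judgments, the trial fails (a strict majority is required).
#'
#' @param assessment A risk-of-bias assessment (see [rob_assessment()]), or a
#'   bare named character vector of element levels.
#' @return `TRUE` when the design condition's bias criterion is met.
#' @examples
#' aggregate_rob(rob_assessment(c(a = "low", b = "low", c = "unclear")))
#' @export
aggregate_rob <- function(assessment) {
  elements <- if (is.list(assessment)) assessment$elements else assessment
  if (length(elements) == 0) stop("empty risk-of-bias element set",
                                  call. = FALSE)
  !any(elements == "high") &&
    sum(elements == "low") > sum(elements == "unclear")
}

#' Assess the design condition
#'
#' A trial fulfills the design condition when a risk-of-bias assessment is
#' available and [aggregate_rob()] judges it not at elevated risk. A trial
#' whose risk of bias cannot be established cannot be shown informative and
#' fails with reason `missing_rob`.
#'
#' @param records Trial-record tibble.
#' @return Verdict tibble with reasons `low_rob`, `elevated_rob`, or
#'   `missing_rob`.
#' @export
assess_design <- function(records) {
  res <- vapply(records$rob_assessment, function(rob) {
    if (is.null(rob)) return("missing_rob")
    if (aggregate_rob(rob)) "low_rob" else "elevated_rob"
  }, "")
  ti_verdict(records$registry_id, "design", res == "low_rob", res)
}
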