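# Sequential gating of the four conditions, funnel summaries, the primary
# outcome and sensitivity analyses, and stratified comparisons.

ti_conditions <- c("feasibility", "reporting", "importance", "design")

#' Classify trials by the four sequential conditions of informativeness
#'
#' Applies the condition assessors in the fixed order feasibility ->
#' reporting -> importance -> design, stopping assessment at the first failed
#' condition: trials not meeting one condition are not advanced for
#' evaluation of subsequent conditions. A trial is informative when it passes
#' all four.
#'
#' @param records Screened trial-record tibble.
#' @param assessment_date Date at which conditions are judged. No wall-clock
#'   default: supply it explicitly for reproducibility.
#' @param threshold Feasibility enrollment threshold (default 0.85).
#' @param window_multiplier Overdue-window multiplier (default 2).
#' @return Tibble with one row per trial: `registry_id`; per condition
#'   `<condition>_assessed`, `<condition>_passed` (`NA` when unassessed),
#'   `<condition>_reason`; and `informative`.
#' @examples
#' cls <- classify_trials(build_reference_cohort(), as.Date("2021-10-06"))
#' sum(cls$informative)
#' @export
classify_trials <- function(records, assessment_date, threshold = 0.85,
                            window_multiplier = 2) {
  if (anyDuplicated(records$registry_id)) {
    stop("duplicate registry_id: ",
         paste(unique(records$registry_id[duplicated(records$registry_id)]),
               collapse = ", "), call. = FALSE)
  }
  n <- nrow(records)
  out <- tibble::tibble(registry_id = records$registry_id)
  for (cond in ti_conditions) {
    out[[paste0(cond, "_assessed")]] <- FALSE
    out[[paste0(cond, "_passed")]] <- NA
    out[[paste0(cond, "_reason")]] <- NA_character_
  }
  alive <- rep(TRUE, n)
  for (cond in ti_conditions) {
    if (!any(alive)) break
    sub <- records[alive, ]
    verdict <- switch(cond,
      feasibility = assess_feasibility(sub, assessment_date, threshold,
                                       window_multiplier),
      reporting = assess_reporting(sub),
      importance = assess_importance(sub),
      design = assess_design(sub)
    )
    out[[paste0(cond, "_assessed")]][alive] <- TRUE
    out[[paste0(cond, "_passed")]][alive] <- verdict$passed
    out[[paste0(cond, "_reason")]][alive] <- verdict$reason
    alive[alive] <- verdict$passed
  }
  out$informative <- alive
  out
}

#' Summarize the classification funnel
#'
#' Counts the cohort surviving each sequential condition and the failures
#' attributed to the stage where gating stopped. Conservation holds by
#' construction: the cohort size minus the summed failures equals the
#' informative count.
#'
#' @param classification Output of [classify_trials()].
#' @return A `funnel_summary` list: `n_cohort`, `survivors` (named count after
#'   each condition), `failures` (named per-condition failure counts),
#'   `n_informative`.
#' @export
build_funnel <- function(classification) {
  if (anyDuplicated(classification$registry_id)) {
    stop("duplicate registry_id in classification", call. = FALSE)
  }
  n <- nrow(classification)
  failures <- survivors <- stats::setNames(integer(4), ti_conditions)
  alive <- n
  for (cond in ti_conditions) {
    failed <- sum(classification[[paste0(cond, "_passed")]] %in% FALSE)
    failures[cond] <- failed
    alive <- alive - failed
    survivors[cond] <- alive
  }
  structure(list(n_cohort = n, survivors = survivors, failures = failures,
                 n_informative = alive),
            class = "funnel_summary")
}

#' @export
print.funnel_summary <- function(x, ...) {
  cat("cohort:", x$n_cohort, "\n")
  for (cond in names(x$survivors)) {
    cat(sprintf("  %-12s -%d -> %d\n", cond, x$failures[cond],
                x$survivors[cond]))
  }
  cat("informative:", x$n_informative, "\n")
  invisible(x)
}

ti_proportion_estimate <- function(x, n, level = 0.95) {
  ci <- clopper_pearson(x, n, level)
  structure(list(x = x, n = n, point = x / n,
                 ci_low = ci[["lower"]], ci_high = ci[["upper"]],
                 level = level),
            class = "proportion_estimate")
}

#' @export
print.proportion_estimate <- function(x, ...) {
  cat(sprintf("%d / %d = %.1f%% (%d%% CI %.1f-%.1f)\n", x$x, x$n,
              100 * x$point, round(100 * x$level), 100 * x$ci_low,
              100 * x$ci_high))
  invisible(x)
}

#' Primary outcome: proportion of informative trials
#'
#' Point estimate and exact (Clopper–Pearson) two-sided binomial confidence
#' interval for the proportion of trials meeting all four conditions.
#'
#' @param classification Output of [classify_trials()].
#' @param level Confidence level (default 0.95).
#' @return A `proportion_estimate` with `x`, `n`, `point`, `ci_low`,
#'   `ci_high`, `level`.
#' @export
primary_outcome <- function(classification, level = 0.95) {
  n <- nrow(classification)
  if (n < 1) stop("empty classification", call. = FALSE)
  ti_proportion_estimate(sum(classification$informative), n, level)
}

# Lowest-quartile exclusion set for target enrollment: trials at or below the
# type-7 empirical 25th percentile (boundary ties all excluded), except in the
# degenerate all-tied case where excluding <= Q1 would empty the cohort, in
# which case nothing is excluded.
ti_quartile_excluded <- function(expected, quantile = 0.25) {
  cut <- stats::quantile(expected, quantile, type = 7, names = FALSE)
  excl <- expected <= cut
  if (all(excl)) excl[] <- FALSE
  excl
}

#' Sensitivity analysis: exclude small, pilot-type trials
#'
#' Recomputes the primary outcome after excluding trials whose anticipated
#' enrollment falls in the lowest quartile of target enrollment for the
#' cohort (empirical type-7 percentile; ties at the boundary are all
#' excluded; in the degenerate case where every trial is tied nothing is
#' excluded).
#'
#' @param records Trial-record tibble (supplies `expected_enrollment`).
#' @param classification Output of [classify_trials()] for the same trials.
#' @param quantile Exclusion quantile (default 0.25).
#' @param level Confidence level (default 0.95).
#' @return A `proportion_estimate` over the retained trials, with attribute
#'   `n_excluded`.
#' @export
sensitivity_exclude_small <- function(records, classification,
                                      quantile = 0.25, level = 0.95) {
  if (any(is.na(records$expected_enrollment))) {
    stop("expected_enrollment missing", call. = FALSE)
  }
  m <- match(classification$registry_id, records$registry_id)
  if (any(is.na(m))) stop("classification ids not found in records",
                          call. = FALSE)
  excl <- ti_quartile_excluded(records$expected_enrollment[m], quantile)
  est <- primary_outcome(classification[!excl, ], level)
  attr(est, "n_excluded") <- sum(excl)
  est
}

#' Sensitivity analysis: exclude phase 1/2 and phase 2 trials
#'
#' @param records Trial-record tibble (supplies `phase`).
#' @param classification Output of [classify_trials()] for the same trials.
#' @param level Confidence level (default 0.95).
#' @return A `proportion_estimate` over trials of phase other than 2
#'   (phase 1/2 counts as phase 2).
#' @export
sensitivity_exclude_phase2 <- function(records, classification,
                                       level = 0.95) {
  m <- match(classification$registry_id, records$registry_id)
  if (any(is.na(m))) stop("classification ids not found in records",
                          call. = FALSE)
  keep <- records$phase[m] != "phase2"
  if (!any(keep)) stop("no trials remain after excluding phase 2",
                       call. = FALSE)
  primary_outcome(classification[keep, ], level)
}

#' Proportion of participants enrolled in informative trials
#'
#' @param records Trial-record tibble (supplies `actual_enrollment`).
#' @param classification Output of [classify_trials()] for the same trials.
#' @return List with `proportion`, `participants_informative`,
#'   `participants_total`.
#' @export
participant_weighted_proportion <- function(records, classification) {
  m <- match(classification$registry_id, records$registry_id)
  if (any(is.na(m))) stop("classification ids not found in records",
                          call. = FALSE)
  enroll <- records$actual_enrollment[m]
  if (any(is.na(enroll))) {
    stop("actual_enrollment missing for: ",
         paste(classification$registry_id[is.na(enroll)], collapse = ", "),
         call. = FALSE)
  }
  total <- sum(as.numeric(enroll))
  inf_total <- sum(as.numeric(enroll[classification$informative]))
  list(proportion = inf_total / total,
       participants_informative = inf_total,
       participants_total = total)
}

# stratifier -> canonical stratum order and test family
ti_stratifiers <- list(
  disease_area = list(levels = ti_enums$disease_area, test = "chi_square"),
  phase = list(levels = c("phase2", "phase3", "phase4", "not_applicable"),
               test = "fisher"),
  intervention_class = list(levels = ti_enums$intervention_class,
                            test = "fisher"),
  sponsor_class = list(levels = ti_enums$sponsor_class, test = "chi_square")
)

#' Stratified analysis of the informative proportion
#'
#' Builds the 2xK table of informative versus non-informative trials across
#' the strata of one trial property and tests for association. The test is
#' fixed by the stratifier: chi-square (with 2x2 continuity correction) for
#' disease area and sponsor class, Fisher exact for trial phase and
#' intervention class. Per-stratum intervals are Clopper–Pearson for every
#' stratifier.
#'
#' @param records Trial-record tibble (supplies the stratifying property).
#' @param classification Output of [classify_trials()] for the same trials.
#' @param stratifier One of `"disease_area"`, `"phase"`,
#'   `"intervention_class"`, `"sponsor_class"`.
#' @param level Confidence level for per-stratum intervals (default 0.95).
#' @return List with `strata` (tibble: label, x, n, point, ci_low, ci_high),
#'   `table` (the [contingency_2xk()]), and `test` (a `ti_test`).
#' @export
stratified_analysis <- function(records, classification,
                                stratifier = c("disease_area", "phase",
                                               "intervention_class",
                                               "sponsor_class"),
                                level = 0.95) {
  stratifier <- match.arg(stratifier)
  spec <- ti_stratifiers[[stratifier]]
  m <- match(classification$registry_id, records$registry_id)
  if (any(is.na(m))) stop("classification ids not found in records",
                          call. = FALSE)
  strat <- records[[stratifier]][m]
  labels <- spec$levels
  totals <- vapply(unname(labels), function(l) sum(strat == l), 0L,
                   USE.NAMES = FALSE)
  if (any(totals == 0)) {
    warning("dropping empty strata: ",
            paste(labels[totals == 0], collapse = ", "))
    labels <- labels[totals > 0]
    totals <- totals[totals > 0]
  }
  if (length(labels) < 2) stop("need at least two non-empty strata",
                               call. = FALSE)
  successes <- vapply(labels, function(l) {
    sum(classification$informative & strat == l)
  }, 0L, USE.NAMES = FALSE)
  tab <- contingency_2xk(successes, totals, labels)
  test <- if (spec$test == "chi_square") pearson_chi_square(tab)
          else fisher_exact_2xk(tab)
  strata <- tibble::tibble(
    label = labels, x = successes, n = totals, point = successes / totals,
    ci_low = vapply(seq_along(labels), function(k) {
      clopper_pearson(successes[k], totals[k], level)[["lower"]]
    }, 0),
    ci_high = vapply(seq_along(labels), function(k) {
      clopper_pearson(successes[k], totals[k], level)[["upper"]]
    }, 0)
  )
  list(strata = strata, table = tab, test = test)
}
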