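# Cohort inclusion/exclusion rules.

# doubled start-to-primary-completion deadline: start + k * (pc - start)
ti_overdue_deadline <- function(start, pc, multiplier = 2) {
  start + multiplier * as.numeric(pc - start)
}

#' Is a trial indeterminate at a screening date?
#'
#' An indeterminate trial is an ongoing trial (active-not-recruiting,
#' recruiting, or unknown status, the latter treated as ongoing) that has not
#' yet surpassed twice its planned start-to-primary-completion window. Such
#' trials can neither be judged feasible nor infeasible and are excluded from
#' the cohort at screening.
#'
#' @param records Trial-record tibble.
#' @param screen_date Date of screening.
#' @param window_multiplier Multiplier for the planned window (default 2).
#' @return Logical vector, one element per record.
#' @export
is_indeterminate <- function(records, screen_date, window_multiplier = 2) {
  screen_date <- as.Date(screen_date)
  deadline <- ti_overdue_deadline(records$start_date,
                                  records$planned_primary_completion_date,
                                  window_multiplier)
  records$status %in% ti_ongoing_statuses & screen_date <= deadline
}

#' Screen trials for cohort eligibility
#'
#' Applies the inclusion/exclusion rules in a fixed order; the first failing
#' rule supplies the exclusion reason. Rules, in order: randomized; at least
#' one US site; disease area in scope; start date within the inclusion window;
#' not an early-phase (0/1) trial; purpose is treatment or prevention (trials
#' exclusively evaluating safety, diagnostic, or screening interventions are
#' excluded); intervention FDA-approved, advanced to approval, or not subject
#' to approval; not indeterminate at the screening date.
#'
#' @param records Trial-record tibble.
#' @param window_start,window_end Inclusive start-date window.
#' @param screen_date Date of screening (for the indeterminate rule).
#' @param window_multiplier Multiplier for the indeterminate rule (default 2).
#' @return Tibble with columns `registry_id`, `included`, `reason` (`"ok"`
#'   when included).
#' @examples
#' recs <- rbind(trial_record("NCT00000001"),
#'               trial_record("NCT00000002", phase = "phase0_or_1"))
#' screen_trials(recs, "2009-01-01", "2010-12-31", "2021-10-06")
#' @export
screen_trials <- function(records, window_start, window_end, screen_date,
                          window_multiplier = 2) {
  window_start <- as.Date(window_start)
  window_end <- as.Date(window_end)
  screen_date <- as.Date(screen_date)
  indet <- is_indeterminate(records, screen_date, window_multiplier)
  reason <- character(nrow(records))
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    reason[i] <-
      if (!r$randomized) "not_randomized"
      else if (!r$has_us_site) "no_us_site"
      else if (!r$disease_area %in% ti_enums$disease_area) "wrong_disease"
      else if (r$start_date < window_start || r$start_date > window_end)
        "wrong_dates"
      else if (r$phase == "phase0_or_1") "early_phase"
      else if (!r$purpose %in% c("treatment", "prevention"))
        "safety_diag_screening_only"
      else if (r$fda_pathway == "never_approved") "fda_pathway_excluded"
      else if (indet[i]) "indeterminate"
      else "ok"
  }
  tibble::tibble(registry_id = records$registry_id,
                 included = reason == "ok",
                 reason = reason)
}

#' Draw a random subsample of trial records
#'
#' Selects `round(fraction * n)` records (round half up) without replacement,
#' preserving the input order of the selected records. Deterministic for a
#' fixed seed; the caller's random-number state is left untouched.
#'
#' @param records Trial-record tibble.
#' @param fraction Sampling fraction in (0, 1].
#' @param seed Integer seed.
#' @return Subset of `records`.
#' @export
subsample <- function(records, fraction, seed) {
  if (!is.numeric(fraction) || length(fraction) != 1 ||
      fraction <= 0 || fraction > 1) {
    stop("fraction must be in (0, 1]", call. = FALSE)
  }
  n <- nrow(records)
  k <- floor(fraction * n + 0.5)  # round half up
  if (k >= n) return(records)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  idx <- sort(sample.int(n, k))
  records[idx, ]
}
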