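# Synthetic cohorts: (a) a deterministic 125-trial fixture satisfying every
# published marginal constraint, so the full pipeline reproduces the published
# summary statistics; (b) random registries with known generative parameters
# for property testing.

# run expr with a private RNG stream, restoring the caller's state
ti_with_seed <- function(seed, expr) {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# fill a vector by consecutive blocks: blocks = list(list(rows, value), ...)
ti_blocks <- function(n, blocks, default = NA) {
  out <- rep(default, n)
  for (b in blocks) out[b[[1]]] <- b[[2]]
  out
}

#' Build the 125-trial reference cohort fixture
#'
#' Deterministically constructs a synthetic cohort of 125 eligible randomized
#' trials whose classification under default parameters (assessment date
#' 2021-10-06, 85% enrollment threshold, doubled-window overdue rule)
#' satisfies every published marginal constraint of the reference cohort:
#'
#' * attribute totals — disease areas 40/57/28, statuses 99/15/5/6
#'   (completed / terminated / active-not-recruiting / unknown), phases
#'   24/50/19/32 (2 / 3 / 4 / not applicable), intervention classes
#'   77/8/8/32, sponsors 58/67 (industry / other), outcome types 42/83
#'   (clinical / surrogate), 93 trials registered within 30 days of start;
#' * informative counts per stratum — disease 11/18/4, phase 2/25/2/4,
#'   intervention 27/2/0/4, sponsor 29/4 (each re-summing to 33);
#' * funnel — stage failures 35/9/18/30, with exactly 21 of the feasibility
#'   failures due to under-enrollment; of the 18 importance failures exactly
#'   8 have registry-posted results and no publication;
#' * lowest-quartile target-enrollment exclusion set of exactly 35 trials, of
#'   which exactly 1 is informative;
#' * participant totals — actual enrollment sums to 193,839 overall and
#'   129,973 over informative trials.
#'
#' The joint attribute assignment is under-determined by the marginal
#' constraints; once the stage labels are fixed the attribute columns
#' decouple, so a direct block construction is used and the result is
#' identical on every call. Any cohort satisfying the margins reproduces all
#' margin-level summary statistics.
#'
#' @param check Verify the full constraint ledger before returning
#'   (default `TRUE`); a violation is a build error naming the constraint.
#' @return A 125-row trial-record tibble.
#' @examples
#' fx <- build_reference_cohort()
#' primary_outcome(classify_trials(fx, as.Date("2021-10-06")))
#' @export
build_reference_cohort <- function(check = TRUE) {
  n <- 125L
  i <- seq_len(n)

  # stage labels: 1-33 informative; 34-68 feasibility fail (34-54 under-
  # enrolled completed, 55-57 non-scientific termination, 58-62 overdue
  # active-NR, 63-68 overdue unknown); 69-77 reporting fail; 78-95 importance
  # fail (78-85 registry-posted without publication, 86-95 published);
  # 96-125 design fail (96-107 terminated for scientific reasons).
  status <- ti_blocks(n, list(
    list(55:57, "terminated"), list(58:62, "active_not_recruiting"),
    list(63:68, "unknown"), list(96:107, "terminated")
  ), default = "completed")
  termination_reason <- ti_blocks(n, list(
    list(55, "accrual"), list(56, "funding"), list(57, "feasibility"),
    list(96:107, rep(c("scientific_futility", "scientific_efficacy",
                       "scientific_toxicity"), 4))
  ), default = "none")

  disease_area <- ti_blocks(n, list(
    list(1:11, "ischemic_heart_disease"), list(12:29, "diabetes_mellitus"),
    list(30:33, "lung_cancer"), list(34:62, "ischemic_heart_disease"),
    list(63:101, "diabetes_mellitus"), list(102:125, "lung_cancer")
  ))
  phase <- ti_blocks(n, list(
    list(1:2, "phase2"), list(3:27, "phase3"), list(28:29, "phase4"),
    list(30:33, "not_applicable"), list(34:55, "phase2"),
    list(56:80, "phase3"), list(81:97, "phase4"),
    list(98:125, "not_applicable")
  ))
  intervention_class <- ti_blocks(n, list(
    list(1:27, "drug_biologic"), list(28:29, "combination"),
    list(30:33, "other"), list(34:83, "drug_biologic"),
    list(84:89, "combination"), list(90:97, "device"), list(98:125, "other")
  ))
  sponsor_class <- ti_blocks(n, list(
    list(1:29, "industry"), list(30:33, "other"), list(34:62, "industry"),
    list(63:125, "other")
  ))
  outcome_type <- ti_blocks(n, list(
    list(1:42, "clinical"), list(43:125, "surrogate")
  ))

  start_date <- as.Date("2009-01-15") + (i * 37L) %% 700L
  pc_date <- start_date + 730L

  # enrollment: 35 trials (rows 33-67) form the lowest-quartile set at the
  # common value 100; sums pinned to the published participant totals
  expected <- ti_blocks(n, list(
    list(1:17, 4059L), list(18:32, 4058L), list(33:67, 100L), list(68, 400L),
    list(69:109, 1086L), list(110:125, 1085L)
  ))
  actual <- ti_blocks(n, list(
    list(1:17, 4059L), list(18:32, 4058L), list(33, 100L), list(34:54, 50L),
    list(55:67, 60L), list(68, 150L), list(69:109, 1086L),
    list(110:125, 1085L)
  ))

  posted <- ti_blocks(n, list(
    list(1:33, TRUE), list(78:85, TRUE)
  ), default = FALSE)
  pub_date <- as.Date(rep(NA, n))
  published_rows <- c(1:33, 86:125)
  pub_date[published_rows] <- pc_date[published_rows] + 200L

  fda_pathway <- ti_blocks(n, list(list(69:74, "not_subject")),
                           default = "approved_or_advanced")
  purpose <- ti_blocks(n, list(list(20:25, "prevention")),
                       default = "treatment")
  registered_30 <- i <= 93L

  sr_cite <- citation_evidence("cochrane_sr", TRUE, TRUE)
  low_all <- stats::setNames(rep("low", 7), ti_rob_elements)
  high_elems <- c("blinding_participants_personnel",
                  "blinding_outcome_assessment", "selective_reporting")
  citation <- vector("list", n)
  rob <- vector("list", n)
  for (k in i) {
    citation[[k]] <-
      if (k <= 30 || (k >= 96 && k <= 125)) sr_cite
      else if (k == 31) citation_evidence("cpg", TRUE, TRUE)
      else if (k == 32) citation_evidence("uptodate", TRUE, TRUE)
      else if (k == 33) citation_evidence("other_sr", TRUE, TRUE)
      else if (k >= 88 && k <= 95) citation_evidence("other_sr", FALSE, TRUE)
      else citation_evidence()
    rob[k] <- list(
      if (k <= 33) rob_assessment(low_all, "extracted_from_sr")
      else if (k >= 96 && k <= 115) {
        e <- low_all
        e[high_elems[(k - 96) %% 3 + 1]] <- "high"
        rob_assessment(e, "extracted_from_sr")
      } else if (k >= 116 && k <= 120) {
        e <- low_all
        e[4:7] <- "unclear"  # 3 low, 4 unclear: no strict majority
        rob_assessment(e, "de_novo")
      } else NULL)  # rows 121-125: risk of bias not locatable
  }

  records <- tibble::tibble(
    registry_id = sprintf("NCT%08d", i),
    disease_area = disease_area,
    randomized = TRUE,
    has_us_site = TRUE,
    purpose = purpose,
    phase = phase,
    intervention_class = intervention_class,
    sponsor_class = sponsor_class,
    fda_pathway = fda_pathway,
    status = status,
    start_date = start_date,
    planned_primary_completion_date = pc_date,
    expected_enrollment = expected,
    actual_enrollment = actual,
    termination_reason = termination_reason,
    registry_results_posted = posted,
    primary_outcome_publication_date = pub_date,
    outcome_type = outcome_type,
    registered_within_30_days = registered_30,
    citation_evidence = citation,
    rob_assessment = rob
  )
  if (check) {
    report <- fixture_constraint_report(records)
    if (!all(report$satisfied)) {
      bad <- report$description[!report$satisfied]
      stop("fixture constraint violated:\n  ",
           paste(bad, collapse = "\n  "), call. = FALSE)
    }
  }
  records
}

#' Verify the reference fixture against its constraint ledger
#'
#' Screens and classifies a cohort with default parameters and checks every
#' constraint listed in [build_reference_cohort()].
#'
#' @param records Trial-record tibble (defaults to a freshly built fixture).
#' @param assessment_date Assessment date (default 2021-10-06, the registry
#'   status-update date of the reference cohort).
#' @return Tibble with columns `scope`, `description`, `satisfied`.
#' @export
fixture_constraint_report <- function(records = build_reference_cohort(FALSE),
                                      assessment_date = as.Date("2021-10-06")) {
  checks <- list()
  add <- function(scope, description, satisfied) {
    checks[[length(checks) + 1]] <<- tibble::tibble(
      scope = scope, description = description, satisfied = satisfied)
  }
  count_by <- function(field, levels) {
    vapply(levels, function(l) sum(records[[field]] == l), 0L)
  }
  add("total", "cohort size 125", nrow(records) == 125L)
  add("total", "all records valid", length(validate_records(records)) == 0)
  screen <- screen_trials(records, "2009-01-01", "2010-12-31",
                          assessment_date)
  add("total", "all records screen-eligible", all(screen$included))
  add("by_disease", "disease totals 40/57/28",
      identical(count_by("disease_area", ti_enums$disease_area),
                stats::setNames(c(40L, 57L, 28L), ti_enums$disease_area)))
  st <- count_by("status", c("completed", "terminated",
                             "active_not_recruiting", "unknown"))
  add("by_status", "status totals 99/15/5/6",
      all(st == c(99L, 15L, 5L, 6L)))
  add("by_phase", "phase totals 24/50/19/32",
      all(count_by("phase", ti_stratifiers$phase$levels) ==
            c(24L, 50L, 19L, 32L)))
  add("by_intervention", "intervention totals 77/8/8/32",
      all(count_by("intervention_class", ti_enums$intervention_class) ==
            c(77L, 8L, 8L, 32L)))
  add("by_sponsor", "sponsor totals 58/67",
      all(count_by("sponsor_class", ti_enums$sponsor_class) == c(58L, 67L)))
  add("total", "outcome-type totals 42/83",
      all(count_by("outcome_type", ti_enums$outcome_type) == c(42L, 83L)))
  add("total", "93 trials registered within 30 days",
      sum(records$registered_within_30_days) == 93L)

  cls <- classify_trials(records, assessment_date)
  funnel <- build_funnel(cls)
  add("funnel", "stage failures 35/9/18/30",
      all(funnel$failures == c(35L, 9L, 18L, 30L)))
  add("funnel", "21 feasibility failures via under-enrollment",
      sum(cls$feasibility_reason %in% "under_enrolled") == 21L)
  add("funnel", "33 informative trials", funnel$n_informative == 33L)
  imp_fail <- cls$importance_passed %in% FALSE
  m <- match(cls$registry_id, records$registry_id)
  add("reporting_detail",
      "8 importance failures registry-posted without publication",
      sum(imp_fail & records$registry_results_posted[m] &
            is.na(records$primary_outcome_publication_date[m])) == 8L)

  inf_by <- function(field, levels) {
    vapply(levels, function(l) {
      sum(cls$informative & records[[field]][m] == l)
    }, 0L)
  }
  add("importance_detail", "informative by disease 11/18/4",
      all(inf_by("disease_area", ti_enums$disease_area) == c(11L, 18L, 4L)))
  add("by_phase", "informative by phase 2/25/2/4",
      all(inf_by("phase", ti_stratifiers$phase$levels) == c(2L, 25L, 2L, 4L)))
  add("by_intervention", "informative by intervention 27/2/0/4",
      all(inf_by("intervention_class", ti_enums$intervention_class) ==
            c(27L, 2L, 0L, 4L)))
  add("by_sponsor", "informative by sponsor 29/4",
      all(inf_by("sponsor_class", ti_enums$sponsor_class) == c(29L, 4L)))

  excl <- ti_quartile_excluded(records$expected_enrollment)
  add("quartile", "35 trials in lowest-quartile exclusion set",
      sum(excl) == 35L)
  add("quartile", "exactly 1 informative trial in exclusion set",
      sum(excl[m] & cls$informative) == 1L)
  add("enrollment_totals", "total enrollment 193,839",
      sum(as.numeric(records$actual_enrollment)) == 193839)
  add("enrollment_totals", "informative enrollment 129,973",
      sum(as.numeric(records$actual_enrollment[m][cls$informative])) ==
        129973)
  add("total", "identical to a fresh deterministic build",
      identical(records, build_reference_cohort(FALSE)))
  do.call(rbind, checks)
}

#' Generate a random trial registry with known pass probabilities
#'
#' Draws the four condition outcomes independently per trial with
#' probabilities `(p_feasible, p_reported, p_important, p_low_rob)` and
#' realizes each outcome through concrete record fields: a feasibility
#' failure becomes an under-enrolled completed trial, a non-scientifically
#' terminated trial, or an overdue ongoing trial (chosen at random);
#' a reporting pass becomes registry deposition, a publication, or both; an
#' importance pass becomes a citation at a randomly chosen tier; a design
#' failure becomes a high-risk element, an unclear majority, or a missing
#' assessment. Under sequential gating the expected informative fraction is
#' the product of the four probabilities.
#'
#' Default probabilities are the reference cohort's conditional stage pass
#' rates (90/125, 81/90, 63/81, 33/63) and its attribute margins. Trial start
#' dates fall in 2009-2010 with planned completion at most two years later,
#' so any assessment date from 2015 on finds ongoing trials overdue; the
#' companion default elsewhere in the package is 2021-10-06.
#'
#' @param n_trials Number of records to generate.
#' @param p_feasible,p_reported,p_important,p_low_rob Per-condition pass
#'   probabilities in \[0, 1\].
#' @param seed Integer seed (the caller's RNG state is preserved).
#' @param disease_probs,phase_probs,intervention_probs,sponsor_probs,outcome_probs
#'   Category probabilities (must sum to 1) in the canonical category orders.
#' @param enrollment_meanlog,enrollment_sdlog Log-normal parameters for
#'   planned enrollment.
#' @return A trial-record tibble of `n_trials` valid, screen-eligible records.
#' @examples
#' reg <- generate_random_registry(200, seed = 1)
#' mean(classify_trials(reg, as.Date("2021-10-06"))$informative)
#' @export
generate_random_registry <- function(n_trials,
                                     p_feasible = 90 / 125,
                                     p_reported = 81 / 90,
                                     p_important = 63 / 81,
                                     p_low_rob = 33 / 63,
                                     seed = 1L,
                                     disease_probs = c(40, 57, 28) / 125,
                                     phase_probs = c(24, 50, 19, 32) / 125,
                                     intervention_probs = c(77, 8, 8, 32) / 125,
                                     sponsor_probs = c(58, 67) / 125,
                                     outcome_probs = c(42, 83) / 125,
                                     enrollment_meanlog = log(500),
                                     enrollment_sdlog = 1) {
  probs <- c(p_feasible, p_reported, p_important, p_low_rob)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1)) {
    stop("pass probabilities must lie in [0, 1]", call. = FALSE)
  }
  for (cp in list(disease_probs, phase_probs, intervention_probs,
                  sponsor_probs, outcome_probs)) {
    if (any(cp < 0) || abs(sum(cp) - 1) > 1e-8) {
      stop("category probabilities must be nonnegative and sum to 1",
           call. = FALSE)
    }
  }
  n <- as.integer(n_trials)
  ti_with_seed(seed, {
    pass_f <- stats::runif(n) < p_feasible
    pass_r <- stats::runif(n) < p_reported
    pass_i <- stats::runif(n) < p_important
    pass_d <- stats::runif(n) < p_low_rob

    start_date <- as.Date("2009-01-01") + sample.int(730L, n, TRUE) - 1L
    pc_date <- start_date + sample(c(180L, 365L, 545L, 730L), n, TRUE)
    expected <- pmax(10L, as.integer(round(
      stats::rlnorm(n, enrollment_meanlog, enrollment_sdlog))))

    status <- rep("completed", n)
    reason <- rep("none", n)
    actual <- as.integer(round(expected * stats::runif(n, 0.85, 1.15)))
    actual <- pmax(actual, as.integer(ceiling(0.85 * expected)))
    term_sci <- pass_f & stats::runif(n) < 0.1
    status[term_sci] <- "terminated"
    reason[term_sci] <- sample(ti_scientific_termination, sum(term_sci), TRUE)
    fail_mode <- sample(c("under", "nonsci", "overdue"), n, TRUE)
    fm_under <- !pass_f & fail_mode == "under"
    actual[fm_under] <- as.integer(floor(
      expected[fm_under] * stats::runif(sum(fm_under), 0.1, 0.8)))
    fm_nonsci <- !pass_f & fail_mode == "nonsci"
    status[fm_nonsci] <- "terminated"
    reason[fm_nonsci] <- sample(c("accrual", "feasibility", "funding",
                                  "other_nonscientific"), sum(fm_nonsci),
                                TRUE)
    actual[fm_nonsci] <- as.integer(floor(
      expected[fm_nonsci] * stats::runif(sum(fm_nonsci), 0.1, 0.9)))
    fm_over <- !pass_f & fail_mode == "overdue"
    status[fm_over] <- sample(ti_ongoing_statuses, sum(fm_over), TRUE)
    actual[fm_over] <- as.integer(floor(
      expected[fm_over] * stats::runif(sum(fm_over), 0.1, 0.9)))

    report_mode <- sample(c("registry_only", "publication_only", "both"),
                          n, TRUE)
    posted <- pass_r & report_mode != "publication_only"
    pub_date <- as.Date(rep(NA, n))
    has_pub <- pass_r & report_mode != "registry_only"
    pub_date[has_pub] <- pc_date[has_pub] +
      sample.int(700L, sum(has_pub), TRUE)

    tier <- sample(c("sr", "cpg", "uptodate"), n, TRUE,
                   prob = c(0.7, 0.2, 0.1))
    fail_cite_mode <- sample(c("none", "low_quality_sr", "uncited_sr"),
                             n, TRUE)
    citation <- vector("list", n)
    for (k in seq_len(n)) {
      citation[[k]] <- if (pass_i[k]) {
        switch(tier[k],
          sr = citation_evidence(sample(c("cochrane_sr", "ahrq_sr",
                                          "other_sr"), 1), TRUE, TRUE),
          cpg = citation_evidence("cpg", TRUE, TRUE),
          uptodate = citation_evidence("uptodate", TRUE, TRUE))
      } else {
        switch(fail_cite_mode[k],
          none = citation_evidence(),
          low_quality_sr = citation_evidence("other_sr", FALSE, TRUE),
          uncited_sr = citation_evidence("cochrane_sr", TRUE, FALSE))
      }
    }

    low_all <- stats::setNames(rep("low", 7), ti_rob_elements)
    rob_fail_mode <- sample(c("high", "unclear_majority", "missing"), n,
                            TRUE, prob = c(0.6, 0.3, 0.1))
    high_pick <- sample(ti_rob_elements, n, TRUE)
    rob_src <- sample(ti_enums$rob_source, n, TRUE)
    rob <- vector("list", n)
    for (k in seq_len(n)) {
      rob[k] <- list(if (pass_d[k]) {
        rob_assessment(low_all, rob_src[k])
      } else if (rob_fail_mode[k] == "high") {
        e <- low_all; e[high_pick[k]] <- "high"
        rob_assessment(e, rob_src[k])
      } else if (rob_fail_mode[k] == "unclear_majority") {
        e <- low_all; e[4:7] <- "unclear"
        rob_assessment(e, rob_src[k])
      } else NULL)
    }

    records <- tibble::tibble(
      registry_id = sprintf("NCT9%07d", seq_len(n)),
      disease_area = sample(ti_enums$disease_area, n, TRUE, disease_probs),
      randomized = TRUE,
      has_us_site = TRUE,
      purpose = sample(c("treatment", "prevention"), n, TRUE, c(0.8, 0.2)),
      phase = sample(ti_stratifiers$phase$levels, n, TRUE, phase_probs),
      intervention_class = sample(ti_enums$intervention_class, n, TRUE,
                                  intervention_probs),
      sponsor_class = sample(ti_enums$sponsor_class, n, TRUE, sponsor_probs),
      fda_pathway = sample(c("approved_or_advanced", "not_subject"), n, TRUE,
                           c(0.9, 0.1)),
      status = status,
      start_date = start_date,
      planned_primary_completion_date = pc_date,
      expected_enrollment = expected,
      actual_enrollment = actual,
      termination_reason = reason,
      registry_results_posted = posted,
      primary_outcome_publication_date = pub_date,
      outcome_type = sample(ti_enums$outcome_type, n, TRUE, outcome_probs),
      registered_within_30_days = stats::runif(n) < 93 / 125,
      citation_evidence = citation,
      rob_assessment = rob
    )
    records
  })
}
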