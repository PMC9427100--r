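#' Parse a registry date string
#'
#' Registry records frequently carry month-precision dates ("June 2010" or
#' "2010-06"). A missing day component deterministically resolves to the first
#' of the month so that interval arithmetic (notably the doubled
#' start-to-primary-completion window) stays computable.
#'
#' @param x Character vector of dates: ISO `"YYYY-MM-DD"`, `"YYYY-MM"`, or
#'   `"Month YYYY"` (English month name or abbreviation). Empty strings and
#'   `NA` yield `NA`.
#' @return A `Date` vector the same length as `x`.
#' @examples
#' parse_registry_date(c("2009-06-15", "June 2010", "2010-06"))
#' @export
parse_registry_date <- function(x) {
  x <- as.character(x)
  out <- rep(as.Date(NA), length(x))
  for (i in seq_along(x)) {
    v <- trimws(x[i])
    if (is.na(v) || v == "") next
    if (grepl("^\\d{4}-\\d{2}-\\d{2}$", v)) {
      out[i] <- as.Date(v)
    } else if (grepl("^\\d{4}-\\d{2}$", v)) {
      out[i] <- as.Date(paste0(v, "-01"))
    } else if (grepl("^[A-Za-z]+ \\d{4}$", v)) {
      parts <- strsplit(v, " ")[[1]]
      m <- match(tolower(parts[1]), tolower(month.name))
      if (is.na(m)) m <- match(tolower(parts[1]), tolower(month.abb))
      if (is.na(m)) stop("unparseable date: '", v, "'", call. = FALSE)
      out[i] <- as.Date(sprintf("%s-%02d-01", parts[2], m))
    } else {
      stop("unparseable date: '", v, "'", call. = FALSE)
    }
  }
  out
}

#' Construct a single trial record
#'
#' Convenience constructor returning a one-row trial-record tibble with
#' screen-eligible defaults; any field can be overridden. Mostly useful for
#' examples and tests; bulk data enters through [read_trial_records()] or the
#' synthetic generators.
#'
#' @param registry_id Trial identifier (e.g. `"NCT00000001"`).
#' @param ... Named fields overriding the defaults (see [read_trial_records()]
#'   for the schema). `citation_evidence` takes a data frame with columns
#'   `doc_type`, `high_quality`, `cites_trial_results`; `rob_assessment` takes
#'   a list with `elements` (named character vector of `"low"`, `"unclear"`,
#'   `"high"`) and `source`.
#' @return A one-row tibble.
#' @examples
#' trial_record("NCT00000001", status = "terminated",
#'              termination_reason = "accrual")
#' @export
trial_record <- function(registry_id = "NCT00000001", ...) {
  rec <- list(
    registry_id = registry_id,
    disease_area = "ischemic_heart_disease",
    randomized = TRUE,
    has_us_site = TRUE,
    purpose = "treatment",
    phase = "phase3",
    intervention_class = "drug_biologic",
    sponsor_class = "industry",
    fda_pathway = "approved_or_advanced",
    status = "completed",
    start_date = as.Date("2009-06-15"),
    planned_primary_completion_date = as.Date("2011-06-15"),
    expected_enrollment = 200L,
    actual_enrollment = 200L,
    termination_reason = "none",
    registry_results_posted = TRUE,
    primary_outcome_publication_date = as.Date("2012-01-15"),
    outcome_type = "clinical",
    registered_within_30_days = TRUE,
    citation_evidence = list(citation_evidence()),
    rob_assessment = list(NULL)
  )
  dots <- list(...)
  for (nm in names(dots)) {
    if (!nm %in% names(rec)) stop("unknown trial record field: ", nm)
    if (nm %in% c("citation_evidence", "rob_assessment")) {
      rec[[nm]] <- list(dots[[nm]])
    } else {
      rec[[nm]] <- dots[[nm]]
    }
  }
  tibble::as_tibble(rec)
}

#' Build a citation-evidence table
#'
#' @param doc_type Document types (`"cochrane_sr"`, `"ahrq_sr"`, `"other_sr"`,
#'   `"cpg"`, `"uptodate"`).
#' @param high_quality Logical; quality judgment. Cochrane/AHRQ SRs and
#'   UpToDate entries are high quality by definition.
#' @param cites_trial_results Logical; whether the document cites the trial's
#'   results in its results/recommendations.
#' @return A data frame with one row per synthesizing document.
#' @export
citation_evidence <- function(doc_type = character(),
                              high_quality = logical(),
                              cites_trial_results = logical()) {
  data.frame(doc_type = as.character(doc_type),
             high_quality = as.logical(high_quality),
             cites_trial_results = as.logical(cites_trial_results),
             stringsAsFactors = FALSE)
}

#' Build a risk-of-bias assessment
#'
#' @param elements Named character vector mapping element names to `"low"`,
#'   `"unclear"`, or `"high"`.
#' @param source `"extracted_from_sr"` or `"de_novo"`.
#' @return A list with components `elements` and `source`.
#' @export
rob_assessment <- function(elements, source = "de_novo") {
  list(elements = elements, source = source)
}

# fields that must be non-missing in every serialized record
ti_mandatory_fields <- c(
  "registry_id", "disease_area", "randomized", "has_us_site", "purpose",
  "phase", "intervention_class", "sponsor_class", "fda_pathway", "status",
  "start_date", "planned_primary_completion_date", "expected_enrollment",
  "termination_reason", "registry_results_posted", "outcome_type",
  "registered_within_30_days"
)

ti_all_fields <- c(ti_mandatory_fields, "actual_enrollment",
                   "primary_outcome_publication_date", "citation_evidence",
                   "rob_assessment")

#' Validate a trial record
#'
#' Checks record invariants and returns stable machine-readable violation
#' codes. Validation is total: it never raises on enum-valid input; problems
#' are returned, not thrown.
#'
#' Codes: `termination_reason_mismatch` (status is terminated iff a
#' termination reason other than `"none"` is present),
#' `completion_not_after_start`, `nonpositive_expected_enrollment`,
#' `negative_actual_enrollment`, `invalid_<field>` for out-of-vocabulary enum
#' values, `citation_quality_flag` (Cochrane/AHRQ/UpToDate entries must be
#' high quality), `rob_elements_empty`, `rob_invalid_level`.
#'
#' @param record A one-row trial-record tibble (rows beyond the first are
#'   ignored; use [validate_records()] for bulk validation).
#' @return Character vector of violation codes (empty when valid).
#' @export
validate_record <- function(record) {
  v <- character()
  enum_fields <- c("disease_area", "purpose", "phase", "intervention_class",
                   "sponsor_class", "fda_pathway", "status",
                   "termination_reason", "outcome_type")
  for (f in enum_fields) {
    val <- record[[f]][1]
    if (is.na(val) || !val %in% ti_enums[[f]]) {
      v <- c(v, paste0("invalid_", f))
    }
  }
  status <- record$status[1]
  reason <- record$termination_reason[1]
  if (!is.na(status) && !is.na(reason)) {
    if ((status == "terminated") != (reason != "none")) {
      v <- c(v, "termination_reason_mismatch")
    }
  }
  sd <- record$start_date[1]
  pc <- record$planned_primary_completion_date[1]
  if (!is.na(sd) && !is.na(pc) && !(pc > sd)) {
    v <- c(v, "completion_not_after_start")
  }
  ee <- record$expected_enrollment[1]
  if (!is.na(ee) && ee <= 0) v <- c(v, "nonpositive_expected_enrollment")
  ae <- record$actual_enrollment[1]
  if (!is.na(ae) && ae < 0) v <- c(v, "negative_actual_enrollment")
  ce <- record$citation_evidence[[1]]
  if (!is.null(ce) && nrow(ce) > 0) {
    auto_hq <- ce$doc_type %in% c("cochrane_sr", "ahrq_sr", "uptodate")
    if (any(auto_hq & !ce$high_quality)) v <- c(v, "citation_quality_flag")
    if (any(!ce$doc_type %in% ti_enums$doc_type)) v <- c(v, "invalid_doc_type")
  }
  rob <- record$rob_assessment[[1]]
  if (!is.null(rob)) {
    if (length(rob$elements) == 0) v <- c(v, "rob_elements_empty")
    else if (any(!rob$elements %in% ti_enums$rob_level)) {
      v <- c(v, "rob_invalid_level")
    }
  }
  v
}

#' Validate many trial records
#'
#' @param records Trial-record tibble.
#' @return Named list (by `registry_id`) of violation-code vectors, one entry
#'   per record with at least one violation; empty list when all records are
#'   valid.
#' @export
validate_records <- function(records) {
  out <- list()
  for (i in seq_len(nrow(records))) {
    v <- validate_record(records[i, ])
    if (length(v) > 0) out[[records$registry_id[i]]] <- v
  }
  out
}

# --- serialization ----------------------------------------------------------

ti_bool_to_chr <- function(x) ifelse(is.na(x), "", ifelse(x, "true", "false"))
ti_chr_to_bool <- function(x) {
  ifelse(x %in% "true", TRUE, ifelse(x %in% "false", FALSE, NA))
}

ti_citations_to_chr <- function(ce) {
  if (is.null(ce) || nrow(ce) == 0) return("")
  paste(sprintf("%s:%s:%s", ce$doc_type, ti_bool_to_chr(ce$high_quality),
                ti_bool_to_chr(ce$cites_trial_results)), collapse = ";")
}

ti_chr_to_citations <- function(x) {
  if (is.na(x) || x == "") return(citation_evidence())
  parts <- strsplit(strsplit(x, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
  citation_evidence(
    doc_type = vapply(parts, `[`, "", 1),
    high_quality = ti_chr_to_bool(vapply(parts, `[`, "", 2)),
    cites_trial_results = ti_chr_to_bool(vapply(parts, `[`, "", 3))
  )
}

ti_rob_to_chr <- function(rob) {
  if (is.null(rob)) return("")
  paste0(rob$source, "|",
         paste(sprintf("%s=%s", names(rob$elements), rob$elements),
               collapse = ","))
}

ti_chr_to_rob <- function(x) {
  if (is.na(x) || x == "") return(NULL)
  halves <- strsplit(x, "|", fixed = TRUE)[[1]]
  pairs <- strsplit(strsplit(halves[2], ",", fixed = TRUE)[[1]], "=",
                    fixed = TRUE)
  elements <- vapply(pairs, `[`, "", 2)
  names(elements) <- vapply(pairs, `[`, "", 1)
  rob_assessment(elements, source = halves[1])
}

#' Read trial records from CSV or JSON
#'
#' Reads a structured registry file into a trial-record tibble. The schema
#' mirrors ClinicalTrials.gov registration fields: one row per trial with
#' identifier, disease area, design flags, phase, intervention and sponsor
#' class, FDA pathway, status, start and planned primary-completion dates,
#' planned/actual enrollment, termination reason, results-availability
#' evidence, citation evidence, and an optional risk-of-bias assessment.
#'
#' The CSV dialect is UTF-8 with a mandatory header; dates are ISO-8601,
#' `"YYYY-MM"`, or `"Month YYYY"` (month precision resolves to the first of
#' the month); logicals are `true`/`false`; enum values are lowercase snake
#' case. `citation_evidence` is a `;`-separated list of
#' `doc_type:high_quality:cites` triples; `rob_assessment` is
#' `source|element=level,...`. JSON files are a top-level array of objects
#' keyed by field name, with `citation_evidence` an array of objects and
#' `rob_assessment` an object with `source` and `elements`.
#'
#' Every record must pass [validate_record()]; otherwise the read fails
#' listing all violations.
#'
#' @param path Path to the file.
#' @param format `"csv"` or `"json"`.
#' @return A trial-record tibble.
#' @seealso [write_trial_records()]
#' @export
read_trial_records <- function(path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "csv") {
    raw <- utils::read.csv(path, colClasses = "character",
                           stringsAsFactors = FALSE, fileEncoding = "UTF-8")
    missing_cols <- setdiff(ti_all_fields, names(raw))
    if (length(missing_cols) > 0) {
      stop("schema error: missing columns: ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
    recs <- tibble::tibble(
      registry_id = raw$registry_id,
      disease_area = raw$disease_area,
      randomized = ti_chr_to_bool(raw$randomized),
      has_us_site = ti_chr_to_bool(raw$has_us_site),
      purpose = raw$purpose,
      phase = raw$phase,
      intervention_class = raw$intervention_class,
      sponsor_class = raw$sponsor_class,
      fda_pathway = raw$fda_pathway,
      status = raw$status,
      start_date = parse_registry_date(raw$start_date),
      planned_primary_completion_date =
        parse_registry_date(raw$planned_primary_completion_date),
      expected_enrollment = suppressWarnings(as.integer(raw$expected_enrollment)),
      actual_enrollment = suppressWarnings(as.integer(raw$actual_enrollment)),
      termination_reason = raw$termination_reason,
      registry_results_posted = ti_chr_to_bool(raw$registry_results_posted),
      primary_outcome_publication_date =
        parse_registry_date(raw$primary_outcome_publication_date),
      outcome_type = raw$outcome_type,
      registered_within_30_days = ti_chr_to_bool(raw$registered_within_30_days),
      citation_evidence = lapply(raw$citation_evidence, ti_chr_to_citations),
      rob_assessment = lapply(raw$rob_assessment, ti_chr_to_rob)
    )
  } else {
    arr <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    recs <- do.call(rbind, lapply(arr, function(o) {
      ce <- if (length(o$citation_evidence) > 0) {
        citation_evidence(
          doc_type = vapply(o$citation_evidence, `[[`, "", "doc_type"),
          high_quality = vapply(o$citation_evidence, `[[`, NA, "high_quality"),
          cites_trial_results =
            vapply(o$citation_evidence, `[[`, NA, "cites_trial_results")
        )
      } else citation_evidence()
      rob <- if (!is.null(o$rob_assessment)) {
        rob_assessment(unlist(o$rob_assessment$elements),
                       source = o$rob_assessment$source)
      } else NULL
      opt_int <- function(x) if (is.null(x)) NA_integer_ else as.integer(x)
      opt_date <- function(x) {
        if (is.null(x)) as.Date(NA) else parse_registry_date(x)
      }
      tibble::tibble(
        registry_id = o$registry_id,
        disease_area = o$disease_area,
        randomized = as.logical(o$randomized),
        has_us_site = as.logical(o$has_us_site),
        purpose = o$purpose,
        phase = o$phase,
        intervention_class = o$intervention_class,
        sponsor_class = o$sponsor_class,
        fda_pathway = o$fda_pathway,
        status = o$status,
        start_date = parse_registry_date(o$start_date),
        planned_primary_completion_date =
          parse_registry_date(o$planned_primary_completion_date),
        expected_enrollment = as.integer(o$expected_enrollment),
        actual_enrollment = opt_int(o$actual_enrollment),
        termination_reason = o$termination_reason,
        registry_results_posted = as.logical(o$registry_results_posted),
        primary_outcome_publication_date =
          opt_date(o$primary_outcome_publication_date),
        outcome_type = o$outcome_type,
        registered_within_30_days = as.logical(o$registered_within_30_days),
        citation_evidence = list(ce),
        rob_assessment = list(rob)
      )
    }))
  }
  # mandatory-field completeness
  problems <- character()
  for (f in ti_mandatory_fields) {
    bad <- which(is.na(recs[[f]]))
    for (i in bad) {
      problems <- c(problems, sprintf("record %s (row %d): missing field '%s'",
                                      recs$registry_id[i], i, f))
    }
  }
  if (length(problems) > 0) {
    stop("schema error:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  }
  viol <- validate_records(recs)
  if (length(viol) > 0) {
    msgs <- vapply(names(viol), function(id) {
      sprintf("%s: %s", id, paste(viol[[id]], collapse = ", "))
    }, "")
    stop("invalid records:\n  ", paste(msgs, collapse = "\n  "),
         call. = FALSE)
  }
  recs
}

#' Write trial records to CSV or JSON
#'
#' Inverse of [read_trial_records()]: a write followed by a read yields
#' records field-equal to the originals for both formats.
#'
#' @param records Trial-record tibble.
#' @param path Output path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_trial_records <- function(records, path, format = c("csv", "json")) {
  format <- match.arg(format)
  date_chr <- function(d) ifelse(is.na(d), "", format(d, "%Y-%m-%d"))
  if (format == "csv") {
    flat <- data.frame(
      registry_id = records$registry_id,
      disease_area = records$disease_area,
      randomized = ti_bool_to_chr(records$randomized),
      has_us_site = ti_bool_to_chr(records$has_us_site),
      purpose = records$purpose,
      phase = records$phase,
      intervention_class = records$intervention_class,
      sponsor_class = records$sponsor_class,
      fda_pathway = records$fda_pathway,
      status = records$status,
      start_date = date_chr(records$start_date),
      planned_primary_completion_date =
        date_chr(records$planned_primary_completion_date),
      expected_enrollment = records$expected_enrollment,
      actual_enrollment = ifelse(is.na(records$actual_enrollment), "",
                                 records$actual_enrollment),
      termination_reason = records$termination_reason,
      registry_results_posted = ti_bool_to_chr(records$registry_results_posted),
      primary_outcome_publication_date =
        date_chr(records$primary_outcome_publication_date),
      outcome_type = records$outcome_type,
      registered_within_30_days =
        ti_bool_to_chr(records$registered_within_30_days),
      citation_evidence = vapply(records$citation_evidence,
                                 ti_citations_to_chr, ""),
      rob_assessment = vapply(records$rob_assessment, ti_rob_to_chr, ""),
      stringsAsFactors = FALSE
    )
    utils::write.csv(flat, path, row.names = FALSE, fileEncoding = "UTF-8")
  } else {
    objs <- lapply(seq_len(nrow(records)), function(i) {
      r <- records[i, ]
      ce <- r$citation_evidence[[1]]
      rob <- r$rob_assessment[[1]]
      o <- list(
        registry_id = r$registry_id,
        disease_area = r$disease_area,
        randomized = r$randomized,
        has_us_site = r$has_us_site,
        purpose = r$purpose,
        phase = r$phase,
        intervention_class = r$intervention_class,
        sponsor_class = r$sponsor_class,
        fda_pathway = r$fda_pathway,
        status = r$status,
        start_date = format(r$start_date, "%Y-%m-%d"),
        planned_primary_completion_date =
          format(r$planned_primary_completion_date, "%Y-%m-%d"),
        expected_enrollment = r$expected_enrollment,
        actual_enrollment = if (is.na(r$actual_enrollment)) NULL
                            else r$actual_enrollment,
        termination_reason = r$termination_reason,
        registry_results_posted = r$registry_results_posted,
        primary_outcome_publication_date =
          if (is.na(r$primary_outcome_publication_date)) NULL
          else format(r$primary_outcome_publication_date, "%Y-%m-%d"),
        outcome_type = r$outcome_type,
        registered_within_30_days = r$registered_within_30_days,
        citation_evidence = if (nrow(ce) == 0) list() else
          lapply(seq_len(nrow(ce)), function(j) as.list(ce[j, ])),
        rob_assessment = if (is.null(rob)) NULL else
          list(source = rob$source, elements = as.list(rob$elements))
      )
      o[!vapply(o, is.null, NA)]
    })
    jsonlite::write_json(objs, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
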