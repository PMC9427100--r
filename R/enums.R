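# Controlled vocabularies for registry record fields. Serialized values are
# lowercase snake case, matching the CSV/JSON dialect.

ti_enums <- list(
  disease_area = c("ischemic_heart_disease", "diabetes_mellitus", "lung_cancer"),
  purpose = c("treatment", "prevention", "safety_only", "diagnostic",
              "screening", "other"),
  phase = c("phase2", "phase3", "phase4", "not_applicable", "phase0_or_1"),
  intervention_class = c("drug_biologic", "combination", "device", "other"),
  sponsor_class = c("industry", "other"),
  fda_pathway = c("approved_or_advanced", "not_subject", "never_approved"),
  status = c("completed", "terminated", "active_not_recruiting", "unknown",
             "recruiting"),
  termination_reason = c("scientific_efficacy", "scientific_futility",
                         "scientific_toxicity", "accrual", "feasibility",
                         "funding", "other_nonscientific", "none"),
  outcome_type = c("clinical", "surrogate"),
  doc_type = c("cochrane_sr", "ahrq_sr", "other_sr", "cpg", "uptodate"),
  rob_level = c("low", "unclear", "high"),
  rob_source = c("extracted_from_sr", "de_novo")
)

# termination reasons counted as scientific (early efficacy/futility/toxicity)
ti_scientific_termination <- c("scientific_efficacy", "scientific_futility",
                               "scientific_toxicity")

# statuses treated as ongoing for the indeterminate / overdue rules;
# unknown-status trials are treated as ongoing
ti_ongoing_statuses <- c("active_not_recruiting", "recruiting", "unknown")

# default risk-of-bias element set (modified Cochrane tool)
ti_rob_elements <- c("sequence_generation", "allocation_concealment",
                     "blinding_participants_personnel",
                     "blinding_outcome_assessment", "incomplete_outcome_data",
                     "selective_reporting", "other")
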