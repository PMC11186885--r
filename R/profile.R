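#' Per-record availability profile of TDP-43 related measures
#'
#' For every record, reports whether each TDP-43 related measure was
#' assessed at all (present *or* absent), as opposed to not assessed.
#' An antibody recorded as `not_listed` counts as unavailable.
#'
#' @param cohort a decoded cohort tibble.
#' @return a tibble with `participant_id` and logical columns
#'   `has_spinal_cord`, `has_amygdala`, `has_hippocampus`, `has_ec_itc`,
#'   `has_neocortex`, `has_regional_any` (any of the four brain regions),
#'   `has_regional_all_brain` (all four), `has_ftld_tdp`, `has_als`,
#'   `has_hs_a`, `has_antibody`.
#' @export
availability_profile <- function(cohort) {
  check_cohort(cohort, c("participant_id", REGION_FIELDS, "ftld_tdp",
                         "mn_inclusion", "hs_a", "tdp_antibody"),
               "availability_profile")
  has_amygdala <- is_assessed(cohort$tdp_amygdala)
  has_hippocampus <- is_assessed(cohort$tdp_hippocampus)
  has_ec_itc <- is_assessed(cohort$tdp_ec_itc)
  has_neocortex <- is_assessed(cohort$tdp_neocortex)
  tibble::tibble(
    participant_id = cohort$participant_id,
    has_spinal_cord = is_assessed(cohort$tdp_spinal_cord),
    has_amygdala = has_amygdala,
    has_hippocampus = has_hippocampus,
    has_ec_itc = has_ec_itc,
    has_neocortex = has_neocortex,
    has_regional_any = has_amygdala | has_hippocampus | has_ec_itc |
      has_neocortex,
    has_regional_all_brain = has_amygdala & has_hippocampus & has_ec_itc &
      has_neocortex,
    has_ftld_tdp = is_assessed(cohort$ftld_tdp),
    has_als = is_assessed(cohort$mn_inclusion),
    has_hs_a = is_assessed(cohort$hs_a),
    has_antibody = !is.na(cohort$tdp_antibody) &
      cohort$tdp_antibody != "not_listed"
  )
}

#' Group raw presumptive etiologic diagnosis labels into eight categories
#'
#' Deterministic eight-way grouping of the last available presumptive
#' etiologic diagnosis: AD; FTLD (FTLD-other plus FTLD motor neuron
#' disease); CBD/PSP; Lewy body dementia; vascular dementia; other
#' impairment; not impaired; and unavailable for records without a usable
#' last-visit label.
#'
#' @param raw character vector of raw labels; `NA` or empty maps to
#'   `"UNAVAILABLE"`.
#' @param labels named character vector mapping raw labels to categories;
#'   defaults to the dialect's `dx_labels` table.
#' @return character vector over the eight diagnosis categories.
#' @export
group_diagnosis <- function(raw, labels = default_dialect()$dx_labels) {
  out <- rep("UNAVAILABLE", length(raw))
  known <- !is.na(raw) & trimws(raw) != ""
  mapped <- unname(labels[raw[known]])
  bad <- unique(raw[known][is.na(mapped)])
  if (length(bad) > 0) {
    abort(sprintf("unrecognized presumptive diagnosis label(s): %s",
                  paste(sprintf("`%s`", bad), collapse = ", ")))
  }
  out[known] <- mapped
  out
}

#' Restrict a cohort to records with complete TDP-43 assessment
#'
#' Keeps records for which every TDP-43 related pathology assessment was
#' performed: all four brain regions (amygdala, hippocampus, EC/ITC,
#' neocortex), the FTLD-TDP designation, the motor-neuron-inclusion
#' assessment, and HS-A. Spinal cord assessment is *not* required. A
#' negative finding counts as assessed; only `not_assessed` excludes.
#' Record order is preserved and the operation is idempotent.
#'
#' @param cohort a decoded cohort tibble.
#' @return the retained subset, same columns and order.
#' @export
complete_case_filter <- function(cohort) {
  check_cohort(cohort, COMPLETE_CASE_FIELDS, "complete_case_filter")
  if (nrow(cohort) == 0) return(cohort)
  keep <- Reduce(`&`, lapply(COMPLETE_CASE_FIELDS,
                             function(f) is_assessed(cohort[[f]])))
  cohort[keep, , drop = FALSE]
}
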