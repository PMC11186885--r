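# TDP-43 category assignment. Rule precedence (top-down):
#   1. ALS/FTLD-TDP designation wins irrespective of any other pathology.
#   2. No brain TDP-43 (and no designation) -> No TDP-43; a spinal-cord
#      finding alone does not change the category (groups are defined on
#      brain TDP-43) but is kept in the trace.
#   3. Exclusionary pathologies (CBD, CTE, acute/chronic TBI, Huntington,
#      Guam/Kii parkinsonism) or an FTD-related / ADAD mutation -> Other
#      TDP-43.
#   4. Neocortical TDP-43 without both amygdala and hippocampal TDP-43 ->
#      Other TDP-43 (not a permissible LATE-NC distribution).
#   5. Everything else -> LATE-NC, with stage 1-3.

#' Assign TDP-43 categories to complete-case records
#'
#' Classifies each record into one of four mutually exclusive, exhaustive
#' categories: `no_tdp43`, `late_nc`, `als_ftld_tdp`, `other_tdp43`.
#' Classification is only defined on records whose TDP-43 assessment is
#' complete (see [complete_case_filter()]); incomplete records are a
#' contract error, not a silent `NA`.
#'
#' A record designated ALS-TDP or FTLD-TDP but with no TDP-43 recorded in
#' any region (brain or spinal cord) keeps its category and is flagged
#' `qc_no_regional`, since that combination may signal a data-entry error.
#'
#' @param cohort a decoded cohort tibble; every row must pass the
#'   complete-case filter.
#' @return a tibble with one row per record: `participant_id`, `category`,
#'   `subtype` (`ftld_only`/`als_only`/`both`, `NA` unless ALS/FTLD-TDP),
#'   `stage` (1-3, `NA` unless LATE-NC), `other_reason` (comma-joined
#'   subset of the exclusion reasons, empty unless Other TDP-43),
#'   `qc_no_regional`, and `trace` (semicolon-joined fired rules).
#' @export
classify_tdp <- function(cohort) {
  check_cohort(cohort, c("participant_id", REGION_FIELDS, "ftld_tdp",
                         "mn_inclusion", "hs_a", EXCLUSION_FLAGS,
                         "ftd_mutation", "adad_mutation"), "classify_tdp")
  if (nrow(cohort) == 0) {
    return(tibble::tibble(participant_id = character(0),
                          category = character(0), subtype = character(0),
                          stage = integer(0), other_reason = character(0),
                          qc_no_regional = logical(0), trace = character(0)))
  }
  incomplete <- !Reduce(`&`, lapply(COMPLETE_CASE_FIELDS,
                                    function(f) is_assessed(cohort[[f]])))
  if (any(incomplete)) {
    abort(sprintf(
      "classify_tdp() requires complete TDP-43 assessment; incomplete: %s",
      paste(utils::head(cohort$participant_id[incomplete], 5),
            collapse = ", ")))
  }

  amyg <- cohort$tdp_amygdala == "present"
  hipp <- cohort$tdp_hippocampus == "present"
  ec <- cohort$tdp_ec_itc == "present"
  neoc <- cohort$tdp_neocortex == "present"
  spinal <- !is.na(cohort$tdp_spinal_cord) &
    cohort$tdp_spinal_cord == "present"
  brain_any <- amyg | hipp | ec | neoc

  ftld <- cohort$ftld_tdp == "present"
  als <- cohort$mn_inclusion == "tdp43"
  designated <- ftld | als

  flag_mat <- vapply(EXCLUSION_FLAGS, function(f) isTRUE_vec(cohort[[f]]),
                     logical(nrow(cohort)))
  flag_mat <- matrix(flag_mat, nrow = nrow(cohort),
                     dimnames = list(NULL, EXCLUSION_FLAGS))
  ftd_mut <- cohort$ftd_mutation == "yes"
  adad_mut <- cohort$adad_mutation == "yes"
  excluded <- rowSums(flag_mat) > 0 | ftd_mut | adad_mut
  neoc_pattern <- neoc & !(amyg & hipp)

  category <- dplyr::case_when(
    designated ~ "als_ftld_tdp",
    !brain_any ~ "no_tdp43",
    excluded ~ "other_tdp43",
    neoc_pattern ~ "other_tdp43",
    TRUE ~ "late_nc"
  )

  subtype <- rep(NA_character_, nrow(cohort))
  is_af <- category == "als_ftld_tdp"
  subtype[is_af] <- dplyr::case_when(
    ftld[is_af] & als[is_af] ~ "both",
    ftld[is_af] ~ "ftld_only",
    TRUE ~ "als_only"
  )

  stage <- rep(NA_integer_, nrow(cohort))
  is_late <- category == "late_nc"
  if (any(is_late)) {
    stage[is_late] <- late_stage(cohort[is_late, , drop = FALSE])
  }

  reasons <- character(nrow(cohort))
  is_other <- category == "other_tdp43"
  if (any(is_other)) {
    reason_mat <- cbind(flag_mat, ftd_mutation = ftd_mut,
                        adad_mutation = adad_mut,
                        neocortical_pattern = neoc_pattern)
    reasons[is_other] <- apply(
      reason_mat[is_other, , drop = FALSE], 1,
      function(r) paste(colnames(reason_mat)[r], collapse = ","))
  }

  qc_no_regional <- designated & !brain_any & !spinal

  trace <- build_trace(category, subtype, stage, reasons, spinal,
                       qc_no_regional)

  tibble::tibble(
    participant_id = cohort$participant_id,
    category = category, subtype = subtype, stage = stage,
    other_reason = reasons, qc_no_regional = qc_no_regional, trace = trace
  )
}

build_trace <- function(category, subtype, stage, reasons, spinal,
                        qc_no_regional) {
  trace <- character(length(category))
  af <- category == "als_ftld_tdp"
  trace[af] <- paste0("R1:als_ftld_designation(", subtype[af], ")")
  trace[af & qc_no_regional] <- paste0(trace[af & qc_no_regional],
                                       ";QC:no_regional_tdp43")
  no <- category == "no_tdp43"
  trace[no] <- "R2:no_brain_tdp43"
  trace[no & spinal] <- "R2:no_brain_tdp43;note:spinal_cord_tdp43_present"
  ot <- category == "other_tdp43"
  trace[ot] <- ifelse(
    grepl("neocortical_pattern", reasons[ot]) &
      reasons[ot] == "neocortical_pattern",
    "R4:neocortical_pattern",
    paste0("R3:exclusionary(", reasons[ot], ")"))
  lt <- category == "late_nc"
  trace[lt] <- paste0("R5:late_nc(stage=", stage[lt], ")")
  trace
}

#' LATE-NC stage from regional TDP-43 presence
#'
#' Stage 3 requires TDP-43 in amygdala, hippocampus, and neocortex;
#' stage 2 requires both amygdala and hippocampus; any other eligible
#' distribution (TDP-43 limited to amygdala, hippocampus, and/or EC/ITC,
#' in any single region or pair short of amygdala+hippocampus) is stage 1.
#' Stages are nested: every stage-3 record also satisfies the stage-2
#' condition.
#'
#' @param regional a data frame with tri-state columns `tdp_amygdala`,
#'   `tdp_hippocampus`, `tdp_ec_itc`, `tdp_neocortex`; every row must have
#'   TDP-43 present in at least one of amygdala, hippocampus, or EC/ITC
#'   (the LATE-NC eligibility precondition).
#' @return integer vector of stages in `1:3`.
#' @export
late_stage <- function(regional) {
  check_cohort(regional, BRAIN_REGION_FIELDS, "late_stage")
  amyg <- regional$tdp_amygdala == "present"
  hipp <- regional$tdp_hippocampus == "present"
  ec <- regional$tdp_ec_itc == "present"
  neoc <- regional$tdp_neocortex == "present"
  if (any(!(amyg | hipp | ec))) {
    abort(paste("late_stage() requires TDP-43 in at least one of amygdala,",
                "hippocampus, or EC/ITC"))
  }
  ifelse(amyg & hipp & neoc, 3L, ifelse(amyg & hipp, 2L, 1L))
}

#' ALS/FTLD-TDP subtype
#'
#' Splits records carrying the ALS/FTLD-TDP category by which designation
#' drives it: `both` when FTLD-TDP is present and motor neuron inclusions
#' are TDP-43; `ftld_only` or `als_only` when only one applies.
#'
#' @param cohort a decoded cohort tibble; every row must carry an ALS-TDP
#'   or FTLD-TDP designation.
#' @return character vector over `ftld_only`, `als_only`, `both`.
#' @export
als_ftld_subtype <- function(cohort) {
  check_cohort(cohort, c("ftld_tdp", "mn_inclusion"), "als_ftld_subtype")
  ftld <- cohort$ftld_tdp == "present"
  als <- cohort$mn_inclusion == "tdp43"
  if (any(!(ftld | als))) {
    abort("als_ftld_subtype() is only defined for ALS/FTLD-TDP records")
  }
  dplyr::case_when(ftld & als ~ "both", ftld ~ "ftld_only",
                   TRUE ~ "als_only")
}
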