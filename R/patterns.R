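#' Regional TDP-43 presence patterns within one category
#'
#' Tabulates, among records of a given TDP-43 category with inclusions in
#' at least one brain region, every observed combination of regional
#' TDP-43 *presence* (amygdala, hippocampus, EC/ITC, neocortex), with
#' counts and percentages of that restricted total.
#'
#' @param cohort a decoded cohort tibble (complete-case subset).
#' @param assignments output of [classify_tdp()] covering the cohort.
#' @param category one of `late_nc`, `als_ftld_tdp`, `other_tdp43`.
#' @return a pattern-count tibble with logical columns `amygdala`,
#'   `hippocampus`, `ec_itc`, `neocortex` plus `count`, `pct`,
#'   `proportion`; attribute `"total"` is the number of records
#'   tabulated.
#' @export
regional_pattern_counts <- function(cohort, assignments, category) {
  if (!category %in% TDP_CATEGORIES) {
    abort(sprintf("unknown category `%s`", category))
  }
  df <- dplyr::left_join(cohort,
                         assignments[, c("participant_id", "category")],
                         by = "participant_id")
  amyg <- df$tdp_amygdala == "present"
  hipp <- df$tdp_hippocampus == "present"
  ec <- df$tdp_ec_itc == "present"
  neoc <- df$tdp_neocortex == "present"
  keep <- df$category == category & (amyg | hipp | ec | neoc)
  membership <- tibble::tibble(
    amygdala = amyg[keep], hippocampus = hipp[keep],
    ec_itc = ec[keep], neocortex = neoc[keep])
  venn_counts(membership)
}

#' Co-occurrence of ALS/FTLD-TDP, LATE-NC, ADNC, and Lewy bodies
#'
#' Membership-pattern counts and proportions for the four pathology sets,
#' excluding (by definition) records classified Other TDP-43 and records
#' missing the ADNC or Lewy-body rating. ALS/FTLD-TDP and LATE-NC are
#' mutually exclusive by construction, so their intersection is always
#' empty.
#'
#' @param cohort a decoded cohort tibble (complete-case subset).
#' @param assignments output of [classify_tdp()] covering the cohort.
#' @return a pattern-count tibble with logical columns `als_ftld_tdp`,
#'   `late_nc`, `adnc` (intermediate/high), `lewy` (present in any
#'   region) plus `count`, `pct`, `proportion`; attribute `"total"` is the
#'   retained total.
#' @export
overlap_proportions <- function(cohort, assignments) {
  df <- dplyr::left_join(cohort,
                         assignments[, c("participant_id", "category")],
                         by = "participant_id")
  keep <- df$category != "other_tdp43" & is_assessed(df$adnc) &
    is_assessed(df$lewy_any)
  df <- df[keep, , drop = FALSE]
  membership <- tibble::tibble(
    als_ftld_tdp = df$category == "als_ftld_tdp",
    late_nc = df$category == "late_nc",
    adnc = df$adnc == "int_high",
    lewy = df$lewy_any == "present")
  venn_counts(membership)
}
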