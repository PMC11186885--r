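# Participant-characteristics table by TDP-43 category, in the style of a
# clinical "Table 1": mean (SD) for continuous variables, n (%) over the
# non-missing for categorical ones, with per-variable missing counts and
# pairwise group tests.

SUMMARY_CONTINUOUS <- c("age_at_death", "education", "interval_visit_death",
                        "cdr_sb")

# categorical variables with display levels and their missing markers
SUMMARY_CATEGORICAL <- list(
  sex = list(levels = c("female", "male"), missing = NA),
  apoe4 = list(levels = c("absent", "present"), missing = "missing"),
  ftd_mutation = list(levels = c("yes", "no_unknown"), missing = NA),
  tdp_antibody = list(levels = c("phospho", "non_phospho", "other"),
                      missing = "not_listed"),
  cognitive_status = list(levels = c("normal", "mci_impaired", "dementia"),
                          missing = NA),
  clinical_ad = list(levels = c("no_impairment", "not_ad", "ad"),
                     missing = NA),
  ppa = list(levels = c("absent", "present"), missing = "missing"),
  bvftd = list(levels = c("absent", "present"), missing = NA),
  hs_a = list(levels = c("absent", "present"), missing = "not_assessed",
              collapse = function(x) ifelse(x %in% HS_A_PRESENT, "present",
                                            x)),
  ftld_tau = list(levels = c("absent", "present"),
                  missing = "not_assessed"),
  adnc = list(levels = c("none_low", "int_high"), missing = "not_assessed"),
  caa = list(levels = c("none_mild", "mod_severe"),
             missing = "not_assessed"),
  lewy_any = list(levels = c("absent", "present"),
                  missing = "not_assessed"),
  atherosclerosis = list(levels = c("none_mild", "mod_severe"),
                         missing = "not_assessed"),
  arteriolosclerosis = list(levels = c("none_mild", "mod_severe"),
                            missing = "not_assessed"),
  infarcts = list(levels = c("absent", "present"),
                  missing = "not_assessed"),
  microinfarcts = list(levels = c("absent", "present"),
                       missing = "not_assessed"),
  hemorrhages = list(levels = c("absent", "present"),
                     missing = "not_assessed"),
  hipp_atrophy = list(levels = c("none_mild", "mod_severe"),
                      missing = "not_assessed"),
  cortical_atrophy = list(levels = c("none_mild", "mod_severe"),
                          missing = "not_assessed"),
  lobar_atrophy = list(levels = c("absent", "present"),
                       missing = "not_assessed")
)

SUMMARY_COMPARISONS <- list(
  c("late_nc", "no_tdp43"),
  c("late_nc", "als_ftld_tdp"),
  c("als_ftld_tdp", "no_tdp43")
)

#' Participant characteristics and co-pathologies by TDP-43 category
#'
#' Builds the group-comparison table for a classified cohort: continuous
#' variables summarized as mean (SD), categorical ones as n (%) over the
#' non-missing records, with missing counted per cell, and pairwise
#' comparisons (LATE-NC vs No TDP-43, LATE-NC vs ALS/FTLD-TDP,
#' ALS/FTLD-TDP vs No TDP-43) by Wilcoxon rank-sum (continuous) or Pearson
#' chi-square (categorical). Percentages are kept as exact counts and
#' proportions; rounding to whole percent happens only at render time
#' ([render_summary()]).
#'
#' @param cohort a decoded cohort tibble (the complete-case subset).
#' @param assignments output of [classify_tdp()] covering the cohort.
#' @return a `tdp_summary` list: `cells` (variable, level, category, n,
#'   proportion, mean, sd, n_missing), `tests` (variable, comparison,
#'   test, statistic, p_value), `n_by_category`.
#' @export
summarize_by_category <- function(cohort, assignments) {
  df <- dplyr::left_join(cohort,
                         assignments[, c("participant_id", "category")],
                         by = "participant_id")
  if (any(is.na(df$category))) abort("assignments do not cover the cohort")
  cats <- TDP_CATEGORIES[TDP_CATEGORIES %in% unique(df$category)]
  n_by_cat <- table(factor(df$category, levels = TDP_CATEGORIES))

  cells <- list()
  tests <- list()

  for (v in SUMMARY_CONTINUOUS) {
    x <- df[[v]]
    for (cat in cats) {
      xi <- x[df$category == cat]
      cells[[length(cells) + 1]] <- tibble::tibble(
        variable = v, level = NA_character_, category = cat,
        n = sum(!is.na(xi)), proportion = NA_real_,
        mean = mean(xi, na.rm = TRUE), sd = stats::sd(xi, na.rm = TRUE),
        n_missing = sum(is.na(xi)))
    }
    for (pr in SUMMARY_COMPARISONS) {
      if (!all(pr %in% cats)) next
      x1 <- x[df$category == pr[1] & !is.na(x)]
      x2 <- x[df$category == pr[2] & !is.na(x)]
      if (length(x1) == 0 || length(x2) == 0) next
      rs <- rank_sum_test(x1, x2)
      tests[[length(tests) + 1]] <- tibble::tibble(
        variable = v, comparison = paste(pr[1], "vs", pr[2]),
        test = "wilcoxon_rank_sum", statistic = rs$statistic,
        p_value = rs$p_value)
    }
  }

  for (v in names(SUMMARY_CATEGORICAL)) {
    spec <- SUMMARY_CATEGORICAL[[v]]
    x <- df[[v]]
    if (!is.null(spec$collapse)) x <- spec$collapse(x)
    miss <- is.na(x) | (!is.na(spec$missing[1]) & x %in% spec$missing)
    x[miss] <- NA
    for (cat in cats) {
      sel <- df$category == cat
      denom <- sum(sel & !miss)
      for (lv in spec$levels) {
        n_lv <- sum(sel & !miss & x == lv)
        cells[[length(cells) + 1]] <- tibble::tibble(
          variable = v, level = lv, category = cat,
          n = n_lv,
          proportion = if (denom > 0) n_lv / denom else NA_real_,
          mean = NA_real_, sd = NA_real_,
          n_missing = sum(sel & miss))
      }
    }
    for (pr in SUMMARY_COMPARISONS) {
      if (!all(pr %in% cats)) next
      sel <- df$category %in% pr & !miss
      if (sum(sel) == 0) next
      tab <- table(factor(df$category[sel], levels = pr),
                   factor(x[sel], levels = spec$levels))
      tab <- tab[, colSums(tab) > 0, drop = FALSE]
      if (nrow(tab) < 2 || ncol(tab) < 2 || any(rowSums(tab) == 0)) next
      chi <- suppressWarnings(chisq.test(tab, correct = FALSE))
      tests[[length(tests) + 1]] <- tibble::tibble(
        variable = v, comparison = paste(pr[1], "vs", pr[2]),
        test = "pearson_chi_square", statistic = unname(chi$statistic),
        p_value = chi$p.value)
    }
  }

  structure(list(cells = dplyr::bind_rows(cells),
                 tests = dplyr::bind_rows(tests),
                 n_by_category = n_by_cat),
            class = "tdp_summary")
}
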