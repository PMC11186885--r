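# Part-I analytics: availability of TDP-43 related measures over time and
# across measures/regions, and follow-up / autopsy rate models.

AVAILABILITY_MEASURES <- c("spinal_cord", "amygdala", "hippocampus",
                           "ec_itc", "neocortex", "regional_any",
                           "ftld_tdp", "als", "hs_a", "antibody")

#' Availability of TDP-43 measures by year of death
#'
#' For each measure and calendar year of death, the fraction of autopsied
#' participants dying that year whose measure was assessed.
#'
#' @param cohort a decoded cohort tibble; records without an autopsy or
#'   without a year of death are ignored.
#' @param measures subset of measures to tabulate (default all).
#' @return a tibble `measure`, `year`, `n_assessed`, `n_total`,
#'   `proportion`; empty if no eligible records.
#' @export
availability_by_year <- function(cohort, measures = AVAILABILITY_MEASURES) {
  check_cohort(cohort, c("autopsied", "year_of_death"),
               "availability_by_year")
  bad <- setdiff(measures, AVAILABILITY_MEASURES)
  if (length(bad) > 0) {
    abort(sprintf("unknown availability measure(s): %s",
                  paste(bad, collapse = ", ")))
  }
  keep <- isTRUE_vec(cohort$autopsied) & !is.na(cohort$year_of_death)
  cohort <- cohort[keep, , drop = FALSE]
  if (nrow(cohort) == 0) {
    return(tibble::tibble(measure = character(0), year = numeric(0),
                          n_assessed = integer(0), n_total = integer(0),
                          proportion = numeric(0)))
  }
  prof <- availability_profile(cohort)
  prof$year <- cohort$year_of_death
  long <- tidyr::pivot_longer(
    prof[, c("year", paste0("has_", measures))],
    cols = -"year", names_to = "measure", names_prefix = "has_",
    values_to = "assessed")
  long |>
    dplyr::group_by(.data$measure, .data$year) |>
    dplyr::summarise(n_assessed = sum(.data$assessed),
                     n_total = dplyr::n(),
                     proportion = mean(.data$assessed), .groups = "drop") |>
    dplyr::arrange(.data$measure, .data$year)
}

# shared pattern-count core for the Venn tabulations
venn_counts <- function(membership, total = nrow(membership)) {
  stopifnot(is.data.frame(membership))
  patterns <- membership |>
    dplyr::count(dplyr::across(dplyr::everything()), name = "count") |>
    dplyr::arrange(dplyr::across(dplyr::everything(), dplyr::desc))
  patterns$pct <- pct_half_up(patterns$count, total)
  patterns$proportion <- patterns$count / total
  attr(patterns, "set_labels") <- names(membership)
  attr(patterns, "total") <- total
  patterns
}

#' Availability pattern counts across the TDP-43 measures
#'
#' Tabulates, over the whole cohort, every observed combination of
#' availability of the four headline measures: any regional TDP-43
#' assessment, the FTLD-TDP designation, the motor-neuron-inclusion (ALS)
#' assessment, and HS-A. The "ALS and HS-A only" row, for example, counts
#' records assessed for those two measures and nothing else.
#'
#' @param cohort a decoded cohort tibble.
#' @return a tibble with logical columns `regional_any`, `ftld_tdp`,
#'   `als`, `hs_a` plus `count`, `pct`, `proportion`; attribute `"total"`
#'   is the cohort size (patterns, including the none-available row, sum
#'   to it).
#' @export
measure_venn <- function(cohort) {
  prof <- availability_profile(cohort)
  membership <- tibble::tibble(
    regional_any = prof$has_regional_any,
    ftld_tdp = prof$has_ftld_tdp,
    als = prof$has_als,
    hs_a = prof$has_hs_a)
  venn_counts(membership, total = nrow(cohort))
}

#' Availability pattern counts across the four brain regions
#'
#' Restricted by precondition to records with at least one brain-region
#' assessment, tabulates availability patterns over amygdala, hippocampus,
#' EC/ITC, and neocortex, and additionally reports the count assessed in
#' all four regions and in the staging-relevant trio (amygdala,
#' hippocampus, neocortex) as attributes `"n_all_four"` /
#' `"n_staging_trio"` (with `"pct_all_four"` / `"pct_staging_trio"`).
#'
#' @param cohort a decoded cohort tibble in which every record has at
#'   least one brain region assessed (contract error otherwise).
#' @return a pattern-count tibble as in [measure_venn()] over the regions.
#' @export
region_venn <- function(cohort) {
  prof <- availability_profile(cohort)
  if (any(!prof$has_regional_any)) {
    abort(paste("region_venn() requires every record to have at least one",
                "brain-region assessment; filter on has_regional_any first"))
  }
  membership <- tibble::tibble(
    amygdala = prof$has_amygdala,
    hippocampus = prof$has_hippocampus,
    ec_itc = prof$has_ec_itc,
    neocortex = prof$has_neocortex)
  out <- venn_counts(membership, total = nrow(cohort))
  n_all_four <- sum(prof$has_regional_all_brain)
  n_trio <- sum(prof$has_amygdala & prof$has_hippocampus &
                  prof$has_neocortex)
  attr(out, "n_all_four") <- n_all_four
  attr(out, "n_staging_trio") <- n_trio
  attr(out, "pct_all_four") <- pct_half_up(n_all_four, nrow(cohort))
  attr(out, "pct_staging_trio") <- pct_half_up(n_trio, nrow(cohort))
  out
}

#' Neocortical TDP-43 availability by hippocampal TDP-43 status, split by era
#'
#' Tests whether, among participants with a presumptive etiologic
#' diagnosis of AD and an assessed hippocampus, the availability of the
#' neocortical TDP-43 assessment depends on whether hippocampal TDP-43 was
#' found -- separately for deaths before the split year and deaths during
#' or after it. A gap confined to the later era is the signature of
#' pathologists foregoing the neocortical stain when the hippocampus is
#' TDP-43 negative.
#'
#' @param cohort a decoded cohort tibble.
#' @param split_year first year of the late era (death year >= split_year
#'   counts as "during or after"); default 2019.
#' @param dx_labels label mapping passed to [group_diagnosis()].
#' @param yates use the Yates continuity correction (default plain
#'   Pearson).
#' @return a tibble with one row per era (`pre`, `post`): stratum counts,
#'   availability proportions by hippocampal status (`NA` when a stratum
#'   is empty), and the chi-square statistic and p-value (`NA` when not
#'   computable).
#' @export
conditional_neocortex_availability <- function(cohort, split_year = 2019,
                                               dx_labels =
                                                 default_dialect()$dx_labels,
                                               yates = FALSE) {
  check_cohort(cohort, c("etiologic_dx_raw", "year_of_death",
                         "tdp_hippocampus", "tdp_neocortex"),
               "conditional_neocortex_availability")
  dx <- group_diagnosis(cohort$etiologic_dx_raw, dx_labels)
  keep <- dx == "AD" & is_assessed(cohort$tdp_hippocampus) &
    !is.na(cohort$year_of_death)
  dat <- cohort[keep, , drop = FALSE]
  era <- ifelse(dat$year_of_death >= split_year, "post", "pre")
  hipp_pos <- dat$tdp_hippocampus == "present"
  neoc_avail <- is_assessed(dat$tdp_neocortex)
  purrr::map(c(pre = "pre", post = "post"), function(e) {
    sel <- era == e
    n_neg <- sum(sel & !hipp_pos)
    n_neg_av <- sum(sel & !hipp_pos & neoc_avail)
    n_pos <- sum(sel & hipp_pos)
    n_pos_av <- sum(sel & hipp_pos & neoc_avail)
    tab <- matrix(c(n_neg_av, n_neg - n_neg_av,
                    n_pos_av, n_pos - n_pos_av),
                  nrow = 2, byrow = TRUE)
    test_ok <- all(rowSums(tab) > 0) && all(colSums(tab) > 0)
    chi <- if (test_ok) {
      suppressWarnings(chisq.test(tab, correct = yates))
    } else NULL
    tibble::tibble(
      era = e, split_year = split_year,
      n_hipp_neg = n_neg, n_hipp_neg_neoc = n_neg_av,
      prop_hipp_neg = if (n_neg > 0) n_neg_av / n_neg else NA_real_,
      n_hipp_pos = n_pos, n_hipp_pos_neoc = n_pos_av,
      prop_hipp_pos = if (n_pos > 0) n_pos_av / n_pos else NA_real_,
      statistic = if (test_ok) unname(chi$statistic) else NA_real_,
      p_value = if (test_ok) chi$p.value else NA_real_)
  }) |> dplyr::bind_rows()
}

#' Follow-up and autopsy rate models by presumptive diagnosis
#'
#' Two logistic regressions over an inactive-participant population:
#' being followed until death (vs lost to follow-up) and, among the
#' deceased, being autopsied -- each on the eight-way presumptive
#' etiologic diagnosis grouping with AD as reference. Fitted single-level
#' (`glm`) and, when requested, with a varying intercept per center
#' (`lme4::glmer`).
#'
#' @param population a tibble with columns `dx_category`, `deceased`,
#'   `autopsied`, `center_id`.
#' @param reference reference diagnosis category (default `"AD"`).
#' @param multilevel also fit the center-varying-intercept variants.
#' @return a tibble of odds-ratio rows: `outcome`
#'   (`followed_to_death` / `autopsied`), `term` (diagnosis category),
#'   `or`, `ci_low`, `ci_high`, `p_value`, `estimable`, `model`, `n_used`.
#' @export
followup_autopsy_models <- function(population, reference = "AD",
                                    multilevel = TRUE) {
  check_cohort(population, c("dx_category", "deceased", "autopsied",
                             "center_id"), "followup_autopsy_models")
  fit_one <- function(dat, yvar, outcome_label) {
    dat$.y <- dat[[yvar]]
    dat$dx <- factor(dat$dx_category,
                     levels = c(reference,
                                setdiff(unique(dat$dx_category),
                                        reference)))
    fits <- list()
    g <- glm(.y ~ dx, family = binomial(), data = dat)
    fits$single <- tidy_dx_or(g, outcome_label, "single_level", nrow(dat),
                              reference)
    if (multilevel && length(unique(dat$center_id)) >= 2) {
      m <- suppressMessages(lme4::glmer(
        .y ~ dx + (1 | center_id), family = binomial(), data = dat,
        control = lme4::glmerControl(calc.derivs = FALSE)))
      fits$multi <- tidy_dx_or(m, outcome_label, "multilevel", nrow(dat),
                               reference)
    }
    dplyr::bind_rows(fits)
  }
  out <- list(
    fit_one(population, "deceased", "followed_to_death"),
    fit_one(population[isTRUE_vec(population$deceased), , drop = FALSE],
            "autopsied", "autopsied"))
  dplyr::bind_rows(out)
}

tidy_dx_or <- function(fit, outcome, model_label, n_used, reference) {
  if (inherits(fit, "glmerMod")) {
    beta <- lme4::fixef(fit)
    V <- as.matrix(vcov(fit))
  } else {
    beta <- coef(fit)
    V <- vcov(fit)
  }
  terms <- grep("^dx", names(beta), value = TRUE)
  est <- unname(beta[terms])
  se <- unname(sqrt(diag(V)[terms]))
  estimable <- is.finite(est) & is.finite(se) & abs(est) < 15 & se < 15
  z <- est / se
  tibble::tibble(
    outcome = outcome,
    term = sub("^dx", "", terms),
    comparison = paste(sub("^dx", "", terms), "vs", reference),
    or = ifelse(estimable, exp(est), NA_real_),
    ci_low = ifelse(estimable, exp(est - qnorm(0.975) * se), NA_real_),
    ci_high = ifelse(estimable, exp(est + qnorm(0.975) * se), NA_real_),
    p_value = ifelse(estimable, 2 * pnorm(-abs(z)), NA_real_),
    estimable = estimable,
    model = model_label,
    n_used = n_used)
}
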