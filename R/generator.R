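# Seeded generator of multicenter autopsy cohorts with known ground truth.
# Defaults encode the study conditions the package is designed around:
# category prevalences 62/27/9/2% (No TDP-43 / LATE-NC / ALS-FTLD-TDP /
# Other), subtype split 79/16/5%, category-specific ages (LATE-NC 84.0
# (9.5), ALS/FTLD 71.5 (11.0) years), APOE4 58% in LATE-NC vs ~32-39%
# elsewhere, an all-four-region inclusion pattern in 78% of ALS/FTLD, the
# typical amygdala+hippocampus+EC/ITC pattern in 46% of LATE-NC, and
# availability that rises by year of death with center-level variation and
# a post-2019 conditional neocortex-skip mechanism.

by_cat <- function(no_tdp43, other_tdp43, late_nc, als_ftld_tdp) {
  c(no_tdp43 = no_tdp43, other_tdp43 = other_tdp43, late_nc = late_nc,
    als_ftld_tdp = als_ftld_tdp)
}

pattern_table <- function(...) {
  rows <- list(...)
  tbl <- dplyr::bind_rows(purrr::map(rows, function(r) {
    tibble::tibble(amygdala = "a" %in% r[[1]], hippocampus = "h" %in% r[[1]],
                   ec_itc = "e" %in% r[[1]], neocortex = "n" %in% r[[1]],
                   prob = r[[2]])
  }))
  tbl
}

default_generator_params <- function() {
  list(
    years = 2014:2022,
    year_weights = NULL,  # NULL = uniform
    category_prevalences = by_cat(0.62, 0.02, 0.27, 0.09),
    subtype_split = c(ftld_only = 0.79, both = 0.16, als_only = 0.05),
    age_params = list(
      no_tdp43 = c(mean = 78.9, sd = 12.1),
      other_tdp43 = c(mean = 81.0, sd = 12.3),
      late_nc = c(mean = 84.0, sd = 9.5),
      als_ftld_tdp = c(mean = 71.5, sd = 11.0)),
    age_bounds = c(40, 110),
    education_params = list(
      no_tdp43 = c(mean = 15.8, sd = 3.0),
      other_tdp43 = c(mean = 15.2, sd = 2.5),
      late_nc = c(mean = 15.8, sd = 2.9),
      als_ftld_tdp = c(mean = 15.8, sd = 2.9)),
    interval_params = list(
      no_tdp43 = c(mean = 2.2, sd = 2.4),
      other_tdp43 = c(mean = 2.4, sd = 3.1),
      late_nc = c(mean = 2.5, sd = 2.6),
      als_ftld_tdp = c(mean = 1.8, sd = 2.0)),
    cdr_sb_params = list(
      no_tdp43 = c(mean = 8.6, sd = 6.7),
      other_tdp43 = c(mean = 10.1, sd = 6.0),
      late_nc = c(mean = 10.9, sd = 5.9),
      als_ftld_tdp = c(mean = 12.3, sd = 5.8)),
    covariate_rates = list(
      sex_female = by_cat(0.48, 0.37, 0.52, 0.47),
      apoe4_present = by_cat(0.39, 0.33, 0.58, 0.32),
      apoe4_missing = by_cat(0.10, 0.12, 0.08, 0.14),
      ftd_mutation_yes = by_cat(0.010, 0, 0, 0.227),
      adad_mutation_yes = by_cat(0.002, 0, 0, 0.005),
      ppa_present = by_cat(0.076, 0.10, 0.045, 0.33),
      ppa_missing = by_cat(0.007, 0.05, 0.004, 0.027),
      bvftd_present = by_cat(0.086, 0.17, 0.029, 0.41),
      hs_a_present = by_cat(0.049, 0.24, 0.27, 0.31),
      ftld_tau_present = by_cat(0.22, 0.51, 0.16, 0.17),
      adnc_int_high = by_cat(0.63, 0.72, 0.85, 0.20),
      caa_mod_severe = by_cat(0.30, 0.32, 0.41, 0.12),
      lewy_present = by_cat(0.35, 0.37, 0.52, 0.15),
      atherosclerosis_mod_severe = by_cat(0.33, 0.29, 0.43, 0.28),
      arteriolosclerosis_mod_severe = by_cat(0.49, 0.59, 0.62, 0.46),
      infarcts_present = by_cat(0.14, 0.12, 0.15, 0.054),
      microinfarcts_present = by_cat(0.23, 0.17, 0.28, 0.13),
      hemorrhages_present = by_cat(0.072, 0.10, 0.057, 0.039),
      hipp_atrophy_mod_severe = by_cat(0.38, 0.51, 0.58, 0.66),
      cortical_atrophy_mod_severe = by_cat(0.42, 0.46, 0.48, 0.75),
      lobar_atrophy_present = by_cat(0.24, 0.22, 0.19, 0.60),
      spinal_present = by_cat(0.005, 0.05, 0.05, 0.30)),
    copath_missing_rates = c(
      ftld_tau = 0.001, adnc = 0.01, caa = 0.002, lewy_any = 0.001,
      atherosclerosis = 0.01, arteriolosclerosis = 0.02, infarcts = 0.003,
      microinfarcts = 0.003, hemorrhages = 0.01, hipp_atrophy = 0.03,
      cortical_atrophy = 0.04, lobar_atrophy = 0.04),
    multinomial_rates = list(
      cognitive_status = list(
        no_tdp43 = c(normal = 0.17, mci_impaired = 0.12, dementia = 0.71),
        other_tdp43 = c(normal = 0.073, mci_impaired = 0.098,
                        dementia = 0.829),
        late_nc = c(normal = 0.059, mci_impaired = 0.071, dementia = 0.87),
        als_ftld_tdp = c(normal = 0.043, mci_impaired = 0.038,
                         dementia = 0.919)),
      clinical_ad = list(
        no_tdp43 = c(no_impairment = 0.17, not_ad = 0.27, ad = 0.56),
        other_tdp43 = c(no_impairment = 0.073, not_ad = 0.317, ad = 0.61),
        late_nc = c(no_impairment = 0.059, not_ad = 0.121, ad = 0.82),
        als_ftld_tdp = c(no_impairment = 0.043, not_ad = 0.677,
                         ad = 0.28)),
      tdp_antibody = list(
        no_tdp43 = c(phospho = 0.71, non_phospho = 0.284, other = 0.006),
        other_tdp43 = c(phospho = 0.76, non_phospho = 0.24, other = 0),
        late_nc = c(phospho = 0.79, non_phospho = 0.203, other = 0.007),
        als_ftld_tdp = c(phospho = 0.62, non_phospho = 0.38, other = 0)),
      hs_a_laterality = list(
        all = c(unilateral = 0.5, bilateral = 0.35,
                laterality_unknown = 0.15))),
    mn_noise = c(fus = 0.0005, sod1 = 0.0005, other = 0.0015),
    regional_pattern_tables = list(
      late_nc = pattern_table(
        list("a", 0.19), list("h", 0.03), list("e", 0.03),
        list(c("e", "h"), 0.04), list(c("e", "a"), 0.06),
        list(c("a", "h"), 0.07), list(c("a", "h", "e"), 0.46),
        list(c("a", "h", "e", "n"), 0.115), list(c("a", "h", "n"), 0.005)),
      als_ftld_tdp = pattern_table(
        list(c("a", "h", "e", "n"), 0.78), list(c("a", "h", "e"), 0.04),
        list(c("h", "e", "n"), 0.06), list(c("a", "e", "n"), 0.02),
        list(c("a", "h", "n"), 0.01), list(c("h", "e"), 0.03),
        list(c("e", "n"), 0.02), list(c("a", "h"), 0.01),
        list("e", 0.015), list("h", 0.01), list("n", 0.005)),
      als_only = pattern_table(
        list(character(0), 0.4), list(c("a", "h"), 0.2), list("h", 0.2),
        list(c("a", "h", "e", "n"), 0.2)),
      other_tdp43 = pattern_table(
        list(c("a", "h", "e", "n"), 0.29), list("n", 0.13),
        list(c("e", "n"), 0.14), list(c("a", "h", "e"), 0.12),
        list(c("a", "h"), 0.08), list("a", 0.08), list(c("h", "e"), 0.06),
        list(c("a", "e"), 0.05), list("e", 0.05))),
    other_reason_weights = c(cbd = 11, cte = 6, tbi_acute = 5,
                             tbi_chronic = 3, ftd_mutation = 6,
                             adad_mutation = 5),
    p_flag_given_neocortical = 0.25,
    corruption_rate_no_regional = 0,
    dx_label_model = list(
      no_tdp43 = c("Alzheimer's disease" = 0.55, "No impairment" = 0.15,
                   "Other impairment" = 0.10, "Lewy body dementia" = 0.07,
                   "Vascular dementia" = 0.03, "FTLD other" = 0.02,
                   "Corticobasal degeneration" = 0.01,
                   "(unavailable)" = 0.07),
      other_tdp43 = c("Alzheimer's disease" = 0.35,
                      "Other impairment" = 0.25, "FTLD other" = 0.10,
                      "Corticobasal degeneration" = 0.10,
                      "No impairment" = 0.05, "(unavailable)" = 0.15),
      late_nc = c("Alzheimer's disease" = 0.75, "No impairment" = 0.05,
                  "Other impairment" = 0.05, "Lewy body dementia" = 0.05,
                  "Vascular dementia" = 0.02, "(unavailable)" = 0.08),
      als_ftld_tdp = c("FTLD other" = 0.40,
                       "FTLD motor neuron disease" = 0.20,
                       "Alzheimer's disease" = 0.15,
                       "Other impairment" = 0.10, "No impairment" = 0.02,
                       "(unavailable)" = 0.13)),
    missingness = list(
      reference_year = 2018,
      center_sd = 0.4,
      post_split_year = 2019,
      p_skip_neocortex_if_hipp_negative = 0.15,
      # availability of the TDP-43 staining workup itself follows a
      # logistic trend in year of death with a center intercept; regions
      # are then assessed conditionally on the workup, which reproduces
      # the strong cross-region availability correlation of real centers
      stain = c(base = 0.85, slope = 0.30),
      given_stain = c(spinal_cord = 0.30, amygdala = 0.88,
                      hippocampus = 0.96, ec_itc = 0.90, neocortex = 0.88,
                      ftld_tdp = 0.93),
      ftld_given_no_stain = 0.24,
      independent = list(als = c(base = 0.94, slope = 0.02),
                         hs_a = c(base = 0.97, slope = 0.05)))
  )
}

#' Build and validate a synthetic-cohort generator configuration
#'
#' Any default can be overridden by name through `...` (nested lists are
#' merged with [utils::modifyList()]). The configuration is validated
#' before any sampling: probability vectors must sum to one, rates must
#' lie in `[0, 1]`, regional pattern tables must put zero mass on
#' patterns inconsistent with their category (a LATE-NC pattern must
#' involve amygdala, hippocampus, or EC/ITC and may not show neocortical
#' TDP-43 without both amygdala and hippocampus), and LATE-NC mutation
#' rates must be zero, since a mutation carrier is by definition not
#' LATE-NC.
#'
#' @param n number of participants.
#' @param n_centers number of contributing centers.
#' @param seed integer seed; the generator is fully deterministic given
#'   the configuration.
#' @param ... overrides of the default parameters (see
#'   `tdpengine:::default_generator_params()` for the full list).
#' @return a validated `generator_config` list.
#' @export
generator_config <- function(n = 2000, n_centers = 25, seed = 1, ...) {
  cfg <- default_generator_params()
  overrides <- list(...)
  if (length(overrides) > 0) {
    bad <- setdiff(names(overrides), c(names(cfg)))
    if (length(bad) > 0) {
      abort(sprintf("unknown generator parameter(s): %s",
                    paste(bad, collapse = ", ")))
    }
    cfg <- merge_params(cfg, overrides)
  }
  cfg$n <- n
  cfg$n_centers <- n_centers
  cfg$seed <- seed
  validate_generator_config(cfg)
}

# recursive override merge; unlike modifyList, a data frame (e.g. a
# pattern table) replaces its default wholesale instead of being merged
# column-wise
merge_params <- function(base, override) {
  for (nm in names(override)) {
    bv <- base[[nm]]
    ov <- override[[nm]]
    if (is.list(bv) && is.list(ov) && !is.data.frame(bv) &&
        !is.data.frame(ov)) {
      base[[nm]] <- merge_params(bv, ov)
    } else {
      base[[nm]] <- ov
    }
  }
  base
}

validate_generator_config <- function(cfg) {
  stopifnot(cfg$n >= 0, cfg$n_centers >= 1)
  check_probs <- function(p, what) {
    if (any(p < 0) || abs(sum(p) - 1) > 1e-6) {
      abort(sprintf("%s must be non-negative and sum to 1", what))
    }
  }
  check_probs(cfg$category_prevalences, "category_prevalences")
  check_probs(cfg$subtype_split, "subtype_split")
  for (nm in names(cfg$covariate_rates)) {
    r <- cfg$covariate_rates[[nm]]
    if (any(r < 0 | r > 1)) {
      abort(sprintf("covariate rate `%s` outside [0, 1]", nm))
    }
  }
  if (cfg$covariate_rates$ftd_mutation_yes[["late_nc"]] != 0 ||
      cfg$covariate_rates$adad_mutation_yes[["late_nc"]] != 0) {
    abort("LATE-NC mutation rates must be zero (mutation carriers are not LATE-NC)")
  }
  for (nm in names(cfg$regional_pattern_tables)) {
    tbl <- cfg$regional_pattern_tables[[nm]]
    check_probs(tbl$prob, sprintf("regional_pattern_tables$%s$prob", nm))
    a <- tbl$amygdala; h <- tbl$hippocampus; e <- tbl$ec_itc
    n_ <- tbl$neocortex
    if (nm == "late_nc") {
      ok <- (a | h | e) & !(n_ & !(a & h))
      if (any(tbl$prob[!ok] > 0)) {
        abort("late_nc pattern table puts mass on non-LATE-eligible patterns")
      }
    }
    if (nm %in% c("als_ftld_tdp", "other_tdp43")) {
      ok <- a | h | e | n_
      if (any(tbl$prob[!ok] > 0)) {
        abort(sprintf("%s pattern table puts mass on the all-absent pattern",
                      nm))
      }
    }
  }
  ms <- cfg$missingness
  rates01 <- c(ms$stain[["base"]], ms$given_stain, ms$ftld_given_no_stain,
               vapply(ms$independent, `[[`, numeric(1), "base"),
               ms$p_skip_neocortex_if_hipp_negative)
  if (any(rates01 < 0 | rates01 > 1)) {
    abort("missingness rates must lie in [0, 1]")
  }
  structure(cfg, class = "generator_config")
}

# evaluate `code` under a temporary RNG seed, restoring the caller's state
with_local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

samp <- function(probs, n) {
  if (n == 0) return(character(0))
  sample(names(probs), n, replace = TRUE, prob = probs)
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  qnorm(runif(n, pnorm(lo, mean, sd), pnorm(hi, mean, sd)), mean, sd)
}

tri <- function(present) ifelse(present, "present", "absent")

#' Generate a synthetic multicenter autopsy cohort with ground truth
#'
#' Samples a cohort of the configured size: centers of varying size, a
#' true TDP-43 category per participant from the configured prevalences,
#' category-conditional demographics (truncated-normal age in
#' `[40, 110]`), clinical diagnoses, co-pathologies, regional TDP-43
#' inclusion patterns from the per-category pattern tables, and
#' exclusionary pathology flags only for Other-TDP-43 truths. The output
#' is fully assessed; apply [apply_missingness()] to inject structured
#' `not_assessed` values. Deterministic given the configuration: random
#' substreams are allocated per center, so enlarging one center does not
#' perturb the records of another.
#'
#' @param config a [generator_config()].
#' @return a list of class `tdp_sim` with `cohort` (a decoded cohort
#'   tibble) and `truth` (per-participant true category, subtype, stage,
#'   reasons, and pre-missingness TDP-43 assessment values, prefixed
#'   `true_`).
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "generator_config")) {
    config <- validate_generator_config(config)
  }
  with_local_seed(config$seed, {
    center_ids <- sprintf("C%03d", seq_len(config$n_centers))
    size_probs <- rgamma(config$n_centers, shape = 3, rate = 1)
    size_probs <- size_probs / sum(size_probs)
    sizes <- if (config$n > 0) {
      as.vector(rmultinom(1, config$n, size_probs))
    } else rep(0L, config$n_centers)
    center_seeds <- sample.int(.Machine$integer.max - 1, config$n_centers)
    parts <- purrr::map(seq_len(config$n_centers), function(i) {
      with_local_seed(center_seeds[i], {
        gen_center(sizes[i], center_ids[i], config)
      })
    })
  })
  cohort <- dplyr::bind_rows(purrr::map(parts, "cohort"))
  truth <- dplyr::bind_rows(purrr::map(parts, "truth"))
  structure(list(cohort = cohort, truth = truth, config = config),
            class = "tdp_sim")
}

gen_center <- function(n, center_id, cfg) {
  cv <- cfg$covariate_rates
  mn <- cfg$multinomial_rates
  category <- samp(cfg$category_prevalences, n)
  rate_of <- function(name) unname(cv[[name]][category])
  draw <- function(name) runif(n) < rate_of(name)
  multi <- function(name) {
    out <- character(n)
    for (cat in unique(category)) {
      sel <- category == cat
      out[sel] <- samp(mn[[name]][[cat]], sum(sel))
    }
    out
  }
  par_of <- function(params) {
    m <- vapply(params, `[[`, numeric(1), "mean")[category]
    s <- vapply(params, `[[`, numeric(1), "sd")[category]
    list(mean = unname(m), sd = unname(s))
  }

  subtype <- rep(NA_character_, n)
  is_af <- category == "als_ftld_tdp"
  subtype[is_af] <- samp(cfg$subtype_split, sum(is_af))

  # regional inclusion pattern per record from the category's table
  amyg <- hipp <- ec <- neoc <- logical(n)
  pick_patterns <- function(sel, tbl) {
    if (!any(sel)) return()
    idx <- sample.int(nrow(tbl), sum(sel), replace = TRUE, prob = tbl$prob)
    amyg[sel] <<- tbl$amygdala[idx]
    hipp[sel] <<- tbl$hippocampus[idx]
    ec[sel] <<- tbl$ec_itc[idx]
    neoc[sel] <<- tbl$neocortex[idx]
  }
  pick_patterns(category == "late_nc", cfg$regional_pattern_tables$late_nc)
  pick_patterns(is_af & subtype != "als_only",
                cfg$regional_pattern_tables$als_ftld_tdp)
  pick_patterns(is_af & subtype == "als_only",
                cfg$regional_pattern_tables$als_only)
  pick_patterns(category == "other_tdp43",
                cfg$regional_pattern_tables$other_tdp43)

  # Other TDP-43: attach an exclusion reason unless the neocortical
  # pattern alone justifies the category (and sometimes even then)
  flags <- matrix(FALSE, n, length(EXCLUSION_FLAGS),
                  dimnames = list(NULL, EXCLUSION_FLAGS))
  ftd_mut <- draw("ftd_mutation_yes")
  adad_mut <- draw("adad_mutation_yes")
  other_reason <- rep("", n)
  is_other <- category == "other_tdp43"
  if (any(is_other)) {
    neoc_pat <- neoc & !(amyg & hipp)
    need_flag <- is_other &
      (!neoc_pat | runif(n) < cfg$p_flag_given_neocortical)
    k <- sum(need_flag)
    if (k > 0) {
      reason <- samp(cfg$other_reason_weights /
                       sum(cfg$other_reason_weights), k)
      for (fl in EXCLUSION_FLAGS) {
        flags[need_flag, fl] <- flags[need_flag, fl] | (reason == fl)
      }
      ftd_mut[need_flag] <- ftd_mut[need_flag] | (reason == "ftd_mutation")
      adad_mut[need_flag] <- adad_mut[need_flag] |
        (reason == "adad_mutation")
    }
    other_reason[is_other] <- ifelse(
      need_flag[is_other],
      vapply(which(is_other), function(i) {
        r <- c(EXCLUSION_FLAGS[flags[i, ]],
               if (ftd_mut[i]) "ftd_mutation",
               if (adad_mut[i]) "adad_mutation",
               if (neoc_pat[i]) "neocortical_pattern")
        paste(r, collapse = ",")
      }, character(1)),
      "neocortical_pattern")
  }
  # LATE-NC carries no mutations by definition (validated in the config)
  ftd_mut[category == "late_nc"] <- FALSE
  adad_mut[category == "late_nc"] <- FALSE

  # designations
  ftld_tdp <- tri(is_af & subtype %in% c("ftld_only", "both"))
  mn_incl <- rep("none", n)
  mn_incl[is_af & subtype %in% c("als_only", "both")] <- "tdp43"
  noise <- cfg$mn_noise
  not_af <- !is_af
  for (lv in names(noise)) {
    hit <- not_af & runif(n) < noise[[lv]]
    mn_incl[hit] <- lv
  }

  # spinal cord: ALS-only records always carry spinal TDP-43
  spinal <- runif(n) < rate_of("spinal_present")
  spinal[is_af & subtype == "als_only"] <- TRUE

  # optional corruption: designated records stripped of all regional TDP-43
  if (cfg$corruption_rate_no_regional > 0 && any(is_af)) {
    corrupt <- is_af & runif(n) < cfg$corruption_rate_no_regional
    amyg[corrupt] <- hipp[corrupt] <- ec[corrupt] <- neoc[corrupt] <- FALSE
    spinal[corrupt] <- FALSE
  }

  hs_present <- draw("hs_a_present")
  hs_a <- rep("absent", n)
  hs_a[hs_present] <- samp(mn$hs_a_laterality$all, sum(hs_present))

  dichot <- function(rate_name, yes, no, missing_name = NULL) {
    out <- ifelse(draw(rate_name), yes, no)
    if (!is.null(missing_name)) {
      mr <- cfg$copath_missing_rates[[missing_name]]
      if (!is.null(mr) && mr > 0) out[runif(n) < mr] <- "not_assessed"
    }
    out
  }

  age <- rtrunc_norm(n, par_of(cfg$age_params)$mean,
                     par_of(cfg$age_params)$sd,
                     cfg$age_bounds[1], cfg$age_bounds[2])
  edu <- pmax(0, round(rnorm(n, par_of(cfg$education_params)$mean,
                             par_of(cfg$education_params)$sd)))
  interval <- rtrunc_norm(n, par_of(cfg$interval_params)$mean,
                          par_of(cfg$interval_params)$sd, 0, 30)
  cdr <- rtrunc_norm(n, par_of(cfg$cdr_sb_params)$mean,
                     par_of(cfg$cdr_sb_params)$sd, 0, 18)

  apoe <- ifelse(draw("apoe4_present"), "present", "absent")
  apoe[runif(n) < rate_of("apoe4_missing")] <- "missing"
  ppa <- ifelse(draw("ppa_present"), "present", "absent")
  ppa[runif(n) < rate_of("ppa_missing")] <- "missing"

  year_w <- cfg$year_weights %||% rep(1, length(cfg$years))
  year <- sample(cfg$years, n, replace = TRUE, prob = year_w)

  dx_raw <- character(n)
  for (cat in unique(category)) {
    sel <- category == cat
    dx_raw[sel] <- samp(cfg$dx_label_model[[cat]], sum(sel))
  }
  dx_raw[dx_raw == "(unavailable)"] <- NA_character_

  cohort <- tibble::tibble(
    participant_id = sprintf("%s-%05d", center_id, seq_len(n)),
    center_id = center_id,
    year_of_death = as.numeric(year),
    tdp_spinal_cord = tri(spinal),
    tdp_amygdala = tri(amyg),
    tdp_hippocampus = tri(hipp),
    tdp_ec_itc = tri(ec),
    tdp_neocortex = tri(neoc),
    ftld_tdp = ftld_tdp,
    mn_inclusion = mn_incl,
    hs_a = hs_a,
    tdp_antibody = multi("tdp_antibody"),
    ftld_tau = dichot("ftld_tau_present", "present", "absent", "ftld_tau"),
    adnc = dichot("adnc_int_high", "int_high", "none_low", "adnc"),
    caa = dichot("caa_mod_severe", "mod_severe", "none_mild", "caa"),
    lewy_any = dichot("lewy_present", "present", "absent", "lewy_any"),
    atherosclerosis = dichot("atherosclerosis_mod_severe", "mod_severe",
                             "none_mild", "atherosclerosis"),
    arteriolosclerosis = dichot("arteriolosclerosis_mod_severe",
                                "mod_severe", "none_mild",
                                "arteriolosclerosis"),
    infarcts = dichot("infarcts_present", "present", "absent", "infarcts"),
    microinfarcts = dichot("microinfarcts_present", "present", "absent",
                           "microinfarcts"),
    hemorrhages = dichot("hemorrhages_present", "present", "absent",
                         "hemorrhages"),
    hipp_atrophy = dichot("hipp_atrophy_mod_severe", "mod_severe",
                          "none_mild", "hipp_atrophy"),
    cortical_atrophy = dichot("cortical_atrophy_mod_severe", "mod_severe",
                              "none_mild", "cortical_atrophy"),
    lobar_atrophy = dichot("lobar_atrophy_present", "present", "absent",
                           "lobar_atrophy"),
    cbd = flags[, "cbd"],
    cte = flags[, "cte"],
    tbi_acute = flags[, "tbi_acute"],
    tbi_chronic = flags[, "tbi_chronic"],
    huntington = flags[, "huntington"],
    guam_kii = flags[, "guam_kii"],
    age_at_death = round(age, 1),
    sex = ifelse(draw("sex_female"), "female", "male"),
    education = edu,
    interval_visit_death = round(interval, 2),
    apoe4 = apoe,
    ftd_mutation = ifelse(ftd_mut, "yes", "no_unknown"),
    adad_mutation = ifelse(adad_mut, "yes", "no_unknown"),
    cognitive_status = multi("cognitive_status"),
    cdr_sb = round(cdr, 1),
    clinical_ad = multi("clinical_ad"),
    ppa = ppa,
    bvftd = ifelse(draw("bvftd_present"), "present", "absent"),
    etiologic_dx_raw = dx_raw,
    deceased = TRUE,
    autopsied = TRUE)

  stage <- rep(NA_integer_, n)
  is_late <- category == "late_nc"
  stage[is_late] <- ifelse(amyg[is_late] & hipp[is_late] & neoc[is_late],
                           3L,
                           ifelse(amyg[is_late] & hipp[is_late], 2L, 1L))

  truth <- tibble::tibble(
    participant_id = cohort$participant_id,
    center_id = center_id,
    category = category,
    subtype = subtype,
    stage = stage,
    other_reason = other_reason,
    true_tdp_spinal_cord = cohort$tdp_spinal_cord,
    true_tdp_amygdala = cohort$tdp_amygdala,
    true_tdp_hippocampus = cohort$tdp_hippocampus,
    true_tdp_ec_itc = cohort$tdp_ec_itc,
    true_tdp_neocortex = cohort$tdp_neocortex,
    true_ftld_tdp = cohort$ftld_tdp,
    true_mn_inclusion = cohort$mn_inclusion,
    true_hs_a = cohort$hs_a)

  list(cohort = cohort, truth = truth)
}

#' Inject structured missingness into a generated cohort
#'
#' Sets assessments to `not_assessed` according to the configured
#' mechanisms: per-measure availability follows a logistic trend in year
#' of death with a normally distributed center intercept; for deaths in
#' or after the configured split year whose hippocampus was assessed and
#' TDP-43 negative, the neocortical assessment is additionally skipped
#' with probability `p_skip_neocortex_if_hipp_negative`; and the TDP-43
#' antibody is listed only when a TDP-43 stain was performed (FTLD-TDP or
#' any regional assessment available). Truth retains all pre-missingness
#' values. Deterministic given the configuration.
#'
#' @param cohort,truth the elements of a [generate_cohort()] result.
#' @param config the same [generator_config()].
#' @return the cohort with `not_assessed` values injected.
#' @export
apply_missingness <- function(cohort, truth, config) {
  ms <- config$missingness
  field_of <- c(spinal_cord = "tdp_spinal_cord", amygdala = "tdp_amygdala",
                hippocampus = "tdp_hippocampus", ec_itc = "tdp_ec_itc",
                neocortex = "tdp_neocortex", ftld_tdp = "ftld_tdp",
                als = "mn_inclusion", hs_a = "hs_a")
  centers <- sort(unique(cohort$center_id))
  n <- nrow(cohort)
  logit_trend <- function(pars, eff) {
    qlogis(pmin(pmax(pars[["base"]], 1e-8), 1 - 1e-8)) +
      pars[["slope"]] * (cohort$year_of_death - ms$reference_year) +
      unname(eff[cohort$center_id])
  }
  with_local_seed((config$seed + 424243L) %% .Machine$integer.max, {
    # shared staining workup: drives all regional and (mostly) FTLD-TDP
    # availability, so regions are available together or not at all
    stain_eff <- setNames(rnorm(length(centers), 0, ms$center_sd), centers)
    stained <- runif(n) < plogis(logit_trend(ms$stain, stain_eff))
    for (m in c("spinal_cord", "amygdala", "hippocampus", "ec_itc",
                "neocortex")) {
      assessed <- stained & runif(n) < ms$given_stain[[m]]
      col <- field_of[[m]]
      cohort[[col]][!assessed] <- "not_assessed"
    }
    p_ftld <- ifelse(stained, ms$given_stain[["ftld_tdp"]],
                     ms$ftld_given_no_stain)
    cohort$ftld_tdp[!(runif(n) < p_ftld)] <- "not_assessed"
    for (m in names(ms$independent)) {
      eff <- setNames(rnorm(length(centers), 0, ms$center_sd), centers)
      assessed <- runif(n) < plogis(logit_trend(ms$independent[[m]], eff))
      col <- field_of[[m]]
      cohort[[col]][!assessed] <- "not_assessed"
    }
    # outcome-conditional mechanism: neocortex skipped when the assessed
    # hippocampus is TDP-43 negative, in the post-split era only
    p_skip <- ms$p_skip_neocortex_if_hipp_negative
    if (p_skip > 0) {
      eligible <- cohort$year_of_death >= ms$post_split_year &
        is_assessed(cohort$tdp_hippocampus) &
        cohort$tdp_hippocampus == "absent" &
        is_assessed(cohort$tdp_neocortex)
      skip <- eligible & runif(n) < p_skip
      cohort$tdp_neocortex[skip] <- "not_assessed"
    }
  })
  stained <- is_assessed(cohort$ftld_tdp) |
    is_assessed(cohort$tdp_spinal_cord) |
    is_assessed(cohort$tdp_amygdala) | is_assessed(cohort$tdp_hippocampus) |
    is_assessed(cohort$tdp_ec_itc) | is_assessed(cohort$tdp_neocortex)
  cohort$tdp_antibody[!stained] <- "not_listed"
  cohort
}

#' Verify that classification recovers the generator's ground truth
#'
#' Restricts the cohort to complete cases, classifies it, and compares
#' category and LATE-NC stage against the ground truth. On any validly
#' generated cohort agreement is 100% by construction; a disagreement
#' pinpoints either a corrupted record or a classifier defect.
#'
#' @param cohort a (possibly missingness-injected) generated cohort.
#' @param truth the matching ground-truth tibble.
#' @return a list: `n_complete`, `agreement` (fraction with matching
#'   category and stage), `confusion` (true vs assigned category counts),
#'   `mismatches` (participant ids).
#' @export
round_trip_check <- function(cohort, truth) {
  cc <- complete_case_filter(cohort)
  asg <- classify_tdp(cc)
  j <- dplyr::inner_join(asg,
                         truth[, c("participant_id", "category", "stage")],
                         by = "participant_id",
                         suffix = c("_assigned", "_true"))
  cat_ok <- j$category_assigned == j$category_true
  stage_ok <- (is.na(j$stage_assigned) & is.na(j$stage_true)) |
    (!is.na(j$stage_assigned) & !is.na(j$stage_true) &
       j$stage_assigned == j$stage_true)
  ok <- cat_ok & stage_ok
  confusion <- dplyr::count(j, .data$category_true, .data$category_assigned)
  list(n_complete = nrow(j),
       agreement = if (nrow(j) > 0) mean(ok) else NA_real_,
       confusion = confusion,
       mismatches = j$participant_id[!ok])
}

#' Generate a synthetic inactive-participant population
#'
#' Simulates the follow-up/autopsy setting: participants no longer active
#' in a multicenter registry, each with a presumptive etiologic diagnosis
#' category, a followed-to-death indicator, and (among the deceased) an
#' autopsy indicator. Log odds are additive: a per-category odds ratio
#' against the AD baseline rate plus an optional normal center intercept,
#' so planted odds ratios are recoverable by logistic regression.
#'
#' @param n number of participants.
#' @param n_centers number of centers.
#' @param seed integer seed.
#' @param dx_probs named probabilities over the eight diagnosis
#'   categories.
#' @param followup_base,autopsy_base baseline (AD) rates of follow-up to
#'   death and of autopsy among the deceased.
#' @param followup_or,autopsy_or named per-category odds ratios vs AD.
#' @param center_sd SD of the center intercept on the log-odds scale
#'   (applied to both outcomes; 0 = no center effect).
#' @return a tibble: `participant_id`, `center_id`, `dx_category`,
#'   `deceased`, `autopsied`.
#' @export
generate_population <- function(n = 10000, n_centers = 30, seed = 1,
                                dx_probs = c(
                                  AD = 0.45, FTLD = 0.05, CBD_PSP = 0.03,
                                  LB = 0.07, VASCULAR = 0.04,
                                  OTHER_IMPAIRED = 0.12,
                                  NOT_IMPAIRED = 0.20, UNAVAILABLE = 0.04),
                                followup_base = 0.50,
                                followup_or = c(
                                  AD = 1, FTLD = 2.0, CBD_PSP = 3.5,
                                  LB = 1.9, VASCULAR = 0.75,
                                  OTHER_IMPAIRED = 0.43,
                                  NOT_IMPAIRED = 0.26, UNAVAILABLE = 0.35),
                                autopsy_base = 0.58,
                                autopsy_or = c(
                                  AD = 1, FTLD = 1.8, CBD_PSP = 1.8,
                                  LB = 1.2, VASCULAR = 0.70,
                                  OTHER_IMPAIRED = 1.0,
                                  NOT_IMPAIRED = 0.63, UNAVAILABLE = 0.71),
                                center_sd = 0) {
  with_local_seed(seed, {
    center_id <- sprintf("C%03d", sample.int(n_centers, n, replace = TRUE))
    dx <- samp(dx_probs / sum(dx_probs), n)
    eff <- rnorm(n_centers, 0, center_sd)
    names(eff) <- sprintf("C%03d", seq_len(n_centers))
    eta_f <- qlogis(followup_base) + log(unname(followup_or[dx])) +
      unname(eff[center_id])
    deceased <- runif(n) < plogis(eta_f)
    eta_a <- qlogis(autopsy_base) + log(unname(autopsy_or[dx])) +
      unname(eff[center_id])
    autopsied <- deceased & (runif(n) < plogis(eta_a))
    tibble::tibble(
      participant_id = sprintf("P%06d", seq_len(n)),
      center_id = center_id,
      dx_category = dx,
      deceased = deceased,
      autopsied = autopsied)
  })
}
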