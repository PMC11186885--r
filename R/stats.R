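#' Wilcoxon rank-sum test
#'
#' Two-sided rank-sum comparison of two samples. Uses the exact null
#' distribution when both samples have eight or fewer observations and no
#' ties are present; otherwise the normal approximation with the tie
#' correction and no continuity correction, so identical samples give
#' p = 1 exactly.
#'
#' @param x,y non-empty numeric vectors.
#' @return a list with `statistic` (the rank-sum W for `x`), `p_value`,
#'   and `method` (`"exact"` or `"normal_approx"`).
#' @export
rank_sum_test <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) {
    abort("rank_sum_test() requires non-empty samples")
  }
  ties <- any(duplicated(c(x, y)))
  exact <- length(x) <= 8 && length(y) <= 8 && !ties
  wt <- suppressWarnings(
    wilcox.test(x, y, exact = exact, correct = FALSE))
  p <- wt$p.value
  # degenerate case: every observation tied across both samples makes the
  # tie-corrected variance zero; there is no evidence of a shift
  if (is.nan(p)) p <- 1
  list(statistic = unname(wt$statistic), p_value = p,
       method = if (exact) "exact" else "normal_approx")
}

#' Odds ratio, Wald interval, and chi-square for a 2x2 table
#'
#' The odds ratio is the cross-product ratio `(a*d)/(b*c)` for a table
#' with rows = groups and columns = (event, non-event). When any single
#' cell is zero (but no margin is), the Haldane-Anscombe correction adds
#' 0.5 to every cell for the odds ratio and its interval. A zero row or
#' column margin makes the statistics non-estimable; they are reported as
#' `NA` with `estimable = FALSE`, never fabricated.
#'
#' @param tab a 2x2 matrix of non-negative integer counts.
#' @param yates use the Yates continuity correction for the chi-square
#'   statistic (default `FALSE`: plain Pearson).
#' @return a one-row tibble: `or`, `ci_low`, `ci_high`, `se_log_or`,
#'   `statistic` (chi-square), `p_value`, `estimable`, `continuity`
#'   (whether the 0.5 correction was applied).
#' @export
two_by_two <- function(tab, yates = FALSE) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2))) abort("two_by_two() requires a 2x2 table")
  if (any(tab < 0) || any(tab != round(tab))) {
    abort("two_by_two() requires non-negative integer counts")
  }
  margin_zero <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
  if (margin_zero) {
    return(tibble::tibble(or = NA_real_, ci_low = NA_real_,
                          ci_high = NA_real_, se_log_or = NA_real_,
                          statistic = NA_real_, p_value = NA_real_,
                          estimable = FALSE, continuity = FALSE))
  }
  continuity <- any(tab == 0)
  w <- if (continuity) tab + 0.5 else tab
  log_or <- log(w[1, 1]) + log(w[2, 2]) - log(w[1, 2]) - log(w[2, 1])
  se <- sqrt(sum(1 / w))
  chi <- suppressWarnings(chisq.test(tab, correct = yates))
  tibble::tibble(
    or = exp(log_or),
    ci_low = exp(log_or - qnorm(0.975) * se),
    ci_high = exp(log_or + qnorm(0.975) * se),
    se_log_or = se,
    statistic = unname(chi$statistic),
    p_value = chi$p.value,
    estimable = TRUE,
    continuity = continuity
  )
}

# ---------------------------------------------------------------------------
# Binary outcome dichotomizations (fixed; see the methods vignette):
# ADNC none/low vs intermediate/high, CAA and the vessel/atrophy measures
# none/mild vs moderate/severe, Lewy bodies present in any region, dementia
# vs normal/MCI, clinical AD vs not-AD/no-impairment.

OUTCOME_DEFS <- list(
  dementia = function(d) na_eq(d$cognitive_status, "dementia"),
  clinical_ad = function(d) na_eq(d$clinical_ad, "ad"),
  ppa = function(d) na_eq(d$ppa, "present", missing = "missing"),
  bvftd = function(d) na_eq(d$bvftd, "present"),
  hs_a = function(d) {
    out <- d$hs_a %in% HS_A_PRESENT
    out[!is_assessed(d$hs_a)] <- NA
    out
  },
  ftld_tau = function(d) na_eq(d$ftld_tau, "present",
                               missing = "not_assessed"),
  adnc = function(d) na_eq(d$adnc, "int_high", missing = "not_assessed"),
  caa = function(d) na_eq(d$caa, "mod_severe", missing = "not_assessed"),
  lewy = function(d) na_eq(d$lewy_any, "present", missing = "not_assessed"),
  atherosclerosis = function(d) na_eq(d$atherosclerosis, "mod_severe",
                                      missing = "not_assessed"),
  arteriolosclerosis = function(d) na_eq(d$arteriolosclerosis, "mod_severe",
                                         missing = "not_assessed"),
  infarcts = function(d) na_eq(d$infarcts, "present",
                               missing = "not_assessed"),
  microinfarcts = function(d) na_eq(d$microinfarcts, "present",
                                    missing = "not_assessed"),
  hemorrhages = function(d) na_eq(d$hemorrhages, "present",
                                  missing = "not_assessed"),
  hipp_atrophy = function(d) na_eq(d$hipp_atrophy, "mod_severe",
                                   missing = "not_assessed"),
  cortical_atrophy = function(d) na_eq(d$cortical_atrophy, "mod_severe",
                                       missing = "not_assessed"),
  lobar_atrophy = function(d) na_eq(d$lobar_atrophy, "present",
                                    missing = "not_assessed")
)

na_eq <- function(x, level, missing = NULL) {
  out <- x == level
  if (!is.null(missing)) out[x %in% missing] <- NA
  out
}

#' Outcome labels understood by the logistic-regression wrappers
#' @return character vector of outcome names.
#' @export
outcome_labels <- function() names(OUTCOME_DEFS)

#' Dichotomize an outcome on a cohort
#'
#' @param cohort a decoded cohort tibble.
#' @param outcome one of [outcome_labels()].
#' @return logical vector, `NA` where the outcome is missing/not assessed.
#' @export
binary_outcome <- function(cohort, outcome) {
  if (!outcome %in% names(OUTCOME_DEFS)) {
    abort(sprintf("unknown outcome `%s`; see outcome_labels()", outcome))
  }
  OUTCOME_DEFS[[outcome]](cohort)
}

DEFAULT_COVARIATES <- c("age_at_death", "sex", "education",
                        "interval_visit_death")

# assemble the model frame for the category regressions
model_frame <- function(cohort, assignments, outcome, covariates,
                        reference) {
  df <- dplyr::left_join(cohort, assignments[, c("participant_id",
                                                 "category")],
                         by = "participant_id")
  if (any(is.na(df$category))) {
    abort("assignments do not cover the cohort")
  }
  y <- binary_outcome(df, outcome)
  dat <- tibble::tibble(
    .y = y,
    category = factor(df$category,
                      levels = c(reference,
                                 setdiff(TDP_CATEGORIES, reference))),
    center_id = df$center_id
  )
  for (cv in covariates) {
    dat[[cv]] <- if (cv == "sex") factor(df[[cv]]) else df[[cv]]
  }
  keep <- complete.cases(dat[, c(".y", "category", covariates)])
  droplevels(dat[keep, , drop = FALSE])
}

# Wald-scale tidy rows for the category terms of a logistic fit
tidy_category_or <- function(fit, outcome, model_label, covariates, n_used,
                             reference) {
  if (inherits(fit, "glmerMod")) {
    beta <- lme4::fixef(fit)
    V <- as.matrix(vcov(fit))
  } else {
    beta <- coef(fit)
    V <- vcov(fit)
  }
  terms <- grep("^category", names(beta), value = TRUE)
  est <- unname(beta[terms])
  se <- unname(sqrt(diag(V)[terms]))
  # Wald 95% CI on the log-odds scale; very large coefficients indicate
  # (quasi-)separation and are reported as non-estimable
  estimable <- is.finite(est) & is.finite(se) & abs(est) < 15 & se < 15
  z <- est / se
  tibble::tibble(
    outcome = outcome,
    comparison = paste(sub("^category", "", terms), "vs", reference),
    term = sub("^category", "", terms),
    or = ifelse(estimable, exp(est), NA_real_),
    ci_low = ifelse(estimable, exp(est - qnorm(0.975) * se), NA_real_),
    ci_high = ifelse(estimable, exp(est + qnorm(0.975) * se), NA_real_),
    p_value = ifelse(estimable, 2 * pnorm(-abs(z)), NA_real_),
    estimable = estimable,
    model = model_label,
    covariates = paste(covariates, collapse = "+"),
    n_used = n_used
  )
}

#' Adjusted logistic regression of an outcome on TDP-43 category
#'
#' Fits `outcome ~ category + age_at_death + sex + education +
#' interval_visit_death` by maximum likelihood on the complete cases for
#' the outcome and covariates, and reports one odds ratio per non-reference
#' category with Wald 95% confidence intervals. Perfect or quasi-perfect
#' separation is flagged as non-estimable rather than reported as a huge
#' odds ratio.
#'
#' @param cohort a decoded cohort tibble (normally the complete-case
#'   subset).
#' @param assignments output of [classify_tdp()] covering the cohort.
#' @param outcome one of [outcome_labels()].
#' @param covariates adjustment covariates; default age at death, sex,
#'   years of education, and last-visit-to-death interval. Use
#'   `character(0)` for an unadjusted fit.
#' @param reference reference category, default `"no_tdp43"`.
#' @return a tibble of odds-ratio rows (one per category); the fitted
#'   `glm` is attached as attribute `"fit"` for [posthoc_contrasts()].
#' @export
adjusted_logistic <- function(cohort, assignments, outcome,
                              covariates = DEFAULT_COVARIATES,
                              reference = "no_tdp43") {
  dat <- model_frame(cohort, assignments, outcome, covariates, reference)
  rhs <- paste(c("category", covariates), collapse = " + ")
  fit <- glm(stats::as.formula(paste(".y ~", rhs)),
             family = binomial(), data = dat)
  out <- tidy_category_or(fit, outcome, "single_level", covariates,
                          nrow(dat), reference)
  if (!fit$converged) out$estimable <- FALSE
  attr(out, "fit") <- fit
  out
}

#' Multilevel logistic regression with a varying intercept for center
#'
#' Same population-level structure as [adjusted_logistic()] plus a random
#' intercept per contributing center, fitted with `lme4::glmer`. With a
#' single center no between-center variance is identifiable and the model
#' degenerates, by design, to the single-level fit (reported as
#' `"single_level_fallback"`). Non-convergence is reported in the
#' `converged` column, never silently ignored.
#'
#' @inheritParams adjusted_logistic
#' @return a tibble of odds-ratio rows with a `converged` column; the fit
#'   is attached as attribute `"fit"`.
#' @export
multilevel_logistic <- function(cohort, assignments, outcome,
                                covariates = DEFAULT_COVARIATES,
                                reference = "no_tdp43") {
  dat <- model_frame(cohort, assignments, outcome, covariates, reference)
  if (length(unique(dat$center_id)) < 2) {
    inform("single center: multilevel model degenerates to single-level fit")
    out <- adjusted_logistic(cohort, assignments, outcome, covariates,
                             reference)
    out$model <- "single_level_fallback"
    out$converged <- TRUE
    return(out)
  }
  rhs <- paste(c("category", covariates, "(1 | center_id)"),
               collapse = " + ")
  fit <- suppressMessages(lme4::glmer(
    stats::as.formula(paste(".y ~", rhs)), family = binomial(), data = dat,
    control = lme4::glmerControl(calc.derivs = FALSE)))
  msgs <- fit@optinfo$conv$lme4$messages
  converged <- is.null(msgs) || length(msgs) == 0
  if (!converged) {
    warn(paste("multilevel fit did not converge cleanly:",
               paste(unlist(msgs), collapse = "; ")))
  }
  out <- tidy_category_or(fit, outcome, "multilevel", covariates,
                          nrow(dat), reference)
  out$converged <- converged
  attr(out, "fit") <- fit
  out
}

#' Post-hoc pairwise contrasts between TDP-43 categories
#'
#' Wald tests on differences of category coefficients using the fitted
#' model's covariance matrix (fixed effects for multilevel fits). Because
#' the adjustment covariates are shared, a coefficient difference is
#' exactly the log odds ratio between the two categories. P-values are
#' reported unadjusted. A contrast involving a non-estimable or absent
#' coefficient is skipped with a note.
#'
#' @param fit a `glm` or `glmerMod` with a `category` factor, e.g. the
#'   `"fit"` attribute of [adjusted_logistic()].
#' @param pairs list of length-2 character vectors of category levels;
#'   defaults to LATE-NC vs ALS/FTLD-TDP, LATE-NC vs Other, ALS/FTLD-TDP
#'   vs Other.
#' @return a tibble: `contrast`, `or` (ratio of odds between the two
#'   categories), `ci_low`, `ci_high`, `se`, `z`, `p_value`, `note`.
#' @export
posthoc_contrasts <- function(fit,
                              pairs = list(
                                c("late_nc", "als_ftld_tdp"),
                                c("late_nc", "other_tdp43"),
                                c("als_ftld_tdp", "other_tdp43"))) {
  if (inherits(fit, "glmerMod")) {
    beta <- lme4::fixef(fit)
    V <- as.matrix(vcov(fit))
  } else {
    beta <- coef(fit)
    V <- vcov(fit)
  }
  rows <- purrr::map(pairs, function(pr) {
    t1 <- paste0("category", pr[1])
    t2 <- paste0("category", pr[2])
    # the reference level has implicit coefficient 0 with no variance
    b1 <- if (t1 %in% names(beta)) beta[[t1]] else 0
    b2 <- if (t2 %in% names(beta)) beta[[t2]] else 0
    v11 <- if (t1 %in% names(beta)) V[t1, t1] else 0
    v22 <- if (t2 %in% names(beta)) V[t2, t2] else 0
    v12 <- if (t1 %in% names(beta) && t2 %in% names(beta)) V[t1, t2] else 0
    est <- b1 - b2
    se <- sqrt(v11 + v22 - 2 * v12)
    if (!is.finite(est) || !is.finite(se) || abs(est) > 15) {
      return(tibble::tibble(contrast = paste(pr[1], "vs", pr[2]),
                            or = NA_real_, ci_low = NA_real_,
                            ci_high = NA_real_, se = NA_real_, z = NA_real_,
                            p_value = NA_real_,
                            note = "non-estimable coefficient"))
    }
    if (pr[1] == pr[2]) {
      return(tibble::tibble(contrast = paste(pr[1], "vs", pr[2]), or = 1,
                            ci_low = 1, ci_high = 1, se = 0, z = 0,
                            p_value = 1, note = "self contrast"))
    }
    z <- if (se == 0) 0 else est / se
    tibble::tibble(
      contrast = paste(pr[1], "vs", pr[2]),
      or = exp(est),
      ci_low = exp(est - qnorm(0.975) * se),
      ci_high = exp(est + qnorm(0.975) * se),
      se = se, z = z, p_value = 2 * pnorm(-abs(z)), note = "")
  })
  dplyr::bind_rows(rows)
}
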