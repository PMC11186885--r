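# Enumerations shared across the package. "not_assessed" is a first-class
# state everywhere: it marks a measurement that was never performed and is
# never conflated with a negative ("absent") finding.

TRI_STATES <- c("present", "absent", "not_assessed")

TDP_CATEGORIES <- c("no_tdp43", "late_nc", "als_ftld_tdp", "other_tdp43")

ALS_FTLD_SUBTYPES <- c("ftld_only", "als_only", "both")

MN_INCLUSION_LEVELS <- c("tdp43", "fus", "sod1", "other", "none", "not_assessed")

HS_A_LEVELS <- c("absent", "unilateral", "bilateral", "laterality_unknown",
                 "not_assessed")

HS_A_PRESENT <- c("unilateral", "bilateral", "laterality_unknown")

ANTIBODY_LEVELS <- c("phospho", "non_phospho", "other", "not_listed")

DX_CATEGORIES <- c("AD", "FTLD", "CBD_PSP", "LB", "VASCULAR",
                   "OTHER_IMPAIRED", "NOT_IMPAIRED", "UNAVAILABLE")

# pathology flags that rule out LATE-NC when brain TDP-43 is present
EXCLUSION_FLAGS <- c("cbd", "cte", "tbi_acute", "tbi_chronic", "huntington",
                     "guam_kii")

OTHER_REASONS <- c(EXCLUSION_FLAGS, "ftd_mutation", "adad_mutation",
                   "neocortical_pattern")

BRAIN_REGION_FIELDS <- c("tdp_amygdala", "tdp_hippocampus", "tdp_ec_itc",
                         "tdp_neocortex")

REGION_FIELDS <- c("tdp_spinal_cord", BRAIN_REGION_FIELDS)

# assessments required for the complete-case restriction
COMPLETE_CASE_FIELDS <- c(BRAIN_REGION_FIELDS, "ftld_tdp", "mn_inclusion",
                          "hs_a")

#' Round a proportion to a whole percentage, half away from zero
#'
#' Report-parity rounding used when rendering tables: `146/185` renders as
#' 79, `29/185` as 16, `10/185` as 5. Base `round()` rounds half to even,
#' which does not match conventional table formatting.
#'
#' @param num numerator count(s).
#' @param den denominator count(s); `pct_half_up(x, 0)` returns `NA`.
#' @return integer percentage(s).
#' @export
#' @examples
#' pct_half_up(c(146, 29, 10), 185)
pct_half_up <- function(num, den) {
  out <- ifelse(den > 0, floor(num / den * 100 + 0.5), NA_real_)
  as.integer(out)
}

# internal: check a cohort tibble has the fields a function needs
check_cohort <- function(cohort, fields, caller = "tdpengine") {
  if (!is.data.frame(cohort)) {
    abort(sprintf("`cohort` must be a data frame (in %s()).", caller))
  }
  missing_fields <- setdiff(fields, names(cohort))
  if (length(missing_fields) > 0) {
    abort(sprintf("`cohort` is missing required column(s): %s (in %s()).",
                  paste(missing_fields, collapse = ", "), caller))
  }
  invisible(cohort)
}

is_assessed <- function(x) !is.na(x) & x != "not_assessed"
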