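#' Parse a coded cohort CSV into a typed cohort tibble
#'
#' Reads a rectangular, UTF-8, header-first CSV of coded autopsy and
#' clinical records and decodes every declared column through the dialect.
#' One row in, one record out; row order is preserved. Blank or
#' "not assessed" codes decode to the `not_assessed` state (or `NA` for
#' clinical fields with no such state) and are never conflated with a
#' negative finding.
#'
#' @param path path to the coded CSV file.
#' @param dialect a `tdp_dialect`, by default [default_dialect()].
#' @return a tibble with one row per participant and one typed column per
#'   dialect field (tri-state pathology fields as character, exclusionary
#'   pathology flags as logical, clinical measures as numeric).
#' @seealso [write_cohort()] for the inverse operation, [validate_cohort()]
#'   for the validation report.
#' @export
parse_records <- function(path, dialect = default_dialect()) {
  if (!file.exists(path)) abort(sprintf("cohort file not found: %s", path))
  raw <- readr::read_csv(path, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE)
  decode_cohort(raw, dialect)
}

# decode an all-character data frame through the dialect (the workhorse
# behind parse_records; exposed internally so tests can feed in-memory rows)
decode_cohort <- function(raw, dialect = default_dialect()) {
  cols <- dialect$columns
  wanted <- vapply(cols, function(s) s$column, character(1))
  missing_cols <- setdiff(wanted, names(raw))
  if (length(missing_cols) > 0) {
    abort(sprintf("input is missing dialect column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  out <- purrr::imap(cols, function(spec, field) {
    decode_column(as.character(raw[[spec$column]]), spec, field)
  })
  cohort <- tibble::as_tibble(out)
  assert_cohort_valid(cohort)
  cohort
}

assert_cohort_valid <- function(cohort) {
  rep <- validate_cohort(cohort)
  if (!rep$valid) {
    abort(paste0("cohort validation failed:\n  ",
                 paste(rep$problems, collapse = "\n  ")))
  }
  invisible(cohort)
}

#' Validate a decoded cohort
#'
#' Checks the structural invariants of a cohort: unique participant ids,
#' non-empty center ids, CDR-SB within 0-18, non-negative visit-to-death
#' intervals, and that autopsied participants are recorded as deceased.
#'
#' @param cohort a decoded cohort tibble.
#' @return a list with `valid` (logical), `n` (records), and `problems`
#'   (character vector of violations); serializable to JSON as the
#'   validation report.
#' @export
validate_cohort <- function(cohort) {
  problems <- character(0)
  if (nrow(cohort) > 0) {
    dup <- unique(cohort$participant_id[duplicated(cohort$participant_id)])
    if (length(dup) > 0) {
      problems <- c(problems, sprintf("duplicate participant_id: %s",
                                      paste(dup, collapse = ", ")))
    }
    if (any(is.na(cohort$participant_id) | cohort$participant_id == "")) {
      problems <- c(problems, "empty participant_id")
    }
    if (any(is.na(cohort$center_id) | cohort$center_id == "")) {
      problems <- c(problems, "empty center_id")
    }
    bad_cdr <- !is.na(cohort$cdr_sb) &
      (cohort$cdr_sb < 0 | cohort$cdr_sb > 18)
    if (any(bad_cdr)) {
      problems <- c(problems, sprintf("cdr_sb outside [0, 18] for: %s",
        paste(cohort$participant_id[bad_cdr], collapse = ", ")))
    }
    bad_int <- !is.na(cohort$interval_visit_death) &
      cohort$interval_visit_death < 0
    if (any(bad_int)) {
      problems <- c(problems, sprintf("negative interval_visit_death for: %s",
        paste(cohort$participant_id[bad_int], collapse = ", ")))
    }
    bad_aut <- isTRUE_vec(cohort$autopsied) & !isTRUE_vec(cohort$deceased)
    if (any(bad_aut)) {
      problems <- c(problems, sprintf("autopsied but not deceased: %s",
        paste(cohort$participant_id[bad_aut], collapse = ", ")))
    }
  }
  list(valid = length(problems) == 0, n = nrow(cohort), problems = problems)
}

#' Serialize a cohort back to its coded CSV form
#'
#' Inverse of [parse_records()]: re-encodes every field through the dialect
#' so that parse -> write -> parse is the identity.
#'
#' @param cohort a decoded cohort tibble.
#' @param path output CSV path.
#' @param dialect a `tdp_dialect`, by default [default_dialect()].
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, dialect = default_dialect()) {
  cols <- dialect$columns
  check_cohort(cohort, names(cols), "write_cohort")
  out <- purrr::imap(cols, function(spec, field) {
    encode_column(cohort[[field]], spec)
  })
  names(out) <- vapply(cols, function(s) s$column, character(1))
  readr::write_csv(tibble::as_tibble(out), path, na = "", progress = FALSE)
  invisible(path)
}
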