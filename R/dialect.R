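# Code dialect: the mapping between coded CSV columns and typed cohort
# fields. Shipped as an editable YAML file so other coding conventions can
# be accommodated without touching code.

#' Read a code dialect from a YAML file
#'
#' A dialect declares, for every typed field of a cohort, which CSV column
#' holds it and how its codes decode. See the packaged default at
#' `system.file("extdata", "dialect.yaml", package = "tdpengine")` for the
#' format. The same dialect drives both parsing ([parse_records()]) and
#' re-serialization ([write_cohort()]), so a parse/write/parse round trip is
#' the identity.
#'
#' @param path path to a dialect YAML file.
#' @return a `tdp_dialect` list with elements `columns` (per-field specs)
#'   and `dx_labels` (named vector mapping raw presumptive-diagnosis labels
#'   to the eight-way grouping).
#' @export
read_dialect <- function(path) {
  if (!file.exists(path)) abort(sprintf("dialect file not found: %s", path))
  raw <- yaml::read_yaml(path)
  if (is.null(raw$columns)) abort("dialect file has no `columns` section")
  validate_dialect(raw)
}

validate_dialect <- function(raw) {
  for (field in names(raw$columns)) {
    spec <- raw$columns[[field]]
    if (is.null(spec$column)) {
      abort(sprintf("dialect field `%s` lacks a `column` name", field))
    }
    type <- spec$type %||% "code"
    if (!type %in% c("code", "flag", "numeric", "character")) {
      abort(sprintf("dialect field `%s` has unknown type `%s`", field, type))
    }
    if (type == "code" && is.null(spec$codes)) {
      abort(sprintf("dialect field `%s` of type code lacks `codes`", field))
    }
    raw$columns[[field]]$type <- type
    if (type == "code") {
      codes <- unlist(spec$codes)
      raw$columns[[field]]$codes <- setNames(as.character(codes), names(codes))
    }
  }
  if (!is.null(raw$dx_labels)) {
    labs <- unlist(raw$dx_labels)
    bad <- setdiff(unique(labs), DX_CATEGORIES)
    if (length(bad) > 0) {
      abort(sprintf("dialect dx_labels maps to unknown categories: %s",
                    paste(bad, collapse = ", ")))
    }
    raw$dx_labels <- setNames(as.character(labs), names(labs))
  }
  structure(raw, class = "tdp_dialect")
}

#' The packaged default code dialect
#'
#' Convention: 0 = absent/No, 1 = present/Yes (HS-A: 1/2/3 =
#' unilateral/bilateral/laterality unknown), 8 or blank = not assessed.
#'
#' @return a `tdp_dialect` list; see [read_dialect()].
#' @export
default_dialect <- function() {
  if (is.null(.dialect_cache$default)) {
    path <- system.file("extdata", "dialect.yaml", package = "tdpengine")
    .dialect_cache$default <- read_dialect(path)
  }
  .dialect_cache$default
}

.dialect_cache <- new.env(parent = emptyenv())

# decode one raw character column into a typed field
decode_column <- function(values, spec, field) {
  blank <- is.na(values) | trimws(values) == ""
  values <- trimws(values)
  switch(spec$type,
    code = {
      out <- unname(spec$codes[values])
      blank_value <- if (is.null(spec$blank)) NA_character_ else spec$blank
      out[blank] <- blank_value
      bad <- which(is.na(out) & !blank)
      if (length(bad) > 0) {
        abort(sprintf(
          "unmappable code `%s` for column %s (field %s) at row %d",
          values[bad[1]], spec$column, field, bad[1]))
      }
      out
    },
    flag = {
      out <- rep(FALSE, length(values))
      out[!blank & values == "1"] <- TRUE
      bad <- which(!blank & !values %in% c("0", "1"))
      if (length(bad) > 0) {
        abort(sprintf(
          "unmappable code `%s` for flag column %s (field %s) at row %d",
          values[bad[1]], spec$column, field, bad[1]))
      }
      out
    },
    numeric = {
      out <- suppressWarnings(as.numeric(values))
      out[blank] <- NA_real_
      bad <- which(is.na(out) & !blank)
      if (length(bad) > 0) {
        abort(sprintf(
          "non-numeric value `%s` in column %s (field %s) at row %d",
          values[bad[1]], spec$column, field, bad[1]))
      }
      out
    },
    character = {
      out <- values
      out[blank] <- NA_character_
      out
    }
  )
}

# encode one typed field back to its coded character column
encode_column <- function(values, spec) {
  switch(spec$type,
    code = {
      # invert the code map; the first code listed for a value wins, so a
      # value reachable from several codes (e.g. blank and 8) serializes to
      # its canonical code
      inverse <- setNames(names(spec$codes), spec$codes)
      inverse <- inverse[!duplicated(spec$codes)]
      out <- unname(inverse[as.character(values)])
      out[is.na(values) | is.na(out)] <- ""
      out
    },
    flag = ifelse(isTRUE_vec(values), "1", "0"),
    numeric = ifelse(is.na(values), "", as.character(values)),
    character = ifelse(is.na(values), "", as.character(values))
  )
}

isTRUE_vec <- function(x) !is.na(x) & x
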