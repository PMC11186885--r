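# End-to-end orchestration: parse or simulate -> profile availability ->
# complete-case filter -> classify -> association analytics, with a
# machine-readable run log that accounts for every record at every stage.

#' Build a pipeline configuration
#'
#' Exactly one of `input` (path to a coded cohort CSV) or `generator` (a
#' [generator_config()]) must be supplied.
#'
#' @param input path to a coded cohort CSV, or `NULL`.
#' @param generator a [generator_config()], or `NULL`.
#' @param dialect path to a dialect YAML, or `NULL` for the default.
#' @param split_year era split for the conditional neocortex-availability
#'   comparison.
#' @param part1,part2 toggles for the availability and association
#'   analyses.
#' @param multilevel also fit center-varying-intercept models in part 2.
#' @param outcomes outcome labels for the part-2 regressions.
#' @param seed integer seed (overrides the generator's seed when set).
#' @return a validated `pipeline_config` list.
#' @export
pipeline_config <- function(input = NULL, generator = NULL, dialect = NULL,
                            split_year = 2019, part1 = TRUE, part2 = TRUE,
                            multilevel = FALSE,
                            outcomes = c("dementia", "clinical_ad", "ppa",
                                         "bvftd", "hs_a", "adnc", "lewy"),
                            seed = NULL) {
  if (is.null(input) == is.null(generator)) {
    abort("supply exactly one of `input` or `generator`")
  }
  if (!is.null(seed) && !is.null(generator)) generator$seed <- seed
  structure(list(input = input, generator = generator, dialect = dialect,
                 split_year = split_year, part1 = part1, part2 = part2,
                 multilevel = multilevel, outcomes = outcomes, seed = seed),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' YAML keys mirror the arguments of [pipeline_config()]; a `generator`
#' mapping is passed to [generator_config()] (keys `n`, `n_centers`,
#' `seed`, plus any parameter overrides).
#'
#' @param path path to a YAML file.
#' @return a `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  gen <- NULL
  if (!is.null(raw$generator)) {
    g <- raw$generator
    # YAML 1.1 reads a bare `n:` key as the boolean FALSE; undo that
    names(g)[names(g) == "FALSE" | names(g) == "n"] <- "n"
    gen <- do.call(generator_config,
                   c(list(n = g[["n"]] %||% 2000,
                          n_centers = g[["n_centers"]] %||% 25,
                          seed = g[["seed"]] %||% 1),
                     g[setdiff(names(g), c("n", "n_centers", "seed"))]))
  }
  pipeline_config(
    input = raw$input, generator = gen, dialect = raw$dialect,
    split_year = raw$split_year %||% 2019,
    part1 = raw$part1 %||% TRUE, part2 = raw$part2 %||% TRUE,
    multilevel = raw$multilevel %||% FALSE,
    outcomes = raw$outcomes %||% c("dementia", "clinical_ad", "ppa",
                                   "bvftd", "hs_a", "adnc", "lewy"),
    seed = raw$seed)
}

#' Run the full analysis pipeline
#'
#' Executes parse (or generate + inject missingness) -> validation ->
#' availability analytics -> complete-case filter -> classification ->
#' association analytics, writing every table as CSV into `out_dir`
#' together with a JSON-lines run log (record counts at every stage) and
#' a MANIFEST marking which components completed. When no record passes
#' the complete-case filter, part 2 is skipped with an explicit notice
#' and part 1 is still produced. Re-running with the same configuration
#' reproduces identical outputs.
#'
#' @param config a `pipeline_config` (or path to its YAML file).
#' @param out_dir output directory, created if needed.
#' @return the artifact bundle (named list of all computed objects),
#'   invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run_log.jsonl")
  if (file.exists(log_path)) unlink(log_path)
  log_lines <- character(0)
  log_stage <- function(stage, ...) {
    entry <- c(list(stage = stage), list(...))
    line <- jsonlite::toJSON(entry, auto_unbox = TRUE)
    log_lines <<- c(log_lines, line)
    cat(line, "\n", sep = "", file = log_path, append = TRUE)
    inform(sprintf("[%s] %s", stage,
                   paste(names(entry)[-1], unlist(entry[-1]),
                         sep = "=", collapse = " ")))
  }
  bundle <- list()
  manifest <- list()

  dialect <- if (is.null(config$dialect)) default_dialect() else {
    read_dialect(config$dialect)
  }

  if (!is.null(config$generator)) {
    sim <- generate_cohort(config$generator)
    cohort <- apply_missingness(sim$cohort, sim$truth, config$generator)
    bundle$truth <- sim$truth
    readr::write_csv(sim$truth, file.path(out_dir, "truth.csv"),
                     progress = FALSE)
    log_stage("generate", n = nrow(cohort),
              seed = config$generator$seed)
  } else {
    cohort <- parse_records(config$input, dialect)
    log_stage("parse", n = nrow(cohort), input = config$input)
  }
  bundle$cohort <- cohort
  write_cohort(cohort, file.path(out_dir, "cohort.csv"), dialect)
  manifest$cohort <- TRUE

  if (isTRUE(config$part1)) {
    bundle$availability_by_year <- availability_by_year(cohort)
    readr::write_csv(bundle$availability_by_year,
                     file.path(out_dir, "availability_by_year.csv"),
                     progress = FALSE)
    bundle$measure_venn <- measure_venn(cohort)
    readr::write_csv(bundle$measure_venn,
                     file.path(out_dir, "measure_venn.csv"),
                     progress = FALSE)
    prof <- availability_profile(cohort)
    with_regional <- cohort[prof$has_regional_any, , drop = FALSE]
    bundle$region_venn <- if (nrow(with_regional) > 0) {
      region_venn(with_regional)
    } else NULL
    if (!is.null(bundle$region_venn)) {
      readr::write_csv(bundle$region_venn,
                       file.path(out_dir, "region_venn.csv"),
                       progress = FALSE)
    }
    bundle$conditional_neocortex <- conditional_neocortex_availability(
      cohort, split_year = config$split_year,
      dx_labels = dialect$dx_labels)
    readr::write_csv(bundle$conditional_neocortex,
                     file.path(out_dir, "conditional_neocortex.csv"),
                     progress = FALSE)
    log_stage("part1", n = nrow(cohort),
              n_with_regional = nrow(with_regional))
    manifest$part1 <- TRUE
  }

  cc <- complete_case_filter(cohort)
  log_stage("complete_case_filter", n_in = nrow(cohort), n_kept = nrow(cc),
            n_excluded = nrow(cohort) - nrow(cc),
            exclusion_reason = "incomplete TDP-43 assessment")

  if (nrow(cc) == 0) {
    inform("no record passes the complete-case filter; part 2 skipped")
    log_stage("part2_skipped", reason = "no complete cases")
    manifest$part2 <- FALSE
  } else {
    assignments <- classify_tdp(cc)
    bundle$assignments <- assignments
    readr::write_csv(assignments, file.path(out_dir, "assignments.csv"),
                     progress = FALSE)
    jsonlite::write_json(
      purrr::map2(assignments$participant_id, assignments$trace,
                  function(id, tr) list(participant_id = id,
                                        trace = strsplit(tr, ";")[[1]])),
      file.path(out_dir, "rule_trace.json"), auto_unbox = TRUE)
    cat_counts <- table(factor(assignments$category,
                               levels = TDP_CATEGORIES))
    log_stage("classify", n = nrow(cc),
              no_tdp43 = cat_counts[["no_tdp43"]],
              late_nc = cat_counts[["late_nc"]],
              als_ftld_tdp = cat_counts[["als_ftld_tdp"]],
              other_tdp43 = cat_counts[["other_tdp43"]])
    manifest$classify <- TRUE

    if (isTRUE(config$part2)) {
      bundle$summary <- summarize_by_category(cc, assignments)
      readr::write_csv(bundle$summary$cells,
                       file.path(out_dir, "table1_cells.csv"),
                       progress = FALSE)
      readr::write_csv(bundle$summary$tests,
                       file.path(out_dir, "table1_tests.csv"),
                       progress = FALSE)

      or_rows <- list()
      contrast_rows <- list()
      for (oc in config$outcomes) {
        res <- adjusted_logistic(cc, assignments, oc)
        or_rows[[length(or_rows) + 1]] <- res
        ct <- posthoc_contrasts(attr(res, "fit"))
        ct$outcome <- oc
        ct$model <- "single_level"
        contrast_rows[[length(contrast_rows) + 1]] <- ct
        if (isTRUE(config$multilevel)) {
          resm <- multilevel_logistic(cc, assignments, oc)
          or_rows[[length(or_rows) + 1]] <- resm
          ctm <- posthoc_contrasts(attr(resm, "fit"))
          ctm$outcome <- oc
          ctm$model <- "multilevel"
          contrast_rows[[length(contrast_rows) + 1]] <- ctm
        }
      }
      if (length(or_rows) > 0) {
        bundle$odds_ratios <- dplyr::bind_rows(or_rows)
        readr::write_csv(bundle$odds_ratios,
                         file.path(out_dir, "table2_odds_ratios.csv"),
                         progress = FALSE)
        bundle$contrasts <- dplyr::bind_rows(contrast_rows)
        readr::write_csv(bundle$contrasts,
                         file.path(out_dir, "posthoc_contrasts.csv"),
                         progress = FALSE)
      }

      for (cat in c("als_ftld_tdp", "late_nc", "other_tdp43")) {
        pat <- regional_pattern_counts(cc, assignments, cat)
        bundle[[paste0("patterns_", cat)]] <- pat
        readr::write_csv(pat,
                         file.path(out_dir,
                                   paste0("regional_patterns_", cat,
                                          ".csv")),
                         progress = FALSE)
      }
      bundle$overlap <- overlap_proportions(cc, assignments)
      readr::write_csv(bundle$overlap, file.path(out_dir, "overlap.csv"),
                       progress = FALSE)
      log_stage("part2", n_complete = nrow(cc),
                n_outcomes = length(config$outcomes))
      manifest$part2 <- TRUE
    }
  }

  manifest$complete <- !isFALSE(manifest$part2)
  jsonlite::write_json(manifest, file.path(out_dir, "MANIFEST.json"),
                       auto_unbox = TRUE)
  bundle$manifest <- manifest
  bundle$log <- log_lines
  invisible(bundle)
}

#' Render a human-readable summary of a pipeline bundle
#'
#' Formats the classification flow accounting, category frequencies,
#' ALS/FTLD subtype shares, LATE-NC stage distribution, and the headline
#' odds ratios with the report conventions: whole percentages (half away
#' from zero) and odds ratios to one decimal. Rendering is deterministic
#' and purely a view: every number is recomputed from the bundle's exact
#' counts. Missing components render as an explicit gap marker.
#'
#' @param bundle result of [run_pipeline()].
#' @return character vector of report lines, invisibly; printed to the
#'   console.
#' @export
render_summary <- function(bundle) {
  lines <- character(0)
  add <- function(...) lines <<- c(lines, sprintf(...))
  gap <- "  [not available in this bundle]"
  add("== TDP-43 pipeline summary ==")
  if (!is.null(bundle$cohort)) {
    add("Records in cohort: %d", nrow(bundle$cohort))
  } else {
    lines <- c(lines, gap)
  }
  if (!is.null(bundle$assignments)) {
    asg <- bundle$assignments
    n <- nrow(asg)
    add("Complete TDP-43 assessment: %d", n)
    cat_counts <- table(factor(asg$category, levels = TDP_CATEGORIES))
    for (cat in TDP_CATEGORIES) {
      add("  %-14s %5d (%d%%)", cat, cat_counts[[cat]],
          pct_half_up(cat_counts[[cat]], n))
    }
    af <- asg[asg$category == "als_ftld_tdp", , drop = FALSE]
    if (nrow(af) > 0) {
      sub_counts <- table(factor(af$subtype, levels = ALS_FTLD_SUBTYPES))
      add("ALS/FTLD-TDP subtypes (n = %d):", nrow(af))
      for (s in ALS_FTLD_SUBTYPES) {
        add("  %-11s %4d (%d%%)", s, sub_counts[[s]],
            pct_half_up(sub_counts[[s]], nrow(af)))
      }
    }
    lt <- asg[asg$category == "late_nc", , drop = FALSE]
    if (nrow(lt) > 0) {
      st_counts <- table(factor(lt$stage, levels = 1:3))
      add("LATE-NC stages (n = %d):", nrow(lt))
      for (s in 1:3) {
        add("  stage %d  %4d (%d%%)", s, st_counts[[as.character(s)]],
            pct_half_up(st_counts[[as.character(s)]], nrow(lt)))
      }
    }
  } else {
    add("Complete TDP-43 assessment:")
    lines <- c(lines, gap)
  }
  if (!is.null(bundle$odds_ratios)) {
    add("Adjusted odds ratios (single-level):")
    sl <- bundle$odds_ratios[bundle$odds_ratios$model == "single_level", ]
    for (i in seq_len(nrow(sl))) {
      if (isTRUE(sl$estimable[i])) {
        add("  %-18s %-28s OR %.1f [%.1f, %.1f]", sl$outcome[i],
            sl$comparison[i], sl$or[i], sl$ci_low[i], sl$ci_high[i])
      } else {
        add("  %-18s %-28s non-estimable", sl$outcome[i], sl$comparison[i])
      }
    }
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
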