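make_classified <- function(n = 1200, seed = 71) {
  cfg <- generator_config(n = n, n_centers = 10, seed = seed)
  sim <- generate_cohort(cfg)
  cc <- complete_case_filter(apply_missingness(sim$cohort, sim$truth, cfg))
  list(cohort = cc, assignments = classify_tdp(cc))
}

test_that("subtype shares render as whole percentages from their counts", {
  cohort <- bind_cohorts(
    make_cohort(146, ftld_tdp = "present", tdp_amygdala = "present",
                tdp_hippocampus = "present"),
    make_cohort(29, ftld_tdp = "present", mn_inclusion = "tdp43",
                tdp_amygdala = "present", tdp_hippocampus = "present"),
    make_cohort(10, mn_inclusion = "tdp43", tdp_spinal_cord = "present"))
  asg <- classify_tdp(cohort)
  counts <- table(asg$subtype)
  expect_equal(as.vector(counts[c("ftld_only", "both", "als_only")]),
               c(146L, 29L, 10L))
  expect_equal(pct_half_up(counts[["ftld_only"]], nrow(cohort)), 79L)
  expect_equal(pct_half_up(counts[["both"]], nrow(cohort)), 16L)
  expect_equal(pct_half_up(counts[["als_only"]], nrow(cohort)), 5L)
  lines <- utils::capture.output(
    render_summary(list(cohort = cohort, assignments = asg)))
  expect_true(any(grepl("ftld_only\\s+146 \\(79%\\)", lines)))
  expect_true(any(grepl("both\\s+29 \\(16%\\)", lines)))
  expect_true(any(grepl("als_only\\s+10 \\(5%\\)", lines)))
})

test_that("summary cells recompute exactly from raw counts", {
  cls <- make_classified()
  smry <- summarize_by_category(cls$cohort, cls$assignments)
  cells <- smry$cells
  cat_counts <- table(cls$assignments$category)
  # categorical percentages within a variable and category sum to one
  cat_cells <- cells[!is.na(cells$level), ]
  sums <- stats::aggregate(proportion ~ variable + category, cat_cells,
                           sum)
  expect_true(all(abs(sums$proportion - 1) < 1e-9 | is.na(sums$proportion)))
  # n + missing accounts for every record of the category
  totals <- stats::aggregate(n ~ variable + category, cat_cells, sum)
  miss <- stats::aggregate(n_missing ~ variable + category, cat_cells, max)
  merged <- merge(totals, miss)
  expect_true(all(merged$n + merged$n_missing ==
                    as.vector(cat_counts[merged$category])))
  # spot-recount one cell by hand
  df <- dplyr::left_join(cls$cohort,
                         cls$assignments[, c("participant_id", "category")],
                         by = "participant_id")
  hand <- sum(df$category == "late_nc" & df$sex == "female")
  cell <- cells[cells$variable == "sex" & cells$level == "female" &
                  cells$category == "late_nc", ]
  expect_equal(cell$n, hand)
})

test_that("summary comparisons use rank-sum and chi-square as declared", {
  cls <- make_classified()
  smry <- summarize_by_category(cls$cohort, cls$assignments)
  tests <- smry$tests
  expect_setequal(unique(tests$test),
                  c("wilcoxon_rank_sum", "pearson_chi_square"))
  expect_true(all(tests$p_value >= 0 & tests$p_value <= 1))
  age_row <- tests[tests$variable == "age_at_death" &
                     tests$comparison == "late_nc vs als_ftld_tdp", ]
  # LATE-NC dies markedly older than ALS/FTLD-TDP under the defaults
  expect_lt(age_row$p_value, 1e-6)
  # identical values across two groups: rank-sum p = 1
  cohort <- bind_cohorts(
    make_cohort(30, age_at_death = 80, tdp_amygdala = "present",
                tdp_hippocampus = "present", tdp_ec_itc = "present"),
    make_cohort(30, age_at_death = 80))
  asg <- classify_tdp(cohort)
  smry2 <- summarize_by_category(cohort, asg)
  p_age <- smry2$tests[smry2$tests$variable == "age_at_death" &
                         smry2$tests$comparison == "late_nc vs no_tdp43", ]
  expect_equal(p_age$p_value, 1)
})

test_that("empty categories are rendered as zeros and their tests skipped", {
  cohort <- make_cohort(40)  # everything classifies as no_tdp43
  asg <- classify_tdp(cohort)
  smry <- summarize_by_category(cohort, asg)
  expect_equal(nrow(smry$tests), 0)
  expect_true(all(smry$cells$category == "no_tdp43"))
})

test_that("regional pattern counts match the recount oracle and the fixture", {
  # ALS/FTLD fixture with 78% carrying the all-four pattern
  cohort <- bind_cohorts(
    make_cohort(78, ftld_tdp = "present", tdp_amygdala = "present",
                tdp_hippocampus = "present", tdp_ec_itc = "present",
                tdp_neocortex = "present"),
    make_cohort(22, ftld_tdp = "present", tdp_hippocampus = "present"))
  asg <- classify_tdp(cohort)
  pat <- regional_pattern_counts(cohort, asg, "als_ftld_tdp")
  all4 <- pat[pat$amygdala & pat$hippocampus & pat$ec_itc & pat$neocortex, ]
  expect_equal(all4$count, 78)
  expect_equal(all4$proportion, 0.78)
  expect_equal(all4$pct, 78L)
  # single LATE-NC record with amygdala only
  one <- make_cohort(1, tdp_amygdala = "present")
  pat1 <- regional_pattern_counts(one, classify_tdp(one), "late_nc")
  expect_equal(nrow(pat1), 1)
  expect_equal(pat1$count, 1)
  # random-cohort recount
  cls <- make_classified(800, seed = 83)
  for (cat in c("late_nc", "als_ftld_tdp")) {
    pat <- regional_pattern_counts(cls$cohort, cls$assignments, cat)
    df <- dplyr::left_join(cls$cohort,
                           cls$assignments[, c("participant_id",
                                               "category")],
                           by = "participant_id")
    df <- df[df$category == cat, ]
    mem <- tibble::tibble(
      amygdala = df$tdp_amygdala == "present",
      hippocampus = df$tdp_hippocampus == "present",
      ec_itc = df$tdp_ec_itc == "present",
      neocortex = df$tdp_neocortex == "present")
    mem <- mem[rowSums(mem) > 0, ]
    key <- apply(mem, 1, paste, collapse = "|")
    counted <- table(key)
    for (i in seq_len(nrow(pat))) {
      k <- paste(unlist(pat[i, c("amygdala", "hippocampus", "ec_itc",
                                 "neocortex")]), collapse = "|")
      expect_equal(pat$count[i], unname(counted[[k]]))
    }
  }
})

test_that("pathology overlap excludes Other TDP-43 and unrated records", {
  cls <- make_classified(1000, seed = 97)
  ov <- overlap_proportions(cls$cohort, cls$assignments)
  # ALS/FTLD-TDP and LATE-NC are disjoint by construction
  expect_true(all(ov$count[ov$als_ftld_tdp & ov$late_nc] == 0) ||
                !any(ov$als_ftld_tdp & ov$late_nc))
  df <- dplyr::left_join(cls$cohort,
                         cls$assignments[, c("participant_id", "category")],
                         by = "participant_id")
  expected_total <- sum(df$category != "other_tdp43" &
                          df$adnc != "not_assessed" &
                          df$lewy_any != "not_assessed")
  expect_equal(attr(ov, "total"), expected_total)
  expect_equal(sum(ov$count), expected_total)
  # a LATE-NC + ADNC + LB record lands in the triple overlap
  r <- make_cohort(1, tdp_amygdala = "present", tdp_hippocampus = "present",
                   adnc = "int_high", lewy_any = "present")
  ov1 <- overlap_proportions(r, classify_tdp(r))
  expect_equal(ov1$count[ov1$late_nc & ov1$adnc & ov1$lewy &
                           !ov1$als_ftld_tdp], 1)
})

test_that("a planted adjusted dementia odds ratio is recovered", {
  set.seed(123)
  n <- 6000
  category <- sample(tdpengine:::TDP_CATEGORIES, n, TRUE,
                     c(0.62, 0.27, 0.09, 0.02))
  eta <- qlogis(0.55) + log(4.2) * (category == "late_nc") +
    log(3.0) * (category == "als_ftld_tdp") +
    log(2.5) * (category == "other_tdp43")
  dementia <- runif(n) < plogis(eta)
  cohort <- make_cohort(
    n,
    age_at_death = round(rnorm(n, 80, 9), 1),
    sex = sample(c("female", "male"), n, TRUE),
    education = round(rnorm(n, 16, 3)),
    interval_visit_death = round(rexp(n, 1 / 2), 2),
    cognitive_status = ifelse(dementia, "dementia", "normal"))
  asg <- tibble::tibble(participant_id = cohort$participant_id,
                        category = category)
  res <- adjusted_logistic(cohort, asg, "dementia")
  late <- res[res$term == "late_nc", ]
  expect_true(late$ci_low < 4.2 && 4.2 < late$ci_high)
  # outcome independent of category: odds ratios near 1
  cohort0 <- cohort
  cohort0$cognitive_status <- sample(c("dementia", "normal"), n, TRUE)
  res0 <- adjusted_logistic(cohort0, asg, "dementia")
  expect_true(all(abs(log(res0$or)) < 0.6))
})

test_that("multilevel fit matches single-level when centers are homogeneous", {
  cls <- make_classified(4000, seed = 101)
  single <- adjusted_logistic(cls$cohort, cls$assignments, "adnc")
  multi <- multilevel_logistic(cls$cohort, cls$assignments, "adnc")
  # generator plants no between-center outcome heterogeneity, so the
  # random-intercept variance is ~0 and fixed effects agree closely
  m <- multi[match(single$term, multi$term), ]
  expect_true(all(abs(m$or / single$or - 1) < 0.02))
  expect_true(all(m$converged))
})

test_that("single-center input degenerates to the single-level fit", {
  cls <- make_classified(600, seed = 103)
  cohort <- cls$cohort
  cohort$center_id <- "C001"
  expect_message(
    multi <- multilevel_logistic(cohort, cls$assignments, "dementia"),
    "single center")
  expect_true(all(multi$model == "single_level_fallback"))
})

test_that("a planted center-intercept effect does not bias category effects", {
  # coverage of the planted FTLD-vs-AD follow-up odds ratio by the
  # multilevel 95% interval across replicates (individual intervals miss
  # ~5% of the time by construction)
  covered <- vapply(1:10, function(s) {
    pop <- generate_population(n = 4000, seed = 200 + s, center_sd = 1.0)
    res <- followup_autopsy_models(pop, multilevel = TRUE)
    ftld <- res[res$outcome == "followed_to_death" & res$term == "FTLD" &
                  res$model == "multilevel", ]
    ftld$ci_low < 2.0 && 2.0 < ftld$ci_high
  }, logical(1))
  expect_gte(sum(covered), 8)
})
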