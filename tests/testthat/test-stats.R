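# Independent oracles: exhaustive rank enumeration, Monte-Carlo
# permutation, and a hand-coded Newton maximizer of the logistic
# likelihood.

enumerate_rank_sum_p <- function(x, y) {
  n1 <- length(x)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n1)])
  combos <- utils::combn(length(r), n1)
  w_all <- apply(combos, 2, function(idx) sum(r[idx]))
  # two-sided: double the smaller tail of the exact distribution
  lo <- mean(w_all <= w_obs)
  hi <- mean(w_all >= w_obs)
  min(1, 2 * min(lo, hi))
}

newton_logistic <- function(X, y, iter = 50) {
  beta <- rep(0, ncol(X))
  for (i in seq_len(iter)) {
    p <- 1 / (1 + exp(-drop(X %*% beta)))
    g <- crossprod(X, y - p)
    H <- crossprod(X, X * (p * (1 - p)))
    step <- solve(H, g)
    beta <- beta + drop(step)
    if (max(abs(step)) < 1e-12) break
  }
  beta
}

test_that("rank-sum test is exact for small untied samples", {
  res <- rank_sum_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$method, "exact")
  expect_equal(res$p_value, enumerate_rank_sum_p(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(res$p_value, 0.1)
  # several random small configurations against the enumeration oracle
  set.seed(99)
  for (i in 1:10) {
    x <- sample(100, sample(3:8, 1))
    y <- sample(200:300, sample(3:8, 1))
    res <- rank_sum_test(x, y)
    expect_equal(res$p_value, enumerate_rank_sum_p(x, y), tolerance = 1e-12)
  }
})

test_that("identical tied samples give p = 1 under the tie-corrected approximation", {
  x <- c(1, 1, 2, 2, 3, 3, 4, 4, 5)
  res <- rank_sum_test(x, x)
  expect_equal(res$method, "normal_approx")
  expect_equal(res$p_value, 1)
  expect_error(rank_sum_test(numeric(0), 1), "non-empty")
})

test_that("normal approximation tracks a permutation oracle at n = 30", {
  set.seed(4242)
  x <- rnorm(30, 0, 1)
  y <- rnorm(30, 0.4, 1)
  res <- rank_sum_test(x, y)
  r <- rank(c(x, y))
  w_perm <- replicate(1e5, sum(sample(r, 30)))
  w_obs <- sum(r[1:30])
  p_perm <- min(1, 2 * min(mean(w_perm <= w_obs), mean(w_perm >= w_obs)))
  expect_lt(abs(res$p_value - p_perm), 0.01)
})

test_that("2x2 odds ratio is the cross-product ratio", {
  # HS-A present/absent in LATE-NC vs No TDP-43 (155/425 vs 66/1270)
  tab <- matrix(c(155, 425, 66, 1270), nrow = 2, byrow = TRUE)
  res <- two_by_two(tab)
  expect_equal(res$or, (155 * 1270) / (425 * 66))
  expect_equal(round(res$or, 3), 7.018)
  expect_true(res$estimable)
  expect_lt(res$p_value, 1e-10)
  # balanced table: OR exactly 1
  expect_equal(two_by_two(matrix(10, 2, 2))$or, 1)
})

test_that("2x2 chi-square equals the hand-coded Pearson formula", {
  set.seed(5)
  for (i in 1:20) {
    tab <- matrix(sample(1:200, 4), 2, 2)
    res <- two_by_two(tab)
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    expect_equal(res$statistic, sum((tab - E)^2 / E), tolerance = 1e-12)
  }
  # identical proportions: statistic 0, p = 1
  res0 <- two_by_two(matrix(c(30, 70, 60, 140), 2, byrow = TRUE))
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p_value, 1)
})

test_that("2x2 zero cells and zero margins follow the documented policy", {
  res <- two_by_two(matrix(c(0, 20, 10, 10), 2, byrow = TRUE))
  expect_true(res$continuity)
  expect_equal(res$or, (0.5 * 10.5) / (20.5 * 10.5))
  res0 <- two_by_two(matrix(c(0, 0, 10, 10), 2, byrow = TRUE))
  expect_false(res0$estimable)
  expect_true(is.na(res0$or))
})

test_that("2x2 odds ratio equals the one-predictor logistic coefficient", {
  tab <- matrix(c(155, 425, 66, 1270), nrow = 2, byrow = TRUE)
  res <- two_by_two(tab)
  dat <- data.frame(
    g = rep(c(1, 1, 0, 0), times = as.vector(t(tab))),
    y = rep(c(1, 0, 1, 0), times = as.vector(t(tab))))
  fit <- glm(y ~ g, family = binomial(), data = dat)
  expect_equal(res$or, unname(exp(coef(fit)["g"])), tolerance = 1e-6)
})

test_that("adjusted logistic matches the Newton likelihood oracle on a 12-row fixture", {
  cohort <- make_cohort(
    12,
    age_at_death = c(72, 85, 90, 67, 78, 88, 81, 74, 93, 70, 84, 79),
    cognitive_status = c("dementia", "normal", "dementia", "normal",
                         "dementia", "dementia", "normal", "dementia",
                         "dementia", "normal", "dementia", "normal"),
    tdp_amygdala = rep(c("absent", "present"), each = 6),
    tdp_hippocampus = rep(c("absent", "present"), each = 6))
  asg <- classify_tdp(cohort)
  expect_equal(unique(asg$category), c("no_tdp43", "late_nc"))
  res <- adjusted_logistic(cohort, asg, "dementia",
                           covariates = "age_at_death")
  fit <- attr(res, "fit")
  X <- cbind(1, as.numeric(asg$category == "late_nc"),
             cohort$age_at_death)
  y <- as.numeric(cohort$cognitive_status == "dementia")
  beta_oracle <- newton_logistic(X, y)
  expect_equal(unname(coef(fit)), beta_oracle, tolerance = 1e-6)
  expect_equal(res$or, exp(beta_oracle[2]), tolerance = 1e-6)
  expect_equal(res$n_used, 12)
})

test_that("unadjusted category fit reduces exactly to the 2x2 odds ratio", {
  set.seed(8)
  n <- 400
  cohort <- make_cohort(
    n,
    tdp_amygdala = rep(c("absent", "present"), each = n / 2),
    tdp_hippocampus = rep(c("absent", "present"), each = n / 2),
    cognitive_status = sample(c("dementia", "normal"), n, TRUE,
                              c(0.6, 0.4)))
  asg <- classify_tdp(cohort)
  res <- adjusted_logistic(cohort, asg, "dementia",
                           covariates = character(0))
  tab <- table(asg$category == "late_nc",
               cohort$cognitive_status == "dementia")[2:1, 2:1]
  expect_equal(res$or[res$term == "late_nc"],
               two_by_two(tab)$or, tolerance = 1e-9)
})

test_that("complete-case bookkeeping conserves records", {
  cfg <- generator_config(n = 800, n_centers = 10, seed = 31)
  sim <- generate_cohort(cfg)
  cc <- complete_case_filter(apply_missingness(sim$cohort, sim$truth, cfg))
  asg <- classify_tdp(cc)
  res <- adjusted_logistic(cc, asg, "ppa")
  n_missing <- sum(is.na(binary_outcome(cc, "ppa")) |
                     is.na(cc$education))
  expect_equal(res$n_used[1] + n_missing, nrow(cc))
})

test_that("post-hoc contrasts equal the reference-switch refit", {
  cfg <- generator_config(n = 1500, n_centers = 10, seed = 51)
  sim <- generate_cohort(cfg)
  cc <- complete_case_filter(apply_missingness(sim$cohort, sim$truth, cfg))
  asg <- classify_tdp(cc)
  res1 <- adjusted_logistic(cc, asg, "dementia")
  ct <- posthoc_contrasts(attr(res1, "fit"))
  # refit with ALS/FTLD-TDP as reference: the LATE-NC coefficient is the
  # LATE-vs-ALS/FTLD contrast
  res2 <- adjusted_logistic(cc, asg, "dementia",
                            reference = "als_ftld_tdp")
  row2 <- res2[res2$term == "late_nc", ]
  row1 <- ct[ct$contrast == "late_nc vs als_ftld_tdp", ]
  expect_equal(row1$or, row2$or, tolerance = 1e-8)
  expect_equal(row1$p_value, row2$p_value, tolerance = 1e-8)
  # all three pairwise contrasts are invariant to the reference choice
  ct2 <- posthoc_contrasts(attr(res2, "fit"),
                           pairs = list(c("late_nc", "other_tdp43"),
                                        c("no_tdp43", "other_tdp43")))
  ct1b <- posthoc_contrasts(attr(res1, "fit"),
                            pairs = list(c("late_nc", "other_tdp43")))
  expect_equal(ct1b$p_value, ct2$p_value[1], tolerance = 1e-8)
  # self contrast: difference 0, p = 1
  self <- posthoc_contrasts(attr(res1, "fit"),
                            pairs = list(c("late_nc", "late_nc")))
  expect_equal(self$or, 1)
  expect_equal(self$p_value, 1)
})

test_that("contrast standard errors agree with an established marginal-means implementation", {
  skip_if_not_installed("emmeans")
  cfg <- generator_config(n = 1200, n_centers = 8, seed = 61)
  sim <- generate_cohort(cfg)
  cc <- complete_case_filter(apply_missingness(sim$cohort, sim$truth, cfg))
  asg <- classify_tdp(cc)
  res <- adjusted_logistic(cc, asg, "adnc")
  fit <- attr(res, "fit")
  ct <- posthoc_contrasts(attr(res, "fit"))
  em <- emmeans::emmeans(fit, "category")
  prs <- as.data.frame(emmeans::contrast(em, "revpairwise", adjust = "none"))
  em_row <- prs[prs$contrast %in% c("late_nc - als_ftld_tdp",
                                    "als_ftld_tdp - late_nc"), ]
  sign <- if (em_row$contrast[1] == "late_nc - als_ftld_tdp") 1 else -1
  my_row <- ct[ct$contrast == "late_nc vs als_ftld_tdp", ]
  expect_equal(log(my_row$or), sign * em_row$estimate, tolerance = 1e-6)
  expect_equal(my_row$se, em_row$SE, tolerance = 1e-6)
  expect_equal(my_row$p_value, em_row$p.value, tolerance = 1e-6)
})
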