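test_that("identical groups give t = 0, p = 1", {
  x <- c(2, 4, 6, 8, 10)
  mc <- mean_contrast(x, x)
  expect_equal(mc$t_statistic, 0)
  expect_equal(mc$p_value, 1)
  # identical constant groups too
  mc0 <- mean_contrast(rep(5, 4), rep(5, 4))
  expect_equal(mc0$t_statistic, 0)
  expect_equal(mc0$p_value, 1)
})

test_that("mean contrast matches the hand-computed pooled-variance t", {
  m <- c(2, 4, 6, 8)
  f <- c(1, 3, 5, 7)
  # textbook pooled t: sp2 = (3*v1 + 3*v2)/6, t = (5 - 4)/sqrt(sp2*(1/4+1/4))
  sp2 <- (3 * var(m) + 3 * var(f)) / 6
  t_hand <- (mean(m) - mean(f)) / sqrt(sp2 * (1 / 4 + 1 / 4))
  p_hand <- 2 * pt(-abs(t_hand), df = 6)
  mc <- mean_contrast(m, f)
  expect_equal(mc$t_statistic, t_hand, tolerance = 1e-12)
  expect_equal(mc$degrees_of_freedom, 6)
  expect_equal(mc$p_value, p_hand, tolerance = 1e-12)
  expect_equal(mc$transform_applied, "none")
})

test_that("strong non-normality triggers the log transform", {
  set.seed(11)
  m <- exp(rnorm(200, 0, 1))
  f <- exp(rnorm(200, 0, 1))
  mc <- mean_contrast(m, f)
  expect_equal(mc$transform_applied, "log")
  # the t statistic is then computed on the log scale
  expect_equal(mc$t_statistic,
               unname(t.test(log(m), log(f), var.equal = TRUE)$statistic))
  # reported means remain on the original scale
  expect_equal(mc$mean_mothers, mean(m))
})

test_that("nearest-rank percentile picks an observed order statistic", {
  expect_equal(percentile_threshold(1:100, 0.95), 95)
  expect_equal(percentile_threshold(sample(1:100), 0.90), 90)
  expect_equal(quantile_nearest_rank(c(3, 1, 2), 0.5), 2)
  # degenerate distribution: the cutoff equals the common value and no
  # father exceeds it
  cut <- suppressWarnings(percentile_threshold(rep(5, 10), 0.95))
  expect_equal(cut, 5)
  expect_equal(sum(rep(5, 10) > cut), 0)
  expect_error(quantile_nearest_rank(numeric(0), 0.95), "empty")
})

test_that("count above the 95th cutoff is within one of ceiling(0.05 n)", {
  set.seed(21)
  for (n in c(100, 466, 721)) {
    f <- rnorm(n)
    cut <- percentile_threshold(f, 0.95)
    above <- sum(f > cut)
    expect_gte(above, floor(0.05 * n) - 1)
    expect_lte(above, ceiling(0.05 * n))
  }
})

test_that("dichotomize_and_test builds the correct table, OR and p", {
  # table (a,b,c,d) = (10,90,5,95) realized through score vectors
  m <- c(rep(1, 10), rep(0, 90))
  f <- c(rep(1, 5), rep(0, 95))
  tc <- dichotomize_and_test(m, f, 0.5)
  expect_equal(c(tc$a, tc$b, tc$c, tc$d), c(10, 90, 5, 95))
  expect_equal(tc$odds_ratio, (10 * 95) / (90 * 5), tolerance = 1e-12)
  expect_equal(tc$fisher_p, fisher_p_enum(10, 90, 5, 95), tolerance = 1e-10)
  # symmetric table: OR 1, p 1
  tc2 <- dichotomize_and_test(c(rep(1, 5), rep(0, 95)),
                              c(rep(1, 5), rep(0, 95)), 0.5)
  expect_equal(tc2$odds_ratio, 1)
  expect_equal(tc2$fisher_p, 1)
})

test_that("Woolf CI brackets the OR and Haldane kicks in on zero cells", {
  tc <- dichotomize_and_test(c(rep(1, 10), rep(0, 90)),
                             c(rep(1, 5), rep(0, 95)), 0.5)
  expect_lt(tc$ci_low, tc$odds_ratio)
  expect_gt(tc$ci_high, tc$odds_ratio)
  or <- tc$odds_ratio
  se <- sqrt(1 / 10 + 1 / 90 + 1 / 5 + 1 / 95)
  expect_equal(tc$ci_low, exp(log(or) - qnorm(0.975) * se), tolerance = 1e-12)
  # zero cell: corrected OR finite and positive
  tc0 <- dichotomize_and_test(rep(0, 20), c(rep(1, 2), rep(0, 18)), 0.5)
  expect_true(tc0$haldane_corrected)
  expect_true(is.finite(tc0$odds_ratio) && tc0$odds_ratio > 0)
  expect_true(is.finite(tc0$ci_low) && is.finite(tc0$ci_high))
})

test_that("label swap maps OR to 1/OR and keeps the Fisher p", {
  set.seed(31)
  for (i in 1:20) {
    m <- rnorm(40)
    f <- rnorm(50)
    cut <- percentile_threshold(f, 0.75)
    t1 <- dichotomize_and_test(m, f, cut)
    t2 <- dichotomize_and_test(f, m, cut)
    if (!t1$haldane_corrected && !t2$haldane_corrected)
      expect_equal(t1$odds_ratio, 1 / t2$odds_ratio, tolerance = 1e-12)
    expect_equal(t1$fisher_p, t2$fisher_p, tolerance = 1e-12)
  }
})

test_that("the full contrast fit has the expected shape and recomputes cutoffs per subgroup", {
  sim <- simulate_trios(sim_config(n_trios = 200, seed = 99))
  roles <- parent_roles(sim$trios)
  grs <- compute_grs(subset_samples(sim$dosages, names(roles)),
                     sim$weights, roles)
  fit <- grs_contrast(grs, sim$trios)
  expect_s3_class(fit, "grs_contrast")
  expect_equal(nrow(fit$thresholds), 12L)  # 4 conditions x 3 levels
  expect_equal(nrow(fit$means), 4L)
  expect_equal(fit$n_mothers, 200L)
  # margins: a+b = mothers, c+d = fathers
  expect_true(all(fit$thresholds$a + fit$thresholds$b == fit$n_mothers))
  expect_true(all(fit$thresholds$c + fit$thresholds$d == fit$n_fathers))
  # coef method returns one OR per row
  expect_length(coef(fit), 12L)

  chop <- grs_contrast(grs, sim$trios, subgroup_spec(cohort = "CHOP"))
  expect_lt(chop$n_mothers, fit$n_mothers)
  # subgroup cutoffs come from the subgroup's fathers
  chop_f <- grs$score_combined[grs$role == "father" &
                                 grs$sample_id %in% sim$trios$father_id[
                                   sim$trios$cohort == "CHOP"]]
  expect_equal(chop$thresholds$cutoff[chop$thresholds$condition == "combined" &
                                        chop$thresholds$quantile_level == 0.95],
               percentile_threshold(chop_f, 0.95))
  # print method runs
  expect_output(print(fit), "mothers as cases")
})

test_that("subgroup filters compose and refuse unstable sizes", {
  sim <- simulate_trios(sim_config(n_trios = 60, seed = 17))
  roles <- parent_roles(sim$trios)
  grs <- compute_grs(subset_samples(sim$dosages, names(roles)),
                     sim$weights, roles)
  excl <- filter_trios(sim$trios, exclude_overt_phenotype = TRUE)
  expect_true(all(excl$maternal_preeclampsia != "yes"))
  expect_true(all(excl$maternal_htn_medication != "yes"))
  expect_error(
    grs_contrast(grs, sim$trios,
                 subgroup_spec(cohort = "PCGC", ctd_subtype = "truncus")),
    "trios|every trio")
})
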