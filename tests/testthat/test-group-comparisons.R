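test_that("one-way ANOVA matches hand-computed sums of squares", {
  # identical constant groups: no between-group variance
  flat <- tibble::tibble(v = rep(5, 8), g = rep(c("a", "b"), each = 4))
  res <- anova_oneway(flat, v, g)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  # {0,1} vs {2,3}: SSB = 4, SSW = 1, F = (4/1)/(1/2) = 8
  two <- tibble::tibble(v = c(0, 1, 2, 3), g = c("a", "a", "b", "b"))
  res <- anova_oneway(two, v, g)
  expect_equal(res$statistic, 8)
  expect_equal(res$df1, 1)
  expect_equal(res$df2, 2)
  expect_equal(res$p_value, pf(8, 1, 2, lower.tail = FALSE))

  expect_error(anova_oneway(tibble::tibble(v = 1:4, g = "a"), v, g),
               "2 groups")
  expect_error(
    anova_oneway(tibble::tibble(v = 1:3, g = c("a", "a", "b")), v, g),
    "at least 2 subjects")
})

test_that("raw-data and summary-statistics ANOVA agree to 1e-10", {
  withr::with_seed(42, {
    for (rep in 1:5) {
      df <- tibble::tibble(
        v = rnorm(60, mean = rep(c(0, 0.4, 1), each = 20)),
        g = rep(c("a", "b", "c"), each = 20)
      )
      smry <- dplyr::summarise(dplyr::group_by(df, g),
                               m = mean(v), s = sd(v), n = dplyr::n())
      raw <- anova_oneway(df, v, g)
      sum_ <- anova_from_summary(smry, m, s, n)
      expect_equal(sum_$statistic, raw$statistic, tolerance = 1e-10)
      expect_equal(sum_$p_value, raw$p_value, tolerance = 1e-10)
    }
  })
})

test_that("published education summaries reproduce the printed ANOVA p", {
  edu <- tibble::tibble(
    mean = c(11.25, 9.29, 10.69, 10.99, 10.10),
    sd = c(4.60, 4.59, 5.00, 5.32, 4.25),
    n = c(77, 24, 62, 78, 21)
  )
  res <- anova_from_summary(edu, mean, sd, n)
  expect_equal(res$p_value, 0.4791612, tolerance = 1e-5)
  expect_equal(res$df1, 4)
  expect_equal(res$df2, 257)
})

test_that("chi-squared on reconstructed counts behaves classically", {
  # identical proportions: chi-squared exactly 0
  same <- cbind(yes = c(10, 20, 40), no = c(10, 20, 40))
  res <- chisq_test_counts(same)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  # hand-computed 2x2 with all expected counts 5: chi-squared = 20
  tab <- rbind(c(10, 0), c(0, 10))
  res <- chisq_test_counts(tab)
  expect_equal(res$statistic, 20)
  expect_equal(res$df1, 1)
  expect_equal(res$p_value, pchisq(20, 1, lower.tail = FALSE))

  expect_error(chisq_test_counts(rbind(c(0, 0), c(3, 4))), "marginal")

  # permutation invariance
  withr::with_seed(9, {
    m <- matrix(rpois(10, 20), nrow = 2)
    base_p <- chisq_test_counts(m)$p_value
    expect_equal(chisq_test_counts(m[, sample(5)])$p_value, base_p)
    expect_equal(chisq_test_counts(m[2:1, ])$p_value, base_p)
  })
})

test_that("count reconstruction from percentages guards integrality", {
  sex <- tibble::tibble(percent = c(72.73, 83.33), n = c(77, 24))
  cc <- counts_from_percent(sex, percent, n)
  expect_equal(cc$count_yes, c(56L, 20L))
  expect_equal(cc$count_no, c(21L, 4L))
  # distance to the nearest integer can never exceed 0.5, so the default
  # tolerance only fires for user-tightened settings
  bad <- tibble::tibble(percent = 50, n = 1001) # implies 500.5 subjects
  expect_error(counts_from_percent(bad, percent, n, tol = 0.2), "integer")
  expect_silent(counts_from_percent(bad, percent, n))
})

test_that("published sex percentages reproduce the printed chi-squared p", {
  sex <- tibble::tibble(
    percent = c(72.73, 83.33, 67.74, 65.38, 76.19),
    n = c(77, 24, 62, 78, 21)
  )
  res <- chisq_from_percent(sex, percent, n)
  expect_lt(abs(res$p_value - 0.459), 0.01)
  expect_equal(res$df1, 4)
})

test_that("ANCOVA reduces to one-way ANOVA when covariates are constant", {
  withr::with_seed(21, {
    df <- tibble::tibble(
      v = rnorm(90, rep(c(0, 0.5, 1), each = 30)),
      g = rep(c("a", "b", "c"), each = 30),
      age = 70, sex = "F"
    )
  })
  expect_message(
    fit <- ancova_adjusted(df, v, g, covariates = c("age", "sex")),
    "constant")
  plain <- anova_oneway(df, v, g)
  expect_equal(fit$test$statistic, plain$statistic, tolerance = 1e-10)
  expect_equal(fit$test$p_value, plain$p_value, tolerance = 1e-10)
})

test_that("ANCOVA detects group effects and flags degenerate designs", {
  co <- simulate_cohort(seed = 31)
  fit <- ancova_adjusted(co, ptau217, group)
  expect_lt(fit$test$p_value, 0.001)
  expect_equal(nrow(fit$adjusted_means), 5L)

  # single group: no contrast to test
  one <- co[co$group == "Abeta_neg_CU", ]
  expect_error(ancova_adjusted(one, ptau217, group), "2 groups")

  # collinear covariates are named
  co$age2 <- co$age
  expect_error(ancova_adjusted(co, ptau217, group,
                               covariates = c("age", "age2")),
               "collinear")
})

test_that("Bonferroni post hoc follows the multiplication rule", {
  co <- simulate_cohort(seed = 41)
  ph <- bonferroni_posthoc(co, ptau217, group)
  expect_equal(nrow(ph), 10L) # 5*4/2 pairs
  expect_equal(ph$p_adjusted, pmin(1, ph$p_value * 10))
  expect_true(all(ph$p_adjusted >= ph$p_value))
  # monotone in the raw p
  ord <- order(ph$p_value)
  expect_true(all(diff(ph$p_adjusted[ord]) >= 0))
})

test_that("Welch t-test matches the hand-computed statistic", {
  df <- tibble::tibble(v = c(0, 0, 1, 1, 1, 1, 2, 2),
                       carrier = rep(c(TRUE, FALSE), each = 4))
  res <- ttest_by_carrier(df, v, carrier)
  # means 0.5 vs 1.5, both variances 1/3: t = -1/sqrt(1/6) = -sqrt(6)
  expect_equal(res$statistic, -sqrt(6), tolerance = 1e-12)
  expect_equal(res$df1, 6, tolerance = 1e-12)
  expect_equal(res$effect_direction, -1)

  # identical strata
  same <- tibble::tibble(v = rep(c(1, 2), 4),
                         carrier = rep(c(TRUE, FALSE), each = 4))
  res <- ttest_by_carrier(same, v, carrier)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  expect_error(
    ttest_by_carrier(tibble::tibble(v = 1:3, carrier = c(TRUE, FALSE, FALSE)),
                     v, carrier),
    "at least 2")
})

test_that("raw and summary Welch tests agree; published example verifies", {
  withr::with_seed(17, {
    df <- tibble::tibble(v = c(rnorm(30, 1, 2), rnorm(50, 0.5, 0.6)),
                         carrier = rep(c(TRUE, FALSE), c(30, 50)))
  })
  smry <- dplyr::summarise(dplyr::group_by(df, dplyr::desc(carrier)),
                           m = mean(v), s = sd(v), n = dplyr::n())
  raw <- ttest_by_carrier(df, v, carrier)
  sum_ <- welch_from_summary(smry, m, s, n)
  expect_equal(sum_$statistic, raw$statistic, tolerance = 1e-10)
  expect_equal(sum_$p_value, raw$p_value, tolerance = 1e-10)

  apoe <- tibble::tibble(mean = c(1.43, 0.94), sd = c(1.58, 0.76),
                         n = c(102, 160))
  res <- welch_from_summary(apoe, mean, sd, n)
  expect_lt(abs(res$p_value - 0.005), 0.002)
  expect_gt(res$effect_direction, 0)
})
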