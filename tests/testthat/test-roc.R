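test_that("Mann-Whitney AUC matches pair counting on worked examples", {
  expect_equal(auc_mann_whitney(1:4, c(FALSE, FALSE, TRUE, TRUE)), 1)
  expect_equal(auc_mann_whitney(1:4, c(FALSE, TRUE, FALSE, TRUE)), 0.75)
  expect_equal(auc_mann_whitney(rep(2, 6), rep(c(TRUE, FALSE), 3)), 0.5)
  expect_error(auc_mann_whitney(1:4, rep(TRUE, 4)), "Both reference classes")
})

test_that("pair-counting AUC equals trapezoidal ROC area to 1e-12", {
  withr::with_seed(101, {
    for (rep in 1:10) {
      n <- sample(20:80, 1)
      scores <- round(rnorm(n), sample(0:2, 1)) # induce ties
      labels <- runif(n) < 0.4
      if (sum(labels) == 0 || sum(!labels) == 0) next
      curve <- roc_points(scores, labels)
      expect_equal(curve$fpr[1], 0)
      expect_equal(curve$tpr[1], 0)
      expect_equal(curve$fpr[nrow(curve)], 1)
      expect_equal(curve$tpr[nrow(curve)], 1)
      expect_true(all(diff(curve$fpr) >= 0))
      expect_true(all(diff(curve$tpr) >= 0))
      area <- sum(diff(curve$fpr) *
                    (head(curve$tpr, -1) + curve$tpr[-1]) / 2)
      expect_equal(auc_mann_whitney(scores, labels), area,
                   tolerance = 1e-12)
    }
  })
})

test_that("AUC is invariant under strictly increasing transforms", {
  withr::with_seed(7, {
    scores <- rnorm(100)
    labels <- runif(100) < 0.5
  })
  base <- auc_mann_whitney(scores, labels)
  expect_equal(auc_mann_whitney(exp(scores), labels), base)
  expect_equal(auc_mann_whitney(scores^3 + 5 * scores, labels), base)
})

test_that("DeLong interval matches the independent pROC implementation", {
  withr::with_seed(55, {
    for (rep in 1:5) {
      scores <- c(rnorm(60, 1), rnorm(80))
      labels <- rep(c(TRUE, FALSE), c(60, 80))
      ours <- delong_ci(scores, labels)
      ref <- pROC::ci.auc(pROC::roc(labels, scores, levels = c(FALSE, TRUE),
                                    direction = "<", quiet = TRUE),
                          method = "delong")
      expect_equal(ours$auc, as.numeric(ref[2]), tolerance = 1e-10)
      expect_equal(ours$ci_low, max(0, as.numeric(ref[1])),
                   tolerance = 1e-10)
      expect_equal(ours$ci_high, min(1, as.numeric(ref[3])),
                   tolerance = 1e-10)
    }
  })
})

test_that("DeLong interval is symmetric under score reversal and clips", {
  withr::with_seed(66, {
    scores <- c(rnorm(40, 2), rnorm(40))
    labels <- rep(c(TRUE, FALSE), each = 40)
  })
  a <- delong_ci(scores, labels)
  b <- delong_ci(-scores, labels)
  expect_equal(b$ci_low, 1 - a$ci_high, tolerance = 1e-12)
  expect_equal(b$ci_high, 1 - a$ci_low, tolerance = 1e-12)
  expect_gte(a$var, 0)

  sep <- toy_separated()
  big <- delong_ci(rep(sep$values, 20), rep(sep$labels, 20))
  expect_equal(big$ci_high, 1)
})

test_that("DeLong CI width shrinks with sample size", {
  withr::with_seed(77, {
    scores <- c(rnorm(400, 1), rnorm(400))
    labels <- rep(c(TRUE, FALSE), each = 400)
  })
  small <- delong_ci(scores[c(1:50, 401:450)], labels[c(1:50, 401:450)])
  large <- delong_ci(scores, labels)
  expect_lt(large$ci_high - large$ci_low, small$ci_high - small$ci_low)
})

test_that("APOE-augmented logistic score behaves as specified", {
  co <- simulate_cohort(seed = 88) |> add_amyloid_status()
  co <- co[!is.na(co$amyloid_positive), ]

  # constant carrier flag: the covariate carries nothing, AUC unchanged
  co2 <- co
  co2$apoe_e4_carrier <- TRUE
  sc <- logistic_augmented_score(co2, ptau217, apoe_e4_carrier,
                                 amyloid_positive)
  expect_equal(auc_mann_whitney(sc, co2$amyloid_positive),
               auc_mann_whitney(co2$ptau217, co2$amyloid_positive),
               tolerance = 1e-12)

  # carrier-shifted risk independent of the biomarker: the augmented
  # model recovers the extra signal at large n
  withr::with_seed(3, {
    n <- 4000
    apoe <- runif(n) < 0.4
    x <- rlnorm(n)
    y <- runif(n) < stats::plogis(-1 + log(x) + 2 * apoe)
  })
  df <- tibble::tibble(x = x, apoe = apoe, y = y)
  sc <- logistic_augmented_score(df, x, apoe, y)
  expect_gt(auc_mann_whitney(sc, y), auc_mann_whitney(x, y))

  # one-class input errors
  df1 <- tibble::tibble(x = rnorm(10), apoe = FALSE, y = TRUE)
  expect_error(logistic_augmented_score(df1, x, apoe, y), "Both reference")

  # complete separation falls back with a warning
  sepdf <- tibble::tibble(x = c(1:10, 101:110), apoe = rep(c(F, T), 10),
                          y = rep(c(FALSE, TRUE), each = 10))
  expect_warning(sc <- logistic_augmented_score(sepdf, x, apoe, y),
                 "separation")
  expect_true(attr(sc, "fallback"))
})

test_that("ROC analysis filters missing centiloid and orients scores", {
  co <- simulate_cohort(seed = 99)
  r <- roc_analysis(co, ratio)
  expect_equal(r$n_pos + r$n_neg, 238L) # 24 missing centiloid dropped
  expect_true(r$auc >= r$ci_low && r$auc <= r$ci_high)

  # a marker falling with disease is reported on the oriented scale
  r_ab <- roc_analysis(co, abeta42)
  expect_gt(r_ab$auc, 0.5)
  expect_match(r_ab$score_spec, "oriented")
  r_raw <- roc_analysis(co, abeta42, direction = "as-is")
  expect_equal(r_raw$auc, 1 - r_ab$auc, tolerance = 1e-12)
})

test_that("cognitive-stage subgroups partition the ROC analysis", {
  co <- simulate_cohort(seed = 108)
  whole <- subgroup_roc(co, ratio, stratum = "all")
  expect_equal(whole$auc, roc_analysis(co, ratio)$auc)

  cu <- subgroup_roc(co, ratio, stratum = "CU")
  imp <- subgroup_roc(co, ratio, stratum = "impaired")
  ok <- !is.na(co$centiloid)
  expect_equal(cu$n_pos + cu$n_neg + imp$n_pos + imp$n_neg, sum(ok))

  # removing dementia records recomputes on the remaining MCI records
  no_ad <- co[co$group != "AD_dementia", ]
  imp2 <- subgroup_roc(no_ad, ratio, stratum = "impaired")
  expect_equal(imp2$n_pos + imp2$n_neg,
               sum(ok & co$group %in% c("Abeta_neg_MCI", "Abeta_pos_MCI")))

  # a stratum holding a single reference class is degenerate
  only_pos <- co[co$group == "Abeta_pos_CU" & !is.na(co$centiloid), ]
  expect_error(subgroup_roc(only_pos, ratio, stratum = "CU"),
               "Both reference classes")
})

test_that("roc_summary tabulates every marker/stratum/covariate cell", {
  co <- simulate_cohort(seed = 117)
  # near-separable strata may trigger the documented logistic fallback
  suppressWarnings(
    tb <- roc_summary(co, markers = c("ptau217", "ratio"),
                      strata = c("all", "CU"), with_apoe = c(FALSE, TRUE)))
  expect_equal(nrow(tb), 8L)
  expect_true(all(tb$auc >= tb$ci_low & tb$auc <= tb$ci_high))
})
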