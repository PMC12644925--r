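test_that("three-zone classification follows the closed-interval rule", {
  expect_equal(as.character(classify_three_zone(c(1, 2, 3), 1.5, 2.5)),
               c("negative", "intermediate", "positive"))
  # boundary values are intermediate; a collapsed zone keeps only them
  z <- classify_three_zone(c(0.9, 1, 1.1), 1, 1)
  expect_equal(as.character(z), c("negative", "intermediate", "positive"))
  # a clearly elevated ratio against representative dual cutoffs
  expect_equal(as.character(classify_three_zone(0.05, 0.0297, 0.0374)),
               "positive")
  expect_error(classify_three_zone(1, 2, 1), "lower")
})

test_that("hand-counted toy table yields the exact metric values", {
  # disease-positive zones (a,b,c) = (8,1,1); disease-negative (d,e,f) =
  # (1,1,8); 20 subjects in total
  labels <- rep(c(TRUE, FALSE), each = 10)
  zones <- factor(
    c(rep("positive", 8), "intermediate", "negative",
      "positive", "intermediate", rep("negative", 8)),
    levels = c("negative", "intermediate", "positive"))
  m <- classification_metrics(zones, labels)
  v <- setNames(m$value, m$metric)
  expect_equal(v[["ppv"]], 8 / 9, tolerance = 1e-15)
  expect_equal(v[["npv"]], 8 / 9, tolerance = 1e-15)
  expect_equal(v[["plr"]], 8, tolerance = 1e-15)
  expect_equal(v[["nlr"]], 0.125, tolerance = 1e-15)
  expect_equal(v[["intermediate_plr"]], 1, tolerance = 1e-15)
  expect_equal(v[["intermediate_fraction"]], 0.1, tolerance = 1e-15)
})

test_that("metric degeneracies are reported, never silently dropped", {
  labels <- rep(c(TRUE, FALSE), each = 5)
  # everything intermediate: predictive values undefined, fraction 1
  z_all <- factor(rep("intermediate", 10),
                  levels = c("negative", "intermediate", "positive"))
  m <- classification_metrics(z_all, labels)
  v <- setNames(m$value, m$metric)
  notes <- setNames(m$note, m$metric)
  expect_true(is.na(v[["ppv"]]))
  expect_true(is.na(v[["npv"]]))
  expect_match(notes[["ppv"]], "undefined")
  expect_identical(v[["intermediate_fraction"]], 1)

  # empty intermediate zone: classical binary identities hold
  vals <- c(1, 2, 3, 4, 6, 7, 8, 9, 5, 5.5)
  labs <- c(rep(FALSE, 4), rep(TRUE, 4), FALSE, TRUE)
  z <- classify_three_zone(vals, 4.8, 4.8)
  m2 <- classification_metrics(z, labs)
  v2 <- setNames(m2$value, m2$metric)
  sens <- v2[["sens_pos"]]; spec <- v2[["spec_neg"]]
  expect_equal(v2[["plr"]], sens / (1 - spec))
  expect_equal(v2[["nlr"]], (1 - sens) / spec)

  expect_error(classification_metrics(z_all, rep(TRUE, 10)), "non-empty")
})

test_that("per-class zone probabilities always sum to one", {
  withr::with_seed(13, {
    for (rep in 1:20) {
      vals <- rnorm(30)
      labs <- runif(30) < 0.5
      if (!any(labs) || all(labs)) next
      cut <- sort(runif(2, -1, 1))
      z <- classify_three_zone(vals, cut[1], cut[2])
      cnt <- three_zone_counts(z, labs)
      expect_identical(cnt$a + cnt$b + cnt$c, sum(labs))
      expect_identical(cnt$d + cnt$e + cnt$f, sum(!labs))
      expect_identical(cnt$N, 30L)
    }
  })
})

test_that("optimizer output is identical to exhaustive enumeration", {
  withr::with_seed(1234, {
    for (rep in 1:30) {
      n <- sample(8:40, 1)
      vals <- round(c(rnorm(n %/% 2, 1), rnorm(n - n %/% 2)), 2)
      labs <- rep(c(TRUE, FALSE), c(n %/% 2, n - n %/% 2))
      df <- tibble::tibble(v = vals, y = labs)
      got <- optimize_dual_cutoffs(df, v, label = y)
      want <- oracle_dual_cutoffs(vals, labs)
      expect_identical(got$lower, want$lower)
      expect_identical(got$upper, want$upper)
      expect_identical(got$feasible, want$feasible)
      mv <- setNames(got$metrics$value, got$metrics$metric)
      expect_identical(mv[["ppv"]], want$ppv)
      expect_identical(mv[["npv"]], want$npv)
      expect_identical(mv[["plr"]], want$plr)
      expect_identical(mv[["nlr"]], want$nlr)
      expect_identical(mv[["intermediate_fraction"]],
                       want$intermediate_fraction)
    }
  })
})

test_that("perfect separation collapses the intermediate zone", {
  sep <- toy_separated()
  df <- tibble::tibble(v = sep$values, y = sep$labels)
  res <- optimize_dual_cutoffs(df, v, label = y)
  expect_true(res$feasible)
  expect_identical(res$lower, res$upper)
  expect_identical(res$lower, 6.5) # midpoint of the class gap
  mv <- setNames(res$metrics$value, res$metrics$metric)
  expect_identical(mv[["intermediate_fraction"]], 0)
})

test_that("vacuous constraints always allow an empty intermediate zone", {
  loose <- cutoff_constraints(min_ppv = 0, min_npv = 0, min_plr = 0,
                              max_nlr = Inf)
  withr::with_seed(71, {
    for (rep in 1:10) {
      df <- tibble::tibble(v = rnorm(30), y = runif(30) < 0.5)
      if (!any(df$y) || all(df$y)) next
      res <- optimize_dual_cutoffs(df, v, label = y, constraints = loose)
      mv <- setNames(res$metrics$value, res$metrics$metric)
      expect_true(res$feasible)
      expect_identical(mv[["intermediate_fraction"]], 0)
    }
  })
})

test_that("tightening a constraint never shrinks the intermediate zone", {
  withr::with_seed(81, {
    df <- tibble::tibble(v = c(rnorm(60, 1.2), rnorm(60)),
                         y = rep(c(TRUE, FALSE), each = 60))
  })
  frac <- function(cstr) {
    res <- optimize_dual_cutoffs(df, v, label = y, constraints = cstr)
    if (!res$feasible) return(Inf)
    setNames(res$metrics$value, res$metrics$metric)[["intermediate_fraction"]]
  }
  base <- cutoff_constraints(min_ppv = 0.7, min_npv = 0.7, min_plr = 2,
                             max_nlr = 0.5)
  for (tweak in list(
    cutoff_constraints(0.9, 0.7, 2, 0.5),
    cutoff_constraints(0.7, 0.9, 2, 0.5),
    cutoff_constraints(0.7, 0.7, 5, 0.5),
    cutoff_constraints(0.7, 0.7, 2, 0.1))) {
    expect_gte(frac(tweak), frac(base))
  }
})

test_that("exchangeable classes admit no useful dual-cutoff rule", {
  # With labels independent of the values, the constraints can only ever
  # be met vacuously, by pushing nearly everyone into the intermediate
  # zone (a lone extreme value can always give PPV = 1); no feasible pair
  # with a small indeterminate zone exists.
  withr::with_seed(91, {
    for (rep in 1:5) {
      vals <- rnorm(400)
      labs <- sample(rep(c(TRUE, FALSE), each = 200))
      res <- optimize_dual_cutoffs(tibble::tibble(v = vals, y = labs), v,
                                   label = y)
      mv <- setNames(res$metrics$value, res$metrics$metric)
      expect_true(!res$feasible ||
                    mv[["intermediate_fraction"]] > 0.9)
    }
  })
})

test_that("bootstrap derivation is deterministic and collapses at B = 1", {
  co <- simulate_cohort(seed = 7)
  a <- bootstrap_dual_cutoffs(co, ratio, B = 30, seed = 5)
  b <- bootstrap_dual_cutoffs(co, ratio, B = 30, seed = 5)
  expect_identical(a$metrics, b$metrics)
  expect_identical(a$lower, b$lower)
  expect_identical(a$bootstrap$cutoff_ci, b$bootstrap$cutoff_ci)
  c2 <- bootstrap_dual_cutoffs(co, ratio, B = 30, seed = 6)
  expect_false(identical(a$lower, c2$lower))

  one <- bootstrap_dual_cutoffs(co, ratio, B = 1, seed = 5)
  expect_equal(one$metrics$ci_low, one$metrics$ci_high)
  expect_error(bootstrap_dual_cutoffs(co, ratio, B = 0, seed = 1), "B")
})

test_that("original-sample mode reproduces the plain optimizer", {
  co <- simulate_cohort(seed = 19)
  plain <- optimize_dual_cutoffs(co, ptau217)
  boot <- bootstrap_dual_cutoffs(co, ptau217, B = 10, seed = 2,
                                 point_estimate = "original")
  expect_identical(boot$lower, plain$lower)
  expect_identical(boot$upper, plain$upper)
  expect_identical(boot$metrics$value, plain$metrics$value)

  strat <- bootstrap_dual_cutoffs(co, ptau217, B = 10, seed = 2,
                                  stratified = TRUE)
  expect_s3_class(strat, "gz_cutoffs")
})

test_that("cutoff_table is publication-shaped", {
  co <- simulate_cohort(seed = 23)
  tb <- cutoff_table(co, B = 20, seed = 3)
  expect_equal(tb$marker, c("ptau217", "ratio"))
  expect_equal(tb$n, c(238L, 238L))
  expect_true(all(tb$lower_cutoff <= tb$upper_cutoff))
  expect_true(all(tb$intermediate_pct >= 0 & tb$intermediate_pct <= 100))
})
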