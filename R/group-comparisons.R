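new_gz_test <- function(test, statistic, df1, df2, p_value, ...) {
  out <- tibble::tibble(
    test = test, statistic = statistic, df1 = df1, df2 = df2,
    p_value = p_value, ...
  )
  class(out) <- c("gz_test", class(out))
  out
}

#' One-way analysis of variance
#'
#' Classical between/within variance decomposition across diagnostic
#' groups; the F statistic has `(k - 1, N - k)` degrees of freedom. The raw
#' data and the summary-statistics entry point
#' ([anova_from_summary()]) produce identical statistics.
#'
#' @param data A data frame.
#' @param value,group Columns (tidy-eval) holding the measurement and the
#'   group label.
#' @return A one-row `gz_test` tibble with `statistic` (F), `df1`, `df2`,
#'   `p_value`.
#' @export
#' @examples
#' cohort <- simulate_cohort(seed = 1)
#' anova_oneway(cohort, education, group)
anova_oneway <- function(data, value, group) {
  v <- dplyr::pull(data, {{ value }})
  g <- droplevels(factor(dplyr::pull(data, {{ group }})))
  keep <- !is.na(v) & !is.na(g)
  v <- v[keep]; g <- g[keep]
  counts <- table(g)
  if (length(counts) < 2) abort("ANOVA needs at least 2 groups.")
  if (any(counts < 2)) {
    abort("Every group must contain at least 2 subjects.")
  }
  if (var(v) == 0) { # all values identical: no variance to decompose
    return(new_gz_test("anova_oneway", statistic = 0,
                       df1 = length(counts) - 1,
                       df2 = length(v) - length(counts), p_value = 1))
  }
  fit <- lm(v ~ g)
  an <- anova(fit)
  new_gz_test("anova_oneway",
              statistic = an$`F value`[1],
              df1 = an$Df[1], df2 = an$Df[2],
              p_value = an$`Pr(>F)`[1])
}

#' One-way ANOVA from group summary statistics
#'
#' Computes the identical F test as [anova_oneway()] from per-group means,
#' SDs, and sizes: `SSB = sum(n_i (m_i - m)^2)`,
#' `SSW = sum((n_i - 1) s_i^2)`, `F = (SSB/(k-1)) / (SSW/(N-k))`. This is
#' how published descriptive tables (mean +/- SD per group) are re-tested
#' without subject-level data.
#'
#' @param data Data frame with one row per group.
#' @param mean,sd,n Columns holding the group summaries.
#' @return A one-row `gz_test` tibble.
#' @export
#' @examples
#' edu <- tibble::tibble(
#'   mean = c(11.25, 9.29, 10.69, 10.99, 10.10),
#'   sd = c(4.60, 4.59, 5.00, 5.32, 4.25),
#'   n = c(77, 24, 62, 78, 21)
#' )
#' anova_from_summary(edu, mean, sd, n)
anova_from_summary <- function(data, mean, sd, n) {
  m <- dplyr::pull(data, {{ mean }})
  s <- dplyr::pull(data, {{ sd }})
  nn <- dplyr::pull(data, {{ n }})
  k <- length(m)
  if (k < 2) abort("ANOVA needs at least 2 groups.")
  if (any(nn < 2)) abort("Every group must contain at least 2 subjects.")
  N <- sum(nn)
  grand <- sum(nn * m) / N
  ssb <- sum(nn * (m - grand)^2)
  ssw <- sum((nn - 1) * s^2)
  Fst <- (ssb / (k - 1)) / (ssw / (N - k))
  new_gz_test("anova_oneway",
              statistic = Fst, df1 = k - 1, df2 = N - k,
              p_value = pf(Fst, k - 1, N - k, lower.tail = FALSE))
}

#' Reconstruct integer counts from printed percentages
#'
#' Published tables report proportions as rounded percentages. This helper
#' recovers the underlying integer counts from `n * percent / 100`,
#' erroring when the implied count is further than `tol` from an integer
#' (i.e. the percentage cannot have come from any integer count of that
#' group size).
#'
#' @param data Data frame, one row per group.
#' @param percent,n Columns with the printed percentage and the group size.
#' @param tol Maximal tolerated distance from an integer (default 0.51).
#' @return The data with integer columns `count_yes` and `count_no` added.
#' @export
counts_from_percent <- function(data, percent, n, tol = 0.51) {
  pct <- dplyr::pull(data, {{ percent }})
  nn <- dplyr::pull(data, {{ n }})
  implied <- nn * pct / 100
  off <- abs(implied - round(implied))
  if (any(off > tol)) {
    bad <- which(off > tol)[1]
    abort(sprintf(
      "Row %d: %g%% of %d implies %.2f subjects, not an integer (off by %.2f).",
      bad, pct[bad], nn[bad], implied[bad], off[bad]))
  }
  dplyr::mutate(data,
                count_yes = as.integer(round(implied)),
                count_no = as.integer(nn - round(implied)))
}

#' Pearson chi-squared test on a contingency table
#'
#' Pearson chi-squared without continuity correction,
#' `df = (rows - 1)(cols - 1)`. Errors when a marginal is zero (degenerate
#' table) and warns via `chisq.test` when expected counts are small.
#'
#' @param counts A matrix or data frame of non-negative counts
#'   (groups x categories).
#' @return A one-row `gz_test` tibble.
#' @export
chisq_test_counts <- function(counts) {
  m <- as.matrix(counts)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    abort("Degenerate contingency table: a row or column marginal is zero.")
  }
  res <- suppressWarnings(chisq.test(m, correct = FALSE))
  new_gz_test("chisq_proportions",
              statistic = unname(res$statistic),
              df1 = unname(res$parameter), df2 = NA_real_,
              p_value = res$p.value)
}

#' Chi-squared test from printed group percentages
#'
#' Reconstructs integer counts with [counts_from_percent()] and runs the
#' 2 x k Pearson chi-squared of [chisq_test_counts()].
#'
#' @inheritParams counts_from_percent
#' @return A one-row `gz_test` tibble.
#' @export
#' @examples
#' sex <- tibble::tibble(
#'   percent = c(72.73, 83.33, 67.74, 65.38, 76.19),
#'   n = c(77, 24, 62, 78, 21)
#' )
#' chisq_from_percent(sex, percent, n)
chisq_from_percent <- function(data, percent, n, tol = 0.51) {
  cc <- counts_from_percent(data, {{ percent }}, {{ n }}, tol = tol)
  chisq_test_counts(cbind(cc$count_yes, cc$count_no))
}

#' Covariate-adjusted group comparison (ANCOVA)
#'
#' Fits `value ~ group + covariates` and tests the group factor with a
#' partial F (full vs. reduced model). Adjusted group means are evaluated
#' at the covariate means via `emmeans`. Covariates with zero variance are
#' dropped with a message (they carry no information), in which case the
#' group F equals the unadjusted one-way ANOVA F.
#'
#' @param data A data frame.
#' @param value,group Measurement and group columns (tidy-eval).
#' @param covariates Character vector of covariate column names
#'   (default age and sex; sex is treated as a factor with female = 1
#'   reference coding in the design matrix).
#' @param adjusted_means Compute the covariate-adjusted group means
#'   (default `TRUE`; disable in simulation loops that only need the
#'   group test).
#' @return A list of class `gz_ancova`: `test` (partial-F `gz_test`),
#'   `adjusted_means` (tibble, or `NULL`), and the fitted `model`.
#' @export
#' @examples
#' cohort <- simulate_cohort(seed = 1)
#' fit <- ancova_adjusted(cohort, ptau217, group)
#' fit$test
ancova_adjusted <- function(data, value, group,
                            covariates = c("age", "sex"),
                            adjusted_means = TRUE) {
  df <- tibble::tibble(
    .value = dplyr::pull(data, {{ value }}),
    .group = droplevels(factor(dplyr::pull(data, {{ group }})))
  )
  if (nlevels(df$.group) < 2) abort("ANCOVA needs at least 2 groups.")
  for (cv in covariates) {
    if (!cv %in% names(data)) abort(paste0("Missing covariate column: ", cv))
    col <- data[[cv]]
    if (is.character(col)) col <- factor(col)
    df[[cv]] <- col
  }
  df <- df[complete.cases(df), ]

  keep <- character()
  for (cv in covariates) {
    uniq <- unique(df[[cv]])
    if (length(uniq) < 2) {
      inform(paste0("Covariate '", cv, "' is constant; dropped."))
    } else {
      keep <- c(keep, cv)
    }
  }

  rhs_full <- paste(c(".group", keep), collapse = " + ")
  rhs_red <- if (length(keep)) paste(keep, collapse = " + ") else "1"
  full <- lm(stats::as.formula(paste(".value ~", rhs_full)), data = df)
  if (any(is.na(coef(full)))) {
    bad <- names(coef(full))[is.na(coef(full))]
    abort(paste0("Rank-deficient ANCOVA design; collinear term(s): ",
                 paste(bad, collapse = ", ")))
  }
  reduced <- lm(stats::as.formula(paste(".value ~", rhs_red)), data = df)
  cmp <- anova(reduced, full)

  adj <- NULL
  if (adjusted_means) {
    emm <- emmeans::emmeans(full, ".group")
    adj <- tibble::as_tibble(as.data.frame(emm))
    names(adj)[1] <- "group"
  }

  structure(
    list(
      test = new_gz_test("ancova_group",
                         statistic = cmp$F[2],
                         df1 = cmp$Df[2], df2 = cmp$Res.Df[2],
                         p_value = cmp$`Pr(>F)`[2]),
      adjusted_means = adj,
      model = full
    ),
    class = "gz_ancova"
  )
}

#' Bonferroni post hoc contrasts of the adjusted means
#'
#' All pairwise contrasts of the ANCOVA-adjusted group means. Raw p-values
#' come from the contrast t-tests of the covariate-adjusted model; adjusted
#' p-values apply the Bonferroni rule `min(1, p * k(k-1)/2)`.
#'
#' @inheritParams ancova_adjusted
#' @param alpha Significance level for the `significant` flag.
#' @return A tibble of class `gz_posthoc` with one row per group pair:
#'   `contrast`, `estimate` (adjusted mean difference), `se`, `df`,
#'   `statistic`, `p_value`, `p_adjusted`, `significant`.
#' @export
bonferroni_posthoc <- function(data, value, group,
                               covariates = c("age", "sex"),
                               alpha = 0.05) {
  fit <- ancova_adjusted(data, {{ value }}, {{ group }},
                         covariates = covariates)
  emm <- emmeans::emmeans(fit$model, ".group")
  prs <- as.data.frame(emmeans::contrast(emm, method = "pairwise",
                                         adjust = "none"))
  m <- nrow(prs)
  out <- tibble::tibble(
    contrast = as.character(prs$contrast),
    estimate = prs$estimate,
    se = prs$SE,
    df = prs$df,
    statistic = prs$t.ratio,
    p_value = prs$p.value,
    p_adjusted = pmin(1, prs$p.value * m),
    significant = pmin(1, prs$p.value * m) < alpha
  )
  class(out) <- c("gz_posthoc", class(out))
  out
}

#' Welch two-sample t-test by APOE-e4 carrier status
#'
#' Unequal-variance (Welch) two-sided t-test comparing a biomarker between
#' carriers and non-carriers, with Welch-Satterthwaite degrees of freedom.
#' Group variances of plasma markers are grossly unequal between carriers
#' and non-carriers, which is why the pooled-variance test is not used.
#'
#' @param data A data frame.
#' @param value,carrier Measurement column and logical carrier column.
#' @return A one-row `gz_test` tibble; `effect_direction` is the carrier
#'   minus non-carrier mean difference.
#' @export
ttest_by_carrier <- function(data, value, carrier) {
  v <- dplyr::pull(data, {{ value }})
  cr <- dplyr::pull(data, {{ carrier }})
  keep <- !is.na(v) & !is.na(cr)
  v <- v[keep]; cr <- as.logical(cr[keep])
  n1 <- sum(cr); n0 <- sum(!cr)
  if (n1 < 2 || n0 < 2) {
    abort("Both carrier strata need at least 2 subjects.")
  }
  res <- t.test(v[cr], v[!cr], var.equal = FALSE)
  new_gz_test("welch_t_carrier",
              statistic = unname(res$statistic),
              df1 = unname(res$parameter), df2 = NA_real_,
              p_value = res$p.value,
              effect_direction = base::mean(v[cr]) - base::mean(v[!cr]))
}

#' Welch t-test from two group summaries
#'
#' The identical Welch statistic computed from printed summaries:
#' `t = (m1 - m2) / sqrt(s1^2/n1 + s2^2/n2)` with Welch-Satterthwaite df.
#'
#' @param data Data frame with exactly two rows (the two strata).
#' @param mean,sd,n Summary columns.
#' @return A one-row `gz_test` tibble.
#' @export
#' @examples
#' apoe <- tibble::tibble(mean = c(1.43, 0.94), sd = c(1.58, 0.76),
#'                        n = c(102, 160))
#' welch_from_summary(apoe, mean, sd, n)
welch_from_summary <- function(data, mean, sd, n) {
  m <- dplyr::pull(data, {{ mean }})
  s <- dplyr::pull(data, {{ sd }})
  nn <- dplyr::pull(data, {{ n }})
  if (length(m) != 2) abort("Exactly two strata are required.")
  if (any(nn < 2)) abort("Both strata need at least 2 subjects.")
  se2 <- s^2 / nn
  tstat <- (m[1] - m[2]) / sqrt(sum(se2))
  df <- sum(se2)^2 / sum(se2^2 / (nn - 1))
  new_gz_test("welch_t_carrier",
              statistic = tstat, df1 = df, df2 = NA_real_,
              p_value = 2 * pt(-abs(tstat), df),
              effect_direction = m[1] - m[2])
}
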