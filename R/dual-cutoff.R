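#' Performance constraints for dual-cutoff derivation
#'
#' The defaults are the published targets: positive predictive value >=
#' 90%, negative predictive value >= 90%, positive likelihood ratio > 5,
#' negative likelihood ratio < 0.1. PPV/NPV constraints are inclusive
#' (`>=`), likelihood-ratio constraints strict (`>`/`<`), exactly as
#' stated.
#'
#' @param min_ppv,min_npv Minimal predictive values in `[0, 1]`.
#' @param min_plr Minimal positive likelihood ratio (exclusive).
#' @param max_nlr Maximal negative likelihood ratio (exclusive).
#' @return A list of class `gz_constraints`.
#' @export
cutoff_constraints <- function(min_ppv = 0.90, min_npv = 0.90,
                               min_plr = 5.0, max_nlr = 0.1) {
  if (min_ppv < 0 || min_ppv > 1 || min_npv < 0 || min_npv > 1) {
    abort("`min_ppv` and `min_npv` must lie in [0, 1].")
  }
  if (min_plr < 0 || max_nlr <= 0) {
    abort("`min_plr` must be >= 0 and `max_nlr` > 0.")
  }
  structure(list(min_ppv = min_ppv, min_npv = min_npv,
                 min_plr = min_plr, max_nlr = max_nlr),
            class = "gz_constraints")
}

#' Three-zone classification of a biomarker value
#'
#' Values above the upper cutoff are called positive, below the lower
#' cutoff negative, and values in the closed interval `[lower, upper]`
#' fall into the intermediate (indeterminate) zone where no binary call is
#' made. Boundary values are intermediate (conservative convention).
#'
#' @param values Numeric biomarker values.
#' @param lower,upper The two cutoffs, `lower <= upper`.
#' @return Factor with levels `negative`, `intermediate`, `positive`.
#' @export
#' @examples
#' classify_three_zone(c(1, 2, 3), 1.5, 2.5)
classify_three_zone <- function(values, lower, upper) {
  if (lower > upper) abort("`lower` must be <= `upper`.")
  out <- ifelse(values > upper, "positive",
                ifelse(values < lower, "negative", "intermediate"))
  factor(out, levels = c("negative", "intermediate", "positive"))
}

#' Three-zone counts
#'
#' Cross-tabulates zone calls against the disease reference: for
#' disease-positive subjects `a` (positive zone), `b` (intermediate), `c`
#' (negative zone); for disease-negative subjects `d`, `e`, `f` in the same
#' order.
#'
#' @param zones Factor from [classify_three_zone()].
#' @param labels Logical disease reference.
#' @return One-row tibble with columns `a`..`f` and `N`.
#' @export
three_zone_counts <- function(zones, labels) {
  labels <- as.logical(labels)
  tibble::tibble(
    a = sum(zones == "positive" & labels),
    b = sum(zones == "intermediate" & labels),
    c = sum(zones == "negative" & labels),
    d = sum(zones == "positive" & !labels),
    e = sum(zones == "intermediate" & !labels),
    f = sum(zones == "negative" & !labels),
    N = length(zones)
  )
}

# Vectorised metric computation from three-zone counts. Conventions:
# a rate with zero denominator is NA ("undefined"); a likelihood ratio with
# zero denominator rate is Inf if its numerator rate is positive and NA
# (0/0) otherwise.
metrics_from_counts <- function(a, b, c, d, e, f) {
  np <- a + b + c
  nn <- d + e + f
  rate <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  lr <- function(num_rate, den_rate) {
    ifelse(den_rate > 0, num_rate / den_rate,
           ifelse(num_rate > 0, Inf, NA_real_))
  }
  sens <- rate(a, np)
  spec <- rate(f, nn)
  list(
    ppv = rate(a, a + d),
    npv = rate(f, c + f),
    sens_pos = sens,
    spec_neg = spec,
    plr = lr(a / np, d / nn),
    nlr = lr(c / np, f / nn),
    intermediate_plr = lr(b / np, e / nn),
    intermediate_fraction = (b + e) / (np + nn)
  )
}

#' Three-zone classification metrics
#'
#' Computes the predictive values and multi-level likelihood ratios of a
#' three-zone (dual-cutoff) test: `PPV = a/(a+d)`, `NPV = f/(c+f)`,
#' positive-zone sensitivity `a/(a+b+c)`, negative-zone specificity
#' `f/(d+e+f)`, `PLR = [a/(a+b+c)] / [d/(d+e+f)]`,
#' `NLR = [c/(a+b+c)] / [f/(d+e+f)]`, the intermediate-zone likelihood
#' ratio `[b/(a+b+c)] / [e/(d+e+f)]`, and the intermediate fraction
#' `(b+e)/N`. Likelihood ratios use full-class denominators, the only
#' convention under which an intermediate-zone likelihood ratio is
#' coherent; when the intermediate zone is empty they reduce to the
#' classical binary `sens/(1-spec)` and `(1-sens)/spec`. Metrics with an
#' undefined denominator are reported as `NA` with the reason in `note`,
#' never silently dropped.
#'
#' @param zones Factor from [classify_three_zone()], or `NULL` if `counts`
#'   is given.
#' @param labels Logical disease reference (with `zones`).
#' @param counts Optionally, a one-row tibble from [three_zone_counts()].
#' @return Tibble of class `gz_metrics`: `metric`, `value`, `note`, with
#'   the counts attached as attribute `counts`.
#' @export
#' @examples
#' z <- classify_three_zone(c(1, 2, 3), 1.5, 2.5)
#' classification_metrics(z, c(FALSE, FALSE, TRUE))
classification_metrics <- function(zones = NULL, labels = NULL,
                                   counts = NULL) {
  if (is.null(counts)) {
    counts <- three_zone_counts(zones, labels)
  }
  if (counts$a + counts$b + counts$c == 0 ||
      counts$d + counts$e + counts$f == 0) {
    abort("Both disease classes must be non-empty.")
  }
  m <- metrics_from_counts(counts$a, counts$b, counts$c,
                           counts$d, counts$e, counts$f)
  notes <- c(
    ppv = if (counts$a + counts$d == 0) "undefined: no positive-zone calls (a+d = 0)" else NA,
    npv = if (counts$c + counts$f == 0) "undefined: no negative-zone calls (c+f = 0)" else NA,
    sens_pos = NA, spec_neg = NA,
    plr = if (counts$d == 0 && counts$a == 0) "undefined: 0/0" else
      if (counts$d == 0) "infinite: no false positives" else NA,
    nlr = if (counts$f == 0 && counts$c == 0) "undefined: 0/0" else
      if (counts$f == 0) "infinite: no true negatives" else NA,
    intermediate_plr = if (counts$e == 0 && counts$b == 0) "undefined: 0/0" else
      if (counts$e == 0) "infinite: empty intermediate zone in controls" else NA,
    intermediate_fraction = NA
  )
  out <- tibble::tibble(
    metric = names(m),
    value = unlist(m, use.names = FALSE),
    note = unname(notes[names(m)])
  )
  attr(out, "counts") <- counts
  class(out) <- c("gz_metrics", class(out))
  out
}

# Constraint satisfaction under the documented NA conventions: an undefined
# metric never satisfies its constraint; an infinite PLR does.
constraints_met <- function(m, constraints) {
  c(
    ppv = !is.na(m$ppv) && m$ppv >= constraints$min_ppv,
    npv = !is.na(m$npv) && m$npv >= constraints$min_npv,
    plr = !is.na(m$plr) && m$plr > constraints$min_plr,
    nlr = !is.na(m$nlr) && m$nlr < constraints$max_nlr
  )
}

# Candidate thresholds: midpoints of consecutive sorted unique values plus
# sentinels below the minimum and above the maximum. Any other threshold
# induces an identical partition of the observed sample.
candidate_cutoffs <- function(values) {
  u <- sort(unique(values))
  if (length(u) == 1) return(c(u - 1, u + 1))
  c(u[1] - 1, (u[-1] + u[-length(u)]) / 2, u[length(u)] + 1)
}

#' Derive dual cutoffs by constrained zone minimisation
#'
#' Searches all ordered pairs of candidate thresholds (midpoints of
#' consecutive sorted unique values, plus sentinels) for the pair that
#' minimises the intermediate-zone fraction subject to the performance
#' constraints (PPV, NPV inclusive; PLR, NLR strict). Ties are broken by
#' (1) smaller cutoff width, (2) larger PPV + NPV, (3) smaller lower
#' cutoff. When no pair is feasible, the returned pair minimises the
#' number of violated constraints first (then the same ordering), and
#' `feasible` is `FALSE`.
#'
#' @param data A data frame (cohort).
#' @param marker Biomarker column (tidy-eval).
#' @param label Optional logical reference column; derived as
#'   `centiloid > cl_threshold` when absent.
#' @param constraints A [cutoff_constraints()] object.
#' @param cl_threshold Centiloid positivity threshold for the derived
#'   label.
#' @return An object of class `gz_cutoffs`: `marker`, `lower`, `upper`,
#'   `feasible`, `n_violated`, `metrics` (a [classification_metrics()]
#'   tibble on the derivation sample), `n`, `n_pos`, `n_neg`,
#'   `constraints`.
#' @export
#' @examples
#' cohort <- simulate_cohort(seed = 1)
#' optimize_dual_cutoffs(cohort, ratio)
optimize_dual_cutoffs <- function(data, marker, label = NULL,
                                  constraints = cutoff_constraints(),
                                  cl_threshold = 20) {
  marker_name <- as_name(enquo(marker))
  values <- dplyr::pull(data, {{ marker }})
  lab_quo <- enquo(label)
  if (rlang::quo_is_null(lab_quo)) {
    if (!"centiloid" %in% names(data)) {
      abort("No `label` given and no `centiloid` column to derive it from.")
    }
    labels <- data$centiloid > cl_threshold
  } else {
    labels <- as.logical(dplyr::pull(data, !!lab_quo))
  }
  keep <- !is.na(values) & !is.na(labels)
  values <- values[keep]; labels <- labels[keep]
  res <- optimize_dual_cutoffs_impl(values, labels, constraints)
  res$marker <- marker_name
  res
}

optimize_dual_cutoffs_impl <- function(values, labels, constraints) {
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) {
    abort("Both disease classes must be non-empty.")
  }
  cand <- candidate_cutoffs(values)
  K <- length(cand)
  # counts of each class strictly below every candidate (candidates never
  # coincide with observed values, so < and <= are equivalent here)
  vp <- sort(values[labels]); vn <- sort(values[!labels])
  cp <- findInterval(cand, vp)
  cn <- findInterval(cand, vn)

  i <- rep.int(seq_len(K), K)
  j <- rep(seq_len(K), each = K)
  keep <- i <= j
  i <- i[keep]; j <- j[keep]

  a <- n_pos - cp[j]; cc <- cp[i]; b <- n_pos - a - cc
  f <- cn[i]; d <- n_neg - cn[j]; e <- n_neg - d - f
  m <- metrics_from_counts(a, b, cc, d, e, f)

  ok <- (!is.na(m$ppv) & m$ppv >= constraints$min_ppv) +
    (!is.na(m$npv) & m$npv >= constraints$min_npv) +
    (!is.na(m$plr) & m$plr > constraints$min_plr) +
    (!is.na(m$nlr) & m$nlr < constraints$max_nlr)
  n_violated <- 4L - ok
  width <- cand[j] - cand[i]
  ppv0 <- ifelse(is.na(m$ppv), 0, m$ppv)
  npv0 <- ifelse(is.na(m$npv), 0, m$npv)

  best <- order(n_violated, m$intermediate_fraction, width,
                -(ppv0 + npv0), cand[i], cand[j])[1]

  lower <- cand[i[best]]; upper <- cand[j[best]]
  zones <- classify_three_zone(values, lower, upper)
  structure(
    list(
      marker = NA_character_,
      lower = lower, upper = upper,
      feasible = n_violated[best] == 0L,
      n_violated = n_violated[best],
      metrics = classification_metrics(zones, labels),
      n = length(values), n_pos = n_pos, n_neg = n_neg,
      constraints = constraints
    ),
    class = "gz_cutoffs"
  )
}

#' @export
print.gz_cutoffs <- function(x, ...) {
  mv <- setNames(x$metrics$value, x$metrics$metric)
  cat(sprintf(
    "<gz_cutoffs> %s: lower %.4g, upper %.4g (%s)\n",
    x$marker %||% "?", x$lower, x$upper,
    if (x$feasible) "feasible" else
      paste0("infeasible, ", x$n_violated, " constraint(s) violated")))
  cat(sprintf(
    "  intermediate %.1f%% | PPV %.1f%% NPV %.1f%% PLR %.2f NLR %.3f\n",
    100 * mv[["intermediate_fraction"]], 100 * mv[["ppv"]],
    100 * mv[["npv"]], mv[["plr"]], mv[["nlr"]]))
  if (!is.null(x$bootstrap)) {
    cat(sprintf("  bootstrap: B = %d, %.1f%% infeasible replicates\n",
                x$bootstrap$B, 100 * x$bootstrap$infeasible_fraction))
  }
  invisible(x)
}

#' Bootstrap dual-cutoff derivation with confidence intervals
#'
#' Resamples subjects with replacement `B` times, re-derives the optimal
#' cutoff pair on every replicate, and aggregates: the final cutoffs are
#' the per-threshold medians across feasible replicates (or the
#' original-sample optimum when `point_estimate = "original"`); the final
#' metrics are the three-zone metrics of the final cutoffs applied to the
#' original sample; 95% CIs are the 2.5/97.5 percentiles across replicates
#' of each metric, each replicate's metric evaluated at that replicate's
#' own cutoffs. The fraction of infeasible replicates is recorded. When
#' every replicate is infeasible the result is flagged and the CIs are
#' undefined.
#'
#' @inheritParams optimize_dual_cutoffs
#' @param B Number of bootstrap iterations (default 1000).
#' @param seed RNG seed for the resampling.
#' @param stratified Resample within disease classes instead of
#'   unstratified (default unstratified).
#' @param point_estimate `"bootstrap_median"` (default) or `"original"`.
#' @param conf Confidence level.
#' @return A `gz_cutoffs` object whose `metrics` tibble gains `ci_low` and
#'   `ci_high` columns, plus a `bootstrap` element with the cutoff CIs,
#'   `B`, `seed`, and the infeasible fraction.
#' @export
bootstrap_dual_cutoffs <- function(data, marker, label = NULL,
                                   constraints = cutoff_constraints(),
                                   B = 1000L, seed = 1L,
                                   stratified = FALSE,
                                   point_estimate = c("bootstrap_median",
                                                      "original"),
                                   cl_threshold = 20,
                                   conf = 0.95) {
  point_estimate <- match.arg(point_estimate)
  if (B < 1) abort("`B` must be >= 1.")
  marker_name <- as_name(enquo(marker))
  values <- dplyr::pull(data, {{ marker }})
  lab_quo <- enquo(label)
  if (rlang::quo_is_null(lab_quo)) {
    labels <- data$centiloid > cl_threshold
  } else {
    labels <- as.logical(dplyr::pull(data, !!lab_quo))
  }
  keep <- !is.na(values) & !is.na(labels)
  values <- values[keep]; labels <- labels[keep]
  n <- length(values)
  if (sum(labels) == 0 || sum(!labels) == 0) {
    abort("Both disease classes must be non-empty.")
  }

  local_seed(seed)
  idx_pos <- which(labels); idx_neg <- which(!labels)
  metric_names <- c("ppv", "npv", "sens_pos", "spec_neg", "plr", "nlr",
                    "intermediate_plr", "intermediate_fraction")
  reps <- matrix(NA_real_, nrow = B, ncol = length(metric_names) + 3,
                 dimnames = list(NULL, c(metric_names, "lower", "upper",
                                         "feasible")))
  for (bi in seq_len(B)) {
    idx <- if (stratified) {
      c(sample(idx_pos, length(idx_pos), replace = TRUE),
        sample(idx_neg, length(idx_neg), replace = TRUE))
    } else {
      sample.int(n, n, replace = TRUE)
    }
    vb <- values[idx]; lb <- labels[idx]
    if (sum(lb) == 0 || sum(!lb) == 0) next # degenerate resample, skip
    r <- optimize_dual_cutoffs_impl(vb, lb, constraints)
    mv <- setNames(r$metrics$value, r$metrics$metric)
    reps[bi, metric_names] <- mv[metric_names]
    reps[bi, "lower"] <- r$lower
    reps[bi, "upper"] <- r$upper
    reps[bi, "feasible"] <- as.numeric(r$feasible)
  }

  feas <- which(reps[, "feasible"] == 1)
  infeasible_fraction <- 1 - length(feas) / B

  if (point_estimate == "original" || length(feas) == 0) {
    base_fit <- optimize_dual_cutoffs_impl(values, labels, constraints)
    lower <- base_fit$lower; upper <- base_fit$upper
  } else {
    lower <- median(reps[feas, "lower"])
    upper <- median(reps[feas, "upper"])
    if (lower > upper) { # medians of dependent thresholds can cross
      mid <- (lower + upper) / 2
      lower <- mid; upper <- mid
    }
  }

  zones <- classify_three_zone(values, lower, upper)
  metrics <- classification_metrics(zones, labels)
  probs <- c((1 - conf) / 2, 1 - (1 - conf) / 2)
  # percentile quantiles robust to undefined (NA) and infinite replicates
  qfun <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0) return(rep(NA_real_, length(probs)))
    type <- if (any(!is.finite(x))) 1 else 7
    quantile(x, probs = probs, names = FALSE, type = type)
  }
  if (length(feas) > 0) {
    ci <- apply(reps[, metric_names, drop = FALSE], 2, qfun)
    metrics$ci_low <- ci[1, ][metrics$metric]
    metrics$ci_high <- ci[2, ][metrics$metric]
    cutoff_ci <- apply(reps[feas, c("lower", "upper"), drop = FALSE], 2,
                       qfun)
  } else {
    metrics$ci_low <- NA_real_
    metrics$ci_high <- NA_real_
    cutoff_ci <- matrix(NA_real_, 2, 2,
                        dimnames = list(NULL, c("lower", "upper")))
  }

  met_all <- constraints_met(
    as.list(setNames(metrics$value, metrics$metric)), constraints)
  structure(
    list(
      marker = marker_name,
      lower = lower, upper = upper,
      feasible = all(met_all) && length(feas) > 0,
      n_violated = sum(!met_all),
      metrics = metrics,
      n = n, n_pos = sum(labels), n_neg = sum(!labels),
      constraints = constraints,
      bootstrap = list(
        B = B, seed = seed, stratified = stratified,
        point_estimate = point_estimate,
        infeasible_fraction = infeasible_fraction,
        cutoff_ci = tibble::tibble(
          cutoff = c("lower", "upper"),
          ci_low = cutoff_ci[1, ], ci_high = cutoff_ci[2, ]
        ),
        all_infeasible = length(feas) == 0
      )
    ),
    class = "gz_cutoffs"
  )
}

#' Publication-shaped dual-cutoff table
#'
#' Runs [bootstrap_dual_cutoffs()] for each marker and assembles one row
#' per marker with the cutoffs, intermediate-zone percentage, PPV, NPV,
#' PLR, NLR, the intermediate-zone likelihood ratio, and their 95% CIs
#' (percentages on the percent scale).
#'
#' @inheritParams bootstrap_dual_cutoffs
#' @param markers Character vector of marker columns (default p-tau217 and
#'   the p-tau217/Abeta42 ratio).
#' @return A tibble, one row per marker.
#' @export
cutoff_table <- function(data, markers = c("ptau217", "ratio"),
                         constraints = cutoff_constraints(),
                         B = 1000L, seed = 1L, cl_threshold = 20, ...) {
  purrr::map_dfr(markers, function(mk) {
    fit <- bootstrap_dual_cutoffs(data, !!rlang::sym(mk),
                                  constraints = constraints, B = B,
                                  seed = seed, cl_threshold = cl_threshold,
                                  ...)
    mv <- setNames(fit$metrics$value, fit$metrics$metric)
    lo <- setNames(fit$metrics$ci_low, fit$metrics$metric)
    hi <- setNames(fit$metrics$ci_high, fit$metrics$metric)
    tibble::tibble(
      marker = mk, n = fit$n,
      lower_cutoff = fit$lower, upper_cutoff = fit$upper,
      feasible = fit$feasible,
      intermediate_pct = 100 * mv[["intermediate_fraction"]],
      ppv_pct = 100 * mv[["ppv"]], npv_pct = 100 * mv[["npv"]],
      plr = mv[["plr"]], nlr = mv[["nlr"]],
      plr_ci = sprintf("%.2f-%.2f", lo[["plr"]], hi[["plr"]]),
      nlr_ci = sprintf("%.2f-%.2f", lo[["nlr"]], hi[["nlr"]]),
      ppv_pct_ci = sprintf("%.1f-%.1f", 100 * lo[["ppv"]], 100 * hi[["ppv"]]),
      npv_pct_ci = sprintf("%.1f-%.1f", 100 * lo[["npv"]], 100 * hi[["npv"]]),
      intermediate_plr = mv[["intermediate_plr"]],
      intermediate_plr_ci = sprintf("%.2f-%.2f", lo[["intermediate_plr"]],
                                    hi[["intermediate_plr"]])
    )
  })
}
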