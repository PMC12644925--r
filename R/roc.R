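#' Mann-Whitney AUC
#'
#' Empirical area under the ROC curve by concordant-pair counting: the
#' fraction of (positive, negative) score pairs with the positive ranked
#' higher, ties contributing 1/2. Equals trapezoidal integration of the
#' empirical ROC curve.
#'
#' @param scores Numeric score vector.
#' @param labels Logical (or 0/1) reference labels; `TRUE` = positive.
#' @return The AUC, a scalar in `[0, 1]`.
#' @export
#' @examples
#' auc_mann_whitney(c(1, 2, 3, 4), c(FALSE, TRUE, FALSE, TRUE)) # 0.75
auc_mann_whitney <- function(scores, labels) {
  labels <- as.logical(labels)
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) {
    abort("Both reference classes must be present.")
  }
  r <- rank(scores) # midranks handle ties as 1/2
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Empirical ROC curve points
#'
#' Ordered (FPR, TPR) points of the empirical ROC curve, starting at
#' (0, 0) and ending at (1, 1); tied scores collapse into a single step.
#'
#' @inheritParams auc_mann_whitney
#' @return Tibble with columns `threshold`, `fpr`, `tpr`.
#' @export
roc_points <- function(scores, labels) {
  labels <- as.logical(labels)
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) {
    abort("Both reference classes must be present.")
  }
  thr <- sort(unique(scores), decreasing = TRUE)
  tp <- vapply(thr, function(t) sum(scores[labels] >= t), 0)
  fp <- vapply(thr, function(t) sum(scores[!labels] >= t), 0)
  tibble::tibble(
    threshold = c(Inf, thr),
    fpr = c(0, fp / n_neg),
    tpr = c(0, tp / n_pos)
  )
}

# Trapezoidal area under an ROC point set (used as a cross-check).
trapezoid_auc <- function(curve) {
  sum(diff(curve$fpr) * (head(curve$tpr, -1) + curve$tpr[-1]) / 2)
}

#' DeLong confidence interval for the AUC
#'
#' Variance of the empirical AUC from DeLong's structural components
#' (placement values), with a normal-approximation two-sided interval
#' clipped to `[0, 1]`.
#'
#' @inheritParams auc_mann_whitney
#' @param conf Confidence level (default 0.95).
#' @return A list with `auc`, `var`, `ci_low`, `ci_high`.
#' @export
delong_ci <- function(scores, labels, conf = 0.95) {
  labels <- as.logical(labels)
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  m <- sum(labels); n <- sum(!labels)
  if (m < 2 || n < 2) {
    abort("DeLong CI needs at least 2 subjects in each class.")
  }
  x <- scores[labels]; y <- scores[!labels]
  r_all <- rank(c(x, y))
  v10 <- (r_all[seq_len(m)] - rank(x)) / n       # placements of positives
  v01 <- 1 - (r_all[m + seq_len(n)] - rank(y)) / m # placements of negatives
  auc <- base::mean(v10)
  s10 <- var(v10); s01 <- var(v01)
  v <- s10 / m + s01 / n
  z <- qnorm(1 - (1 - conf) / 2)
  list(auc = auc, var = v,
       ci_low = max(0, auc - z * sqrt(v)),
       ci_high = min(1, auc + z * sqrt(v)))
}

#' APOE-augmented logistic score
#'
#' Maximum-likelihood logistic regression of the reference label on a
#' biomarker plus APOE-e4 carrier status; the fitted probabilities serve as
#' the combined score for ROC analysis. The fit uses iteratively reweighted
#' least squares (tolerance 1e-8, at most 100 iterations). When the fit
#' does not converge or the classes are separable, a warning is raised and
#' the raw biomarker ranking is returned instead, flagged in the
#' `fallback` attribute.
#'
#' @param data A data frame.
#' @param marker,apoe,label Columns (tidy-eval): biomarker, logical carrier
#'   flag, logical reference label.
#' @return Numeric vector of fitted probabilities (or raw marker values on
#'   fallback), with attributes `fallback` and `coefficients`.
#' @export
logistic_augmented_score <- function(data, marker, apoe, label) {
  df <- tibble::tibble(
    .y = as.logical(dplyr::pull(data, {{ label }})),
    .x = dplyr::pull(data, {{ marker }}),
    .apoe = as.numeric(as.logical(dplyr::pull(data, {{ apoe }})))
  )
  df <- df[complete.cases(df), ]
  if (length(unique(df$.y)) < 2) {
    abort("Both reference classes must be present for the logistic fit.")
  }
  trouble <- FALSE
  fit <- withCallingHandlers(
    glm(.y ~ .x + .apoe, family = binomial(), data = df,
        control = glm.control(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      trouble <<- TRUE
      invokeRestart("muffleWarning")
    }
  )
  if (!fit$converged) trouble <- TRUE
  cf <- coef(fit)
  # complete separation: the fitted linear predictor splits the classes
  # perfectly, so the MLE diverges and the coefficients are meaningless
  eta <- fit$linear.predictors
  if (min(eta[df$.y]) > max(eta[!df$.y])) trouble <- TRUE
  if (trouble) {
    warn(paste("Logistic fit did not converge cleanly (possible",
               "separation); falling back to the raw biomarker ranking."))
    out <- df$.x
    attr(out, "fallback") <- TRUE
    attr(out, "coefficients") <- cf
    return(out)
  }
  out <- unname(fit$fitted.values)
  attr(out, "fallback") <- FALSE
  attr(out, "coefficients") <- cf
  out
}

#' ROC analysis of a biomarker for amyloid-PET positivity
#'
#' Computes the empirical ROC of a plasma marker (or of its APOE-augmented
#' logistic score) against amyloid positivity (Centiloid > `cl_threshold`),
#' with the Mann-Whitney AUC and DeLong 95% CI. Records without a Centiloid
#' value are dropped, mirroring analyses restricted to the subsample with a
#' valid amyloid-PET quantification.
#'
#' @param data Cohort tibble.
#' @param marker Biomarker column (tidy-eval).
#' @param label Optional logical reference column (tidy-eval); when absent
#'   the label is derived as `centiloid > cl_threshold`.
#' @param with_apoe Augment the marker with APOE-e4 carriage through a
#'   logistic model?
#' @param cl_threshold Centiloid positivity threshold (default 20).
#' @param direction `"auto"` orients the score so the AUC is >= 0.5 (a
#'   marker that falls with disease, like Abeta42, is reported on the
#'   oriented scale, as published ROC tables do); `"as-is"` keeps the raw
#'   orientation.
#' @param conf Confidence level for the DeLong interval.
#' @return An object of class `gz_roc`: list with `auc`, `ci_low`,
#'   `ci_high`, `var`, `n_pos`, `n_neg`, `curve` (tibble), `score_spec`,
#'   `marker`.
#' @export
#' @examples
#' cohort <- simulate_cohort(seed = 1)
#' roc_analysis(cohort, ratio)
roc_analysis <- function(data, marker, label = NULL,
                         with_apoe = FALSE, cl_threshold = 20,
                         direction = c("auto", "as-is"),
                         conf = 0.95) {
  direction <- match.arg(direction)
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
  df <- data[keep, , drop = FALSE]
  values <- values[keep]; labels <- labels[keep]
  if (sum(labels) == 0 || sum(!labels) == 0) {
    abort("Both reference classes must be present.")
  }

  spec <- paste0("raw(", marker_name, ")")
  if (with_apoe) {
    df$.label <- labels
    scores <- logistic_augmented_score(df, {{ marker }},
                                       .data$apoe_e4_carrier, .data$.label)
    spec <- paste0("logistic(", marker_name, " + APOE e4)")
    if (isTRUE(attr(scores, "fallback"))) {
      spec <- paste0(spec, " [fallback: raw ranking]")
    }
    scores <- as.numeric(scores)
  } else {
    scores <- values
  }

  if (direction == "auto" && auc_mann_whitney(scores, labels) < 0.5) {
    scores <- -scores
    spec <- paste0(spec, " [oriented: decreasing]")
  }

  dl <- delong_ci(scores, labels, conf = conf)
  structure(
    list(
      marker = marker_name,
      auc = dl$auc, var = dl$var,
      ci_low = dl$ci_low, ci_high = dl$ci_high,
      n_pos = sum(labels), n_neg = sum(!labels),
      curve = roc_points(scores, labels),
      score_spec = spec
    ),
    class = "gz_roc"
  )
}

#' @export
print.gz_roc <- function(x, ...) {
  cat(sprintf("<gz_roc> %s: AUC %.3f (95%% CI %.3f-%.3f), %d+/%d-\n",
              x$score_spec, x$auc, x$ci_low, x$ci_high, x$n_pos, x$n_neg))
  invisible(x)
}

#' ROC analysis within a cognitive stratum
#'
#' Runs [roc_analysis()] on the cognitively unimpaired (CU) groups, on the
#' cognitively impaired groups (MCI and dementia), or on the whole cohort.
#'
#' @inheritParams roc_analysis
#' @param stratum `"all"`, `"CU"`, or `"impaired"`.
#' @return A `gz_roc` object.
#' @export
subgroup_roc <- function(data, marker, stratum = c("all", "CU", "impaired"),
                         ...) {
  stratum <- match.arg(stratum)
  if (stratum != "all") {
    data <- data[cognitive_stage(data$group) == stratum, , drop = FALSE]
  }
  out <- roc_analysis(data, {{ marker }}, ...)
  out$stratum <- stratum
  out
}

#' Tidy ROC summary across markers and strata
#'
#' One row per marker x stratum x score specification, ready to write as a
#' publication-shaped TSV.
#'
#' @param data Cohort tibble.
#' @param markers Character vector of marker columns.
#' @param strata Character vector of strata (`"all"`, `"CU"`, `"impaired"`).
#' @param with_apoe Logical vector: run without and/or with the APOE
#'   covariate.
#' @inheritParams roc_analysis
#' @return Tibble: `marker`, `stratum`, `apoe`, `auc`, `ci_low`, `ci_high`,
#'   `n_pos`, `n_neg`, `score_spec`.
#' @export
roc_summary <- function(data, markers = BIOMARKERS,
                        strata = c("all", "CU", "impaired"),
                        with_apoe = c(FALSE, TRUE),
                        cl_threshold = 20) {
  grid <- tidyr::expand_grid(marker = markers, stratum = strata,
                             apoe = with_apoe)
  purrr::pmap_dfr(grid, function(marker, stratum, apoe) {
    r <- subgroup_roc(data, !!rlang::sym(marker), stratum = stratum,
                      with_apoe = apoe, cl_threshold = cl_threshold)
    tibble::tibble(
      marker = marker, stratum = stratum, apoe = apoe,
      auc = r$auc, ci_low = r$ci_low, ci_high = r$ci_high,
      n_pos = r$n_pos, n_neg = r$n_neg, score_spec = r$score_spec
    )
  })
}
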