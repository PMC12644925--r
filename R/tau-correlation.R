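#' Least-squares residuals against covariates
#'
#' Ordinary least-squares residuals of a response on an intercept plus
#' covariates; by construction the residuals are orthogonal to every
#' covariate column.
#'
#' @param values Numeric response vector.
#' @param covariates Data frame (or matrix) of covariates; character
#'   columns are treated as factors.
#' @return Numeric residual vector.
#' @export
residualize <- function(values, covariates) {
  covariates <- as.data.frame(covariates)
  if (length(values) != nrow(covariates)) {
    abort("`values` and `covariates` must have the same length.")
  }
  if (length(values) <= ncol(covariates) + 1) {
    abort("Need n > number of covariates + 1 observations.")
  }
  # constant covariates carry no information; keep the intercept only
  keep <- vapply(covariates, function(col) length(unique(col)) > 1, TRUE)
  covariates <- covariates[, keep, drop = FALSE]
  if (ncol(covariates) == 0) {
    return(values - base::mean(values))
  }
  df <- cbind(.value = values, covariates)
  fit <- lm(.value ~ ., data = df)
  if (any(is.na(coef(fit)))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    abort(paste0("Rank-deficient covariate design; collinear term(s): ",
                 paste(bad, collapse = ", ")))
  }
  unname(fit$residuals)
}

#' Partial correlation after covariate adjustment
#'
#' Pearson correlation of the two residual vectors after regressing both
#' variables on the covariates (residual-based partial correlation). The
#' p-value uses `t = r sqrt(df / (1 - r^2))` with `df = n - 2 - k`
#' covariate-adjusted degrees of freedom, two-tailed.
#'
#' @param x,y Numeric vectors.
#' @param covariates Data frame of covariates (k columns).
#' @return One-row tibble: `r`, `p_value`, `n`, `note` (`NA` unless the
#'   correlation is undefined, e.g. zero-variance residuals).
#' @export
partial_corr <- function(x, y, covariates) {
  covariates <- as.data.frame(covariates)
  keep <- complete.cases(x, y, covariates)
  x <- x[keep]; y <- y[keep]
  covariates <- covariates[keep, , drop = FALSE]
  n <- length(x)
  k <- ncol(covariates)
  if (n <= k + 2) {
    return(tibble::tibble(r = NA_real_, p_value = NA_real_, n = n,
                          note = "too few observations"))
  }
  rx <- residualize(x, covariates)
  ry <- residualize(y, covariates)
  # residuals of an (almost) perfectly explained variable are numerical
  # noise; treat them as zero-variance
  tol <- 1e-10
  if (sd(rx) <= tol * max(1, sd(x)) || sd(ry) <= tol * max(1, sd(y))) {
    return(tibble::tibble(r = NA_real_, p_value = NA_real_, n = n,
                          note = "zero-variance residuals"))
  }
  r <- stats::cor(rx, ry)
  df <- n - 2 - k
  tstat <- r * sqrt(df / max(1e-300, 1 - r^2))
  p <- 2 * pt(-abs(tstat), df)
  tibble::tibble(r = r, p_value = p, n = n, note = NA_character_)
}

#' Braak-stratified biomarker-tau correlation matrix
#'
#' Age/sex-adjusted partial correlations between each plasma biomarker and
#' each regional tau-PET SUVR, with columns grouped and ordered by
#' Braak-stage topography and per-cell significance tiers (`*` p < 0.05,
#' `**` p < 0.01, `***` p < 0.001; raw p-values, no multiplicity
#' correction, matching how such heatmaps are reported). Subjects missing
#' a given region are dropped cell-wise, and the per-cell n is reported.
#'
#' @param cohort Cohort tibble with `tau_<region>` columns.
#' @param mapping Region-to-stage tibble ([braak_mapping()]).
#' @param stratum `"all"`, `"CU"`, or `"impaired"`.
#' @param markers Plasma marker columns to correlate.
#' @param covariates Adjustment covariates (default age and sex).
#' @return Tibble of class `gz_taucor`: `marker`, `region`, `stage_group`,
#'   `r`, `p_value`, `n`, `tier`.
#' @export
#' @examples
#' cohort <- simulate_cohort(seed = 1) |> simulate_tau_panel(seed = 2)
#' tau_correlation_matrix(cohort)
tau_correlation_matrix <- function(cohort,
                                   mapping = braak_mapping(),
                                   stratum = c("all", "CU", "impaired"),
                                   markers = BIOMARKERS,
                                   covariates = c("age", "sex")) {
  stratum <- match.arg(stratum)
  cols <- tau_columns(cohort)
  if (length(cols) == 0) {
    abort("`cohort` has no tau_<region> columns; add a tau panel first.")
  }
  regions <- sub("^tau_", "", cols)
  missing_map <- setdiff(regions, mapping$region)
  if (length(missing_map) > 0) {
    abort(paste0("Region(s) absent from the mapping: ",
                 paste(missing_map, collapse = ", ")))
  }

  if (stratum != "all") {
    cohort <- cohort[cognitive_stage(cohort$group) == stratum, ,
                     drop = FALSE]
  }
  has_tau <- rowSums(!is.na(cohort[, cols, drop = FALSE])) > 0
  cohort <- cohort[has_tau, , drop = FALSE]
  k <- length(covariates)
  if (nrow(cohort) < k + 3) {
    abort("Stratum has too few subjects with tau data.")
  }

  mapping <- mapping[match(regions, mapping$region), ]
  ord <- order(mapping$stage_group)
  mapping <- mapping[ord, ]

  cells <- tidyr::expand_grid(marker = markers, region = mapping$region)
  out <- purrr::pmap_dfr(cells, function(marker, region) {
    pc <- partial_corr(cohort[[marker]], cohort[[paste0("tau_", region)]],
                       cohort[, covariates, drop = FALSE])
    tibble::tibble(
      marker = marker, region = region,
      stage_group = mapping$stage_group[mapping$region == region],
      r = pc$r, p_value = pc$p_value, n = pc$n
    )
  })
  out$tier <- signif_tier(out$p_value)
  out$marker <- factor(out$marker, levels = markers)
  out$region <- factor(out$region, levels = mapping$region)
  attr(out, "stratum") <- stratum
  class(out) <- c("gz_taucor", class(out))
  out
}
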