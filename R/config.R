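#' Log-normal parameters from natural-scale moments
#'
#' Moment-matches a log-normal distribution to a requested natural-scale mean
#' and standard deviation. A log-normal with the returned log-scale
#' parameters has exactly the requested moments:
#' `sigma^2 = log(1 + (sd/mean)^2)` and `mu = log(mean) - sigma^2/2`.
#'
#' Concentration measurements are strictly positive and right-skewed, which
#' is why the cohort generator draws them from moment-matched log-normals
#' rather than normals (a normal with SD close to its mean would put
#' substantial mass below zero).
#'
#' @param mean Natural-scale mean(s), strictly positive.
#' @param sd Natural-scale standard deviation(s), non-negative.
#' @return A tibble with columns `mu` and `sigma` (log-scale parameters),
#'   one row per input pair.
#' @export
#' @examples
#' lognormal_params(27.64, 6.91)
#' lognormal_params(1, 0) # degenerate point mass at 1
lognormal_params <- function(mean, sd) {
  if (any(!is.finite(mean)) || any(!is.finite(sd))) {
    abort("`mean` and `sd` must be finite.")
  }
  if (any(mean <= 0)) abort("`mean` must be strictly positive.")
  if (any(sd < 0)) abort("`sd` must be non-negative.")
  sigma2 <- log(1 + (sd / mean)^2)
  tibble::tibble(mu = log(mean) - sigma2 / 2, sigma = sqrt(sigma2))
}

default_biomarker_moments <- function() {
  tibble::tribble(
    ~group,           ~marker,   ~mean,  ~sd,   ~interpolated,
    "Abeta_neg_CU",   "ptau217",  0.55,  0.36,  FALSE,
    "Abeta_pos_CU",   "ptau217",  1.15,  0.46,  FALSE,
    "Abeta_neg_MCI",  "ptau217",  0.55,  0.36,  TRUE,
    "Abeta_pos_MCI",  "ptau217",  1.75,  1.69,  FALSE,
    "AD_dementia",    "ptau217",  1.95,  1.11,  FALSE,
    "Abeta_neg_CU",   "abeta42", 27.64,  6.91,  FALSE,
    "Abeta_pos_CU",   "abeta42", 23.54,  4.63,  FALSE,
    "Abeta_neg_MCI",  "abeta42", 27.64,  6.91,  TRUE,
    "Abeta_pos_MCI",  "abeta42", 23.00,  5.00,  TRUE,
    "AD_dementia",    "abeta42", 22.62,  5.56,  FALSE,
    "Abeta_neg_CU",   "gfap",    12.30,  7.36,  FALSE,
    "Abeta_pos_CU",   "gfap",    20.67, 10.63,  FALSE,
    "Abeta_neg_MCI",  "gfap",    12.30,  7.36,  TRUE,
    "Abeta_pos_MCI",  "gfap",    21.55,  9.53,  FALSE,
    "AD_dementia",    "gfap",    22.81, 11.04,  FALSE
  )
}

# Global SUVR group moments mapped to Centiloid via CL = 188*SUVR - 96.56,
# anchored so that SUVR 0.62 corresponds to the CL 20 positivity threshold.
CL_SLOPE <- 188
CL_INTERCEPT <- 20 - 188 * 0.62

default_centiloid_moments <- function() {
  suvr <- tibble::tribble(
    ~group,          ~suvr_mean, ~suvr_sd,
    "Abeta_neg_CU",   0.47,       0.07,
    "Abeta_pos_CU",   0.70,       0.07,
    "Abeta_neg_MCI",  0.47,       0.08,
    "Abeta_pos_MCI",  0.73,       0.09,
    "AD_dementia",    0.77,       0.08
  )
  tibble::tibble(
    group = suvr$group,
    mean = CL_SLOPE * suvr$suvr_mean + CL_INTERCEPT,
    sd = CL_SLOPE * suvr$suvr_sd
  )
}

#' Cohort generator configuration
#'
#' Bundles every parameter of the synthetic cohort generator: diagnostic
#' group sizes, per-group biomarker moments on the natural scale,
#' demographic moments, carrier and sex probabilities, the Centiloid
#' (amyloid-PET reference) moments, the latent-factor loadings that induce
#' within-subject biomarker dependence, and the regional tau-PET model.
#'
#' The generator ties the plasma markers of a subject together through two
#' standard-normal latent factors: a disease *severity* factor (raising
#' p-tau217, GFAP, and Centiloid, lowering Abeta42) and a shared
#' *nuisance* factor emulating pre-analytical/volume variation common to the
#' p-tau217 and Abeta42 assays, which the p-tau217/Abeta42 ratio largely
#' cancels. `latent_loadings` holds one `(severity, nuisance)` pair per
#' marker; each pair must satisfy `severity^2 + nuisance^2 <= 1`.
#'
#' @param group_sizes Named integer vector of subjects per diagnostic group.
#' @param biomarker_moments Tibble with columns `group`, `marker`, `mean`,
#'   `sd`, `interpolated` (natural-scale moments; `interpolated` flags
#'   values that are designed stand-ins rather than published summaries).
#' @param age_moments,education_moments Tibbles with `group`, `mean`, `sd`
#'   (years). Age draws are truncated at 55 (study inclusion age),
#'   education at 0.
#' @param sex_female_prob,apoe_carrier_prob Named probability vectors per
#'   group; sex is encoded `"F"`/`"M"` with female as the reference level 1
#'   in adjustment models.
#' @param centiloid_moments Tibble with `group`, `mean`, `sd` on the
#'   Centiloid scale. Draws are truncated to the group's amyloid sign
#'   (amyloid-positive groups above 20 CL, negative groups below), because
#'   the diagnostic groups are defined by amyloid-PET status.
#' @param latent_loadings Tibble with columns `marker`, `severity`,
#'   `nuisance` for `ptau217`, `abeta42`, `gfap`, `centiloid`.
#' @param severity_offsets Named numeric vector: mean latent disease
#'   severity per group (drives the regional tau model).
#' @param tau_model Regional tau-PET model, see [default_tau_model()].
#' @param n_missing_centiloid Number of subjects whose Centiloid (and global
#'   SUVR) is set missing, emulating incomplete quantification; ROC and
#'   cutoff analyses drop these records.
#' @param seed Optional default RNG seed recorded with the config.
#' @return An object of class `gz_config` (a named list).
#' @seealso [default_cohort_config()], [simulate_cohort()]
#' @export
cohort_config <- function(group_sizes,
                          biomarker_moments,
                          age_moments,
                          education_moments,
                          sex_female_prob,
                          apoe_carrier_prob,
                          centiloid_moments,
                          latent_loadings,
                          severity_offsets,
                          tau_model = default_tau_model(),
                          n_missing_centiloid = 0L,
                          seed = NULL) {
  cfg <- structure(
    list(
      group_sizes = group_sizes,
      biomarker_moments = tibble::as_tibble(biomarker_moments),
      age_moments = tibble::as_tibble(age_moments),
      education_moments = tibble::as_tibble(education_moments),
      sex_female_prob = sex_female_prob,
      apoe_carrier_prob = apoe_carrier_prob,
      centiloid_moments = tibble::as_tibble(centiloid_moments),
      latent_loadings = tibble::as_tibble(latent_loadings),
      severity_offsets = severity_offsets,
      tau_model = tau_model,
      n_missing_centiloid = as.integer(n_missing_centiloid),
      seed = seed
    ),
    class = "gz_config"
  )
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  if (!setequal(names(cfg$group_sizes), GROUP_LEVELS)) {
    abort("`group_sizes` must name exactly the five diagnostic groups.")
  }
  if (any(cfg$group_sizes < 0)) abort("Group sizes must be >= 0.")
  for (tb in list(cfg$biomarker_moments, cfg$age_moments,
                  cfg$education_moments, cfg$centiloid_moments)) {
    if (any(tb$sd < 0)) abort("All SDs in the config must be >= 0.")
  }
  if (any(cfg$biomarker_moments$mean <= 0)) {
    abort("Biomarker means must be strictly positive.")
  }
  probs <- c(cfg$sex_female_prob, cfg$apoe_carrier_prob)
  if (any(probs < 0 | probs > 1)) {
    abort("All probabilities must lie in [0, 1].")
  }
  ll <- cfg$latent_loadings
  if (any(ll$severity^2 + ll$nuisance^2 > 1 + 1e-12)) {
    abort("Latent loadings must satisfy severity^2 + nuisance^2 <= 1.")
  }
  need <- c("ptau217", "abeta42", "gfap", "centiloid")
  if (!setequal(ll$marker, need)) {
    abort("`latent_loadings` must cover ptau217, abeta42, gfap, centiloid.")
  }
  validate_tau_model(cfg$tau_model)
  if (cfg$n_missing_centiloid < 0 ||
      cfg$n_missing_centiloid > sum(cfg$group_sizes)) {
    abort("`n_missing_centiloid` must be between 0 and the cohort size.")
  }
  invisible(cfg)
}

#' Default configuration emulating the published cohort
#'
#' Returns the generator configuration whose group sizes (77/24/62/78/21)
#' and per-group biomarker, age, education, sex, and global-SUVR-derived
#' Centiloid summaries equal the published values. Moments that were not
#' published (the amyloid-negative MCI plasma panel and the amyloid-positive
#' MCI Abeta42) are designed stand-ins flagged `interpolated = TRUE` in
#' `biomarker_moments`. APOE carrier probabilities are designed so the
#' expected carrier count matches the published 102/262 split, with carriers
#' enriched in amyloid-positive groups.
#'
#' @return A `gz_config` object.
#' @export
#' @examples
#' cfg <- default_cohort_config()
#' cfg$group_sizes
default_cohort_config <- function() {
  cohort_config(
    group_sizes = setNames(c(77L, 24L, 62L, 78L, 21L), GROUP_LEVELS),
    biomarker_moments = default_biomarker_moments(),
    age_moments = tibble::tibble(
      group = GROUP_LEVELS,
      mean = c(72.22, 77.96, 77.79, 74.28, 70.24),
      sd = c(8.03, 6.21, 7.38, 7.64, 10.83)
    ),
    education_moments = tibble::tibble(
      group = GROUP_LEVELS,
      mean = c(11.25, 9.29, 10.69, 10.99, 10.10),
      sd = c(4.60, 4.59, 5.00, 5.32, 4.25)
    ),
    sex_female_prob = setNames(
      c(0.7273, 0.8333, 0.6774, 0.6538, 0.7619), GROUP_LEVELS),
    apoe_carrier_prob = setNames(
      c(0.22, 0.55, 0.28, 0.55, 0.65), GROUP_LEVELS),
    centiloid_moments = default_centiloid_moments(),
    latent_loadings = tibble::tribble(
      ~marker,     ~severity, ~nuisance,
      "ptau217",    0.5,       0.5,
      "abeta42",   -0.3,       0.6,
      "gfap",       0.5,       0.0,
      "centiloid",  0.6,       0.0
    ),
    severity_offsets = setNames(c(0, 0.8, 0.2, 1.4, 2.0), GROUP_LEVELS),
    tau_model = default_tau_model(),
    n_missing_centiloid = 24L
  )
}

#' @export
print.gz_config <- function(x, ...) {
  cat("<gz_config> synthetic cohort configuration\n")
  cat("  groups:", paste0(names(x$group_sizes), " (", x$group_sizes, ")",
                          collapse = ", "), "\n")
  n_interp <- sum(x$biomarker_moments$interpolated)
  cat("  biomarker moments:", nrow(x$biomarker_moments), "rows (",
      n_interp, "interpolated )\n")
  cat("  tau regions:", nrow(x$tau_model$regions),
      "| missing centiloid:", x$n_missing_centiloid, "\n")
  invisible(x)
}

# Uniform rescaling of group sizes, used by convergence checks.
scale_group_sizes <- function(config, sizes) {
  if (length(sizes) == 1) sizes <- setNames(rep(sizes, 5), GROUP_LEVELS)
  config$group_sizes <- setNames(as.integer(sizes[GROUP_LEVELS]),
                                 GROUP_LEVELS)
  config$n_missing_centiloid <- 0L
  validate_config(config)
  config
}

# Null configuration: every group shares the same moments/probabilities.
# Used for type-I-error calibration of the adjusted group tests.
null_cohort_config <- function(n_per_group = 40L) {
  cfg <- default_cohort_config()
  cfg$group_sizes <- setNames(rep(as.integer(n_per_group), 5), GROUP_LEVELS)
  cfg$biomarker_moments <- cfg$biomarker_moments |>
    dplyr::group_by(.data$marker) |>
    dplyr::mutate(
      mean = .data$mean[.data$group == "Abeta_neg_CU"],
      sd = .data$sd[.data$group == "Abeta_neg_CU"],
      interpolated = TRUE
    ) |>
    dplyr::ungroup()
  flat <- function(tb) {
    tb$mean <- tb$mean[tb$group == "Abeta_neg_CU"]
    tb$sd <- tb$sd[tb$group == "Abeta_neg_CU"]
    tb
  }
  cfg$age_moments <- flat(cfg$age_moments)
  cfg$education_moments <- flat(cfg$education_moments)
  cfg$sex_female_prob[] <- cfg$sex_female_prob[["Abeta_neg_CU"]]
  cfg$apoe_carrier_prob[] <- cfg$apoe_carrier_prob[["Abeta_neg_CU"]]
  cfg$centiloid_moments$mean <- cfg$centiloid_moments$mean[1]
  cfg$centiloid_moments$sd <- cfg$centiloid_moments$sd[1]
  cfg$severity_offsets[] <- 0
  cfg$n_missing_centiloid <- 0L
  validate_config(cfg)
  cfg
}
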