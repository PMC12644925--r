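#' Default Braak-stage mapping of tau-PET regions
#'
#' The 15 regional tau-PET variables shipped with the generator, grouped by
#' Braak-stage-related cortical topography: mesial temporal composites
#' (Braak I-II, transentorhinal), meta-temporal and temporo-parietal
#' composites (Braak III-IV, limbic/associative), frontal composites
#' (Braak V-VI, isocortical), and global composites. The exact regional
#' variables of the emulated study are not public, so this mapping is an
#' editable synthetic stand-in shipped as data the analyses take as
#' configuration; any region-to-stage table with the same columns works.
#'
#' @return Tibble with columns `region` and `stage_group` (ordered factor:
#'   `Braak I-II`, `Braak III-IV`, `Braak V-VI`, `Global`).
#' @export
#' @examples
#' dplyr::count(braak_mapping(), stage_group)
braak_mapping <- function() {
  tb <- tibble::tribble(
    ~region,                    ~stage_group,
    "mesial_temporal_left",     "Braak I-II",
    "mesial_temporal_right",    "Braak I-II",
    "mesial_temporal_centaur",  "Braak I-II",
    "meta_temporal_left",       "Braak III-IV",
    "meta_temporal_right",      "Braak III-IV",
    "meta_temporal_centaur",    "Braak III-IV",
    "temporo_parietal_left",    "Braak III-IV",
    "temporo_parietal_right",   "Braak III-IV",
    "temporo_parietal_centaur", "Braak III-IV",
    "frontal_left",             "Braak V-VI",
    "frontal_right",            "Braak V-VI",
    "frontal_centaur",          "Braak V-VI",
    "global_left",              "Global",
    "global_right",             "Global",
    "global_centaur",           "Global"
  )
  tb$stage_group <- factor(tb$stage_group, levels = BRAAK_LEVELS)
  tb
}

BRAAK_LEVELS <- c("Braak I-II", "Braak III-IV", "Braak V-VI", "Global")

#' Default regional tau-PET generative model
#'
#' Each region's SUVR is generated as
#' `baseline + loading * latent_severity + noise`, with stage-specific
#' baselines, loadings, and noise SDs. Loadings are calibrated by
#' construction (not fitted to any data) so that, under the default cohort
#' configuration, age/sex-adjusted partial correlations between the
#' p-tau217/Abeta42 ratio and regional SUVR are strong (about 0.5) while
#' Abeta42 correlations are negative, reproducing the designed ordering of
#' marker-tau associations. Early-stage (Braak I-II) regions carry slightly
#' higher loadings than isocortical ones.
#'
#' @param mapping A region-to-stage tibble, see [braak_mapping()].
#' @return A list of class `gz_tau_model` with elements `regions` (tibble:
#'   `region`, `stage_group`, `baseline`, `loading`, `noise_sd`) and
#'   `subset_by_stage` (named vector: default tau-PET subsample sizes per
#'   cognitive stage, `CU = 24`, `impaired = 52`).
#' @export
default_tau_model <- function(mapping = braak_mapping()) {
  pars <- tibble::tribble(
    ~stage_group,   ~baseline, ~loading, ~noise_sd,
    "Braak I-II",    1.25,      0.28,     0.20,
    "Braak III-IV",  1.20,      0.25,     0.18,
    "Braak V-VI",    1.10,      0.20,     0.18,
    "Global",        1.18,      0.24,     0.15
  )
  regions <- mapping |>
    dplyr::mutate(stage_group = as.character(.data$stage_group)) |>
    dplyr::left_join(pars, by = "stage_group") |>
    dplyr::mutate(
      # small lateral offsets so left/right/composite variants differ
      baseline = .data$baseline +
        0.01 * (grepl("_right$", .data$region)) -
        0.01 * (grepl("_left$", .data$region)),
      stage_group = factor(.data$stage_group, levels = BRAAK_LEVELS)
    )
  structure(
    list(regions = regions,
         subset_by_stage = c(CU = 24L, impaired = 52L)),
    class = "gz_tau_model"
  )
}

validate_tau_model <- function(model) {
  if (!inherits(model, "gz_tau_model")) abort("`tau_model` must be a gz_tau_model.")
  r <- model$regions
  need <- c("region", "stage_group", "baseline", "loading", "noise_sd")
  if (!all(need %in% names(r))) {
    abort("tau model regions must have region, stage_group, baseline, loading, noise_sd.")
  }
  if (anyDuplicated(r$region)) {
    abort("Each region must map to exactly one stage group.")
  }
  if (any(r$noise_sd < 0)) abort("Regional noise SDs must be >= 0.")
  invisible(model)
}

#' Add a regional tau-PET panel to a cohort
#'
#' Fills regional SUVR values (`tau_<region>` columns) for a subset of
#' subjects, emulating a tau-PET subsample. Regions are generated as
#' `baseline + loading * latent_severity + stage-specific noise`. The
#' default subset sizes mirror a 76-subject tau subsample split as 24
#' cognitively unimpaired and 52 cognitively impaired participants.
#'
#' @param cohort A simulated cohort (needs the `latent_severity` column).
#' @param tau_model A [default_tau_model()]-shaped model.
#' @param n_tau Either `NULL` (use the model's per-stage defaults), a named
#'   vector `c(CU = , impaired = )`, a single count (split across stages in
#'   the default 24:52 proportion), or `Inf` for the whole cohort.
#' @param seed Integer RNG seed.
#' @return The cohort with one `tau_<region>` column per configured region
#'   (`NA` outside the selected subset).
#' @export
#' @examples
#' cohort <- simulate_cohort(seed = 1) |> simulate_tau_panel(seed = 2)
#' sum(stats::complete.cases(cohort[, grep("^tau_", names(cohort))]))
simulate_tau_panel <- function(cohort,
                               tau_model = default_tau_model(),
                               n_tau = NULL,
                               seed = 1L) {
  validate_tau_model(tau_model)
  if (nrow(cohort) == 0) abort("`cohort` must be non-empty.")
  if (!"latent_severity" %in% names(cohort)) {
    abort(paste("`cohort` lacks the `latent_severity` column; tau panels can",
                "only be simulated for generator-produced cohorts."))
  }
  local_seed(seed)

  stage <- cognitive_stage(cohort$group)
  targets <- tau_subset_sizes(n_tau, tau_model, table(stage))
  selected <- logical(nrow(cohort))
  for (s in names(targets)) {
    idx <- which(stage == s)
    k <- targets[[s]]
    if (k > length(idx)) {
      abort(sprintf(
        "Requested tau subset (%d '%s' subjects) exceeds the %d available.",
        k, s, length(idx)))
    }
    selected[sample(idx, k)] <- TRUE
  }

  n_sel <- sum(selected)
  sev <- cohort$latent_severity[selected]
  for (i in seq_len(nrow(tau_model$regions))) {
    r <- tau_model$regions[i, ]
    col <- paste0("tau_", r$region)
    vals <- rep(NA_real_, nrow(cohort))
    vals[selected] <- r$baseline + r$loading * sev + rnorm(n_sel, 0, r$noise_sd)
    cohort[[col]] <- vals
  }
  cohort
}

tau_subset_sizes <- function(n_tau, tau_model, available) {
  default <- tau_model$subset_by_stage
  if (is.null(n_tau)) return(default)
  if (length(n_tau) == 1 && is.infinite(n_tau)) {
    return(setNames(as.integer(available[c("CU", "impaired")]),
                    c("CU", "impaired")))
  }
  if (!is.null(names(n_tau)) && setequal(names(n_tau), c("CU", "impaired"))) {
    return(vapply(n_tau[c("CU", "impaired")], as.integer, 1L))
  }
  if (length(n_tau) == 1) {
    frac <- default / sum(default)
    cu <- round(n_tau * frac[["CU"]])
    return(c(CU = as.integer(cu), impaired = as.integer(n_tau - cu)))
  }
  abort("`n_tau` must be NULL, Inf, a single count, or c(CU=, impaired=).")
}

tau_columns <- function(cohort) {
  grep("^tau_", names(cohort), value = TRUE)
}
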