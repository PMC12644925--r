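#' Pipeline run configuration
#'
#' Parameterises a full analysis run: where the cohort comes from
#' (simulate or load), which markers to analyse, the amyloid reference
#' definition, the cutoff constraints, bootstrap settings, strata, and the
#' output directory. One global seed feeds deterministic per-stage
#' sub-seeds, so adding a stage never perturbs the randomness of earlier
#' stages.
#'
#' @param mode `"simulate"` or `"load"`.
#' @param cohort_path CSV path (load mode).
#' @param generator [cohort_config()] (simulate mode).
#' @param with_tau Simulate a regional tau panel? (simulate mode)
#' @param markers Markers to analyse.
#' @param cutoff_markers Markers for the dual-cutoff stage.
#' @param cl_threshold Centiloid positivity threshold (default 20).
#' @param constraints [cutoff_constraints()].
#' @param bootstrap_iters Bootstrap iterations for the cutoff stage.
#' @param seed Global RNG seed.
#' @param strata Strata for ROC and tau stages.
#' @param out_dir Output directory (created if absent).
#' @return A list of class `gz_runconfig`.
#' @export
run_config <- function(mode = c("simulate", "load"),
                       cohort_path = NULL,
                       generator = default_cohort_config(),
                       with_tau = TRUE,
                       markers = BIOMARKERS,
                       cutoff_markers = c("ptau217", "ratio"),
                       cl_threshold = 20,
                       constraints = cutoff_constraints(),
                       bootstrap_iters = 1000L,
                       seed = 1L,
                       strata = c("all", "CU", "impaired"),
                       out_dir = tempfile("greyzone_run_")) {
  mode <- match.arg(mode)
  if (mode == "load" && is.null(cohort_path)) {
    abort("Load mode requires `cohort_path`.")
  }
  if (bootstrap_iters < 1) abort("`bootstrap_iters` must be >= 1.")
  if (!is.finite(cl_threshold)) abort("`cl_threshold` must be finite.")
  structure(
    list(mode = mode, cohort_path = cohort_path, generator = generator,
         with_tau = with_tau, markers = markers,
         cutoff_markers = cutoff_markers, cl_threshold = cl_threshold,
         constraints = constraints,
         bootstrap_iters = as.integer(bootstrap_iters),
         seed = as.integer(seed), strata = strata, out_dir = out_dir),
    class = "gz_runconfig"
  )
}

#' Descriptive characteristics table
#'
#' A publication-shaped descriptive table: per-group mean +/- SD for the
#' continuous variables with the one-way ANOVA p-value, and the female
#' percentage with the chi-squared p-value.
#'
#' @param cohort Cohort tibble.
#' @return Tibble with one row per variable and one column per group.
#' @export
descriptives_table <- function(cohort) {
  groups <- levels(droplevels(factor(cohort$group)))
  cont_vars <- c("age", "education", "ptau217", "abeta42", "ratio", "gfap",
                 "global_suvr")
  cont_vars <- intersect(cont_vars, names(cohort))
  rows <- purrr::map_dfr(cont_vars, function(vn) {
    p <- anova_oneway(cohort, !!rlang::sym(vn), .data$group)$p_value
    cells <- vapply(groups, function(g) {
      x <- cohort[[vn]][cohort$group == g]
      sprintf("%.2f ± %.2f", base::mean(x, na.rm = TRUE),
              sd(x, na.rm = TRUE))
    }, "")
    tibble::tibble(variable = vn, !!!setNames(as.list(cells), groups),
                   p_value = p)
  })
  counts <- table(factor(cohort$group, groups),
                  factor(cohort$sex, c("F", "M")))
  sex_p <- chisq_test_counts(counts)$p_value
  sex_cells <- vapply(groups, function(g) {
    sprintf("%.1f%%", 100 * base::mean(cohort$sex[cohort$group == g] == "F"))
  }, "")
  dplyr::bind_rows(
    tibble::tibble(variable = "sex_female",
                   !!!setNames(as.list(sex_cells), groups),
                   p_value = sex_p),
    rows
  )
}

#' Adjusted biomarker group-comparison table
#'
#' Per marker: the age/sex-adjusted ANCOVA group F and p, plus the Welch
#' t-test between APOE-e4 carriers and non-carriers.
#'
#' @param cohort Cohort tibble.
#' @param markers Marker columns.
#' @return Tibble, one row per marker.
#' @export
group_comparison_table <- function(cohort, markers = BIOMARKERS) {
  purrr::map_dfr(markers, function(mk) {
    anc <- ancova_adjusted(cohort, !!rlang::sym(mk), .data$group)
    tt <- ttest_by_carrier(cohort, !!rlang::sym(mk), .data$apoe_e4_carrier)
    tibble::tibble(
      marker = mk,
      ancova_F = anc$test$statistic,
      ancova_df1 = anc$test$df1, ancova_df2 = anc$test$df2,
      ancova_p = anc$test$p_value,
      carrier_t = tt$statistic, carrier_df = tt$df1,
      carrier_p = tt$p_value,
      carrier_minus_noncarrier = tt$effect_direction
    )
  })
}

#' Run the full analysis pipeline
#'
#' Simulates (or loads) the cohort, then runs the descriptive, adjusted
#' group-comparison, ROC, dual-cutoff, and tau-correlation stages, writing
#' publication-shaped TSVs, a JSON block with every test result, and a
#' manifest listing every emitted file. The tau stage is skipped (and
#' logged) when no `tau_` columns exist. Reruns with the same config are
#' byte-identical.
#'
#' @param config A [run_config()].
#' @return A list of class `gz_manifest`: `files`, `warnings`, `seed`,
#'   `version`, `config`. Also written as `manifest.json`.
#' @export
run_pipeline <- function(config = run_config()) {
  if (!inherits(config, "gz_runconfig")) abort("`config` must be a gz_runconfig.")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  warns <- character()
  emit <- function(name) {
    path <- file.path(config$out_dir, name)
    files <<- c(files, name)
    path
  }

  # --- cohort stage ---------------------------------------------------------
  if (config$mode == "simulate") {
    cohort <- simulate_cohort(config$generator,
                              seed = stage_seed(config$seed, "cohort"))
    if (config$with_tau) {
      cohort <- simulate_tau_panel(cohort, config$generator$tau_model,
                                   seed = stage_seed(config$seed, "tau"))
    }
    write_cohort_csv(cohort, emit("cohort.csv"))
    write_config_json(config$generator, emit("generator_config.json"))
  } else {
    violations <- validate_cohort_csv(config$cohort_path)
    if (nrow(violations) > 0) {
      abort(paste0(
        "Cohort schema violations (", nrow(violations), "); first: row ",
        violations$row[1], ", column ",
        violations$column[1] %||% "<file>", ": ", violations$message[1]))
    }
    cohort <- read_cohort_csv(config$cohort_path)
  }

  # --- descriptives ---------------------------------------------------------
  desc <- descriptives_table(cohort)
  write_result_tsv(desc, emit("descriptives.tsv"))
  comp <- group_comparison_table(cohort, config$markers)
  write_result_tsv(comp, emit("group_comparisons.tsv"))

  # --- ROC ------------------------------------------------------------------
  roc <- roc_summary(cohort, markers = config$markers,
                     strata = config$strata,
                     cl_threshold = config$cl_threshold)
  write_result_tsv(roc, emit("roc_summary.tsv"))

  # --- dual cutoffs ---------------------------------------------------------
  cuts <- cutoff_table(cohort, markers = config$cutoff_markers,
                       constraints = config$constraints,
                       B = config$bootstrap_iters,
                       seed = stage_seed(config$seed, "bootstrap"),
                       cl_threshold = config$cl_threshold)
  write_result_tsv(cuts, emit("dual_cutoffs.tsv"))
  if (any(!cuts$feasible)) {
    warns <- c(warns, paste0(
      "dual-cutoff constraints infeasible for: ",
      paste(cuts$marker[!cuts$feasible], collapse = ", ")))
  }

  # --- tau correlations -----------------------------------------------------
  if (length(tau_columns(cohort)) > 0) {
    taus <- purrr::map_dfr(config$strata, function(s) {
      tc <- tau_correlation_matrix(cohort, stratum = s)
      tc$stratum <- s
      tc
    })
    write_result_tsv(taus, emit("tau_correlations.tsv"))
  } else {
    warns <- c(warns, "tau stage skipped: no tau_ columns in cohort")
  }

  # --- JSON result block ----------------------------------------------------
  results <- list(
    descriptives_p = setNames(as.list(desc$p_value), desc$variable),
    ancova = setNames(as.list(comp$ancova_p), comp$marker),
    carrier_t = setNames(as.list(comp$carrier_p), comp$marker),
    auc = purrr::pmap(roc, function(marker, stratum, apoe, auc, ...) {
      list(marker = marker, stratum = stratum, apoe = apoe, auc = auc)
    })
  )
  jsonlite::write_json(results, emit("results.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  manifest <- structure(
    list(
      files = files,
      warnings = warns,
      seed = config$seed,
      version = as.character(packageVersion("greyzone")),
      n_subjects = nrow(cohort),
      mode = config$mode
    ),
    class = "gz_manifest"
  )
  jsonlite::write_json(unclass(manifest),
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest$files <- c(manifest$files, "manifest.json")
  manifest
}

#' @export
print.gz_manifest <- function(x, ...) {
  cat("<gz_manifest>", x$mode, "run, seed", x$seed, "-", x$n_subjects,
      "subjects\n")
  cat("  files:", paste(x$files, collapse = ", "), "\n")
  if (length(x$warnings)) {
    cat("  warnings:\n")
    for (w in x$warnings) cat("   -", w, "\n")
  }
  invisible(x)
}
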