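COHORT_REQUIRED_COLS <- c(
  "subject_id", "group", "age", "sex", "education", "apoe_e4_carrier",
  "ptau217", "abeta42", "ratio", "gfap", "centiloid"
)

#' Write a cohort to CSV
#'
#' One row per subject; tau regions as `tau_`-prefixed columns; sex encoded
#' `"F"`/`"M"`; missing values as empty fields. The generator-internal
#' `latent_severity` column is dropped on write.
#'
#' @param cohort A cohort tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  out <- dplyr::select(cohort, -dplyr::any_of("latent_severity"))
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Read a cohort from CSV
#'
#' Reads a [write_cohort_csv()]-shaped file and restores column types. The
#' result carries fingerprint `"external"`.
#'
#' @param path CSV file path.
#' @return A `gz_cohort` tibble.
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  df <- readr::read_csv(path, na = c("", "NA"), show_col_types = FALSE)
  violations <- validate_cohort(df)
  if (nrow(violations) > 0) {
    abort(paste0(
      "Cohort CSV fails validation (", nrow(violations), " violation(s)); ",
      "first: row ", violations$row[1], ", column ", violations$column[1],
      ": ", violations$message[1]))
  }
  df$group <- factor(df$group, levels = GROUP_LEVELS)
  df$apoe_e4_carrier <- as.logical(df$apoe_e4_carrier)
  new_cohort(df, fingerprint = "external")
}

#' Validate a cohort CSV against the schema
#'
#' Checks required columns, column types, positivity of concentrations,
#' membership of group labels in the five-level vocabulary, agreement of
#' `ratio` with `ptau217/abeta42`, and uniqueness of `subject_id`.
#'
#' @param path CSV file path.
#' @return Tibble of violations (`row`, `column`, `message`); empty on
#'   success. Row 0 denotes file-level problems.
#' @export
validate_cohort_csv <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  df <- tryCatch(
    readr::read_csv(path, na = c("", "NA"), show_col_types = FALSE),
    error = function(e) abort(paste0("Cannot read ", path, ": ",
                                     conditionMessage(e)))
  )
  validate_cohort(df)
}

validate_cohort <- function(df) {
  v <- list()
  note <- function(row, column, message) {
    v[[length(v) + 1]] <<- tibble::tibble(row = row, column = column,
                                          message = message)
  }
  missing_cols <- setdiff(COHORT_REQUIRED_COLS, names(df))
  for (mc in missing_cols) note(0L, mc, "required column missing")
  if (nrow(df) == 0) note(0L, NA_character_, "cohort has zero rows")
  if (length(missing_cols) > 0 || nrow(df) == 0) {
    return(dplyr::bind_rows(v))
  }

  dup <- which(duplicated(df$subject_id))
  for (r in dup) note(r, "subject_id", "duplicated subject_id")
  bad_group <- which(!df$group %in% GROUP_LEVELS)
  for (r in bad_group) {
    note(r, "group", paste0("unknown group label '", df$group[r], "'"))
  }
  bad_sex <- which(!is.na(df$sex) & !df$sex %in% c("F", "M"))
  for (r in bad_sex) note(r, "sex", "sex must be 'F' or 'M'")
  for (col in c("ptau217", "abeta42", "gfap")) {
    bad <- which(!is.na(df[[col]]) & df[[col]] <= 0)
    for (r in bad) note(r, col, "concentration must be strictly positive")
  }
  for (col in c("age", "education", "centiloid", "ptau217", "abeta42",
                "ratio", "gfap")) {
    if (!is.numeric(df[[col]])) {
      note(0L, col, "column must be numeric")
    } else {
      bad <- which(is.nan(df[[col]]) | is.infinite(df[[col]]))
      for (r in bad) note(r, col, "value must be finite")
    }
  }
  if (is.numeric(df$ratio) && is.numeric(df$ptau217) &&
      is.numeric(df$abeta42)) {
    ok_rows <- !is.na(df$ratio) & !is.na(df$ptau217) & !is.na(df$abeta42) &
      df$abeta42 > 0
    bad <- which(ok_rows &
                   abs(df$ratio - df$ptau217 / df$abeta42) >
                     1e-6 * pmax(1e-12, abs(df$ratio)))
    for (r in bad) note(r, "ratio", "ratio != ptau217/abeta42")
  }
  out <- dplyr::bind_rows(v)
  if (nrow(out) == 0) {
    out <- tibble::tibble(row = integer(), column = character(),
                          message = character())
  }
  out
}

# ---- generator config sidecar (JSON) ---------------------------------------

config_to_list <- function(config) {
  list(
    schema = "greyzone-cohort-config/1",
    group_sizes = as.list(config$group_sizes),
    biomarker_moments = as.data.frame(config$biomarker_moments),
    age_moments = as.data.frame(config$age_moments),
    education_moments = as.data.frame(config$education_moments),
    sex_female_prob = as.list(config$sex_female_prob),
    apoe_carrier_prob = as.list(config$apoe_carrier_prob),
    centiloid_moments = as.data.frame(config$centiloid_moments),
    latent_loadings = as.data.frame(config$latent_loadings),
    severity_offsets = as.list(config$severity_offsets),
    tau_model = list(
      regions = as.data.frame(
        dplyr::mutate(config$tau_model$regions,
                      stage_group = as.character(.data$stage_group))),
      subset_by_stage = as.list(config$tau_model$subset_by_stage)
    ),
    n_missing_centiloid = config$n_missing_centiloid,
    seed = config$seed
  )
}

config_from_list <- function(x) {
  unvec <- function(lst) setNames(unlist(lst), names(lst))
  tau <- structure(
    list(
      regions = dplyr::mutate(
        tibble::as_tibble(x$tau_model$regions),
        stage_group = factor(.data$stage_group, levels = BRAAK_LEVELS)),
      subset_by_stage = vapply(x$tau_model$subset_by_stage, as.integer, 1L)
    ),
    class = "gz_tau_model"
  )
  cohort_config(
    group_sizes = vapply(x$group_sizes, as.integer, 1L),
    biomarker_moments = tibble::as_tibble(x$biomarker_moments),
    age_moments = tibble::as_tibble(x$age_moments),
    education_moments = tibble::as_tibble(x$education_moments),
    sex_female_prob = unvec(x$sex_female_prob),
    apoe_carrier_prob = unvec(x$apoe_carrier_prob),
    centiloid_moments = tibble::as_tibble(x$centiloid_moments),
    latent_loadings = tibble::as_tibble(x$latent_loadings),
    severity_offsets = unvec(x$severity_offsets),
    tau_model = tau,
    n_missing_centiloid = x$n_missing_centiloid,
    seed = x$seed
  )
}

#' Write / read a generator configuration (JSON sidecar)
#'
#' The sidecar stores every generator parameter and the seed under a
#' documented JSON schema (`greyzone-cohort-config/1`), so a simulated
#' cohort CSV can always be regenerated byte-identically.
#'
#' @param config A `gz_config`.
#' @param path JSON file path.
#' @return `write_config_json()` returns `path` invisibly;
#'   `read_config_json()` returns a `gz_config`.
#' @export
write_config_json <- function(config, path) {
  jsonlite::write_json(config_to_list(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_config_json
#' @export
read_config_json <- function(path) {
  config_from_list(jsonlite::read_json(path, simplifyVector = TRUE))
}

# Tab-separated writer with 4-significant-digit numbers (p-values at 3).
write_result_tsv <- function(df, path) {
  out <- df
  for (col in names(out)) {
    if (is.numeric(out[[col]])) {
      out[[col]] <- if (grepl("^p_|p_value|_p$", col)) {
        fmt_p(out[[col]])
      } else {
        fmt_sig(out[[col]])
      }
    }
  }
  readr::write_tsv(out, path, na = "")
  invisible(path)
}
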