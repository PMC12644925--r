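#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy methods for greyzone results
#'
#' `gz_test`, `gz_posthoc`, `gz_metrics`, and `gz_taucor` objects are
#' already tibbles; their `tidy()` methods return them unchanged (class
#' stripped). `tidy.gz_roc` returns the one-row AUC summary and
#' `tidy.gz_cutoffs` the metric table with cutoffs attached;
#' `tidy.gz_ancova` returns the adjusted group means.
#'
#' @param x A greyzone result object.
#' @param ... Unused.
#' @return A tibble.
#' @name greyzone-tidiers
NULL

strip_tbl <- function(x) {
  tibble::as_tibble(unclass(x))
}

#' @rdname greyzone-tidiers
#' @export
tidy.gz_test <- function(x, ...) strip_tbl(x)

#' @rdname greyzone-tidiers
#' @export
tidy.gz_posthoc <- function(x, ...) strip_tbl(x)

#' @rdname greyzone-tidiers
#' @export
tidy.gz_metrics <- function(x, ...) strip_tbl(x)

#' @rdname greyzone-tidiers
#' @export
tidy.gz_taucor <- function(x, ...) strip_tbl(x)

#' @rdname greyzone-tidiers
#' @export
tidy.gz_roc <- function(x, ...) {
  tibble::tibble(
    marker = x$marker,
    stratum = x$stratum %||% "all",
    auc = x$auc, ci_low = x$ci_low, ci_high = x$ci_high,
    n_pos = x$n_pos, n_neg = x$n_neg, score_spec = x$score_spec
  )
}

#' @rdname greyzone-tidiers
#' @export
glance.gz_roc <- function(x, ...) tidy.gz_roc(x)

#' @rdname greyzone-tidiers
#' @export
tidy.gz_cutoffs <- function(x, ...) {
  out <- strip_tbl(x$metrics)
  out$marker <- x$marker
  out$lower <- x$lower
  out$upper <- x$upper
  dplyr::relocate(out, "marker")
}

#' @rdname greyzone-tidiers
#' @export
glance.gz_cutoffs <- function(x, ...) {
  mv <- setNames(x$metrics$value, x$metrics$metric)
  tibble::tibble(
    marker = x$marker, n = x$n, lower = x$lower, upper = x$upper,
    feasible = x$feasible, n_violated = x$n_violated,
    intermediate_fraction = mv[["intermediate_fraction"]],
    ppv = mv[["ppv"]], npv = mv[["npv"]],
    plr = mv[["plr"]], nlr = mv[["nlr"]],
    infeasible_replicates = if (!is.null(x$bootstrap))
      x$bootstrap$infeasible_fraction else NA_real_
  )
}

#' @rdname greyzone-tidiers
#' @export
tidy.gz_ancova <- function(x, ...) x$adjusted_means

#' @rdname greyzone-tidiers
#' @export
glance.gz_ancova <- function(x, ...) strip_tbl(x$test)

# ---- plots -----------------------------------------------------------------

#' Plot methods
#'
#' `autoplot.gz_roc` draws the ROC curve with the AUC in the subtitle;
#' `autoplot.gz_cutoffs` shows the score distribution per reference class
#' with the two cutoffs and the shaded intermediate zone;
#' `autoplot.gz_taucor` renders the Braak-stratified correlation heatmap
#' with significance asterisks.
#'
#' @param object A greyzone result object.
#' @param data For `autoplot.gz_cutoffs`: the cohort the cutoffs were
#'   derived from.
#' @param cl_threshold Centiloid threshold used to colour the reference
#'   classes.
#' @param ... Unused.
#' @return A ggplot object.
#' @name greyzone-plots
NULL

#' @rdname greyzone-plots
#' @export
autoplot.gz_roc <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.7, colour = "#2c7fb8") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = object$score_spec,
      subtitle = sprintf("AUC %.3f (95%% CI %.3f-%.3f)",
                         object$auc, object$ci_low, object$ci_high)) +
    ggplot2::theme_minimal()
}

#' @rdname greyzone-plots
#' @export
autoplot.gz_cutoffs <- function(object, data, cl_threshold = 20, ...) {
  df <- tibble::tibble(
    value = data[[object$marker]],
    status = ifelse(data$centiloid > cl_threshold,
                    "amyloid-positive", "amyloid-negative")
  )
  df <- df[complete.cases(df), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value, fill = .data$status)) +
    ggplot2::annotate("rect", xmin = object$lower, xmax = object$upper,
                      ymin = -Inf, ymax = Inf, alpha = 0.15,
                      fill = "grey40") +
    ggplot2::geom_density(alpha = 0.5, colour = NA) +
    ggplot2::geom_vline(xintercept = c(object$lower, object$upper),
                        linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = object$marker, y = "density", fill = NULL,
                  title = sprintf(
                    "Dual cutoffs %.4g / %.4g (intermediate zone shaded)",
                    object$lower, object$upper)) +
    ggplot2::theme_minimal()
}

#' @rdname greyzone-plots
#' @export
autoplot.gz_taucor <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$region, y = .data$marker,
                               fill = .data$r)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::geom_text(
      ggplot2::aes(label = ifelse(.data$tier == "ns" | is.na(.data$tier),
                                  "", .data$tier)),
      size = 3) +
    ggplot2::facet_grid(~stage_group, scales = "free_x",
                        space = "free_x") +
    ggplot2::scale_fill_gradient2(low = "#313695", mid = "white",
                                  high = "#a50026", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "partial r",
                  title = paste0("Biomarker-tau partial correlations (",
                                 attr(object, "stratum") %||% "all", ")")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
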