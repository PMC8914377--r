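#' Tidy and summarize an analysis bundle
#'
#' `tidy()` returns one of the bundle's result tables as a tibble;
#' `glance()` gives a one-row summary. The `"time_effects"` table is shaped
#' like a significant-time-effects report (condition x region x
#' minute with z, p, d); `"interaction"` like the correlation report
#' (rho with moderate/strong class).
#'
#' @param x an `msfme_analysis` from [run_study_analysis()].
#' @param table which result table to return.
#' @param ... unused.
#' @return A tibble.
#' @export
tidy.msfme_analysis <- function(x, table = c("time_effects", "interaction",
                                             "condition_effects",
                                             "trajectories",
                                             "condition_medians",
                                             "scale_selection"), ...) {
  table <- match.arg(table)
  out <- x[[table]]
  if (table == "condition_effects" && nrow(out))
    out <- dplyr::select(out, -"posthoc")
  if (table == "scale_selection" && nrow(out))
    out <- dplyr::select(out, -"profile")
  tibble::as_tibble(out)
}

#' @rdname tidy.msfme_analysis
#' @export
glance.msfme_analysis <- function(x, ...) {
  tibble::tibble(
    n_subjects = nrow(x$subjects),
    n_conditions = dplyr::n_distinct(x$subjects$condition),
    n_regions = dplyr::n_distinct(x$trajectories$region),
    n_minutes = dplyr::n_distinct(x$trajectories$minute),
    scale_max = x$config$params$scale_max,
    n_significant_time = sum(x$time_effects$significant),
    n_moderate_plus = sum(x$interaction$class != "negligible"))
}

#' @export
tidy.stat_result <- function(x, ...) tibble::as_tibble(x)

#' @export
tidy.kw_result <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(tibble::as_tibble(x$omnibus), term = "omnibus",
                  p_adj = NA_real_),
    if (nrow(x$posthoc))
      dplyr::transmute(x$posthoc,
                       statistic_kind = "pairwise_rank",
                       statistic = .data$statistic, p = .data$p_raw,
                       d = NA_real_, n = NA_integer_,
                       comparison = paste(.data$group1, "vs", .data$group2),
                       term = "posthoc", p_adj = .data$p_adj))
}

#' @export
tidy.scale_selection <- function(x, ...) {
  dplyr::mutate(x$profile, selected = .data$scale == x$selected_scale)
}

#' Significant-time-effects and interaction reports
#'
#' Convenience accessors shaping the analysis output into the two standard
#' report layouts: `report_time_effects()` (condition x region x minute
#' with z, p, Cohen's d; optionally only cells at or below `alpha`) and
#' `report_interaction()` (Spearman rho with class; optionally only at
#' least moderate cells).
#'
#' @param x an `msfme_analysis`.
#' @param significant_only,moderate_only filter to the conventionally
#'   reported cells.
#' @return A tibble.
#' @export
report_time_effects <- function(x, significant_only = FALSE) {
  out <- x$time_effects
  if (significant_only) out <- dplyr::filter(out, .data$significant)
  dplyr::arrange(out, .data$condition, .data$region, .data$minute)
}

#' @rdname report_time_effects
#' @export
report_interaction <- function(x, moderate_only = FALSE) {
  out <- x$interaction
  if (moderate_only) out <- dplyr::filter(out, .data$class != "negligible")
  dplyr::arrange(out, .data$condition, .data$region, .data$minute)
}

#' Trajectory plot of baseline-normalized entropy
#'
#' Per-condition median Delta% MSFME trajectories over post-rest minutes at
#' a given scale, faceted by region.
#'
#' @param x an `msfme_analysis`.
#' @param scale scale factor to display (default: smallest present).
#' @return a ggplot object.
#' @export
plot_trajectories <- function(x, scale = NULL) {
  med <- x$condition_medians
  if (is.null(scale)) scale <- min(med$scale)
  med <- med[med$scale == scale, ]
  ggplot2::ggplot(med, ggplot2::aes(x = .data$minute, y = .data$delta_pct,
                                    colour = .data$condition)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~region) +
    ggplot2::labs(x = "post-rest minute", y = "Δ% MSFME (of baseline)",
                  colour = "condition",
                  title = sprintf("scale τ = %d", scale)) +
    ggplot2::theme_minimal()
}
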