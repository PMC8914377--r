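#' Heterogeneity of condition medians
#'
#' Sum of absolute differences over all unordered pairs of per-condition
#' median values at one scale: with medians `x_1..x_K`,
#' `H = sum_{a<b} |x_a - x_b|` over the `choose(K, 2)` pairs. Invariant to
#' condition order and to adding a constant; scales linearly with the
#' medians.
#'
#' @param medians numeric vector of per-condition median Delta% values at
#'   one scale (length >= 2).
#' @return non-negative scalar H.
#' @examples
#' heterogeneity(c(0, 1, 2, 3))  # 10
#' @export
heterogeneity <- function(medians) {
  if (length(medians) < 2L) abort("need >= 2 conditions.")
  sum(stats::dist(matrix(medians, ncol = 1), method = "manhattan"))
}

#' Heterogeneity profile and scale selection
#'
#' The condition-independent scale selector: for each scale factor, compute
#' the heterogeneity of the condition-median baseline-normalized values
#' (Delta% MSFME), then select the scale maximizing it. Ties break toward
#' the smallest scale, which retains the most coarse-grained samples.
#' Selection runs separately per post-rest minute and region, and separately
#' for EEG and ECG; this function handles one such cell.
#'
#' @param medians a data frame with columns `condition`, `scale`, and a
#'   median Delta% column (`delta_pct` by default).
#' @param value_col name of the median column.
#' @return An object of class `scale_selection`: a list with
#'   `selected_scale` and `profile` (tibble `scale`, `H`).
#' @examples
#' tbl <- tidyr::expand_grid(condition = c("A", "B", "C"), scale = 1:5)
#' tbl$delta_pct <- seq_len(nrow(tbl))
#' select_scale(tbl)
#' @export
select_scale <- function(medians, value_col = "delta_pct") {
  medians <- tibble::as_tibble(medians)
  if (!all(c("condition", "scale", value_col) %in% names(medians)))
    abort(sprintf("`medians` needs columns condition, scale, %s.", value_col))
  conds <- unique(medians$condition)
  if (length(conds) < 2L) abort("need >= 2 conditions.")
  scales <- sort(unique(medians$scale))
  counts <- table(medians$scale)
  if (any(counts != length(conds)))
    abort("every scale must carry a median for every condition.")
  profile <- medians |>
    dplyr::group_by(.data$scale) |>
    dplyr::summarise(H = heterogeneity(.data[[value_col]]), .groups = "drop") |>
    dplyr::arrange(.data$scale)
  sel <- profile$scale[which.max(profile$H)]  # which.max = first max: smallest scale
  structure(list(selected_scale = sel, profile = profile),
            class = "scale_selection")
}

#' @export
print.scale_selection <- function(x, ...) {
  cat(sprintf("<scale_selection> selected scale %d (H = %.4g) of %d scales\n",
              x$selected_scale,
              x$profile$H[x$profile$scale == x$selected_scale],
              nrow(x$profile)))
  invisible(x)
}

#' @rdname select_scale
#' @param object,... passed through from the generic.
#' @export
autoplot.scale_selection <- function(object, ...) {
  ggplot2::ggplot(object$profile, ggplot2::aes(x = .data$scale, y = .data$H)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$selected_scale, linetype = 2) +
    ggplot2::labs(x = "scale factor τ",
                  y = "heterogeneity H (sum of pairwise |Δ| of condition medians)") +
    ggplot2::theme_minimal()
}
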