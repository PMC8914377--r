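#' Wilcoxon signed-rank test via the normal approximation
#'
#' Paired test of differences against zero with the conventions that
#' fix its reported z statistic exactly: zero differences are
#' excluded, ranks of the absolute differences use average ranks for ties,
#' `W` is the positive-rank sum, and
#' `z = (W - n(n+1)/4) / sqrt(n(n+1)(2n+1)/24)` with **no** continuity
#' correction. The reported z therefore carries the direction of change
#' (negative when decreases dominate). The two-sided p comes from the
#' normal; Cohen's d is attached via [cohens_d_from_z()] when `|z| < sqrt(n)`.
#'
#' For example, n = 7 all-positive distinct differences give
#' `z = 14 / sqrt(35) = 2.366`; n = 8 with only the smallest-magnitude
#' difference negative gives `z = 17 / sqrt(51) = 2.380`.
#'
#' @param differences numeric vector of paired differences (post minus
#'   baseline); at least 5 non-zero values required.
#' @param comparison optional label describing the comparison.
#' @return An object of class `stat_result`: a one-row tibble with
#'   `statistic_kind`, `statistic` (z), `p`, `d`, `n`, `comparison`.
#' @examples
#' wilcoxon_signed_rank_z(c(1, 2, 3, 4, 5, 6, 7))
#' @export
wilcoxon_signed_rank_z <- function(differences, comparison = NA_character_) {
  d <- differences[differences != 0]
  if (length(d) < 5L)
    abort(sprintf("need >= 5 non-zero differences (have %d).", length(d)))
  n <- length(d)
  rk <- rank(abs(d))
  W <- sum(rk[d > 0])
  mu <- n * (n + 1) / 4
  sdW <- sqrt(n * (n + 1) * (2 * n + 1) / 24)
  z <- (W - mu) / sdW
  p <- 2 * pnorm(-abs(z))
  dd <- if (abs(z) < sqrt(n)) cohens_d_from_z(z, n) else NA_real_
  tibble::new_tibble(
    tibble::tibble(statistic_kind = "wilcoxon_z", statistic = z,
                   p = min(p, 1), d = dd, n = n, comparison = comparison),
    class = "stat_result")
}

#' Cohen's d from a paired-test z statistic
#'
#' The rank-biserial chain `r` = z / sqrt(n) (n = number of pairs), then
#' `d = 2 r / sqrt(1 - r^2)`, reported as a magnitude (the test's direction
#' travels on the sign of z). Requires `|z| < sqrt(n)` so that `|r| < 1`.
#'
#' @param z the signed-rank z statistic.
#' @param n number of pairs.
#' @return Cohen's d (non-negative magnitude).
#' @examples
#' cohens_d_from_z(2.366, 7)  # ~3.996
#' cohens_d_from_z(2.1, 8)    # ~2.217
#' @export
cohens_d_from_z <- function(z, n) {
  if (any(abs(z) >= sqrt(n)))
    abort("|z| must be < sqrt(n) so that r = z/sqrt(n) stays in (-1, 1).")
  r <- abs(z) / sqrt(n)
  2 * r / sqrt(1 - r^2)
}

#' Kruskal-Wallis condition test with Bonferroni post hoc
#'
#' Standard rank-based H with tie correction (via [stats::kruskal.test()]).
#' When the omnibus p is at or below `alpha`, all pairwise two-sample rank
#' comparisons are run and their p-values Bonferroni-adjusted (multiplied by
#' the number of pairs, capped at 1).
#'
#' @param values numeric outcome vector.
#' @param groups group labels, same length; >= 2 groups of >= 2 values.
#' @param alpha omnibus gate for running the post hoc (default 0.05).
#' @param comparison optional label.
#' @return A list of class `kw_result`: `omnibus` (one-row `stat_result`
#'   tibble with the H statistic) and `posthoc` (tibble of pairwise
#'   comparisons with `p_raw`, `p_adj`; empty when the gate fails).
#' @examples
#' kruskal_wallis_bonferroni(c(1, 2, 3, 4, 5, 6, 7, 8, 9),
#'                           rep(c("a", "b", "c"), each = 3))
#' @export
kruskal_wallis_bonferroni <- function(values, groups, alpha = 0.05,
                                      comparison = NA_character_) {
  groups <- as.factor(groups)
  if (nlevels(groups) < 2L) abort("need >= 2 groups.")
  if (any(table(groups) < 2L)) abort("every group needs >= 2 values.")
  kt <- kruskal.test(values, groups)
  omnibus <- tibble::new_tibble(
    tibble::tibble(statistic_kind = "kruskal_H",
                   statistic = unname(kt$statistic),
                   p = kt$p.value, d = NA_real_,
                   n = length(values), comparison = comparison),
    class = "stat_result")
  lv <- levels(groups)
  pairs <- utils::combn(lv, 2, simplify = FALSE)
  posthoc <- if (kt$p.value <= alpha) {
    purrr::map_dfr(pairs, function(pr) {
      wt <- suppressWarnings(
        wilcox.test(values[groups == pr[1]], values[groups == pr[2]],
                    exact = FALSE, correct = FALSE))
      tibble::tibble(group1 = pr[1], group2 = pr[2],
                     statistic = unname(wt$statistic), p_raw = wt$p.value)
    }) |>
      dplyr::mutate(p_adj = pmin(1, .data$p_raw * length(pairs)))
  } else {
    tibble::tibble(group1 = character(), group2 = character(),
                   statistic = numeric(), p_raw = numeric(),
                   p_adj = numeric())
  }
  structure(list(omnibus = omnibus, posthoc = posthoc), class = "kw_result")
}

#' @export
print.kw_result <- function(x, ...) {
  cat(sprintf("<kw_result> H = %.4g, p = %.4g; %d post-hoc pair(s)\n",
              x$omnibus$statistic, x$omnibus$p, nrow(x$posthoc)))
  invisible(x)
}

#' Classify a Spearman coefficient
#'
#' `strong` when `|rho| >= 0.5`, `moderate` when `0.3 <= |rho| < 0.5`,
#' `negligible` otherwise. The magnitude rule is symmetric in sign.
#'
#' @param rho Spearman coefficient(s).
#' @param thresholds `c(moderate, strong)` magnitude cut points.
#' @return character vector of classes.
#' @examples
#' classify_correlation(c(0.45, -0.543, 0.1))
#' @export
classify_correlation <- function(rho, thresholds = c(moderate = 0.3,
                                                     strong = 0.5)) {
  dplyr::case_when(
    abs(rho) >= thresholds[["strong"]] ~ "strong",
    abs(rho) >= thresholds[["moderate"]] ~ "moderate",
    TRUE ~ "negligible")
}

#' Spearman interaction between EEG and ECG entropy series
#'
#' Rank correlation (average ranks for ties) between paired 10-s entropy
#' values of an EEG region at its selected scale and the ECG at its own
#' selected scale, pooled across a condition's subjects within one
#' post-rest minute.
#'
#' @param eeg_entropy,ecg_entropy paired numeric vectors of equal length
#'   >= 6.
#' @param thresholds passed to [classify_correlation()].
#' @param comparison optional label.
#' @return A one-row `stat_result` tibble with `statistic_kind =
#'   "spearman_rho"`, plus columns `class`.
#' @export
spearman_interaction <- function(eeg_entropy, ecg_entropy,
                                 thresholds = c(moderate = 0.3, strong = 0.5),
                                 comparison = NA_character_) {
  if (length(eeg_entropy) != length(ecg_entropy))
    abort("paired vectors must have equal length.")
  if (length(eeg_entropy) < 6L) abort("need >= 6 pairs.")
  rho <- cor(eeg_entropy, ecg_entropy, method = "spearman")
  p <- suppressWarnings(
    cor.test(eeg_entropy, ecg_entropy, method = "spearman",
             exact = FALSE)$p.value)
  out <- tibble::tibble(statistic_kind = "spearman_rho", statistic = rho,
                        p = p, d = NA_real_, n = length(eeg_entropy),
                        comparison = comparison,
                        class = classify_correlation(rho, thresholds))
  tibble::new_tibble(out, class = "stat_result")
}
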