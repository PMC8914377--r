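#' Z-transform a series (population SD convention)
#'
#' Centers to mean 0 and scales to SD 1 using the population SD (divisor N).
#' Entropy downstream is invariant to the divisor convention by affine
#' invariance; the population form is fixed so that identical inputs always
#' give bit-identical pipelines.
#'
#' @param x numeric vector, length >= 2, non-constant.
#' @return numeric vector with mean 0 and population SD 1.
#' @examples
#' zscore_series(c(1, 2, 3))
#' @export
zscore_series <- function(x) {
  if (length(x) < 2L) abort("series must have length >= 2.")
  mu <- mean(x)
  s <- sqrt(mean((x - mu)^2))
  if (s == 0) abort("degenerate interval: constant series has no z-transform.")
  (x - mu) / s
}

#' Coarse-grain a series at scale factor tau
#'
#' Replaces each block of `tau` consecutive samples by its mean, producing
#' `floor(N / tau)` points; the trailing remainder is discarded. `tau = 1`
#' is the identity.
#'
#' @param x numeric vector.
#' @param tau integer scale factor >= 1.
#' @param min_len minimum acceptable output length (default 1; [msfme()]
#'   passes `m + 2` so entropy stays computable downstream).
#' @return numeric vector of length `floor(length(x) / tau)`.
#' @examples
#' coarse_grain(c(1, 2, 3, 4), 2)  # 1.5 3.5
#' @export
coarse_grain <- function(x, tau, min_len = 1L) {
  tau <- as.integer(tau)
  if (tau < 1L) abort("`tau` must be >= 1.")
  n_out <- length(x) %/% tau
  if (n_out < min_len)
    abort(sprintf(
      "series too short to coarse-grain: %d samples give %d points at scale %d (need >= %d, i.e. %d samples)",
      length(x), n_out, tau, min_len, min_len * tau))
  if (tau == 1L) return(x)
  colMeans(matrix(x[seq_len(n_out * tau)], nrow = tau))
}

#' Exponential fuzzy membership of a distance
#'
#' Similarity score in (0, 1] for a non-negative Chebyshev distance `d`:
#' `exp(-d^n / r)` under `"exp_pow_over_r"` (default convention) or
#' `exp(-(d / r)^n)` under `"exp_ratio_pow"`. Strictly decreasing in `d`,
#' equal to 1 at `d = 0`.
#'
#' @param d numeric vector of distances, all >= 0.
#' @param r similarity threshold > 0.
#' @param n fuzzy weight > 0.
#' @param form membership convention, see [entropy_params()].
#' @return numeric vector of similarities in (0, 1].
#' @examples
#' fuzzy_membership(0.387, r = 0.15, n = 2)  # ~0.368
#' @export
fuzzy_membership <- function(d, r = 0.15, n = 2,
                             form = c("exp_pow_over_r", "exp_ratio_pow")) {
  form <- match.arg(form)
  if (any(d < 0)) abort("distances must be >= 0.")
  if (form == "exp_pow_over_r") exp(-d^n / r) else exp(-(d / r)^n)
}

#' Fuzzy measure entropy of a series
#'
#' Entropy estimator combining a *local* similarity branch (each embedding
#' vector minus its own mean) and a *global* branch (each vector minus the
#' whole-series mean). For window lengths `m` and `m + 1`, mean fuzzy
#' similarities `phiL` and `phiG` are taken over all pairs `i != j`
#' (self-matches excluded) of Chebyshev distances scored by
#' [fuzzy_membership()], and the entropy is
#' `ln(phiL_m / phiL_{m+1}) + ln(phiG_m / phiG_{m+1})` (nats).
#'
#' A constant series has all distances 0 and all similarities 1; it returns
#' entropy 0 carrying a `degenerate` attribute rather than failing, so that
#' tables over many intervals can flag rather than abort.
#'
#' @param x numeric series, length >= `m + 2`; z-transform upstream (the
#'   thresholds are expressed in SD units).
#' @param params an [entropy_params()] object.
#' @return entropy in nats (a non-negative scalar for non-degenerate input),
#'   with attribute `degenerate = TRUE` when the series is constant.
#' @examples
#' set.seed(1)
#' fuzzy_measure_entropy(zscore_series(rnorm(200)))
#' @export
fuzzy_measure_entropy <- function(x, params = entropy_params()) {
  stopifnot(inherits(params, "entropy_params"))
  if (length(x) < params$m + 2L)
    abort(sprintf("series length %d < m + 2 = %d.", length(x), params$m + 2L))
  if (max(x) == min(x)) {
    return(structure(0, degenerate = TRUE))
  }
  .fme_cpp(as.numeric(x), params$m,
           params$r_local, params$n_local,
           params$r_global, params$n_global,
           membership_code(params$membership_form))
}

#' Multiscale fuzzy measure entropy curve
#'
#' Evaluates [fuzzy_measure_entropy()] on coarse-grained versions of the
#' series for every scale factor in `scale_min:scale_max`. Thresholds are not
#' rescaled per scale. The series should be one z-transformed analysis
#' interval (for the canonical 10-s interval at 256 Hz: 2,560 samples at
#' scale 1, 128 at scale 20).
#'
#' @param x numeric series (one z-transformed interval).
#' @param params an [entropy_params()] object.
#' @return A tibble of class `msfme_curve` with columns `scale`, `n_samples`
#'   (`floor(N / scale)`), and `entropy` (nats).
#' @examples
#' set.seed(1)
#' msfme(zscore_series(rnorm(512)), entropy_params(scale_max = 4))
#' @export
msfme <- function(x, params = entropy_params()) {
  stopifnot(inherits(params, "entropy_params"))
  scales <- params$scale_min:params$scale_max
  need <- params$scale_max * (params$m + 2L)
  if (length(x) < need)
    abort(sprintf("series length %d cannot support scale %d (need >= %d).",
                  length(x), params$scale_max, need))
  out <- purrr::map_dbl(scales, function(tau) {
    cg <- tryCatch(coarse_grain(x, tau, min_len = params$m + 2L),
                   error = function(e) abort(
                     sprintf("scale %d: %s", tau, conditionMessage(e))))
    tryCatch(as.numeric(fuzzy_measure_entropy(cg, params)),
             error = function(e) abort(
               sprintf("scale %d: %s", tau, conditionMessage(e))))
  })
  tibble::new_tibble(
    tibble::tibble(scale = scales,
                   n_samples = length(x) %/% scales,
                   entropy = out),
    class = "msfme_curve")
}

#' @rdname msfme
#' @param object,... passed through from the generic.
#' @export
autoplot.msfme_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$scale, y = .data$entropy)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "scale factor τ", y = "MSFME (nats)") +
    ggplot2::theme_minimal()
}
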