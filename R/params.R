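#' Entropy parameter set
#'
#' Bundles every tunable of the fuzzy measure entropy and its multiscale
#' extension. The defaults are the analysis conventions used throughout the
#' package: embedding dimension `m = 2`, a single similarity threshold
#' `r` of 0.15 (in SD units of the z-transformed interval) applied to both the
#' local and the global similarity branch, fuzzy weight `n = 2` on both
#' branches, and scale factors 1 through 20.
#'
#' Two exponential membership conventions are supported. The default
#' `"exp_pow_over_r"` scores a Chebyshev distance `d` as `exp(-d^n / r)`;
#' the alternative `"exp_ratio_pow"` uses `exp(-(d / r)^n)`. Both are strictly
#' decreasing in `d` and equal 1 at `d = 0`. Thresholds are *not* rescaled per
#' coarse-graining scale: the multiscale curve applies one fixed `r` to every
#' scale, the usual multiscale-entropy convention.
#'
#' @param m embedding dimension (window length of template vectors), >= 1.
#' @param r_local,r_global similarity thresholds for the local (own-mean
#'   removed) and global (series-mean removed) branches, > 0.
#' @param n_local,n_global fuzzy similarity weights, > 0.
#' @param membership_form `"exp_pow_over_r"` or `"exp_ratio_pow"`.
#' @param scale_min,scale_max inclusive bounds of the coarse-graining scale
#'   factor range, `1 <= scale_min <= scale_max`.
#'
#' @return An object of class `entropy_params` (a named list).
#' @examples
#' entropy_params()
#' entropy_params(scale_max = 5)
#' @export
entropy_params <- function(m = 2L,
                           r_local = 0.15, r_global = 0.15,
                           n_local = 2, n_global = 2,
                           membership_form = c("exp_pow_over_r",
                                               "exp_ratio_pow"),
                           scale_min = 1L, scale_max = 20L) {
  membership_form <- match.arg(membership_form)
  m <- as.integer(m)
  scale_min <- as.integer(scale_min)
  scale_max <- as.integer(scale_max)
  if (m < 1L) abort("`m` must be >= 1.")
  if (r_local <= 0 || r_global <= 0) abort("thresholds must be > 0.")
  if (n_local <= 0 || n_global <= 0) abort("fuzzy weights must be > 0.")
  if (scale_min < 1L || scale_min > scale_max)
    abort("need 1 <= scale_min <= scale_max.")
  structure(
    list(m = m, r_local = r_local, r_global = r_global,
         n_local = n_local, n_global = n_global,
         membership_form = membership_form,
         scale_min = scale_min, scale_max = scale_max),
    class = "entropy_params")
}

#' @export
print.entropy_params <- function(x, ...) {
  cat("<entropy_params>\n")
  cat(sprintf("  m = %d, r = (%g local, %g global), n = (%g, %g)\n",
              x$m, x$r_local, x$r_global, x$n_local, x$n_global))
  cat(sprintf("  membership = %s, scales %d:%d\n",
              x$membership_form, x$scale_min, x$scale_max))
  invisible(x)
}

membership_code <- function(form) {
  switch(form, exp_pow_over_r = 1L, exp_ratio_pow = 2L,
         abort("unknown membership form"))
}
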