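# Brute-force reference implementations, independent of the package's
# kernels: plain double loops, no vectorization of the pairwise step.

fme_oracle <- function(x, m = 2, r_local = 0.15, n_local = 2,
                       r_global = 0.15, n_global = 2,
                       form = c("exp_pow_over_r", "exp_ratio_pow")) {
  form <- match.arg(form)
  mu <- function(d, r, n)
    if (form == "exp_pow_over_r") exp(-d^n / r) else exp(-(d / r)^n)
  N <- length(x)
  gmean <- mean(x)
  nv <- N - m
  sLm <- sLm1 <- sGm <- sGm1 <- 0
  cnt <- 0
  for (i in seq_len(nv)) {
    for (j in seq_len(nv)) {
      if (i == j) next
      ui <- x[i:(i + m - 1)]; uj <- x[j:(j + m - 1)]
      vi <- x[i:(i + m)]; vj <- x[j:(j + m)]
      sLm <- sLm + mu(max(abs((ui - mean(ui)) - (uj - mean(uj)))),
                      r_local, n_local)
      sLm1 <- sLm1 + mu(max(abs((vi - mean(vi)) - (vj - mean(vj)))),
                        r_local, n_local)
      sGm <- sGm + mu(max(abs((ui - gmean) - (uj - gmean))),
                      r_global, n_global)
      sGm1 <- sGm1 + mu(max(abs((vi - gmean) - (vj - gmean))),
                        r_global, n_global)
      cnt <- cnt + 1
    }
  }
  log((sLm / cnt) / (sLm1 / cnt)) + log((sGm / cnt) / (sGm1 / cnt))
}

# exhaustive argmax-of-heterogeneity over a condition x scale median table
select_scale_oracle <- function(tbl) {
  scales <- sort(unique(tbl$scale))
  best_scale <- NA_integer_
  best_h <- -Inf
  for (s in scales) {
    v <- tbl$delta_pct[tbl$scale == s]
    h <- 0
    for (a in seq_along(v)) {
      for (b in seq_along(v)) {
        if (a < b) h <- h + abs(v[a] - v[b])
      }
    }
    if (h > best_h + 1e-12) {  # strict improvement: ties keep smaller scale
      best_h <- h
      best_scale <- s
    }
  }
  best_scale
}

# small single-condition synthetic study for pipeline-level tests
tiny_study <- function(n_subjects = 8, deltas = NULL, rho = 0, seed = 1,
                       fs = 64, pre_minutes = 1, post_minutes = 1) {
  eff <- study_effect_spec(conditions = "DL0",
                          n_subjects_per_condition = n_subjects,
                          lobe_entropy_deltas = deltas,
                          coupling_rho = rho, fs = fs)
  simulate_study(eff, pre_minutes = pre_minutes,
                 post_minutes = post_minutes, seed = seed)
}
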