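test_that("zscore_series standardizes, is idempotent and affine invariant", {
  z <- zscore_series(c(1, 2, 3))
  expect_equal(mean(z), 0)
  expect_equal(sqrt(mean(z^2)), 1)
  expect_equal(zscore_series(z), z, tolerance = 1e-12)
  set.seed(11)
  x <- rnorm(100)
  expect_equal(zscore_series(3.7 * x + 2), zscore_series(x),
               tolerance = 1e-12)
  expect_error(zscore_series(rep(2, 10)), "degenerate")
  expect_error(zscore_series(1), "length")
})

test_that("coarse_grain averages blocks and follows the floor rule", {
  expect_equal(coarse_grain(c(1, 2, 3, 4), 2), c(1.5, 3.5))
  expect_identical(coarse_grain(1:10 * 1.0, 1), 1:10 * 1.0)
  expect_length(coarse_grain(rnorm(2560), 20), 128)
  for (tau in c(1, 3, 7, 20)) {
    expect_length(coarse_grain(rnorm(513), tau), 513 %/% tau)
  }
  expect_error(coarse_grain(rnorm(10), 5, min_len = 4), "too short")
})

test_that("fuzzy_membership follows both exponential conventions", {
  expect_equal(fuzzy_membership(0, 0.15, 2), 1)
  expect_equal(fuzzy_membership(0.387, 0.15, 2), exp(-0.387^2 / 0.15),
               tolerance = 1e-12)
  expect_equal(fuzzy_membership(0.3, 0.15, 2, form = "exp_ratio_pow"),
               exp(-(0.3 / 0.15)^2), tolerance = 1e-12)
  d <- seq(0, 2, by = 0.05)
  for (form in c("exp_pow_over_r", "exp_ratio_pow")) {
    mu <- fuzzy_membership(d, 0.15, 2, form = form)
    expect_true(all(diff(mu) < 0))
    expect_true(all(mu > 0 & mu <= 1))
  }
  expect_error(fuzzy_membership(-0.1), ">= 0")
})

test_that("fuzzy_measure_entropy matches the brute-force oracle", {
  set.seed(101)
  cases <- data.frame(
    n = sample(50:250, 12, replace = TRUE),
    m = sample(1:3, 12, replace = TRUE),
    form = sample(c("exp_pow_over_r", "exp_ratio_pow"), 12, replace = TRUE))
  for (k in seq_len(nrow(cases))) {
    x <- zscore_series(rnorm(cases$n[k]))
    p <- entropy_params(m = cases$m[k], membership_form = cases$form[k])
    got <- fuzzy_measure_entropy(x, p)
    want <- fme_oracle(x, m = cases$m[k], form = cases$form[k])
    expect_equal(as.numeric(got), want, tolerance = 1e-12)
    expect_gte(as.numeric(got), 0)
  }
})

test_that("entropy is exactly invariant to affine input transforms", {
  set.seed(7)
  for (i in 1:5) {
    x <- rnorm(300)
    a <- rexp(1) + 0.1
    b <- rnorm(1)
    expect_equal(as.numeric(fuzzy_measure_entropy(zscore_series(a * x + b))),
                 as.numeric(fuzzy_measure_entropy(zscore_series(x))),
                 tolerance = 1e-12)
  }
})

test_that("constant series yields entropy 0 with a degeneracy flag", {
  v <- fuzzy_measure_entropy(rep(1, 50))
  expect_identical(as.numeric(v), 0)
  expect_true(attr(v, "degenerate"))
})

test_that("white noise is more irregular than a sinusoid", {
  p <- entropy_params()
  t <- seq_len(2560)
  for (seed in 1:10) {
    set.seed(seed)
    noise <- fuzzy_measure_entropy(zscore_series(rnorm(2560)), p)
    sine <- fuzzy_measure_entropy(
      zscore_series(sin(2 * pi * 7 * t / 2560 + runif(1, 0, 2 * pi))), p)
    expect_gt(noise, sine)
  }
})

test_that("msfme curve obeys the sample-count law and scale_max = 1 case", {
  set.seed(5)
  x <- zscore_series(rnorm(400))
  cur <- msfme(x, entropy_params(scale_max = 8))
  expect_s3_class(cur, "msfme_curve")
  expect_equal(cur$scale, 1:8)
  expect_equal(cur$n_samples, 400 %/% (1:8))
  one <- msfme(x, entropy_params(scale_max = 1))
  expect_equal(nrow(one), 1L)
  expect_equal(one$entropy, as.numeric(fuzzy_measure_entropy(x)))
  expect_error(msfme(rnorm(30), entropy_params(scale_max = 20)), "support")
})

test_that("multiscale signature: white noise decays more than 1/f noise", {
  p <- entropy_params()
  drops <- vapply(1:10, function(seed) {
    white <- zscore_series(colored_noise(2560, beta = 0, seed = seed))
    pink <- zscore_series(colored_noise(2560, beta = 1, seed = seed + 500))
    cw <- msfme(white, p)
    cp <- msfme(pink, p)
    c(white = cw$entropy[1] - cw$entropy[20],
      pink = cp$entropy[1] - cp$entropy[20])
  }, c(white = 0, pink = 0))
  # white-noise curve decreases from scale 1 to 20 in >= 9/10 replicates
  expect_gte(sum(drops["white", ] > 0), 9)
  # and its decrease exceeds the 1/f decrease on the replicate median
  expect_gt(median(drops["white", ] - drops["pink", ]), 0)
})
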