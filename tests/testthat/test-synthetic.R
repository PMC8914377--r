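fme1 <- function(x) as.numeric(fuzzy_measure_entropy(zscore_series(x)))

test_that("synthetic EEG produces the 19-electrode montage deterministically", {
  eff <- study_effect_spec(fs = 64)
  rec <- generate_synthetic_eeg(eff, "S01", "DL0", "pre", duration_s = 20,
                                seed = 5)
  expect_identical(rec$channels,
                   c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "T3", "C3",
                     "Cz", "C4", "T4", "T5", "P3", "Pz", "P4", "T6", "O1",
                     "O2"))
  expect_equal(dim(rec$signals), c(19L, 20L * 64L))
  rec2 <- generate_synthetic_eeg(eff, "S01", "DL0", "pre", duration_s = 20,
                                 seed = 5)
  expect_identical(rec$signals, rec2$signals)
  rec3 <- generate_synthetic_eeg(eff, "S01", "DL0", "pre", duration_s = 20,
                                 seed = 6)
  expect_false(identical(rec$signals, rec3$signals))
  expect_error(generate_synthetic_eeg(eff, "S01", "RL", "pre"), "DL005")
})

test_that("effect spec validates labels, group sizes and coupling", {
  expect_error(study_effect_spec(n_subjects_per_condition = 1), ">= 2")
  expect_error(study_effect_spec(coupling_rho = 1.2), "-1, 1")
  expect_error(study_effect_spec(
    lobe_entropy_deltas = data.frame(condition = "DL9", lobe = "O",
                                     minute = 1, delta_pct = -10)), "valid")
  expect_error(study_effect_spec(
    lobe_entropy_deltas = data.frame(condition = "DL0", lobe = "X",
                                     minute = 1, delta_pct = -10)), "valid")
  expect_error(study_effect_spec(
    lobe_entropy_deltas = data.frame(condition = "DL0", lobe = "O",
                                     minute = 1, delta_pct = -100)), "-100")
})

test_that("synthetic ECG beats at the programmed cadence", {
  eff <- study_effect_spec(fs = 256)
  spec <- ecg_spec(mean_rr = 0.5, rr_sd = 0, waveform_noise_sd = 0)
  rec <- generate_synthetic_ecg(spec, eff, "S01", "DL0", "pre",
                                duration_s = 60, seed = 2)
  x <- rec$signals[1, ]
  beats <- sum(x[2:(length(x) - 1)] > 0.5 &
                 diff(sign(diff(x)))[1:(length(x) - 2)] == -2)
  expect_equal(beats, 120, tolerance = 0.02)  # ~120 bpm
  expect_error(generate_synthetic_ecg(spec, eff, "S01", "DL0", "pre",
                                      duration_s = 30), "60 s")
  expect_error(ecg_spec(rr_sd = 0.2), "mean_rr / 3")
})

test_that("waveform noise raises ECG entropy; white noise beats periodicity", {
  eff <- study_effect_spec(fs = 128)
  for (seed in 1:10) {
    clean <- generate_synthetic_ecg(
      ecg_spec(rr_sd = 0, waveform_noise_sd = 0), eff, "S01", "DL0", "pre",
      duration_s = 60, seed = seed)
    noisy <- generate_synthetic_ecg(
      ecg_spec(rr_sd = 0, waveform_noise_sd = 0.2), eff, "S01", "DL0", "pre",
      duration_s = 60, seed = seed)
    e_clean <- fme1(clean$signals[1, 1:1280])
    e_noisy <- fme1(noisy$signals[1, 1:1280])
    expect_lt(e_clean, e_noisy)
    # white noise at the same length is more irregular than the clean
    # periodic template
    expect_gt(fme1(colored_noise(1280, beta = 0, seed = seed)), e_clean)
  }
})

test_that("null generator: pre and post are statistically exchangeable", {
  passes <- vapply(1:10, function(seed) {
    eff <- study_effect_spec(conditions = "DL0",
                             n_subjects_per_condition = 2, fs = 64)
    pre <- generate_synthetic_eeg(eff, "S01", "DL0", "pre",
                                  duration_s = 60, seed = seed)
    post <- generate_synthetic_eeg(eff, "S01", "DL0", "post",
                                   duration_s = 60, seed = seed)
    e_pre <- vapply(1:6, function(k)
      fme1(pre$signals[1, ((k - 1) * 640 + 1):(k * 640)]), 0)
    e_post <- vapply(1:6, function(k)
      fme1(post$signals[1, ((k - 1) * 640 + 1):(k * 640)]), 0)
    suppressWarnings(
      wilcox.test(e_pre, e_post, exact = FALSE)$p.value) > 0.05
  }, logical(1))
  expect_gte(sum(passes), 9)
})

test_that("a programmed negative occipital shift lowers O entropy", {
  deltas <- data.frame(condition = "DL0", lobe = "O", minute = 1,
                       delta_pct = -10)
  eff <- study_effect_spec(conditions = "DL0", n_subjects_per_condition = 2,
                           lobe_entropy_deltas = deltas, fs = 64)
  hits <- vapply(1:10, function(seed) {
    pre <- generate_synthetic_eeg(eff, "S01", "DL0", "pre",
                                  duration_s = 60, seed = seed)
    post <- generate_synthetic_eeg(eff, "S01", "DL0", "post",
                                   duration_s = 60, seed = seed)
    o <- which(pre$channels == "O1")
    mean(vapply(1:6, function(k)
      fme1(post$signals[o, ((k - 1) * 640 + 1):(k * 640)]), 0)) <
      mean(vapply(1:6, function(k)
        fme1(pre$signals[o, ((k - 1) * 640 + 1):(k * 640)]), 0))
  }, logical(1))
  expect_gte(sum(hits), 8)
})
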