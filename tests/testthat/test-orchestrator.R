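# A small but fully structured study shared by the orchestrator tests:
# two conditions so scale selection and condition tests run, 64 Hz, one
# pre-rest and one post-rest minute, scales 1-2.
small_analysis <- function(seed = 17) {
  eff <- study_effect_spec(conditions = c("DL0", "DL1"),
                           n_subjects_per_condition = 5, fs = 64)
  st <- simulate_study(eff, pre_minutes = 1, post_minutes = 1, seed = seed)
  run_study_analysis(st, params = entropy_params(scale_max = 2),
                     target_fs = 64)
}

test_that("the analysis bundle has the full report structure", {
  an <- small_analysis()
  expect_s3_class(an, "msfme_analysis")
  regions <- c("TC", "FP", "F", "C", "T", "P", "O")
  expect_setequal(unique(an$trajectories$region), c(regions, "ECG"))
  # exactly 7 cerebral region rows per condition-minute in the medians
  per_cell <- dplyr::count(
    dplyr::filter(an$condition_medians, .data$region != "ECG",
                  .data$scale == 1),
    condition, minute)
  expect_true(all(per_cell$n == 7))
  # scale selection ran separately for EEG and ECG
  expect_setequal(unique(an$scale_selection$signal), c("EEG", "ECG"))
  expect_true(all(an$scale_selection$selected_scale %in% 1:2))
  # Wilcoxon cells: one per condition x region x minute
  expect_equal(nrow(an$time_effects), 2 * 8)
  expect_true(all(an$time_effects$n == 5))
  # condition tests across the two conditions
  expect_equal(nrow(an$condition_effects), 8)
  # interaction: EEG regions only, per condition
  expect_setequal(unique(an$interaction$region), regions)
  expect_true(all(an$interaction$n == 5 * 6))
  # tidiers
  expect_s3_class(tidy(an, "time_effects"), "tbl_df")
  expect_equal(nrow(glance(an)), 1)
  expect_s3_class(plot_trajectories(an), "ggplot")
})

test_that("identical seeds give identical analysis bundles", {
  a <- small_analysis(seed = 23)
  b <- small_analysis(seed = 23)
  expect_identical(a$trajectories, b$trajectories)
  expect_identical(a$time_effects, b$time_effects)
  expect_identical(a$interaction, b$interaction)
  c <- small_analysis(seed = 24)
  expect_false(identical(a$trajectories, c$trajectories))
})

test_that("the demo study mirrors the 7/8/8/8 group design", {
  an <- demo_synthetic_study(seed = 3, fs = 64, pre_minutes = 1,
                             post_minutes = 1,
                             params = entropy_params(scale_max = 1))
  sizes <- dplyr::count(an$study$subjects, condition)
  expect_equal(sizes$n[sizes$condition == "DL0"], 7)
  expect_equal(sort(sizes$n), c(7, 8, 8, 8))
  regions <- dplyr::count(
    dplyr::filter(an$condition_medians, .data$region != "ECG"),
    condition, minute)
  expect_true(all(regions$n == 7))
  expect_equal(nrow(dplyr::distinct(an$time_effects, condition)), 4)
})

test_that("single-condition studies fall back to the minimum scale", {
  st <- tiny_study(n_subjects = 5, seed = 31)
  an <- run_study_analysis(st, params = entropy_params(scale_max = 2),
                           target_fs = 64)
  expect_true(all(an$scale_selection$selected_scale == 1))
  expect_equal(nrow(an$condition_effects), 0)
})

test_that("the 1024 Hz path is bandpassed and decimated before entropy", {
  eff <- study_effect_spec(conditions = "DL0", n_subjects_per_condition = 2,
                           fs = 256)
  st <- simulate_study(eff, pre_minutes = 1, post_minutes = 1, seed = 41)
  an <- run_study_analysis(st, params = entropy_params(scale_max = 1),
                           target_fs = 128)
  # 10-s intervals at the target rate: 1280 samples at scale 1
  expect_true(all(an$intervals$n_samples == 1280))
})
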