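#' Bandpass filter and downsample a recording
#'
#' Applies a linear-phase FIR bandpass (Hamming-windowed, applied forward
#' and backward for zero phase) to every channel, then decimates by an
#' integer factor. The two analysis chains use `band = c(4, 70)` Hz for EEG
#' and `c(0.02, 40)` Hz for ECG before entropy; a very low lower edge
#' (< 0.5 Hz) is realized as mean removal plus the low-pass half, which has
#' the same passband behaviour without a many-second filter kernel.
#'
#' @param rec a [session_recording()].
#' @param band `c(low, high)` passband edges in Hz, inside the Nyquist band
#'   of both the source and target rate.
#' @param target_fs output sampling rate; must divide `rec$fs`.
#' @param order FIR order; default one second of taps (capped to a quarter
#'   of the signal), giving a transition width of roughly 3.3 Hz and
#'   passband ripple well under 1 dB after the two-pass application.
#' @return A `session_recording` at `target_fs`.
#' @export
bandpass_and_downsample <- function(rec, band, target_fs = rec$fs,
                                    order = NULL) {
  stopifnot(inherits(rec, "session_recording"))
  fs <- rec$fs
  if (length(band) != 2L || band[1] >= band[2]) abort("`band` must be c(low, high).")
  if (band[2] >= min(fs, target_fs) / 2)
    abort(sprintf("band edge %g Hz is not below Nyquist (%g Hz).",
                  band[2], min(fs, target_fs) / 2))
  if (fs %% target_fs != 0)
    abort(sprintf("target_fs %g must divide fs %g.", target_fs, fs))
  n <- ncol(rec$signals)
  if (is.null(order)) order <- min(round(fs), floor(n / 4))
  order <- 2L * (order %/% 2L)  # even order, symmetric kernel
  lowpass_only <- band[1] < 0.5
  wc <- if (lowpass_only) band[2] / (fs / 2) else band / (fs / 2)
  h <- signal::fir1(order, wc, type = if (lowpass_only) "low" else "pass")
  filt <- t(apply(rec$signals, 1, function(x) {
    if (lowpass_only) x <- x - mean(x)
    signal::filtfilt(h, x)
  }))
  dec <- as.integer(fs / target_fs)
  if (dec > 1L) filt <- filt[, seq(1L, ncol(filt), by = dec), drop = FALSE]
  session_recording(filt, target_fs, rec$channels, rec$phase,
                    rec$subject, rec$condition)
}

#' Segment a recording into z-transformed analysis intervals
#'
#' Splits every channel into non-overlapping, contiguous intervals of
#' `interval_s` seconds starting at the recording start; a trailing partial
#' interval is discarded. Each interval is z-transformed independently
#' ([zscore_series()]).
#'
#' @param rec a [session_recording()].
#' @param interval_s interval duration in seconds; `interval_s * fs` must be
#'   a whole number of samples. Default 10 s.
#' @return A tibble with columns `subject`, `condition`, `phase`, `channel`,
#'   `interval` (1-based index) and `data` (list column of z-scored numeric
#'   vectors).
#' @export
segment_intervals <- function(rec, interval_s = 10) {
  stopifnot(inherits(rec, "session_recording"))
  len <- interval_s * rec$fs
  if (abs(len - round(len)) > 1e-9)
    abort("`interval_s * fs` must be integral.")
  len <- as.integer(round(len))
  n_int <- ncol(rec$signals) %/% len
  if (n_int < 1L) abort("recording shorter than one interval.")
  grid <- tidyr::expand_grid(channel = rec$channels,
                             interval = seq_len(n_int))
  grid$data <- purrr::pmap(grid, function(channel, interval) {
    row <- match(channel, rec$channels)
    zscore_series(rec$signals[row, ((interval - 1L) * len + 1L):(interval * len)])
  })
  tibble::tibble(subject = rec$subject, condition = rec$condition,
                 phase = rec$phase, grid)
}

#' Per-interval MSFME table for a recording
#'
#' Runs [segment_intervals()] and evaluates the [msfme()] curve on every
#' interval of every channel.
#'
#' @inheritParams segment_intervals
#' @param params an [entropy_params()] object.
#' @return A tidy tibble: `subject`, `condition`, `phase`, `channel`,
#'   `interval`, `scale`, `n_samples`, `entropy`.
#' @export
compute_entropy_table <- function(rec, params = entropy_params(),
                                  interval_s = 10) {
  seg <- segment_intervals(rec, interval_s)
  seg |>
    dplyr::mutate(curve = purrr::map(.data$data, msfme, params = params)) |>
    dplyr::select(-"data") |>
    tidyr::unnest("curve")
}

#' Average 10-s interval entropies to minutes
#'
#' Arithmetic mean of the interval MSFME values within each whole minute
#' (six 10-s intervals per minute by default). Minutes with fewer than the
#' full complement of intervals are flagged `complete = FALSE` and dropped
#' unless `keep_partial = TRUE`.
#'
#' @param entropy an interval-level entropy table from
#'   [compute_entropy_table()].
#' @param interval_s the interval duration used upstream (default 10 s).
#' @param keep_partial keep incomplete minutes (flagged) instead of
#'   excluding them.
#' @return A tibble with `minute` replacing `interval`, plus `complete`.
#' @export
minute_average <- function(entropy, interval_s = 10, keep_partial = FALSE) {
  per_min <- as.integer(60 / interval_s)
  out <- entropy |>
    dplyr::mutate(minute = (.data$interval - 1L) %/% per_min + 1L) |>
    dplyr::group_by(dplyr::across(dplyr::any_of(
      c("subject", "condition", "phase", "channel", "scale", "minute")))) |>
    dplyr::summarise(entropy = mean(.data$entropy),
                     n_intervals = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(complete = .data$n_intervals == per_min)
  if (!keep_partial) out <- dplyr::filter(out, .data$complete)
  dplyr::select(out, -"n_intervals")
}

#' Baseline entropies from the pre-rest block
#'
#' The baseline is the last complete minute of the pre-rest recording, per
#' (subject, channel, scale).
#'
#' @param pre_entropy a minute-level table ([minute_average()]) of the
#'   pre-rest phase.
#' @return A tibble `subject`, `channel`, `scale`, `baseline`.
#' @export
extract_baseline <- function(pre_entropy) {
  if (!nrow(pre_entropy)) abort("pre-rest table is empty.")
  pre_entropy |>
    dplyr::group_by(dplyr::across(dplyr::any_of(
      c("subject", "condition", "channel", "scale")))) |>
    dplyr::slice_max(.data$minute, n = 1L, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::select(dplyr::any_of(c("subject", "condition", "channel", "scale")),
                  baseline = "entropy")
}

#' Normalize post-rest entropies to the pre-rest baseline
#'
#' Expresses values relative to baseline: `pct_baseline = 100 * value /
#' baseline` and `delta_pct = pct_baseline - 100`, per (subject, channel,
#' scale). Works on minute-level or interval-level tables (any table with
#' an `entropy` column and the join keys).
#'
#' @param post_entropy a post-rest entropy table.
#' @param baseline output of [extract_baseline()].
#' @return the input table with `pct_baseline` and `delta_pct` columns.
#' @export
normalize_to_baseline <- function(post_entropy, baseline) {
  bad <- baseline[!is.finite(baseline$baseline) | baseline$baseline <= 0, ]
  if (nrow(bad))
    abort(sprintf("non-positive baseline at: %s",
                  paste(utils::head(paste0(bad$subject, "/", bad$channel,
                                           "/scale", bad$scale), 5),
                        collapse = "; ")))
  keys <- intersect(c("subject", "condition", "channel", "scale"),
                    intersect(names(post_entropy), names(baseline)))
  out <- dplyr::inner_join(post_entropy, baseline, by = keys)
  if (nrow(out) < nrow(post_entropy))
    abort("baseline missing for some (subject, channel, scale) cells.")
  dplyr::mutate(out,
                pct_baseline = 100 * .data$entropy / .data$baseline,
                delta_pct = .data$pct_baseline - 100)
}

#' Aggregate electrode values over cerebral lobes
#'
#' Region value = mean over the member electrodes; TC (total cortex) = mean
#' over all electrodes in the map directly, which differs from the mean of
#' the lobe means whenever lobe sizes differ. A non-EEG channel (`"ECG"`)
#' passes through as its own region.
#'
#' @param tbl a tidy table with a `channel` column and one or more value
#'   columns.
#' @param value_cols names of the value columns to average (default:
#'   whichever of `entropy`, `pct_baseline`, `delta_pct` are present).
#' @param lobe_map named list of electrode vectors (default
#'   [eeg_lobe_map()]). Every mapped electrode must be present in `tbl`.
#' @return the table with `region` replacing `channel`, averaged over
#'   member channels within each remaining key combination.
#' @export
aggregate_lobes <- function(tbl, value_cols = NULL, lobe_map = eeg_lobe_map()) {
  if (is.null(value_cols))
    value_cols <- intersect(c("entropy", "pct_baseline", "delta_pct"),
                            names(tbl))
  electrodes <- unlist(lobe_map, use.names = FALSE)
  have <- unique(tbl$channel)
  missing <- setdiff(electrodes, have)
  if (length(missing))
    abort(sprintf("electrode(s) missing from table: %s",
                  paste(missing, collapse = ", ")))
  assign_tbl <- tibble::tibble(
    channel = c(unlist(lobe_map, use.names = FALSE), electrodes),
    region = c(rep(names(lobe_map), lengths(lobe_map)),
               rep("TC", length(electrodes))))
  extra <- setdiff(have, electrodes)  # e.g. ECG passes through
  if (length(extra))
    assign_tbl <- dplyr::bind_rows(assign_tbl,
                                   tibble::tibble(channel = extra,
                                                  region = extra))
  keys <- setdiff(names(tbl), c("channel", value_cols))
  dplyr::inner_join(tbl, assign_tbl, by = "channel",
                    relationship = "many-to-many") |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(keys, "region")))) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(value_cols), mean),
                     .groups = "drop")
}

#' Per-condition median trajectory
#'
#' Element-wise median over subjects (midpoint convention for even counts),
#' per (condition, region, scale, minute) or whatever grouping keys are
#' present. The median is used instead of the mean to damp outliers at the
#' small per-condition sample sizes this design targets.
#'
#' @param tbl a subject-level table with one or more value columns.
#' @param value_cols value columns to take medians of (default as in
#'   [aggregate_lobes()]).
#' @return the table with subjects collapsed to medians and an `n_subjects`
#'   count.
#' @export
condition_median <- function(tbl, value_cols = NULL) {
  if (is.null(value_cols))
    value_cols <- intersect(c("entropy", "pct_baseline", "delta_pct"),
                            names(tbl))
  keys <- setdiff(names(tbl), c("subject", value_cols))
  counts <- tbl |>
    dplyr::group_by(dplyr::across(dplyr::all_of("condition"))) |>
    dplyr::summarise(n_subjects = dplyr::n_distinct(.data$subject),
                     .groups = "drop")
  if (any(counts$n_subjects < 2L))
    abort("need >= 2 subjects per condition for condition medians.")
  tbl |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(value_cols), median),
                     n_subjects = dplyr::n(), .groups = "drop")
}

#' Heart-rate change relative to pre-rest baseline
#'
#' Expresses a training-bout heart rate relative to the pre-rest baseline
#' (pre-rest = 100%): returns `100 * training_hr / pre_hr - 100`, the Delta%
#' convention of the descriptive statistics.
#'
#' @param pre_hr pre-rest mean heart rate (bpm), > 0.
#' @param training_hr training-bout mean heart rate (bpm).
#' @return Delta% of baseline (vectorized).
#' @examples
#' normalize_heart_rate(70, 148.8)  # ~ +112.6
#' @export
normalize_heart_rate <- function(pre_hr, training_hr) {
  if (any(pre_hr <= 0)) abort("`pre_hr` must be > 0.")
  100 * training_hr / pre_hr - 100
}
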