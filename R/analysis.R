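preprocess_recording <- function(rec, target_fs,
                                 eeg_band = c(4, 70), ecg_band = c(0.02, 40)) {
  # decimation needs the passband below the target Nyquist (anti-aliasing)
  clip <- function(band) c(band[1], min(band[2], 0.45 * target_fs))
  eeg_band <- clip(eeg_band)
  ecg_band <- clip(ecg_band)
  eeg_idx <- which(rec$channels != "ECG")
  ecg_idx <- which(rec$channels == "ECG")
  parts <- list()
  if (length(eeg_idx)) {
    eeg <- session_recording(rec$signals[eeg_idx, , drop = FALSE], rec$fs,
                             rec$channels[eeg_idx], rec$phase, rec$subject,
                             rec$condition)
    parts$eeg <- bandpass_and_downsample(eeg, eeg_band, target_fs)
  }
  if (length(ecg_idx)) {
    ecg <- session_recording(rec$signals[ecg_idx, , drop = FALSE], rec$fs,
                             rec$channels[ecg_idx], rec$phase, rec$subject,
                             rec$condition)
    parts$ecg <- bandpass_and_downsample(ecg, ecg_band, target_fs)
  }
  sig <- do.call(rbind, purrr::map(parts, "signals"))
  session_recording(sig, target_fs,
                    unlist(purrr::map(parts, "channels"), use.names = FALSE),
                    rec$phase, rec$subject, rec$condition)
}

select_scales_by_cell <- function(medians, scale_min) {
  cells <- dplyr::distinct(medians, .data$region, .data$minute)
  purrr::pmap_dfr(cells, function(region, minute) {
    sub <- medians[medians$region == region & medians$minute == minute, ]
    if (dplyr::n_distinct(sub$condition) < 2L) {
      return(tibble::tibble(region = region, minute = minute,
                            selected_scale = scale_min,
                            profile = list(NULL)))
    }
    sel <- select_scale(sub)
    tibble::tibble(region = region, minute = minute,
                   selected_scale = sel$selected_scale,
                   profile = list(sel$profile))
  })
}

#' Run the full recovery analysis on a study
#'
#' End-to-end chain: (optional) bandpass + downsample, 10-s segmentation
#' and z-transform, per-interval MSFME over the scale range, minute
#' averaging, normalization to the last pre-rest minute (baseline = 100%),
#' lobe aggregation (FP/F/C/T/P/O/TC plus ECG), condition medians,
#' heterogeneity-based scale selection per (region, minute) separately for
#' EEG and ECG, Wilcoxon time tests (baseline vs each post minute, per
#' condition) with the z -> Cohen's d chain, Kruskal-Wallis condition tests
#' with Bonferroni post hoc, and the pooled Spearman EEG-ECG entropy
#' interaction per (condition, region, minute).
#'
#' @param study a study object supporting [get_recording()] (a
#'   [simulate_study()] result or a [read_study()] manifest).
#' @param params an [entropy_params()].
#' @param interval_s analysis interval in seconds (default 10).
#' @param minutes post-rest minute indices to analyze (default: all complete
#'   minutes present; the canonical reporting grid is Post1-5 and Post25).
#' @param alpha significance level (default 0.05).
#' @param thresholds correlation magnitude cut points
#'   `c(moderate = 0.3, strong = 0.5)`.
#' @param lobe_map electrode-to-lobe assignment (default [eeg_lobe_map()]).
#' @param target_fs analysis sampling rate; recordings at a higher rate are
#'   bandpassed (EEG 4-70 Hz, ECG 0.02-40 Hz) and decimated to it,
#'   recordings already at (or below) it are taken as cleaned analysis-rate
#'   input.
#' @param correlation_pooling `"condition"` pools all subjects' 10-s values
#'   within a condition (default; gives usable n = subjects x intervals per
#'   cell); `"subject"` correlates per subject and reports the median rho.
#' @param channels optional subset of channel labels to analyze (with a
#'   matching reduced `lobe_map`); `NULL` analyzes every channel.
#' @return An object of class `msfme_analysis`; see [tidy.msfme_analysis()].
#' @export
run_study_analysis <- function(study,
                               params = entropy_params(),
                               interval_s = 10,
                               minutes = NULL,
                               alpha = 0.05,
                               thresholds = c(moderate = 0.3, strong = 0.5),
                               lobe_map = eeg_lobe_map(),
                               target_fs = 256,
                               correlation_pooling = c("condition",
                                                       "subject"),
                               channels = NULL) {
  correlation_pooling <- match.arg(correlation_pooling)
  subjects <- study$subjects

  intervals <- purrr::pmap_dfr(
    subjects[, c("subject", "condition")], function(subject, condition) {
      purrr::map_dfr(c("pre", "post"), function(phase) {
        rec <- get_recording(study, subject, phase)
        if (!is.null(channels)) {
          keep <- match(channels, rec$channels)
          if (anyNA(keep))
            abort(sprintf("channel(s) not in recording: %s",
                          paste(channels[is.na(keep)], collapse = ", ")))
          rec <- session_recording(rec$signals[keep, , drop = FALSE],
                                   rec$fs, rec$channels[keep], rec$phase,
                                   rec$subject, rec$condition)
        }
        if (rec$fs > target_fs) rec <- preprocess_recording(rec, target_fs)
        compute_entropy_table(rec, params, interval_s)
      })
    })

  per_minute <- minute_average(intervals, interval_s)
  baseline <- extract_baseline(
    dplyr::select(dplyr::filter(per_minute, .data$phase == "pre"), -"phase"))
  post_min <- dplyr::select(
    dplyr::filter(per_minute, .data$phase == "post"), -"phase")
  if (!is.null(minutes)) post_min <- dplyr::filter(post_min,
                                                   .data$minute %in% minutes)
  norm_min <- normalize_to_baseline(post_min, baseline)
  traj <- aggregate_lobes(
    dplyr::select(norm_min, dplyr::any_of(c(
      "subject", "condition", "channel", "scale", "minute",
      "entropy", "pct_baseline", "delta_pct"))),
    lobe_map = lobe_map)
  medians <- condition_median(
    dplyr::select(traj, dplyr::any_of(c(
      "subject", "condition", "region", "scale", "minute", "delta_pct"))))

  # interval-level normalized values (for the interaction stage)
  post_int <- dplyr::filter(intervals, .data$phase == "post")
  post_int$minute <- (post_int$interval - 1L) %/%
    as.integer(60 / interval_s) + 1L
  if (!is.null(minutes)) post_int <- dplyr::filter(post_int,
                                                   .data$minute %in% minutes)
  norm_int <- normalize_to_baseline(
    dplyr::select(post_int, -"phase", -"n_samples"), baseline)
  region_int <- aggregate_lobes(
    dplyr::select(norm_int, dplyr::any_of(c(
      "subject", "condition", "channel", "scale", "minute", "interval",
      "pct_baseline"))),
    value_cols = "pct_baseline", lobe_map = lobe_map)

  eeg_regions <- c(names(lobe_map), "TC")
  sel_eeg <- select_scales_by_cell(
    dplyr::filter(medians, .data$region %in% eeg_regions), params$scale_min)
  sel_ecg <- if ("ECG" %in% medians$region)
    select_scales_by_cell(dplyr::filter(medians, .data$region == "ECG"),
                          params$scale_min)
  else tibble::tibble(region = character(), minute = integer(),
                      selected_scale = integer(), profile = list())
  selection <- dplyr::bind_rows(
    dplyr::mutate(sel_eeg, signal = "EEG"),
    dplyr::mutate(sel_ecg, signal = "ECG"))

  sel_keys <- dplyr::select(selection, "region", "minute", "selected_scale")
  traj_sel <- dplyr::inner_join(traj, sel_keys,
                                by = c("region", "minute")) |>
    dplyr::filter(.data$scale == .data$selected_scale)

  # Wilcoxon time effects: baseline vs post minute, per condition/region
  time_cells <- dplyr::distinct(traj_sel, .data$condition, .data$region,
                                .data$minute)
  empty_time <- tibble::tibble(
    condition = character(), region = character(), minute = integer(),
    scale = integer(), z = numeric(), p = numeric(), d = numeric(),
    n = integer(), significant = logical())
  time_effects <- purrr::pmap_dfr(
    time_cells, function(condition, region, minute) {
      dsub <- traj_sel$delta_pct[traj_sel$condition == condition &
                                   traj_sel$region == region &
                                   traj_sel$minute == minute]
      res <- tryCatch(
        wilcoxon_signed_rank_z(
          dsub, comparison = sprintf("baseline vs Post%d", minute)),
        error = function(e) NULL)
      if (is.null(res)) return(NULL)
      tibble::tibble(condition = condition, region = region, minute = minute,
                     scale = traj_sel$selected_scale[
                       traj_sel$region == region &
                         traj_sel$minute == minute][1],
                     z = res$statistic, p = res$p, d = res$d, n = res$n,
                     significant = res$p <= alpha)
    })
  time_effects <- dplyr::bind_rows(empty_time, time_effects)

  # Kruskal-Wallis condition comparisons per region/minute
  kw_cells <- dplyr::distinct(traj_sel, .data$region, .data$minute)
  condition_effects <- purrr::pmap_dfr(kw_cells, function(region, minute) {
    sub <- traj_sel[traj_sel$region == region & traj_sel$minute == minute, ]
    if (dplyr::n_distinct(sub$condition) < 2L) return(NULL)
    res <- tryCatch(
      kruskal_wallis_bonferroni(sub$delta_pct, sub$condition, alpha = alpha),
      error = function(e) NULL)
    if (is.null(res)) return(NULL)
    tibble::tibble(region = region, minute = minute,
                   H = res$omnibus$statistic, p = res$omnibus$p,
                   significant = res$omnibus$p <= alpha,
                   posthoc = list(res$posthoc))
  })

  # Spearman EEG-ECG interaction at separately selected scales
  interaction <- if ("ECG" %in% region_int$region && nrow(sel_ecg)) {
    ecg_int <- dplyr::inner_join(
      dplyr::filter(region_int, .data$region == "ECG"),
      dplyr::select(sel_ecg, "minute", ecg_scale = "selected_scale"),
      by = "minute") |>
      dplyr::filter(.data$scale == .data$ecg_scale) |>
      dplyr::select("subject", "condition", "minute", "interval",
                    ecg_pct = "pct_baseline")
    eeg_int <- dplyr::inner_join(
      dplyr::filter(region_int, .data$region %in% eeg_regions),
      dplyr::select(sel_eeg, "region", "minute",
                    eeg_scale = "selected_scale"),
      by = c("region", "minute")) |>
      dplyr::filter(.data$scale == .data$eeg_scale) |>
      dplyr::select("subject", "condition", "region", "minute", "interval",
                    eeg_pct = "pct_baseline")
    paired <- dplyr::inner_join(eeg_int, ecg_int,
                                by = c("subject", "condition", "minute",
                                       "interval"))
    cells <- dplyr::distinct(paired, .data$condition, .data$region,
                             .data$minute)
    purrr::pmap_dfr(cells, function(condition, region, minute) {
      sub <- paired[paired$condition == condition &
                      paired$region == region & paired$minute == minute, ]
      if (correlation_pooling == "subject") {
        rhos <- sub |>
          dplyr::group_by(.data$subject) |>
          dplyr::summarise(rho = cor(.data$eeg_pct, .data$ecg_pct,
                                     method = "spearman"), .groups = "drop")
        rho <- median(rhos$rho)
        return(tibble::tibble(condition = condition, region = region,
                              minute = minute, rho = rho, p = NA_real_,
                              n = nrow(sub),
                              class = classify_correlation(rho, thresholds)))
      }
      res <- tryCatch(spearman_interaction(sub$eeg_pct, sub$ecg_pct,
                                           thresholds = thresholds),
                      error = function(e) NULL)
      if (is.null(res)) return(NULL)
      tibble::tibble(condition = condition, region = region, minute = minute,
                     rho = res$statistic, p = res$p, n = res$n,
                     class = res$class)
    })
  } else {
    tibble::tibble(condition = character(), region = character(),
                   minute = integer(), rho = numeric(), p = numeric(),
                   n = integer(), class = character())
  }

  structure(
    list(subjects = subjects,
         intervals = intervals,
         minutes = per_minute,
         baseline = baseline,
         trajectories = traj,
         condition_medians = medians,
         scale_selection = selection,
         time_effects = time_effects,
         condition_effects = condition_effects,
         interaction = interaction,
         config = list(params = params, interval_s = interval_s,
                       minutes = minutes, alpha = alpha,
                       thresholds = thresholds, target_fs = target_fs,
                       correlation_pooling = correlation_pooling)),
    class = "msfme_analysis")
}

#' @export
print.msfme_analysis <- function(x, ...) {
  cat(sprintf(
    "<msfme_analysis> %d subjects, %d condition(s)\n  %d time-effect cells (%d significant), %d interaction cells (%d at least moderate)\n",
    nrow(x$subjects), dplyr::n_distinct(x$subjects$condition),
    nrow(x$time_effects), sum(x$time_effects$significant),
    nrow(x$interaction), sum(x$interaction$class != "negligible")))
  invisible(x)
}

#' One-command synthetic study demonstration
#'
#' Generates a four-condition study with group sizes 7/8/8/8 (one group one
#' short, mirroring a typical exclusion), programmed occipital and temporal
#' entropy shifts, and condition-dependent EEG-ECG coupling, then runs
#' [run_study_analysis()]. The default problem size (64 Hz generation, 5
#' pre-rest and 6 post-rest minutes, scales 1-20) keeps a full run within
#' roughly ten minutes on one CPU; pass smaller `pre_minutes`,
#' `post_minutes`, or `params` for a quicker look.
#'
#' @param seed study seed.
#' @param fs generation sampling rate.
#' @param pre_minutes,post_minutes block lengths in minutes.
#' @param params an [entropy_params()].
#' @return the `msfme_analysis` bundle, with the study attached as
#'   `$study`.
#' @export
demo_synthetic_study <- function(seed = 1, fs = 64,
                                 pre_minutes = 5, post_minutes = 6,
                                 params = entropy_params()) {
  deltas <- dplyr::bind_rows(
    tibble::tibble(condition = "DL0", lobe = "O", minute = 1,
                   delta_pct = 15),
    tibble::tibble(condition = "DL005", lobe = "O", minute = 2:3,
                   delta_pct = -12),
    tibble::tibble(condition = "DL01", lobe = "T", minute = 1,
                   delta_pct = -10))
  effects <- study_effect_spec(
    n_subjects_per_condition = c(7, 8, 8, 8),
    lobe_entropy_deltas = deltas,
    coupling_rho = c(DL0 = 0, DL005 = -0.5, DL01 = 0.8, DL1 = 0.4),
    fs = fs)
  study <- simulate_study(effects, pre_minutes = pre_minutes,
                          post_minutes = post_minutes, seed = seed)
  out <- run_study_analysis(study, params = params, target_fs = fs)
  out$study <- study
  out
}
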