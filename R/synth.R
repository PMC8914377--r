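# Deterministic sub-seed from a study seed and a string key, kept below
# 2^31 so it is always a valid R seed.
derive_seed <- function(seed, ...) {
  key <- paste(..., sep = "/")
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147480009
  as.integer((as.numeric(seed) %% 1000003 * 2099 + h) %% 2147483647)
}

# Baseline white-noise proportion per lobe: irregularity differs by lobe.
lobe_base_weights <- function() {
  c(FP = 0.55, F = 0.52, C = 0.50, T = 0.48, P = 0.50, O = 0.45)
}

# Gain translating a programmed entropy shift (Delta% of baseline MSFME)
# into a shift of the white-noise mixing weight. Calibrated once against the
# measured response of scale-1 fuzzy measure entropy to the mixing weight
# around w = 0.5 (dFME/dw ~ 1.9 at FME ~ 2.5).
DELTA_WEIGHT_GAIN <- 1.3

# Amplitudes of the latent coupling modulation on the EEG mixing weight and
# on the log of the ECG noise SD.
COUPLING_EEG_AMP <- 0.15
COUPLING_ECG_AMP <- 0.4

#' Synthetic ECG waveform specification
#'
#' Parameters of the quasi-periodic synthetic ECG: a Gaussian-bump QRS
#' template repeated at jittered beat intervals plus additive white noise.
#'
#' @param mean_rr mean beat interval in seconds, > 0 (0.5 s = 120 bpm, the
#'   skipping-cadence regime).
#' @param rr_sd beat-interval jitter SD in seconds, >= 0 and < `mean_rr / 3`
#'   so beats never reorder.
#' @param waveform_noise_sd additive noise SD relative to the unit waveform
#'   amplitude, >= 0.
#' @param seed integer seed (optional; study-level seeds usually govern).
#' @return An object of class `ecg_spec`.
#' @export
ecg_spec <- function(mean_rr = 0.5, rr_sd = 0.02, waveform_noise_sd = 0.2,
                     seed = NULL) {
  if (mean_rr <= 0) abort("`mean_rr` must be > 0.")
  if (rr_sd < 0) abort("`rr_sd` must be >= 0.")
  if (rr_sd >= mean_rr / 3)
    abort("`rr_sd` must be < mean_rr / 3 (no beat-order inversions).")
  if (waveform_noise_sd < 0) abort("`waveform_noise_sd` must be >= 0.")
  structure(list(mean_rr = mean_rr, rr_sd = rr_sd,
                 waveform_noise_sd = waveform_noise_sd, seed = seed),
            class = "ecg_spec")
}

#' Synthetic study design specification
#'
#' Describes the statistical structure a synthetic study should realize:
#' conditions, group sizes, programmed per-lobe entropy shifts in post-rest
#' minutes, and an optional latent coupling that induces correlation between
#' EEG-entropy and ECG-entropy trajectories.
#'
#' Programmed shifts are expressed as the intended Delta% change of lobe
#' MSFME relative to baseline and are realized by shifting the lobe's
#' white/1-over-f mixing weight (the generator's irregularity knob, see
#' vignette) for the given post minute.
#'
#' @param conditions condition labels (default the four motor-learning
#'   approaches DL0, DL005, DL01, DL1).
#' @param n_subjects_per_condition group size(s), >= 2; recycled across
#'   conditions (e.g. `c(7, 8, 8, 8)`).
#' @param lobe_entropy_deltas `NULL`, or a data frame with columns
#'   `condition`, `lobe` (FP/F/C/T/P/O), `minute` (post-minute index), and
#'   `delta_pct` (> -100): the programmed entropy shifts.
#' @param coupling_rho target sign/strength of the latent EEG-ECG entropy
#'   coupling in \[-1, 1\]; a scalar or one value per condition.
#' @param fs sampling rate in Hz (256 generates directly at the analysis
#'   rate; 1024 exercises the downsampling path).
#' @return An object of class `study_effect_spec`.
#' @examples
#' study_effect_spec(n_subjects_per_condition = c(7, 8, 8, 8))
#' @export
study_effect_spec <- function(conditions = c("DL0", "DL005", "DL01", "DL1"),
                              n_subjects_per_condition = 8L,
                              lobe_entropy_deltas = NULL,
                              coupling_rho = 0,
                              fs = 256) {
  n <- as.integer(rep_len(n_subjects_per_condition, length(conditions)))
  if (any(n < 2L)) abort("need >= 2 subjects per condition.")
  if (any(abs(coupling_rho) > 1)) abort("`coupling_rho` must lie in [-1, 1].")
  rho <- rep_len(coupling_rho, length(conditions))
  names(rho) <- conditions
  if (!is.null(lobe_entropy_deltas)) {
    lobe_entropy_deltas <- tibble::as_tibble(lobe_entropy_deltas)
    need <- c("condition", "lobe", "minute", "delta_pct")
    if (!all(need %in% names(lobe_entropy_deltas)))
      abort(sprintf("`lobe_entropy_deltas` needs columns: %s",
                    paste(need, collapse = ", ")))
    bad_cond <- setdiff(unique(lobe_entropy_deltas$condition), conditions)
    if (length(bad_cond))
      abort(sprintf("unknown condition(s) in deltas: %s (valid: %s)",
                    paste(bad_cond, collapse = ", "),
                    paste(conditions, collapse = ", ")))
    bad_lobe <- setdiff(unique(lobe_entropy_deltas$lobe),
                        names(eeg_lobe_map()))
    if (length(bad_lobe))
      abort(sprintf("unknown lobe(s) in deltas: %s (valid: %s)",
                    paste(bad_lobe, collapse = ", "),
                    paste(names(eeg_lobe_map()), collapse = ", ")))
    if (any(lobe_entropy_deltas$delta_pct <= -100))
      abort("`delta_pct` must be > -100.")
  }
  structure(
    list(conditions = conditions, n_subjects = n,
         lobe_entropy_deltas = lobe_entropy_deltas,
         coupling_rho = rho, fs = fs),
    class = "study_effect_spec")
}

# Stationary AR(1) latent series (marginal N(0,1)), one value per 10-s
# interval; the slow drive behind the EEG-ECG entropy coupling.
latent_series <- function(n, seed, phi = 0.5) {
  with_seed(seed, {
    z <- numeric(n)
    z[1] <- rnorm(1)
    for (k in seq_len(n - 1L))
      z[k + 1L] <- phi * z[k] + sqrt(1 - phi^2) * rnorm(1)
    z
  })
}

# Per-interval modulation series for one side (EEG or ECG) of the coupling:
# corr(a_eeg, a_ecg) = |rho| by construction (shared + private latent).
coupling_modulation <- function(rho, n_int, seed, side) {
  if (rho == 0 || n_int == 0L) return(numeric(n_int))
  shared <- latent_series(n_int, derive_seed(seed, "latent-shared"))
  private <- latent_series(n_int, derive_seed(seed, "latent", side))
  sqrt(abs(rho)) * shared + sqrt(1 - abs(rho)) * private
}

delta_lookup <- function(effects, condition, lobe, minute) {
  d <- effects$lobe_entropy_deltas
  if (is.null(d)) return(0)
  hit <- d$condition == condition & d$lobe == lobe & d$minute == minute
  if (!any(hit)) 0 else sum(d$delta_pct[hit])
}

check_condition <- function(effects, condition) {
  if (!condition %in% effects$conditions)
    abort(sprintf("unknown condition '%s' (valid: %s)", condition,
                  paste(effects$conditions, collapse = ", ")))
}

#' Generate a synthetic 19-channel EEG block
#'
#' Produces the 19-electrode montage for one subject and phase. Each lobe's
#' channels share a lobe-level irregularity parameter (the white-noise
#' proportion of a variance-normalized white/pink mixture); programmed
#' Delta% entropy shifts move that proportion per post minute, and a latent
#' slow series shared with the ECG generator modulates it per 10-s interval
#' when coupling is programmed.
#'
#' @param effects a [study_effect_spec()].
#' @param subject subject identifier (enters the derived seed).
#' @param condition condition label, one of `effects$conditions`.
#' @param phase `"pre"` or `"post"`.
#' @param duration_s block duration in seconds (a whole number of 10-s
#'   intervals).
#' @param seed study-level integer seed.
#' @param amplitude_sd per-channel signal SD in microvolts.
#' @return A `session_recording` with the 19 EEG channels.
#' @export
generate_synthetic_eeg <- function(effects, subject, condition,
                                   phase = c("pre", "post"),
                                   duration_s = 300, seed = 1,
                                   amplitude_sd = 10) {
  phase <- match.arg(phase)
  stopifnot(inherits(effects, "study_effect_spec"))
  check_condition(effects, condition)
  fs <- effects$fs
  n_int <- as.integer(ceiling(duration_s / 10))
  n_per <- as.integer(10 * fs)
  rho <- unname(effects$coupling_rho[condition])
  a <- if (phase == "post")
    coupling_modulation(rho, n_int, derive_seed(seed, subject, phase), "eeg")
  else numeric(n_int)
  w0 <- lobe_base_weights()
  lobe_of <- stats::setNames(
    rep(names(eeg_lobe_map()), lengths(eeg_lobe_map())),
    unlist(eeg_lobe_map()))
  sig <- matrix(0, nrow = 19L, ncol = n_int * n_per)
  for (ci in seq_along(eeg_channels())) {
    ch <- eeg_channels()[ci]
    lobe <- lobe_of[[ch]]
    for (k in seq_len(n_int)) {
      minute <- (k - 1L) %/% 6L + 1L
      delta <- if (phase == "post")
        delta_lookup(effects, condition, lobe, minute) else 0
      w <- w0[[lobe]] + DELTA_WEIGHT_GAIN * delta / 100 +
        COUPLING_EEG_AMP * a[k]
      w <- min(max(w, 0.05), 0.95)
      sig[ci, ((k - 1L) * n_per + 1L):(k * n_per)] <-
        mixed_noise(n_per, w, amplitude_sd = amplitude_sd,
                    seed = derive_seed(seed, subject, phase, ch, k))
    }
  }
  sig <- sig[, seq_len(round(duration_s * fs)), drop = FALSE]
  session_recording(sig, fs, eeg_channels(), phase, subject, condition)
}

#' Generate a synthetic ECG channel
#'
#' A quasi-periodic waveform: a Gaussian-bump QRS template repeated at
#' jittered beat intervals, plus additive white noise. Entropy of the
#' waveform increases monotonically with `waveform_noise_sd`. When the
#' study programs an EEG-ECG coupling, the shared latent series scales the
#' per-interval noise SD (log-linearly), with the sign of `coupling_rho`
#' deciding whether ECG irregularity moves with or against the EEG's.
#'
#' @param spec an [ecg_spec()].
#' @inheritParams generate_synthetic_eeg
#' @return A `session_recording` with the single channel `"ECG"` (mV).
#' @export
generate_synthetic_ecg <- function(spec, effects, subject, condition,
                                   phase = c("pre", "post"),
                                   duration_s = 300, seed = 1) {
  phase <- match.arg(phase)
  stopifnot(inherits(spec, "ecg_spec"), inherits(effects, "study_effect_spec"))
  check_condition(effects, condition)
  if (duration_s < 60) abort("ECG blocks must be >= 60 s.")
  fs <- effects$fs
  n <- round(duration_s * fs)
  n_int <- as.integer(ceiling(duration_s / 10))
  n_per <- as.integer(10 * fs)
  rho <- unname(effects$coupling_rho[condition])
  a <- if (phase == "post")
    coupling_modulation(rho, n_int, derive_seed(seed, subject, phase), "ecg")
  else numeric(n_int)

  # beat grid
  n_beats <- ceiling(duration_s / spec$mean_rr) + 2L
  rr <- with_seed(derive_seed(seed, subject, phase, "rr"), {
    if (spec$rr_sd == 0) rep(spec$mean_rr, n_beats)
    else pmax(rnorm(n_beats, spec$mean_rr, spec$rr_sd), spec$mean_rr / 3)
  })
  beat_t <- cumsum(c(spec$mean_rr / 2, rr))
  beat_t <- beat_t[beat_t < duration_s + 0.2]

  # Gaussian QRS bumps (sigma 15 ms, unit amplitude)
  x <- numeric(n + n_per)  # pad so the last interval block is full
  sigma <- 0.015
  half <- ceiling(5 * sigma * fs)
  tt <- (-half:half) / fs
  bump <- exp(-tt^2 / (2 * sigma^2))
  for (bt in beat_t) {
    c0 <- round(bt * fs)
    idx <- (c0 - half):(c0 + half) + 1L
    keep <- idx >= 1L & idx <= length(x)
    x[idx[keep]] <- x[idx[keep]] + bump[keep]
  }

  # interval-wise additive noise
  if (spec$waveform_noise_sd > 0) {
    noise <- with_seed(derive_seed(seed, subject, phase, "ecg-noise"),
                       rnorm(n_int * n_per))
    sd_k <- if (rho == 0) rep(spec$waveform_noise_sd, n_int)
      else spec$waveform_noise_sd * exp(COUPLING_ECG_AMP * sign(rho) * a)
    scale_vec <- rep(sd_k, each = n_per)
    x[seq_len(n_int * n_per)] <- x[seq_len(n_int * n_per)] +
      noise * scale_vec
  }
  session_recording(matrix(x[seq_len(n)], nrow = 1L), fs, "ECG",
                    phase, subject, condition)
}
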