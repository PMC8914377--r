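#' Simulate a multi-condition synthetic study
#'
#' Builds a lazy study object: a subject table plus the generator
#' specifications. Recordings are synthesized on demand by
#' [get_recording()], so arbitrarily long studies never have to be held in
#' memory at once. The same study object can be materialized to EDF or CSV
#' files with [write_study()].
#'
#' @param effects a [study_effect_spec()].
#' @param ecg an [ecg_spec()] shared by all subjects.
#' @param pre_minutes,post_minutes length of the pre-rest and post-rest
#'   blocks in whole minutes.
#' @param seed study-level integer seed; every subject's signals derive
#'   deterministically from it.
#' @return An object of class `synthetic_study` with a `$subjects` tibble
#'   (`subject`, `condition`).
#' @examples
#' st <- simulate_study(study_effect_spec(n_subjects_per_condition = 2),
#'                      pre_minutes = 1, post_minutes = 1, seed = 1)
#' st$subjects
#' @export
simulate_study <- function(effects = study_effect_spec(),
                           ecg = ecg_spec(),
                           pre_minutes = 5, post_minutes = 6,
                           seed = 1) {
  stopifnot(inherits(effects, "study_effect_spec"), inherits(ecg, "ecg_spec"))
  subjects <- purrr::map2_dfr(
    effects$conditions, effects$n_subjects,
    function(cond, n) tibble::tibble(condition = cond,
                                     k = seq_len(n)))
  subjects$subject <- sprintf("S%02d", seq_len(nrow(subjects)))
  structure(
    list(subjects = subjects[, c("subject", "condition")],
         effects = effects, ecg = ecg,
         pre_minutes = pre_minutes, post_minutes = post_minutes,
         seed = as.integer(seed)),
    class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf(
    "<synthetic_study> %d subjects, conditions %s (n = %s)\n  pre %g min, post %g min, fs %g Hz, seed %d\n",
    nrow(x$subjects), paste(x$effects$conditions, collapse = "/"),
    paste(x$effects$n_subjects, collapse = "/"),
    x$pre_minutes, x$post_minutes, x$effects$fs, x$seed))
  invisible(x)
}

#' Fetch one subject-phase recording from a study
#'
#' For a `synthetic_study` the block is synthesized deterministically from
#' the study seed; for a `file_study` (see [read_study()]) it is read from
#' the EDF or CSV file listed in the manifest.
#'
#' @param study a study object.
#' @param subject subject identifier present in `study$subjects`.
#' @param phase `"pre"` or `"post"`.
#' @return A `session_recording` with 20 channels (19 EEG + ECG).
#' @export
get_recording <- function(study, subject, phase) {
  UseMethod("get_recording")
}

#' @export
get_recording.synthetic_study <- function(study, subject, phase) {
  row <- study$subjects[study$subjects$subject == subject, ]
  if (nrow(row) != 1L)
    abort(sprintf("unknown subject '%s'", subject))
  dur <- 60 * if (phase == "pre") study$pre_minutes else study$post_minutes
  eeg <- generate_synthetic_eeg(study$effects, subject, row$condition,
                                phase, duration_s = dur, seed = study$seed)
  ecg <- generate_synthetic_ecg(study$ecg, study$effects, subject,
                                row$condition, phase, duration_s = dur,
                                seed = study$seed)
  session_recording(rbind(eeg$signals, ecg$signals), study$effects$fs,
                    c(eeg$channels, "ECG"), phase, subject, row$condition)
}

#' Write a study to disk and read it back
#'
#' `write_study()` materializes every subject-phase block of a study as an
#' EDF file (16-bit, one data record per second) or a plain CSV matrix
#' (channels as columns), plus a YAML manifest mapping subjects to
#' conditions and file paths. `read_study()` loads a manifest and returns a
#' `file_study` whose recordings are read lazily by [get_recording()].
#'
#' @param study a study object supporting [get_recording()].
#' @param dir output directory (created if missing).
#' @param format `"edf"` or `"csv"`.
#' @return `write_study()`: the manifest path, invisibly.
#'   `read_study()`: a `file_study` object.
#' @export
write_study <- function(study, dir, format = c("edf", "csv")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- purrr::pmap(study$subjects, function(subject, condition) {
    files <- list()
    for (phase in c("pre", "post")) {
      rec <- get_recording(study, subject, phase)
      path <- file.path(dir, sprintf("%s_%s.%s", subject, phase, format))
      if (format == "edf") write_edf(rec, path) else write_csv_matrix(rec, path)
      files[[phase]] <- basename(path)
    }
    list(subject = subject, condition = condition,
         pre = files$pre, post = files$post)
  })
  manifest <- list(format = format, fs = study$effects$fs,
                   subjects = entries)
  path <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(manifest, path)
  invisible(path)
}

#' @rdname write_study
#' @param manifest path to a `manifest.yaml` written by [write_study()].
#' @export
read_study <- function(manifest) {
  m <- yaml::read_yaml(manifest)
  subjects <- purrr::map_dfr(m$subjects, function(e)
    tibble::tibble(subject = e$subject, condition = e$condition,
                   pre = e$pre, post = e$post))
  structure(list(subjects = subjects, dir = dirname(manifest),
                 format = m$format, fs = m$fs),
            class = "file_study")
}

#' @export
get_recording.file_study <- function(study, subject, phase) {
  row <- study$subjects[study$subjects$subject == subject, ]
  if (nrow(row) != 1L) abort(sprintf("unknown subject '%s'", subject))
  path <- file.path(study$dir, row[[phase]])
  rec <- if (study$format == "edf") read_edf(path)
         else read_csv_matrix(path, fs = study$fs)
  rec$phase <- phase
  rec$subject <- subject
  rec$condition <- row$condition
  rec
}

# plain CSV matrix: one column per channel, header row of labels
write_csv_matrix <- function(rec, path) {
  df <- as.data.frame(t(rec$signals))
  names(df) <- rec$channels
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

read_csv_matrix <- function(path, fs) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- unname(t(as.matrix(df)))
  session_recording(m, fs, names(df))
}
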