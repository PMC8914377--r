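# Minimal EDF (European Data Format) writer/reader: 16-bit continuous
# recordings, one data record per second, enough for the study manifests
# this package emits. Values round-trip up to the 16-bit quantization of
# each channel's physical range.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = width, flag = "-")
}

edf_num <- function(x, width) {
  s <- formatC(x, format = "g", digits = width - 2)
  if (nchar(s) > width) s <- substr(s, 1, width)
  edf_pad(s, width)
}

#' Write and read EDF recordings
#'
#' `write_edf()` stores a [session_recording()] as a 16-bit EDF file with a
#' 1-second data record, channel labels preserved, and each channel scaled
#' to its own physical range. `read_edf()` reads such a file back. Samples
#' beyond the last whole second are dropped on write (EDF stores whole data
#' records only).
#'
#' @param rec a `session_recording`.
#' @param path file path.
#' @return `write_edf()`: `path`, invisibly. `read_edf()`: a
#'   `session_recording` (phase/subject/condition metadata are not part of
#'   EDF and come back unset; [read_study()] restores them from the
#'   manifest).
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "session_recording"))
  fs <- rec$fs
  if (fs != round(fs)) abort("EDF writer requires an integer sampling rate.")
  ns <- nrow(rec$signals)
  n_rec <- ncol(rec$signals) %/% fs
  if (n_rec < 1L) abort("recording shorter than one data record (1 s).")
  sig <- rec$signals[, seq_len(n_rec * fs), drop = FALSE]

  pmin <- apply(sig, 1, min)
  pmax <- apply(sig, 1, max)
  flat <- pmax - pmin < 1e-12
  pmin[flat] <- pmin[flat] - 1
  pmax[flat] <- pmax[flat] + 1
  dmin <- -32768; dmax <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8), edf_pad("X X X X", 80), edf_pad("Startdate X X X X", 80),
    "01.01.00", "00.00.00",
    edf_pad(256 * (1 + ns), 8), edf_pad("", 44),
    edf_pad(n_rec, 8), edf_pad(1, 8), edf_pad(ns, 4))
  writeChar(hdr, con, eos = NULL)
  field <- function(f, width)
    writeChar(paste0(vapply(f, edf_pad, "", width = width), collapse = ""),
              con, eos = NULL)
  field(rec$channels, 16)
  field(rep("", ns), 80)
  field(rep("uV", ns), 8)
  field(vapply(pmin, edf_num, "", width = 8), 8)
  field(vapply(pmax, edf_num, "", width = 8), 8)
  field(rep(dmin, ns), 8)
  field(rep(dmax, ns), 8)
  field(rep("", ns), 80)
  field(rep(fs, ns), 8)
  field(rep("", ns), 32)

  # re-read the printed physical ranges so the scaling matches the header
  pmin_h <- as.numeric(vapply(pmin, edf_num, "", width = 8))
  pmax_h <- as.numeric(vapply(pmax, edf_num, "", width = 8))
  gain <- (dmax - dmin) / (pmax_h - pmin_h)
  for (r in seq_len(n_rec)) {
    for (s in seq_len(ns)) {
      x <- sig[s, ((r - 1L) * fs + 1L):(r * fs)]
      d <- round((x - pmin_h[s]) * gain[s] + dmin)
      writeBin(as.integer(pmin(pmax(d, dmin), dmax)), con,
               size = 2L, endian = "little")
    }
  }
  invisible(path)
}

#' @rdname write_edf
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)  # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)      # transducer
  for (i in seq_len(ns)) rd(8)       # physical dim
  pmin <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  pmax <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dmin <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dmax <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  for (i in seq_len(ns)) rd(80)      # prefiltering
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8)), 0L)
  for (i in seq_len(ns)) rd(32)
  if (length(unique(spr)) != 1L)
    abort("mixed per-channel sampling rates are not supported.")
  fs <- spr[1] / dur
  sig <- matrix(0, nrow = ns, ncol = n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    for (s in seq_len(ns)) {
      d <- readBin(con, "integer", n = spr[s], size = 2L, signed = TRUE,
                   endian = "little")
      sig[s, ((r - 1L) * spr[s] + 1L):(r * spr[s])] <-
        (d - dmin[s]) / (dmax[s] - dmin[s]) * (pmax[s] - pmin[s]) + pmin[s]
    }
  }
  session_recording(sig, fs, labels)
}
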