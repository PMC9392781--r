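#' @name filtering
#' @title Frequency filtering
#' @description Band-pass plus powerline-notch filtering, applied
#'   zero-phase (forward-backward) per channel. The band-pass is a
#'   Butterworth of order `bp_order` designed directly as a band filter;
#'   the notch is a Butterworth band-stop of order `notch_order` and
#'   width `notch_bw` centred on `notch_freq`.
NULL

.design_bandpass <- function(cfg, fs) {
  signal::butter(cfg$bp_order, c(cfg$bp_low, cfg$bp_high) / (fs / 2),
                 type = "pass")
}

.design_notch <- function(cfg, fs) {
  signal::butter(cfg$notch_order,
                 c(cfg$notch_freq - cfg$notch_bw / 2,
                   cfg$notch_freq + cfg$notch_bw / 2) / (fs / 2),
                 type = "stop")
}

.design_pop_lowpass <- function(cfg, fs) {
  signal::butter(cfg$pop_lp_order, cfg$pop_lp / (fs / 2), type = "low")
}

.filtfilt_rows <- function(data, flt) {
  out <- data
  for (i in seq_len(nrow(data))) {
    out[i, ] <- signal::filtfilt(flt, data[i, ])
  }
  out
}

#' Apply the band-pass and notch filters to a recording
#'
#' Removes DC and drifts below `bp_low`, content above `bp_high`, and
#' powerline interference at `notch_freq`. Both filters run zero-phase
#' (forward-backward), so the effective magnitude response is the square
#' of the designed one and no group delay is introduced.
#'
#' @param rec an `eeg_recording`.
#' @param cfg a [pipeline_config()].
#' @return A filtered `eeg_recording` of identical shape.
#' @export
apply_bandpass_notch <- function(rec, cfg = pipeline_config()) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (rec$fs <= 2 * cfg$bp_high) {
    stop("sampling-rate error: fs = ", rec$fs,
         " Hz cannot represent the ", cfg$bp_high, " Hz band edge",
         call. = FALSE)
  }
  bp <- .design_bandpass(cfg, rec$fs)
  nt <- .design_notch(cfg, rec$fs)
  out <- .filtfilt_rows(.filtfilt_rows(rec$data, bp), nt)
  eeg_recording(out, rec$channel_labels, rec$fs, rec$origin)
}

#' Magnitude response of the filtering cascade
#'
#' Evaluates the designed transfer function (band-pass times notch) at
#' the given frequencies, squared to account for the zero-phase
#' (forward-backward) application. Used by tests as the response oracle
#' and exported because it is handy when choosing band edges.
#'
#' @param freqs frequencies (Hz).
#' @param fs sampling rate (Hz).
#' @param cfg a [pipeline_config()].
#' @return Numeric vector of linear magnitude gains.
#' @export
cascade_response <- function(freqs, fs, cfg = pipeline_config()) {
  bp <- .design_bandpass(cfg, fs)
  nt <- .design_notch(cfg, fs)
  H <- function(flt, f) {
    z <- exp(-1i * 2 * pi * f / fs)
    vapply(z, function(zz) {
      num <- sum(flt$b * zz^(seq_along(flt$b) - 1))
      den <- sum(flt$a * zz^(seq_along(flt$a) - 1))
      Mod(num / den)
    }, 0)
  }
  (H(bp, freqs) * H(nt, freqs))^2
}
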