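#' Pipeline configuration
#'
#' Collects every tunable constant of the preprocessing pipeline in one
#' validated object. Amplitudes are in millivolts, durations in seconds,
#' frequencies in Hz throughout the package.
#'
#' @param bp_low,bp_high,bp_order band-pass edges (Hz) and Butterworth
#'   order (0.5-100 Hz, 4th order by default).
#' @param notch_freq,notch_bw,notch_order powerline notch centre (Hz),
#'   stop-band width (Hz) and order (50 Hz, 2nd order by default).
#' @param peak_thresh absolute amplitude (mV) defining an abnormal peak.
#' @param margin seconds of data excised before and after each detected
#'   error.
#' @param sentinel_channels electrodes that must all exceed `peak_thresh`
#'   near-simultaneously for a global movement artifact.
#' @param coincidence_win width (s) of the sliding window within which
#'   sentinel exceedances count as simultaneous.
#' @param seg_len,min_seg segment length and minimum kept length (s).
#' @param chan_frac per-channel flagged-sample fraction above which a
#'   channel is marked for interpolation (strictly greater).
#' @param max_interp maximum number of channels interpolated per segment;
#'   more marks reject the segment (strictly greater).
#' @param pop_win,pop_overlap,pop_lp,pop_amp electrode-pop detection:
#'   window length (s), fractional overlap, low-pass cutoff (Hz) and
#'   flagging amplitude (mV).
#' @param pop_lp_order order of the pop low-pass Butterworth filter
#'   (applied zero-phase on a copy).
#' @param flat_eps,flat_min_dur flatline/saturation tolerance (mV) and
#'   minimum duration (s).
#' @param psd_lo,psd_hi retained PSD band (Hz).
#' @param psd_win,psd_overlap Welch estimator window length (s) and
#'   fractional overlap.
#' @param topo_size side length (pixels) of the square topographic map.
#' @param topo_fill value written to pixels outside the head disc.
#' @param spline_m,spline_terms,spline_lambda spherical-spline order,
#'   Legendre truncation degree and ridge regularization.
#' @param ica_max_iter,ica_wchange,ica_ext_points extended-infomax
#'   stopping parameters: iteration cap, weight-change tolerance, and
#'   subsample size for the sub/super-Gaussian sign estimate.
#' @param rng_seed integer seed recorded with every decomposition.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(bp_low = 0.5, bp_high = 100, bp_order = 4,
                            notch_freq = 50, notch_bw = 4, notch_order = 2,
                            peak_thresh = 5, margin = 10,
                            sentinel_channels = c("Fp1", "Fp2", "O1", "O2", "T5", "T6", "Cz"),
                            coincidence_win = 1,
                            seg_len = 600, min_seg = 10,
                            chan_frac = 0.20, max_interp = 2,
                            pop_win = 5, pop_overlap = 0.5, pop_lp = 5,
                            pop_amp = 0.5, pop_lp_order = 4,
                            flat_eps = 1e-4, flat_min_dur = 1,
                            psd_lo = 1, psd_hi = 90,
                            psd_win = 2, psd_overlap = 0.5,
                            topo_size = 67, topo_fill = 0,
                            spline_m = 4, spline_terms = 7, spline_lambda = 1e-5,
                            ica_max_iter = 512, ica_wchange = 1e-6,
                            ica_ext_points = 6000,
                            rng_seed = 1L) {
  cfg <- list(
    bp_low = bp_low, bp_high = bp_high, bp_order = bp_order,
    notch_freq = notch_freq, notch_bw = notch_bw, notch_order = notch_order,
    peak_thresh = peak_thresh, margin = margin,
    sentinel_channels = normalize_labels(sentinel_channels),
    coincidence_win = coincidence_win,
    seg_len = seg_len, min_seg = min_seg,
    chan_frac = chan_frac, max_interp = max_interp,
    pop_win = pop_win, pop_overlap = pop_overlap, pop_lp = pop_lp,
    pop_amp = pop_amp, pop_lp_order = pop_lp_order,
    flat_eps = flat_eps, flat_min_dur = flat_min_dur,
    psd_lo = psd_lo, psd_hi = psd_hi,
    psd_win = psd_win, psd_overlap = psd_overlap,
    topo_size = topo_size, topo_fill = topo_fill,
    spline_m = spline_m, spline_terms = spline_terms,
    spline_lambda = spline_lambda,
    ica_max_iter = ica_max_iter, ica_wchange = ica_wchange,
    ica_ext_points = ica_ext_points,
    rng_seed = as.integer(rng_seed)
  )
  num <- c("bp_low", "bp_high", "bp_order", "notch_freq", "notch_bw",
           "notch_order", "peak_thresh", "margin", "coincidence_win",
           "seg_len", "min_seg", "max_interp", "pop_win", "pop_lp",
           "pop_amp", "pop_lp_order", "flat_eps", "flat_min_dur",
           "psd_lo", "psd_hi", "psd_win", "topo_size", "spline_m",
           "spline_terms", "spline_lambda", "ica_max_iter", "ica_wchange",
           "ica_ext_points")
  bad <- num[!vapply(cfg[num], function(v) is.numeric(v) && v > 0, TRUE)]
  if (length(bad)) {
    stop("pipeline_config: fields must be strictly positive: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!(cfg$chan_frac > 0 && cfg$chan_frac < 1)) {
    stop("pipeline_config: chan_frac must be in (0, 1)", call. = FALSE)
  }
  if (!(cfg$pop_overlap >= 0 && cfg$pop_overlap < 1)) {
    stop("pipeline_config: pop_overlap must be in [0, 1)", call. = FALSE)
  }
  if (!(cfg$min_seg < cfg$seg_len)) {
    stop("pipeline_config: min_seg must be smaller than seg_len", call. = FALSE)
  }
  structure(cfg, class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  cat("  band-pass ", x$bp_low, "-", x$bp_high, " Hz (order ", x$bp_order,
      "), notch ", x$notch_freq, " Hz (order ", x$notch_order, ")\n", sep = "")
  cat("  peak |x| > ", x$peak_thresh, " mV on ",
      paste(x$sentinel_channels, collapse = ","),
      "; margin ", x$margin, " s\n", sep = "")
  cat("  segments ", x$seg_len, " s (min ", x$min_seg, " s); QC > ",
      100 * x$chan_frac, "% marks, > ", x$max_interp, " marks reject\n", sep = "")
  cat("  pops: ", x$pop_win, " s windows, ", 100 * x$pop_overlap,
      "% overlap, < ", x$pop_lp, " Hz, > ", x$pop_amp, " mV\n", sep = "")
  invisible(x)
}
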