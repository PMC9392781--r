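#' Min-max normalization to [0, 1]
#'
#' `(x - min) / (max - min)`, preserving shape and attributes of numeric
#' vectors and matrices. A constant input cannot be scaled; it maps to
#' all 0.5 with a warning so downstream file formats stay well-defined.
#'
#' @param x non-empty numeric vector or matrix.
#' @return Same shape as `x`, values in `[0, 1]`.
#' @export
minmax_normalize <- function(x) {
  if (length(x) == 0L) stop("minmax_normalize: empty input", call. = FALSE)
  lo <- min(x); hi <- max(x)
  if (hi - lo <= 0) {
    warning("minmax_normalize: constant input, returning 0.5 everywhere")
    x[] <- 0.5
    return(x)
  }
  (x - lo) / (hi - lo)
}

#' Welch power spectral density of a component, 1-90 Hz
#'
#' Averaged modified periodogram: `psd_win`-second Hamming windows with
#' `psd_overlap` fractional overlap, power in dB, cropped to the
#' `[psd_lo, psd_hi]` Hz band (inclusive) to discard the roll-off of the
#' analog-band filtering, then min-max normalized to `[0, 1]`. With the
#' 2 s default window the resolution is 0.5 Hz.
#'
#' @param source numeric vector, one IC time-series.
#' @param fs sampling rate (Hz).
#' @param cfg a [pipeline_config()].
#' @param normalize set `FALSE` to obtain the raw dB spectrum (used by
#'   tests and plots).
#' @return Numeric vector of PSD values with attribute `freq` (Hz).
#' @export
compute_psd <- function(source, fs, cfg = pipeline_config(),
                        normalize = TRUE) {
  wl <- as.integer(round(cfg$psd_win * fs))
  if (length(source) < wl) {
    stop("length error: source has ", length(source),
         " samples but one Welch window needs ", wl, call. = FALSE)
  }
  hop <- max(1L, as.integer(round(wl * (1 - cfg$psd_overlap))))
  win <- 0.54 - 0.46 * cos(2 * pi * (seq_len(wl) - 1) / (wl - 1))  # Hamming
  starts <- seq.int(0L, length(source) - wl, by = hop)
  acc <- numeric(wl %/% 2 + 1)
  for (s in starts) {
    x <- source[(s + 1):(s + wl)] * win
    p <- abs(stats::fft(x))^2 / (fs * sum(win^2))
    acc <- acc + p[seq_len(wl %/% 2 + 1)]
  }
  pxx <- acc / length(starts)
  # one-sided: double everything except DC (and Nyquist for even lengths)
  ny <- wl %/% 2 + 1
  pxx[2:(ny - 1)] <- 2 * pxx[2:(ny - 1)]
  freq <- (seq_len(ny) - 1) * fs / wl
  keep <- freq >= cfg$psd_lo & freq <= cfg$psd_hi
  out <- 10 * log10(pmax(pxx[keep], .Machine$double.xmin))
  if (normalize) out <- minmax_normalize(out)
  attr(out, "freq") <- freq[keep]
  out
}

# grid coordinates and head-disc mask; pure function of the config
.topo_grid <- function(cfg) {
  ax <- seq(-1, 1, length.out = cfg$topo_size)
  gx <- matrix(rep(ax, each = cfg$topo_size), cfg$topo_size)   # col -> x
  gy <- matrix(rep(rev(ax), cfg$topo_size), cfg$topo_size)     # row 1 -> +y
  r <- sqrt(gx^2 + gy^2)
  list(x = gx, y = gy, inside = r <= 1)
}

#' Topographic scalp map of a component pattern
#'
#' Projects the montage's electrodes onto the head disc (azimuthal
#' equidistant projection, nasion up), evaluates the spherical-spline
#' interpolant of the per-channel pattern on a `topo_size` x `topo_size`
#' pixel grid, min-max normalizes the in-head pixels to `[0, 1]` and
#' fills pixels outside the head disc with `topo_fill`. Row 1 of the
#' returned matrix is the front of the head, so the upper-left pixel is
#' the left-nasion corner and the lower-right the right-inion corner.
#'
#' @param component_pattern numeric vector, one weight per channel
#'   (typically a column of the ICA mixing matrix).
#' @param montage a `montage_positions` with one entry per pattern value.
#' @param cfg a [pipeline_config()].
#' @return `topo_size` x `topo_size` numeric matrix.
#' @export
compute_topomap <- function(component_pattern, montage,
                            cfg = pipeline_config()) {
  if (length(component_pattern) != length(montage$labels)) {
    stop("dimension error: pattern has ", length(component_pattern),
         " values for ", length(montage$labels), " electrodes",
         call. = FALSE)
  }
  g <- .topo_grid(cfg)
  # map in-head pixels back onto the sphere (inverse of the projection)
  px <- g$x[g$inside]; py <- g$y[g$inside]
  rho <- sqrt(px^2 + py^2)
  outer_frac <- 0.95
  inc <- rho / outer_frac * (pi / 2)
  azi <- atan2(px, py)
  sph <- cbind(sin(inc) * sin(azi), sin(inc) * cos(azi), cos(inc))
  L <- spherical_spline_operator(montage$pos3d, sph, m = cfg$spline_m,
                                 terms = cfg$spline_terms,
                                 lambda = cfg$spline_lambda)
  vals <- as.numeric(L %*% component_pattern)
  grid <- matrix(cfg$topo_fill, cfg$topo_size, cfg$topo_size)
  grid[g$inside] <- minmax_normalize(vals)
  grid
}

#' Assemble one labelled IC sample
#'
#' Bundles a component's unnormalized time-series with its normalized
#' PSD and topographic map. The time-series is stored exactly as given —
#' amplitude is informative and must survive to the written files.
#'
#' @param source IC time-series (numeric vector).
#' @param pattern per-channel scalp weights (mixing-matrix column).
#' @param label `"artifact"` or `"not-artifact"`.
#' @param provenance list with at least `patient` and `segment`
#'   identifiers; an `ic` index is added by callers that have one.
#' @param montage a `montage_positions`.
#' @param fs sampling rate of the source (Hz).
#' @param cfg a [pipeline_config()].
#' @return An `ic_sample`: `label`, `timeseries`, `psd`, `topomap`,
#'   `provenance`.
#' @export
assemble_sample <- function(source, pattern, label, provenance, montage,
                            fs = 256, cfg = pipeline_config()) {
  label <- match.arg(label, c("artifact", "not-artifact"))
  structure(list(label = label,
                 timeseries = as.numeric(source),
                 psd = compute_psd(as.numeric(source), fs, cfg),
                 topomap = compute_topomap(as.numeric(pattern), montage, cfg),
                 provenance = provenance),
            class = "ic_sample")
}

#' @export
print.ic_sample <- function(x, ...) {
  cat("<ic_sample> ", x$label, ", ", length(x$timeseries), " samples, psd[",
      length(x$psd), "], topomap ", nrow(x$topomap), "x", ncol(x$topomap),
      "\n", sep = "")
  invisible(x)
}
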