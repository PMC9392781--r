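#' @name synthetic_data
#' @title Synthetic EEG with ground-truth artifact annotations
#' @description The generator emulates what the detectors must cope
#'   with: per-channel pink (1/f) background at physiological amplitude
#'   (about 0.05 mV RMS) with a shared 10 Hz alpha rhythm weighted
#'   toward posterior electrodes, plus injected flatlines, saturation
#'   rails, global movement peaks and single-electrode pops, each
#'   annotated with its exact sample span so detector recall can be
#'   scored. It is deliberately not a biophysical head model.
NULL

#' Ground-truth artifact annotations
#'
#' @param type one of `"flatline"`, `"saturation"`, `"global_peak"`,
#'   `"electrode_pop"` per event.
#' @param channel affected channel label, or `"all"` for multi-channel
#'   events.
#' @param start,end half-open 0-based sample span.
#' @param magnitude event amplitude in mV (interpretation per type).
#' @return Data frame of class `annotation_set`.
#' @export
annotation_set <- function(type = character(), channel = character(),
                           start = integer(), end = integer(),
                           magnitude = numeric()) {
  ok <- c("flatline", "saturation", "global_peak", "electrode_pop")
  if (!all(type %in% ok)) {
    stop("plan error: unknown event type(s): ",
         paste(setdiff(type, ok), collapse = ", "), call. = FALSE)
  }
  df <- data.frame(type = type, channel = channel,
                   start = as.numeric(start), end = as.numeric(end),
                   magnitude = magnitude, stringsAsFactors = FALSE)
  class(df) <- c("annotation_set", "data.frame")
  df
}

# pink noise by shaping white Gaussian noise with a 1/sqrt(f) amplitude
# envelope in the frequency domain
.pink_noise <- function(n, fs) {
  wn <- stats::rnorm(n)
  sp <- stats::fft(wn)
  f <- c(1, seq_len(n - 1))                # avoid dividing DC by zero
  f <- pmin(f, n - f + 1)                  # mirror for negative freqs
  sp <- sp / sqrt(f)
  sp[1] <- 0
  Re(stats::fft(sp, inverse = TRUE)) / n
}

#' Generate background EEG
#'
#' Pink-noise channels plus a shared 10 Hz alpha oscillation whose
#' amplitude is tripled on the posterior electrodes (O1, O2, P3, P4,
#' Pz), scaled to about 0.05 mV total RMS — far below every detector
#' threshold, so clean background must produce zero detections.
#'
#' @param n_channels number of channels (labels taken from the canonical
#'   montage order).
#' @param duration_s recording length in seconds (>= 1).
#' @param fs sampling rate (Hz).
#' @param seed integer RNG seed; identical seeds give identical output.
#' @return An `eeg_recording`.
#' @export
gen_background <- function(n_channels = 19, duration_s = 60, fs = 256,
                           seed = 1L) {
  if (duration_s < 1) stop("gen_background: duration_s must be >= 1",
                           call. = FALSE)
  labels <- eegic_channels()[seq_len(n_channels)]
  n <- as.integer(round(duration_s * fs))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  target_rms <- 0.05
  t <- (seq_len(n) - 1) / fs
  alpha <- sin(2 * pi * 10 * t + stats::runif(1, 0, 2 * pi))
  posterior <- c("O1", "O2", "P3", "P4", "Pz")
  data <- matrix(0, n_channels, n)
  for (i in seq_len(n_channels)) {
    pk <- .pink_noise(n, fs)
    pk <- pk / stats::sd(pk)
    aw <- if (labels[i] %in% posterior) 0.9 else 0.3
    x <- pk + aw * alpha
    data[i, ] <- x / stats::sd(x) * target_rms
  }
  eeg_recording(data, labels, fs,
                origin = sprintf("synthetic(seed=%d)", as.integer(seed)))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Inject annotated artifacts into a recording
#'
#' Event morphologies mirror what long-term monitoring produces:
#' * `flatline` — the scoped channel(s) pinned to an exact constant;
#' * `saturation` — clamped at the magnitude rail (default 2 mV);
#' * `global_peak` — a smooth transient of at least 6 mV applied to all
#'   sentinel channels simultaneously (and attenuated elsewhere);
#' * `electrode_pop` — a single-channel step with slow exponential
#'   recovery, energy below 5 Hz and amplitude above 0.5 mV.
#' Samples outside every event span are bit-identical to the input.
#'
#' @param rec an `eeg_recording`.
#' @param plan an `annotation_set` within bounds.
#' @param cfg a [pipeline_config()] (for the sentinel set).
#' @return The modified recording; the plan is returned unchanged as the
#'   ground truth via attribute `"plan"`.
#' @export
inject_artifacts <- function(rec, plan, cfg = pipeline_config()) {
  n <- ncol(rec$data)
  if (nrow(plan) && (any(plan$start < 0) || any(plan$end > n) ||
                     any(plan$end <= plan$start))) {
    stop("plan error: event outside recording bounds", call. = FALSE)
  }
  data <- rec$data
  for (i in seq_len(nrow(plan))) {
    ev <- plan[i, ]
    span <- (ev$start + 1):ev$end
    len <- length(span)
    chans <- if (ev$channel == "all") rec$channel_labels else
      normalize_labels(ev$channel)
    switch(ev$type,
      flatline = {
        data[chans, span] <- ev$magnitude
      },
      saturation = {
        data[chans, span] <- ev$magnitude
      },
      global_peak = {
        # trapezoid-enveloped 8 Hz oscillation: exceeds the detection
        # threshold over nearly the whole annotated span, and its energy
        # sits inside the analysis band so the event survives band-pass
        # filtering (a pure baseline swell would not)
        ramp <- max(1, round(0.05 * len))
        env <- pmin(1, pmin(seq_len(len), len + 1 - seq_len(len)) / ramp)
        carrier <- sin(2 * pi * 8 * (seq_len(len) - 1) / rec$fs)
        pulse <- ev$magnitude * env * carrier
        targets <- union(cfg$sentinel_channels,
                         if (ev$channel == "all") rec$channel_labels else
                           chans)
        for (ch in targets) {
          w <- if (ch %in% cfg$sentinel_channels) 1 else 0.5
          data[ch, span] <- data[ch, span] + w * pulse
        }
      },
      electrode_pop = {
        # abrupt baseline step with slow exponential recovery; the decay
        # constant keeps the shift near its full value over the whole
        # event, so every overlapping analysis window sees it
        step <- ev$magnitude * exp(-(seq_len(len) - 1) / (4.5 * len))
        for (ch in chans) data[ch, span] <- data[ch, span] + step
      }
    )
  }
  out <- eeg_recording(data, rec$channel_labels, rec$fs, rec$origin)
  attr(out, "plan") <- plan
  out
}

#' Specification of a known source mixture
#'
#' @param mixing full-column-rank mixing matrix (channels x sources).
#' @param distributions per-source: `"laplacian"` (super-Gaussian),
#'   `"uniform"` (sub-Gaussian) or `"sinusoid"`.
#' @param duration_s duration (s).
#' @param fs sampling rate (Hz).
#' @param seed integer RNG seed.
#' @return List of class `mixture_spec`.
#' @export
mixture_spec <- function(mixing, distributions, duration_s = 60, fs = 256,
                         seed = 1L) {
  mixing <- as.matrix(mixing)
  if (ncol(mixing) != length(distributions)) {
    stop("spec error: one distribution per mixing column", call. = FALSE)
  }
  if (qr(mixing)$rank < ncol(mixing)) {
    stop("spec error: mixing matrix is rank-deficient", call. = FALSE)
  }
  ok <- c("laplacian", "uniform", "sinusoid")
  if (!all(distributions %in% ok)) {
    stop("spec error: unknown distribution(s): ",
         paste(setdiff(distributions, ok), collapse = ", "), call. = FALSE)
  }
  structure(list(mixing = mixing, distributions = distributions,
                 duration_s = duration_s, fs = fs,
                 seed = as.integer(seed)),
            class = "mixture_spec")
}

#' Generate a recording from a known mixture
#'
#' Draws unit-variance sources per the spec's distributions, mixes them
#' with the given matrix and returns both — the harness for ICA
#' source-recovery scoring.
#'
#' @param spec a [mixture_spec()].
#' @return List with `mixed` (channels x samples matrix), `sources`
#'   (sources x samples) and `spec`.
#' @export
gen_mixture <- function(spec) {
  stopifnot(inherits(spec, "mixture_spec"))
  n <- as.integer(round(spec$duration_s * spec$fs))
  k <- length(spec$distributions)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  S <- matrix(0, k, n)
  for (i in seq_len(k)) {
    S[i, ] <- switch(spec$distributions[i],
      laplacian = {
        u <- stats::runif(n, -0.5, 0.5)
        -sign(u) * log(1 - 2 * abs(u)) / sqrt(2)
      },
      uniform = stats::runif(n, -sqrt(3), sqrt(3)),
      sinusoid = sqrt(2) * sin(2 * pi * (5 + i) * (seq_len(n) - 1) / spec$fs)
    )
  }
  list(mixed = spec$mixing %*% S, sources = S, spec = spec)
}

#' Match recovered sources to truth by greedy correlation
#'
#' One-to-one assignment of estimated to true sources maximizing
#' absolute Pearson correlation (greedy on the correlation matrix).
#'
#' @param est,true matrices with one source per row.
#' @return Data frame with `true`, `est`, `abs_corr` per matched pair.
#' @export
match_sources <- function(est, true) {
  C <- abs(stats::cor(t(true), t(est)))
  k <- nrow(true)
  out <- data.frame(true = integer(k), est = integer(k), abs_corr = numeric(k))
  for (i in seq_len(k)) {
    idx <- which(C == max(C, na.rm = TRUE), arr.ind = TRUE)[1, ]
    out$true[i] <- idx[1]; out$est[i] <- idx[2]
    out$abs_corr[i] <- C[idx[1], idx[2]]
    C[idx[1], ] <- -Inf
    C[, idx[2]] <- -Inf
  }
  out[order(out$true), ]
}

#' Intersection-over-union of two sample intervals
#'
#' @param a_start,a_end,b_start,b_end half-open interval bounds.
#' @return IoU in `[0, 1]`.
#' @export
interval_iou <- function(a_start, a_end, b_start, b_end) {
  inter <- max(0, min(a_end, b_end) - max(a_start, b_start))
  uni <- (a_end - a_start) + (b_end - b_start) - inter
  if (uni <= 0) return(0)
  inter / uni
}
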