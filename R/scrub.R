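#' Detect isoelectric flatlines and amplifier saturation
#'
#' A flatline is a run of at least `flat_min_dur` seconds during which
#' consecutive-sample absolute differences on some channel stay below
#' `flat_eps` mV. Saturation is a run of at least the same duration
#' during which a channel stays within `flat_eps` of its own amplitude
#' rail (the channel's minimum or maximum over the whole recording).
#' Detection on any single channel marks the span for excision on all
#' channels.
#'
#' @param rec a (filtered) `eeg_recording`.
#' @param cfg a [pipeline_config()].
#' @return An `interval_set` with reasons `"flat"` / `"saturated"`.
#' @export
find_flat_saturated <- function(rec, cfg = pipeline_config()) {
  n <- ncol(rec$data)
  min_run <- max(2L, as.integer(ceiling(cfg$flat_min_dur * rec$fs)))
  out <- interval_set()
  runs_of <- function(mask, min_len) {
    r <- rle(mask)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    ok <- r$values & r$lengths >= min_len
    cbind(starts[ok], ends[ok])
  }
  for (i in seq_len(nrow(rec$data))) {
    x <- rec$data[i, ]
    # flat: n consecutive near-equal samples show as n-1 small diffs
    dm <- abs(diff(x)) < cfg$flat_eps
    fr <- runs_of(dm, min_run - 1L)
    if (nrow(fr)) {
      out <- rbind(out, interval_set(fr[, 1], fr[, 2] + 1L, "flat"))
    }
    for (rail in c(min(x), max(x))) {
      sm <- abs(x - rail) < cfg$flat_eps
      sr <- runs_of(sm, min_run)
      if (nrow(sr)) {
        out <- rbind(out, interval_set(sr[, 1], sr[, 2], "saturated"))
      }
    }
  }
  if (nrow(out) == 0L) return(interval_set())
  out <- interval_set(out$start, out$end, out$reason)
  iv_merge(out)
}

#' Detect global abnormal peaks on the sentinel electrodes
#'
#' Finds spans where every sentinel channel exceeds `peak_thresh` mV in
#' absolute value within the same `coincidence_win`-second sliding
#' window. Exceedances confined to a proper subset of the sentinels are
#' ignored: a genuine whole-head movement artifact registers on all of
#' them at (physiologically) the same time.
#'
#' @param rec an `eeg_recording` containing all sentinel channels.
#' @param cfg a [pipeline_config()].
#' @return An `interval_set` with reason `"peak"`.
#' @export
find_global_peaks <- function(rec, cfg = pipeline_config()) {
  sent <- cfg$sentinel_channels
  missing <- setdiff(sent, rec$channel_labels)
  if (length(missing)) {
    stop("montage error: sentinel channel(s) absent: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  n <- ncol(rec$data)
  half <- as.integer(round(cfg$coincidence_win * rec$fs / 2))
  dilate <- function(mask, w) {
    if (!any(mask) || w == 0L) return(mask)
    iv <- iv_from_mask(mask)
    iv_mask(iv_dilate(iv, w, n), n)
  }
  co <- rep(TRUE, n)     # samples near which *every* sentinel exceeds
  any_exc <- rep(FALSE, n)
  for (ch in sent) {
    exc <- abs(rec$data[ch, ]) > cfg$peak_thresh
    any_exc <- any_exc | exc
    co <- co & dilate(exc, half)
    if (!any(co)) return(interval_set())
  }
  # report the actual exceedance samples inside coincidence regions;
  # exceedance runs closer than one coincidence window belong to the
  # same physical event and are fused
  final <- any_exc & dilate(co, half)
  if (!any(final)) return(interval_set())
  iv <- iv_from_mask(final, "peak")
  gap <- 2L * half
  if (nrow(iv) > 1L) {
    s <- iv$start[1]; e <- iv$end[1]
    out_s <- numeric(0); out_e <- numeric(0)
    for (i in seq_len(nrow(iv))[-1]) {
      if (iv$start[i] - e <= gap) {
        e <- iv$end[i]
      } else {
        out_s <- c(out_s, s); out_e <- c(out_e, e)
        s <- iv$start[i]; e <- iv$end[i]
      }
    }
    iv <- interval_set(c(out_s, s), c(out_e, e), "peak")
  }
  iv
}

#' Excise bad intervals with safety margins
#'
#' Every bad interval is widened by `margin` seconds on each side,
#' widened intervals are unioned and clipped to the recording, and the
#' retained complement is returned as an ordered list of contiguous runs.
#' Runs keep their offset into the parent recording; they are never
#' concatenated, preserving each run's internal temporal coherence.
#'
#' @param rec an `eeg_recording`.
#' @param bad an `interval_set` of detected errors.
#' @param cfg a [pipeline_config()].
#' @return List of `eeg_run` objects: `data`, `offset` (0-based sample
#'   index into `rec`), `fs`, `parent`.
#' @export
excise <- function(rec, bad, cfg = pipeline_config()) {
  n <- ncol(rec$data)
  if (nrow(bad) && max(bad$end) > n) {
    stop("excise: interval beyond recording end", call. = FALSE)
  }
  pad <- as.integer(round(cfg$margin * rec$fs))
  dil <- iv_dilate(bad, pad, n)
  keep <- iv_complement(dil, n)
  lapply(seq_len(nrow(keep)), function(i) {
    s <- keep$start[i]; e <- keep$end[i]
    structure(list(data = rec$data[, (s + 1):e, drop = FALSE],
                   offset = s, fs = rec$fs, parent = rec$origin,
                   channel_labels = rec$channel_labels),
              class = "eeg_run")
  })
}

#' @export
print.eeg_run <- function(x, ...) {
  cat("<eeg_run> ", nrow(x$data), " ch x ", ncol(x$data), " samples @ ",
      x$fs, " Hz, offset ", x$offset, "\n", sep = "")
  invisible(x)
}

#' Full error scrub of one recording
#'
#' Convenience wrapper running flat/saturation detection, global-peak
#' detection and margin excision in the pipeline's order.
#'
#' @inheritParams excise
#' @return List with `runs` (list of `eeg_run`), `bad` (merged
#'   `interval_set`) and `excised_samples` (count after dilation).
#' @export
scrub_recording <- function(rec, cfg = pipeline_config()) {
  bad <- iv_merge(rbind_intervals(find_flat_saturated(rec, cfg),
                                  find_global_peaks(rec, cfg)))
  runs <- excise(rec, bad, cfg)
  n <- ncol(rec$data)
  kept <- sum(vapply(runs, function(r) ncol(r$data), 0))
  list(runs = runs, bad = bad, excised_samples = n - kept)
}

# rbind two interval sets preserving the class
rbind_intervals <- function(a, b) {
  interval_set(c(a$start, b$start), c(a$end, b$end), c(a$reason, b$reason))
}
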