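#' Split a retained run into analysis segments
#'
#' Runs of at least `seg_len` seconds yield consecutive non-overlapping
#' `seg_len` segments; when a remainder is left, one extra full-length
#' segment ending exactly at the run's end is added, deliberately
#' overlapping its predecessor so no retained data is dropped. Runs
#' shorter than `seg_len` but at least `min_seg` yield a single segment
#' of the run's full length; anything shorter yields nothing.
#'
#' @param run an `eeg_run` from [excise()].
#' @param cfg a [pipeline_config()].
#' @return List of `eeg_segment` objects.
#' @export
segment_run <- function(run, cfg = pipeline_config()) {
  stopifnot(inherits(run, "eeg_run"))
  n <- ncol(run$data)
  L <- as.integer(round(cfg$seg_len * run$fs))
  m <- as.integer(round(cfg$min_seg * run$fs))
  if (n < m) return(list())
  starts <- if (n < L) 0L else {
    full <- seq.int(0L, by = L, length.out = n %/% L)
    if (n %% L > 0L) c(full, n - L) else full
  }
  lapply(starts, function(s) {
    len <- min(L, n)
    new_segment(run$data[, (s + 1):(s + len), drop = FALSE], run$fs,
                parent = run$parent,
                run_offset = run$offset, start = s)
  })
}

new_segment <- function(data, fs, parent = "", run_offset = 0L, start = 0L) {
  structure(list(data = data, fs = fs,
                 channel_labels = rownames(data),
                 provenance = list(parent = parent, run_offset = run_offset,
                                   start = start),
                 interpolated_channels = character(0),
                 rejected = FALSE,
                 windows_interpolated = data.frame(start = integer(),
                                                   end = integer(),
                                                   channel = character())),
            class = "eeg_segment")
}

#' @export
print.eeg_segment <- function(x, ...) {
  cat("<eeg_segment> ", nrow(x$data), " ch x ", ncol(x$data),
      " samples @ ", x$fs, " Hz",
      if (x$rejected) " [REJECTED]",
      if (length(x$interpolated_channels))
        paste0(" interp: ", paste(x$interpolated_channels, collapse = ",")),
      "\n", sep = "")
  invisible(x)
}

#' Per-segment channel quality control
#'
#' For each channel, computes the fraction of the segment that would be
#' excised were the abnormal-peak rule (|x| > `peak_thresh`, widened by
#' `margin` on each side, clipped to the segment) applied to that channel
#' alone. Channels whose fraction strictly exceeds `chan_frac` are marked
#' for whole-channel interpolation; the segment is rejected when strictly
#' more than `max_interp` channels are marked.
#'
#' @param seg an `eeg_segment`.
#' @param cfg a [pipeline_config()].
#' @return A `qc_result`: list with `fractions` (named numeric),
#'   `marked_channels`, `rejected`.
#' @export
qc_mark <- function(seg, cfg = pipeline_config()) {
  stopifnot(inherits(seg, "eeg_segment"))
  n <- ncol(seg$data)
  pad <- as.integer(round(cfg$margin * seg$fs))
  fr <- vapply(seq_len(nrow(seg$data)), function(i) {
    exc <- abs(seg$data[i, ]) > cfg$peak_thresh
    if (!any(exc)) return(0)
    mean(iv_mask(iv_dilate(iv_from_mask(exc), pad, n), n))
  }, 0)
  names(fr) <- seg$channel_labels
  marked <- names(fr)[fr > cfg$chan_frac]
  structure(list(fractions = fr, marked_channels = marked,
                 rejected = length(marked) > cfg$max_interp),
            class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  cat("<qc_result> marked: ",
      if (length(x$marked_channels)) paste(x$marked_channels, collapse = ",")
      else "none",
      if (x$rejected) " [REJECTED]", "\n", sep = "")
  invisible(x)
}

# window starts (0-based) for pop scanning; a trailing partial window is
# not emitted
.pop_windows <- function(n, fs, cfg) {
  wl <- as.integer(round(cfg$pop_win * fs))
  hop <- as.integer(round(cfg$pop_win * (1 - cfg$pop_overlap) * fs))
  if (n < wl) return(integer(0))
  seq.int(0L, n - wl, by = hop)
}

#' Detect electrode pops in sliding windows
#'
#' The segment is scanned in `pop_win`-second windows advancing by
#' `pop_win * (1 - pop_overlap)`. Each window is low-pass filtered at
#' `pop_lp` Hz on a copy (zero-phase), and a (window, channel) pair is
#' flagged when the filtered trace's peak absolute amplitude exceeds
#' `pop_amp` mV. Pops are step-like single-electrode baseline shifts, so
#' they survive the low-pass while ordinary EEG rhythms do not.
#'
#' @param seg an `eeg_segment`.
#' @param cfg a [pipeline_config()].
#' @return Data frame with columns `start`, `end` (0-based half-open
#'   sample span of the window) and `channel`; zero rows when nothing is
#'   flagged or the segment is shorter than one window.
#' @export
detect_pops <- function(seg, cfg = pipeline_config()) {
  stopifnot(inherits(seg, "eeg_segment"))
  n <- ncol(seg$data)
  wl <- as.integer(round(cfg$pop_win * seg$fs))
  starts <- .pop_windows(n, seg$fs, cfg)
  flags <- list()
  if (length(starts) == 0L) {
    return(data.frame(start = integer(), end = integer(),
                      channel = character()))
  }
  lp <- .design_pop_lowpass(cfg, seg$fs)
  for (i in seq_len(nrow(seg$data))) {
    x <- seg$data[i, ]
    for (s in starts) {
      w <- x[(s + 1):(s + wl)]
      filt <- signal::filtfilt(lp, w)
      if (max(abs(filt)) > cfg$pop_amp) {
        flags[[length(flags) + 1L]] <-
          data.frame(start = s, end = s + wl,
                     channel = seg$channel_labels[i])
      }
    }
  }
  if (length(flags) == 0L) {
    return(data.frame(start = integer(), end = integer(),
                      channel = character()))
  }
  do.call(rbind, flags)
}

#' Repair flagged pop windows by spherical-spline interpolation
#'
#' Windows whose flagged-channel count is at most `max_interp` have those
#' channels' original (unfiltered) samples replaced by the
#' spherical-spline estimate from the remaining channels; windows with
#' more flagged channels are left untouched. Overlapping flagged windows
#' on one channel are unioned first, so each sample is interpolated once.
#'
#' @param seg an `eeg_segment`.
#' @param flags output of [detect_pops()] on the same segment.
#' @param montage a `montage_positions` covering the segment's channels.
#' @param cfg a [pipeline_config()].
#' @return The segment with repaired windows and an updated
#'   `windows_interpolated` log.
#' @export
resolve_pops <- function(seg, flags, montage, cfg = pipeline_config()) {
  stopifnot(inherits(seg, "eeg_segment"))
  if (nrow(flags) == 0L) return(seg)
  n <- ncol(seg$data)
  # windows eligible for repair: flagged-channel count <= max_interp
  key <- paste(flags$start, flags$end)
  cnt <- table(key)
  eligible <- flags[cnt[key] <= cfg$max_interp, , drop = FALSE]
  if (nrow(eligible) == 0L) return(seg)
  # per channel, union the eligible window spans
  done <- list()
  for (ch in unique(eligible$channel)) {
    f <- eligible[eligible$channel == ch, , drop = FALSE]
    iv <- iv_merge(interval_set(f$start, f$end, "pop"))
    done[[ch]] <- iv
  }
  pos <- montage$pos3d[seg$channel_labels, , drop = FALSE]
  out <- seg$data
  log <- seg$windows_interpolated
  for (ch in names(done)) {
    iv <- done[[ch]]
    for (j in seq_len(nrow(iv))) {
      span <- (iv$start[j] + 1):iv$end[j]
      # exclude any channel flagged in a window overlapping this span
      ov <- eligible$start < iv$end[j] & eligible$end > iv$start[j]
      excl <- unique(eligible$channel[ov])
      good <- setdiff(seg$channel_labels, excl)
      L <- spherical_spline_operator(pos[good, , drop = FALSE],
                                     pos[ch, , drop = FALSE],
                                     m = cfg$spline_m,
                                     terms = cfg$spline_terms,
                                     lambda = cfg$spline_lambda)
      out[ch, span] <- L %*% seg$data[good, span, drop = FALSE]
      log <- rbind(log, data.frame(start = iv$start[j], end = iv$end[j],
                                   channel = ch))
    }
  }
  seg$data <- out
  seg$windows_interpolated <- log
  seg
}

#' Replace whole channels by their spherical-spline estimate
#'
#' Used for channels marked at QC: the listed channels' entire segment is
#' reconstructed from the remaining channels. At most `max_interp`
#' channels may be interpolated; more is a QC contract violation.
#'
#' @param seg an `eeg_segment`.
#' @param channels labels to interpolate (empty is a no-op).
#' @param montage a `montage_positions`.
#' @param cfg a [pipeline_config()].
#' @return The segment with replaced channels and updated
#'   `interpolated_channels`.
#' @export
interpolate_channels <- function(seg, channels, montage,
                                 cfg = pipeline_config()) {
  stopifnot(inherits(seg, "eeg_segment"))
  if (length(channels) == 0L) return(seg)
  channels <- normalize_labels(channels)
  if (length(channels) > cfg$max_interp) {
    stop("QC contract error: asked to interpolate ", length(channels),
         " channels but max_interp = ", cfg$max_interp, call. = FALSE)
  }
  if (!all(channels %in% seg$channel_labels)) {
    stop("montage error: channel(s) not in segment: ",
         paste(setdiff(channels, seg$channel_labels), collapse = ", "),
         call. = FALSE)
  }
  good <- setdiff(seg$channel_labels, channels)
  pos <- montage$pos3d[seg$channel_labels, , drop = FALSE]
  L <- spherical_spline_operator(pos[good, , drop = FALSE],
                                 pos[channels, , drop = FALSE],
                                 m = cfg$spline_m, terms = cfg$spline_terms,
                                 lambda = cfg$spline_lambda)
  seg$data[channels, ] <- L %*% seg$data[good, , drop = FALSE]
  seg$interpolated_channels <- union(seg$interpolated_channels, channels)
  seg
}

#' Write a per-segment QC report as TSV
#'
#' @param seg an `eeg_segment` (after QC / pop handling).
#' @param qc its `qc_result`.
#' @param path output file path.
#' @export
write_qc_report <- function(seg, qc, path) {
  hdr <- c(sprintf("# rejected\t%s", qc$rejected),
           sprintf("# marked\t%s", paste(qc$marked_channels, collapse = ",")),
           sprintf("# pop_windows\t%d", nrow(seg$windows_interpolated)))
  writeLines(hdr, path)
  df <- data.frame(channel = names(qc$fractions),
                   flagged_fraction = unname(qc$fractions))
  suppressWarnings(utils::write.table(df, path, sep = "\t", quote = FALSE,
                                      row.names = FALSE, append = TRUE))
  invisible(path)
}
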