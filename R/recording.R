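#' Multichannel EEG recording container
#'
#' A recording is a channels x samples numeric matrix in millivolts, with
#' canonical 10-20 row labels and a sampling rate. All detector thresholds
#' in the package are in mV, so the loader is responsible for unit
#' conversion.
#'
#' @param data numeric matrix, channels x samples, in mV.
#' @param channel_labels one label per row (10-20 names; aliases ok).
#' @param fs sampling rate, Hz.
#' @param origin free-text provenance tag.
#' @return Object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, channel_labels, fs = 256, origin = "") {
  data <- as.matrix(data)
  labels <- normalize_labels(channel_labels)
  if (nrow(data) != length(labels)) {
    stop("eeg_recording: data has ", nrow(data), " rows but ",
         length(labels), " channel labels", call. = FALSE)
  }
  if (anyDuplicated(labels)) {
    stop("eeg_recording: duplicate channel labels", call. = FALSE)
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("eeg_recording: fs must be a positive scalar", call. = FALSE)
  }
  if (!all(is.finite(data))) {
    stop("eeg_recording: data contains non-finite values", call. = FALSE)
  }
  rownames(data) <- labels
  structure(list(data = data, channel_labels = labels, fs = fs,
                 origin = origin),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat("<eeg_recording> ", nrow(x$data), " ch x ", ncol(x$data),
      " samples @ ", x$fs, " Hz (",
      sprintf("%.1f", ncol(x$data) / x$fs), " s)",
      if (nzchar(x$origin)) paste0(" [", x$origin, "]"), "\n", sep = "")
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec an `eeg_recording`.
#' @export
rec_duration <- function(rec) ncol(rec$data) / rec$fs

.unit_scale_to_mv <- function(unit) {
  u <- tolower(trimws(unit))
  u <- sub("µ", "u", u)     # micro sign
  switch(u,
    "v" = 1000,
    "mv" = 1,
    "uv" = 1e-3,
    "nv" = 1e-6,
    stop("unit error: unknown physical unit '", unit, "'", call. = FALSE)
  )
}

#' Save / load the package's raw text container
#'
#' The container is a pair of files: `<stem>.tsv` holding the sample
#' matrix (one column per channel, one row per sample, headed by channel
#' labels) and `<stem>.json` holding metadata (labels, fs, unit, origin).
#' It exists so synthetic fixtures round-trip losslessly through plain
#' text.
#'
#' @param rec an `eeg_recording`.
#' @param stem path without extension; both files are derived from it.
#' @return `save_recording` returns the stem invisibly; `load_recording`
#'   returns an `eeg_recording`.
#' @export
save_recording <- function(rec, stem) {
  stopifnot(inherits(rec, "eeg_recording"))
  df <- as.data.frame(t(rec$data))
  names(df) <- rec$channel_labels
  utils::write.table(format(df, digits = 17, scientific = TRUE, trim = TRUE),
                     paste0(stem, ".tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(channel_labels = rec$channel_labels, fs = rec$fs,
               unit = "mV", origin = rec$origin)
  jsonlite::write_json(meta, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(stem)
}

.read_raw_container <- function(stem, unit_hint = NULL) {
  tsv <- paste0(stem, ".tsv"); js <- paste0(stem, ".json")
  if (!file.exists(tsv) || !file.exists(js)) {
    stop("format error: raw container needs both ", tsv, " and ", js,
         call. = FALSE)
  }
  meta <- jsonlite::read_json(js, simplifyVector = TRUE)
  df <- utils::read.table(tsv, header = TRUE, sep = "\t",
                          check.names = FALSE)
  unit <- meta$unit
  if (is.null(unit) || !nzchar(unit)) {
    if (is.null(unit_hint)) {
      stop("unit error: container metadata has no unit and no unit_hint given",
           call. = FALSE)
    }
    unit <- unit_hint
  }
  data <- t(as.matrix(df)) * .unit_scale_to_mv(unit)
  eeg_recording(data, names(df), fs = meta$fs,
                origin = if (!is.null(meta$origin)) meta$origin else stem)
}

#' Load an EEG recording from disk
#'
#' Reads either an EDF/EDF+ file (`.edf`) or the package's raw text
#' container, converts amplitudes to millivolts, resolves channel aliases
#' and reorders channels to the canonical 10-20 order. Channels outside
#' the requested montage are dropped with a message; a missing requested
#' channel is an error.
#'
#' @param path file path (`.edf`, or the container's `.tsv`/`.json`/stem).
#' @param unit_hint fallback physical unit (`"uV"`, `"mV"`, `"V"`) used
#'   when the file carries no unit metadata.
#' @param channels the electrode set the pipeline requires.
#' @return An `eeg_recording` in canonical channel order, mV.
#' @export
load_recording <- function(path, unit_hint = NULL,
                           channels = eegic_channels()) {
  if (grepl("\\.edf$", path, ignore.case = TRUE)) {
    rec <- read_edf(path, unit_hint = unit_hint)
  } else {
    stem <- sub("\\.(tsv|json)$", "", path)
    rec <- .read_raw_container(stem, unit_hint = unit_hint)
  }
  want <- normalize_labels(channels)
  missing <- setdiff(want, rec$channel_labels)
  if (length(missing)) {
    stop("montage error: recording is missing required electrode(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  eeg_recording(rec$data[want, , drop = FALSE], want, rec$fs, rec$origin)
}

# ---- minimal EDF/EDF+ support -------------------------------------------
# Fixed-layout 256-byte main header, 256 bytes per signal, then data
# records of 16-bit little-endian integers mapped linearly from
# [dig_min, dig_max] to [phys_min, phys_max].

.edf_pad <- function(x, n) {
  s <- as.character(x)
  if (nchar(s) > n) s <- substr(s, 1, n)
  formatC(s, width = -n, flag = " ")
}

#' Write a recording as EDF
#'
#' Minimal continuous EDF writer (one data record per second, 16-bit).
#' Amplitudes are written in the requested physical unit.
#'
#' @param rec an `eeg_recording` (data in mV).
#' @param path output path.
#' @param unit physical dimension written to the header (`"uV"` or
#'   `"mV"`); samples are scaled accordingly.
#' @export
write_edf <- function(rec, path, unit = "uV") {
  stopifnot(inherits(rec, "eeg_recording"))
  scl <- 1 / .unit_scale_to_mv(unit)         # mV -> unit
  x <- rec$data * scl
  ns <- nrow(x)
  spr <- as.integer(round(rec$fs))           # samples per 1 s record
  nrec <- floor(ncol(x) / spr)
  if (nrec < 1) stop("write_edf: recording shorter than one data record",
                     call. = FALSE)
  x <- x[, seq_len(nrec * spr), drop = FALSE]
  pmin_ <- apply(x, 1, min); pmax_ <- apply(x, 1, max)
  flat <- pmax_ - pmin_ < .Machine$double.eps
  pmax_[flat] <- pmin_[flat] + 1
  dmin <- -32768L; dmax <- 32767L
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s, n) writeChar(.edf_pad(s, n), con, nchars = n, eos = NULL)
  wr("0", 8); wr("X X X X", 80); wr("Startdate X X X X", 80)
  wr("01.01.00", 8); wr("00.00.00", 8)
  wr(256 + 256 * ns, 8); wr("", 44); wr(nrec, 8); wr("1", 8); wr(ns, 4)
  for (lab in rec$channel_labels) wr(paste("EEG", lab), 16)
  for (i in seq_len(ns)) wr("", 80)                       # transducer
  for (i in seq_len(ns)) wr(unit, 8)                      # physical dim
  for (i in seq_len(ns)) wr(formatC(pmin_[i], digits = 6, format = "g"), 8)
  for (i in seq_len(ns)) wr(formatC(pmax_[i], digits = 6, format = "g"), 8)
  for (i in seq_len(ns)) wr(dmin, 8)
  for (i in seq_len(ns)) wr(dmax, 8)
  for (i in seq_len(ns)) wr("", 80)                       # prefiltering
  for (i in seq_len(ns)) wr(spr, 8)
  for (i in seq_len(ns)) wr("", 32)                       # reserved
  dig <- matrix(0L, ns, ncol(x))
  for (i in seq_len(ns)) {
    g <- (dmax - dmin) / (pmax_[i] - pmin_[i])
    dig[i, ] <- as.integer(round((x[i, ] - pmin_[i]) * g) + dmin)
  }
  for (r in seq_len(nrec)) {
    cols <- ((r - 1) * spr + 1):(r * spr)
    writeBin(as.integer(t(dig[, cols, drop = FALSE]))[seq_len(ns * spr)],
             con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read an EDF/EDF+ file
#'
#' Minimal reader for continuous recordings with a common sampling rate
#' across EEG signals. Annotation signals ("EDF Annotations") are skipped.
#'
#' @param path EDF file path.
#' @param unit_hint unit used when a signal's physical-dimension field is
#'   blank.
#' @return An `eeg_recording` (mV). Channel labels are taken from the
#'   header with an optional "EEG " prefix stripped.
#' @export
read_edf <- function(path, unit_hint = NULL) {
  if (!file.exists(path)) stop("format error: no such file: ", path,
                               call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  ver <- trimws(rd(8))
  if (!identical(ver, "0")) stop("format error: not an EDF file (version '",
                                 ver, "')", call. = FALSE)
  rd(80); rd(80); rd(8); rd(8)
  hdr_bytes <- as.integer(trimws(rd(8))); rd(44)
  nrec <- as.integer(trimws(rd(8)))
  rec_dur <- as.numeric(trimws(rd(8)))
  ns <- as.integer(trimws(rd(4)))
  fld <- function(w) vapply(seq_len(ns), function(i) trimws(rd(w)), "")
  labels <- fld(16); fld(80)
  units <- fld(8)
  pmin_ <- as.numeric(fld(8)); pmax_ <- as.numeric(fld(8))
  dmin <- as.numeric(fld(8)); dmax <- as.numeric(fld(8))
  fld(80)
  spr <- as.integer(fld(8)); fld(32)
  seek(con, hdr_bytes)
  keep <- !grepl("annotation", labels, ignore.case = TRUE)
  if (nrec < 0) stop("format error: EDF with unknown record count",
                     call. = FALSE)
  out <- lapply(which(keep), function(i) numeric(nrec * spr[i]))
  names(out) <- labels[keep]
  for (r in seq_len(nrec)) {
    for (i in seq_len(ns)) {
      v <- readBin(con, "integer", n = spr[i], size = 2, signed = TRUE,
                   endian = "little")
      if (length(v) < spr[i]) stop("format error: truncated EDF record",
                                   call. = FALSE)
      if (keep[i]) {
        k <- which(which(keep) == i)
        out[[k]][((r - 1) * spr[i] + 1):(r * spr[i])] <- v
      }
    }
  }
  ki <- which(keep)
  if (length(unique(spr[ki])) != 1L) {
    stop("format error: EEG signals with differing sampling rates",
         call. = FALSE)
  }
  fs <- spr[ki[1]] / rec_dur
  data <- matrix(0, length(ki), nrec * spr[ki[1]])
  for (j in seq_along(ki)) {
    i <- ki[j]
    g <- (pmax_[i] - pmin_[i]) / (dmax[i] - dmin[i])
    u <- units[i]
    if (!nzchar(u)) {
      if (is.null(unit_hint)) {
        stop("unit error: signal '", labels[i],
             "' has no physical dimension and no unit_hint was given",
             call. = FALSE)
      }
      u <- unit_hint
    }
    data[j, ] <- ((out[[j]] - dmin[i]) * g + pmin_[i]) * .unit_scale_to_mv(u)
  }
  lab <- sub("^EEG[ _]*", "", names(out))
  known <- vapply(lab, function(l) !inherits(try(normalize_labels(l),
                                                 silent = TRUE), "try-error"),
                  TRUE)
  if (!all(known)) {
    message("read_edf: dropping non-montage signal(s): ",
            paste(lab[!known], collapse = ", "))
  }
  eeg_recording(data[known, , drop = FALSE], lab[known], fs = fs,
                origin = basename(path))
}
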