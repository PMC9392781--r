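#' Half-open sample-index interval sets
#'
#' An interval set is the package's bookkeeping for stretches of signal that
#' are to be excised. It is a data frame with integer columns `start` and
#' `end` (0-based, half-open `[start, end)`) and a character `reason`
#' column. [iv_merge()] sorts and fuses overlapping or touching intervals;
#' all detector output passes through it, so downstream code may assume
#' sorted, disjoint intervals.
#'
#' @param start,end integer vectors of equal length; `0 <= start < end`.
#' @param reason character vector (recycled) tagging why each interval is bad.
#' @return A data frame of class `interval_set`.
#' @export
interval_set <- function(start = integer(), end = integer(), reason = character()) {
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (length(start) != length(end)) {
    stop("interval_set: start and end must have equal length", call. = FALSE)
  }
  if (any(start < 0) || any(end <= start)) {
    stop("interval_set: intervals must satisfy 0 <= start < end", call. = FALSE)
  }
  if (length(reason) == 0L) reason <- character(length(start))
  iv <- data.frame(
    start = start, end = end,
    reason = rep_len(as.character(reason), length(start)),
    stringsAsFactors = FALSE
  )
  iv <- iv[order(iv$start, iv$end), , drop = FALSE]
  rownames(iv) <- NULL
  class(iv) <- c("interval_set", "data.frame")
  iv
}

#' @rdname interval_set
#' @param iv an `interval_set`.
#' @export
iv_merge <- function(iv) {
  if (nrow(iv) <= 1L) return(iv)
  iv <- iv[order(iv$start, iv$end), , drop = FALSE]
  out_s <- numeric(0); out_e <- numeric(0); out_r <- character(0)
  cs <- iv$start[1]; ce <- iv$end[1]; cr <- iv$reason[1]
  for (i in seq_len(nrow(iv))[-1]) {
    if (iv$start[i] <= ce) {            # overlap or touch: fuse
      if (iv$end[i] > ce) ce <- iv$end[i]
      if (!grepl(iv$reason[i], cr, fixed = TRUE) && nzchar(iv$reason[i])) {
        cr <- if (nzchar(cr)) paste(cr, iv$reason[i], sep = "+") else iv$reason[i]
      }
    } else {
      out_s <- c(out_s, cs); out_e <- c(out_e, ce); out_r <- c(out_r, cr)
      cs <- iv$start[i]; ce <- iv$end[i]; cr <- iv$reason[i]
    }
  }
  interval_set(c(out_s, cs), c(out_e, ce), c(out_r, cr))
}

#' @rdname interval_set
#' @param pad number of samples added to each side before clipping to
#'   `[0, n)`.
#' @param n total sample count of the parent recording.
#' @export
iv_dilate <- function(iv, pad, n) {
  if (nrow(iv) == 0L) return(iv)
  s <- pmax(0, iv$start - pad)
  e <- pmin(n, iv$end + pad)
  iv_merge(interval_set(s, e, iv$reason))
}

#' @rdname interval_set
#' @export
iv_complement <- function(iv, n) {
  iv <- iv_merge(iv)
  if (nrow(iv) == 0L) return(interval_set(0, n, "kept"))
  s <- c(0, iv$end)
  e <- c(iv$start, n)
  keep <- s < e
  if (!any(keep)) return(interval_set())
  interval_set(s[keep], e[keep], "kept")
}

#' @rdname interval_set
#' @export
iv_mask <- function(iv, n) {
  m <- logical(n)
  for (i in seq_len(nrow(iv))) {
    if (iv$end[i] > iv$start[i]) m[(iv$start[i] + 1):iv$end[i]] <- TRUE
  }
  m
}

#' Convert a logical mask to an interval set
#'
#' @param mask logical vector; `TRUE` marks samples inside an interval.
#' @param reason tag applied to every emitted interval.
#' @return An `interval_set` whose mask equals `mask`.
#' @export
iv_from_mask <- function(mask, reason = "") {
  r <- rle(as.logical(mask))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  interval_set(starts[keep], ends[keep], rep(reason, sum(keep)))
}

#' Write an excision log as a 3-column TSV
#'
#' One row per excised interval: `start_sample`, `end_sample` (half-open,
#' 0-based) and `reason`.
#'
#' @param iv an `interval_set`.
#' @param path output file path.
#' @export
write_excision_log <- function(iv, path) {
  df <- data.frame(start_sample = iv$start, end_sample = iv$end, reason = iv$reason)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
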