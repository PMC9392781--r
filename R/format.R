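#' @name dataset_layout
#' @title Labelled-IC text dataset layout
#' @description The on-disk corpus is plain text: two top-level split
#'   directories (`training/`, `test/`), each holding `artifact/`,
#'   `not-artifact/` and `ica-weights/`. Every IC sample is a triple of
#'   files `<patient>_<segment>_<ic>_{timeseries,psd,topomap}.txt`;
#'   time-series and PSD files are one-dimensional (values chronological
#'   resp. ascending in frequency from 1 to 90 Hz), topomaps are square
#'   row-major grids with the nasion at the top row (upper-left pixel =
#'   left-nasion corner). Each segment's weights live in
#'   `ica-weights/<patient>_<segment>_weights.txt`, rows = ICs, columns =
#'   channels. Values are whitespace-separated, 8 significant digits on
#'   write; scientific notation is accepted on read.
NULL

.fmt_num <- function(x) formatC(x, digits = 8, format = "g")

.write_mat_txt <- function(m, path) {
  m <- rbind(m)
  lines <- apply(m, 1, function(r) paste(.fmt_num(r), collapse = " "))
  writeLines(lines, path)
}

.read_mat_txt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  rows <- lapply(seq_along(lines), function(i) {
    toks <- strsplit(trimws(lines[[i]]), "[ \t,]+")[[1]]
    v <- suppressWarnings(as.numeric(toks))
    if (anyNA(v)) {
      stop("parse error: ", path, " line ", i, ": non-numeric token '",
           toks[which(is.na(v))[1]], "'", call. = FALSE)
    }
    v
  })
  ncols <- lengths(rows)
  if (length(unique(ncols)) != 1L) {
    stop("schema error: ", path, ": ragged rows (", min(ncols), "-",
         max(ncols), " values)", call. = FALSE)
  }
  do.call(rbind, rows)
}

.splits <- c("training", "test")
.label_dirs <- c("artifact", "not-artifact")

#' Write IC samples and weights in the dataset layout
#'
#' @param samples list of `ic_sample` objects; each sample's
#'   `provenance` must name `patient`, `segment`, `ic` and a `split`
#'   (`"training"` or `"test"`).
#' @param weights named list of unmixing matrices (one per
#'   `<patient>_<segment>` key, rows = ICs, columns = channels); each
#'   matrix may carry a `split` attribute (default `"training"`).
#' @param root output directory (created if needed).
#' @return Invisibly, a manifest data frame (one row per written sample).
#' @export
write_dataset <- function(samples, weights = list(), root) {
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(root)) stop("I/O error: cannot create ", root,
                              call. = FALSE)
  for (sp in .splits) {
    for (d in c(.label_dirs, "ica-weights")) {
      dir.create(file.path(root, sp, d), recursive = TRUE,
                 showWarnings = FALSE)
    }
  }
  rows <- list()
  for (s in samples) {
    if (!inherits(s, "ic_sample")) stop("schema error: not an ic_sample",
                                        call. = FALSE)
    pv <- s$provenance
    need <- c("patient", "segment", "ic")
    if (!all(need %in% names(pv))) {
      stop("schema error: sample provenance must name ",
           paste(need, collapse = ", "), call. = FALSE)
    }
    split <- if (!is.null(pv$split)) pv$split else "training"
    stem <- sprintf("%s_%s_%s", pv$patient, pv$segment, pv$ic)
    dir <- file.path(root, split, s$label)
    .write_mat_txt(matrix(s$timeseries, nrow = 1),
                   file.path(dir, paste0(stem, "_timeseries.txt")))
    .write_mat_txt(matrix(as.numeric(s$psd), nrow = 1),
                   file.path(dir, paste0(stem, "_psd.txt")))
    .write_mat_txt(s$topomap,
                   file.path(dir, paste0(stem, "_topomap.txt")))
    rows[[length(rows) + 1L]] <-
      data.frame(split = split, label = s$label, patient = pv$patient,
                 segment = pv$segment, ic = pv$ic,
                 n_samples = length(s$timeseries))
  }
  for (key in names(weights)) {
    w <- weights[[key]]
    split <- attr(w, "split")
    if (is.null(split)) split <- "training"
    .write_mat_txt(unclass(w),
                   file.path(root, split, "ica-weights",
                             paste0(key, "_weights.txt")))
  }
  invisible(if (length(rows)) do.call(rbind, rows) else
            data.frame(split = character(), label = character()))
}

.discover_samples <- function(dir, label, split) {
  ts <- list.files(dir, pattern = "_timeseries\\.txt$", full.names = TRUE)
  lapply(ts, function(f) {
    stem <- sub("_timeseries\\.txt$", "", f)
    list(stem = basename(stem), label = label, split = split,
         timeseries_file = f,
         psd_file = paste0(stem, "_psd.txt"),
         topomap_file = paste0(stem, "_topomap.txt"))
  })
}

#' Read a dataset directory
#'
#' Parses every sample (labels inferred from the subdirectory) and all
#' weight matrices, and computes the split index (counts and class
#' percentages).
#'
#' @param root dataset directory following the layout.
#' @return List with `samples` (each: `label`, `split`, `timeseries`,
#'   `psd`, `topomap`, `stem`), `weights` (named list per split) and
#'   `index` (see [dataset_index()]).
#' @export
read_dataset <- function(root) {
  if (!dir.exists(root)) stop("I/O error: no such directory: ", root,
                              call. = FALSE)
  samples <- list()
  counts <- list()
  weights <- list()
  for (sp in .splits) {
    counts[[sp]] <- c(artifact = 0L, `not-artifact` = 0L)
    for (lab in .label_dirs) {
      d <- file.path(root, sp, lab)
      if (!dir.exists(d)) next
      for (meta in .discover_samples(d, lab, sp)) {
        ts <- .read_mat_txt(meta$timeseries_file)
        psd <- .read_mat_txt(meta$psd_file)
        tm <- .read_mat_txt(meta$topomap_file)
        if (nrow(tm) != ncol(tm)) {
          stop("schema error: ", meta$topomap_file, ": topomap is ",
               nrow(tm), "x", ncol(tm), ", not square", call. = FALSE)
        }
        samples[[length(samples) + 1L]] <-
          list(stem = meta$stem, label = lab, split = sp,
               timeseries = as.numeric(ts), psd = as.numeric(psd),
               topomap = tm)
        counts[[sp]][lab] <- counts[[sp]][lab] + 1L
      }
    }
    wd <- file.path(root, sp, "ica-weights")
    if (dir.exists(wd)) {
      for (f in list.files(wd, pattern = "\\.txt$", full.names = TRUE)) {
        key <- sub("_weights\\.txt$", "", basename(f))
        key <- sub("\\.txt$", "", key)
        weights[[sp]][[key]] <- .read_mat_txt(f)
      }
    }
  }
  list(samples = samples, weights = weights,
       index = dataset_index(counts))
}

#' Split index with class balances
#'
#' Percentages are `round(100 * count / total, 2)`; `artifact` here means
#' the artifact class, `brain` the not-artifact class.
#'
#' @param counts named list per split of named counts (`artifact`,
#'   `not-artifact`).
#' @return Data frame, one row per split plus a `total` row.
#' @export
dataset_index <- function(counts) {
  rows <- lapply(names(counts), function(sp) {
    a <- unname(counts[[sp]]["artifact"])
    b <- unname(counts[[sp]]["not-artifact"])
    tot <- a + b
    data.frame(split = sp, total = tot, brain = b, artifact = a,
               brain_pct = if (tot > 0) round(100 * b / tot, 2) else NA_real_,
               artifact_pct = if (tot > 0) round(100 * a / tot, 2) else NA_real_)
  })
  idx <- do.call(rbind, rows)
  tot <- sum(idx$total)
  idx$split_pct <- if (tot > 0) round(100 * idx$total / tot, 2) else NA_real_
  idx
}

#' Validate a dataset directory
#'
#' Checks, per sample: the file triple is complete, every token parses
#' as a number, the topomap is square, and PSD and topomap values lie in
#' `[0, 1]`; per weights file: the matrix is rectangular. Problems are
#' collected, not thrown.
#'
#' @param root dataset directory.
#' @return List with `index` (may be partial when files fail), `failures`
#'   (character vector, one message per problem) and `n_checked`.
#' @export
validate_dataset <- function(root) {
  failures <- character(0)
  counts <- list()
  n_checked <- 0L
  rng_ok <- function(x) all(x >= 0 & x <= 1)
  for (sp in .splits) {
    counts[[sp]] <- c(artifact = 0L, `not-artifact` = 0L)
    for (lab in .label_dirs) {
      d <- file.path(root, sp, lab)
      if (!dir.exists(d)) next
      for (meta in .discover_samples(d, lab, sp)) {
        n_checked <- n_checked + 1L
        ok <- TRUE
        for (kind in c("timeseries", "psd", "topomap")) {
          f <- meta[[paste0(kind, "_file")]]
          if (!file.exists(f)) {
            failures <- c(failures, paste0("missing file: ", f))
            ok <- FALSE
            next
          }
          m <- tryCatch(.read_mat_txt(f), error = function(e) {
            failures <<- c(failures, conditionMessage(e))
            NULL
          })
          if (is.null(m)) { ok <- FALSE; next }
          if (kind == "topomap") {
            if (nrow(m) != ncol(m)) {
              failures <- c(failures,
                            paste0("topomap not square: ", f, " (",
                                   nrow(m), "x", ncol(m), ")"))
              ok <- FALSE
            } else if (!rng_ok(m)) {
              failures <- c(failures,
                            paste0("topomap values outside [0,1]: ", f))
              ok <- FALSE
            }
          }
          if (kind == "psd" && !rng_ok(m)) {
            failures <- c(failures, paste0("psd values outside [0,1]: ", f))
            ok <- FALSE
          }
        }
        if (ok) counts[[sp]][lab] <- counts[[sp]][lab] + 1L
      }
    }
    wd <- file.path(root, sp, "ica-weights")
    if (dir.exists(wd)) {
      for (f in list.files(wd, pattern = "\\.txt$", full.names = TRUE)) {
        tryCatch(.read_mat_txt(f), error = function(e) {
          failures <<- c(failures, conditionMessage(e))
        })
      }
    }
  }
  list(index = dataset_index(counts), failures = failures,
       n_checked = n_checked)
}

#' Write a validation report as JSON
#'
#' @param report output of [validate_dataset()].
#' @param path JSON file path.
#' @export
write_validation_report <- function(report, path) {
  jsonlite::write_json(list(index = report$index,
                            failures = report$failures,
                            n_checked = report$n_checked),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
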