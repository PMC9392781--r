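#' Run the full preprocessing pipeline
#'
#' For each input recording: band-pass + notch filtering; detection and
#' margin-excision of flatlines, saturation and global abnormal peaks;
#' 10-minute segmentation of the retained runs; per-segment channel QC
#' (mark > 20% channels, reject on > 2 marks); electrode-pop detection
#' and window repair; whole-channel spherical-spline interpolation of
#' QC-marked channels; average re-referencing; extended-infomax ICA; and
#' per-component feature extraction. Samples, weights and a run manifest
#' are written in the text dataset layout.
#'
#' A recording that fails at any stage is recorded in the manifest and
#' skipped; the run continues.
#'
#' @param inputs list of `eeg_recording` objects and/or file paths
#'   accepted by [load_recording()].
#' @param cfg a [pipeline_config()].
#' @param out_root output dataset directory, or `NULL` to skip writing.
#' @param split dataset split the outputs belong to (`"training"` or
#'   `"test"`).
#' @param label class subdirectory for the emitted samples; components
#'   are unlabelled at this stage, so they default into `"not-artifact"`
#'   pending expert annotation.
#' @param seed integer seed; recording `i` uses `seed + i - 1` for its
#'   decompositions.
#' @param verbose log per-stage progress to stderr.
#' @return A `run_manifest`: config snapshot, per-recording accounting
#'   (input/retained/excised hours), per-segment QC outcomes and IC
#'   counts, and the sample table.
#' @export
run_pipeline <- function(inputs, cfg = pipeline_config(), out_root = NULL,
                         split = "training", label = "not-artifact",
                         seed = cfg$rng_seed, verbose = FALSE) {
  log <- function(...) if (verbose) message(sprintf(...))
  montage <- standard_1020_montage()
  recordings <- list()
  segments_tbl <- list()
  samples <- list()
  weights <- list()
  errors <- character(0)

  for (ri in seq_along(inputs)) {
    rec <- inputs[[ri]]
    rec_id <- sprintf("rec%03d", ri)
    res <- tryCatch({
      if (is.character(rec)) rec <- load_recording(rec)
      stopifnot(inherits(rec, "eeg_recording"))
      in_s <- rec_duration(rec)
      log("[%s] %.1f s input; filtering", rec_id, in_s)
      filt <- apply_bandpass_notch(rec, cfg)
      sc <- scrub_recording(filt, cfg)
      kept_s <- sum(vapply(sc$runs, function(r) ncol(r$data), 0)) / rec$fs
      log("[%s] scrub: %d bad interval(s), %.1f s retained in %d run(s)",
          rec_id, nrow(sc$bad), kept_s, length(sc$runs))
      seg_count <- 0L
      for (run_i in seq_along(sc$runs)) {
        run <- sc$runs[[run_i]]
        run$parent <- rec_id
        for (seg in segment_run(run, cfg)) {
          seg_count <- seg_count + 1L
          seg_id <- sprintf("%s-r%02d-s%03d", rec_id, run_i, seg_count)
          qc <- qc_mark(seg, cfg)
          if (qc$rejected) {
            segments_tbl[[length(segments_tbl) + 1L]] <- data.frame(
              recording = rec_id, segment = seg_id,
              n_samples = ncol(seg$data), rejected = TRUE, n_ICs = 0L,
              marked = paste(qc$marked_channels, collapse = ","))
            log("[%s] %s rejected (%d channels marked)", rec_id, seg_id,
                length(qc$marked_channels))
            next
          }
          flags <- detect_pops(seg, cfg)
          seg <- resolve_pops(seg, flags, montage, cfg)
          seg <- interpolate_channels(seg, qc$marked_channels, montage, cfg)
          seg <- average_reference(seg)
          ica <- fit_extended_infomax(seg, seed = seed + ri - 1L, cfg = cfg)
          log("[%s] %s: %d ICs in %d iterations", rec_id, seg_id,
              ica$n_ICs, ica$iterations)
          key <- sprintf("%s_%s", rec_id, seg_id)
          w <- ica$W
          attr(w, "split") <- split
          weights[[key]] <- w
          for (ic in seq_len(ica$n_ICs)) {
            samples[[length(samples) + 1L]] <- assemble_sample(
              ica$S[ic, ], ica$A[, ic], label,
              provenance = list(patient = rec_id, segment = seg_id,
                                ic = ic, split = split),
              montage = montage, fs = seg$fs, cfg = cfg)
          }
          segments_tbl[[length(segments_tbl) + 1L]] <- data.frame(
            recording = rec_id, segment = seg_id,
            n_samples = ncol(seg$data), rejected = FALSE,
            n_ICs = ica$n_ICs,
            marked = paste(qc$marked_channels, collapse = ","))
        }
      }
      data.frame(recording = rec_id, input_h = in_s / 3600,
                 retained_h = kept_s / 3600,
                 excised_h = (in_s - kept_s) / 3600,
                 n_segments = seg_count, error = "")
    }, error = function(e) {
      errors <<- c(errors, paste0(rec_id, ": ", conditionMessage(e)))
      data.frame(recording = rec_id, input_h = NA_real_,
                 retained_h = NA_real_, excised_h = NA_real_,
                 n_segments = 0L, error = conditionMessage(e))
    })
    recordings[[ri]] <- res
  }

  manifest <- structure(list(
    config = unclass(cfg),
    seed = as.integer(seed),
    recordings = if (length(recordings)) do.call(rbind, recordings) else
      data.frame(),
    segments = if (length(segments_tbl)) do.call(rbind, segments_tbl) else
      data.frame(),
    n_samples = length(samples),
    out_root = if (is.null(out_root)) NA_character_ else out_root,
    errors = errors
  ), class = "run_manifest")

  if (!is.null(out_root)) {
    write_dataset(samples, weights, out_root)
    write_manifest(manifest, file.path(out_root, "manifest.tsv"))
  }
  manifest$samples <- samples
  manifest$weights <- weights
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("<run_manifest> ", nrow(x$recordings), " recording(s), ",
      nrow(x$segments), " segment(s), ", x$n_samples, " IC sample(s)\n",
      sep = "")
  if (nrow(x$recordings)) {
    cat(sprintf("  input %.3f h, retained %.3f h, excised %.3f h\n",
                sum(x$recordings$input_h, na.rm = TRUE),
                sum(x$recordings$retained_h, na.rm = TRUE),
                sum(x$recordings$excised_h, na.rm = TRUE)))
  }
  if (length(x$errors)) cat("  errors:", length(x$errors), "\n")
  invisible(x)
}

#' Write the per-recording manifest as TSV
#'
#' @param manifest a `run_manifest`.
#' @param path output path.
#' @export
write_manifest <- function(manifest, path) {
  cfg <- manifest$config
  cfg$sentinel_channels <- paste(cfg$sentinel_channels, collapse = ",")
  hdr <- c(sprintf("# seed\t%d", manifest$seed),
           sprintf("# config\t%s",
                   paste(names(cfg), unlist(cfg), sep = "=",
                         collapse = ";")))
  writeLines(hdr, path)
  suppressWarnings(utils::write.table(manifest$recordings, path, sep = "\t",
                                      quote = FALSE, row.names = FALSE,
                                      append = TRUE))
  invisible(path)
}

#' Generate a synthetic fixture dataset on disk
#'
#' Builds an annotated synthetic recording (background plus a default or
#' user-given artifact plan), saves it in the raw text container next to
#' its plan, and returns both.
#'
#' @param out_stem path stem for the container files.
#' @param duration_s recording length (s).
#' @param plan an [annotation_set()], or `NULL` for a default plan with
#'   one flatline, one global peak and one electrode pop.
#' @param seed integer RNG seed.
#' @param cfg a [pipeline_config()].
#' @return List with `recording` and `plan`.
#' @export
synthesize_fixture <- function(out_stem = NULL, duration_s = 300,
                               plan = NULL, seed = 1L,
                               cfg = pipeline_config()) {
  fs <- 256
  n <- duration_s * fs
  if (is.null(plan)) {
    pop_len <- min(40, 0.2 * duration_s) * fs
    plan <- annotation_set(
      type = c("flatline", "global_peak", "electrode_pop"),
      channel = c("C3", "all", "F7"),
      start = round(c(0.1 * n, 0.45 * n, 0.75 * n)),
      end = round(pmin(n, c(0.1 * n + 5 * fs, 0.45 * n + 2 * fs,
                            0.75 * n + pop_len))),
      magnitude = c(0, 1.5 * cfg$peak_thresh, 1.5 * cfg$pop_amp))
  }
  rec <- gen_background(19, duration_s, fs, seed)
  rec <- inject_artifacts(rec, plan, cfg)
  if (!is.null(out_stem)) {
    save_recording(rec, out_stem)
    jsonlite::write_json(as.data.frame(plan), paste0(out_stem, "_plan.json"),
                         digits = NA)
  }
  list(recording = rec, plan = plan)
}
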