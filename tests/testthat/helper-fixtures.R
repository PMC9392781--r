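# Shared fixture builders. Everything is generated in code at test time;
# nothing is read from disk except files the tests themselves write to
# tempdir().

fix_cfg <- pipeline_config()
fix_montage <- standard_1020_montage()

# a bare segment from a channels x samples matrix (rows named)
make_segment <- function(data, fs = 256) {
  if (is.null(rownames(data))) {
    rownames(data) <- eegic_channels()[seq_len(nrow(data))]
  }
  eegic:::new_segment(data, fs)
}

# quiet multichannel noise, channels named canonically
noise_matrix <- function(n_channels = 19, n = 2560, sd = 0.05, seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(n_channels * n, sd = sd), n_channels, n)
  rownames(m) <- eegic_channels()[seq_len(n_channels)]
  m
}

# a channel whose samples are exactly the spherical-spline prediction of
# the remaining channels
spline_consistent_segment <- function(target = "Cz", n = 1000, seed = 4) {
  m <- noise_matrix(19, n, seed = seed)
  good <- setdiff(eegic_channels(), target)
  L <- spherical_spline_operator(fix_montage$pos3d[good, , drop = FALSE],
                                 fix_montage$pos3d[target, , drop = FALSE])
  m[target, ] <- L %*% m[good, , drop = FALSE]
  make_segment(m)
}

# brute-force boolean excision mask: dilate each interval sample by
# sample, independent of the interval arithmetic under test
brute_mask <- function(iv, n, pad) {
  m <- logical(n)
  for (i in seq_len(nrow(iv))) {
    lo <- max(0, iv$start[i] - pad)
    hi <- min(n, iv$end[i] + pad)
    for (s in seq.int(lo, hi - 1)) m[s + 1] <- TRUE
  }
  m
}

# greedy IoU of one truth event against a set of detected intervals,
# taking the best single detected interval
best_iou <- function(ev_start, ev_end, iv) {
  if (nrow(iv) == 0) return(0)
  max(vapply(seq_len(nrow(iv)), function(i) {
    interval_iou(ev_start, ev_end, iv$start[i], iv$end[i])
  }, 0))
}
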