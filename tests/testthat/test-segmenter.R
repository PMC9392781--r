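cfg <- fix_cfg
fs <- 256

make_run <- function(n, seed = 1) {
  structure(list(data = noise_matrix(19, n, seed = seed), offset = 0L,
                 fs = fs, parent = "t", channel_labels = eegic_channels()),
            class = "eeg_run")
}

test_that("segmentation follows the 10-minute / overlap-tail / 10 s rules", {
  # 25 minutes: [0,10), [10,20) and an overlapping tail [15,25)
  segs <- segment_run(make_run(25 * 60 * fs), cfg)
  starts_min <- vapply(segs, function(s) s$provenance$start / fs / 60, 0)
  lens_min <- vapply(segs, function(s) ncol(s$data) / fs / 60, 0)
  expect_equal(starts_min, c(0, 10, 15))
  expect_equal(lens_min, c(10, 10, 10))
  # segments cover the run exactly
  covered <- logical(25 * 60 * fs)
  for (s in segs) {
    covered[(s$provenance$start + 1):(s$provenance$start + ncol(s$data))] <- TRUE
  }
  expect_true(all(covered))

  # 9 minutes: kept whole
  segs9 <- segment_run(make_run(9 * 60 * fs), cfg)
  expect_length(segs9, 1)
  expect_equal(ncol(segs9[[1]]$data), 9 * 60 * fs)

  # exact multiple: no overlap tail
  segs20 <- segment_run(make_run(20 * 60 * fs), cfg)
  expect_length(segs20, 2)

  # 8 seconds: dropped
  expect_length(segment_run(make_run(8 * fs), cfg), 0)
  # exactly 10 seconds: kept
  expect_length(segment_run(make_run(10 * fs), cfg), 1)
})

test_that("QC marks above 20 percent, rejects above two channels", {
  n <- 600 * fs
  pad <- cfg$margin * fs
  base <- noise_matrix(19, n, seed = 41)
  put_fraction <- function(m, ch, frac) {
    # an exceedance run at the segment start whose dilated mask is
    # exactly frac of the segment
    m[ch, 1:(frac * n - pad)] <- 6
    m
  }
  # exactly 20%: unmarked (strictly-greater rule)
  seg <- make_segment(put_fraction(base, "Fp1", 0.20))
  qc <- qc_mark(seg, cfg)
  expect_equal(unname(qc$fractions["Fp1"]), 0.20)
  expect_length(qc$marked_channels, 0)
  expect_false(qc$rejected)

  # 25% on one channel: marked, segment kept
  seg1 <- make_segment(put_fraction(base, "Fp1", 0.25))
  qc1 <- qc_mark(seg1, cfg)
  expect_equal(qc1$marked_channels, "Fp1")
  expect_false(qc1$rejected)

  # two channels marked: still kept
  m2 <- put_fraction(put_fraction(base, "Fp1", 0.25), "O1", 0.30)
  qc2 <- qc_mark(make_segment(m2), cfg)
  expect_setequal(qc2$marked_channels, c("Fp1", "O1"))
  expect_false(qc2$rejected)

  # three channels marked: rejected
  m3 <- put_fraction(m2, "T4", 0.22)
  qc3 <- qc_mark(make_segment(m3), cfg)
  expect_length(qc3$marked_channels, 3)
  expect_true(qc3$rejected)

  # determinism: identical marks on a re-run
  expect_identical(qc_mark(make_segment(m3), cfg), qc3)
})

test_that("a 600 s segment is scanned in 239 analysis windows", {
  # hop-count oracle: floor((600 - 5) / 2.5) + 1
  expect_equal(length(eegic:::.pop_windows(600 * fs, fs, cfg)),
               floor((600 - 5) / 2.5) + 1)
  expect_equal(length(eegic:::.pop_windows(600 * fs, fs, cfg)), 239)
  # shorter than one window: none
  expect_equal(length(eegic:::.pop_windows(4 * fs, fs, cfg)), 0)
})

test_that("a sustained baseline jump is flagged; fast rhythms are not", {
  n <- 60 * fs
  m <- noise_matrix(19, n, sd = 0.02, seed = 42)
  m["F7", (20 * fs):(40 * fs)] <- m["F7", (20 * fs):(40 * fs)] + 1
  seg <- make_segment(m)
  flags <- detect_pops(seg, cfg)
  expect_true(all(flags$channel == "F7"))
  expect_gte(nrow(flags), 1)
  # flagged windows cover the jump
  expect_lte(min(flags$start), 20 * fs)
  expect_gte(max(flags$end), 40 * fs)

  # a 0.8 mV 30 Hz rhythm is attenuated below the 0.5 mV flag level
  lp <- eegic:::.design_pop_lowpass(cfg, fs)
  h <- eegic:::.filtfilt_rows  # not the oracle; evaluate H analytically
  z <- exp(-1i * 2 * pi * 30 / fs)
  H30 <- Mod(sum(lp$b * z^(seq_along(lp$b) - 1)) /
             sum(lp$a * z^(seq_along(lp$a) - 1)))^2
  expect_lt(0.8 * H30, cfg$pop_amp)
  m2 <- noise_matrix(19, n, sd = 0.02, seed = 43)
  m2["F7", ] <- m2["F7", ] + 0.8 * sin(2 * pi * 30 * seq_len(n) / fs)
  expect_equal(nrow(detect_pops(make_segment(m2), cfg)), 0)
})

test_that("pop repair is local: only flagged spans of flagged channels move", {
  n <- 30 * fs
  m <- noise_matrix(19, n, sd = 0.02, seed = 44)
  m["F7", (10 * fs):(15 * fs)] <- m["F7", (10 * fs):(15 * fs)] + 1
  seg <- make_segment(m)
  flags <- detect_pops(seg, cfg)
  fixed <- resolve_pops(seg, flags, fix_montage, cfg)
  other <- setdiff(eegic_channels(), "F7")
  expect_identical(fixed$data[other, ], seg$data[other, ])
  touched <- iv_mask(iv_merge(interval_set(flags$start, flags$end)), n)
  expect_identical(fixed$data["F7", !touched], seg$data["F7", !touched])
  expect_false(identical(fixed$data["F7", touched], seg$data["F7", touched]))
  expect_gt(nrow(fixed$windows_interpolated), 0)
})

test_that("windows with more than two flagged channels are left untouched", {
  n <- 30 * fs
  m <- noise_matrix(19, n, sd = 0.02, seed = 45)
  span <- (10 * fs + 1):(12.5 * fs)          # exactly one window at 50% grid
  for (ch in c("F7", "T3", "O1")) m[ch, span] <- m[ch, span] + 1
  seg <- make_segment(m)
  flags <- detect_pops(seg, cfg)
  per_win <- table(paste(flags$start, flags$end))
  expect_true(any(per_win >= 3))
  fixed <- resolve_pops(seg, flags, fix_montage, cfg)
  expect_identical(fixed$data, seg$data)
})

test_that("a spline-consistent channel is reproduced by window repair", {
  seg <- spline_consistent_segment("F7", n = 10 * fs)
  flags <- data.frame(start = 2 * fs, end = 7 * fs, channel = "F7")
  fixed <- resolve_pops(seg, flags, fix_montage, cfg)
  span <- (2 * fs + 1):(7 * fs)
  rms <- sqrt(mean((fixed$data["F7", span] - seg$data["F7", span])^2))
  expect_lt(rms, 1e-6)
})

test_that("whole-channel interpolation recovers a spline-consistent channel", {
  seg <- spline_consistent_segment("Cz", n = 2000)
  out <- interpolate_channels(seg, "Cz", fix_montage, cfg)
  rms <- sqrt(mean((out$data["Cz", ] - seg$data["Cz", ])^2))
  expect_lt(rms, 1e-6)
  expect_equal(out$interpolated_channels, "Cz")

  # empty list: identity
  expect_identical(interpolate_channels(seg, character(0), fix_montage, cfg),
                   seg)
  # constant scalp field is reproduced exactly
  const <- make_segment(matrix(0.7, 19, 100,
                               dimnames = list(eegic_channels(), NULL)))
  ic <- interpolate_channels(const, c("Cz", "F3"), fix_montage, cfg)
  expect_equal(max(abs(ic$data - 0.7)), 0, tolerance = 1e-9)
  # more than max_interp channels is a contract error
  expect_error(interpolate_channels(seg, c("Cz", "F3", "O1"), fix_montage,
                                    cfg),
               "QC contract")
})

test_that("the spline operator is linear in the data", {
  pos <- fix_montage$pos3d
  L <- spherical_spline_operator(pos[-10, ], pos[10, , drop = FALSE])
  set.seed(46)
  v1 <- rnorm(18); v2 <- rnorm(18)
  expect_equal(as.numeric(L %*% (2 * v1 - 3 * v2)),
               as.numeric(2 * (L %*% v1) - 3 * (L %*% v2)),
               tolerance = 1e-12)
})
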