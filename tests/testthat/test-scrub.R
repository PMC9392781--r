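cfg <- fix_cfg
fs <- 256

test_that("an exact constant run is detected over its full span", {
  rec <- gen_background(19, 90, fs, seed = 21)
  plan <- annotation_set("flatline", "C3", 10 * fs, 70 * fs, 0)
  inj <- inject_artifacts(rec, plan, cfg)
  iv <- find_flat_saturated(inj, cfg)
  expect_equal(nrow(iv), 1)
  expect_equal(iv$start, 10 * fs)
  expect_equal(iv$end, 70 * fs)
})

test_that("a channel pinned at its amplitude rail is detected", {
  rec <- gen_background(19, 60, fs, seed = 22)
  plan <- annotation_set("saturation", "F3", 20 * fs, 50 * fs, 2)
  inj <- inject_artifacts(rec, plan, cfg)
  iv <- find_flat_saturated(inj, cfg)
  expect_equal(nrow(iv), 1)
  expect_match(iv$reason, "saturated")
  expect_gte(interval_iou(20 * fs, 50 * fs, iv$start, iv$end), 0.99)
})

test_that("white noise yields no flat or saturated intervals", {
  # independent brute-force scan: longest run of small consecutive diffs
  set.seed(23)
  x <- rnorm(5000)
  m <- matrix(rep(x, 3), 3, byrow = TRUE) + matrix(rnorm(15000), 3)
  rownames(m) <- c("Fp1", "Fp2", "Cz")
  rec <- eeg_recording(m, rownames(m), fs)
  longest <- max(vapply(1:3, function(i) {
    r <- rle(abs(diff(m[i, ])) < cfg$flat_eps)
    if (any(r$values)) max(r$lengths[r$values]) else 0L
  }, 0L))
  expect_lt(longest, cfg$flat_min_dur * fs - 1)
  expect_equal(nrow(find_flat_saturated(rec, cfg)), 0)
})

test_that("global peaks require every sentinel above threshold together", {
  rec <- gen_background(19, 60, fs, seed = 24)
  # all sentinels simultaneously: detected
  plan <- annotation_set("global_peak", "all", 30 * fs, 32 * fs, 6)
  inj <- inject_artifacts(rec, plan, cfg)
  iv <- find_global_peaks(inj, cfg)
  expect_gte(nrow(iv), 1)
  expect_gte(best_iou(30 * fs, 32 * fs, iv_merge(iv)), 0.8)

  # a single sentinel only: ignored
  one <- rec
  one$data["Fp1", (30 * fs):(32 * fs)] <- 6
  expect_equal(nrow(find_global_peaks(one, cfg)), 0)

  # below threshold on all sentinels: ignored
  sub <- rec
  for (ch in cfg$sentinel_channels) {
    sub$data[ch, (30 * fs):(32 * fs)] <- 4.9
  }
  expect_equal(nrow(find_global_peaks(sub, cfg)), 0)
})

test_that("sentinel exceedances within the coincidence window still count", {
  rec <- gen_background(19, 60, fs, seed = 25)
  # stagger the sentinels by 100 ms each, inside the 1 s window
  for (k in seq_along(cfg$sentinel_channels)) {
    ch <- cfg$sentinel_channels[k]
    s <- 30 * fs + (k - 1) * round(0.1 * fs)
    rec$data[ch, s:(s + fs / 4)] <- 6
  }
  expect_gte(nrow(find_global_peaks(rec, cfg)), 1)
})

test_that("a missing sentinel channel is a montage error", {
  rec <- gen_background(19, 5, fs, seed = 26)
  sub <- eeg_recording(rec$data[-1, ], rec$channel_labels[-1], fs)
  expect_error(find_global_peaks(sub, cfg), "montage error.*Fp1")
})

test_that("excision dilates by the 10 s margin on each side", {
  rec <- gen_background(19, 120, fs, seed = 27)
  a <- 50 * fs; b <- 55 * fs
  runs <- excise(rec, interval_set(a, b, "flat"), cfg)
  expect_length(runs, 2)
  expect_equal(ncol(runs[[1]]$data), a - 10 * fs)
  expect_equal(runs[[1]]$offset, 0)
  expect_equal(runs[[2]]$offset, b + 10 * fs)
  expect_equal(ncol(runs[[2]]$data), 120 * fs - (b + 10 * fs))
})

test_that("an empty interval set retains the whole recording as one run", {
  rec <- gen_background(3, 5, fs, seed = 28)
  runs <- excise(rec, interval_set(), cfg)
  expect_length(runs, 1)
  expect_equal(runs[[1]]$data, rec$data)
})

test_that("excision equals the brute-force mask oracle, including overlaps", {
  set.seed(29)
  n <- 120 * fs
  rec <- gen_background(5, 120, fs, seed = 29)
  pad <- cfg$margin * fs
  for (rep in 1:5) {
    k <- sample(1:4, 1)
    s <- sort(sample(0:(n - fs), k))
    iv <- interval_set(s, pmin(n, s + sample(fs:(15 * fs), k, replace = TRUE)))
    runs <- excise(rec, iv, cfg)
    kept <- logical(n)
    for (r in runs) kept[(r$offset + 1):(r$offset + ncol(r$data))] <- TRUE
    expect_equal(kept, !brute_mask(iv, n, pad))
    # conservation: retained + excised = total
    tot <- sum(vapply(runs, function(r) ncol(r$data), 0))
    expect_equal(tot + sum(brute_mask(iv, n, pad)), n)
    # no retained sample inside any dilated interval
    expect_false(any(kept & brute_mask(iv, n, pad)))
  }
})

test_that("raising the peak threshold never excises more", {
  rec <- gen_background(19, 120, fs, seed = 30)
  plan <- annotation_set(rep("global_peak", 2), rep("all", 2),
                         c(30, 80) * fs, c(33, 82) * fs, c(5.5, 7))
  inj <- inject_artifacts(rec, plan, cfg)
  excised_at <- function(th) {
    c2 <- pipeline_config(peak_thresh = th)
    scrub_recording(inj, c2)$excised_samples
  }
  counts <- vapply(c(4, 5, 6, 7.5), excised_at, 0)
  expect_true(all(diff(counts) <= 0))
})

test_that("re-scrubbing retained runs removes nothing new", {
  rec <- gen_background(19, 150, fs, seed = 31)
  plan <- annotation_set(c("flatline", "global_peak"), c("C3", "all"),
                         c(30, 100) * fs, c(40, 102) * fs, c(0, 7.5))
  inj <- inject_artifacts(rec, plan, cfg)
  sc <- scrub_recording(inj, cfg)
  for (r in sc$runs) {
    rec2 <- eeg_recording(r$data, rec$channel_labels, fs)
    sc2 <- scrub_recording(rec2, cfg)
    expect_equal(sc2$excised_samples, 0)
  }
})
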