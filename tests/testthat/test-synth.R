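fs <- 256
cfg <- fix_cfg

test_that("the generator is deterministic and leaves the global RNG alone", {
  a <- gen_background(19, 10, fs, seed = 71)
  b <- gen_background(19, 10, fs, seed = 71)
  expect_identical(a$data, b$data)
  expect_false(identical(a$data, gen_background(19, 10, fs, seed = 72)$data))
  set.seed(1); before <- rnorm(1)
  set.seed(1); gen_background(3, 1, fs, seed = 73); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("background has posterior alpha and benign amplitude", {
  rec <- gen_background(19, 60, fs, seed = 74)
  expect_equal(sqrt(mean(rec$data^2)), 0.05, tolerance = 0.05)
  p <- compute_psd(rec$data["O1", ], fs, cfg, normalize = FALSE)
  f <- attr(p, "freq")
  alpha <- max(p[f >= 8 & f <= 12])
  floor_ <- max(p[f >= 15 & f <= 20])
  expect_gt(alpha, floor_)
  # nothing approaches the 5 mV peak threshold
  expect_lt(max(abs(rec$data)), cfg$peak_thresh)
  expect_equal(nrow(find_global_peaks(rec, cfg)), 0)
})

test_that("injection is local: untouched samples are bit-identical", {
  rec <- gen_background(19, 60, fs, seed = 75)
  plan <- annotation_set(
    type = c("flatline", "global_peak", "electrode_pop"),
    channel = c("C3", "all", "F7"),
    start = c(5, 25, 40) * fs, end = c(10, 27, 55) * fs,
    magnitude = c(0, 7.5, 0.75))
  inj <- inject_artifacts(rec, plan, cfg)
  mask <- logical(60 * fs)
  for (i in seq_len(nrow(plan))) mask[(plan$start[i] + 1):plan$end[i]] <- TRUE
  expect_identical(inj$data[, !mask], rec$data[, !mask])
  # empty plan: unchanged
  expect_identical(inject_artifacts(rec, annotation_set(), cfg)$data,
                   rec$data)
  # out-of-bounds plan rejected
  expect_error(inject_artifacts(rec, annotation_set("flatline", "C3",
                                                    59 * fs, 61 * fs, 0),
                                cfg),
               "plan error")
})

test_that("each injected artifact is found by its detector", {
  rec <- gen_background(19, 300, fs, seed = 76)
  plan <- annotation_set(
    type = c("flatline", "saturation", "global_peak"),
    channel = c("C3", "F3", "all"),
    start = c(30, 100, 200) * fs, end = c(50, 130, 202) * fs,
    magnitude = c(0, 2, 7.5))
  inj <- inject_artifacts(rec, plan, cfg)
  fl <- find_flat_saturated(inj, cfg)
  expect_gte(best_iou(30 * fs, 50 * fs, fl), 0.8)
  expect_gte(best_iou(100 * fs, 130 * fs, fl), 0.8)
  pk <- find_global_peaks(inj, cfg)
  expect_gte(best_iou(200 * fs, 202 * fs, iv_merge(pk)), 0.8)

  # electrode pop: flagged on F7 and nowhere else
  rec2 <- gen_background(19, 120, fs, seed = 77)
  pop <- annotation_set("electrode_pop", "F7", 40 * fs, 80 * fs, 0.75)
  inj2 <- inject_artifacts(rec2, pop, cfg)
  flags <- detect_pops(make_segment(inj2$data), cfg)
  expect_true(all(flags$channel == "F7"))
  expect_gte(nrow(flags), 1)
  span <- iv_merge(interval_set(flags$start, flags$end))
  expect_gte(interval_iou(40 * fs, 80 * fs, span$start[1],
                          span$end[nrow(span)]), 0.8)
})

test_that("mixtures reproduce their spec and reject bad ones", {
  S3 <- gen_mixture(mixture_spec(diag(3), rep("laplacian", 3),
                                 duration_s = 2, fs = fs, seed = 78))
  expect_equal(S3$mixed, S3$sources)
  expect_error(mixture_spec(matrix(c(1, 1, 2, 2), 2), rep("laplacian", 2)),
               "rank")
  expect_error(mixture_spec(diag(2), c("laplacian", "cauchy")),
               "distribution")
  a <- gen_mixture(mixture_spec(diag(2), c("uniform", "sinusoid"),
                                duration_s = 1, fs = fs, seed = 79))
  b <- gen_mixture(mixture_spec(diag(2), c("uniform", "sinusoid"),
                                duration_s = 1, fs = fs, seed = 79))
  expect_identical(a$mixed, b$mixed)
})

test_that("fixture synthesis writes a loadable container and plan", {
  stem <- tempfile()
  fx <- synthesize_fixture(out_stem = stem, duration_s = 30, seed = 80)
  back <- load_recording(paste0(stem, ".tsv"))
  expect_equal(back$data, fx$recording$data, tolerance = 0)
  plan <- jsonlite::read_json(paste0(stem, "_plan.json"),
                              simplifyVector = TRUE)
  expect_equal(nrow(plan), nrow(fx$plan))
})
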