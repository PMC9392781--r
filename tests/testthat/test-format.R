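fs <- 256

make_sample <- function(patient, segid, ic, label, split, seed = 1,
                        n = 10 * fs) {
  set.seed(seed)
  assemble_sample(rnorm(n), rnorm(19), label,
                  list(patient = patient, segment = segid, ic = ic,
                       split = split),
                  fix_montage, fs = fs, cfg = fix_cfg)
}

mini_dataset <- function(root, n_brain = 3, n_art = 2) {
  samples <- c(
    lapply(seq_len(n_brain), function(i)
      make_sample("p1", "s1", i, "not-artifact", "training", seed = i)),
    lapply(seq_len(n_art), function(i)
      make_sample("p1", "s1", n_brain + i, "artifact", "training",
                  seed = 100 + i))
  )
  set.seed(7)
  W <- matrix(rnorm(18 * 19), 18, 19)
  write_dataset(samples, list(p1_s1 = W), root)
  list(samples = samples, W = W)
}

test_that("write then read round-trips all numeric content", {
  root <- tempfile()
  made <- mini_dataset(root)
  back <- read_dataset(root)
  expect_length(back$samples, 5)
  for (s in back$samples) {
    ref <- made$samples[[match(s$stem,
      vapply(made$samples, function(x)
        sprintf("%s_%s_%s", x$provenance$patient, x$provenance$segment,
                x$provenance$ic), ""))]]
    expect_equal(s$label, ref$label)
    expect_equal(s$timeseries, ref$timeseries, tolerance = 1e-6)
    expect_equal(s$psd, as.numeric(ref$psd), tolerance = 1e-6)
    expect_equal(unname(s$topomap), unname(ref$topomap), tolerance = 1e-6)
  }
  expect_equal(back$weights$training$p1_s1, made$W, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(dim(back$weights$training$p1_s1), c(18, 19))
})

test_that("the split index computes counts and rounded percentages", {
  root <- tempfile()
  mini_dataset(root, n_brain = 7, n_art = 3)
  idx <- read_dataset(root)$index
  tr <- idx[idx$split == "training", ]
  expect_equal(tr$total, 10)
  expect_equal(tr$brain_pct, 70.00)
  expect_equal(tr$artifact_pct, 30.00)
  # empty artifact directory is valid
  root2 <- tempfile()
  mini_dataset(root2, n_brain = 2, n_art = 0)
  idx2 <- read_dataset(root2)$index
  expect_equal(idx2[idx2$split == "training", "artifact"], 0)
})

test_that("a pristine dataset validates with zero failures", {
  root <- tempfile()
  mini_dataset(root)
  rep <- validate_dataset(root)
  expect_length(rep$failures, 0)
  expect_equal(rep$n_checked, 5)
  jf <- tempfile(fileext = ".json")
  write_validation_report(rep, jf)
  expect_true(jsonlite::validate(paste(readLines(jf), collapse = "")))
})

test_that("corruption is localised to the offending file", {
  root <- tempfile()
  mini_dataset(root)
  psds <- list.files(file.path(root, "training", "not-artifact"),
                     pattern = "_psd", full.names = TRUE)
  writeLines("0.1 0.2 oops", psds[1])
  rep <- validate_dataset(root)
  expect_length(rep$failures, 1)
  expect_match(rep$failures[1], basename(psds[1]), fixed = TRUE)

  # non-square topomap
  root2 <- tempfile()
  mini_dataset(root2)
  tms <- list.files(file.path(root2, "training", "artifact"),
                    pattern = "_topomap", full.names = TRUE)
  lines <- readLines(tms[1])
  writeLines(lines[-1], tms[1])      # 66 x 67
  rep2 <- validate_dataset(root2)
  expect_length(rep2$failures, 1)
  expect_match(rep2$failures[1], "not square")
  # the reader refuses it outright
  expect_error(read_dataset(root2), "schema error")

  # out-of-range PSD values
  root3 <- tempfile()
  mini_dataset(root3)
  psd3 <- list.files(file.path(root3, "training", "not-artifact"),
                     pattern = "_psd", full.names = TRUE)[1]
  writeLines("0.5 1.5 0.2", psd3)
  expect_match(validate_dataset(root3)$failures, "outside")
})

test_that("weights files carry rows = ICs and columns = channels", {
  root <- tempfile()
  made <- mini_dataset(root)
  wf <- list.files(file.path(root, "training", "ica-weights"),
                   full.names = TRUE)
  expect_length(wf, 1)
  lines <- readLines(wf)
  expect_length(lines, 18)
  expect_length(strsplit(trimws(lines[1]), " +")[[1]], 19)
})

test_that("topomap files are 67 rows of 67 values", {
  root <- tempfile()
  mini_dataset(root, n_brain = 1, n_art = 0)
  tm <- list.files(file.path(root, "training", "not-artifact"),
                   pattern = "_topomap", full.names = TRUE)
  lines <- readLines(tm[1])
  expect_length(lines, 67)
  expect_true(all(vapply(lines, function(l)
    length(strsplit(trimws(l), " +")[[1]]), 0L) == 67))
})
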