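# eegic

Quality-controlled segmentation and independent-component feature
extraction for long-term 19-channel scalp EEG.

## What problem this solves

Scalp EEG recorded over days of presurgical epilepsy monitoring is
riddled with experimental errors — isoelectric flatlines from
disconnected electrodes, amplifier saturation, whole-head movement
artifacts, electrode "pops". Independent component analysis (ICA) can
separate brain activity from such artifacts, but building and training
IC classifiers requires large corpora of components produced by a
*consistent, auditable* preprocessing chain. `eegic` implements that
chain for the standard 10–20 montage (19 electrodes, 256 Hz) and writes
its output in a plain-text dataset layout of labelled component
samples, for anyone assembling or validating such corpora.

The pipeline, in order:

1. 0.5–100 Hz 4th-order Butterworth band-pass + 50 Hz 2nd-order notch
   (zero-phase);
2. excision of flatlines and saturated runs, with 10 s margins, across
   all channels;
3. excision of global abnormal peaks: |x| > 5 mV simultaneously on the
   sentinel electrodes Fp1, Fp2, O1, O2, T5, T6, Cz (±10 s margins);
4. segmentation of the retained runs into 10-minute segments (a final
   overlapping segment covers any remainder; segments < 10 s are
   dropped);
5. per-segment channel QC: a channel whose peak-rule excision fraction
   exceeds 20% is marked for interpolation; > 2 marked channels reject
   the segment;
6. electrode-pop handling in 5 s windows (50% overlap): windows whose
   5 Hz-low-passed trace exceeds 0.5 mV on ≤ 2 channels are repaired by
   spherical-spline interpolation;
7. spherical-spline interpolation of QC-marked channels (order m = 4,
   7 Legendre terms), average re-referencing, and extended-infomax ICA
   with PCA sphering to the data's effective rank
   (`n_channels − 1 − n_interpolated`).

Per component *k* the package emits the unnormalized source
`s_k = W_k · X` (W the unmixing matrix composed with sphering, X the
channel data), a min–max-normalized Welch power spectrum over 1–90 Hz,
and a min–max-normalized 67×67 topographic map of the mixing-matrix
column `A_k` (nasion at the top of the grid). A synthetic-EEG generator
with ground-truth artifact annotations makes the whole chain testable
without any clinical data.

## Worked example

Generate five minutes of synthetic EEG with one flatline, one global
movement artifact and one electrode pop, run the full pipeline, and
validate the written dataset:

```r
library(eegic)

cfg <- pipeline_config()          # all thresholds, inspectable/overridable
fx  <- synthesize_fixture(duration_s = 300, seed = 42)
fx$plan
#>            type channel start   end magnitude
#> 1      flatline      C3  7680  8960      0.00
#> 2   global_peak     all 34560 35072      7.50
#> 3 electrode_pop      F7 57600 67840      0.75

mf <- run_pipeline(list(fx$recording), cfg, out_root = "ic_corpus", seed = 42)
mf
#> <run_manifest> 1 recording(s), 3 segment(s), 54 IC sample(s)
#>   input 0.083 h, retained 0.071 h, excised 0.013 h
```

The flatline (5 s) and the movement artifact (2 s) each cost their own
span plus the two 10 s margins, so 0.0127 h ≈ 45.6 s were excised and
the remainder survives in runs that the segmenter split into three
segments (the retained runs here are shorter than 10 minutes, so each
becomes one segment; the pop on F7 was repaired in place, not excised).
Each accepted segment decomposed into 18 components — 19 channels minus
one dimension for the average reference:

```r
mf$recordings[, c("input_h", "retained_h", "excised_h", "n_segments")]
#>      input_h retained_h  excised_h n_segments
#> 1 0.08333333 0.07065538 0.01267795          3

rep <- validate_dataset("ic_corpus")
rep$index
#>      split total brain artifact brain_pct artifact_pct split_pct
#> 1 training    54    54        0       100            0       100
#> 2     test     0     0        0        NA           NA         0
length(rep$failures)
#> [1] 0

mf$samples[[1]]
#> <ic_sample> not-artifact, 5292 samples, psd[179], topomap 67x67
```

Every component sample carries its raw time-series (amplitude is never
rescaled — it matters for artifact judgement), a 179-bin normalized
spectrum (1–90 Hz at 0.5 Hz resolution) and the 67×67 map. On disk,
`ic_corpus/` holds `training/` and `test/` splits with `artifact/`,
`not-artifact/` and `ica-weights/` subdirectories of whitespace-
delimited text files; `read_dataset()` parses them back and
`validate_dataset()` checks completeness, parsability, map squareness
and feature ranges. Components are filed under `not-artifact` pending
expert labelling, which is outside this package's scope.

A thin command-line front end is installed with the package
(`system.file("cli", "eegic", package = "eegic")`) with `run`, `synth`
and `validate` subcommands.

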