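---
title: "From long-term scalp EEG to labelled independent components: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From long-term scalp EEG to labelled independent components: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Long-term scalp EEG recorded during presurgical epilepsy monitoring is
contaminated by everything daily life produces: electrode disconnections
(isoelectric flatlines), amplifier saturation, whole-head movement
artifacts, and transient electrode-contact failures ("pops").
Independent component analysis (ICA) separates such recordings into
statistically independent sources, but training classifiers that
recognise artifactual components requires corpora of components with
consistent preprocessing and features. `eegic` implements that
preprocessing end to end for the classic 19-electrode 10–20 montage at
256 Hz: quality-controlled 10-minute segments, extended-infomax
decompositions, and per-component features (time-series, 1–90 Hz power
spectrum, 67×67 scalp map) written in a plain-text corpus layout.

All amplitudes inside the package are **millivolts**; every published
threshold the pipeline uses (5 mV peaks, 0.5 mV pops) is natively in mV,
so the loader converts on ingestion (EDF files typically store µV).
Sample indices are 0-based and all intervals half-open `[start, end)`,
which keeps every excision, segmentation and windowing rule free of
off-by-one ambiguity.

## Pipeline stages and their parameters

1. **Frequency filtering.** 0.5–100 Hz 4th-order Butterworth band-pass
   plus a 50 Hz 2nd-order Butterworth band-stop (default width 4 Hz).
   Both run forward–backward (zero phase), so the effective magnitude
   response is the square of the designed one; `cascade_response()`
   exposes the analytic response that the tests compare against. The
   band-pass ordering matters for everything downstream: detection
   happens on filtered data.

2. **Flatline / saturation excision.** A flatline is a run of at least
   `flat_min_dur` (1 s) in which consecutive-sample differences on some
   channel stay below `flat_eps` (1e-4 mV); saturation is a run pinned
   within `flat_eps` of the channel's own amplitude rail, estimated as
   its minimum/maximum over the recording. Neither constant is dictated
   by the corpus description, so both are configurable; the defaults
   separate digitizer-constant runs from genuine low-amplitude sleep
   EEG. Detection on *any* channel excises the span on *all* channels.
   Two practical notes: a clamped run whose level is not the channel
   extreme is still caught by the flatline rule (a constant run is
   isoelectric by definition); and because detection follows filtering,
   the filter's edge transients erode roughly 1–2 s from each end of an
   exactly constant run — the excision margins absorb this in practice.

3. **Global abnormal peaks.** Samples beyond ±`peak_thresh` (5 mV) count
   only when *all* sentinel electrodes (default Fp1, Fp2, O1, O2, T5,
   T6, Cz) exceed the threshold within a sliding 1 s coincidence
   window: a genuine whole-head movement registers everywhere at
   physiologically — not sample-exactly — the same time. Exceedance runs
   closer than one coincidence window are fused into one event, since
   the crests of a single oscillatory movement artifact are one
   artifact, not many. The description of the source corpus lists the
   sentinel set twice with a discrepancy (T5/T6 in the text, T7/T8 in a
   figure); under 10–20 naming these are different electrodes. The
   package follows the textual set and accepts both nomenclatures as
   aliases, so either choice is one configuration away.

4. **Margin excision.** Every detected interval is widened by `margin`
   (10 s) on each side; the retained complement is kept as separate
   *runs* that are never concatenated, preserving temporal coherence.
   Conservation (retained + excised = total, per channel) is asserted
   property-style in the tests against a brute-force boolean-mask
   oracle.

5. **Segmentation.** Runs ≥ 600 s yield consecutive 10-minute segments
   plus, if a remainder exists, one final full-length segment ending at
   the run's end (overlapping its predecessor); shorter runs are kept
   whole if ≥ 10 s, else dropped. The overlap rule is applied uniformly
   to any run with a remainder.

6. **Channel QC.** Per channel, the fraction of the segment that the
   peak rule *would* excise (dilated by the same 10 s margins, clipped
   to the segment) is computed; fractions strictly above `chan_frac`
   (20%) mark the channel, and strictly more than `max_interp` (2)
   marks reject the segment. Both comparisons are strict, so exact-20%
   channels and exactly-two-marked segments pass — the boundary tests
   pin this down.

7. **Electrode pops.** 5-second windows with 50% overlap (239 windows
   for a full segment; a trailing partial window is not emitted) are
   low-pass filtered at 5 Hz on a copy — zero-phase, 4th-order
   Butterworth, so the pop is not shifted relative to its window — and
   a (window, channel) is flagged when the filtered peak absolute
   amplitude exceeds `pop_amp` (0.5 mV). Windows with ≤ 2 flagged
   channels have those channels' original samples replaced by
   spherical-spline interpolation from the others; overlapping flagged
   windows are unioned per channel so no sample is interpolated twice;
   windows with ≥ 3 flagged channels are left untouched. Detection does
   not re-run after repair.

8. **Whole-channel interpolation, re-referencing, ICA.** QC-marked
   channels are rebuilt by the spherical spline, every segment is
   re-referenced to the common average, and extended-infomax ICA is
   run. IC time-series are the plain product `W · data` and are never
   re-scaled — component amplitude is informative downstream.

## Spherical-spline interpolation

The interpolation operator uses the truncated Legendre kernel

$$g(x) = \frac{1}{4\pi}\sum_{n=1}^{N}\frac{2n+1}{(n(n+1))^{m}}P_n(x)$$

with order `m = 4`, truncation `N = 7` and ridge regularization
`1e-5` on the Gram diagonal — the defaults of the widely used scalp
toolchains. Solving the standard constrained system (spline
coefficients summing to zero plus a free constant) makes the operator
reproduce constant scalp fields exactly and keeps it linear in the
data, so it is precomputed once per electrode set and applied to whole
segments as a single matrix product. Electrode positions come from an
idealized spherical 10–20 montage: the outer ring at 90° inclination,
midline and central electrodes at 45°, and F3/F4/P3/P4 as exact arc
midpoints (spherical interpolation of their neighbours), which makes
left–right mirror symmetry exact by construction.

## Extended-infomax ICA

The data are PCA-sphered to `n_comp` dimensions, then rotated by the
natural-gradient infomax iteration with the per-component
sub/super-Gaussian switch: block updates
`ΔW ∝ (I − K tanh(u)uᵀ − uuᵀ)W` with `K = diag(±1)` re-estimated each
pass from the kurtosis proxy `E[sech²u]·E[u²] − E[u tanh u]` on a fixed
random subsample (6000 points). Learning-rate annealing (factor 0.98
when successive update directions differ by more than 60°), weight
blow-up restarts, and a weight-change stopping rule follow the standard
published algorithm; in addition the learning rate is damped whenever
the per-pass weight change *increases*, which settles the iteration on
stochastic plateaus that the angle rule alone does not catch (near
Gaussian background activity the update direction decorrelates without
widening beyond 60°). The stopping tolerance defaults to `1e-6` on the
summed squared weight change — the reference implementations use this
value for montages up to 32 channels — with a 512-iteration cap;
exceeding the cap raises a convergence error that the pipeline records
before moving on.

**Rank handling.** Average re-referencing removes one dimension and
each wholly interpolated channel removes another, so the default
component count is `n_channels − 1 − n_interpolated`, reached through
the PCA sphering step; requesting more than the effective rank is an
error rather than a degenerate fit. Sphering is computed on the
uncentred second-moment matrix: segments arriving at ICA are high-pass
filtered and average-referenced, so channel means are already
negligible, and skipping the centring makes `mixing × sources`
reconstruct the input exactly at full rank. The unmixing matrix stored
and written to disk is the infomax rotation *composed with* the
sphering transform, so `weights × channel data = sources` holds
literally for everything the package writes.

## Component features

* **PSD.** Welch average of 2-second Hamming windows with 50% overlap,
  in dB, cropped to 1–90 Hz inclusive (0.5 Hz resolution, 179 bins with
  the default window — asserted in tests, not hard-coded), then min–max
  normalized. Normalization operates on the dB scale, matching how such
  spectra are displayed and compared; the choice is configurable via
  `normalize = FALSE` plus an explicit rescale if linear-power
  normalization is wanted.
* **Topographic map.** The component's scalp pattern is the
  corresponding *column of the mixing matrix* (the convention of the
  standard plotting tools; the unmixing row is the other defensible
  choice). Electrodes are projected azimuthal-equidistantly onto a
  disc with the outer 10–20 ring at 95% of the radius, the spherical
  spline is evaluated on a 67×67 pixel grid (top row = front of the
  head, so the upper-left pixel is the left-nasion corner), in-head
  pixels are min–max normalized and off-disc pixels filled with 0. The
  fill-pixel set is a pure function of the grid geometry and identical
  for every sample.
* **Time-series.** Stored exactly as extracted; min–max normalization
  of a constant input (which would divide by zero) falls back to 0.5
  everywhere with a warning.

## The synthetic generator

Real inputs for this pipeline are access-restricted clinical
recordings, so every stage is exercised against a generator that
emulates just enough structure to make the detectors' decisions
meaningful: per-channel pink (1/f) noise with a shared 10 Hz alpha
rhythm weighted ×3 toward posterior electrodes (giving topomaps
non-trivial structure), scaled to 0.05 mV RMS — physiological scale,
far below every threshold, so the false-positive rate on clean
background is testably zero. Injected events carry exact ground-truth
spans: flatlines are exact constants, saturation clamps at a rail,
global peaks are trapezoid-enveloped 8 Hz oscillations (in-band, so
the event survives the band-pass the pipeline applies before
detection; a pure baseline swell would be filtered away), and pops are
single-channel steps with slow exponential recovery whose energy sits
below 5 Hz. Event magnitudes default to 1.5× their detector thresholds
so recall tests do not sit on a knife edge; boundary behaviour is
tested separately and explicitly. The generator is deliberately *not*
a biophysical head model: no volume conduction, no ocular/cardiac
source geometry, no ictal patterns. Passing tests therefore demonstrate
the pipeline's decision rules and numerics, not clinical artifact
coverage on real data.

Known-mixture fixtures (`gen_mixture`) drive the ICA recovery tests:
unit-variance Laplacian (super-Gaussian), uniform (sub-Gaussian) and
sinusoidal sources mixed through a full-rank matrix, recovered sources
matched one-to-one by greedy absolute correlation.

## Problem sizes and tolerances in the shipped tests

The test suite runs entirely on generated data: detector and QC
properties on 2–5-minute recordings, ICA recovery on 3×3 mixtures of
30–40 s, one 30-minute end-to-end run whose artifact plan leaves a
single clean ~2-minute segment for decomposition (the surrounding
segments exercise QC rejection), and dataset round-trips on dozens of
samples. Numeric contracts: spline recovery and ICA reconstruction to
1e-6, unmixing–mixing product to 1e-6 of the identity, text round-trips
to 1e-6 relative (files carry 8 significant digits), source-recovery
correlation > 0.95, detector IoU ≥ 0.8 against injected spans, and
filter gains within 1 dB of the analytic response.

## Known limitations

* The loader targets the 19-electrode 10–20 montage only; high-density
  caps and non-EEG polygraphy channels are out of scope (non-montage
  EDF signals are dropped with a message).
* Saturation rails are estimated per recording; a rail that drifts
  between sessions is only caught via the flatline rule.
* Pop detection after the 0.5 Hz high-pass sees step edges rather than
  sustained offsets; slow pops are therefore flagged near their onset,
  which is where the interpolation repair matters most.
* The pipeline emits unlabelled components (filed under `not-artifact`
  by default, configurable); assigning artifact labels is an
  expert-annotation step outside this package's scope.
* EDF support covers continuous recordings with a common sampling rate
  across EEG signals — the subset the pipeline consumes.
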