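---
title: "Methods: dynamic-contrast rendering, wound kinetics and optical flow"
author: "dynwound"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dynamic-contrast rendering, wound kinetics and optical flow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, parameter choices and numerical
decisions behind `dynwound`. It states no empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

# The dynamic profile

A D-FFOCT acquisition records a burst of `T` interferometric frames (512
at 100 Hz by default) at a fixed plane. Intracellular motion modulates
the backscattered field, so the temporal fluctuation spectrum of each
pixel carries a motion signature. Per pixel we compute a single
mean-removed periodogram — no taper, no Welch averaging — the simplest
estimator consistent with a per-voxel power-spectrum analysis.

**Normalization.** With `X_k` the DFT of the mean-removed series, the
power at positive bin `k` is `2|X_k|^2 / T^2` (the Nyquist bin, when `T`
is even, counts once as `|X_k|^2 / T^2`). Under this convention the
positive-frequency powers sum exactly to the population variance of the
mean-removed series; a property test asserts this Parseval identity to
1e-8 relative.

The three HSV channels are:

- **Hue** — the power-weighted mean frequency, normalized into
  `hueFreqRange` (default 0 Hz to Nyquist = 50 Hz) and mapped onto the
  240° → 0° arc, i.e. blue for slow fluctuations through green and
  yellow to red for fast ones. The arc deliberately stops at red rather
  than wrapping through magenta so that hue order is frequency order.
  The stored `hue` channel is the normalized position in [0, 1].
- **Saturation** — `1 − Δf / bandwidthScale`, clamped to [0, 1], where
  `Δf` is the power-weighted standard deviation of frequency and
  `bandwidthScale` defaults to `frameRate / 4` (25 Hz). A sharp spectral
  line therefore renders vivid, broadband noise grey. The inverse-
  bandwidth law is bounded and monotone in `1/Δf` over the relevant
  range, which is all the rendering requires.
- **Value** — the population standard deviation over a sliding 50-frame
  window (stride 1), averaged over windows, then divided by its 99.5th
  percentile over the frame and clamped. Percentile clipping makes the
  display robust to isolated hot pixels; the percentile is a parameter
  so renders are reproducible. Sliding rather than disjoint windows is
  used; with mean removal the channel is invariant under constant
  intensity offsets.

Pixels with zero fluctuation power are flagged *silent* and carry zero
mean frequency and bandwidth, so a constant burst renders exactly black.

Static FFOCT amplitude is `|I⁺ − I⁻| / 2` for a π-phase-shifted frame
pair — amplitude, not signed phase, is what is displayed. Plane
re-locking selects the plane of an axial rescan maximizing the
zero-normalized (Pearson) cross-correlation with the reference image at
zero lateral lag; ties break toward the lowest index. Lateral
registration is out of scope.

# Wound segmentation and kinetics

The profiling pipeline runs, in order:

1. **Threshold.** Multi-level Otsu (exact dynamic program over a 256-bin
   histogram) on the first and last frames; the *first* level — the
   lowest threshold — separates the near-black scratch from everything
   else, so cell interstices count as cells. Thresholds are computed
   inside the bounding box of the user ROI (the calculation window
   around the wound): on a nearly closed final frame the scratch class
   is a tiny fraction of the full field and whole-frame Otsu would
   drift into the next intensity class. The default `nClasses = 3`
   (scratch / cytoplasm / bright organelles) is configurable.
2. **Interpolate.** The threshold varies linearly from the first-frame
   to the last-frame value, absorbing slow illumination drift.
3. **Rotate.** The stack is rotated so the user-drawn scratch line is
   vertical (the smaller-magnitude of the two equivalent rotations;
   bilinear resampling for intensity, nearest-neighbour for binary
   frames), then cropped to the maximal axis-aligned rectangle free of
   fill pixels (closed-form inscribed-rectangle, verified against the
   resampling validity mask). Exact 0°/90° cases stay exact.
4. **Mask and measure.** Wound pixels are those strictly below the
   per-frame threshold and inside the ROI polygon (drawn on the first
   frame for closing wounds, the last for expanding ones; pixel-centre
   point-in-polygon test, boundary inclusive). Area is the mask pixel
   count; width per image row is the wound-pixel count in that row, and
   min/mean/max are taken over rows intersecting the ROI. No
   morphological cleanup is applied by default; a small-object removal
   flag exists but is off.
5. **Closure and fit.** `closure(t) = (area(0) − area(t))/area(0) × 100`
   — 100 at full closure, negative for expansion. The mean width in µm
   is fitted with `w(t) = closingLimit + a·e^{bt} + c·e^{dt}`.

**Fit details.** The fit is Levenberg–Marquardt least squares
(`minpack.lm`) on the excess width over the closing limit, with a
deterministic multi-start grid: amplitude splits 0.9/0.5/0.1 of the
initial excess and rate starts −1/T, −0.1/T, −0.01/T (T the acquisition
span); the best residual wins, so results are reproducible. Both rates
are constrained to be ≤ 0: growing exponentials are not part of the
closing-kinetics model, and unconstrained fits can acquire a
negligible-amplitude positive-rate term that explodes under the
extrapolation used below (expanding wounds remain representable through
negative amplitudes with negative rates). Fitting is done in µm, and the
time axis is in minutes.

**Derived quantities.** Neither the characteristic time nor the average
speed has a unique definition, so the package documents its own:

- *Characteristic time* — the smallest `t` at which the fitted excess
  falls to 1/e of its initial value above its plateau, solved
  numerically (grid bracket + `uniroot`). The plateau is the analytic
  `t → ∞` limit of the fitted excess (decaying terms vanish, zero-rate
  terms persist), floored at zero because the width cannot settle below
  the closing limit — the limit *is* the residual inter-cell interstice
  (default 1.5 µm, mid-range of the plausible 1–2 µm band). For a pure
  single exponential with plateau at the limit, this definition returns
  exactly its time constant τ.
- *Average closing speed* — `(w_fit(0) − limit) / t_reach × 60` µm/h,
  where `t_reach` is the first time the fitted curve reaches the limit.
  If the curve does not reach the limit within the acquisition, the
  speed over the observed interval,
  `(w_fit(0) − w_fit(t_max)) / t_max × 60`, is reported and the result
  is flagged *not closed*.

# Optical flow

Frames are median-filtered (3×3, exact sorting network; removes camera
line noise), lightly Gaussian-presmoothed (three binomial passes,
σ ≈ 1 px — standard practice before differential flow estimation, and
essential under measurement noise, which otherwise dilutes the
brightness-constancy regression toward zero flow), and averaged in
non-overlapping temporal blocks of `blockAvg` frames (default 8,
multiplying the effective frame interval).

Horn–Schunck then solves brightness constancy plus smoothness by the
classic fixed-point iteration with the original forward-difference cube
estimators for `Ex`, `Ey`, `Et`, the 6/12-weighted 8-neighbour average,
zero initialization and a fixed iteration count (default 200; the mean
update norm of the last iteration is reported for convergence
monitoring). The smoothness weight `alpha` is expressed in intensity-
gradient units: the default 0.1 suits [0, 1]-normalized frames and
corresponds to the conventional weight of 1 used with 8-bit (0–255)
imagery. Fields from consecutive pairs are averaged per pixel and
converted to µm/h via `pixelSize × 60 / (frameInterval × blockAvg)`.

**Operating envelope.** The method linearizes brightness change, so the
displacement between consecutive (block-averaged) frames must stay
sub-pixel — in practice ≤ ~0.8 px. `blockAvg` should be chosen so that
`frontSpeed/60 × frameInterval × blockAvg / pixelSize` respects this;
the CLI `simulate` command writes such a recommendation into the
generated configuration. Pyramidal coarse-to-fine schemes that lift this
restriction are out of scope.

**Summaries.** Pixels with magnitude below the 2 µm/h floor are
excluded from all statistics (applying the display floor to summaries
too avoids noise-floor bias); pixels inside a supplied wound mask and
the axis column itself are excluded from front means. The two fronts
are the half-planes either side of the wound axis column; the total
closure speed is twice the mean of the per-front mean speeds, because
two opposite fronts approach each other. If every pixel falls below the
floor the summary is zero and flagged. The arrow export decimates the
field on a fixed grid, drops sub-floor arrows, and scales length
proportionally to speed with a recorded scale factor.

# The synthetic-data generator

`simulateWoundTimelapse` renders a Voronoi cell mosaic with dimmer
inter-cell interstices (0.38 vs cell bodies 0.55–0.9 and a near-black
scratch at 0.08), band-limited by a PSF-scale Gaussian — microscope
images carry no energy at the pixel scale — and modulated by spatially
correlated multiplicative speckle (amplitude 0.15) standing in for
organelle-scale dynamic contrast. The wound is a dark band whose two
borders move independently:

- *speed* kinetics — constant border speeds in µm/h until the width
  reaches the closing limit;
- *rate* kinetics — each border's half-width excess over the limit
  decays exponentially (per-border exponentials summing to a double
  exponential across the wound);
- scenarios *close*, *attempt_then_retract* (close until an onset time,
  then linear retraction) and *expand*.

The cell sheet on each side advects rigidly with its border (cells
migrate with the front), sampled bilinearly from a padded texture
canvas, so optical flow sees physical sheet motion, not just an edge.
Additive Gaussian noise (fraction of dynamic range) is applied last.
Truth masks are pixel-exact against the pre-noise dark band; the truth
record carries analytic widths, border positions and speeds. All
generators are reproducible from (config, seed), and the caller's RNG
state is left untouched.

`simulateDynamicBurst` synthesizes pixel series directly in the
frequency domain: complex Gaussian coefficients on the bins inside
`centerFreq ± bandwidth/2`, Hermitian symmetry, inverse FFT, per-pixel
normalization to unit variance, then amplitude scaling and baseline
offset. Zero bandwidth yields a pure tone at the nearest frequency bin
with a random phase. Bin-centred tones are deliberate: they make the
mean-frequency recovery checks exact up to one bin without involving
leakage, which a plain periodogram does not control.

**What the generator does not emulate** — and hence what passing tests
do not show about real data: interferometric speckle statistics and
phase noise, illumination drift and vignetting, cell-shape changes,
proliferation and individual cell motility within the sheet, the partial
advection of tissue away from the first row of cells, camera fixed-
pattern artefacts beyond the column-noise robustness check, and focus
drift. Recovery accuracies measured here are therefore upper bounds on
what identical settings achieve on instrument data.

# Study conditions and problem sizes

The cross-method consistency analyses use 256 px (0.5 µm/px) stacks of
60 frames, an initial width of 24 µm closing to the 1.5 µm limit exactly
at the final frame (frame interval scaled per speed), 5% noise, and
`FlowParams(blockAvg = 2)` so the per-pair displacement is ~0.76 px.
Choosing closure-at-end makes the segmentation speed definition
(Δwidth / time-to-limit), the optical-flow temporal mean, and the
configured truth refer to the same number — with exponential kinetics
the early-interval mean speed and the time-to-limit average would
differ by construction, not by error. Unit and property tests use 64–128
px images and bursts of 128–512 frames; the full suite runs in about
four minutes on one CPU.

# Known limitations

- Horn–Schunck underestimates speed as displacements approach a pixel
  per pair and under heavy noise; the block size must respect the
  envelope above. No coarse-to-fine extension is provided.
- Multi-level Otsu assumes the scratch is the darkest distinct class
  inside the calculation window; stacks whose wound brightness overlaps
  the interstices will segment poorly whatever the class count.
- The characteristic time is only meaningful for decaying width traces;
  for static or expanding wounds it is `NA` by design.
- Width statistics assume an approximately straight scratch; strongly
  curved wounds violate the rotate-to-vertical geometry.
- The rotation crop discards the image corners; geometry near the frame
  border is not measured.
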