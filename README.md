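# dynwound

Quantification of scratch-assay wound healing from dynamic full-field
optical coherence tomography (D-FFOCT) live-cell imaging, with a
ground-truthed synthetic data generator so the whole pipeline is testable
without instrument data.

D-FFOCT images a cell monolayer (here modelled on retinal pigment
epithelium, RPE) by recording bursts of interferometric frames at a fixed
plane; temporal fluctuations of the backscattered signal report
intracellular organelle motion. A scratch assay wounds the confluent
monolayer and the wound margins are imaged once per minute; the analysis
question is how fast, and how completely, the wound closes.

## What the package computes

**Dynamic profile rendering** (`computeDynamicImage`). Each pixel's burst
(512 frames at 100 Hz by default) is reduced to a periodogram; the
rendering maps

- Hue — power-weighted mean fluctuation frequency `f̄ = Σ f·P(f) / Σ P(f)`,
  laid on the blue (low) → red (high) arc;
- Saturation — inverse frequency bandwidth, `S = 1 − Δf / Δf₀` with `Δf`
  the power-weighted standard deviation of frequency;
- Value — the standard deviation of the signal over a 50-frame moving
  window, averaged over windows.

Static FFOCT amplitude from π-phase-shifted frame pairs
(`ffoctStatic`) and cross-correlation plane re-locking
(`bestPlaneByCrossCorrelation`) are included.

**Wound segmentation and kinetics** (`runSaveProfiler`). Multi-level Otsu
thresholding (first level = scratch), linear threshold interpolation
through the time-lapse, rotation of the stack so the user-drawn scratch
line is vertical, ROI masking, per-frame wound area and per-row width
statistics, wound closure

    closure(t) = (area(0) − area(t)) / area(0) × 100,

and a bi-exponential fit of the mean width,
`w(t) = limit + a·e^{bt} + c·e^{dt}` (limit ≈ 1.5 µm, the residual
inter-cell interstice), from which the characteristic closing time (1/e
decay of the fitted excess) and the average closing speed in µm/h are
derived.

**Optical flow** (`runOpticalFlow`). Median filtering, temporal block
averaging, Horn–Schunck dense flow on consecutive frames, per-pixel
temporal averaging, calibration to µm/h, and a front-resolved summary:
pixels below a 2 µm/h floor are excluded, the field is split at the wound
axis, and the total closure speed is twice the mean per-front speed.

**Synthetic data** (`simulateWoundTimelapse`, `simulateDynamicBurst`).
Textured epithelial sheets (Voronoi mosaic, PSF-band-limited, speckled)
with a dark scratch whose borders close, retract or expand with known
kinetics — the sheet advects with its front — and raw bursts whose pixel
series have configured centre frequency, bandwidth and amplitude. Every
stack carries exact analytic truth.

## Worked example

A 128 px (0.5 µm/px) simulated scratch, 24 µm wide, closing at
16 µm/h total under 5% noise, analysed by both methods:

```r
library(dynwound)

cfg <- WoundSimConfig(imageSize = 128L, pixelSize = 0.5, frameInterval = 1.43,
                      nFrames = 60L, initialWidth = 24, closingLimit = 1.5,
                      borderSpeeds = c(8, 8), textureSeed = 1L, noiseSigma = 0.05)
sim <- simulateWoundTimelapse(cfg)

line <- ScratchLine(c(5, 63.5), c(122, 63.5))
roi  <- RoiPolygon(rbind(c(4, 28), c(4, 99), c(123, 99), c(123, 28)))
res  <- runSaveProfiler(sim$stack, line, roi, pixelSize = 0.5, frameInterval = 1.43)
res$fit
#> ClosureFit: w(t) = 1.5 + -692 exp( 0 t ) + 714.5 exp( -0.000376 t )
#>   characteristic time: 53.66 min; average speed: 15.87 um/h (not closed)
#>   converged: TRUE ; residual RMS: 0.2858 um

head(traceTable(res$trace), 3)
#>   time_min area_px area_um2 width_min_um width_mean_um width_max_um closure_pct
#> 1     0.00    5769  1442.25         24.0      24.03750         25.0  0.00000000
#> 2     1.43    5774  1443.50         24.0      24.05833         25.0 -0.08667013
#> 3     2.86    5526  1381.50         22.5      23.02500         23.5  4.21216849

flow <- runOpticalFlow(sim$stack, 63.5, FlowParams(blockAvg = 2L),
                       pixelSize = 0.5, frameInterval = 1.43,
                       woundMask = trueMasks(sim$truth)[, , 1])
flow$summary
#> FlowSummary: per-front 7.597 / 7.479 um/h; total closure 15.08 um/h
```

The segmentation-based average closing speed (15.87 µm/h) and the
optical-flow total speed (15.08 µm/h = 2 × mean per-front speed) agree
with each other and with the simulated truth of 16 µm/h — the same
cross-method consistency the two analyses are designed to exhibit on real
acquisitions. The initial mean width (24.04 µm) matches the constructed
24 µm, and the fit's residual RMS (0.29 µm) reflects the segmentation
noise at 5% intensity noise.

## Command line

A thin CLI is installed as `exec/dynwound`:

```sh
dynwound simulate --preset small-close --seed 7 --out sim/
dynwound scratch  --input sim/stack.tif --geometry sim/geometry.json \
                  --config sim/config.yaml --out scratch/
dynwound flow     --input sim/stack.tif --axis-col 127.5 \
                  --config sim/config.yaml --out flow/
dynwound report   --scratch scratch/ --flow flow/ --out report/
```

`simulate` writes the stack (multi-page float TIFF), the analytic truth
(CSV + JSON), a geometry sidecar (0-based row/col convention) and a
matching YAML configuration; `report` merges the two speed estimates side
by side.

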