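## Shared fixtures: study stacks with known kinetics and small image
## builders. Everything is generated in code; nothing is read from disk.

## A closing-wound study stack: initial width 24 um closing to the 1.5 um
## limit exactly at the last frame, so the average-speed definition, the
## flow temporal mean and the nominal speed coincide.
studyStack <- function(vTotal, imageSize = 256L, nFrames = 60L,
                       noise = 0.05, seed = 1L, initialWidth = 24,
                       closingLimit = 1.5) {
  interval <- (initialWidth - closingLimit) / vTotal * 60 / (nFrames - 1)
  cfg <- WoundSimConfig(imageSize = imageSize, pixelSize = 0.5,
                        frameInterval = interval, nFrames = nFrames,
                        initialWidth = initialWidth,
                        closingLimit = closingLimit,
                        borderSpeeds = c(vTotal / 2, vTotal / 2),
                        kinetics = "speed", scenario = "close",
                        textureSeed = seed, noiseSigma = noise)
  sim <- simulateWoundTimelapse(cfg)
  sim$interval <- interval
  sim
}

## default analysis geometry for a studyStack (vertical scratch)
studyGeometry <- function(imageSize, halfRoiCols = 36) {
  c0 <- (imageSize - 1) / 2
  lo <- floor(c0 - halfRoiCols); hi <- ceiling(c0 + halfRoiCols)
  list(line = ScratchLine(c(5, c0), c(imageSize - 6, c0)),
       roi = RoiPolygon(rbind(c(4, lo), c(4, hi),
                              c(imageSize - 5, hi), c(imageSize - 5, lo))),
       axisCol = c0)
}

## SAVE-profiler speed on a study stack (default threshold classes)
profileStudy <- function(sim) {
  n <- sim$truth@config@imageSize
  g <- studyGeometry(n)
  runSaveProfiler(sim$stack, g$line, g$roi,
                  closingLimit = sim$truth@config@closingLimit,
                  pixelSize = sim$truth@config@pixelSize,
                  frameInterval = sim$interval)
}

## optical-flow total closure speed on a study stack; block averaging of
## 2 keeps the per-pair displacement ~0.76 px (sub-pixel envelope)
flowStudy <- function(sim) {
  n <- sim$truth@config@imageSize
  g <- studyGeometry(n)
  runOpticalFlow(sim$stack, g$axisCol, FlowParams(blockAvg = 2L),
                 pixelSize = sim$truth@config@pixelSize,
                 frameInterval = sim$interval,
                 woundMask = sim$truth@masks[, , 1L])
}

## band-limited random texture for flow tests (no wound)
flowTexture <- function(n, seed = 1L, pad = 8L) {
  makeCellTexture(n + 2L * pad, seed)
}

## sample a texture canvas at a (fractional) column shift, bilinear
shiftedFrame <- function(canvas, n, shift, pad = 8L) {
  rr <- rep(seq_len(n) - 1, times = n)
  cc <- rep(seq_len(n) - 1, each = n) - shift
  h <- nrow(canvas)
  r <- pmin(pmax(rr + pad, 0), h - 1); c_ <- pmin(pmax(cc + pad, 0), h - 1)
  r0 <- floor(r); c0 <- floor(c_)
  fr <- r - r0; fc <- c_ - c0
  r1 <- pmin(r0 + 1, h - 1); c1 <- pmin(c0 + 1, h - 1)
  v <- canvas[cbind(r0 + 1, c0 + 1)] * (1 - fr) * (1 - fc) +
    canvas[cbind(r1 + 1, c0 + 1)] * fr * (1 - fc) +
    canvas[cbind(r0 + 1, c1 + 1)] * (1 - fr) * fc +
    canvas[cbind(r1 + 1, c1 + 1)] * fr * fc
  matrix(v, n, n)
}

## brute-force O(T^2) discrete Fourier power oracle matching the
## package's documented normalization (positive bins sum to the
## population variance)
dftPowerOracle <- function(series, frameRate) {
  n <- length(series)
  x <- series - mean(series)
  half <- n %/% 2L
  freqs <- seq_len(half) * frameRate / n
  power <- vapply(seq_len(half), function(k) {
    re <- sum(x * cos(2 * pi * k * (0:(n - 1)) / n))
    im <- -sum(x * sin(2 * pi * k * (0:(n - 1)) / n))
    p <- 2 * (re^2 + im^2) / n^2
    if (n %% 2L == 0L && k == half) p / 2 else p
  }, numeric(1))
  list(frequencies = freqs, power = power)
}
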