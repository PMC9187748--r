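## dynamics: per-voxel power-spectrum features and the HSV dynamic profile.

#' Periodogram of a single pixel time series
#'
#' Removes the temporal mean, applies the discrete Fourier transform and
#' returns the power at the positive frequencies (DC excluded). The
#' normalization is chosen so that the positive-frequency powers sum to
#' the population variance of the mean-removed series (each bin carries
#' 2|X_k|^2/T^2, the Nyquist bin, when present, |X_k|^2/T^2).
#'
#' @param series numeric vector, length T >= 4, a pixel intensity trace.
#' @param frameRate sampling rate in Hz.
#' @return list with \code{frequencies} (Hz, spacing frameRate/T) and
#'   \code{power} (non-negative).
#' @examples
#' t <- seq(0, 5.11, by = 0.01)
#' ps <- pixelPowerSpectrum(sin(2 * pi * 10 * t), 100)
#' ps$frequencies[which.max(ps$power)]  # ~10 Hz
#' @export
pixelPowerSpectrum <- function(series, frameRate) {
  if (!is.numeric(series) || length(series) < 4L)
    invalidInput("series must be numeric with at least 4 samples")
  if (!all(is.finite(series))) invalidInput("series must be finite")
  if (frameRate <= 0) invalidParam("frameRate must be > 0")
  n <- length(series)
  x <- stats::fft(series - mean(series))
  half <- n %/% 2L
  k <- seq_len(half)
  pw <- 2 * Mod(x[k + 1L])^2 / n^2
  if (n %% 2L == 0L) pw[half] <- pw[half] / 2  # Nyquist counted once
  list(frequencies = k * frameRate / n, power = pw)
}

#' Power-weighted mean frequency
#'
#' @param frequencies,power as returned by \code{\link{pixelPowerSpectrum}}.
#' @return mean frequency in Hz; 0 with attribute \code{silent = TRUE}
#'   when the total power is zero.
#' @export
meanFrequency <- function(frequencies, power) {
  tot <- sum(power)
  if (tot <= 0) return(structure(0, silent = TRUE))
  structure(sum(frequencies * power) / tot, silent = FALSE)
}

#' Power-weighted frequency bandwidth
#'
#' The power-weighted standard deviation of frequency.
#'
#' @inheritParams meanFrequency
#' @return bandwidth in Hz; 0 with attribute \code{silent = TRUE} when the
#'   total power is zero.
#' @export
spectralBandwidth <- function(frequencies, power) {
  tot <- sum(power)
  if (tot <= 0) return(structure(0, silent = TRUE))
  mu <- sum(frequencies * power) / tot
  structure(sqrt(max(sum((frequencies - mu)^2 * power) / tot, 0)),
            silent = FALSE)
}

#' Averaged running standard deviation of a pixel series
#'
#' Population standard deviation over every contiguous stride-1 window of
#' the given length, averaged over windows. This is the value (intensity)
#' channel of the dynamic profile. Invariant under adding a constant.
#'
#' @param series numeric vector, length >= window.
#' @param window window length in frames (>= 2).
#' @return mean windowed standard deviation, intensity units.
#' @export
runningStdAmplitude <- function(series, window = 50L) {
  window <- as.integer(window)
  if (window < 2L) invalidParam("window must be >= 2")
  n <- length(series)
  if (n < window) invalidInput("series shorter than window")
  if (!all(is.finite(series))) invalidInput("series must be finite")
  cs <- c(0, cumsum(series))
  cs2 <- c(0, cumsum(series^2))
  i <- seq_len(n - window + 1L)
  m <- (cs[i + window] - cs[i]) / window
  v <- (cs2[i + window] - cs2[i]) / window - m^2
  mean(sqrt(pmax(v, 0)))
}

## Vectorized spectral features over all pixels of a burst.
burstSpectralFeatures <- function(burst) {
  stopifnot(is(burst, "RawBurst"))
  d <- dim(burst@frames)
  h <- d[1L]; w <- d[2L]; n <- d[3L]
  fs <- burst@params@frameRate
  ## pixels as columns of a T x (H*W) matrix
  m <- matrix(aperm(burst@frames, c(3L, 1L, 2L)), nrow = n)
  m <- sweep(m, 2L, colMeans(m))
  x <- stats::mvfft(m)
  half <- n %/% 2L
  pw <- 2 * Mod(x[1L + seq_len(half), , drop = FALSE])^2 / n^2
  if (n %% 2L == 0L) pw[half, ] <- pw[half, ] / 2
  freqs <- seq_len(half) * fs / n
  tot <- colSums(pw)
  silent <- tot <= 0
  tot[silent] <- 1
  mu <- colSums(freqs * pw) / tot
  bw <- sqrt(pmax(colSums(freqs^2 * pw) / tot - mu^2, 0))
  mu[silent] <- 0
  bw[silent] <- 0
  ## value channel: mean running std per pixel
  win <- burst@params@valueWindow
  cs <- apply(rbind(0, m), 2L, cumsum)
  cs2 <- apply(rbind(0, m^2), 2L, cumsum)
  i <- seq_len(n - win + 1L)
  mm <- (cs[i + win, , drop = FALSE] - cs[i, , drop = FALSE]) / win
  vv <- (cs2[i + win, , drop = FALSE] - cs2[i, , drop = FALSE]) / win - mm^2
  amp <- colMeans(sqrt(pmax(vv, 0)))
  new("SpectralFeatures",
      meanFreq = matrix(mu, h, w), bandwidth = matrix(bw, h, w),
      amplitude = matrix(amp, h, w), silent = matrix(silent, h, w))
}

#' Compute the dynamic-profile HSV image of a raw burst
#'
#' Per-pixel spectral features are mapped to HSV: hue is the mean
#' fluctuation frequency normalized into \code{hueFreqRange} and laid on
#' the blue-to-red arc (hue angle 240 degrees at \code{f_lo} descending to
#' 0 degrees at \code{f_hi}); saturation is \code{1 - bandwidth /
#' bandwidthScale}; value is the averaged running standard deviation
#' normalized by its \code{valueClipPercentile} percentile over the frame.
#' All channels are clamped to [0,1].
#'
#' @param burst a \linkS4class{RawBurst}.
#' @param hueFreqRange numeric length 2, (f_lo, f_hi) in Hz; default 0 to
#'   Nyquist.
#' @param bandwidthScale Hz; default frameRate/4.
#' @param valueClipPercentile percentile (0-100] for value normalization.
#' @return A \linkS4class{DynamicImage}.
#' @export
computeDynamicImage <- function(burst,
                                hueFreqRange = c(0, burst@params@frameRate / 2),
                                bandwidthScale = burst@params@frameRate / 4,
                                valueClipPercentile = 99.5) {
  if (!is(burst, "RawBurst")) invalidInput("burst must be a RawBurst")
  if (length(hueFreqRange) != 2L || hueFreqRange[2L] <= hueFreqRange[1L])
    invalidParam("hueFreqRange must satisfy f_hi > f_lo")
  if (bandwidthScale <= 0) invalidParam("bandwidthScale must be > 0")
  feats <- burstSpectralFeatures(burst)
  clamp01 <- function(x) pmin(pmax(x, 0), 1)
  hue <- clamp01((feats@meanFreq - hueFreqRange[1L]) / diff(hueFreqRange))
  sat <- clamp01(1 - feats@bandwidth / bandwidthScale)
  ref <- stats::quantile(feats@amplitude, valueClipPercentile / 100,
                         names = FALSE)
  val <- if (ref > 0) clamp01(feats@amplitude / ref)
         else feats@amplitude * 0
  rgb <- hsvToRgb(hue, sat, val)
  new("DynamicImage", hue = hue, saturation = sat, value = val, rgb = rgb,
      features = feats, hueFreqRange = as.numeric(hueFreqRange),
      bandwidthScale = bandwidthScale,
      valueClipPercentile = valueClipPercentile)
}

## normalized hue in [0,1] (0 = blue end) -> RGB via the 240->0 degree arc
hsvToRgb <- function(hue, sat, val) {
  h <- (2 / 3) * (1 - as.vector(hue))  # R hsv(): 2/3 = 240 deg = blue
  cols <- grDevices::hsv(h, as.vector(sat), as.vector(val))
  m <- grDevices::col2rgb(cols) / 255
  array(c(matrix(m[1L, ], nrow(hue)), matrix(m[2L, ], nrow(hue)),
          matrix(m[3L, ], nrow(hue))), dim = c(dim(hue), 3L))
}

#' Static FFOCT amplitude from a pi-phase-shifted pair
#'
#' The coherent part of the interference signal: half the absolute
#' difference of the two pi-shifted frames.
#'
#' @param iPlus,iMinus H x W intensity matrices.
#' @return H x W non-negative amplitude matrix.
#' @export
ffoctStatic <- function(iPlus, iMinus) {
  if (!identical(dim(iPlus), dim(iMinus)))
    invalidInput("iPlus and iMinus shapes differ")
  if (!all(is.finite(iPlus)) || !all(is.finite(iMinus)))
    invalidInput("inputs must be finite")
  abs(iPlus - iMinus) / 2
}

#' Select the z-plane best matching a reference image
#'
#' Zero-normalized cross-correlation (Pearson, zero lateral lag) between
#' each plane of an axial stack and the reference; used by the plane
#' lock-in stabilisation that rescans the sample axially to retrieve the
#' imaging plane. Ties break toward the lowest plane index.
#'
#' @param zstack H x W x K array of candidate planes.
#' @param reference H x W matrix.
#' @return integer plane index (1-based).
#' @export
bestPlaneByCrossCorrelation <- function(zstack, reference) {
  if (length(dim(zstack)) != 3L) invalidInput("zstack must be H x W x K")
  if (!identical(dim(zstack)[1:2], dim(reference)))
    invalidInput("reference shape must match zstack planes")
  r <- as.vector(reference)
  if (stats::sd(r) == 0) invalidInput("reference has zero variance")
  k <- dim(zstack)[3L]
  cc <- vapply(seq_len(k), function(i) {
    p <- as.vector(zstack[, , i])
    if (stats::sd(p) == 0) -Inf else stats::cor(p, r)
  }, numeric(1))
  which.max(cc)  # which.max returns the first (lowest) maximizer
}
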