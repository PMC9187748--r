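test_that("periodogram matches a brute-force DFT oracle and Parseval", {
  set.seed(42)
  x <- rnorm(64)
  ps <- pixelPowerSpectrum(x, frameRate = 100)
  oracle <- dftPowerOracle(x, 100)
  expect_equal(ps$frequencies, oracle$frequencies, tolerance = 1e-12)
  expect_equal(ps$power, oracle$power, tolerance = 1e-10)
  ## documented normalization: positive bins sum to the population
  ## variance of the mean-removed series
  expect_equal(sum(ps$power), mean((x - mean(x))^2), tolerance = 1e-8)
  ## grid spacing is frameRate / T
  expect_equal(diff(ps$frequencies)[1L], 100 / 64, tolerance = 1e-12)

  expect_error(pixelPowerSpectrum(c(1, 2, 3), 100),
               class = "dynwound_invalid_input")
  expect_error(pixelPowerSpectrum(c(1, NA, 3, 4), 100),
               class = "dynwound_invalid_input")
})

test_that("tone spectra give exact spectral summaries", {
  n <- 512L; fs <- 100
  bin <- fs / n
  tt <- 0:(n - 1L)
  ## constant series: no power anywhere
  psc <- pixelPowerSpectrum(rep(3, n), fs)
  expect_true(all(psc$power == 0))
  mf <- meanFrequency(psc$frequencies, psc$power)
  expect_identical(as.numeric(mf), 0)
  expect_true(attr(mf, "silent"))
  expect_true(attr(spectralBandwidth(psc$frequencies, psc$power), "silent"))

  ## bin-centred tone: all power in one bin, zero bandwidth
  f0 <- 51 * bin
  ps1 <- pixelPowerSpectrum(sin(2 * pi * f0 * tt / fs), fs)
  expect_gt(max(ps1$power) / sum(ps1$power), 0.999)
  expect_equal(as.numeric(meanFrequency(ps1$frequencies, ps1$power)), f0,
               tolerance = bin)
  expect_lt(as.numeric(spectralBandwidth(ps1$frequencies, ps1$power)), bin)

  ## off-bin 10 Hz tone: peak at the nearest bin, mean within one bin
  ps2 <- pixelPowerSpectrum(sin(2 * pi * 10 * tt / fs), fs)
  expect_equal(ps2$frequencies[which.max(ps2$power)], round(10 / bin) * bin,
               tolerance = 1e-9)
  expect_lt(abs(as.numeric(meanFrequency(ps2$frequencies, ps2$power)) - 10),
            bin)

  ## equal-power tones at 10 and 30 Hz: mean 20, bandwidth 10
  f1 <- round(10 / bin) * bin; f2 <- round(30 / bin) * bin
  s <- sin(2 * pi * f1 * tt / fs) + sin(2 * pi * f2 * tt / fs)
  ps3 <- pixelPowerSpectrum(s, fs)
  expect_equal(as.numeric(meanFrequency(ps3$frequencies, ps3$power)), 20,
               tolerance = bin)
  expect_equal(as.numeric(spectralBandwidth(ps3$frequencies, ps3$power)), 10,
               tolerance = bin)

  ## weighted-mean and weighted-std oracles on a noise spectrum
  set.seed(9); x <- rnorm(128)
  ps4 <- pixelPowerSpectrum(x, fs)
  mu <- sum(ps4$frequencies * ps4$power) / sum(ps4$power)
  expect_equal(as.numeric(meanFrequency(ps4$frequencies, ps4$power)), mu,
               tolerance = 1e-10)
  sd4 <- sqrt(sum((ps4$frequencies - mu)^2 * ps4$power) / sum(ps4$power))
  expect_equal(as.numeric(spectralBandwidth(ps4$frequencies, ps4$power)),
               sd4, tolerance = 1e-10)
})

test_that("running-std amplitude matches a naive windowed oracle", {
  expect_equal(runningStdAmplitude(rep(5, 100), 50), 0)
  expect_equal(runningStdAmplitude(rep(c(2, -2), 50), 50), 2)
  set.seed(7)
  x <- rnorm(200)
  naive <- mean(vapply(seq_len(151), function(i) {
    w <- x[i:(i + 49)]
    sqrt(mean((w - mean(w))^2))
  }, numeric(1)))
  expect_equal(runningStdAmplitude(x, 50), naive, tolerance = 1e-12)
  ## invariant under a constant offset
  expect_equal(runningStdAmplitude(x + 100, 50),
               runningStdAmplitude(x, 50), tolerance = 1e-9)
  expect_error(runningStdAmplitude(x, 1), class = "dynwound_invalid_parameter")
})

test_that("dynamic image maps spectral features onto HSV as documented", {
  ## two-region burst: 5 Hz left, 40 Hz right, equal amplitude
  h <- 10L; w <- 16L
  left <- matrix(FALSE, h, w); left[, 1:8] <- TRUE
  cfg <- BurstSimConfig(list(
    list(mask = left, centerFreq = 5, bandwidth = 0, amplitude = 1,
         baseline = 2),
    list(mask = !left, centerFreq = 40, bandwidth = 0, amplitude = 1,
         baseline = 2)), frameRate = 100, nFrames = 256L, seed = 2L)
  sim <- simulateDynamicBurst(cfg)
  dimg <- computeDynamicImage(sim$burst, hueFreqRange = c(0, 50))
  expect_lt(mean(hueChannel(dimg)[left]), mean(hueChannel(dimg)[!left]))
  expect_equal(mean(amplitudeMap(dimg)[left]),
               mean(amplitudeMap(dimg)[!left]), tolerance = 0.01)
  ## all channels in [0,1]
  for (ch in list(hueChannel(dimg), saturationChannel(dimg),
                  valueChannel(dimg), rgbArray(dimg))) {
    expect_true(all(ch >= 0 & ch <= 1))
  }
  ## hue is monotone in mean frequency by construction of the map
  expect_equal(hueChannel(dimg),
               pmin(pmax(meanFreqMap(dimg) / 50, 0), 1), tolerance = 1e-12)

  ## amplitude is linear: doubling the tone amplitude doubles the value
  cfg2 <- BurstSimConfig(list(
    list(mask = left, centerFreq = 10, bandwidth = 0, amplitude = 1,
         baseline = 2),
    list(mask = !left, centerFreq = 10, bandwidth = 0, amplitude = 2,
         baseline = 2)), frameRate = 100, nFrames = 256L, seed = 3L)
  dimg2 <- computeDynamicImage(simulateDynamicBurst(cfg2)$burst)
  expect_equal(mean(amplitudeMap(dimg2)[!left]) /
               mean(amplitudeMap(dimg2)[left]), 2, tolerance = 0.01)

  ## constant burst renders black
  dimgC <- computeDynamicImage(RawBurst(array(1, c(4, 4, 128))))
  expect_identical(max(valueChannel(dimgC)), 0)

  expect_error(computeDynamicImage(sim$burst, hueFreqRange = c(10, 10)),
               class = "dynwound_invalid_parameter")
})

test_that("static FFOCT is the absolute half-difference of a phase pair", {
  expect_equal(ffoctStatic(matrix(10, 3, 3), matrix(4, 3, 3)),
               matrix(3, 3, 3))
  m <- matrix(rnorm(9), 3, 3)
  expect_equal(ffoctStatic(m, m), matrix(0, 3, 3))
  ## constructed pi-shifted pair: B + A cos(phi) vs B - A cos(phi)
  set.seed(1)
  phi <- matrix(runif(25, 0, 2 * pi), 5, 5)
  A <- matrix(runif(25, 0.5, 2), 5, 5)
  expect_equal(ffoctStatic(7 + A * cos(phi), 7 - A * cos(phi)),
               abs(A * cos(phi)), tolerance = 1e-12)
  expect_error(ffoctStatic(matrix(0, 2, 2), matrix(0, 3, 3)),
               class = "dynwound_invalid_input")
})

test_that("plane matching maximizes zero-normalized cross-correlation", {
  set.seed(5)
  ref <- matrix(rnorm(400), 20, 20)
  z <- array(rnorm(400 * 5), c(20, 20, 5))
  z[, , 3] <- ref
  expect_identical(bestPlaneByCrossCorrelation(z, ref), 3L)
  expect_identical(bestPlaneByCrossCorrelation(array(ref, c(20, 20, 1)), ref),
                   1L)
  ## blurred copies: exhaustive correlation-scan oracle
  blur <- function(m, k) { for (i in seq_len(k)) m <- dynwound:::binomialSmooth(m); m }
  z2 <- array(0, c(20, 20, 6))
  for (k in 1:6) z2[, , k] <- blur(ref, k) + 0.05 * rnorm(400)
  oracle <- which.max(vapply(1:6, function(k)
    cor(as.vector(z2[, , k]), as.vector(ref)), numeric(1)))
  expect_identical(bestPlaneByCrossCorrelation(z2, ref), oracle)
  expect_error(bestPlaneByCrossCorrelation(z, matrix(1, 20, 20)),
               class = "dynwound_invalid_input")
})
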