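test_that("cell texture is seeded, bimodal and reproducible", {
  t1 <- makeCellTexture(64L, seed = 3L)
  t2 <- makeCellTexture(64L, seed = 3L)
  expect_identical(t1, t2)
  t3 <- makeCellTexture(64L, seed = 4L)
  expect_gt(mean(t1 != t3), 0.99)
  expect_true(all(t1 >= 0 & t1 <= 1))
  ## at least two modes (interstices vs cell bodies) in the smoothed
  ## intensity density
  d <- density(makeCellTexture(128L, seed = 1L), bw = 0.03)
  peaks <- sum(diff(sign(diff(d$y))) == -2)
  expect_gte(peaks, 2)
  expect_error(makeCellTexture(32L), class = "dynwound_invalid_parameter")
})

test_that("wound time-lapses carry exact analytic truth", {
  cfg <- WoundSimConfig(imageSize = 96L, pixelSize = 0.5, nFrames = 10L,
                        initialWidth = 18, borderSpeeds = c(6, 6),
                        frameInterval = 5, noiseSigma = 0, textureSeed = 8L)
  sim <- simulateWoundTimelapse(cfg)
  ## t = 0 width is the configured initial width, exactly
  expect_identical(trueWidthUm(sim$truth)[1L], 18)
  ## truth masks match the rendered dark band pixel-exactly (pre-noise:
  ## wound pixels are the constant fill value)
  for (t in c(1L, 5L, 10L)) {
    expect_identical(trueMasks(sim$truth)[, , t],
                     sim$stack[, , t] == 0.08)
  }
  ## reproducible from (config, seed)
  sim2 <- simulateWoundTimelapse(cfg)
  expect_identical(sim$stack, sim2$stack)

  ## expanding scenario: area strictly increasing
  cfgE <- WoundSimConfig(imageSize = 96L, pixelSize = 0.5, nFrames = 10L,
                         initialWidth = 12, borderSpeeds = c(5, 5),
                         scenario = "expand", frameInterval = 5,
                         noiseSigma = 0, textureSeed = 8L)
  simE <- simulateWoundTimelapse(cfgE)
  expect_true(all(diff(simE$truth@areaUm2) > 0))

  ## attempt-then-retract: width decreases, then increases after onset
  cfgR <- WoundSimConfig(imageSize = 96L, pixelSize = 0.5, nFrames = 20L,
                         initialWidth = 20, borderSpeeds = c(6, 6),
                         scenario = "attempt_then_retract",
                         retractOnset = 25, frameInterval = 5,
                         noiseSigma = 0, textureSeed = 8L)
  wR <- simulateWoundTimelapse(cfgR)$truth@widthUm
  expect_lt(wR[5L], wR[1L])
  expect_gt(wR[20L], wR[7L])

  expect_error(WoundSimConfig(scenario = "melt"),
               class = "dynwound_invalid_parameter")
})

test_that("exponential border kinetics reproduce a single-exponential width", {
  tau <- 30
  cfg <- WoundSimConfig(imageSize = 128L, pixelSize = 0.5, nFrames = 60L,
                        initialWidth = 20, closingLimit = 1.5,
                        borderSpeeds = c(1 / tau, 1 / tau),
                        kinetics = "rate", frameInterval = 1.5,
                        noiseSigma = 0, textureSeed = 4L)
  sim <- simulateWoundTimelapse(cfg)
  tt <- sim$truth@times
  expect_equal(trueWidthUm(sim$truth),
               1.5 + (20 - 1.5) * exp(-tt / tau), tolerance = 1e-12)
  ## the profiler recovers tau within 5% at sigma = 0
  g <- studyGeometry(128L)
  res <- runSaveProfiler(sim$stack, g$line, g$roi,
                         pixelSize = 0.5, frameInterval = 1.5)
  expect_equal(characteristicTime(res$fit), tau, tolerance = 0.05)
})

test_that("burst simulator round-trips through the dynamics pipeline", {
  mask <- matrix(TRUE, 8L, 8L)
  cfg <- BurstSimConfig(list(list(mask = mask, centerFreq = 10,
                                  bandwidth = 0, amplitude = 1,
                                  baseline = 2)),
                        frameRate = 100, nFrames = 256L, seed = 7L)
  sim <- simulateDynamicBurst(cfg)
  sim2 <- simulateDynamicBurst(cfg)
  expect_identical(frames(sim$burst), frames(sim2$burst))
  dimg <- computeDynamicImage(sim$burst)
  expect_lt(max(abs(meanFreqMap(dimg) - 10)), 100 / 256)

  ## a zero-amplitude region has a strictly zero value channel
  left <- matrix(FALSE, 8L, 8L); left[, 1:4] <- TRUE
  cfg2 <- BurstSimConfig(list(
    list(mask = left, centerFreq = 10, bandwidth = 0, amplitude = 0,
         baseline = 3),
    list(mask = !left, centerFreq = 10, bandwidth = 0, amplitude = 1,
         baseline = 3)), frameRate = 100, nFrames = 256L, seed = 7L)
  dimg2 <- computeDynamicImage(simulateDynamicBurst(cfg2)$burst)
  expect_identical(max(valueChannel(dimg2)[left]), 0)

  ## hue ordering follows frequency ordering (5 vs 40 Hz)
  cfg3 <- BurstSimConfig(list(
    list(mask = left, centerFreq = 5, bandwidth = 2, amplitude = 1,
         baseline = 3),
    list(mask = !left, centerFreq = 40, bandwidth = 2, amplitude = 1,
         baseline = 3)), frameRate = 100, nFrames = 256L, seed = 9L)
  dimg3 <- computeDynamicImage(simulateDynamicBurst(cfg3)$burst)
  expect_lt(max(hueChannel(dimg3)[left]), min(hueChannel(dimg3)[!left]))

  ## band edges must stay inside (0, Nyquist)
  expect_error(BurstSimConfig(list(list(mask = mask, centerFreq = 49,
                                        bandwidth = 10, amplitude = 1,
                                        baseline = 0))),
               class = "dynwound_invalid_parameter")
})

test_that("speed recovery is accurate at zero noise and degrades gracefully", {
  ## SAVE profiler within 10% across {4, 8, 16} um/h at sigma = 0
  for (v in c(4, 8, 16)) {
    sim <- studyStack(v, imageSize = 128L, nFrames = 60L, noise = 0,
                      seed = 20L)
    expect_lt(abs(averageSpeed(profileStudy(sim)$fit) - v) / v, 0.1)
  }
  ## flow within 20% up to sigma = 10%, degrading gracefully
  errs <- vapply(c(0, 0.05, 0.1), function(sg) {
    sim <- studyStack(16, imageSize = 128L, nFrames = 60L, noise = sg,
                      seed = 21L)
    abs(totalClosureSpeed(flowStudy(sim)$summary) - 16) / 16
  }, numeric(1))
  expect_true(all(errs < 0.2))
  expect_gt(errs[3L] + 0.05, errs[1L])  # graceful, not catastrophic
})
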