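test_that("multi-level Otsu first level matches an exhaustive oracle", {
  ## two well-separated values: threshold strictly between them
  img2 <- matrix(rep(c(0, 255), each = 50), 10, 10)
  t2 <- multithresholdFirstLevel(img2, nClasses = 2L)
  expect_gt(t2, 0); expect_lt(t2, 255)

  ## three populations: first threshold separates the lowest
  set.seed(21)
  img3 <- matrix(c(rnorm(200, 10, 1), rnorm(200, 100, 3),
                   rnorm(200, 200, 3)), 20, 30)
  t3 <- multithresholdFirstLevel(img3, nClasses = 3L)
  expect_gt(t3, 12); expect_lt(t3, 97)

  ## exhaustive double-loop oracle over the same 256-bin histogram
  vals <- as.vector(img3)
  nBins <- 256L
  edges <- seq(min(vals), max(vals), length.out = nBins + 1L)
  b <- pmin(pmax(findInterval(vals, edges, rightmost.closed = TRUE), 1L), nBins)
  h <- tabulate(b, nBins)
  centers <- (edges[-1L] + edges[-(nBins + 1L)]) / 2
  bcv <- function(i, j) { # classes (0,i], (i,j], (j,nBins]
    s <- 0
    for (rg in list(1:i, (i + 1L):j, (j + 1L):nBins)) {
      wgt <- sum(h[rg])
      if (wgt > 0) s <- s + sum(h[rg] * centers[rg])^2 / wgt
    }
    s
  }
  best <- c(-Inf, 0L, 0L)
  for (i in 1:(nBins - 2L)) for (j in (i + 1L):(nBins - 1L)) {
    v <- bcv(i, j)
    if (v > best[1L]) best <- c(v, i, j)
  }
  expect_equal(t3, edges[best[2L] + 1L], tolerance = 1e-12)

  expect_error(multithresholdFirstLevel(matrix(5, 4, 4), 2L),
               class = "dynwound_degenerate_input")
})

test_that("thresholds interpolate linearly through the stack", {
  expect_equal(interpolateThresholds(10, 20, 3), c(10, 15, 20))
  expect_equal(interpolateThresholds(7, 7, 5), rep(7, 5))
  expect_equal(interpolateThresholds(0, 1, 11), (0:10) / 10)
  expect_equal(interpolateThresholds(3, 9, 1), 3)
})

test_that("rotation makes the scratch vertical and preserves stripe area", {
  ## already-vertical line: identity
  set.seed(2)
  img <- matrix(runif(900), 30, 30)
  rotId <- rotateToVertical(img, ScratchLine(c(0, 10), c(29, 10)))
  expect_equal(rotId$angle, 0)
  expect_equal(rotId$stack[, , 1L], img)

  ## 45-degree stripe becomes vertical, area preserved within 2%
  n <- 101L
  diagImg <- matrix(0.8, n, n)
  idx <- which(abs(row(diagImg) - col(diagImg)) <= 4)
  diagImg[idx] <- 0.1
  rot <- rotateToVertical(diagImg, ScratchLine(c(0, 0), c(100, 100)))
  expect_equal(abs(rot$angle), 45, tolerance = 0.5)
  fr <- rot$stack[, , 1L]
  dark <- fr < 0.45
  widths <- rowSums(dark)
  inner <- widths[5:(nrow(fr) - 5L)]
  ## a |r-c| <= 4 band is 9 px wide along a row, 9/sqrt(2) perpendicular,
  ## hence ~6.4 px wide once vertical
  expect_true(all(inner %in% c(6, 7)))
  expect_equal(sum(dark), mean(inner) * nrow(fr), tolerance = 0.02 * sum(dark))

  ## horizontal line: 90-degree rotation, width/height swap
  rect <- matrix(runif(100 * 200), 100, 200)
  rot90 <- rotateToVertical(rect, ScratchLine(c(50, 10), c(50, 150)))
  expect_equal(abs(rot90$angle), 90)
  expect_equal(dim(rot90$stack)[1:2], c(199L, 98L))

  ## mapPoints sends line endpoints onto one column
  pts <- rot$mapPoints(rbind(c(20, 20), c(60, 60)))
  expect_equal(pts[1L, 2L], pts[2L, 2L], tolerance = 1e-6)
})

test_that("wound segmentation is the sub-threshold set inside the ROI", {
  n <- 40L
  frame <- matrix(0.9, n, n)
  frame[, 15:24] <- 0.05          # dark vertical band, cols 15..24
  roi <- RoiPolygon(rbind(c(4, 9), c(4, 30), c(35, 30), c(35, 9)))
  masks <- segmentWound(frame, thresholds = 0.5, roi = roi)
  expected <- matrix(FALSE, n, n)
  expected[5:36, 15:24] <- TRUE   # band (1-based cols 15..24) inside the ROI
  expect_identical(masks[, , 1L], expected)
  ## mask is always inside the ROI
  expect_true(all(!masks[, , 1L] | attr(masks, "roiMask")))

  ## frame entirely above threshold: empty mask
  expect_identical(sum(segmentWound(matrix(0.9, n, n), 0.5, roi)), 0L)

  ## dark pixels only outside the ROI: empty mask
  frame2 <- matrix(0.9, n, n); frame2[, 1:3] <- 0.05
  expect_identical(sum(segmentWound(frame2, 0.5, roi)), 0L)

  ## ROI with no pixels
  tiny <- RoiPolygon(rbind(c(-9, -9), c(-9, -8), c(-8, -8.5)))
  expect_error(segmentWound(frame, 0.5, tiny),
               class = "dynwound_invalid_input")
})

test_that("per-row width profiles count wound pixels", {
  m <- matrix(FALSE, 20, 40); m[, 11:20] <- TRUE
  wp <- widthProfile(m)
  expect_true(all(wp$widths == 10))
  expect_equal(c(wp$min, wp$mean, wp$max), c(10, 10, 10))

  expect_equal(widthProfile(matrix(FALSE, 5, 5))$mean, 0)

  ## trapezoid from 4 px (top) to 12 px (bottom)
  nr <- 9L
  tz <- matrix(FALSE, nr, 30)
  for (r in seq_len(nr)) tz[r, seq_len(4 + (r - 1))] <- TRUE
  wp2 <- widthProfile(tz)
  expect_equal(c(wp2$min, wp2$mean, wp2$max), c(4, 8, 12))
})

test_that("closure percentage rejects an empty initial wound", {
  expect_error(woundClosure(c(0, 10)), class = "dynwound_invalid_input")
})

test_that("bi-exponential fit flags static wounds and bounds residuals", {
  tt <- seq(0, 100, by = 2)
  fitC <- fitBiexponential(tt, rep(12, length(tt)), closingLimit = 1.5)
  expect_true(fitC@notClosed)
  expect_lt(abs(averageSpeed(fitC)), 0.05)

  ## residual RMS stays within 1.5x the injected noise
  set.seed(31)
  sigma <- 0.3
  w <- 1.5 + 14 * exp(-tt / 25) + rnorm(length(tt), sd = sigma)
  fitN <- fitBiexponential(tt, pmax(w, 0), closingLimit = 1.5)
  expect_lt(fitN@residualRms, 1.5 * sigma)
  expect_error(fitBiexponential(1:5, 1:5), class = "dynwound_invalid_input")
})

test_that("the profiler recovers simulated kinetics end to end", {
  ## closing at 12 um/h: speed within 10%
  sim <- studyStack(12, imageSize = 128L, nFrames = 60L, noise = 0.05,
                    seed = 2L)
  res <- profileStudy(sim)
  expect_lt(abs(averageSpeed(res$fit) - 12) / 12, 0.1)
  ## area equals the mask pixel count, and masks stay inside the ROI
  tr <- traceTable(res$trace)
  expect_equal(tr$area_px, apply(res$masks, 3L, sum))
  expect_true(all(!res$masks[, , 1L] | attr(res$masks, "roiMask")))

  ## closure is invariant under uniform intensity rescaling
  g <- studyGeometry(128L)
  res2 <- runSaveProfiler(sim$stack * 0.55, g$line, g$roi,
                          pixelSize = 0.5, frameInterval = sim$interval)
  expect_equal(traceTable(res2$trace)$closure_pct, tr$closure_pct,
               tolerance = 0.02)

  ## a static wound stays within +/- 5% closure
  cfgS <- WoundSimConfig(imageSize = 96L, pixelSize = 0.5, nFrames = 20L,
                         initialWidth = 16, borderSpeeds = c(0, 0),
                         frameInterval = 2, noiseSigma = 0.05,
                         textureSeed = 5L)
  simS <- simulateWoundTimelapse(cfgS)
  gS <- studyGeometry(96L, halfRoiCols = 28)
  resS <- runSaveProfiler(simS$stack, gS$line, gS$roi,
                          pixelSize = 0.5, frameInterval = 2)
  expect_lt(max(abs(traceTable(resS$trace)$closure_pct)), 5)

  ## an expanding wound gives negative, non-increasing closure
  cfgE <- WoundSimConfig(imageSize = 96L, pixelSize = 0.5, nFrames = 20L,
                         initialWidth = 12, borderSpeeds = c(6, 6),
                         scenario = "expand", frameInterval = 2,
                         noiseSigma = 0.03, textureSeed = 6L)
  simE <- simulateWoundTimelapse(cfgE)
  resE <- runSaveProfiler(simE$stack, gS$line, gS$roi,
                          pixelSize = 0.5, frameInterval = 2)
  cl <- traceTable(resE$trace)$closure_pct
  expect_lt(cl[length(cl)], -50)
  expect_true(all(diff(cl) < 2))  # monotone decrease up to noise
})
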