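## simulate: ground-truthed synthetic stacks and bursts.

## run expr with a fixed seed, restoring the caller's RNG state
withSeed <- function(seed, expr) {
  hasOld <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (hasOld) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (hasOld) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Seeded Voronoi cell texture
#'
#' A granular epithelial-sheet texture: a Voronoi mosaic with dark
#' inter-cell borders, per-cell brightness and multiplicative speckle.
#' Deterministic for a given seed; values in [0,1]. The histogram is
#' bimodal (dark borders vs bright cell bodies).
#'
#' @param size side length in pixels (>= 64).
#' @param seed integer seed.
#' @param nCells number of Voronoi cells.
#' @param borderWidth border thickness parameter in pixels.
#' @return size x size numeric matrix in [0,1].
#' @export
makeCellTexture <- function(size, seed = 1L, nCells = max(16L, round((size / 16)^2)),
                            borderWidth = 2.6) {
  size <- as.integer(size)
  if (size < 64L) invalidParam("size must be >= 64 px")
  withSeed(seed, {
    sr <- stats::runif(nCells, 0, size - 1)
    sc <- stats::runif(nCells, 0, size - 1)
    bright <- stats::runif(nCells, 0.55, 0.9)
    rr <- rep(seq_len(size) - 1, times = size)
    cc <- rep(seq_len(size) - 1, each = size)
    d1 <- rep(Inf, size^2); d2 <- rep(Inf, size^2); id1 <- integer(size^2)
    for (i in seq_len(nCells)) {
      di <- (rr - sr[i])^2 + (cc - sc[i])^2
      closer <- di < d1
      d2 <- ifelse(closer, d1, pmin(d2, di))
      id1[closer] <- i
      d1 <- pmin(d1, di)
    }
    border <- (sqrt(d2) - sqrt(d1)) < borderWidth
    tex <- bright[id1]
    ## inter-cell interstices are dimmer than cell bodies but well above
    ## the near-black scratch, as in dynamic-contrast images
    tex[border] <- 0.38
    tex <- matrix(tex, size, size)
    ## band-limit the mosaic by the optical transfer function: microscope
    ## images carry no energy at the pixel scale (three binomial passes
    ## ~ Gaussian PSF of sigma ~ 1 px)
    for (i in 1:3) tex <- binomialSmooth(tex)
    ## multiplicative organelle speckle, spatially correlated just above
    ## the PSF scale, as in dynamic-contrast imagery
    sp <- binomialSmooth(matrix(stats::rnorm(size^2), size, size))
    tex <- tex * (1 + 0.15 * sp)
    matrix(pmin(pmax(tex, 0), 1), size, size)
  })
}

## one pass of the separable binomial kernel (per-axis variance 1/3 px^2)
binomialSmooth <- function(m) {
  (shiftMat(m, -1L, 0L) + shiftMat(m, 1L, 0L) +
   shiftMat(m, 0L, -1L) + shiftMat(m, 0L, 1L) + 2 * m) / 6
}

## analytic per-border half-widths (um) at time t (minutes)
borderHalfWidths <- function(config, t) {
  w0 <- config@initialWidth
  lim <- config@closingLimit
  bs <- config@borderSpeeds
  half0 <- w0 / 2
  closeHalf <- function(tt) {
    if (config@kinetics == "speed") {
      cbind(pmax(half0 - bs[1L] * tt / 60, lim / 2),
            pmax(half0 - bs[2L] * tt / 60, lim / 2))
    } else {
      cbind(lim / 2 + (half0 - lim / 2) * exp(-bs[1L] * tt),
            lim / 2 + (half0 - lim / 2) * exp(-bs[2L] * tt))
    }
  }
  switch(config@scenario,
    close = closeHalf(t),
    expand = cbind(half0 + abs(bs[1L]) * t / 60,
                   half0 + abs(bs[2L]) * t / 60),
    attempt_then_retract = {
      on <- config@retractOnset
      pre <- closeHalf(pmin(t, on))
      post <- pmax(t - on, 0)
      ## linear retraction after onset at the border-speed magnitudes
      pre + cbind(abs(bs[1L]) * post / 60, abs(bs[2L]) * post / 60)
    })
}

#' Simulate a scratch-wound time-lapse with known ground truth
#'
#' Renders a textured epithelial sheet with a dark scratch whose two
#' borders move with the configured kinetics; the cell sheet on each side
#' advects with its border (cells migrate with the front). Gaussian noise
#' is added after rendering; the truth masks are pixel-exact against the
#' pre-noise dark band.
#'
#' @param config a \linkS4class{WoundSimConfig}.
#' @return list with \code{stack} (H x W x T array in [0,1]) and
#'   \code{truth} (a \linkS4class{SimTruth}).
#' @export
simulateWoundTimelapse <- function(config) {
  stopifnot(is(config, "WoundSimConfig"))
  validObject(config)
  n <- config@imageSize
  px <- config@pixelSize
  nT <- config@nFrames
  times <- (seq_len(nT) - 1L) * config@frameInterval
  halves <- borderHalfWidths(config, times)     # nT x 2, um
  widthUm <- rowSums(halves)
  c0 <- (n - 1) / 2
  r0 <- (n - 1) / 2
  theta <- config@woundAngle * pi / 180
  ## displacement of each sheet along the wound-normal axis, px
  dispL <- (halves[1L, 1L] - halves[, 1L]) / px
  dispR <- (halves[1L, 2L] - halves[, 2L]) / px
  pad <- ceiling(max(abs(c(dispL, dispR)), 1)) + 2L
  canvas <- makeCellTexture(n + 2L * pad, config@textureSeed)
  rr <- rep(seq_len(n) - 1, times = n)
  cc <- rep(seq_len(n) - 1, each = n)
  dAxis <- (cc - c0) * cos(theta) + (rr - r0) * sin(theta)
  eR <- sin(theta); eC <- cos(theta)   # unit wound-normal in (row, col)
  bilinearCanvas <- function(r, c_) {
    h <- nrow(canvas)
    r <- pmin(pmax(r, 0), h - 1); c_ <- pmin(pmax(c_, 0), h - 1)
    r0i <- floor(r); c0i <- floor(c_)
    fr <- r - r0i; fc <- c_ - c0i
    r1i <- pmin(r0i + 1, h - 1); c1i <- pmin(c0i + 1, h - 1)
    canvas[cbind(r0i + 1, c0i + 1)] * (1 - fr) * (1 - fc) +
      canvas[cbind(r1i + 1, c0i + 1)] * fr * (1 - fc) +
      canvas[cbind(r0i + 1, c1i + 1)] * (1 - fr) * fc +
      canvas[cbind(r1i + 1, c1i + 1)] * fr * fc
  }
  stack <- array(0, c(n, n, nT))
  masks <- array(FALSE, c(n, n, nT))
  borderCols <- cbind(c0 - halves[, 1L] / px, c0 + halves[, 2L] / px)
  woundVal <- 0.08
  noise <- withSeed(config@textureSeed + 1L,
                    array(stats::rnorm(n * n * nT), c(n, n, nT)))
  for (t in seq_len(nT)) {
    hL <- halves[t, 1L] / px; hR <- halves[t, 2L] / px
    wound <- dAxis >= -hL & dAxis <= hR
    leftSide <- dAxis < -hL
    shift <- ifelse(leftSide, dispL[t], -dispR[t])
    frame <- bilinearCanvas(rr + pad - shift * eR, cc + pad - shift * eC)
    frame[wound] <- woundVal
    masks[, , t] <- matrix(wound, n, n)
    frame <- frame + config@noiseSigma * as.vector(noise[, , t])
    stack[, , t] <- matrix(pmin(pmax(frame, 0), 1), n, n)
  }
  tSpan <- times[nT]
  nominal <- if (config@kinetics == "speed" && config@scenario != "attempt_then_retract")
    sum(abs(config@borderSpeeds)) else NA_real_
  truth <- new("SimTruth", masks = masks, widthUm = widthUm,
               areaUm2 = widthUm * n * px,
               borderCols = borderCols, nominalSpeed = nominal,
               meanObservedSpeed = (widthUm[1L] - widthUm[nT]) / tSpan * 60,
               times = times, config = config)
  list(stack = stack, truth = truth)
}

#' Named wound-simulation presets
#'
#' Presets mirroring the three observed scratch regimes: small wounds
#' (< 25 um) that close, medium wounds (25-100 um) that attempt to close
#' and then retract, and large wounds (> 100 um) that expand.
#'
#' @param preset "small-close", "medium-retract" or "large-expand".
#' @param seed texture/noise seed.
#' @return A \linkS4class{WoundSimConfig}.
#' @export
woundPreset <- function(preset = c("small-close", "medium-retract",
                                   "large-expand"), seed = 1L) {
  preset <- match.arg(preset)
  switch(preset,
    "small-close" = WoundSimConfig(imageSize = 256L, pixelSize = 0.5,
      nFrames = 75L, initialWidth = 20, borderSpeeds = c(8, 8),
      scenario = "close", textureSeed = seed),
    "medium-retract" = WoundSimConfig(imageSize = 256L, pixelSize = 0.5,
      nFrames = 90L, initialWidth = 40, borderSpeeds = c(7.5, 7.5),
      scenario = "attempt_then_retract", retractOnset = 30,
      textureSeed = seed),
    "large-expand" = WoundSimConfig(imageSize = 256L, pixelSize = 1.0,
      nFrames = 60L, initialWidth = 110, borderSpeeds = c(5, 5),
      scenario = "expand", textureSeed = seed))
}

#' Simulate a raw interferometric burst with controlled spectral content
#'
#' Each region's pixel time series is unit-variance Gaussian noise
#' band-limited to centerFreq +/- bandwidth/2 by spectral synthesis
#' (complex Gaussian coefficients on the in-band bins, Hermitian
#' symmetry), scaled by the region amplitude and offset by the baseline.
#' Zero bandwidth gives a pure tone of the nearest frequency bin with a
#' seeded random phase. Pixels are independent.
#'
#' @param config a \linkS4class{BurstSimConfig}.
#' @return list with \code{burst} (a \linkS4class{RawBurst}) and
#'   \code{truth} (list of per-region spectral parameters).
#' @export
simulateDynamicBurst <- function(config) {
  stopifnot(is(config, "BurstSimConfig"))
  validObject(config)
  n <- config@nFrames
  fs <- config@frameRate
  half <- n %/% 2L
  freqs <- seq_len(half) * fs / n
  d <- dim(config@regions[[1L]]$mask)
  stackMat <- matrix(0, n, prod(d))
  withSeed(config@seed, {
    for (rg in config@regions) {
      idx <- which(rg$mask)
      if (!length(idx)) next
      if (rg$amplitude <= 0) {
        stackMat[, idx] <- rg$baseline
        next
      }
      if (rg$bandwidth <= 0) {
        bins <- which.min(abs(freqs - rg$centerFreq))
      } else {
        bins <- which(freqs >= rg$centerFreq - rg$bandwidth / 2 - 1e-9 &
                      freqs <= rg$centerFreq + rg$bandwidth / 2 + 1e-9)
        if (!length(bins)) bins <- which.min(abs(freqs - rg$centerFreq))
      }
      npix <- length(idx)
      spec <- matrix(0 + 0i, n, npix)
      coefs <- matrix(complex(real = stats::rnorm(length(bins) * npix),
                              imaginary = stats::rnorm(length(bins) * npix)),
                      length(bins), npix)
      if (n %% 2L == 0L && half %in% bins)
        coefs[bins == half, ] <- complex(real = Re(coefs[bins == half, ]))
      spec[bins + 1L, ] <- coefs
      conjRows <- n - bins + 1L
      keepConj <- conjRows > half + 1L
      spec[conjRows[keepConj], ] <- Conj(coefs[keepConj, , drop = FALSE])
      x <- Re(stats::mvfft(spec, inverse = TRUE)) / n
      sdv <- sqrt(pmax(colMeans(x^2) - colMeans(x)^2, .Machine$double.eps))
      x <- sweep(sweep(x, 2L, colMeans(x)), 2L, sdv, "/")
      stackMat[, idx] <- x * rg$amplitude + rg$baseline
    }
  })
  frames <- aperm(array(stackMat, c(n, d[1L], d[2L])), c(2L, 3L, 1L))
  params <- AcquisitionParams(frameRate = fs, burstLength = n,
                              valueWindow = min(50L, n %/% 2L))
  truth <- lapply(config@regions, function(rg)
    rg[c("centerFreq", "bandwidth", "amplitude", "baseline")])
  list(burst = RawBurst(frames, params), truth = truth)
}
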