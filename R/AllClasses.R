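#' @import methods
NULL

## Conditions -----------------------------------------------------------------

## Classed errors so callers can distinguish bad data from bad parameters.
dwStop <- function(msg, class) {
  stop(structure(class = c(class, "dynwound_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

invalidInput   <- function(msg) dwStop(msg, "dynwound_invalid_input")
invalidParam   <- function(msg) dwStop(msg, "dynwound_invalid_parameter")
degenerateInput <- function(msg) dwStop(msg, "dynwound_degenerate_input")
formatError    <- function(msg) dwStop(msg, "dynwound_format_error")

## AcquisitionParams ----------------------------------------------------------

#' Acquisition parameters of a D-FFOCT experiment
#'
#' Physical calibration and timing of an acquisition: camera frame rate
#' during a burst, burst length, the moving-window length used for the
#' value (intensity) channel, the lateral pixel size and the time-lapse
#' frame interval. Defaults correspond to 512 frames recorded at 100 Hz,
#' a 50-frame window, a 320 um field of view on 1440 px (0.222 um/px) and
#' one dynamic image per minute.
#'
#' @slot frameRate numeric, burst sampling rate in Hz.
#' @slot burstLength integer, frames per burst.
#' @slot valueWindow integer, moving-window length (frames) for the value
#'   channel.
#' @slot pixelSize numeric, lateral calibration in micrometres per pixel.
#' @slot timelapseInterval numeric, minutes between successive dynamic
#'   images in a time-lapse.
#' @export
setClass("AcquisitionParams",
  representation(frameRate = "numeric", burstLength = "integer",
                 valueWindow = "integer", pixelSize = "numeric",
                 timelapseInterval = "numeric"),
  prototype(frameRate = 100, burstLength = 512L, valueWindow = 50L,
            pixelSize = 320 / 1440, timelapseInterval = 1))

setValidity("AcquisitionParams", function(object) {
  msg <- character()
  if (object@frameRate <= 0) msg <- c(msg, "frameRate must be > 0")
  if (object@pixelSize <= 0) msg <- c(msg, "pixelSize must be > 0")
  if (object@burstLength < 2L * object@valueWindow)
    msg <- c(msg, "burstLength must be >= 2 * valueWindow")
  if (object@timelapseInterval <= 0)
    msg <- c(msg, "timelapseInterval must be > 0")
  if (length(msg)) msg else TRUE
})

#' @param frameRate,burstLength,valueWindow,pixelSize,timelapseInterval see
#'   slot documentation.
#' @return An \code{AcquisitionParams} object.
#' @rdname AcquisitionParams-class
#' @export
AcquisitionParams <- function(frameRate = 100, burstLength = 512L,
                              valueWindow = 50L, pixelSize = 320 / 1440,
                              timelapseInterval = 1) {
  new("AcquisitionParams", frameRate = frameRate,
      burstLength = as.integer(burstLength),
      valueWindow = as.integer(valueWindow), pixelSize = pixelSize,
      timelapseInterval = timelapseInterval)
}

## RawBurst -------------------------------------------------------------------

#' A raw interferometric burst
#'
#' A stack of camera frames recorded at a fixed plane without phase
#' stepping, from which the dynamic profile is computed. Frames are stored
#' as an H x W x T array (image rows, image columns, time).
#'
#' @slot frames numeric array, H x W x T, non-negative intensities.
#' @slot params an \linkS4class{AcquisitionParams}.
#' @export
setClass("RawBurst",
  representation(frames = "array", params = "AcquisitionParams"))

setValidity("RawBurst", function(object) {
  d <- dim(object@frames)
  if (length(d) != 3L) return("frames must be an H x W x T array")
  if (d[3L] != object@params@burstLength)
    return("number of frames must equal params@burstLength")
  if (!all(is.finite(object@frames))) return("frames must be finite")
  TRUE
})

#' @param frames H x W x T numeric array.
#' @param params an \code{AcquisitionParams}.
#' @return A \code{RawBurst}.
#' @rdname RawBurst-class
#' @export
RawBurst <- function(frames, params = AcquisitionParams(burstLength = dim(frames)[3L])) {
  new("RawBurst", frames = frames, params = params)
}

## SpectralFeatures -----------------------------------------------------------

#' Per-pixel spectral features of a burst
#'
#' Power-weighted mean frequency, power-weighted frequency bandwidth
#' (standard deviation) and fluctuation amplitude of every pixel of a
#' burst. Pixels with zero fluctuation power carry zero mean frequency and
#' bandwidth and are flagged silent.
#'
#' @slot meanFreq H x W matrix, Hz.
#' @slot bandwidth H x W matrix, Hz.
#' @slot amplitude H x W matrix, intensity units.
#' @slot silent H x W logical matrix, TRUE where fluctuation power is zero.
#' @export
setClass("SpectralFeatures",
  representation(meanFreq = "matrix", bandwidth = "matrix",
                 amplitude = "matrix", silent = "matrix"))

setValidity("SpectralFeatures", function(object) {
  if (!identical(dim(object@meanFreq), dim(object@bandwidth)) ||
      !identical(dim(object@meanFreq), dim(object@amplitude)))
    return("feature maps must share one shape")
  if (any(object@bandwidth < 0) || any(object@amplitude < 0))
    return("bandwidth and amplitude must be non-negative")
  TRUE
})

## DynamicImage ---------------------------------------------------------------

#' The dynamic-profile HSV rendering of a burst
#'
#' Hue encodes the mean fluctuation frequency on the blue-to-red arc
#' (stored as the normalized position in [0,1]: 0 = blue = \code{f_lo},
#' 1 = red = \code{f_hi}), saturation the inverse frequency bandwidth, and
#' value the averaged running standard deviation of the signal.
#'
#' @slot hue,saturation,value H x W matrices in [0,1].
#' @slot rgb H x W x 3 array in [0,1], the HSV-to-RGB conversion with hue
#'   angle 240 degrees (blue) at hue 0 down to 0 degrees (red) at hue 1.
#' @slot features the underlying \linkS4class{SpectralFeatures}.
#' @slot hueFreqRange numeric length 2, (f_lo, f_hi) in Hz.
#' @slot bandwidthScale numeric, Hz; saturation = 1 - bandwidth / scale.
#' @slot valueClipPercentile numeric, percentile used to normalize the
#'   value channel.
#' @export
setClass("DynamicImage",
  representation(hue = "matrix", saturation = "matrix", value = "matrix",
                 rgb = "array", features = "SpectralFeatures",
                 hueFreqRange = "numeric", bandwidthScale = "numeric",
                 valueClipPercentile = "numeric"))

setValidity("DynamicImage", function(object) {
  chans <- list(object@hue, object@saturation, object@value)
  if (any(vapply(chans, function(m) any(m < 0 | m > 1), logical(1))))
    return("hue, saturation and value must lie in [0,1]")
  if (any(object@rgb < 0 | object@rgb > 1)) return("rgb must lie in [0,1]")
  if (length(object@hueFreqRange) != 2L ||
      diff(object@hueFreqRange) <= 0)
    return("hueFreqRange must be (f_lo, f_hi) with f_hi > f_lo")
  TRUE
})

## Geometry -------------------------------------------------------------------

#' A user-drawn line along the scratch
#'
#' Coordinates are 0-based (row, col) with the origin at the top-left
#' pixel centre.
#'
#' @slot p0,p1 numeric length 2, (row, col) endpoints.
#' @export
setClass("ScratchLine", representation(p0 = "numeric", p1 = "numeric"))

setValidity("ScratchLine", function(object) {
  if (length(object@p0) != 2L || length(object@p1) != 2L)
    return("p0 and p1 must be (row, col) pairs")
  if (all(object@p0 == object@p1)) return("p0 and p1 must differ")
  TRUE
})

#' @param p0,p1 (row, col) endpoints, 0-based.
#' @return A \code{ScratchLine}.
#' @rdname ScratchLine-class
#' @export
ScratchLine <- function(p0, p1) new("ScratchLine", p0 = as.numeric(p0),
                                    p1 = as.numeric(p1))

#' A region-of-interest polygon around the wound
#'
#' A simple polygon drawn on one reference frame (the first for closing
#' wounds, the last for expanding ones) and applied to every frame.
#'
#' @slot vertices n x 2 numeric matrix of (row, col) coordinates, 0-based.
#' @slot referenceFrame "first" or "last".
#' @export
setClass("RoiPolygon",
  representation(vertices = "matrix", referenceFrame = "character"),
  prototype(referenceFrame = "first"))

setValidity("RoiPolygon", function(object) {
  if (ncol(object@vertices) != 2L || nrow(object@vertices) < 3L)
    return("vertices must be an n x 2 matrix with n >= 3")
  if (!object@referenceFrame %in% c("first", "last"))
    return("referenceFrame must be 'first' or 'last'")
  if (selfIntersects(object@vertices))
    return("polygon must be simple (non-self-intersecting)")
  TRUE
})

#' @param vertices n x 2 matrix of (row, col) vertices.
#' @param referenceFrame "first" (closing wound) or "last" (expanding).
#' @return A \code{RoiPolygon}.
#' @rdname RoiPolygon-class
#' @export
RoiPolygon <- function(vertices, referenceFrame = "first")
  new("RoiPolygon", vertices = as.matrix(vertices),
      referenceFrame = referenceFrame)

## segment test for polygon simplicity (proper crossings only)
selfIntersects <- function(v) {
  n <- nrow(v)
  if (n < 4L) return(FALSE)
  seg <- cbind(v, v[c(2:n, 1L), , drop = FALSE])
  cross <- function(o, a, b)
    (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  for (i in seq_len(n - 2L)) {
    for (j in (i + 2L):n) {
      if (i == 1L && j == n) next
      p1 <- seg[i, 1:2]; p2 <- seg[i, 3:4]
      q1 <- seg[j, 1:2]; q2 <- seg[j, 3:4]
      d1 <- cross(q1, q2, p1); d2 <- cross(q1, q2, p2)
      d3 <- cross(p1, p2, q1); d4 <- cross(p1, p2, q2)
      if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
          ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
    }
  }
  FALSE
}

## WoundTrace -----------------------------------------------------------------

#' Per-frame wound area and width statistics
#'
#' One row per time-lapse frame: time in minutes, wound area in pixels and
#' square micrometres, minimum/mean/maximum scratch width (per-row pixel
#' counts over ROI rows) in micrometres, and wound-closure percentage.
#'
#' @slot trace data.frame with columns \code{time_min}, \code{area_px},
#'   \code{area_um2}, \code{width_min_um}, \code{width_mean_um},
#'   \code{width_max_um}, \code{closure_pct}.
#' @slot pixelSize micrometres per pixel used for the conversions.
#' @export
setClass("WoundTrace",
  representation(trace = "data.frame", pixelSize = "numeric"))

traceColumns <- c("time_min", "area_px", "area_um2", "width_min_um",
                  "width_mean_um", "width_max_um", "closure_pct")

setValidity("WoundTrace", function(object) {
  tr <- object@trace
  if (!identical(names(tr), traceColumns))
    return(paste("trace columns must be", paste(traceColumns, collapse = ",")))
  if (nrow(tr) == 0L) return(TRUE)
  if (any(tr$area_px < 0)) return("areas must be non-negative")
  if (any(tr$width_min_um > tr$width_mean_um + 1e-9) ||
      any(tr$width_mean_um > tr$width_max_um + 1e-9))
    return("width_min <= width_mean <= width_max violated")
  if (abs(tr$closure_pct[1L]) > 1e-9)
    return("closure_pct must be 0 at the first frame")
  TRUE
})

#' @param trace data.frame with the canonical columns.
#' @param pixelSize micrometres per pixel.
#' @return A \code{WoundTrace}.
#' @rdname WoundTrace-class
#' @export
WoundTrace <- function(trace, pixelSize)
  new("WoundTrace", trace = trace, pixelSize = pixelSize)

## ClosureFit -----------------------------------------------------------------

#' Bi-exponential wound-width kinetics
#'
#' Result of fitting w(t) = limit + a e^{bt} + c e^{dt} to the mean-width
#' trace. The characteristic time is the 1/e decay time of the fitted
#' excess width over its plateau; the average speed is the initial excess
#' over the limit divided by the time the fitted curve takes to reach the
#' limit (or, for wounds that do not close within the acquisition, the
#' fitted width change over the observed interval), converted to um/h.
#'
#' @slot a,c amplitudes, micrometres.
#' @slot b,d rates, 1/min.
#' @slot closingLimit residual interstice width, micrometres.
#' @slot characteristicTime minutes (NA when undefined).
#' @slot averageSpeed micrometres per hour.
#' @slot converged logical, FALSE when no start converged.
#' @slot notClosed logical, TRUE when the fitted curve does not reach the
#'   closing limit within the acquisition.
#' @slot residualRms micrometres.
#' @slot times,widths the fitted data (minutes, micrometres).
#' @export
setClass("ClosureFit",
  representation(a = "numeric", b = "numeric", c = "numeric", d = "numeric",
                 closingLimit = "numeric", characteristicTime = "numeric",
                 averageSpeed = "numeric", converged = "logical",
                 notClosed = "logical", residualRms = "numeric",
                 times = "numeric", widths = "numeric"))

setValidity("ClosureFit", function(object) {
  if (isTRUE(object@converged) && !is.na(object@characteristicTime) &&
      object@characteristicTime <= 0)
    return("characteristicTime must be > 0 when converged")
  TRUE
})

## Flow -----------------------------------------------------------------------

#' Optical-flow parameters
#'
#' @slot alpha Horn-Schunck smoothness weight, in the units of the image
#'   intensity gradient. The default 0.1 suits intensities normalized to
#'   [0,1]; it corresponds to the conventional weight of 1 used with
#'   8-bit (0-255) imagery.
#' @slot nIter fixed number of iterations.
#' @slot medianSize spatial median-filter size in pixels (odd).
#' @slot presmooth number of binomial smoothing passes applied to each
#'   frame after the median filter (each pass has per-axis variance
#'   1/3 px^2; the default 3 is a Gaussian presmoothing of sigma ~ 1 px,
#'   standard practice before differential flow estimation).
#' @slot blockAvg number of consecutive frames averaged into one before
#'   flow estimation; multiplies the effective frame interval.
#' @slot minVelocity display/summary floor in micrometres per hour.
#' @export
setClass("FlowParams",
  representation(alpha = "numeric", nIter = "integer", medianSize = "integer",
                 presmooth = "integer", blockAvg = "integer",
                 minVelocity = "numeric"),
  prototype(alpha = 0.1, nIter = 200L, medianSize = 3L, presmooth = 3L,
            blockAvg = 8L, minVelocity = 2.0))

setValidity("FlowParams", function(object) {
  msg <- character()
  if (object@alpha <= 0) msg <- c(msg, "alpha must be > 0")
  if (object@nIter < 1L) msg <- c(msg, "nIter must be >= 1")
  if (object@blockAvg < 1L) msg <- c(msg, "blockAvg must be >= 1")
  if (object@presmooth < 0L) msg <- c(msg, "presmooth must be >= 0")
  if (object@medianSize %% 2L == 0L) msg <- c(msg, "medianSize must be odd")
  if (length(msg)) msg else TRUE
})

#' @param alpha,nIter,medianSize,presmooth,blockAvg,minVelocity see slots.
#' @return A \code{FlowParams}.
#' @rdname FlowParams-class
#' @export
FlowParams <- function(alpha = 0.1, nIter = 200L, medianSize = 3L,
                       presmooth = 3L, blockAvg = 8L, minVelocity = 2.0)
  new("FlowParams", alpha = alpha, nIter = as.integer(nIter),
      medianSize = as.integer(medianSize), presmooth = as.integer(presmooth),
      blockAvg = as.integer(blockAvg), minVelocity = minVelocity)

#' A dense velocity field
#'
#' u is the column-direction (x) component, v the row-direction (y)
#' component; positive u points toward increasing column index, positive v
#' toward increasing row index. Units are px/frame straight out of
#' Horn-Schunck, or um/h after calibration.
#'
#' @slot u,v H x W matrices.
#' @slot unit "px/frame" or "um/h".
#' @export
setClass("FlowField",
  representation(u = "matrix", v = "matrix", unit = "character"),
  prototype(unit = "px/frame"))

setValidity("FlowField", function(object) {
  if (!identical(dim(object@u), dim(object@v))) return("u and v shapes differ")
  if (!all(is.finite(object@u)) || !all(is.finite(object@v)))
    return("flow components must be finite")
  if (!object@unit %in% c("px/frame", "um/h"))
    return("unit must be 'px/frame' or 'um/h'")
  TRUE
})

#' Front-resolved speed summary of a flow field
#'
#' @slot meanSpeed mean magnitude above the velocity floor, um/h.
#' @slot perFrontSpeed named numeric, left/right front mean speeds, um/h.
#' @slot totalClosureSpeed 2 x mean per-front speed, um/h.
#' @slot angleHistogram list with \code{counts} and \code{breaks}
#'   (radians), over pixels above the floor.
#' @slot allBelowFloor TRUE when every pixel fell below the velocity floor.
#' @export
setClass("FlowSummary",
  representation(meanSpeed = "numeric", perFrontSpeed = "numeric",
                 totalClosureSpeed = "numeric", angleHistogram = "list",
                 allBelowFloor = "logical"))

## Simulation configs ---------------------------------------------------------

#' Configuration of the scratch-wound time-lapse simulator
#'
#' A textured epithelial sheet with a dark scratch whose two borders move
#' with configurable kinetics. In "speed" mode each border advances at a
#' constant speed (um/h) until the width reaches the closing limit; in
#' "rate" mode each border's half-width excess over the limit decays
#' exponentially at the given rate (1/min), the per-border
#' exponential. Scenarios: "close", "attempt_then_retract" (close until
#' \code{retractOnset}, then linear expansion), "expand".
#'
#' @slot imageSize pixels (square frames).
#' @slot pixelSize micrometres per pixel.
#' @slot frameInterval minutes between frames.
#' @slot nFrames number of time-lapse frames.
#' @slot initialWidth micrometres.
#' @slot closingLimit micrometres, residual interstice width.
#' @slot borderSpeeds length 2, (left, right) border speeds in um/h
#'   ("speed" mode) or exponential rates in 1/min ("rate" mode).
#' @slot kinetics "speed" or "rate".
#' @slot scenario "close", "attempt_then_retract" or "expand".
#' @slot retractOnset minutes (attempt_then_retract only).
#' @slot textureSeed integer seed for texture and noise.
#' @slot noiseSigma additive Gaussian noise, fraction of dynamic range.
#' @slot woundAngle degrees; 0 = vertical scratch.
#' @export
setClass("WoundSimConfig",
  representation(imageSize = "integer", pixelSize = "numeric",
                 frameInterval = "numeric", nFrames = "integer",
                 initialWidth = "numeric", closingLimit = "numeric",
                 borderSpeeds = "numeric", kinetics = "character",
                 scenario = "character", retractOnset = "numeric",
                 textureSeed = "integer", noiseSigma = "numeric",
                 woundAngle = "numeric"))

setValidity("WoundSimConfig", function(object) {
  msg <- character()
  if (object@nFrames < 2L) msg <- c(msg, "nFrames must be >= 2")
  if (object@closingLimit < 0) msg <- c(msg, "closingLimit must be >= 0")
  if (object@initialWidth <= object@closingLimit)
    msg <- c(msg, "initialWidth must exceed closingLimit")
  if (!object@scenario %in% c("close", "attempt_then_retract", "expand"))
    msg <- c(msg, "unknown scenario")
  if (!object@kinetics %in% c("speed", "rate"))
    msg <- c(msg, "kinetics must be 'speed' or 'rate'")
  if (length(object@borderSpeeds) != 2L)
    msg <- c(msg, "borderSpeeds must be length 2 (left, right)")
  if (length(msg)) msg else TRUE
})

#' @param imageSize,pixelSize,frameInterval,nFrames,initialWidth,closingLimit
#'   see slots.
#' @param borderSpeeds,kinetics,scenario,retractOnset,textureSeed,noiseSigma,woundAngle
#'   see slots.
#' @return A \code{WoundSimConfig}.
#' @rdname WoundSimConfig-class
#' @export
WoundSimConfig <- function(imageSize = 256L, pixelSize = 0.5,
                           frameInterval = 1, nFrames = 60L,
                           initialWidth = 17.5, closingLimit = 1.5,
                           borderSpeeds = c(8, 8), kinetics = "speed",
                           scenario = "close", retractOnset = 30,
                           textureSeed = 1L, noiseSigma = 0.05,
                           woundAngle = 0) {
  if (!scenario %in% c("close", "attempt_then_retract", "expand"))
    invalidParam(sprintf("invalid scenario '%s'", scenario))
  new("WoundSimConfig", imageSize = as.integer(imageSize),
      pixelSize = pixelSize, frameInterval = frameInterval,
      nFrames = as.integer(nFrames), initialWidth = initialWidth,
      closingLimit = closingLimit, borderSpeeds = borderSpeeds,
      kinetics = kinetics, scenario = scenario, retractOnset = retractOnset,
      textureSeed = as.integer(textureSeed), noiseSigma = noiseSigma,
      woundAngle = woundAngle)
}

#' Configuration of the raw-burst simulator
#'
#' Each region is a list with elements \code{mask} (H x W logical),
#' \code{centerFreq} (Hz), \code{bandwidth} (Hz), \code{amplitude} and
#' \code{baseline}. Pixel time series are unit-variance Gaussian noise
#' band-limited to centerFreq +/- bandwidth/2 (a pure tone with seeded
#' random phase when bandwidth is 0), scaled by amplitude and offset by
#' baseline, independent across pixels.
#'
#' @slot regions list of region descriptors.
#' @slot frameRate Hz.
#' @slot nFrames frames per burst.
#' @slot seed integer seed.
#' @export
setClass("BurstSimConfig",
  representation(regions = "list", frameRate = "numeric",
                 nFrames = "integer", seed = "integer"))

setValidity("BurstSimConfig", function(object) {
  nyq <- object@frameRate / 2
  for (rg in object@regions) {
    need <- c("mask", "centerFreq", "bandwidth", "amplitude", "baseline")
    if (!all(need %in% names(rg))) return("region is missing fields")
    if (rg$centerFreq < 0 || rg$centerFreq > nyq)
      return("centerFreq must lie in [0, Nyquist]")
    if (rg$amplitude < 0) return("amplitude must be >= 0")
    lo <- rg$centerFreq - rg$bandwidth / 2
    hi <- rg$centerFreq + rg$bandwidth / 2
    if (rg$amplitude > 0 && (lo < 0 || hi > nyq))
      return("frequency band must lie inside (0, Nyquist)")
  }
  TRUE
})

#' @param regions,frameRate,nFrames,seed see slots.
#' @return A \code{BurstSimConfig}.
#' @rdname BurstSimConfig-class
#' @export
BurstSimConfig <- function(regions, frameRate = 100, nFrames = 512L,
                           seed = 1L) {
  obj <- try(new("BurstSimConfig", regions = regions, frameRate = frameRate,
                 nFrames = as.integer(nFrames), seed = as.integer(seed)),
             silent = TRUE)
  if (inherits(obj, "try-error"))
    invalidParam(attr(obj, "condition")$message)
  obj
}

#' Ground truth of a simulated stack
#'
#' @slot masks H x W x T logical array of true wound masks (pre-noise,
#'   pixel-exact).
#' @slot widthUm analytic true mean width per frame, micrometres.
#' @slot areaUm2 analytic wound area inside the full frame, um^2.
#' @slot borderCols T x 2 matrix of (left, right) border column positions
#'   in pixels (0-based, continuous).
#' @slot nominalSpeed configured total closing/expansion speed, um/h (NA
#'   for rate kinetics).
#' @slot meanObservedSpeed (w(0) - w(T)) / T in um/h over the acquisition.
#' @slot times minutes per frame.
#' @slot config the generating \linkS4class{WoundSimConfig}.
#' @export
setClass("SimTruth",
  representation(masks = "array", widthUm = "numeric", areaUm2 = "numeric",
                 borderCols = "matrix", nominalSpeed = "numeric",
                 meanObservedSpeed = "numeric", times = "numeric",
                 config = "WoundSimConfig"))
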