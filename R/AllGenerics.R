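## Accessor generics ----------------------------------------------------------

#' @title Accessors for dynwound objects
#' @description Slot accessors for the core data classes. Use these rather
#'   than \code{@} access.
#' @param object a dynwound S4 object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("frames", function(object) standardGeneric("frames"))
#' @rdname accessors
#' @export
setGeneric("acqParams", function(object) standardGeneric("acqParams"))
#' @rdname accessors
#' @export
setGeneric("hueChannel", function(object) standardGeneric("hueChannel"))
#' @rdname accessors
#' @export
setGeneric("saturationChannel",
           function(object) standardGeneric("saturationChannel"))
#' @rdname accessors
#' @export
setGeneric("valueChannel", function(object) standardGeneric("valueChannel"))
#' @rdname accessors
#' @export
setGeneric("rgbArray", function(object) standardGeneric("rgbArray"))
#' @rdname accessors
#' @export
setGeneric("meanFreqMap", function(object) standardGeneric("meanFreqMap"))
#' @rdname accessors
#' @export
setGeneric("bandwidthMap", function(object) standardGeneric("bandwidthMap"))
#' @rdname accessors
#' @export
setGeneric("amplitudeMap", function(object) standardGeneric("amplitudeMap"))
#' @rdname accessors
#' @export
setGeneric("silentMask", function(object) standardGeneric("silentMask"))
#' @rdname accessors
#' @export
setGeneric("traceTable", function(object) standardGeneric("traceTable"))
#' @rdname accessors
#' @export
setGeneric("flowU", function(object) standardGeneric("flowU"))
#' @rdname accessors
#' @export
setGeneric("flowV", function(object) standardGeneric("flowV"))
#' @rdname accessors
#' @export
setGeneric("flowMagnitude", function(object) standardGeneric("flowMagnitude"))
#' @rdname accessors
#' @export
setGeneric("flowAngle", function(object) standardGeneric("flowAngle"))
#' @rdname accessors
#' @export
setGeneric("characteristicTime",
           function(object) standardGeneric("characteristicTime"))
#' @rdname accessors
#' @export
setGeneric("averageSpeed", function(object) standardGeneric("averageSpeed"))
#' @rdname accessors
#' @export
setGeneric("totalClosureSpeed",
           function(object) standardGeneric("totalClosureSpeed"))
#' @rdname accessors
#' @export
setGeneric("perFrontSpeed", function(object) standardGeneric("perFrontSpeed"))
#' @rdname accessors
#' @export
setGeneric("trueMasks", function(object) standardGeneric("trueMasks"))
#' @rdname accessors
#' @export
setGeneric("trueWidthUm", function(object) standardGeneric("trueWidthUm"))

## Methods --------------------------------------------------------------------

#' @rdname accessors
setMethod("frames", "RawBurst", function(object) object@frames)
#' @rdname accessors
setMethod("acqParams", "RawBurst", function(object) object@params)
#' @rdname accessors
setMethod("hueChannel", "DynamicImage", function(object) object@hue)
#' @rdname accessors
setMethod("saturationChannel", "DynamicImage",
          function(object) object@saturation)
#' @rdname accessors
setMethod("valueChannel", "DynamicImage", function(object) object@value)
#' @rdname accessors
setMethod("rgbArray", "DynamicImage", function(object) object@rgb)
#' @rdname accessors
setMethod("meanFreqMap", "DynamicImage",
          function(object) object@features@meanFreq)
#' @rdname accessors
setMethod("bandwidthMap", "DynamicImage",
          function(object) object@features@bandwidth)
#' @rdname accessors
setMethod("amplitudeMap", "DynamicImage",
          function(object) object@features@amplitude)
#' @rdname accessors
setMethod("meanFreqMap", "SpectralFeatures", function(object) object@meanFreq)
#' @rdname accessors
setMethod("bandwidthMap", "SpectralFeatures", function(object) object@bandwidth)
#' @rdname accessors
setMethod("amplitudeMap", "SpectralFeatures", function(object) object@amplitude)
#' @rdname accessors
setMethod("silentMask", "SpectralFeatures", function(object) object@silent)
#' @rdname accessors
setMethod("traceTable", "WoundTrace", function(object) object@trace)
#' @rdname accessors
setMethod("flowU", "FlowField", function(object) object@u)
#' @rdname accessors
setMethod("flowV", "FlowField", function(object) object@v)
#' @rdname accessors
setMethod("flowMagnitude", "FlowField",
          function(object) sqrt(object@u^2 + object@v^2))
#' @rdname accessors
setMethod("flowAngle", "FlowField",
          function(object) atan2(object@v, object@u))
#' @rdname accessors
setMethod("characteristicTime", "ClosureFit",
          function(object) object@characteristicTime)
#' @rdname accessors
setMethod("averageSpeed", "ClosureFit", function(object) object@averageSpeed)
#' @rdname accessors
setMethod("totalClosureSpeed", "FlowSummary",
          function(object) object@totalClosureSpeed)
#' @rdname accessors
setMethod("perFrontSpeed", "FlowSummary", function(object) object@perFrontSpeed)
#' @rdname accessors
setMethod("trueMasks", "SimTruth", function(object) object@masks)
#' @rdname accessors
setMethod("trueWidthUm", "SimTruth", function(object) object@widthUm)

#' @param object a \code{ClosureFit}.
#' @describeIn ClosureFit-class fitted coefficients (a, b, c, d).
#' @export
setMethod("coef", "ClosureFit", function(object)
  c(a = object@a, b = object@b, c = object@c, d = object@d))

## show methods ---------------------------------------------------------------

setMethod("show", "AcquisitionParams", function(object) {
  cat("AcquisitionParams:", object@burstLength, "frames @",
      object@frameRate, "Hz; value window", object@valueWindow,
      "; pixel", signif(object@pixelSize, 4), "um; timelapse",
      object@timelapseInterval, "min/frame\n")
})

setMethod("show", "RawBurst", function(object) {
  d <- dim(object@frames)
  cat("RawBurst:", d[1], "x", d[2], "px,", d[3], "frames @",
      object@params@frameRate, "Hz\n")
})

setMethod("show", "DynamicImage", function(object) {
  d <- dim(object@hue)
  cat("DynamicImage:", d[1], "x", d[2], "px; hue maps",
      object@hueFreqRange[1], "-", object@hueFreqRange[2],
      "Hz onto blue->red\n")
})

setMethod("show", "WoundTrace", function(object) {
  tr <- object@trace
  cat("WoundTrace:", nrow(tr), "frames;")
  if (nrow(tr)) {
    cat(" mean width", round(tr$width_mean_um[1], 2), "->",
        round(tr$width_mean_um[nrow(tr)], 2), "um; final closure",
        round(tr$closure_pct[nrow(tr)], 1), "%")
  }
  cat("\n")
})

setMethod("show", "ClosureFit", function(object) {
  cat("ClosureFit: w(t) =", signif(object@closingLimit, 3), "+",
      signif(object@a, 4), "exp(", signif(object@b, 4), "t ) +",
      signif(object@c, 4), "exp(", signif(object@d, 4), "t )\n")
  cat("  characteristic time:", signif(object@characteristicTime, 4),
      "min; average speed:", signif(object@averageSpeed, 4), "um/h",
      if (object@notClosed) "(not closed)" else "", "\n")
  cat("  converged:", object@converged, "; residual RMS:",
      signif(object@residualRms, 4), "um\n")
})

setMethod("show", "FlowField", function(object) {
  d <- dim(object@u)
  cat("FlowField:", d[1], "x", d[2], "px in", object@unit,
      "; mean |v| =", signif(mean(sqrt(object@u^2 + object@v^2)), 4), "\n")
})

setMethod("show", "FlowSummary", function(object) {
  cat("FlowSummary: per-front",
      paste(signif(object@perFrontSpeed, 4), collapse = " / "),
      "um/h; total closure", signif(object@totalClosureSpeed, 4), "um/h\n")
  if (object@allBelowFloor) cat("  (all pixels below velocity floor)\n")
})

setMethod("show", "WoundSimConfig", function(object) {
  cat("WoundSimConfig:", object@imageSize, "px,", object@nFrames,
      "frames; scenario", object@scenario, "(", object@kinetics,
      "kinetics ); initial width", object@initialWidth, "um\n")
})

setMethod("show", "SimTruth", function(object) {
  cat("SimTruth:", length(object@times), "frames; width",
      round(object@widthUm[1], 2), "->",
      round(object@widthUm[length(object@widthUm)], 2), "um\n")
})
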