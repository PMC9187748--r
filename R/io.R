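## io: TIFF stacks, CSV traces, geometry sidecars, YAML config, PNG renders.

#' Read a multi-page grayscale TIFF as a stack
#'
#' Pages must be grayscale and share one shape. Physical calibration is
#' deliberately not taken from TIFF tags: it comes from the pipeline
#' configuration (instrument knowledge wins over file metadata).
#'
#' @param path TIFF file.
#' @return H x W x T numeric array.
#' @export
readStack <- function(path) {
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                    error = function(e) formatError(
                      paste("cannot read TIFF:", conditionMessage(e))))
  if (is.matrix(pages) || (is.array(pages) && length(dim(pages)) <= 3L &&
                           !is.list(pages)))
    pages <- list(pages)
  if (!length(pages)) formatError("TIFF contains no pages")
  for (p in pages) {
    if (!is.matrix(p)) formatError("TIFF pages must be grayscale")
    if (!identical(dim(p), dim(pages[[1L]])))
      formatError("TIFF pages have mixed shapes")
  }
  array(unlist(pages), c(dim(pages[[1L]]), length(pages)))
}

#' Write a stack as a multi-page TIFF
#'
#' @param stack H x W x T array with values in [0,1] (H x W matrices are
#'   accepted as single pages).
#' @param path output file.
#' @param bitDepth 16 (integer) or 32 (float).
#' @return the path, invisibly.
#' @export
writeStack <- function(stack, path, bitDepth = 32L) {
  if (is.matrix(stack)) stack <- array(stack, c(dim(stack), 1L))
  if (!bitDepth %in% c(16L, 32L)) invalidParam("bitDepth must be 16 or 32")
  pages <- lapply(seq_len(dim(stack)[3L]), function(t) stack[, , t])
  ok <- try(tiff::writeTIFF(pages, path, bits.per.sample = bitDepth),
            silent = TRUE)
  if (inherits(ok, "try-error"))
    dwStop(paste("cannot write TIFF:", path), "dynwound_io_error")
  invisible(path)
}

#' Export a wound trace as CSV
#'
#' Header is exactly \code{time_min,area_px,area_um2,width_min_um,
#' width_mean_um,width_max_um,closure_pct}, one row per frame, full float
#' precision.
#'
#' @param trace a \linkS4class{WoundTrace}.
#' @param path output file.
#' @return the path, invisibly.
#' @export
exportTrace <- function(trace, path) {
  if (!is(trace, "WoundTrace")) invalidInput("trace must be a WoundTrace")
  ok <- try(utils::write.csv(format(trace@trace, digits = 17, trim = TRUE,
                                    scientific = FALSE),
                             path, row.names = FALSE, quote = FALSE),
            silent = TRUE)
  if (inherits(ok, "try-error"))
    dwStop(paste("cannot write:", path), "dynwound_io_error")
  invisible(path)
}

#' Read a wound-trace CSV back
#'
#' @param path CSV written by \code{\link{exportTrace}}.
#' @param pixelSize micrometres per pixel to attach.
#' @return A \linkS4class{WoundTrace}.
#' @export
readTrace <- function(path, pixelSize = 320 / 1440) {
  df <- utils::read.csv(path)
  if (!identical(names(df), traceColumns))
    formatError("unexpected trace columns")
  WoundTrace(df, pixelSize)
}

## -- geometry sidecar --------------------------------------------------------

#' Write / read a scratch-line + ROI geometry sidecar (JSON)
#'
#' Coordinates are 0-based (row, col) with the origin at the top-left
#' pixel centre; the file states this convention in its \code{origin}
#' field.
#'
#' @param line a \linkS4class{ScratchLine}.
#' @param roi a \linkS4class{RoiPolygon}.
#' @param path JSON file.
#' @return \code{writeGeometry}: the path invisibly; \code{readGeometry}:
#'   list with \code{line} and \code{roi}.
#' @export
writeGeometry <- function(line, roi, path) {
  obj <- list(origin = "0-based (row, col), top-left pixel centre",
              line = list(p0 = line@p0, p1 = line@p1),
              roi = list(vertices = unname(apply(roi@vertices, 1L, c,
                                                 simplify = FALSE)),
                         reference_frame = roi@referenceFrame))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeGeometry
#' @export
readGeometry <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) formatError(
                    paste("cannot read geometry:", conditionMessage(e))))
  if (is.null(obj$line) || is.null(obj$roi))
    formatError("geometry file must contain 'line' and 'roi'")
  v <- obj$roi$vertices
  if (is.list(v)) v <- do.call(rbind, lapply(v, unlist))
  list(line = ScratchLine(obj$line$p0, obj$line$p1),
       roi = RoiPolygon(matrix(as.numeric(v), ncol = 2L),
                        obj$roi$reference_frame %||% "first"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## -- pipeline configuration --------------------------------------------------

configDefaults <- function() {
  list(
    acquisition = list(frame_rate = 100, burst_length = 512L,
                       value_window = 50L, pixel_size = 320 / 1440,
                       timelapse_interval = 1),
    rendering = list(hue_freq_lo = 0, hue_freq_hi = 50,
                     bandwidth_scale = 25, value_clip_percentile = 99.5),
    segmentation = list(n_classes = 3L, closing_limit = 1.5,
                        remove_small = FALSE, min_object_size = 16L),
    flow = list(alpha = 0.1, n_iter = 200L, median_size = 3L,
                presmooth = 3L, block_avg = 8L, min_velocity = 2.0),
    io = list(overwrite = FALSE),
    seed = 1L)
}

mergeConfig <- function(defaults, user, path = "") {
  for (key in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(defaults))
      invalidParam(paste("unknown configuration key:", full))
    if (is.list(defaults[[key]])) {
      if (!is.list(user[[key]]))
        invalidParam(paste("configuration key", full, "must be a section"))
      defaults[[key]] <- mergeConfig(defaults[[key]], user[[key]], full)
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

#' Read, validate and resolve a pipeline configuration (YAML)
#'
#' Unknown keys are rejected with a clear error. Returns the merged
#' key-value list plus resolved parameter objects
#' (\code{$acquisitionParams}, \code{$flowParams}).
#'
#' @param path YAML file, or NULL for the defaults.
#' @return named list.
#' @export
readPipelineConfig <- function(path = NULL) {
  cfg <- configDefaults()
  if (!is.null(path)) {
    user <- tryCatch(yaml::read_yaml(path),
                     error = function(e) formatError(
                       paste("cannot read config:", conditionMessage(e))))
    if (!is.null(user)) cfg <- mergeConfig(cfg, user)
  }
  cfg$acquisitionParams <- AcquisitionParams(
    frameRate = cfg$acquisition$frame_rate,
    burstLength = cfg$acquisition$burst_length,
    valueWindow = cfg$acquisition$value_window,
    pixelSize = cfg$acquisition$pixel_size,
    timelapseInterval = cfg$acquisition$timelapse_interval)
  cfg$flowParams <- FlowParams(
    alpha = cfg$flow$alpha, nIter = cfg$flow$n_iter,
    medianSize = cfg$flow$median_size, presmooth = cfg$flow$presmooth,
    blockAvg = cfg$flow$block_avg, minVelocity = cfg$flow$min_velocity)
  cfg
}

#' Write a pipeline configuration to YAML
#'
#' @param config list as returned by \code{\link{readPipelineConfig}}
#'   (resolved parameter objects are stripped).
#' @param path output YAML file.
#' @return the path, invisibly.
#' @export
writePipelineConfig <- function(config, path) {
  config$acquisitionParams <- NULL
  config$flowParams <- NULL
  yaml::write_yaml(config, path)
  invisible(path)
}

## -- renders -----------------------------------------------------------------

#' Write the dynamic image as an RGB PNG
#'
#' @param dimg a \linkS4class{DynamicImage}.
#' @param path output PNG.
#' @return the path, invisibly.
#' @export
writeDynamicPng <- function(dimg, path) {
  png::writePNG(dimg@rgb, path)
  invisible(path)
}

#' Write the per-channel feature maps as float TIFFs
#'
#' Writes mean_freq.tif, bandwidth.tif and amplitude.tif (32-bit float)
#' into a directory. Frequency maps are stored in Hz normalized by the
#' Nyquist frequency implied by the hue range upper bound so that values
#' stay in [0,1] for TIFF storage; the normalization constant is recorded
#' in \code{channels.json} alongside.
#'
#' @param dimg a \linkS4class{DynamicImage}.
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
writeChannelTiffs <- function(dimg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fHi <- dimg@hueFreqRange[2L]
  ampRef <- max(dimg@features@amplitude, 1e-12)
  writeStack(pmin(dimg@features@meanFreq / fHi, 1),
             file.path(dir, "mean_freq.tif"))
  writeStack(pmin(dimg@features@bandwidth / fHi, 1),
             file.path(dir, "bandwidth.tif"))
  writeStack(dimg@features@amplitude / ampRef,
             file.path(dir, "amplitude.tif"))
  jsonlite::write_json(list(frequency_scale_hz = fHi,
                            amplitude_scale = ampRef),
                       file.path(dir, "channels.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Write a hue colorbar legend
#'
#' A blue-to-red gradient strip written as PNG, with the frequency limits
#' recorded in a JSON sidecar of the same basename (no text is rendered
#' into the image).
#'
#' @param hueFreqRange numeric length 2, (f_lo, f_hi) in Hz.
#' @param path output PNG path.
#' @param width,height strip size in pixels.
#' @return the path, invisibly.
#' @export
writeColorbarLegend <- function(hueFreqRange, path, width = 256L,
                                height = 24L) {
  hue <- matrix(rep(seq(0, 1, length.out = width), each = height),
                height, width)
  strip <- hsvToRgb(hue, matrix(1, height, width), matrix(1, height, width))
  png::writePNG(strip, path)
  jsonlite::write_json(list(f_lo_hz = hueFreqRange[1L],
                            f_hi_hz = hueFreqRange[2L],
                            orientation = "left = f_lo (blue), right = f_hi (red)"),
                       paste0(sub("\\.[^.]+$", "", path), ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
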