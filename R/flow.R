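## flow: Horn-Schunck optical flow and front-speed summaries.

shiftMat <- function(m, dr, dc) {
  h <- nrow(m); w <- ncol(m)
  ri <- pmin(pmax(seq_len(h) + dr, 1L), h)
  ci <- pmin(pmax(seq_len(w) + dc, 1L), w)
  m[ri, ci, drop = FALSE]
}

#' Spatial median filter
#'
#' 3 x 3 median via an exact sorting network (the default); other odd
#' sizes use a direct neighbourhood sort. Edges are replicated.
#'
#' @param frame numeric matrix.
#' @param size odd window size in pixels.
#' @return filtered matrix, same shape.
#' @export
medianFilter2D <- function(frame, size = 3L) {
  size <- as.integer(size)
  if (size %% 2L == 0L || size < 1L) invalidParam("size must be odd, >= 1")
  if (size == 1L) return(frame)
  offs <- seq_len(size) - (size + 1L) %/% 2L
  if (size == 3L) {
    p <- list()
    k <- 0L
    for (dc in offs) for (dr in offs) {
      k <- k + 1L
      p[[k]] <- shiftMat(frame, dr, dc)
    }
    sw <- function(i, j) {
      lo <- pmin(p[[i]], p[[j]]); hi <- pmax(p[[i]], p[[j]])
      p[[i]] <<- lo; p[[j]] <<- hi
    }
    ## Paeth's 19-exchange median-of-9 network
    sw(2,3); sw(5,6); sw(8,9); sw(1,2); sw(4,5); sw(7,8); sw(2,3); sw(5,6)
    sw(8,9); sw(1,4); sw(6,9); sw(5,8); sw(4,7); sw(2,5); sw(3,6); sw(5,8)
    sw(3,5); sw(7,5); sw(3,5)
    return(p[[5]])
  }
  shifted <- array(NA_real_, c(dim(frame), size^2))
  k <- 0L
  for (dc in offs) for (dr in offs) {
    k <- k + 1L
    shifted[, , k] <- shiftMat(frame, dr, dc)
  }
  apply(shifted, c(1L, 2L), stats::median)
}

#' Preprocess a time-lapse for optical flow
#'
#' Applies a per-frame median filter (removing e.g. camera line noise)
#' and a light Gaussian presmoothing (binomial passes; see
#' \linkS4class{FlowParams}), then averages non-overlapping blocks of
#' \code{blockAvg} consecutive frames; a trailing partial block is
#' dropped. The effective frame interval of the output is multiplied by
#' \code{blockAvg}.
#'
#' @param stack H x W x T intensity array.
#' @param params a \linkS4class{FlowParams}.
#' @return H x W x floor(T / blockAvg) array.
#' @export
preprocessForFlow <- function(stack, params = FlowParams()) {
  d <- dim(stack)
  if (length(d) != 3L) invalidInput("stack must be H x W x T")
  b <- params@blockAvg
  if (d[3L] < 2L * b)
    invalidInput("need at least 2 * blockAvg frames")
  filtered <- stack
  for (t in seq_len(d[3L])) {
    f <- stack[, , t]
    if (params@medianSize > 1L) f <- medianFilter2D(f, params@medianSize)
    if (params@presmooth > 0L)
      for (i in seq_len(params@presmooth)) f <- binomialSmooth(f)
    filtered[, , t] <- f
  }
  nb <- d[3L] %/% b
  out <- array(0, c(d[1L], d[2L], nb))
  for (i in seq_len(nb)) {
    idx <- ((i - 1L) * b + 1L):(i * b)
    out[, , i] <- apply(filtered[, , idx, drop = FALSE], c(1L, 2L), mean)
  }
  out
}

hsNeighbourMean <- function(m) {
  (shiftMat(m, -1L, 0L) + shiftMat(m, 1L, 0L) +
   shiftMat(m, 0L, -1L) + shiftMat(m, 0L, 1L)) / 6 +
  (shiftMat(m, -1L, -1L) + shiftMat(m, -1L, 1L) +
   shiftMat(m, 1L, -1L) + shiftMat(m, 1L, 1L)) / 12
}

#' Horn-Schunck optical flow between two frames
#'
#' The classic global variational method: brightness constancy plus a
#' smoothness penalty, solved by fixed-point iteration
#' u <- ubar - Ex (Ex ubar + Ey vbar + Et) / (alpha^2 + Ex^2 + Ey^2)
#' (and symmetrically for v) from zero initialization, with the original
#' forward-difference cube estimators for Ex, Ey, Et and the standard
#' 6/12-weighted 8-neighbour average. u is the column (x) component, v
#' the row (y) component, in px/frame.
#'
#' @param frameA,frameB H x W matrices.
#' @param params a \linkS4class{FlowParams} (alpha, nIter).
#' @return A \linkS4class{FlowField} in px/frame; attribute
#'   \code{meanUpdate} reports the mean update norm at the last iteration.
#' @export
hornSchunck <- function(frameA, frameB, params = FlowParams()) {
  if (!identical(dim(frameA), dim(frameB)))
    invalidInput("frames must share one shape")
  if (!all(is.finite(frameA)) || !all(is.finite(frameB)))
    invalidInput("frames must be finite")
  sE <- function(m) shiftMat(m, 0L, 1L)   # col + 1
  sS <- function(m) shiftMat(m, 1L, 0L)   # row + 1
  sSE <- function(m) shiftMat(m, 1L, 1L)
  Ex <- (sE(frameA) - frameA + sSE(frameA) - sS(frameA) +
         sE(frameB) - frameB + sSE(frameB) - sS(frameB)) / 4
  Ey <- (sS(frameA) - frameA + sSE(frameA) - sE(frameA) +
         sS(frameB) - frameB + sSE(frameB) - sE(frameB)) / 4
  Et <- (frameB - frameA + sS(frameB) - sS(frameA) +
         sE(frameB) - sE(frameA) + sSE(frameB) - sSE(frameA)) / 4
  den <- params@alpha^2 + Ex^2 + Ey^2
  u <- v <- matrix(0, nrow(frameA), ncol(frameA))
  upd <- NA_real_
  for (it in seq_len(params@nIter)) {
    ub <- hsNeighbourMean(u); vb <- hsNeighbourMean(v)
    num <- (Ex * ub + Ey * vb + Et) / den
    un <- ub - Ex * num
    vn <- vb - Ey * num
    if (it == params@nIter)
      upd <- mean(sqrt((un - u)^2 + (vn - v)^2))
    u <- un; v <- vn
  }
  structure(new("FlowField", u = u, v = v, unit = "px/frame"),
            meanUpdate = upd)
}

#' Mean velocity field of a time-lapse in micrometres per hour
#'
#' Runs Horn-Schunck on every consecutive pair of the (preprocessed)
#' stack, averages the components per pixel over time, and converts
#' px/frame to um/h with pixelSize x 60 / (frameInterval x blockAvg),
#' where frameInterval is the original (pre-block-averaging) interval.
#'
#' @param stack preprocessed H x W x T array (T >= 2).
#' @param params a \linkS4class{FlowParams}.
#' @param pixelSize micrometres per pixel.
#' @param frameInterval original frame interval, minutes.
#' @return A \linkS4class{FlowField} in um/h.
#' @export
accumulateFlow <- function(stack, params = FlowParams(),
                           pixelSize = 320 / 1440, frameInterval = 1) {
  d <- dim(stack)
  if (length(d) != 3L || d[3L] < 2L)
    invalidInput("need >= 2 preprocessed frames")
  u <- v <- matrix(0, d[1L], d[2L])
  for (t in seq_len(d[3L] - 1L)) {
    f <- hornSchunck(stack[, , t], stack[, , t + 1L], params)
    u <- u + f@u; v <- v + f@v
  }
  npairs <- d[3L] - 1L
  scale <- pixelSize * 60 / (frameInterval * params@blockAvg)
  new("FlowField", u = u / npairs * scale, v = v / npairs * scale,
      unit = "um/h")
}

#' Front-resolved speed summary of a velocity field
#'
#' Pixels below the minimum-velocity floor are excluded, as are pixels
#' inside the wound mask when one is given and the pixels of the axis
#' column itself. The remaining pixels are split into the left and right
#' fronts by the wound axis column; the total closure speed is twice the
#' mean of the per-front mean speeds (two opposite moving fronts).
#'
#' @param field a \linkS4class{FlowField} in um/h.
#' @param woundAxisCol column of the wound axis, 0-based.
#' @param params a \linkS4class{FlowParams} (minVelocity).
#' @param woundMask optional H x W logical mask of wound pixels to
#'   exclude.
#' @return A \linkS4class{FlowSummary}.
#' @export
summarizeFronts <- function(field, woundAxisCol, params = FlowParams(),
                            woundMask = NULL) {
  if (field@unit != "um/h") invalidInput("field must be calibrated in um/h")
  mag <- flowMagnitude(field)
  ang <- flowAngle(field)
  include <- mag >= params@minVelocity
  if (!is.null(woundMask)) include <- include & !woundMask
  cols0 <- matrix(rep(seq_len(ncol(mag)) - 1L, each = nrow(mag)),
                  nrow(mag), ncol(mag))
  leftPx <- include & cols0 < woundAxisCol
  rightPx <- include & cols0 > woundAxisCol
  if (!any(include)) {
    return(new("FlowSummary", meanSpeed = 0,
               perFrontSpeed = c(left = 0, right = 0),
               totalClosureSpeed = 0,
               angleHistogram = list(counts = integer(16L),
                                     breaks = seq(-pi, pi, length.out = 17L)),
               allBelowFloor = TRUE))
  }
  frontMean <- function(sel) if (any(sel)) mean(mag[sel]) else NA_real_
  pf <- c(left = frontMean(leftPx), right = frontMean(rightPx))
  total <- 2 * mean(pf, na.rm = TRUE)
  breaks <- seq(-pi, pi, length.out = 17L)
  counts <- tabulate(findInterval(ang[include], breaks,
                                  rightmost.closed = TRUE), 16L)
  new("FlowSummary", meanSpeed = mean(mag[include]), perFrontSpeed = pf,
      totalClosureSpeed = total,
      angleHistogram = list(counts = counts, breaks = breaks),
      allBelowFloor = FALSE)
}

#' Decimated arrow (quiver) representation of a flow field
#'
#' One arrow per decimation block, placed at the block centre, with
#' direction (u, v) and length proportional to the speed; arrows below
#' the minimum velocity are dropped.
#'
#' @param field a \linkS4class{FlowField}.
#' @param decimation grid step in pixels (>= 1).
#' @param minVelocity magnitude floor (same unit as the field).
#' @param scale length per unit speed (arrow length = scale x speed).
#' @return data.frame with columns row, col (0-based origins), u, v,
#'   speed, length; attribute \code{scale} records the factor.
#' @export
exportArrowField <- function(field, decimation = 8L, minVelocity = 0,
                             scale = 1) {
  decimation <- as.integer(decimation)
  if (decimation < 1L) invalidParam("decimation must be >= 1")
  h <- nrow(field@u); w <- ncol(field@u)
  rows <- seq.int(1L + decimation %/% 2L, h, by = decimation)
  cols <- seq.int(1L + decimation %/% 2L, w, by = decimation)
  idx <- expand.grid(row = rows, col = cols)
  u <- field@u[as.matrix(idx)]
  v <- field@v[as.matrix(idx)]
  speed <- sqrt(u^2 + v^2)
  keep <- speed >= minVelocity
  out <- data.frame(row = idx$row[keep] - 1L, col = idx$col[keep] - 1L,
                    u = u[keep], v = v[keep], speed = speed[keep],
                    length = scale * speed[keep])
  attr(out, "scale") <- scale
  out
}

#' Preprocess, estimate and summarize optical flow in one call
#'
#' @param stack raw H x W x T intensity time-lapse.
#' @param woundAxisCol wound axis column, 0-based, in stack coordinates.
#' @param params a \linkS4class{FlowParams}.
#' @param pixelSize micrometres per pixel.
#' @param frameInterval minutes per original frame.
#' @param woundMask optional wound mask passed to
#'   \code{\link{summarizeFronts}}.
#' @return list with \code{field} (um/h), \code{summary}
#'   (\linkS4class{FlowSummary}) and \code{preprocessed}.
#' @export
runOpticalFlow <- function(stack, woundAxisCol, params = FlowParams(),
                           pixelSize = 320 / 1440, frameInterval = 1,
                           woundMask = NULL) {
  pre <- preprocessForFlow(stack, params)
  field <- accumulateFlow(pre, params, pixelSize, frameInterval)
  summary <- summarizeFronts(field, woundAxisCol, params, woundMask)
  list(field = field, summary = summary, preprocessed = pre)
}
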