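## profiler: scratch segmentation, wound-closure and width kinetics.

#' First level of a multi-level Otsu threshold
#'
#' Computes the (nClasses - 1) thresholds that maximize the between-class
#' variance of the image histogram (multi-level Otsu, solved exactly by
#' dynamic programming over 256 histogram bins) and returns the lowest
#' one, which separates the dark scratch from the cells.
#'
#' @param image numeric matrix.
#' @param nClasses number of intensity classes (>= 2, default 3: wound,
#'   cytoplasm, bright organelles).
#' @param nBins histogram bins.
#' @return the first (lowest) threshold value, on the intensity scale of
#'   the image; pixels strictly below it belong to the first class.
#' @export
multithresholdFirstLevel <- function(image, nClasses = 3L, nBins = 256L) {
  nClasses <- as.integer(nClasses)
  if (nClasses < 2L) invalidParam("nClasses must be >= 2")
  vals <- as.vector(image)
  if (!all(is.finite(vals))) invalidInput("image must be finite")
  if (length(unique(vals)) < nClasses)
    degenerateInput("image has fewer distinct values than classes")
  rng <- range(vals)
  edges <- seq(rng[1L], rng[2L], length.out = nBins + 1L)
  bin <- pmin(pmax(findInterval(vals, edges, rightmost.closed = TRUE), 1L),
              nBins)
  h <- tabulate(bin, nBins)
  centers <- (edges[-1L] + edges[-(nBins + 1L)]) / 2
  ## cumulative weight and first moment; class (i..j] statistics in O(1)
  W <- c(0, cumsum(h))
  M <- c(0, cumsum(h * centers))
  cost <- function(i, j) {            # bins (i, j], 0-based i
    w <- W[j + 1L] - W[i + 1L]
    if (w == 0) return(0)
    (M[j + 1L] - M[i + 1L])^2 / w
  }
  ## DP: best[m, j] = max sum of w*mu^2 splitting bins 1..j into m classes
  best <- matrix(-Inf, nClasses, nBins)
  argmax <- matrix(0L, nClasses, nBins)
  for (j in seq_len(nBins)) best[1L, j] <- cost(0L, j)
  for (m in 2L:nClasses) {
    for (j in m:nBins) {
      prev <- best[m - 1L, (m - 1L):(j - 1L)]
      tail <- vapply((m - 1L):(j - 1L), function(i) cost(i, j), numeric(1))
      s <- prev + tail
      k <- which.max(s)
      best[m, j] <- s[k]
      argmax[m, j] <- (m - 1L) + (k - 1L)
    }
  }
  ## backtrack the class boundaries
  cuts <- integer(nClasses - 1L)
  j <- nBins
  for (m in nClasses:2L) {
    cuts[m - 1L] <- argmax[m, j]
    j <- argmax[m, j]
  }
  edges[cuts[1L] + 1L]  # upper edge of the last bin of the first class
}

#' Linearly interpolated per-frame thresholds
#'
#' The threshold is computed on the first and last frames and smoothed
#' linearly through the stack, absorbing slow intensity drift.
#'
#' @param tFirst,tLast thresholds of the first and last frames.
#' @param nFrames number of frames (>= 1).
#' @return numeric vector of length nFrames.
#' @export
interpolateThresholds <- function(tFirst, tLast, nFrames) {
  nFrames <- as.integer(nFrames)
  if (nFrames < 1L) invalidParam("nFrames must be >= 1")
  if (nFrames == 1L) return(tFirst)
  seq(tFirst, tLast, length.out = nFrames)
}

## -- rotation ----------------------------------------------------------------

## Largest axis-aligned rectangle inscribed in a w x h rectangle rotated
## by `angle` radians (classic closed form).
inscribedRect <- function(w, h, angle) {
  a <- abs(angle %% pi)
  if (a > pi / 2) a <- pi - a
  sinA <- sin(a); cosA <- cos(a)
  if (sinA < 1e-12) return(c(w, h))
  longer <- max(w, h); shorter <- min(w, h)
  if (shorter <= 2 * sinA * cosA * longer || abs(sinA - cosA) < 1e-10) {
    x <- 0.5 * shorter
    if (w >= h) c(x / sinA, x / cosA) else c(x / cosA, x / sinA)
  } else {
    cos2a <- cosA^2 - sinA^2
    c((w * cosA - h * sinA) / cos2a, (h * cosA - w * sinA) / cos2a)
  }
}

## Sampling geometry for rotating an H x W frame so that a direction at
## `theta` radians from the row (vertical) axis becomes vertical.
rotationGeometry <- function(h, w, theta) {
  ct <- cos(theta); st <- sin(theta)
  nh <- ceiling(h * abs(ct) + w * abs(st))
  nw <- ceiling(h * abs(st) + w * abs(ct))
  cIn <- c((h - 1) / 2, (w - 1) / 2)
  cOut <- c((nh - 1) / 2, (nw - 1) / 2)
  rp <- rep(seq_len(nh) - 1, times = nw) - cOut[1L]
  cp <- rep(seq_len(nw) - 1, each = nh) - cOut[2L]
  ## inverse map: rotate output coords by +theta back into the input
  r <- ct * rp - st * cp + cIn[1L]
  c_ <- st * rp + ct * cp + cIn[2L]
  valid <- r >= -1e-9 & r <= h - 1 + 1e-9 & c_ >= -1e-9 & c_ <= w - 1 + 1e-9
  ## crop to the largest fill-free axis-aligned rectangle
  wh <- inscribedRect(w, h, theta)
  cropW <- max(1L, floor(min(wh[1L], nw)) - 1L)
  cropH <- max(1L, floor(min(wh[2L], nh)) - 1L)
  validMap <- matrix(valid, nh, nw)
  repeat {
    r0 <- floor(cOut[1L] - cropH / 2) + 1L; r1 <- r0 + cropH - 1L
    c0 <- floor(cOut[2L] - cropW / 2) + 1L; c1 <- c0 + cropW - 1L
    r0 <- max(r0, 1L); c0 <- max(c0, 1L)
    r1 <- min(r1, nh); c1 <- min(c1, nw)
    if (all(validMap[r0:r1, c0:c1]) || (cropH <= 2L && cropW <= 2L)) break
    cropH <- cropH - 1L; cropW <- cropW - 1L
  }
  list(nh = nh, nw = nw, r = r, c = c_, valid = valid,
       cIn = cIn, cOut = cOut, theta = theta,
       rows = r0:r1, cols = c0:c1)
}

sampleFrame <- function(frame, geom, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  h <- nrow(frame); w <- ncol(frame)
  out <- rep(NA_real_, geom$nh * geom$nw)
  r <- pmin(pmax(geom$r[geom$valid], 0), h - 1)
  c_ <- pmin(pmax(geom$c[geom$valid], 0), w - 1)
  if (method == "nearest") {
    out[geom$valid] <- frame[cbind(round(r) + 1L, round(c_) + 1L)]
  } else {
    r0 <- floor(r); c0 <- floor(c_)
    fr <- r - r0; fc <- c_ - c0
    r1 <- pmin(r0 + 1, h - 1); c1 <- pmin(c0 + 1, w - 1)
    out[geom$valid] <-
      frame[cbind(r0 + 1L, c0 + 1L)] * (1 - fr) * (1 - fc) +
      frame[cbind(r1 + 1L, c0 + 1L)] * fr * (1 - fc) +
      frame[cbind(r0 + 1L, c1 + 1L)] * (1 - fr) * fc +
      frame[cbind(r1 + 1L, c1 + 1L)] * fr * fc
  }
  matrix(out, geom$nh, geom$nw)[geom$rows, geom$cols, drop = FALSE]
}

#' Rotate a stack so the scratch is vertical
#'
#' Rotates every frame so that the user-drawn scratch line maps onto the
#' image column (vertical) axis, choosing the smaller-magnitude of the two
#' equivalent rotations, and crops to the maximal axis-aligned rectangle
#' free of fill pixels. Intensity frames are resampled bilinearly, binary
#' frames nearest-neighbour.
#'
#' @param stack H x W x T numeric array (a single H x W matrix is also
#'   accepted).
#' @param line a \linkS4class{ScratchLine}.
#' @param method "bilinear" (intensity) or "nearest" (binary).
#' @return list with \code{stack} (rotated, cropped), \code{angle} (the
#'   line's angle from vertical that was removed, degrees) and
#'   \code{mapPoints}, a function mapping (row, col) points in the
#'   original frame to the rotated, cropped frame.
#' @export
rotateToVertical <- function(stack, line, method = "bilinear") {
  if (!is(line, "ScratchLine")) invalidInput("line must be a ScratchLine")
  if (is.matrix(stack)) stack <- array(stack, c(dim(stack), 1L))
  d <- dim(stack)
  dr <- line@p1[1L] - line@p0[1L]
  dc <- line@p1[2L] - line@p0[2L]
  theta <- atan2(dc, dr)
  if (theta > pi / 2 + 1e-12) theta <- theta - pi
  if (theta <= -pi / 2 + 1e-12) theta <- theta + pi
  ## snap near-axis angles so exact 0/90 degree cases stay exact
  for (snap in c(0, pi / 2)) if (abs(abs(theta) - snap) < 1e-9)
    theta <- sign(theta) * snap
  if (abs(theta) < 1e-12) {
    geomId <- NULL
    out <- stack
    mapPoints <- function(pts) pts
    return(list(stack = out, angle = 0, mapPoints = mapPoints))
  }
  geom <- rotationGeometry(d[1L], d[2L], theta)
  out <- array(NA_real_, c(length(geom$rows), length(geom$cols), d[3L]))
  for (t in seq_len(d[3L]))
    out[, , t] <- sampleFrame(stack[, , t], geom, method)
  off <- c(geom$rows[1L] - 1L, geom$cols[1L] - 1L)
  ct <- cos(theta); st <- sin(theta)
  mapPoints <- function(pts) {
    pts <- matrix(pts, ncol = 2L)
    rr <- pts[, 1L] - geom$cIn[1L]; cc <- pts[, 2L] - geom$cIn[2L]
    ## forward map is the inverse rotation of the sampling map
    cbind(ct * rr + st * cc + geom$cOut[1L] - off[1L],
          -st * rr + ct * cc + geom$cOut[2L] - off[2L])
  }
  list(stack = out, angle = theta * 180 / pi, mapPoints = mapPoints)
}

## -- segmentation ------------------------------------------------------------

#' Rasterize an ROI polygon onto a pixel grid
#'
#' @param roi a \linkS4class{RoiPolygon} (vertices in the target frame's
#'   coordinates, 0-based).
#' @param dim c(H, W) of the target frame.
#' @return H x W logical mask of pixel centres inside (or on) the polygon.
#' @export
rasterizeRoi <- function(roi, dim) {
  v <- roi@vertices
  rr <- rep(seq_len(dim[1L]) - 1, times = dim[2L])
  cc <- rep(seq_len(dim[2L]) - 1, each = dim[1L])
  inside <- pracma::inpolygon(cc, rr, v[, 2L], v[, 1L], boundary = TRUE)
  matrix(inside, dim[1L], dim[2L])
}

#' Segment the wound in a rotated stack
#'
#' Wound pixels are those strictly below the per-frame threshold and
#' inside the ROI polygon. The polygon is drawn on the first frame for a
#' closing wound and on the last for an expanding one; the resulting mask
#' is applied to every frame.
#'
#' @param stack rotated H x W x T intensity array.
#' @param thresholds per-frame thresholds (length T).
#' @param roi a \linkS4class{RoiPolygon} in the stack's coordinates.
#' @param removeSmall drop connected wound components smaller than
#'   \code{minObjectSize} pixels (off by default).
#' @param minObjectSize pixels.
#' @return H x W x T logical array; attribute \code{roiMask} carries the
#'   rasterized ROI.
#' @export
segmentWound <- function(stack, thresholds, roi, removeSmall = FALSE,
                         minObjectSize = 16L) {
  if (is.matrix(stack)) stack <- array(stack, c(dim(stack), 1L))
  d <- dim(stack)
  if (length(thresholds) != d[3L])
    invalidInput("need one threshold per frame")
  roiMask <- rasterizeRoi(roi, d[1:2])
  if (!any(roiMask)) invalidInput("ROI contains no pixels")
  masks <- array(FALSE, d)
  for (t in seq_len(d[3L])) {
    m <- stack[, , t] < thresholds[t] & roiMask
    if (removeSmall) m <- removeSmallObjects(m, minObjectSize)
    masks[, , t] <- m
  }
  attr(masks, "roiMask") <- roiMask
  masks
}

## 4-connected component labelling by flood fill; drops components below
## minSize. Only used when small-object removal is requested.
removeSmallObjects <- function(mask, minSize) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  nextLab <- 0L
  keep <- mask
  for (start in which(mask & lab == 0L)) {
    if (lab[start] != 0L) next
    nextLab <- nextLab + 1L
    queue <- start
    members <- integer(0)
    lab[start] <- nextLab
    while (length(queue)) {
      px <- queue[length(queue)]; queue <- queue[-length(queue)]
      members <- c(members, px)
      r <- (px - 1L) %% h + 1L; c_ <- (px - 1L) %/% h + 1L
      for (nb in c(if (r > 1L) px - 1L, if (r < h) px + 1L,
                   if (c_ > 1L) px - h, if (c_ < w) px + h)) {
        if (mask[nb] && lab[nb] == 0L) { lab[nb] <- nextLab; queue <- c(queue, nb) }
      }
    }
    if (length(members) < minSize) keep[members] <- FALSE
  }
  keep
}

#' Wound-closure percentage
#'
#' (area(t=0) - area(t)) / area(t=0) x 100: positive while the wound
#' closes, 100 when fully closed, negative when it expands.
#'
#' @param areaSeries per-frame wound areas (any consistent unit).
#' @return percentage series, first element 0.
#' @export
woundClosure <- function(areaSeries) {
  if (length(areaSeries) < 1L || areaSeries[1L] <= 0)
    invalidInput("area at t = 0 must be > 0")
  (areaSeries[1L] - areaSeries) / areaSeries[1L] * 100
}

#' Per-row scratch widths of a binary frame
#'
#' With the scratch vertical, the width at each image row is the count of
#' wound pixels in that row. Summaries are taken over the rows that
#' intersect the ROI (all rows when no ROI is given).
#'
#' @param mask H x W logical matrix (rotated, scratch vertical).
#' @param roiRows optional integer vector of rows to summarize over.
#' @return list with \code{widths} (per summarized row, pixels) and
#'   \code{min}, \code{mean}, \code{max}.
#' @export
widthProfile <- function(mask, roiRows = NULL) {
  widths <- rowSums(mask)
  if (!is.null(roiRows)) widths <- widths[roiRows]
  list(widths = widths, min = min(widths), mean = mean(widths),
       max = max(widths))
}

## -- kinetics ----------------------------------------------------------------

#' Fit bi-exponential wound-width kinetics
#'
#' Fits w(t) = closingLimit + a e^{bt} + c e^{dt} to the mean-width trace
#' by Levenberg-Marquardt least squares with a deterministic multi-start
#' grid (amplitude splits 0.9/0.5/0.1 of the initial excess; rate starts
#' -1/T, -0.1/T, -0.01/T), keeping the best residual. The characteristic
#' time is the 1/e decay time of the fitted excess over its plateau; the
#' average closing speed is (w(0) - closingLimit) / t_reach x 60 where
#' t_reach is when the fitted curve first reaches the closing limit. If
#' the curve does not reach the limit within the acquisition the speed
#' over the observed interval is reported and \code{notClosed} is set.
#'
#' @param times minutes, length >= 8.
#' @param widths mean widths in micrometres, same length, >= 0.
#' @param closingLimit residual interstice width in micrometres (the
#'   1-2 um inter-cell interstice; default 1.5).
#' @return A \linkS4class{ClosureFit}.
#' @export
fitBiexponential <- function(times, widths, closingLimit = 1.5) {
  if (length(times) < 8L || length(widths) != length(times))
    invalidInput("need >= 8 matching timepoints")
  if (any(widths < 0)) invalidInput("widths must be >= 0")
  tt <- times - times[1L]
  excess <- widths - closingLimit
  tspan <- max(tt[length(tt)], 1)
  w0ex <- max(excess[1L], 1e-6)
  rates <- c(-1, -0.1, -0.01) / tspan
  best <- NULL; bestDev <- Inf
  df <- data.frame(tt = tt, excess = excess)
  for (s in c(0.9, 0.5, 0.1)) {
    for (i in seq_along(rates)) for (j in i:length(rates)) {
      fit <- try(suppressWarnings(minpack.lm::nlsLM(
        excess ~ a * exp(b * tt) + c * exp(d * tt), data = df,
        start = list(a = s * w0ex, b = rates[i],
                     c = (1 - s) * w0ex, d = rates[j]),
        ## rates constrained to the decaying family: growing exponentials
        ## are not part of the closing-kinetics model, and unconstrained
        ## near-zero positive rates destabilize the extrapolated plateau
        lower = c(-Inf, -Inf, -Inf, -Inf), upper = c(Inf, 0, Inf, 0),
        control = minpack.lm::nls.lm.control(maxiter = 200))),
        silent = TRUE)
      if (inherits(fit, "try-error")) next
      dev <- sum(stats::residuals(fit)^2)
      if (is.finite(dev) && dev < bestDev) { bestDev <- dev; best <- fit }
    }
  }
  if (is.null(best)) {
    return(new("ClosureFit", a = NA_real_, b = NA_real_, c = NA_real_,
               d = NA_real_, closingLimit = closingLimit,
               characteristicTime = NA_real_, averageSpeed = NA_real_,
               converged = FALSE, notClosed = TRUE, residualRms = NA_real_,
               times = times, widths = widths))
  }
  p <- stats::coef(best)
  wfit <- function(t) closingLimit + p["a"] * exp(p["b"] * t) +
    p["c"] * exp(p["d"] * t)
  res <- closureKinetics(p["a"], p["b"], p["c"], p["d"], closingLimit,
                         tMax = tt[length(tt)])
  new("ClosureFit", a = unname(p["a"]), b = unname(p["b"]),
      c = unname(p["c"]), d = unname(p["d"]), closingLimit = closingLimit,
      characteristicTime = res$charTime, averageSpeed = res$speed,
      converged = TRUE, notClosed = res$notClosed,
      residualRms = sqrt(mean((excess - (wfit(tt) - closingLimit))^2)),
      times = times, widths = widths)
}

## characteristic time (1/e decay of fitted excess over plateau) and
## average speed from fitted coefficients
closureKinetics <- function(a, b, c, d, limit, tMax) {
  ex <- function(t) a * exp(b * t) + c * exp(d * t)
  horizon <- max(10 * tMax, tMax + 1)
  grid <- seq(0, horizon, length.out = 4001L)
  firstCrossing <- function(f, target) {
    y <- f(grid) - target
    if (y[1L] <= 0) return(0)
    k <- which(y <= 0)[1L]
    if (is.na(k)) return(NA_real_)
    stats::uniroot(function(t) f(t) - target, c(grid[k - 1L], grid[k]),
                   tol = 1e-10)$root
  }
  ## plateau of the fitted excess as t -> infinity: decaying terms vanish,
  ## zero-rate terms persist (rates are constrained to be <= 0). The
  ## plateau is floored at zero excess: the width cannot settle below the
  ## closing limit, which is itself the residual interstice width.
  plate <- max(0, (if (b > -1e-9) a else 0) + (if (d > -1e-9) c else 0))
  charTime <- NA_real_
  ex0 <- ex(0) - plate
  if (ex0 > 0) {
    charTime <- firstCrossing(function(t) ex(t) - plate, ex0 / exp(1))
    if (!is.na(charTime) && charTime <= 0) charTime <- NA_real_
  }
  tReach <- firstCrossing(ex, 0)
  if (!is.na(tReach) && tReach > 1e-9 && tReach <= tMax + 1e-9) {
    speed <- ex(0) / tReach * 60
    notClosed <- FALSE
  } else if (!is.na(tReach) && tReach <= 1e-9) {
    speed <- 0
    notClosed <- FALSE
  } else {
    speed <- if (tMax > 0) (ex(0) - ex(tMax)) / tMax * 60 else 0
    notClosed <- TRUE
  }
  list(charTime = charTime, speed = unname(speed), notClosed = notClosed)
}

#' Run the full scratch-assay profiling pipeline
#'
#' Thresholds the first and last frames (multi-level Otsu, first level,
#' computed within the bounding box of the user ROI -- the calculation
#' window around the wound), interpolates the threshold linearly through
#' the stack, rotates the stack so the scratch is vertical, masks with
#' the ROI, and computes the per-frame area and width statistics, the
#' wound-closure percentage and the bi-exponential width kinetics.
#'
#' @param stack H x W x T intensity array (time-lapse of dynamic-image
#'   intensity frames).
#' @param line a \linkS4class{ScratchLine} in the stack's coordinates.
#' @param roi a \linkS4class{RoiPolygon} in the stack's (unrotated)
#'   coordinates.
#' @param nClasses threshold classes (default 3).
#' @param closingLimit micrometres (default 1.5).
#' @param pixelSize micrometres per pixel.
#' @param frameInterval minutes per frame.
#' @param removeSmall,minObjectSize optional small-object cleanup.
#' @return list with \code{trace} (\linkS4class{WoundTrace}), \code{fit}
#'   (\linkS4class{ClosureFit}), \code{masks} (rotated binary stack),
#'   \code{angle} (degrees) and \code{thresholds}.
#' @export
runSaveProfiler <- function(stack, line, roi, nClasses = 3L,
                            closingLimit = 1.5, pixelSize = 320 / 1440,
                            frameInterval = 1, removeSmall = FALSE,
                            minObjectSize = 16L) {
  d <- dim(stack)
  if (length(d) != 3L || d[3L] < 2L)
    invalidInput("stack must be H x W x T with T >= 2")
  ## threshold inside the calculation window so the scratch class stays
  ## prominent even when the wound is nearly closed
  rows <- max(1L, floor(min(roi@vertices[, 1L])) + 1L):
    min(d[1L], ceiling(max(roi@vertices[, 1L])) + 1L)
  cols <- max(1L, floor(min(roi@vertices[, 2L])) + 1L):
    min(d[2L], ceiling(max(roi@vertices[, 2L])) + 1L)
  tFirst <- multithresholdFirstLevel(stack[rows, cols, 1L], nClasses)
  tLast <- multithresholdFirstLevel(stack[rows, cols, d[3L]], nClasses)
  thr <- interpolateThresholds(tFirst, tLast, d[3L])
  rot <- rotateToVertical(stack, line, method = "bilinear")
  roiRot <- RoiPolygon(rot$mapPoints(roi@vertices), roi@referenceFrame)
  masks <- segmentWound(rot$stack, thr, roiRot, removeSmall, minObjectSize)
  roiMask <- attr(masks, "roiMask")
  roiRows <- which(rowSums(roiMask) > 0)
  nT <- d[3L]
  areaPx <- numeric(nT)
  wmin <- wmean <- wmax <- numeric(nT)
  for (t in seq_len(nT)) {
    m <- masks[, , t]
    areaPx[t] <- sum(m)
    wp <- widthProfile(m, roiRows)
    wmin[t] <- wp$min; wmean[t] <- wp$mean; wmax[t] <- wp$max
  }
  times <- (seq_len(nT) - 1L) * frameInterval
  trace <- WoundTrace(data.frame(
    time_min = times, area_px = areaPx, area_um2 = areaPx * pixelSize^2,
    width_min_um = wmin * pixelSize, width_mean_um = wmean * pixelSize,
    width_max_um = wmax * pixelSize,
    closure_pct = woundClosure(areaPx)), pixelSize)
  fit <- fitBiexponential(times, wmean * pixelSize, closingLimit)
  list(trace = trace, fit = fit, masks = masks, angle = rot$angle,
       thresholds = thr)
}
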