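#' Segment the oocyte on a single optical plane
#'
#' Automatic (Otsu) thresholding, followed by selection of the largest
#' connected foreground component with holes filled. The oocyte diameter is
#' the equivalent circular diameter \code{2*sqrt(area/pi)} and the center is
#' the mask centroid. Bright specks smaller than the cell are excluded by
#' the largest-component rule; a ring-shaped threshold result (a strongly
#' peripheral cell) is closed by hole filling.
#'
#' @param plane 2-D numeric intensity matrix.
#' @param planeIndex 1-based z index recorded in the result.
#' @return a [SegmentedOocyte-class].
#' @examples
#' oo <- makeOocyteScene(radiusPx = 60, trueRatio = 1.4, seed = 1)
#' segmentOocyte(getPlane(oo$scene, role = "mito"))
#' @export
segmentOocyte <- function(plane, planeIndex = 1L) {
  if (!is.matrix(plane) || length(plane) == 0L)
    stop("plane must be a nonempty matrix")
  thr <- tryCatch(otsuThreshold(plane),
                  error = function(e) stop("no oocyte detected: ",
                                           conditionMessage(e)))
  mask <- largestComponent(plane > thr, fill = TRUE)
  area <- sum(mask)
  if (area < 0.01 * length(plane))
    stop("no oocyte detected: foreground below 1% of the frame")
  idx <- which(mask, arr.ind = TRUE)
  centerXY <- c(mean(idx[, 2L]), mean(idx[, 1L]))
  new("SegmentedOocyte", mask = mask, centerXY = centerXY,
      diameterPx = 2 * sqrt(area / pi), planeIndex = as.integer(planeIndex))
}

#' Select the equatorial plane of an oocyte z-stack
#'
#' The equator is the plane with the maximum segmented cross-section area
#' (the maximum optical X-Y section of the z-stack). Ties are broken toward
#' the stack middle; planes on which segmentation fails are skipped.
#'
#' @param scene a [MultiChannelScene-class] with a \code{mito} channel.
#' @return 1-based index of the equatorial z-plane.
#' @export
selectEquator <- function(scene) {
  stopifnot(is(scene, "MultiChannelScene"))
  nz <- nPlanes(scene)
  areas <- rep(NA_real_, nz)
  for (k in seq_len(nz)) {
    oo <- tryCatch(segmentOocyte(getPlane(scene, role = "mito", z = k), k),
                   error = function(e) NULL)
    if (!is.null(oo)) areas[k] <- sum(oo@mask)
  }
  if (all(is.na(areas)))
    stop("segmentation failed on every z-plane")
  best <- which(areas == max(areas, na.rm = TRUE))
  if (length(best) > 1L) {
    mid <- (nz + 1) / 2
    best <- best[order(abs(best - mid), best)]
  }
  best[1L]
}

#' Relative peripheral intensity (cortex vs center) of an oocyte
#'
#' The center region is the part of the oocyte mask within
#' \code{centerFraction} of the cell radius from the centroid (by default
#' the inner 80\% of the diameter); the cortex is the rest of the mask (the
#' outer 10\% of the diameter on each side of the cell). Both compartments
#' are summarized as mean fluorescence intensity per pixel, which normalizes
#' away their different pixel areas, and the relative peripheral intensity
#' is the cortex/center ratio of these per-pixel means. A zero center mean
#' leaves the ratio undefined (\code{NA}), never infinite.
#'
#' @param plane 2-D intensity matrix (the \code{mito} channel plane).
#' @param oocyte a [SegmentedOocyte-class]; segmented from \code{plane} when
#'   omitted.
#' @param centerFraction fraction of the diameter treated as the center,
#'   in (0, 1); default 0.8.
#' @return a [MitoProfile-class].
#' @examples
#' oo <- makeOocyteScene(radiusPx = 60, trueRatio = 3, seed = 1)
#' relativePeripheralIntensity(getPlane(oo$scene, role = "mito"))
#' @export
relativePeripheralIntensity <- function(plane, oocyte = NULL,
                                        centerFraction = 0.8) {
  if (centerFraction <= 0 || centerFraction >= 1)
    stop("centerFraction must lie strictly between 0 and 1")
  if (is.null(oocyte)) oocyte <- segmentOocyte(plane)
  stopifnot(is(oocyte, "SegmentedOocyte"))
  if (!identical(dim(plane), dim(oocyte@mask)))
    stop("plane and oocyte mask dimensions differ")

  rCut <- centerFraction * oocyte@diameterPx / 2
  d2 <- distSqGrid(nrow(plane), ncol(plane),
                   oocyte@centerXY[1L], oocyte@centerXY[2L])
  centerMask <- oocyte@mask & d2 <= rCut^2
  cortexMask <- oocyte@mask & !centerMask

  centerMean <- if (any(centerMask)) mean(plane[centerMask]) else 0
  cortexMean <- if (any(cortexMask)) mean(plane[cortexMask]) else 0
  ratio <- if (centerMean > 0) cortexMean / centerMean else NA_real_
  new("MitoProfile", centerMean = centerMean, cortexMean = cortexMean,
      ratio = ratio, centerFraction = centerFraction)
}

#' Mitochondrial distribution profile of an oocyte scene
#'
#' Convenience wrapper: selects the equatorial plane of the stack, segments
#' the oocyte, and computes the relative peripheral intensity on that plane
#' (or, optionally, averaged over all segmentable planes).
#'
#' @param scene a [MultiChannelScene-class] with a \code{mito} channel.
#' @param centerFraction see [relativePeripheralIntensity()].
#' @param aggregate \code{"equator"} (default; single equatorial plane) or
#'   \code{"mean"} (mean of the per-plane ratios over the stack).
#' @return a one-row data.frame: \code{plane_index}, \code{center_mean},
#'   \code{cortex_mean}, \code{ratio}.
#' @export
mitoProfile <- function(scene, centerFraction = 0.8,
                        aggregate = c("equator", "mean")) {
  aggregate <- match.arg(aggregate)
  eq <- selectEquator(scene)
  if (aggregate == "equator") {
    plane <- getPlane(scene, role = "mito", z = eq)
    prof <- relativePeripheralIntensity(plane,
                                        centerFraction = centerFraction)
    return(data.frame(plane_index = eq, center_mean = prof@centerMean,
                      cortex_mean = prof@cortexMean, ratio = prof@ratio))
  }
  ratios <- cm <- xm <- c()
  for (k in seq_len(nPlanes(scene))) {
    prof <- tryCatch(
      relativePeripheralIntensity(getPlane(scene, role = "mito", z = k),
                                  centerFraction = centerFraction),
      error = function(e) NULL)
    if (!is.null(prof) && !is.na(prof@ratio)) {
      ratios <- c(ratios, prof@ratio)
      cm <- c(cm, prof@centerMean); xm <- c(xm, prof@cortexMean)
    }
  }
  data.frame(plane_index = eq, center_mean = mean(cm),
             cortex_mean = mean(xm), ratio = mean(ratios))
}
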