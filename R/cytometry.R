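#' Rolling-ball-style background subtraction
#'
#' Estimates the background of a fluorescence plane as its morphological
#' opening with a disc structuring element of radius \code{bgRadiusPx}
#' (larger than any nucleus), and subtracts it, clipping at zero. A pure
#' intensity offset or a smooth gradient is removed; spots survive.
#'
#' @param plane 2-D intensity matrix.
#' @param bgRadiusPx disc radius of the structuring element, pixels.
#' @return background-subtracted plane (same dimensions).
#' @export
subtractBackground <- function(plane, bgRadiusPx = 15) {
  stopifnotScalar(bgRadiusPx, "bgRadiusPx", positive = TRUE)
  brush <- EBImage::makeBrush(2L * ceiling(bgRadiusPx) + 1L, shape = "disc")
  bg <- EBImage::opening(EBImage::Image(plane / 65535), brush) * 65535
  pmax(plane - as.matrix(bg), 0)
}

#' Threshold a fluorescence channel into a positivity mask
#'
#' Background subtraction followed by automatic Otsu thresholding; used to
#' build the TUNEL and EthD1 positivity masks.
#'
#' @inheritParams subtractBackground
#' @param smoothSigmaPx Gaussian pre-smoothing sigma in pixels (0 = none);
#'   suppresses pixel noise before thresholding.
#' @return logical matrix.
#' @export
thresholdChannel <- function(plane, bgRadiusPx = 15, smoothSigmaPx = 2) {
  if (smoothSigmaPx > 0)
    plane <- as.matrix(EBImage::gblur(EBImage::Image(plane / 65535),
                                      sigma = smoothSigmaPx)) * 65535
  sub <- subtractBackground(plane, bgRadiusPx)
  if (diff(range(sub)) == 0)   # flat after background removal: no signal
    return(matrix(FALSE, nrow(plane), ncol(plane)))
  thr <- otsuThreshold(sub)
  # a threshold inside the noise floor means there is no real signal
  if (thr <= 4 * stats::mad(sub))
    return(matrix(FALSE, nrow(plane), ncol(plane)))
  sub > thr
}

#' Detect nucleus particles on one channel plane
#'
#' Reimplements the classic particle-counting recipe: Gaussian noise
#' suppression, rolling-ball-style background subtraction, automatic (Otsu)
#' thresholding, distance-transform watershed separation of touching blobs,
#' and size filtering of the resulting components. The size window defaults
#' to \code{[0.25, 4] * median} component area estimated from the image
#' itself. Particles touching the frame border are excluded by default and
#' flagged.
#'
#' @param plane 2-D intensity matrix (typically the Hoechst channel).
#' @param smoothSigmaPx Gaussian pre-smoothing sigma, pixels (0 = none).
#' @param bgRadiusPx background structuring-element radius, pixels.
#' @param sizeMinPx,sizeMaxPx particle area window in pixels;
#'   \code{NULL} = derive from the median component area.
#' @param excludeBorder drop particles touching the frame border.
#' @param planeIndex 1-based z index recorded with each particle.
#' @return \code{list(particles, labels)}: a data.frame with one row per
#'   retained particle (\code{nucleus_id}, \code{plane_index}, \code{x},
#'   \code{y}, \code{area_px}, \code{on_border}) and the integer label
#'   matrix (labels of dropped particles are zeroed).
#' @examples
#' nf <- makeCocNucleusScene(nTotal = 30, frameSide = 256, seed = 2)
#' nrow(detectParticles(getPlane(nf$scene, role = "hoechst"))$particles)
#' @export
detectParticles <- function(plane, bgRadiusPx = 15, sizeMinPx = NULL,
                            sizeMaxPx = NULL, excludeBorder = TRUE,
                            planeIndex = 1L, smoothSigmaPx = 2) {
  if (!is.null(sizeMinPx) && !is.null(sizeMaxPx) && sizeMinPx >= sizeMaxPx)
    stop("sizeMinPx must be smaller than sizeMaxPx")
  if (diff(range(plane)) == 0)
    stop("threshold undefined: image is constant")
  if (smoothSigmaPx > 0)
    plane <- as.matrix(EBImage::gblur(EBImage::Image(plane / 65535),
                                      sigma = smoothSigmaPx)) * 65535
  sub <- subtractBackground(plane, bgRadiusPx)

  empty <- data.frame(nucleus_id = integer(0), plane_index = integer(0),
                      x = numeric(0), y = numeric(0), area_px = integer(0),
                      on_border = logical(0))
  emptyOut <- list(particles = empty,
                   labels = matrix(0L, nrow(plane), ncol(plane)))
  if (diff(range(sub)) == 0) return(emptyOut)  # flat: blank channel
  thr <- otsuThreshold(sub)
  # blank guard: a threshold within the noise floor (4x the robust noise
  # scale of the subtracted image) indicates there are no real spots
  if (thr <= 4 * stats::mad(sub)) return(emptyOut)
  binary <- sub > thr
  if (!any(binary)) return(emptyOut)

  dm <- EBImage::distmap(EBImage::Image(binary * 1))
  labels <- EBImage::watershed(dm, tolerance = 1, ext = 1)
  labels <- matrix(as.integer(labels), nrow(plane), ncol(plane))

  n <- max(labels)
  areas <- tabulate(labels[labels > 0L], nbins = n)
  present <- which(areas > 0L)
  if (is.null(sizeMinPx) || is.null(sizeMaxPx)) {
    med <- stats::median(areas[present])
    if (is.null(sizeMinPx)) sizeMinPx <- 0.25 * med
    if (is.null(sizeMaxPx)) sizeMaxPx <- 4 * med
  }

  idx <- which(labels > 0L, arr.ind = TRUE)
  lab <- labels[labels > 0L]
  cx <- vapply(split(idx[, 2L], lab), mean, numeric(1))
  cy <- vapply(split(idx[, 1L], lab), mean, numeric(1))
  ids <- as.integer(names(cx))

  borderLabs <- unique(c(labels[1L, ], labels[nrow(labels), ],
                         labels[, 1L], labels[, ncol(labels)]))
  onBorder <- ids %in% borderLabs[borderLabs > 0L]

  keep <- areas[ids] >= sizeMinPx & areas[ids] <= sizeMaxPx
  if (excludeBorder) keep <- keep & !onBorder
  drop <- ids[!keep]
  if (length(drop)) labels[labels %in% drop] <- 0L

  kept <- ids[keep]
  particles <- data.frame(
    nucleus_id = kept,
    plane_index = as.integer(planeIndex),
    x = unname(cx[as.character(kept)]),
    y = unname(cy[as.character(kept)]),
    area_px = areas[kept],
    on_border = onBorder[keep]
  )
  list(particles = particles, labels = labels)
}

#' Classify nuclei from TUNEL/EthD1 positivity flags
#'
#' The staining logic: TUNEL-only marks late apoptosis, EthD1-only marks
#' necrosis (membrane-compromised cells), and double-positive nuclei are
#' secondary apoptotic/necrotic. Neither stain means the nucleus is scored
#' healthy.
#'
#' @param tunelPos,ethd1Pos logical vectors of equal length.
#' @return character vector with values \code{healthy}, \code{apoptotic},
#'   \code{necrotic_only}, \code{secondary}.
#' @examples
#' classifyNuclei(c(TRUE, TRUE, FALSE, FALSE), c(FALSE, TRUE, TRUE, FALSE))
#' @export
classifyNuclei <- function(tunelPos, ethd1Pos) {
  stopifnot(length(tunelPos) == length(ethd1Pos))
  ifelse(tunelPos & ethd1Pos, "secondary",
    ifelse(tunelPos, "apoptotic",
      ifelse(ethd1Pos, "necrotic_only", "healthy")))
}

#' Assign channel positivity and class to detected nuclei
#'
#' A nucleus is TUNEL-positive (resp. EthD1-positive) iff at least
#' \code{overlapMin} of its pixel area overlaps the thresholded TUNEL
#' (resp. EthD1) mask (overlap exactly at \code{overlapMin} counts as
#' positive). A centroid-in-mask rule is available as an alternative.
#'
#' @param detection result of [detectParticles()] on the Hoechst plane.
#' @param tunelMask,ethd1Mask logical matrices co-registered with the
#'   Hoechst plane (see [thresholdChannel()]).
#' @param overlapMin minimum overlap fraction for positivity (default 0.5).
#' @param rule \code{"area"} (overlap fraction) or \code{"centroid"}
#'   (positivity of the centroid pixel).
#' @return a nucleus table: data.frame with columns \code{nucleus_id},
#'   \code{plane_index}, \code{x}, \code{y}, \code{area_px},
#'   \code{hoechst_pos}, \code{tunel_pos}, \code{ethd1_pos}, \code{class}.
#' @export
assignPositivity <- function(detection, tunelMask, ethd1Mask,
                             overlapMin = 0.5, rule = c("area", "centroid")) {
  rule <- match.arg(rule)
  particles <- detection$particles
  labels <- detection$labels
  if (!identical(dim(labels), dim(tunelMask)) ||
      !identical(dim(labels), dim(ethd1Mask)))
    stop("channel planes have mismatched shapes")

  posFrac <- function(mask) {
    if (nrow(particles) == 0L) return(logical(0))
    if (rule == "centroid") {
      i <- cbind(pmin(pmax(round(particles$y), 1L), nrow(mask)),
                 pmin(pmax(round(particles$x), 1L), ncol(mask)))
      return(mask[i])
    }
    inMask <- labels[mask & labels > 0L]
    hits <- tabulate(inMask, nbins = max(labels, 1L))
    hits[particles$nucleus_id] / particles$area_px >= overlapMin
  }

  particles$hoechst_pos <- rep(TRUE, nrow(particles))
  particles$tunel_pos <- posFrac(tunelMask)
  particles$ethd1_pos <- posFrac(ethd1Mask)
  particles$class <- classifyNuclei(particles$tunel_pos, particles$ethd1_pos)
  particles
}

#' Pool nucleus tables into per-COC apoptotic and necrotic rates
#'
#' Counts are pooled over the analyzed optical planes without inter-plane
#' nucleus matching. The apoptotic rate is TUNEL-positive/EthD1-negative
#' nuclei per total Hoechst nuclei; the necrotic rate is EthD1-positive
#' (with or without TUNEL) per total.
#'
#' @param tables one nucleus table (from [assignPositivity()]) or a list of
#'   them, one per analyzed plane.
#' @param cocId identifier carried into the result.
#' @return one-row data.frame: \code{coc_id}, \code{n_total},
#'   \code{n_apoptotic}, \code{n_necrotic}, \code{n_secondary},
#'   \code{apoptotic_rate}, \code{necrotic_rate}, \code{rates_defined}.
#'   Zero detected nuclei leave the rates \code{NA} with
#'   \code{rates_defined = FALSE}.
#' @export
cocRates <- function(tables, cocId = "coc") {
  if (is.data.frame(tables)) tables <- list(tables)
  if (!length(tables)) stop("at least one plane table is required")
  tab <- do.call(rbind, tables)
  nTotal <- nrow(tab)
  nApo <- sum(tab$class == "apoptotic")
  nSec <- sum(tab$class == "secondary")
  nNec <- sum(tab$class == "necrotic_only") + nSec
  defined <- nTotal > 0L
  data.frame(
    coc_id = cocId,
    n_total = nTotal,
    n_apoptotic = nApo,
    n_necrotic = nNec,
    n_secondary = nSec,
    apoptotic_rate = if (defined) nApo / nTotal else NA_real_,
    necrotic_rate = if (defined) nNec / nTotal else NA_real_,
    rates_defined = defined,
    stringsAsFactors = FALSE
  )
}

#' Select optical planes evenly through the informative depth of a stack
#'
#' Planes carrying spot signal (a bright upper tail above their median
#' background) delimit the informative depth range; \code{nPlanes} indices
#' are then spaced evenly through that range, excluding its extreme ends.
#'
#' @param scene a [MultiChannelScene-class] (the \code{hoechst} channel is
#'   scored) or a 3-D array \code{[y, x, z]}.
#' @param nPlanes number of planes to select (default 3).
#' @return integer vector of 1-based plane indices.
#' @examples
#' # a 9-plane stack yields planes 3, 5, 7
#' @export
selectPlanes <- function(scene, nPlanes = 3L) {
  nPlanes <- as.integer(nPlanes)
  if (is(scene, "MultiChannelScene")) {
    ch <- which(channelRoles(scene) == "hoechst")
    if (length(ch) != 1L) ch <- 1L
    stack <- scene@pixels[, , ch, , drop = TRUE]
    if (length(dim(stack)) == 2L) dim(stack) <- c(dim(stack), 1L)
  } else {
    stack <- scene
    if (length(dim(stack)) != 3L) stop("expected a [y, x, z] array")
  }
  nz <- dim(stack)[3L]
  if (nz < nPlanes)
    stop(sprintf("stack too shallow: %d plane(s), %d requested", nz, nPlanes))

  # bright-tail score: mass above the per-plane median background
  score <- vapply(seq_len(nz), function(k) {
    p <- stack[, , k]
    mean(pmax(p - stats::median(p), 0))
  }, numeric(1))
  info <- which(score > 0.05 * max(score))
  if (!length(info)) info <- seq_len(nz)
  lo <- min(info); hi <- max(info)
  if (hi - lo + 1L < nPlanes) { lo <- 1L; hi <- nz }

  k <- seq_len(nPlanes)
  idx <- lo + round((hi - lo) * k / (nPlanes + 1))
  as.integer(idx)
}

#' Full cytometry of a COC nucleus-field scene
#'
#' Chains plane selection, particle detection on the Hoechst channel,
#' TUNEL/EthD1 mask thresholding, positivity assignment and rate pooling.
#'
#' @param scene 3-channel [MultiChannelScene-class] (hoechst/tunel/ethd1).
#' @param nPlanes number of optical planes to analyze (default 3; capped at
#'   the stack depth).
#' @param cocId identifier for the result.
#' @param bgRadiusPx,sizeMinPx,sizeMaxPx,overlapMin,rule passed through to
#'   [detectParticles()] and [assignPositivity()].
#' @return \code{list(nuclei, rates)}: the pooled nucleus table and the
#'   one-row [cocRates()] summary.
#' @export
cocCytometry <- function(scene, nPlanes = 3L, cocId = "coc",
                         bgRadiusPx = 15, sizeMinPx = NULL,
                         sizeMaxPx = NULL, overlapMin = 0.5,
                         rule = "area") {
  stopifnot(is(scene, "MultiChannelScene"))
  nPlanes <- min(as.integer(nPlanes), nPlanes(scene))
  planes <- selectPlanes(scene, nPlanes)
  tabs <- lapply(planes, function(z) {
    det <- detectParticles(getPlane(scene, role = "hoechst", z = z),
                           bgRadiusPx = bgRadiusPx, sizeMinPx = sizeMinPx,
                           sizeMaxPx = sizeMaxPx, planeIndex = z)
    tun <- thresholdChannel(getPlane(scene, role = "tunel", z = z),
                            bgRadiusPx)
    eth <- thresholdChannel(getPlane(scene, role = "ethd1", z = z),
                            bgRadiusPx)
    assignPositivity(det, tun, eth, overlapMin = overlapMin, rule = rule)
  })
  list(nuclei = do.call(rbind, tabs), rates = cocRates(tabs, cocId))
}
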