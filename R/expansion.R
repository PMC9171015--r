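#' Projected surface area of a COC on a single image
#'
#' Automatic (Otsu) thresholding followed by selection of the largest
#' connected component with holes filled, so a dark core inside the cumulus
#' mass (the oocyte shadow) is counted as part of the projected area.
#'
#' @param plane 2-D numeric intensity matrix containing one dominant object.
#' @return \code{list(mask, areaPx)}: the logical foreground mask and its
#'   pixel count.
#' @examples
#' ep <- makeExpansionPair(5000, fold = 3.6, seed = 1)
#' segmentCocArea(getPlane(ep$before, role = "brightfield"))$areaPx
#' @export
segmentCocArea <- function(plane) {
  if (!is.matrix(plane) || length(plane) == 0L)
    stop("plane must be a nonempty matrix")
  thr <- tryCatch(otsuThreshold(plane),
                  error = function(e) stop("no COC detected: ",
                                           conditionMessage(e)))
  mask <- largestComponent(plane > thr, fill = TRUE)
  area <- sum(mask)
  if (area == 0L) stop("no COC detected: empty foreground")
  list(mask = mask, areaPx = area)
}

#' Fold-increase of COC projected area over maturation
#'
#' The ratio of the projected surface area after IVM to the area before
#' IVM, reported at full precision (downstream reporting may round to one
#' decimal). Shrinkage (fold < 1) is representable.
#'
#' @param areaBeforePx,areaAfterPx projected areas in pixels, both > 0.
#' @return the exact quotient \code{areaAfterPx / areaBeforePx}.
#' @examples
#' foldIncrease(13231, 38061)  # 2.877
#' @export
foldIncrease <- function(areaBeforePx, areaAfterPx) {
  stopifnotScalar(areaBeforePx, "areaBeforePx", positive = TRUE)
  stopifnotScalar(areaAfterPx, "areaAfterPx", positive = TRUE)
  areaAfterPx / areaBeforePx
}

#' Pair before/after COC area measurements into expansion records
#'
#' @param before,after data.frames with columns \code{coc_id} and
#'   \code{area_px}; ids must match one-to-one across the two tables.
#'   Unmatched or duplicated ids raise an error naming the offending ids
#'   (never silently dropped).
#' @return data.frame with one row per COC: \code{coc_id},
#'   \code{area_before_px}, \code{area_after_px}, \code{fold_increase}.
#' @examples
#' pairAndTabulate(data.frame(coc_id = "a", area_px = 13231),
#'                 data.frame(coc_id = "a", area_px = 38061))
#' @export
pairAndTabulate <- function(before, after) {
  for (nm in c("before", "after")) {
    tab <- get(nm)
    if (!all(c("coc_id", "area_px") %in% names(tab)))
      stop(sprintf("'%s' must have columns coc_id and area_px", nm))
    dup <- unique(tab$coc_id[duplicated(tab$coc_id)])
    if (length(dup))
      stop(sprintf("duplicate coc_id in '%s': %s", nm,
                   paste(dup, collapse = ", ")))
  }
  onlyB <- setdiff(before$coc_id, after$coc_id)
  onlyA <- setdiff(after$coc_id, before$coc_id)
  if (length(onlyB) || length(onlyA))
    stop(sprintf("unmatched coc_id(s): %s",
                 paste(c(onlyB, onlyA), collapse = ", ")))
  if (any(before$area_px <= 0) || any(after$area_px <= 0))
    stop("areas must be positive")
  idx <- match(before$coc_id, after$coc_id)
  data.frame(
    coc_id = before$coc_id,
    area_before_px = before$area_px,
    area_after_px = after$area_px[idx],
    fold_increase = after$area_px[idx] / before$area_px,
    stringsAsFactors = FALSE
  )
}

#' Measure the fold-increase of a synthetic or imaged COC pair
#'
#' Convenience wrapper segmenting two single-COC images and forming the
#' expansion record.
#'
#' @param beforeScene,afterScene [MultiChannelScene-class] objects, one COC
#'   each (any single channel is used).
#' @param cocId identifier carried into the record.
#' @return one-row data.frame as in [pairAndTabulate()].
#' @export
measureExpansion <- function(beforeScene, afterScene, cocId = "coc") {
  a1 <- segmentCocArea(getPlane(beforeScene, channel = 1L))$areaPx
  a2 <- segmentCocArea(getPlane(afterScene, channel = 1L))$areaPx
  pairAndTabulate(data.frame(coc_id = cocId, area_px = a1),
                  data.frame(coc_id = cocId, area_px = a2))
}
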