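#' Construct a MultiChannelScene
#'
#' @param pixels numeric array. Accepted shapes: \code{[y, x]} (one channel,
#'   one plane), \code{[y, x, channel]} (one plane), or
#'   \code{[y, x, channel, z]}.
#' @param channelRoles character vector of channel roles, one per channel;
#'   each must be one of \code{"hoechst"}, \code{"tunel"}, \code{"ethd1"},
#'   \code{"mito"}, \code{"brightfield"}.
#' @param pixelSizeUm optional physical pixel size in micrometres.
#'
#' @return a [MultiChannelScene-class] object.
#' @examples
#' sc <- MultiChannelScene(matrix(100, 32, 32), "mito")
#' nChannels(sc)
#' @export
MultiChannelScene <- function(pixels, channelRoles, pixelSizeUm = NA_real_) {
  d <- dim(pixels)
  if (is.null(d)) stop("pixels must be a matrix or array")
  if (length(d) == 2L) dim(pixels) <- c(d, 1L, 1L)
  else if (length(d) == 3L) dim(pixels) <- c(d, 1L)
  else if (length(d) != 4L) stop("pixels must have 2 to 4 dimensions")
  new("MultiChannelScene", pixels = pixels,
      channelRoles = as.character(channelRoles),
      pixelSizeUm = as.numeric(pixelSizeUm))
}

#' @rdname MultiChannelScene-class
#' @export
setMethod("channelRoles", "MultiChannelScene", function(object)
  object@channelRoles)

#' @rdname MultiChannelScene-class
#' @export
setMethod("scenePixels", "MultiChannelScene", function(object) object@pixels)

#' @rdname MultiChannelScene-class
#' @export
setMethod("nChannels", "MultiChannelScene", function(object)
  dim(object@pixels)[3L])

#' @rdname MultiChannelScene-class
#' @export
setMethod("nPlanes", "MultiChannelScene", function(object)
  dim(object@pixels)[4L])

#' @rdname MultiChannelScene-class
#' @export
setMethod("pixelSizeUm", "MultiChannelScene", function(object)
  object@pixelSizeUm)

setMethod("show", "MultiChannelScene", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("MultiChannelScene: %d x %d px, %d channel(s) [%s], %d z-plane(s)\n",
              d[1L], d[2L], d[3L],
              paste(object@channelRoles, collapse = ", "), d[4L]))
  if (!is.na(object@pixelSizeUm))
    cat(sprintf("  pixel size: %g um\n", object@pixelSizeUm))
  cat(sprintf("  intensity range: [%g, %g] AU\n",
              min(object@pixels), max(object@pixels)))
})

#' Extract one 2-D plane from a scene
#'
#' @param scene a [MultiChannelScene-class].
#' @param channel channel index, or \code{NULL} to select by \code{role}.
#' @param role channel role name (used when \code{channel} is \code{NULL});
#'   must identify exactly one channel.
#' @param z 1-based z-plane index.
#' @return numeric matrix \code{[y, x]}.
#' @export
getPlane <- function(scene, channel = NULL, role = NULL, z = 1L) {
  stopifnot(is(scene, "MultiChannelScene"))
  if (is.null(channel)) {
    if (is.null(role)) stop("supply either channel or role")
    channel <- which(scene@channelRoles == role)
    if (length(channel) != 1L)
      stop(sprintf("role '%s' matches %d channels", role, length(channel)))
  }
  d <- dim(scene@pixels)
  if (channel < 1 || channel > d[3L]) stop("channel index out of range")
  if (z < 1 || z > d[4L]) stop("z index out of range")
  scene@pixels[, , channel, z]
}

#' Construct a GroupCounts contingency table
#'
#' @param counts nonnegative integer matrix, groups in rows and outcome
#'   categories in columns, with dimnames.
#' @return a [GroupCounts-class] object.
#' @examples
#' gc <- GroupCounts(matrix(c(76, 3, 14, 94), 2,
#'   dimnames = list(c("vehicle", "1e-5 M"), c("MII", "abnormal"))))
#' deriveRates(gc)
#' @export
GroupCounts <- function(counts) {
  storage.mode(counts) <- "double"
  new("GroupCounts", counts = counts)
}

#' @rdname GroupCounts-class
#' @export
setMethod("groupNames", "GroupCounts", function(object)
  rownames(object@counts))

#' @rdname GroupCounts-class
#' @export
setMethod("categoryNames", "GroupCounts", function(object)
  colnames(object@counts))

#' @rdname GroupCounts-class
#' @export
setMethod("counts", "GroupCounts", function(object) object@counts)

setMethod("show", "GroupCounts", function(object) {
  cat(sprintf("GroupCounts: %d group(s) x %d categorie(s), N = %d\n",
              nrow(object@counts), ncol(object@counts), sum(object@counts)))
  print(object@counts)
})

setMethod("show", "SceneTruth", function(object) {
  cat(sprintf("SceneTruth <%s> (seed %d)\n", object@kind, object@seed))
  switch(object@kind,
    oocyte = cat(sprintf("  true cortex/center ratio: %g\n", object@trueRatio)),
    expansion_pair = cat(sprintf(
      "  areas: before %d px, after %d px (fold %.3f)\n",
      object@trueAreaPx[["before"]], object@trueAreaPx[["after"]],
      object@trueAreaPx[["after"]] / object@trueAreaPx[["before"]])),
    nucleus_field = {
      tab <- table(factor(object@nucleusTruth$class,
        levels = c("healthy", "apoptotic", "necrotic", "secondary")))
      cat(sprintf("  %d nuclei: %s\n", nrow(object@nucleusTruth),
          paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
    })
})

setMethod("show", "SegmentedOocyte", function(object) {
  cat(sprintf(
    "SegmentedOocyte: area %d px, eq. diameter %.1f px, center (%.1f, %.1f), plane %d\n",
    sum(object@mask), object@diameterPx,
    object@centerXY[1L], object@centerXY[2L], object@planeIndex))
})

setMethod("show", "MitoProfile", function(object) {
  cat(sprintf(
    "MitoProfile: center %.2f AU/px, cortex %.2f AU/px (center = inner %d%% of diameter)\n",
    object@centerMean, object@cortexMean,
    round(100 * object@centerFraction)))
  if (is.na(object@ratio))
    cat("  relative peripheral intensity: undefined (center mean is 0)\n")
  else
    cat(sprintf("  relative peripheral intensity: %.3f\n", object@ratio))
})

#' @rdname StatReport-class
#' @export
setMethod("pairwise", "StatReport", function(object) object@pairwise)

setMethod("show", "StatReport", function(object) {
  dfTxt <- paste(format(object@df, digits = 4), collapse = ", ")
  pTxt <- if (is.na(object@pValue)) "p undefined"
          else if (object@pValue < 0.001) "p < 0.001"
          else sprintf("p = %.3f", object@pValue)
  cat(sprintf("%s: statistic(%s) = %.4g, %s (alpha = %g)\n",
              object@testName, dfTxt, object@statistic, pTxt, object@alpha))
  if (nrow(object@pairwise)) {
    cat(sprintf("  %d pairwise comparison(s), %d significant:\n",
                nrow(object@pairwise), sum(object@pairwise$significant)))
    print(object@pairwise, digits = 4)
  }
})
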