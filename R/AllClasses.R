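#' @import methods
NULL

.validChannelRoles <- c("hoechst", "tunel", "ethd1", "mito", "brightfield")

#' MultiChannelScene: a multi-channel, optionally z-stacked fluorescence image
#'
#' The common image currency of the package. Pixels are stored as a 4-D
#' numeric array indexed \code{[y, x, channel, z]}; single-plane scenes have
#' \code{dim(pixels)[4] == 1}. Intensities are nonnegative arbitrary units
#' (AU) on an integer 16-bit grid, the convention of confocal acquisition.
#'
#' @slot pixels numeric array \code{[y, x, channel, z]}, intensities >= 0.
#' @slot channelRoles character vector, one role per channel, each one of
#'   \code{"hoechst"}, \code{"tunel"}, \code{"ethd1"}, \code{"mito"},
#'   \code{"brightfield"}.
#' @slot pixelSizeUm positive scalar or \code{NA_real_}; physical pixel size.
#'
#' @seealso [MultiChannelScene()], [getPlane()], [writeScene()]
#' @exportClass MultiChannelScene
setClass("MultiChannelScene",
  representation(
    pixels = "array",
    channelRoles = "character",
    pixelSizeUm = "numeric"
  ),
  prototype(pixelSizeUm = NA_real_)
)

setValidity("MultiChannelScene", function(object) {
  p <- object@pixels
  if (length(dim(p)) != 4L)
    return("pixels must be a 4-D array [y, x, channel, z]")
  if (any(p < 0))
    return("intensities must be nonnegative")
  nc <- dim(p)[3L]
  if (nc < 1L)
    return("at least one channel is required")
  if (length(object@channelRoles) != nc)
    return(sprintf("channelRoles has length %d but the scene has %d channels",
                   length(object@channelRoles), nc))
  bad <- setdiff(object@channelRoles, .validChannelRoles)
  if (length(bad))
    return(sprintf("unknown channel role(s): %s", paste(bad, collapse = ", ")))
  if (length(object@pixelSizeUm) != 1L ||
      (!is.na(object@pixelSizeUm) && object@pixelSizeUm <= 0))
    return("pixelSizeUm must be a positive scalar or NA")
  TRUE
})

#' SceneTruth: ground truth attached to a synthetic scene
#'
#' Records the known quantities of a generated scene so recovery by the
#' measurement stages can be tested. Exactly the fields relevant to the
#' scene kind are populated.
#'
#' @slot kind one of \code{"oocyte"}, \code{"expansion_pair"},
#'   \code{"nucleus_field"}.
#' @slot trueRatio true cortex/center per-pixel intensity ratio (oocyte
#'   scenes; length 0 otherwise).
#' @slot trueAreaPx realized foreground pixel areas, named \code{before} /
#'   \code{after} (expansion scenes; length 0 otherwise).
#' @slot nucleusTruth data.frame with columns \code{nucleus_id}, \code{x},
#'   \code{y}, \code{class} (nucleus fields; 0 rows otherwise). Classes are
#'   \code{healthy}, \code{apoptotic}, \code{necrotic}, \code{secondary}.
#' @slot seed integer seed the scene was generated with.
#'
#' @exportClass SceneTruth
setClass("SceneTruth",
  representation(
    kind = "character",
    trueRatio = "numeric",
    trueAreaPx = "numeric",
    nucleusTruth = "data.frame",
    seed = "integer"
  ),
  prototype(
    trueRatio = numeric(0),
    trueAreaPx = numeric(0),
    nucleusTruth = data.frame(
      nucleus_id = integer(0), x = numeric(0), y = numeric(0),
      class = character(0)
    )
  )
)

setValidity("SceneTruth", function(object) {
  kinds <- c("oocyte", "expansion_pair", "nucleus_field")
  if (length(object@kind) != 1L || !object@kind %in% kinds)
    return(sprintf("kind must be one of: %s", paste(kinds, collapse = ", ")))
  pop <- c(
    oocyte = length(object@trueRatio) == 1L &&
      length(object@trueAreaPx) == 0L && nrow(object@nucleusTruth) == 0L,
    expansion_pair = length(object@trueAreaPx) == 2L &&
      length(object@trueRatio) == 0L && nrow(object@nucleusTruth) == 0L,
    nucleus_field = length(object@trueRatio) == 0L &&
      length(object@trueAreaPx) == 0L
  )
  if (!pop[[object@kind]])
    return(sprintf("fields populated do not match kind '%s'", object@kind))
  if (object@kind == "oocyte" && object@trueRatio <= 0)
    return("trueRatio must be positive")
  if (object@kind == "expansion_pair" && any(object@trueAreaPx <= 0))
    return("trueAreaPx must be positive")
  if (object@kind == "nucleus_field") {
    cls <- c("healthy", "apoptotic", "necrotic", "secondary")
    if (!all(object@nucleusTruth$class %in% cls))
      return("nucleus classes must be healthy/apoptotic/necrotic/secondary")
  }
  TRUE
})

#' SegmentedOocyte: segmentation of a single oocyte on one optical plane
#'
#' @slot mask logical matrix, a single connected region with holes filled.
#' @slot centerXY numeric length-2 subpixel centroid \code{(x, y)}, 1-based.
#' @slot diameterPx equivalent circular diameter \code{2*sqrt(area/pi)}.
#' @slot planeIndex 1-based z index the mask was computed on.
#'
#' @exportClass SegmentedOocyte
setClass("SegmentedOocyte",
  representation(
    mask = "matrix",
    centerXY = "numeric",
    diameterPx = "numeric",
    planeIndex = "integer"
  )
)

setValidity("SegmentedOocyte", function(object) {
  if (!is.logical(object@mask)) return("mask must be logical")
  if (!any(object@mask)) return("mask is empty")
  if (length(object@centerXY) != 2L) return("centerXY must have length 2")
  if (object@diameterPx <= 0) return("diameterPx must be positive")
  cx <- round(object@centerXY[1L]); cy <- round(object@centerXY[2L])
  if (cx < 1 || cy < 1 || cy > nrow(object@mask) || cx > ncol(object@mask) ||
      !object@mask[cy, cx])
    return("center must lie inside the mask")
  TRUE
})

#' MitoProfile: cortex vs center intensity profile of one oocyte
#'
#' Holds the per-pixel mean fluorescence of the central disc (inner
#' \code{centerFraction} of the diameter) and the cortical annulus (the
#' remainder of the cell), and their ratio, the relative peripheral
#' intensity. The ratio is \code{NA} (flagged undefined) when the center
#' mean is zero.
#'
#' @slot centerMean mean intensity per pixel of the center region (AU).
#' @slot cortexMean mean intensity per pixel of the cortex annulus (AU).
#' @slot ratio relative peripheral intensity, \code{cortexMean/centerMean}.
#' @slot centerFraction fraction of the diameter assigned to the center
#'   (default 0.8, i.e. the cortex is the outer 10\% on each side).
#'
#' @exportClass MitoProfile
setClass("MitoProfile",
  representation(
    centerMean = "numeric",
    cortexMean = "numeric",
    ratio = "numeric",
    centerFraction = "numeric"
  )
)

setValidity("MitoProfile", function(object) {
  if (object@centerMean < 0 || object@cortexMean < 0)
    return("means must be nonnegative")
  if (object@centerFraction <= 0 || object@centerFraction >= 1)
    return("centerFraction must be in (0, 1)")
  if (object@centerMean > 0) {
    if (!isTRUE(all.equal(object@ratio,
                          object@cortexMean / object@centerMean)))
      return("ratio must equal cortexMean/centerMean")
  } else if (!is.na(object@ratio)) {
    return("ratio must be NA when centerMean is 0")
  }
  TRUE
})

#' GroupCounts: a group-by-category contingency table
#'
#' Wraps a nonnegative integer matrix with experimental groups as rows and
#' outcome categories as columns (e.g. meiotic status MII/abnormal, cleavage
#' category, blastocyst/no-blastocyst).
#'
#' @slot counts integer matrix with dimnames \code{list(group, category)}.
#'
#' @seealso [GroupCounts()], [readCounts()], [contingencyChiSquare()],
#'   [deriveRates()]
#' @exportClass GroupCounts
setClass("GroupCounts", representation(counts = "matrix"))

setValidity("GroupCounts", function(object) {
  m <- object@counts
  if (!is.numeric(m)) return("counts must be numeric")
  if (any(m < 0)) return("counts must be nonnegative")
  if (any(m != round(m))) return("counts must be integers")
  if (nrow(m) < 2L || ncol(m) < 2L)
    return("at least 2 groups and 2 categories are required")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    return("counts must carry group rownames and category colnames")
  if (anyDuplicated(rownames(m)) || anyDuplicated(colnames(m)))
    return("group and category labels must be unique")
  TRUE
})

#' StatReport: result of one statistical test with post hoc comparisons
#'
#' @slot testName e.g. \code{"Pearson chi-square"}, \code{"one-way ANOVA"},
#'   \code{"Kruskal-Wallis"}.
#' @slot statistic the test statistic (chi-square, F, or H).
#' @slot df degrees of freedom (length 1, or 2 for an F statistic).
#' @slot pValue the omnibus p-value.
#' @slot pairwise data.frame of post hoc comparisons with columns
#'   \code{group1}, \code{group2}, \code{statistic}, \code{raw_p},
#'   \code{adjusted_p}, \code{significant} (plus method-specific columns).
#' @slot alpha significance level used for the \code{significant} flags.
#' @slot details list of method-specific extras (expected counts, flags for
#'   low expected cells, adjustment method, ...).
#'
#' @exportClass StatReport
setClass("StatReport",
  representation(
    testName = "character",
    statistic = "numeric",
    df = "numeric",
    pValue = "numeric",
    pairwise = "data.frame",
    alpha = "numeric",
    details = "list"
  ),
  prototype(pairwise = data.frame(), alpha = 0.05, details = list())
)

setValidity("StatReport", function(object) {
  if (!is.na(object@pValue) &&
      (object@pValue < 0 || object@pValue > 1))
    return("pValue must lie in [0, 1]")
  pw <- object@pairwise
  if (nrow(pw)) {
    if (!all(c("group1", "group2", "raw_p", "adjusted_p") %in% names(pw)))
      return("pairwise must have group1/group2/raw_p/adjusted_p columns")
    ok <- stats::complete.cases(pw[, c("raw_p", "adjusted_p")])
    if (any(pw$adjusted_p[ok] < pw$raw_p[ok] - 1e-12))
      return("adjusted p-values must be >= raw p-values")
    if (any(pw$adjusted_p[ok] > 1 + 1e-12))
      return("adjusted p-values must be <= 1")
  }
  if (object@alpha <= 0 || object@alpha >= 1)
    return("alpha must lie in (0, 1)")
  TRUE
})
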