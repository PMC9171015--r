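#' @rdname MultiChannelScene-class
#' @param object a \code{MultiChannelScene}
#' @export
setGeneric("channelRoles", function(object) standardGeneric("channelRoles"))

#' @rdname MultiChannelScene-class
#' @export
setGeneric("scenePixels", function(object) standardGeneric("scenePixels"))

#' @rdname MultiChannelScene-class
#' @export
setGeneric("nChannels", function(object) standardGeneric("nChannels"))

#' @rdname MultiChannelScene-class
#' @export
setGeneric("nPlanes", function(object) standardGeneric("nPlanes"))

#' @rdname MultiChannelScene-class
#' @export
setGeneric("pixelSizeUm", function(object) standardGeneric("pixelSizeUm"))

#' @rdname GroupCounts-class
#' @param object a \code{GroupCounts}
#' @export
setGeneric("groupNames", function(object) standardGeneric("groupNames"))

#' @rdname GroupCounts-class
#' @export
setGeneric("categoryNames", function(object) standardGeneric("categoryNames"))

#' @rdname GroupCounts-class
#' @export
setGeneric("counts", function(object) standardGeneric("counts"))

#' @rdname StatReport-class
#' @param object a \code{StatReport}
#' @export
setGeneric("pairwise", function(object) standardGeneric("pairwise"))
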