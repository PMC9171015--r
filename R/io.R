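#' Write a scene as a multi-page 16-bit TIFF with a JSON sidecar
#'
#' Channels and z-planes are written as TIFF pages in z-major order (all
#' channels of plane 1, then plane 2, ...). The sidecar
#' \code{<path>.json} records the channel role map, the z count and the
#' pixel size, so [readScene()] can restore the scene exactly. Intensities
#' must sit on the integer 16-bit grid (as produced by the generators);
#' raw values are preserved, no normalization is applied.
#'
#' @param scene a [MultiChannelScene-class].
#' @param path output TIFF path; the sidecar is written next to it.
#' @return \code{path}, invisibly.
#' @export
writeScene <- function(scene, path) {
  stopifnot(is(scene, "MultiChannelScene"))
  p <- scene@pixels
  if (any(p != round(p)) || max(p) > 65535)
    stop("intensities must be integers in [0, 65535] to write 16-bit TIFF")
  d <- dim(p)
  pages <- vector("list", d[3L] * d[4L])
  i <- 0L
  for (z in seq_len(d[4L])) for (ch in seq_len(d[3L])) {
    i <- i + 1L
    pages[[i]] <- p[, , ch, z] / 65535
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  sidecar <- list(channel_roles = as.list(scene@channelRoles),
                  n_z = d[4L],
                  pixel_size_um = if (is.na(scene@pixelSizeUm)) NULL
                                  else scene@pixelSizeUm)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' Read a scene written by [writeScene()]
#'
#' The page count must be an exact multiple of the number of channel roles
#' declared in the sidecar (or supplied directly); orphan pages are an
#' error. Raw 16-bit values are restored exactly; no intensity
#' normalization is applied, so 8-bit and 16-bit inputs keep their native
#' scales.
#'
#' @param path TIFF path.
#' @param channelRoles optional character vector overriding the sidecar
#'   role map.
#' @return a [MultiChannelScene-class].
#' @export
readScene <- function(path, channelRoles = NULL) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  if (is.null(channelRoles)) {
    sidecarPath <- paste0(path, ".json")
    if (!file.exists(sidecarPath))
      stop(sprintf("no channel role map: sidecar %s missing and no ",
                   "channelRoles supplied", sidecarPath))
    sidecar <- jsonlite::read_json(sidecarPath)
    channelRoles <- unlist(sidecar$channel_roles)
    pixelSizeUm <- if (is.null(sidecar$pixel_size_um)) NA_real_
                   else as.numeric(sidecar$pixel_size_um)
  } else pixelSizeUm <- NA_real_

  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  nc <- length(channelRoles)
  if (length(pages) %% nc != 0L)
    stop(sprintf(
      "page count %d is not a multiple of the %d declared channel(s): %d orphan page(s)",
      length(pages), nc, length(pages) %% nc))
  dims <- unique(lapply(pages, dim))
  if (length(dims) != 1L) stop("inconsistent page shapes in TIFF")
  nz <- length(pages) %/% nc
  d <- dims[[1L]]
  pixels <- array(0, dim = c(d[1L], d[2L], nc, nz))
  i <- 0L
  for (z in seq_len(nz)) for (ch in seq_len(nc)) {
    i <- i + 1L
    pixels[, , ch, z] <- round(pages[[i]] * 65535)
  }
  new("MultiChannelScene", pixels = pixels, channelRoles = channelRoles,
      pixelSizeUm = pixelSizeUm)
}

#' Read a long-format contingency CSV into GroupCounts
#'
#' Expected header: \code{group,category,count}. Duplicated
#' (group, category) rows are summed with a warning; negative or
#' non-numeric counts raise an error naming the offending row.
#'
#' @param path CSV path.
#' @return a [GroupCounts-class]; groups and categories keep their order
#'   of first appearance.
#' @export
readCounts <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(tab) == 0L) stop(sprintf("empty counts file: %s", path))
  need <- c("group", "category", "count")
  if (!all(need %in% names(tab)))
    stop(sprintf("counts CSV must have columns %s",
                 paste(need, collapse = ", ")))
  cnt <- suppressWarnings(as.numeric(tab$count))
  bad <- which(is.na(cnt))
  if (length(bad))
    stop(sprintf("non-numeric count at row %s", paste(bad, collapse = ", ")))
  bad <- which(cnt < 0)
  if (length(bad))
    stop(sprintf("negative count at row %s", paste(bad, collapse = ", ")))
  key <- paste(tab$group, tab$category, sep = "\r")
  if (anyDuplicated(key))
    warning("duplicated (group, category) rows summed")
  groups <- unique(tab$group)
  cats <- unique(tab$category)
  m <- matrix(0, length(groups), length(cats),
              dimnames = list(groups, cats))
  for (i in seq_len(nrow(tab)))
    m[tab$group[i], tab$category[i]] <- m[tab$group[i], tab$category[i]] +
      cnt[i]
  GroupCounts(m)
}

#' Write GroupCounts as a long-format CSV
#'
#' Inverse of [readCounts()]: the written file round-trips losslessly.
#'
#' @param gc a [GroupCounts-class].
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeCounts <- function(gc, path) {
  stopifnot(is(gc, "GroupCounts"))
  m <- counts(gc)
  long <- expand.grid(category = colnames(m), group = rownames(m),
                      stringsAsFactors = FALSE)
  long <- long[, c("group", "category")]
  long$count <- m[cbind(long$group, long$category)]
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a long-format grouped-values CSV
#'
#' Expected header: \code{group,replicate,value} (replicate optional).
#' Non-numeric values raise an error naming the row.
#'
#' @param path CSV path.
#' @return data.frame with columns \code{group}, \code{replicate},
#'   \code{value}.
#' @export
readValues <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(tab) == 0L) stop(sprintf("empty values file: %s", path))
  if (!all(c("group", "value") %in% names(tab)))
    stop("values CSV must have columns group and value")
  v <- suppressWarnings(as.numeric(tab$value))
  bad <- which(is.na(v) & !is.na(tab$value))
  if (length(bad))
    stop(sprintf("non-numeric value at row %s", paste(bad, collapse = ", ")))
  if (is.null(tab$replicate)) tab$replicate <- seq_len(nrow(tab))
  data.frame(group = tab$group, replicate = tab$replicate, value = v,
             stringsAsFactors = FALSE)
}

#' Convert a StatReport to a plain list (for JSON serialization)
#'
#' @param report a [StatReport-class].
#' @return a nested list mirroring the report slots.
#' @export
statReportToList <- function(report) {
  stopifnot(is(report, "StatReport"))
  list(test = report@testName,
       statistic = report@statistic,
       df = report@df,
       p_value = report@pValue,
       alpha = report@alpha,
       pairwise = report@pairwise,
       details = report@details[setdiff(names(report@details), "expected")])
}
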