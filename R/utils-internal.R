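# internal helpers shared across modules

# Evaluate expr with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards. All generator determinism flows through this.
withSeed <- function(seed, expr) {
  seed <- as.integer(seed)
  if (is.na(seed)) stop("seed must be an integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Derive a deterministic 31-bit sub-seed from a root seed and a stream tag,
# so different scenes within one run use independent substreams.
subSeed <- function(seed, stream) {
  (as.numeric(seed) * 48271 + stream * 16807) %% 2147483647
}

# Squared distance of every pixel to (cx, cy), 1-based pixel centers.
distSqGrid <- function(ny, nx, cx, cy) {
  dx2 <- (seq_len(nx) - cx)^2
  dy2 <- (seq_len(ny) - cy)^2
  outer(dy2, dx2, `+`)
}

# Otsu threshold on the raw intensity scale. EBImage::otsu works on [0, 1],
# so the plane is rescaled by its maximum. A constant plane has no
# foreground/background split.
otsuThreshold <- function(plane) {
  rng <- range(plane)
  if (!is.finite(diff(rng)) || diff(rng) == 0)
    stop("threshold undefined: image is constant")
  img <- EBImage::Image((plane - rng[1L]) / diff(rng))
  EBImage::otsu(img, range = c(0, 1)) * diff(rng) + rng[1L]
}

# Largest connected foreground component of a logical matrix, holes filled.
largestComponent <- function(binary, fill = TRUE) {
  lab <- EBImage::bwlabel(EBImage::Image(binary * 1))
  n <- max(lab)
  if (n == 0) return(matrix(FALSE, nrow(binary), ncol(binary)))
  sizes <- tabulate(as.integer(lab[lab > 0]), nbins = n)
  keep <- which.max(sizes)
  m <- matrix(as.integer(lab) == keep, nrow(binary), ncol(binary))
  if (fill) {
    m <- matrix(as.logical(EBImage::fillHull(EBImage::Image(m * 1)) > 0),
                nrow(binary), ncol(binary))
  }
  m
}

# Round half away from zero (the convention of the printed tables).
roundHalfUp <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Quantize intensities to the nonnegative 16-bit integer grid.
quantize16 <- function(x) {
  pmin(pmax(round(x), 0), 65535)
}

stopifnotScalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x))
    stop(sprintf("%s must be a single number", name))
  if (positive && x <= 0) stop(sprintf("%s must be positive", name))
  if (nonneg && x < 0) stop(sprintf("%s must be nonnegative", name))
  invisible(x)
}
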