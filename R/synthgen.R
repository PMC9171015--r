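#' Generate a synthetic oocyte scene with a known cortex/center ratio
#'
#' Renders a centered oocyte disc in a \code{mito} channel. The cell is
#' modeled as a sphere: each z-plane is a disc whose radius is the spherical
#' cross-section at that depth, so the equatorial (largest) section sits at
#' the middle of the stack. Within each plane the cortical annulus (the
#' outer \code{1 - centerFraction} of the diameter) is rendered at
#' \code{trueRatio} times the per-pixel intensity of the central disc, so
#' the relative peripheral intensity of the noiseless scene equals
#' \code{trueRatio} up to pixel discretization.
#'
#' @param radiusPx equatorial oocyte radius in pixels (>= 20 so both
#'   compartments hold at least a few pixel rings).
#' @param trueRatio true cortex/center per-pixel mean intensity ratio. The
#'   default 1.4 is a typical vehicle-group value for in vitro matured
#'   bovine oocytes.
#' @param noiseSd Gaussian pixel noise SD in AU (0 = noiseless).
#' @param nZ number of z-planes (1 = single plane).
#' @param seed integer seed; identical arguments and seed give bit-identical
#'   scenes.
#' @param centerFraction fraction of the diameter belonging to the center
#'   compartment (default 0.8).
#' @param baseIntensity per-pixel intensity of the center compartment, AU.
#'
#' @return \code{list(scene, truth)}: a [MultiChannelScene-class] and the
#'   matching [SceneTruth-class].
#' @examples
#' oo <- makeOocyteScene(radiusPx = 60, trueRatio = 3, seed = 1)
#' oo$truth
#' @export
makeOocyteScene <- function(radiusPx, trueRatio = 1.4, noiseSd = 0,
                            nZ = 1L, seed = 1L, centerFraction = 0.8,
                            baseIntensity = 1000) {
  stopifnotScalar(radiusPx, "radiusPx", positive = TRUE)
  stopifnotScalar(trueRatio, "trueRatio", positive = TRUE)
  stopifnotScalar(noiseSd, "noiseSd", nonneg = TRUE)
  if (radiusPx < 20)
    stop("radiusPx must be >= 20: the cortex annulus would be too thin ",
         "to hold both compartments")
  nZ <- as.integer(nZ)
  if (nZ < 1L) stop("nZ must be a positive integer")

  pad <- max(10L, ceiling(radiusPx * 0.1))
  side <- 2L * (as.integer(ceiling(radiusPx)) + pad) + 1L
  cx <- cy <- (side + 1) / 2

  # spherical cross-sections; offsets span +/- 0.7 R so every plane keeps a
  # segmentable disc and the middle plane is strictly the largest
  offsets <- if (nZ == 1L) 0 else seq(-0.7, 0.7, length.out = nZ) * radiusPx
  d2 <- distSqGrid(side, side, cx, cy)

  pixels <- array(0, dim = c(side, side, 1L, nZ))
  withSeed(seed, {
    for (k in seq_len(nZ)) {
      rz <- radiusPx * sqrt(pmax(0, 1 - (offsets[k] / radiusPx)^2))
      inner <- d2 <= (centerFraction * rz)^2
      annulus <- d2 <= rz^2 & !inner
      plane <- matrix(0, side, side)
      plane[inner] <- baseIntensity
      plane[annulus] <- baseIntensity * trueRatio
      if (noiseSd > 0)
        plane <- plane + matrix(stats::rnorm(side * side, 0, noiseSd),
                                side, side)
      pixels[, , 1L, k] <- quantize16(plane)
    }
  })

  scene <- new("MultiChannelScene", pixels = pixels, channelRoles = "mito",
               pixelSizeUm = NA_real_)
  truth <- new("SceneTruth", kind = "oocyte", trueRatio = trueRatio,
               seed = as.integer(seed))
  list(scene = scene, truth = truth)
}

# Rasterize a star-shaped blob of target pixel area. The radius is a
# low-order harmonic perturbation of a circle; the base radius is rescaled
# until the realized pixel count is within `tol` of the target.
.rasterBlob <- function(targetArea, irregularity, side, cx, cy,
                       harmonics, tol = 0.005) {
  yy <- matrix(seq_len(side), side, side)
  xx <- matrix(seq_len(side), side, side, byrow = TRUE)
  dy <- yy - cy; dx <- xx - cx
  theta <- atan2(dy, dx)
  dist <- sqrt(dx^2 + dy^2)
  shape <- rep(1, length(theta))
  if (irregularity > 0) {
    for (j in seq_along(harmonics$k)) {
      shape <- shape + irregularity * harmonics$a[j] *
        cos(harmonics$k[j] * theta + harmonics$phi[j])
    }
    shape <- pmax(shape, 0.2)
  }
  r0 <- sqrt(targetArea / (pi * mean(shape^2)))
  for (i in 1:12) {
    mask <- dist <= r0 * shape
    area <- sum(mask)
    if (area == 0) { r0 <- r0 * 1.5; next }
    if (abs(area - targetArea) / targetArea <= tol) break
    r0 <- r0 * sqrt(targetArea / area)
  }
  matrix(mask, side, side)
}

#' Generate a before/after COC expansion scene pair
#'
#' Two single-channel brightfield-like scenes containing one foreground blob
#' each, with pixel areas \code{areaBeforePx} and
#' \code{round(fold * areaBeforePx)} (each realized within 1\% after
#' rasterization). \code{irregularity} in \code{[0, 1]} perturbs the blob
#' outline with low-order harmonics (0 = perfect disc).
#'
#' @param areaBeforePx projected surface area before maturation, pixels.
#' @param fold true fold-increase of projected area (after/before).
#' @param irregularity outline irregularity in \code{[0, 1]}.
#' @param seed integer seed.
#' @param frameSide optional frame side length; defaults to a frame that
#'   comfortably holds the larger blob. A blob that cannot fit the frame is
#'   a parameter error.
#'
#' @return \code{list(before, after, truth)} with two
#'   [MultiChannelScene-class] objects and a [SceneTruth-class] whose
#'   \code{trueAreaPx} holds the realized pixel areas.
#' @examples
#' ep <- makeExpansionPair(areaBeforePx = 13231, fold = 2.877, seed = 1)
#' ep$truth
#' @export
makeExpansionPair <- function(areaBeforePx, fold, irregularity = 0,
                              seed = 1L, frameSide = NULL) {
  stopifnotScalar(areaBeforePx, "areaBeforePx", positive = TRUE)
  stopifnotScalar(fold, "fold", positive = TRUE)
  stopifnotScalar(irregularity, "irregularity", nonneg = TRUE)
  if (irregularity > 1) stop("irregularity must lie in [0, 1]")

  areaAfter <- round(fold * areaBeforePx)
  rMax <- sqrt(max(areaBeforePx, areaAfter) / pi) * (1 + 0.45 * irregularity)
  need <- 2L * ceiling(rMax) + 11L
  if (is.null(frameSide)) frameSide <- need
  frameSide <- as.integer(frameSide)
  if (frameSide < need)
    stop(sprintf(
      "requested area does not fit the frame: need >= %d px side, got %d",
      need, frameSide))
  cx <- cy <- (frameSide + 1) / 2

  fg <- 30000; bg <- 1000
  res <- withSeed(seed, {
    harm <- list(k = 2:5, a = stats::runif(4, -0.12, 0.12),
                 phi = stats::runif(4, 0, 2 * pi))
    mb <- .rasterBlob(areaBeforePx, irregularity, frameSide, cx, cy, harm)
    ma <- .rasterBlob(areaAfter, irregularity, frameSide, cx, cy, harm)
    list(mb = mb, ma = ma)
  })

  toScene <- function(mask) {
    plane <- matrix(bg, frameSide, frameSide)
    plane[mask] <- fg
    MultiChannelScene(quantize16(plane), "brightfield")
  }
  truth <- new("SceneTruth", kind = "expansion_pair",
               trueAreaPx = c(before = sum(res$mb), after = sum(res$ma)),
               seed = as.integer(seed))
  list(before = toScene(res$mb), after = toScene(res$ma), truth = truth)
}

#' Generate a cumulus nucleus field with Hoechst/TUNEL/EthD1 channels
#'
#' Renders \code{nTotal} nuclei as 2-D Gaussian spots (truncated at 3 sigma)
#' in the Hoechst channel. Nuclei of class \code{apoptotic} (TUNEL-only) and
#' \code{secondary} (double positive) are also lit in the TUNEL channel;
#' \code{necrotic} (EthD1-only) and \code{secondary} nuclei in the EthD1
#' channel. Spot centers honor \code{minSepPx} unless it is 0, the
#' touching-nuclei stress case for watershed splitting.
#'
#' @param nTotal total number of Hoechst-positive nuclei.
#' @param nTunelOnly,nEthd1Only,nDouble counts of apoptotic (TUNEL-only),
#'   necrotic-only (EthD1-only) and secondary (double positive) nuclei;
#'   their sum may not exceed \code{nTotal}.
#' @param frameSide frame side length in pixels.
#' @param spotSigmaPx Gaussian sigma of a rendered nucleus, pixels.
#' @param minSepPx minimum center-to-center separation (0 allows overlap).
#' @param bgGradient add a linear background gradient across x (makes the
#'   background-subtraction step non-trivial).
#' @param noiseSd Gaussian pixel noise SD in AU. The spot peak amplitude is
#'   \code{peak}, so the scene SNR is \code{peak / noiseSd}.
#' @param seed integer seed.
#' @param centers optional \code{nTotal x 2} matrix of (x, y) spot centers,
#'   overriding random placement (used to construct specific geometries).
#' @param bgLevel constant background level, AU.
#' @param peak spot peak amplitude above background, AU.
#'
#' @return \code{list(scene, truth)}: a 3-channel [MultiChannelScene-class]
#'   (hoechst, tunel, ethd1) and a [SceneTruth-class] whose
#'   \code{nucleusTruth} lists each nucleus center and class.
#' @examples
#' nf <- makeCocNucleusScene(nTotal = 50, nTunelOnly = 3, nDouble = 2,
#'                           frameSide = 256, seed = 1)
#' nf$truth
#' @export
makeCocNucleusScene <- function(nTotal, nTunelOnly = 0L, nEthd1Only = 0L,
                                nDouble = 0L, frameSide = 512L,
                                spotSigmaPx = 3, minSepPx = 4 * spotSigmaPx,
                                bgGradient = FALSE, noiseSd = 0, seed = 1L,
                                centers = NULL, bgLevel = 2000, peak = 10000) {
  nTotal <- as.integer(nTotal)
  nTunelOnly <- as.integer(nTunelOnly)
  nEthd1Only <- as.integer(nEthd1Only)
  nDouble <- as.integer(nDouble)
  if (any(c(nTotal, nTunelOnly, nEthd1Only, nDouble) < 0L))
    stop("nucleus counts must be nonnegative")
  if (nTunelOnly + nEthd1Only + nDouble > nTotal)
    stop("nTunelOnly + nEthd1Only + nDouble may not exceed nTotal")
  stopifnotScalar(spotSigmaPx, "spotSigmaPx", positive = TRUE)
  stopifnotScalar(minSepPx, "minSepPx", nonneg = TRUE)
  stopifnotScalar(noiseSd, "noiseSd", nonneg = TRUE)
  frameSide <- as.integer(frameSide)

  margin <- ceiling(3 * spotSigmaPx) + 2
  if (frameSide <= 2 * margin) stop("frameSide too small for the spot size")

  res <- withSeed(seed, {
    if (is.null(centers)) {
      centers <- matrix(NA_real_, nTotal, 2L)
      placed <- 0L
      attempts <- 0L
      maxAttempts <- 5000L * max(nTotal, 1L)
      while (placed < nTotal) {
        attempts <- attempts + 1L
        if (attempts > maxAttempts)
          stop(sprintf(
            "cannot place %d spots at min separation %g in a %d px frame",
            nTotal, minSepPx, frameSide))
        cand <- stats::runif(2, margin + 1, frameSide - margin)
        if (placed > 0L && minSepPx > 0) {
          dd <- sqrt((centers[seq_len(placed), 1L] - cand[1L])^2 +
                     (centers[seq_len(placed), 2L] - cand[2L])^2)
          if (any(dd < minSepPx)) next
        }
        placed <- placed + 1L
        centers[placed, ] <- cand
      }
    } else {
      centers <- as.matrix(centers)
      if (nrow(centers) != nTotal || ncol(centers) != 2L)
        stop("centers must be an nTotal x 2 matrix of (x, y)")
    }
    classes <- rep("healthy", nTotal)
    if (nTunelOnly + nEthd1Only + nDouble > 0L) {
      pick <- sample.int(nTotal, nTunelOnly + nEthd1Only + nDouble)
      classes[pick] <- rep(c("apoptotic", "necrotic", "secondary"),
                           c(nTunelOnly, nEthd1Only, nDouble))
    }
    noise <- if (noiseSd > 0)
      array(stats::rnorm(frameSide * frameSide * 3, 0, noiseSd),
            dim = c(frameSide, frameSide, 3L)) else NULL
    list(centers = centers, classes = classes, noise = noise)
  })
  centers <- res$centers; classes <- res$classes

  renderSpots <- function(which) {
    plane <- matrix(0, frameSide, frameSide)
    r <- ceiling(3 * spotSigmaPx)
    for (i in which) {
      cx <- centers[i, 1L]; cy <- centers[i, 2L]
      xs <- max(1L, floor(cx - r)):min(frameSide, ceiling(cx + r))
      ys <- max(1L, floor(cy - r)):min(frameSide, ceiling(cy + r))
      d2 <- outer((ys - cy)^2, (xs - cx)^2, `+`)
      spot <- peak * exp(-d2 / (2 * spotSigmaPx^2))
      spot[d2 > (3 * spotSigmaPx)^2] <- 0   # truncate at 3 sigma
      plane[ys, xs] <- pmax(plane[ys, xs], spot)
    }
    plane
  }

  bg <- matrix(bgLevel, frameSide, frameSide)
  if (bgGradient) {
    ramp <- matrix(seq(0, 0.5 * bgLevel, length.out = frameSide),
                   frameSide, frameSide, byrow = TRUE)
    bg <- bg + ramp
  }

  hoechst <- bg + renderSpots(seq_len(nTotal))
  tunel <- bg + renderSpots(which(classes %in% c("apoptotic", "secondary")))
  ethd1 <- bg + renderSpots(which(classes %in% c("necrotic", "secondary")))

  pixels <- array(0, dim = c(frameSide, frameSide, 3L, 1L))
  chans <- list(hoechst, tunel, ethd1)
  for (c in 1:3) {
    plane <- chans[[c]]
    if (!is.null(res$noise)) plane <- plane + res$noise[, , c]
    pixels[, , c, 1L] <- quantize16(plane)
  }

  scene <- new("MultiChannelScene", pixels = pixels,
               channelRoles = c("hoechst", "tunel", "ethd1"),
               pixelSizeUm = NA_real_)
  truth <- new("SceneTruth", kind = "nucleus_field",
               nucleusTruth = data.frame(
                 nucleus_id = seq_len(nTotal),
                 x = centers[, 1L], y = centers[, 2L],
                 class = classes, stringsAsFactors = FALSE),
               seed = as.integer(seed))
  list(scene = scene, truth = truth)
}

#' Simulate multinomial experiment outcome counts
#'
#' Draws one multinomial outcome row per experimental group, emulating the
#' structure of nuclear-maturation / cleavage / blastocyst contingency
#' tables.
#'
#' @param categoryProbs named list, one probability vector per group; all
#'   vectors must share category names and sum to 1 (within 1e-9).
#' @param nPerGroup integer vector of group sizes (recycled to the number
#'   of groups).
#' @param seed integer seed.
#' @return a [GroupCounts-class] with one row per group.
#' @examples
#' simulateExperimentCounts(
#'   list(vehicle = c(MII = 0.84, abnormal = 0.16),
#'        high = c(MII = 0.03, abnormal = 0.97)),
#'   nPerGroup = c(90, 97), seed = 1)
#' @export
simulateExperimentCounts <- function(categoryProbs, nPerGroup, seed = 1L) {
  if (!is.list(categoryProbs) || is.null(names(categoryProbs)))
    stop("categoryProbs must be a named list of probability vectors")
  cats <- names(categoryProbs[[1L]])
  if (is.null(cats)) stop("probability vectors must have category names")
  for (g in names(categoryProbs)) {
    p <- categoryProbs[[g]]
    if (!identical(names(p), cats))
      stop("all groups must share the same category names")
    if (any(p < 0)) stop("negative probabilities are not allowed")
    if (abs(sum(p) - 1) > 1e-9)
      stop(sprintf("probabilities for group '%s' sum to %g, not 1", g, sum(p)))
  }
  nPerGroup <- rep_len(as.integer(nPerGroup), length(categoryProbs))
  m <- withSeed(seed, {
    t(vapply(seq_along(categoryProbs), function(i)
      as.numeric(stats::rmultinom(1L, nPerGroup[i], categoryProbs[[i]])),
      numeric(length(cats))))
  })
  dimnames(m) <- list(names(categoryProbs), cats)
  GroupCounts(m)
}

#' Steroid analytes quantifiable in spent maturation medium
#'
#' The panel of steroid hormones detectable above the limit of detection in
#' conditioned bovine IVM medium.
#' @export
steroidPanel <- function() {
  c("11-deoxycorticosterone", "pregnenolone", "progesterone",
    "testosterone", "estrone", "17b-estradiol")
}

#' Default steroid generator settings (vehicle vs high-dose DES)
#'
#' Mean and SD of pregnenolone and progesterone concentrations (ng/ml) in
#' spent maturation medium for the vehicle (0.01\% DMSO) group and the
#' 1e-5 M DES group, the effect sizes a positive screen should detect.
#' @return list with matrices \code{means} and \code{sds}
#'   (analyte x group, ng/ml).
#' @export
defaultSteroidSettings <- function() {
  groups <- c("vehicle", "1e-5 M")
  means <- matrix(c(2.79, 7.30,
                    6.40, 11.20), 2, 2, byrow = TRUE,
                  dimnames = list(c("pregnenolone", "progesterone"), groups))
  sds <- matrix(c(0.28, 0.89,
                  0.47, 0.86), 2, 2, byrow = TRUE,
                dimnames = list(c("pregnenolone", "progesterone"), groups))
  list(means = means, sds = sds)
}

#' Simulate a replicate-level steroid concentration table
#'
#' Concentrations are drawn per (analyte, group) from a normal distribution
#' truncated at zero (concentrations cannot be negative).
#'
#' @param groupMeans analyte x group matrix of mean concentrations (ng/ml),
#'   with dimnames; analytes must belong to [steroidPanel()].
#' @param groupSds matrix of SDs, same shape as \code{groupMeans}.
#' @param nReps biological replicates per group (>= 2).
#' @param seed integer seed.
#' @return data.frame with columns \code{group}, \code{replicate},
#'   \code{analyte}, \code{concentration}.
#' @examples
#' head(simulateSteroidTable(seed = 7))
#' @export
simulateSteroidTable <- function(groupMeans = defaultSteroidSettings()$means,
                                 groupSds = defaultSteroidSettings()$sds,
                                 nReps = 3L, seed = 1L) {
  if (!is.matrix(groupMeans) || !is.matrix(groupSds) ||
      !identical(dim(groupMeans), dim(groupSds)))
    stop("groupMeans and groupSds must be matrices of identical shape")
  if (is.null(rownames(groupMeans)) || is.null(colnames(groupMeans)))
    stop("groupMeans must have analyte rownames and group colnames")
  unknown <- setdiff(rownames(groupMeans), steroidPanel())
  if (length(unknown))
    stop(sprintf("unknown analyte(s): %s", paste(unknown, collapse = ", ")))
  if (any(groupSds < 0)) stop("SDs must be nonnegative")
  if (any(groupMeans < 0)) stop("means must be nonnegative")
  nReps <- as.integer(nReps)
  if (nReps < 2L) stop("nReps must be >= 2")

  rtnorm <- function(n, mean, sd) {
    if (sd == 0) return(rep(mean, n))
    out <- stats::rnorm(n, mean, sd)
    while (any(out < 0)) {
      bad <- out < 0
      out[bad] <- stats::rnorm(sum(bad), mean, sd)
    }
    out
  }
  withSeed(seed, {
    rows <- expand.grid(replicate = seq_len(nReps),
                        analyte = rownames(groupMeans),
                        group = colnames(groupMeans),
                        stringsAsFactors = FALSE)
    rows$concentration <- NA_real_
    for (a in rownames(groupMeans)) for (g in colnames(groupMeans)) {
      sel <- rows$analyte == a & rows$group == g
      rows$concentration[sel] <- rtnorm(nReps, groupMeans[a, g],
                                        groupSds[a, g])
    }
    rows[, c("group", "replicate", "analyte", "concentration")]
  })
}
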