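#' Construct a Micrograph
#'
#' @param image numeric intensity matrix (any scale; dark = stained for
#'   DAB-style material).
#' @param aoi logical area-of-interest mask of equal shape; defaults to the
#'   whole raster.
#' @param pixelArea physical area per pixel.
#' @param animalId,region,side,id labels.
#' @return A [Micrograph-class] object.
#' @export
micrograph <- function(image, aoi = NULL, pixelArea = 1,
                       animalId = "NA", region = "DCN",
                       side = "ipsilateral", id = "mg1") {
  if (is.null(aoi)) aoi <- matrix(TRUE, nrow(image), ncol(image))
  new("Micrograph", image = image, aoi = aoi, pixelArea = pixelArea,
      animalId = as.character(animalId), region = region, side = side,
      id = as.character(id))
}

#' Convert a raster to single-channel grayscale
#'
#' Identity for single-channel input; Rec. 709 luminance weighting
#' (0.2126 R + 0.7152 G + 0.0722 B) for 3-channel input.
#'
#' @param x numeric matrix (1 channel) or H x W x 3 array.
#' @return numeric matrix.
#' @export
toGrayscale <- function(x) {
  if (is.matrix(x)) return(x)
  if (is.array(x) && length(dim(x)) == 3L && dim(x)[3] == 3L)
    return(0.2126 * x[, , 1] + 0.7152 * x[, , 2] + 0.0722 * x[, , 3])
  stop("unsupported channel count: expected a matrix or an H x W x 3 array")
}

## Exact Otsu on the empirical AOI intensities (bins = the observed values):
## maximize between-class variance over every split between distinct values.
## Midpoint thresholds make the mask equivariant under positive affine
## rescaling.
.otsuThreshold <- function(v) {
  s <- sort(v)
  n <- length(s)
  if (s[n] <= s[1])
    stop("image is constant within the AOI; Otsu is undefined - ",
         "use method 'fixed' or 'percentile'")
  i <- seq_len(n - 1L)
  csum <- cumsum(s)
  w0 <- i / n
  mu0 <- csum[i] / i
  mu1 <- (csum[n] - csum[i]) / (n - i)
  sigmaB <- w0 * (1 - w0) * (mu0 - mu1)^2
  sigmaB[s[i] == s[i + 1L]] <- -Inf   # splits only between distinct values
  istar <- which.max(sigmaB)
  (s[istar] + s[istar + 1L]) / 2
}

#' Threshold a micrograph within its AOI
#'
#' Computes an intensity threshold from AOI pixels only, so the per-image
#' adaptation mirrors per-micrograph visual adjustment while remaining
#' reproducible, then marks the dark (stained) side: mask = intensity < t.
#'
#' @param mg a [Micrograph-class] object.
#' @param method "otsu" (default), "percentile" or "fixed".
#' @param q stained-fraction quantile for method "percentile".
#' @param t threshold for method "fixed".
#' @return list with `mask` (logical matrix over the full raster, TRUE where
#'   stained) and `threshold` (the value used, for audit).
#' @export
thresholdImage <- function(mg, method = c("otsu", "percentile", "fixed"),
                           q = 0.1, t = NULL) {
  stopifnot(is(mg, "Micrograph"))
  method <- match.arg(method)
  v <- mg@image[mg@aoi]
  thr <- switch(method,
    otsu = .otsuThreshold(v),
    percentile = unname(stats::quantile(v, q)),
    fixed = {
      if (is.null(t)) stop("method 'fixed' requires a threshold t")
      t
    })
  list(mask = mg@image < thr, threshold = thr)
}

#' 8-connected component labeling
#'
#' Labels connected sets of TRUE pixels under 8-connectivity (edge- and
#' corner-adjacent pixels connect) by iterative minimum-label propagation.
#'
#' @param mask logical matrix.
#' @return integer matrix: 0 outside the mask, components numbered 1..K in
#'   order of first (column-major) appearance.
#' @export
labelComponents <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(Inf, nr, nc)
  lab[mask] <- which(mask)
  shifts <- list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1),
                 c(0, 1), c(1, -1), c(1, 0), c(1, 1))
  repeat {
    nb <- lab
    for (s in shifts) {
      sh <- matrix(Inf, nr, nc)
      r <- s[1]; c <- s[2]
      srcR <- seq_len(nr) - r; srcC <- seq_len(nc) - c
      okR <- srcR >= 1 & srcR <= nr; okC <- srcC >= 1 & srcC <= nc
      sh[okR, okC] <- lab[srcR[okR], srcC[okC]]
      nb <- pmin(nb, sh)
    }
    nb[!mask] <- Inf
    if (identical(nb, lab)) break
    lab <- nb
  }
  out <- matrix(0L, nr, nc)
  if (any(mask)) {
    vals <- lab[mask]
    out[mask] <- match(vals, sort(unique(vals)))
  }
  out
}

#' Particle analysis within an AOI
#'
#' Connected components (8-connectivity) of the stained mask are intersected
#' with the AOI; components touching the raster border (section edges,
#' border-hugging blemishes) and components contributing fewer than
#' `minSize` pixels inside the AOI are excluded. Stained area is the
#' surviving pixel count times `pixelArea`; percent area is relative to the
#' AOI area.
#'
#' @param mask logical stained mask (full raster), e.g. from
#'   [thresholdImage()].
#' @param aoiMask logical AOI mask of equal shape.
#' @param pixelArea physical area per pixel.
#' @param minSize minimum within-AOI component size in pixels (default 4).
#' @param excludeBorder drop components touching the raster border.
#' @param thresholdUsed threshold recorded on the result, for audit.
#' @return A [ParticleStats-class] object.
#' @export
particleAnalysis <- function(mask, aoiMask, pixelArea = 1, minSize = 4,
                             excludeBorder = TRUE, thresholdUsed = NA_real_) {
  stopifnot(identical(dim(mask), dim(aoiMask)))
  if (!any(aoiMask)) stop("empty AOI")
  lab <- labelComponents(mask)
  keep <- seq_len(max(lab))
  if (excludeBorder && length(keep)) {
    border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
    keep <- setdiff(keep, border)
  }
  inAoiSizes <- if (length(keep)) {
    sel <- lab != 0L & aoiMask & lab %in% keep
    tab <- tabulate(lab[sel], nbins = max(lab))
    tab[keep]
  } else integer(0)
  surviving <- keep[inAoiSizes >= minSize]
  px <- sum(inAoiSizes[inAoiSizes >= minSize])
  aoiPx <- sum(aoiMask)
  new("ParticleStats",
      nParticles = length(surviving),
      stainedArea = px * pixelArea,
      aoiArea = aoiPx * pixelArea,
      percentArea = 100 * px / aoiPx,
      thresholdUsed = thresholdUsed)
}

#' Threshold and quantify one micrograph
#'
#' @param mg a [Micrograph-class] object.
#' @param method,q,t see [thresholdImage()].
#' @param minSize,excludeBorder see [particleAnalysis()].
#' @return A [ParticleStats-class] object.
#' @export
quantifyMicrograph <- function(mg, method = "otsu", q = 0.1, t = NULL,
                               minSize = 4, excludeBorder = TRUE) {
  th <- thresholdImage(mg, method = method, q = q, t = t)
  particleAnalysis(th$mask, mg@aoi, pixelArea = mg@pixelArea,
                   minSize = minSize, excludeBorder = excludeBorder,
                   thresholdUsed = th$threshold)
}

#' Quantify a labelled set of micrographs
#'
#' One row of particle statistics per micrograph, plus per-animal means of
#' percent area by animal x region x side (replicate sections averaged).
#' Micrograph ids must be unique.
#'
#' @param micrographs list of [Micrograph-class] objects.
#' @param method,q,t,minSize,excludeBorder quantification settings, see
#'   [quantifyMicrograph()].
#' @return list with `micrographs` (id, animal_id, region, side,
#'   n_particles, stained_area, aoi_area, percent_area, threshold) and
#'   `animals` (animal_id, region, side, mean percent_area, n_micrographs).
#' @export
quantifyCohort <- function(micrographs, method = "otsu", q = 0.1, t = NULL,
                           minSize = 4, excludeBorder = TRUE) {
  ids <- vapply(micrographs, function(m) m@id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate micrograph ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  rows <- lapply(micrographs, function(m) {
    ps <- quantifyMicrograph(m, method = method, q = q, t = t,
                             minSize = minSize, excludeBorder = excludeBorder)
    data.frame(id = m@id, animal_id = m@animalId, region = m@region,
               side = m@side, n_particles = ps@nParticles,
               stained_area = ps@stainedArea, aoi_area = ps@aoiArea,
               percent_area = ps@percentArea, threshold = ps@thresholdUsed,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  key <- interaction(tab$animal_id, tab$region, tab$side, drop = TRUE)
  animals <- do.call(rbind, lapply(split(tab, key), function(d) {
    data.frame(animal_id = d$animal_id[1], region = d$region[1],
               side = d$side[1], percent_area = mean(d$percent_area),
               n_micrographs = nrow(d), stringsAsFactors = FALSE)
  }))
  rownames(animals) <- NULL
  list(micrographs = tab, animals = animals)
}

## Rejection-sample non-overlapping disk centers within the AOI rectangle.
.placeBlobs <- function(n, radii, rowRange, colRange, maxTries = 400L) {
  cy <- numeric(0); cx <- numeric(0)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (tr in seq_len(maxTries)) {
      y <- stats::runif(1, rowRange[1] + radii[i], rowRange[2] - radii[i])
      x <- stats::runif(1, colRange[1] + radii[i], colRange[2] - radii[i])
      if (i == 1L || all(sqrt((cy - y)^2 + (cx - x)^2) >=
                         radii[seq_len(i - 1)] + radii[i] + 2)) {
        cy <- c(cy, y); cx <- c(cx, x); placed <- TRUE; break
      }
    }
    if (!placed)
      stop("infeasible blob density: could not place ", n,
           " non-overlapping particles in the AOI")
  }
  cbind(y = cy, x = cx)
}

.diskMask <- function(nr, nc, cy, cx, r) {
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  m <- matrix(FALSE, nr, nc)
  for (i in seq_along(cy))
    m <- m | ((rows - cy[i])^2 + (cols - cx[i])^2 <= r[i]^2)
  m
}

#' Synthesize a DAB-style micrograph with known ground truth
#'
#' Emulates a DAB-stained section photographed at low magnification: a
#' bright background with Gaussian noise, dark disk-shaped immunoreactive
#' somata inside a rectangular AOI, and optionally dark blemish patches
#' hugging the raster border (which the border-exclusion filter of
#' [particleAnalysis()] must reject). The truth records the exact stained
#' fraction by pixel counting of the noiseless particle mask within the AOI.
#'
#' @param width,height raster size in pixels.
#' @param nBlobs number of stained particles (with `radiusRange` and the AOI
#'   size this sets the stained-area density).
#' @param radiusRange particle radius range in pixels (uniform draw).
#' @param background mean background intensity (bright, scale \[0, 1\]).
#' @param contrast intensity drop of stained pixels below background.
#' @param noiseSd Gaussian pixel noise SD.
#' @param nBlemishes number of dark border-hugging blemish disks.
#' @param blemishRadius blemish radius in pixels.
#' @param aoiMargin AOI inset from the raster border in pixels.
#' @param pixelArea physical area per pixel.
#' @param seed integer seed; byte-identical output for a fixed seed.
#' @param animalId,region,side,id labels stored on the micrograph.
#' @return list with `micrograph` ([Micrograph-class]) and `truth` (centers,
#'   radii, stained intensity, `trueFraction`, background mean/SD, blemish
#'   descriptors).
#' @export
#' @examples
#' sm <- synthMicrograph(nBlobs = 5, seed = 1)
#' sm$truth$trueFraction
synthMicrograph <- function(width = 200, height = 200, nBlobs = 20,
                            radiusRange = c(3, 6), background = 0.8,
                            contrast = 0.55, noiseSd = 0.03,
                            nBlemishes = 0, blemishRadius = 15,
                            aoiMargin = 8, pixelArea = 1, seed = 1L,
                            animalId = "synthetic", region = "DCN",
                            side = "ipsilateral", id = NULL) {
  stopifnot(width > 2 * aoiMargin, height > 2 * aoiMargin,
            contrast > 0, noiseSd >= 0)
  nr <- height; nc <- width
  aoiMask <- matrix(FALSE, nr, nc)
  aoiMask[(aoiMargin + 1):(nr - aoiMargin),
          (aoiMargin + 1):(nc - aoiMargin)] <- TRUE

  res <- withr::with_seed(seed, {
    radii <- if (nBlobs > 0)
      stats::runif(nBlobs, radiusRange[1], radiusRange[2]) else numeric(0)
    centers <- if (nBlobs > 0)
      .placeBlobs(nBlobs, radii,
                  c(aoiMargin + 1, nr - aoiMargin),
                  c(aoiMargin + 1, nc - aoiMargin))
      else cbind(y = numeric(0), x = numeric(0))
    blemishes <- if (nBlemishes > 0) {
      ## centers on the raster border so blemish components touch it
      edgePick <- sample(4, nBlemishes, replace = TRUE)
      t(vapply(seq_len(nBlemishes), function(i) {
        switch(edgePick[i],
               c(1, stats::runif(1, 1, nc)),
               c(nr, stats::runif(1, 1, nc)),
               c(stats::runif(1, 1, nr), 1),
               c(stats::runif(1, 1, nr), nc))
      }, numeric(2)))
    } else matrix(numeric(0), ncol = 2)
    noise <- matrix(stats::rnorm(nr * nc, 0, noiseSd), nr, nc)
    list(radii = radii, centers = centers, blemishes = blemishes,
         noise = noise)
  })

  blobMask <- .diskMask(nr, nc, res$centers[, 1], res$centers[, 2], res$radii)
  img <- matrix(background, nr, nc)
  img[blobMask] <- background - contrast
  if (nrow(res$blemishes)) {
    blemMask <- .diskMask(nr, nc, res$blemishes[, 1], res$blemishes[, 2],
                          rep(blemishRadius, nrow(res$blemishes)))
    img[blemMask] <- background - contrast
  }
  img <- pmin(pmax(img + res$noise, 0), 1)

  if (is.null(id)) id <- sprintf("%s_%s_%s", animalId, region, side)
  mg <- micrograph(img, aoiMask, pixelArea = pixelArea, animalId = animalId,
                   region = region, side = side, id = id)
  truth <- list(centers = res$centers, radii = res$radii,
                stainIntensity = background - contrast,
                trueFraction = sum(blobMask & aoiMask) / sum(aoiMask),
                backgroundMean = background, noiseSd = noiseSd,
                blemishes = res$blemishes, blemishRadius = blemishRadius)
  list(micrograph = mg, truth = truth)
}

#' Synthesize an IHC cohort with a known group effect
#'
#' Generates one micrograph per animal, region and side with per-animal
#' particle counts drawn around a target stained fraction, emulating an
#' exposed-vs-unexposed immunoreactivity contrast.
#'
#' @param nExposed,nUnexposed animals per group.
#' @param fractionExposed,fractionUnexposed target stained area fractions
#'   (not percent) per group.
#' @param seed master integer seed.
#' @param width,height,radiusRange,noiseSd,aoiMargin forwarded to
#'   [synthMicrograph()].
#' @param region,side labels applied to all micrographs.
#' @return list with `micrographs` (list of [Micrograph-class]) and `truth`
#'   (data.frame: animal_id, exposed, true_fraction).
#' @export
synthIhcCohort <- function(nExposed = 4, nUnexposed = 3,
                           fractionExposed = 0.08, fractionUnexposed = 0.04,
                           seed = 1L, width = 200, height = 200,
                           radiusRange = c(3, 6), noiseSd = 0.03,
                           aoiMargin = 8, region = "DCN",
                           side = "ipsilateral") {
  ids <- c(sprintf("E%02d", seq_len(nExposed)),
           sprintf("U%02d", seq_len(nUnexposed)))
  exposed <- rep(c(TRUE, FALSE), c(nExposed, nUnexposed))
  target <- ifelse(exposed, fractionExposed, fractionUnexposed)
  aoiPx <- (width - 2 * aoiMargin) * (height - 2 * aoiMargin)
  meanBlobPx <- pi * mean(radiusRange^2)   # E[r^2] approx for a narrow range
  draws <- withr::with_seed(seed, list(
    nBlobs = stats::rpois(length(ids), target * aoiPx / meanBlobPx),
    seeds = sample.int(.Machine$integer.max, length(ids))
  ))
  mgs <- vector("list", length(ids))
  truthFrac <- numeric(length(ids))
  for (i in seq_along(ids)) {
    sm <- synthMicrograph(width = width, height = height,
                          nBlobs = draws$nBlobs[i],
                          radiusRange = radiusRange, noiseSd = noiseSd,
                          aoiMargin = aoiMargin, seed = draws$seeds[i],
                          animalId = ids[i], region = region, side = side,
                          id = sprintf("%s_%s_%s", ids[i], region, side))
    mgs[[i]] <- sm$micrograph
    truthFrac[i] <- sm$truth$trueFraction
  }
  list(micrographs = mgs,
       truth = data.frame(animal_id = ids, exposed = exposed,
                          true_fraction = truthFrac,
                          stringsAsFactors = FALSE))
}

#' Read a micrograph from a PNG or TIFF file
#'
#' Multi-channel images are converted with [toGrayscale()].
#'
#' @param path file path ending in .png, .tif or .tiff.
#' @param aoi optional logical AOI mask; defaults to the whole raster.
#' @param pixelArea,animalId,region,side,id metadata, see [micrograph()].
#' @return A [Micrograph-class] object.
#' @export
readMicrograph <- function(path, aoi = NULL, pixelArea = 1,
                           animalId = "NA", region = "DCN",
                           side = "ipsilateral", id = basename(path)) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext, " (use PNG or TIFF)"))
  micrograph(toGrayscale(img), aoi = aoi, pixelArea = pixelArea,
             animalId = animalId, region = region, side = side, id = id)
}

#' Write a micrograph's intensity raster to PNG or TIFF
#'
#' @param mg a [Micrograph-class] object (intensities in \[0, 1\]).
#' @param path destination path ending in .png, .tif or .tiff.
#' @return `path`, invisibly.
#' @export
writeMicrograph <- function(mg, path) {
  stopifnot(is(mg, "Micrograph"))
  ext <- tolower(tools::file_ext(path))
  img <- pmin(pmax(mg@image, 0), 1)
  switch(ext,
    png = png::writePNG(img, path),
    tif = ,
    tiff = tiff::writeTIFF(img, path),
    stop("unsupported image format: .", ext, " (use PNG or TIFF)"))
  invisible(path)
}
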