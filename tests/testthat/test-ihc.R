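test_that("grayscale conversion is identity for 1 channel and luminance-weighted for 3", {
  m <- matrix(runif(12), 3, 4)
  expect_identical(toGrayscale(m), m)
  rgb <- array(0.4, dim = c(3, 4, 3))
  expect_equal(toGrayscale(rgb), matrix(0.4, 3, 4))
  # pure-channel images order as the luminance weights: G > R > B
  pure <- function(ch) { a <- array(0, dim = c(2, 2, 3)); a[, , ch] <- 1; a }
  vals <- vapply(1:3, function(ch) toGrayscale(pure(ch))[1, 1], numeric(1))
  expect_gt(vals[2], vals[1]); expect_gt(vals[1], vals[3])
  expect_error(toGrayscale(array(0, dim = c(2, 2, 5))), "channel")
})

test_that("synthetic micrographs record exact ground truth and are reproducible", {
  zero <- synthMicrograph(nBlobs = 0, seed = 1)
  expect_equal(zero$truth$trueFraction, 0)

  sm <- synthMicrograph(nBlobs = 5, radiusRange = c(4, 4), seed = 2)
  # verify the recorded fraction by independent pixel counting
  img <- intensity(sm$micrograph); msk <- aoi(sm$micrograph)
  cnt <- 0L
  for (i in seq_len(nrow(img))) for (j in seq_len(ncol(img))) {
    if (msk[i, j] &&
        any((i - sm$truth$centers[, 1])^2 + (j - sm$truth$centers[, 2])^2 <=
            sm$truth$radii^2)) cnt <- cnt + 1L
  }
  expect_equal(sm$truth$trueFraction, cnt / sum(msk))

  expect_identical(synthMicrograph(nBlobs = 7, seed = 9),
                   synthMicrograph(nBlobs = 7, seed = 9))
  expect_error(synthMicrograph(width = 40, height = 40, nBlobs = 50,
                               radiusRange = c(5, 6), seed = 1),
               "infeasible")
})

test_that("thresholding separates a two-valued image exactly and adapts within the AOI", {
  img <- matrix(200, 30, 30)
  img[10:14, 10:14] <- 50
  mg <- micrograph(img)
  th <- thresholdImage(mg, "otsu")
  expect_identical(th$mask, img == 50)
  expect_gt(th$threshold, 50); expect_lt(th$threshold, 200)

  # fixed(t) is the literal definition
  expect_identical(thresholdImage(mg, "fixed", t = 120)$mask, img < 120)
  expect_error(thresholdImage(mg, "fixed"), "requires")
  # constant image: otsu refuses with advice
  expect_error(thresholdImage(micrograph(matrix(1, 5, 5)), "otsu"),
               "fixed.*percentile|percentile.*fixed")
  # percentile
  thp <- thresholdImage(mg, "percentile", q = 0.5)
  expect_identical(thp$mask, img < thp$threshold)

  # threshold is computed from AOI pixels only
  dark <- img; dark[1:5, 1:5] <- 0   # junk outside the AOI
  aoiMask <- matrix(FALSE, 30, 30); aoiMask[8:20, 8:20] <- TRUE
  mgA <- micrograph(dark, aoiMask)
  thA <- thresholdImage(mgA, "otsu")
  expect_identical(thA$mask & aoiMask, (dark == 50) & aoiMask)
})

test_that("the otsu mask is equivariant under positive affine rescaling", {
  set.seed(23)
  for (i in 1:20) {
    v <- sample(0:255, 400, replace = TRUE) / 255
    img <- matrix(v, 20, 20)
    m1 <- thresholdImage(micrograph(img), "otsu")$mask
    m2 <- thresholdImage(micrograph(3.7 * img + 10), "otsu")$mask
    expect_identical(m1, m2)
  }
})

test_that("histogram otsu agrees with exhaustive between-class-variance search", {
  set.seed(29)
  for (i in 1:50) {
    # bimodal 8-bit-style intensities
    v <- c(pmin(pmax(round(rnorm(150, 180, 20)), 0), 255),
           pmin(pmax(round(rnorm(50, 60, 15)), 0), 255)) / 255
    img <- matrix(sample(v), 20, 10)
    got <- thresholdImage(micrograph(img), "otsu")
    want <- otsuExhaustive(as.vector(img))
    expect_identical(got$mask, img < want)
  }
})

test_that("8-connected labeling matches the flood-fill oracle", {
  diagonalPair <- matrix(FALSE, 3, 3)
  diagonalPair[1, 1] <- diagonalPair[2, 2] <- TRUE
  expect_equal(max(labelComponents(diagonalPair)), 1L)

  set.seed(31)
  for (i in 1:200) {
    nr <- sample(1:12, 1); nc <- sample(1:12, 1)
    mask <- matrix(runif(nr * nc) < runif(1, 0.2, 0.8), nr, nc)
    expect_identical(canonLabels(labelComponents(mask)),
                     canonLabels(floodFillLabels(mask)))
  }
})

test_that("particle analysis applies AOI, border and size filters", {
  a <- matrix(TRUE, 20, 20)
  expect_error(particleAnalysis(matrix(FALSE, 2, 2), matrix(FALSE, 2, 2)),
               "empty AOI")
  empty <- particleAnalysis(matrix(FALSE, 20, 20), a)
  expect_equal(empty@nParticles, 0L)
  expect_equal(percentArea(empty), 0)

  # entire AOI stained, no exclusions -> 100 percent
  full <- particleAnalysis(matrix(TRUE, 20, 20), a, minSize = 0,
                           excludeBorder = FALSE)
  expect_equal(percentArea(full), 100)
  expect_equal(full@nParticles, 1L)

  # border-touching and undersized components are excluded
  msk <- matrix(FALSE, 20, 20)
  msk[1:6, 1:6] <- TRUE          # touches the border
  msk[10:12, 10:12] <- TRUE      # 9 px, kept
  msk[16, 16] <- TRUE            # 1 px < minSize
  ps <- particleAnalysis(msk, a, minSize = 4)
  expect_equal(ps@nParticles, 1L)
  expect_equal(ps@stainedArea, 9)

  # percent area is calibration-invariant; stained area scales with pixelArea
  ps2 <- particleAnalysis(msk, a, pixelArea = 2.5, minSize = 4)
  expect_equal(percentArea(ps2), percentArea(ps))
  expect_equal(ps2@stainedArea, 9 * 2.5)
})

test_that("percent area recovers generator truth and grows when blobs are added", {
  sm <- synthMicrograph(width = 200, height = 200, nBlobs = 25,
                        radiusRange = c(4, 6), seed = 5)
  ps <- quantifyMicrograph(sm$micrograph)
  expect_lt(abs(percentArea(ps) - 100 * sm$truth$trueFraction), 1)
  expect_equal(ps@nParticles, 25L)

  # blemishes hugging the border do not contaminate the estimate
  smb <- synthMicrograph(width = 200, height = 200, nBlobs = 25,
                         radiusRange = c(4, 6), nBlemishes = 3,
                         blemishRadius = 12, seed = 5)
  psb <- quantifyMicrograph(smb$micrograph)
  expect_lt(abs(percentArea(psb) - 100 * smb$truth$trueFraction), 1)

  # monotonicity: adding a blob never decreases percent area
  base <- matrix(FALSE, 40, 40)
  base[5:8, 5:8] <- TRUE
  a <- matrix(TRUE, 40, 40)
  with1 <- percentArea(particleAnalysis(base, a))
  base2 <- base; base2[20:24, 20:24] <- TRUE
  expect_gte(percentArea(particleAnalysis(base2, a)), with1)
})

test_that("cohort quantification averages replicate sections and rejects duplicate ids", {
  s1 <- synthMicrograph(nBlobs = 10, seed = 1, animalId = "A", id = "m1")
  s2 <- synthMicrograph(nBlobs = 20, seed = 2, animalId = "A", id = "m2")
  q <- quantifyCohort(list(s1$micrograph, s2$micrograph))
  expect_equal(nrow(q$micrographs), 2L)
  expect_equal(nrow(q$animals), 1L)
  expect_equal(q$animals$percent_area, mean(q$micrographs$percent_area))
  expect_equal(q$animals$n_micrographs, 2L)
  expect_error(quantifyCohort(list(s1$micrograph, s1$micrograph)),
               "duplicate micrograph ids")

  blank <- micrograph(matrix(1, 30, 30), id = "b1")
  qb <- quantifyCohort(list(blank), method = "fixed", t = 0.5)
  expect_equal(qb$micrographs$percent_area, 0)
})

test_that("micrographs round-trip through PNG and TIFF", {
  img <- matrix(sample(0:255, 600, replace = TRUE) / 255, 20, 30)
  mg <- micrograph(img, animalId = "A", id = "rt")
  for (ext in c("png", "tiff")) {
    f <- withr::local_tempfile(fileext = paste0(".", ext))
    writeMicrograph(mg, f)
    back <- readMicrograph(f, animalId = "A", id = "rt")
    expect_equal(intensity(back), img, tolerance = 1e-7)
  }
  expect_error(readMicrograph("x.bmp"), "unsupported image format")
})
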