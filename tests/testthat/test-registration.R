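# Registration: transform algebra, rigid recovery, B-spline deformation
# recovery, RMS-vs-distance QC, image/mask/point transform consistency.

test_that("rigid transforms compose with their inverse to identity", {
  set.seed(3)
  for (i in 1:10) {
    tf <- rigidTransform(runif(1, -10, 10), runif(2, -20, 20), c(63.5, 63.5))
    pts <- cbind(runif(40, 0, 127), runif(40, 0, 127))
    back <- corrtaste:::rigidMapPoints(invertTransform(tf),
                                       corrtaste:::rigidMapPoints(tf, pts))
    expect_lt(max(abs(back - pts)), 1e-6)
  }
})

test_that("applyTransform treats images, masks and points consistently", {
  sc <- generateScene(nCells = 6, imgSize = c(96, 96), budDiameterUm = 35,
                      warpMaxPx = 0, nNerves = 0, seed = 8)
  mask <- cellMask(sc@labels)

  idt <- rigidTransform(0, c(0, 0), c(47.5, 47.5))
  expect_identical(applyTransform(mask, idt)@labels, mask@labels)

  tf <- rigidTransform(10, c(6, -4), c(47.5, 47.5))
  mT <- applyTransform(mask, tf)
  # label set preserved (no clipping at borders for this geometry)
  expect_setequal(cellLabels(mT), cellLabels(mask))

  # transformed points stay inside their transformed label
  set.seed(4)
  inside <- which(sc@labels > 0, arr.ind = TRUE)
  pick <- inside[sample.int(nrow(inside), 100), ]
  pts <- data.frame(x = pick[, 2] - 1, y = pick[, 1] - 1)
  labs <- sc@labels[pick]
  ptsT <- applyTransform(pts, tf)
  hit <- vapply(seq_len(nrow(ptsT)), function(i) {
    xi <- round(ptsT$x[i]); yi <- round(ptsT$y[i])
    win <- mT@labels[max(1, yi):min(96, yi + 2), max(1, xi):min(96, xi + 2)]
    labs[i] %in% win
  }, TRUE)
  expect_gte(mean(hit), 0.97)   # nearest-neighbor edge pixels may flip

  # round trip on points
  back <- applyTransform(applyTransform(pts, tf), invertTransform(tf))
  expect_lt(max(abs(back$x - pts$x)), 1e-6)
  expect_lt(max(abs(back$y - pts$y)), 1e-6)
})

test_that("rigid registration is exact on identical images and under the
           stated rotation/translation/noise/attenuation conditions", {
  sc <- generateScene(nCells = 25, imgSize = c(256, 256), budDiameterUm = 70,
                      warpMaxPx = 0, seed = 7)
  rds0 <- renderHistologyRounds(sc, nRounds = 1, noiseSigma = 0.02, seed = 7)
  same <- registerRigid(rds0[[1]]@nuclear, rds0[[1]]@nuclear)
  expect_lt(abs(same@rotationDeg), 0.05)
  expect_lt(max(abs(same@translationPx)), 0.1)

  sc@rigidTruth[[2]] <- rigidTransform(3, c(15, -10),
                                       sc@rigidTruth[[2]]@centerPx)
  rds <- renderHistologyRounds(sc, nRounds = 2, noiseSigma = 0.05,
                               nuclearAttenuation = 0.8, seed = 7)
  est <- registerRigid(rds[[1]]@nuclear, rds[[2]]@nuclear)
  truthInv <- invertTransform(sc@rigidTruth[[2]])
  expect_lt(abs(est@rotationDeg - truthInv@rotationDeg), 0.2)
  expect_lt(max(abs(est@translationPx - truthInv@translationPx)), 0.5)

  expect_error(registerRigid(matrix(1, 32, 32), matrix(1, 32, 32)),
               "degenerate content")
})

test_that("rigid recovery errors stay small across random conditions", {
  rotErr <- transErr <- numeric(12)
  for (s in 1:12) {
    set.seed(s)
    sc <- generateScene(nCells = 12, imgSize = c(128, 128),
                        budDiameterUm = 50, warpMaxPx = 0, seed = s)
    tru <- rigidTransform(runif(1, -5, 5), runif(2, -20, 20), c(63.5, 63.5))
    sc@rigidTruth[[2]] <- tru
    rds <- renderHistologyRounds(sc, nRounds = 2, noiseSigma = 0.05,
                                 seed = s)
    est <- registerRigid(rds[[1]]@nuclear, rds[[2]]@nuclear)
    ti <- invertTransform(tru)
    rotErr[s] <- abs(est@rotationDeg - ti@rotationDeg)
    transErr[s] <- max(abs(est@translationPx - ti@translationPx))
  }
  expect_lte(median(rotErr), 0.2)
  expect_lte(median(transErr), 0.5)
})

test_that("B-spline registration recovers a known smooth warp", {
  # identical images: essentially zero field
  sc <- generateScene(nCells = 15, imgSize = c(128, 128), budDiameterUm = 55,
                      warpMaxPx = 0, nNerves = 0, seed = 21)
  img <- renderInvivoReporter(sc, noiseSigma = 0.02, seed = 1)
  r0 <- registerNonrigid(img, img)
  expect_lt(mean(sqrt(r0$field@ux^2 + r0$field@uy^2)), 0.1)

  # known warp, max 3 px: foreground residual RMS < 0.5 px and the
  # registration strictly reduces the displacement RMS
  for (s in c(2, 3)) {
    scw <- generateScene(nCells = 15, imgSize = c(128, 128),
                         budDiameterUm = 55, warpMaxPx = 3, nNerves = 0,
                         seed = s)
    fixed <- renderHistologyRounds(scw, nRounds = 1, noiseSigma = 0.02,
                                   seed = s)[[1]]@reporter
    moving <- renderInvivoReporter(scw, noiseSigma = 0.02, seed = s + 50)
    r <- registerNonrigid(fixed, moving)
    fg <- scw@labels > 0
    resid <- sqrt((r$field@ux - scw@warpTruth@ux)^2 +
                    (r$field@uy - scw@warpTruth@uy)^2)
    pre <- sqrt(scw@warpTruth@ux^2 + scw@warpTruth@uy^2)
    expect_lt(sqrt(mean(resid[fg]^2)), 0.5)
    expect_lt(sqrt(mean(resid[fg]^2)), sqrt(mean(pre[fg]^2)))
    # warped moving matches the fixed image better than before
    expect_gt(cor(as.numeric(r$warped), as.numeric(fixed)),
              cor(as.numeric(moving), as.numeric(fixed)))
  }
})

test_that("deformation RMS error matches a brute-force oracle", {
  zf <- new("DeformationField", ux = matrix(0, 64, 64),
            uy = matrix(0, 64, 64), gridSpacingPx = 16,
            rmsVsDistance = data.frame())
  pts <- data.frame(x = c(10, 50), y = c(10, 50))
  r0 <- deformationRmsError(zf, pts, cbind(c(0, 0), c(0, 0)))
  expect_identical(r0$overallRmsPct, 0)

  # uniform 1 px relative residual at 200 px distance -> 0.5%
  f1 <- new("DeformationField", ux = matrix(0, 256, 256),
            uy = matrix(0, 256, 256), gridSpacingPx = 16,
            rmsVsDistance = data.frame())
  pts1 <- data.frame(x = c(10, 210), y = c(10, 10))
  tr1 <- rbind(c(1, 0), c(0, 0))     # true offsets differ by 1 px
  r1 <- deformationRmsError(f1, pts1, tr1)
  expect_equal(r1$overallRmsPct, 0.5, tolerance = 1e-12)

  # random field vs hand-computed oracle on 5 points
  set.seed(9)
  fld <- new("DeformationField",
             ux = matrix(rnorm(64 * 64, 0, 0.5), 64, 64),
             uy = matrix(rnorm(64 * 64, 0, 0.5), 64, 64),
             gridSpacingPx = 8, rmsVsDistance = data.frame())
  p5 <- data.frame(x = runif(5, 5, 58), y = runif(5, 5, 58))
  tru <- cbind(rnorm(5, 0, 1), rnorm(5, 0, 1))
  got <- deformationRmsError(fld, p5, tru)
  pred <- fieldAt(fld, p5$x, p5$y)
  pcts <- c()
  for (i in 1:4) for (j in (i + 1):5) {
    d <- sqrt((p5$x[i] - p5$x[j])^2 + (p5$y[i] - p5$y[j])^2)
    rt <- tru[i, ] - tru[j, ]; rp <- pred[i, ] - pred[j, ]
    pcts <- c(pcts, 100 * sqrt(sum((rt - rp)^2)) / d)
  }
  expect_equal(got$overallRmsPct, sqrt(mean(pcts^2)), tolerance = 1e-9)
  expect_error(deformationRmsError(zf, pts[1, , drop = FALSE],
                                   cbind(0, 0)), ">= 2")
})

test_that("registration QC reports perfect alignment and shift sensitivity", {
  sc <- generateScene(nCells = 10, imgSize = c(128, 128), budDiameterUm = 50,
                      warpMaxPx = 0, seed = 13)
  nuc <- renderHistologyRounds(sc, nRounds = 1, noiseSigma = 0.02,
                               seed = 13)[[1]]@nuclear
  qc <- registrationQC(nuc, nuc)
  expect_equal(qc$pearsonR, 1)
  expect_true(all(qc$peakOffsetsPx == 0))

  # shifting the registered image along x moves the horizontal-line peak
  qc5 <- registrationQC(nuc, shiftImage(nuc, 5, 0))
  expect_equal(qc5$peakOffsetsPx[1], 5, tolerance = 0.5)
})

test_that("transforms serialize to JSON and back", {
  tf <- rigidTransform(2.5, c(7.25, -3.5), c(63.5, 63.5))
  f <- tempfile(fileext = ".json")
  writeTransformJson(tf, f)
  tf2 <- readTransformJson(f)
  expect_equal(tf@rotationDeg, tf2@rotationDeg)
  expect_equal(tf@translationPx, tf2@translationPx)

  fld <- new("DeformationField", ux = matrix(rnorm(64), 8, 8),
             uy = matrix(rnorm(64), 8, 8), gridSpacingPx = 4,
             rmsVsDistance = data.frame())
  f2 <- tempfile(fileext = ".json")
  writeTransformJson(fld, f2)
  fld2 <- readTransformJson(f2)
  expect_equal(fld@ux, fld2@ux, tolerance = 1e-6)
})
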