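# Synthetic-data generator: determinism, class composition, count-model
# invariants, functional-movie closed form, histology-round geometry.

test_that("scene generation is deterministic and validates parameters", {
  s1 <- generateScene(nCells = 8, imgSize = c(96, 96), budDiameterUm = 42, seed = 7)
  s2 <- generateScene(nCells = 8, imgSize = c(96, 96), budDiameterUm = 42, seed = 7)
  expect_identical(s1@labels, s2@labels)
  expect_identical(s1@trueCounts, s2@trueCounts)
  expect_identical(s1@spots, s2@spots)
  expect_identical(s1@warpTruth@ux, s2@warpTruth@ux)

  expect_error(generateScene(classFractions = c(sweet = 0.6, umami = 0.3)),
               "sum to 1")
  expect_error(generateScene(nCells = 500, imgSize = c(96, 96),
                             budDiameterUm = 40), "packing")
})

test_that("a pure sour scene obeys the count-model floor and ceiling", {
  p <- defaultGeneCountParams()
  sc <- makeOneCellScene("sour", seed = 1)
  expect_identical(sc@cellClass, "sour")
  expect_gte(sc@trueCounts[1, "CA4"], p$floorHigh)
  expect_true(all(sc@trueCounts[1, c("Tas1R1", "Tas1R2", "Tas1R3")] <=
                    p$ceilingNeg))
  # spots lie inside (or within 2 px of) their cell footprint
  sp <- sc@spots
  for (i in seq_len(nrow(sp))) {
    xi <- round(sp$x[i]); yi <- round(sp$y[i])
    nb <- sc@labels[max(1, yi - 1):min(nrow(sc@labels), yi + 3),
                    max(1, xi - 1):min(ncol(sc@labels), xi + 3)]
    expect_true(any(nb == sp$cell[i]))
  }
})

test_that("empirical class proportions converge to the requested fractions", {
  fr <- c(sweet = 0.3, umami = 0.3, dual = 0.2, sour = 0.1, silent = 0.1)
  # law of large numbers over seeds; direct tally oracle
  tally <- table(factor(unlist(lapply(1:120, function(s)
    generateScene(nCells = 20, classFractions = fr, imgSize = c(96, 96), budDiameterUm = 42,
                  warpMaxPx = 0, nNerves = 0, seed = s)@cellClass)),
    names(fr)))
  props <- tally / sum(tally)
  expect_true(all(abs(props - fr) < 0.03))
})

test_that("scene invariants hold: contiguous labels, silent cells mute", {
  for (s in 1:5) {
    sc <- generateScene(nCells = 10, imgSize = c(96, 96), budDiameterUm = 42, seed = s)
    labs <- sort(unique(as.integer(sc@labels)))
    expect_identical(labs[labs > 0], 1:10)
    sil <- sc@cellClass == "silent"
    if (any(sil)) expect_true(all(sc@amplitudes[sil, ] == 0))
  }
})

test_that("noise-free silent movie has a constant G/R ratio everywhere", {
  sc <- makeOneCellScene("silent", seed = 3)
  sch <- stimulusSchedule("sweet")
  mv <- renderFunctionalMovie(sc, sch, noiseSigma = 0, motionAmplitudePx = 0,
                              seed = 1)
  rat <- mv@green / mv@red
  expect_lt(max(abs(sweep(rat, c(1, 2, 3), rat[, , , 1]))), 1e-12)
  expect_error(renderFunctionalMovie(sc, sch, noiseSigma = -1), "noiseSigma")
})

test_that("rendered sweet response matches the closed-form ratio gain", {
  sc <- makeOneCellScene("sweet", seed = 2)
  sch <- stimulusSchedule("sweet")
  mv <- renderFunctionalMovie(sc, sch, noiseSigma = 0.01, seed = 3)
  inMask <- sc@labels > 0
  base <- mean(vapply(1:15, function(t)
    mean(mv@green[, , 1, t][inMask]) / mean(mv@red[, , 1, t][inMask]), 0))
  # plateau of the stimulus epoch (rise time constant 1 s, epoch 20-40 s)
  plateau <- mean(vapply(26:39, function(t)
    mean(mv@green[, , 1, t][inMask]) / mean(mv@red[, , 1, t][inMask]), 0))
  expect_equal(plateau / base, 1.5, tolerance = 0.02)
})

test_that("silent-cell ratio is epoch-independent across seeds", {
  # two-sample t-test on baseline vs epoch ratio, alpha 0.01
  pass <- vapply(1:40, function(s) {
    sc <- makeOneCellScene("silent", seed = s)
    sch <- stimulusSchedule("sweet")
    mv <- renderFunctionalMovie(sc, sch, noiseSigma = 0.02, seed = s)
    tr <- extractTraces(mv, sc@labels)[[1]]
    base <- tr@ratio[tr@timeS < 20]
    epoch <- tr@ratio[tr@timeS >= 20 & tr@timeS < 40]
    stats::t.test(base, epoch)$p.value > 0.01
  }, TRUE)
  expect_gte(mean(pass), 0.95)
})

test_that("histology rounds place spots at rigidly transformed positions", {
  sc <- suppressWarnings(   # count truncation to the packable number is intended
    generateScene(nCells = 5, imgSize = c(96, 96), budDiameterUm = 35,
                  warpMaxPx = 0, nNerves = 0, nRounds = 3, spotMinSepPx = 7,
                  geneCountParams = list(nbMean = 4, nbSize = 5,
                                         poisMean = 0.3, floorHigh = 2,
                                         ceilingNeg = 1), seed = 11))
  sc@rigidTruth[[3]] <- rigidTransform(3, c(15, -10),
                                       sc@rigidTruth[[3]]@centerPx)
  rds <- renderHistologyRounds(sc, nRounds = 3, noiseSigma = 0, seed = 1)

  # round 1, identity: channel maxima within 0.5 px of the true positions
  checkRound <- function(r) {
    truth <- spotPositionsInRound(sc, r)
    for (g in names(rds[[r]]@fish)) {
      tg <- truth[truth$gene == g, ]
      tg <- tg[tg$x > 3 & tg$x < 92 & tg$y > 3 & tg$y < 92, ]
      img <- rds[[r]]@fish[[g]]
      for (i in seq_len(nrow(tg))) {
        rows <- (round(tg$y[i]) - 2):(round(tg$y[i]) + 4)  # 1-based rows
        cols <- (round(tg$x[i]) - 2):(round(tg$x[i]) + 4)
        sub <- img[rows, cols]
        pk <- which(sub == max(sub), arr.ind = TRUE)[1, ]
        peakY <- rows[pk[1]] - 1; peakX <- cols[pk[2]] - 1
        # integer-grid argmax of a clean Gaussian is the rounded center
        expect_lt(sqrt((peakX - tg$x[i])^2 + (peakY - tg$y[i])^2), 0.75)
      }
    }
  }
  checkRound(1)
  checkRound(3)

  # reporter quenching: absent from round 2 onward
  expect_false(is.null(rds[[1]]@reporter))
  expect_null(rds[[2]]@reporter)
  expect_null(rds[[3]]@reporter)
  # nuclear attenuation is monotone
  expect_gt(max(rds[[1]]@nuclear), max(rds[[3]]@nuclear))
  # spectral budget
  expect_error(renderHistologyRounds(sc, nRounds = 1,
                                     geneRounds = list(tasteGenes())),
               "channel-budget")
})

test_that("rendered histology is deterministic for fixed seed", {
  sc <- generateScene(nCells = 5, imgSize = c(64, 64), budDiameterUm = 28,
                      seed = 4)
  r1 <- renderHistologyRounds(sc, nRounds = 2, seed = 9)
  r2 <- renderHistologyRounds(sc, nRounds = 2, seed = 9)
  expect_identical(r1[[1]]@nuclear, r2[[1]]@nuclear)
  expect_identical(r1[[2]]@fish, r2[[2]]@fish)
})

test_that("schedule YAML round-trips and validates", {
  sch <- stimulusSchedule(c("sweet", "umami"), frameRate = 2)
  f <- tempfile(fileext = ".yaml")
  writeScheduleYaml(sch, f)
  sch2 <- readScheduleYaml(f)
  expect_equal(sch@onset, sch2@onset)
  expect_equal(sch@tastant, sch2@tastant)
  expect_error(new("StimulusSchedule", tastant = c("a", "b"),
                   onset = c(20, 30), offset = c(40, 50),
                   baselineWindow = c(0, 20), frameRate = 1),
               "non-overlapping")
})
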