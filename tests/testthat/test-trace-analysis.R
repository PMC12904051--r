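# Trace analysis: motion correction, ratiometric extraction, dF/F / Z-score
# identities, responsiveness rules, response index and tuning classes.

test_that("motion correction is exact on static movies and recovers jitter", {
  sc <- makeOneCellScene("sweet", seed = 5, imgSize = c(48, 48))
  sch <- stimulusSchedule("sweet", frameRate = 1)
  still <- renderFunctionalMovie(sc, sch, noiseSigma = 0.01,
                                 motionAmplitudePx = 0, seed = 1)
  mc <- motionCorrect(still)
  expect_lt(max(abs(c(mc$shifts$dx, mc$shifts$dy))), 0.1)

  jittery <- renderFunctionalMovie(sc, sch, noiseSigma = 0.01,
                                   motionAmplitudePx = 3, seed = 2)
  mc2 <- motionCorrect(jittery)
  rmse <- sqrt(mean((mc2$shifts$dx - jittery@shiftsTruth$dx)^2 +
                      (mc2$shifts$dy - jittery@shiftsTruth$dy)^2))
  expect_lt(rmse, 0.5)

  zero <- still
  zero@red[] <- 0
  expect_error(motionCorrect(zero), "degenerate reference")
})

test_that("correction never decreases mean frame-to-reference correlation", {
  for (s in 1:20) {
    sc <- makeOneCellScene("silent", seed = s, imgSize = c(40, 40))
    sch <- stimulusSchedule("sweet", baselineS = 10, stimS = 10, washS = 10)
    mv <- renderFunctionalMovie(sc, sch, noiseSigma = 0.02,
                                motionAmplitudePx = 2, seed = s + 100)
    mc <- motionCorrect(mv)
    corTo <- function(m) {
      ref <- apply(m@red[, , 1, ], c(1, 2), mean)
      mean(vapply(seq_len(nFrames(m)), function(t)
        cor(as.numeric(ref), as.numeric(m@red[, , 1, t])), 0))
    }
    expect_gte(corTo(mc$movie), corTo(mv) - 1e-6)
  }
})

test_that("trace extraction is ratiometric and recovers the rendered dF/F", {
  # uniform channels: G = 2, R = 1 -> constant ratio 2
  mv <- new("TasteBudMovie",
            green = array(2, c(8, 8, 1, 10)), red = array(1, c(8, 8, 1, 10)),
            schedule = stimulusSchedule("sweet", baselineS = 5, stimS = 3,
                                        washS = 2),
            shiftsTruth = data.frame(), pixelSizeUm = 0.5)
  lab <- matrix(0, 8, 8); lab[3:6, 3:6] <- 1
  tr <- extractTraces(mv, lab)[[1]]
  expect_equal(tr@ratio, rep(2, 10))

  # scaling both channels leaves the ratio unchanged to 1e-12
  mv2 <- mv; mv2@green <- mv@green * 7.3; mv2@red <- mv@red * 7.3
  tr2 <- extractTraces(mv2, lab)[[1]]
  expect_lt(max(abs(tr2@ratio - tr@ratio)), 1e-12)

  # empty ROI warns and is skipped
  lab2 <- lab; lab2[lab2 == 1] <- 0; lab2[1, 1] <- 2
  lab2[1, 1] <- 0; lab2[8, 8] <- 5
  expect_length(extractTraces(mv, lab2), 1)

  # rendered amplitude 0.5 recovered in dF/F
  sc <- makeOneCellScene("sweet", seed = 2)
  sch <- stimulusSchedule("sweet")
  mvr <- renderFunctionalMovie(sc, sch, noiseSigma = 0.01, seed = 3)
  trr <- computeDffZscore(extractTraces(mvr, sc@labels)[[1]], c(0, 20))
  expect_equal(max(trr@dff), 0.5, tolerance = 0.1)
})

test_that("dF/F and Z-score identities hold and degenerate baselines error", {
  set.seed(42)
  ratio <- c(rnorm(20, 1, 0.05), rnorm(20, 1.5, 0.05))
  tr <- computeDffZscore(makeTrace(ratio), c(0, 20))
  expect_equal(tr@dff, ratio / tr@baselineMean - 1)
  expect_lt(abs(mean(tr@zscore[1:20])), 1e-9)
  expect_lt(abs(sd(tr@zscore[1:20]) - 1), 1e-9)

  # direct formula: baseline mean 1 sd 0.05, stimulus 1.5 -> dff 0.5, z 10
  base <- rep(c(0.95, 1.05), 10)          # mean 1, sd 0.05127
  s <- sd(base)
  tr2 <- computeDffZscore(makeTrace(c(base, 1.5)), c(0, 20))
  expect_equal(tr2@dff[21], 0.5, tolerance = 1e-12)
  expect_equal(tr2@zscore[21], 0.5 / s, tolerance = 1e-9)

  expect_error(computeDffZscore(makeTrace(rep(2, 30)), c(0, 20)),
               "degenerate baseline")
  expect_error(computeDffZscore(makeTrace(1:30 / 30), c(0, 3)),
               ">= 5 frames")
})

test_that("responsiveness conjoins the peak-SD and mean-Z rules", {
  sch <- stimulusSchedule("sweet", baselineS = 20, stimS = 20, washS = 10)
  zToRatio <- function(z) 1 + z * 0.01    # baseline sd ~0.01 around 1
  set.seed(7)
  base <- rnorm(20, 0, 1)
  base <- (base - mean(base)) / sd(base)  # exactly mean 0 sd 1

  # peak 3, mean 1.5 -> responsive, clamp = mean z
  epoch <- c(rep(1.4, 19), 3.0); epoch[1] <- 1.5 * 20 - sum(epoch[-1])
  tr <- computeDffZscore(makeTrace(zToRatio(c(base, epoch, rep(0, 10)))),
                         c(0, 20))
  r <- classifyResponsiveness(tr, sch)
  expect_true(r$responsive)
  expect_equal(r$mean_z_clamped, 1.5, tolerance = 1e-6)

  # mean 0.8 -> clamped to 0 even with a high peak
  epoch2 <- c(rep(0.5, 19), 3.0); epoch2[1] <- 0.8 * 20 - sum(epoch2[-1])
  tr2 <- computeDffZscore(makeTrace(zToRatio(c(base, epoch2, rep(0, 10)))),
                          c(0, 20))
  r2 <- classifyResponsiveness(tr2, sch)
  expect_false(r2$responsive)
  expect_identical(r2$mean_z_clamped, 0)

  # pure-noise null: responsive in <= 5% of seeds
  hits <- vapply(1:200, function(s) {
    set.seed(s)
    tr <- computeDffZscore(makeTrace(1 + rnorm(50, 0, 0.01)), c(0, 20))
    classifyResponsiveness(tr, sch)$responsive
  }, TRUE)
  expect_lte(mean(hits), 0.05)
})

test_that("response index hits the printed endpoints and excludes 0/0", {
  mk <- function(s, u) data.frame(tastant = c("sweet", "umami"),
                                  mean_z_clamped = c(s, u))
  expect_identical(responseIndex(mk(2.0, 0)), 1)
  expect_identical(responseIndex(mk(0, 3.1)), -1)
  expect_identical(responseIndex(mk(1.7, 1.7)), 0)
  expect_true(is.na(responseIndex(mk(0, 0))))

  # antisymmetry under swapping sweet/umami
  set.seed(1)
  for (i in 1:25) {
    s <- runif(1, 0, 4); u <- runif(1, 0, 4)
    if (s == 0 && u == 0) next
    expect_equal(responseIndex(mk(s, u)), -responseIndex(mk(u, s)),
                 tolerance = 1e-12)
  }
})

test_that("tuning classes follow the index and excluded sentinel", {
  expect_identical(classifyTuning(1), "sweet")
  expect_identical(classifyTuning(-1), "umami")
  expect_identical(classifyTuning(0.37), "dual")
  expect_identical(classifyTuning(NA_real_), "excluded")
  expect_error(classifyTuning(1.2), "internal-consistency")
})

test_that("tuning classes are recovered from rendered movies", {
  sch <- stimulusSchedule(c("sweet", "umami"))
  classOf <- c(sweet = "sweet", umami = "umami", dual = "dual",
               sour = "excluded", silent = "excluded")
  total <- 0; good <- 0
  for (s in 1:20) {
    sc <- makeTuningBud(seed = s)
    mv <- renderFunctionalMovie(sc, sch, noiseSigma = 0.02, seed = s)
    summ <- summarizeResponses(extractTraces(mv, sc@labels), sch)
    got <- summ$rois$tuning_class[order(as.integer(summ$rois$roi_id))]
    want <- unname(classOf[sc@cellClass])
    total <- total + length(want)
    good <- good + sum(got == want)
  }
  expect_gte(good / total, 0.95)
})
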