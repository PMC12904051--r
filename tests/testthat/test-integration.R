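# Correlative integration: profile assembly, IF positivity, ROC statistics,
# receptor-class calling, adjacency and dual-tuning attribution.

test_that("cell profiles merge modalities with explicit nulls", {
  lab <- matrix(0, 32, 32); lab[4:10, 4:10] <- 1; lab[15:25, 15:25] <- 2
  mask <- cellMask(lab)
  counts <- data.frame(cell = 1L, CA4 = 20L, Tas1R1 = 1L)
  ifTab <- data.frame(cell = c(1L, 2L), protein = "CA4",
                      intensity = c(8, 1), positive = c(TRUE, FALSE))
  resp <- data.frame(roi_id = c("1", "2"), tastant = "sour",
                     mean_z = c(3.2, 0.1), responsive = c(TRUE, FALSE),
                     mean_z_clamped = c(3.2, 0))
  prof <- buildCellProfiles(mask, counts, ifTab, resp)
  expect_identical(nrow(prof), 2L)
  # the sour cell carries all three facts
  expect_identical(prof$count_CA4[1], 20L)
  expect_true(prof$if_CA4[1])
  expect_equal(prof$mean_z_sour[1], 3.2)
  # missing FISH data stays NA, never silent zero
  expect_true(is.na(prof$count_CA4[2]))

  bad <- data.frame(cell = 99L, CA4 = 1L)
  expect_error(buildCellProfiles(mask, bad), "consistency error")
})

test_that("IF positivity splits bimodal intensities and is scale-invariant", {
  x <- c(1, 1, 1, 10, 11)
  expect_identical(classifyIfPositive(x), c(FALSE, FALSE, FALSE, TRUE, TRUE))
  expect_identical(classifyIfPositive(x * 2), classifyIfPositive(x))
  expect_identical(classifyIfPositive(c(1, 2, 3), method = "threshold",
                                      threshold = 5), rep(FALSE, 3))
  expect_error(classifyIfPositive(rep(2, 6)), "degenerate")
  expect_error(classifyIfPositive(c(1, 2, 3)), ">= 4")
})

test_that("ROC equals the Mann-Whitney identity and pROC cross-check", {
  # perfectly separated
  r <- rocCurve(c(1, 2, 3, 10, 11, 12), c(F, F, F, T, T, T))
  expect_identical(r$auc, 1)
  expect_gte(r$optimalThreshold, 3)
  expect_lt(r$optimalThreshold, 10)

  # AUC == U / (n1 n2) to 1e-9 (with ties), over random draws
  for (s in 1:25) {
    set.seed(s)
    lab <- rep(c(TRUE, FALSE), c(12, 15))
    x <- c(rpois(12, 8), rpois(15, 5))       # ties guaranteed
    r <- rocCurve(x, lab)
    u <- unname(suppressWarnings(
      stats::wilcox.test(x[lab], x[!lab])$statistic))
    expect_equal(r$auc, u / (12 * 15), tolerance = 1e-9)
  }

  # cross-check against pROC
  skip_if_not_installed("pROC")
  set.seed(99)
  x <- rnorm(60); lab <- x + rnorm(60) > 0
  if (sum(lab) %in% c(0, 60)) lab[1] <- !lab[1]
  expect_equal(rocCurve(x, lab)$auc,
               as.numeric(suppressMessages(pROC::auc(pROC::roc(lab, x)))),
               tolerance = 1e-9)

  # label-independent feature: AUC ~ 0.5
  aucs <- vapply(1:100, function(s) {
    set.seed(s + 1000)
    rocCurve(rnorm(300), rep(c(TRUE, FALSE), 150))$auc
  }, 0)
  expect_equal(mean(aucs), 0.5, tolerance = 0.05)
  expect_error(rocCurve(1:5, rep(TRUE, 5)), "class error")
})

test_that("count classifier separates high expressers from negatives", {
  # synthetic CA4 cohort: NegBin(25, 5) positives vs Poisson(1) negatives
  for (s in 1:5) {
    set.seed(s)
    pos <- rnbinom(25, size = 5, mu = 25); neg <- rpois(25, 1)
    r <- rocCurve(c(pos, neg), rep(c(TRUE, FALSE), each = 25))
    expect_gte(r$auc, 0.95)
    expect_gt(r$optimalThreshold, median(neg))
    expect_lt(r$optimalThreshold, median(pos))
  }
})

test_that("expression classes follow the negative-control percentile rule", {
  prof <- data.frame(cell_id = 1:5,
                     count_Tas1R1 = c(20, 0, 18, 0, 1),
                     count_Tas1R2 = c(18, 15, 0, 0, 2),
                     count_Tas1R3 = c(25, 20, 22, 0, 0),
                     count_CA4 = c(0, 1, 0, 0, 30))
  # cell 5 is the CA4+ control (threshold 13); its Tas1R counts {1,2,0}
  # give 95th-percentile cuts, so cells with counts > cut are positive
  cls <- callExpressionClass(prof)
  expect_identical(cls$class, c("dual", "sweet", "umami", "negative", "sour"))

  # fixed thresholds: (0,15,20) with cut 3 -> sweet
  p2 <- data.frame(cell_id = 1, count_Tas1R1 = 0, count_Tas1R2 = 15,
                   count_Tas1R3 = 20, count_CA4 = 0)
  c2 <- callExpressionClass(p2, fixedThresholds = c(Tas1R1 = 3, Tas1R2 = 3,
                                                    Tas1R3 = 3))
  expect_identical(c2$class, "sweet")

  # all-zero counts -> negative
  p3 <- data.frame(cell_id = 1, count_Tas1R1 = 0, count_Tas1R2 = 0,
                   count_Tas1R3 = 0, count_CA4 = 0)
  expect_identical(callExpressionClass(p3, fixedThresholds = c(
    Tas1R1 = 3, Tas1R2 = 3, Tas1R3 = 3))$class, "negative")

  # control counts {0,1,2}: cell (20,18,25) -> dual
  p4 <- data.frame(cell_id = 1:4,
                   count_Tas1R1 = c(20, 0, 1, 2),
                   count_Tas1R2 = c(18, 1, 0, 2),
                   count_Tas1R3 = c(25, 2, 1, 0),
                   count_CA4 = c(0, 20, 25, 30))
  expect_identical(callExpressionClass(p4)$class[1], "dual")

  expect_error(callExpressionClass(prof[1:4, ]), "configuration error")
})

test_that("afferent adjacency follows the dilation-radius rule", {
  lab <- matrix(0, 64, 64)
  lab[10:20, 10:20] <- 1
  lab[10:20, 30:40] <- 2
  mask <- cellMask(lab)
  circle <- function(cx, cy, r) {
    a <- seq(0, 2 * pi, length.out = 13)[-13]
    list(id = "n1", polygon = cbind(cx + r * cos(a), cy + r * sin(a)))
  }
  # ROI overlapping label 1 only
  adj1 <- afferentAdjacency(list(circle(14, 14, 3)), mask, radiusUm = 1,
                            pixelSizeUm = 0.5)
  expect_identical(adj1$n1, 1L)
  # ROI between the two labels, radius large enough to reach both
  adj2 <- afferentAdjacency(list(circle(24.5, 15, 3)), mask, radiusUm = 2,
                            pixelSizeUm = 0.5)
  expect_identical(adj2$n1, c(1L, 2L))
  # isolated ROI
  adj3 <- afferentAdjacency(list(circle(55, 55, 3)), mask, radiusUm = 1,
                            pixelSizeUm = 0.5)
  expect_length(adj3$n1, 0)
  empty <- list(list(id = "n0", polygon = cbind(c(-10, -9, -9), c(-10, -10, -9))))
  expect_error(afferentAdjacency(empty, mask), "geometry error")
})

test_that("dual-tuning attribution recovers the cohort ground truth", {
  coh <- simulateDualTuningCohort(nNerves = 40, intrinsicFrac = 0.9, seed = 5)
  cls <- callExpressionClass(coh$profiles |>
    (\(p) data.frame(cell_id = p$cell_id, count_Tas1R1 = p$Tas1R1,
                     count_Tas1R2 = p$Tas1R2, count_Tas1R3 = p$Tas1R3,
                     count_CA4 = p$CA4))(),
    fixedThresholds = c(Tas1R1 = 5, Tas1R2 = 5, Tas1R3 = 5))
  prof <- data.frame(cell_id = coh$profiles$cell_id,
                     expression_class = cls$class)
  res <- summarizeDualTuning(coh$nerveSummaries, coh$adjacency, prof)
  expect_identical(res$nDual, 40L)
  # per-nerve attribution equals the generated truth
  expect_identical(res$perNerve$attribution, coh$truth)
  # fractions near 0.9/0.1 within binomial error (3 SD of Binom(40, .9))
  expect_lt(abs(res$fractions["intrinsic"] - 0.9),
            3 * sqrt(0.9 * 0.1 / 40) + 1e-9)
  # categories exclusive and exhaustive
  expect_equal(sum(res$fractions), 1)

  # nerve adjacent only to a dual cell -> intrinsic
  one <- summarizeDualTuning(
    data.frame(nerve_id = "n", tuning_class = "dual"),
    list(n = 1L), data.frame(cell_id = 1L, expression_class = "dual"))
  expect_identical(one$perNerve$attribution, "intrinsic")

  # no dual-tuned nerves: zero-denominator flag
  none <- summarizeDualTuning(
    data.frame(nerve_id = "n", tuning_class = "sweet"),
    list(n = 1L), data.frame(cell_id = 1L, expression_class = "dual"))
  expect_true(none$zeroDenominator)
  expect_identical(none$nDual, 0L)

  expect_error(summarizeDualTuning(
    data.frame(nerve_id = "nX", tuning_class = "dual"), list(),
    prof), "consistency error")
})

test_that("mean in-mask intensity feeds IF calls per cell", {
  lab <- matrix(0, 16, 16); lab[2:5, 2:5] <- 1; lab[10:14, 10:14] <- 2
  img <- matrix(0.1, 16, 16); img[lab == 1] <- 0.9
  tab <- meanIntensityPerCell(img, cellMask(lab))
  expect_equal(tab$intensity, c(0.9, 0.1))
})
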