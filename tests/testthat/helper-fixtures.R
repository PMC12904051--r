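# Shared fixtures and independent oracles for the test suite. Everything is
# generated in code; no binary fixtures.

# Small bud for movie-based tests: 6 cells, 2 planes (apical + basolateral),
# 48x48 px.
makeTuningBud <- function(seed, nNerves = 0, amplitude = 0.5) {
  generateScene(nCells = 6,
                classFractions = c(sweet = 0.25, umami = 0.25, dual = 0.25,
                                   sour = 0.1, silent = 0.15),
                imgSize = c(48, 48), budDiameterUm = 20, nPlanes = 2L,
                nNerves = nNerves, warpMaxPx = 0, amplitude = amplitude,
                cellAxesPx = c(7, 3.5), seed = seed)
}

# A single-class one-cell scene (small, no nerves, no warp).
makeOneCellScene <- function(class, seed = 1, imgSize = c(64, 64)) {
  fr <- setNames(numeric(5), c("sweet", "umami", "dual", "sour", "silent"))
  fr[class] <- 1
  generateScene(nCells = 1, classFractions = fr, imgSize = imgSize,
                budDiameterUm = floor(0.42 * min(imgSize)), nPlanes = 2L,
                nNerves = 0, warpMaxPx = 0, seed = seed)
}

# Build a CalciumTrace directly from a ratio vector (1 Hz).
makeTrace <- function(ratio, id = "t", compartment = "cell_apical") {
  new("CalciumTrace", roiId = id, compartment = compartment,
      timeS = seq_along(ratio) - 1, ratio = ratio, dff = numeric(0),
      zscore = numeric(0), baselineMean = numeric(0), baselineSd = numeric(0))
}

# Independent subpixel localization oracle: dense grid search of the center
# of an isotropic Gaussian (fixed sigma), amplitude/offset solved linearly.
gridSearchSpotCenter <- function(img, px, py, sigma, win = 3, step = 0.02) {
  xs <- (px - win):(px + win); ys <- (py - win):(py + win)
  X <- rep(xs, each = length(ys)); Y <- rep(ys, times = length(xs))
  zv <- as.numeric(img[ys + 1, xs + 1])
  cand <- expand.grid(x = seq(px - 1, px + 1, by = step),
                      y = seq(py - 1, py + 1, by = step))
  sse <- vapply(seq_len(nrow(cand)), function(i) {
    g <- exp(-((X - cand$x[i])^2 + (Y - cand$y[i])^2) / (2 * sigma^2))
    A <- cbind(g, 1)
    b <- qr.solve(A, zv)
    sum((zv - A %*% b)^2)
  }, 0)
  unlist(cand[which.min(sse), ])
}

# Synthetic spot field with a guaranteed minimum separation.
makeSpotField <- function(n, h, w, sep, seed, margin = 8) {
  set.seed(seed)
  pts <- matrix(numeric(0), 0, 2)
  tries <- 0
  while (nrow(pts) < n && tries < 5000) {
    tries <- tries + 1
    p <- c(runif(1, margin, w - 1 - margin), runif(1, margin, h - 1 - margin))
    if (!nrow(pts) || min(sqrt(colSums((t(pts) - p)^2))) >= sep)
      pts <- rbind(pts, p)
  }
  pts
}

# Rigid-transform discrepancy: max displacement of bud-area points mapped by
# estimate vs truth-inverse (the alignment transform the estimate targets).
rigidDiscrepancyPx <- function(est, truthInv, h, w) {
  pts <- cbind(runif(50, 0.25 * w, 0.75 * w), runif(50, 0.25 * h, 0.75 * h))
  pe <- corrtaste:::rigidMapPoints(est, pts)
  pt <- corrtaste:::rigidMapPoints(truthInv, pts)
  max(sqrt(rowSums((pe - pt)^2)))
}
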