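# Ground-truthed synthetic taste-bud scenes. The generator emulates the
# statistical structure the analysis assumes: a circular bud of elongated,
# non-overlapping taste cells; per-class receptor transcript counts
# (negative-binomial high expressers vs low-Poisson negatives); peak dF/F
# response amplitudes per tastant; basolateral afferent-nerve ROIs; per-round
# rigid transforms; a smooth fixation warp; and persistent fiducial blobs.

#' Default per-class peak dF/F response amplitudes
#'
#' Sweet cells respond to sweet, umami cells to umami, dual cells to both,
#' sour cells to sour, silent cells to nothing.
#'
#' @param amplitude peak dF/F of a responding cell (dimensionless).
#' @return Matrix classes x tastants.
#' @export
defaultAmplitudeMap <- function(amplitude = 0.5) {
  cls <- c("sweet", "umami", "dual", "sour", "silent")
  m <- matrix(0, length(cls), 3, dimnames = list(cls, tasteTastants()))
  m["sweet", "sweet"] <- amplitude
  m["umami", "umami"] <- amplitude
  m["dual", c("sweet", "umami")] <- amplitude
  m["sour", "sour"] <- amplitude
  m
}

#' Default transcript-count model parameters
#'
#' High expressers follow a negative binomial (mean 25, dispersion size 5)
#' truncated below at `floorHigh`; negative cells a Poisson (mean 1) capped
#' at `ceilingNeg`. The high/negative separation straddles a count threshold
#' of ~13 spots, the scale at which digital HCR counting distinguishes
#' marker-positive cells.
#'
#' @return Named list of parameters.
#' @export
defaultGeneCountParams <- function() {
  list(nbMean = 25, nbSize = 5, poisMean = 1, floorHigh = 10, ceilingNeg = 5)
}

# Which genes are "high" per cell class.
classHighGenes <- list(
  sweet = c("Tas1R2", "Tas1R3"),
  umami = c("Tas1R1", "Tas1R3"),
  dual = c("Tas1R1", "Tas1R2", "Tas1R3"),
  sour = "CA4",
  silent = character(0))

drawCounts <- function(classes, params) {
  genes <- tasteGenes()
  n <- length(classes)
  cnt <- matrix(0L, n, length(genes), dimnames = list(NULL, genes))
  for (i in seq_len(n)) {
    hi <- classHighGenes[[classes[i]]]
    for (g in genes) {
      if (g %in% hi) {
        v <- stats::rnbinom(1, size = params$nbSize, mu = params$nbMean)
        cnt[i, g] <- max(params$floorHigh, v)
      } else {
        cnt[i, g] <- min(params$ceilingNeg, stats::rpois(1, params$poisMean))
      }
    }
  }
  cnt
}

# Random smooth displacement field built on a coarse cubic B-spline lattice,
# rescaled so the maximum displacement magnitude equals maxPx.
randomWarpField <- function(h, w, maxPx, gridSpacingPx = 64) {
  bx <- bsplineBasis(w, gridSpacingPx)
  by <- bsplineBasis(h, gridSpacingPx)
  cx <- matrix(stats::rnorm(ncol(by$B) * ncol(bx$B)), ncol(by$B), ncol(bx$B))
  cy <- matrix(stats::rnorm(ncol(by$B) * ncol(bx$B)), ncol(by$B), ncol(bx$B))
  ux <- by$B %*% cx %*% t(bx$B)
  uy <- by$B %*% cy %*% t(bx$B)
  mag <- sqrt(ux^2 + uy^2)
  s <- if (max(mag) > 0) maxPx / max(mag) else 0
  new("DeformationField", ux = ux * s, uy = uy * s,
      gridSpacingPx = gridSpacingPx,
      rmsVsDistance = data.frame())
}

#' Generate a ground-truthed synthetic taste-bud scene
#'
#' Packs `nCells` elongated, radially oriented cells into a circular bud,
#' draws per-cell classes from `classFractions`, transcript counts from the
#' count model, spot positions inside each cell footprint, response
#' amplitudes, basolateral nerve ROIs, per-round rigid transforms, a smooth
#' fixation warp, and fiducial blob positions. Deterministic for fixed seed.
#'
#' @param nCells number of cells (>= 1).
#' @param classFractions named fractions over sweet/umami/dual/sour/silent;
#'   must sum to 1 (+/- 1e-9).
#' @param geneCountParams list as [defaultGeneCountParams()].
#' @param imgSize c(height, width) px.
#' @param budDiameterUm bud diameter in microns (default 60, within the
#'   40-80 um range typical of a mouse fungiform bud).
#' @param pixelSizeUm microns per pixel (default 0.5).
#' @param nPlanes axial planes for functional rendering (3-4).
#' @param nNerves number of basolateral afferent-nerve ROIs.
#' @param nRounds number of histology rounds for which rigid truth is drawn.
#' @param warpMaxPx maximum fixation-warp displacement (px); 0 disables.
#' @param rigidRotSdDeg,rigidTransSdPx spread of the per-round rigid truth.
#' @param amplitude peak dF/F of responding cells.
#' @param spotMinSepPx if > 0, enforce this minimum separation between true
#'   spot positions of the same gene (resamples; may lower a cell's count if
#'   its footprint cannot hold the draw, with a warning).
#' @param cellAxesPx c(long, short) semi-axes of the elongated footprints.
#' @param seed integer seed.
#' @return A [SceneGroundTruth-class].
#' @export
generateScene <- function(nCells = 20,
                          classFractions = c(sweet = 0.3, umami = 0.3,
                                             dual = 0.2, sour = 0.1,
                                             silent = 0.1),
                          geneCountParams = defaultGeneCountParams(),
                          imgSize = c(128, 128), budDiameterUm = 60,
                          pixelSizeUm = 0.5, nPlanes = 3L, nNerves = 3L,
                          nRounds = 3L, warpMaxPx = 2,
                          rigidRotSdDeg = 2, rigidTransSdPx = 10,
                          amplitude = 0.5, spotMinSepPx = 0,
                          cellAxesPx = c(12, 5), seed = 1) {
  stopifnot(nCells >= 1)
  if (abs(sum(classFractions) - 1) > 1e-9)
    stop("class fractions must sum to 1")
  if (is.null(names(classFractions)) ||
      !all(names(classFractions) %in% names(classHighGenes)))
    stop("classFractions must be named with sweet/umami/dual/sour/silent")
  set.seed(deriveSeed(seed, "scene"))
  h <- imgSize[1]; w <- imgSize[2]
  cx <- (w - 1) / 2; cy <- (h - 1) / 2
  budR <- budDiameterUm / pixelSizeUm / 2
  if (budR > min(h, w) / 2 - 2) stop("bud does not fit in the image")
  a <- cellAxesPx[1]; b <- cellAxesPx[2]
  if (nCells * pi * a * b > 0.95 * pi * budR^2)
    stop("packing error: bud too small for ", nCells, " cells of this size")

  # --- centroid packing: rejection sampling with minimum separation
  minSep <- 1.9 * b
  cent <- matrix(NA_real_, nCells, 2)
  placed <- 0L; tries <- 0L
  while (placed < nCells) {
    tries <- tries + 1L
    if (tries > 20000L) stop("packing error: could not place ", nCells, " cells")
    r <- budR * (0.15 + 0.75 * sqrt(stats::runif(1)))
    th <- stats::runif(1, 0, 2 * pi)
    p <- c(cx + r * cos(th), cy + r * sin(th))
    if (placed > 0 &&
        min(sqrt(colSums((t(cent[seq_len(placed), , drop = FALSE]) - p)^2))) < minSep)
      next
    placed <- placed + 1L
    cent[placed, ] <- p
  }

  # --- elongated footprints, radially oriented, assigned by normalized
  # elliptical distance (nearest cell wins, so footprints never overlap)
  g <- coordGrid(h, w)
  inBud <- (g$x - cx)^2 + (g$y - cy)^2 <= budR^2
  best <- matrix(Inf, h, w); lab <- matrix(0, h, w)
  for (i in seq_len(nCells)) {
    phi <- atan2(cent[i, 2] - cy, cent[i, 1] - cx)
    dx <- g$x - cent[i, 1]; dy <- g$y - cent[i, 2]
    u <- dx * cos(phi) + dy * sin(phi)
    v <- -dx * sin(phi) + dy * cos(phi)
    d <- (u / a)^2 + (v / b)^2
    upd <- inBud & d <= 1 & d < best
    best[upd] <- d[upd]; lab[upd] <- i
  }
  if (length(setdiff(seq_len(nCells), unique(as.integer(lab)))))
    stop("packing error: a cell footprint collapsed; lower nCells")

  classes <- sample(names(classFractions), nCells, replace = TRUE,
                    prob = classFractions)
  counts <- drawCounts(classes, geneCountParams)

  # --- true spot positions: uniform over the cell footprint (optionally
  # with a same-gene minimum separation for well-separated-spot studies)
  pix <- lapply(seq_len(nCells), function(i) which(lab == i, arr.ind = TRUE))
  spots <- list()
  for (gene in tasteGenes()) {
    acc <- matrix(numeric(0), 0, 2)
    for (i in seq_len(nCells)) {
      k <- counts[i, gene]
      if (k == 0) next
      px <- pix[[i]]
      got <- matrix(numeric(0), 0, 2); attempts <- 0L
      while (nrow(got) < k && attempts < 200L * k) {
        attempts <- attempts + 1L
        j <- sample.int(nrow(px), 1)
        p <- c(px[j, 2] - 1 + stats::runif(1, -0.5, 0.5),
               px[j, 1] - 1 + stats::runif(1, -0.5, 0.5))
        if (spotMinSepPx > 0) {
          prev <- rbind(got, acc)
          if (nrow(prev) &&
              min(sqrt(colSums((t(prev) - p)^2))) < spotMinSepPx) next
        }
        got <- rbind(got, p)
      }
      if (nrow(got) < k) {
        warning("spot packing: cell ", i, " gene ", gene, " holds only ",
                nrow(got), " of ", k, " spots at separation ", spotMinSepPx)
        counts[i, gene] <- nrow(got)
      }
      if (nrow(got))
        spots[[length(spots) + 1L]] <- data.frame(
          gene = gene, x = got[, 1], y = got[, 2], z_plane = 0L, cell = i)
      acc <- rbind(acc, got)
    }
  }
  spots <- if (length(spots)) do.call(rbind, spots) else
    data.frame(gene = character(0), x = numeric(0), y = numeric(0),
               z_plane = integer(0), cell = integer(0))

  ampMap <- defaultAmplitudeMap(amplitude)
  amps <- ampMap[classes, , drop = FALSE]
  rownames(amps) <- NULL

  # --- basolateral nerve ROIs: small circular polygons at the bud periphery
  nerves <- list()
  if (nNerves > 0) {
    tunings <- sample(c("sweet", "umami", "dual"), nNerves, replace = TRUE)
    thetas <- stats::runif(1, 0, 2 * pi) + 2 * pi * seq_len(nNerves) / nNerves
    for (j in seq_len(nNerves)) {
      c0 <- c(cx + 0.75 * budR * cos(thetas[j]),
              cy + 0.75 * budR * sin(thetas[j]))
      ang <- seq(0, 2 * pi, length.out = 17)[-17]
      poly <- cbind(c0[1] + 4.5 * cos(ang), c0[2] + 4.5 * sin(ang))
      amp <- setNames(numeric(3), tasteTastants())
      if (tunings[j] %in% c("sweet", "dual")) amp["sweet"] <- amplitude
      if (tunings[j] %in% c("umami", "dual")) amp["umami"] <- amplitude
      nerves[[j]] <- list(id = paste0("nerve", j), polygon = poly,
                          tuning = tunings[j], amplitudes = amp)
    }
  }

  rigid <- vector("list", nRounds)
  rigid[[1]] <- rigidTransform(0, c(0, 0), c(cx, cy))
  for (r in seq_len(nRounds)[-1])
    rigid[[r]] <- rigidTransform(stats::rnorm(1, 0, rigidRotSdDeg),
                                 stats::rnorm(2, 0, rigidTransSdPx),
                                 c(cx, cy))

  warp <- if (warpMaxPx > 0) randomWarpField(h, w, warpMaxPx) else
    new("DeformationField", ux = matrix(0, h, w), uy = matrix(0, h, w),
        gridSpacingPx = 64, rmsVsDistance = data.frame())

  nf <- 5L
  fid <- data.frame(
    x = cx + (budR + 8) * cos(2 * pi * seq_len(nf) / nf + 0.3),
    y = cy + (budR + 8) * sin(2 * pi * seq_len(nf) / nf + 0.3))
  fid <- fid[fid$x > 4 & fid$x < w - 5 & fid$y > 4 & fid$y < h - 5, ]

  cen <- data.frame(cell = seq_len(nCells), x = cent[, 1], y = cent[, 2],
                    z_plane = 0L)
  new("SceneGroundTruth", labels = lab, centroids = cen,
      cellClass = classes, trueCounts = counts, spots = spots,
      amplitudes = amps, nerveRois = nerves, rigidTruth = rigid,
      warpTruth = warp, fiducials = fid, pixelSizeUm = pixelSizeUm,
      nPlanes = as.integer(nPlanes), seed = seed)
}
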