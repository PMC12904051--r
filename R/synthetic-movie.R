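# Render a two-channel functional movie from a scene: red (tdTomato) is a
# static structural channel; green (GCaMP6f) is red modulated by per-ROI
# dF/F kinetics during matching stimulus epochs. Apical taste-cell somata and
# basolateral afferent-nerve signals live on distinct axial planes.

# dF/F kinetics: fast exponential rise during the epoch, exponential decay
# after offset. Plateaus near the peak amplitude well before epoch end.
dffKinetics <- function(timeS, onset, offset, amp, tauOn = 1, tauOff = 4) {
  d <- numeric(length(timeS))
  during <- timeS >= onset & timeS < offset
  d[during] <- amp * (1 - exp(-(timeS[during] - onset) / tauOn))
  post <- timeS >= offset
  dEnd <- amp * (1 - exp(-(offset - onset) / tauOn))
  d[post] <- dEnd * exp(-(timeS[post] - offset) / tauOff)
  d
}

#' Render a synthetic functional movie
#'
#' The red channel is the static structural image of the scene (per-cell
#' tdTomato levels plus background); the green channel equals red times
#' `1 + dF/F(t)` with the scene's per-cell/per-nerve amplitudes driving the
#' kinetics during matching epochs. Cell responses are rendered on plane 1
#' (apical); nerve-ROI responses on the deepest plane (basolateral). Optional
#' per-frame rigid jitter (<= `motionAmplitudePx`, uniform) is applied
#' identically to both channels and recorded as ground truth; Gaussian noise
#' with SD `noiseSigma` (fraction of the dynamic range) is added per frame.
#'
#' @param scene a [SceneGroundTruth-class].
#' @param schedule a [StimulusSchedule-class]; must fit the movie duration.
#' @param noiseSigma Gaussian noise SD as a fraction of dynamic range (>= 0).
#' @param motionAmplitudePx max |jitter| per axis in px (0 disables).
#' @param seed integer seed.
#' @return A [TasteBudMovie-class].
#' @export
renderFunctionalMovie <- function(scene, schedule, noiseSigma = 0.02,
                                  motionAmplitudePx = 0, seed = 1) {
  if (noiseSigma < 0) stop("noiseSigma must be >= 0")
  set.seed(deriveSeed(seed, "movie"))
  h <- nrow(scene@labels); w <- ncol(scene@labels)
  np <- scene@nPlanes
  dur <- scheduleDuration(schedule)
  nt <- floor(dur * schedule@frameRate)
  timeS <- (seq_len(nt) - 1) / schedule@frameRate
  n <- nCells(scene)

  # static red structural image: per-cell tdTomato level + dim background
  levels <- stats::runif(n, 0.5, 1)
  red0 <- matrix(0.05, h, w)
  red0[scene@labels > 0] <- levels[scene@labels[scene@labels > 0]]
  nerveMasks <- lapply(scene@nerveRois, function(nv)
    polygonMask(nv$polygon, h, w))
  redBaso <- matrix(0.05, h, w)
  redBaso[scene@labels > 0] <- 0.3 * levels[scene@labels[scene@labels > 0]]
  for (m in nerveMasks) redBaso[m] <- 0.8

  # per-ROI dF/F time courses
  cellDff <- matrix(0, n, nt)
  tast <- intersect(schedule@tastant, colnames(scene@amplitudes))
  for (tt in tast) {
    i <- which(schedule@tastant == tt)[1]
    for (cId in seq_len(n)) {
      a <- scene@amplitudes[cId, tt]
      if (a > 0)
        cellDff[cId, ] <- cellDff[cId, ] +
          dffKinetics(timeS, schedule@onset[i], schedule@offset[i], a)
    }
  }
  nerveDff <- matrix(0, max(1, length(scene@nerveRois)), nt)
  for (j in seq_along(scene@nerveRois)) {
    for (tt in tast) {
      i <- which(schedule@tastant == tt)[1]
      a <- scene@nerveRois[[j]]$amplitudes[tt]
      if (!is.na(a) && a > 0)
        nerveDff[j, ] <- nerveDff[j, ] +
          dffKinetics(timeS, schedule@onset[i], schedule@offset[i], a)
    }
  }

  green <- array(0, c(h, w, np, nt))
  red <- array(0, c(h, w, np, nt))
  cellIdx <- lapply(seq_len(n), function(i) which(scene@labels == i))
  jit <- if (motionAmplitudePx > 0)
    cbind(dx = stats::runif(nt, -motionAmplitudePx, motionAmplitudePx),
          dy = stats::runif(nt, -motionAmplitudePx, motionAmplitudePx))
  else cbind(dx = numeric(nt), dy = numeric(nt))

  for (t in seq_len(nt)) {
    gA <- red0                       # apical plane green
    for (i in seq_len(n)) {
      d <- cellDff[i, t]
      if (d != 0) gA[cellIdx[[i]]] <- red0[cellIdx[[i]]] * (1 + d)
    }
    gB <- redBaso                    # basolateral plane green
    for (j in seq_along(scene@nerveRois)) {
      d <- nerveDff[j, t]
      if (d != 0) gB[nerveMasks[[j]]] <- redBaso[nerveMasks[[j]]] * (1 + d)
    }
    for (p in seq_len(np)) {
      isBaso <- p == np
      gp <- if (isBaso) gB else gA
      rp <- if (isBaso) redBaso else red0
      if (jit[t, 1] != 0 || jit[t, 2] != 0) {
        gp <- shiftImage(gp, jit[t, 1], jit[t, 2])
        rp <- shiftImage(rp, jit[t, 1], jit[t, 2])
      }
      if (noiseSigma > 0) {
        gp <- gp + matrix(stats::rnorm(h * w, 0, noiseSigma), h, w)
        rp <- rp + matrix(stats::rnorm(h * w, 0, noiseSigma), h, w)
      }
      green[, , p, t] <- gp
      red[, , p, t] <- rp
    }
  }
  new("TasteBudMovie", green = green, red = red, schedule = schedule,
      shiftsTruth = data.frame(frame = seq_len(nt), dx = jit[, 1],
                               dy = jit[, 2]),
      pixelSizeUm = scene@pixelSizeUm)
}
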