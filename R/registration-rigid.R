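# Rigid (rotation + translation) registration of nuclear-stained round
# images to the round-1 reference: exhaustive coarse rotation search with
# FFT cross-correlation for translation, then Nelder-Mead refinement of
# normalized cross-correlation under bilinear warping.

# NCC between ref and the rigidly warped moving image, over the warp-valid
# region.
rigidScore <- function(ref, moving, par, center) {
  tf <- rigidTransform(par[1], par[2:3], center)
  g <- coordGrid(nrow(ref), ncol(ref))
  inv <- invertTransform(tf)
  p <- rigidMapPoints(inv, cbind(as.numeric(g$x), as.numeric(g$y)))
  valid <- p[, 1] >= 0 & p[, 1] <= ncol(ref) - 1 &
    p[, 2] >= 0 & p[, 2] <= nrow(ref) - 1
  if (sum(valid) < 0.25 * length(valid)) return(-1)
  wv <- bilinearSample(moving, p[valid, 1], p[valid, 2])
  stats::cor(wv, as.numeric(ref)[valid])
}

#' Rigid registration of a round image to the reference
#'
#' Estimates the rotation + translation that aligns `roundNuclear` to
#' `referenceNuclear`: for each rotation on a coarse grid the best
#' translation is found by FFT cross-correlation, and the best candidate is
#' refined by Nelder-Mead on the normalized cross-correlation. Deterministic
#' for fixed inputs.
#'
#' @param referenceNuclear round-1 nuclear image (matrix).
#' @param roundNuclear later-round nuclear image (same geometry).
#' @param rotRangeDeg coarse rotation search half-range (deg).
#' @param rotStepDeg coarse rotation step (deg).
#' @return A [RigidTransform2D-class] `T` such that
#'   `applyTransform(roundNuclear, T)` is aligned to the reference.
#' @export
registerRigid <- function(referenceNuclear, roundNuclear, rotRangeDeg = 8,
                          rotStepDeg = 1) {
  stopifnot(all(dim(referenceNuclear) == dim(roundNuclear)))
  if (stats::sd(referenceNuclear) < 1e-12 || stats::sd(roundNuclear) < 1e-12)
    stop("degenerate content: featureless image")
  h <- nrow(referenceNuclear); w <- ncol(referenceNuclear)
  center <- c((w - 1) / 2, (h - 1) / 2)
  nrm <- function(m) (m - mean(m)) / stats::sd(m)
  ref <- nrm(referenceNuclear); mov <- nrm(roundNuclear)

  best <- NULL
  for (th in seq(-rotRangeDeg, rotRangeDeg, by = rotStepDeg)) {
    rot <- applyTransform(mov, rigidTransform(th, c(0, 0), center))
    s <- estimateShiftFFT(ref, rot, subpixel = FALSE)
    par <- c(th, -s[1], -s[2])
    sc <- rigidScore(ref, mov, par, center)
    if (is.null(best) || sc > best$score) best <- list(par = par, score = sc)
  }
  res <- stats::optim(best$par, function(p) -rigidScore(ref, mov, p, center),
                      method = "Nelder-Mead",
                      control = list(maxit = 600, reltol = 1e-10,
                                     parscale = c(0.5, 1, 1)))
  rigidTransform(res$par[1], res$par[2:3], center)
}
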