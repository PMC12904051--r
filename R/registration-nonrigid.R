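# B-spline free-form non-rigid registration. The displacement field is a
# tensor-product cubic B-spline over a regular control lattice; coefficients
# are optimized by L-BFGS-B on the mean squared intensity difference with an
# analytic gradient, over a 3-level multiresolution pyramid. Returns the
# dense deformation vector field used for distortion QC.

# Cubic B-spline kernel (support |s| < 2, in units of the grid spacing).
bspline3 <- function(s) {
  s <- abs(s)
  out <- numeric(length(s))
  i1 <- s < 1; i2 <- !i1 & s < 2
  out[i1] <- (4 - 6 * s[i1]^2 + 3 * s[i1]^3) / 6
  out[i2] <- (2 - s[i2])^3 / 6
  out
}

# Basis matrix for n pixels at full-resolution coordinates `coords`
# (default 0..n-1) against a lattice with spacing h covering [0, extent-1].
bsplineBasis <- function(n, h, extent = n, coords = 0:(n - 1)) {
  k <- seq(-1, ceiling((extent - 1) / h) + 1)
  g <- k * h
  B <- outer(coords, g, function(x, gk) bspline3((x - gk) / h))
  list(B = B, knots = g)
}

#' Non-rigid (B-spline) registration of two images
#'
#' Estimates a smooth displacement field u such that
#' `moving(p + u(p)) ~= fixed(p)`, by multiresolution L-BFGS-B minimization
#' of the mean squared intensity difference over a cubic B-spline control
#' lattice. Intended for the small fixation-induced distortion between the
#' in vivo reporter image and the round-1 fixed reporter image.
#'
#' @param fixed,moving numeric matrices of identical size.
#' @param gridSpacingPx control-grid spacing in px (default 32).
#' @param levels downsampling factors of the pyramid, coarse to fine.
#' @param maxIter L-BFGS-B iteration budget per level.
#' @param tol relative convergence tolerance (factr-style).
#' @return List with `field` (a [DeformationField-class]) and `warped`
#'   (the moving image resampled through the field, bilinear).
#' @export
registerNonrigid <- function(fixed, moving, gridSpacingPx = 32,
                             levels = c(4, 2, 1), maxIter = 80,
                             tol = 1e-10) {
  stopifnot(all(dim(fixed) == dim(moving)))
  h <- nrow(fixed); w <- ncol(fixed)
  # normalize intensities so the metric scale is image-independent
  nrm <- function(m) (m - mean(m)) / max(stats::sd(m), 1e-12)
  fixed <- nrm(fixed); moving <- nrm(moving)
  kx <- ncol(bsplineBasis(w, gridSpacingPx)$B)
  ky <- ncol(bsplineBasis(h, gridSpacingPx)$B)
  Cx <- matrix(0, ky, kx); Cy <- matrix(0, ky, kx)

  for (f in levels) {
    fL <- downsampleImage(fixed, f); mL <- downsampleImage(moving, f)
    hL <- nrow(fL); wL <- ncol(fL)
    # full-resolution coordinates of level pixel centers
    xc <- f * (0:(wL - 1)) + (f - 1) / 2
    yc <- f * (0:(hL - 1)) + (f - 1) / 2
    Bx <- bsplineBasis(wL, gridSpacingPx, extent = w, coords = xc)$B
    By <- bsplineBasis(hL, gridSpacingPx, extent = h, coords = yc)$B
    stopifnot(ncol(Bx) == kx, ncol(By) == ky)
    gr <- imageGradients(mL)
    g <- coordGrid(hL, wL)
    npix <- hL * wL
    unpack <- function(par) list(
      Cx = matrix(par[seq_len(ky * kx)], ky, kx),
      Cy = matrix(par[ky * kx + seq_len(ky * kx)], ky, kx))
    evalWarp <- function(C) {
      ux <- (By %*% C$Cx %*% t(Bx)) / f   # level-pixel units
      uy <- (By %*% C$Cy %*% t(Bx)) / f
      sx <- g$x + ux; sy <- g$y + uy
      list(sx = sx, sy = sy)
    }
    fn <- function(par) {
      s <- evalWarp(unpack(par))
      wv <- bilinearSample(mL, as.numeric(s$sx), as.numeric(s$sy))
      mean((wv - as.numeric(fL))^2)
    }
    grad <- function(par) {
      s <- evalWarp(unpack(par))
      sx <- as.numeric(s$sx); sy <- as.numeric(s$sy)
      wv <- bilinearSample(mL, sx, sy)
      r <- matrix(2 * (wv - as.numeric(fL)) / npix, hL, wL)
      gxs <- matrix(bilinearSample(gr$gx, sx, sy), hL, wL)
      gys <- matrix(bilinearSample(gr$gy, sx, sy), hL, wL)
      dX <- t(By) %*% (r * gxs) %*% Bx / f
      dY <- t(By) %*% (r * gys) %*% Bx / f
      c(as.numeric(dX), as.numeric(dY))
    }
    res <- stats::optim(c(as.numeric(Cx), as.numeric(Cy)), fn, grad,
                        method = "L-BFGS-B",
                        control = list(maxit = maxIter, factr = tol / 1e-15))
    C <- unpack(res$par)
    Cx <- C$Cx; Cy <- C$Cy
  }

  BxF <- bsplineBasis(w, gridSpacingPx)$B
  ByF <- bsplineBasis(h, gridSpacingPx)$B
  ux <- ByF %*% Cx %*% t(BxF)
  uy <- ByF %*% Cy %*% t(BxF)
  field <- new("DeformationField", ux = ux, uy = uy,
               gridSpacingPx = gridSpacingPx, rmsVsDistance = data.frame())
  gFull <- coordGrid(h, w)
  warped <- matrix(bilinearSample(moving, as.numeric(gFull$x) + as.numeric(ux),
                                  as.numeric(gFull$y) + as.numeric(uy)), h, w)
  list(field = field, warped = warped)
}

#' RMS error of a deformation field against matched point truth
#'
#' For every pair (i, j) of matched centroids, the residual between the true
#' and the field-predicted relative displacement,
#' `|(u_true(p_i) - u_true(p_j)) - (u(p_i) - u(p_j))|`, is expressed as a
#' percentage of the inter-point distance and aggregated as an RMS per
#' distance bin. This is the distortion-QC curve (RMS error vs measured
#' distance).
#'
#' @param field recovered [DeformationField-class].
#' @param points data.frame/matrix of matched centroids (x, y), 0-based px.
#' @param trueOffsets two-column matrix of true displacements at `points`
#'   (same convention as the field), or a [DeformationField-class] holding
#'   the ground-truth warp.
#' @param breaks distance bin edges in px.
#' @param distRange pairs outside this distance range (px) are ignored.
#' @return List with `table` (data.frame distance_px, rms_pct, n_pairs) and
#'   `overallRmsPct` (RMS over all retained pairs); the table is also stored
#'   in the returned `field`'s `rmsVsDistance` slot (`$field`).
#' @export
deformationRmsError <- function(field, points, trueOffsets,
                                breaks = seq(0, 300, by = 20),
                                distRange = c(0, Inf)) {
  pts <- as.matrix(points[, c("x", "y")])
  if (nrow(pts) < 2) stop("need >= 2 matched points")
  if (is(trueOffsets, "DeformationField"))
    trueOffsets <- fieldAt(trueOffsets, pts[, 1], pts[, 2])
  trueOffsets <- as.matrix(trueOffsets)
  pred <- fieldAt(field, pts[, 1], pts[, 2])
  n <- nrow(pts)
  ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  dvec <- pts[ij[, 1], , drop = FALSE] - pts[ij[, 2], , drop = FALSE]
  dist <- sqrt(rowSums(dvec^2))
  relTrue <- trueOffsets[ij[, 1], , drop = FALSE] -
    trueOffsets[ij[, 2], , drop = FALSE]
  relPred <- pred[ij[, 1], , drop = FALSE] - pred[ij[, 2], , drop = FALSE]
  resid <- sqrt(rowSums((relTrue - relPred)^2))
  keep <- dist >= distRange[1] & dist <= distRange[2] & dist > 0
  dist <- dist[keep]; resid <- resid[keep]
  pct <- 100 * resid / dist
  bin <- cut(dist, breaks, include.lowest = TRUE)
  tab <- do.call(rbind, lapply(levels(bin), function(b) {
    sel <- bin == b
    if (!any(sel)) return(NULL)
    data.frame(distance_px = mean(dist[sel]),
               rms_pct = sqrt(mean(pct[sel]^2)), n_pairs = sum(sel))
  }))
  field@rmsVsDistance <- tab
  list(table = tab, overallRmsPct = sqrt(mean(pct^2)), field = field)
}
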