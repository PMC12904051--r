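# Applying rigid transforms and deformation fields to images, label masks
# and point sets. Intensity images are resampled with bilinear interpolation;
# label masks with nearest-neighbor lookup (labels are never blended); points
# are mapped analytically.

rotMat <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
}

# Forward map of 0-based points (n x 2 matrix): p' = R (p - c) + c + t
rigidMapPoints <- function(tf, pts) {
  pts <- as.matrix(pts)
  R <- rotMat(tf@rotationDeg)
  sweep(sweep(pts, 2, tf@centerPx) %*% t(R), 2,
        tf@centerPx + tf@translationPx, "+")
}

#' Invert a rigid transform
#'
#' @param transform a [RigidTransform2D-class].
#' @return The inverse transform (same center).
#' @export
invertTransform <- function(transform) {
  Rinv <- rotMat(-transform@rotationDeg)
  rigidTransform(-transform@rotationDeg,
                 as.numeric(-Rinv %*% transform@translationPx),
                 transform@centerPx)
}

#' Apply a spatial transform to an image, label mask or point set
#'
#' For a [RigidTransform2D-class] `T`, the output image at position p is the
#' input sampled at `T^-1(p)` (so image content moves forward through `T`),
#' and points are mapped forward as `T(p)`. For a [DeformationField-class]
#' `u`, the output image at p is the input sampled at `p + u(p)` (pull-back
#' warp, as produced by [registerNonrigid()]), and points p are mapped to
#' their sample position `p + u(p)` in the moving frame.
#'
#' @param obj numeric matrix (intensity image), [CellMask-class], or a
#'   two-column matrix/data.frame of 0-based (x, y) points.
#' @param transform a [RigidTransform2D-class] or [DeformationField-class].
#' @param interpolation "bilinear" (default for intensity images) or
#'   "nearest" (always used for label masks).
#' @return Transformed object of the same kind.
#' @export
setGeneric("applyTransform", function(obj, transform, ...)
  standardGeneric("applyTransform"))

resampleAt <- function(img, sx, sy, interpolation) {
  h <- nrow(img); w <- ncol(img)
  if (interpolation == "nearest") {
    xi <- pmin(pmax(round(sx), 0), w - 1)
    yi <- pmin(pmax(round(sy), 0), h - 1)
    matrix(img[cbind(yi + 1, xi + 1)], h, w)
  } else {
    matrix(bilinearSample(img, sx, sy), h, w)
  }
}

#' @rdname applyTransform
#' @export
setMethod("applyTransform", signature("matrix", "RigidTransform2D"),
  function(obj, transform, interpolation = "bilinear") {
    g <- coordGrid(nrow(obj), ncol(obj))
    inv <- invertTransform(transform)
    p <- rigidMapPoints(inv, cbind(as.numeric(g$x), as.numeric(g$y)))
    resampleAt(obj, p[, 1], p[, 2], interpolation)
  })

#' @rdname applyTransform
#' @export
setMethod("applyTransform", signature("matrix", "DeformationField"),
  function(obj, transform, interpolation = "bilinear") {
    g <- coordGrid(nrow(obj), ncol(obj))
    sx <- as.numeric(g$x) + as.numeric(transform@ux)
    sy <- as.numeric(g$y) + as.numeric(transform@uy)
    resampleAt(obj, sx, sy, interpolation)
  })

#' @rdname applyTransform
#' @export
setMethod("applyTransform", signature("CellMask", "RigidTransform2D"),
  function(obj, transform, ...) {
    lab <- applyTransform(obj@labels, transform, interpolation = "nearest")
    cellMask(lab, round = obj@round, provenance = obj@provenance)
  })

#' @rdname applyTransform
#' @export
setMethod("applyTransform", signature("CellMask", "DeformationField"),
  function(obj, transform, ...) {
    lab <- applyTransform(obj@labels, transform, interpolation = "nearest")
    cellMask(lab, round = obj@round, provenance = obj@provenance)
  })

#' @rdname applyTransform
#' @export
setMethod("applyTransform", signature("data.frame", "RigidTransform2D"),
  function(obj, transform, ...) {
    stopifnot(all(c("x", "y") %in% names(obj)))
    p <- rigidMapPoints(transform, cbind(obj$x, obj$y))
    obj$x <- p[, 1]; obj$y <- p[, 2]
    obj
  })

#' @rdname applyTransform
#' @export
setMethod("applyTransform", signature("data.frame", "DeformationField"),
  function(obj, transform, ...) {
    stopifnot(all(c("x", "y") %in% names(obj)))
    u <- fieldAt(transform, obj$x, obj$y)
    obj$x <- obj$x + u[, 1]; obj$y <- obj$y + u[, 2]
    obj
  })

#' @rdname applyTransform
#' @export
setMethod("applyTransform", signature("HistologyRound", "RigidTransform2D"),
  function(obj, transform, ...) {
    obj@nuclear <- applyTransform(obj@nuclear, transform)
    if (!is.null(obj@reporter))
      obj@reporter <- applyTransform(obj@reporter, transform)
    obj@fish <- lapply(obj@fish, applyTransform, transform = transform)
    obj
  })
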