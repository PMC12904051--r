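# Low-level image helpers shared by the synthetic renderer, registration and
# spot calling. Convention everywhere: images are R matrices indexed
# [row, col] = [y + 1, x + 1]; coordinates are 0-based, pixel-center, with
# x = column and y = row. Transforms act about the image center
# ((W-1)/2, (H-1)/2).

#' Sample an image at subpixel positions (bilinear)
#'
#' Coordinates are 0-based pixel-center; positions outside the image are
#' clamped to the border (replicate padding).
#'
#' @param img numeric matrix.
#' @param x,y numeric vectors of equal length, 0-based coordinates.
#' @return Numeric vector of sampled values.
#' @export
bilinearSample <- function(img, x, y) {
  h <- nrow(img); w <- ncol(img)
  x <- pmin(pmax(as.numeric(x), 0), w - 1)
  y <- pmin(pmax(as.numeric(y), 0), h - 1)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  x1 <- pmin(x0 + 1, w - 1); y1 <- pmin(y0 + 1, h - 1)
  i00 <- cbind(y0 + 1, x0 + 1); i01 <- cbind(y0 + 1, x1 + 1)
  i10 <- cbind(y1 + 1, x0 + 1); i11 <- cbind(y1 + 1, x1 + 1)
  (1 - fy) * ((1 - fx) * img[i00] + fx * img[i01]) +
    fy * ((1 - fx) * img[i10] + fx * img[i11])
}

# Pixel-center coordinate grids (0-based) for an H x W image.
coordGrid <- function(h, w) {
  list(x = matrix(rep(0:(w - 1), each = h), h, w),
       y = matrix(rep(0:(h - 1), times = w), h, w))
}

#' Shift an image by a subpixel translation
#'
#' `shiftImage(img, dx, dy)` moves the image content by `(+dx, +dy)` pixels:
#' the output at position `p` equals the input at `p - (dx, dy)` (replicate
#' padding at the borders).
#'
#' @param img numeric matrix.
#' @param dx,dy translation in pixels (x = columns, y = rows).
#' @return Shifted matrix of the same size.
#' @export
shiftImage <- function(img, dx, dy) {
  g <- coordGrid(nrow(img), ncol(img))
  matrix(bilinearSample(img, g$x - dx, g$y - dy), nrow(img), ncol(img))
}

# Separable Gaussian blur with replicate padding. Kernel radius 3*sigma.
gaussBlur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2)); k <- k / sum(k)
  pad <- function(m, r) {
    m <- rbind(m[rep(1L, r), , drop = FALSE], m, m[rep(nrow(m), r), , drop = FALSE])
    cbind(m[, rep(1L, r), drop = FALSE], m, m[, rep(ncol(m), r), drop = FALSE])
  }
  p <- pad(img, r)
  # convolve rows then columns
  conv1 <- function(m, k, r) {
    out <- matrix(0, nrow(m) - 2 * r, ncol(m))
    for (j in seq_along(k)) out <- out + k[j] * m[j:(j + nrow(out) - 1L), , drop = FALSE]
    out
  }
  q <- conv1(p, k, r)
  t(conv1(t(q), k, r))[, , drop = TRUE]
}

# Block-mean downsample by integer factor f (with light pre-blur), used by the
# multiresolution registration pyramid. Crops to a multiple of f.
downsampleImage <- function(img, f) {
  if (f == 1) return(img)
  img <- gaussBlur(img, f / 2)
  h <- (nrow(img) %/% f) * f; w <- (ncol(img) %/% f) * f
  img <- img[seq_len(h), seq_len(w), drop = FALSE]
  m <- matrix(0, h %/% f, w %/% f)
  for (i in seq_len(f)) for (j in seq_len(f))
    m <- m + img[seq(i, h, by = f), seq(j, w, by = f)]
  m / (f * f)
}

# Central-difference spatial gradients (replicate borders).
imageGradients <- function(img) {
  h <- nrow(img); w <- ncol(img)
  gx <- (img[, c(2:w, w)] - img[, c(1, 1:(w - 1))]) / 2
  gy <- (img[c(2:h, h), ] - img[c(1, 1:(h - 1)), ]) / 2
  list(gx = gx, gy = gy)
}

#' Otsu threshold of a numeric vector or image
#'
#' Exhaustive between-class-variance maximization over a 256-bin histogram of
#' the input values. Deterministic; invariant under positive affine scaling
#' of the input up to binning.
#'
#' @param x numeric vector or matrix.
#' @param nbins number of histogram bins.
#' @return Scalar threshold; values strictly greater are foreground.
#' @export
otsuThreshold <- function(x, nbins = 256L) {
  v <- as.numeric(x)
  v <- v[is.finite(v)]
  rng <- range(v)
  if (diff(rng) == 0) stop("otsuThreshold: input is constant (degenerate)")
  br <- seq(rng[1], rng[2], length.out = nbins + 1L)
  h <- tabulate(findInterval(v, br, rightmost.closed = TRUE), nbins)
  p <- h / sum(h)
  mids <- (br[-1] + br[-length(br)]) / 2
  w0 <- cumsum(p); mu <- cumsum(p * mids); muT <- mu[nbins]
  w1 <- 1 - w0
  ok <- w0 > 0 & w1 > 0
  bcv <- rep(-Inf, nbins)
  bcv[ok] <- (muT * w0[ok] - mu[ok])^2 / (w0[ok] * w1[ok])
  mids[which.max(bcv)]
}

# Pearson correlation between two images over an optional logical mask.
imageCor <- function(a, b, mask = NULL) {
  if (!is.null(mask)) { a <- a[mask]; b <- b[mask] }
  stats::cor(as.numeric(a), as.numeric(b))
}

# FFT cross-correlation translation estimate with parabolic subpixel
# refinement. Returns s = (dx, dy) such that img(p) ~= ref(p - s), i.e. the
# content of `img` is displaced by +s relative to `ref`.
estimateShiftFFT <- function(ref, img, subpixel = TRUE) {
  h <- nrow(ref); w <- ncol(ref)
  a <- ref - mean(ref); b <- img - mean(img)
  cc <- Re(stats::fft(stats::fft(b) * Conj(stats::fft(a)), inverse = TRUE)) / (h * w)
  pk <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  wrap <- function(i, n) ifelse(i > n / 2, i - n, i)
  dy <- wrap(pk[1] - 1, h); dx <- wrap(pk[2] - 1, w)
  if (subpixel) {
    at <- function(iy, ix) cc[((iy - 1) %% h) + 1, ((ix - 1) %% w) + 1]
    para <- function(cm, c0, cp) {
      den <- cm - 2 * c0 + cp
      if (den == 0) 0 else max(-0.5, min(0.5, 0.5 * (cm - cp) / den))
    }
    dx <- dx + para(at(pk[1], pk[2] - 1), at(pk[1], pk[2]), at(pk[1], pk[2] + 1))
    dy <- dy + para(at(pk[1] - 1, pk[2]), at(pk[1], pk[2]), at(pk[1] + 1, pk[2]))
  }
  c(dx = unname(dx), dy = unname(dy))
}

# Rasterize a polygon (vertices in 0-based x,y) to a logical mask using the
# even-odd rule at pixel centers.
polygonMask <- function(poly, h, w) {
  g <- coordGrid(h, w)
  px <- poly[, 1]; py <- poly[, 2]
  n <- length(px)
  inside <- matrix(FALSE, h, w)
  j <- n
  for (i in seq_len(n)) {
    cross <- ((py[i] > g$y) != (py[j] > g$y)) &
      (g$x < (px[j] - px[i]) * (g$y - py[i]) / (py[j] - py[i]) + px[i])
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

# Render isotropic Gaussian blobs at subpixel positions into an H x W image.
# pos: matrix/data.frame with columns x, y (0-based); amp: per-blob amplitude.
renderGaussians <- function(h, w, pos, amp, sigma) {
  img <- matrix(0, h, w)
  if (NROW(pos) == 0) return(img)
  r <- ceiling(4 * sigma)
  for (i in seq_len(NROW(pos))) {
    x0 <- pos[i, 1]; y0 <- pos[i, 2]
    xs <- max(0, floor(x0) - r):min(w - 1, floor(x0) + r)
    ys <- max(0, floor(y0) - r):min(h - 1, floor(y0) + r)
    if (!length(xs) || !length(ys)) next
    gx <- exp(-((xs - x0)^2) / (2 * sigma^2))
    gy <- exp(-((ys - y0)^2) / (2 * sigma^2))
    img[ys + 1, xs + 1] <- img[ys + 1, xs + 1] + amp[i] * outer(gy, gx)
  }
  img
}

# Deterministic per-purpose seed derivation: keeps independent stages
# decorrelated under a single user seed while staying below 2^31.
deriveSeed <- function(seed, salt) {
  (as.numeric(seed) * 2654435761 + sum(utf8ToInt(salt)) * 97) %% 2147483647
}
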