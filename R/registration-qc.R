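# Registration quality control: image correlation over the foreground and
# line-profile peak offsets between reference and registered images.

# Sample an image along a line (0-based endpoints), step ~1 px, Gaussian
# smoothing sigma (px) before peak picking.
lineProfile <- function(img, x0, y0, x1, y1) {
  len <- sqrt((x1 - x0)^2 + (y1 - y0)^2)
  n <- max(2L, ceiling(len) + 1L)
  tpos <- seq(0, 1, length.out = n)
  list(t = tpos * len,
       v = bilinearSample(img, x0 + tpos * (x1 - x0), y0 + tpos * (y1 - y0)))
}

smooth1d <- function(v, sigma = 1) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2)); k <- k / sum(k)
  vp <- c(rep(v[1], r), v, rep(v[length(v)], r))
  out <- numeric(length(v))
  for (j in seq_along(k)) out <- out + k[j] * vp[j:(j + length(v) - 1L)]
  out
}

#' Default QC profile lines
#'
#' Three lines (horizontal, vertical, diagonal) through the brightest
#' structure of the (smoothed) reference, so each profile carries one
#' dominant peak -- the equivalent of drawing a line through a clearly
#' identifiable landmark.
#'
#' @param reference reference image.
#' @return List of c(x0, y0, x1, y1) 0-based endpoints.
#' @export
defaultProfileLines <- function(reference) {
  h <- nrow(reference); w <- ncol(reference)
  sm <- gaussBlur(reference, 2)
  pk <- which(sm == max(sm), arr.ind = TRUE)[1, ]
  py <- pk[1] - 1; px <- pk[2] - 1
  r <- min(px, w - 1 - px, py, h - 1 - py)
  list(c(0, py, w - 1, py), c(px, 0, px, h - 1),
       c(px - r, py - r, px + r, py + r))
}

#' Registration QC: foreground correlation and line-profile peak offsets
#'
#' Pearson correlation between reference and registered image over the
#' reference's Otsu foreground, plus per-line peak offsets: each profile is
#' smoothed (Gaussian sigma 1 px) and the distance between the argmax
#' positions in the two images is reported (ties broken to the leftmost
#' maximum; flat profiles are flagged with `NA`).
#'
#' @param reference,registered numeric matrices of identical size.
#' @param profileLines list of c(x0, y0, x1, y1); default
#'   [defaultProfileLines()].
#' @param peakWindowPx the registered profile's peak is searched within this
#'   distance of the reference peak, so the offset measures the displacement
#'   of the *corresponding* structure rather than jumping to an unrelated
#'   maximum elsewhere on the line.
#' @return List (class `RegistrationQC`): `pearsonR`, `peakOffsetsPx`,
#'   `maxPeakOffsetPx`.
#' @export
registrationQC <- function(reference, registered, profileLines = NULL,
                           peakWindowPx = 15) {
  stopifnot(all(dim(reference) == dim(registered)))
  if (is.null(profileLines)) profileLines <- defaultProfileLines(reference)
  fg <- reference > otsuThreshold(reference)
  r <- imageCor(reference, registered, fg)
  offs <- vapply(profileLines, function(ln) {
    pr <- lineProfile(reference, ln[1], ln[2], ln[3], ln[4])
    pg <- lineProfile(registered, ln[1], ln[2], ln[3], ln[4])
    sr <- smooth1d(pr$v); sg <- smooth1d(pg$v)
    if (diff(range(sr)) < 1e-12 || diff(range(sg)) < 1e-12) return(NA_real_)
    iRef <- which.max(sr)
    win <- abs(pg$t - pr$t[iRef]) <= peakWindowPx
    iReg <- which(win)[which.max(sg[win])]
    abs(pr$t[iRef] - pg$t[iReg])
  }, 0)
  structure(list(pearsonR = r, peakOffsetsPx = offs,
                 maxPeakOffsetPx = if (all(is.na(offs))) NA_real_
                 else max(offs, na.rm = TRUE)),
            class = "RegistrationQC")
}

#' @export
print.RegistrationQC <- function(x, ...) {
  cat(sprintf("RegistrationQC: pearson r = %.4f, max peak offset = %s px\n",
              x$pearsonR,
              if (is.na(x$maxPeakOffsetPx)) "NA"
              else sprintf("%.2f", x$maxPeakOffsetPx)))
  invisible(x)
}
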