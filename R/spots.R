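# smFISH spot calling: difference-of-Gaussians filtering, global background
# subtraction, thresholded local maxima with minimum-separation suppression,
# subpixel 2-D Gaussian fitting with a local planar background term, and
# digital (dHCR) per-cell counting against a label mask.

#' Spot-calling parameters
#'
#' @param dogSigmaSmall,dogSigmaLarge DoG sigmas in px (small < large);
#'   defaults (1, 2) match a ~1.5 px spot PSF.
#' @param minSeparationPx minimum distance between accepted maxima (default
#'   5; among maxima within this radius only the brightest is kept).
#' @param threshold absolute DoG threshold, or "auto" (median + 5 x robust
#'   SD, 1.4826*MAD, of the DoG image).
#' @param fitWindowPx half-width of the Gaussian-fit window (px).
#' @return Named list of parameters.
#' @export
spotCallParams <- function(dogSigmaSmall = 1, dogSigmaLarge = 2,
                           minSeparationPx = 5, threshold = "auto",
                           fitWindowPx = 3L) {
  stopifnot(dogSigmaSmall < dogSigmaLarge, minSeparationPx > 0)
  list(dogSigmaSmall = dogSigmaSmall, dogSigmaLarge = dogSigmaLarge,
       minSeparationPx = minSeparationPx, threshold = threshold,
       fitWindowPx = as.integer(fitWindowPx))
}

# Gaussian + planar-background least squares fit in a window around an
# integer peak. Returns subpixel center, amplitude, and a convergence flag;
# falls back to the integer maximum on divergence.
fitSpotGaussian <- function(img, px, py, win, sigma0) {
  h <- nrow(img); w <- ncol(img)
  xs <- max(0, px - win):min(w - 1, px + win)
  ys <- max(0, py - win):min(h - 1, py + win)
  z <- img[ys + 1, xs + 1, drop = FALSE]
  X <- rep(xs, each = length(ys)); Y <- rep(ys, times = length(xs))
  zv <- as.numeric(z)
  # profile out the linear parameters (amplitude + planar background); only
  # (x0, y0, sigma) are optimized
  linfit <- function(p) {
    g <- exp(-((X - p[1])^2 + (Y - p[2])^2) / (2 * p[3]^2))
    A <- cbind(g, 1, X - px, Y - py)
    beta <- tryCatch(qr.solve(A, zv), error = function(e) NULL)
    if (is.null(beta)) return(NULL)
    list(beta = beta, sse = sum((zv - A %*% beta)^2))
  }
  obj <- function(p) {
    if (p[3] < 0.3 || p[3] > 4 * sigma0) return(1e12)
    lf <- linfit(p)
    if (is.null(lf)) return(1e12)
    lf$sse
  }
  fit <- tryCatch(
    stats::optim(c(px, py, sigma0), obj, method = "Nelder-Mead",
                 control = list(maxit = 500, reltol = 1e-12)),
    error = function(e) NULL)
  ok <- FALSE
  if (!is.null(fit) && abs(fit$par[1] - px) <= win &&
      abs(fit$par[2] - py) <= win) {
    lf <- linfit(fit$par)
    ok <- !is.null(lf) && lf$beta[1] > 0
  }
  if (ok) list(x = fit$par[1], y = fit$par[2], amplitude = lf$beta[1],
               fitted = TRUE)
  else list(x = px, y = py, amplitude = max(zv) - stats::median(zv),
            fitted = FALSE)
}

#' Detect smFISH spots in a single-channel image
#'
#' DoG filter, global background (image median) subtraction, local maxima
#' above threshold with minimum-separation suppression (brightest wins),
#' then a subpixel 2-D Gaussian fit with a local planar background term.
#'
#' @param image numeric matrix.
#' @param params list from [spotCallParams()].
#' @param gene,round annotations copied into the output.
#' @param zPlane plane index annotation.
#' @return data.frame: x, y, z_plane, gene, round, amplitude, dog_value,
#'   fitted, cell_label (0 = unassigned). Empty for a blank image.
#' @export
detectSpots <- function(image, params = spotCallParams(), gene = NA_character_,
                        round = 1L, zPlane = 0L) {
  stopifnot(is.matrix(image))
  dog <- gaussBlur(image, params$dogSigmaSmall) -
    gaussBlur(image, params$dogSigmaLarge)
  dog <- dog - stats::median(dog)
  thr <- if (identical(params$threshold, "auto")) {
    # robust-SD rule with an absolute floor so clean (noise-free) images do
    # not degenerate to a zero threshold
    max(5 * stats::mad(dog), 1e-3 * diff(range(image)))
  } else params$threshold
  h <- nrow(dog); w <- ncol(dog)
  emptyTab <- data.frame(x = numeric(0), y = numeric(0), z_plane = integer(0),
                         gene = character(0), round = integer(0),
                         amplitude = numeric(0), dog_value = numeric(0),
                         fitted = logical(0), cell_label = integer(0))
  if (thr <= 0 || !any(dog > thr)) return(emptyTab)
  # 8-neighborhood local maxima above threshold
  pad <- matrix(-Inf, h + 2, w + 2); pad[2:(h + 1), 2:(w + 1)] <- dog
  isMax <- dog > thr
  for (dy in -1:1) for (dx in -1:1) {
    if (dx == 0 && dy == 0) next
    isMax <- isMax & dog >= pad[(2 + dy):(h + 1 + dy), (2 + dx):(w + 1 + dx)]
  }
  idx <- which(isMax, arr.ind = TRUE)
  if (!nrow(idx)) return(emptyTab)
  cand <- data.frame(px = idx[, 2] - 1, py = idx[, 1] - 1,
                     v = dog[idx])
  cand <- cand[order(-cand$v), ]
  # minimum-separation suppression: greedily keep the brightest
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (i == 1) { keep[1] <- TRUE; next }
    prev <- cand[keep, , drop = FALSE]
    d2 <- (prev$px - cand$px[i])^2 + (prev$py - cand$py[i])^2
    keep[i] <- min(d2) >= params$minSeparationPx^2
  }
  cand <- cand[keep, , drop = FALSE]
  out <- lapply(seq_len(nrow(cand)), function(i) {
    f <- fitSpotGaussian(image, cand$px[i], cand$py[i], params$fitWindowPx,
                         params$dogSigmaSmall * 1.5)
    data.frame(x = min(max(f$x, 0), w - 1), y = min(max(f$y, 0), h - 1),
               z_plane = as.integer(zPlane), gene = gene,
               round = as.integer(round), amplitude = f$amplitude,
               dog_value = cand$v[i], fitted = f$fitted, cell_label = 0L)
  })
  do.call(rbind, out)
}

#' Merge duplicate spot detections across adjacent planes
#'
#' Detections of the same gene within `lateralTolPx` laterally on adjacent
#' z-planes are collapsed to the brightest one, preventing double counting
#' in pseudo-volumetric acquisitions.
#'
#' @param spots data.frame from [detectSpots()] (possibly several planes).
#' @param lateralTolPx lateral merge radius (default 2 px).
#' @return Filtered spot data.frame.
#' @export
mergeSpotsAcrossPlanes <- function(spots, lateralTolPx = 2) {
  if (!nrow(spots)) return(spots)
  spots <- spots[order(spots$gene, -spots$amplitude), ]
  drop <- logical(nrow(spots))
  for (i in seq_len(nrow(spots))) {
    if (drop[i]) next
    same <- which(!drop & spots$gene == spots$gene[i] &
                    abs(spots$z_plane - spots$z_plane[i]) == 1 &
                    (spots$x - spots$x[i])^2 + (spots$y - spots$y[i])^2 <=
                      lateralTolPx^2)
    drop[setdiff(same, i)] <- TRUE
  }
  spots[!drop, ]
}

#' Digital per-cell, per-gene spot counting
#'
#' Each spot is assigned to the label it falls inside; background spots
#' within `assignRadiusPx` of exactly one label go to that label, of several
#' labels to the nearest boundary (a deterministic stand-in for manual
#' dense-region curation; exact ties are left unassigned), and farther
#' spots stay unassigned. Counts are integer tallies (digital HCR).
#'
#' @param spots data.frame with x, y, gene (round-1 frame; transform first
#'   with [applyTransform()] if detected on a later round).
#' @param mask [CellMask-class] or label matrix in the round-1 frame.
#' @param assignRadiusPx background-assignment radius (default 2).
#' @return List: `counts` (data.frame cell x gene, one row per label,
#'   including zero rows), `spots` (input with cell_label filled),
#'   `unassigned` (number of unassigned spots).
#' @export
countSpotsPerCell <- function(spots, mask, assignRadiusPx = 2) {
  lab <- if (is(mask, "CellMask")) mask@labels else mask
  h <- nrow(lab); w <- ncol(lab)
  labs <- sort(unique(as.integer(lab[lab > 0])))
  genes <- sort(unique(as.character(spots$gene)))
  if (nrow(spots)) {
    if (any(spots$x < -0.5 | spots$x > w - 0.5 |
            spots$y < -0.5 | spots$y > h - 0.5))
      stop("geometry error: spot outside mask bounds")
    assign1 <- function(x, y) {
      xi <- min(max(round(x), 0), w - 1); yi <- min(max(round(y), 0), h - 1)
      l0 <- lab[yi + 1, xi + 1]
      if (l0 > 0) return(l0)
      r <- ceiling(assignRadiusPx) + 1L
      xs <- max(0, xi - r):min(w - 1, xi + r)
      ys <- max(0, yi - r):min(h - 1, yi + r)
      sub <- lab[ys + 1, xs + 1, drop = FALSE]
      px <- rep(xs, each = length(ys)); py <- rep(ys, times = length(xs))
      lv <- as.integer(sub)
      sel <- lv > 0
      if (!any(sel)) return(0L)
      d <- sqrt((px[sel] - x)^2 + (py[sel] - y)^2)
      near <- lv[sel][d <= assignRadiusPx]
      dn <- d[d <= assignRadiusPx]
      if (!length(near)) return(0L)
      cands <- unique(near)
      if (length(cands) == 1) return(cands)
      dmin <- vapply(cands, function(l) min(dn[near == l]), 0)
      o <- order(dmin)
      if (length(cands) > 1 && abs(dmin[o[1]] - dmin[o[2]]) < 1e-9)
        return(0L)                      # exact tie -> unassigned
      cands[o[1]]
    }
    spots$cell_label <- vapply(seq_len(nrow(spots)), function(i)
      as.integer(assign1(spots$x[i], spots$y[i])), 0L)
  }
  counts <- matrix(0L, length(labs), length(genes),
                   dimnames = list(labs, genes))
  if (nrow(spots) && length(genes)) {
    asg <- spots[spots$cell_label > 0, , drop = FALSE]
    if (nrow(asg)) {
      tb <- table(factor(asg$cell_label, labs), factor(asg$gene, genes))
      counts <- counts + as.integer(tb)
      dim(counts) <- c(length(labs), length(genes))
      dimnames(counts) <- list(labs, genes)
    }
  }
  countsDf <- data.frame(cell = labs, counts, check.names = FALSE)
  list(counts = countsDf, spots = spots,
       unassigned = if (nrow(spots)) sum(spots$cell_label == 0) else 0L)
}

#' Round-to-round spot-count stability
#'
#' Per-cell count differences between two rounds probing the same gene, the
#' least-squares concordance slope through the origin, and a two-sided
#' Wilcoxon matched-pairs test.
#'
#' @param countsA,countsB numeric vectors named by cell (or data.frames with
#'   columns cell and one gene column).
#' @param gene gene column to compare when data.frames are given.
#' @return List: `deltas`, `slope`, `wilcoxonP`.
#' @export
spotCountStability <- function(countsA, countsB, gene = NULL) {
  getv <- function(x) {
    if (is.data.frame(x)) {
      g <- if (is.null(gene)) setdiff(names(x), "cell")[1] else gene
      stats::setNames(x[[g]], x$cell)
    } else x
  }
  a <- getv(countsA); b <- getv(countsB)
  if (!is.null(names(a)) && !is.null(names(b))) {
    common <- intersect(names(a), names(b))
    if (!length(common)) stop("index error: disjoint cell sets")
    a <- a[common]; b <- b[common]
  } else if (length(a) != length(b)) stop("index error: length mismatch")
  slope <- if (sum(a^2) > 0) sum(a * b) / sum(a^2) else NA_real_
  p <- if (all(a == b)) 1 else
    suppressWarnings(stats::wilcox.test(a, b, paired = TRUE)$p.value)
  list(deltas = b - a, slope = slope, wilcoxonP = p)
}
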