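# Cell segmentation from the round-1 cytosolic reporter (tdTomato):
# Otsu foreground -> distance-transform watershed -> area filter. A
# programmatic, deterministic stand-in for interactive curation; imported
# hand-curated masks are first-class via loadMask().

#' Segment cells from a cytosolic reporter image
#'
#' Otsu thresholding of the (lightly smoothed) reporter, Euclidean distance
#' transform, watershed with peak-merging tolerance, then an area filter.
#' Labels are relabeled to contiguous 1..n. Deterministic.
#'
#' @param reporterImage numeric matrix (round-1 reporter channel).
#' @param minAreaPx,maxAreaPx area bounds in px^2 (defaults 50-2000, the
#'   taste-cell footprint scale at 0.5 um/px).
#' @param smoothSigma Gaussian presmoothing sigma (px).
#' @param tolerance watershed peak-merging tolerance (distance-map units).
#' @return A [CellMask-class] with provenance "programmatic". An image with
#'   no foreground yields an empty mask with a warning, not an error.
#' @export
segmentCells <- function(reporterImage, minAreaPx = 50, maxAreaPx = 2000,
                         smoothSigma = 1, tolerance = 2) {
  img <- gaussBlur(reporterImage, smoothSigma)
  thr <- tryCatch(otsuThreshold(img), error = function(e) NA_real_)
  if (is.na(thr) || !any(img > thr)) {
    warning("no foreground found; returning empty mask")
    return(cellMask(matrix(0, nrow(img), ncol(img))))
  }
  fg <- img > thr
  dm <- EBImage::distmap(matrix(as.numeric(fg), nrow(fg), ncol(fg)))
  ws <- EBImage::watershed(dm, tolerance = tolerance, ext = 2)
  lab <- as.matrix(ws)
  # area filter + contiguous relabeling
  areas <- tabulate(lab[lab > 0])
  keep <- which(areas >= minAreaPx & areas <= maxAreaPx)
  out <- matrix(0, nrow(lab), ncol(lab))
  for (i in seq_along(keep)) out[lab == keep[i]] <- i
  cellMask(out)
}

#' Load a label mask from a TIFF file
#'
#' Reads a 16-bit label-image TIFF (as written by [writeMask()]), validates
#' the [CellMask-class] invariants, and marks the provenance as imported --
#' the entry point for hand-curated masks.
#'
#' @param path TIFF path.
#' @param round imaging round the mask belongs to.
#' @return A [CellMask-class].
#' @export
loadMask <- function(path, round = 1L) {
  m <- tiff::readTIFF(path)
  if (is.array(m) && length(dim(m)) == 3) m <- m[, , 1]
  lab <- round(m * 65535)
  if (any(lab < 0)) stop("validation error: negative labels")
  cellMask(lab, round = round, provenance = "imported")
}

#' Write a label mask to a 16-bit TIFF
#'
#' @param mask a [CellMask-class] (labels must be < 65536).
#' @param path output path.
#' @return Invisibly, the path.
#' @export
writeMask <- function(mask, path) {
  lab <- mask@labels
  if (max(lab) > 65535) stop("labels exceed 16-bit range")
  tiff::writeTIFF(lab / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Propagate a round-1 mask to later rounds
#'
#' Nearest-neighbor label transport through each round's rigid transform
#' (labels are never blended, so label identity is preserved across rounds).
#'
#' @param mask round-1 [CellMask-class].
#' @param transforms named/indexed list of [RigidTransform2D-class], the
#'   transform for round r mapping round-1 coordinates into round-r
#'   coordinates (i.e. the inverse of the round-to-reference registration
#'   result).
#' @return List of [CellMask-class], one per transform.
#' @export
propagateMask <- function(mask, transforms) {
  if (!length(transforms)) stop("configuration error: no transforms supplied")
  lapply(seq_along(transforms), function(r) {
    tf <- transforms[[r]]
    if (is.null(tf))
      stop("configuration error: missing transform for round ", r)
    out <- applyTransform(mask, tf)
    out@round <- as.integer(r)
    out
  })
}

# Per-label IoU against a ground-truth mask with greedy best-overlap
# matching; used by tests and the pipeline report.
maskIoU <- function(mask, truthLabels) {
  lab <- if (is(mask, "CellMask")) mask@labels else mask
  segs <- sort(unique(lab[lab > 0])); trus <- sort(unique(truthLabels[truthLabels > 0]))
  iou <- matrix(0, length(trus), length(segs))
  for (i in seq_along(trus)) {
    ti <- truthLabels == trus[i]
    for (j in seq_along(segs)) {
      sj <- lab == segs[j]
      inter <- sum(ti & sj)
      if (inter > 0) iou[i, j] <- inter / sum(ti | sj)
    }
  }
  best <- apply(iou, 1, max)
  data.frame(truth = trus, iou = best)
}
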