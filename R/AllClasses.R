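# S4 containers for the correlative pipeline.

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' StimulusSchedule: tastant epochs of a functional recording
#'
#' Ordered, non-overlapping tastant application epochs plus the baseline
#' (artificial saliva) window, in seconds, and the acquisition frame rate.
#' The default protocol applies artificial saliva for the first 20 s, then
#' for each tastant 20 s of stimulus followed by 50 s of washout.
#'
#' @slot tastant character vector of epoch tastant names.
#' @slot onset,offset numeric vectors (s).
#' @slot baselineWindow numeric length-2 (start, end) in s.
#' @slot frameRate frames per second.
#' @export
setClass("StimulusSchedule",
  representation(tastant = "character", onset = "numeric", offset = "numeric",
                 baselineWindow = "numeric", frameRate = "numeric"),
  validity = function(object) {
    n <- length(object@tastant)
    if (length(object@onset) != n || length(object@offset) != n)
      return("onset/offset length must match tastant")
    if (any(object@offset <= object@onset)) return("epoch offset must exceed onset")
    if (n > 1) {
      o <- order(object@onset)
      if (any(object@onset[o][-1] < object@offset[o][-n]))
        return("epochs must be non-overlapping")
    }
    if (length(object@baselineWindow) != 2 ||
        diff(object@baselineWindow) <= 0)
      return("baselineWindow must be (start, end) with end > start")
    if (n > 0 && object@baselineWindow[2] > min(object@onset))
      return("baseline must precede the first stimulus epoch")
    if (object@frameRate <= 0) return("frameRate must be positive")
    TRUE
  })

#' Construct the default stimulus schedule
#'
#' @param tastants tastants applied, in order.
#' @param baselineS baseline (saliva) duration in s.
#' @param stimS stimulus duration per tastant in s.
#' @param washS washout duration after each tastant in s.
#' @param frameRate acquisition rate (Hz).
#' @return A [StimulusSchedule-class] object.
#' @export
stimulusSchedule <- function(tastants = tasteTastants(), baselineS = 20,
                             stimS = 20, washS = 50, frameRate = 1) {
  n <- length(tastants)
  onset <- baselineS + (seq_len(n) - 1) * (stimS + washS)
  new("StimulusSchedule", tastant = tastants, onset = onset,
      offset = onset + stimS, baselineWindow = c(0, baselineS),
      frameRate = frameRate)
}

#' @describeIn StimulusSchedule-class total duration in seconds.
#' @param x,object a `StimulusSchedule`.
#' @export
setGeneric("scheduleDuration", function(x) standardGeneric("scheduleDuration"))
#' @export
setMethod("scheduleDuration", "StimulusSchedule", function(x) {
  if (length(x@offset)) max(x@offset) + 50 else x@baselineWindow[2]
})

setMethod("show", "StimulusSchedule", function(object) {
  cat("StimulusSchedule:", length(object@tastant), "epochs @",
      object@frameRate, "Hz\n")
  cat(sprintf("  baseline %g-%g s\n", object@baselineWindow[1],
              object@baselineWindow[2]))
  for (i in seq_along(object@tastant))
    cat(sprintf("  %-6s %g-%g s\n", object@tastant[i], object@onset[i],
                object@offset[i]))
})

#' RigidTransform2D: rotation + translation about a center
#'
#' Forward mapping of a point p (0-based x,y): `p' = R (p - c) + c + t`,
#' where R is the rotation by `rotationDeg` (counter-clockwise in the x-right,
#' y-down convention), c the center and t the translation in px.
#'
#' @slot rotationDeg rotation in degrees.
#' @slot translationPx numeric length-2 (dx, dy) in px.
#' @slot centerPx numeric length-2 (cx, cy) in px.
#' @export
setClass("RigidTransform2D",
  representation(rotationDeg = "numeric", translationPx = "numeric",
                 centerPx = "numeric"),
  validity = function(object) {
    if (length(object@translationPx) != 2) return("translationPx must be length 2")
    if (length(object@centerPx) != 2) return("centerPx must be length 2")
    if (!is.finite(object@rotationDeg)) return("rotationDeg must be finite")
    TRUE
  })

#' @rdname RigidTransform2D-class
#' @param rotationDeg,translationPx,centerPx see slots.
#' @export
rigidTransform <- function(rotationDeg = 0, translationPx = c(0, 0),
                           centerPx = c(0, 0)) {
  new("RigidTransform2D", rotationDeg = rotationDeg,
      translationPx = as.numeric(translationPx), centerPx = as.numeric(centerPx))
}

setMethod("show", "RigidTransform2D", function(object) {
  cat(sprintf("RigidTransform2D: %.4f deg, t = (%.3f, %.3f) px, center (%.1f, %.1f)\n",
              object@rotationDeg, object@translationPx[1], object@translationPx[2],
              object@centerPx[1], object@centerPx[2]))
})

#' DeformationField: dense per-pixel displacement from non-rigid registration
#'
#' `ux`/`uy` give, for each pixel of the fixed frame, the displacement (px)
#' such that the fixed image at p corresponds to the moving image sampled at
#' `p + (ux(p), uy(p))`.
#'
#' @slot ux,uy numeric matrices (same size as the registered images).
#' @slot gridSpacingPx control-grid spacing used by the B-spline model.
#' @slot rmsVsDistance data.frame QC table (filled by
#'   [deformationRmsError()]), or empty.
#' @export
setClass("DeformationField",
  representation(ux = "matrix", uy = "matrix", gridSpacingPx = "numeric",
                 rmsVsDistance = "data.frame"),
  validity = function(object) {
    if (!all(dim(object@ux) == dim(object@uy)))
      return("ux and uy must have identical dimensions")
    if (!all(is.finite(object@ux)) || !all(is.finite(object@uy)))
      return("displacement must be finite everywhere")
    if (nrow(object@rmsVsDistance) &&
        any(object@rmsVsDistance$rms_pct < 0, na.rm = TRUE))
      return("rms_vs_distance entries must be >= 0")
    TRUE
  })

setMethod("show", "DeformationField", function(object) {
  mag <- sqrt(object@ux^2 + object@uy^2)
  cat(sprintf("DeformationField %dx%d px, |u| mean %.3f max %.3f, grid %g px\n",
              nrow(object@ux), ncol(object@ux), mean(mag), max(mag),
              object@gridSpacingPx))
})

#' Evaluate a deformation field at points
#'
#' Bilinear interpolation of the (ux, uy) displacement at 0-based positions.
#'
#' @param field a [DeformationField-class].
#' @param x,y coordinates (0-based px).
#' @return Two-column matrix (ux, uy).
#' @export
fieldAt <- function(field, x, y) {
  cbind(ux = bilinearSample(field@ux, x, y),
        uy = bilinearSample(field@uy, x, y))
}

#' TasteBudMovie: two-channel pseudo-volumetric calcium movie
#'
#' Green (GCaMP6f) and red (tdTomato) channels as 4-D arrays
#' `[y, x, plane, time]`, plus the stimulus schedule. Apical planes carry
#' taste-cell somatic signals; the deepest (basolateral) plane carries
#' afferent-nerve signals.
#'
#' @slot green,red numeric arrays `[y, x, plane, time]`.
#' @slot schedule the [StimulusSchedule-class].
#' @slot shiftsTruth data.frame of injected per-frame rigid jitter
#'   (frame, dx, dy), or empty when none was simulated.
#' @slot pixelSizeUm microns per pixel.
#' @export
setClass("TasteBudMovie",
  representation(green = "array", red = "array", schedule = "StimulusSchedule",
                 shiftsTruth = "data.frame", pixelSizeUm = "numeric"),
  validity = function(object) {
    if (length(dim(object@green)) != 4 || length(dim(object@red)) != 4)
      return("green/red must be 4-D [y, x, plane, time] arrays")
    if (!all(dim(object@green) == dim(object@red)))
      return("green and red must have identical dimensions")
    TRUE
  })

#' @describeIn TasteBudMovie-class number of frames.
#' @param x,object a `TasteBudMovie`.
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
#' @export
setMethod("nFrames", "TasteBudMovie", function(x) dim(x@green)[4])

#' @describeIn TasteBudMovie-class number of axial planes.
#' @export
setGeneric("nPlanes", function(x) standardGeneric("nPlanes"))
#' @export
setMethod("nPlanes", "TasteBudMovie", function(x) dim(x@green)[3])

setMethod("show", "TasteBudMovie", function(object) {
  d <- dim(object@green)
  cat(sprintf("TasteBudMovie %dx%d px, %d planes, %d frames @ %g Hz (%.1f um/px)\n",
              d[1], d[2], d[3], d[4], object@schedule@frameRate,
              object@pixelSizeUm))
})

#' CellMask: integer label image of segmented cells
#'
#' Background is 0; cell labels are positive integers. `provenance` records
#' whether the mask was produced programmatically (watershed) or imported
#' (e.g. hand-curated).
#'
#' @slot labels integer matrix.
#' @slot round imaging round the mask geometry refers to.
#' @slot provenance "programmatic" or "imported".
#' @export
setClass("CellMask",
  representation(labels = "matrix", round = "integer", provenance = "character"),
  validity = function(object) {
    if (any(object@labels < 0)) return("labels must be >= 0 (0 = background)")
    if (any(object@labels != round(object@labels)))
      return("labels must be integers")
    if (!object@provenance %in% c("programmatic", "imported"))
      return("provenance must be 'programmatic' or 'imported'")
    TRUE
  })

#' @rdname CellMask-class
#' @param labels,round,provenance see slots.
#' @export
cellMask <- function(labels, round = 1L, provenance = "programmatic") {
  storage.mode(labels) <- "double"
  new("CellMask", labels = labels, round = as.integer(round),
      provenance = provenance)
}

#' @describeIn CellMask-class sorted vector of cell labels present.
#' @param x,object a `CellMask`.
#' @export
setGeneric("cellLabels", function(x) standardGeneric("cellLabels"))
#' @export
setMethod("cellLabels", "CellMask", function(x) {
  l <- sort(unique(as.integer(x@labels))); l[l > 0]
})

setMethod("show", "CellMask", function(object) {
  cat(sprintf("CellMask %dx%d px, %d cells (round %d, %s)\n",
              nrow(object@labels), ncol(object@labels),
              length(cellLabels(object)), object@round, object@provenance))
})

#' HistologyRound: one round of fixed-tissue imaging
#'
#' A nuclear (Hoechst) channel, an optional cytosolic reporter channel
#' (round 1 only; the reporter is quenched by formamide stripping afterwards)
#' and up to three smFISH payload channels, each tied to a gene.
#'
#' @slot round round number (1-based).
#' @slot nuclear numeric matrix.
#' @slot reporter numeric matrix or NULL (NULL from round 2 on).
#' @slot fish named list of numeric matrices, one per probed gene.
#' @slot transformTruth the simulated round-to-reference rigid transform
#'   (identity for round 1) -- present only for synthetic data.
#' @export
setClass("HistologyRound",
  representation(round = "integer", nuclear = "matrix",
                 reporter = "matrixOrNULL", fish = "list",
                 transformTruth = "RigidTransform2D"),
  validity = function(object) {
    if (length(object@fish) > 3)
      return("at most 3 payload (smFISH) channels per round")
    if (length(object@fish) && is.null(names(object@fish)))
      return("fish channels must be named by gene")
    if (object@round >= 2 && !is.null(object@reporter))
      return("reporter channel must be absent from round 2 onward (quenched)")
    TRUE
  })

setMethod("show", "HistologyRound", function(object) {
  cat(sprintf("HistologyRound %d: nuclear%s%s\n", object@round,
              if (!is.null(object@reporter)) " + reporter" else "",
              if (length(object@fish))
                paste0(" + FISH[", paste(names(object@fish), collapse = ", "), "]")
              else ""))
})

#' SceneGroundTruth: fully known synthetic taste-bud scene
#'
#' Geometry, molecular content and functional amplitudes of a simulated
#' taste bud, in the in-vivo frame. All downstream renderings (functional
#' movie, histology rounds) derive from this object, so every pipeline stage
#' can be scored against truth.
#'
#' @slot labels integer label image (0 background).
#' @slot centroids data.frame (cell, x, y, z_plane).
#' @slot cellClass character per cell: sweet, umami, dual, sour, silent.
#' @slot trueCounts integer matrix cells x genes.
#' @slot spots data.frame (gene, x, y, z_plane, cell) of true mRNA positions.
#' @slot amplitudes numeric matrix cells x tastants (peak dF/F).
#' @slot nerveRois list of lists (id, polygon, tuning, amplitudes).
#' @slot rigidTruth list of [RigidTransform2D-class], one per histology round.
#' @slot warpTruth [DeformationField-class] (in vivo -> fixed) or NULL-sized.
#' @slot fiducials data.frame (x, y) of persistent NIRB-like landmark blobs.
#' @slot pixelSizeUm microns per pixel. @slot nPlanes axial planes.
#' @slot seed generator seed.
#' @export
setClass("SceneGroundTruth",
  representation(labels = "matrix", centroids = "data.frame",
                 cellClass = "character", trueCounts = "matrix",
                 spots = "data.frame", amplitudes = "matrix",
                 nerveRois = "list", rigidTruth = "list",
                 warpTruth = "ANY", fiducials = "data.frame",
                 pixelSizeUm = "numeric", nPlanes = "integer",
                 seed = "numeric"),
  validity = function(object) {
    labs <- sort(unique(as.integer(object@labels)))
    labs <- labs[labs > 0]
    n <- length(object@cellClass)
    if (!identical(labs, seq_len(n)))
      return("labels must be contiguous 1..n_cells")
    if (nrow(object@trueCounts) != n) return("trueCounts rows must match cells")
    if (any(object@trueCounts < 0)) return("trueCounts must be nonnegative")
    bad <- !object@cellClass %in% c("sweet", "umami", "dual", "sour", "silent")
    if (any(bad)) return("unknown cell class")
    sil <- object@cellClass == "silent"
    if (any(object@amplitudes[sil, ] != 0))
      return("silent cells must have zero response amplitude")
    TRUE
  })

#' @describeIn SceneGroundTruth-class number of cells.
#' @param x,object a `SceneGroundTruth`.
#' @export
setGeneric("nCells", function(x) standardGeneric("nCells"))
#' @export
setMethod("nCells", "SceneGroundTruth", function(x) length(x@cellClass))

setMethod("show", "SceneGroundTruth", function(object) {
  cat(sprintf("SceneGroundTruth %dx%d px, %d cells, %d nerve ROIs, seed %g\n",
              nrow(object@labels), ncol(object@labels), nCells(object),
              length(object@nerveRois), object@seed))
  print(table(factor(object@cellClass,
                     c("sweet", "umami", "dual", "sour", "silent"))))
})

#' CalciumTrace: ratiometric trace of one ROI
#'
#' The per-frame ratio mean(G)/mean(R) over the ROI (the ROI means are taken
#' before division, which suppresses division noise at dim pixels), and after
#' [computeDffZscore()] the derived dF/F and Z-score traces with the baseline
#' statistics. Invariants: `dff = ratio/baselineMean - 1` exactly; the
#' Z-score has mean 0 and SD 1 over the baseline window.
#'
#' @slot roiId ROI label (cell label or nerve ROI id).
#' @slot compartment "cell_apical" or "nerve_basolateral".
#' @slot timeS frame times (s).
#' @slot ratio,dff,zscore numeric traces (dff/zscore empty until annotated).
#' @slot baselineMean,baselineSd baseline statistics of the ratio.
#' @export
setClass("CalciumTrace",
  representation(roiId = "character", compartment = "character",
                 timeS = "numeric", ratio = "numeric", dff = "numeric",
                 zscore = "numeric", baselineMean = "numeric",
                 baselineSd = "numeric"),
  validity = function(object) {
    if (!object@compartment %in% c("cell_apical", "nerve_basolateral"))
      return("compartment must be cell_apical or nerve_basolateral")
    if (length(object@dff) && length(object@dff) != length(object@ratio))
      return("dff length must match ratio")
    TRUE
  })

setMethod("show", "CalciumTrace", function(object) {
  cat(sprintf("CalciumTrace %s (%s), %d frames%s\n", object@roiId,
              object@compartment, length(object@ratio),
              if (length(object@baselineMean))
                sprintf(", baseline %.3f +/- %.4f", object@baselineMean,
                        object@baselineSd) else ""))
})
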