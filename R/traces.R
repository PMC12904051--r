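# Functional-trace analysis: rigid motion correction, ratiometric trace
# extraction, dF/F and Z-score conversion, responsiveness classification and
# the sweet-umami response index
#   response index = (meanZ_sweet - meanZ_umami) / (meanZ_sweet + meanZ_umami)
# computed on clamped mean Z-scores (subthreshold responses set to 0).

#' Rigid motion correction of a functional movie
#'
#' Per-frame translational shifts are estimated on the red (tdTomato)
#' structural channel -- summed over planes -- against the temporal-mean
#' reference by FFT cross-correlation with parabolic subpixel refinement,
#' and applied identically to both channels and all planes.
#'
#' @param movie a [TasteBudMovie-class] (>= 2 frames).
#' @return List with `movie` (corrected) and `shifts` (data.frame frame,
#'   dx, dy of the estimated content displacement that was removed).
#' @export
motionCorrect <- function(movie) {
  nt <- nFrames(movie)
  if (nt < 2) stop("motion correction needs >= 2 frames")
  np <- nPlanes(movie)
  sumR <- function(t) {
    m <- movie@red[, , 1, t]
    if (np > 1) for (p in 2:np) m <- m + movie@red[, , p, t]
    m
  }
  frames <- lapply(seq_len(nt), sumR)
  ref <- Reduce(`+`, frames) / nt
  if (stats::sd(ref) < 1e-12)
    stop("degenerate reference: red channel has no structure")
  shifts <- t(vapply(frames, function(f) estimateShiftFFT(ref, f),
                     c(dx = 0, dy = 0)))
  g <- movie@green; r <- movie@red
  for (t in seq_len(nt)) {
    if (abs(shifts[t, 1]) < 1e-3 && abs(shifts[t, 2]) < 1e-3) next
    for (p in seq_len(np)) {
      g[, , p, t] <- shiftImage(g[, , p, t], -shifts[t, 1], -shifts[t, 2])
      r[, , p, t] <- shiftImage(r[, , p, t], -shifts[t, 1], -shifts[t, 2])
    }
  }
  out <- movie; out@green <- g; out@red <- r
  list(movie = out,
       shifts = data.frame(frame = seq_len(nt), dx = shifts[, 1],
                           dy = shifts[, 2]))
}

#' Extract ratiometric traces from a movie
#'
#' One trace per cell label (apical plane 1) and per nerve ROI polygon
#' (deepest, basolateral plane). The ratio is mean(G)/mean(R) with the ROI
#' means taken per frame before the division. Empty ROIs are skipped with a
#' warning.
#'
#' @param movie a [TasteBudMovie-class].
#' @param masks [CellMask-class] (or label matrix) in movie geometry.
#' @param nerveRois optional list of nerve ROIs (each a list with `id` and
#'   `polygon`, as in [SceneGroundTruth-class]).
#' @return List of [CalciumTrace-class] objects.
#' @export
extractTraces <- function(movie, masks, nerveRois = list()) {
  lab <- if (is(masks, "CellMask")) masks@labels else masks
  d <- dim(movie@green)
  if (!all(dim(lab) == d[1:2]))
    stop("masks are not aligned to the movie frame geometry")
  nt <- d[4]; np <- d[3]
  timeS <- (seq_len(nt) - 1) / movie@schedule@frameRate
  traces <- list()
  roiTrace <- function(idx, plane, id, compartment) {
    if (!length(idx)) {
      warning("empty ROI ", id, " skipped")
      return(NULL)
    }
    gm <- vapply(seq_len(nt), function(t) mean(movie@green[, , plane, t][idx]),
                 0)
    rm_ <- vapply(seq_len(nt), function(t) mean(movie@red[, , plane, t][idx]),
                  0)
    new("CalciumTrace", roiId = as.character(id), compartment = compartment,
        timeS = timeS, ratio = gm / rm_, dff = numeric(0),
        zscore = numeric(0), baselineMean = numeric(0),
        baselineSd = numeric(0))
  }
  for (l in sort(unique(lab[lab > 0]))) {
    tr <- roiTrace(which(lab == l), 1L, l, "cell_apical")
    if (!is.null(tr)) traces[[length(traces) + 1L]] <- tr
  }
  for (nv in nerveRois) {
    m <- polygonMask(nv$polygon, d[1], d[2])
    tr <- roiTrace(which(m), np, nv$id, "nerve_basolateral")
    if (!is.null(tr)) traces[[length(traces) + 1L]] <- tr
  }
  traces
}

#' Annotate a trace with dF/F, Z-score and baseline statistics
#'
#' `dff = ratio/baselineMean - 1`; `zscore = (ratio - baselineMean) /
#' baselineSd`, with the baseline mean and (sample) SD computed over the
#' baseline window. A constant baseline (SD 0) is an error, not silent
#' zeros.
#'
#' @param trace a [CalciumTrace-class].
#' @param baselineWindow numeric (start, end) in s; >= 5 frames long.
#' @return The annotated trace.
#' @export
computeDffZscore <- function(trace, baselineWindow) {
  sel <- trace@timeS >= baselineWindow[1] & trace@timeS < baselineWindow[2]
  if (sum(sel) < 5) stop("baseline window must span >= 5 frames")
  bm <- mean(trace@ratio[sel]); bs <- stats::sd(trace@ratio[sel])
  if (bs == 0)
    stop("degenerate baseline: ratio is constant over the baseline window")
  trace@baselineMean <- bm; trace@baselineSd <- bs
  trace@dff <- trace@ratio / bm - 1
  trace@zscore <- (trace@ratio - bm) / bs
  trace
}

#' Classify per-tastant responsiveness of a trace
#'
#' A tastant epoch is called responsive when both printed criteria hold:
#' the peak Z-score during stimulation exceeds `sdMult` (the 2-SD rule) AND
#' the mean Z-score during stimulation exceeds `meanZCutoff` (the mean-Z >= 1
#' rule). Non-responsive epochs have their mean Z clamped to 0
#' (`mean_z_clamped`), which is what the response index consumes.
#'
#' @param trace an annotated [CalciumTrace-class] (see [computeDffZscore()]).
#' @param schedule a [StimulusSchedule-class] within the trace duration.
#' @param sdMult peak-Z threshold (default 2).
#' @param meanZCutoff mean-Z threshold (default 1).
#' @return data.frame: roi_id, compartment, tastant, max_z, mean_z,
#'   responsive, mean_z_clamped.
#' @export
classifyResponsiveness <- function(trace, schedule, sdMult = 2,
                                   meanZCutoff = 1) {
  if (!length(trace@zscore))
    stop("trace must be annotated with computeDffZscore() first")
  if (max(schedule@offset) > max(trace@timeS) + 1 / schedule@frameRate)
    stop("schedule epochs extend beyond the trace duration")
  out <- lapply(seq_along(schedule@tastant), function(i) {
    sel <- trace@timeS >= schedule@onset[i] & trace@timeS < schedule@offset[i]
    mz <- mean(trace@zscore[sel]); mx <- max(trace@zscore[sel])
    resp <- (mx > sdMult) && (mz > meanZCutoff)
    data.frame(roi_id = trace@roiId, compartment = trace@compartment,
               tastant = schedule@tastant[i], max_z = mx, mean_z = mz,
               responsive = resp,
               mean_z_clamped = if (resp) max(mz, 0) else 0)
  })
  do.call(rbind, out)
}

#' Sweet-umami response index
#'
#' `(S - U) / (S + U)` on the clamped mean Z-scores: +1 for sweet-only
#' responders, -1 for umami-only, intermediate values for dual-tuned. When
#' both clamped values are 0 the ROI is excluded (`NA` is returned).
#'
#' @param summary data.frame from [classifyResponsiveness()] for one ROI, or
#'   any data.frame with columns tastant and mean_z_clamped.
#' @param sweet,umami tastant names.
#' @return Numeric index in [-1, 1], or `NA` (excluded).
#' @export
responseIndex <- function(summary, sweet = "sweet", umami = "umami") {
  s <- summary$mean_z_clamped[summary$tastant == sweet]
  u <- summary$mean_z_clamped[summary$tastant == umami]
  if (!length(s) || !length(u))
    stop("summary must contain both the sweet and the umami tastant")
  s <- s[1]; u <- u[1]
  if (s < 0 || u < 0) stop("clamped mean-Z values must be >= 0")
  if (s == 0 && u == 0) return(NA_real_)
  (s - u) / (s + u)
}

#' Tuning class from a response index
#'
#' +1 -> "sweet", -1 -> "umami", intermediate -> "dual" (the analysis is
#' about responsiveness, not magnitude, so every intermediate value counts
#' as dual-tuned), `NA` -> "excluded".
#'
#' @param index numeric response index or `NA`.
#' @return Character tuning class.
#' @export
classifyTuning <- function(index) {
  if (is.na(index)) return("excluded")
  if (abs(index) > 1 + 1e-12)
    stop("internal-consistency error: |response index| > 1")
  if (index >= 1) "sweet" else if (index <= -1) "umami" else "dual"
}

#' Per-ROI response summary table
#'
#' Convenience wrapper: annotates every trace, classifies responsiveness per
#' tastant, and appends the response index and tuning class per ROI.
#'
#' @param traces list of [CalciumTrace-class].
#' @param schedule a [StimulusSchedule-class].
#' @param baselineWindow optional (start, end) s; defaults to the schedule's
#'   baseline (the initial saliva epoch).
#' @param sdMult,meanZCutoff responsiveness thresholds.
#' @return List with `epochs` (ROI x tastant rows) and `rois` (one row per
#'   ROI with response_index and tuning_class).
#' @export
summarizeResponses <- function(traces, schedule, baselineWindow = NULL,
                               sdMult = 2, meanZCutoff = 1) {
  if (is.null(baselineWindow)) baselineWindow <- schedule@baselineWindow
  epochs <- do.call(rbind, lapply(traces, function(tr) {
    tr <- computeDffZscore(tr, baselineWindow)
    classifyResponsiveness(tr, schedule, sdMult, meanZCutoff)
  }))
  rois <- do.call(rbind, lapply(split(epochs, epochs$roi_id), function(d) {
    idx <- if (all(c("sweet", "umami") %in% d$tastant))
      responseIndex(d) else NA_real_
    data.frame(roi_id = d$roi_id[1], compartment = d$compartment[1],
               response_index = idx,
               tuning_class = classifyTuning(idx))
  }))
  rownames(rois) <- NULL
  list(epochs = epochs, rois = rois)
}
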