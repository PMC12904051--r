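# Correlative integration: merge per-cell functional, mRNA and IF data into
# multimodal profiles and run the correlative statistics (IF positivity,
# receptor-class calling against the CA4+ negative control, afferent
# adjacency, dual-tuning attribution).

#' Build multimodal single-cell profiles
#'
#' One row per cell label of the round-1 mask, merging spot counts
#' (`count_<gene>`), IF intensity/status (`if_<protein>`,
#' `if_intensity_<protein>`) and functional summaries (`mean_z_<tastant>`,
#' `responsive_<tastant>`, tuning). A modality missing for a cell stays
#' `NA` (explicit null), never a silent zero. A label present in a table but
#' absent from the mask is a consistency error.
#'
#' @param mask [CellMask-class] (round-1 frame) or vector of cell labels.
#' @param countTable data.frame with `cell` + one column per gene, or NULL.
#' @param ifTable data.frame with `cell`, `protein`, `intensity`
#'   (+ optional `positive`), or NULL.
#' @param responseSummary data.frame with `roi_id`, `tastant`, `mean_z`,
#'   `responsive`, `mean_z_clamped` (cell-compartment rows of
#'   [summarizeResponses()]`$epochs`), or NULL.
#' @param roiMap optional data.frame (cell, roi_id) linking mask labels to
#'   functional ROI ids; defaults to identity.
#' @return data.frame of cell profiles.
#' @export
buildCellProfiles <- function(mask, countTable = NULL, ifTable = NULL,
                              responseSummary = NULL, roiMap = NULL) {
  labs <- if (is(mask, "CellMask")) cellLabels(mask) else sort(unique(mask))
  prof <- data.frame(cell_id = labs)
  if (!is.null(countTable)) {
    if (!all(countTable$cell %in% labs))
      stop("consistency error: count table has labels absent from the mask")
    for (g in setdiff(names(countTable), "cell"))
      prof[[paste0("count_", g)]] <-
        countTable[[g]][match(labs, countTable$cell)]
  }
  if (!is.null(ifTable)) {
    if (!all(ifTable$cell %in% labs))
      stop("consistency error: IF table has labels absent from the mask")
    for (p in unique(ifTable$protein)) {
      sub <- ifTable[ifTable$protein == p, ]
      prof[[paste0("if_intensity_", p)]] <-
        sub$intensity[match(labs, sub$cell)]
      if ("positive" %in% names(sub))
        prof[[paste0("if_", p)]] <- sub$positive[match(labs, sub$cell)]
    }
  }
  if (!is.null(responseSummary)) {
    if (is.null(roiMap))
      roiMap <- data.frame(cell = labs, roi_id = as.character(labs))
    rs <- merge(responseSummary, roiMap, by = "roi_id")
    if (!all(rs$cell %in% labs))
      stop("consistency error: response summary has labels absent from the mask")
    for (tt in unique(rs$tastant)) {
      sub <- rs[rs$tastant == tt, ]
      prof[[paste0("mean_z_", tt)]] <- sub$mean_z[match(labs, sub$cell)]
      prof[[paste0("responsive_", tt)]] <-
        sub$responsive[match(labs, sub$cell)]
    }
  }
  prof
}

#' Call IF positivity from per-cell intensities
#'
#' Default method is a two-component Otsu split of the per-cell mean
#' intensities (scale-invariant); a fixed manual threshold is also
#' supported.
#'
#' @param intensity numeric per-cell intensities (>= 4 cells for "otsu").
#' @param method "otsu" or "threshold".
#' @param threshold manual threshold when `method = "threshold"`.
#' @return Logical vector.
#' @export
classifyIfPositive <- function(intensity, method = c("otsu", "threshold"),
                               threshold = NULL) {
  method <- match.arg(method)
  if (method == "threshold") {
    if (is.null(threshold)) stop("manual method needs a threshold")
    return(intensity > threshold)
  }
  if (length(intensity) < 4) stop("need >= 4 cells for the Otsu split")
  if (diff(range(intensity)) == 0)
    stop("degenerate error: all intensities equal")
  intensity > otsuThreshold(intensity)
}

#' Receptor-class calling against the CA4+ negative control
#'
#' Per-gene positivity thresholds for the Tas1R subunits are set from the
#' distribution of that gene's counts in CA4+ (sour) cells -- cells that do
#' not express sweet/umami receptors, hence an in-tissue negative control --
#' at the given percentile. Classes follow the heterodimer logic:
#' CA4+ -> "sour"; Tas1R2+/R3+ -> "sweet"; Tas1R1+/R3+ -> "umami";
#' Tas1R1+/R2+/R3+ -> "dual"; anything else -> "negative".
#'
#' @param profiles data.frame with `count_Tas1R1/2/3` and `count_CA4`.
#' @param controlCells indices/cell_ids of CA4+ control cells; if NULL they
#'   are taken as cells with `count_CA4 >= ca4Threshold`.
#' @param percentile control percentile for the positivity cut (default
#'   0.95).
#' @param ca4Threshold digital count threshold for CA4 positivity (default
#'   13 spots).
#' @param fixedThresholds optional named per-gene thresholds overriding the
#'   control distribution (required if no control cell exists).
#' @return List: `class` (character per row), `thresholds` (per gene).
#' @export
callExpressionClass <- function(profiles, controlCells = NULL,
                                percentile = 0.95, ca4Threshold = 13,
                                fixedThresholds = NULL) {
  genes <- c("Tas1R1", "Tas1R2", "Tas1R3")
  cols <- paste0("count_", genes)
  stopifnot(all(cols %in% names(profiles)))
  ca4 <- profiles$count_CA4
  sour <- !is.na(ca4) & ca4 >= ca4Threshold
  if (is.null(controlCells)) ctrl <- which(sour)
  else ctrl <- match(controlCells, profiles$cell_id)
  if (!is.null(fixedThresholds)) {
    thr <- fixedThresholds[genes]
  } else {
    if (!length(ctrl))
      stop("configuration error: no CA4+ control cells and no fixed thresholds")
    thr <- vapply(cols, function(cc)
      stats::quantile(profiles[[cc]][ctrl], percentile, na.rm = TRUE,
                      names = FALSE), 0)
    names(thr) <- genes
  }
  pos <- sapply(genes, function(g)
    !is.na(profiles[[paste0("count_", g)]]) &
      profiles[[paste0("count_", g)]] > thr[[g]])
  if (is.null(dim(pos))) pos <- matrix(pos, nrow = 1, dimnames = list(NULL, genes))
  cls <- rep("negative", nrow(profiles))
  cls[pos[, "Tas1R2"] & pos[, "Tas1R3"] & !pos[, "Tas1R1"]] <- "sweet"
  cls[pos[, "Tas1R1"] & pos[, "Tas1R3"] & !pos[, "Tas1R2"]] <- "umami"
  cls[pos[, "Tas1R1"] & pos[, "Tas1R2"] & pos[, "Tas1R3"]] <- "dual"
  cls[sour] <- "sour"
  list(class = cls, thresholds = thr)
}

#' Cells adjacent to each afferent-nerve ROI
#'
#' A cell is adjacent to a nerve when any pixel of its label comes within
#' `radiusUm` of the nerve ROI polygon (distance-transform test).
#' Deterministic ordering by cell id.
#'
#' @param nerveRois list of nerve ROIs (lists with `id`, `polygon`).
#' @param mask [CellMask-class] or label matrix (round-1 frame).
#' @param radiusUm adjacency radius in microns (default 2).
#' @param pixelSizeUm microns per pixel.
#' @return Named list nerve id -> integer vector of adjacent cell ids.
#' @export
afferentAdjacency <- function(nerveRois, mask, radiusUm = 2,
                              pixelSizeUm = 0.5) {
  lab <- if (is(mask, "CellMask")) mask@labels else mask
  h <- nrow(lab); w <- ncol(lab)
  radiusPx <- radiusUm / pixelSizeUm
  out <- list()
  for (nv in nerveRois) {
    m <- polygonMask(nv$polygon, h, w)
    if (!any(m)) stop("geometry error: empty nerve ROI ", nv$id)
    dm <- EBImage::distmap(matrix(as.numeric(!m), h, w))
    near <- lab > 0 & as.matrix(dm) <= radiusPx
    out[[nv$id]] <- sort(unique(as.integer(lab[near])))
  }
  out
}

#' Attribute dual-tuned afferent responses
#'
#' For every dual-tuned nerve: "intrinsic" when at least one adjacent cell
#' has the dual (Tas1R1+/R2+/R3+) expression class -- intrinsic receptor
#' co-expression takes precedence as the primary driver; otherwise
#' "spillover" when an adjacent sweet cell and an adjacent umami cell
#' coexist (shared-space ATP spillover configuration); otherwise
#' "unexplained".
#'
#' @param nerveSummaries data.frame with `nerve_id` and `tuning_class`.
#' @param adjacency named list nerve id -> adjacent cell ids.
#' @param profiles data.frame with `cell_id` and `expression_class`.
#' @return List: `perNerve` (data.frame nerve_id, attribution),
#'   `fractions` (named numeric), `counts`, `nDual`,
#'   `zeroDenominator` flag.
#' @export
summarizeDualTuning <- function(nerveSummaries, adjacency, profiles) {
  dual <- nerveSummaries[nerveSummaries$tuning_class == "dual", ,
                         drop = FALSE]
  cats <- c("intrinsic", "spillover", "unexplained")
  if (!nrow(dual)) {
    return(list(perNerve = data.frame(nerve_id = character(0),
                                      attribution = character(0)),
                fractions = setNames(rep(NA_real_, 3), cats),
                counts = setNames(rep(0L, 3), cats), nDual = 0L,
                zeroDenominator = TRUE))
  }
  attr1 <- vapply(dual$nerve_id, function(id) {
    if (is.null(adjacency[[id]]))
      stop("consistency error: nerve ", id, " has no adjacency entry")
    cls <- profiles$expression_class[match(adjacency[[id]],
                                           profiles$cell_id)]
    if (any(cls == "dual", na.rm = TRUE)) "intrinsic"
    else if (any(cls == "sweet", na.rm = TRUE) &&
             any(cls == "umami", na.rm = TRUE)) "spillover"
    else "unexplained"
  }, "")
  counts <- setNames(vapply(cats, function(k) sum(attr1 == k), 0L), cats)
  list(perNerve = data.frame(nerve_id = dual$nerve_id, attribution = attr1),
       fractions = counts / nrow(dual), counts = counts,
       nDual = nrow(dual), zeroDenominator = FALSE)
}

#' Match segmented fixed-frame cells to in-vivo functional ROIs
#'
#' Maps each fixed-frame (round-1) cell centroid through the recovered
#' deformation field into the in-vivo frame and links it to the in-vivo
#' label found there (nearest within `maxDistPx` if the mapped point lands
#' on background).
#'
#' @param fixedMask [CellMask-class] in the round-1 frame.
#' @param invivoMask [CellMask-class] (or label matrix) in the in-vivo frame.
#' @param field [DeformationField-class] from [registerNonrigid()] (fixed ->
#'   in-vivo sampling convention).
#' @param maxDistPx search radius when the mapped centroid is background.
#' @return data.frame: cell (fixed label), roi_id (in-vivo label or NA).
#' @export
matchCellsAcrossFrames <- function(fixedMask, invivoMask, field,
                                   maxDistPx = 5) {
  lab <- fixedMask@labels
  ivl <- if (is(invivoMask, "CellMask")) invivoMask@labels else invivoMask
  labs <- cellLabels(fixedMask)
  h <- nrow(ivl); w <- ncol(ivl)
  out <- lapply(labs, function(l) {
    px <- which(lab == l, arr.ind = TRUE)
    cx <- mean(px[, 2] - 1); cy <- mean(px[, 1] - 1)
    u <- fieldAt(field, cx, cy)
    x <- cx + u[1]; y <- cy + u[2]
    xi <- min(max(round(x), 0), w - 1); yi <- min(max(round(y), 0), h - 1)
    hit <- ivl[yi + 1, xi + 1]
    if (hit == 0) {
      r <- ceiling(maxDistPx)
      xs <- max(0, xi - r):min(w - 1, xi + r)
      ys <- max(0, yi - r):min(h - 1, yi + r)
      sub <- ivl[ys + 1, xs + 1, drop = FALSE]
      pxs <- rep(xs, each = length(ys)); pys <- rep(ys, times = length(xs))
      sel <- as.integer(sub) > 0 &
        (pxs - x)^2 + (pys - y)^2 <= maxDistPx^2
      hit <- if (any(sel)) {
        d <- (pxs[sel] - x)^2 + (pys[sel] - y)^2
        as.integer(sub)[sel][which.min(d)]
      } else NA_integer_
    }
    data.frame(cell = l, roi_id = as.character(hit))
  })
  do.call(rbind, out)
}

#' Mean in-mask intensity per cell
#'
#' @param image intensity image.
#' @param mask [CellMask-class] or label matrix.
#' @return data.frame (cell, intensity).
#' @export
meanIntensityPerCell <- function(image, mask) {
  lab <- if (is(mask, "CellMask")) mask@labels else mask
  labs <- sort(unique(as.integer(lab[lab > 0])))
  data.frame(cell = labs,
             intensity = vapply(labs, function(l) mean(image[lab == l]), 0))
}
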