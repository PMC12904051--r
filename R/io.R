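# File I/O: multi-page float TIFF for images and movies, 16-bit TIFF for
# label masks, CSV for tables, JSON for transforms/reports, YAML for
# schedules and pipeline configuration.

#' Write / read a float image (or stack) as TIFF
#'
#' Images are stored as 32-bit float TIFF, one page per plane/frame.
#'
#' @param img matrix, or list of matrices (pages).
#' @param path file path.
#' @return `readImageTiff` returns a matrix (single page) or list of
#'   matrices.
#' @export
writeImageTiff <- function(img, path) {
  if (is.matrix(img)) img <- list(img)
  # the TIFF writer stores [0, 1] samples; rescale globally and keep the
  # affine range in a sidecar so the reader restores exact intensities
  lo <- min(vapply(img, min, 0)); hi <- max(vapply(img, max, 0))
  sc <- if (hi > lo) hi - lo else 1
  tiff::writeTIFF(lapply(img, function(m) (m - lo) / sc), path,
                  bits.per.sample = 32L, reduce = FALSE)
  jsonlite::write_json(list(min = lo, max = hi),
                       paste0(path, ".range.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname writeImageTiff
#' @export
readImageTiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  rj <- paste0(path, ".range.json")
  if (file.exists(rj)) {
    r <- jsonlite::read_json(rj, simplifyVector = TRUE)
    sc <- if (r$max > r$min) r$max - r$min else 1
    pages <- lapply(pages, function(m) m * sc + r$min)
  }
  if (length(pages) == 1) pages[[1]] else pages
}

#' Write / read a two-channel movie as per-channel TIFF stacks
#'
#' Pages are ordered plane-fastest (plane 1..P of frame 1, then frame 2, ...).
#'
#' @param movie a [TasteBudMovie-class].
#' @param dir output directory (created if needed).
#' @param schedule used by the reader to rebuild the object.
#' @param pixelSizeUm pixel size for the reader.
#' @return `readMovie` returns a [TasteBudMovie-class].
#' @export
writeMovie <- function(movie, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(movie@green)
  flat <- function(a) {
    pages <- vector("list", d[3] * d[4])
    k <- 0L
    for (t in seq_len(d[4])) for (p in seq_len(d[3])) {
      k <- k + 1L; pages[[k]] <- a[, , p, t]
    }
    pages
  }
  writeImageTiff(flat(movie@green), file.path(dir, "green.tif"))
  writeImageTiff(flat(movie@red), file.path(dir, "red.tif"))
  jsonlite::write_json(list(nPlanes = d[3], nFrames = d[4],
                            pixelSizeUm = movie@pixelSizeUm),
                       file.path(dir, "movie.json"), auto_unbox = TRUE)
  write.csv(movie@shiftsTruth, file.path(dir, "shifts_truth.csv"),
            row.names = FALSE)
  invisible(dir)
}

#' @rdname writeMovie
#' @export
readMovie <- function(dir, schedule, pixelSizeUm = NULL) {
  meta <- jsonlite::read_json(file.path(dir, "movie.json"),
                              simplifyVector = TRUE)
  g <- readImageTiff(file.path(dir, "green.tif"))
  r <- readImageTiff(file.path(dir, "red.tif"))
  if (is.matrix(g)) { g <- list(g); r <- list(r) }
  h <- nrow(g[[1]]); w <- ncol(g[[1]])
  toArr <- function(pages) {
    a <- array(0, c(h, w, meta$nPlanes, meta$nFrames))
    k <- 0L
    for (t in seq_len(meta$nFrames)) for (p in seq_len(meta$nPlanes)) {
      k <- k + 1L; a[, , p, t] <- pages[[k]]
    }
    a
  }
  sh <- file.path(dir, "shifts_truth.csv")
  new("TasteBudMovie", green = toArr(g), red = toArr(r), schedule = schedule,
      shiftsTruth = if (file.exists(sh)) read.csv(sh) else data.frame(),
      pixelSizeUm = if (is.null(pixelSizeUm)) meta$pixelSizeUm
      else pixelSizeUm)
}

#' Serialize / restore transforms as JSON
#'
#' Rigid transforms store rotation, translation and center; deformation
#' fields store the grid spacing and are accompanied by a 2-page float TIFF
#' (ux, uy) next to the JSON file.
#'
#' @param transform [RigidTransform2D-class] or [DeformationField-class].
#' @param path JSON path (a field writes `<path>.field.tif` alongside).
#' @return `readTransformJson` returns the transform object.
#' @export
writeTransformJson <- function(transform, path) {
  if (is(transform, "RigidTransform2D")) {
    jsonlite::write_json(list(type = "rigid",
                              rotation_deg = transform@rotationDeg,
                              translation_px = transform@translationPx,
                              center_px = transform@centerPx),
                         path, auto_unbox = TRUE, digits = NA)
  } else if (is(transform, "DeformationField")) {
    jsonlite::write_json(list(type = "bspline",
                              grid_spacing_px = transform@gridSpacingPx,
                              field_tif = paste0(basename(path), ".field.tif")),
                         path, auto_unbox = TRUE, digits = NA)
    writeImageTiff(list(transform@ux, transform@uy),
                   paste0(path, ".field.tif"))
  } else stop("unknown transform type")
  invisible(path)
}

#' @rdname writeTransformJson
#' @export
readTransformJson <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (j$type == "rigid") {
    rigidTransform(j$rotation_deg, j$translation_px, j$center_px)
  } else {
    pages <- readImageTiff(paste0(path, ".field.tif"))
    new("DeformationField", ux = pages[[1]], uy = pages[[2]],
        gridSpacingPx = j$grid_spacing_px, rmsVsDistance = data.frame())
  }
}

#' Write / read a stimulus schedule as YAML
#'
#' @param schedule a [StimulusSchedule-class].
#' @param path YAML path.
#' @return `readScheduleYaml` returns a [StimulusSchedule-class].
#' @export
writeScheduleYaml <- function(schedule, path) {
  yaml::write_yaml(list(
    frame_rate = schedule@frameRate,
    baseline = as.list(setNames(schedule@baselineWindow, c("start", "end"))),
    epochs = lapply(seq_along(schedule@tastant), function(i)
      list(tastant = schedule@tastant[i], onset = schedule@onset[i],
           offset = schedule@offset[i]))), path)
  invisible(path)
}

#' @rdname writeScheduleYaml
#' @export
readScheduleYaml <- function(path) {
  y <- yaml::read_yaml(path)
  new("StimulusSchedule",
      tastant = vapply(y$epochs, `[[`, "", "tastant"),
      onset = vapply(y$epochs, `[[`, 0, "onset"),
      offset = vapply(y$epochs, `[[`, 0, "offset"),
      baselineWindow = c(y$baseline$start, y$baseline$end),
      frameRate = y$frame_rate)
}
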