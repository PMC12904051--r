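# Pipeline orchestration: simulate -> traces -> register -> segment ->
# spots -> integrate, each stage writing its outputs plus a manifest
# (inputs, parameters, output checksums) under the output directory.
# Reruns with an identical config and seed reproduce identical CSV outputs;
# a stage whose upstream outputs are missing raises a dependency error.

#' Default pipeline configuration
#'
#' Parameter blocks per stage; override any element through the `config`
#' argument of [runPipeline()].
#'
#' @param seed master seed propagated to all stochastic stages.
#' @return Nested list.
#' @export
defaultPipelineConfig <- function(seed = 1) {
  list(
    seed = seed,
    scene = list(nCells = 12, imgSize = c(128, 128), nRounds = 2,
                 warpMaxPx = 1.5, nNerves = 3, amplitude = 0.5,
                 spotMinSepPx = 6,
                 geneCountParams = list(nbMean = 6, nbSize = 5, poisMean = 0.5,
                                        floorHigh = 4, ceilingNeg = 2)),
    movie = list(noiseSigma = 0.01, motionAmplitudePx = 1),
    schedule = list(tastants = c("sweet", "umami", "sour"), frameRate = 1),
    rounds = list(nRounds = 2, noiseSigma = 0.01, spotPsfSigmaPx = 1.5),
    traces = list(sdMult = 2, meanZCutoff = 1),
    register = list(gridSpacingPx = 32),
    segment = list(minAreaPx = 40, maxAreaPx = 3000),
    spots = list(minSeparationPx = 5, assignRadiusPx = 2),
    integrate = list(adjacencyRadiusUm = 2, percentile = 0.95,
                     ca4Threshold = 4))
}

stageDirs <- function(outdir)
  lapply(setNames(nm = c("simulate", "traces", "register", "segment",
                         "spots", "integrate")),
         function(s) file.path(outdir, s))

needFile <- function(path, stage) {
  if (!file.exists(path))
    stop("dependency error: stage '", stage, "' requires missing input ",
         path)
  path
}

writeManifest <- function(dir, stage, params, inputs, outputs) {
  sums <- tools::md5sum(outputs[file.exists(outputs)])
  jsonlite::write_json(
    list(stage = stage, parameters = params, inputs = inputs,
         outputs = as.list(sums)),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA,
    force = TRUE)
}

#' Run the correlative pipeline
#'
#' Executes the requested stages in dependency order on one synthetic
#' experiment. Every stage writes CSV/TIFF/JSON outputs and a manifest into
#' `outdir/<stage>/`; `integrate` additionally writes `report.json` bundling
#' thresholds, attribution fractions and QC.
#'
#' @param config list as [defaultPipelineConfig()] (partial overrides are
#'   merged over the defaults), or a YAML file path.
#' @param outdir output directory.
#' @param stages subset of simulate, traces, register, segment, spots,
#'   integrate.
#' @param seed overrides `config$seed` when non-NULL.
#' @return The report list (invisibly when no integrate stage is run).
#' @export
runPipeline <- function(config = list(), outdir,
                        stages = c("simulate", "traces", "register",
                                   "segment", "spots", "integrate"),
                        seed = NULL) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  cfg <- modifyList(defaultPipelineConfig(), config)
  if (!is.null(seed)) cfg$seed <- seed
  stages <- match.arg(stages, several.ok = TRUE)
  dirs <- stageDirs(outdir)
  for (s in stages) dir.create(dirs[[s]], showWarnings = FALSE,
                               recursive = TRUE)
  schedule <- do.call(stimulusSchedule, cfg$schedule)
  warnings <- character(0)
  logMsg <- function(...) message("[corrtaste] ", ...)

  if ("simulate" %in% stages) {
    logMsg("simulate: scene + movie + ", cfg$rounds$nRounds, " rounds")
    scene <- do.call(generateScene,
                     c(cfg$scene[setdiff(names(cfg$scene), "nRounds")],
                       list(nRounds = cfg$scene$nRounds, seed = cfg$seed)))
    movie <- renderFunctionalMovie(scene, schedule,
                                   noiseSigma = cfg$movie$noiseSigma,
                                   motionAmplitudePx = cfg$movie$motionAmplitudePx,
                                   seed = cfg$seed)
    rounds <- renderHistologyRounds(scene, nRounds = cfg$rounds$nRounds,
                                    spotPsfSigmaPx = cfg$rounds$spotPsfSigmaPx,
                                    noiseSigma = cfg$rounds$noiseSigma,
                                    seed = cfg$seed)
    d <- dirs$simulate
    writeMask(cellMask(scene@labels), file.path(d, "labels_truth.tif"))
    write.csv(scene@spots, file.path(d, "spots_truth.csv"), row.names = FALSE)
    write.csv(data.frame(cell = seq_len(nCells(scene)),
                         class = scene@cellClass, scene@trueCounts,
                         check.names = FALSE),
              file.path(d, "cells_truth.csv"), row.names = FALSE)
    writeScheduleYaml(schedule, file.path(d, "schedule.yaml"))
    writeMovie(movie, file.path(d, "movie"))
    for (r in seq_along(rounds)) {
      rd <- rounds[[r]]
      writeImageTiff(rd@nuclear, file.path(d, sprintf("round%d_nuclear.tif", r)))
      if (!is.null(rd@reporter))
        writeImageTiff(rd@reporter, file.path(d, sprintf("round%d_reporter.tif", r)))
      for (g in names(rd@fish))
        writeImageTiff(rd@fish[[g]],
                       file.path(d, sprintf("round%d_%s.tif", r, g)))
      writeTransformJson(rd@transformTruth,
                         file.path(d, sprintf("round%d_rigid_truth.json", r)))
    }
    writeTransformJson(scene@warpTruth, file.path(d, "warp_truth.json"))
    saveSceneMeta <- list(nRounds = cfg$rounds$nRounds,
                          genes = lapply(rounds, function(r) names(r@fish)),
                          pixelSizeUm = scene@pixelSizeUm,
                          nerveIds = vapply(scene@nerveRois, `[[`, "", "id"))
    jsonlite::write_json(saveSceneMeta, file.path(d, "scene_meta.json"),
                         auto_unbox = TRUE, digits = NA)
    for (j in seq_along(scene@nerveRois))
      write.csv(as.data.frame(scene@nerveRois[[j]]$polygon) |>
                  setNames(c("x", "y")),
                file.path(d, sprintf("nerve%d_roi.csv", j)), row.names = FALSE)
    writeManifest(d, "simulate", cfg[c("seed", "scene", "movie", "rounds")],
                  character(0), list.files(d, full.names = TRUE,
                                           recursive = TRUE))
  }

  sim <- dirs$simulate
  if ("traces" %in% stages) {
    logMsg("traces: motion correction + ratiometric extraction")
    schedule <- readScheduleYaml(needFile(file.path(sim, "schedule.yaml"),
                                          "traces"))
    movie <- readMovie(needFile(file.path(sim, "movie"), "traces"), schedule)
    mask <- loadMask(needFile(file.path(sim, "labels_truth.tif"), "traces"))
    meta <- jsonlite::read_json(file.path(sim, "scene_meta.json"),
                                simplifyVector = TRUE)
    nerves <- lapply(seq_along(meta$nerveIds), function(j) {
      p <- read.csv(file.path(sim, sprintf("nerve%d_roi.csv", j)))
      list(id = meta$nerveIds[j], polygon = as.matrix(p))
    })
    mc <- motionCorrect(movie)
    traces <- withCallingHandlers(
      extractTraces(mc$movie, mask, nerves),
      warning = function(w) {
        warnings <<- c(warnings, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    summ <- summarizeResponses(traces, schedule,
                               sdMult = cfg$traces$sdMult,
                               meanZCutoff = cfg$traces$meanZCutoff)
    d <- dirs$traces
    ratios <- do.call(rbind, lapply(traces, function(tr)
      data.frame(roi_id = tr@roiId, compartment = tr@compartment,
                 time_s = tr@timeS, ratio = tr@ratio)))
    write.csv(ratios, file.path(d, "traces.csv"), row.names = FALSE)
    write.csv(mc$shifts, file.path(d, "shifts.csv"), row.names = FALSE)
    write.csv(summ$epochs, file.path(d, "epochs.csv"), row.names = FALSE)
    write.csv(summ$rois, file.path(d, "rois.csv"), row.names = FALSE)
    writeManifest(d, "traces", cfg$traces, file.path(sim, "movie"),
                  file.path(d, c("traces.csv", "shifts.csv", "epochs.csv",
                                 "rois.csv")))
  }

  if ("register" %in% stages) {
    logMsg("register: in-vivo -> round 1 (B-spline), rounds -> round 1 (rigid)")
    meta <- jsonlite::read_json(needFile(file.path(sim, "scene_meta.json"),
                                         "register"), simplifyVector = TRUE)
    rep1 <- readImageTiff(needFile(file.path(sim, "round1_reporter.tif"),
                                   "register"))
    schedule <- readScheduleYaml(file.path(sim, "schedule.yaml"))
    movie <- readMovie(needFile(file.path(sim, "movie"), "register"),
                       schedule)
    invivoRef <- apply(movie@red[, , 1, , drop = FALSE], c(1, 2), mean)
    nr <- registerNonrigid(rep1, invivoRef,
                           gridSpacingPx = cfg$register$gridSpacingPx)
    d <- dirs$register
    writeTransformJson(nr$field, file.path(d, "warp_est.json"))
    nuc1 <- readImageTiff(needFile(file.path(sim, "round1_nuclear.tif"),
                                   "register"))
    qcs <- list()
    for (r in seq_len(meta$nRounds)[-1]) {
      nucR <- readImageTiff(needFile(
        file.path(sim, sprintf("round%d_nuclear.tif", r)), "register"))
      tf <- registerRigid(nuc1, nucR)
      writeTransformJson(tf, file.path(d, sprintf("round%d_rigid.json", r)))
      qc <- registrationQC(nuc1, applyTransform(nucR, tf))
      qcs[[length(qcs) + 1L]] <- data.frame(
        round = r, pearson_r = qc$pearsonR,
        max_peak_offset_px = qc$maxPeakOffsetPx)
    }
    qcdf <- if (length(qcs)) do.call(rbind, qcs) else
      data.frame(round = integer(0), pearson_r = numeric(0),
                 max_peak_offset_px = numeric(0))
    write.csv(qcdf, file.path(d, "rigid_qc.csv"), row.names = FALSE)
    writeManifest(d, "register", cfg$register,
                  file.path(sim, "round1_nuclear.tif"),
                  list.files(d, full.names = TRUE))
  }

  if ("segment" %in% stages) {
    logMsg("segment: watershed on round-1 reporter")
    rep1 <- readImageTiff(needFile(file.path(sim, "round1_reporter.tif"),
                                   "segment"))
    mask <- segmentCells(rep1, minAreaPx = cfg$segment$minAreaPx,
                         maxAreaPx = cfg$segment$maxAreaPx)
    writeMask(mask, file.path(dirs$segment, "mask_round1.tif"))
    writeManifest(dirs$segment, "segment", cfg$segment,
                  file.path(sim, "round1_reporter.tif"),
                  file.path(dirs$segment, "mask_round1.tif"))
  }

  if ("spots" %in% stages) {
    logMsg("spots: DoG detection + digital counting")
    meta <- jsonlite::read_json(needFile(file.path(sim, "scene_meta.json"),
                                         "spots"), simplifyVector = TRUE)
    mask <- loadMask(needFile(file.path(dirs$segment, "mask_round1.tif"),
                              "spots"))
    params <- spotCallParams(minSeparationPx = cfg$spots$minSeparationPx)
    allSpots <- list()
    for (r in seq_len(meta$nRounds)) {
      genes <- if (is.list(meta$genes)) meta$genes[[r]] else meta$genes[r]
      tf <- if (r > 1)
        readTransformJson(needFile(
          file.path(dirs$register, sprintf("round%d_rigid.json", r)),
          "spots"))
      else NULL
      for (g in genes) {
        img <- readImageTiff(needFile(
          file.path(sim, sprintf("round%d_%s.tif", r, g)), "spots"))
        sp <- detectSpots(img, params, gene = g, round = r)
        if (nrow(sp) && !is.null(tf)) sp <- applyTransform(sp, tf)
        allSpots[[length(allSpots) + 1L]] <- sp
      }
    }
    spots <- do.call(rbind, allSpots)
    cnt <- countSpotsPerCell(spots, mask,
                             assignRadiusPx = cfg$spots$assignRadiusPx)
    d <- dirs$spots
    write.csv(cnt$spots, file.path(d, "spots.csv"), row.names = FALSE)
    write.csv(cnt$counts, file.path(d, "counts.csv"), row.names = FALSE)
    writeManifest(d, "spots", cfg$spots,
                  file.path(dirs$segment, "mask_round1.tif"),
                  file.path(d, c("spots.csv", "counts.csv")))
  }

  report <- NULL
  if ("integrate" %in% stages) {
    logMsg("integrate: profiles + correlative statistics")
    meta <- jsonlite::read_json(needFile(file.path(sim, "scene_meta.json"),
                                         "integrate"), simplifyVector = TRUE)
    mask <- loadMask(needFile(file.path(dirs$segment, "mask_round1.tif"),
                              "integrate"))
    counts <- read.csv(needFile(file.path(dirs$spots, "counts.csv"),
                                "integrate"), check.names = FALSE)
    epochs <- read.csv(needFile(file.path(dirs$traces, "epochs.csv"),
                                "integrate"))
    field <- readTransformJson(needFile(
      file.path(dirs$register, "warp_est.json"), "integrate"))
    invivoMask <- loadMask(file.path(sim, "labels_truth.tif"))
    link <- matchCellsAcrossFrames(mask, invivoMask, field)
    cellEpochs <- epochs[epochs$compartment == "cell_apical", ]
    prof <- buildCellProfiles(mask, countTable = counts,
                              responseSummary = cellEpochs, roiMap = link)
    missingGene <- setdiff(paste0("count_", tasteGenes()), names(prof))
    for (g in missingGene) prof[[g]] <- NA_integer_
    cls <- tryCatch(
      callExpressionClass(prof, percentile = cfg$integrate$percentile,
                          ca4Threshold = cfg$integrate$ca4Threshold),
      error = function(e) {
        warnings <<- c(warnings, conditionMessage(e))
        list(class = rep(NA_character_, nrow(prof)), thresholds = NULL)
      })
    prof$expression_class <- cls$class
    nerves <- lapply(seq_along(meta$nerveIds), function(j) {
      p <- read.csv(file.path(sim, sprintf("nerve%d_roi.csv", j)))
      list(id = meta$nerveIds[j], polygon = as.matrix(p))
    })
    adj <- afferentAdjacency(nerves, mask,
                             radiusUm = cfg$integrate$adjacencyRadiusUm,
                             pixelSizeUm = meta$pixelSizeUm)
    rois <- read.csv(file.path(dirs$traces, "rois.csv"))
    nerveSumm <- rois[rois$compartment == "nerve_basolateral", ]
    names(nerveSumm)[names(nerveSumm) == "roi_id"] <- "nerve_id"
    dual <- summarizeDualTuning(nerveSumm, adj, prof)
    d <- dirs$integrate
    write.csv(prof, file.path(d, "profiles.csv"), row.names = FALSE)
    write.csv(dual$perNerve, file.path(d, "dual_attribution.csv"),
              row.names = FALSE)
    report <- list(
      seed = cfg$seed,
      n_cells = nrow(prof),
      expression_classes = as.list(table(prof$expression_class)),
      thresholds = as.list(cls$thresholds),
      adjacency_radius_um = cfg$integrate$adjacencyRadiusUm,
      dual_tuning = list(n_dual = dual$nDual,
                         fractions = as.list(dual$fractions),
                         zero_denominator = dual$zeroDenominator),
      warnings = warnings)
    jsonlite::write_json(report, file.path(d, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    writeManifest(d, "integrate", cfg$integrate,
                  file.path(dirs$spots, "counts.csv"),
                  file.path(d, c("profiles.csv", "dual_attribution.csv",
                                 "report.json")))
  }
  invisible(report)
}
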