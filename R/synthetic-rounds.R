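# Render multi-round fixed-tissue histology from a scene. Content (nuclei,
# reporter, smFISH spots, fiducials) is defined in the in-vivo frame; the
# round-1 image samples it through the fixation warp
# (round1(p) = content(p + u(p))), and round r >= 2 additionally through that
# round's rigid truth. The cytosolic reporter appears only in round 1 (it is
# quenched by formamide probe stripping afterwards); the nuclear channel is
# attenuated by a fixed factor per round; NIRB-like fiducial blobs persist in
# every round unattenuated.

#' Default gene-to-round probing plan
#'
#' Round 1 carries a single gene (spectral budget next to reporter + nuclear),
#' later rounds up to three. Round 3, when present, re-probes Tas1R3 for
#' count-stability assessment.
#'
#' @param nRounds number of rounds.
#' @return List of character vectors, one per round.
#' @export
defaultGeneRounds <- function(nRounds = 2) {
  plan <- list("Tas1R3", c("Tas1R1", "Tas1R2", "CA4"), "Tas1R3")
  if (nRounds > 3) plan <- c(plan, rep(list(character(0)), nRounds - 3))
  plan[seq_len(nRounds)]
}

# Render all in-vivo-frame content channels once.
renderSceneContent <- function(scene, spotPsfSigmaPx, spotAmps) {
  h <- nrow(scene@labels); w <- ncol(scene@labels)
  nuc <- renderGaussians(h, w, as.matrix(scene@centroids[, c("x", "y")]),
                         rep(1, nCells(scene)), 3)
  rep0 <- matrix(0.02, h, w)
  rep0[scene@labels > 0] <- 1
  rep0 <- gaussBlur(rep0, 1)
  fid <- renderGaussians(h, w, as.matrix(scene@fiducials),
                         rep(2, nrow(scene@fiducials)), 2)
  fish <- list()
  for (g in tasteGenes()) {
    sp <- scene@spots[scene@spots$gene == g, , drop = FALSE]
    fish[[g]] <- renderGaussians(h, w, cbind(sp$x, sp$y),
                                 spotAmps[[g]], spotPsfSigmaPx)
  }
  list(nuclear = nuc, reporter = rep0, fiducial = fid, fish = fish)
}

# Sample an in-vivo-frame content image into round-r fixed coordinates:
# out(p) = img(q + u(q)) with q = T_r^-1(p).
sampleToRound <- function(img, scene, r) {
  h <- nrow(img); w <- ncol(img)
  g <- coordGrid(h, w)
  q <- cbind(as.numeric(g$x), as.numeric(g$y))
  if (r > 1) q <- rigidMapPoints(invertTransform(scene@rigidTruth[[r]]), q)
  u <- fieldAt(scene@warpTruth, q[, 1], q[, 2])
  matrix(bilinearSample(img, q[, 1] + u[, 1], q[, 2] + u[, 2]), h, w)
}

#' True spot positions in a round's fixed frame
#'
#' Maps the scene's in-vivo spot positions through the fixation warp (by
#' fixed-point iteration of `p = s - u(p)`) and the round's rigid truth.
#'
#' @param scene a [SceneGroundTruth-class].
#' @param round round number.
#' @return The scene spot table with x, y in round coordinates.
#' @export
spotPositionsInRound <- function(scene, round = 1L) {
  sp <- scene@spots
  if (!nrow(sp)) return(sp)
  p <- cbind(sp$x, sp$y)
  for (it in 1:4) {
    u <- fieldAt(scene@warpTruth, p[, 1], p[, 2])
    p <- cbind(sp$x - u[, 1], sp$y - u[, 2])
  }
  if (round > 1) p <- rigidMapPoints(scene@rigidTruth[[round]], p)
  sp$x <- p[, 1]; sp$y <- p[, 2]
  sp
}

#' Render the in-vivo-frame reporter image
#'
#' The clean cytosolic reporter (tdTomato) structural image in the in-vivo
#' frame -- the moving image of the in-vivo-to-fixed non-rigid registration
#' problem (the round-1 reporter is this content seen through the fixation
#' warp).
#'
#' @param scene a [SceneGroundTruth-class].
#' @param noiseSigma optional Gaussian noise SD.
#' @param seed seed for the noise.
#' @return Numeric matrix.
#' @export
renderInvivoReporter <- function(scene, noiseSigma = 0, seed = 1) {
  h <- nrow(scene@labels); w <- ncol(scene@labels)
  m <- matrix(0.02, h, w)
  m[scene@labels > 0] <- 1
  m <- gaussBlur(m, 1)
  if (noiseSigma > 0) {
    set.seed(deriveSeed(seed, "invivoRep"))
    m <- m + matrix(stats::rnorm(h * w, 0, noiseSigma), h, w)
  }
  m
}

#' Render multi-round synthetic histology
#'
#' @param scene a [SceneGroundTruth-class].
#' @param nRounds number of rounds (>= 1, at most the scene's rigid truth).
#' @param geneRounds list of gene vectors per round (<= 3 genes per round);
#'   defaults to [defaultGeneRounds()].
#' @param spotPsfSigmaPx Gaussian sigma of a rendered spot (px).
#' @param noiseSigma Gaussian noise SD (fraction of dynamic range).
#' @param nuclearAttenuation multiplicative nuclear signal retention per
#'   round (default 0.8, i.e. a 20% loss per stripping cycle).
#' @param seed integer seed.
#' @return List of [HistologyRound-class] objects.
#' @export
renderHistologyRounds <- function(scene, nRounds = 2,
                                  geneRounds = defaultGeneRounds(nRounds),
                                  spotPsfSigmaPx = 1.5, noiseSigma = 0.02,
                                  nuclearAttenuation = 0.8, seed = 1) {
  stopifnot(nRounds >= 1, nRounds <= length(scene@rigidTruth))
  if (any(lengths(geneRounds) > 3))
    stop("channel-budget error: at most 3 smFISH channels per round")
  set.seed(deriveSeed(seed, "rounds"))
  spotAmps <- lapply(setNames(tasteGenes(), tasteGenes()), function(g) {
    k <- sum(scene@spots$gene == g)
    stats::runif(k, 0.7, 1.3)
  })
  content <- renderSceneContent(scene, spotPsfSigmaPx, spotAmps)
  h <- nrow(scene@labels); w <- ncol(scene@labels)
  addNoise <- function(img) {
    if (noiseSigma > 0) img + matrix(stats::rnorm(h * w, 0, noiseSigma), h, w)
    else img
  }
  rounds <- vector("list", nRounds)
  for (r in seq_len(nRounds)) {
    att <- nuclearAttenuation^(r - 1)
    nuc <- sampleToRound(att * content$nuclear + content$fiducial, scene, r)
    fish <- list()
    for (g in geneRounds[[r]])
      fish[[g]] <- addNoise(sampleToRound(content$fish[[g]], scene, r))
    rep <- if (r == 1) addNoise(sampleToRound(content$reporter, scene, r))
      else NULL
    rounds[[r]] <- new("HistologyRound", round = as.integer(r),
                       nuclear = addNoise(nuc), reporter = rep, fish = fish,
                       transformTruth = scene@rigidTruth[[r]])
  }
  rounds
}
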