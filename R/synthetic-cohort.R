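# Table-level cohort generator for the dual-tuning attribution statistics:
# a set of dual-tuned afferent nerves, each adjacent either to a taste cell
# co-expressing all three Tas1R subunits (intrinsic dual tuning) or to a
# separate sweet cell plus umami cell (spillover), with known ground truth.

#' Simulate a dual-tuned afferent cohort
#'
#' Generates, at the table level (no imaging), `nNerves` dual-tuned nerves
#' with known attribution: with probability `intrinsicFrac` the nerve is
#' adjacent to one Tas1R1+/R2+/R3+ (dual) cell; otherwise to one sweet and
#' one umami cell (spillover configuration). Every nerve also gets one
#' bystander negative cell. Transcript counts follow the scene count model.
#'
#' @param nNerves number of dual-tuned nerves.
#' @param intrinsicFrac probability a nerve is intrinsically dual-tuned.
#' @param geneCountParams list as [defaultGeneCountParams()].
#' @param seed integer seed.
#' @return List with `nerveSummaries` (data.frame nerve_id, tuning_class,
#'   clamped mean-Z per tastant), `adjacency` (named list nerve -> cell ids),
#'   `profiles` (data.frame cell_id, counts, expression_class),
#'   `truth` (character attribution per nerve).
#' @export
simulateDualTuningCohort <- function(nNerves = 40, intrinsicFrac = 0.9,
                                     geneCountParams = defaultGeneCountParams(),
                                     seed = 1) {
  set.seed(deriveSeed(seed, "cohort"))
  truth <- ifelse(stats::runif(nNerves) < intrinsicFrac, "intrinsic",
                  "spillover")
  profiles <- list(); adjacency <- list()
  cellId <- 0L
  addCell <- function(cls) {
    cellId <<- cellId + 1L
    cnt <- drawCounts(cls, geneCountParams)
    data.frame(cell_id = cellId, class_truth = cls,
               Tas1R1 = cnt[1, "Tas1R1"], Tas1R2 = cnt[1, "Tas1R2"],
               Tas1R3 = cnt[1, "Tas1R3"], CA4 = cnt[1, "CA4"])
  }
  for (j in seq_len(nNerves)) {
    cells <- if (truth[j] == "intrinsic") list(addCell("dual"))
      else list(addCell("sweet"), addCell("umami"))
    cells <- c(cells, list(addCell("silent")))
    profiles <- c(profiles, cells)
    adjacency[[paste0("nerve", j)]] <-
      vapply(cells, function(d) d$cell_id, integer(1))
  }
  profiles <- do.call(rbind, profiles)
  sZ <- stats::runif(nNerves, 1.5, 4)
  uZ <- stats::runif(nNerves, 1.5, 4)
  nerveSummaries <- data.frame(
    nerve_id = paste0("nerve", seq_len(nNerves)),
    sweet = sZ, umami = uZ,
    response_index = (sZ - uZ) / (sZ + uZ),
    tuning_class = "dual")
  list(nerveSummaries = nerveSummaries, adjacency = adjacency,
       profiles = profiles, truth = truth)
}
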