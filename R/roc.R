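# Empirical ROC analysis for univariate marker-function linking. The
# classifier is "feature > threshold"; the curve is traced over all observed
# feature values, AUC by the trapezoid rule (which equals the Mann-Whitney
# U statistic divided by n1*n2), and the operating threshold maximizes
# Youden's J = TPR - FPR (ties resolved to the lower threshold).

#' Empirical ROC of a univariate classifier
#'
#' @param feature numeric vector.
#' @param label logical (or 0/1) vector; TRUE = positive class.
#' @return List (class `RocResult`): `thresholds`, `tpr`, `fpr`, `auc`,
#'   `optimalThreshold`, `youdenJ`.
#' @export
rocCurve <- function(feature, label) {
  label <- as.logical(label)
  if (any(is.na(feature)) || any(is.na(label)))
    stop("feature/label must not contain NA")
  n1 <- sum(label); n0 <- sum(!label)
  if (n1 == 0 || n0 == 0) stop("class error: both classes must be non-empty")
  thr <- c(-Inf, sort(unique(feature)))
  tpr <- vapply(thr, function(t) mean(feature[label] > t), 0)
  fpr <- vapply(thr, function(t) mean(feature[!label] > t), 0)
  # trapezoid AUC over the (fpr, tpr) polyline (fpr is non-increasing in thr)
  o <- order(fpr, tpr)
  auc <- sum(diff(fpr[o]) * (tpr[o][-1] + tpr[o][-length(o)]) / 2)
  j <- tpr - fpr
  best <- which(j == max(j))
  optimal <- min(thr[best])
  structure(list(thresholds = thr, tpr = tpr, fpr = fpr, auc = auc,
                 optimalThreshold = optimal, youdenJ = max(j)),
            class = "RocResult")
}

#' @export
print.RocResult <- function(x, ...) {
  cat(sprintf("RocResult: AUC = %.4f, optimal threshold = %.4g (J = %.3f)\n",
              x$auc, x$optimalThreshold, x$youdenJ))
  invisible(x)
}

#' ROC of a profile feature against an IF label
#'
#' Runs [rocCurve()] with a feature drawn from cell profiles -- a per-tastant
#' mean Z-score (`feature = "mean_z"`, with `tastant`) or a per-gene spot
#' count (`feature = "counts"`, with `gene`) -- against per-cell IF
#' positivity for `protein`.
#'
#' @param profiles data.frame from [buildCellProfiles()].
#' @param feature "mean_z" or "counts".
#' @param tastant,gene selector for the feature column.
#' @param protein IF protein whose positivity is the class label.
#' @return A `RocResult`.
#' @export
rocUnivariate <- function(profiles, feature = c("mean_z", "counts"),
                          tastant = "sour", gene = "CA4", protein = "CA4") {
  feature <- match.arg(feature)
  col <- if (feature == "mean_z") paste0("mean_z_", tastant)
    else paste0("count_", gene)
  labcol <- paste0("if_", protein)
  if (!col %in% names(profiles)) stop("missing feature column ", col)
  if (!labcol %in% names(profiles)) stop("missing label column ", labcol)
  ok <- !is.na(profiles[[col]]) & !is.na(profiles[[labcol]])
  rocCurve(profiles[[col]][ok], profiles[[labcol]][ok])
}
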