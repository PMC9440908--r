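#' Rank-based ROC AUC
#'
#' Area under the ROC curve for a single continuous score against binary
#' labels, computed with the Mann-Whitney rank identity (midranks for
#' ties). Equals the fraction of (positive, negative) pairs in which the
#' positive scores higher, counting ties as half.
#'
#' @param score numeric score (higher = more likely positive).
#' @param label logical (or 0/1) truth.
#' @return AUC in [0, 1].
#' @export
rocAuc <- function(score, label) {
  label <- as.logical(label)
  if (!any(label) || all(label))
    stop("calibration error: both classes are required to compute an AUC")
  r <- rank(score)
  nP <- sum(label)
  nN <- sum(!label)
  (sum(r[label]) - nP * (nP + 1) / 2) / (nP * nN)
}

#' Calibrate the responder thresholds against annotated traces
#'
#' Sweeps a grid of (amplitude threshold, sigma multiplier) pairs over an
#' annotated set of (peak, noise SD, label) measurements, computes
#' sensitivity and specificity at every grid point against the labels, and
#' selects the point maximizing the weighted Youden objective
#' `sensitivity + specificityWeight * specificity`. A weight above 1
#' deliberately tilts the choice toward specificity, minimizing false
#' positives. Ties are broken toward higher specificity, then toward the
#' higher amplitude threshold, then the higher multiplier. The reported
#' AUC is the rank AUC of the peak amplitude as a score (see [rocAuc()]).
#'
#' @param annotations data.frame with columns `peak_amp`, `noise_sigma`
#'   and logical `label`.
#' @param ampGrid,sigmaGrid numeric grids to sweep.
#' @param specificityWeight weight on specificity in the objective.
#' @return an object of class `ThresholdCalibration`: a list with
#'   `amp_threshold`, `sigma_mult`, `sensitivity`, `specificity`, `auc`,
#'   and the full `roc_curve` sweep table.
#' @export
calibrateThresholds <- function(annotations,
                                ampGrid = seq(0.25, 3, by = 0.25),
                                sigmaGrid = seq(2, 10, by = 1),
                                specificityWeight = 1.25) {
  stopifnot(all(c("peak_amp", "noise_sigma", "label") %in% names(annotations)))
  lab <- as.logical(annotations$label)
  if (!any(lab) || all(lab))
    stop("calibration error: annotations contain a single class")
  grid <- expand.grid(amp_threshold = ampGrid, sigma_mult = sigmaGrid,
                      KEEP.OUT.ATTRS = FALSE)
  res <- t(apply(grid, 1L, function(g) {
    pred <- annotations$peak_amp > g[1] &
      annotations$peak_amp > g[2] * annotations$noise_sigma
    c(sensitivity = sum(pred & lab) / sum(lab),
      specificity = sum(!pred & !lab) / sum(!lab))
  }))
  tab <- cbind(grid, res)
  tab$objective <- tab$sensitivity + specificityWeight * tab$specificity
  ord <- order(-tab$objective, -tab$specificity, -tab$amp_threshold,
               -tab$sigma_mult)
  best <- tab[ord[1], ]
  out <- list(amp_threshold = best$amp_threshold,
              sigma_mult = best$sigma_mult,
              sensitivity = best$sensitivity,
              specificity = best$specificity,
              objective = best$objective,
              specificity_weight = specificityWeight,
              auc = rocAuc(annotations$peak_amp, lab),
              roc_curve = tab)
  class(out) <- "ThresholdCalibration"
  out
}

#' @export
print.ThresholdCalibration <- function(x, ...) {
  cat(sprintf(paste0("ThresholdCalibration: amp > %.2f dF/F, > %.1f sigma ",
                     "(sens %.3f, spec %.3f, amplitude AUC %.3f)\n"),
              x$amp_threshold, x$sigma_mult, x$sensitivity, x$specificity,
              x$auc))
  invisible(x)
}
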