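# Pixel-wise ROC evaluation of probability maps against reference scar masks:
# one curve per patient (pooling all the patient's slices), then vertical
# averaging across patients with a pointwise 95% confidence band.

#' ROC curve and AUC from scores and binary labels
#'
#' Threshold sweep over the unique score values (score >= threshold is called
#' positive); the AUC is the trapezoidal area, which with tied scores grouped
#' equals the pairwise probability `P(score_pos > score_neg) + 0.5
#' P(score_pos = score_neg)` — and hence `U / (n_pos * n_neg)` for the
#' Mann-Whitney U on the same samples.
#'
#' @param scores numeric vector (e.g. posterior probabilities).
#' @param labels binary vector; 1/TRUE marks positives (scar pixels).
#' @return An object of class `"roc_result"`: list with `thresholds`, `fpr`,
#'   `tpr` (curves from (0,0) to (1,1)), `auc`, `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  ok <- is.finite(scores) & !is.na(labels)
  scores <- scores[ok]
  labels <- labels[ok]
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0)
    stop("both classes must be present to compute a ROC curve")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  grp_end <- which(c(s[-1] != s[-length(s)], TRUE))   # last index of each tie group
  tp <- cumsum(l)[grp_end]
  fp <- cumsum(!l)[grp_end]
  tpr <- c(0, tp / n_pos, 1)
  fpr <- c(0, fp / n_neg, 1)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(thresholds = c(Inf, s[grp_end], -Inf), fpr = fpr, tpr = tpr,
                 auc = auc, n_pos = n_pos, n_neg = n_neg),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.4f  (%d positive, %d negative)\n",
              x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' ROC of a probability map against the reference scar mask
#'
#' Scores are the posterior values on the evaluated pixels; positives are the
#' reference scar pixels.  `exclude` removes pixels from the evaluation
#' (typically the gray-zone band, whose label is genuinely ambiguous).
#'
#' @param maps a [probability_map()] or list of them (one patient's slices).
#' @param annotations matching [region_annotation()]s (reference labels).
#' @param exclude optional logical mask (or list of masks) of pixels to drop.
#' @return A `"roc_result"` pooled over the slices.
#' @export
map_roc <- function(maps, annotations, exclude = NULL) {
  if (!is.null(dim(maps))) maps <- list(maps)
  if (inherits(annotations, "region_annotation")) annotations <- list(annotations)
  if (!is.null(exclude) && !is.list(exclude)) exclude <- list(exclude)
  scores <- c()
  labels <- c()
  for (i in seq_along(maps)) {
    keep <- !is.na(maps[[i]])
    if (!is.null(exclude)) keep <- keep & !exclude[[i]]
    scores <- c(scores, unclass(maps[[i]])[keep])
    labels <- c(labels, annotations[[i]]$scar[keep])
  }
  roc_auc(scores, labels)
}

#' Vertically averaged ROC with a 95% confidence band
#'
#' Each patient's TPR curve is linearly interpolated onto a common FPR grid
#' (vertical jumps collapse to their upper envelope); the band is the
#' pointwise normal interval `mean +/- 1.96 sd / sqrt(n)`, clipped to
#' `[0, 1]`.
#'
#' @param per_patient list of `"roc_result"`s, one per patient (>= 2).
#' @param grid_points number of FPR grid points.
#' @return An object of class `"averaged_roc"`: list with `fpr_grid`,
#'   `mean_tpr`, `ci_low`, `ci_high`, `per_patient_aucs`.
#' @export
average_roc <- function(per_patient, grid_points = 101L) {
  if (length(per_patient) < 2) stop("need at least 2 patients to average")
  grid <- seq(0, 1, length.out = grid_points)
  tprs <- vapply(per_patient, function(r) {
    keep <- !duplicated(r$fpr, fromLast = TRUE)   # upper envelope of jumps
    stats::approx(r$fpr[keep], r$tpr[keep], xout = grid, rule = 2)$y
  }, numeric(grid_points))
  mean_tpr <- rowMeans(tprs)
  sd_tpr <- apply(tprs, 1, stats::sd)
  half <- 1.96 * sd_tpr / sqrt(length(per_patient))
  structure(list(fpr_grid = grid, mean_tpr = mean_tpr,
                 ci_low = pmax(mean_tpr - half, 0),
                 ci_high = pmin(mean_tpr + half, 1),
                 per_patient_aucs = vapply(per_patient, `[[`, 0, "auc")),
            class = "averaged_roc")
}

#' @export
print.averaged_roc <- function(x, ...) {
  cat(sprintf("averaged ROC over %d patients: mean AUC = %.4f (range %.4f-%.4f)\n",
              length(x$per_patient_aucs), mean(x$per_patient_aucs),
              min(x$per_patient_aucs), max(x$per_patient_aucs)))
  invisible(x)
}

#' Plot an averaged ROC curve with its confidence band
#'
#' @param x an `"averaged_roc"`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.averaged_roc <- function(x, ...) {
  graphics::plot(x$fpr_grid, x$mean_tpr, type = "l", lwd = 2,
                 xlab = "false positive rate", ylab = "true positive rate",
                 xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::polygon(c(x$fpr_grid, rev(x$fpr_grid)),
                    c(x$ci_low, rev(x$ci_high)),
                    col = grDevices::adjustcolor("steelblue", 0.3), border = NA)
  graphics::lines(x$fpr_grid, x$mean_tpr, lwd = 2)
  graphics::abline(0, 1, lty = 3, col = "grey50")
  invisible(x)
}
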