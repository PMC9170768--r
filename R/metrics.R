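#' ROC curve and area under it
#'
#' Threshold sweep in descending score order with tie groups collapsed
#' (every distinct score is one operating point: predict positive when
#' \code{score >= threshold}). The area is computed by the trapezoid rule
#' over (FPR, TPR), anchored at (0, 0); it equals the pairwise concordance
#' probability \eqn{P(s^+ > s^-) + \frac12 P(s^+ = s^-)}.
#'
#' @param scores numeric prediction scores.
#' @param labels binary labels (0/1 or logical).
#' @return a list with \code{points} (data.frame \code{threshold},
#'   \code{fpr}, \code{tpr}) and \code{auroc}.
#' @export
rocAuroc <- function(scores, labels) {
    sw <- sweepCounts(scores, labels)
    tpr <- sw$tp / sw$nPos
    fpr <- sw$fp / sw$nNeg
    auroc <- sum(diff(c(0, fpr)) * (c(0, tpr[-length(tpr)]) + tpr) / 2)
    list(points = data.frame(threshold = sw$thr, fpr = fpr, tpr = tpr),
         auroc = auroc)
}

#' Precision-recall curve and area under it
#'
#' Same descending-threshold sweep as [rocAuroc()];
#' \code{precision = TP / (TP + FP)}, \code{recall = TP / (TP + FN)}. The
#' area is the trapezoid rule over recall, anchored at recall 0 with the
#' precision of the most stringent threshold.
#'
#' @inheritParams rocAuroc
#' @return a list with \code{points} (data.frame \code{threshold},
#'   \code{recall}, \code{precision}) and \code{auprc}.
#' @export
prAuprc <- function(scores, labels) {
    sw <- sweepCounts(scores, labels)
    recall <- sw$tp / sw$nPos
    precision <- sw$tp / (sw$tp + sw$fp)
    auprc <- sum(diff(c(0, recall)) *
                 (c(precision[1L], precision[-length(precision)]) +
                  precision) / 2)
    list(points = data.frame(threshold = sw$thr, recall = recall,
                             precision = precision),
         auprc = auprc)
}

# cumulative TP/FP at every distinct threshold, descending
sweepCounts <- function(scores, labels) {
    labels <- as.integer(labels)
    if (length(scores) != length(labels))
        stop("'scores' and 'labels' must have equal length")
    nPos <- sum(labels == 1L)
    nNeg <- sum(labels == 0L)
    if (nPos == 0L || nNeg == 0L)
        stop("both classes must be present to sweep thresholds")
    ord <- order(scores, decreasing = TRUE)
    s <- scores[ord]
    y <- labels[ord]
    tp <- cumsum(y)
    fp <- cumsum(1L - y)
    last <- which(!duplicated(s, fromLast = TRUE))   # collapse tie groups
    list(thr = s[last], tp = tp[last], fp = fp[last],
         nPos = nPos, nNeg = nNeg)
}

#' Write ROC / PR operating points as TSV
#'
#' @param metric result of [rocAuroc()] or [prAuprc()].
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
writeMetricPoints <- function(metric, path) {
    utils::write.table(metric$points, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
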