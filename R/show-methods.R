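setMethod("show", "OCRModelSpec", function(object) {
    cat("OCRModelSpec\n")
    cat(sprintf("  conv1: %d filters x %d bp   conv2: %d filters x %d\n",
                object@conv1Filters, object@conv1Width,
                object@conv2Filters, object@conv2Width))
    cat(sprintf("  fc: %d units   dropout: %.2f   input: %d bp\n",
                object@fcUnits, object@dropout, object@inputLength))
    cat(sprintf("  adam lr %.2g, batch %d, %d epochs, seed %d\n",
                object@learningRate, object@batchSize, object@epochs,
                object@seed))
})

setMethod("show", "OCRModel", function(object) {
    cat(sprintf("OCRModel (%s, %d parameters)\n",
                if (object@trained) "trained" else "untrained",
                paramCount(object)))
    show(object@spec)
    if (!is.null(object@history)) {
        n <- nrow(object@history)
        best <- which.min(object@history$valLoss)
        cat(sprintf("  %d epochs run; best validation loss %.4f at epoch %d\n",
                    n, object@history$valLoss[best], best))
    }
})

setMethod("show", "OCRDataset", function(object) {
    n <- length(object@labels)
    cat(sprintf("OCRDataset: %d fragments (%d pairs) of %d bp\n",
                n, n %/% 2L, object@fragmentLength))
    if (all(is.na(object@partition))) {
        cat("  partitions: unassigned\n")
    } else {
        tab <- table(factor(object@partition,
                            c("train", "validation", "test")))
        cat(sprintf("  partitions: train %d, validation %d, test %d\n",
                    tab[1L], tab[2L], tab[3L]))
    }
})

setMethod("show", "PFMotif", function(object) {
    cat(sprintf("PFMotif: %d bp, %d sites\n", ncol(object@counts),
                object@nSites))
})

setMethod("show", "PWMotif", function(object) {
    cat(sprintf("PWMotif '%s': %d bp, %.2f bits total IC\n",
                object@name, ncol(object@probs), sum(object@ic)))
    cat("  consensus:", paste(rownames(object@probs)[
        apply(object@probs, 2L, which.max)], collapse = ""), "\n")
})

setMethod("show", "ProbabilityTrack", function(object) {
    cat(sprintf(
        "ProbabilityTrack %s: %d windows of %d bp, step %d (%d bp scanned)\n",
        object@chrom, length(object@starts), object@windowWidth,
        object@step, object@chromLength))
    if (length(object@probs))
        cat(sprintf("  probabilities: min %.3f, median %.3f, max %.3f\n",
                    min(object@probs), stats::median(object@probs),
                    max(object@probs)))
})

setMethod("show", "SyntheticSpec", function(object) {
    cat(sprintf(
        "SyntheticSpec: %d bp in %d chrom(s), %d OCRs (~%.0f +/- %.0f bp)\n",
        object@genomeLength, object@nChroms, object@nOCRs,
        object@ocrLengthMean, object@ocrLengthSD))
    cat(sprintf("  %d motif(s), %d instance(s)/OCR, detection rate %.2f, seed %d\n",
                length(object@motifs), object@motifsPerOCR,
                object@detectionRate, object@seed))
})

#' Accessors
#'
#' \code{modelSpec} returns the specification of a model;
#' \code{trainingHistory} its per-epoch history; \code{motifProbs},
#' \code{motifIC} and \code{motifCounts} the matrices inside motif
#' objects; \code{trackProbs} the window probabilities of a track.
#'
#' @param x the object to access.
#' @return the corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
modelSpec <- function(x) { stopifnot(is(x, "OCRModel")); x@spec }

#' @rdname accessors
#' @export
trainingHistory <- function(x) { stopifnot(is(x, "OCRModel")); x@history }

#' @rdname accessors
#' @export
motifProbs <- function(x) { stopifnot(is(x, "PWMotif")); x@probs }

#' @rdname accessors
#' @export
motifIC <- function(x) { stopifnot(is(x, "PWMotif")); x@ic }

#' @rdname accessors
#' @export
motifCounts <- function(x) { stopifnot(is(x, "PFMotif")); x@counts }

#' @rdname accessors
#' @export
trackProbs <- function(x) { stopifnot(is(x, "ProbabilityTrack")); x@probs }
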