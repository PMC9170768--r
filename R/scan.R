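#' Sliding-window start coordinates
#'
#' 0-based starts \code{0, step, 2*step, ...} of fixed-width windows along
#' a sequence; incomplete tail windows are dropped, so the count is
#' \code{floor((L - width) / step) + 1} when \code{L >= width} and 0 (with
#' a warning) otherwise. The defaults — 36 bp windows every 5 bp — trade
#' positional resolution against the number of fragments to score.
#'
#' @param seqLength sequence length in bp.
#' @param width window width in bp (default 36).
#' @param step distance between starts in bp (default 5).
#' @return integer vector of 0-based starts.
#' @examples
#' slidingWindowStarts(46)   # 0, 5, 10
#' @export
slidingWindowStarts <- function(seqLength, width = 36L, step = 5L) {
    stopifnot(width >= 1L, step >= 1L)
    if (seqLength < width) {
        warning("sequence (", seqLength, " bp) shorter than window (",
                width, " bp); no windows")
        return(integer(0))
    }
    seq.int(0L, seqLength - width, by = step)
}

#' Score a genome with sliding windows
#'
#' Slides fixed-width windows along every chromosome, one-hot encodes each
#' window, scores it with [predictProba()] in batches, and returns one
#' [ProbabilityTrack] per chromosome. Chromosomes shorter than the window
#' are skipped with a warning. Scores are clipped into
#' \eqn{(10^{-12}, 1 - 10^{-12})} so saturated sigmoid outputs stay inside
#' the open interval.
#'
#' @param model a trained [OCRModel].
#' @param genome a named [Biostrings::DNAStringSet].
#' @param width window width in bp (default 36).
#' @param step sliding step in bp (default 5).
#' @param batchSize windows encoded and scored per batch.
#' @return a named list of [ProbabilityTrack], one per scored chromosome.
#' @export
scoreGenome <- function(model, genome, width = 36L, step = 5L,
                        batchSize = 2048L) {
    if (!is(model, "OCRModel") || !model@trained)
        stop("'model' must be a trained OCRModel")
    if (width < minInputLength(model@spec))
        stop("window width ", width, " is below the model's ",
             minInputLength(model@spec), " bp receptive field")
    out <- list()
    for (chrom in names(genome)) {
        chromSeq <- as.character(genome[[chrom]])
        chromLen <- nchar(chromSeq)
        if (chromLen < width) {
            warning("chromosome '", chrom, "' (", chromLen,
                    " bp) shorter than window; skipped")
            next
        }
        starts <- seq.int(0L, chromLen - width, by = step)
        probs <- numeric(length(starts))
        i <- 1L
        while (i <= length(starts)) {
            j <- min(length(starts), i + batchSize - 1L)
            frag <- substring(chromSeq, starts[i:j] + 1L, starts[i:j] + width)
            probs[i:j] <- predictBatched(model@weights, model@spec,
                                         oneHotBatch(frag))
            i <- j + 1L
        }
        probs <- pmin(pmax(probs, 1e-12), 1 - 1e-12)
        out[[chrom]] <- methods::new("ProbabilityTrack",
            chrom = chrom, starts = starts, windowWidth = as.integer(width),
            step = as.integer(step), probs = probs,
            chromLength = as.integer(chromLen))
    }
    out
}

#' Per-base scores from a window probability track
#'
#' Each base receives the maximum probability over all windows covering it
#' (the default aggregation: the max preserves peak sharpness at a small
#' step); \code{method = "mean"} averages the covering windows instead.
#' Bases covered by no window score 0.
#'
#' @param track a [ProbabilityTrack].
#' @param chromLength length of the score vector to produce (defaults to
#'   the track's chromosome length).
#' @param method \code{"max"} (default) or \code{"mean"}.
#' @return numeric vector of length \code{chromLength}.
#' @export
trackToBaseScores <- function(track, chromLength = track@chromLength,
                              method = c("max", "mean")) {
    method <- match.arg(method)
    score <- numeric(chromLength)
    if (!length(track@starts)) return(score)
    w <- track@windowWidth
    if (method == "max") {
        for (off in seq_len(w) - 1L) {
            idx <- track@starts + 1L + off
            score[idx] <- pmax(score[idx], track@probs)
        }
    } else {
        cnt <- numeric(chromLength)
        for (off in seq_len(w) - 1L) {
            idx <- track@starts + 1L + off
            score[idx] <- score[idx] + track@probs
            cnt[idx] <- cnt[idx] + 1
        }
        cov <- cnt > 0
        score[cov] <- score[cov] / cnt[cov]
    }
    score
}

#' Call peaks from per-base scores
#'
#' A threshold-merge caller: maximal runs of bases scoring at least
#' \code{threshold} are peak seeds; runs separated by fewer than
#' \code{mergeGap} sub-threshold bases are merged; merged runs shorter
#' than \code{minLength} bp are discarded. The summit is the leftmost base
#' attaining the run's maximal score, and the peak score is that maximum.
#'
#' @param baseScores numeric per-base score vector (see
#'   [trackToBaseScores()]).
#' @param chrom chromosome name for the returned ranges.
#' @param threshold calling threshold in (0, 1) (default 0.5, the sigmoid
#'   decision point).
#' @param mergeGap maximal unscored gap to bridge, in bp (default 50,
#'   about ten sliding steps).
#' @param minLength minimal peak length in bp (default 36, one window).
#' @return a [GenomicRanges::GRanges] with metadata columns \code{score}
#'   (peak maximum probability) and \code{summit} (0-based offset of the
#'   summit within the peak).
#' @export
callPeaks <- function(baseScores, chrom = "chr1", threshold = 0.5,
                      mergeGap = 50L, minLength = 36L) {
    stopifnot(threshold > 0, threshold < 1)
    above <- baseScores >= threshold
    if (!any(above))
        return(GenomicRanges::GRanges(score = numeric(0),
                                      summit = integer(0)))
    r <- rle(above)
    ends <- cumsum(r$lengths)
    startsRun <- ends - r$lengths + 1L
    runStart <- startsRun[r$values]
    runEnd <- ends[r$values]
    # merge runs separated by < mergeGap sub-threshold bases
    if (length(runStart) > 1L) {
        gap <- runStart[-1L] - runEnd[-length(runEnd)] - 1L
        newBlock <- c(TRUE, gap >= mergeGap)
        block <- cumsum(newBlock)
        runStart <- tapply(runStart, block, min)
        runEnd <- tapply(runEnd, block, max)
    }
    keep <- (runEnd - runStart + 1L) >= minLength
    runStart <- runStart[keep]; runEnd <- runEnd[keep]
    if (!length(runStart))
        return(GenomicRanges::GRanges(score = numeric(0),
                                      summit = integer(0)))
    score <- numeric(length(runStart))
    summit <- integer(length(runStart))
    for (i in seq_along(runStart)) {
        seg <- baseScores[runStart[i]:runEnd[i]]
        score[i] <- max(seg)
        summit[i] <- which.max(seg) - 1L   # leftmost max, 0-based offset
    }
    GenomicRanges::GRanges(chrom,
        IRanges::IRanges(start = as.integer(runStart),
                         end = as.integer(runEnd)),
        score = score, summit = summit)
}

#' Predict open chromatin regions across a genome
#'
#' The full de novo route: slide windows, score them, aggregate to
#' per-base scores, and call threshold-merge peaks on every chromosome.
#'
#' @inheritParams scoreGenome
#' @inheritParams callPeaks
#' @param aggregate per-base aggregation method, see [trackToBaseScores()].
#' @return a [GenomicRanges::GRanges] of predicted OCRs, sorted by
#'   chromosome and start, named \code{OCR_1 ...}, with \code{score} and
#'   \code{summit} metadata.
#' @export
predictOCRs <- function(model, genome, width = 36L, step = 5L,
                        threshold = 0.5, mergeGap = 50L, minLength = 36L,
                        batchSize = 2048L, aggregate = c("max", "mean")) {
    aggregate <- match.arg(aggregate)
    tracks <- scoreGenome(model, genome, width, step, batchSize)
    peaks <- lapply(tracks, function(tr)
        callPeaks(trackToBaseScores(tr, method = aggregate),
                  chrom = tr@chrom, threshold = threshold,
                  mergeGap = mergeGap, minLength = minLength))
    out <- suppressWarnings(do.call(c, unname(peaks)))
    if (length(out)) {
        out <- GenomicRanges::sort(out, ignore.strand = TRUE)
        names(out) <- sprintf("OCR_%d", seq_along(out))
    }
    out
}

#' Write predicted OCRs as BED6
#'
#' Scores are written per BED convention as the peak maximum probability
#' scaled by 1000 and rounded to an integer.
#'
#' @param peaks a \code{GRanges} from [predictOCRs()].
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
writePredictionsBed <- function(peaks, path) {
    gr <- peaks
    mc <- S4Vectors::mcols(gr)
    S4Vectors::mcols(gr) <- NULL
    S4Vectors::mcols(gr)$name <- if (is.null(names(peaks)))
        sprintf("OCR_%d", seq_along(peaks)) else names(peaks)
    S4Vectors::mcols(gr)$score <- if ("score" %in% colnames(mc))
        as.integer(round(1000 * mc$score)) else 0L
    names(gr) <- NULL
    writeBed(gr, path, format = "bed6")
}

#' Export above-threshold windows for an external peak caller
#'
#' Writes every window with probability at least \code{threshold} as a
#' BED6 line (interval, window probability as score), sorted by chromosome
#' and start — the input route for users who want to run an external
#' caller such as MACS2 on the window scores instead of the built-in
#' threshold-merge caller.
#'
#' @param tracks a [ProbabilityTrack] or list of them.
#' @param threshold minimal window probability to export.
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
exportFragmentsBed <- function(tracks, threshold, path) {
    if (is(tracks, "ProbabilityTrack")) tracks <- list(tracks)
    ord <- order(vapply(tracks, function(t) t@chrom, character(1)))
    lines <- character(0)
    k <- 0L
    for (tr in tracks[ord]) {
        sel <- which(tr@probs >= threshold)
        if (!length(sel)) next
        lines <- c(lines, paste(
            tr@chrom, tr@starts[sel], tr@starts[sel] + tr@windowWidth,
            sprintf("frag_%d", k + seq_along(sel)),
            sprintf("%.6f", tr@probs[sel]), ".", sep = "\t"))
        k <- k + length(sel)
    }
    writeLines(lines, path)
    invisible(path)
}

#' Export per-base scores as bedGraph
#'
#' Run-length-compressed four-column bedGraph (0-based half-open) of the
#' per-base aggregated probabilities.
#'
#' @param tracks a [ProbabilityTrack] or list of them.
#' @param path output file path.
#' @param aggregate aggregation method, see [trackToBaseScores()].
#' @return invisibly, \code{path}.
#' @export
writeBedGraph <- function(tracks, path, aggregate = c("max", "mean")) {
    aggregate <- match.arg(aggregate)
    if (is(tracks, "ProbabilityTrack")) tracks <- list(tracks)
    con <- file(path, "w")
    on.exit(close(con))
    for (tr in tracks) {
        score <- round(trackToBaseScores(tr, method = aggregate), 6)
        r <- rle(score)
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths
        keep <- r$values > 0
        if (any(keep))
            writeLines(paste(tr@chrom, starts[keep], ends[keep],
                             format(r$values[keep], scientific = FALSE,
                                    trim = TRUE),
                             sep = "\t"), con)
    }
    invisible(path)
}
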