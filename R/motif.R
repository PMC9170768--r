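#' Harvest high-activation subsequences for each first-layer filter
#'
#' Every convolution filter is a motif probe: for each filter, the
#' positive fragments are scanned and every position whose pre-activation
#' score exceeds \code{thresholdFrac} times that filter's maximum score
#' over the whole positive set is recorded, and the aligned
#' \code{conv1Width}-bp subsequence under the receptive field is
#' extracted. Subsequences containing \code{N} are skipped (they carry no
#' base-frequency information), and filters with fewer than
#' \code{minSites} hits are flagged inactive.
#'
#' @param model a trained [OCRModel].
#' @param positives positive fragments (a [Biostrings::DNAStringSet] or
#'   character vector of equal-length sequences).
#' @param thresholdFrac fraction of the per-filter maximum activation
#'   (default 0.5) a position must exceed (strictly) to be harvested.
#' @param minSites minimum number of hits for a filter to count as active.
#' @return a list with one element per filter: \code{subsequences}
#'   (character), \code{active} (logical), \code{maxScore}.
#' @export
harvestActivations <- function(model, positives, thresholdFrac = 0.5,
                               minSites = 10L) {
    if (!is(model, "OCRModel") || !model@trained)
        stop("'model' must be a trained OCRModel")
    stopifnot(thresholdFrac > 0, thresholdFrac <= 1)
    seqs <- as.character(positives)
    L <- unique(nchar(seqs))
    if (length(L) != 1L) stop("positive fragments must share one length")
    spec <- model@spec
    w1 <- spec@conv1Width
    F1 <- spec@conv1Filters
    P1 <- L - w1 + 1L
    X <- oneHotBatch(seqs)
    idx1 <- im2colIndex(4L, L, w1)
    Z1 <- model@weights$W1 %*% im2col(X, idx1, 4L * w1) + model@weights$b1
    # columns of Z1: P1 positions of fragment 1, then fragment 2, ...
    maxScore <- apply(Z1, 1L, max)
    out <- vector("list", F1)
    colFrag <- rep(seq_along(seqs), each = P1)
    colPos <- rep(seq_len(P1), times = length(seqs))
    for (f in seq_len(F1)) {
        thr <- thresholdFrac * maxScore[f]
        hits <- which(Z1[f, ] > thr & maxScore[f] > 0)
        subs <- substring(seqs[colFrag[hits]], colPos[hits],
                          colPos[hits] + w1 - 1L)
        subs <- subs[!grepl("N", subs, fixed = TRUE)]
        out[[f]] <- list(subsequences = subs,
                         active = length(subs) >= minSites,
                         maxScore = maxScore[f])
    }
    names(out) <- sprintf("filter_%03d", seq_len(F1))
    out
}

#' Position frequency matrix from aligned subsequences
#'
#' Counts each base at each position over a set of equal-width
#' subsequences.
#'
#' @param subsequences character vector (or \code{DNAStringSet}) of
#'   equal-width sequences over A, C, G, T.
#' @return a [PFMotif].
#' @examples
#' buildPFM(c("ACG", "ACG"))
#' @export
buildPFM <- function(subsequences) {
    subsequences <- as.character(subsequences)
    if (!length(subsequences)) stop("need at least one subsequence")
    if (length(unique(nchar(subsequences))) != 1L)
        stop("subsequences must all have the same width")
    cm <- Biostrings::consensusMatrix(
        Biostrings::DNAStringSet(subsequences))
    counts <- matrix(0L, 4L, nchar(subsequences[1L]),
                     dimnames = list(c("A", "C", "G", "T"), NULL))
    common <- intersect(rownames(cm), rownames(counts))
    counts[common, ] <- cm[common, , drop = FALSE]
    methods::new("PFMotif", counts = counts,
                 nSites = length(subsequences))
}

#' Convert a PFM to a pseudocounted PWM with information content
#'
#' Probabilities are \eqn{(counts + c) / (n + 4c)} with pseudocount
#' \eqn{c} per base; the per-column information content is
#' \eqn{2 + \sum_b p_b \log_2 p_b} bits (0 for a uniform column, 2 for a
#' fixed base), and the logo heights are the probabilities scaled by the
#' column information content.
#'
#' @param pfm a [PFMotif].
#' @param pseudocount pseudocount per base (default 0.25).
#' @param name motif name carried into the result.
#' @return a [PWMotif].
#' @export
pfmToPwm <- function(pfm, pseudocount = 0.25, name = "motif") {
    stopifnot(is(pfm, "PFMotif"), pfm@nSites >= 1L, pseudocount >= 0)
    probs <- (pfm@counts + pseudocount) /
        (pfm@nSites + 4 * pseudocount)
    pwmFromProbs(probs, name = name)
}

# assemble a PWMotif from a column-stochastic matrix
pwmFromProbs <- function(probs, name = "motif") {
    rownames(probs) <- c("A", "C", "G", "T")
    plogp <- ifelse(probs > 0, probs * log2(probs), 0)
    ic <- pmin(pmax(2 + colSums(plogp), 0), 2)
    methods::new("PWMotif", probs = probs, ic = ic,
                 logoHeights = sweep(probs, 2L, ic, `*`), name = name)
}

#' Best ungapped alignment similarity between two PWMs
#'
#' Slides \code{b} along \code{a} over every ungapped offset with at least
#' \code{minOverlap} overlapping columns, in both orientations (forward
#' and reverse complement), and returns the maximal Pearson correlation of
#' the overlapping probability entries.
#'
#' @param a,b [PWMotif] objects of width >= \code{minOverlap}.
#' @param minOverlap minimum overlapping columns (default 4).
#' @return a list with \code{score} in \[-1, 1\], \code{offset} (columns of
#'   \code{a} the start of \code{b} is shifted by; may be negative) and
#'   \code{orientation} (\code{"forward"} or \code{"reverse"}).
#' @export
pwmSimilarity <- function(a, b, minOverlap = 4L) {
    stopifnot(is(a, "PWMotif"), is(b, "PWMotif"))
    wa <- ncol(a@probs); wb <- ncol(b@probs)
    if (min(wa, wb) < minOverlap)
        stop("motifs must have at least ", minOverlap, " columns")
    best <- list(score = -Inf, offset = NA_integer_,
                 orientation = NA_character_)
    for (orient in c("forward", "reverse")) {
        pb <- if (orient == "forward") b@probs else revcompPwm(b@probs)
        for (off in seq.int(-(wb - minOverlap), wa - minOverlap)) {
            ja <- seq_len(wa)
            jb <- ja - off
            keep <- jb >= 1L & jb <= wb
            if (sum(keep) < minOverlap) next
            va <- as.vector(a@probs[, ja[keep], drop = FALSE])
            vb <- as.vector(pb[, jb[keep], drop = FALSE])
            r <- suppressWarnings(stats::cor(va, vb))
            if (!is.na(r) && r > best$score)
                best <- list(score = r, offset = off, orientation = orient)
        }
    }
    if (!is.finite(best$score))
        stop("no alignment with ", minOverlap, " overlapping columns")
    best
}

revcompPwm <- function(probs) {
    out <- probs[c("T", "G", "C", "A"), rev(seq_len(ncol(probs))),
                 drop = FALSE]
    rownames(out) <- c("A", "C", "G", "T")
    out
}

#' Extract filter motifs from a trained model
#'
#' Composes [harvestActivations()], [buildPFM()] and [pfmToPwm()]: for
#' every active filter the harvested subsequences become a PFM and a
#' pseudocounted PWM.
#'
#' @inheritParams harvestActivations
#' @param pseudocount pseudocount per base for [pfmToPwm()].
#' @return a list with \code{pwm} (list of [PWMotif]), \code{pfm} (list of
#'   [PFMotif]), \code{nSites} and \code{active} (per-filter), each named
#'   by filter.
#' @export
extractMotifs <- function(model, positives, thresholdFrac = 0.5,
                          pseudocount = 0.25, minSites = 10L) {
    harv <- harvestActivations(model, positives, thresholdFrac, minSites)
    active <- vapply(harv, `[[`, logical(1), "active")
    pfms <- lapply(harv[active], function(h) buildPFM(h$subsequences))
    pwms <- mapply(function(pfm, nm) pfmToPwm(pfm, pseudocount, name = nm),
                   pfms, names(pfms), SIMPLIFY = FALSE)
    list(pwm = pwms, pfm = pfms,
         nSites = vapply(harv, function(h) length(h$subsequences),
                         integer(1)),
         active = active)
}

#' Export logo-height matrices
#'
#' Writes each motif's 4 x w logo-height matrix (probability times column
#' information content, the quantity a sequence-logo renderer stacks) as a
#' TSV file named after the motif.
#'
#' @param pwms a list of [PWMotif].
#' @param dir output directory (created if needed).
#' @return invisibly, the written paths.
#' @export
writeLogoHeights <- function(pwms, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- vapply(pwms, function(p) {
        path <- file.path(dir, paste0(p@name, "_logo.tsv"))
        df <- data.frame(base = rownames(p@logoHeights),
                         p@logoHeights, check.names = FALSE)
        colnames(df) <- c("base", sprintf("pos%d", seq_len(ncol(p@probs))))
        utils::write.table(df, path, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        path
    }, character(1))
    invisible(paths)
}
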