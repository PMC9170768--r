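#' Sample a random motif PWM with a target information content
#'
#' Draws a random column-stochastic PWM whose mean per-column information
#' content lies within 0.1 bits of \code{targetIC}. Each column places a
#' randomly chosen dominant base and mixes it toward the uniform
#' distribution until the (slightly jittered) per-column target is met, so
#' consecutive columns differ in both dominant base and sharpness.
#'
#' @param width motif width in bp (4 to 30; regulatory motifs are
#'   typically 6-19 bp).
#' @param targetIC target mean per-column information content in bits
#'   (0 to 2).
#' @param seed integer seed.
#' @param name motif name.
#' @return a [PWMotif].
#' @examples
#' sampleMotif(12, 1.6, seed = 1)
#' @export
sampleMotif <- function(width, targetIC, seed = 1L, name = "planted") {
    stopifnot(width >= 4L, width <= 30L, targetIC >= 0, targetIC <= 2)
    withSeed(seed, {
        jitterAmp <- min(0.15, targetIC, 2 - targetIC)
        probs <- vapply(seq_len(width), function(j) {
            tj <- targetIC + stats::runif(1, -jitterAmp, jitterAmp)
            dom <- sample.int(4L, 1L)
            colIC <- function(alpha) {
                p <- (1 - alpha) * as.numeric(seq_len(4L) == dom) +
                    alpha * 0.25
                plogp <- ifelse(p > 0, p * log2(p), 0)
                2 + sum(plogp) - tj
            }
            alpha <- if (tj >= 2) 0 else if (tj <= 0) 1 else
                stats::uniroot(colIC, c(0, 1), tol = 1e-10)$root
            (1 - alpha) * as.numeric(seq_len(4L) == dom) + alpha * 0.25
        }, numeric(4L))
        pwmFromProbs(probs, name = name)
    })
}

#' Construct a synthetic-genome specification
#'
#' @param genomeLength total genome length in bp.
#' @param nChroms number of chromosomes (the length is split near-equally).
#' @param backgroundProbs background base probabilities (A, C, G, T).
#' @param motifs list of [PWMotif] to plant.
#' @param nOCRs number of ground-truth open regions.
#' @param ocrLengthMean,ocrLengthSD OCR length distribution in bp;
#'   lengths are truncated to be strictly greater than 200 bp so the
#'   positive-sample length filter retains every generated region.
#' @param motifsPerOCR planted motif instances per OCR.
#' @param detectionRate probability that a true OCR appears in the
#'   "observed" assay peak set.
#' @param seed integer seed.
#' @return a [SyntheticSpec].
#' @export
syntheticSpec <- function(genomeLength = 500000L, nChroms = 1L,
                          backgroundProbs = rep(0.25, 4),
                          motifs = list(sampleMotif(12L, 1.6)),
                          nOCRs = 400L, ocrLengthMean = 250,
                          ocrLengthSD = 30, motifsPerOCR = 3L,
                          detectionRate = 0.8, seed = 2021L) {
    methods::new("SyntheticSpec",
        genomeLength = as.integer(genomeLength),
        nChroms = as.integer(nChroms),
        backgroundProbs = backgroundProbs, motifs = motifs,
        nOCRs = as.integer(nOCRs), ocrLengthMean = ocrLengthMean,
        ocrLengthSD = ocrLengthSD, motifsPerOCR = as.integer(motifsPerOCR),
        detectionRate = detectionRate, seed = as.integer(seed))
}

#' The canonical benchmark scenario
#'
#' One 500 kb chromosome of uniform background, a single planted 12-bp
#' motif at 1.6 bits per column mean information content, 400
#' non-overlapping OCRs of about 250 +/- 30 bp (all strictly longer than
#' 200 bp), 3 motif instances per OCR, and an observed peak set keeping
#' each true OCR with probability 0.8.
#'
#' @param seed integer seed (the planted motif is derived from it too, so
#'   different seeds give fully independent scenarios).
#' @return a [SyntheticSpec].
#' @export
defaultScenario <- function(seed = 2021L) {
    seed <- as.integer(seed)
    syntheticSpec(
        genomeLength = 500000L, nChroms = 1L,
        backgroundProbs = rep(0.25, 4),
        motifs = list(sampleMotif(12L, 1.6, seed = seed + 7919L)),
        nOCRs = 400L, ocrLengthMean = 250, ocrLengthSD = 30,
        motifsPerOCR = 3L, detectionRate = 0.8, seed = seed)
}

#' Generate a synthetic genome with planted OCRs
#'
#' Draws background sequence from the background base probabilities,
#' places non-overlapping OCR intervals (at least 50 bp apart, mimicking
#' separated assay peaks), plants \code{motifsPerOCR} independent draws
#' from the motif PWMs at random non-overlapping offsets inside each OCR,
#' and subsamples the truth set at \code{detectionRate} to form the
#' "observed" peak set a single assay would report. Fully deterministic
#' for a fixed \code{spec@seed}.
#'
#' @param spec a [SyntheticSpec].
#' @param dir optional directory; when given, \code{genome.fa},
#'   \code{truth.bed} and \code{observed.bed} are written there.
#' @return a list with \code{genome} (DNAStringSet), \code{truth}
#'   (GRanges of all OCRs), \code{observed} (GRanges subset), and
#'   \code{motifSites} (GRanges of planted instances, with motif name).
#' @export
buildGenome <- function(spec, dir = NULL) {
    methods::validObject(spec)
    res <- withSeed(spec@seed, {
        chromLens <- rep(spec@genomeLength %/% spec@nChroms, spec@nChroms)
        chromLens[1L] <- chromLens[1L] +
            spec@genomeLength - sum(chromLens)
        chromNames <- sprintf("chr%d", seq_len(spec@nChroms))
        perChrom <- largestRemainder(spec@nOCRs,
                                     chromLens / sum(chromLens))
        bases <- c("A", "C", "G", "T")
        genome <- character(spec@nChroms)
        truthL <- list(); siteL <- list()
        for (ci in seq_len(spec@nChroms)) {
            letters <- sample(bases, chromLens[ci], replace = TRUE,
                              prob = spec@backgroundProbs)
            starts <- integer(0); ends <- integer(0)
            for (k in seq_len(perChrom[ci])) {
                len <- 0L
                while (len <= 200L)
                    len <- as.integer(round(stats::rnorm(
                        1, spec@ocrLengthMean, spec@ocrLengthSD)))
                placed <- FALSE
                for (try in seq_len(1000L)) {
                    s <- sample.int(chromLens[ci] - len + 1L, 1L)
                    e <- s + len - 1L
                    if (!any(s <= ends + 50L & e >= starts - 50L)) {
                        starts <- c(starts, s); ends <- c(ends, e)
                        placed <- TRUE
                        break
                    }
                }
                if (!placed)
                    stop("failed to place OCR ", k, " on ", chromNames[ci],
                         " after 1000 attempts; reduce nOCRs or lengths")
            }
            ord <- order(starts)
            starts <- starts[ord]; ends <- ends[ord]
            # plant motifs at non-overlapping offsets inside each OCR
            siteStart <- integer(0); siteMotif <- character(0)
            for (k in seq_along(starts)) {
                placedS <- integer(0); placedE <- integer(0)
                for (m in seq_len(spec@motifsPerOCR)) {
                    pw <- spec@motifs[[((m - 1L) %% length(spec@motifs)) + 1L]]
                    w <- ncol(pw@probs)
                    for (try in seq_len(200L)) {
                        s <- starts[k] +
                            sample.int(ends[k] - starts[k] - w + 2L, 1L) - 1L
                        e <- s + w - 1L
                        if (!any(s <= placedE & e >= placedS)) {
                            placedS <- c(placedS, s); placedE <- c(placedE, e)
                            inst <- vapply(seq_len(w), function(j)
                                sample(bases, 1L, prob = pw@probs[, j]),
                                character(1))
                            letters[s:e] <- inst
                            siteStart <- c(siteStart, s)
                            siteMotif <- c(siteMotif, pw@name)
                            break
                        }
                    }
                }
            }
            genome[ci] <- paste(letters, collapse = "")
            truthL[[ci]] <- GenomicRanges::GRanges(
                chromNames[ci], IRanges::IRanges(start = starts, end = ends))
            siteW <- vapply(siteMotif, function(nm)
                ncol(spec@motifs[[match(nm, vapply(spec@motifs, function(p)
                    p@name, character(1)))]]@probs), integer(1))
            siteL[[ci]] <- GenomicRanges::GRanges(
                chromNames[ci],
                IRanges::IRanges(start = siteStart, width = siteW),
                motif = unname(siteMotif))
        }
        genomeSet <- Biostrings::DNAStringSet(genome)
        names(genomeSet) <- chromNames
        truth <- suppressWarnings(do.call(c, truthL))
        observed <- truth[stats::rbinom(length(truth), 1L,
                                        spec@detectionRate) == 1L]
        list(genome = genomeSet, truth = truth, observed = observed,
             motifSites = suppressWarnings(do.call(c, siteL)))
    })
    if (!is.null(dir)) {
        dir.create(dir, showWarnings = FALSE, recursive = TRUE)
        writeFasta(res$genome, file.path(dir, "genome.fa"))
        writeBed(res$truth, file.path(dir, "truth.bed"), format = "bed3")
        writeBed(res$observed, file.path(dir, "observed.bed"),
                 format = "bed3")
    }
    res
}
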