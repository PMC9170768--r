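#' Keep accessibility peaks long enough to train on
#'
#' Retains exactly the peaks strictly longer than \code{minLength} bp
#' (longer fragments carry more statistical power; the cutoff is strict, so
#' a peak of exactly \code{minLength} bp is excluded), preserving input
#' order.
#'
#' @param peaks a [GenomicRanges::GRanges] of assay peaks.
#' @param minLength length cutoff in bp (default 200).
#' @return the retained \code{GRanges}; a warning is raised if nothing
#'   survives.
#' @export
filterPeaks <- function(peaks, minLength = 200L) {
    stopifnot(minLength >= 1L)
    keep <- GenomicRanges::width(peaks) > minLength
    if (!any(keep))
        warning("no peaks longer than ", minLength, " bp; empty result")
    peaks[keep]
}

#' Fixed-width training windows from peaks
#'
#' Turns variable-length peaks into equal-length sequence fragments for the
#' fixed-width network input. \code{mode = "center"} takes one window of
#' \code{L} bp centered on each peak midpoint (windows running off a
#' chromosome end are dropped with a warning); \code{mode = "tile"} takes
#' non-overlapping \code{L}-bp windows left-aligned across each peak.
#'
#' @param genome a named [Biostrings::DNAStringSet].
#' @param peaks a [GenomicRanges::GRanges] of (already length-filtered)
#'   peaks.
#' @param L window length in bp.
#' @param mode \code{"center"} or \code{"tile"}.
#' @return a [Biostrings::DNAStringSet] of \code{L}-bp fragments; names
#'   record the source coordinates (0-based half-open).
#' @export
makePositiveWindows <- function(genome, peaks, L = 200L,
                                mode = c("center", "tile")) {
    mode <- match.arg(mode)
    stopifnot(L >= 1L)
    if (L > min(Biostrings::width(genome)))
        stop("window length L = ", L, " exceeds the shortest chromosome")
    chrom <- as.character(GenomicRanges::seqnames(peaks))
    chromLen <- Biostrings::width(genome)[match(chrom, names(genome))]
    if (mode == "center") {
        start0 <- GenomicRanges::start(peaks) - 1L
        end0 <- GenomicRanges::end(peaks)
        mid <- (start0 + end0) %/% 2L
        ws <- mid - L %/% 2L
        we <- ws + L
        ok <- ws >= 0L & we <= chromLen
        if (!all(ok))
            warning(sum(!ok), " window(s) clipped by a chromosome end; dropped")
        wins <- GenomicRanges::GRanges(
            chrom[ok], IRanges::IRanges(start = ws[ok] + 1L, width = L))
    } else {
        n <- GenomicRanges::width(peaks) %/% L
        if (any(n == 0L))
            warning(sum(n == 0L), " peak(s) shorter than L = ", L,
                    " cannot be tiled; dropped")
        idx <- rep(seq_along(peaks), n)
        off <- unlist(lapply(n, function(k) seq_len(k) - 1L), use.names = FALSE)
        wins <- GenomicRanges::GRanges(
            chrom[idx],
            IRanges::IRanges(start = GenomicRanges::start(peaks)[idx] +
                                 off * L, width = L))
    }
    extractSequence(genome, wins)
}

#' Composition-preserving shuffle of one sequence
#'
#' Returns a random permutation of the letters of \code{seq}: per-base
#' counts (including N) are exactly conserved, so the shuffle serves as a
#' matched negative example. Deterministic for a fixed \code{seed}.
#'
#' @param seq a single sequence (character or \code{DNAString}).
#' @param seed integer seed, or \code{NULL} to use the current RNG stream.
#' @return a character string.
#' @examples
#' shuffleNegative("ACGTACGT", seed = 1)
#' @export
shuffleNegative <- function(seq, seed = NULL) {
    seq <- as.character(seq)
    stopifnot(length(seq) == 1L, nchar(seq) >= 1L)
    ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
    withSeed(seed, paste(ch[sample.int(length(ch))], collapse = ""))
}

#' Build a balanced labelled dataset from a genome and peak set
#'
#' Runs the dataset-construction recipe: peaks are length-filtered
#' (strictly longer than \code{minPeakLength} bp), one fixed-width fragment
#' is taken per peak (see [makePositiveWindows()]), and one shuffled
#' negative is generated from each positive so classes are exactly
#' balanced. Partitions are unset; call [splitDataset()] next.
#'
#' @param genome a named [Biostrings::DNAStringSet].
#' @param peaks a [GenomicRanges::GRanges] of assay peaks.
#' @param fragmentLength training fragment length in bp (default 200, the
#'   positive-filter floor, so every retained peak can supply a full
#'   window).
#' @param minPeakLength peak length cutoff in bp passed to [filterPeaks()].
#' @param mode windowing mode, see [makePositiveWindows()].
#' @param seed integer seed driving the negative shuffles.
#' @return an [OCRDataset] with \code{NA} partitions.
#' @export
buildTrainingSet <- function(genome, peaks, fragmentLength = 200L,
                             minPeakLength = 200L,
                             mode = c("center", "tile"), seed = 1L) {
    mode <- match.arg(mode)
    kept <- filterPeaks(peaks, minPeakLength)
    pos <- makePositiveWindows(genome, kept, L = fragmentLength, mode = mode)
    if (!length(pos))
        stop("no positive fragments could be constructed")
    posChar <- as.character(pos)
    neg <- withSeed(seed, vapply(posChar, function(s)
        shuffleNegative(s, seed = NULL), character(1), USE.NAMES = FALSE))
    n <- length(posChar)
    seqs <- Biostrings::DNAStringSet(c(posChar, neg))
    names(seqs) <- c(sprintf("pos_%d|%s", seq_len(n), names(pos)),
                     sprintf("neg_%d|shuffled", seq_len(n)))
    methods::new("OCRDataset",
        sequences = seqs,
        labels = c(rep(1L, n), rep(0L, n)),
        pairId = c(seq_len(n), seq_len(n)),
        partition = rep(NA_character_, 2L * n),
        fragmentLength = as.integer(fragmentLength))
}

#' Randomly partition a dataset into train/validation/test
#'
#' Assigns positive/negative pairs (never individual fragments, so every
#' partition stays balanced and no shuffled copy leaks across a boundary)
#' to the three partitions at the given fractions, sized by
#' largest-remainder rounding. Deterministic for a fixed seed.
#'
#' @param ds an [OCRDataset].
#' @param fractions numeric 3-vector (train, validation, test) summing to 1.
#' @param seed integer seed.
#' @return the dataset with its \code{partition} slot filled.
#' @export
splitDataset <- function(ds, fractions = c(0.60, 0.20, 0.20), seed = 1L) {
    stopifnot(is(ds, "OCRDataset"),
              length(fractions) == 3L,
              abs(sum(fractions) - 1) < 1e-8)
    pairs <- unique(ds@pairId)
    n <- length(pairs)
    if (n < 5L)
        stop("need at least 5 pairs to honor the split fractions")
    sizes <- largestRemainder(n, fractions)
    lab <- rep(c("train", "validation", "test"), times = sizes)
    perm <- withSeed(seed, sample.int(n))
    assign <- stats::setNames(lab, pairs[perm])
    ds@partition <- unname(assign[as.character(ds@pairId)])
    methods::validObject(ds)
    ds
}

#' k-fold cross-validation split
#'
#' Divides \code{n} samples (or the pairs of an [OCRDataset]) into \code{k}
#' near-equal folds (sizes differ by at most 1); each sample appears in
#' exactly one test fold. For a dataset, positive/negative pairs are
#' assigned to folds together and the returned indices are fragment
#' indices.
#'
#' @param x an integer sample count, or an [OCRDataset].
#' @param k number of folds (default 10).
#' @param seed integer seed.
#' @return a list of \code{k} lists with elements \code{train} and
#'   \code{test} (integer index vectors).
#' @export
kfoldSplit <- function(x, k = 10L, seed = 1L) {
    stopifnot(k >= 2L)
    if (is(x, "OCRDataset")) {
        pairs <- unique(x@pairId)
        folds <- kfoldAssign(length(pairs), k, seed)
        lapply(seq_len(k), function(i) {
            testPairs <- pairs[folds == i]
            test <- which(x@pairId %in% testPairs)
            list(train = setdiff(seq_along(x@labels), test), test = test)
        })
    } else {
        n <- as.integer(x)
        folds <- kfoldAssign(n, k, seed)
        lapply(seq_len(k), function(i)
            list(train = which(folds != i), test = which(folds == i)))
    }
}

kfoldAssign <- function(n, k, seed) {
    if (k > n) stop("k = ", k, " exceeds the number of samples (", n, ")")
    sizes <- rep(n %/% k, k)
    extra <- n %% k
    if (extra) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    withSeed(seed, sample(rep(seq_len(k), times = sizes)))
}

#' Serialize / load a dataset as tab-separated text
#'
#' One record per fragment: \code{id}, \code{label}, \code{partition},
#' \code{pairId}, \code{sequence}. The file is plain TSV with a header, and
#' a write/read round trip reproduces the dataset exactly.
#'
#' @param ds an [OCRDataset].
#' @param path output (input) file path.
#' @return \code{writeDatasetTsv}: invisibly, \code{path};
#'   \code{readDatasetTsv}: an [OCRDataset].
#' @export
writeDatasetTsv <- function(ds, path) {
    df <- data.frame(
        id = names(ds@sequences),
        label = ds@labels,
        partition = ifelse(is.na(ds@partition), ".", ds@partition),
        pairId = ds@pairId,
        sequence = as.character(ds@sequences))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' @rdname writeDatasetTsv
#' @export
readDatasetTsv <- function(path) {
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            colClasses = c("character", "integer",
                                           "character", "integer",
                                           "character"))
    seqs <- Biostrings::DNAStringSet(df$sequence)
    names(seqs) <- df$id
    part <- df$partition
    part[part == "."] <- NA_character_
    methods::new("OCRDataset", sequences = seqs,
                 labels = df$label, pairId = df$pairId, partition = part,
                 fragmentLength = as.integer(unique(nchar(df$sequence))))
}

#' Export dataset fragments as FASTA
#'
#' Writes the positive and negative fragments to two FASTA files for use
#' with external motif tools.
#'
#' @param ds an [OCRDataset].
#' @param posPath,negPath output FASTA paths.
#' @return invisibly, \code{c(posPath, negPath)}.
#' @export
exportDatasetFasta <- function(ds, posPath, negPath) {
    writeFasta(ds@sequences[ds@labels == 1L], posPath)
    writeFasta(ds@sequences[ds@labels == 0L], negPath)
    invisible(c(posPath, negPath))
}

#' Subset accessors for OCRDataset
#'
#' \code{datasetPartition} returns the fragments (and labels) belonging to
#' one partition.
#'
#' @param ds an [OCRDataset].
#' @param partition \code{"train"}, \code{"validation"} or \code{"test"}.
#' @return a list with \code{sequences} (DNAStringSet) and \code{labels}.
#' @export
datasetPartition <- function(ds, partition) {
    stopifnot(partition %in% c("train", "validation", "test"))
    sel <- !is.na(ds@partition) & ds@partition == partition
    if (!any(sel)) stop("partition '", partition, "' is empty; ",
                        "run splitDataset() first")
    list(sequences = ds@sequences[sel], labels = ds@labels[sel])
}
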