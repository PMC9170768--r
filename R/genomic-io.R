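#' Read a FASTA file into a DNAStringSet
#'
#' Reads a (multi-record, wrapped or unwrapped) FASTA file, uppercases the
#' sequences, and normalizes the alphabet to \code{A,C,G,T,N}: lowercase
#' (soft-masked) bases are used as-is after uppercasing, and IUPAC ambiguity
#' codes are mapped to \code{N} with a warning. Any character outside the
#' IUPAC DNA alphabet raises a format error naming the offending symbol.
#'
#' @param path path to a FASTA file.
#' @return a [Biostrings::DNAStringSet]; one element per record, in file
#'   order. An empty file yields an empty set.
#' @examples
#' tf <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1", "acgtn"), tf)
#' readFasta(tf)
#' @export
readFasta <- function(path) {
    if (!file.exists(path))
        stop("FASTA file not found: ", path)
    x <- tryCatch(
        Biostrings::readBStringSet(path, format = "fasta"),
        error = function(e)
            stop("malformed FASTA in '", path, "': ", conditionMessage(e),
                 call. = FALSE)
    )
    seqs <- toupper(as.character(x))
    if (any(nchar(seqs) == 0L))
        stop("malformed FASTA in '", path, "': record '",
             names(x)[which(nchar(seqs) == 0L)[1L]], "' has no sequence")
    bad <- gsub("[ACGTNRYSWKMBDHV]", "", seqs)
    if (any(nchar(bad) > 0L)) {
        i <- which(nchar(bad) > 0L)[1L]
        stop("illegal character '", substr(bad[i], 1L, 1L),
             "' in FASTA record '", names(x)[i], "'")
    }
    iupac <- grepl("[RYSWKMBDHV]", seqs)
    if (any(iupac)) {
        warning(sum(iupac), " record(s) contain IUPAC ambiguity codes; ",
                "mapped to N")
        seqs <- gsub("[RYSWKMBDHV]", "N", seqs)
    }
    out <- Biostrings::DNAStringSet(seqs)
    names(out) <- sub("\\s.*$", "", names(x))
    out
}

#' Write sequences to a FASTA file
#'
#' @param x a [Biostrings::DNAStringSet] (or named character vector).
#' @param path output file path.
#' @param width line-wrap width.
#' @return invisibly, \code{path}.
#' @export
writeFasta <- function(x, path, width = 70L) {
    if (is.character(x)) x <- Biostrings::DNAStringSet(x)
    Biostrings::writeXStringSet(x, path, width = width)
    invisible(path)
}

#' Read a BED file into a GRanges
#'
#' Parses BED3+ (tab-separated, no header; columns beyond 6 are ignored).
#' On-disk coordinates are 0-based half-open; the returned
#' [GenomicRanges::GRanges] follows the Bioconductor 1-based closed
#' convention, so \code{chr1 10 50} becomes \code{chr1:11-50} (width 40).
#' Name, score and strand columns are kept as metadata when present.
#'
#' @param path path to a BED file.
#' @return a \code{GRanges}, in file order.
#' @examples
#' tf <- tempfile(fileext = ".bed")
#' writeLines("chr1\t10\t50", tf)
#' readBed(tf)
#' @export
readBed <- function(path) {
    if (!file.exists(path))
        stop("BED file not found: ", path)
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    if (!length(lines))
        return(GenomicRanges::GRanges())
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 3L))
        stop("BED line ", which(nf < 3L)[1L], " has fewer than 3 fields")
    chrom <- vapply(fields, `[[`, character(1), 1L)
    start <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 2L)))
    end <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 3L)))
    bad <- which(is.na(start) | is.na(end) |
                 start != floor(start) | end != floor(end))
    if (length(bad))
        stop("non-integer coordinate at BED line ", bad[1L])
    bad <- which(start >= end | start < 0)
    if (length(bad))
        stop("invalid interval (start >= end or start < 0) at BED line ",
             bad[1L])
    gr <- GenomicRanges::GRanges(
        chrom, IRanges::IRanges(start = start + 1L, end = end))
    if (all(nf >= 4L)) {
        nm <- vapply(fields, `[[`, character(1), 4L)
        if (!all(nm == ".")) S4Vectors::mcols(gr)$name <- nm
    }
    if (all(nf >= 5L)) {
        sc <- vapply(fields, `[[`, character(1), 5L)
        if (!all(sc == "."))
            S4Vectors::mcols(gr)$score <- as.numeric(sc)
    }
    if (all(nf >= 6L)) {
        st <- vapply(fields, `[[`, character(1), 6L)
        st[!st %in% c("+", "-")] <- "*"
        GenomicRanges::strand(gr) <- st
    }
    gr
}

#' Write a GRanges to a BED file
#'
#' Writes 0-based half-open BED. With \code{format = "auto"} (default) a
#' plain BED3 is written when the ranges carry no name/score/strand, which
#' makes BED3 round trips through [readBed()] byte-identical; otherwise
#' BED6 is written with \code{"."} for missing names, \code{0} for missing
#' scores and \code{"."} for unset strand.
#'
#' @param gr a [GenomicRanges::GRanges].
#' @param path output file path.
#' @param format \code{"auto"}, \code{"bed3"} or \code{"bed6"}.
#' @return invisibly, \code{path}.
#' @export
writeBed <- function(gr, path, format = c("auto", "bed3", "bed6")) {
    format <- match.arg(format)
    chrom <- as.character(GenomicRanges::seqnames(gr))
    start0 <- GenomicRanges::start(gr) - 1L
    end0 <- GenomicRanges::end(gr)
    mc <- S4Vectors::mcols(gr)
    hasMeta <- any(c("name", "score") %in% colnames(mc)) ||
        any(as.character(GenomicRanges::strand(gr)) != "*")
    if (format == "auto") format <- if (hasMeta) "bed6" else "bed3"
    if (format == "bed3") {
        lines <- paste(chrom, start0, end0, sep = "\t")
    } else {
        nm <- if ("name" %in% colnames(mc)) as.character(mc$name)
              else rep(".", length(gr))
        sc <- if ("score" %in% colnames(mc)) formatBedScore(mc$score)
              else rep("0", length(gr))
        st <- as.character(GenomicRanges::strand(gr))
        st[st == "*"] <- "."
        lines <- paste(chrom, start0, end0, nm, sc, st, sep = "\t")
    }
    writeLines(lines, path)
    invisible(path)
}

# integer scores print without decimals so reruns are byte-stable
formatBedScore <- function(x) {
    ifelse(x == round(x), format(as.integer(round(x)), scientific = FALSE,
                                 trim = TRUE),
           format(x, scientific = FALSE, trim = TRUE, digits = 6))
}

#' Extract the sequence under an interval
#'
#' Returns the forward-strand genome substring covered by each range.
#'
#' @param genome a [Biostrings::DNAStringSet] with named chromosomes.
#' @param gr a [GenomicRanges::GRanges] of regions to extract.
#' @return a \code{DNAStringSet}, one element per range.
#' @export
extractSequence <- function(genome, gr) {
    chrom <- as.character(GenomicRanges::seqnames(gr))
    unknown <- setdiff(unique(chrom), names(genome))
    if (length(unknown))
        stop("chromosome(s) not present in genome: ",
             paste(unknown, collapse = ", "))
    lens <- Biostrings::width(genome)[match(chrom, names(genome))]
    bad <- which(GenomicRanges::end(gr) > lens | GenomicRanges::start(gr) < 1L)
    if (length(bad))
        stop("interval out of chromosome bounds: ", chrom[bad[1L]], ":",
             GenomicRanges::start(gr)[bad[1L]] - 1L, "-",
             GenomicRanges::end(gr)[bad[1L]])
    out <- Biostrings::DNAStringSet(substr(
        as.character(genome)[match(chrom, names(genome))],
        GenomicRanges::start(gr), GenomicRanges::end(gr)))
    names(out) <- sprintf("%s:%d-%d", chrom,
                          GenomicRanges::start(gr) - 1L,
                          GenomicRanges::end(gr))
    out
}

#' Overlapping pairs between two interval sets
#'
#' Reports every pair of ranges (one from \code{a}, one from \code{b}) that
#' share at least \code{minOverlap} bp on the same chromosome. Each pair is
#' reported once.
#'
#' @param a,b [GenomicRanges::GRanges] objects.
#' @param minOverlap minimum shared bases (>= 1).
#' @return a \code{data.frame} with columns \code{queryIdx},
#'   \code{subjectIdx}, \code{overlap} (bp).
#' @export
intersectIntervals <- function(a, b, minOverlap = 1L) {
    stopifnot(minOverlap >= 1L)
    # disjoint seqlevel sets are a legitimate no-overlap case, not a warning
    hits <- suppressWarnings(
        GenomicRanges::findOverlaps(a, b, minoverlap = minOverlap,
                                    ignore.strand = TRUE))
    qi <- S4Vectors::queryHits(hits)
    si <- S4Vectors::subjectHits(hits)
    ov <- pmin(GenomicRanges::end(a)[qi], GenomicRanges::end(b)[si]) -
        pmax(GenomicRanges::start(a)[qi], GenomicRanges::start(b)[si]) + 1L
    data.frame(queryIdx = qi, subjectIdx = si, overlap = ov)
}
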