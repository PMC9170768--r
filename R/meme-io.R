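#' Write motifs in MEME minimal format
#'
#' Writes a version header, the ACGT alphabet, uniform background
#' frequencies and one letter-probability matrix per motif — the minimal
#' motif text format understood by the MEME suite and by JASPAR exports,
#' so filter motifs can be compared against reference databases.
#'
#' @param pwms a list of [PWMotif] (may be empty: a valid header-only file
#'   is written).
#' @param path output file path.
#' @param nsites site counts recorded per motif (recycled; default 20).
#' @return invisibly, \code{path}.
#' @seealso [readMeme()]
#' @export
writeMeme <- function(pwms, path, nsites = 20L) {
    lines <- c("MEME version 4", "",
               "ALPHABET= ACGT", "",
               "strands: + -", "",
               "Background letter frequencies",
               "A 0.25000 C 0.25000 G 0.25000 T 0.25000", "")
    nsites <- rep_len(as.integer(nsites), max(1L, length(pwms)))
    for (i in seq_along(pwms)) {
        p <- pwms[[i]]
        if (ncol(p@probs) == 0L || max(abs(colSums(p@probs) - 1)) > 1e-6)
            stop("motif '", p@name, "' has non-stochastic columns")
        lines <- c(lines,
            paste("MOTIF", p@name),
            sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
                    ncol(p@probs), nsites[i]),
            apply(p@probs, 2L, function(col)
                paste(sprintf("%.6f", col), collapse = " ")),
            "")
    }
    writeLines(lines, path)
    invisible(path)
}

#' Read motifs from a MEME minimal format file
#'
#' Parses the letter-probability matrices of a MEME minimal motif file
#' (as written by [writeMeme()] or exported from JASPAR) into [PWMotif]
#' objects; information content is recomputed from the probabilities.
#'
#' @param path path to a MEME format file.
#' @return a named list of [PWMotif] (empty for a header-only file).
#' @export
readMeme <- function(path) {
    if (!file.exists(path)) stop("MEME file not found: ", path)
    lines <- readLines(path)
    if (!length(grep("^MEME version", lines)))
        stop("'", path, "' is not a MEME format file (missing version line)")
    starts <- grep("^MOTIF\\b", lines)
    out <- list()
    for (s in starts) {
        name <- sub("^MOTIF\\s+(\\S+).*$", "\\1", lines[s])
        h <- s + which(grepl("^letter-probability matrix",
                             lines[(s + 1):min(s + 5, length(lines))]))[1L]
        if (is.na(h)) stop("motif '", name, "' has no probability matrix")
        w <- as.integer(sub(".*\\bw=\\s*(\\d+).*", "\\1", lines[h]))
        rows <- lines[(h + 1):(h + w)]
        vals <- lapply(strsplit(trimws(rows), "\\s+"), as.numeric)
        probs <- t(do.call(rbind, vals))
        if (nrow(probs) != 4L)
            stop("motif '", name, "' matrix must have 4 columns per row")
        probs <- sweep(probs, 2L, colSums(probs), `/`)  # renormalize rounding
        out[[name]] <- pwmFromProbs(probs, name = name)
    }
    out
}
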