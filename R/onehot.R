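ONEHOT_ROWS <- c("A", "C", "G", "T")

#' One-hot encode a DNA sequence
#'
#' Maps a sequence over \code{A,C,G,T,N} to a 4 x n binary matrix
#' (rows A, C, G, T): \code{A} becomes column \code{(1,0,0,0)}, \code{C}
#' \code{(0,1,0,0)}, \code{G} \code{(0,0,1,0)}, \code{T} \code{(0,0,0,1)}
#' and \code{N} the all-zero column.
#'
#' @param seq a single character string (or \code{DNAString}/length-1
#'   \code{DNAStringSet}) over \code{A,C,G,T,N}.
#' @return a 4 x n numeric matrix with rownames A, C, G, T.
#' @examples
#' oneHotEncode("ACGTN")
#' @export
oneHotEncode <- function(seq) {
    seq <- as.character(seq)
    stopifnot(length(seq) == 1L)
    ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
    idx <- match(ch, c(ONEHOT_ROWS, "N"))
    if (anyNA(idx))
        stop("illegal symbol '", ch[which(is.na(idx))[1L]],
             "' at position ", which(is.na(idx))[1L],
             "; expected A, C, G, T or N")
    m <- matrix(0, nrow = 4L, ncol = length(ch),
                dimnames = list(ONEHOT_ROWS, NULL))
    hit <- idx <= 4L
    m[cbind(idx[hit], which(hit))] <- 1
    m
}

#' Decode a one-hot matrix back to a sequence
#'
#' Inverse of [oneHotEncode()]; all-zero columns decode to \code{N}.
#'
#' @param m a 4 x n one-hot matrix.
#' @return a character string.
#' @export
oneHotDecode <- function(m) {
    stopifnot(is.matrix(m), nrow(m) == 4L)
    if (ncol(m) == 0L) return("")
    cs <- colSums(m)
    if (any(!cs %in% c(0, 1)) || any(!m %in% c(0, 1)))
        stop("not a valid one-hot matrix (entries 0/1, column sums 0 or 1)")
    base <- rep("N", ncol(m))
    hit <- cs == 1
    base[hit] <- ONEHOT_ROWS[apply(m[, hit, drop = FALSE], 2L, which.max)]
    paste(base, collapse = "")
}

# Encode many equal-length fragments into a (4*L) x n matrix, one flattened
# one-hot matrix per column. This is the batch layout the network consumes.
oneHotBatch <- function(seqs) {
    seqs <- as.character(seqs)
    L <- unique(nchar(seqs))
    if (length(L) != 1L)
        stop("fragments must all have equal length")
    ch <- unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE)
    idx <- match(ch, c(ONEHOT_ROWS, "N"))
    if (anyNA(idx))
        stop("illegal symbol '", ch[which(is.na(idx))[1L]], "' in fragment ",
             ceiling(which(is.na(idx))[1L] / L))
    out <- matrix(0, nrow = 4L * L, ncol = length(seqs))
    pos <- seq_along(ch)            # global position over concatenated bases
    col <- ceiling(pos / L)
    within <- pos - (col - 1L) * L  # 1..L within each fragment
    hit <- idx <= 4L
    out[cbind(4L * (within[hit] - 1L) + idx[hit], col[hit])] <- 1
    out
}
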