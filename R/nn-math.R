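#' Rectified linear unit
#'
#' \code{relu(x) = max(0, x)}, applied elementwise; the activation used by
#' all hidden layers of the accessibility CNN.
#'
#' @param x numeric vector, matrix or array.
#' @return object of the same shape.
#' @examples
#' relu(c(-3, 0, 2.5))
#' @export
relu <- function(x) pmax(x, 0)

#' Logistic sigmoid
#'
#' Maps a real-valued score from \eqn{(-\infty, +\infty)} to \eqn{(0, 1)};
#' the output unit interpreting the network score as the probability that a
#' fragment is open chromatin. Computed in a numerically stable form so
#' large \code{|z|} saturates without overflow.
#'
#' @param z numeric vector/matrix of scores.
#' @return values in (0, 1), same shape as \code{z}.
#' @examples
#' sigmoid(0)       # 0.5
#' sigmoid(c(-700, 700))
#' @export
sigmoid <- function(z) {
    out <- z
    pos <- !is.na(z) & z >= 0
    out[pos] <- 1 / (1 + exp(-z[pos]))
    ez <- exp(z[!pos])
    out[!pos] <- ez / (1 + ez)
    out
}

#' Binary cross-entropy loss
#'
#' Mean of \eqn{-[y \log p + (1-y) \log(1-p)]} with probabilities clipped
#' to \eqn{[\epsilon, 1-\epsilon]} for numerical safety.
#'
#' @param p predicted probabilities.
#' @param y labels in \{0, 1\}.
#' @param eps clipping constant (default \code{1e-7}).
#' @return a single numeric loss value.
#' @examples
#' bceLoss(rep(0.5, 4), c(0, 1, 0, 1))  # log(2)
#' @export
bceLoss <- function(p, y, eps = 1e-7) {
    if (length(p) != length(y))
        stop("'p' and 'y' must have equal length")
    p <- pmin(pmax(p, eps), 1 - eps)
    -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Inverted dropout
#'
#' In training mode each unit is independently zeroed with probability
#' \code{p} and the survivors are rescaled by \eqn{1/(1-p)}, so the
#' expected activation is unchanged and inference is a plain forward pass.
#' In inference mode the input is returned untouched.
#'
#' @param a numeric vector/matrix of activations.
#' @param p dropout probability in [0, 1).
#' @param mode \code{"train"} or \code{"infer"}.
#' @param seed optional seed for a reproducible mask.
#' @return activations with the mask applied.
#' @export
applyDropout <- function(a, p = 0.6, mode = c("train", "infer"),
                         seed = NULL) {
    mode <- match.arg(mode)
    stopifnot(p >= 0, p < 1)
    if (mode == "infer" || p == 0) return(a)
    withSeed(seed, a * dropoutMask(length(a), p))
}

dropoutMask <- function(n, p) {
    if (p == 0) return(rep(1, n))
    (stats::runif(n) >= p) / (1 - p)
}

# --- im2col machinery -------------------------------------------------------
# A batch of one-hot fragments is a (rows*L) x B matrix (one flattened
# fragment per column). Valid cross-correlation with filters of width w is a
# single matrix product after gathering, for every output position, the
# flattened receptive field into a column ("im2col").

# row indices that gather a (rows x L) map into a (rows*w x P) column block
im2colIndex <- function(rows, L, w) {
    P <- L - w + 1L
    if (P < 1L) stop("filter width ", w, " exceeds input length ", L)
    pos <- rep(seq_len(P), each = rows * w)
    off <- rep(rep(seq_len(w) - 1L, each = rows), times = P)
    chan <- rep(seq_len(rows), times = w * P)
    rows * (pos + off - 1L) + chan
}

# gather: (rows*L x B) -> (rows*w x P*B), sample-major column blocks
im2col <- function(Xflat, idx, rowsW) {
    matrix(Xflat[idx, , drop = FALSE], nrow = rowsW)
}

# scatter-add transpose of im2col: (rows*w x P*B) -> (rows*L x B)
col2im <- function(dC, idx, rowsL, B) {
    v <- matrix(dC, nrow = length(idx))
    out <- rowsum(v, group = idx, reorder = TRUE)
    # every input row is covered by at least one window when w <= L, so
    # rowsum yields all rowsL groups
    dimnames(out) <- NULL
    matrix(out, nrow = rowsL, ncol = B)
}
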