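#' Construct a model specification
#'
#' Defaults follow the package's reference configuration: 64 first-layer
#' filters of width 19 bp (wide enough to span the 6-19 bp motifs typical
#' of plant regulatory sequence), 32 second-layer filters of width 11, a
#' 200-neuron fully connected layer, dropout 0.4 after every hidden layer,
#' 200 bp training fragments, and Adam with learning rate 1e-3, batch size
#' 32, 60 epochs. The defaults target desk-scale peak sets (hundreds to a
#' few thousand peaks); on assay-scale datasets of tens of thousands of
#' peaks a heavier dropout (0.6) is appropriate, since the many more
#' gradient updates average out the regularization noise.
#'
#' @param conv1Filters,conv1Width first convolution layer geometry.
#' @param conv2Filters,conv2Width second convolution layer geometry.
#' @param fcUnits fully connected layer width.
#' @param dropout dropout probability in [0, 1).
#' @param inputLength training fragment length in bp.
#' @param learningRate,batchSize,epochs optimizer settings.
#' @param seed integer seed for initialization and training.
#' @return an [OCRModelSpec].
#' @examples
#' ocrModelSpec(conv1Filters = 8, epochs = 5)
#' @export
ocrModelSpec <- function(conv1Filters = 64L, conv1Width = 19L,
                         conv2Filters = 32L, conv2Width = 11L,
                         fcUnits = 200L, dropout = 0.4,
                         inputLength = 200L, learningRate = 1e-3,
                         batchSize = 32L, epochs = 60L, seed = 1L) {
    methods::new("OCRModelSpec",
        conv1Filters = as.integer(conv1Filters),
        conv1Width = as.integer(conv1Width),
        conv2Filters = as.integer(conv2Filters),
        conv2Width = as.integer(conv2Width),
        fcUnits = as.integer(fcUnits),
        dropout = as.numeric(dropout),
        inputLength = as.integer(inputLength),
        learningRate = as.numeric(learningRate),
        batchSize = as.integer(batchSize),
        epochs = as.integer(epochs),
        seed = as.integer(seed))
}

#' Build an untrained model from a specification
#'
#' Lays out the network
#' \code{conv(F1 x 4 x w1, stride 1) -> ReLU -> dropout ->
#' conv(F2 x w2, stride 1) -> ReLU -> global max pool -> dropout ->
#' fully-connected(fcUnits) -> ReLU -> dropout -> fully-connected(1) ->
#' sigmoid} and initializes the weights (He-scaled Gaussians, seeded by
#' \code{spec@seed}). Dropout follows every hidden layer; for the second
#' convolution it acts on the pooled feature vector, so the pooled
#' maximum is not inflated by rescaled survivors.
#' The global max pool over positions collapses each
#' second-layer feature map to a single value, which makes the network
#' length-agnostic: the same weights score any fragment at least
#' \code{conv1Width + conv2Width - 1} bp long, so peak-scale training
#' fragments and short scanning windows share one model.
#'
#' @param spec an [OCRModelSpec].
#' @return an untrained [OCRModel].
#' @seealso [trainModel()], [predictProba()], [paramCount()]
#' @export
buildModel <- function(spec) {
    methods::validObject(spec)
    w <- withSeed(spec@seed, {
        he <- function(nr, nc, fanIn)
            matrix(stats::rnorm(nr * nc, sd = sqrt(2 / fanIn)), nr, nc)
        list(
            W1 = he(spec@conv1Filters, 4L * spec@conv1Width,
                    4L * spec@conv1Width),
            b1 = numeric(spec@conv1Filters),
            W2 = he(spec@conv2Filters, spec@conv1Filters * spec@conv2Width,
                    spec@conv1Filters * spec@conv2Width),
            b2 = numeric(spec@conv2Filters),
            W3 = he(spec@fcUnits, spec@conv2Filters, spec@conv2Filters),
            b3 = numeric(spec@fcUnits),
            W4 = he(1L, spec@fcUnits, spec@fcUnits),
            b4 = numeric(1L))
    })
    methods::new("OCRModel", spec = spec, weights = w, history = NULL,
                 trained = FALSE)
}

#' Number of trainable parameters
#'
#' A pure function of the architecture: convolution weights and biases,
#' the fully connected layer on the pooled feature vector, and the output
#' unit.
#'
#' @param x an [OCRModelSpec] or [OCRModel].
#' @return integer parameter count.
#' @export
paramCount <- function(x) {
    spec <- if (is(x, "OCRModel")) x@spec else x
    as.integer(
        spec@conv1Filters * 4L * spec@conv1Width + spec@conv1Filters +
        spec@conv2Filters * spec@conv1Filters * spec@conv2Width +
            spec@conv2Filters +
        spec@fcUnits * spec@conv2Filters + spec@fcUnits +
        spec@fcUnits + 1L)
}

# minimum fragment length the architecture can score
minInputLength <- function(spec) spec@conv1Width + spec@conv2Width - 1L

# Forward pass over a batch.
#   X: (4*L x B) flattened one-hot batch; mode "train" draws dropout masks
#   from the current RNG stream and returns the cache needed by the
#   backward pass.
nnForward <- function(weights, spec, X, mode = c("infer", "train")) {
    mode <- match.arg(mode)
    B <- ncol(X)
    L <- nrow(X) %/% 4L
    if (L < minInputLength(spec))
        stop("fragments of ", L, " bp are shorter than the ",
             minInputLength(spec), " bp receptive field")
    F1 <- spec@conv1Filters; F2 <- spec@conv2Filters
    w1 <- spec@conv1Width; w2 <- spec@conv2Width
    P1 <- L - w1 + 1L; P2 <- P1 - w2 + 1L
    p <- spec@dropout
    train <- mode == "train"

    idx1 <- im2colIndex(4L, L, w1)
    C1 <- im2col(X, idx1, 4L * w1)                   # (4 w1 x P1 B)
    Z1 <- weights$W1 %*% C1 + weights$b1             # (F1 x P1 B)
    A1 <- pmax(Z1, 0)
    m1 <- NULL
    if (train && p > 0) {
        m1 <- matrix(dropoutMask(length(A1), p), nrow(A1))
        A1 <- A1 * m1
    }
    A1flat <- matrix(A1, nrow = F1 * P1)             # (F1 P1 x B)
    idx2 <- im2colIndex(F1, P1, w2)
    C2 <- im2col(A1flat, idx2, F1 * w2)              # (F1 w2 x P2 B)
    Z2 <- weights$W2 %*% C2 + weights$b2             # (F2 x P2 B)
    A2 <- pmax(Z2, 0)
    # global max pool over the P2 positions of each sample
    posCols <- function(q) seq.int(q, by = P2, length.out = B)
    M <- A2[, posCols(1L), drop = FALSE]             # (F2 x B)
    amax <- matrix(1L, F2, B)
    if (P2 > 1L) for (q in 2L:P2) {
        cand <- A2[, posCols(q), drop = FALSE]
        upd <- cand > M                              # strict: leftmost max
        M[upd] <- cand[upd]
        amax[upd] <- q
    }
    # the second conv layer's dropout acts on its pooled output, so the
    # pooled maximum is not biased by rescaled survivors
    m2 <- NULL
    if (train && p > 0) {
        m2 <- matrix(dropoutMask(length(M), p), nrow(M))
        M <- M * m2
    }
    Z3 <- weights$W3 %*% M + weights$b3              # (fc x B)
    A3 <- pmax(Z3, 0)
    m3 <- NULL
    if (train && p > 0) {
        m3 <- matrix(dropoutMask(length(A3), p), nrow(A3))
        A3 <- A3 * m3
    }
    Z4 <- drop(weights$W4 %*% A3) + weights$b4       # length B
    probs <- sigmoid(Z4)
    if (!train) return(probs)
    list(probs = probs, X = X, C1 = C1, Z1 = Z1, m1 = m1, idx2 = idx2,
         C2 = C2, Z2 = Z2, m2 = m2, M = M, amax = amax, Z3 = Z3, m3 = m3,
         A3 = A3, dims = list(B = B, L = L, P1 = P1, P2 = P2,
                              F1 = F1, F2 = F2))
}

# Backward pass for BCE loss; returns gradients named like the weights.
nnBackward <- function(weights, spec, cache, y) {
    d <- cache$dims
    p <- spec@dropout
    dZ4 <- (cache$probs - y) / d$B                   # length B
    gW4 <- matrix(dZ4, 1L) %*% t(cache$A3)
    gb4 <- sum(dZ4)
    dA3 <- drop(t(weights$W4)) %o% dZ4               # (fc x B)
    if (!is.null(cache$m3)) dA3 <- dA3 * cache$m3
    dZ3 <- dA3 * (cache$Z3 > 0)
    gW3 <- dZ3 %*% t(cache$M)
    gb3 <- rowSums(dZ3)
    dM <- t(weights$W3) %*% dZ3                      # (F2 x B)
    if (!is.null(cache$m2)) dM <- dM * cache$m2
    # un-pool: route gradient to each channel's (leftmost) argmax position
    dA2 <- matrix(0, d$F2, d$P2 * d$B)
    col <- (rep(seq_len(d$B), each = d$F2) - 1L) * d$P2 + as.vector(cache$amax)
    dA2[cbind(rep(seq_len(d$F2), d$B), col)] <- as.vector(dM)
    dZ2 <- dA2 * (cache$Z2 > 0)
    gW2 <- dZ2 %*% t(cache$C2)
    gb2 <- rowSums(dZ2)
    dC2 <- t(weights$W2) %*% dZ2                     # (F1 w2 x P2 B)
    dA1flat <- col2im(dC2, cache$idx2, d$F1 * d$P1, d$B)
    dA1 <- matrix(dA1flat, nrow = d$F1)              # (F1 x P1 B)
    if (!is.null(cache$m1)) dA1 <- dA1 * cache$m1
    dZ1 <- dA1 * (cache$Z1 > 0)
    gW1 <- dZ1 %*% t(cache$C1)
    gb1 <- rowSums(dZ1)
    list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2,
         W3 = gW3, b3 = gb3, W4 = gW4, b4 = gb4)
}
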