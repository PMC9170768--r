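#' Train the accessibility CNN
#'
#' Minibatch gradient descent (Adam) on the binary cross-entropy loss for
#' \code{spec@epochs} epochs over the \code{train} partition, with the
#' \code{validation} partition scored after every epoch. The weights with
#' the lowest validation loss seen are retained in the returned model.
#' Fully deterministic for a fixed \code{spec@seed} (single-threaded
#' execution assumed).
#'
#' @param spec an [OCRModelSpec], or an untrained [OCRModel] built from
#'   one.
#' @param ds an [OCRDataset] with \code{train} and \code{validation}
#'   partitions assigned (see [splitDataset()]).
#' @param verbose print per-epoch losses.
#' @return a trained [OCRModel] with a filled \code{history}.
#' @export
trainModel <- function(spec, ds, verbose = FALSE) {
    model <- if (is(spec, "OCRModel")) spec else buildModel(spec)
    spec <- model@spec
    if (Biostrings::width(ds@sequences)[1L] != spec@inputLength)
        stop("dataset fragment length (", ds@fragmentLength,
             ") does not match spec inputLength (", spec@inputLength, ")")
    tr <- datasetPartition(ds, "train")
    va <- datasetPartition(ds, "validation")
    Xtr <- oneHotBatch(tr$sequences); ytr <- tr$labels
    Xva <- oneHotBatch(va$sequences); yva <- va$labels
    nTr <- ncol(Xtr)

    withSeed(spec@seed, {
        weights <- buildModel(spec)@weights
        adam <- adamInit(weights)
        bestVal <- Inf
        bestW <- weights
        hist <- vector("list", spec@epochs)
        for (epoch in seq_len(spec@epochs)) {
            perm <- sample.int(nTr)
            batches <- split(perm, ceiling(seq_along(perm) / spec@batchSize))
            epLoss <- 0; epAcc <- 0
            for (b in batches) {
                cache <- nnForward(weights, spec,
                                   Xtr[, b, drop = FALSE], mode = "train")
                loss <- bceLoss(cache$probs, ytr[b])
                if (!is.finite(loss))
                    stop("non-finite training loss at epoch ", epoch,
                         "; try a smaller learning rate")
                grads <- nnBackward(weights, spec, cache, ytr[b])
                upd <- adamStep(adam, weights, grads, spec@learningRate)
                weights <- upd$weights; adam <- upd$state
                epLoss <- epLoss + loss * length(b)
                epAcc <- epAcc + sum((cache$probs >= 0.5) == (ytr[b] == 1L))
            }
            pva <- predictBatched(weights, spec, Xva)
            valLoss <- bceLoss(pva, yva)
            valAcc <- mean((pva >= 0.5) == (yva == 1L))
            if (valLoss < bestVal) {
                bestVal <- valLoss
                bestW <- weights
            }
            hist[[epoch]] <- data.frame(
                epoch = epoch, trainLoss = epLoss / nTr,
                trainAcc = epAcc / nTr, valLoss = valLoss, valAcc = valAcc)
            if (verbose)
                message(sprintf(
                    "epoch %3d  train %.4f (acc %.3f)  val %.4f (acc %.3f)",
                    epoch, epLoss / nTr, epAcc / nTr, valLoss, valAcc))
        }
        model@weights <- bestW
        model@history <- do.call(rbind, hist)
        model@trained <- TRUE
    })
    model
}

adamInit <- function(weights) {
    zero <- lapply(weights, function(w) w * 0)
    list(m = zero, v = zero, t = 0L)
}

adamStep <- function(state, weights, grads, lr,
                     beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
    state$t <- state$t + 1L
    bc1 <- 1 - beta1^state$t
    bc2 <- 1 - beta2^state$t
    for (k in names(weights)) {
        state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * grads[[k]]
        state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * grads[[k]]^2
        weights[[k]] <- weights[[k]] -
            lr * (state$m[[k]] / bc1) / (sqrt(state$v[[k]] / bc2) + eps)
    }
    list(weights = weights, state = state)
}

# inference forward pass in memory-bounded chunks
predictBatched <- function(weights, spec, X) {
    B <- ncol(X)
    L <- nrow(X) %/% 4L
    P2 <- max(1L, L - spec@conv1Width - spec@conv2Width + 2L)
    chunk <- max(16L, min(B, floor(8e6 / (spec@conv1Filters *
                                          spec@conv2Width * P2))))
    out <- numeric(B)
    i <- 1L
    while (i <= B) {
        j <- min(B, i + chunk - 1L)
        out[i:j] <- nnForward(weights, spec, X[, i:j, drop = FALSE],
                              mode = "infer")
        i <- j + 1L
    }
    out
}

#' Predict open-chromatin probabilities for fragments
#'
#' Scores equal-length DNA fragments with a trained model. Dropout is
#' disabled, so the result is a deterministic function of the weights and
#' the input. Fragments may have any length at least as long as the
#' model's receptive field (\code{conv1Width + conv2Width - 1} bp); the
#' global max pool absorbs the length difference.
#'
#' @param model a trained [OCRModel].
#' @param x fragments: a [Biostrings::DNAStringSet], character vector, a
#'   single 4 x n one-hot matrix, a list of such matrices, or a
#'   pre-flattened \code{(4n) x B} batch matrix.
#' @return numeric vector of probabilities in (0, 1), one per fragment.
#' @export
predictProba <- function(model, x) {
    if (!is(model, "OCRModel") || !model@trained)
        stop("'model' must be a trained OCRModel")
    X <- fragmentsToBatch(x)
    predictBatched(model@weights, model@spec, X)
}

fragmentsToBatch <- function(x) {
    if (is.matrix(x) && !is.null(rownames(x)) &&
        identical(rownames(x), ONEHOT_ROWS))
        return(matrix(as.vector(x), ncol = 1L))
    if (is.matrix(x)) return(x)
    if (is.list(x)) {
        ln <- unique(vapply(x, ncol, integer(1)))
        if (length(ln) != 1L) stop("one-hot matrices must share one width")
        return(vapply(x, as.vector, numeric(4L * ln)))
    }
    oneHotBatch(x)
}
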