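test_that("activation and loss primitives match their closed forms", {
    expect_equal(relu(c(-3, 0, 2.5)), c(0, 0, 2.5))
    expect_equal(sigmoid(0), 0.5)
    expect_equal(sigmoid(1000), 1)               # saturation, no overflow
    expect_equal(sigmoid(-1000), 0)
    z <- rnorm(50, sd = 5)
    expect_equal(sigmoid(z) + sigmoid(-z), rep(1, 50))

    expect_equal(bceLoss(rep(0.5, 10), rep(c(0, 1), 5)), log(2))
    expect_lt(bceLoss(c(1, 0), c(1, 0)), 1e-5)   # perfect fit, clipped
    expect_equal(bceLoss(c(0.9, 0.2), c(1, 0)),
                 -(log(0.9) + log(0.8)) / 2)
    expect_error(bceLoss(c(0.5, 0.5), 1), "equal length")
})

test_that("dropout is identity at inference and conserves expectation", {
    a <- rep(1, 10000)
    expect_identical(applyDropout(a, 0.6, "infer"), a)
    expect_identical(applyDropout(a, 0, "train"), a)
    set.seed(1)
    out <- applyDropout(a, 0.6, "train")
    expect_true(all(out %in% c(0, 1 / 0.4)))
    # inverted rescaling keeps the mean within 2% over many units
    means <- replicate(20, mean(applyDropout(a, 0.6, "train")))
    expect_lt(abs(mean(means) - 1), 0.02)
})

test_that("model layout produces probabilities and the exact parameter count", {
    spec <- ocrModelSpec(conv1Filters = 8L, conv1Width = 5L,
                         conv2Filters = 4L, conv2Width = 3L,
                         fcUnits = 10L, dropout = 0, inputLength = 36L,
                         seed = 2L)
    m <- buildModel(spec)
    p <- predictProba(methods::initialize(m, trained = TRUE),
                      "ACGTACGTACGTACGTACGTACGTACGTACGTACGT")
    expect_true(p > 0 && p < 1)

    # hand-computed: conv1 2x(4*3)+2, conv2 2x(2*2)+2, fc 4x2+4, out 1x4+1
    s2 <- ocrModelSpec(conv1Filters = 2L, conv1Width = 3L,
                       conv2Filters = 2L, conv2Width = 2L,
                       fcUnits = 4L, inputLength = 8L)
    expect_equal(paramCount(s2), 26L + 10L + 12L + 5L)

    expect_error(ocrModelSpec(conv1Width = 40L, inputLength = 36L),
                 "exceeds")
    expect_error(ocrModelSpec(conv2Width = 30L, conv1Width = 19L,
                              inputLength = 36L), "feature map")
})

test_that("analytic gradients agree with numerical differentiation", {
    ns <- asNamespace("OCRscan")
    spec <- ocrModelSpec(conv1Filters = 3L, conv1Width = 4L,
                         conv2Filters = 2L, conv2Width = 3L,
                         fcUnits = 5L, dropout = 0, inputLength = 12L,
                         seed = 3L)
    m <- buildModel(spec)
    set.seed(9)
    X <- ns$oneHotBatch(randomDna(6, 12))
    y <- rep(c(0, 1), 3)
    cache <- ns$nnForward(m@weights, spec, X, mode = "train")
    grads <- ns$nnBackward(m@weights, spec, cache, y)
    lossAt <- function(w) bceLoss(ns$nnForward(w, spec, X, "infer"), y)
    eps <- 1e-6
    for (k in names(m@weights)) {
        for (i in seq_len(min(length(m@weights[[k]]), 10L))) {
            wp <- m@weights; wp[[k]][i] <- wp[[k]][i] + eps
            wm <- m@weights; wm[[k]][i] <- wm[[k]][i] - eps
            num <- (lossAt(wp) - lossAt(wm)) / (2 * eps)
            expect_equal(grads[[k]][i], num, tolerance = 1e-4)
        }
    }
})

test_that("forward passes are deterministic without dropout", {
    spec <- ocrModelSpec(conv1Filters = 4L, conv1Width = 4L,
                         conv2Filters = 3L, conv2Width = 3L,
                         fcUnits = 6L, dropout = 0, inputLength = 20L)
    ns <- asNamespace("OCRscan")
    m <- buildModel(spec)
    X <- ns$oneHotBatch(randomDna(4, 20))
    p1 <- ns$nnForward(m@weights, spec, X, mode = "train")$probs
    p2 <- ns$nnForward(m@weights, spec, X, mode = "train")$probs
    expect_identical(p1, p2)
})

test_that("training separates a toy dataset and is seed-deterministic", {
    pos <- rep(paste(rep("TATAAT", 4), collapse = ""), 16)  # 24 bp
    neg <- rep(paste(rep("GCGCCA", 4), collapse = ""), 16)
    ds <- methods::new("OCRDataset",
        sequences = Biostrings::DNAStringSet(c(pos, neg)),
        labels = c(rep(1L, 16), rep(0L, 16)),
        pairId = c(1:16, 1:16),
        partition = rep(NA_character_, 32),
        fragmentLength = 24L)
    ds <- splitDataset(ds, seed = 2L)
    spec <- ocrModelSpec(conv1Filters = 4L, conv1Width = 6L,
                         conv2Filters = 4L, conv2Width = 3L,
                         fcUnits = 8L, dropout = 0, inputLength = 24L,
                         batchSize = 8L, epochs = 20L, seed = 4L)
    m1 <- trainModel(spec, ds)
    p <- predictProba(m1, ds@sequences)
    expect_equal(mean((p >= 0.5) == (ds@labels == 1L)), 1)
    # on separable data the epoch losses descend almost monotonically
    expect_gte(mean(diff(m1@history$trainLoss) <= 0), 0.8)
    m2 <- trainModel(spec, ds)
    expect_identical(m1@history$valLoss, m2@history$valLoss)
    expect_identical(m1@weights, m2@weights)
    expect_equal(nrow(m1@history), 20L)
})

test_that("training loss decreases on the planted-motif fixture", {
    fx <- trainedFixture()
    h <- fx$model@history
    # deterministic-mode validation loss descends as the motif is learned
    expect_lt(min(h$valLoss), 0.6 * h$valLoss[1L])
    expect_lt(h$trainLoss[nrow(h)], 0.5 * h$trainLoss[1L])
    # planted-motif fragments outscore their shuffles after training
    te <- datasetPartition(fx$ds, "test")
    p <- predictProba(fx$model, te$sequences)
    expect_gt(mean(p[te$labels == 1L]), mean(p[te$labels == 0L]))
})

test_that("prediction is a pure function of weights and input", {
    fx <- trainedFixture()
    te <- datasetPartition(fx$ds, "test")
    p1 <- predictProba(fx$model, te$sequences)
    p2 <- predictProba(fx$model, te$sequences)
    expect_identical(p1, p2)
    expect_true(all(p1 > 0 & p1 < 1))
    expect_error(predictProba(buildModel(smallModelSpec()), "ACGT"),
                 "trained")
})

test_that("checkpoints round trip through a versioned file", {
    fx <- trainedFixture()
    tf <- withr::local_tempfile(fileext = ".rds")
    saveModel(fx$model, tf)
    back <- loadModel(tf)
    te <- datasetPartition(fx$ds, "test")
    expect_identical(predictProba(back, te$sequences),
                     predictProba(fx$model, te$sequences))
    expect_identical(back@history, fx$model@history)
    bad <- withr::local_tempfile(fileext = ".rds")
    saveRDS(list(a = 1), bad)
    expect_error(loadModel(bad), "not an OCRscan model")
})
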