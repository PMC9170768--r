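test_that("a filter hand-set to a motif harvests exactly that site", {
    spec <- ocrModelSpec(conv1Filters = 2L, conv1Width = 6L,
                         conv2Filters = 2L, conv2Width = 3L,
                         fcUnits = 4L, dropout = 0, inputLength = 30L)
    m <- buildModel(spec)
    # filter 1 = one-hot weights for TATAAT; filter 2 all zeros
    W1 <- matrix(0, 2L, 24L)
    for (j in seq_along(c("T", "A", "T", "A", "A", "T"))) {
        base <- c("T", "A", "T", "A", "A", "T")[j]
        W1[1L, 4L * (j - 1L) + match(base, c("A", "C", "G", "T"))] <- 1
    }
    m@weights$W1 <- W1
    m@weights$b1 <- c(0, 0)
    m@trained <- TRUE
    seqs <- c(paste0("GGGGGGGGGG", "TATAAT", "GGGGGGGGGGGGGG"),
              paste0(strrep("C", 30)))
    h <- harvestActivations(m, seqs, thresholdFrac = 0.5, minSites = 1L)
    expect_equal(h$filter_001$subsequences, "TATAAT")
    # the all-zero filter never activates and is inactive
    expect_length(h$filter_002$subsequences, 0L)
    expect_false(h$filter_002$active)
    # thresholdFrac = 1 is strict, so even the argmax is excluded
    h1 <- harvestActivations(m, seqs, thresholdFrac = 1, minSites = 1L)
    expect_length(h1$filter_001$subsequences, 0L)
    expect_error(harvestActivations(buildModel(spec), seqs), "trained")
})

test_that("PFM counting conserves column sums", {
    pfm <- buildPFM(c("ACG", "ACG"))
    expect_equal(unname(motifCounts(pfm)["A", 1]), 2L)
    expect_equal(unname(motifCounts(pfm)["C", 2]), 2L)
    expect_equal(unname(colSums(motifCounts(pfm))), rep(2L, 3L))

    pfm2 <- buildPFM(c("AT", "TA"))
    expect_equal(unname(motifCounts(pfm2)["A", ]), c(1L, 1L))
    expect_equal(unname(motifCounts(pfm2)["T", ]), c(1L, 1L))

    set.seed(3)
    subs <- randomDna(25, 8)
    expect_equal(unname(colSums(motifCounts(buildPFM(subs)))),
                 rep(25L, 8L))
    expect_error(buildPFM(c("AC", "ACG")), "same width")
    expect_error(buildPFM(character(0)), "at least one")
})

test_that("information content matches hand-computed entropies", {
    uniform <- buildPFM(c("A", "C", "G", "T"))
    expect_equal(motifIC(pfmToPwm(uniform, pseudocount = 0))[1L], 0)
    pure <- buildPFM(c("A", "A", "A", "A"))
    expect_equal(motifIC(pfmToPwm(pure, pseudocount = 0))[1L], 2)

    skew <- buildPFM(c(rep("A", 7), "C", "G", "T"))
    ic <- motifIC(pfmToPwm(skew, pseudocount = 0))[1L]
    expect_equal(ic, 2 + 0.7 * log2(0.7) + 0.3 * log2(0.1),
                 tolerance = 1e-9)
    expect_equal(ic, 0.6432, tolerance = 1e-4)

    # pseudocounted PWMs are column-stochastic with IC in [0, 2]
    set.seed(4)
    pwm <- pfmToPwm(buildPFM(randomDna(30, 10)))
    expect_equal(unname(colSums(motifProbs(pwm))), rep(1, 10))
    expect_true(all(motifIC(pwm) >= 0 & motifIC(pwm) <= 2))
})

test_that("PWM similarity finds itself, its reverse complement, and the oracle optimum", {
    set.seed(5)
    a <- sampleMotif(10L, 1.4, seed = 21L)
    self <- pwmSimilarity(a, a)
    expect_equal(self$score, 1)
    expect_equal(self$offset, 0L)
    expect_equal(self$orientation, "forward")

    rc <- motifProbs(a)[4:1, 10:1]
    rownames(rc) <- c("A", "C", "G", "T")
    ns <- asNamespace("OCRscan")
    arc <- ns$pwmFromProbs(rc, "rc")
    got <- pwmSimilarity(a, arc)
    expect_equal(got$score, 1)
    expect_equal(got$orientation, "reverse")

    for (rep in 1:10) {
        x <- sampleMotif(sample(6:14, 1), runif(1, 0.5, 1.8),
                         seed = rep)
        y <- sampleMotif(sample(6:14, 1), runif(1, 0.5, 1.8),
                         seed = rep + 100L)
        expect_equal(pwmSimilarity(x, y)$score,
                     brutePwmSimilarity(x, y), tolerance = 1e-12)
    }
})

test_that("MEME minimal format round trips and parses by hand", {
    pwms <- list(sampleMotif(8L, 1.2, seed = 31L, name = "m1"),
                 sampleMotif(6L, 1.8, seed = 32L, name = "m2"))
    tf <- withr::local_tempfile(fileext = ".meme")
    writeMeme(pwms, tf)
    back <- readMeme(tf)
    expect_equal(names(back), c("m1", "m2"))
    for (i in 1:2)
        expect_equal(motifProbs(back[[i]]), motifProbs(pwms[[i]]),
                     tolerance = 1e-5)

    writeMeme(list(), tf)                        # header-only file
    expect_length(readMeme(tf), 0L)
    expect_match(readLines(tf)[1L], "MEME version")

    hand <- c("MEME version 4", "", "ALPHABET= ACGT", "",
              "MOTIF toy",
              "letter-probability matrix: alength= 4 w= 2 nsites= 5 E= 0",
              "1.0 0.0 0.0 0.0", "0.0 0.5 0.5 0.0")
    writeLines(hand, tf)
    toy <- readMeme(tf)$toy
    expect_equal(unname(motifProbs(toy)[, 1L]), c(1, 0, 0, 0))
    expect_equal(unname(motifProbs(toy)[, 2L]), c(0, 0.5, 0.5, 0))
})

test_that("trained filters recover the planted motif", {
    fx <- trainedFixture()
    mots <- extractMotifs(fx$model,
                          fx$ds@sequences[fx$ds@labels == 1L])
    expect_gt(sum(mots$active), 0L)
    sims <- vapply(mots$pwm, function(p)
        pwmSimilarity(p, fx$scenario@motifs[[1L]])$score, numeric(1))
    expect_gte(max(sims), 0.75)
    tf <- withr::local_tempfile()
    writeLogoHeights(mots$pwm[which.max(sims)], tf)
    expect_true(file.exists(list.files(tf, full.names = TRUE)[1L]))
})
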