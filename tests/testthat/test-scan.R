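test_that("window starts follow the closed-form count", {
    expect_equal(slidingWindowStarts(36), 0L)
    expect_equal(slidingWindowStarts(46), c(0L, 5L, 10L))
    expect_warning(empty <- slidingWindowStarts(35), "shorter")
    expect_length(empty, 0L)

    for (L in c(36:60, sample(61:5000, 40))) {
        s <- slidingWindowStarts(L)
        expect_equal(length(s), floor((L - 36) / 5) + 1)
        if (length(s) > 1) expect_true(all(diff(s) == 5L))
    }
})

test_that("per-base max aggregation matches the naive loop", {
    mk <- function(starts, probs, width = 36L, len = 300L)
        methods::new("ProbabilityTrack", chrom = "c1",
                     starts = as.integer(starts), windowWidth = width,
                     step = 5L, probs = probs, chromLength = len)
    tr <- mk(0L, 0.9)
    bs <- trackToBaseScores(tr)
    expect_equal(bs[1:36], rep(0.9, 36))
    expect_equal(bs[37:300], rep(0, 264))

    tr2 <- mk(c(0L, 5L), c(0.2, 0.8))
    bs2 <- trackToBaseScores(tr2)
    expect_equal(bs2[6:36], rep(0.8, 31))        # overlap takes the max
    expect_equal(bs2[1:5], rep(0.2, 5))

    set.seed(11)
    for (rep in 1:5) {
        n <- sample(5:40, 1)
        starts <- seq(0L, by = 5L, length.out = n)
        probs <- runif(n, 0.01, 0.99)
        tr3 <- mk(starts, probs, len = max(starts) + 36L + 20L)
        expect_equal(trackToBaseScores(tr3),
                     bruteBaseScores(starts, probs, 36L,
                                     tr3@chromLength))
    }

    # mean aggregation averages covering windows
    bsMean <- trackToBaseScores(tr2, method = "mean")
    expect_equal(bsMean[1:5], rep(0.2, 5))
    expect_equal(bsMean[6:36], rep(0.5, 31))
})

test_that("peak calling applies threshold, merge and length rules", {
    expect_length(callPeaks(rep(0.3, 200)), 0L)

    bs <- rep(0, 300); bs[51:150] <- 0.7
    pk <- callPeaks(bs)
    expect_length(pk, 1L)
    expect_equal(GenomicRanges::start(pk), 51L)
    expect_equal(GenomicRanges::end(pk), 150L)
    expect_equal(S4Vectors::mcols(pk)$score, 0.7)

    # two 40-base runs, 10 apart -> merged; 60 apart -> separate
    near <- rep(0, 300); near[11:50] <- 0.6; near[61:100] <- 0.8
    expect_length(callPeaks(near), 1L)
    far <- rep(0, 300); far[11:50] <- 0.6; far[111:150] <- 0.8
    expect_length(callPeaks(far), 2L)

    # sub-minimum runs are discarded
    short <- rep(0, 300); short[11:30] <- 0.9
    expect_length(callPeaks(short, minLength = 36L), 0L)

    # summit is the leftmost base attaining the maximum
    bs2 <- rep(0, 200); bs2[21:80] <- 0.6; bs2[c(30, 40)] <- 0.95
    pk2 <- callPeaks(bs2)
    expect_equal(S4Vectors::mcols(pk2)$summit, 30L - 21L)
})

test_that("emitted peaks are disjoint, sorted and above threshold", {
    set.seed(12)
    bs <- pmin(pmax(stats::filter(runif(2000), rep(1 / 30, 30),
                                  circular = TRUE), 0.01), 0.99)
    pk <- callPeaks(as.numeric(bs), threshold = 0.55, mergeGap = 20L,
                    minLength = 10L)
    if (length(pk) > 1L) {
        expect_true(all(diff(GenomicRanges::start(pk)) > 0))
        expect_true(all(GenomicRanges::start(pk)[-1L] >
                        GenomicRanges::end(pk)[-length(pk)]))
    }
    expect_true(all(S4Vectors::mcols(pk)$score >= 0.55))
    expect_true(all(GenomicRanges::width(pk) >= 10L))
})

test_that("genome scoring obeys window geometry and constant inputs", {
    fx <- trainedFixture()
    g <- Biostrings::DNAStringSet(c(c1 = strrep("N", 300),
                                    c2 = strrep("A", 20)))
    expect_warning(tracks <- scoreGenome(fx$model, g), "skipped")
    expect_named(tracks, "c1")
    tr <- tracks$c1
    expect_length(trackProbs(tr), floor((300 - 36) / 5) + 1)
    # an all-N chromosome is a constant input, so scores are constant
    expect_equal(diff(range(trackProbs(tr))), 0)
})

test_that("scores are high inside planted OCRs and low outside", {
    fx <- trainedFixture()
    tracks <- scoreGenome(fx$model, fx$gen$genome)
    tr <- tracks[[1L]]
    mid <- tr@starts + 18L
    truth <- fx$gen$truth
    inOcr <- rep(FALSE, length(mid))
    for (i in seq_along(truth))
        inOcr <- inOcr | (mid >= GenomicRanges::start(truth)[i] &
                          mid <= GenomicRanges::end(truth)[i])
    expect_gt(mean(trackProbs(tr)[inOcr]),
              mean(trackProbs(tr)[!inOcr]))
})

test_that("fragment export writes exactly the above-threshold windows", {
    tr <- methods::new("ProbabilityTrack", chrom = "c1",
                       starts = c(0L, 5L, 10L), windowWidth = 36L,
                       step = 5L, probs = c(0.2, 0.9, 0.7),
                       chromLength = 100L)
    tf <- withr::local_tempfile(fileext = ".bed")
    exportFragmentsBed(tr, 0.5, tf)
    back <- readBed(tf)
    expect_length(back, 2L)
    expect_equal(GenomicRanges::start(back) - 1L, c(5L, 10L))
    expect_equal(S4Vectors::mcols(back)$score, c(0.9, 0.7))

    emptyTrack <- methods::new("ProbabilityTrack", chrom = "c1",
                               starts = integer(0), windowWidth = 36L,
                               step = 5L, probs = numeric(0),
                               chromLength = 10L)
    exportFragmentsBed(emptyTrack, 0.5, tf)
    expect_length(readLines(tf), 0L)
})

test_that("bedGraph export compresses runs and preserves coordinates", {
    tr <- methods::new("ProbabilityTrack", chrom = "c1",
                       starts = c(0L, 5L), windowWidth = 36L, step = 5L,
                       probs = c(0.4, 0.4), chromLength = 60L)
    tf <- withr::local_tempfile(fileext = ".bedGraph")
    writeBedGraph(tr, tf)
    lines <- readLines(tf)
    expect_equal(lines, "c1\t0\t41\t0.4")
})
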