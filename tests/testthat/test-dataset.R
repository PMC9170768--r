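test_that("one-hot encoding follows the 5-symbol table and inverts", {
    m <- oneHotEncode("ACGT")
    expect_equal(unname(m), diag(4))
    expect_equal(rownames(m), c("A", "C", "G", "T"))
    expect_equal(unname(oneHotEncode("N")), matrix(0, 4, 1))
    expect_error(oneHotEncode("ACB"), "illegal symbol 'B'")

    set.seed(1)
    s <- paste(sample(c("A", "C", "G", "T", "N"), 100, TRUE),
               collapse = "")
    expect_equal(oneHotDecode(oneHotEncode(s)), s)
})

test_that("peak length filter is strictly greater-than", {
    peaks <- GenomicRanges::GRanges("c1", IRanges::IRanges(
        start = c(1, 1001, 2001, 3001),
        width = c(150, 200, 201, 400)))
    kept <- filterPeaks(peaks, 200L)
    expect_equal(GenomicRanges::width(kept), c(201, 400))
    expect_warning(filterPeaks(peaks[1:2], 200L), "no peaks")
})

test_that("centered windows sit on the peak midpoint and clip at ends", {
    g <- Biostrings::DNAStringSet(c(c1 = paste(rep("A", 500),
                                               collapse = "")))
    pk <- GenomicRanges::GRanges("c1", IRanges::IRanges(101, 400))  # 0b 100-400
    w <- makePositiveWindows(g, pk, L = 36L, mode = "center")
    expect_equal(names(w), "c1:232-268")
    expect_equal(Biostrings::width(w), 36L)

    # one window per surviving peak
    pks <- GenomicRanges::GRanges("c1", IRanges::IRanges(
        start = c(101, 201, 150), width = 220))
    expect_length(makePositiveWindows(g, pks, L = 36L), 3L)

    # a peak hugging the chromosome start is dropped with a warning
    edge <- GenomicRanges::GRanges("c1", IRanges::IRanges(1, 10))
    expect_warning(out <- makePositiveWindows(g, edge, L = 36L),
                   "clipped")
    expect_length(out, 0L)
    expect_error(makePositiveWindows(g, pk, L = 600L), "exceeds")
})

test_that("tile mode covers peaks with non-overlapping windows", {
    g <- Biostrings::DNAStringSet(c(c1 = paste(rep("ACGT", 250),
                                               collapse = "")))
    pk <- GenomicRanges::GRanges("c1", IRanges::IRanges(11, 100))  # 90 bp
    w <- makePositiveWindows(g, pk, L = 36L, mode = "tile")
    expect_length(w, 2L)                         # floor(90/36)
    expect_equal(names(w), c("c1:10-46", "c1:46-82"))
})

test_that("shuffled negatives conserve base composition deterministically", {
    s <- "ACGTACGTACGTNNAA"
    counts <- function(x) table(strsplit(x, "")[[1]])
    for (seed in 1:5)
        expect_equal(counts(shuffleNegative(s, seed)), counts(s))
    expect_equal(shuffleNegative("AAAA", 1), "AAAA")
    expect_identical(shuffleNegative(s, 3), shuffleNegative(s, 3))
    perms <- vapply(1:20, function(k)
        shuffleNegative("ACGTACGTACGT", k), character(1))
    expect_gt(length(unique(perms)), 1L)
})

test_that("dataset construction balances classes and pairs negatives", {
    fx <- trainedFixture()
    ds <- fx$ds
    expect_equal(sum(ds@labels == 1L), sum(ds@labels == 0L))
    # every negative is a permutation of its paired positive
    sortChars <- function(x) paste(sort(strsplit(x, "")[[1]]),
                                   collapse = "")
    for (pid in sample(unique(ds@pairId), 10L)) {
        pair <- as.character(ds@sequences[ds@pairId == pid])
        expect_equal(sortChars(pair[1]), sortChars(pair[2]))
    }
    # pairs never straddle partitions
    tab <- table(ds@pairId, ds@partition)
    expect_true(all(rowSums(tab > 0) == 1L))
})

test_that("splits follow largest-remainder fractions at pair level", {
    ds <- randomPairDataset(10L, seed = 3L)
    ds <- splitDataset(ds, seed = 1L)
    tab <- table(ds@partition) / 2L              # pairs
    expect_equal(unname(tab[c("train", "validation", "test")]),
                 c(6, 2, 2), ignore_attr = TRUE)
    # union of partitions is everything, disjointly
    expect_false(anyNA(ds@partition))
    expect_error(splitDataset(randomPairDataset(3L), seed = 1L),
                 "at least 5 pairs")
})

test_that("identical inputs and seeds rebuild the dataset byte-identically", {
    fx <- trainedFixture()
    ds2 <- splitDataset(
        buildTrainingSet(fx$gen$genome, fx$gen$observed,
                         fragmentLength = 200L, seed = 1L), seed = 1L)
    f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
    writeDatasetTsv(fx$ds, f1)
    writeDatasetTsv(ds2, f2)
    expect_identical(readLines(f1), readLines(f2))
})

test_that("dataset TSV and FASTA exports round trip", {
    ds <- splitDataset(randomPairDataset(8L, seed = 2L), seed = 5L)
    tf <- withr::local_tempfile(fileext = ".tsv")
    writeDatasetTsv(ds, tf)
    back <- readDatasetTsv(tf)
    expect_equal(as.character(back@sequences), as.character(ds@sequences),
                 ignore_attr = TRUE)
    expect_equal(back@labels, ds@labels)
    expect_equal(back@partition, ds@partition)

    pf <- withr::local_tempfile(fileext = ".fa")
    nf <- withr::local_tempfile(fileext = ".fa")
    exportDatasetFasta(ds, pf, nf)
    expect_length(readFasta(pf), 8L)
    expect_length(readFasta(nf), 8L)
})

test_that("k-fold splits are near-equal, disjoint and exhaustive", {
    folds <- kfoldSplit(100L, k = 10L, seed = 1L)
    expect_length(folds, 10L)
    expect_true(all(lengths(lapply(folds, `[[`, "test")) == 10L))

    folds23 <- kfoldSplit(23L, k = 10L, seed = 2L)
    sizes <- sort(lengths(lapply(folds23, `[[`, "test")),
                  decreasing = TRUE)
    expect_equal(sizes, c(3L, 3L, 3L, rep(2L, 7L)))
    allTest <- sort(unlist(lapply(folds23, `[[`, "test")))
    expect_equal(allTest, 1:23)                  # each sample tested once
    for (f in folds23)
        expect_length(intersect(f$train, f$test), 0L)
    expect_error(kfoldSplit(5L, k = 10L), "exceeds")

    dsFolds <- kfoldSplit(randomPairDataset(12L), k = 3L, seed = 1L)
    expect_equal(sort(unlist(lapply(dsFolds, `[[`, "test"))), 1:24)
})
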