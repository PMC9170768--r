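# Shared planted-motif fixture: one small synthetic scenario built and one
# model trained once per test run, reused by the motif/scan/model tests.

.fixtureCache <- new.env(parent = emptyenv())

smallScenario <- function() {
    syntheticSpec(genomeLength = 120000L, nChroms = 1L,
                  motifs = list(sampleMotif(12L, 1.6, seed = 101L)),
                  nOCRs = 100L, ocrLengthMean = 250, ocrLengthSD = 30,
                  motifsPerOCR = 3L, detectionRate = 0.8, seed = 11L)
}

smallModelSpec <- function(inputLength = 200L) {
    ocrModelSpec(conv1Filters = 24L, conv1Width = 19L,
                 conv2Filters = 12L, conv2Width = 11L, fcUnits = 64L,
                 dropout = 0.2, inputLength = inputLength,
                 batchSize = 32L, epochs = 40L, seed = 7L)
}

trainedFixture <- function() {
    if (!is.null(.fixtureCache$fx)) return(.fixtureCache$fx)
    sc <- smallScenario()
    gen <- buildGenome(sc)
    ds <- buildTrainingSet(gen$genome, gen$observed,
                           fragmentLength = 200L, seed = 1L)
    ds <- splitDataset(ds, seed = 1L)
    model <- trainModel(smallModelSpec(), ds)
    .fixtureCache$fx <- list(scenario = sc, gen = gen, ds = ds,
                             model = model)
    .fixtureCache$fx
}

# a tiny two-chromosome genome for I/O and windowing tests
tinyGenome <- function() {
    g <- Biostrings::DNAStringSet(c(
        chr1 = paste(rep("ACGT", 250), collapse = ""),   # 1000 bp
        chr2 = paste(rep("GGCCA", 80), collapse = "")))  # 400 bp
    g
}

randomIntervals <- function(n, chroms = c("c1", "c2"), maxPos = 500L,
                            maxLen = 60L) {
    start <- sample.int(maxPos, n, replace = TRUE)
    GenomicRanges::GRanges(
        sample(chroms, n, replace = TRUE),
        IRanges::IRanges(start = start,
                         width = sample.int(maxLen, n, replace = TRUE)))
}
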