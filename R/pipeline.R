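#' Default pipeline configuration
#'
#' Every tunable of the five pipeline stages with its default. The
#' structure mirrors a \code{config.yaml}: top-level sections
#' \code{paths}, \code{dataset}, \code{model}, \code{motif}, \code{scan},
#' \code{simulate}, \code{logging}.
#'
#' @return a nested named list.
#' @seealso [readPipelineConfig()], [runPreprocess()]
#' @export
defaultConfig <- function() {
    list(
        paths = list(
            genome = NULL,        # FASTA; filled by the user or runSimulate
            peaks = NULL,         # BED of assay peaks
            outdir = "ocrscan_out"),
        dataset = list(
            minPeakLength = 200L, # strict > filter on peak length (bp)
            fragmentLength = 200L,# training fragment length (bp)
            mode = "center",      # center | tile
            fractions = c(0.60, 0.20, 0.20),
            seed = 1L),
        model = list(
            conv1Filters = 64L, conv1Width = 19L,
            conv2Filters = 32L, conv2Width = 11L,
            fcUnits = 200L, dropout = 0.4,
            learningRate = 1e-3, batchSize = 32L, epochs = 60L,
            seed = 1L),
        motif = list(
            thresholdFrac = 0.5, pseudocount = 0.25, minSites = 10L),
        scan = list(
            width = 36L, step = 5L, threshold = 0.5,
            mergeGap = 50L, minLength = 36L, batchSize = 2048L,
            aggregate = "max",
            exportFragments = FALSE, exportBedGraph = FALSE),
        simulate = list(
            genomeLength = 500000L, nChroms = 1L,
            backgroundProbs = rep(0.25, 4),
            motifWidth = 12L, motifIC = 1.6,
            nOCRs = 400L, ocrLengthMean = 250, ocrLengthSD = 30,
            motifsPerOCR = 3L, detectionRate = 0.8, seed = 2021L),
        logging = list(verbose = FALSE))
}

#' Read and validate a pipeline configuration
#'
#' Loads a YAML file (if given), merges it over [defaultConfig()], applies
#' \code{key.subkey=value} overrides, and validates: unknown keys are
#' rejected with a message listing every offending key, and value classes
#' are coerced to the defaults' types.
#'
#' @param path path to a YAML config, or \code{NULL} for pure defaults.
#' @param overrides named list (or \code{"section.key=value"} strings) of
#'   values that win over the file.
#' @return the effective configuration (nested list).
#' @export
readPipelineConfig <- function(path = NULL, overrides = list()) {
    config <- defaultConfig()
    if (!is.null(path)) {
        if (!file.exists(path)) stop("config file not found: ", path)
        user <- yaml::read_yaml(path)
        config <- mergeConfig(config, user, "")
    }
    if (is.character(overrides))
        overrides <- parseOverrides(overrides)
    if (length(overrides))
        config <- mergeConfig(config, overrides, "")
    validateConfig(config)
    config
}

mergeConfig <- function(base, user, prefix) {
    if (!length(user)) return(base)
    bad <- setdiff(names(user), names(base))
    if (length(bad))
        stop("unknown configuration key(s): ",
             paste0(prefix, bad, collapse = ", "))
    for (k in names(user)) {
        if (is.list(base[[k]]) && !is.null(names(base[[k]]))) {
            base[[k]] <- mergeConfig(base[[k]], user[[k]],
                                     paste0(prefix, k, "."))
        } else {
            v <- user[[k]]
            if (!is.null(base[[k]]) && !is.null(v)) {
                if (is.integer(base[[k]])) v <- as.integer(v)
                else if (is.numeric(base[[k]])) v <- as.numeric(v)
            }
            base[k] <- list(v)   # keeps the key even when v is NULL
        }
    }
    base
}

parseOverrides <- function(x) {
    out <- list()
    for (s in x) {
        kv <- strsplit(s, "=", fixed = TRUE)[[1L]]
        if (length(kv) < 2L) stop("override must be key=value: ", s)
        keys <- strsplit(kv[1L], ".", fixed = TRUE)[[1L]]
        val <- yaml::yaml.load(paste(kv[-1L], collapse = "="))
        node <- val
        for (k in rev(keys)) node <- stats::setNames(list(node), k)
        out <- utils::modifyList(out, node)
    }
    out
}

validateConfig <- function(config) {
    d <- config$dataset
    if (abs(sum(d$fractions) - 1) > 1e-8)
        stop("dataset.fractions must sum to 1")
    if (!d$mode %in% c("center", "tile"))
        stop("dataset.mode must be 'center' or 'tile'")
    m <- config$model
    methods::validObject(do.call(ocrModelSpec, c(
        m, list(inputLength = d$fragmentLength))))
    s <- config$scan
    if (s$threshold <= 0 || s$threshold >= 1)
        stop("scan.threshold must be in (0, 1)")
    if (!s$aggregate %in% c("max", "mean"))
        stop("scan.aggregate must be 'max' or 'mean'")
    if (config$motif$thresholdFrac <= 0 || config$motif$thresholdFrac > 1)
        stop("motif.thresholdFrac must be in (0, 1]")
    invisible(TRUE)
}

#' Write the effective configuration as YAML
#'
#' The dump re-validates through [readPipelineConfig()] and reproduces the
#' run.
#'
#' @param config a configuration list.
#' @param path output YAML path.
#' @return invisibly, \code{path}.
#' @export
writePipelineConfig <- function(config, path) {
    yaml::write_yaml(config, path)
    invisible(path)
}

stageLog <- function(config, stage, lines) {
    dir.create(config$paths$outdir, showWarnings = FALSE, recursive = TRUE)
    path <- file.path(config$paths$outdir, "run.log")
    hdr <- sprintf("[%s] OCRscan %s", stage,
                   as.character(utils::packageVersion("OCRscan")))
    cat(c(hdr, paste0("  ", lines)), file = path, sep = "\n",
        append = TRUE)
    if (isTRUE(config$logging$verbose))
        message(paste(c(hdr, paste0("  ", lines)), collapse = "\n"))
}

outPath <- function(config, ...) file.path(config$paths$outdir, ...)

needsFile <- function(path, stage) {
    if (!file.exists(path))
        stop("missing '", path, "'; run ", stage, " first")
    path
}

#' Pipeline stages
#'
#' The five stages of the toolkit, each reading its inputs and writing
#' its outputs into \code{paths.outdir}; stages are idempotent for
#' identical inputs and seeds and fail with an actionable error naming
#' the stage to run first when an upstream artifact is missing.
#' \describe{
#'   \item{\code{runSimulate}}{materializes the synthetic scenario of the
#'     \code{simulate} section (\code{genome.fa}, \code{truth.bed},
#'     \code{observed.bed}); when \code{paths.genome}/\code{paths.peaks}
#'     are unset, later stages fall back to these files.}
#'   \item{\code{runPreprocess}}{genome + peaks to balanced split dataset
#'     (\code{dataset.tsv}, \code{positives.fa}, \code{negatives.fa}).}
#'   \item{\code{runTrain}}{dataset to checkpoint (\code{model.rds}),
#'     training history (\code{history.tsv}) and held-out test metrics
#'     (\code{metrics.tsv}, \code{roc.tsv}, \code{pr.tsv}).}
#'   \item{\code{runMotif}}{checkpoint + positives to MEME motif file
#'     (\code{motifs.meme}) and logo-height matrices (\code{logos/}).}
#'   \item{\code{runPredict}}{checkpoint + genome to predicted OCRs
#'     (\code{predictions.bed}, optional \code{fragments.bed} and
#'     \code{scores.bedGraph}).}
#' }
#'
#' @param config a configuration list from [readPipelineConfig()].
#' @return each stage invisibly returns its main artifact path; a run log
#'   (\code{run.log}) accumulates versions, seeds, parameters and record
#'   counts.
#' @name pipeline
NULL

#' @rdname pipeline
#' @export
runSimulate <- function(config) {
    s <- config$simulate
    spec <- syntheticSpec(
        genomeLength = s$genomeLength, nChroms = s$nChroms,
        backgroundProbs = s$backgroundProbs,
        motifs = list(sampleMotif(s$motifWidth, s$motifIC,
                                  seed = s$seed + 7919L)),
        nOCRs = s$nOCRs, ocrLengthMean = s$ocrLengthMean,
        ocrLengthSD = s$ocrLengthSD, motifsPerOCR = s$motifsPerOCR,
        detectionRate = s$detectionRate, seed = s$seed)
    dir.create(config$paths$outdir, showWarnings = FALSE, recursive = TRUE)
    res <- buildGenome(spec, dir = config$paths$outdir)
    writeMeme(spec@motifs, outPath(config, "planted_motifs.meme"))
    stageLog(config, "simulate", c(
        sprintf("seed=%d genome=%d bp in %d chrom(s)", s$seed,
                s$genomeLength, s$nChroms),
        sprintf("truth OCRs=%d observed peaks=%d motif sites=%d",
                length(res$truth), length(res$observed),
                length(res$motifSites))))
    invisible(outPath(config, "genome.fa"))
}

# resolve the genome/peaks paths, falling back to simulated artifacts
resolveInput <- function(config, what) {
    p <- config$paths[[what]]
    if (!is.null(p)) {
        if (!file.exists(p)) stop("paths.", what, " not found: ", p)
        return(p)
    }
    fallback <- outPath(config,
                        if (what == "genome") "genome.fa" else "observed.bed")
    needsFile(fallback, "runSimulate() (or set paths.genome/paths.peaks)")
}

#' @rdname pipeline
#' @export
runPreprocess <- function(config) {
    genome <- readFasta(resolveInput(config, "genome"))
    peaks <- readBed(resolveInput(config, "peaks"))
    d <- config$dataset
    ds <- buildTrainingSet(genome, peaks,
                           fragmentLength = d$fragmentLength,
                           minPeakLength = d$minPeakLength,
                           mode = d$mode, seed = d$seed)
    ds <- splitDataset(ds, fractions = d$fractions, seed = d$seed)
    dir.create(config$paths$outdir, showWarnings = FALSE, recursive = TRUE)
    writeDatasetTsv(ds, outPath(config, "dataset.tsv"))
    exportDatasetFasta(ds, outPath(config, "positives.fa"),
                       outPath(config, "negatives.fa"))
    tab <- table(ds@partition)
    stageLog(config, "preprocess", c(
        sprintf("seed=%d fragmentLength=%d mode=%s minPeakLength=%d",
                d$seed, d$fragmentLength, d$mode, d$minPeakLength),
        sprintf("peaks in=%d fragments=%d (train %d / validation %d / test %d)",
                length(peaks), length(ds@labels),
                tab[["train"]], tab[["validation"]], tab[["test"]])))
    invisible(outPath(config, "dataset.tsv"))
}

#' @rdname pipeline
#' @export
runTrain <- function(config) {
    ds <- readDatasetTsv(needsFile(outPath(config, "dataset.tsv"),
                                   "runPreprocess()"))
    m <- config$model
    spec <- do.call(ocrModelSpec, c(
        m, list(inputLength = ds@fragmentLength)))
    model <- trainModel(spec, ds,
                        verbose = isTRUE(config$logging$verbose))
    saveModel(model, outPath(config, "model.rds"))
    utils::write.table(model@history, outPath(config, "history.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    te <- datasetPartition(ds, "test")
    p <- predictProba(model, te$sequences)
    roc <- rocAuroc(p, te$labels)
    pr <- prAuprc(p, te$labels)
    writeMetricPoints(roc, outPath(config, "roc.tsv"))
    writeMetricPoints(pr, outPath(config, "pr.tsv"))
    utils::write.table(
        data.frame(metric = c("test_auroc", "test_auprc"),
                   value = c(roc$auroc, pr$auprc)),
        outPath(config, "metrics.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
    stageLog(config, "train", c(
        sprintf("seed=%d epochs=%d batch=%d lr=%g dropout=%g params=%d",
                m$seed, m$epochs, m$batchSize, m$learningRate, m$dropout,
                paramCount(model)),
        sprintf("test AUROC=%.4f AUPRC=%.4f", roc$auroc, pr$auprc)))
    invisible(outPath(config, "model.rds"))
}

#' @rdname pipeline
#' @export
runMotif <- function(config) {
    model <- loadModel(needsFile(outPath(config, "model.rds"),
                                 "runTrain()"))
    ds <- readDatasetTsv(needsFile(outPath(config, "dataset.tsv"),
                                   "runPreprocess()"))
    mo <- config$motif
    positives <- ds@sequences[ds@labels == 1L]
    motifs <- extractMotifs(model, positives,
                            thresholdFrac = mo$thresholdFrac,
                            pseudocount = mo$pseudocount,
                            minSites = mo$minSites)
    writeMeme(motifs$pwm, outPath(config, "motifs.meme"),
              nsites = motifs$nSites[motifs$active])
    writeLogoHeights(motifs$pwm, outPath(config, "logos"))
    stageLog(config, "motif", c(
        sprintf("thresholdFrac=%g pseudocount=%g minSites=%d",
                mo$thresholdFrac, mo$pseudocount, mo$minSites),
        sprintf("active filters=%d / %d", sum(motifs$active),
                length(motifs$active))))
    invisible(outPath(config, "motifs.meme"))
}

#' @rdname pipeline
#' @export
runPredict <- function(config) {
    model <- loadModel(needsFile(outPath(config, "model.rds"),
                                 "runTrain()"))
    genome <- readFasta(resolveInput(config, "genome"))
    s <- config$scan
    tracks <- scoreGenome(model, genome, width = s$width, step = s$step,
                          batchSize = s$batchSize)
    peaks <- lapply(tracks, function(tr)
        callPeaks(trackToBaseScores(tr, method = s$aggregate),
                  chrom = tr@chrom, threshold = s$threshold,
                  mergeGap = s$mergeGap, minLength = s$minLength))
    ocrs <- suppressWarnings(do.call(c, unname(peaks)))
    if (length(ocrs)) {
        ocrs <- GenomicRanges::sort(ocrs, ignore.strand = TRUE)
        names(ocrs) <- sprintf("OCR_%d", seq_along(ocrs))
    }
    writePredictionsBed(ocrs, outPath(config, "predictions.bed"))
    if (isTRUE(s$exportFragments))
        exportFragmentsBed(tracks, s$threshold,
                           outPath(config, "fragments.bed"))
    if (isTRUE(s$exportBedGraph))
        writeBedGraph(tracks, outPath(config, "scores.bedGraph"),
                      aggregate = s$aggregate)
    stageLog(config, "predict", c(
        sprintf("width=%d step=%d threshold=%g mergeGap=%d minLength=%d",
                s$width, s$step, s$threshold, s$mergeGap, s$minLength),
        sprintf("windows=%d predicted OCRs=%d",
                sum(vapply(tracks, function(t) length(t@probs),
                           integer(1))), length(ocrs))))
    invisible(outPath(config, "predictions.bed"))
}
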