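#' @import methods
#' @importFrom Biostrings DNAStringSet width
NULL

setClassUnion("data.frameOrNULL", c("data.frame", "NULL"))

#' Architecture and training hyperparameters for the accessibility CNN
#'
#' An \code{OCRModelSpec} fixes everything needed to build and train the
#' convolutional open-chromatin classifier: two convolutional layers
#' (filter counts and widths), a fully connected layer, the dropout
#' probability applied after every hidden layer, the training fragment
#' length, and the optimizer settings.
#'
#' @slot conv1Filters integer, number of first-layer convolution filters.
#' @slot conv1Width integer, first-layer filter width in bp.
#' @slot conv2Filters integer, number of second-layer filters.
#' @slot conv2Width integer, second-layer filter width (in conv1 positions).
#' @slot fcUnits integer, neurons in the fully connected layer.
#' @slot dropout numeric in [0, 1), dropout probability after each hidden layer.
#' @slot inputLength integer, training fragment length in bp.
#' @slot learningRate numeric, Adam learning rate.
#' @slot batchSize integer, minibatch size.
#' @slot epochs integer, training epochs.
#' @slot seed integer, seed for weight initialization and training randomness.
#'
#' @seealso [ocrModelSpec()], [buildModel()], [trainModel()]
#' @export
setClass("OCRModelSpec",
    representation(
        conv1Filters = "integer", conv1Width = "integer",
        conv2Filters = "integer", conv2Width = "integer",
        fcUnits = "integer", dropout = "numeric",
        inputLength = "integer", learningRate = "numeric",
        batchSize = "integer", epochs = "integer", seed = "integer"
    )
)

setValidity("OCRModelSpec", function(object) {
    msg <- character()
    one <- function(x) length(x) == 1L && !is.na(x)
    for (s in c("conv1Filters", "conv1Width", "conv2Filters", "conv2Width",
                "fcUnits", "inputLength", "batchSize", "epochs", "seed"))
        if (!one(slot(object, s)))
            msg <- c(msg, sprintf("'%s' must be a single non-NA integer", s))
    if (length(msg)) return(msg)
    if (object@dropout < 0 || object@dropout >= 1)
        msg <- c(msg, "'dropout' must be in [0, 1)")
    if (object@fcUnits < 1L) msg <- c(msg, "'fcUnits' must be >= 1")
    if (object@conv1Width > object@inputLength)
        msg <- c(msg, "'conv1Width' exceeds 'inputLength'")
    if (object@conv2Width > object@inputLength - object@conv1Width + 1L)
        msg <- c(msg, "'conv2Width' exceeds the first-layer feature map length")
    if (object@learningRate <= 0) msg <- c(msg, "'learningRate' must be > 0")
    if (object@batchSize < 1L) msg <- c(msg, "'batchSize' must be >= 1")
    if (object@epochs < 1L) msg <- c(msg, "'epochs' must be >= 1")
    if (length(msg)) msg else TRUE
})

#' A (possibly trained) accessibility CNN
#'
#' Holds the [OCRModelSpec], the parameter store (a named list of weight
#' matrices and bias vectors), and the per-epoch training history once
#' [trainModel()] has run. Prediction with a trained model is deterministic:
#' dropout is disabled at inference.
#'
#' @slot spec an [OCRModelSpec].
#' @slot weights named list of numeric matrices/vectors.
#' @slot history \code{data.frame} with one row per epoch actually run
#'   (columns \code{epoch}, \code{trainLoss}, \code{trainAcc},
#'   \code{valLoss}, \code{valAcc}) or \code{NULL} before training.
#' @slot trained logical scalar.
#'
#' @seealso [buildModel()], [trainModel()], [predictProba()]
#' @export
setClass("OCRModel",
    representation(
        spec = "OCRModelSpec", weights = "list",
        history = "data.frameOrNULL", trained = "logical"
    )
)

#' Balanced, labelled, partitioned training fragments
#'
#' Equal-length DNA fragments with binary accessibility labels. Every
#' positive (an accessibility-peak fragment) is paired with exactly one
#' negative (its base-composition-preserving shuffle) through \code{pairId},
#' so classes are balanced by construction and a pair never straddles a
#' partition boundary.
#'
#' @slot sequences a [Biostrings::DNAStringSet] of equal-width fragments.
#' @slot labels integer vector of 0 (shuffled negative) / 1 (peak positive).
#' @slot pairId integer vector linking each negative to its source positive.
#' @slot partition character vector, \code{"train"}, \code{"validation"},
#'   \code{"test"}, or \code{NA} before [splitDataset()] has run.
#' @slot fragmentLength integer, common fragment width in bp.
#'
#' @seealso [buildTrainingSet()], [splitDataset()], [kfoldSplit()]
#' @export
setClass("OCRDataset",
    representation(
        sequences = "DNAStringSet", labels = "integer",
        pairId = "integer", partition = "character",
        fragmentLength = "integer"
    )
)

setValidity("OCRDataset", function(object) {
    n <- length(object@sequences)
    msg <- character()
    if (length(object@labels) != n || length(object@pairId) != n ||
        length(object@partition) != n)
        msg <- c(msg, "labels, pairId and partition must match sequence count")
    if (!all(object@labels %in% c(0L, 1L)))
        msg <- c(msg, "labels must be 0 or 1")
    if (n > 0L && !all(Biostrings::width(object@sequences) ==
                       object@fragmentLength))
        msg <- c(msg, "all fragments must have width 'fragmentLength'")
    if (sum(object@labels == 1L) != sum(object@labels == 0L))
        msg <- c(msg, "positive and negative counts must be equal")
    if (n > 0L) {
        tab <- table(object@pairId, object@labels)
        if (!all(tab == 1L))
            msg <- c(msg, "each pairId must hold exactly one positive and one negative")
    }
    ok <- object@partition %in% c("train", "validation", "test") |
        is.na(object@partition)
    if (!all(ok))
        msg <- c(msg, "partition must be train/validation/test or NA")
    if (length(msg)) msg else TRUE
})

#' Position frequency matrix for one filter-derived motif
#'
#' Raw base counts over the aligned subsequences harvested for one
#' convolution filter. Columns sum to the number of contributing sites
#' (subsequences containing N are excluded at harvest).
#'
#' @slot counts 4 x w non-negative integer matrix, rows A, C, G, T.
#' @slot nSites integer, number of contributing subsequences.
#'
#' @seealso [buildPFM()], [pfmToPwm()]
#' @export
setClass("PFMotif",
    representation(counts = "matrix", nSites = "integer"))

setValidity("PFMotif", function(object) {
    msg <- character()
    if (!identical(rownames(object@counts), c("A", "C", "G", "T")))
        msg <- c(msg, "counts rows must be A, C, G, T")
    if (any(object@counts < 0)) msg <- c(msg, "counts must be non-negative")
    if (ncol(object@counts) > 0 &&
        !all(colSums(object@counts) == object@nSites))
        msg <- c(msg, "every column must sum to nSites")
    if (length(msg)) msg else TRUE
})

#' Position weight matrix with per-column information content
#'
#' Pseudocounted base probabilities together with the information content
#' (in bits, 0 for a uniform column, 2 for a fixed base) and the
#' probability-times-information "logo heights" used for sequence logos.
#'
#' @slot probs 4 x w column-stochastic matrix, rows A, C, G, T.
#' @slot ic numeric vector of per-column information content in bits.
#' @slot logoHeights 4 x w matrix, \code{probs} scaled column-wise by \code{ic}.
#' @slot name character, motif identifier.
#'
#' @seealso [pfmToPwm()], [pwmSimilarity()], [writeMeme()]
#' @export
setClass("PWMotif",
    representation(probs = "matrix", ic = "numeric",
                   logoHeights = "matrix", name = "character"))

setValidity("PWMotif", function(object) {
    msg <- character()
    if (!identical(rownames(object@probs), c("A", "C", "G", "T")))
        msg <- c(msg, "probs rows must be A, C, G, T")
    if (ncol(object@probs) > 0) {
        if (max(abs(colSums(object@probs) - 1)) > 1e-6)
            msg <- c(msg, "probs columns must each sum to 1")
        if (length(object@ic) != ncol(object@probs))
            msg <- c(msg, "ic length must equal motif width")
        else if (any(object@ic < -1e-9 | object@ic > 2 + 1e-9))
            msg <- c(msg, "information content must lie in [0, 2] bits")
    }
    if (length(msg)) msg else TRUE
})

#' Per-window open-chromatin probabilities along one chromosome
#'
#' The result of sliding a trained model along a sequence: window start
#' coordinates (0-based, fixed step), the common window width, and one
#' probability per window.
#'
#' @slot chrom character, chromosome name.
#' @slot starts integer vector of 0-based window starts, increasing by
#'   \code{step}.
#' @slot windowWidth integer, window width in bp.
#' @slot step integer, distance between consecutive starts in bp.
#' @slot probs numeric vector in (0, 1), aligned with \code{starts}.
#' @slot chromLength integer, length of the scanned chromosome in bp.
#'
#' @seealso [scoreGenome()], [trackToBaseScores()], [callPeaks()]
#' @export
setClass("ProbabilityTrack",
    representation(chrom = "character", starts = "integer",
                   windowWidth = "integer", step = "integer",
                   probs = "numeric", chromLength = "integer"))

setValidity("ProbabilityTrack", function(object) {
    msg <- character()
    if (length(object@probs) != length(object@starts))
        msg <- c(msg, "probs and starts must have equal length")
    if (length(object@starts) > 1L) {
        d <- diff(object@starts)
        if (!all(d == object@step))
            msg <- c(msg, "starts must increase by exactly 'step'")
    }
    if (length(object@probs) && (min(object@probs) <= 0 ||
                                 max(object@probs) >= 1))
        msg <- c(msg, "probs must lie strictly inside (0, 1)")
    if (length(object@starts) &&
        max(object@starts) + object@windowWidth > object@chromLength)
        msg <- c(msg, "windows must fit inside the chromosome")
    if (length(msg)) msg else TRUE
})

#' Specification of a synthetic benchmark genome
#'
#' Describes a random genome with planted motif instances inside
#' non-overlapping ground-truth open chromatin regions (OCRs), plus an
#' "observed" peak set obtained by keeping each true OCR independently with
#' probability \code{detectionRate} — emulating the incomplete view a single
#' accessibility assay gives of the true OCR repertoire.
#'
#' @slot genomeLength integer, total genome length in bp.
#' @slot nChroms integer, number of chromosomes (equal split of the length).
#' @slot backgroundProbs numeric 4-vector (A, C, G, T) summing to 1.
#' @slot motifs list of [PWMotif] to plant.
#' @slot nOCRs integer, number of ground-truth OCRs.
#' @slot ocrLengthMean,ocrLengthSD numeric, OCR length distribution in bp
#'   (truncated so every OCR is strictly longer than 200 bp).
#' @slot motifsPerOCR integer, motif instances planted per OCR.
#' @slot detectionRate numeric in (0, 1], per-OCR probability of appearing
#'   in the observed peak set.
#' @slot seed integer, generator seed.
#'
#' @seealso [syntheticSpec()], [defaultScenario()], [buildGenome()]
#' @export
setClass("SyntheticSpec",
    representation(genomeLength = "integer", nChroms = "integer",
                   backgroundProbs = "numeric", motifs = "list",
                   nOCRs = "integer", ocrLengthMean = "numeric",
                   ocrLengthSD = "numeric", motifsPerOCR = "integer",
                   detectionRate = "numeric", seed = "integer"))

setValidity("SyntheticSpec", function(object) {
    msg <- character()
    if (abs(sum(object@backgroundProbs) - 1) > 1e-8 ||
        length(object@backgroundProbs) != 4L)
        msg <- c(msg, "backgroundProbs must be 4 values summing to 1")
    if (object@detectionRate <= 0 || object@detectionRate > 1)
        msg <- c(msg, "detectionRate must be in (0, 1]")
    if (!all(vapply(object@motifs, is, logical(1), "PWMotif")))
        msg <- c(msg, "motifs must be a list of PWMotif objects")
    if (object@nOCRs * object@ocrLengthMean > 0.5 * object@genomeLength)
        msg <- c(msg, "total OCR footprint must stay below half the genome")
    if (length(msg)) msg else TRUE
})
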