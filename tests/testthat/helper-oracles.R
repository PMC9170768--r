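# Independent brute-force oracles used to validate the vectorized
# implementations. These deliberately take the naive route.

# AUROC as the pairwise concordance statistic P(s+ > s-) + 0.5 P(s+ = s-)
bruteAuroc <- function(scores, labels) {
    sp <- scores[labels == 1]
    sn <- scores[labels == 0]
    cmp <- outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b))
    mean(cmp)
}

# ROC/PR points by an explicit per-threshold confusion-count loop
bruteSweep <- function(scores, labels) {
    thr <- sort(unique(scores), decreasing = TRUE)
    nPos <- sum(labels == 1)
    nNeg <- sum(labels == 0)
    out <- data.frame(threshold = thr, tp = NA_real_, fp = NA_real_)
    for (i in seq_along(thr)) {
        pred <- scores >= thr[i]
        out$tp[i] <- sum(pred & labels == 1)
        out$fp[i] <- sum(pred & labels == 0)
    }
    out$tpr <- out$tp / nPos
    out$fpr <- out$fp / nNeg
    out$recall <- out$tpr
    out$precision <- out$tp / (out$tp + out$fp)
    out
}

bruteAuprc <- function(scores, labels) {
    sw <- bruteSweep(scores, labels)
    r <- sw$recall
    p <- sw$precision
    sum(diff(c(0, r)) * (c(p[1], p[-length(p)]) + p) / 2)
}

# all-pairs interval overlap scan
bruteIntersect <- function(a, b, minOverlap = 1L) {
    out <- NULL
    for (i in seq_along(a)) for (j in seq_along(b)) {
        if (as.character(GenomicRanges::seqnames(a)[i]) !=
            as.character(GenomicRanges::seqnames(b)[j])) next
        ov <- min(GenomicRanges::end(a)[i], GenomicRanges::end(b)[j]) -
            max(GenomicRanges::start(a)[i], GenomicRanges::start(b)[j]) + 1L
        if (ov >= minOverlap)
            out <- rbind(out, c(i, j, ov))
    }
    if (is.null(out)) return(data.frame(queryIdx = integer(0),
                                        subjectIdx = integer(0),
                                        overlap = integer(0)))
    data.frame(queryIdx = out[, 1], subjectIdx = out[, 2],
               overlap = out[, 3])
}

# per-base max aggregation by a plain double loop over windows and bases
bruteBaseScores <- function(starts, probs, width, chromLength) {
    score <- numeric(chromLength)
    for (i in seq_along(starts)) {
        for (b in (starts[i] + 1):(starts[i] + width)) {
            if (probs[i] > score[b]) score[b] <- probs[i]
        }
    }
    score
}

# exhaustive PWM alignment search, written independently of pwmSimilarity
brutePwmSimilarity <- function(a, b, minOverlap = 4L) {
    pa <- motifProbs(a)
    best <- -Inf
    for (orient in 1:2) {
        pb <- motifProbs(b)
        if (orient == 2) {
            pb <- pb[4:1, ncol(pb):1, drop = FALSE]
            rownames(pb) <- c("A", "C", "G", "T")
        }
        for (off in -30:30) {
            va <- c(); vb <- c()
            for (j in seq_len(ncol(pb))) {
                ja <- j + off
                if (ja >= 1 && ja <= ncol(pa)) {
                    va <- c(va, pa[, ja])
                    vb <- c(vb, pb[, j])
                }
            }
            if (length(va) >= 4 * minOverlap) {
                r <- suppressWarnings(cor(va, vb))
                if (!is.na(r) && r > best) best <- r
            }
        }
    }
    best
}

randomDna <- function(n, len) {
    vapply(seq_len(n), function(i)
        paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
              collapse = ""), character(1))
}

# a balanced dataset of n pairs of random fragments (no genome needed)
randomPairDataset <- function(nPairs, len = 20L, seed = 1L) {
    set.seed(seed)
    pos <- randomDna(nPairs, len)
    neg <- vapply(pos, function(s) shuffleNegative(s), character(1),
                  USE.NAMES = FALSE)
    seqs <- Biostrings::DNAStringSet(c(pos, neg))
    names(seqs) <- c(sprintf("pos_%d", seq_len(nPairs)),
                     sprintf("neg_%d", seq_len(nPairs)))
    methods::new("OCRDataset", sequences = seqs,
                 labels = c(rep(1L, nPairs), rep(0L, nPairs)),
                 pairId = c(seq_len(nPairs), seq_len(nPairs)),
                 partition = rep(NA_character_, 2L * nPairs),
                 fragmentLength = len)
}
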