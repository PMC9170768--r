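---
title: "OCRscan: model, design choices and validation strategy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{OCRscan: model, design choices and validation strategy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## What the method assumes

OCRscan rests on one biological premise: open chromatin regions (OCRs)
are enriched for clustered transcription-factor binding motifs, so a
classifier that learns those motifs — and the logic by which they
combine — from an assayed peak set can recognize accessible-looking
sequence anywhere in the genome, including tissues and conditions the
assay never sampled. Two modelling assumptions follow:

* **The negative class is a base-composition-matched shuffle.** Each
  positive fragment is paired with a permutation of its own letters.
  This guarantees balanced classes and identical mononucleotide
  composition, so the network cannot win by counting bases; it must find
  positional structure. It also means the classifier is *not* trained to
  distinguish open regions from arbitrary closed genomic sequence —
  see "Limitations".
* **Accessibility is recognizable at window scale.** Genome scanning
  scores 36 bp windows; the model must therefore transfer from
  peak-scale training fragments to short windows, which drives the
  architecture choice below.

## The network

Fragments are one-hot encoded (A, C, G, T as unit 4-vectors, N as zeros)
and passed through

```
conv(64 filters, 4 x 19, stride 1) -> ReLU -> dropout
conv(32 filters, 11, stride 1)     -> ReLU -> global max pool -> dropout
fully connected (200 units)        -> ReLU -> dropout
fully connected (1 unit)           -> sigmoid
```

trained with Adam on the binary cross-entropy loss; the epoch with the
lowest validation loss supplies the final weights. Everything is
implemented in vectorized base R: convolutions are im2col gathers
followed by BLAS matrix products, and the backward pass is the exact
adjoint (the test suite checks analytic gradients against central
differences at tolerance 1e-4).

**Why a global max pool.** Training fragments are peak-scale (200 bp by
default) while scanning windows are 36 bp. A flatten-to-dense head would
hard-wire the input length into the first dense layer, forcing either
36 bp training fragments or padded scan windows. Both fail for a
principled reason: a 36 bp slice of a ~250 bp peak usually misses the
motifs (so most "positive" windows would be indistinguishable from their
shuffles, capping achievable discrimination), and a dense head
calibrated on multi-motif peaks under-scores single-motif windows
because its response grows with motif *count*. Max pooling over
positions — the standard head of sequence-to-activity CNNs — makes the
score depend on motif *presence*, is invariant to fragment length down
to the 29 bp receptive field, and lets one set of weights serve both
training and scanning. The pooled feature vector is what the dense stack
flattens.

**Dropout: rate and placement.** Inverted dropout (survivors rescaled by
1/(1−p), inference untouched) follows every hidden layer. For the second
convolution it is applied to the *pooled* vector rather than the
pre-pool feature maps: dropping map entries before a max distorts the
pooled expectation (the max of rescaled survivors is biased upward
relative to inference), which we found mis-calibrates the sigmoid. The
reference dropout rate is 0.4 with batch size 32 and 60 epochs. A rate
of 0.6 is the better choice on assay-scale peak sets (tens of thousands
of peaks), where the vastly larger number of gradient updates averages
out the regularization noise; at desk scale (hundreds of peaks, a few
hundred updates) 0.6 keeps the optimizer pinned at the ln 2 saddle, so
the smaller default is used and 0.6 is exposed in the configuration.
`applyDropout()` itself defaults to p = 0.6, the canonical rate.

## Tunable parameters

| Parameter | Default | Unit | Why |
|---|---|---|---|
| `minPeakLength` | 200 | bp | strict lower bound on training peaks; longer fragments carry more signal |
| `fragmentLength` | 200 | bp | one window per peak, centered on its midpoint; equals the filter floor so every retained peak supplies a full fragment |
| `fractions` | 0.6/0.2/0.2 | — | train/validation/test split, largest-remainder rounding, positive+shuffle pairs kept together |
| `conv1Filters x conv1Width` | 64 x 19 | — x bp | width spans the 6–19 bp range typical of plant regulatory motifs |
| `conv2Filters x conv2Width` | 32 x 11 | — | combines first-layer motif detections into local arrangements |
| `fcUnits` | 200 | — | capacity of the decision layer |
| `dropout` | 0.4 | prob. | see above; 0.6 for assay-scale data |
| `learningRate`, `batchSize`, `epochs` | 1e-3, 32, 60 | — | Adam settings sized to desk-scale datasets |
| `thresholdFrac` | 0.5 | — | filter-to-motif harvesting: sites scoring above this fraction of the per-filter maximum; the established convention for sequence CNNs |
| `pseudocount` | 0.25 | counts/base | avoids log 0 in PWM columns with minimal distortion |
| scan `width`, `step` | 36, 5 | bp | window geometry; the step trades positional resolution against compute |
| `threshold` | 0.5 | prob. | the sigmoid decision point |
| `mergeGap` | 50 | bp | about ten steps; bridges jitter between adjacent high windows |
| `minLength` | 36 | bp | one window; discards fragments too short to be a credible OCR |

All of these are exposed in the YAML pipeline configuration; unknown keys
are rejected at load time.

## Coordinates and containers

Intervals live in `GRanges` (1-based, closed — the Bioconductor
convention) inside the package; BED files on disk are 0-based,
half-open, and the converters round-trip BED3 byte-identically. Genomes
and fragments are `DNAStringSet`s; lowercase (soft-masked) bases are
uppercased and used, and IUPAC ambiguity codes are mapped to N with a
warning, because the encoding defines exactly five symbols.

## The synthetic benchmark

`defaultScenario()` generates one 500 kb chromosome of uniform
background, 400 non-overlapping OCRs of ~250 ± 30 bp (truncated so all
exceed the 200 bp filter, and at least 50 bp apart, as separated assay
peaks would be), three instances of a single 12 bp planted motif
(1.6 bits/column mean information content) per OCR at random
non-overlapping offsets, and an "observed" peak set that keeps each true
OCR with probability 0.8 — emulating an assay that reveals only part of
the real repertoire. Generation is fully seed-deterministic, down to
byte-identical FASTA/BED outputs.

What this fixture *does* show: that the pipeline recovers a planted
sequence signal end to end — held-out discrimination, filter-to-motif
recovery, and base-level localization of unseen OCRs, all against exact
ground truth. What it does *not* show: performance on real chromatin,
where background composition is non-uniform, motif vocabularies are
large and degenerate, accessibility reflects more than motif content
(chromatin context, epigenetic state), and peak boundaries are noisy.
Passing the synthetic benchmark is a correctness statement about the
machinery, not an accuracy claim about any genome.

Problem sizes used in the shipped validation: the end-to-end benchmark
runs the 500 kb scenario once (about four minutes on one CPU); unit and
property tests use 30–120 kb scenarios and a shared small trained model;
the byte-level reproducibility check runs a reduced 40 kb configuration
twice, since byte identity is scale-free.

## Numerical choices

* Probabilities are clipped at 1e-7 inside the cross-entropy (log
  safety) and at 1e-12 when stored in probability tracks (sigmoid
  saturation can otherwise emit exact 0/1).
* `sigmoid` is computed in the two-branch numerically stable form, so
  ±1000 logits saturate without overflow.
* ROC/PR sweeps collapse tied scores into single operating points;
  AUROC integrates by trapezoid from an anchored (0, 0) and equals the
  pairwise concordance statistic exactly (tested against an O(n²)
  oracle); the PR curve is anchored at recall 0 with the precision of
  the most stringent threshold.
* The max pool breaks ties leftmost, making gradients and harvested
  argmax positions deterministic.
* Per-base aggregation of window scores takes the maximum over covering
  windows (sharpness-preserving at a 5 bp step); mean aggregation is
  available.
* Weight initialization is He-scaled Gaussian, seeded; training is
  fully deterministic given single-threaded BLAS.

## Peak calling

The built-in caller is deliberately simple — threshold (0.5), merge
(< 50 bp gaps), minimum length (36 bp), summit at the leftmost maximal
base — because the probability track is already smooth at a 5 bp step
and model-based background estimation (fragment pileups, local lambda)
addresses sequencing noise the scanner does not have. Users who want the
classic route can export above-threshold windows as scored BED
(`exportFragmentsBed()`) and run an external caller such as MACS2 on
them; per-base scores can also be exported as bedGraph.

## Known limitations

* Shuffled negatives mean the decision boundary is "motif structure vs
  none", not "open vs closed chromatin"; genome scanning therefore
  over-calls compositionally unusual but closed regions in real data.
* Only the forward strand is scanned by default; reverse-complement
  motifs score through filter symmetry, not explicit scanning.
* The scanner loads one chromosome string at a time; genomes are fine,
  but no streaming/indexed FASTA access is provided.
* Single-threaded by design for determinism; wall-clock scales linearly
  with genome size (about 15 s per 500 kb at the default settings).
* Motif similarity uses Pearson correlation on probability columns over
  ungapped alignments; it has no significance calibration and is meant
  for ranking filters against a known reference, not for database-scale
  motif matching.
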