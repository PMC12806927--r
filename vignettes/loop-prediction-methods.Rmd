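---
title: "Methods: sequence-based chromatin loop prediction by deep hybrid learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sequence-based chromatin loop prediction by deep hybrid learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

A chromatin loop is a pair of genomic *anchors* — short regions, here
treated as protein (CTCF or RNA polymerase II) binding sites — held
spatially close in the nucleus. `dhloop` asks whether the loop can be
recognised from the anchor sequences alone, framed as binary
classification of anchor *pairs*: label 1 for an observed interaction,
label 0 for a random background pair.

Each anchor is reduced to a fixed window: the anchor centre is
`floor((start + end) / 2)` and the window is the half-open interval
`[centre - flank, centre + flank)`, exactly `2 * flank` bases
(256 bp at the default `flank = 128`). A pair example is therefore a
512 bp payload, stored as `seq_a [SEP] seq_b`. Two representations are
derived from it:

* **k-mer frequency features.** Overlapping windows of width `k`
  (stride 1; `len - k + 1` windows) are counted in lexicographic slot
  order over `{A,C,G,T}^k`; windows touching an ambiguous base are
  excluded. Counts are divided by the number of valid windows
  ("frequencies"), so each anchor's vector sums to one; a raw-count
  mode is retained since either reading of "frequency" is defensible.
  The two anchor vectors are concatenated: `2 * 4^k` features, 128 at
  the default `k = 3`.
* **token streams.** The same k-mers act as tokens of a DNA language
  with a `4^k + 5` vocabulary: the specials `[PAD] [UNK] [CLS] [SEP]
  [MASK]` at indices 0–4, then the k-mers lexicographically. A pair
  tokenizes to `[CLS] tokens(seq_a) [SEP] tokens(seq_b) [SEP]`, padded
  to 515 positions (512 token slots plus the three boundary specials,
  mirroring the 256 bp-per-anchor limit of current DNA language
  models). Tokens touching an N map to `[UNK]`; the feature path
  instead drops those windows from the counts.

Three classical learners are trained on the feature vectors — an SVM
with radial-basis kernel and probability calibration, a random forest
whose score is the fraction of trees voting positive, and a
k-nearest-neighbour classifier whose score is the neighbour vote
fraction. Each emits aligned per-example labels (score ≥ 0.5) and
scores in [0, 1].

The deep route is specified as a contract — fit on pair examples,
predict aligned labels and scores from the tokenized form — so that a
fine-tuned transformer, an imported prediction file, or the built-in
stand-in are interchangeable from the fusion's point of view. The
package records the fine-tuning configuration used with a pretrained
DNA language model (learning rate 2e-4, warmup 10 %, weight decay 1 %,
hidden dropout 10 %, long-sequence backbone `dnalongcat`); pretraining
and fine-tuning such a model is deliberately out of scope (GPU-scale,
external weights), as is its masked-token pretraining objective, which
enters only through the inherited backbone.

### The stand-in deep classifier

The shipped stand-in embeds the tokenized stream segment-wise: the
average one-hot representation of each anchor's token segment (its
token-frequency vector over the vocabulary), concatenated so the pair
structure survives pooling, then a single-hidden-layer network (16
units, logistic output, cross-entropy loss, L2 decay equal to the
configured weight decay, at most 500 BFGS iterations). Inputs are
standardised with training-set means and standard deviations — the raw
frequencies are of order 1/254 and would otherwise be flattened by the
decay penalty. An earlier draft pooled both segments into a single
average; it consistently lost several accuracy points because pooling
discards which anchor carries which signal, and the segment-wise form
was adopted. The stand-in trains in seconds on one CPU at synthetic
scale and is deterministic given its seed.

### Decision fusion

Fusion is Boolean, on hard labels, exactly as defined:
`l_mv = [l_s + l_r + l_k >= 2]`, `f(t) = l_mv AND (l_s OR l_r OR l_k)`,
and the final decision `d OR f(t)`. The conjunct in `f(t)` is
redundant — a 2-of-3 majority implies at least one positive — so
`f(t) ≡ l_mv` on all eight input rows; the formula is evaluated as
written rather than simplified, and the identity is asserted
exhaustively in the tests. Two consequences are worth knowing:
the fused positive set is a superset of the deep model's and of the
majority vote's, so fused recall dominates both (at a precision cost
when the routes disagree); and because fusion consumes labels, the
fused "score" is the label itself — ROC AUC of the fused output is
degenerate and flagged `auc_label_only` in reports rather than omitted.

## Dataset construction

From a FASTA genome and BEDPE anchor pairs (0-based half-open
throughout; the convention is fixed by the package, since interaction
files in the wild are BEDPE-native):

1. **Filtering.** Keep intra-chromosomal loops whose centre-to-centre
   distance is at most 1 Mb — inclusive, i.e. exactly 1 Mb survives;
   the cap is configurable — and whose two centred windows lie within
   the chromosome. Distance is centre-to-centre because the centres
   define the extracted windows.
2. **Negative sampling.** `round(ratio * n_pos)` background pairs
   (default ratio 1) are drawn by rejection sampling: each negative is
   placed on the chromosome of a matched positive, with centre distance
   uniform on `[2 * flank, 1 Mb]` (an alternative mode resamples the
   empirical positive distances), both windows in bounds, at most 10 %
   N per window, and neither window overlapping *any* positive anchor
   window — "excluding the positive data" is enforced as window-overlap
   exclusion, which is stricter than exact-coordinate exclusion and
   testable. Matching chromosomes per positive makes the 1:1 balance
   hold within every chromosome, hence within the training and holdout
   splits separately; genome-wide balancing alone would not guarantee
   that.
3. **Extraction.** Plus-strand sequence of both windows (strand is
   never specified for interaction anchors; the choice is recorded
   here). Positive examples with more than 10 % ambiguous bases in a
   window are dropped before negatives are drawn, so the balance is
   exact; for negatives the N-rule is part of the rejection predicate.
4. **Holdout split.** Examples whose chromosome is in the holdout set
   (chr9 by default) form the test set; balancing happens before the
   split, matching the order in which the protocol is usually stated.

The whole build is a pure function of (genome, positives,
configuration) including the seed; byte-level determinism is asserted
in the tests.

## The synthetic data generator

The simulator stands in for a real ChIA-PET study so that every stage,
and the planted-signal recovery tests, run with no downloads. It
emulates: a multi-chromosome genome of i.i.d. random bases; positive
loops whose two anchors carry planted motifs; negatives from motif-free
background (drawn by the dataset builder, not the simulator, mirroring
the random-background negative protocol); loop lengths bounded by a
cap; and a held-out chromosome.

Defaults, chosen once as a plausible desk-scale miniature of a human
CTCF loop study:

| parameter | default | why |
|---|---|---|
| chromosomes | 4 × 500 kb (chr1–chr3, chr9) | smallest genome that exercises a multi-chromosome holdout; ~2 Mb total keeps a full run under a minute |
| loops | 500 | ~1000 balanced examples, enough for stable holdout estimates (~240 test examples) |
| motif pair | `TGGCCACCAGGGGGCGCTA` / reverse complement | a JASPAR-style 19 bp CTCF consensus in convergent orientation, the dominant geometry at real CTCF loops |
| motif_prob | 1.0 | the recovery benchmark plants the signal in every positive anchor; 0 gives the matched null |
| loop lengths | uniform 256 bp – 100 kb | sub-domain scale; the cap adapts downward for short test chromosomes |
| base composition | A/T 0.295, C/G 0.205 | the ~41 % GC of the human genome, which also gives the GC-rich consensus its natural contrast against background |

Motifs *overwrite* the anchor centre rather than inserting, so all
coordinates stay valid and windows keep their length; every insertion
is recorded in a truth manifest that the tests check against the
genome. Anchor neighbourhoods (±200 bp) are kept pairwise disjoint
across loops so extraction windows never overlap.

What the simulator does **not** model — and therefore what passing
tests do not show about real data: sequence context beyond i.i.d.
composition (no CpG depletion, repeats, or isochores), motif strength
variation (a fixed consensus, not a position weight matrix), anchor
calling noise, cell-type specificity, and any relationship between
loop span and signal. The planted-signal benchmark measures whether
each learner can recover a known, clean signal through the full
pipeline; accuracy on real ChIA-PET interactions will be lower for
every route, and real benchmarks additionally require the pretrained
deep model that is out of scope here.

## Evaluation protocol and numerical choices

* **Metric panel**: accuracy, precision, recall, F1, Matthews
  correlation, ROC AUC and precision-recall AUC. Any 0/0 ratio returns
  0 with an explicit `degenerate` flag rather than NaN — degenerate
  cases are reported, never silently dropped.
* **ROC AUC** is the rank statistic (probability a random positive
  outscores a random negative, ties ½, via average ranks), identical
  to trapezoidal ROC integration and cross-checked in the tests against
  an all-pairs enumeration and against an independent reference
  implementation. **AUPRC** uses step-wise interpolation (the
  average-precision convention), evaluated at the last index of each
  tied-score block.
* **Cross-validation** is stratified 5-fold: within each class,
  examples are shuffled under the fold seed and dealt round-robin, so
  per-class fold sizes differ by at most one and each example is tested
  exactly once. The reported average is the arithmetic fold mean.
  Whole-data ("WD") training — one model on the full training split,
  evaluated only on the chromosome holdout — is the mode carried into
  fusion, since fold-level model selection is not reconstructable from
  the usual statement of the protocol and WD puts the classical models
  on the deep model's footing.
* **Determinism**: one global seed derives a stage seed per component
  (simulation, negative sampling, per-algorithm fold assignment and
  training, the stand-in) via a fixed integer hash kept below 2^31, so
  stages are independently reproducible and two runs with one seed are
  byte-identical, which the tests assert on the serialised report.
* **Tie-breaks and edge cases**: anchor centres use the floor midpoint;
  the distance cap is inclusive; an even-length anchor's ±flank window
  is half-open, resolving the boundary to exactly `2 * flank` bases;
  KNN with the default 5 neighbours cannot tie on votes in a binary
  problem, and its (rare) distance ties are resolved under the stored
  model seed.

## Problem sizes used by the shipped checks

Module tests run on reduced simulations (2–3 chromosomes of 50–200 kb,
20–150 loops) chosen so the whole suite stays interactive; the
planted-signal benchmark runs the full default conditions (4 × 500 kb,
500 loops) at motif probabilities 0, 0.5 and 1. These sizes are the
package's own test design, balancing statistical resolution (about 240
holdout examples gives a 3σ binomial band of ±0.097 around chance)
against runtime.

## Known limitations

* The k-nearest-neighbour route is structurally weak here: a single
  19 bp motif per 256 bp window shifts only ~15 of 128 feature
  dimensions by fractions of their noise standard deviation, and
  nearest-neighbour distances in 128 dimensions are dominated by the
  unshifted coordinates. On the synthetic defaults KNN plateaus around
  0.76–0.83 holdout accuracy (across seeds and neighbour counts up to
  61) while SVM, RF and the stand-in exceed 0.9 — consistent with KNN
  being the weakest learner in published sequence-pair benchmarks. The
  package reports it as is.
* Fusion is fixed Boolean majority/OR; no stacking, weighting or
  probabilistic fusion is provided, and fused scores are labels.
* The deep route's scientific ceiling (a fine-tuned transformer) is
  represented by contract only; the stand-in demonstrates the pipeline
  and the fusion algebra, not transformer-level accuracy on real data.
* Only intra-chromosomal loops up to the distance cap are modelled;
  inter-chromosomal contacts are filtered out by design.
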