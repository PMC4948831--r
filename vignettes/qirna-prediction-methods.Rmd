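---
title: "Methods: positional log-odds features for qiRNA-like small RNA prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: positional log-odds features for qiRNA-like small RNA prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

qiRNAs are ~20–21 nt DNA-damage-induced small interfering RNAs of
*Neurospora crassa*. At this length there is no usable secondary structure
and no reported cross-species conservation, so the discriminative signal
this package exploits is positional composition: a strong preference for U
at the first (5′) base and for A at the last (3′) base, with weaker
structure at the other terminal positions.

The model is deliberately simple. For a window width $w$ (default 10),
position probability matrices (PPMs) are estimated over the signed position
set $j \in \{1..w\} \cup \{-1..-w\}$ — $j$ counts from the 5′ end, $-j$
from the 3′ end — separately for the positive and negative training sets:
$P_{ij}$ and $N_{ij}$ are the fractions of sequences carrying nucleotide
$i$ at position $j$. Each (nucleotide, position) pair gets a log-odds score

$$S(i,j) = \log_2 \frac{P_{ij}}{N_{ij}},$$

set to 0 when $P_{ij} = N_{ij}$ (no information) and also when either
probability is 0: at a training size of a few hundred sequences a zero cell
reflects sampling, not impossibility, and the guard avoids infinite scores
without introducing a smoothing parameter. An optional additive
`pseudocount` is available for users who prefer smoothing; it is 0 by
default because the zero-score guard already handles the degenerate cells.

A sequence is encoded as the $8w$-vector of one-hot-masked scores: the
entry for $(i, j)$ is $S(i,j)$ if the sequence carries $i$ at $j$, else 0.
This is a genuine design decision rather than a forced consequence of the
model: the score matrix itself is a single global object, and only a
per-sequence encoding lets one compute per-feature F-scores and train a
classifier. A `binary` mode (plain 0/1 indicators) is provided for
sensitivity analysis; with score weighting the forest sees the effect size
of each observed base, not just its identity.

Two further featurization rules matter for short sequences:

* Sequences shorter than $2w$ contribute the same base to an overlapping
  pair of positions $j$ and $-j'$; both cells are counted. This keeps both
  windows fully defined for every contributing sequence and makes every
  PPM column an exact probability distribution.
* Sequences shorter than $w$ cannot fill either window and are skipped,
  with the skipped count reported — never silently dropped. They reappear
  in prediction output as explicitly skipped identifiers.

k-mer frequency features (all words of length 1..k, overlapping counts
divided by $L-m+1$; 1364 dimensions at k = 5) are provided as the standard
composition-based alternative, and `combine_features()` concatenates the
two classes with name prefixes.

## F-score ranking

Per-feature discrimination is measured by the F-score,
$$F(i) = \frac{(\bar x_i^{+}-\bar x_i)^2 + (\bar x_i^{-}-\bar x_i)^2}
{\tfrac{1}{n_+-1}\sum_k (x^{+}_{k,i}-\bar x^{+}_i)^2 +
 \tfrac{1}{n_--1}\sum_k (x^{-}_{k,i}-\bar x^{-}_i)^2},$$
a ratio of between-class separation to pooled within-class variance. Two
degenerate cases are defined explicitly: a constant feature (0/0) scores 0;
perfect separation with zero within-class variance scores flagged-infinite
and sorts first. On data generated with the default terminal enrichment the
features `1U` and `-1A` dominate the ranking, which is the qualitative
behavior the encoding is designed to capture.

## Classifier

The forest is the off-the-shelf `randomForest` implementation behind a
thin contract — bagging plus random feature subsets is standard machinery,
and the package's contribution lives in the features and dataset
construction, not in tree induction. Defaults are 500 trees and
$\lfloor\sqrt d\rfloor$ features per split (the upstream package defaults;
no hyperparameter search is performed). The prediction score is the
fraction of trees voting positive, so it lives on $[0,1]$ and the decision
cutoffs (default 0.5, stringent 0.667 — ties go positive) are vote
fractions. The training-time score matrix is bundled inside the model:
novel candidates must be featurized with the *training* PPM statistics,
never with statistics of the query set, or the encoding would change
meaning between training and prediction. Out-of-bag accuracy (each tree's
bootstrap omits about $e^{-1}$ of the samples) is recorded on the model as
a free internal estimate.

Class weighting is off by default even for imbalanced designs such as 155
positives against 325 curated negatives; a `balanced` option downsamples
each bootstrap to the minority class when required.

## Negative-set construction

Two negative styles are built from any user-supplied non-coding RNA pool:

* **Fragment negatives** — the pool sequences are cut left-to-right into
  contiguous, non-overlapping segments whose lengths are drawn from the
  positives' length histogram proportionally to remaining demand. No
  cutting rule beyond non-overlap is canonical; the greedy seeded rule
  guarantees demand coverage whenever capacity suffices and raises an
  explicit shortfall error (listing the deficient lengths) otherwise.
* **Random negatives** — the same segments, each additionally replaced by a
  uniformly random permutation of its own characters to destroy any
  functional structure while preserving composition. One uniform
  permutation is distributionally equivalent to composing many, so a single
  Fisher–Yates pass is the default; a `rounds` argument exists for literal
  reproduction of repeated-shuffle protocols. Shuffling is mononucleotide;
  a dinucleotide-preserving mode is not implemented.

Candidates are over-generated (factor 2) so that any candidate identical to
a positive sequence can be rejected and replaced before the final
length-matched sample; the final sample is drawn without replacement,
per-length, so the negative histogram equals the positives' *exactly* (no
off-by-one tolerance). Shuffling happens before length-matched selection.
Curated negative sets (e.g. fungal milRNAs) are ordinary FASTA inputs and
need no construction.

## Cross-validation

Folds are stratified by class and seeded; leave-one-out is k-fold with
k = n. Inside every fold the PPMs and the score matrix are rebuilt from the
training partition only. This fold-local featurization is the package's
default because computing PPMs globally lets held-out labels contaminate
the features; the leaky variant is available as `global_ppm = TRUE` (it
warns) for measuring exactly how much the leak inflates performance.
Held-out scores are pooled across folds into a single confusion matrix per
cutoff and a single ROC — leave-one-out forces pooling, and using the same
convention for k-fold keeps schemes comparable. Per-fold accuracies are
reported alongside. A fold whose training partition contains one class is
an error naming the fold.

Metrics are the standard confusion-matrix set: Sn, Sp, Ac (percent, printed
to 2 decimals) and MCC; with a zero marginal the MCC is reported as 0 and
flagged rather than NaN. For balanced evaluation sets Ac = (Sn + Sp)/2
exactly, which the tests use as an identity check. ROC curves sweep the
threshold over distinct scores with AUC by the trapezoidal rule, equal to
the tie-corrected Mann–Whitney concordance; the suite cross-checks this
against both an $O(n^2)$ pair-counting oracle and pROC.

## Synthetic data: what it does and does not show

The generator emulates the data shapes the method assumes: lengths split
evenly between 20 and 21 nt, positives with U at position 1 (probability
0.8) and A at the last position (probability 0.7) over an otherwise uniform
background, negatives fully uniform. The signal strengths are package
choices — strong enough that class separation is stable at the study size
of 155 + 155 — and are *not* measured frequencies from any real dataset.
Only the two documented terminal preferences are simulated; real qiRNAs
show weaker structure at other terminal positions, real background pools
are compositionally biased, and curated negatives (milRNAs) share the 5′-U
preference, all of which make the real problem harder. Passing the
end-to-end checks therefore demonstrates that the pipeline recovers a
planted positional signal without leakage, not that any particular
accuracy will be achieved on biological data.

Problem sizes used by the test suite and the acceptance script: parameter
recovery on 2 000 generated positives (binomial 3-SE bounds);
leave-one-out cross-validation at 155 + 155 with 500-tree forests, both
with the default signal (expected AUC well above 0.8) and with the signal
removed (`pos_first_U = pos_last_A = 0.25`), where the AUC must fall back
to the chance band [0.4, 0.6].

## Numerical and interface choices

* All randomness is seeded and routed through `withr::with_seed`, so every
  generator, shuffle, fold assignment and forest is reproducible and the
  caller's RNG state is never touched.
* PPM column sums equal 1 to 1e-9; score/F-score computations are checked
  against brute-force oracles at 1e-9.
* Classification ties (score == cutoff) go positive, documented and tested.
* FASTA is read and written through Biostrings; sequences are written
  single-line so files round-trip byte-for-byte. T is silently normalized
  to U (one internal alphabet); any other non-ACGU character marks a
  sequence as ambiguous for `filter_ambiguous()`. Duplicate removal is
  exact full-string identity after normalization — strand or orientation
  variants are not collapsed.
* Models are serialized with version metadata; loading a foreign or
  version-mismatched file is an explicit error.
* TSV outputs carry a one-line provenance header (`#` prefixed: version,
  command, seed, timestamp) so reruns are byte-comparable apart from that
  line; reports are JSON.

## Known limitations

* The per-sequence encoding of the 80 score features is one interpretation
  (one-hot-masked scores); a global score vector cannot train a
  per-sequence classifier, but other per-sequence encodings (e.g. binary
  indicators) are possible and exposed via `binary`.
* No secondary-structure or precursor features; no gapped k-mers; no
  feature selection beyond the F-score ranking.
* Dinucleotide-preserving shuffling is not implemented; shuffled negatives
  preserve mononucleotide composition only.
* Cross-validation runs a single seeded split per scheme; repeat with
  different seeds to estimate split variance.
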