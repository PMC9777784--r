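---
title: "Curriculum batching for long-tailed multi-label text classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curriculum batching for long-tailed multi-label text classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Automatic ICD coding assigns a *set* of diagnosis codes to a free-text
clinical note. Two properties make it a hard multi-label problem. First,
the label space is enormous (thousands of codes) and severely long-tailed:
a handful of codes account for most incidences while the bulk of the
catalog appears in only a few documents. Second, models are trained by
minibatch gradient descent (MBGD), and under the standard shuffle batching
each minibatch is a small random subset whose *local* label distribution
fluctuates around the global one — and systematically starves the rare
codes of gradient signal. In practice a shuffle-trained classifier learns
the head of the catalog and ignores the tail: micro-averaged F1 looks
respectable while macro-averaged F1 (which weights every label equally)
collapses.

Curriculum batching addresses this by building three batch sets offline
from the same training corpus, each with a different label exposure, and
training on them in sequence from easy to hard:

* **UDD** (uniform) via *stratified sampling with replacement* (SSR):
  each batch draws `M` labels uniformly at random over the training label
  set, then one example uniformly (with replacement) from each drawn
  label's stratum — the examples whose label set contains it. Every code,
  however rare, gets the same expected exposure.
* **SDD** (shuffled) via plain shuffle batching: a seeded permutation of
  the corpus cut by a sliding window of size `M` into
  `K = ceiling(|D|/M)` batches.
* **IDD** (identical-to-global) via *probability sampling with
  replacement* (PSR): as SSR, except the `M` labels are drawn i.i.d. from
  the *empirical* label distribution, so each batch's exposure tracks the
  global distribution.

All three batch sets have `ceiling(|D|/M)` batches so that one pass over
any of them costs one epoch. The default schedule trains 50 epochs on
each in the order UDD → SDD → IDD (150 in total); `build_schedule()`
accepts arbitrary phase lists for ablations (shuffle-only, UDD+SDD, ...).

## Batch-set difficulty diagnostics

How far a batch set's label exposure sits from the global training
distribution is quantified with the Kullback–Leibler divergence (natural
log, direction `KL(batch set || corpus)`) and the Jensen–Shannon
*distance* (the metric square root of the JS divergence, bounded by
`sqrt(ln 2)`).

A design point deserves emphasis. A shuffled batch set *partitions* the
corpus, so the label distribution of all its batches pooled together is
exactly the corpus distribution — pooled divergences are identically zero
for SDD and say nothing about it. What drives minibatch gradient noise is
the *batch-level* mismatch, so `difficulty_report()` computes, by
default, the divergence between each single batch's label distribution
and the global one and averages over batches (`aggregate = "per_batch"`).
Under this measure the expected ordering on long-tailed corpora is
UDD > SDD > IDD for both divergences: uniform exposure is farthest from
the data, random subsets fluctuate in between, and distribution-matched
sampling is closest. The pooled variant remains available
(`aggregate = "pooled"`) and is useful for auditing the samplers'
marginals (it is 0 for SDD and near 0 for IDD). Because UDD batch sets can
miss rare labels entirely, the KLD applies additive smoothing
(`epsilon = 1e-10`, both arguments, then renormalization); the KL
orientation is flippable via `direction`.

## The synthetic corpus generator

Real ICD-coded corpora are access-restricted, so the package ships a
seeded generator of structurally similar corpora; it is first-class,
tested code, and every claim below is computed on its output.

Each document draws a label count from a Poisson distribution (clipped to
configured bounds), then that many *distinct* labels with probability
proportional to a Zipf rank-frequency law `P(r) ∝ r^(-s)`. Tokens are a
mixture: with probability `signal_strength` a token comes from the token
block of one of the document's labels (blocks are disjoint slices of
roughly half the vocabulary), otherwise from a shared background block.
The per-label blocks guarantee the labels are learnable from the text by
a small classifier.

What the generator does **not** emulate: clinical language (tokens are
symbols, not words), label co-occurrence structure beyond what joint
Zipf draws induce, section structure, or shared vocabulary between
labels. Passing tests therefore demonstrate the *mechanics* of the
samplers, schedule, metrics and trainer and the *direction* of the
training effects on long-tailed data — not clinical performance.

Two reference corpora recur throughout the tests:

* **Sampler-study corpus** (the `synth_config()` defaults): 2,000
  documents, 200 labels, Zipf exponent 1.2, ~3 labels per document
  (clipped to 1–8), 100–300 tokens per document, batch size 100. At
  full scale a document carries ~11 of ~7,000 codes, i.e. touches ~0.2%
  of the catalog; when the catalog is scaled down ~35x, keeping 11
  labels per document would make every batch cover most of the catalog
  and erase the batch-level distribution differences under study, so the
  per-document label count is scaled down with it.
* **Training-study corpus** (`training_study_config()`): 2,000 documents,
  50 labels, Zipf exponent 1.8, ~2 labels per document, 60–120 tokens,
  vocabulary 1,000. The sharper exponent keeps the tail genuinely rare
  (the bottom half of the catalog has at most a few dozen training
  documents) at a catalog size small enough for minutes-scale training.

## The reference classifier and training loop

The bundled model is a small convolutional text classifier: an embedding
table (with dedicated padding and unknown-token rows), parallel
convolutions of widths 2/3/4 with max-over-time pooling, and a linear
layer to one logit per label. The loss is the numerically stable sigmoid
binary cross-entropy on logits, averaged over all example × label cells;
the per-batch gradient is the average over the batch's examples, and
parameters are updated by Adam. Forward and backward passes are written
directly in matrix algebra, and the backward pass is verified against
finite differences in the test suite. The model is deliberately a
*contract*: `train_classifier()` only needs init/forward/backward, so
other architectures can be slotted in.

Defaults follow the conventional full-scale protocol: Adam with learning
rate 0.008, 150 epochs as UDD 50 / SDD 50 / IDD 50, decision threshold
0.5 (a score ≥ 0.5 predicts the label; chosen as the standard convention
since no decision rule is forced by the loss), batch sets built offline
once and reused across the epochs of a phase, and a 7:1:2
train/validation/test split (validation and test sizes are the floors of
their shares; the remainder goes to training). Validation micro-F1 can
drive best-epoch selection (`select_best = "micro_f1"`); the bundled
study uses final-epoch parameters so that both arms see identical
selection.

## The bundled training study and its conditions

The study compares the full curriculum (30 epochs as 10/10/10) against
shuffle-only training (`sdd:30`) at equal epochs, three seeds, on the
training-study corpus, reporting test macro-F1 and long-tailed
precision/recall.

Three of its conditions were set by scaling arguments rather than the
full-scale defaults, and they matter:

* **Step size 0.0025 rather than 0.008.** The curriculum effect is an
  optimization-trajectory phenomenon: it exists while training is still
  far from convergence, which is the regime full-scale ICD models occupy
  for all 150 epochs (their shuffle baselines end with macro-F1 of a few
  percent). The reference network on the desk-scale corpus *saturates
  within a handful of epochs* at 0.008, after which every batching
  strategy reaches the same optimum and the comparison degenerates. At
  0.0025 the 30-epoch budget is genuinely under-converged, which is the
  honest desk-scale analogue of the full-scale regime.
* **Long-tail threshold `gamma = 30`** (training documents). The
  package default of 219 is the customary full-scale choice; on a
  ~7,000-code catalog it marks the overwhelming majority of codes as
  long-tailed, including codes with up to a couple of hundred positive
  documents. A literal proportional rescaling to this study's
  1,400-document training split (≈ 8) would instead isolate labels with
  at most 7 training documents, whose recall is near zero under every
  training arm and which therefore measure nothing. `gamma = 30` marks
  roughly the bottom three quarters of the 50-label catalog, matching the
  *coverage* of the full-scale convention. The package default for
  `longtail_metrics()` remains 219.
* **Final-epoch parameters** for both arms, so that model selection
  cannot differ between them.

Under these conditions the curriculum arm consistently dominates the
shuffle arm on macro-F1 and long-tailed recall (with micro-F1 at least
comparable), reproducing the qualitative full-scale finding: balanced
early exposure buys the tail without costing the head.

## Loss behavior at phase switches — a known desk-scale limitation

At full scale, the training loss shows a steep rise then drop at each
curriculum switch (epochs 50 and 100): the batch distribution changes
abruptly and the model must re-adapt. At the desk scale used here, the
SDD → IDD switch reproduces that rise reliably, but the UDD → SDD switch
does **not** — the loss *drops*. The reason is structural. At full scale
the batch size is a small fraction of the label count (M/L ≈ 0.14), so
uniform label draws barely perturb a batch's label mix and the UDD phase
converges to a low loss before the switch. At the desk-scale sizes
(M = 100, L = 50, M/L = 2) every UDD batch is dominated by heavily
oversampled, still-unlearned tail labels, so in the under-converged
regime the UDD epoch losses sit well above the following SDD epoch losses
and the switch can only fall. The corresponding check in the acceptance
suite is asserted as stated and fails by design at this scale; the
SDD → IDD half holds on every seed.

## Numerical and procedural choices

* **Seeding.** One root seed; every stage (generation, split, each
  sampler, initialization) forks its own stream via `fork_seed()`, so
  runs are bit-reproducible (`run_experiment()` writes a manifest of file
  checksums; identical configs produce identical manifests).
* **TF-IDF vocabulary truncation.** Corpus-level score
  `tf(t) · ln(N/df(t))` (total term frequency × unsmoothed IDF), ties
  broken by total frequency then lexicographically; a token in every
  document has IDF 0 and ranks last. This is the simplest deterministic
  corpus-level aggregate; it is encapsulated in `build_vocabulary()` and
  swappable.
* **Cleaning.** Lowercase; punctuation characters become spaces;
  whitespace tokenization; digit-only tokens and stopwords (a pinned,
  packaged English list, overridable) are removed. The operation is
  idempotent.
* **Sampling conventions.** Within-stratum draws are uniform with
  replacement; duplicate examples within a UDD/IDD batch are permitted;
  the shuffle's short remainder batch is kept. UDD/IDD batch sets retain
  their label draws (`$drawn_labels`) so the sampler marginals can be
  audited directly.
* **Statistical checks.** "Each count within 3σ" assertions over many
  labels are applied family-wise (Bonferroni-adjusted z threshold at the
  3σ family error level, plus a chi-square goodness-of-fit check at the
  3σ level where expected counts are small); a literal per-label 3σ rule
  over 200 labels would fail ~40% of the time by construction.
* **Metric conventions.** Any precision/recall with a zero denominator
  is 0. Macro precision/recall average the per-label rates over the
  *full* catalog (labels absent from the evaluation set included under
  the 0/0 rule), and macro-F1 is the harmonic mean of those two averages
  — not the mean of per-label F1 scores. Long-tail label frequencies are
  counted on the training split (strictly below `gamma` qualifies).
* **Degenerate inputs.** Empty corpora are valid (with a warning) and
  yield all-zero statistics; a batch size above the corpus size yields a
  single batch with a warning; zero-epoch schedules return the initial
  parameters untouched; an infinite KLD at `epsilon = 0` is reported as
  `Inf`, not an error.

## Problem sizes

All bundled studies are sized for minutes-scale CPU execution: the
sampler and divergence diagnostics run on the 2,000-document/200-label
corpus in seconds, and the full training study (two arms × three seeds ×
30 epochs) completes in a few minutes. The same code paths scale to
larger corpora; only wall time changes.

## Known limitations

* The trainer is plain R matrix algebra — faithful and verifiable, but
  not a replacement for GPU-scale deep learning tooling.
* The generator's independence assumptions (labels drawn independently
  per document, disjoint token blocks) make the task *more* separable
  than clinical text; directional results transfer, absolute metric
  values do not.
* Only the convolutional reference architecture is bundled; recurrent
  variants are out of scope, though the training contract admits them.
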