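# curribatch

Curriculum batching for long-tailed multi-label text classification in R.

## The problem

Automatic ICD coding — predicting the set of diagnosis codes carried by a
clinical note — is multi-label classification over a catalog of thousands
of codes whose frequencies are severely long-tailed. Models trained by
minibatch gradient descent with ordinary shuffle batching learn the head
of the catalog and starve the tail: each random minibatch's *local* label
distribution both fluctuates around and systematically under-represents
the rare codes, so micro-averaged F1 looks fine while macro-averaged F1
collapses.

`curribatch` implements a curriculum batching strategy for this setting,
aimed at practitioners and researchers studying batch construction under
label imbalance. Three batch sets are built offline from the training
corpus D with batch size M, each with a different label exposure, and
trained in sequence from easy to hard:

| batch set | sampler | label exposure per batch |
|-----------|---------|--------------------------|
| B_UDD | stratified sampling with replacement (SSR): draw M labels uniformly over the training label set, then one example uniformly (with replacement) from each drawn label's stratum | uniform over labels |
| B_SDD | shuffle: a seeded permutation of D cut by a sliding window of size M | random subsets of the data |
| B_IDD | probability sampling with replacement (PSR): as SSR but labels drawn i.i.d. from the empirical label distribution | matched to the global distribution |

Every batch set has ceiling(|D|/M) batches, so one pass over any of them
costs one epoch; the default schedule is UDD 50 → SDD 50 → IDD 50 with
Adam (learning rate 0.008) and the sigmoid binary cross-entropy
`-mean(y·log σ(x) + (1-y)·log(1-σ(x)))` on the logits of a pluggable
classifier (a small convolutional text model with a hand-verified
backward pass is bundled).

The distance between each batch's label distribution and the global one —
the "learning difficulty" of a batch set — is measured with the
Kullback–Leibler divergence and the Jensen–Shannon distance, averaged
over batches; on long-tailed corpora they order UDD > SDD > IDD.
Evaluation covers micro/macro precision/recall/F1 (macro-F1 as the
harmonic mean of catalog-averaged precision and recall) and long-tailed
precision/recall pooled over the labels with training frequency below a
threshold γ.

Everything is exercised on a bundled generator of synthetic long-tailed
corpora (Zipf label frequencies, label-specific token blocks), so no
restricted clinical data is needed.

## Worked example

```r
library(curribatch)

# 1. a synthetic long-tailed corpus (2,000 docs, 200 labels, Zipf 1.2)
corpus <- generate_corpus(synth_config(seed = 42))
corpus_stats(corpus)

# 2. split 7:1:2, build the TF-IDF vocabulary, encode
splits <- split_corpus(corpus, c(0.7, 0.1, 0.2), seed = 42)
vocab  <- build_vocabulary(splits$train, top_k = 5000)
enc    <- lapply(splits, encode_corpus, vocab = vocab)

# 3. the three batch sets (M = 100) and their difficulty
bs <- build_batchsets(enc$train, 100, seed = 42)
as.data.frame(difficulty_report(bs, enc$train))
```

```
Corpus statistics
  examples: 2000   unique labels: 199
  words  per example: avg 198.60 (min 100, max 300)
  labels per example: avg 3.02 (min 1, max 8)

  kind   kld   jsd n_batches
1  UDD 0.376 0.292        14
2  SDD 0.260 0.267        14
3  IDD 0.227 0.249        14
```

The uniform batch set is farthest from the corpus distribution, the
shuffled one in between, the distribution-matched one closest — harder
batch sets are more like the raw data.

The bundled training study compares the full curriculum against
shuffle-only training at equal epochs (30, as 10/10/10) on a 50-label
corpus with a severely rare tail, three seeds:

```r
study <- training_study_config()
runs <- lapply(1:3, function(s) list(cur = run_training_arm(s, study$curriculum),
                                     base = run_training_arm(s, study$baseline)))
```

```
mean over 3 seeds (curriculum | shuffle-only):
  macro-F1           0.243 | 0.179
  micro-F1           0.914 | 0.891
  long-tailed recall 0.073 | 0.020
```

Balanced early exposure buys the rare labels (macro-F1, tail recall)
without costing the common ones (micro-F1). Individual seeds vary; the
comparison is a mean over seeds by protocol.

End-to-end runs with one config file (simulate → preprocess →
make-batches → diagnose → train → evaluate, all seeded, with a checksum
manifest) are available as `run_experiment()`, or from the shell:

```sh
Rscript inst/cli/curribatch.R run --seed 1 --schedule "udd:10,sdd:10,idd:10" --out-dir runs/curriculum
Rscript inst/cli/curribatch.R compare --dirs runs/curriculum,runs/baseline
```

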