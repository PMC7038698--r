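---
title: "Zero-shot activity recognition from ambient sensors: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Zero-shot activity recognition from ambient sensors: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(adlzero)
```

## The problem and the model

Smart homes instrumented with binary ambient sensors (motion `ON`/`OFF`,
doors `OPEN`/`CLOSE`) log a timestamped event every time a sensor changes
state, and annotated corpora additionally mark where each activity of daily
living begins and ends. A supervised classifier trained on such logs can
only ever output the labels it was trained on. The zero-shot approach
implemented here removes that ceiling by routing recognition through
language: activity *names* live in a word-embedding space, and a model that
learns to map sensor statistics of seen activities onto their name vectors
can score the name vectors of activities it has never observed.

Formally, a labeled training set (X_tr, Y_tr, T_tr) of seen activities and
a test set (X_ts, Y_ts, T_ts) of unseen ones satisfy T_tr ∩ T_ts = ∅. Each
label t has a semantic class prototype Y(t) ∈ ℝ^L; here the prototype of a
multi-word label is the unweighted mean of its tokens' word vectors
(lowercased, split on spaces, underscores and camel-case boundaries, so
"WashDinnerDishes" → wash, dinner, dishes). The mean is the standard
composition convention; nothing in the method constrains the choice, and it
has the testable property that repeated tokens leave the prototype
unchanged.

An activity instance is summarized by its activation counts: entry j of its
feature vector is the number of `ON`/`OPEN` events its j-th sensor emitted
between the instance's begin and end annotations (inclusive). We treat
`OPEN` as an activation alongside `ON` so door sensors participate;
`OFF`/`CLOSE` transitions contribute nothing. Stacking instances gives the
count matrix **R** ∈ ℕ^(m×n). Counting is order-free and conserves the
total number of in-vocabulary activations — both properties are tested.

The mapping F is a shallow network,

    x → dense(128, SELU) → dense(L, SELU) → [batch norm] → W → softmax,

whose final layer W (L×K_seen) holds the seen-class prototypes as fixed,
non-trainable columns: it is literally a matrix multiplication at the end
of the network. We L2-normalize the columns so each logit is proportional
to the cosine between the L-dimensional activation and the corresponding
prototype, making logits scale-comparable across classes (the choice is
ours; nothing else in the construction fixes the column norms). Training
with cross-entropy over the seen classes therefore pulls F(x) toward the
right prototype direction. At test time the L-unit activation — the
representation immediately before the frozen multiplication — is the
network's image of x in word-vector space, and an unseen instance receives
the label of the unseen prototype with maximal cosine similarity
Dis(x, y) = x·y/(‖x‖‖y‖). That expression is sometimes written as a
"distance", but larger values mean closer; this package consistently calls
it a similarity.

A softmax/cross-entropy head is the default reading of the architecture;
`network_config(loss = "prototype")` provides the alternative reading — a
least-squares regression of the L-unit activation directly onto the class
prototype — for comparison. Batch normalization is applied after each
hidden layer; the placement is a documented choice among several the
architecture description admits.

## Tunable parameters

| Parameter | Default | Meaning / rationale |
|---|---|---|
| `hidden1` | 128 units | first hidden layer width (fixed by the architecture) |
| `embedding_dim` (= L) | 300 | word-vector dimension; the second hidden layer must match it |
| `learning_rate` | 1e-3 | Adam step size; conventional default |
| `batch_size` | 32 | mini-batch size |
| `epochs` | 200 | enough for the small training sets typical of annotated homes |
| `batch_norm` | TRUE | after each hidden layer |
| `class_weights` | FALSE | optional inverse-frequency loss weights; real homes are heavily imbalanced (single activities range from a handful to hundreds of instances) |
| `seed` | 1 | fixes initialization and shuffling; identical seed ⇒ identical fit |

The optimizer settings behind the published per-class results came from an
unreported grid search, so none of these defaults claims to reproduce them;
`grid_search_config()` ranks candidate settings on your own data. Feature
columns are standardized with mean/sd fitted on training data only (raw
counts span orders of magnitude); the scaler and the sensor vocabulary are
frozen at training time and reused verbatim at test time — the package
treats any unseen-class label appearing in training data as an error
(leakage guard). Numeric environmental sensors (temperature, light) are
excluded from the default vocabulary because the count construction is
defined on binary states; `numeric_threshold` optionally counts a numeric
sensor as activated whenever consecutive readings differ by more than the
threshold.

## Event-log semantics and edge cases

* Lines are split on runs of whitespace; dates are `YYYY-MM-DD`, times
  `HH:MM:SS` with optional fractional seconds; everything between the
  message field and a trailing `begin`/`end` token is the activity label,
  which accommodates multi-word labels. A `field_order` option covers
  dialect drift in the first four fields.
* Out-of-order timestamps are reported with a warning and never silently
  reordered; unmatched `begin`/`end` annotations are reported and skipped.
* An instance contains exactly the events whose timestamps lie in its
  `[begin, end]` window, boundaries included (the annotated events belong
  to the activity). During interleaved activities an event can therefore
  belong to two instances — each instance keeps its own time window.
* Events between an `end` and the next `begin` belong to no instance and
  are unused.
* Parsed events retain their verbatim date/time strings, so
  write-then-parse round trips are lossless.

## Numerical choices

* SELU uses the standard self-normalizing constants (α ≈ 1.6733,
  λ ≈ 1.0507); hidden weights use seeded Lecun-normal initialization, the
  variance-preserving choice for SELU.
* Batch normalization uses ε = 1e-5 and running-statistic momentum 0.9;
  inference always uses running statistics, so two identical inputs embed
  identically.
* Nearest-prototype ties (exact cosine equality) break to the
  lexicographically smallest label, for reproducibility.
* One-vs-rest metrics use the 0/0 → 0 convention for precision, recall and
  F1; reported tables round accuracy (percent) and ratios to 2 decimals.
* Cosine similarity with a zero vector is an error, not NaN; a constant
  vector under Pearson correlation likewise.
* Constant feature columns get unit scale in the standardizer (they map to
  0 rather than NaN).
* Checkpoints serialize every parameter at 17 significant digits, which
  round-trips IEEE doubles exactly — a reloaded network reproduces
  predictions bit-for-bit.

## What the synthetic generator emulates — and what it does not

`make_congruent_scenario()` builds seen classes with disjoint dominant
sensor blocks (expected activation count `separation = 6` per dominant
sensor, background 0.2) and draws per-instance counts from a Poisson law,
emitting each activation as an ON/OFF pair inside begin/end-annotated
spans; instance durations follow from random inter-event gaps of 0.5–3 s
and a one-minute gap separates instances. The defaults — 5 seen and 3
unseen classes, 30 sensors, 40 training instances per seen class, 200 test
instances, toy embedding dimension 16, prototype noise 0.05 — mirror the
scale of a single-resident annotated home study: a handful of well-sampled
activities, tens of sensors, class counts in the tens-to-hundreds.

Each unseen class is tied to a convex mixture of seen classes (by default
an equal mix of two consecutive ones), and the *same* mixing matrix is used
twice: unseen Poisson rates are mixtures of seen rate profiles, and unseen
toy prototypes are the matching mixtures of the mutually orthogonal seen
prototypes (plus isotropic noise, re-normalized). This congruence is the
transfer assumption of the method made literal, so end-to-end recovery on
this generator tests the machinery, not the realism: real homes have
diurnal structure, activity sequences, sensor noise and drift, shared
sensors between activities, and word-embedding geometry far messier than an
orthogonal frame. Passing synthetic tests says the pipeline is correct and
that transfer works when the semantic space is faithful to the feature
space; it does not certify accuracy on any real home.

The negative control deserves a note. "Break the congruence" could mean
relabeling unseen feature profiles by a fixed permutation, but that
produces *systematically wrong* predictions — accuracy near 0, not chance.
The control implemented (`incongruent = TRUE`) instead draws each test
instance's counts from a uniformly random class profile, independent of its
label: features then carry no information about the label and accuracy must
fall at the 1/K_unseen chance floor, which is the falsifiable prediction
the acceptance suite checks (within the binomial 99% band).

## Worked-example tables and known discrepancies

Three published confusion matrices for the CASAS HH101/HH125 homes are
bundled (`reference_confusion()`) and serve as exact worked examples for
`class_metrics()`: with rows as truth and columns as predictions, the
one-vs-rest equations reproduce the published per-class accuracy and
F-measure columns after rounding. Two discrepancies in the published
tables are documented rather than imitated:

* under any fixed matrix orientation the published precision and recall
  columns are exchanged relative to their definitions (accuracy and F are
  consistent either way, as F is symmetric in precision and recall — a
  property the suite tests); this package follows the definitions;
* the HH125 scenario-1 matrix is internally inconsistent with its own
  per-class table (its Toilet row duplicates HH101's), so it is excluded
  from the worked examples and not bundled.

The correlation analysis behind seen/unseen transfer is exposed as
`correlation_matrix()` with both Pearson (on class feature centroids) and
cosine (on prototypes) variants, because the published figure does not
state which vectors it correlates; `run_pipeline()` reports both.

## Problem sizes

The test suite trains small networks (8–16 hidden units, 30–60 epochs,
toy embedding dimensions 6–8) on scenarios of 60–200 instances; the
acceptance script runs the full default scenario (200 training and 200
test instances, 128-unit first layer, 200 epochs) twice — congruent and
control. These sizes were chosen so the whole pipeline, written in plain R
matrix algebra, runs in seconds while still exercising every code path at
realistic class counts.

## Limitations

* Windowing of unannotated, streaming data is out of scope; instances come
  from begin/end annotations (online best-fitting-sensor windowing is a
  separate line of work).
* Generalized zero-shot evaluation (test pools mixing seen and unseen
  classes) is not implemented beyond the distractor-vocabulary experiment
  (`evaluate_with_distractors()`, random-noun and k-nearest-neighbor
  modes).
* Hubness and seen-class bias — known failure modes of nearest-neighbor
  matching in high dimensions — are not corrected for.
* Only the word2vec text format is read; binary embeddings must be
  converted first, and out-of-vocabulary tokens have no subword fallback
  (a label with no known token is an error).
* Multi-resident homes and sensor-layout information are not modeled.
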