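---
title: "Models and methods behind tcmrx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind tcmrx}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

An inpatient chart in a TCM hospital contains, scattered over many
sections, everything a physician uses to compose a herbal prescription:
demographics, chief complaints, histories, tongue and pulse findings,
vital signs, laboratory results, nursing notes and previously issued
orders. `tcmrx` models the mapping from that chart — truncated at a
clinical decision time — to the *set* of medicines the physician orders,
as a multilabel classification problem over first-category medicines.

Two domain facts shape everything:

1. **Within-category substitution.** Two physicians routinely prescribe
   different herbs (or different category-II formulas) with the same
   therapeutic intent. A recommendation is therefore judged correct when
   it falls in the same first category as the human order, so both the
   label space and the scoring operate after *rollup* to parent
   categories (`rollup()`, `match_counts()`).
2. **Information accrues over the stay.** Orders are written at
   admission, 24 h, 48 h, 72 h and one week; later orders can draw on
   more observations, so evaluation is sliced by cutoff time
   (`evaluate_timeline()`) and performance is expected to improve down
   the rows of the report.

# Pipeline and model

## Featurization

`extract_tokens()` converts a structured record into a chronological
token sequence: demographics first (at time zero), then every clinical
fact as up to three tokens — the fact name, its value binned into
low/normal/high against reference ranges, and its unit. Facts sharing a
timestamp are ordered by the canonical section listing
(`box1_sections()`), then by name; this tie-break is our choice, fixed so
that truncating at an earlier cutoff always yields a prefix of a later
one. Prescriptions issued *before* the cutoff enter as medicines-taken
tokens with a small administration lag (so the order being predicted at
the cutoff is never part of its own input); feeding earlier orders back
is configurable and on by default, since medicines taken are a listed
chart feature and carry real signal.

## Embeddings

Tokens are embedded by a skip-gram model (`train_embeddings()`;
`min_count = 2`, `vector_size = 100`, `window = 5` at full scale). The
clinical token vocabulary here is a few hundred types, so the trainer
optimises the exact softmax over the vocabulary — the objective that
hierarchical softmax and negative sampling approximate — with the classic
dynamic context window, using Adam so the vectors reach their natural
magnitude within a few epochs. `vectorize()` then lays a sequence into a
fixed `max_num_tokens x vector_size` matrix: zero padding below the cap,
and clipping by dropping the oldest-timestamped tokens above it. A
boolean mask marks real in-vocabulary rows; out-of-vocabulary tokens
(guaranteed to exist by `min_count = 2`) keep their position as zero rows
with mask off, which the mask disambiguates from padding.

## The classifier

`fit_transformer()` trains the prescription model: embeddings scaled by
`sqrt(model_dim)` plus a sinusoidal positional code feed two identical
cascaded encoders, each a multihead self-attention sublayer (4 heads of
dimension 8), residual + layer normalisation, a 2048-wide position-wise
feedforward, and a second residual + normalisation. The per-head
projections map `model_dim` down to `head_dim` and the concatenated
32-dimensional head output is projected back to `model_dim` before the
residual add; head width and model width are deliberately decoupled. After
the second encoder the token positions are pooled by a masked mean (an
optional learned end-of-sequence attention query is available via
`pooling = "eos"`), and the head runs linear → 2048-wide feedforward →
128-unit hidden layer with dropout and normalisation → sigmoid outputs,
one per first-category medicine. `decode()` thresholds the probabilities
(default 0.5, tunable on validation F1); lowering the threshold can only
grow the decoded set.

Padded and out-of-vocabulary rows are excluded from attention and pooling
entirely — the forward pass subsets to the masked-in rows — so padded
content provably cannot influence predictions.

Training minimises the per-label binary log loss *averaged* over labels
(the scale-free choice; summing only rescales the learning rate) with an
L2 weight penalty (`1.566e-6`), Adam, and global gradient-norm clipping
(`0.1245`). Two printed tuned values from the source system deserve
comment: a "learning rate" of 0.4375 is implausible as an Adam step size,
so the default step is `1e-3` and the larger value can be passed
explicitly; and the two distinct loss-rate entries are interpreted as
input-embedding dropout (0.4410) and hidden-layer dropout (0.4740).
`tune_transformer()` reproduces the unusual published tuning protocol:
a grid search inside each of 10 cross-validation folds, with the final
numeric hyperparameters *averaged* over the per-fold winners (integer
fields rounded) and categorical ones chosen by majority vote.

## The GAN augmenter

`fit_gan()` trains an LSTM generator/discriminator pair on the training
embeddings. The generator adds i.i.d. Gaussian noise (σ = 0.05 by default, a small
fraction of the embedding coordinate scale so that a noise-added sample
keeps its source's label semantics)
to the input rows, passes them through an input projection, two stacked
width-279 LSTM layers each followed by layer normalisation with a
residual connection, and projects back to the embedding width; a global
residual connection from the noised input means a freshly initialised
generator (zero output projection) is exactly the identity-plus-noise
map, which keeps early generated samples usable. The discriminator is an
LSTM (width 279), masked mean pooling, a width-100 residual +
normalisation layer, a width-256 fully connected layer and a sigmoid
scalar. The published architecture leaves the width mismatches between
the 100-dimensional embeddings and the 279-unit LSTMs unstated; linear
projections bracket the LSTM stacks, the standard resolution.

One alternating epoch trains the discriminator on a balanced
`2 x batch_size` batch (fixed fakes) until its binary cross-entropy
plateaus, then freezes it and trains the generator (fresh noise each
step, non-saturating objective) until its adversarial cross-entropy stops
increasing; "stops" means no relative improvement of `1e-3` for 5
consecutive evaluations. "Nash equilibrium reached" is operationalised as
the discriminator's balanced accuracy staying inside [0.45, 0.55] for 5
consecutive epochs, with `max_epochs` as a hard stop. `augment_dataset()`
then generates exactly one noise-added sample per original — labels
inherited from the source, originals passed through untouched — doubling
the training set. Whether generated samples should inherit labels is
implied but never stated by the source system; without inheritance the
doubled set would be unusable for supervised training, so inheritance is
the only coherent reading. The generator is unconditional by default.

# The synthetic cohort generator

Hospital corpora of this kind are proprietary, so `generate_cohort()`
plants a known mechanism with the statistical structure the model
assumes. Each patient carries 1–3 latent syndromes. A syndrome emits its
characteristic symptom tokens at admission (with tongue and pulse
findings reflecting the primary syndrome), plus abnormal values of one
distinctive laboratory analyte over the stay; generic in-range vitals are
interleaved. The reference order at each decision time contains, per
target category, one *uniformly chosen leaf* of that category — the
within-category physician substitution that motivates rollup scoring.
`label_noise` swaps a target category for a random other one per order;
`symptom_noise` injects spurious symptoms from unrelated syndromes at
admission. Numeric facts are emitted as name–value–unit triples and
binned by the featurizer, keeping the vocabulary finite. The
syndrome-to-category map is injective (cycling) so the planted rule is
identifiable; category frequencies are uniform, as no class-balance
statistics are published for the real label space.

What the generator deliberately does **not** emulate: free-text
narratives (the package starts from structured records, downstream of
NER), realistic symptom co-occurrence and comorbidity structure, dosage,
and the long-tailed drug frequencies of a real pharmacy. Tests passing on
these cohorts therefore demonstrate that the machinery recovers a planted
signal under noise — not clinical-grade performance on real charts.

`corrupt_records()` plants the four chart-review discard conditions
(missing basic fields, inconsistent duplicates, nonstandard descriptions,
special-circumstance markers such as chemotherapy) that `qc_filter()`
detects, mirroring the quality-control stage of a real corpus.

# Numerical and design choices

- **Embedding scale.** Frozen skip-gram vectors can be small relative to
  the unit-amplitude positional code, which would bury content under
  position; inputs are multiplied by `sqrt(model_dim)` (the conventional
  scaling), overridable via `embed_scale`.
- **Desk-scale profiles.** `desk_transformer_config()` /
  `desk_gan_config()` shrink widths (model 32, feedforward 128, hidden
  32, 64-token window; LSTM 16) so that recovery experiments run on one
  CPU in minutes. The full-scale dropout rates (0.441/0.474) were tuned
  on a corpus three orders of magnitude larger and stall optimisation at
  desk scale, so the desk profile uses 0.1/0.1.
- **Zero denominators.** Precision is 1 when nothing is predicted and
  recall is 1 when nothing is due: the empty-versus-empty case is
  perfect, not an error. Aggregation is micro (counts summed over
  patients before dividing); macro averaging is available.
- **Rollup level.** Published material is ambiguous about whether the
  819-label space sits at category I or category II; the rollup level is
  a parameter (`level = "category1"` or `"category2"`) covering both
  readings, with category I the default.
- **Window constants.** The classifier's input window defaults to 759
  tokens; the 560 appearing in the augmenter's sizing example is treated
  as an illustrative alternative, not a second pipeline constant — the
  cap is a single parameter shared by `vectorize()` and both networks.
- **Degenerate inputs.** An all-padding input (empty chart) bypasses the
  encoders and classifies a zero pooled vector, returning finite
  probabilities. Empty prescriptions roll up to empty sets. Training
  aborts with a diagnostic on non-finite loss.
- **Unplaced published details.** A "self-learned averaging of vectors of
  the same type and time" is mentioned in the source system's tuning
  notes without an architectural placement; it is not implemented. The
  end-of-sequence multiplication it describes for multilabel decoding is
  offered, in spirit, as the optional learned-query pooling.

# Problem sizes used by the test suite

The packaged experiments are sized for a single CPU: parameter recovery
uses 500 noiseless patients, 10 categories × 5 leaves, and the desk
transformer (a few minutes); the augmentation ablation uses 150 patients
at 20% label noise across 5 seeds; the GAN equilibrium diagnostic uses a
toy Gaussian embedding set; metric and rollup properties are fuzzed over
1,000 random ontology/prescription instances. The acceptance script
(`scripts/acceptance.R`) reruns the recovery, time-slice and ablation
experiments from scratch at these sizes and writes the resulting
precision/recall figures as JSON.

# Known limitations

Base-R implementations of the transformer and LSTM are orders of
magnitude slower than GPU frameworks; the full-scale constants (759×100
inputs, 2048-wide feedforward, 819 labels) are faithful but practical
only with substantial compute. The synthetic generator's independence
assumptions make its cohorts easier than real charts; results on it
bound what the machinery can do, not what a hospital deployment would
achieve. Dosage and decoction instructions are out of scope.
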