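---
title: "Cross-sharing multi-task models for biomedical NER: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-sharing multi-task models for biomedical NER: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Biomedical named entity recognition (BioNER) tags genes, proteins,
diseases, chemicals, species and cell types in text that is pre-tokenized
and annotated per token with IOB labels (`B-GENE`, `I-GENE`, `O`, ...).
Annotated corpora are small and heterogeneous: each uses its own tag
inventory, most cover a single entity category, and models trained on one
corpus transfer poorly to another.  Multi-task training couples a *main*
corpus (whose test performance we care about) with an *auxiliary* corpus
(which supplies transferable signal), trading off shared statistical
strength against interference between unrelated label inventories.

`crossner` implements one single-task baseline and four two-dataset
multi-task architectures over a common BiLSTM-CNN-CRF backbone, together
with the turn-based training protocol, evaluation, IOB corpus handling and
a synthetic corpus generator.

# The backbone

**Token representation.** Each token `t` is represented as
`x_t = w_t (+) r_t`: a word vector `w_t` (dimension `d_w`, default 100,
optionally initialized from pretrained GloVe/word2vec text files and then
fine-tuned) concatenated with a character-level CNN feature `r_t`.  The
CNN embeds the characters of the word (dimension `d_c`, default 30),
convolves them with `n_filters` filters (default 30) of width `l_f`
(default 3) using padding `l_f - 1` — giving `l_c + l_f - 1` positions for
a word of `l_c` characters — and max-pools over positions.  Character
morphology matters in this domain (`-ase`, `-itis`, alphanumeric gene
symbols), which is why the char-CNN is part of the baseline rather than an
option.

**Encoder.** A single bidirectional LSTM layer (hidden size 256 per
direction) with the standard forget/input/output gate equations; the
forward and backward outputs are concatenated (forward half first) and
passed through a linear unit projecting 512 to 128 dimensions.  Dropout
(rate 0.5) is applied at the CNN input, at the BiLSTM input and at its
output, as inverted dropout so evaluation needs no rescaling.

**CRF.** A linear-chain CRF scores tag sequences with one pairwise factor
per adjacent tag pair; a virtual START label provides the left context of
the first position and there is no end factor.  Training minimizes the
exact negative log-likelihood computed by the forward algorithm in log
space; decoding is Viterbi with ties broken toward the lower label index.
Two parameterizations of the factor are provided:

* `factorized` (default): `score_i(j, k) = T[j, k] + (E z_i + b)[k]` —
  one transition matrix plus a label-wise emission projection, the
  standard BiLSTM-CRF form;
* `pairwise`: `score_i(j, k) = W[j, k, ] . z_i + b[j, k]` — the literal
  form in which every ordered label pair owns a weight vector over the
  emission.  This squares the parameter count in the label inventory and
  is provided as a configuration switch; both forms are affine in `z_i`
  per label pair and share all downstream code, tests and oracles.

An exhaustive-enumeration oracle (`crf_enumerate_oracle`) recomputes
scores, partition and argmax for state spaces up to `10^6` sequences and
is the reference for every CRF test.

# The five architectures

With datasets `D1` (main) and `D2` (auxiliary):

* **stm** — embedding, one BiLSTM, one CRF head; single dataset.
* **fs** (fully-shared) — shared embedding and BiLSTM, one CRF head per
  dataset; the batch's source dataset selects the head and the other head
  is untouched.
* **sp** (shared-private) — one shared BiLSTM plus one private BiLSTM per
  dataset; only the source dataset's private encoder runs; the CRF head
  reads `[private | shared]` (256 dimensions).  The concatenation order is
  a fixed convention; it affects nothing but reproducibility.
* **adv** (adversarial) — sp plus two auxiliary losses.
  `L_diff = sum_k ||S^T P_k||_F^2` (computed per batch on the
  time-stacked, pre-dropout projected outputs, averaged over batch size)
  pushes shared and private features toward orthogonal subspaces.
  `L_adv` is the cross-entropy of a softmax discriminator
  `D(s) = softmax(W s + b)` that reads the shared encoder's projected
  output at the final real time step of each sentence and tries to name
  the source dataset; a gradient-reversal operation between the shared
  encoder and the discriminator negates the backward-flowing gradient, so
  a single backward pass trains the discriminator to identify the dataset
  while the shared encoder learns to confuse it.  The total loss is
  `L = L_task + alpha L_adv + beta L_diff`, with `alpha` in
  `{0, 0.1, 0.01}` and `beta` in `{0, 0.01, 0.001}` as the grid-search
  candidate sets.  With `alpha = beta = 0` the architecture is numerically
  identical to sp, which the tests assert bit-for-bit.
* **cs** (cross-sharing) — both private encoders run regardless of the
  batch's source.  A gated interaction unit mixes them:
  `G1 = P1 * sigmoid(W21 P2 + b21)` and symmetrically `G2`; the source
  dataset selects `G`, and the CRF head reads `V = [G | S]`.  The gate
  matrices act per token with parameters shared across time.  The unit
  adds exactly `2 (128^2 + 128) = 33,024` parameters over sp, and it
  routes gradient into the *other* dataset's private encoder even on
  single-source batches — the mechanism by which auxiliary-only lexical
  knowledge reaches the main task.

## Decisions taken where the design was open

* **Discriminator input.**  The sentence summary fed to the discriminator
  is the projected shared output at the last real (non-padded) position.
  A pooled summary would also be defensible; the final step was chosen as
  the natural sequence summary and is asserted in tests only through the
  loss values, so changing it is localized.
* **Projection placement.**  Each BiLSTM owns its 512-to-128 projection
  and the shared/private concatenation happens *after* projection, giving
  256-dimensional CRF inputs in the shared-private family.  This keeps
  every encoder's interface identical across architectures.
* **Adversarial minimax.**  Implemented as standard domain-adversarial
  training: one optimizer, discriminator cross-entropy minimized over the
  discriminator parameters, gradient reversal supplying the maximization
  over the shared encoder.  `L_adv` is reported as the per-batch mean
  cross-entropy (log 2 for a perfectly confused two-dataset
  discriminator).
* **CRF boundary factors.**  No STOP transition: the sequence probability
  has factors only for positions `1..n`, with START context at position 1.
* **Word embeddings are trainable**, including rows seeded from
  pretrained vectors; out-of-vocabulary rows are drawn uniformly in
  `[-sqrt(3/d_w), +sqrt(3/d_w)]` and the PAD row is fixed at zero.  Word
  lookup falls back to the lowercased surface before UNK, because
  pretrained vector files are typically lowercase-keyed.
* **Parameter counting.**  `count_parameters()` counts every entry of
  every tensor; published totals for comparable models differ in whether
  embedding tables are included, so `param_breakdown()` reports each
  component and the tests assert the architecture *deltas* (gate unit,
  extra CRF head, discriminator), which are unambiguous.

# Training protocol

RMSprop (decay 0.95, momentum 0, epsilon 1e-8), batch size 16, learning
rate `0.001 * 0.97^epoch` (3% decay at the end of every epoch), global
gradient L2 norm clipped at 5.0, dropout 0.5, 80 epochs by default.

Multi-task training is turn-based: one *turn* is one optimization step on
a main-dataset batch followed by one on an auxiliary batch.  An epoch has
exactly as many turns as the main dataset has batches — every main batch
appears exactly once per epoch (so the main dataset is fully trained),
while auxiliary batches are drawn at random with replacement (the
auxiliary corpus may be larger or smaller than the main one).  Batches are
bucketed by sentence length before a seeded shuffle, an efficiency choice
that limits padding and is covered by the reproducibility tests.

Model selection: the dev split is the declared instrument for training
decisions, so `train()` returns the epoch snapshot with the best
main-dataset dev macro-F1 (`select = "best_dev"`), with `"final"`
available.  Grid search over `(alpha, beta)` selects by main-dataset dev
F1 with ties broken toward the smaller pair in lexicographic order.

All randomness flows from one integer seed: parameter tensors are
initialized from seeds derived from their own names (so two architectures
sharing a tensor name initialize it identically), and generator, batching,
schedule and dropout streams are derived from the run seed.  Two runs with
the same configuration are bit-identical.

# Evaluation

The primary metric is **tag-level macro-averaged precision/recall/F1** on
the percent scale: a predicted tag is correct only if it equals the
ground-truth tag; per-label scores are averaged without weighting.  Two
conventions the metric definition leaves open are fixed as: the `O` label
is excluded from the macro average (it would otherwise dominate the mean),
and a label with no predictions gets precision 0 while a label absent from
the gold standard is excluded from the mean.  **Entity-level exact-span
scoring** is also provided: an entity counts only on exact boundary and
category match; for span extraction (only), illegal `I-` openings are
repaired as `B-` ("I-as-B").  Span coordinates are 0-based half-open.
Decoding is unconstrained: illegal IOB transitions are discouraged by the
learned CRF transitions rather than forbidden.

# The synthetic corpus generator

Real corpus pairs cannot be bundled, so `synthetic_spec()` /
`generate_corpus_pair()` emulate their statistical structure: a
single-category main corpus, a multi-category auxiliary corpus, entity
lexicons with category-specific morphology (alphanumeric gene symbols,
`-itis`/`-oma` disease suffixes, binomial species names) so the char-CNN
has signal, 1-3-token entity surfaces so B/I transitions are exercised,
and deliberately different tag names across the pair (`B-GENE` vs
`B-DNA`) because real corpus pairs keep their native inventories.  The
number of entities per sentence is Poisson (mean 1.5 by default); each
entity sits in a sampled single-slot context template and filler tokens
pad sentences into a 6-14 token range.  The cross-dataset lever is `rho`:
the auxiliary lexicon of a shared category contains exactly
`round(rho * size)` surfaces of the main lexicon.
`generate_embeddings()` optionally supplies word vectors clustered by
category with a controllable separation.

What the generator does *not* emulate: natural language fluency, context
that disambiguates entity types, nested or discontinuous mentions,
annotation noise, and realistic type ambiguity (a surface is an entity in
every occurrence).  Passing the learnability checks therefore shows that
the architectures, losses and training loop function as specified — not
that the implementation reaches any particular accuracy on real corpora.

# Verification strategy and problem sizes

The test suite checks every layer against an independent reference:
exhaustive enumeration for the CRF (200 random instances with at most 4
labels and length 6), hand or scalar computations for the CNN, LSTM cell,
gate and discriminator, finite differences for every gradient path
(including the sign flip through gradient reversal), and construction
algebra for the architectures (adv with zero weights equals sp
bit-for-bit; parameter-count deltas).

Two seeded end-to-end runs use reduced dimensions (word 25, char 10 with
10 filters, hidden 32, projection 32) chosen so each run completes in a
few minutes on one CPU while leaving the architecture topology untouched:

* a single-task run on a separable 2,000-sentence corpus (20 epochs) that
  must reach at least 0.95 dev macro-F1;
* a small-main transfer setting — 200 main training sentences against a
  2,000-sentence auxiliary with lexicon overlap 0.8 and a 300-surface
  lexicon, so most entity surfaces in the main test set were never seen
  in main training — where the mean cross-sharing test F1 over three
  seeds must be at least the single-task mean.  This mirrors the
  qualitative claim that cross-dataset sharing helps most when the main
  dataset is small.

`scripts/acceptance.R` recomputes all of these quantities from scratch
against the installed package and writes them as JSON.

# Known limitations

* Two datasets only; three-or-more-dataset generalization is out of
  scope, as is any entity-type unification across inventories.
* Pure-R numerics: batched matrix operations keep the reduced
  configurations fast, but the full 256-hidden configuration on corpora
  of tens of thousands of sentences is a multi-hour run.
* The `pairwise` CRF form is exact but quadratic in the label inventory;
  inventories beyond a few dozen labels should use the factorized form.
* No early stopping, warmup, or subword vocabularies.
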