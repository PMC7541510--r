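---
title: "Modelling and designing toehold switches from sequence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and designing toehold switches from sequence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The system

A toehold switch is a synthetic riboregulator: a hairpin RNA that hides a
ribosome binding site (RBS) and start codon until a complementary 30-nt
*trigger* RNA hybridizes to its unstructured 5' end and melts the stem,
switching translation of a downstream reporter on. Performance is summarized
by the ON/OFF ratio — reporter signal with trigger over signal without.

`toeholdr` provides the full sequence-level workflow around this part:

1. a **structural grammar** that deterministically completes a 59-nt switch
   from any 30-nt trigger and can validate or repair arbitrary candidates;
2. a **synthetic-data module** that generates in-silico corpora and
   oracle-labeled datasets so every downstream model is testable without
   external data;
3. two trainable **sequence-function models** — a convolutional two-head
   ON/OFF regressor and a k-mer language-model classifier;
4. **interpretability tooling** (filter logos, k-mer enrichment, saliency,
   in-silico mutagenesis, intrinsic attention);
5. two **design optimizers** — gradient ascent on a relaxed sequence
   (STORM) and exhaustive stem-variant enumeration ranked by a consensus of
   both models (NuSpeak).

## The structural grammar

Coordinates are 1-based and inclusive throughout. The default 59-nt
template is:

| region | positions | content |
|---|---|---|
| trigger-binding region | 1–30 | reverse complement of the trigger |
| conserved loop (incl. RBS) | 31–41 | `AACAGAGGAGA` |
| descending stem (paired) | 42–47 | reverse complement of 25–30 |
| start codon | 48–50 | `AUG` |
| coding triplets (paired) | 51–59 | reverse complement of 13–21 |

The 3-nt bulge at 22–24 sits unpaired opposite the start codon. The
pairing map is encoded as *data* (`dependency_rules`) rather than code, so
an alternative hairpin geometry is a configuration change. The conserved
loop default is a reconstruction of the canonical switch series — it
carries the Shine–Dalgarno octamer `AGAGGAGA` — and is explicitly
user-configurable; all validation, repair, and enumeration honor whatever
template is supplied.

Two conventions worth stating because both appear in the wild:

* the trigger-binding region is the **reverse complement** of the trigger
  (antiparallel hybridization), not a position-wise complement;
* the mutable stem used by the enumeration optimizer is **22–30**, nine
  positions, chosen so that exhaustive enumeration has 4^9 = 262,144
  members. (Descriptions of this stem region are sometimes given as a
  10-position range "21–30" labelled nine nucleotides; the 9-position
  reading is the one consistent with the 4^9 count, so it is the default,
  and the range is configurable.)

`fix_sequence()` projects any 59-mer onto the valid set: conserved letters
are overwritten and each pairing dependency re-derived, from the trigger
side by default (`authority = "coding_side"` reverses the direction of
repair). It is idempotent and never touches the bulge or other free
positions.

Genome tiling is forward-strand with window 30 and stride 5 by default,
matching the screening design; the CLI's `tile --both-strands` adds the
reverse strand.

## Synthetic ground truth: the sequence oracle

Real switch measurements are noisy, expensive, and external; the package
instead ships a deterministic, interpretable *oracle* that maps any valid
switch to ON and OFF values in (0, 1). The oracle reads features that
mirror the sequence determinants repeatedly seen in screening data:

* GC fraction of positions 13–30 (the stem-forming trigger half) — strong
  negative weight on both channels: a GC-rich ascending stem resists
  unwinding;
* U count at positions 26–30 — positive ON weight (U-richness next to the
  loop aids melting);
* an in-frame stop codon in the coding triplets 51–59 — large ON penalty
  (a stop at the reporter's N-terminus kills translation);
* a `UA` bonus at the bulge (positions 23–24).

Scores are logistic-linked linear combinations plus seeded Gaussian noise
(`noise_sd = 0.05` by default). The `preset1` constants are fixed and
shipped so benchmarks are reproducible; they were chosen once so that the
signal is learnable but not linearly trivial (the logistic link and the
discrete stop feature keep a linear probe clearly below a converged CNN).
The oracle is *synthetic ground truth for testing the machinery* — it does
not emulate flow-seq measurement error or the QC pipeline of real
screens, so passing benchmarks demonstrate correct learning and
optimization machinery, not wet-lab accuracy.

ON/OFF for records is `on / max(off, 1e-6)`; the floor avoids division
blow-ups and is a library constant.

### Corpus collinearity

Random uniform triggers sample a 4^30 space, so an in-silico corpus is
highly diverse. Summarized with `pairwise_distance_summary()`, 300 random
triggers have a median pairwise distance of ~22–23 nt and their assembled
59-nt switches ~34 nt. These figures use per-position mismatch counting
(the default method): for uniform random 30-mers the expected mismatch
count is 0.75 × 30 = 22.5, and the stem dependencies make the full-switch
expectation 0.75 × 45 = 33.75 — the classic collinearity figures for this
corpus design. Levenshtein distance (also available, and the definition
behind `edit_distance()`) runs systematically lower on the same sets
(~18/28) because alignment exploits shifts; the mismatch convention is the
one under which the known centers arise, which is why it is the default
for the corpus summary while the alignment distance remains the pairwise
primitive.

### Distribution balancing

`balance_distribution()` flattens the ON and OFF histograms before
training: each channel is split into 1000 equal-width bins over its
observed range, each bin is down-sampled without replacement to the
rounded mean count over occupied bins, and the union of the two channels'
survivors is kept. Equal-width bins were chosen over quantile bins because
quantile bins would by construction change nothing; occupied-bin averaging
makes a single-bin (constant-valued) channel a no-op, which is the
behavior a density-flattening filter should degrade to.

## The convolutional ON/OFF regressor

The CNN treats the one-hot switch (59 × 4, column order A,C,G,U
everywhere, recorded in checkpoints) as an image-like input:

* conv layer 1: 10 filters of width 5, ReLU, "valid" padding;
* conv layer 2: 5 filters of width 3, ReLU;
* flatten → dense 150 → 60 → 15, all ReLU;
* two independent *linear* heads for ON and OFF, trained jointly on MSE.

Dropout 0.3 follows every hidden layer, and an L2 penalty (0.001) is
applied to hidden-layer *activations* — not weights — which discourages
confidently large feature responses. Adam at learning rate 0.005, batches
of 128, early stopping on a 15% held-out split with patience 10 and at
most 200 epochs. Padding is "valid" so that first-layer filters map to
literal 5-nt sequence windows, which is what makes `filter_logos()`
directly readable. No pooling layers: with a 59-nt input the flattened
second-layer activations (53 × 5 = 265) are already small.

The whole network is plain matrix algebra with hand-derived
backpropagation, so the gradient of either head with respect to the input
one-hot matrix is exact — this is what the saliency maps and the STORM
optimizer consume. Training is bit-reproducible given the seed.

Two footnotes on the published recipe. The architecture section gives
learning rate 0.005 while the hyperparameter search grid lists only
{0.0005, 0.001}; the package defaults to 0.005 and `random_search()`
accepts whatever grid you pass. And the search is *random* (each draw
samples every field independently from its value list), not
combinatorial, ranked by the mean of ON and OFF R² under 5-fold CV.

Cross-validation is stratified on the top-quartile ON/OFF class. Within
each fold, half of the test fold drives early stopping and only the other
half is scored, so reported metrics never touch sequences the stopping
rule saw.

`transfer_cnn()` freezes both convolutional layers bit-for-bit, replaces
the two heads with a single linear output, and fine-tunes the dense stack
on a small single-target dataset — the few-shot regime where a frozen
feature extractor beats training from scratch.

## The k-mer language model

Sequences are tokenized into non-overlapping 3-mers (k = 3, stride = 3; a
59-mer gives 19 tokens and the 2-nt tail is dropped — the same tokens the
attention profiles are reported over). The vocabulary is all 64 3-mers in
lexicographic order, stored with every checkpoint.

The encoder is a stacked quasi-recurrent network (QRNN) with f-pooling:
per token, candidate `z_t = tanh(W_z x_t + b_z)` and forget gate
`f_t = sigmoid(W_f x_t + b_f)` are computed from the embedded input alone,
and the state updates as `h_t = f_t ⊙ h_(t-1) + (1 − f_t) ⊙ z_t`. The
gates here are width-1 (per-token) maps — a deliberate simplification of
the width-2 convolutional gates sometimes used; since the gates carry no
recurrent weight matrix, there is nothing for recurrent weight-drop to act
on, and plain L2 weight decay is exposed instead — defaulting to zero,
because at desk scale any appreciable decay applied through the Adam
update measurably throttles pre-training and collapses the fine-tuned
classifier toward the majority class. A learned positional
embedding is added to the token embeddings: the toehold grammar is
strongly positional (conserved loop at tokens 11–13, start codon around
tokens 16–17), and position information would otherwise have to be
inferred by integrating the recurrence, which is needlessly slow to learn.

Pre-training is next-token prediction with the decoder weights tied to the
embedding (tying reduces perplexity and halves the parameters), Adam under
a cosine learning-rate schedule. The classifier replaces the decoder with
a linear head over the token-averaged final hidden state, trained with
label-smoothing cross-entropy (0.1) and output dropout 0.5; dropouts
elsewhere are output 0.15, hidden 0.20, input 0.30, embedding 0.05 (the
embedding and input dropouts are elementwise and act multiplicatively on
the embedded tokens). Good/bad labels default to the top 25% of ON/OFF —
the threshold is recorded in the checkpoint (`threshold_spec`) and
alternative percentiles are a parameter.

Direction-agnostic prediction trains a second classifier on reversed token
streams and averages the two probabilities at prediction time
(`classify_switches()`).

Two scales are built in: the `paper` preset is the full-size architecture
(4 QRNN layers, 1552 hidden activations, 400-dim embedding, 15 epochs),
and the `desk` preset (2 layers, 256 hidden, 64-dim embedding) keeps every
contract but fits interactive work; the test suite runs the desk preset
with corpora of a few thousand switches. The optimizer is plain Adam — the
rectified-Adam/LookAhead combination used at full scale is an orthogonal
training refinement that the desk-scale contracts do not depend on.

## Interpretability

* `filter_logos()` reads first-layer filter weights directly as width × 4
  position-weight matrices.
* `filter_kmer_enrichment()` takes per-column argmax consensus strings of
  every filter across an ensemble of independently trained models, slides
  3-nt windows, and compares counts to the uniform expectation
  (total windows / 64). Consensus-then-count is the default because it is
  parameter-free; `method = "threshold"` instead counts only windows whose
  filter sub-score clears a cutoff. Filter-width edge windows are
  included.
* `saliency()` is the absolute input gradient of one head, summed over
  channels per position, attributed to the letter each sequence actually
  carries, normalized by how often that letter occurs at that position,
  and averaged. Absolute values are taken before summation (the sign
  convention is a choice; magnitudes answer "how sensitive", which is the
  question the map is used for).
* `mutagenesis_scan_cnn()` substitutes all four letters at every position
  (identity included, so the baseline is in the set) and scores positions
  by the standard deviation of the four predictions, aggregated with a
  95% CI across sequences.
* `mutagenesis_scan_lm()` mutates each position to one random letter per
  sequence (seeded) and records the classifier probability of the mutant.
* `attention_profile()` is the gradient of the predicted-class logit with
  respect to each embedded token, L1-aggregated and normalized to sum to
  one per sequence — every row sums to 1, not just the mean.

All profiles are invariant to input order and reproducible given the
seed. Embedding scatter plots (UMAP and friends) are presentation-layer:
the tested artifact is the embedding matrix from `lm_embed()`.

## The optimizers

**NuSpeak** enumerates all 4^9 = 262,144 assignments of the mutable stem
(22–30), repairs the pairing dependencies of each variant, and preserves
positions 1–21 — so every variant keeps binding the intended target.
Variants are scored by the classifier pair (p_good) and the regressor
(predicted ON/OFF, min–max normalized *within the candidate set* — the
probability and the ratio are not commensurable otherwise, and the
normalization is recorded in the output), and ranked by the geometric mean
`sqrt(p_good × score_norm)`; the geometric mean is robust to one model
being extreme. Ties break lexicographically, so rankings are
deterministic. If candidate A dominates B on both scores it always ranks
above B.

**STORM** relaxes the sequence to a 59 × 4 logit matrix, feeds the
row-softmax probabilities through the CNN, and walks the logits down the
gradient of `(on − target_on)² + (off − target_off)²`. Targets default to
ON → 1, OFF → 0: the published target "ON/OFF value of 1" is ambiguous
between a ratio and per-head values, and per-head targets are the reading
consistent with a two-head regressor (`target_mode = "ratio"` steers the
predicted ratio itself instead). An entropy bonus (weight 1e-3, annealed linearly to zero)
keeps early steps exploratory. The whole sequence varies freely during
ascent; after each of 5 rounds the argmax sequence is repaired with
`fix_sequence()` and re-scored, and the best repaired sequence across
rounds is returned — so the result always validates, and the best-of
selection makes the reported objective monotone in the seed's. Step
counts and sizes are unpublished; the defaults (300 steps/round, step 0.5
on logits) are library constants. A base-pairing penalty *in* the loss
(`pairing_weight`) is available but off by default — repairing after free
optimization avoids the local minima that constrained ascent tends to
settle into.

`consensus_select()` implements the simplex-style pick: rank all
candidates by geometric mean, then draw the requested numbers of
predicted-good and predicted-bad picks at random (seeded) from the top and
bottom quarters. Pick sets are disjoint and every good pick outranks every
bad pick.

## Numerical and testing choices

* All randomness flows through explicit integer seeds via an internal
  save/restore wrapper; no function leaks global RNG state.
* Logos use a 0.5 pseudocount per cell; backgrounds are normalized and
  must be positive.
* MCC of a degenerate single-class prediction is defined as 0.
* Quartile bookkeeping uses bottom = floor((1 − q)·n) — the unique
  convention reproducing the printed screening-partition counts
  (22,884 / 68,650 of 91,534).
* All three standard stop codons (UAA, UAG, UGA) are flagged by default;
  a restricted set is a parameter.
* The test suite trains at reduced problem sizes chosen once as
  representative desk-scale conditions: CNN benchmark n = 5,000 oracle
  records (80-epoch cap), LM pre-training corpus n = 3,000 at 15 epochs,
  classifier fine-tuning n = 5,000 at 8 epochs, ablation comparisons at
  n = 736, the pre-training-benefit comparison at n = 1,000 (the low-data
  regime where transfer shows; the gap closes by n ≈ 2,000), transfer at
  n = 168, STORM on the 20 worst oracle switches, NuSpeak improvement
  trials on reduced 4-position stems (full 9-position enumeration is
  tested by exact counting). These sizes are the package's benchmark
  conditions; the full-scale presets remain available.

## Known limitations

* The oracle is a linear-logistic stand-in: it cannot express epistasis
  between positions, and benchmark results on it say nothing quantitative
  about real flow-seq data.
* The desk-scale LM is far smaller than the full preset; its perplexities
  and MCCs are not comparable to full-scale numbers.
* Thermodynamic scoring (MFE, secondary-structure prediction) is out of
  scope; the NuSpeak hook accepts precomputed MFE values for tie-breaking
  but never computes them.
* The 109-nt wet-lab construct (promoter + linker + reporter) is not
  assembled here; the package ends at the 59-nt switch.
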