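---
title: "Methods: multi-granularity encoding and multi-scaled self-attention for binding affinity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-granularity encoding and multi-scaled self-attention for binding affinity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the modelling and numerical decisions behind
`msadta`: what the model computes, which knobs matter, what the synthetic
data generator does and does not emulate, and where the design was
genuinely open.

## The encoding: byte-pair segmentation of molecular strings

Drug SMILES and protein sequences are strings without word boundaries, yet
they contain multi-character units that behave as atoms of meaning:
two-letter element symbols (`Cl`, `Br`), bracket atoms with stereo marks
(`[C@@H]`), repeated runs (`CCCC`), and recurring amino-acid motifs.
`bpe_train()` learns these bottom-up: starting from single characters it
repeatedly merges the most frequent adjacent token pair across the corpus,
until the merge budget `threshold` is exhausted or the best remaining pair
occurs fewer than `min_frequency` (default 2) times — merging a pair seen
once compresses nothing. Decisions the algorithm statement leaves open,
fixed here for determinism:

* **Tie-breaking.** Pairs with equal frequency are resolved to the
  byte-order (C-locale) smallest `(left, right)` pair. Any fixed rule
  would do; this one is platform-independent and makes training
  replayable byte for byte.
* **No word segmentation.** Each corpus line is one unbroken token
  stream; merges may span any adjacent positions within a sequence and
  never across sequences. There is no end-of-word marker because
  molecular strings have no words.
* **No normalization.** Sequences are consumed verbatim (isomeric SMILES
  included); case carries chemical meaning (`c` aromatic vs `C`
  aliphatic), so lowercasing would be destructive.

`bpe_vocabulary()` assigns ids deterministically — sorted alphabet first,
then merged tokens in merge order — so the vocabulary size is exactly
`|alphabet| + #merges`. Id 0 is reserved for padding and never assigned;
out-of-vocabulary tokens at encode time map to the reserved id
`size + 1`. `bpe_encode()` right-truncates sequences longer than the
length cap *l* and zero-pads shorter ones; truncation from the right is
the natural counterpart of the stated padding rule, which only defines
behaviour for short inputs.

One behaviour worth knowing: with a generous merge budget, BPE keeps
merging *past* a recovered motif, absorbing it into longer context tokens
(`[C@@H]` → `[C@@H]Br`). The motif remains a vocabulary token and mostly
surfaces intact, but a segmentation is not guaranteed to show every
planted motif as a standalone token.

## The model

For one drug–protein pair, each side is embedded as token table plus
learned position table (`l × e`), then passed through `L` multi-scaled
attention blocks. Head `h` of a block computes scaled dot-product
attention with an additive band mask `M_h`: zero on the diagonal band of
half-width `m_h`, a large negative constant off it. The defaults assign
windows 0, 1, 2, 3 to four heads, so one head copies its value projection
(m = 0), and the others mix progressively wider local context; with
`m ≥ l − 1` a head reduces exactly to ordinary attention (a property the
test suite checks against an independent implementation).

Choices the architecture statement left open, and how they were resolved:

* **No output projection.** The head concatenation is added directly to
  the block input (`LN(concat(heads) + E)`), so `d_h = e/N` is enforced
  and there is no `W_O`. This is the literal reading of the block's
  residual equation rather than the common Transformer convention.
* **Head/window assignment.** The head count is not separately specified;
  `n_heads` defaults to 4, one listed window per head. If `n_heads`
  exceeds the window list, windows cycle.
* **Position-wise layer.** The block's feed-forward part is a single
  affine layer of width `e` with ReLU under its own residual + layer
  norm, per the stated hidden size `e`.
* **Padding.** Padded key positions (id 0) receive the masking constant
  in every head on top of the band mask; a query row whose whole band is
  padded outputs zeros. Unmasked padding would let zero-id rows leak into
  every window.
* **Aggregation.** Drug and protein representations are flattened
  (`l × e` → `l·e`) and concatenated before the interaction stack,
  mirroring the stated concatenation literally; `"mean"` and `"max"`
  pooling are available in the config for memory-constrained settings
  (flatten at benchmark scale makes the first interaction matrix by far
  the largest tensor in the model).
* **Protein embedding size.** Not listed separately in the benchmark
  settings; `e_p` defaults to `e_d`.
* **Dropout placement.** The rate (0.1 at benchmark scale) is specified
  but not the placement; it is applied at the Transformer-conventional
  points — after the embedding sum, on attention weights, and after each
  hidden interaction layer.

The interaction stack is four dense layers (defaults 1024/1024/512/1,
ReLU on hidden layers, linear output) applied to the concatenated
representations, yielding the scalar affinity.

## Training and numerical choices

* **Optimizer.** Adam (β₁ = 0.9, β₂ = 0.999, ε = 1e−8) on the MSE loss at
  the configured learning rate (default 1e−4), fully seeded: identical
  data and seed give bit-identical loss traces.
* **Target standardization.** Affinities are centred and scaled on the
  training split before optimization and predictions are mapped back.
  This is pure conditioning: pK_d-scale targets (~5–11) would otherwise
  spend the entire small-step budget moving the output bias toward the
  mean. The loss being minimized is unchanged.
* **Masking constant.** "−∞" is realized as −1e9 before the softmax;
  exp of the shifted logits underflows to exactly 0 at double precision
  without generating NaNs.
* **Layer-norm ε.** 1e−6, inside the square root.
* **r²_m through-origin term.** The through-origin coefficient of
  determination uses the slope `k = Σ(y·ŷ)/Σ(ŷ²)` (observed regressed on
  predicted), the standard formulation in the QSAR-validation literature
  this metric comes from. The radicand `r² − r²₀` is clamped at zero in
  the rare numerical case `r²₀ > r²`, keeping the statistic real.
* **Concordance index ties.** Only ordered pairs with strictly larger
  true affinity enter the denominator (ties in the truth carry no
  ordering information); exactly tied predictions earn half credit.
* **Divergence guard.** A non-finite training loss aborts with a
  diagnostic rather than propagating NaNs into the parameters.
* **Initialization.** Glorot-uniform for projections and dense layers,
  N(0, 0.02²) for embedding tables, unit gains / zero shifts for layer
  norms, zero biases.

The cross-validation protocol reads the benchmark phrase "five-time
leave-one-out" as seeded 5-fold cross-validation over the training
portion with one fixed held-out test split (the protocol of the data
release the benchmarks inherit): `split_folds()` holds out 1/6 of the
triples as the test split and partitions the rest into five folds;
`run_cv()` trains one model per fold on the other four and evaluates all
models on the shared test split, reporting mean (sd) per metric.

## The synthetic data, and what passing on it shows

`generate_affinity_dataset()` emulates the *structure* of the real task,
not its chemistry. Drugs are SMILES-like strings carrying 0–2 copies of
each of four multi-character motifs (`Cl`, `Br`, `[C@@H]`, `CCCC`) among
random filler symbols; proteins carry 0/1 copies of four amino-acid
repeat motifs. The affinity of a pair is

    y = 5 + 1.0 × Σ_k count_k(drug) · tag_k(protein) + N(0, 0.1²)

so it is learnable from the sequences alone, lives on a pK_d-like 5–11
scale (so loss magnitudes and learning rates transfer), and has a known
noise floor: a regressor given the true motif counts reaches
MSE ≈ 0.01, which bounds what any sequence model can achieve here. The
default panel is 40 drugs × 10 proteins (400 dense pairs), sequence
lengths 18–26 (drug) and 14–20 (protein) characters so that encoded
inputs essentially fit the tiny configuration's 16-token cap.

What this does *not* emulate: chemical validity, realistic protein
families, the heavy-tailed affinity distributions and assay noise of real
panels, or benchmark scale (hundreds of proteins, thousands of drugs,
300-epoch training). Passing here demonstrates that the pipeline is
implemented correctly and can extract a planted sequence-level
interaction signal; it says nothing about accuracy on real kinase panels.

## Desk-scale configuration

The `"tiny"` preset used throughout the tests and the acceptance script
is the package's own choice of a configuration that trains in about a
minute on one CPU: length caps 16/16, embedding size 16, four heads at
windows 0–3, one block per side, interaction stack 64/64/32/1, no
dropout, batch size 8, 50 epochs of Adam at 1e−4, BPE budget 50 merges
per side. The `"kiba"` and `"davis"` presets mirror the published
benchmark settings (length caps 80/800 and 36/900, embedding sizes 128
and 64, two drug blocks, two resp. one protein blocks, interaction stack
1024/1024/512/1, dropout 0.1, 300 epochs, BPE budgets 20k/36k) and are
shipped as YAML under `inst/config/`; training them requires the
benchmark downloads and far more compute than a desk run.

## Known limitations

* The hand-written reverse-mode pass is validated by central differences
  but is not a general autodiff: architectural changes require matching
  gradient code.
* Flatten aggregation ties the interaction stack to the length caps; at
  benchmark scale the first interaction matrix dominates the parameter
  count (~117M of the KIBA configuration's parameters).
* `format = "deepdta"` reads the benchmark release's JSON tables plus a
  *text* export of the affinity matrix; the release's pickled binaries
  must be exported to text first.
* BPE training is the naive quadratic-in-corpus algorithm; fine for
  corpora up to a few thousand sequences, not for the 10⁵-sequence
  corpora behind the benchmark vocabularies.
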