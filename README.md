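# msadta

Sequence-based drug–target binding-affinity regression with
multi-granularity subword encoding and multi-scaled (banded) self-attention.

## The problem

Predicting how strongly a small molecule binds a protein target — the
dissociation constant K_d, its log transform pK_d = −log₁₀(K_d/10⁹), or a
composite score such as KIBA — from the two sequences alone (drug SMILES,
protein amino acids) is a standard task in computational drug discovery.
Character-level encodings lose chemically meaningful multi-character units
(`Cl`, `Br`, `[C@@H]`, repeated carbon chains), and plain self-attention
treats every pairwise position interaction identically, washing out local
chemical context. This package implements both remedies end to end for R
users: a byte-pair-encoding (BPE) tokenizer that learns multi-granularity
vocabularies from sequence corpora, and a self-attention regressor whose
heads attend within diagonal bands of different half-widths.

## The model

Each input sequence is segmented by a learned BPE merge table, mapped to
integer ids, truncated/zero-padded to a length cap *l*, and embedded as the
sum of a token table and a learned position table (an *l* × *e* matrix per
sequence). An encoder block runs *N* attention heads; head *h* computes

    head_h = softmax( Q_h K_hᵀ / √d_h + M_h ) V_h,   d_h = e / N

where `M_h` is an additive band mask: entry (i, j) is 0 when
|i − j| ≤ m_h and −∞ otherwise. With window m = 0 a head copies its value
projection; with m ≥ l − 1 it is ordinary global attention; intermediate
windows capture chemical patterns at intermediate scales. The default head
windows are m = 0, 1, 2, 3. Head outputs are concatenated back to
dimension *e* (no output projection), followed by residual + layer norm, a
position-wise affine layer of width *e* with ReLU, and a second
residual + layer norm. Stacks of `L_d` (drug) and `L_p` (protein) blocks
produce representations that are flattened, concatenated, and passed
through a 4-layer feed-forward stack (default widths 1024/1024/512/1) to a
scalar affinity. Training minimizes mean squared error with Adam; the
whole forward/backward pass is implemented in base R and verified against
a finite-difference oracle.

Evaluation uses the field's standard statistics: MSE, the concordance
index (probability that two pairs with different true affinities are
predicted in the right order, ties counting ½), and Roy's
r²_m = r²·(1 − √(r² − r²₀)), which penalizes miscalibrated predictions by
comparing the with-intercept and through-origin fits; r²_m > 0.5 is the
conventional bar for an acceptable model.

## Worked example

```r
library(msadta)

## a dense synthetic panel with a planted motif-sharing signal
d <- generate_affinity_dataset(synthetic_spec(n_drugs = 12, n_proteins = 5, seed = 4))
d <- split_folds(d, k = 5, test_fraction = 1/6, seed = 4)
d
#> Affinity dataset: 12 drugs x 5 proteins, 60 triples (dense)
#>   affinity range: [4.865, 11.02]
#>   folds: 10 test, 5 train folds of sizes 10/10/10/10/10

fit <- msaan(d, msaan_config("tiny", epochs = 20), seed = 4)
fit
#> Multi-scaled self-attention affinity model
#>   config: tiny  heads: 4 windows 0,1,2,3
#>   vocabularies: 48 drug tokens, 28 protein tokens
#>   trained 20 epochs on 50 pairs; final train MSE 0.108

test_idx <- which(d$folds == 0)
round(evaluate_predictions(d$triples$affinity[test_idx],
                           predict(fit, d, subset = test_idx)), 3)
#>   mse    ci   r2m
#> 1.185 0.822 0.469
```

The held-out concordance index of 0.82 says the 20-epoch model ranks four
of five affinity pairs correctly; r²_m below 0.5 says its calibration is
not yet acceptable at this budget (the 50-epoch default clears the bar —
see below). Cross-validated training reports the benchmark-style
mean (sd) across folds:

```r
run_cv(d, msaan_config("tiny", epochs = 20), seed = 4)
#> Cross-validated multi-scaled SAN (5 folds, 10 shared test pairs)
#>   CI   0.827 (0.092)
#>   MSE  1.254 (0.342)
#>   R2M  0.424 (0.069)
```

The tokenizer is usable on its own; merges learned on the panel's SMILES
recover multi-character chemical units:

```r
bp <- bpe_train(unname(d$drugs), threshold = 30)
bp
#> BPE merge table: 30 merges (threshold 30 ), 17 alphabet symbols
#>   first merges: C+C C+l CC+CC @+@ @@+H @@H+] B+r C+@@H] [+C@@H] )+c
bpe_segment(unname(d$drugs)[1], bp)[[1]]
#> [1] "nCl"    "[C@@H]" "BrCCCC" ")"      "Cl="    "NO"     "11"     "O"
```

A command-line front end with `tokenize-train`, `encode`, `simulate`,
`train`, `predict`, `evaluate` and `run-cv` subcommands ships at
`system.file("cli", "msadta.R", package = "msadta")`.

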