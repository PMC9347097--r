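# Parameter initialization and bookkeeping.

glorot <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
}

init_block <- function(e, n_heads) {
  dh <- e %/% n_heads
  list(
    heads = lapply(seq_len(n_heads), function(h) {
      list(Wq = glorot(e, dh), Wk = glorot(e, dh), Wv = glorot(e, dh))
    }),
    ln1_g = rep(1, e), ln1_b = rep(0, e),
    ffn_W = glorot(e, e), ffn_b = rep(0, e),
    ln2_g = rep(1, e), ln2_b = rep(0, e)
  )
}

init_side <- function(vocab_size, l, e, L, n_heads) {
  list(
    token = matrix(stats::rnorm((vocab_size + 2L) * e, sd = 0.02),
                   vocab_size + 2L, e),
    pos = matrix(stats::rnorm(l * e, sd = 0.02), l, e),
    blocks = lapply(seq_len(L), function(b) init_block(e, n_heads))
  )
}

agg_dim <- function(config) {
  switch(config$aggregation,
    flatten = config$l_d * config$e_d + config$l_p * config$e_p,
    config$e_d + config$e_p
  )
}

#' Initialize model parameters
#'
#' Draws a fresh, fully seeded parameter set for the model described by
#' `config`: token and position embedding tables for both sides (token
#' tables have `vocab size + 2` rows to cover the padding and unknown ids),
#' `L` attention blocks per side with per-head query/key/value projections
#' of size `e` x `e/N`, and the four-layer interaction stack. Projection
#' and dense weights use Glorot-uniform initialization; embedding tables
#' use Gaussian entries with sd 0.02; normalization gains start at 1,
#' biases at 0.
#'
#' @param config An [msaan_config()].
#' @param vocab_drug_size,vocab_protein_size Token counts of the two
#'   vocabularies (excluding the reserved pad/unk ids).
#' @param seed Integer seed.
#' @return Nested list of parameter arrays with components `drug`,
#'   `protein` and `inter`.
#' @export
msaan_params <- function(config, vocab_drug_size, vocab_protein_size,
                         seed = 1L) {
  stopifnot(inherits(config, "msaan_config"))
  with_seed(seed, {
    h <- config$ffn_hidden
    d_in <- agg_dim(config)
    list(
      drug = init_side(vocab_drug_size, config$l_d, config$e_d, config$L_d,
                       config$n_heads),
      protein = init_side(vocab_protein_size, config$l_p, config$e_p,
                          config$L_p, config$n_heads),
      inter = list(
        W1 = glorot(d_in, h[1L]), b1 = rep(0, h[1L]),
        W2 = glorot(h[1L], h[2L]), b2 = rep(0, h[2L]),
        W3 = glorot(h[2L], h[3L]), b3 = rep(0, h[3L]),
        W4 = glorot(h[3L], 1L), b4 = 0
      )
    )
  })
}

#' Closed-form parameter count
#'
#' Computes, from the configuration alone, the number of trainable scalars
#' the model will hold: per side `(v + 2) e + l e` embedding entries plus
#' `L (4 e^2 + 5 e)` per-block entries (three `e x e/N` projections per
#' head across `N` heads make `3 e^2`, the position-wise affine layer
#' `e^2 + e`, and two normalizations `4 e`), plus the interaction stack.
#' Regression-tested against the instantiated parameter set.
#'
#' @inheritParams msaan_params
#' @return Integer count.
#' @export
n_parameters <- function(config, vocab_drug_size, vocab_protein_size) {
  stopifnot(inherits(config, "msaan_config"))
  side <- function(v, l, e, L) {
    (v + 2) * e + l * e + L * (4 * e^2 + 5 * e)
  }
  h <- config$ffn_hidden
  d_in <- agg_dim(config)
  inter <- d_in * h[1L] + h[1L] + h[1L] * h[2L] + h[2L] +
    h[2L] * h[3L] + h[3L] + h[3L] * h[4L] + h[4L]
  as.integer(side(vocab_drug_size, config$l_d, config$e_d, config$L_d) +
             side(vocab_protein_size, config$l_p, config$e_p, config$L_p) +
             inter)
}
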