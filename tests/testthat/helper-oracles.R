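# Independent reference implementations used as test oracles. These share
# no code with the package internals they check.

# Naive BPE trainer: explicit nested loops, a data-frame pair census per
# iteration, ordering by (-count, left, right) in C-locale byte order.
naive_bpe <- function(corpus, threshold, min_frequency = 2L) {
  seqs <- lapply(corpus, function(s) strsplit(s, "")[[1L]])
  merges <- list()
  for (step in seq_len(threshold)) {
    lefts <- character(0); rights <- character(0)
    for (s in seqs) {
      if (length(s) >= 2L) {
        for (i in seq_len(length(s) - 1L)) {
          lefts <- c(lefts, s[i]); rights <- c(rights, s[i + 1L])
        }
      }
    }
    if (length(lefts) == 0L) break
    census <- stats::aggregate(
      list(count = rep(1L, length(lefts))),
      by = list(left = lefts, right = rights), FUN = sum)
    census <- census[order(-census$count, census$left, census$right,
                           method = "radix"), ]
    if (census$count[1L] < min_frequency) break
    a <- census$left[1L]; b <- census$right[1L]
    merges[[length(merges) + 1L]] <- c(a, b)
    seqs <- lapply(seqs, function(s) {
      out <- character(0); i <- 1L
      while (i <= length(s)) {
        if (i < length(s) && s[i] == a && s[i + 1L] == b) {
          out <- c(out, paste0(a, b)); i <- i + 2L
        } else {
          out <- c(out, s[i]); i <- i + 1L
        }
      }
      out
    })
  }
  merges
}

# Standard (unmasked) transformer block with the same parameter layout as
# the package's block but its own softmax and normalization code.
ref_vanilla_block <- function(E, block, eps = 1e-6) {
  softmax_rows <- function(S) {
    t(apply(S, 1L, function(r) { e <- exp(r - max(r)); e / sum(e) }))
  }
  ln_rows <- function(x, g, b) {
    t(apply(x, 1L, function(r) {
      (r - mean(r)) / sqrt(mean((r - mean(r))^2) + eps)
    })) %*% diag(g) + matrix(b, nrow(x), length(b), byrow = TRUE)
  }
  heads <- lapply(block$heads, function(hp) {
    Q <- E %*% hp$Wq; K <- E %*% hp$Wk; V <- E %*% hp$Wv
    softmax_rows(Q %*% t(K) / sqrt(ncol(hp$Wq))) %*% V
  })
  Z <- ln_rows(do.call(cbind, heads) + E, block$ln1_g, block$ln1_b)
  P <- Z %*% block$ffn_W + matrix(block$ffn_b, nrow(Z), ncol(Z), byrow = TRUE)
  ln_rows(Z + pmax(P, 0), block$ln2_g, block$ln2_b)
}

# O(n^2) concordance index by explicit double loop.
ci_brute <- function(y_true, y_pred) {
  num <- 0; den <- 0
  n <- length(y_true)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (y_true[i] > y_true[j]) {
        den <- den + 1
        d <- y_pred[i] - y_pred[j]
        num <- num + if (d > 0) 1 else if (d == 0) 0.5 else 0
      }
    }
  }
  num / den
}

# Two-regression r^2_m oracle via lm(): Pearson r^2 from the with-intercept
# fit, through-origin coefficient of determination from the k-slope fit.
r2m_lm_oracle <- function(y_true, y_pred) {
  r2 <- summary(stats::lm(y_true ~ y_pred))$r.squared
  fit0 <- stats::lm(y_true ~ 0 + y_pred)
  r20 <- 1 - sum(stats::resid(fit0)^2) / sum((y_true - mean(y_true))^2)
  r2 * (1 - sqrt(max(r2 - r20, 0)))
}

# Small model configuration for layer-level and gradient tests.
micro_config <- function(...) {
  msaan_config("tiny", l_d = 6L, l_p = 6L, e_d = 8L, e_p = 8L, n_heads = 2L,
               window_sizes = c(0L, 2L), ffn_hidden = c(8L, 8L, 4L, 1L), ...)
}

random_block_params <- function(e, n_heads, seed = 1) {
  msadta:::with_seed(seed, msadta:::init_block(e, n_heads))
}
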