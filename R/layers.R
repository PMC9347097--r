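# Building blocks of the multi-scaled self-attention encoder.
#
# Each attention head h sees the sequence through a diagonal band of
# half-width m^h: the additive mask is 0 where (i - m) <= j <= (i + m) and
# "minus infinity" elsewhere, so a head with m = 0 copies its value
# projection and a head with m >= l - 1 is ordinary global attention.
# Minus infinity is realized as -1e9, large enough to zero the softmax at
# double precision without producing NaNs.

MASK_NEG <- -1e9
LN_EPS <- 1e-6

#' Banded attention mask
#'
#' Builds the `l` x `l` additive mask of a head with window half-width `m`:
#' entry `(i, j)` is 0 when `|i - j| <= m` and a large negative constant
#' (standing in for minus infinity) otherwise. The diagonal is always
#' unmasked, so every query attends at least to itself.
#'
#' @param l Sequence length (>= 1).
#' @param m Window half-width (>= 0); `m >= l - 1` gives an all-zero mask.
#' @return `l` x `l` numeric matrix with attribute `window`.
#' @examples
#' band_mask(4, 1)  # zeros on the tridiagonal band
#' @export
band_mask <- function(l, m) {
  l <- as.integer(l); m <- as.integer(m)
  if (is.na(l) || l < 1L) stop("`l` must be >= 1", call. = FALSE)
  if (is.na(m) || m < 0L) stop("`m` must be >= 0", call. = FALSE)
  idx <- seq_len(l)
  M <- ifelse(abs(outer(idx, idx, `-`)) <= m, 0, MASK_NEG)
  attr(M, "window") <- m
  M
}

# --- layer normalization ----------------------------------------------------

ln_fwd <- function(x, gamma, beta) {
  mu <- rowMeans(x)
  xc <- x - mu
  inv <- 1 / sqrt(rowMeans(xc^2) + LN_EPS)
  xhat <- xc * inv
  y <- t(t(xhat) * gamma + beta)
  list(y = y, xhat = xhat, inv = inv)
}

ln_bwd <- function(dy, cache, gamma) {
  xhat <- cache$xhat
  dgamma <- colSums(dy * xhat)
  dbeta <- colSums(dy)
  dxhat <- t(t(dy) * gamma)
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dx <- (dxhat - m1 - xhat * m2) * cache$inv
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

#' Layer normalization
#'
#' Normalizes each row of `x` to zero mean and unit variance, then applies
#' the learned per-feature gain and shift.
#'
#' @param x Numeric matrix (rows are sequence positions).
#' @param gamma,beta Numeric vectors of length `ncol(x)`.
#' @return Matrix of the same shape as `x`.
#' @export
layer_norm <- function(x, gamma = rep(1, ncol(x)), beta = rep(0, ncol(x))) {
  ln_fwd(x, gamma, beta)$y
}

# --- one attention head -----------------------------------------------------

head_fwd <- function(E, Wq, Wk, Wv, mask, drop_p = 0, training = FALSE) {
  dh <- ncol(Wq)
  Q <- E %*% Wq
  K <- E %*% Wk
  V <- E %*% Wv
  S <- tcrossprod(Q, K) / sqrt(dh) + mask
  dead <- rowSums(mask > MASK_NEG / 2) == 0L
  rm <- apply(S, 1L, max)
  A <- exp(S - rm)
  A <- A / rowSums(A)
  if (any(dead)) A[dead, ] <- 0
  Adrop <- A
  dmask <- NULL
  if (training && drop_p > 0) {
    dmask <- matrix(stats::rbinom(length(A), 1L, 1 - drop_p) / (1 - drop_p),
                    nrow(A), ncol(A))
    Adrop <- A * dmask
  }
  H <- Adrop %*% V
  list(H = H, A = A, Adrop = Adrop, dmask = dmask, Q = Q, K = K, V = V,
       dh = dh)
}

head_bwd <- function(dH, cache, E, Wq, Wk, Wv) {
  dAdrop <- tcrossprod(dH, cache$V)
  dV <- crossprod(cache$Adrop, dH)
  dA <- if (is.null(cache$dmask)) dAdrop else dAdrop * cache$dmask
  A <- cache$A
  dS <- A * (dA - rowSums(dA * A))
  scale <- 1 / sqrt(cache$dh)
  dQ <- (dS %*% cache$K) * scale
  dK <- crossprod(dS, cache$Q) * scale
  list(
    dE = dQ %*% t(Wq) + dK %*% t(Wk) + dV %*% t(Wv),
    dWq = crossprod(E, dQ),
    dWk = crossprod(E, dK),
    dWv = crossprod(E, dV)
  )
}

#' One banded self-attention head
#'
#' Projects the input into query, key and value subspaces, forms
#' scaled-dot-product attention logits, adds the additive mask, and returns
#' the softmax-weighted values. Rows whose mask admits no key at all (which
#' happens for padded queries whose whole band is padded) output zeros.
#'
#' @param E `l` x `e` input matrix.
#' @param W_q,W_k,W_v `e` x `d_h` projection matrices.
#' @param mask `l` x `l` additive mask, typically [band_mask()] output plus
#'   any padding mask.
#' @return `l` x `d_h` matrix with attribute `"weights"`, the `l` x `l`
#'   attention weight matrix (rows sum to 1 on unmasked rows, exactly 0
#'   outside the mask support up to double precision).
#' @export
attention_head <- function(E, W_q, W_k, W_v, mask) {
  if (ncol(E) != nrow(W_q) || ncol(E) != nrow(W_k) || ncol(E) != nrow(W_v)) {
    stop("projection matrices must have `ncol(E)` rows", call. = FALSE)
  }
  if (!all(dim(mask) == nrow(E))) {
    stop("`mask` must be ", nrow(E), " x ", nrow(E), call. = FALSE)
  }
  out <- head_fwd(E, W_q, W_k, W_v, mask)
  structure(out$H, weights = out$A)
}

# --- one multi-scaled self-attention block ---------------------------------

block_fwd <- function(E, bp, masks, drop_p = 0, training = FALSE) {
  n_heads <- length(bp$heads)
  hcaches <- vector("list", n_heads)
  heads_out <- vector("list", n_heads)
  for (h in seq_len(n_heads)) {
    hp <- bp$heads[[h]]
    hcaches[[h]] <- head_fwd(E, hp$Wq, hp$Wk, hp$Wv, masks[[h]],
                             drop_p = drop_p, training = training)
    heads_out[[h]] <- hcaches[[h]]$H
  }
  concat <- do.call(cbind, heads_out)
  ln1 <- ln_fwd(concat + E, bp$ln1_g, bp$ln1_b)
  Z <- ln1$y
  P <- t(t(Z %*% bp$ffn_W) + bp$ffn_b)
  Fr <- pmax(P, 0)
  ln2 <- ln_fwd(Z + Fr, bp$ln2_g, bp$ln2_b)
  list(out = ln2$y, E = E, hcaches = hcaches, ln1 = ln1, Z = Z, P = P,
       ln2 = ln2)
}

block_bwd <- function(dout, cache, bp) {
  g <- zero_like(bp)
  l2 <- ln_bwd(dout, cache$ln2, bp$ln2_g)
  g$ln2_g <- l2$dgamma; g$ln2_b <- l2$dbeta
  dS2 <- l2$dx
  dP <- dS2 * (cache$P > 0)
  g$ffn_W <- crossprod(cache$Z, dP)
  g$ffn_b <- colSums(dP)
  dZ <- dS2 + tcrossprod(dP, bp$ffn_W)
  l1 <- ln_bwd(dZ, cache$ln1, bp$ln1_g)
  g$ln1_g <- l1$dgamma; g$ln1_b <- l1$dbeta
  dZ1 <- l1$dx
  dE <- dZ1  # residual path
  dh <- ncol(bp$heads[[1L]]$Wq)
  for (h in seq_along(bp$heads)) {
    cols <- ((h - 1L) * dh + 1L):(h * dh)
    hb <- head_bwd(dZ1[, cols, drop = FALSE], cache$hcaches[[h]], cache$E,
                   bp$heads[[h]]$Wq, bp$heads[[h]]$Wk, bp$heads[[h]]$Wv)
    dE <- dE + hb$dE
    g$heads[[h]]$Wq <- hb$dWq
    g$heads[[h]]$Wk <- hb$dWk
    g$heads[[h]]$Wv <- hb$dWv
  }
  list(dE = dE, grads = g)
}

#' One multi-scaled self-attention block
#'
#' Runs every head with its own band half-width, concatenates the head
#' outputs back to the model dimension (no output projection: the
#' concatenation is added directly to the input), applies the residual
#' connection and layer normalization, then a single position-wise affine
#' layer of width `e` with ReLU under a second residual + normalization.
#'
#' @param E `l` x `e` input matrix.
#' @param block Block parameter list as produced by [msaan_params()]
#'   (fields `heads` with `Wq`/`Wk`/`Wv` per head, `ln1_g`, `ln1_b`,
#'   `ffn_W`, `ffn_b`, `ln2_g`, `ln2_b`).
#' @param window_sizes Band half-width of each head (recycled over heads).
#' @param pad_ids Optional integer id vector of length `l`; positions with
#'   id 0 are treated as padding and masked out as attention keys in every
#'   head.
#' @return `l` x `e` output matrix.
#' @export
msaan_block <- function(E, block, window_sizes, pad_ids = NULL) {
  n_heads <- length(block$heads)
  dh <- ncol(block$heads[[1L]]$Wq)
  if (n_heads * dh != ncol(E)) {
    stop("head dimensions must concatenate to ncol(E)", call. = FALSE)
  }
  masks <- make_masks(nrow(E), rep_len(window_sizes, n_heads), pad_ids)
  block_fwd(E, block, masks)$out
}

# Per-head additive masks: band plus (optionally) key-side padding.
make_masks <- function(l, windows, pad_ids = NULL) {
  pad_row <- if (is.null(pad_ids)) NULL else ifelse(pad_ids == 0L, MASK_NEG, 0)
  lapply(windows, function(m) {
    M <- band_mask(l, min(m, l - 1L))
    if (!is.null(pad_row)) M <- M + matrix(pad_row, l, l, byrow = TRUE)
    M
  })
}

#' Token-plus-position embedding of an encoded sequence
#'
#' Row `i` of the result is the token-table row of id `ids[i]` plus row `i`
#' of the position table. Id 0 (padding) selects the first token row; the
#' reserved unknown id selects the last.
#'
#' @param ids Integer vector of length `l` (0-padded ids from
#'   [bpe_encode()]).
#' @param token_table `(vocab size + 2)` x `e` matrix: row 1 is the padding
#'   embedding, rows `2 .. size+1` the real tokens, the last row the
#'   unknown token.
#' @param position_table `l` x `e` matrix of position embeddings.
#' @return `l` x `e` embedding matrix.
#' @export
embed_sequence <- function(ids, token_table, position_table) {
  l <- nrow(position_table)
  if (length(ids) != l) {
    stop("`ids` must have length nrow(position_table)", call. = FALSE)
  }
  if (any(ids < 0L) || any(ids + 1L > nrow(token_table))) {
    stop("token id out of range for the embedding table", call. = FALSE)
  }
  token_table[ids + 1L, , drop = FALSE] + position_table
}

# Zero-filled copy of a (nested) parameter list.
zero_like <- function(p) {
  if (is.list(p)) return(lapply(p, zero_like))
  p * 0
}
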