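# Full-model forward and reverse passes.
#
# The network is small enough that reverse-mode gradients are coded by hand
# against the same caches the forward pass produces; a central-difference
# oracle in the test suite checks every parameter tensor.

drop_mask <- function(n, p) {
  stats::rbinom(n, 1L, 1 - p) / (1 - p)
}

enc_fwd <- function(ids, side, windows, drop_p = 0, training = FALSE) {
  E <- side$token[ids + 1L, , drop = FALSE] + side$pos
  emb_mask <- NULL
  if (training && drop_p > 0) {
    emb_mask <- matrix(stats::rbinom(length(E), 1L, 1 - drop_p) / (1 - drop_p),
                       nrow(E), ncol(E))
    E <- E * emb_mask
  }
  masks <- make_masks(nrow(side$pos), windows, pad_ids = ids)
  caches <- vector("list", length(side$blocks))
  for (b in seq_along(side$blocks)) {
    caches[[b]] <- block_fwd(E, side$blocks[[b]], masks,
                             drop_p = drop_p, training = training)
    E <- caches[[b]]$out
  }
  list(R = E, caches = caches, emb_mask = emb_mask, ids = ids)
}

enc_bwd <- function(dR, fwd, side) {
  g <- list(token = side$token * 0, pos = side$pos * 0,
            blocks = vector("list", length(side$blocks)))
  dE <- dR
  for (b in rev(seq_along(side$blocks))) {
    bb <- block_bwd(dE, fwd$caches[[b]], side$blocks[[b]])
    g$blocks[[b]] <- bb$grads
    dE <- bb$dE
  }
  if (!is.null(fwd$emb_mask)) dE <- dE * fwd$emb_mask
  g$pos <- dE
  rs <- rowsum(dE, group = fwd$ids + 1L)
  g$token[as.integer(rownames(rs)), ] <- rs
  g
}

aggregate_fwd <- function(Rd, Rp, how) {
  switch(how,
    flatten = list(r = c(as.vector(Rd), as.vector(Rp))),
    mean = list(r = c(colMeans(Rd), colMeans(Rp))),
    max = {
      id <- apply(Rd, 2L, which.max); ip <- apply(Rp, 2L, which.max)
      list(r = c(Rd[cbind(id, seq_len(ncol(Rd)))],
                 Rp[cbind(ip, seq_len(ncol(Rp)))]),
           argmax_d = id, argmax_p = ip)
    }
  )
}

aggregate_bwd <- function(dr, agg, Rd_dim, Rp_dim, how) {
  nd <- switch(how, flatten = prod(Rd_dim), Rd_dim[2L])
  dr_d <- dr[seq_len(nd)]
  dr_p <- dr[(nd + 1L):length(dr)]
  dRd <- matrix(0, Rd_dim[1L], Rd_dim[2L])
  dRp <- matrix(0, Rp_dim[1L], Rp_dim[2L])
  if (how == "flatten") {
    dRd[] <- dr_d
    dRp[] <- dr_p
  } else if (how == "mean") {
    dRd <- matrix(dr_d / Rd_dim[1L], Rd_dim[1L], Rd_dim[2L], byrow = TRUE)
    dRp <- matrix(dr_p / Rp_dim[1L], Rp_dim[1L], Rp_dim[2L], byrow = TRUE)
  } else {
    dRd[cbind(agg$argmax_d, seq_len(Rd_dim[2L]))] <- dr_d
    dRp[cbind(agg$argmax_p, seq_len(Rp_dim[2L]))] <- dr_p
  }
  list(dRd = dRd, dRp = dRp)
}

inter_fwd <- function(r, ip, drop_p = 0, training = FALSE) {
  z1 <- drop(r %*% ip$W1) + ip$b1; a1 <- pmax(z1, 0)
  m1 <- NULL
  if (training && drop_p > 0) { m1 <- drop_mask(length(a1), drop_p); a1 <- a1 * m1 }
  z2 <- drop(a1 %*% ip$W2) + ip$b2; a2 <- pmax(z2, 0)
  m2 <- NULL
  if (training && drop_p > 0) { m2 <- drop_mask(length(a2), drop_p); a2 <- a2 * m2 }
  z3 <- drop(a2 %*% ip$W3) + ip$b3; a3 <- pmax(z3, 0)
  m3 <- NULL
  if (training && drop_p > 0) { m3 <- drop_mask(length(a3), drop_p); a3 <- a3 * m3 }
  y <- sum(a3 * ip$W4[, 1L]) + ip$b4
  list(y = y, r = r, z1 = z1, a1 = a1, z2 = z2, a2 = a2, z3 = z3, a3 = a3,
       m1 = m1, m2 = m2, m3 = m3)
}

inter_bwd <- function(dy, cache, ip) {
  g <- zero_like(ip)
  g$W4 <- matrix(cache$a3 * dy, ncol = 1L)
  g$b4 <- dy
  da3 <- dy * ip$W4[, 1L]
  if (!is.null(cache$m3)) da3 <- da3 * cache$m3
  dz3 <- da3 * (cache$z3 > 0)
  g$W3 <- outer(cache$a2, dz3); g$b3 <- dz3
  da2 <- drop(ip$W3 %*% dz3)
  if (!is.null(cache$m2)) da2 <- da2 * cache$m2
  dz2 <- da2 * (cache$z2 > 0)
  g$W2 <- outer(cache$a1, dz2); g$b2 <- dz2
  da1 <- drop(ip$W2 %*% dz2)
  if (!is.null(cache$m1)) da1 <- da1 * cache$m1
  dz1 <- da1 * (cache$z1 > 0)
  g$W1 <- outer(cache$r, dz1); g$b1 <- dz1
  dr <- drop(ip$W1 %*% dz1)
  list(dr = dr, grads = g)
}

# Forward pass for one drug-protein pair; returns the scalar prediction and
# (when `keep = TRUE`) every cache the reverse pass needs.
pair_fwd <- function(params, ids_d, ids_p, config, training = FALSE,
                     keep = FALSE) {
  windows <- head_windows(config)
  p <- config$dropout
  fd <- enc_fwd(ids_d, params$drug, windows, drop_p = p, training = training)
  fp <- enc_fwd(ids_p, params$protein, windows, drop_p = p,
                training = training)
  agg <- aggregate_fwd(fd$R, fp$R, config$aggregation)
  ic <- inter_fwd(agg$r, params$inter, drop_p = p, training = training)
  if (!keep) return(list(y = ic$y))
  list(y = ic$y, fd = fd, fp = fp, agg = agg, ic = ic)
}

pair_bwd <- function(dy, fwd, params, config) {
  ib <- inter_bwd(dy, fwd$ic, params$inter)
  ab <- aggregate_bwd(ib$dr, fwd$agg, dim(fwd$fd$R), dim(fwd$fp$R),
                      config$aggregation)
  list(
    drug = enc_bwd(ab$dRd, fwd$fd, params$drug),
    protein = enc_bwd(ab$dRp, fwd$fp, params$protein),
    inter = ib$grads
  )
}

# Sum two parameter trees of identical shape.
tree_add <- function(a, b) {
  if (is.list(a)) return(mapply(tree_add, a, b, SIMPLIFY = FALSE))
  a + b
}

tree_scale <- function(a, s) {
  if (is.list(a)) return(lapply(a, tree_scale, s = s))
  a * s
}

# Mean-squared-error loss and its gradient over a batch of encoded pairs.
# `batch` is a list of lists with integer vectors `ids_d`, `ids_p` and the
# (possibly standardized) target `y`.
batch_loss_grad <- function(params, batch, config, training = TRUE) {
  n <- length(batch)
  grads <- NULL
  preds <- numeric(n)
  for (i in seq_len(n)) {
    fwd <- pair_fwd(params, batch[[i]]$ids_d, batch[[i]]$ids_p, config,
                    training = training, keep = TRUE)
    preds[i] <- fwd$y
    dy <- 2 * (fwd$y - batch[[i]]$y) / n
    g <- pair_bwd(dy, fwd, params, config)
    grads <- if (is.null(grads)) g else tree_add(grads, g)
  }
  ys <- vapply(batch, `[[`, 0, "y")
  list(loss = mean((preds - ys)^2), grads = grads, preds = preds)
}
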