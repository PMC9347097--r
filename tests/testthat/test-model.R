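test_that("band mask realizes the window condition", {
  m0 <- band_mask(3, 0)
  expect_true(all(diag(m0) == 0))
  expect_true(all(m0[row(m0) != col(m0)] < 0))

  expect_true(all(band_mask(4, 3) == 0))
  expect_true(all(band_mask(4, 10) == 0))

  m1 <- band_mask(4, 1)
  on_band <- abs(row(m1) - col(m1)) <= 1
  expect_true(all(m1[on_band] == 0))
  expect_true(all(m1[!on_band] < 0))

  expect_error(band_mask(0, 1), ">= 1")
  expect_error(band_mask(3, -1), ">= 0")
})

test_that("a head with window 0 copies its value projection", {
  set.seed(5)
  E <- matrix(rnorm(6 * 8), 6, 8)
  hp <- random_block_params(8, 2, seed = 5)$heads[[1L]]
  out <- attention_head(E, hp$Wq, hp$Wk, hp$Wv, band_mask(6, 0))
  expect_equal(unclass(out), E %*% hp$Wv, ignore_attr = TRUE)
  W <- attr(out, "weights")
  expect_equal(W, diag(6), ignore_attr = TRUE)
})

test_that("a full-width head equals unmasked scaled-dot-product attention", {
  set.seed(6)
  E <- matrix(rnorm(6 * 8), 6, 8)
  hp <- random_block_params(8, 2, seed = 6)$heads[[2L]]
  out <- attention_head(E, hp$Wq, hp$Wk, hp$Wv, band_mask(6, 5))
  # independent reference: plain softmax(QK'/sqrt(d)) V
  Q <- E %*% hp$Wq; K <- E %*% hp$Wk; V <- E %*% hp$Wv
  S <- Q %*% t(K) / sqrt(ncol(hp$Wq))
  A <- t(apply(S, 1, function(r) exp(r - max(r)) / sum(exp(r - max(r)))))
  expect_equal(unclass(out), A %*% V, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("attention weights are row-stochastic and vanish outside the band", {
  set.seed(7)
  E <- matrix(rnorm(10 * 8), 10, 8)
  hp <- random_block_params(8, 2, seed = 7)$heads[[1L]]
  for (m in c(0L, 1L, 3L, 9L)) {
    W <- attr(attention_head(E, hp$Wq, hp$Wk, hp$Wv, band_mask(10, m)),
              "weights")
    expect_equal(rowSums(W), rep(1, 10), tolerance = 1e-6)
    off_band <- abs(row(W) - col(W)) > m
    if (any(off_band)) expect_true(all(W[off_band] < 1e-12))
  }
  expect_error(attention_head(E, hp$Wq[1:3, ], hp$Wk, hp$Wv,
                              band_mask(10, 1)), "rows")
})

test_that("the block preserves shape, is deterministic, and stacks", {
  set.seed(8)
  E <- matrix(rnorm(6 * 8), 6, 8)
  bp <- random_block_params(8, 2, seed = 8)
  out1 <- msaan_block(E, bp, window_sizes = c(0L, 2L))
  out2 <- msaan_block(E, bp, window_sizes = c(0L, 2L))
  expect_identical(dim(out1), dim(E))
  expect_identical(out1, out2)
  # stacking composes without shape change
  stacked <- msaan_block(out1, bp, window_sizes = c(0L, 2L))
  expect_identical(dim(stacked), dim(E))
})

test_that("with all heads at full width the block matches a vanilla
           multi-head attention block", {
  set.seed(9)
  for (rep in 1:3) {
    E <- matrix(rnorm(7 * 8), 7, 8)
    bp <- random_block_params(8, 4, seed = 100 + rep)
    ours <- msaan_block(E, bp, window_sizes = rep(6L, 4L))
    ref <- ref_vanilla_block(E, bp)
    expect_equal(ours, ref, tolerance = 1e-6)
  }
})

test_that("embedding adds token and position tables", {
  set.seed(10)
  tok <- matrix(rnorm(7 * 4), 7, 4)
  pos <- matrix(rnorm(5 * 4), 5, 4)
  ids <- c(3L, 1L, 0L, 0L, 0L)
  E <- embed_sequence(ids, tok, pos)
  expect_identical(dim(E), c(5L, 4L))
  expect_equal(E, tok[ids + 1L, ] + pos)
  # zero token table leaves only positions
  expect_equal(embed_sequence(ids, tok * 0, pos), pos)
  expect_error(embed_sequence(c(9L, 0L, 0L, 0L, 0L), tok, pos),
               "out of range")
})

test_that("padded keys are masked and fully padded queries output zero", {
  cfg <- micro_config()
  params <- msaan_params(cfg, 9, 7, seed = 2)
  ids <- c(3L, 5L, 0L, 0L, 0L, 0L)
  fwd <- msadta:::enc_fwd(ids, params$drug, msadta:::head_windows(cfg))
  # head 1 has window 0: padded queries see only their own padded key
  A1 <- fwd$caches[[1L]]$hcaches[[1L]]$A
  expect_true(all(A1[3:6, ] == 0))
  # real queries never place weight on padded keys, in any head
  for (h in 1:2) {
    A <- fwd$caches[[1L]]$hcaches[[h]]$A
    expect_true(all(A[1:2, 3:6] < 1e-12))
    expect_equal(rowSums(A[1:2, , drop = FALSE]), c(1, 1), tolerance = 1e-6)
  }
})

test_that("position embeddings make the model order-sensitive", {
  cfg <- micro_config()
  params <- msaan_params(cfg, 9, 7, seed = 4)
  ids_d <- c(1L, 2L, 3L, 4L, 5L, 6L)
  ids_p <- c(2L, 4L, 6L, 1L, 3L, 5L)
  y1 <- msadta:::pair_fwd(params, ids_d, ids_p, cfg)$y
  y2 <- msadta:::pair_fwd(params, rev(ids_d), ids_p, cfg)$y
  expect_false(isTRUE(all.equal(y1, y2)))
})

test_that("interaction stack with zero weights predicts zero", {
  cfg <- micro_config()
  params <- msaan_params(cfg, 9, 7, seed = 6)
  params$inter <- msadta:::zero_like(params$inter)
  y <- msadta:::pair_fwd(params, c(1L, 2L, 3L, 0L, 0L, 0L),
                         c(4L, 5L, 0L, 0L, 0L, 0L), cfg)$y
  expect_identical(y, 0)
})

test_that("closed-form parameter count matches instantiated models", {
  cfg <- micro_config()
  expect_identical(n_parameters(cfg, 9, 7),
                   length(unlist(msaan_params(cfg, 9, 7))))
  # benchmark-structure config (two blocks per side, e = 128); mean
  # aggregation keeps the interaction stack small enough to instantiate
  kiba_mean <- msaan_config("kiba", aggregation = "mean")
  expect_identical(n_parameters(kiba_mean, 500, 800),
                   length(unlist(msaan_params(kiba_mean, 500, 800))))
})

test_that("the shipped benchmark config's parameter count matches an
           independently written expansion", {
  kiba <- msaan_config("kiba")
  v_d <- 500; v_p <- 800
  # embeddings + per-block (N heads x 3 projections of e x e/N, one e x e
  # affine + bias, two norms of 2e) + flatten interaction stack
  e <- 128; N <- 4
  per_block <- N * 3 * e * (e / N) + (e * e + e) + 2 * 2 * e
  drug <- (v_d + 2) * e + 80 * e + 2 * per_block
  prot <- (v_p + 2) * e + 800 * e + 2 * per_block
  d_in <- 80 * e + 800 * e
  inter <- d_in * 1024 + 1024 + 1024 * 1024 + 1024 +
    1024 * 512 + 512 + 512 * 1 + 1
  expect_identical(n_parameters(kiba, v_d, v_p),
                   as.integer(drug + prot + inter))
})

test_that("aggregation variants stay differentiable and well-shaped", {
  for (how in c("flatten", "mean", "max")) {
    cfg <- micro_config(aggregation = how)
    params <- msaan_params(cfg, 9, 7, seed = 8)
    batch <- list(list(ids_d = c(3L, 5L, 9L, 1L, 0L, 0L),
                       ids_p = c(2L, 7L, 4L, 4L, 6L, 0L), y = 0.5))
    res <- msadta:::batch_loss_grad(params, batch, cfg, training = FALSE)
    expect_true(is.finite(res$loss))
    flat <- unlist(params); g <- unlist(res$grads)
    # spot-check a handful of coordinates against central differences
    set.seed(41)
    for (i in sample(length(flat), 25L)) {
      h <- 1e-5
      up <- flat; up[i] <- up[i] + h
      dn <- flat; dn[i] <- dn[i] - h
      num <- (msadta:::batch_loss_grad(utils::relist(up, params), batch, cfg,
                                       training = FALSE)$loss -
              msadta:::batch_loss_grad(utils::relist(dn, params), batch, cfg,
                                       training = FALSE)$loss) / (2 * h)
      expect_equal(unname(g[i]), num, tolerance = 1e-5)
    }
  }
})

test_that("training beats the constant mean predictor on planted data", {
  d <- generate_affinity_dataset(
    synthetic_spec(n_drugs = 20, n_proteins = 10, seed = 5))
  expect_identical(nrow(d$triples), 200L)
  cfg <- msaan_config("tiny", l_d = 12L, l_p = 12L, epochs = 30L)
  fit <- msaan(d, cfg, seed = 3)
  y <- d$triples$affinity
  mean_mse <- mean((y - mean(y))^2)
  expect_lt(fit$loss_trace[cfg$epochs], mean_mse)
  expect_lt(mse_score(y, fit$fitted_values), mean_mse)
})

test_that("identical seeds give identical loss traces; lr 0 freezes them", {
  d <- generate_affinity_dataset(
    synthetic_spec(n_drugs = 6, n_proteins = 4, seed = 9))
  cfg <- micro_config(epochs = 3L, batch_size = 8L)
  f1 <- msaan(d, cfg, seed = 11)
  f2 <- msaan(d, cfg, seed = 11)
  expect_identical(f1$loss_trace, f2$loss_trace)
  expect_identical(unlist(f1$params), unlist(f2$params))

  frozen <- msaan(d, micro_config(epochs = 3L, learning_rate = 0), seed = 11)
  expect_equal(frozen$loss_trace, rep(frozen$loss_trace[1L], 3L))
})

test_that("model methods print, summarize, predict and simulate", {
  d <- generate_affinity_dataset(
    synthetic_spec(n_drugs = 6, n_proteins = 4, seed = 13))
  fit <- msaan(d, micro_config(epochs = 2L), seed = 1)
  expect_output(print(fit), "Multi-scaled")
  expect_output(print(summary(fit)), "trainable parameters")
  expect_length(residuals(fit), 24L)
  expect_equal(fitted(fit) + residuals(fit), d$triples$affinity)
  expect_type(coef(fit), "list")
  expect_length(coef(fit, flatten = TRUE),
                n_parameters(fit$config, fit$vocab_drug$size,
                             fit$vocab_protein$size))
  preds <- predict(fit, data.frame(smiles = unname(d$drugs)[1:2],
                                   sequence = unname(d$proteins)[1:2]))
  expect_length(preds, 2L)
  expect_true(all(is.finite(preds)))
  sims <- simulate(fit, nsim = 2, seed = 5)
  expect_identical(dim(sims), c(24L, 2L))
  expect_identical(sims, simulate(fit, nsim = 2, seed = 5))
  pdf(NULL); on.exit(dev.off())
  expect_invisible(plot(fit))
})

test_that("config validation rejects inconsistent settings", {
  expect_error(msaan_config("tiny", e_d = 15L), "divide")
  expect_error(msaan_config("tiny", window_sizes = c(-1L, 1L)),
               "non-negative")
  expect_error(msaan_config("tiny", window_sizes = 0:5), "more window")
  expect_error(msaan_config("tiny", ffn_hidden = c(8L, 4L)), "4 layer")
  expect_error(msaan_config("tiny", dropout = 1), "dropout")
  expect_error(msaan_config("tiny", nonsense = 1), "unknown config")
  # windows cycle over extra heads
  cfg <- msaan_config("tiny", n_heads = 8L, e_d = 16L, e_p = 16L)
  expect_identical(msadta:::head_windows(cfg), rep(0:3, 2L))
})
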