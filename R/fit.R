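# The fitting front end: msaan() and its methods.

#' Fit a multi-scaled self-attention affinity regressor
#'
#' Trains the full pipeline on an affinity dataset: BPE vocabularies are
#' learned on the dataset's drug and protein tables (unless pre-trained
#' vocabularies are supplied), every sequence is encoded as a fixed-length
#' padded id vector, and the attention model is optimized with Adam on the
#' mean-squared-error loss at the configured learning rate. Targets are
#' standardized internally on the training split (and predictions mapped
#' back), which conditions the optimization without changing the loss being
#' minimized. Training is fully seeded: identical inputs and seed give
#' bit-identical parameter trajectories and loss traces.
#'
#' @param data An [affinity_dataset()].
#' @param config An [msaan_config()]; default the `"tiny"` preset.
#' @param seed Integer seed covering initialization, shuffling and dropout.
#' @param subset Integer indices of `data$triples` to train on. Default:
#'   all triples, or all non-test triples when `data` carries folds.
#' @param vocab_drug,vocab_protein Optional pre-trained [bpe_vocabulary()]
#'   objects; by default vocabularies are trained on the dataset's own
#'   sequence tables at the config's BPE thresholds.
#' @param verbose Print the per-epoch training loss.
#' @return An object of class `"msaan"` with components `params`, `config`,
#'   `vocab_drug`, `vocab_protein`, `loss_trace` (per-epoch training MSE on
#'   the original affinity scale), `y_center`, `y_scale`, `train_idx`,
#'   `fitted_values`, `data` and `call`. Supports `print()`, `summary()`,
#'   `predict()`, `coef()`, `residuals()`, `plot()` and `simulate()`.
#' @examples
#' \donttest{
#' d <- generate_affinity_dataset(synthetic_spec(n_drugs = 8, n_proteins = 4))
#' fit <- msaan(d, msaan_config("tiny", epochs = 3), seed = 1)
#' print(fit)
#' }
#' @export
msaan <- function(data, config = msaan_config("tiny"), seed = 1L,
                  subset = NULL, vocab_drug = NULL, vocab_protein = NULL,
                  verbose = FALSE) {
  stopifnot(inherits(data, "affinity_dataset"),
            inherits(config, "msaan_config"))
  if (is.null(subset)) {
    subset <- if (is.null(data$folds)) seq_len(nrow(data$triples))
              else which(data$folds != 0L)
  }
  if (length(subset) == 0L) stop("empty training split", call. = FALSE)

  if (is.null(vocab_drug)) {
    vocab_drug <- bpe_vocabulary(
      bpe_train(unname(data$drugs), config$bpe_threshold_drug))
  }
  if (is.null(vocab_protein)) {
    vocab_protein <- bpe_vocabulary(
      bpe_train(unname(data$proteins), config$bpe_threshold_protein))
  }

  enc_d <- bpe_encode_matrix(data$drugs, vocab_drug, config$l_d)
  enc_p <- bpe_encode_matrix(data$proteins, vocab_protein, config$l_p)

  y_raw <- data$triples$affinity[subset]
  y_center <- mean(y_raw)
  y_scale <- stats::sd(y_raw)
  if (!is.finite(y_scale) || y_scale == 0) y_scale <- 1
  y_std <- (y_raw - y_center) / y_scale

  batch <- lapply(seq_along(subset), function(i) {
    tr <- data$triples[subset[i], ]
    list(ids_d = enc_d[tr$drug_id, ], ids_p = enc_p[tr$protein_id, ],
         y = y_std[i])
  })

  params <- msaan_params(config, vocab_drug$size, vocab_protein$size,
                         seed = seed)
  skeleton <- params
  flat <- unlist(params, use.names = FALSE)
  trace <- numeric(config$epochs)

  with_seed(seed + 1L, {
    m <- v <- numeric(length(flat))
    t_step <- 0L
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    lr <- config$learning_rate
    n <- length(batch)
    bs <- min(config$batch_size, n)
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = bs)
      ep_loss <- 0
      for (s in starts) {
        idx <- ord[s:min(s + bs - 1L, n)]
        params <- utils::relist(flat, skeleton)
        res <- batch_loss_grad(params, batch[idx], config, training = TRUE)
        if (!is.finite(res$loss)) {
          stop("training diverged: non-finite loss at epoch ", epoch,
               " (learning rate ", lr, "); lower the learning rate or ",
               "inspect the affinities for outliers", call. = FALSE)
        }
        ep_loss <- ep_loss + res$loss * length(idx)
        gflat <- unlist(res$grads, use.names = FALSE)
        t_step <- t_step + 1L
        m <- b1 * m + (1 - b1) * gflat
        v <- b2 * v + (1 - b2) * gflat^2
        mhat <- m / (1 - b1^t_step)
        vhat <- v / (1 - b2^t_step)
        flat <- flat - lr * mhat / (sqrt(vhat) + eps)
      }
      trace[epoch] <- ep_loss / n * y_scale^2
      if (verbose) {
        message(sprintf("epoch %3d  train MSE %.5f", epoch, trace[epoch]))
      }
    }
  })
  params <- utils::relist(flat, skeleton)

  fitted_std <- vapply(batch, function(b) {
    pair_fwd(params, b$ids_d, b$ids_p, config)$y
  }, 0)
  fitted_values <- fitted_std * y_scale + y_center

  structure(
    list(params = params, config = config,
         vocab_drug = vocab_drug, vocab_protein = vocab_protein,
         y_center = y_center, y_scale = y_scale,
         loss_trace = trace, train_idx = subset,
         fitted_values = fitted_values, y_train = y_raw,
         data = data, seed = seed, call = match.call()),
    class = "msaan"
  )
}

encode_for_model <- function(object, smiles, sequences) {
  list(
    d = bpe_encode_matrix(smiles, object$vocab_drug, object$config$l_d),
    p = bpe_encode_matrix(sequences, object$vocab_protein, object$config$l_p)
  )
}

#' Predict binding affinities from a fitted model
#'
#' @param object A fitted `"msaan"` model.
#' @param newdata Either an [affinity_dataset()] (predictions for all its
#'   triples, or the rows in `subset`), or a data frame with character
#'   columns `smiles` and `sequence`, one drug-protein pair per row.
#'   Default: the training dataset.
#' @param subset Optional triple indices when `newdata` is a dataset.
#' @param ... Unused.
#' @return Numeric vector of predicted affinities on the original scale.
#' @export
predict.msaan <- function(object, newdata = NULL, subset = NULL, ...) {
  if (is.null(newdata)) newdata <- object$data
  if (inherits(newdata, "affinity_dataset")) {
    idx <- subset %||% seq_len(nrow(newdata$triples))
    enc <- encode_for_model(object, newdata$drugs, newdata$proteins)
    preds <- vapply(idx, function(i) {
      tr <- newdata$triples[i, ]
      pair_fwd(object$params, enc$d[tr$drug_id, ], enc$p[tr$protein_id, ],
               object$config)$y
    }, 0)
  } else {
    if (!all(c("smiles", "sequence") %in% names(newdata))) {
      stop("`newdata` must be an affinity_dataset or have columns ",
           "`smiles` and `sequence`", call. = FALSE)
    }
    enc <- encode_for_model(object, as.character(newdata$smiles),
                            as.character(newdata$sequence))
    preds <- vapply(seq_len(nrow(newdata)), function(i) {
      pair_fwd(object$params, enc$d[i, ], enc$p[i, ], object$config)$y
    }, 0)
  }
  preds * object$y_scale + object$y_center
}

#' @export
print.msaan <- function(x, ...) {
  cat("Multi-scaled self-attention affinity model\n")
  cat("  config:", x$config$preset, " heads:", x$config$n_heads,
      "windows", paste(head_windows(x$config), collapse = ","), "\n")
  cat("  vocabularies:", x$vocab_drug$size, "drug tokens,",
      x$vocab_protein$size, "protein tokens\n")
  cat("  trained", x$config$epochs, "epochs on", length(x$train_idx),
      "pairs; final train MSE",
      format(x$loss_trace[length(x$loss_trace)], digits = 4), "\n")
  invisible(x)
}

#' @export
summary.msaan <- function(object, ...) {
  res <- object$y_train - object$fitted_values
  out <- list(
    config = object$config,
    n_train = length(object$train_idx),
    n_params = n_parameters(object$config, object$vocab_drug$size,
                            object$vocab_protein$size),
    train_metrics = evaluate_predictions(object$y_train,
                                         object$fitted_values),
    residual_summary = summary(res),
    final_loss = object$loss_trace[length(object$loss_trace)]
  )
  class(out) <- "summary.msaan"
  out
}

#' @export
print.summary.msaan <- function(x, ...) {
  cat("Multi-scaled self-attention affinity model\n")
  print(x$config)
  cat("  trainable parameters:", x$n_params, "\n")
  cat("  training pairs:", x$n_train, "\n")
  cat("  training metrics: MSE", format(x$train_metrics["mse"], digits = 4),
      " CI", format(x$train_metrics["ci"], digits = 4),
      " r2m", format(x$train_metrics["r2m"], digits = 4), "\n")
  cat("  residuals:\n")
  print(x$residual_summary)
  invisible(x)
}

#' @export
coef.msaan <- function(object, flatten = FALSE, ...) {
  if (flatten) unlist(object$params) else object$params
}

#' @export
residuals.msaan <- function(object, ...) {
  object$y_train - object$fitted_values
}

#' @export
fitted.msaan <- function(object, ...) {
  object$fitted_values
}

#' Plot the training loss trace
#'
#' @param x A fitted `"msaan"` model.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.msaan <- function(x, ...) {
  graphics::plot(seq_along(x$loss_trace), x$loss_trace, type = "l",
                 xlab = "epoch", ylab = "training MSE",
                 main = "Training loss", ...)
  invisible(x)
}

#' Simulate affinities from a fitted model
#'
#' Draws predictions for the training pairs plus Gaussian noise with the
#' residual standard deviation, the model's implicit observation model.
#'
#' @param object A fitted `"msaan"` model.
#' @param nsim Number of simulated replicates.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return Data frame with `nsim` columns.
#' @export
simulate.msaan <- function(object, nsim = 1L, seed = NULL, ...) {
  sd_hat <- stats::sd(residuals(object))
  n <- length(object$fitted_values)
  draw <- function() object$fitted_values + stats::rnorm(n, sd = sd_hat)
  sims <- if (is.null(seed)) {
    replicate(nsim, draw())
  } else {
    with_seed(seed, replicate(nsim, draw()))
  }
  out <- as.data.frame(matrix(sims, nrow = n))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}
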