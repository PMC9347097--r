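# Cross-validated training and the run manifest.

#' Run k-fold cross-validated training
#'
#' Implements the benchmark protocol: the dataset carries a fixed held-out
#' test split plus `k` training folds ([split_folds()] assigns them if
#' absent); one model is trained per fold on the other `k - 1` folds and
#' every model is evaluated on the shared test split with MSE, concordance
#' index and r^2_m. Per-fold metrics and their mean and standard deviation
#' are collected in a manifest, every aggregate of which is recomputable
#' from the raw per-fold entries.
#'
#' @param data An [affinity_dataset()]; folds are assigned with the default
#'   protocol (`k` folds, test fraction 1/6) if missing.
#' @param config An [msaan_config()].
#' @param seed Integer seed; fold `i` trains with seed `seed + i`.
#' @param k Number of folds when folds must be assigned (default 5).
#' @param verbose Print per-fold progress.
#' @return An object of class `"msaan_cv"`: a list with `per_fold` (data
#'   frame of fold, mse, ci, r2m), `mean`, `sd`, `config`, `seed`,
#'   `vocab_hashes` and `models` (the fitted `"msaan"` objects).
#' @export
run_cv <- function(data, config = msaan_config("tiny"), seed = 1L, k = 5L,
                   verbose = FALSE) {
  stopifnot(inherits(data, "affinity_dataset"))
  if (is.null(data$folds)) data <- split_folds(data, k = k, seed = seed)
  k <- max(data$folds)
  test_idx <- which(data$folds == 0L)
  if (length(test_idx) < 3L) stop("test split too small", call. = FALSE)
  y_test <- data$triples$affinity[test_idx]

  vocab_drug <- bpe_vocabulary(
    bpe_train(unname(data$drugs), config$bpe_threshold_drug))
  vocab_protein <- bpe_vocabulary(
    bpe_train(unname(data$proteins), config$bpe_threshold_protein))

  rows <- vector("list", k)
  models <- vector("list", k)
  for (f in seq_len(k)) {
    if (verbose) message("fold ", f, "/", k)
    train_idx <- which(data$folds != 0L & data$folds != f)
    fit <- msaan(data, config, seed = seed + f, subset = train_idx,
                 vocab_drug = vocab_drug, vocab_protein = vocab_protein,
                 verbose = verbose)
    preds <- predict(fit, data, subset = test_idx)
    met <- evaluate_predictions(y_test, preds)
    rows[[f]] <- data.frame(fold = f, mse = met["mse"], ci = met["ci"],
                            r2m = met["r2m"], row.names = NULL)
    models[[f]] <- fit
  }
  per_fold <- do.call(rbind, rows)
  structure(
    list(
      per_fold = per_fold,
      mean = colMeans(per_fold[c("mse", "ci", "r2m")]),
      sd = vapply(per_fold[c("mse", "ci", "r2m")], stats::sd, 0),
      config = config, seed = seed, k = k,
      n_test = length(test_idx),
      vocab_hashes = c(drug = object_hash(vocab_drug),
                       protein = object_hash(vocab_protein)),
      models = models
    ),
    class = "msaan_cv"
  )
}

#' @export
print.msaan_cv <- function(x, digits = 3, ...) {
  cat("Cross-validated multi-scaled SAN (", x$k, " folds, ", x$n_test,
      " shared test pairs)\n", sep = "")
  for (m in c("ci", "mse", "r2m")) {
    cat(sprintf("  %-4s %s (%s)\n", toupper(m),
                format(round(x$mean[[m]], digits), nsmall = digits),
                format(round(x$sd[[m]], digits), nsmall = digits)))
  }
  invisible(x)
}

#' Write a cross-validation manifest to JSON
#'
#' Serializes the config snapshot, seeds, vocabulary hashes and the raw
#' per-fold metrics (from which every reported mean and standard deviation
#' can be recomputed) to a JSON file.
#'
#' @param cv An `"msaan_cv"` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(cv, path) {
  stopifnot(inherits(cv, "msaan_cv"))
  cfg <- unclass(cv$config)
  obj <- list(
    config = cfg,
    seed = cv$seed,
    k = cv$k,
    n_test = cv$n_test,
    vocab_hashes = as.list(cv$vocab_hashes),
    per_fold = cv$per_fold,
    mean = as.list(cv$mean),
    sd = as.list(cv$sd)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
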