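# Model configuration and shipped presets.

#' Model configuration
#'
#' Collects every hyper-parameter of the multi-scaled self-attention
#' regressor. Three presets are shipped: `"kiba"` and `"davis"` mirror the
#' benchmark settings (length caps 80/800 and 36/900, embedding sizes 128
#' and 64, window sizes 0-3, two drug blocks, two resp. one protein blocks,
#' interaction stack 1024/1024/512/1, dropout 0.1, Adam at 1e-4 for 300
#' epochs), while `"tiny"` is a desk-scale configuration for synthetic data
#' (length caps 16/16, embedding size 16, four heads at windows 0-3, one
#' block per side, interaction stack 64/64/32/1, no dropout, 50 epochs).
#'
#' @param preset `"tiny"`, `"kiba"` or `"davis"`.
#' @param ... Named overrides of individual fields, e.g. `epochs = 10`.
#' @return An object of class `"msaan_config"`: a validated list with
#'   fields `l_d`, `l_p` (length caps), `e_d`, `e_p` (embedding sizes),
#'   `n_heads`, `window_sizes` (band half-widths, one per head, cycled if
#'   fewer than `n_heads`), `L_d`, `L_p` (block counts), `ffn_hidden`
#'   (interaction-stack widths, last entry 1), `dropout`, `learning_rate`,
#'   `epochs`, `batch_size`, `aggregation` (`"flatten"`, `"mean"` or
#'   `"max"`), and BPE thresholds `bpe_threshold_drug`,
#'   `bpe_threshold_protein`.
#' @examples
#' msaan_config("tiny", epochs = 5)
#' @export
msaan_config <- function(preset = c("tiny", "kiba", "davis"), ...) {
  preset <- match.arg(preset)
  cfg <- switch(preset,
    tiny = list(
      l_d = 16L, l_p = 16L, e_d = 16L, e_p = 16L,
      n_heads = 4L, window_sizes = c(0L, 1L, 2L, 3L),
      L_d = 1L, L_p = 1L, ffn_hidden = c(64L, 64L, 32L, 1L),
      dropout = 0, learning_rate = 1e-4, epochs = 50L, batch_size = 8L,
      aggregation = "flatten",
      bpe_threshold_drug = 50L, bpe_threshold_protein = 50L
    ),
    kiba = list(
      l_d = 80L, l_p = 800L, e_d = 128L, e_p = 128L,
      n_heads = 4L, window_sizes = c(0L, 1L, 2L, 3L),
      L_d = 2L, L_p = 2L, ffn_hidden = c(1024L, 1024L, 512L, 1L),
      dropout = 0.1, learning_rate = 1e-4, epochs = 300L, batch_size = 256L,
      aggregation = "flatten",
      bpe_threshold_drug = 20000L, bpe_threshold_protein = 36000L
    ),
    davis = list(
      l_d = 36L, l_p = 900L, e_d = 64L, e_p = 64L,
      n_heads = 4L, window_sizes = c(0L, 1L, 2L, 3L),
      L_d = 2L, L_p = 1L, ffn_hidden = c(1024L, 1024L, 512L, 1L),
      dropout = 0.1, learning_rate = 1e-4, epochs = 300L, batch_size = 256L,
      aggregation = "flatten",
      bpe_threshold_drug = 20000L, bpe_threshold_protein = 36000L
    )
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0L) {
    stop("unknown config fields: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(dots)] <- dots
  cfg$preset <- preset
  validate_config(cfg)
}

validate_config <- function(cfg) {
  int_fields <- c("l_d", "l_p", "e_d", "e_p", "n_heads", "L_d", "L_p",
                  "epochs", "batch_size", "bpe_threshold_drug",
                  "bpe_threshold_protein")
  for (f in int_fields) cfg[[f]] <- as.integer(cfg[[f]])
  cfg$window_sizes <- as.integer(cfg$window_sizes)
  cfg$ffn_hidden <- as.integer(cfg$ffn_hidden)
  with(cfg, {
    if (l_d < 1L || l_p < 1L) stop("length caps must be >= 1", call. = FALSE)
    if (e_d %% n_heads != 0L || e_p %% n_heads != 0L) {
      stop("`n_heads` must divide both embedding sizes so that ",
           "concatenated heads restore the model dimension", call. = FALSE)
    }
    if (any(window_sizes < 0L)) {
      stop("window sizes must be non-negative", call. = FALSE)
    }
    if (length(window_sizes) > n_heads) {
      stop("more window sizes than heads", call. = FALSE)
    }
    if (length(ffn_hidden) != 4L || ffn_hidden[4L] != 1L) {
      stop("`ffn_hidden` must list 4 layer widths ending in 1", call. = FALSE)
    }
    if (dropout < 0 || dropout >= 1) stop("`dropout` must be in [0, 1)",
                                          call. = FALSE)
    if (L_d < 1L || L_p < 1L) stop("block counts must be >= 1", call. = FALSE)
    if (!aggregation %in% c("flatten", "mean", "max")) {
      stop("`aggregation` must be flatten, mean or max", call. = FALSE)
    }
  })
  class(cfg) <- "msaan_config"
  cfg
}

# Window size of each head: listed sizes cycled over the heads.
head_windows <- function(cfg) {
  rep_len(cfg$window_sizes, cfg$n_heads)
}

#' @export
print.msaan_config <- function(x, ...) {
  cat("Multi-scaled SAN config (preset ", x$preset, "):\n", sep = "")
  cat("  drug: l =", x$l_d, " e =", x$e_d, " blocks =", x$L_d, "\n")
  cat("  protein: l =", x$l_p, " e =", x$e_p, " blocks =", x$L_p, "\n")
  cat("  heads:", x$n_heads, "with windows",
      paste(head_windows(x), collapse = ","), "\n")
  cat("  interaction stack:", paste(x$ffn_hidden, collapse = "/"),
      "(", x$aggregation, ")\n")
  cat("  dropout", x$dropout, " lr", x$learning_rate, " epochs", x$epochs,
      " batch", x$batch_size, "\n")
  invisible(x)
}

#' Read a model configuration from YAML or JSON
#'
#' The file may name a `preset` and override any field; fields absent from
#' the file keep the preset's value.
#'
#' @param path YAML (`.yaml`/`.yml`) or JSON file.
#' @return An `"msaan_config"`.
#' @export
read_msaan_config <- function(path) {
  obj <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  preset <- obj$preset %||% "tiny"
  obj$preset <- NULL
  do.call(msaan_config, c(list(preset = preset), obj))
}
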