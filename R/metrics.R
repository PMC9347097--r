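# Evaluation statistics for binding-affinity regression.

check_pred_pair <- function(y_true, y_pred, min_n = 1L) {
  if (length(y_true) != length(y_pred)) {
    stop("`y_true` and `y_pred` must have equal length", call. = FALSE)
  }
  if (length(y_true) < min_n) {
    stop("need at least ", min_n, " pairs", call. = FALSE)
  }
  if (anyNA(y_true) || anyNA(y_pred)) {
    stop("missing values in predictions or truth", call. = FALSE)
  }
  invisible(TRUE)
}

#' Mean squared error
#'
#' @param y_true Observed affinities.
#' @param y_pred Predicted affinities.
#' @return Mean of squared residuals.
#' @export
mse_score <- function(y_true, y_pred) {
  check_pred_pair(y_true, y_pred, min_n = 1L)
  mean((y_pred - y_true)^2)
}

#' Concordance index
#'
#' The probability that, for two drug-target pairs with different true
#' affinities, the predictions are in the correct order. Only ordered pairs
#' `(i, j)` with strictly larger true affinity `y_true[i] > y_true[j]`
#' enter the sum (ties in the truth carry no ordering information); each
#' contributes 1 when `y_pred[i] > y_pred[j]`, 0.5 when the predictions are
#' exactly tied, and 0 otherwise.
#'
#' @param y_true Observed affinities (length at least 2, not all equal).
#' @param y_pred Predicted affinities.
#' @return A number in `[0, 1]`; 1 for perfect ranking, 0.5 for random.
#' @examples
#' concordance_index(c(1, 2, 3), c(0.1, 0.4, 0.9))  # 1
#' @export
concordance_index <- function(y_true, y_pred) {
  check_pred_pair(y_true, y_pred, min_n = 2L)
  gt <- outer(y_true, y_true, `>`)
  if (!any(gt)) {
    stop("concordance index undefined: all true affinities are equal",
         call. = FALSE)
  }
  dpred <- outer(y_pred, y_pred, `-`)
  credit <- (dpred > 0) + 0.5 * (dpred == 0)
  sum(credit[gt]) / sum(gt)
}

#' Roy's modified squared correlation (r^2_m)
#'
#' External-validation statistic `r2 * (1 - sqrt(r2 - r2_0))`, where `r2` is
#' the squared Pearson correlation between observed and predicted values
#' (regression with intercept) and `r2_0` is the coefficient of
#' determination of the through-origin regression of observed on predicted,
#' with slope `k = sum(y * y_pred) / sum(y_pred^2)`. The statistic penalizes
#' models whose predictions correlate with the truth but are poorly
#' calibrated in scale or offset; a value above 0.5 is conventionally taken
#' as acceptable. The radicand is clamped at zero in the rare numerical case
#' `r2_0 > r2`, keeping the statistic real-valued.
#'
#' @param y_true Observed affinities (length at least 3, non-constant).
#' @param y_pred Predicted affinities (non-constant).
#' @return A number no larger than `r2`.
#' @export
r2m <- function(y_true, y_pred) {
  check_pred_pair(y_true, y_pred, min_n = 3L)
  if (stats::var(y_true) == 0 || stats::var(y_pred) == 0) {
    stop("r^2_m undefined: zero variance in observed or predicted values",
         call. = FALSE)
  }
  r2 <- stats::cor(y_true, y_pred)^2
  k <- sum(y_true * y_pred) / sum(y_pred^2)
  r20 <- 1 - sum((y_true - k * y_pred)^2) / sum((y_true - mean(y_true))^2)
  r2 * (1 - sqrt(max(r2 - r20, 0)))
}

#' Dissociation constant to pKd
#'
#' Transforms a dissociation constant in nanomolar units into log space:
#' `pKd = -log10(Kd / 1e9)`. Higher pKd means tighter binding; Kd = 1 nM
#' maps to pKd = 9.
#'
#' @param kd Positive dissociation constant(s), in nM.
#' @return pKd value(s).
#' @examples
#' kd_to_pkd(c(1e9, 100, 1))  # 0 7 9
#' @export
kd_to_pkd <- function(kd) {
  if (anyNA(kd) || any(kd <= 0)) {
    stop("`kd` must be positive (nM)", call. = FALSE)
  }
  -log10(kd / 1e9)
}

#' Evaluate a prediction set with the standard affinity metrics
#'
#' @param y_true Observed affinities.
#' @param y_pred Predicted affinities.
#' @param metrics Which of `"mse"`, `"ci"`, `"r2m"` to compute.
#' @return Named numeric vector.
#' @export
evaluate_predictions <- function(y_true, y_pred,
                                 metrics = c("mse", "ci", "r2m")) {
  metrics <- match.arg(metrics, several.ok = TRUE)
  out <- vapply(metrics, function(m) {
    switch(m,
      mse = mse_score(y_true, y_pred),
      ci = concordance_index(y_true, y_pred),
      r2m = r2m(y_true, y_pred)
    )
  }, 0)
  names(out) <- metrics
  out
}
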