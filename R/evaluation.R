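to_percent <- function(x, unit) {
  if (unit == "fraction") x * 100 else x
}

#' Mean absolute error between true and predicted RSA
#'
#' Mode `"absolute"` (default) is the conventional `mean(|x - y|)` on the
#' percent scale, the form in which headline errors are reported
#' throughout the RSA literature. Mode `"relative"` is the literal
#' normalized form `mean(|x - y| / x)`, which is singular at fully buried
#' residues: positions with true RSA of exactly 0 are skipped with a
#' warning reporting the skip count.
#'
#' @param true_rsa,pred_rsa numeric vectors of equal length (>= 1), on a
#'   common scale.
#' @param mode `"absolute"` or `"relative"`.
#' @param unit scale of the inputs, `"fraction"` (default) or
#'   `"percent"`; absolute-mode output is always on the percent scale.
#' @return Scalar error: percent for `"absolute"`, a unitless ratio for
#'   `"relative"`.
#' @export
#' @examples
#' mae(c(10, 20), c(12, 16), unit = "percent")
mae <- function(true_rsa, pred_rsa, mode = c("absolute", "relative"),
                unit = c("fraction", "percent")) {
  mode <- match.arg(mode)
  unit <- match.arg(unit)
  if (length(true_rsa) != length(pred_rsa) || length(true_rsa) < 1L) {
    abort_config("`true_rsa` and `pred_rsa` must have equal positive length")
  }
  x <- to_percent(true_rsa, unit)
  y <- to_percent(pred_rsa, unit)
  if (mode == "absolute") {
    return(mean(abs(x - y)))
  }
  keep <- x != 0
  if (any(!keep)) {
    warn(sprintf("relative MAE: %d position(s) with true RSA 0 skipped",
                 sum(!keep)))
  }
  if (!any(keep)) abort_config("no position with non-zero true RSA")
  mean(abs((x[keep] - y[keep]) / x[keep]))
}

#' Pearson correlation between true and predicted RSA
#'
#' The product-moment correlation of the two tracks, computed from the
#' centered cross-product over the root of the centered sums of squares.
#' Equals 1 for perfectly positively correlated tracks and -1 for
#' perfectly anti-correlated ones.
#'
#' @param true_rsa,pred_rsa numeric vectors of equal length (>= 2),
#'   neither constant.
#' @return Scalar in `[-1, 1]`.
#' @export
pcc <- function(true_rsa, pred_rsa) {
  if (length(true_rsa) != length(pred_rsa) || length(true_rsa) < 2L) {
    abort_config("`true_rsa` and `pred_rsa` must have equal length >= 2")
  }
  dx <- true_rsa - mean(true_rsa)
  dy <- pred_rsa - mean(pred_rsa)
  den <- sqrt(sum(dx^2) * sum(dy^2))
  if (den == 0) {
    abort("correlation undefined for a constant vector",
          class = "rsapred_undefined_correlation_error")
  }
  sum(dx * dy) / den
}

#' Two-state (buried/exposed) classification accuracy
#'
#' Both tracks are binarized by the same rule -- a residue whose RSA is
#' no less than the threshold is exposed, otherwise buried -- and the
#' accuracy is the percentage of residues whose state matches.
#'
#' @inheritParams mae
#' @param threshold exposure threshold in percent RSA, in `(0, 100)`.
#' @return Accuracy in percent.
#' @export
#' @examples
#' two_state_accuracy(c(4, 6), c(6, 4), threshold = 5, unit = "percent")
two_state_accuracy <- function(true_rsa, pred_rsa, threshold = 25,
                               unit = c("fraction", "percent")) {
  unit <- match.arg(unit)
  if (length(true_rsa) != length(pred_rsa) || length(true_rsa) < 1L) {
    abort_config("`true_rsa` and `pred_rsa` must have equal positive length")
  }
  if (threshold <= 0 || threshold >= 100) {
    abort_config("`threshold` must lie in (0, 100) percent")
  }
  x <- to_percent(true_rsa, unit) >= threshold
  y <- to_percent(pred_rsa, unit) >= threshold
  mean(x == y) * 100
}

#' Per-residue-type prediction summary
#'
#' For each amino-acid letter present: the mean true RSA, mean predicted
#' RSA, mean absolute error and the standard deviation of the true RSA
#' (all in percent). The attribute `"error_sd_pcc"` carries the
#' correlation between per-type error and per-type RSA standard
#' deviation, the summary statistic relating prediction difficulty to
#' intrinsic RSA variability.
#'
#' @param data tibble with columns `residue`, `rsa_true`, `rsa_pred`.
#' @param unit scale of the RSA columns.
#' @return A tibble `residue`, `n`, `mean_true`, `mean_pred`,
#'   `mean_abs_error`, `sd_true`, sorted by residue letter.
#' @export
per_type_summary <- function(data, unit = c("fraction", "percent")) {
  unit <- match.arg(unit)
  need <- c("residue", "rsa_true", "rsa_pred")
  if (!all(need %in% names(data))) {
    abort_config("`data` needs columns residue, rsa_true, rsa_pred")
  }
  absent <- setdiff(AA_PSSM_ORDER, unique(data$residue))
  if (length(absent)) {
    warn(sprintf("no residues of type: %s", paste(absent, collapse = ", ")))
  }
  out <- data |>
    dplyr::mutate(rsa_true = to_percent(.data$rsa_true, unit),
                  rsa_pred = to_percent(.data$rsa_pred, unit)) |>
    dplyr::group_by(.data$residue) |>
    dplyr::summarise(n = dplyr::n(),
                     mean_true = mean(.data$rsa_true),
                     mean_pred = mean(.data$rsa_pred),
                     mean_abs_error = mean(abs(.data$rsa_true - .data$rsa_pred)),
                     sd_true = sd(.data$rsa_true),
                     .groups = "drop") |>
    dplyr::arrange(.data$residue)
  ok <- !is.na(out$sd_true)
  attr(out, "error_sd_pcc") <- if (sum(ok) >= 2) {
    tryCatch(pcc(out$mean_abs_error[ok], out$sd_true[ok]),
             rsapred_undefined_correlation_error = function(e) NA_real_)
  } else NA_real_
  out
}

#' Histogram of residues by absolute-error band
#'
#' Counts residues whose absolute prediction error (percent scale) falls
#' in each band. Bands are left-closed (`[a, b)`), with the last band
#' closed on both sides, and the edges must cover the whole error range.
#'
#' @inheritParams mae
#' @param band_edges strictly increasing numeric edges covering
#'   `[0, 100]`; default steps of 10.
#' @return A tibble `band` (label), `lower`, `upper`, `count`; counts sum
#'   to the number of residues.
#' @export
error_band_histogram <- function(true_rsa, pred_rsa,
                                 band_edges = seq(0, 100, by = 10),
                                 unit = c("fraction", "percent")) {
  unit <- match.arg(unit)
  if (length(true_rsa) != length(pred_rsa) || length(true_rsa) < 1L) {
    abort_config("`true_rsa` and `pred_rsa` must have equal positive length")
  }
  if (any(diff(band_edges) <= 0) || band_edges[1] > 0 ||
      band_edges[length(band_edges)] < 100) {
    abort_config("band edges must be strictly increasing and cover [0, 100]")
  }
  err <- abs(to_percent(true_rsa, unit) - to_percent(pred_rsa, unit))
  k <- length(band_edges) - 1L
  idx <- findInterval(err, band_edges, rightmost.closed = TRUE)
  counts <- tabulate(idx, nbins = k)
  tibble(band = sprintf("[%g,%g%s", band_edges[-length(band_edges)],
                        band_edges[-1], c(rep(")", k - 1L), "]")),
         lower = band_edges[-length(band_edges)],
         upper = band_edges[-1],
         count = counts)
}

#' Full evaluation report for predicted RSA
#'
#' Bundles every assessment the package reports: pooled MAE and Pearson
#' correlation, two-state accuracy across exposure thresholds,
#' per-residue-type summaries and the absolute-error histogram. Per-chain
#' MAE/PCC are included alongside the pooled (residue-weighted) values.
#'
#' @param data tibble with columns `chain_id`, `residue`, `rsa_true`,
#'   `rsa_pred`.
#' @param thresholds two-state exposure thresholds (percent).
#' @param unit scale of the RSA columns (default fraction).
#' @return An object of class `rsa_eval`; see [tidy.rsa_eval()] and
#'   [glance.rsa_eval()].
#' @export
evaluate_predictions <- function(data,
                                 thresholds = c(5, 10, 20, 25, 30, 40, 50,
                                                60, 70, 80, 90),
                                 unit = c("fraction", "percent")) {
  unit <- match.arg(unit)
  need <- c("chain_id", "residue", "rsa_true", "rsa_pred")
  if (!all(need %in% names(data))) {
    abort_config("`data` needs columns chain_id, residue, rsa_true, rsa_pred")
  }
  two_state <- tibble(
    threshold = thresholds,
    accuracy = vapply(thresholds, function(t) {
      two_state_accuracy(data$rsa_true, data$rsa_pred, t, unit)
    }, numeric(1)))
  per_chain <- data |>
    dplyr::group_by(.data$chain_id) |>
    dplyr::summarise(
      n = dplyr::n(),
      mae = mae(.data$rsa_true, .data$rsa_pred, unit = unit),
      pcc = if (sd(.data$rsa_true) > 0 && sd(.data$rsa_pred) > 0)
        pcc(.data$rsa_true, .data$rsa_pred) else NA_real_,
      .groups = "drop")
  structure(list(
    n = nrow(data),
    mae = mae(data$rsa_true, data$rsa_pred, unit = unit),
    pcc = pcc(data$rsa_true, data$rsa_pred),
    two_state = two_state,
    per_type = per_type_summary(data, unit),
    error_bands = error_band_histogram(data$rsa_true, data$rsa_pred,
                                       unit = unit),
    per_chain = per_chain
  ), class = "rsa_eval")
}

#' @export
print.rsa_eval <- function(x, ...) {
  cat(sprintf("<rsa_eval> %d residues | MAE %.2f%% | PCC %.3f\n",
              x$n, x$mae, x$pcc))
  acc <- x$two_state
  cat("two-state accuracy (%):\n")
  cat(paste(sprintf("  %g%%: %.1f", acc$threshold, acc$accuracy),
            collapse = "\n"), "\n")
  invisible(x)
}

#' Tidy and summarize evaluation reports
#'
#' `tidy()` returns the per-residue-type table; `glance()` the one-row
#' headline summary (pooled MAE, PCC, residue count, and the
#' error-vs-variability correlation).
#'
#' @param x an `rsa_eval` object.
#' @param ... unused.
#' @return A tibble.
#' @export
tidy.rsa_eval <- function(x, ...) {
  x$per_type
}

#' @rdname tidy.rsa_eval
#' @export
glance.rsa_eval <- function(x, ...) {
  tibble(n = x$n, mae = x$mae, pcc = x$pcc,
         error_sd_pcc = attr(x$per_type, "error_sd_pcc"))
}
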