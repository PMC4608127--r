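#' Build the neighbor-regression design matrix from RSA tracks
#'
#' For every residue with a complete window (no padding: the first and
#' last `(N-1)/2` residues of each chain are excluded), one design row
#' holds the RSA values of its `N - 1` window neighbors, columns ordered
#' by offset `-(N-1)/2 .. -1, +1 .. +(N-1)/2`; the response is the central
#' residue's RSA.
#'
#' @param rsa_tracks list of numeric RSA vectors (one per chain), or a
#'   [chain_set()] with RSA attached, or a tidy RSA tibble
#'   (`chain_id`, `pos`, `rsa`).
#' @param window odd window length `N`.
#' @return A list with `x` (M x (N-1) matrix, offset-labelled columns)
#'   and `y` (length-M response vector).
#' @export
build_neighbor_design <- function(rsa_tracks, window = 9) {
  n <- check_window(window)
  half <- (n - 1L) %/% 2L
  tracks <- as_rsa_tracks(rsa_tracks)
  tracks <- tracks[vapply(tracks, length, integer(1)) >= n]
  if (length(tracks) == 0L) {
    abort_insufficient(sprintf("no track is at least %d residues long", n))
  }
  offsets <- c(-half:-1, 1:half)
  per <- lapply(tracks, function(v) {
    e <- stats::embed(v, n)          # e[t, j] = v[t + n - j]
    slot <- function(off) e[, n - half - off]
    list(x = vapply(offsets, slot, numeric(nrow(e))), y = slot(0L))
  })
  x <- do.call(rbind, lapply(per, `[[`, "x"))
  colnames(x) <- off_label(offsets)
  list(x = x, y = unlist(lapply(per, `[[`, "y"), use.names = FALSE))
}

as_rsa_tracks <- function(rsa_tracks) {
  if (is.list(rsa_tracks) && !inherits(rsa_tracks, "data.frame")) {
    return(rsa_tracks)
  }
  if (inherits(rsa_tracks, "data.frame")) {
    if ("rsa" %in% names(rsa_tracks) && is.list(rsa_tracks$rsa)) {
      tr <- rsa_tracks$rsa
      if (any(vapply(tr, is.null, logical(1)))) {
        abort_missing_input("some chains have no RSA track attached")
      }
      return(tr)
    }
    if (all(c("chain_id", "rsa") %in% names(rsa_tracks))) {
      return(unname(split(rsa_tracks$rsa, factor(rsa_tracks$chain_id,
                                                 levels = unique(rsa_tracks$chain_id)))))
    }
  }
  abort_config("cannot interpret `rsa_tracks` as RSA tracks")
}

#' Fit neighbor-influence window weights by least squares
#'
#' Ordinary least squares of each residue's RSA on the RSA of its window
#' neighbors, pooled over all complete windows of all chains. The fitted
#' coefficients quantify how strongly each window position influences the
#' central residue and drive the weighted sliding-window feature scheme.
#'
#' @inheritParams build_neighbor_design
#' @return A `window_weights` object: list with `window`, `offsets`,
#'   `coefficients` (named by offset), `intercept` and `fit_stats`
#'   (`n`, `sigma`, `r_squared`).
#' @export
#' @examples
#' tracks <- replicate(4, pmin(pmax(stats::filter(rnorm(60, 0.4, 0.2),
#'   rep(1 / 3, 3), circular = TRUE), 0), 1), simplify = FALSE)
#' fit_window_weights(tracks, window = 5)
fit_window_weights <- function(rsa_tracks, window = 9) {
  n <- check_window(window)
  d <- build_neighbor_design(rsa_tracks, n)
  p <- ncol(d$x) + 1L
  if (nrow(d$x) <= p) {
    abort_insufficient("design matrix has no more rows than columns")
  }
  fit <- stats::lm.fit(cbind(`(Intercept)` = 1, d$x), d$y)
  if (fit$rank < p) {
    abort_singular("rank-deficient neighbor design (constant RSA tracks?)")
  }
  res <- fit$residuals
  tss <- sum((d$y - mean(d$y))^2)
  new_window_weights(
    window = n,
    coefficients = fit$coefficients[-1L],
    intercept = unname(fit$coefficients[1L]),
    fit_stats = list(n = nrow(d$x),
                     sigma = sqrt(sum(res^2) / (nrow(d$x) - p)),
                     r_squared = if (tss > 0) 1 - sum(res^2) / tss else NA_real_)
  )
}

new_window_weights <- function(window, coefficients, intercept,
                               fit_stats = list()) {
  half <- (window - 1L) %/% 2L
  offsets <- c(-half:-1, 1:half)
  if (length(coefficients) != window - 1L) {
    abort_config("number of coefficients must be window - 1")
  }
  names(coefficients) <- off_label(offsets)
  structure(list(window = as.integer(window), offsets = offsets,
                 coefficients = coefficients, intercept = intercept,
                 fit_stats = fit_stats),
            class = "window_weights")
}

#' Construct a window-weights object from known coefficients
#'
#' @param window odd window length.
#' @param coefficients numeric vector of `window - 1` neighbor
#'   coefficients ordered by offset (`-(N-1)/2 .. -1, +1 .. +(N-1)/2`).
#' @param intercept regression intercept (RSA units).
#' @return A `window_weights` object.
#' @export
window_weights <- function(window, coefficients, intercept) {
  new_window_weights(window, coefficients, intercept)
}

#' Reference 9-residue window coefficients
#'
#' The published neighbor-influence model for the 9-residue window,
#' fitted on a large non-redundant chain set (PSAP2312): coefficients for
#' offsets -4..+4 (excluding the center) and the intercept. The profile
#' decreases nearly linearly and symmetrically away from the center, with
#' every neighbor contributing positively.
#'
#' @return A `window_weights` object.
#' @export
#' @examples
#' tidy(reference_window_weights())
reference_window_weights <- function() {
  new_window_weights(
    window = 9L,
    coefficients = c(0.04169, 0.14068, 0.267318, 0.39247,
                     0.39149, 0.262833, 0.13861, 0.04328),
    intercept = -0.5863
  )
}

#' @export
print.window_weights <- function(x, ...) {
  cat(sprintf("<window_weights> N = %d, intercept = %.5g\n",
              x$window, x$intercept))
  print(round(x$coefficients, 5))
  invisible(x)
}

#' Predict central-residue RSA from neighbor RSA values
#'
#' Applies the linear neighbor model: the dot product of the fitted
#' coefficients with the `N - 1` neighbor RSA values, plus the intercept.
#'
#' @param weights a `window_weights` object.
#' @param neighbor_rsa numeric vector of length `N - 1`, ordered by
#'   offset as in [build_neighbor_design()].
#' @return Scalar RSA estimate.
#' @export
predict_rsa_linear <- function(weights, neighbor_rsa) {
  if (length(neighbor_rsa) != weights$window - 1L) {
    abort_config(sprintf("expected %d neighbor values, got %d",
                         weights$window - 1L, length(neighbor_rsa)))
  }
  sum(weights$coefficients * neighbor_rsa) + weights$intercept
}

#' Tabulate and diagnose a fitted weight profile
#'
#' Orders the coefficients by offset and reports two diagnostics: the
#' symmetry score `max_k |w_k - w_{-k}|` and whether coefficient
#' magnitude increases monotonically toward the center on each side.
#'
#' @param weights a `window_weights` object.
#' @return A list with `profile` (tibble of `offset`, `coefficient`),
#'   `symmetry_score` and `monotone_toward_center`.
#' @export
weight_profile_report <- function(weights) {
  half <- (weights$window - 1L) %/% 2L
  w <- unname(weights$coefficients)
  left <- w[seq_len(half)]            # offsets -half .. -1
  right <- w[half + seq_len(half)]    # offsets +1 .. +half
  profile <- tibble(offset = weights$offsets, coefficient = w)
  sym <- max(abs(left - rev(right)))
  mono <- all(diff(abs(left)) >= 0) && all(diff(abs(rev(right))) >= 0)
  list(profile = profile, symmetry_score = sym,
       monotone_toward_center = mono)
}

#' @export
tidy.window_weights <- function(x, ...) {
  tibble(term = names(x$coefficients), offset = x$offsets,
         estimate = unname(x$coefficients))
}

#' @export
glance.window_weights <- function(x, ...) {
  tibble(window = x$window, intercept = x$intercept,
         nobs = x$fit_stats$n %||% NA_integer_,
         sigma = x$fit_stats$sigma %||% NA_real_,
         r.squared = x$fit_stats$r_squared %||% NA_real_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize window weights to and from JSON
#'
#' @param weights a `window_weights` object.
#' @param path file path.
#' @return `write_window_weights()` returns `path` invisibly;
#'   `read_window_weights()` returns the `window_weights` object.
#' @export
write_window_weights <- function(weights, path) {
  jsonlite::write_json(
    list(window = weights$window, offsets = weights$offsets,
         coefficients = unname(weights$coefficients),
         intercept = weights$intercept, fit_stats = weights$fit_stats),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_window_weights
#' @export
read_window_weights <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_window_weights(j$window, j$coefficients, j$intercept,
                     fit_stats = as.list(j$fit_stats))
}
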