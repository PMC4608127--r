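#' Chain-level cross-validation folds
#'
#' Randomly partitions chains (never residues) into `n` folds whose sizes
#' differ by at most one. The same seed always yields the same
#' assignment.
#'
#' @param chain_ids character vector of chain identifiers.
#' @param n number of folds (default 3).
#' @param seed integer seed.
#' @return A tibble with columns `chain_id` and `fold` (1..n).
#' @export
make_folds <- function(chain_ids, n = 3, seed = 1L) {
  m <- length(chain_ids)
  if (n < 2) abort_config("at least 2 folds are required")
  if (n > m) abort_config(sprintf("%d folds requested for %d chains", n, m))
  withr::with_seed(as.integer(seed), {
    shuffled <- sample(chain_ids)
  })
  tibble(chain_id = shuffled, fold = rep_len(seq_len(n), m)) |>
    dplyr::arrange(match(.data$chain_id, chain_ids))
}

#' Epsilon-SVR hyperparameters
#'
#' @param C regularization constant (> 0).
#' @param gamma Gaussian kernel width (> 0); `NULL` defers to the
#'   conventional `1 / n_features` at fit time.
#' @param epsilon width of the insensitive tube (>= 0), on fraction-scale
#'   RSA.
#' @return A list of class `svr_params`.
#' @export
svr_params <- function(C = 1, gamma = NULL, epsilon = 0.1) {
  check_scalar_number(C, "C")
  if (C <= 0) abort_config("`C` must be positive")
  if (!is.null(gamma)) {
    check_scalar_number(gamma, "gamma")
    if (gamma <= 0) abort_config("`gamma` must be positive")
  }
  check_scalar_number(epsilon, "epsilon")
  if (epsilon < 0) abort_config("`epsilon` must be non-negative")
  structure(list(C = C, gamma = gamma, epsilon = epsilon),
            class = "svr_params")
}

#' Reference tuned hyperparameters for the 9-window predictor
#'
#' The swarm-tuned Gaussian-kernel hyperparameters reported for the
#' full-scale predictor (`C = 0.00762`, `gamma = 0.00130`,
#' `epsilon = 0.04129`), alongside the grid-search counterpart
#' (`C = 0.01`, `gamma = 0.0025`, `epsilon = 0.05`).
#'
#' @param which `"pso"` (default) or `"grid"`.
#' @return An [svr_params()] object.
#' @export
reference_svr_params <- function(which = c("pso", "grid")) {
  which <- match.arg(which)
  if (which == "pso") svr_params(C = 0.00762, gamma = 0.00130, epsilon = 0.04129)
  else svr_params(C = 0.01, gamma = 0.0025, epsilon = 0.05)
}

#' Train an epsilon-SVR with Gaussian kernel
#'
#' Thin wrapper over the LIBSVM epsilon-regression solver with a radial
#' basis kernel. Features are used as-is (no rescaling): every encoded
#' feature already lives in `[0, 1]`.
#'
#' @param x numeric feature matrix (rows = residues).
#' @param y numeric target vector (fraction-scale RSA).
#' @param params an [svr_params()] object.
#' @return A fitted `e1071::svm` object.
#' @export
train_svr <- function(x, y, params = svr_params()) {
  if (is.null(dim(x)) || nrow(x) == 0L) {
    abort_config("no training rows")
  }
  if (nrow(x) != length(y)) abort_length("`x` rows and `y` length differ")
  fit <- tryCatch(
    e1071::svm(x = x, y = y, scale = FALSE, type = "eps-regression",
               kernel = "radial", cost = params$C,
               gamma = params$gamma %||% (1 / ncol(x)),
               epsilon = params$epsilon),
    error = function(e) {
      if (!grepl("empty", conditionMessage(e), ignore.case = TRUE)) {
        stop(e)
      }
      # every target sits inside the insensitive tube around its mean, so
      # the solver keeps no support vectors; the flat function is optimal
      structure(list(constant = mean(y)), class = "svr_flat_fit")
    })
  fit
}

#' @export
predict.svr_flat_fit <- function(object, newdata, ...) {
  rep(object$constant, nrow(rbind(newdata)))
}

#' Encode a chain set for model fitting
#'
#' Bundles the assembled feature table with its numeric matrix, the
#' per-residue metadata and (when every chain has an RSA track) the
#' fraction-scale target vector. Encoding once and reusing the bundle is
#' the intended pattern for cross-validation and tuning, where the same
#' features are scored under many hyperparameter settings.
#'
#' @inheritParams assemble_features
#' @return A list of class `encoded_chains` with elements `x`, `meta`
#'   (`chain_id`, `pos`, `residue`), `y` (or `NULL`) and `config`.
#' @export
encode_for_model <- function(chains, window = 9, blocks = FEATURE_BLOCKS,
                             scales = physchem_scales(), weights = NULL,
                             weighting = c("max", "raw", "none"),
                             terminal_flag = c("pseudo_only", "real_termini")) {
  weighting <- match.arg(weighting)
  terminal_flag <- match.arg(terminal_flag)
  feats <- assemble_features(chains, window = window, blocks = blocks,
                             scales = scales, weights = weights,
                             weighting = weighting,
                             terminal_flag = terminal_flag)
  y <- NULL
  if (!any(vapply(chains$rsa, is.null, logical(1)))) {
    y <- unlist(chains$rsa, use.names = FALSE)
  }
  structure(list(
    x = feature_matrix(feats),
    meta = feats[c("chain_id", "pos", "residue")],
    y = y,
    config = list(window = attr(feats, "window"),
                  blocks = attr(feats, "blocks"),
                  weighting = if (is.null(weights)) "none" else weighting,
                  terminal_flag = terminal_flag,
                  scales_hash = rlang::hash(scales),
                  weights = weights)
  ), class = "encoded_chains")
}

#' Chain-level cross-validated predictions and fitness
#'
#' For each fold, an SVR is trained on the residues of all out-of-fold
#' chains and predicts the in-fold residues, so no chain ever contributes
#' to its own training set. `cv_fitness()` reduces the pooled
#' out-of-fold predictions to the residue-weighted mean absolute error on
#' the percent scale -- the quantity the hyperparameter search minimizes.
#'
#' @param encoded an [encode_for_model()] bundle with targets.
#' @param folds fold assignment from [make_folds()].
#' @param params an [svr_params()] object.
#' @param engine model engine, by default [train_svr()]; any function
#'   `(x, y, params)` returning an object with a `predict` method.
#' @return `cv_predict()`: a tibble `chain_id`, `pos`, `residue`, `fold`,
#'   `rsa_true`, `rsa_pred`. `cv_fitness()`: scalar MAE (%).
#' @export
cv_predict <- function(encoded, folds, params = svr_params(),
                       engine = train_svr) {
  if (is.null(encoded$y)) abort_missing_input("encoded bundle has no RSA targets")
  fold_of <- setNames(folds$fold, folds$chain_id)
  if (anyNA(fold_of[unique(encoded$meta$chain_id)])) {
    abort_config("folds do not cover every encoded chain")
  }
  row_fold <- unname(fold_of[encoded$meta$chain_id])
  out <- vector("list", max(folds$fold))
  for (f in sort(unique(folds$fold))) {
    test <- row_fold == f
    fit <- engine(encoded$x[!test, , drop = FALSE], encoded$y[!test], params)
    pred <- as.numeric(predict(fit, encoded$x[test, , drop = FALSE]))
    out[[f]] <- dplyr::bind_cols(encoded$meta[test, ],
                                 tibble(fold = f, rsa_true = encoded$y[test],
                                        rsa_pred = pred))
  }
  dplyr::bind_rows(out)
}

#' @rdname cv_predict
#' @export
cv_fitness <- function(encoded, folds, params = svr_params(),
                       engine = train_svr) {
  cv <- cv_predict(encoded, folds, params, engine)
  mean(abs(cv$rsa_true - cv$rsa_pred)) * 100
}

default_svr_bounds <- function() {
  list(log10_C = c(-4, 3), log10_gamma = c(-5, 1), epsilon = c(0, 0.5))
}

params_from_position <- function(theta) {
  svr_params(C = 10^theta[1], gamma = 10^theta[2], epsilon = theta[3])
}

position_from_params <- function(params, n_features) {
  c(log10(params$C), log10(params$gamma %||% (1 / n_features)),
    params$epsilon)
}

#' Tune SVR hyperparameters by particle swarm optimization
#'
#' Minimizes the chain-level cross-validated MAE over `(C, gamma,
#' epsilon)`, searching `C` and `gamma` in log10 space and `epsilon`
#' linearly. One particle of the initial swarm is seeded at the
#' `incumbent` parameters, so the returned optimum can never be worse
#' than the incumbent as evaluated on the same folds.
#'
#' @param encoded an [encode_for_model()] bundle with targets.
#' @param folds fold assignment from [make_folds()].
#' @param pso a [pso_config()].
#' @param bounds named list of `(lower, upper)` pairs for `log10_C`,
#'   `log10_gamma` and `epsilon`.
#' @param incumbent [svr_params()] seeded into the swarm (`NULL` to skip).
#' @return A list with `params` (best [svr_params()]), `fitness`
#'   (its CV MAE, %), and the PSO `trace`.
#' @export
tune_svr_pso <- function(encoded, folds, pso = pso_config(),
                         bounds = default_svr_bounds(),
                         incumbent = svr_params()) {
  lower <- vapply(bounds, `[`, numeric(1), 1L)
  upper <- vapply(bounds, `[`, numeric(1), 2L)
  if (!is.null(incumbent)) {
    pso$init <- rbind(pso$init,
                      position_from_params(incumbent, ncol(encoded$x)))
  }
  fitness <- function(theta) cv_fitness(encoded, folds, params_from_position(theta))
  res <- pso_optimize(fitness, lower, upper, pso)
  list(params = params_from_position(res$par), fitness = res$value,
       trace = res$trace)
}

#' Tune on a reduced chain subset
#'
#' Reproduces the reduced-subset tuning strategy used at full scale,
#' where hyperparameters are searched on a random subset of chains drawn
#' from each cross-validation fold and then applied to the full set:
#' folds are assigned on the complete chain set, `subset_size` chains are
#' sampled per fold (all of them if `NULL` or larger than the fold), and
#' [tune_svr_pso()] runs on the reduced set with the induced folds.
#'
#' @inheritParams encode_for_model
#' @param n_folds number of chain-level folds.
#' @param subset_size chains sampled per fold (`NULL` = use every chain).
#' @param seed integer seed for fold assignment and subset sampling.
#' @param pso a [pso_config()].
#' @param incumbent [svr_params()] seeded into the swarm.
#' @return As [tune_svr_pso()], plus `subset_ids` and `folds`.
#' @export
tune_on_subset <- function(chains, n_folds = 3, subset_size = NULL,
                           seed = 1L, window = 9, blocks = FEATURE_BLOCKS,
                           scales = physchem_scales(), weights = NULL,
                           weighting = "max", pso = pso_config(),
                           incumbent = svr_params()) {
  validate_chain_set(chains)
  folds <- make_folds(chains$chain_id, n = n_folds,
                      seed = derive_seed(seed, "folds"))
  picked <- folds
  if (!is.null(subset_size)) {
    per_fold <- split(folds$chain_id, folds$fold)
    if (any(vapply(per_fold, length, integer(1)) < subset_size)) {
      abort_config("subset_size exceeds the size of a fold")
    }
    withr::with_seed(derive_seed(seed, "subset"), {
      keep <- unlist(lapply(per_fold, sample, size = subset_size))
    })
    picked <- folds[folds$chain_id %in% keep, ]
  }
  sub_chains <- chains[chains$chain_id %in% picked$chain_id, ]
  encoded <- encode_for_model(sub_chains, window = window, blocks = blocks,
                              scales = scales, weights = weights,
                              weighting = weighting)
  res <- tune_svr_pso(encoded, picked, pso = pso, incumbent = incumbent)
  res$subset_ids <- picked$chain_id
  res$folds <- folds
  res
}

#' Train the full RSA prediction model
#'
#' Encodes the chain set and fits the epsilon-SVR on every residue. The
#' returned model carries its complete encoder configuration (window,
#' enabled blocks, weighting mode, scale checksum, window weights and
#' hyperparameters), and prediction refuses a chain set that would be
#' encoded differently.
#'
#' @inheritParams encode_for_model
#' @param params an [svr_params()] object.
#' @return An object of class `rsa_model`.
#' @export
train_rsa_model <- function(chains, params = svr_params(), window = 9,
                            blocks = FEATURE_BLOCKS,
                            scales = physchem_scales(), weights = NULL,
                            weighting = c("max", "raw", "none"),
                            terminal_flag = c("pseudo_only", "real_termini")) {
  weighting <- match.arg(weighting)
  terminal_flag <- match.arg(terminal_flag)
  encoded <- encode_for_model(chains, window = window, blocks = blocks,
                              scales = scales, weights = weights,
                              weighting = weighting,
                              terminal_flag = terminal_flag)
  if (is.null(encoded$y)) {
    abort_missing_input("every training chain needs an RSA track")
  }
  fit <- train_svr(encoded$x, encoded$y, params)
  structure(list(fit = fit, params = params, config = encoded$config,
                 scales = scales, n_train = nrow(encoded$x)),
            class = "rsa_model")
}

#' @export
print.rsa_model <- function(x, ...) {
  cat(sprintf(
    "<rsa_model> eps-SVR (RBF), window %d, %d block(s), %d training residues\n",
    x$config$window, length(x$config$blocks), x$n_train))
  cat(sprintf("  C = %g, gamma = %g, epsilon = %g\n", x$params$C,
              x$params$gamma %||% NA, x$params$epsilon))
  invisible(x)
}

#' Predict RSA for new chains
#'
#' @param object an `rsa_model`.
#' @param chains a [chain_set()] with the profiles the model's encoder
#'   needs.
#' @param window optional window check: if supplied and different from
#'   the model's training window, prediction is refused.
#' @param clamp clamp predictions into `[0, 1]` (default `TRUE`).
#' @param ... unused.
#' @return A tibble `chain_id`, `pos`, `residue`, `rsa` (fraction scale).
#' @export
predict.rsa_model <- function(object, chains, window = NULL, clamp = TRUE, ...) {
  if (!is.null(window) && window != object$config$window) {
    abort_config(sprintf(
      "model was trained with window %d; refusing prediction at window %s",
      object$config$window, window))
  }
  encoded <- encode_for_model(
    chains, window = object$config$window, blocks = object$config$blocks,
    scales = object$scales, weights = object$config$weights,
    weighting = if (object$config$weighting == "none") "max" else object$config$weighting,
    terminal_flag = object$config$terminal_flag)
  if (!identical(encoded$config$scales_hash, object$config$scales_hash)) {
    abort_config("scale table mismatch between training and prediction")
  }
  pred <- as.numeric(predict(object$fit, encoded$x))
  if (clamp) pred <- pmin(pmax(pred, 0), 1)
  dplyr::bind_cols(encoded$meta, tibble(rsa = pred))
}

#' @export
glance.rsa_model <- function(x, ...) {
  tibble(window = x$config$window, blocks = paste(x$config$blocks, collapse = "+"),
         weighting = x$config$weighting, C = x$params$C,
         gamma = x$params$gamma %||% NA_real_, epsilon = x$params$epsilon,
         n_train = x$n_train, n_support = x$fit$tot.nSV)
}
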