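#' Default neighbor weights of the synthetic RSA process
#'
#' A symmetric, stationary neighbor-influence profile for the 9-residue
#' window, shaped like the fitted reference profile (small at the window
#' edge, largest next to the center) but scaled so the weights sum to
#' less than 1, as the spatial process requires. Ordered by offset
#' `-4..-1, +1..+4`.
#'
#' @return Named numeric vector of length 8.
#' @export
default_neighbor_weights <- function() {
  one_side <- c(0.023, 0.077, 0.147, 0.216)
  setNames(c(one_side, rev(one_side)), off_label(c(-4:-1, 1:4)))
}

#' Generate an RSA track with known neighbor-linear structure
#'
#' Draws a track whose conditional expectation at every interior residue
#' is exactly `intercept + sum_k weights_k * rsa_{i+k}` -- the estimand
#' of [fit_window_weights()] -- so fitted weights can be compared
#' directly against the generating ones. The track is built from two
#' parts: a structural mean profile that satisfies the neighbor
#' recurrence exactly (solved from random boundary values), plus, when
#' `noise > 0`, a zero-mean Gaussian field sampled from the conditional
#' autoregression the symmetric weights imply (conditional standard
#' deviation `noise`). With `noise = 0` the track satisfies the
#' recurrence exactly and least squares recovers the weights to
#' numerical precision. Values are clamped to `[0, 1]`.
#'
#' @param length chain length (must be at least the window length).
#' @param weights symmetric neighbor weights, full vector of even length
#'   ordered by offset; their sum must be below 1 (stationarity).
#' @param intercept recurrence intercept `b` (fraction-scale RSA).
#' @param noise conditional standard deviation of the Gaussian field.
#' @param seed integer seed.
#' @return Numeric RSA vector of `length` values in `[0, 1]`.
#' @export
generate_rsa_neighbor_linear <- function(length,
                                         weights = default_neighbor_weights(),
                                         intercept = 0.035, noise = 0.02,
                                         seed = 1L) {
  w <- unname(weights)
  if (base::length(w) %% 2L != 0L) {
    abort_config("`weights` must have even length (offsets -h..-1, +1..+h)")
  }
  half <- base::length(w) %/% 2L
  left <- w[seq_len(half)]
  right <- w[half + seq_len(half)]
  if (max(abs(left - rev(right))) > 1e-8) {
    abort_config("`weights` must be symmetric about the center")
  }
  s <- sum(w)
  if (sum(abs(w)) >= 1) {
    abort_config("non-stationary neighbor weights: |weights| must sum below 1")
  }
  l <- as.integer(length)
  if (l < 2L * half + 1L) {
    abort_config("chain shorter than the neighbor window")
  }
  if (noise < 0) abort_config("`noise` must be non-negative")
  mu <- intercept / (1 - s)
  side <- rev(left)  # weights for offsets 1..half
  withr::with_seed(as.integer(seed), {
    if (all(w == 0)) {
      m <- rep(intercept, l)
    } else {
      # boundary values ride the smooth dominant recurrence mode (the
      # positive real root of 1 - sum_k w_k (z^k + z^-k)), with a small
      # jitter that excites the remaining modes so the induced design
      # stays full rank; the interior solve is exact either way
      z0 <- smooth_mode_root(side)
      amp <- runif(2, -0.38, 0.42)
      idx <- c(seq_len(half), (l - half + 1L):l)
      bound <- mu + amp[1] * z0^(idx - 1L) + amp[2] * z0^(l - idx) +
        rnorm(2L * half, 0, 0.02)
      bound <- pmin(pmax(bound, 0.02), 0.98)
      m <- solve_recurrence_mean(l, side, half, intercept, bound = bound)
    }
    x <- m
    if (noise > 0) {
      q <- Matrix::bandSparse(
        l, k = 0:half,
        diagonals = c(list(rep(1, l)),
                      lapply(seq_len(half), function(k) rep(-side[k], l - k))),
        symmetric = TRUE)
      r <- Matrix::chol(q)
      x <- m + noise * as.numeric(Matrix::solve(r, rnorm(l)))
    }
  })
  pmin(pmax(x, 0), 1)
}

## smallest-decay smooth mode of the symmetric neighbor recurrence: the
## root z in (0, 1) of 1 - sum_k side_k (z^k + z^-k)
smooth_mode_root <- function(side) {
  if (any(side < 0)) return(0.9)  # fallback profile for exotic weight signs
  f <- function(z) 1 - sum(side * (z^seq_along(side) + z^-seq_along(side)))
  stats::uniroot(f, c(1e-6, 1 - 1e-9))$root
}

## solve x_i = b + sum_k side_k (x_{i-k} + x_{i+k}) exactly on the interior,
## given fixed boundary values (half residues at each end)
solve_recurrence_mean <- function(l, side, half, intercept, bound) {
  m <- rep(NA_real_, l)
  m[c(seq_len(half), (l - half + 1L):l)] <- bound
  interior <- (half + 1L):(l - half)
  ni <- base::length(interior)
  ii <- integer(0); jj <- integer(0); vv <- numeric(0)
  rhs <- rep(intercept, ni)
  for (k in seq_len(half)) {
    for (sgn in c(-1L, 1L)) {
      nb <- interior + sgn * k
      inside <- nb >= (half + 1L) & nb <= (l - half)
      ii <- c(ii, which(inside))
      jj <- c(jj, nb[inside] - half)
      vv <- c(vv, rep(-side[k], sum(inside)))
      out <- which(!inside)
      rhs[out] <- rhs[out] + side[k] * m[nb[out]]
    }
  }
  a <- Matrix::sparseMatrix(i = c(seq_len(ni), ii), j = c(seq_len(ni), jj),
                            x = c(rep(1, ni), vv), dims = c(ni, ni))
  m[interior] <- as.numeric(Matrix::solve(a, rhs))
  m
}

#' Generate an RSA track linked to a chain's encoded features
#'
#' Gives the regression engine a learnable signal: RSA is a logistic
#' function of the residue's physicochemical values (hydrophilic,
#' surface-prone residues are more exposed), its local secondary
#' structure probabilities (coil up, strand down) and its position
#' feature (termini more exposed), plus Gaussian observation noise,
#' clamped to `[0, 1]`.
#'
#' @param chains a [chain_set()] with `ss3` attached.
#' @param chain chain index or id (default first).
#' @param coeffs named coefficients: `intercept`, `hydrophilicity`,
#'   `exposed_surface`, `coil`, `strand`, `position`.
#' @param noise observation noise standard deviation.
#' @param seed integer seed.
#' @param scales normalized scale matrix from [physchem_scales()].
#' @return Numeric RSA vector in `[0, 1]`.
#' @export
generate_rsa_feature_linked <- function(chains, chain = 1L,
                                        coeffs = c(intercept = -1.6,
                                                   hydrophilicity = 2.2,
                                                   exposed_surface = 1.2,
                                                   coil = 0.9, strand = -0.9,
                                                   position = 0.7),
                                        noise = 0.05, seed = 1L,
                                        scales = physchem_scales()) {
  row <- chain_row(chains, chain)
  ss3 <- need_profile(row, "ss3")
  letters <- strsplit(row$sequence, "", fixed = TRUE)[[1]]
  l <- row$length
  sq <- encode_sequence_features(l, seq_len(l))
  lin <- coeffs[["intercept"]] +
    coeffs[["hydrophilicity"]] * scales[letters, "hydrophilicity"] +
    coeffs[["exposed_surface"]] * scales[letters, "exposed_surface"] +
    coeffs[["coil"]] * ss3$probs[, "C"] +
    coeffs[["strand"]] * ss3$probs[, "E"] +
    coeffs[["position"]] * sq[, "seq_pos"]
  withr::with_seed(as.integer(seed), {
    x <- stats::plogis(as.numeric(lin)) + rnorm(l, 0, noise)
  })
  pmin(pmax(x, 0), 1)
}

#' Generate a fully profiled synthetic chain set
#'
#' Emulates every upstream input the pipeline consumes: sequences drawn
#' from UniProt-like background frequencies; PSSM profiles whose
#' own-residue column is elevated (integer log-odds, as PSI-BLAST
#' prints); 3-state secondary structure from a first-order Markov chain
#' with realistic run lengths, with per-residue probabilities
#' concentrated on the true state; disorder probabilities low along the
#' chain and elevated in a few contiguous segments; and an RSA track
#' from one of the two generative models. Fully deterministic under a
#' fixed seed.
#'
#' @param n_chains number of chains.
#' @param min_len,max_len chain length range (uniform).
#' @param seed integer seed for everything.
#' @param rsa_model `"feature_linked"` (default), `"neighbor_linear"`, or
#'   `"none"` to leave RSA unattached.
#' @param ss_self named self-transition probabilities of the
#'   secondary-structure Markov chain (expected run length
#'   `1 / (1 - p)`).
#' @param neighbor_weights,neighbor_intercept,neighbor_noise parameters
#'   of the neighbor-linear RSA process.
#' @param feature_coeffs,feature_noise parameters of the feature-linked
#'   RSA process.
#' @param scales normalized physicochemical scales.
#' @return A [chain_set()] with all profiles (and RSA unless `"none"`).
#' @export
#' @examples
#' generate_chain_set(2, 30, 40, seed = 7)
generate_chain_set <- function(n_chains, min_len = 50, max_len = 150,
                               seed = 1L,
                               rsa_model = c("feature_linked",
                                             "neighbor_linear", "none"),
                               ss_self = c(C = 0.85, H = 0.9, E = 0.8),
                               neighbor_weights = default_neighbor_weights(),
                               neighbor_intercept = 0.035,
                               neighbor_noise = 0.02,
                               feature_coeffs = NULL,
                               feature_noise = 0.05,
                               scales = physchem_scales()) {
  rsa_model <- match.arg(rsa_model)
  if (min_len < 1 || max_len > 10000 || min_len > max_len) {
    abort_config("chain lengths must satisfy 1 <= min_len <= max_len <= 10000")
  }
  seed <- as.integer(seed)
  withr::with_seed(seed, {
    len_range <- seq.int(min_len, max_len)
    lens <- len_range[sample.int(length(len_range), n_chains, replace = TRUE)]
    seqs <- vapply(lens, function(l) {
      paste(sample(AA_PSSM_ORDER, l, replace = TRUE,
                   prob = AA_BACKGROUND_FREQ[AA_PSSM_ORDER]), collapse = "")
    }, character(1))
  })
  chains <- chain_set(sprintf("syn%03d", seq_len(n_chains)), seqs)
  pssms <- vector("list", n_chains)
  ss3s <- vector("list", n_chains)
  disos <- vector("list", n_chains)
  for (i in seq_len(n_chains)) {
    l <- chains$length[i]
    letters <- strsplit(chains$sequence[i], "", fixed = TRUE)[[1]]
    withr::with_seed(derive_seed(seed, paste0("prof", i)), {
      p <- matrix(round(rnorm(l * 20L, -2, 2)), nrow = l,
                  dimnames = list(NULL, AA_PSSM_ORDER))
      own <- match(letters, AA_PSSM_ORDER)
      p[cbind(seq_len(l), own)] <- round(rnorm(l, 5, 2))
      pssms[[i]] <- p
      ss3s[[i]] <- simulate_ss3(l, ss_self)
      disos[[i]] <- simulate_disorder(l)
    })
  }
  chains <- attach_pssm(chains, pssms)
  chains <- attach_ss3(chains, ss3s)
  chains <- attach_disorder(chains, disos)
  if (rsa_model == "neighbor_linear") {
    tracks <- lapply(seq_len(n_chains), function(i) {
      generate_rsa_neighbor_linear(chains$length[i], neighbor_weights,
                                   neighbor_intercept, neighbor_noise,
                                   seed = derive_seed(seed, paste0("rsa", i)))
    })
    chains <- attach_rsa(chains, tracks)
  } else if (rsa_model == "feature_linked") {
    default_coeffs <- eval(formals(generate_rsa_feature_linked)$coeffs)
    co <- feature_coeffs %||% default_coeffs
    tracks <- lapply(seq_len(n_chains), function(i) {
      generate_rsa_feature_linked(chains, i, coeffs = co,
                                  noise = feature_noise,
                                  seed = derive_seed(seed, paste0("rsa", i)),
                                  scales = scales)
    })
    chains <- attach_rsa(chains, tracks)
  }
  chains
}

simulate_ss3 <- function(l, ss_self) {
  states <- character(l)
  states[1] <- sample(SS3_STATES, 1L, prob = c(0.45, 0.35, 0.2))
  for (i in seq_len(l - 1L)) {
    cur <- states[i]
    stay <- ss_self[[cur]]
    others <- setdiff(SS3_STATES, cur)
    states[i + 1L] <- sample(c(cur, others), 1L,
                             prob = c(stay, rep((1 - stay) / 2, 2L)))
  }
  p_true <- round(runif(l, 0.7, 0.95), 3)
  u <- runif(l, 0.25, 0.75)
  p2 <- round((1 - p_true) * u, 3)
  p3 <- round(1 - p_true - p2, 3)
  probs <- matrix(0, l, 3L, dimnames = list(NULL, SS3_STATES))
  for (i in seq_len(l)) {
    k <- match(states[i], SS3_STATES)
    rest <- setdiff(1:3, k)
    probs[i, k] <- p_true[i]
    probs[i, rest] <- c(p2[i], p3[i])
  }
  list(states = states, probs = probs)
}

simulate_disorder <- function(l) {
  p <- runif(l, 0.02, 0.25)
  n_seg <- sample(0:2, 1L, prob = c(0.2, 0.5, 0.3))
  for (s in seq_len(n_seg)) {
    len <- sample(5:15, 1L)
    if (len >= l) len <- max(1L, l - 1L)
    start <- sample(seq_len(max(1L, l - len)), 1L)
    p[start:(start + len - 1L)] <- runif(len, 0.55, 0.9)
  }
  p <- round(p, 3)
  tibble(p_disorder = p, p_order = 1 - p, state = as.integer(p >= 0.5))
}

#' Write a chain set out as fixture files in every supported dialect
#'
#' Writes, per chain, a single-record FASTA, a PSI-BLAST ASCII PSSM, a
#' PSIPRED `.ss2` file, a DISOPRED-style disorder table and an RSA TSV
#' (five files per chain), plus a `manifest.tsv` listing every file with
#' its MD5 checksum. Parsing the files back reproduces the source chains
#' exactly.
#'
#' @param chains a fully profiled [chain_set()].
#' @param out_dir output directory (created if missing).
#' @return The manifest tibble, invisibly.
#' @export
write_fixture_files <- function(chains, out_dir) {
  validate_chain_set(chains)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) abort("cannot create output directory",
                                  class = "rsapred_io_error")
  rows <- list()
  for (i in seq_len(nrow(chains))) {
    id <- chains$chain_id[i]
    seqs <- chains$sequence[i]
    files <- c(fasta = file.path(out_dir, paste0(id, ".fasta")),
               pssm = file.path(out_dir, paste0(id, ".pssm")),
               ss2 = file.path(out_dir, paste0(id, ".ss2")),
               disorder = file.path(out_dir, paste0(id, ".diso")),
               rsa = file.path(out_dir, paste0(id, "_rsa.tsv")))
    write_fasta(chains[i, ], files[["fasta"]])
    write_pssm(chains$pssm[[i]], seqs, files[["pssm"]])
    write_ss2(chains$ss3[[i]], seqs, files[["ss2"]])
    write_disopred(chains$disorder[[i]], seqs, files[["disorder"]])
    rsa <- chains$rsa[[i]]
    if (is.null(rsa)) abort_missing_input(
      sprintf("chain '%s' has no RSA track to write", id))
    write_predictions(tibble(chain_id = id, pos = seq_len(chains$length[i]),
                             residue = strsplit(seqs, "")[[1]], rsa = rsa),
                      files[["rsa"]])
    rows[[i]] <- tibble(file = basename(files), chain_id = id,
                        format = names(files),
                        md5 = unname(tools::md5sum(files)))
  }
  manifest <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble(file = character(), chain_id = character(),
           format = character(), md5 = character())
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest)
}

#' Read fixture files written by [write_fixture_files()] back into a chain set
#'
#' @param dir directory containing the fixture files and manifest.
#' @param threshold disorder decision threshold.
#' @return A fully profiled [chain_set()].
#' @export
read_fixture_files <- function(dir, threshold = 0.5) {
  manifest_path <- file.path(dir, "manifest.tsv")
  if (!file.exists(manifest_path)) abort_format("no manifest.tsv in directory")
  manifest <- utils::read.delim(manifest_path, stringsAsFactors = FALSE)
  ids <- unique(manifest$chain_id)
  sets <- lapply(ids, function(id) {
    read_fasta(file.path(dir, paste0(id, ".fasta")))
  })
  chains <- dplyr::bind_rows(sets)
  class(chains) <- c("chain_set", class(tibble()))
  l <- chains$length
  chains <- attach_pssm(chains, lapply(seq_along(ids), function(i) {
    read_pssm(file.path(dir, paste0(ids[i], ".pssm")), l[i])
  }))
  chains <- attach_ss3(chains, lapply(seq_along(ids), function(i) {
    read_psipred_ss2(file.path(dir, paste0(ids[i], ".ss2")), l[i])
  }))
  chains <- attach_disorder(chains, lapply(seq_along(ids), function(i) {
    read_disopred(file.path(dir, paste0(ids[i], ".diso")), l[i], threshold)
  }))
  attach_rsa(chains, lapply(seq_along(ids), function(i) {
    read_rsa_table(file.path(dir, paste0(ids[i], "_rsa.tsv")))$rsa
  }))
}
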