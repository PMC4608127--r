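FEATURE_BLOCKS <- c("pssm", "ss_local", "ss_global", "disorder",
                    "seq_len", "seq_pos", "physchem")

#' Logistic normalization of PSSM scores
#'
#' Maps a raw log-odds score onto `(0, 1)` with the standard logistic
#' function `1 / (1 + exp(-x))`, the normalization applied to every PSSM
#' value before window assembly.
#'
#' @param x numeric vector of finite raw scores.
#' @return Values in `(0, 1)`, strictly increasing in `x`.
#' @export
#' @examples
#' logistic_normalize(c(-2, 0, 2))
logistic_normalize <- function(x) {
  if (any(!is.finite(x))) {
    abort("non-finite PSSM score", class = c("rsapred_domain_error",
                                             "rsapred_format_error"))
  }
  1 / (1 + exp(-x))
}

off_label <- function(k) {
  ifelse(k < 0, paste0("m", -k), ifelse(k > 0, paste0("p", k), "c0"))
}

#' Feature layout for a window size
#'
#' Describes the named blocks of the assembled feature matrix: a PSSM
#' window block of width `21 N` (20 normalized scores + 1 terminal flag
#' per window position), local secondary structure (`3 N`), global
#' secondary structure (6), disorder (`3 N`), sequence length (1),
#' residue position (1) and physicochemical scales (`6 N`); the full
#' layout is `33 N + 8` columns wide.
#'
#' @param window odd window length `N`.
#' @param blocks character vector of enabled blocks (subset of
#'   `r paste(FEATURE_BLOCKS, collapse = ", ")`).
#' @return A tibble with columns `block`, `width`, `start`, `end`.
#' @export
feature_layout <- function(window = 9, blocks = FEATURE_BLOCKS) {
  n <- check_window(window)
  blocks <- match.arg(blocks, FEATURE_BLOCKS, several.ok = TRUE)
  widths <- c(pssm = 21L * n, ss_local = 3L * n, ss_global = 6L,
              disorder = 3L * n, seq_len = 1L, seq_pos = 1L,
              physchem = 6L * n)
  blocks <- FEATURE_BLOCKS[FEATURE_BLOCKS %in% blocks]  # canonical order
  w <- unname(widths[blocks])
  tibble(block = blocks, width = w,
         start = cumsum(c(1L, head(w, -1L))),
         end = cumsum(w))
}

## pad a per-residue matrix with `half` pseudo rows on each side and
## concatenate the N window slots column-wise -> L x (ncol * N)
window_stack <- function(m, half, pseudo_row) {
  l <- nrow(m)
  n <- 2L * half + 1L
  pad <- matrix(if (half > 0) pseudo_row else numeric(0), nrow = half,
                ncol = length(pseudo_row), byrow = TRUE)
  padded <- rbind(pad, m, pad)
  do.call(cbind, lapply(seq_len(n), function(j) {
    padded[j:(j + l - 1L), , drop = FALSE]
  }))
}

block_colnames <- function(prefix, half, feature_names) {
  n <- 2L * half + 1L
  offs <- off_label(seq_len(n) - half - 1L)
  as.vector(vapply(offs, function(o) paste(prefix, o, feature_names, sep = "_"),
                   character(length(feature_names))))
}

pssm_block_chain <- function(pssm, half, terminal_flag) {
  l <- nrow(pssm)
  flag <- rep(0, l)
  if (terminal_flag == "real_termini" && l >= 1L) flag[c(1L, l)] <- 1
  m <- cbind(logistic_normalize(pssm), flag)
  # pseudo residues carry literal zeros (normalization bypassed) and flag 1
  x <- window_stack(m, half, c(rep(0, 20L), 1))
  colnames(x) <- block_colnames("pssm", half, c(AA_PSSM_ORDER, "flag"))
  x
}

ss_local_block_chain <- function(ss3, half) {
  x <- window_stack(ss3$probs, half, rep(0, 3L))
  colnames(x) <- block_colnames("ss", half, SS3_STATES)
  x
}

disorder_block_chain <- function(disorder, half) {
  m <- cbind(disorder$p_disorder, disorder$p_order, as.numeric(disorder$state))
  x <- window_stack(m, half, rep(0, 3L))
  colnames(x) <- block_colnames("diso", half, c("pdis", "pord", "state"))
  x
}

physchem_block_chain <- function(letters, scales, half) {
  miss <- setdiff(unique(letters), rownames(scales))
  if (length(miss)) {
    abort_config(sprintf("physicochemical scales lack letter(s): %s",
                         paste(miss, collapse = ", ")))
  }
  x <- window_stack(scales[letters, , drop = FALSE], half, rep(0, 6L))
  colnames(x) <- block_colnames("pc", half, colnames(scales))
  x
}

#' Global secondary-structure composition features
#'
#' Computes the six global features from a chain's 3-state string: the
#' fraction of residues in helix, strand and coil, and the fraction of
#' uniform-state segments of each type. Before segment counting, maximal
#' helix runs of length one or two are rewritten to coil, since such short
#' runs cannot form a real helix segment; contents are computed from the
#' unmodified string.
#'
#' @param states character vector (or single string) of per-residue states
#'   over `C`, `H`, `E`.
#' @return Named numeric vector
#'   `(content_H, content_E, content_C, segment_H, segment_E, segment_C)`;
#'   each triple sums to 1 for a non-empty chain.
#' @export
#' @examples
#' encode_ss_global(strsplit("HHHHECCC", "")[[1]])
encode_ss_global <- function(states) {
  if (length(states) == 1L && nchar(states[1]) > 1L) {
    states <- strsplit(states, "", fixed = TRUE)[[1]]
  }
  if (length(states) == 0L) abort_format("empty state string")
  if (!all(states %in% SS3_STATES)) abort_format("states outside {C,H,E}")
  content <- vapply(c("H", "E", "C"), function(s) mean(states == s), numeric(1))
  # short-helix replacement: H runs of length <= 2 become coil
  r <- rle(states)
  r$values[r$values == "H" & r$lengths <= 2L] <- "C"
  rewritten <- inverse.rle(r)
  r2 <- rle(rewritten)
  seg <- vapply(c("H", "E", "C"), function(s) sum(r2$values == s), numeric(1))
  total <- sum(seg)
  stopifnot(total > 0)  # every residue belongs to some run
  c(content_H = content[["H"]], content_E = content[["E"]],
    content_C = content[["C"]], segment_H = seg[["H"]] / total,
    segment_E = seg[["E"]] / total, segment_C = seg[["C"]] / total)
}

#' Chain-length and residue-position features
#'
#' The two sequence-derived structural descriptors: the chain length
#' scaled by 1/1000, and the relative distance of a residue from the
#' chain center, `1 - |i - (L+1)/2| / (L/2)` (1 at the center, near 0 at
#' the termini).
#'
#' @param length chain length `L`.
#' @param pos 1-based residue index (vectorized).
#' @return A matrix with columns `seq_len` and `seq_pos`.
#' @export
encode_sequence_features <- function(length, pos) {
  if (any(pos < 1L | pos > length)) abort_config("residue index out of range")
  cbind(seq_len = rep(length / 1000, base::length(pos)),
        seq_pos = 1 - abs(pos - (length + 1) / 2) / (length / 2))
}

chain_row <- function(chains, chain = 1L) {
  validate_chain_set(chains)
  if (is.character(chain)) chain <- match(chain, chains$chain_id)
  if (is.na(chain) || chain < 1L || chain > nrow(chains)) {
    abort_config("no such chain")
  }
  chains[chain, ]
}

need_profile <- function(row, what) {
  v <- row[[what]][[1]]
  if (is.null(v)) {
    abort_missing_input(sprintf("chain '%s' has no %s profile attached",
                                row$chain_id, what))
  }
  v
}

#' Encode a single residue's windowed feature blocks
#'
#' Single-residue views of the window encodings, mainly useful for
#' inspection and testing; [assemble_features()] computes all residues of
#' all chains at once. Window positions outside the chain are pseudo
#' residues: they contribute literal zeros for every feature, except the
#' PSSM terminal flag which is 1.
#'
#' @param chains a [chain_set()] with the required profile attached.
#' @param chain chain index or `chain_id` (default: first chain).
#' @param i 1-based residue index.
#' @param window odd window length `N`.
#' @param terminal_flag `"pseudo_only"` (default; only pseudo positions
#'   are flagged) or `"real_termini"` (the chain's real first and last
#'   residues are flagged too).
#' @return A named numeric vector: length `21 N` for the PSSM block,
#'   `3 N` for the local secondary-structure and disorder blocks, `6 N`
#'   for the physicochemical block.
#' @name encode-residue
NULL

#' @rdname encode-residue
#' @export
encode_pssm_window <- function(chains, chain = 1L, i, window = 9,
                               terminal_flag = c("pseudo_only", "real_termini")) {
  terminal_flag <- match.arg(terminal_flag)
  n <- check_window(window)
  row <- chain_row(chains, chain)
  pssm <- need_profile(row, "pssm")
  pssm_block_chain(pssm, (n - 1L) %/% 2L, terminal_flag)[i, ]
}

#' @rdname encode-residue
#' @export
encode_ss_local <- function(chains, chain = 1L, i, window = 9) {
  n <- check_window(window)
  row <- chain_row(chains, chain)
  ss3 <- need_profile(row, "ss3")
  ss_local_block_chain(ss3, (n - 1L) %/% 2L)[i, ]
}

#' @rdname encode-residue
#' @export
encode_disorder_window <- function(chains, chain = 1L, i, window = 9) {
  n <- check_window(window)
  row <- chain_row(chains, chain)
  dis <- need_profile(row, "disorder")
  disorder_block_chain(dis, (n - 1L) %/% 2L)[i, ]
}

#' @rdname encode-residue
#' @param scales normalized scale matrix from [physchem_scales()].
#' @export
encode_physchem_window <- function(chains, chain = 1L, i, window = 9,
                                   scales = physchem_scales()) {
  n <- check_window(window)
  row <- chain_row(chains, chain)
  letters <- strsplit(row$sequence, "", fixed = TRUE)[[1]]
  physchem_block_chain(letters, scales, (n - 1L) %/% 2L)[i, ]
}

#' Position multipliers of the weighted sliding window
#'
#' Turns fitted neighbor-influence coefficients into per-slot feature
#' multipliers. Mode `"max"` (default) rescales the coefficients by their
#' maximum so the strongest neighbor keeps near-full magnitude; `"raw"`
#' uses the coefficients directly; `"none"` gives unit multipliers. The
#' central slot always has multiplier 1.
#'
#' @param weights a [window_weights] object (see [fit_window_weights()]).
#' @param mode `"max"`, `"raw"` or `"none"`.
#' @return Numeric vector of length `N`, ordered from offset `-(N-1)/2`
#'   to `+(N-1)/2`.
#' @export
window_multipliers <- function(weights, mode = c("max", "raw", "none")) {
  mode <- match.arg(mode)
  n <- weights$window
  if (mode == "none") return(rep(1, n))
  w <- unname(weights$coefficients)
  m <- if (mode == "raw") w else w / max(w)
  half <- (n - 1L) %/% 2L
  c(m[seq_len(half)], 1, m[half + seq_len(half)])
}

#' Apply weighted-window multipliers to a windowed block vector
#'
#' Each of the `N` sub-blocks of a windowed feature vector is multiplied
#' by its slot's multiplier; the central sub-block is untouched.
#'
#' @param block_vector numeric vector whose length is divisible by the
#'   window length.
#' @param window odd window length the block was built with.
#' @param weights a [window_weights] object with matching window.
#' @param mode multiplier mode, see [window_multipliers()].
#' @return The weighted vector (same length and names).
#' @export
apply_window_weighting <- function(block_vector, window, weights,
                                   mode = c("max", "raw", "none")) {
  n <- check_window(window)
  if (length(block_vector) %% n != 0L) {
    abort_config("block width is not divisible by the window length")
  }
  if (!is.null(weights) && weights$window != n) {
    abort_config("window weights were fitted for a different window length")
  }
  m <- window_multipliers(weights, mode)
  sub <- length(block_vector) %/% n
  block_vector * rep(m, each = sub)
}

#' Assemble per-residue feature matrices for a chain set
#'
#' Builds the full feature table: every enabled block, every residue of
#' every chain, in the canonical block order (PSSM window, local
#' secondary structure, global secondary structure, disorder window,
#' sequence length, residue position, physicochemical window). With
#' `weights` supplied, the windowed blocks are scaled by the weighted
#' sliding-window multipliers.
#'
#' @inheritParams feature_layout
#' @param chains a [chain_set()] with the profiles needed by the enabled
#'   blocks attached.
#' @param scales normalized physicochemical scale matrix.
#' @param weights optional [window_weights] for the weighted window.
#' @param weighting multiplier mode, see [window_multipliers()].
#' @param terminal_flag see [encode_pssm_window()].
#' @return A tibble with `chain_id`, `pos`, `residue` and one column per
#'   feature (`33 N + 8` feature columns for the full layout); the block
#'   layout is attached as attribute `"layout"` and the window as
#'   `"window"`.
#' @export
assemble_features <- function(chains, window = 9, blocks = FEATURE_BLOCKS,
                              scales = physchem_scales(), weights = NULL,
                              weighting = c("max", "raw", "none"),
                              terminal_flag = c("pseudo_only", "real_termini")) {
  weighting <- match.arg(weighting)
  terminal_flag <- match.arg(terminal_flag)
  n <- check_window(window)
  half <- (n - 1L) %/% 2L
  blocks <- match.arg(blocks, FEATURE_BLOCKS, several.ok = TRUE)
  blocks <- FEATURE_BLOCKS[FEATURE_BLOCKS %in% blocks]
  validate_chain_set(chains)
  if (!is.null(weights) && weights$window != n) {
    abort_config("window weights were fitted for a different window length")
  }
  mult <- if (is.null(weights)) rep(1, n) else window_multipliers(weights, weighting)

  per_chain <- lapply(seq_len(nrow(chains)), function(ci) {
    row <- chains[ci, ]
    l <- row$length
    letters <- strsplit(row$sequence, "", fixed = TRUE)[[1]]
    parts <- list()
    if ("pssm" %in% blocks) {
      x <- pssm_block_chain(need_profile(row, "pssm"), half, terminal_flag)
      parts$pssm <- sweep_window(x, mult, 21L)
    }
    if ("ss_local" %in% blocks || "ss_global" %in% blocks) {
      ss3 <- need_profile(row, "ss3")
    }
    if ("ss_local" %in% blocks) {
      x <- ss_local_block_chain(ss3, half)
      parts$ss_local <- sweep_window(x, mult, 3L)
    }
    if ("ss_global" %in% blocks) {
      g <- encode_ss_global(ss3$states)
      parts$ss_global <- matrix(g, nrow = l, ncol = 6L, byrow = TRUE,
                                dimnames = list(NULL, names(g)))
    }
    if ("disorder" %in% blocks) {
      x <- disorder_block_chain(need_profile(row, "disorder"), half)
      parts$disorder <- sweep_window(x, mult, 3L)
    }
    if ("seq_len" %in% blocks || "seq_pos" %in% blocks) {
      sq <- encode_sequence_features(l, seq_len(l))
      if ("seq_len" %in% blocks) parts$seq_len <- sq[, "seq_len", drop = FALSE]
      if ("seq_pos" %in% blocks) parts$seq_pos <- sq[, "seq_pos", drop = FALSE]
    }
    if ("physchem" %in% blocks) {
      x <- physchem_block_chain(letters, scales, half)
      parts$physchem <- sweep_window(x, mult, 6L)
    }
    m <- do.call(cbind, parts[blocks[blocks %in% names(parts)]])
    dplyr::bind_cols(tibble(chain_id = row$chain_id, pos = seq_len(l),
                            residue = letters),
                     as_tibble(m))
  })
  out <- dplyr::bind_rows(per_chain)
  attr(out, "layout") <- feature_layout(n, blocks)
  attr(out, "window") <- n
  attr(out, "blocks") <- blocks
  out
}

## multiply each window slot of an L x (slots * width) block by its multiplier
sweep_window <- function(x, mult, width_per_slot) {
  if (all(mult == 1)) return(x)
  x * matrix(rep(mult, each = width_per_slot), nrow = nrow(x),
             ncol = length(mult) * width_per_slot, byrow = TRUE)
}

#' Extract the numeric feature matrix from an assembled feature table
#'
#' @param features output of [assemble_features()].
#' @return Numeric matrix (residues x features), id columns dropped.
#' @export
feature_matrix <- function(features) {
  id <- c("chain_id", "pos", "residue")
  as.matrix(features[setdiff(names(features), id)])
}
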