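#' Build a chain set from identifiers and sequences
#'
#' A chain set is the package's central container: a tibble with one row per
#' protein chain and list-columns holding the per-chain profile tracks.
#' Columns are `chain_id`, `sequence`, `length`, and the list-columns `pssm`
#' (L x 20 numeric matrix of raw log-odds), `ss3` (list with `states`, a
#' length-L character vector over C/H/E, and `probs`, an L x 3 matrix),
#' `disorder` (tibble with `p_disorder`, `p_order`, `state`) and `rsa`
#' (length-L numeric vector of fraction-scale RSA). Profiles start out as
#' `NULL` and are attached by the readers or the synthetic generator.
#'
#' @param chain_id character vector of non-empty, unique identifiers.
#' @param sequence character vector of sequences over the 20 standard
#'   amino-acid letters plus `X`; non-standard letters are mapped to `X`
#'   with a warning.
#' @return A tibble of class `chain_set`.
#' @export
#' @examples
#' chain_set("c1", "ACDEF")
chain_set <- function(chain_id, sequence) {
  if (length(chain_id) != length(sequence)) {
    abort_config("`chain_id` and `sequence` must have the same length.")
  }
  if (any(!nzchar(chain_id)) || anyNA(chain_id)) {
    abort_format("chain identifiers must be non-empty")
  }
  if (anyDuplicated(chain_id)) {
    abort_format("duplicate chain identifiers")
  }
  sequence <- toupper(sequence)
  if (any(!nzchar(sequence))) {
    abort_format("zero-length sequence entry")
  }
  cleaned <- clean_sequences(sequence)
  out <- tibble(
    chain_id = as.character(chain_id),
    sequence = cleaned,
    length = nchar(cleaned),
    pssm = vector("list", length(chain_id)),
    ss3 = vector("list", length(chain_id)),
    disorder = vector("list", length(chain_id)),
    rsa = vector("list", length(chain_id))
  )
  class(out) <- c("chain_set", class(out))
  out
}

clean_sequences <- function(sequence) {
  letters_ok <- c(AA_PSSM_ORDER, "X")
  n_bad <- 0L
  out <- vapply(sequence, function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    bad <- !(ch %in% letters_ok)
    if (any(bad)) {
      n_bad <<- n_bad + sum(bad)
      ch[bad] <- "X"
    }
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
  if (n_bad > 0L) {
    warn(sprintf("%d non-standard residue letter(s) mapped to X", n_bad))
  }
  out
}

#' @export
print.chain_set <- function(x, ...) {
  cat(sprintf("<chain_set> %d chain(s), %d residues total\n",
              nrow(x), sum(x$length)))
  NextMethod()
}

validate_chain_set <- function(chains) {
  if (!inherits(chains, "data.frame") ||
      !all(c("chain_id", "sequence", "length") %in% names(chains))) {
    abort_config("expected a chain_set tibble (see `chain_set()`)")
  }
  invisible(chains)
}

## attach a per-chain profile list-column, checking row counts against L
attach_profile <- function(chains, column, values, check_len) {
  validate_chain_set(chains)
  if (length(values) != nrow(chains)) {
    abort_length("one profile per chain is required")
  }
  for (i in seq_len(nrow(chains))) {
    got <- check_len(values[[i]])
    if (got != chains$length[i]) {
      abort_length(sprintf(
        "profile for chain '%s' has %d rows; sequence length is %d",
        chains$chain_id[i], got, chains$length[i]))
    }
  }
  chains[[column]] <- values
  chains
}

#' Attach profile tracks to a chain set
#'
#' @param chains a [chain_set()] tibble.
#' @param values a list with one element per chain: an L x 20 matrix for
#'   `attach_pssm()`, a `list(states=, probs=)` pair for `attach_ss3()`, a
#'   tibble with `p_disorder`/`p_order`/`state` for `attach_disorder()`, or
#'   a length-L fraction-scale numeric vector for `attach_rsa()`.
#' @return The chain set with the list-column filled in.
#' @name attach-profiles
NULL

#' @rdname attach-profiles
#' @export
attach_pssm <- function(chains, values) {
  attach_profile(chains, "pssm", values, function(v) {
    if (!is.matrix(v) || ncol(v) != 20L) {
      abort_format("a PSSM profile must be an L x 20 matrix")
    }
    nrow(v)
  })
}

#' @rdname attach-profiles
#' @export
attach_ss3 <- function(chains, values) {
  attach_profile(chains, "ss3", values, function(v) {
    if (!is.list(v) || !all(c("states", "probs") %in% names(v))) {
      abort_format("an ss3 profile must be a list(states=, probs=)")
    }
    if (length(v$states) != nrow(v$probs)) {
      abort_format("ss3 states and probability rows disagree")
    }
    length(v$states)
  })
}

#' @rdname attach-profiles
#' @export
attach_disorder <- function(chains, values) {
  attach_profile(chains, "disorder", values, function(v) {
    if (!all(c("p_disorder", "p_order", "state") %in% names(v))) {
      abort_format("a disorder profile needs p_disorder, p_order and state")
    }
    nrow(v)
  })
}

#' @rdname attach-profiles
#' @export
attach_rsa <- function(chains, values) {
  attach_profile(chains, "rsa", values, function(v) {
    if (!is.numeric(v)) abort_format("an RSA track must be numeric")
    length(v)
  })
}

#' Default maximum accessible surface area table
#'
#' Per-residue maximum accessible surface areas (A^2) in an extended
#' Ala-X-Ala tri-peptide conformation, used to normalize absolute
#' accessibility into relative solvent accessibility. The bundled values
#' follow the extended-tripeptide convention common in the RSA literature;
#' the table is a user-replaceable config, not a constant of the method.
#' `X` (unknown residue) receives the mean of the 20 tabulated values.
#'
#' @param path optional path to a two-column TSV (`aa`, `max_asa`)
#'   replacing the bundled table.
#' @return Named numeric vector of 21 positive values (20 residues + `X`).
#' @export
max_asa_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "max_asa_tripeptide.tsv", package = "rsapred")
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("aa", "max_asa") %in% names(tab)) || nrow(tab) != 20L) {
    abort_format("max-ASA table must have 20 rows with columns aa, max_asa")
  }
  vals <- setNames(as.numeric(tab$max_asa), tab$aa)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    abort_format("max-ASA values must all be positive")
  }
  c(vals, X = mean(vals))
}

#' Derive relative solvent accessibility from DSSP accessibility values
#'
#' Divides each residue's absolute accessible surface area (the DSSP `ACC`
#' column, A^2) by the maximum accessibility of its residue type. Values
#' that exceed the tabulated maximum (which DSSP occasionally produces)
#' are clamped to the scale ceiling with a warning.
#'
#' @param acc numeric vector of non-negative accessibilities (A^2).
#' @param sequence single string, same length as `acc`.
#' @param max_asa named numeric table from [max_asa_table()].
#' @param unit output scale: `"fraction"` (values in 0..1, default) or
#'   `"percent"` (0..100).
#' @return Numeric RSA vector on the requested scale.
#' @export
#' @examples
#' rsa_from_dssp_acc(c(55.1, 0), "AC")
rsa_from_dssp_acc <- function(acc, sequence, max_asa = max_asa_table(),
                              unit = c("fraction", "percent")) {
  unit <- match.arg(unit)
  if (any(!is.finite(acc)) || any(acc < 0)) {
    abort_format("ACC values must be finite and non-negative")
  }
  letters <- strsplit(sequence, "", fixed = TRUE)[[1]]
  if (length(letters) != length(acc)) {
    abort_length("`acc` and `sequence` lengths differ")
  }
  missing <- setdiff(unique(letters), names(max_asa))
  if (length(missing)) {
    abort_config(sprintf("max-ASA table lacks letter(s): %s",
                         paste(missing, collapse = ", ")))
  }
  rsa <- acc / as.numeric(max_asa[letters])
  over <- rsa > 1
  if (any(over)) {
    warn(sprintf("%d RSA value(s) above the ceiling clamped", sum(over)))
    rsa[over] <- 1
  }
  if (unit == "percent") rsa <- rsa * 100
  rsa
}
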