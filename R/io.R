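#' Read protein chains from a FASTA file
#'
#' Parses every record into a [chain_set()] row. Letters outside the 20
#' standard amino acids are mapped to `X` with a warning; headers are
#' truncated at the first whitespace to form the chain identifier.
#'
#' @param path path to a FASTA file.
#' @return A `chain_set` tibble with sequence information only.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort_format(sprintf("no such file: %s", path))
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || all(!nzchar(trimws(lines)))) {
    abort_format(sprintf("%s: empty FASTA file", path))
  }
  first <- which(nzchar(trimws(lines)))[1]
  if (!startsWith(trimws(lines[first]), ">")) {
    abort_format(sprintf("%s: line %d: expected a '>' header", path, first))
  }
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0L) abort_format(sprintf("%s: no FASTA records", path))
  ids <- vapply(strsplit(names(seqs), "\\s+"), `[`, character(1), 1L)
  sequence <- as.character(seqs)
  if (any(!nzchar(sequence))) {
    bad <- ids[!nzchar(sequence)][1]
    abort_format(sprintf("%s: zero-length sequence for record '%s'", path, bad))
  }
  chain_set(ids, sequence)
}

#' Write a chain set to FASTA
#'
#' @param chains a [chain_set()] tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(chains, path) {
  validate_chain_set(chains)
  x <- Biostrings::AAStringSet(setNames(chains$sequence, chains$chain_id))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

pssm_data_rows <- function(lines) {
  grep("^\\s*\\d+\\s+[A-Z]\\s", lines)
}

#' Read a PSI-BLAST ASCII PSSM profile
#'
#' Parses the per-residue rows of the ASCII matrix dialect (header lines,
#' then rows of index, residue letter and 20 log-odds columns). Scores are
#' returned raw; logistic normalization happens at feature-encoding time.
#'
#' @param path path to the profile file.
#' @param length expected number of residues (chain length).
#' @return An `length` x 20 numeric matrix, columns in PSI-BLAST
#'   alphabet order (ARNDCQEGHILKMFPSTWYV).
#' @export
read_pssm <- function(path, length) {
  if (!file.exists(path)) abort_format(sprintf("no such file: %s", path))
  lines <- readLines(path, warn = FALSE)
  rows <- pssm_data_rows(lines)
  if (length(rows) != length) {
    abort_length(sprintf("%s: %d profile rows; expected %d",
                         path, base::length(rows), length))
  }
  scores <- matrix(NA_real_, nrow = length, ncol = 20L,
                   dimnames = list(NULL, AA_PSSM_ORDER))
  for (r in seq_along(rows)) {
    tok <- strsplit(trimws(lines[rows[r]]), "\\s+")[[1]]
    if (base::length(tok) < 22L) {
      abort_format(sprintf("%s: line %d: fewer than 20 score columns",
                           path, rows[r]))
    }
    vals <- suppressWarnings(as.numeric(tok[3:22]))
    if (anyNA(vals)) {
      abort_format(sprintf("%s: line %d: non-numeric score cell", path, rows[r]))
    }
    scores[r, ] <- vals
  }
  scores
}

#' Write a PSSM profile in the PSI-BLAST ASCII dialect
#'
#' @param scores L x 20 numeric matrix of raw log-odds scores.
#' @param sequence chain sequence (length L string).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pssm <- function(scores, sequence, path) {
  letters <- strsplit(sequence, "", fixed = TRUE)[[1]]
  if (nrow(scores) != length(letters)) {
    abort_length("`scores` rows and `sequence` length differ")
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("",
               "Last position-specific scoring matrix computed",
               paste0("   ", paste(sprintf("%3s", AA_PSSM_ORDER), collapse = " "))),
             con)
  for (i in seq_len(nrow(scores))) {
    writeLines(sprintf("%5d %s %s", i, letters[i],
                       paste(sprintf("%3d", as.integer(round(scores[i, ]))),
                             collapse = " ")), con)
  }
  invisible(path)
}

#' Read a PSIPRED `.ss2` secondary-structure profile
#'
#' Comment lines (starting `#`) and blank lines are skipped; data rows are
#' (index, residue, state, pC, pH, pE). Probabilities are taken verbatim --
#' rows whose probabilities do not sum to 1 are accepted unchanged.
#'
#' @param path path to the `.ss2` file.
#' @param length expected chain length.
#' @return A list with `states` (length-L character vector over C/H/E) and
#'   `probs` (L x 3 matrix, columns C, H, E).
#' @export
read_psipred_ss2 <- function(path, length) {
  if (!file.exists(path)) abort_format(sprintf("no such file: %s", path))
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  data <- lines[keep]
  if (base::length(data) != length) {
    abort_length(sprintf("%s: %d data rows; expected %d",
                         path, base::length(data), length))
  }
  states <- character(length)
  probs <- matrix(NA_real_, length, 3L, dimnames = list(NULL, SS3_STATES))
  for (i in seq_along(data)) {
    tok <- strsplit(trimws(data[i]), "\\s+")[[1]]
    if (base::length(tok) < 6L) {
      abort_format(sprintf("%s: malformed .ss2 row %d", path, i))
    }
    states[i] <- tok[3]
    vals <- suppressWarnings(as.numeric(tok[4:6]))
    if (anyNA(vals)) abort_format(sprintf("%s: non-numeric probability, row %d", path, i))
    probs[i, ] <- vals
  }
  if (!all(states %in% SS3_STATES)) {
    abort_format(sprintf("%s: secondary-structure state outside {C,H,E}", path))
  }
  list(states = states, probs = probs)
}

#' Write a secondary-structure profile in the `.ss2` dialect
#'
#' @param ss3 list with `states` and `probs` (see [read_psipred_ss2()]).
#' @param sequence chain sequence.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ss2 <- function(ss3, sequence, path) {
  letters <- strsplit(sequence, "", fixed = TRUE)[[1]]
  if (length(ss3$states) != length(letters)) {
    abort_length("`ss3` rows and `sequence` length differ")
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# PSF format remark", ""), con)
  for (i in seq_along(letters)) {
    writeLines(sprintf("%4d %s %s  %6.3f %6.3f %6.3f", i, letters[i],
                       ss3$states[i], ss3$probs[i, 1], ss3$probs[i, 2],
                       ss3$probs[i, 3]), con)
  }
  invisible(path)
}

#' Read a per-residue disorder prediction table
#'
#' Parses DISOPRED-style rows of (index, residue, state mark, disorder
#' probability). The order probability is the complement of the disorder
#' probability, and the binary state is 1 wherever the disorder
#' probability is greater than or equal to `threshold`.
#'
#' @param path path to the disorder file.
#' @param length expected chain length.
#' @param threshold disorder decision threshold in `[0,1]` (default 0.5).
#' @return A tibble with columns `p_disorder`, `p_order`, `state`.
#' @export
read_disopred <- function(path, length, threshold = 0.5) {
  if (!file.exists(path)) abort_format(sprintf("no such file: %s", path))
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  data <- lines[keep]
  if (base::length(data) != length) {
    abort_length(sprintf("%s: %d data rows; expected %d",
                         path, base::length(data), length))
  }
  p <- vapply(data, function(l) {
    tok <- strsplit(trimws(l), "\\s+")[[1]]
    if (base::length(tok) < 4L) abort_format(sprintf("%s: malformed disorder row", path))
    suppressWarnings(as.numeric(tok[4]))
  }, numeric(1), USE.NAMES = FALSE)
  if (anyNA(p) || any(p < 0) || any(p > 1)) {
    abort_format(sprintf("%s: disorder probability outside [0,1]", path))
  }
  tibble(p_disorder = p, p_order = 1 - p, state = as.integer(p >= threshold))
}

#' Write a disorder profile in the DISOPRED-style dialect
#'
#' @param disorder tibble from [read_disopred()] (or the generator).
#' @param sequence chain sequence.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_disopred <- function(disorder, sequence, path) {
  letters <- strsplit(sequence, "", fixed = TRUE)[[1]]
  if (nrow(disorder) != length(letters)) {
    abort_length("`disorder` rows and `sequence` length differ")
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# per-residue disorder prediction", con)
  mark <- ifelse(disorder$state == 1L, "*", ".")
  for (i in seq_along(letters)) {
    writeLines(sprintf("%5d %s %s %6.3f", i, letters[i], mark[i],
                       disorder$p_disorder[i]), con)
  }
  invisible(path)
}

#' Read and write per-residue RSA tables
#'
#' The table dialect is a four-column TSV -- `chain_id`, `pos` (1-based),
#' `residue`, `rsa` -- used both for ground-truth RSA tracks and for
#' written predictions. Rows are sorted by position within each chain on
#' read; duplicate positions are a format error. Values are written with
#' full precision so a write/read cycle is lossless.
#'
#' @param path path to the TSV file.
#' @param unit declared scale of the `rsa` column: `"fraction"` or
#'   `"percent"`. Values are validated against the declared ceiling.
#' @return A tibble with columns `chain_id`, `pos`, `residue`, `rsa`.
#' @export
read_rsa_table <- function(path, unit = c("fraction", "percent")) {
  unit <- match.arg(unit)
  if (!file.exists(path)) abort_format(sprintf("no such file: %s", path))
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (nrow(tab) == 0L) abort_format(sprintf("%s: empty RSA table", path))
  if (!all(c("chain_id", "pos", "residue", "rsa") %in% names(tab))) {
    abort_format(sprintf("%s: expected columns chain_id, pos, residue, rsa", path))
  }
  if (anyDuplicated(tab[c("chain_id", "pos")])) {
    abort_format(sprintf("%s: duplicate (chain_id, pos) rows", path))
  }
  ceiling_val <- if (unit == "fraction") 1 else 100
  if (any(!is.finite(tab$rsa)) || any(tab$rsa < 0) || any(tab$rsa > ceiling_val)) {
    abort_format(sprintf("%s: RSA values outside [0, %s]", path, ceiling_val))
  }
  tab$chain_id <- as.character(tab$chain_id)
  out <- dplyr::arrange(as_tibble(tab),
                        match(.data$chain_id, unique(tab$chain_id)), .data$pos)
  out[c("chain_id", "pos", "residue", "rsa")]
}

#' @param data a tibble with columns `chain_id`, `pos`, `residue`, `rsa`
#'   (predicted or true RSA).
#' @rdname read_rsa_table
#' @export
write_predictions <- function(data, path) {
  need <- c("chain_id", "pos", "residue", "rsa")
  if (!all(need %in% names(data))) {
    abort_config("prediction table needs chain_id, pos, residue, rsa")
  }
  out <- data.frame(chain_id = data$chain_id, pos = data$pos,
                    residue = data$residue,
                    rsa = sprintf("%.17g", data$rsa))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read DSSP-derived accessibility values from a TSV extract
#'
#' Full DSSP parsing is out of scope; this reads the minimal per-residue
#' extract (columns `pos`, `residue`, `acc` in A^2) that pairs with
#' [rsa_from_dssp_acc()].
#'
#' @param path path to the TSV extract.
#' @return A tibble with columns `pos`, `residue`, `acc`.
#' @export
read_dssp_acc <- function(path) {
  if (!file.exists(path)) abort_format(sprintf("no such file: %s", path))
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("pos", "residue", "acc") %in% names(tab))) {
    abort_format(sprintf("%s: expected columns pos, residue, acc", path))
  }
  if (any(tab$acc < 0)) abort_format(sprintf("%s: negative ACC value", path))
  as_tibble(tab[c("pos", "residue", "acc")])
}
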