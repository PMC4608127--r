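# deterministic hand-built fixtures used across the format and encoding tests

manual_chain <- function() {
  ch <- chain_set("c1", "ACDEF")
  pssm <- matrix(((seq_len(5 * 20) * 3) %% 13) - 6, nrow = 5,
                 dimnames = list(NULL, c("A", "R", "N", "D", "C", "Q", "E",
                                         "G", "H", "I", "L", "K", "M", "F",
                                         "P", "S", "T", "W", "Y", "V")))
  ch <- attach_pssm(ch, list(pssm))
  probs <- matrix(c(1, 0, 0,
                    1, 0, 0,
                    0.1, 0.8, 0.1,
                    0.1, 0.8, 0.1,
                    0.2, 0.1, 0.7), nrow = 5, byrow = TRUE,
                  dimnames = list(NULL, c("C", "H", "E")))
  ch <- attach_ss3(ch, list(list(states = c("C", "C", "H", "H", "E"),
                                 probs = probs)))
  ch <- attach_disorder(ch, list(tibble::tibble(
    p_disorder = c(0.1, 0.2, 0.7, 0.6, 0.3),
    p_order = 1 - c(0.1, 0.2, 0.7, 0.6, 0.3),
    state = c(0L, 0L, 1L, 1L, 0L))))
  attach_rsa(ch, list(c(0.1, 0.4, 0.8, 0.5, 0.2)))
}

# independent oracle model: "predicts" by reading a designated feature column
predict.truth_lookup <- function(object, newdata, ...) {
  newdata[, object$column]
}
registerS3method("predict", "truth_lookup", predict.truth_lookup,
                 envir = asNamespace("stats"))

truth_lookup_engine <- function(column) {
  function(x, y, params) structure(list(column = column),
                                   class = "truth_lookup")
}
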