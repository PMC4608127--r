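test_that("logistic normalization matches its closed form and symmetry", {
  expect_equal(logistic_normalize(0), 0.5)
  expect_equal(logistic_normalize(2), 0.880797, tolerance = 1e-6)
  x <- c(-3.2, -0.5, 0.7, 4.1)
  expect_equal(logistic_normalize(x) + logistic_normalize(-x),
               rep(1, length(x)))
  expect_true(all(diff(logistic_normalize(seq(-10, 10, by = 0.5))) > 0))
  expect_error(logistic_normalize(Inf), class = "rsapred_domain_error")
  expect_error(logistic_normalize(NA_real_), class = "rsapred_domain_error")
})

test_that("PSSM window encoding pads with flagged zero pseudo residues", {
  ch <- manual_chain()
  v <- encode_pssm_window(ch, i = 1, window = 9)
  expect_length(v, 189)
  # first four 21-wide sub-blocks are pseudo: zeros + flag 1
  for (k in 0:3) {
    blk <- v[(k * 21 + 1):(k * 21 + 21)]
    expect_equal(unname(blk), c(rep(0, 20), 1))
  }
  # fifth sub-block is the residue itself: normalized scores, flag 0
  own <- v[(4 * 21 + 1):(4 * 21 + 21)]
  expect_equal(unname(own), c(logistic_normalize(ch$pssm[[1]][1, ]), 0),
               ignore_attr = TRUE)
  # real (non-pseudo) values are strictly inside (0,1)
  real <- v[v != 0 & v != 1]
  expect_true(all(real > 0 & real < 1))

  # degenerate window: just the residue's own scores + flag
  v1 <- encode_pssm_window(ch, i = 3, window = 1)
  expect_equal(unname(v1),
               c(logistic_normalize(ch$pssm[[1]][3, ]), 0),
               ignore_attr = TRUE)

  # optional convention: real terminal residues flagged too
  vt <- encode_pssm_window(ch, i = 1, window = 1,
                           terminal_flag = "real_termini")
  expect_equal(unname(vt[21]), 1)

  ch_bare <- chain_set("c1", "ACDEF")
  expect_error(encode_pssm_window(ch_bare, i = 1, window = 9),
               class = "rsapred_missing_input_error")
})

test_that("local secondary-structure window carries probability triples", {
  ch <- manual_chain()
  v <- encode_ss_local(ch, i = 3, window = 5)
  expect_length(v, 15)
  expect_equal(unname(v), as.vector(t(ch$ss3[[1]]$probs)))
  # chain start: first two triples are pseudo zeros
  v0 <- encode_ss_local(ch, i = 1, window = 5)
  expect_equal(unname(v0[1:6]), rep(0, 6))
  # N = 1 is the residue's own triple
  expect_equal(unname(encode_ss_local(ch, i = 5, window = 1)),
               unname(ch$ss3[[1]]$probs[5, ]))
})

test_that("global secondary-structure features follow the short-helix rule", {
  expect_equal(unname(encode_ss_global("CCCCC")), c(0, 0, 1, 0, 0, 1))
  g <- encode_ss_global("HHHHECCC")
  expect_equal(unname(g), c(0.5, 0.125, 0.375, 1 / 3, 1 / 3, 1 / 3))
  # two consecutive H cannot form a helix segment: rewritten to coil for
  # segment counting, but contents use the raw string
  g2 <- encode_ss_global("CCHHCCC")
  expect_equal(unname(g2), c(2 / 7, 0, 5 / 7, 0, 0, 1))
  # content and segment triples each sum to 1
  set.seed(8)
  for (i in 1:20) {
    states <- sample(c("C", "H", "E"), sample(3:40, 1), replace = TRUE)
    g <- encode_ss_global(states)
    expect_equal(sum(g[1:3]), 1)
    expect_equal(sum(g[4:6]), 1)
  }
})

test_that("disorder window encodes (p_disorder, p_order, state) triples", {
  ch <- manual_chain()
  v <- encode_disorder_window(ch, i = 3, window = 1)
  expect_equal(unname(v), c(0.7, 0.3, 1))
  v5 <- encode_disorder_window(ch, i = 1, window = 5)
  expect_equal(unname(v5[1:6]), rep(0, 6))  # pseudo padding
  # a fully ordered chain gives (0, 1, 0) triples
  ch2 <- chain_set("c2", "AAAA")
  ch2 <- attach_disorder(ch2, list(tibble::tibble(
    p_disorder = rep(0, 4), p_order = rep(1, 4), state = rep(0L, 4))))
  v <- encode_disorder_window(ch2, i = 2, window = 3)
  expect_equal(unname(v), rep(c(0, 1, 0), 3))
})

test_that("sequence features follow the center-distance formula", {
  m <- encode_sequence_features(11, c(6, 1, 11))
  expect_equal(unname(m[, "seq_pos"]), c(1, 1 - 5 / 5.5, 1 - 5 / 5.5))
  expect_equal(unname(m[1, "seq_pos"]), 1)
  expect_equal(unname(m[2, "seq_pos"]), 0.090909, tolerance = 1e-5)
  expect_equal(unname(encode_sequence_features(500, 1)[, "seq_len"]), 0.5)
  expect_error(encode_sequence_features(5, 6), class = "rsapred_config_error")
})

test_that("physicochemical window uses normalized per-letter scale values", {
  scales <- physchem_scales()
  expect_equal(dim(scales), c(21, 6))
  expect_true(all(scales >= 0 & scales <= 1))
  expect_equal(unname(scales["X", ]), unname(colMeans(scales[1:20, ])))

  ch <- chain_set("c1", "AAAAA")
  v <- encode_physchem_window(ch, i = 3, window = 5, scales = scales)
  expect_equal(unname(v), rep(unname(scales["A", ]), 5))
  v0 <- encode_physchem_window(ch, i = 1, window = 5, scales = scales)
  expect_equal(unname(v0[1:12]), rep(0, 12))  # two pseudo slots
  v1 <- encode_physchem_window(ch, i = 2, window = 1, scales = scales)
  expect_equal(unname(v1), unname(scales["A", ]))
})

test_that("assembled layout has the declared block widths at every window", {
  for (n in c(5, 7, 9, 11, 13)) {
    lay <- feature_layout(n)
    expect_equal(lay$width,
                 c(21L * n, 3L * n, 6L, 3L * n, 1L, 1L, 6L * n))
    expect_equal(sum(lay$width), 33L * n + 8L)
  }
  ch <- manual_chain()
  f <- assemble_features(ch, window = 9)
  expect_equal(ncol(f) - 3L, 33L * 9L + 8L)
  expect_equal(nrow(f), 5L)
  # PSSM-only encoding is exactly the (20+1) x N block
  f_pssm <- assemble_features(ch, window = 9, blocks = "pssm")
  expect_equal(ncol(f_pssm) - 3L, 189L)
})

test_that("a single-residue chain encodes as one all-pseudo-flanked row", {
  ch <- chain_set("c1", "A")
  ch <- attach_pssm(ch, list(matrix(0, 1, 20)))
  ch <- attach_ss3(ch, list(list(states = "C",
                                 probs = matrix(c(1, 0, 0), 1,
                                                dimnames = list(NULL, c("C", "H", "E"))))))
  ch <- attach_disorder(ch, list(tibble::tibble(p_disorder = 0, p_order = 1,
                                                state = 0L)))
  f <- assemble_features(ch, window = 9)
  expect_equal(nrow(f), 1L)
  m <- feature_matrix(f)
  flags <- m[1, grep("^pssm_.*_flag$", colnames(m))]
  expect_equal(unname(flags), c(rep(1, 4), 0, rep(1, 4)))
})

test_that("windowed encoding is position-local outside the window radius", {
  ch1 <- generate_chain_set(1, 30, 30, seed = 21, rsa_model = "none")
  ch2 <- ch1
  # perturb residue 25's profile inputs
  p <- ch2$pssm[[1]]; p[25, ] <- p[25, ] + 3
  ch2$pssm[[1]] <- p
  d <- ch2$disorder[[1]]; d$p_disorder[25] <- 0.99; d$p_order[25] <- 0.01
  ch2$disorder[[1]] <- d
  f1 <- assemble_features(ch1, window = 9)
  f2 <- assemble_features(ch2, window = 9)
  m1 <- feature_matrix(f1); m2 <- feature_matrix(f2)
  local_cols <- grep("^(pssm|diso)_", colnames(m1))
  affected <- which(rowSums(m1[, local_cols] != m2[, local_cols]) > 0)
  expect_true(all(abs(affected - 25) <= 4))
  expect_true(25 %in% affected)
})

test_that("window weighting scales sub-blocks and unit weights are identity", {
  ch <- manual_chain()
  w_unit <- window_weights(5, rep(1, 4), 0)
  v <- encode_ss_local(ch, i = 3, window = 5)
  expect_equal(apply_window_weighting(v, 5, w_unit, mode = "raw"), v)
  # zero neighbor multipliers keep only the central sub-block
  w_zero <- window_weights(5, rep(0, 4), 0)
  out <- apply_window_weighting(v, 5, w_zero, mode = "raw")
  expect_equal(unname(out), c(rep(0, 6), unname(v[7:9]), rep(0, 6)))
  # max-normalized multipliers: strongest neighbor keeps full magnitude
  w <- window_weights(5, c(0.1, 0.4, 0.38, 0.12), 0)
  m <- window_multipliers(w, "max")
  expect_equal(m, c(0.25, 1, 1, 0.95, 0.3))
  expect_error(apply_window_weighting(v[1:14], 5, w_unit),
               class = "rsapred_config_error")
  expect_error(apply_window_weighting(v, 5, window_weights(7, rep(1, 6), 0)),
               class = "rsapred_config_error")
})

test_that("weighted assembly equals manual scaling of windowed blocks", {
  ch <- manual_chain()
  w <- window_weights(5, c(0.1, 0.4, 0.38, 0.12), 0)
  f0 <- assemble_features(ch, window = 5)
  f1 <- assemble_features(ch, window = 5, weights = w, weighting = "max")
  m0 <- feature_matrix(f0); m1 <- feature_matrix(f1)
  # global + sequence blocks untouched
  fixed <- grep("^(content|segment|seq_)", colnames(m0))
  expect_equal(m1[, fixed], m0[, fixed])
  # a windowed block row equals apply_window_weighting of the unweighted row
  ss_cols <- grep("^ss_", colnames(m0))
  expect_equal(unname(m1[3, ss_cols]),
               unname(apply_window_weighting(m0[3, ss_cols], 5, w, "max")))
})
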