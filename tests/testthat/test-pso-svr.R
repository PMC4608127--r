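sphere <- function(x) sum(x^2)

test_that("fold assignment is chain-level, balanced and deterministic", {
  ids <- sprintf("c%02d", 1:6)
  f <- make_folds(ids, n = 3, seed = 9)
  expect_setequal(f$chain_id, ids)
  expect_equal(sort(as.integer(table(f$fold))), c(2L, 2L, 2L))
  expect_identical(f, make_folds(ids, n = 3, seed = 9))
  expect_false(identical(f$fold, make_folds(ids, n = 3, seed = 10)$fold) &&
                 identical(f$chain_id, make_folds(ids, n = 3, seed = 10)$chain_id))
  # 7 chains over 3 folds: sizes differ by at most one
  f7 <- make_folds(sprintf("c%02d", 1:7), n = 3, seed = 1)
  expect_lte(diff(range(as.integer(table(f7$fold)))), 1)
  expect_error(make_folds(ids[1:2], n = 3), class = "rsapred_config_error")
  expect_error(make_folds(ids, n = 1), class = "rsapred_config_error")
})

test_that("epsilon-SVR fits flat and near-linear toy data as expected", {
  x <- matrix(seq(0, 1, length.out = 12))
  # constant targets: prediction is the constant everywhere
  fit <- train_svr(x, rep(0.37, 12), svr_params(C = 1, epsilon = 0.05))
  expect_equal(unname(predict(fit, x)), rep(0.37, 12), tolerance = 1e-6)
  # noise-free linear data with a tight tube: training MAE below epsilon
  y <- 0.2 + 0.5 * x[, 1]
  fit <- train_svr(x, y, svr_params(C = 100, gamma = 2, epsilon = 0.02))
  expect_lt(mean(abs(predict(fit, x) - y)), 0.02 + 1e-6)
  expect_error(train_svr(x[0, , drop = FALSE], numeric(0)),
               class = "rsapred_config_error")
  expect_error(svr_params(C = -1), class = "rsapred_config_error")
  expect_error(svr_params(epsilon = -0.1), class = "rsapred_config_error")
})

test_that("PSO finds the sphere optimum and its trace never increases", {
  res <- pso_optimize(sphere, rep(-5, 3), rep(5, 3),
                      pso_config(swarm = 20, iterations = 100, seed = 4))
  expect_lt(res$value, 1e-3)
  expect_lt(max(abs(res$par)), 1e-2 * 5)
  expect_true(all(diff(res$trace) <= 0))
  # a single particle seeded at the optimum with zero velocity stays there
  res1 <- pso_optimize(sphere, rep(-5, 3), rep(5, 3),
                       pso_config(swarm = 1, iterations = 5, seed = 1,
                                  init = matrix(0, 1, 3)))
  expect_equal(res1$value, 0)
  expect_equal(res1$par, rep(0, 3))
})

test_that("immobile PSO equals pure random search over the initial swarm", {
  cfg <- pso_config(swarm = 15, iterations = 10, inertia = 0,
                    c1 = 0, c2 = 0, seed = 12)
  res <- pso_optimize(sphere, rep(-5, 2), rep(5, 2), cfg)
  expect_equal(res$value, min(res$initial_values))
  expect_equal(res$value, min(apply(res$initial, 1, sphere)))
  expect_true(all(res$trace == res$trace[1]))
})

test_that("non-finite fitness values are quarantined as +Inf", {
  holed <- function(x) if (x[1] > 0) NaN else sphere(x)
  warned <- 0L
  res <- withCallingHandlers(
    pso_optimize(holed, -5, 5, pso_config(swarm = 8, iterations = 5,
                                          seed = 3)),
    warning = function(w) {
      if (grepl("non-finite", conditionMessage(w))) warned <<- warned + 1L
      invokeRestart("muffleWarning")
    })
  expect_gt(warned, 0L)
  expect_true(is.finite(res$value))
  expect_lte(res$par, 0)
})

test_that("grid search equals independent exhaustive enumeration", {
  axes <- list(a = c(-2, -1, 0, 1), b = c(0.5, 1.5), c = c(-3, 3))
  res <- grid_search(sphere, axes)
  # independent oracle: enumerate the full product with nested loops
  best <- Inf; best_p <- NULL
  for (a in axes$a) for (b in axes$b) for (cc in axes$c) {
    v <- sphere(c(a, b, cc))
    if (v < best) { best <- v; best_p <- c(a, b, cc) }
  }
  expect_equal(res$value, best)
  expect_equal(unname(res$par), best_p)
  # grid containing the origin returns the origin
  res0 <- grid_search(sphere, list(x = -1:1, y = -1:1))
  expect_equal(unname(res0$par), c(0, 0))
  expect_equal(res0$value, 0)
  # single-point grid returns that point
  res1 <- grid_search(sphere, list(x = 2))
  expect_equal(unname(res1$par), 2)
  # constant fitness: tie broken by first visit in row-major order
  resc <- grid_search(function(p) 1, axes)
  expect_equal(unname(resc$par), c(-2, 0.5, -3))
})

test_that("cross-validated fitness is zero under an oracle regressor", {
  ch <- generate_chain_set(6, 25, 35, seed = 31)
  encoded <- encode_for_model(ch, window = 5, blocks = c("physchem", "seq_pos"))
  # graft the target onto the feature matrix so a lookup engine can read it
  encoded$x <- cbind(encoded$x, truth = encoded$y)
  folds <- make_folds(ch$chain_id, 3, seed = 1)
  fit <- cv_fitness(encoded, folds, svr_params(),
                    engine = truth_lookup_engine("truth"))
  expect_equal(fit, 0)
})

test_that("chain-level CV never leaks a test chain into its own training", {
  ch <- generate_chain_set(9, 25, 35, seed = 32)
  encoded <- encode_for_model(ch, window = 5,
                              blocks = c("physchem", "ss_local", "seq_pos"))
  folds <- make_folds(ch$chain_id, 3, seed = 2)
  base <- cv_predict(encoded, folds, svr_params(C = 5, epsilon = 0.05))
  target <- ch$chain_id[1]
  # corrupt the test chain's targets: its own predictions must not move
  enc2 <- encoded
  enc2$y[enc2$meta$chain_id == target] <- 0.99
  pert <- cv_predict(enc2, folds, svr_params(C = 5, epsilon = 0.05))
  expect_equal(pert$rsa_pred[pert$chain_id == target],
               base$rsa_pred[base$chain_id == target])
  # and every residue appears in exactly one test fold
  expect_equal(nrow(base), sum(ch$length))
  expect_false(any(duplicated(base[c("chain_id", "pos")])))
})

test_that("PSO tuning with a seeded incumbent never loses to the default", {
  ch <- generate_chain_set(12, 25, 40, seed = 33)
  encoded <- encode_for_model(ch, window = 5,
                              blocks = c("physchem", "ss_local", "ss_global",
                                         "seq_len", "seq_pos"))
  folds <- make_folds(ch$chain_id, 3, seed = 3)
  default_fit <- cv_fitness(encoded, folds, svr_params())
  tuned <- tune_svr_pso(encoded, folds,
                        pso = pso_config(swarm = 4, iterations = 3, seed = 5),
                        incumbent = svr_params())
  expect_lte(tuned$fitness, default_fit + 1e-9)
  expect_true(all(diff(tuned$trace) <= 0))
  expect_s3_class(tuned$params, "svr_params")
})

test_that("subset tuning is deterministic and honors fold structure", {
  ch <- generate_chain_set(9, 25, 35, seed = 34)
  res1 <- tune_on_subset(ch, n_folds = 3, subset_size = 2, seed = 7,
                         window = 5,
                         blocks = c("physchem", "seq_pos"),
                         pso = pso_config(swarm = 3, iterations = 2, seed = 8))
  res2 <- tune_on_subset(ch, n_folds = 3, subset_size = 2, seed = 7,
                         window = 5,
                         blocks = c("physchem", "seq_pos"),
                         pso = pso_config(swarm = 3, iterations = 2, seed = 8))
  expect_equal(res1$params, res2$params)
  expect_equal(res1$subset_ids, res2$subset_ids)
  expect_length(res1$subset_ids, 6L)
  expect_error(tune_on_subset(ch, n_folds = 3, subset_size = 10, seed = 1),
               class = "rsapred_config_error")
})

test_that("trained models carry their encoder and refuse mismatches", {
  ch <- generate_chain_set(6, 25, 35, seed = 35)
  model <- train_rsa_model(ch, svr_params(C = 2, epsilon = 0.05), window = 5,
                           blocks = c("physchem", "ss_local", "seq_pos"))
  pred <- predict(model, ch)
  expect_named(pred, c("chain_id", "pos", "residue", "rsa"))
  expect_equal(nrow(pred), sum(ch$length))
  expect_true(all(pred$rsa >= 0 & pred$rsa <= 1))
  expect_error(predict(model, ch, window = 9), class = "rsapred_config_error")
  gl <- glance(model)
  expect_equal(gl$window, 5L)
})
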