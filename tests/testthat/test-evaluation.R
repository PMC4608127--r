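test_that("absolute and relative MAE behave per contract", {
  expect_equal(mae(c(10, 20), c(12, 16), unit = "percent"), 3)
  x <- runif(30)
  expect_equal(mae(x, x), 0)
  expect_equal(mae(x, x, mode = "relative"), 0)
  # fraction inputs are reported on the percent scale
  expect_equal(mae(c(0.1, 0.2), c(0.12, 0.16)), 3)
  # translation invariance of the absolute mode
  y <- runif(30)
  expect_equal(mae(x, y, unit = "percent"), mae(x + 7, y + 7, unit = "percent"))
  # zero true values are skipped in relative mode, with a count
  expect_warning(r <- mae(c(0, 10, 20), c(5, 5, 25), mode = "relative",
                          unit = "percent"),
                 "1 position")
  expect_equal(r, mean(c(5 / 10, 5 / 20)))
  expect_error(mae(1:3, 1:2), class = "rsapred_config_error")
})

test_that("Pearson correlation matches the textbook formula and its limits", {
  x <- c(0.3, 0.1, 0.8, 0.5, 0.9)
  expect_equal(pcc(x, x), 1)
  expect_equal(pcc(x, -x + 0.4), -1)
  withr::with_seed(5, {
    for (i in 1:20) {
      a <- rnorm(50); b <- rnorm(50)
      num <- sum((a - mean(a)) * (b - mean(b)))
      den <- sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
      expect_equal(pcc(a, b), num / den, tolerance = 1e-12)
      expect_equal(pcc(a, b), stats::cor(a, b), tolerance = 1e-12)
    }
  })
  # invariance to positive affine transforms
  a <- runif(20); b <- runif(20)
  expect_equal(pcc(a, b), pcc(2 * a + 1, b), tolerance = 1e-12)
  expect_error(pcc(rep(0.5, 10), runif(10)),
               class = "rsapred_undefined_correlation_error")
})

test_that("two-state accuracy applies the >= exposure rule symmetrically", {
  x <- runif(40, 0, 100)
  expect_equal(two_state_accuracy(x, x, 25, unit = "percent"), 100)
  expect_equal(two_state_accuracy(c(4, 6), c(6, 4), 5, unit = "percent"), 0)
  # exhaustive-count oracle on random vectors
  withr::with_seed(6, {
    for (i in 1:10) {
      a <- runif(25, 0, 100); b <- runif(25, 0, 100); t <- runif(1, 1, 99)
      agree <- 0
      for (j in seq_along(a)) {
        sa <- if (a[j] >= t) "E" else "B"
        sb <- if (b[j] >= t) "E" else "B"
        if (sa == sb) agree <- agree + 1
      }
      expect_equal(two_state_accuracy(a, b, t, unit = "percent"),
                   100 * agree / 25)
    }
  })
  # equivalent to 100 * (1 - hamming/N) on the binarized vectors
  a <- runif(30, 0, 100); b <- runif(30, 0, 100)
  ham <- sum((a >= 25) != (b >= 25))
  expect_equal(two_state_accuracy(a, b, 25, unit = "percent"),
               100 * (1 - ham / 30))
  expect_error(two_state_accuracy(a, b, 0, unit = "percent"),
               class = "rsapred_config_error")
})

test_that("per-type summary aggregates by true residue identity", {
  d <- tibble::tibble(
    chain_id = "c1",
    residue = c("A", "A", "K", "K", "V"),
    rsa_true = c(0.2, 0.4, 0.6, 0.8, 0.1),
    rsa_pred = c(0.2, 0.4, 0.6, 0.8, 0.1))
  suppressWarnings(s <- per_type_summary(d))
  expect_equal(s$mean_abs_error, rep(0, 3))
  expect_equal(s$residue, c("A", "K", "V"))
  expect_equal(s$mean_true[s$residue == "A"], 30)  # percent scale
  # single-letter input yields a single row
  suppressWarnings(s1 <- per_type_summary(d[d$residue == "A", ]))
  expect_equal(nrow(s1), 1L)
  # error/variability correlation is the pcc of the two summary columns
  d2 <- tibble::tibble(chain_id = "c1",
                       residue = rep(c("A", "K", "V", "L"), each = 10),
                       rsa_true = runif(40), rsa_pred = runif(40))
  suppressWarnings(s2 <- per_type_summary(d2))
  expect_equal(attr(s2, "error_sd_pcc"), pcc(s2$mean_abs_error, s2$sd_true))
})

test_that("error-band histogram conserves residues and bins by hand", {
  h <- error_band_histogram(c(0, 0, 0), c(5, 15, 35), unit = "percent")
  expect_equal(h$count, c(1, 1, 0, 1, rep(0, 6)))
  expect_equal(sum(h$count), 3)
  x <- runif(200, 0, 100); y <- runif(200, 0, 100)
  h2 <- error_band_histogram(x, y, unit = "percent")
  expect_equal(sum(h2$count), 200)
  # perfect predictions all fall in the first band
  h3 <- error_band_histogram(x, x, unit = "percent")
  expect_equal(h3$count[1], 200)
  expect_error(error_band_histogram(x, y, band_edges = c(0, 50),
                                    unit = "percent"),
               class = "rsapred_config_error")
})

test_that("evaluation reports bundle every summary coherently", {
  ch <- generate_chain_set(4, 40, 60, seed = 44)
  truth <- unlist(ch$rsa)
  d <- tibble::tibble(
    chain_id = rep(ch$chain_id, ch$length),
    residue = unlist(strsplit(ch$sequence, "")),
    rsa_true = truth,
    rsa_pred = pmin(pmax(truth + rnorm(length(truth), 0, 0.05), 0), 1))
  suppressWarnings(ev <- evaluate_predictions(d))
  expect_s3_class(ev, "rsa_eval")
  expect_equal(ev$n, nrow(d))
  expect_equal(ev$mae, mae(d$rsa_true, d$rsa_pred))
  expect_equal(sum(ev$error_bands$count), nrow(d))
  expect_equal(ev$two_state$threshold[1], 5)
  expect_true(all(ev$two_state$accuracy >= 0 & ev$two_state$accuracy <= 100))
  gl <- glance(ev)
  expect_named(gl, c("n", "mae", "pcc", "error_sd_pcc"))
  td <- tidy(ev)
  expect_true(all(td$n > 0))
  p <- autoplot(ev)
  expect_s3_class(p, "ggplot")
  expect_s3_class(autoplot(ev, "two_state"), "ggplot")
})
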