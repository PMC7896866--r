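test_that("the seeded split assigns 8/2 scans per mixture reproducibly", {
  sp <- split_calibration_validation(fx_campaign$scansets,
                                     fx_campaign$records, split_plan(1))
  expect_length(sp$calibration$spectra, 80L)
  expect_length(sp$validation$spectra, 20L)
  expect_equal(as.vector(table(sp$calibration$mixture_id)), rep(8L, 10L))
  expect_equal(as.vector(table(sp$validation$mixture_id)), rep(2L, 10L))

  sp2 <- split_calibration_validation(fx_campaign$scansets,
                                      fx_campaign$records, split_plan(1))
  expect_identical(lapply(sp$validation$spectra, `[[`, "label"),
                   lapply(sp2$validation$spectra, `[[`, "label"))

  sp3 <- split_calibration_validation(fx_campaign$scansets,
                                      fx_campaign$records, split_plan(2))
  expect_false(identical(lapply(sp$validation$spectra, `[[`, "label"),
                         lapply(sp3$validation$spectra, `[[`, "label")))

  short <- list(scanset(fx_campaign$scansets[[1L]]$spectra[1:5], "std-01"))
  expect_error(split_calibration_validation(short, fx_campaign$records,
                                            split_plan(1)),
               "has 5 scans")
})

test_that("NIPALS recovers a single informative channel with one factor", {
  set.seed(3)
  X <- matrix(0, 8, 5)
  X[, 3] <- rnorm(8)
  y <- 2 * X[, 3] + 7
  fit <- nipals_pls1(X, y, 1L)
  expect_equal(rmse(predict_pls1_for_test(fit, X), y), 0, tolerance = 1e-10)
})

test_that("full-rank PLS-1 equals ordinary least squares", {
  set.seed(9)
  for (i in 1:5) {
    X <- matrix(rnorm(8 * 6), 8, 6)
    y <- rnorm(8)
    fit <- nipals_pls1(X, y, 6L)
    Xc <- cbind(1, X)
    beta <- qr.solve(Xc, y)
    expect_equal(predict_pls1_for_test(fit, X), as.numeric(Xc %*% beta),
                 tolerance = 1e-8)
  }
})

test_that("NIPALS predictions match the independent Krylov-subspace PLS oracle", {
  set.seed(21)
  for (i in 1:8) {
    X <- matrix(rnorm(8 * 6), 8, 6)
    y <- rnorm(8)
    Xnew <- matrix(rnorm(4 * 6), 4, 6)
    for (k in 1:4) {
      fit <- nipals_pls1(X, y, k)
      expect_equal(predict_pls1_for_test(fit, Xnew),
                   krylov_pls1_predict(X, y, k, Xnew), tolerance = 1e-8)
    }
  }
})

test_that("nipals_pls1 guards degenerate input and caps factor counts", {
  X <- matrix(rnorm(12), 4, 3)
  expect_error(nipals_pls1(X, rep(5, 4), 1L), "zero-variance")
  expect_error(nipals_pls1(X, rnorm(4), 4L), "k must be in")
  # rank collapse: duplicated rows support fewer factors than requested
  X2 <- matrix(rnorm(10), 2, 5)[c(1, 1, 2, 2, 2), ]
  expect_warning(fit <- nipals_pls1(X2, c(1, 1, 2, 2, 2) + 0.0, 4L),
                 "collapsed")
  expect_lt(fit$n_factors, 4L)
})

test_that("rmse and pearson_r agree with hand arithmetic", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(2, 4), c(1, 2)), sqrt(2.5))
  expect_equal(rmse(5, 2), 3)
  expect_error(rmse(1:3, 1:2), "equal")

  expect_equal(pearson_r(1:5, 1:5), 1)
  expect_equal(pearson_r(1:5, 7 - (1:5)), -1)
  p <- c(1.2, 3.4, 2.2, 5.0, 4.1)
  t <- c(1.0, 3.0, 2.5, 4.8, 4.4)
  manual <- sum((p - mean(p)) * (t - mean(t))) /
    sqrt(sum((p - mean(p))^2) * sum((t - mean(t))^2))
  expect_equal(pearson_r(p, t), manual, tolerance = 1e-14)
  expect_error(pearson_r(rep(1, 5), 1:5), "constant")
})

test_that("factor scan shows monotone RMSEC and a widening gap past the optimum", {
  scan <- fx_model$scan
  expect_true(all(diff(scan$rmsec) <= 1e-10))
  expect_true(all(is.finite(unlist(scan[c("rmsec", "rmsev", "r_c", "r_v")]))))
  expect_true(all(scan$r_c >= -1 & scan$r_c <= 1))

  k <- select_factors(scan)
  expect_lte(k, 6L)
  gap <- scan$rmsev - scan$rmsec
  expect_true(all(gap[scan$k > k + 1] > gap[scan$k == k]))
})

test_that("select_factors picks the first qualifying factor count", {
  rows <- data.frame(k = 1:4, r_c = c(0.99, 0.997, 0.9985, 0.999),
                     r_v = c(0.99, 0.997, 0.9985, 0.999),
                     rmsec = c(4, 3, 2, 1), rmsev = c(4, 3, 2.5, 2))
  expect_equal(select_factors(rows), 3L)
  low <- rows
  low$r_v <- low$r_v - 0.01
  expect_error(select_factors(low), "best r_v")
  expect_error(select_factors(rows[0, ]), "empty")
})

test_that("factor selection is stable across 20 simulation seeds", {
  ks <- vapply(1:20, function(s) {
    camp <- simulate_calibration_campaign(seed = s)
    scan <- factor_scan(camp$scansets, camp$records, split_plan(s), k_max = 8L)
    select_factors(scan)
  }, numeric(1L))
  expect_lte(diff(range(ks)), 2L)
})

test_that("predict_r honors centering and stays within the error budget", {
  # a preprocessed vector equal to the stored x_mean predicts exactly y_mean
  expect_equal(predict_pls1_for_test(fx_model$fit, fx_model$fit$x_mean),
               fx_model$fit$y_mean)

  # a default-noise scan of a true R = 50 mixture predicts within 50 +/- 1.5
  tm <- simulate_test_mixture(seed = 77)
  for (sp in tm$scans$spectra) {
    expect_lt(abs(predict_r(fx_model, sp) - 50), 1.5)
  }

  # in-sample predictions reproduce the stored RMSEC
  d <- split_calibration_validation(fx_campaign$scansets, fx_campaign$records,
                                    split_plan(1))
  pred <- vapply(d$calibration$spectra, function(s) predict_r(fx_model, s),
                 numeric(1L))
  expect_equal(rmse(pred, d$calibration$r), fx_model$diagnostics$rmsec,
               tolerance = 1e-8)

  # wrong-window spectrum is rejected at predict time
  narrow <- spectrum(seq(1500, 1400, by = -4), rep(1, 26))
  expect_error(predict_r(fx_model, narrow), "window mismatch")
})

test_that("noiseless synthetic mixtures are recovered exactly at high factor count", {
  camp <- simulate_calibration_campaign(noise = noise_free(), seed = 3)
  model <- fit_calibration(camp$scansets, camp$records, split_plan(3),
                           n_factors = 6L)
  truth <- design_r(camp$records)
  for (i in seq_along(camp$scansets)) {
    expect_equal(predict_r(model, camp$scansets[[i]]$spectra[[1L]]), truth[i],
                 tolerance = 1e-6)
  }
})

test_that("model save/load round-trips to bit-identical predictions", {
  path <- withr::local_tempfile(fileext = ".json")
  save_model(fx_model, path)
  back <- load_model(path)
  s <- fx_campaign$scansets[[1L]]$spectra[[1L]]
  expect_identical(predict_r(back, s), predict_r(fx_model, s))
  expect_equal(back$n_factors, fx_model$n_factors)
  expect_equal(back$preprocess$msc_reference$absorbance,
               fx_model$preprocess$msc_reference$absorbance)

  # truncated file
  bad <- withr::local_tempfile(fileext = ".json")
  writeLines(substr(paste(readLines(path), collapse = "\n"), 1, 200), bad)
  expect_error(load_model(bad), "cannot parse")

  # schema guard
  other <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(schema = "something/else"), other,
                       auto_unbox = TRUE)
  expect_error(load_model(other), "schema")
})
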