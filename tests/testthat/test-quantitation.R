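test_that("design_r covers its boundary, symmetry and worked cases", {
  m <- mixture_record("a", 260.25, 101.43, p_par = 0.997, c_s = 0.3794)
  expect_equal(round(design_r(m), 2), 49.40)

  sym <- mixture_record("b", 100, 100 * 0.3794 / 0.997, p_par = 0.997,
                        c_s = 0.3794)
  expect_equal(design_r(sym), 50, tolerance = 1e-12)

  unknown <- mixture_record("c", 100, 100, role = "test")
  expect_error(design_r(unknown), "c_s")
})

test_that("content_from_r reproduces the worked assay values and inverts design_r", {
  expect_equal(round_half_up(content_from_r(
    49.72, data.frame(m_p_mg = 263.55, m_par_mg = 100.29, p_par = 0.997)), 1),
    37.5)
  expect_equal(round_half_up(content_from_r(
    49.95, data.frame(m_p_mg = 267.28, m_par_mg = 100.08, p_par = 0.997)), 1),
    37.3)
  expect_error(content_from_r(100, data.frame(m_p_mg = 1, m_par_mg = 1,
                                              p_par = 1)), "inside")
  expect_error(content_from_r(0, data.frame(m_p_mg = 1, m_par_mg = 1,
                                            p_par = 1)), "inside")

  # exact algebraic inverse over random valid mixtures
  set.seed(17)
  for (i in 1:1000) {
    m <- data.frame(m_p_mg = runif(1, 50, 500), m_par_mg = runif(1, 20, 300),
                    p_par = runif(1, 0.9, 1), c_s = runif(1, 0.05, 0.95))
    expect_equal(content_from_r(design_r(m), m), 100 * m$c_s,
                 tolerance = 1e-12)
  }
})

test_that("recovered_mass and recovery_rate match the recovery-study arithmetic", {
  expect_equal(round_half_up(recovered_mass(51.02, 99.28, 0.997), 2), 103.10)
  expect_equal(round_half_up(recovered_mass(64.15, 71.68, 0.997), 2), 127.88)
  expect_equal(recovered_mass(50, 100, 1), 100)

  rec <- recovered_mass(51.02, 99.28, 0.997)
  expect_equal(round_half_up(recovery_rate(rec, 268.15, 0.3794), 1), 101.3)
  expect_equal(recovery_rate(90, 90 / 0.3794, 0.3794), 100)

  # two routes to recovery agree: via recovered mass and via content
  m <- data.frame(m_p_mg = 268.15, m_par_mg = 99.28, p_par = 0.997,
                  c_s = 0.3794)
  via_content <- 100 * content_from_r(51.02, m) / (100 * m$c_s)
  via_mass <- recovery_rate(recovered_mass(51.02, m$m_par_mg, m$p_par),
                            m$m_p_mg, m$c_s)
  expect_equal(via_content, via_mass, tolerance = 1e-12)
})

test_that("rsd matches hand arithmetic and guards degenerate input", {
  expect_equal(rsd(c(4, 4, 4)), 0)
  expect_equal(rsd(c(1, 2, 3)), 50)
  expect_error(rsd(5), "two values")
  expect_error(rsd(c(-1, 1)), "zero mean")
})

test_that("the recovery study table reproduces its published summaries", {
  acc <- assay_validation_data("accuracy")
  rs <- recovery_summary(acc)
  expect_equal(rs$levels$mean_recovery_1dp, c(100.1, 100.6, 99.8))
  expect_equal(rs$levels$rsd_1dp[c(1, 3)], c(1.3, 1.2))
  expect_equal(rs$replicates$recovered_mg_2dp[7], 103.10)
})

test_that("precision and application tables reproduce their published statistics", {
  prec <- assay_validation_data("precision")
  day1 <- content_summary(prec[prec$day == 1, ])
  expect_equal(day1$mean_content_1dp, 38.2)
  expect_equal(day1$rsd_1dp, 1.1)

  app <- content_summary(assay_validation_data("application"))
  expect_equal(app$mean_content_1dp, 38.1)
  expect_equal(app$replicates$content_1dp[1], 37.3)
})

test_that("round_half_up rounds exact halves away from zero", {
  expect_equal(round_half_up(0.25, 1), 0.3)
  expect_equal(round_half_up(-0.25, 1), -0.3)
  expect_equal(round_half_up(103.095, 2), 103.10)
  expect_equal(round_half_up(2.5, 0), 3)
})

test_that("quantify predicts content within the assay tolerance end to end", {
  tm <- simulate_test_mixture(seed = 42)
  q <- quantify(fx_model, tm$scans, tm$record)
  expect_length(q$r_per_scan, 5L)
  expect_lt(abs(q$content - 37.94), 1.0)

  # noiseless limit with a high-factor model is essentially exact
  campn <- simulate_calibration_campaign(noise = noise_free(), seed = 3)
  modn <- fit_calibration(campn$scansets, campn$records, split_plan(3),
                          n_factors = 6L)
  tmn <- simulate_test_mixture(noise = noise_free(), seed = 5)
  qn <- quantify(modn, tmn$scans, tmn$record)
  expect_lt(abs(qn$content - 37.94), 0.01)

  expect_error(quantify(fx_model, tm$scans, tm$record[0, ]), "single")
  expect_error(quantify(fx_model,
                        structure(list(spectra = list(), mixture_id = "x"),
                                  class = "scanset"),
                        tm$record), "no scans")
  std <- mixture_record("s", 100, 100, c_s = 0.3794, role = "standard")
  expect_error(quantify(fx_model, tm$scans, std), "test-role")
})

test_that("the validation battery passes at default noise and flags inflated noise", {
  vc <- simulate_validation_campaign(seed = 11)
  rep <- validate_method(fx_model, vc$scansets, vc$records)
  expect_s3_class(rep, "validation_report")
  expect_equal(nrow(rep$recovery), 3L)
  expect_true(all(rep$recovery$pass_recovery))
  expect_true(all(rep$recovery$pass_rsd))
  expect_true(rep$repeatability$pass)
  expect_false(is.null(rep$intermediate))
  expect_true(rep$intermediate$pass)
  expect_true(rep$pass)

  # ten-fold noise must blow at least one RSD flag
  noisy <- simulate_validation_campaign(
    noise = noise_model(0.5, 1e-4, 5e-2, 2e-2, 0.1), seed = 11)
  rep10 <- validate_method(fx_model, noisy$scansets, noisy$records)
  expect_false(all(rep10$recovery$pass_rsd) && rep10$repeatability$pass)

  # five replicates per level is insufficient
  vshort <- simulate_validation_campaign(replicates = 5L, seed = 11)
  expect_error(validate_method(fx_model, vshort$scansets, vshort$records),
               "fewer than 6")
})
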