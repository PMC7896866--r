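test_that("component_spectrum places peaks and is additive", {
  g <- default_grid()
  one <- component_spectrum(data.frame(center = 1697.6, height = 1, sigma = 10), g)
  expect_equal(g[which.max(one$absorbance)], 1696)  # nearest grid point
  expect_lte(max(one$absorbance), 1)

  none <- component_spectrum(data.frame(center = numeric(0),
                                        height = numeric(0),
                                        sigma = numeric(0)), g)
  expect_equal(none$absorbance, numeric(length(g)))

  b1 <- data.frame(center = 1700, height = 0.5, sigma = 5)
  b2 <- data.frame(center = 1400, height = 0.8, sigma = 5)
  expect_equal(component_spectrum(rbind(b1, b2), g)$absorbance,
               component_spectrum(b1, g)$absorbance +
                 component_spectrum(b2, g)$absorbance,
               tolerance = 1e-14)
})

test_that("mixture_spectrum is seeded, deterministic when noise-free, and respects limits", {
  rec <- mixture_record("m", 260, 100, c_s = STOCK_CONTENT)

  a <- mixture_spectrum(rec, seed = 7L)
  b <- mixture_spectrum(rec, seed = 7L)
  expect_identical(a$absorbance, b$absorbance)
  c <- mixture_spectrum(rec, seed = 8L)
  expect_false(identical(a$absorbance, c$absorbance))

  # noise off: scans coincide regardless of seed
  n1 <- mixture_spectrum(rec, noise = noise_free(), seed = 1L)
  n2 <- mixture_spectrum(rec, noise = noise_free(), seed = 99L)
  expect_equal(n1$absorbance, n2$absorbance, tolerance = 1e-15)

  # pure-component limit: almost pure analyte powder, linear instrument
  pure <- mixture_record("p", 100, 1e-9 * 100, c_s = 0.999999,
                         p_par = 1e-6)
  ps <- mixture_spectrum(pure, noise = noise_free(), saturation = 0, seed = 1L)
  analyte <- component_spectrum(default_band_table()$analyte)
  expect_equal(ps$absorbance, analyte$absorbance, tolerance = 1e-4)
})

test_that("window spectra are linear in mass fractions for the ideal instrument", {
  # superposition: spectrum(mix) = sum of fraction-weighted pure spectra
  rec <- mixture_record("m", 260, 100, c_s = STOCK_CONTENT)
  mixed <- extract_window(mixture_spectrum(rec, noise = noise_free(),
                                           saturation = 0, seed = 1L),
                          1300, 1800)
  comp <- lapply(default_band_table(), function(b) {
    extract_window(component_spectrum(b), 1300, 1800)$absorbance
  })
  f <- c(260 * 0.3794, 100 * 0.997,
         260 * (1 - 0.3794) + 100 * (1 - 0.997))
  f <- f / sum(f)
  manual <- f[1] * comp$analyte + f[2] * comp$standard + f[3] * comp$matrix
  expect_equal(mixed$absorbance, manual, tolerance = 1e-12)
})

test_that("increasing R raises the analyte-to-standard band ratio monotonically", {
  ratios <- vapply(seq(30, 70, by = 10), function(target) {
    m_p <- 360 * (target / 100) * 0.997 /
      (0.3794 * (1 - target / 100) + (target / 100) * 0.997)
    rec <- mixture_record(sprintf("r%d", target), m_p, 360 - m_p,
                          c_s = STOCK_CONTENT)
    s <- mixture_spectrum(rec, noise = noise_free(), seed = 1L)
    s$absorbance[nearest_index(s, 1697.6)] / s$absorbance[nearest_index(s, 1651.4)]
  }, numeric(1L))
  expect_true(all(diff(ratios) > 0))
})

test_that("the calibration campaign matches its stated design", {
  expect_length(fx_campaign$scansets, 10L)
  expect_equal(sum(vapply(fx_campaign$scansets,
                          function(s) length(s$spectra), integer(1L))), 100L)
  r <- design_r(fx_campaign$records)
  expect_true(all(abs(r - rep(c(30, 40, 50, 60, 70), each = 2)) < 1.5))

  # zero preparation error lands exactly on the targets
  exact <- simulate_calibration_campaign(prep_sd = 0, seed = 4)
  expect_equal(design_r(exact$records), rep(c(30, 40, 50, 60, 70), each = 2),
               tolerance = 1e-9)

  # seeding contract: identical mass tables on re-run
  again <- simulate_calibration_campaign(seed = 1)
  expect_identical(again$records, fx_campaign$records)

  expect_error(simulate_calibration_campaign(targets = c(50, 120)), "inside")
})

test_that("test mixtures are designed at R ~ 50 under the nominal content", {
  tm <- simulate_test_mixture(seed = 2)
  expect_length(tm$scans$spectra, 5L)
  expect_true(is.na(tm$record$c_s))

  known <- tm$record
  known$c_s <- tm$true_content
  expect_equal(design_r(known), 50, tolerance = 1e-9)

  # a powder at 90% of the nominal content realizes a predictably lower R
  off <- simulate_test_mixture(true_content = 0.9 * STOCK_CONTENT, seed = 2)
  known$c_s <- 0.9 * STOCK_CONTENT
  expected <- design_r(known)
  expect_lt(expected, 48)
  real <- off$record
  real$c_s <- off$true_content
  expect_equal(design_r(real), expected, tolerance = 1e-9)
})

test_that("campaign export/read round-trips scansets, records and truth", {
  dir <- withr::local_tempdir()
  small <- simulate_calibration_campaign(targets = c(40, 60), duplicates = 1L,
                                         scans_per_mixture = 3L, seed = 5)
  export_campaign(dir, small$scansets, small$records,
                  truth = list(`std-01` = 0.3794))
  back <- read_campaign(dir)
  expect_equal(back$records$mixture_id, small$records$mixture_id)
  expect_equal(back$records$m_p_mg, small$records$m_p_mg, tolerance = 1e-12)
  expect_equal(back$scansets[[1L]]$spectra[[2L]]$absorbance,
               small$scansets[[1L]]$spectra[[2L]]$absorbance,
               tolerance = 1e-10)
  expect_equal(back$truth$`std-01`, 0.3794)
})
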