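#' Default instrument grid
#'
#' The measurement grid: 2000 down to 400 cm-1 at 4 cm-1 resolution,
#' descending (401 points).
#'
#' @return Numeric vector of wavenumbers.
#' @export
default_grid <- function() seq(2000, 400, by = -4)

#' Band tables for the synthetic mixture components
#'
#' Gaussian band parameters (center cm-1, height, sigma cm-1) for the three
#' spectroscopic components of a tablet/internal-standard mixture:
#'
#' * `analyte` — sildenafil citrate surrogate, dominated by its strongest
#'   band at 1697.6 cm-1 plus four further bands inside 1800-1300 cm-1 (the
#'   real molecule is rich in this zone, which is what makes several PLS
#'   factors necessary) and two outside the window;
#' * `standard` — paracetamol surrogate with its characteristic maxima at
#'   1651.4, 1609.2, 1562.2, 1505.2 and 1434.9 cm-1;
#' * `matrix` — the unknown excipient matrix, modeled as broad
#'   (sigma >= 30 cm-1) weak bands inside the analysis window plus a strong
#'   carbohydrate-like C-O band near 1050 cm-1 outside it.
#'
#' Heights and widths are fixture constants of the simulator, not fits to
#' any measured spectrum.
#'
#' @return Named list of data frames with columns `center`, `height`,
#'   `sigma`.
#' @export
default_band_table <- function() {
  list(
    analyte = data.frame(
      center = c(1697.6, 1733, 1588, 1528, 1358, 1240, 940),
      height = c(3.00, 0.90, 1.05, 0.84, 1.20, 1.50, 1.05),
      sigma  = c(9, 10, 13, 11, 14, 15, 18)),
    standard = data.frame(
      center = c(1651.4, 1609.2, 1562.2, 1505.2, 1434.9, 1227, 836),
      height = c(2.85, 2.10, 1.95, 2.40, 1.35, 1.80, 1.20),
      sigma  = c(10, 9, 10, 9, 10, 14, 12)),
    matrix = data.frame(
      center = c(1640, 1420, 1050),
      height = c(0.21, 0.18, 1.50),
      sigma  = c(45, 60, 40))
  )
}

#' Per-scan noise model for synthetic spectra
#'
#' Describes the stochastic structure of repeated ATR scans of one powder
#' mixture:
#'
#' * `scatter_sigma` — sd of the log-normal multiplicative gain per scan
#'   (unstable crystal/powder contact in ATR mode);
#' * `baseline_offset_sigma`, `baseline_slope_sigma` — a linear baseline
#'   drawn per scan (offset, and slope per cm-1 about the window center);
#' * `noise_sigma` — additive white noise per grid point;
#' * `heterogeneity_sigma` — sd of per-scan log-normal jitter on the
#'   effective local mass fractions, emulating scanning a heterogeneous
#'   powder at different positions.
#'
#' @param scatter_sigma,baseline_slope_sigma,baseline_offset_sigma,noise_sigma,heterogeneity_sigma
#'   Non-negative standard deviations; defaults 0.05, 1e-5, 5e-3, 2e-3, 0.01.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(scatter_sigma = 0.05,
                        baseline_slope_sigma = 1e-5,
                        baseline_offset_sigma = 5e-3,
                        noise_sigma = 2e-3,
                        heterogeneity_sigma = 0.01) {
  v <- c(scatter_sigma, baseline_slope_sigma, baseline_offset_sigma,
         noise_sigma, heterogeneity_sigma)
  if (any(v < 0)) stop("all noise sigmas must be >= 0", call. = FALSE)
  structure(list(scatter_sigma = scatter_sigma,
                 baseline_slope_sigma = baseline_slope_sigma,
                 baseline_offset_sigma = baseline_offset_sigma,
                 noise_sigma = noise_sigma,
                 heterogeneity_sigma = heterogeneity_sigma),
            class = "noise_model")
}

#' Noise-free noise model
#'
#' Convenience constructor with every sigma zero, for linearity and
#' determinism checks. Note this only silences the stochastic terms; the
#' deterministic instrument response (`saturation` in [mixture_spectrum])
#' is a separate setting.
#' @return A [noise_model] with all sigmas 0.
#' @export
noise_free <- function() {
  noise_model(0, 0, 0, 0, 0)
}

#' Default absorbance saturation of the simulated instrument
#'
#' Strength `gamma` of the point-wise compressive response
#' `A_measured = A / (1 + gamma * A)` applied to the ideal mixture spectrum.
#' ATR measurement and detector response compress strong bands relative to
#' weak ones, so measured spectra deviate smoothly from exact
#' Beer-Lambert additivity; this is what makes several PLS factors both
#' necessary and useful on real spectra, and the simulator reproduces it.
#' Set `saturation = 0` in the generator calls for an ideal linear
#' instrument.
#'
#' @return The default gamma (unitless, per absorbance unit).
#' @export
default_saturation <- function() 1.0

#' Pure-component spectrum from a band table
#'
#' Evaluates the sum of Gaussian bands on a grid. Deterministic.
#'
#' @param bands Data frame with columns `center`, `height`, `sigma`.
#' @param grid Wavenumber grid (cm-1); default [default_grid()].
#' @param label Spectrum label.
#' @return A [spectrum].
#' @export
component_spectrum <- function(bands, grid = default_grid(), label = "") {
  a <- numeric(length(grid))
  if (nrow(bands) > 0L) {
    for (i in seq_len(nrow(bands))) {
      a <- a + bands$height[i] *
        exp(-(grid - bands$center[i])^2 / (2 * bands$sigma[i]^2))
    }
  }
  spectrum(grid, a, label = label)
}

# Mass fractions of (analyte, internal standard, matrix) implied by a
# mixture record; the matrix collects the non-analyte powder mass plus the
# internal standard's impurity.
mass_fractions <- function(m, c_s = NULL) {
  cs <- if (is.null(c_s)) m$c_s else c_s
  f <- c(analyte = m$m_p_mg * cs,
         standard = m$m_par_mg * m$p_par,
         matrix = m$m_p_mg * (1 - cs) + m$m_par_mg * (1 - m$p_par))
  f / sum(f)
}

#' Simulate one ATR scan of a powder mixture
#'
#' The ideal spectrum is the mass-fraction-weighted linear combination of
#' the pure-component spectra (Beer-Lambert mixing). Each scan is then
#' corrupted by per-scan heterogeneity jitter on the effective fractions,
#' a log-normal multiplicative gain, a linear baseline, and additive white
#' noise, per the [noise_model]. Seeded and reproducible.
#'
#' @param m One-row mixture record (see [mixture_record]).
#' @param bands Band tables from [default_band_table()].
#' @param noise A [noise_model].
#' @param seed Integer seed for this scan; `NULL` draws from the current
#'   RNG stream.
#' @param grid Wavenumber grid.
#' @param true_content Optional true analyte content overriding `m$c_s`
#'   (used for test mixtures whose record carries only a nominal content).
#' @param saturation Instrument-response compression strength gamma (see
#'   [default_saturation]); 0 gives an ideal linear instrument.
#' @param label Spectrum label.
#' @return A [spectrum].
#' @export
mixture_spectrum <- function(m, bands = default_band_table(),
                             noise = noise_model(), seed = NULL,
                             grid = default_grid(), true_content = NULL,
                             saturation = default_saturation(),
                             label = m$mixture_id) {
  gen <- function() {
    f <- mass_fractions(m, c_s = true_content)
    comp <- vapply(bands, function(b) component_spectrum(b, grid)$absorbance,
                   numeric(length(grid)))
    if (noise$heterogeneity_sigma > 0) {
      f <- f * exp(stats::rnorm(3L, 0, noise$heterogeneity_sigma))
      f <- f / sum(f)
    }
    ideal <- comp %*% f
    if (saturation > 0) ideal <- ideal / (1 + saturation * ideal)
    gain <- exp(stats::rnorm(1L, 0, noise$scatter_sigma))
    offset <- stats::rnorm(1L, 0, noise$baseline_offset_sigma)
    slope <- stats::rnorm(1L, 0, noise$baseline_slope_sigma)
    a <- gain * ideal[, 1L] + offset + slope * (grid - 1550) +
      stats::rnorm(length(grid), 0, noise$noise_sigma)
    spectrum(grid, a, label = label)
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

# Solve the powder mass (mg) giving design ratio r_pct at fixed total mass.
solve_powder_mass <- function(r_pct, total_mg, c_s, p_par) {
  r <- r_pct / 100
  if (r <= 0 || r >= 1) stop("target R must be inside (0, 100)", call. = FALSE)
  m_p <- total_mg * r * p_par / (c_s * (1 - r) + r * p_par)
  if (m_p <= 0 || m_p >= total_mg) {
    stop(sprintf("target R = %g unsatisfiable at total mass %g", r_pct,
                 total_mg), call. = FALSE)
  }
  m_p
}

#' Simulate a calibration campaign of working standard mixtures
#'
#' Emulates the calibration design: working standard mixtures prepared in
#' duplicate at five target R levels (about 30, 40, 50, 60, 70%), each
#' scanned `scans_per_mixture` times. Masses are solved at a fixed total
#' mixture mass so the designed R hits each target up to a small random
#' preparation error, and every scan is generated with [mixture_spectrum].
#' A single integer seed drives all draws via derived sub-seeds.
#'
#' @param targets Target R levels in percent.
#' @param duplicates Mixtures prepared per level.
#' @param scans_per_mixture Scans recorded per mixture (default 10).
#' @param total_mg Total mixture mass in mg (default 360, the scale of a
#'   one-tablet preparation).
#' @param prep_sd Sd of the preparation error on realized R, in percentage
#'   points (default 0.3).
#' @param c_s Analyte content of the stock powder (fraction).
#' @param p_par Internal-standard purity (fraction).
#' @param bands,noise Generator settings.
#' @param saturation Instrument-response strength (see [default_saturation]).
#' @param seed Integer master seed.
#' @return A list with `scansets` (list of [scanset]) and `records`
#'   (manifest data frame with the realized masses; `design_r` of each row
#'   is the true R of that mixture).
#' @export
simulate_calibration_campaign <- function(targets = c(30, 40, 50, 60, 70),
                                          duplicates = 2L,
                                          scans_per_mixture = 10L,
                                          total_mg = 360, prep_sd = 0.3,
                                          c_s = STOCK_CONTENT,
                                          p_par = PARACETAMOL_PURITY,
                                          bands = default_band_table(),
                                          noise = noise_model(),
                                          saturation = default_saturation(),
                                          seed = 1L) {
  if (any(targets <= 0 | targets >= 100)) {
    stop("targets must lie inside (0, 100)", call. = FALSE)
  }
  records <- NULL
  scansets <- list()
  idx <- 0L
  for (li in seq_along(targets)) {
    for (dup in seq_len(duplicates)) {
      idx <- idx + 1L
      sub <- (as.numeric(seed) * 1000 + idx * 7) %% 2147483647
      realized <- with_seed(sub, targets[li] + stats::rnorm(1L, 0, prep_sd))
      m_p <- solve_powder_mass(realized, total_mg, c_s, p_par)
      rec <- mixture_record(sprintf("std-%02d", idx), m_p, total_mg - m_p,
                            p_par = p_par, c_s = c_s, role = "standard",
                            level_label = as.character(targets[li]))
      records <- rbind(records, rec)
      scans <- lapply(seq_len(scans_per_mixture), function(sc) {
        mixture_spectrum(rec, bands, noise,
                         seed = (sub + sc * 101) %% 2147483647,
                         saturation = saturation,
                         label = sprintf("%s/scan-%02d", rec$mixture_id, sc))
      })
      scansets[[idx]] <- scanset(scans, rec$mixture_id)
    }
  }
  list(scansets = scansets, records = records)
}

#' Simulate a test mixture of unknown powder
#'
#' Emulates the preparation of a test mixture: the powder mass is chosen so
#' that the estimated R is about `target_r` under the *nominal* content
#' (label claim), while the spectra are generated from the *true* content.
#' The true content is returned separately for scoring; the returned record
#' carries `c_s = NA` as for a real unknown.
#'
#' @param true_content True analyte content fraction of the powder.
#' @param nominal_content Nominal content used to design the mixture.
#' @param target_r Designed R under the nominal content (default 50%).
#' @param scans Number of scans (default 5).
#' @param total_mg Total mixture mass in mg.
#' @param p_par Internal-standard purity.
#' @param bands,noise Generator settings.
#' @param saturation Instrument-response strength (see [default_saturation]).
#' @param seed Integer seed.
#' @param mixture_id Identifier for the record.
#' @return A list with `scans` (a [scanset]), `record` (c_s hidden), and
#'   `true_content`.
#' @export
simulate_test_mixture <- function(true_content = STOCK_CONTENT,
                                  nominal_content = STOCK_CONTENT,
                                  target_r = 50, scans = 5L, total_mg = 360,
                                  p_par = PARACETAMOL_PURITY,
                                  bands = default_band_table(),
                                  noise = noise_model(),
                                  saturation = default_saturation(), seed = 1L,
                                  mixture_id = "test-01") {
  if (true_content <= 0 || true_content >= 1) {
    stop("true_content must be in (0, 1)", call. = FALSE)
  }
  m_p <- solve_powder_mass(target_r, total_mg, nominal_content, p_par)
  rec <- mixture_record(mixture_id, m_p, total_mg - m_p, p_par = p_par,
                        c_s = NA_real_, role = "test", level_label = "")
  sp <- lapply(seq_len(scans), function(sc) {
    mixture_spectrum(rec, bands, noise,
                     seed = (as.numeric(seed) * 1000 + sc * 37) %% 2147483647,
                     true_content = true_content, saturation = saturation,
                     label = sprintf("%s/scan-%02d", mixture_id, sc))
  })
  list(scans = scanset(sp, mixture_id), record = rec,
       true_content = true_content)
}

#' Simulate a validation campaign
#'
#' Generates the mixtures of an ICH-style validation study from stock powder
#' of known content: `replicates` mixtures at each recovery level (default
#' about 35, 50 and 65% R) on day 1, plus a second day of replicates at the
#' working level for intermediate precision. Each mixture is scanned
#' `scans` times.
#'
#' @param levels Target R levels in percent.
#' @param replicates Replicates per level (default 6).
#' @param scans Scans per mixture (default 5).
#' @param days Number of days at the working level (default 2; day >= 2
#'   replicates only exist at the working level).
#' @param c_s True/known content of the stock powder.
#' @param total_mg,prep_sd,p_par,bands,noise,saturation,seed As in
#'   [simulate_calibration_campaign].
#' @return A list with `scansets` and `records` (manifest with
#'   `level_label` and `day` columns).
#' @export
simulate_validation_campaign <- function(levels = c(35, 50, 65),
                                         replicates = 6L, scans = 5L,
                                         days = 2L, c_s = STOCK_CONTENT,
                                         total_mg = 360, prep_sd = 0.3,
                                         p_par = PARACETAMOL_PURITY,
                                         bands = default_band_table(),
                                         noise = noise_model(),
                                         saturation = default_saturation(),
                                         seed = 1L) {
  working <- levels[which.min(abs(levels - 50))]
  records <- NULL
  scansets <- list()
  idx <- 0L
  add_mixture <- function(level, day, rep) {
    idx <<- idx + 1L
    sub <- (as.numeric(seed) * 1000 + 500 + idx * 13) %% 2147483647
    realized <- with_seed(sub, level + stats::rnorm(1L, 0, prep_sd))
    m_p <- solve_powder_mass(realized, total_mg, c_s, p_par)
    rec <- mixture_record(sprintf("val-L%g-d%d-r%d", level, day, rep),
                          m_p, total_mg - m_p, p_par = p_par, c_s = c_s,
                          role = "standard", level_label = as.character(level))
    rec$day <- day
    records <<- rbind(records, rec)
    sp <- lapply(seq_len(scans), function(sc) {
      mixture_spectrum(rec, bands, noise,
                       seed = (sub + sc * 211) %% 2147483647,
                       saturation = saturation,
                       label = sprintf("%s/scan-%02d", rec$mixture_id, sc))
    })
    scansets[[idx]] <<- scanset(sp, rec$mixture_id)
  }
  for (lv in levels) {
    for (rep in seq_len(replicates)) add_mixture(lv, 1L, rep)
  }
  if (days > 1L) {
    for (day in 2L:days) {
      for (rep in seq_len(replicates)) add_mixture(working, day, rep)
    }
  }
  list(scansets = scansets, records = records)
}

#' Write or read a simulated campaign as a plain-text fixture directory
#'
#' `export_campaign` writes `manifest.csv` (the mixture records), one
#' spectrum CSV per scan under `spectra/`, and, when true contents are
#' supplied, `truth.json`. `read_campaign` reads such a directory back into
#' scansets and records. This round-trip is the file contract for driving
#' the pipeline from disk.
#'
#' @param dir Directory to create/read.
#' @param scansets List of [scanset]s.
#' @param records Manifest data frame.
#' @param truth Optional named list/vector of true contents keyed by
#'   mixture id, written to `truth.json`.
#' @return `export_campaign`: `dir` invisibly. `read_campaign`: a list with
#'   `scansets`, `records`, and `truth` (or `NULL`).
#' @export
export_campaign <- function(dir, scansets, records, truth = NULL) {
  dir.create(file.path(dir, "spectra"), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(records, file.path(dir, "manifest.csv"), row.names = FALSE)
  for (ss in scansets) {
    for (i in seq_along(ss$spectra)) {
      write_spectrum_csv(ss$spectra[[i]],
                         file.path(dir, "spectra",
                                   sprintf("%s_scan%02d.csv", ss$mixture_id, i)))
    }
  }
  if (!is.null(truth)) {
    jsonlite::write_json(as.list(truth), file.path(dir, "truth.json"),
                         digits = NA, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(dir)
}

#' @rdname export_campaign
#' @export
read_campaign <- function(dir) {
  records <- utils::read.csv(file.path(dir, "manifest.csv"),
                             stringsAsFactors = FALSE)
  scansets <- lapply(records$mixture_id, function(id) {
    files <- sort(list.files(file.path(dir, "spectra"),
                             pattern = paste0("^", id, "_scan[0-9]+\\.csv$"),
                             full.names = TRUE))
    if (length(files) == 0L) {
      stop(sprintf("no spectrum files for mixture '%s' in %s", id, dir),
           call. = FALSE)
    }
    scanset(lapply(files, read_spectrum_csv), id)
  })
  truth_path <- file.path(dir, "truth.json")
  truth <- if (file.exists(truth_path)) {
    jsonlite::read_json(truth_path, simplifyVector = TRUE)
  } else NULL
  list(scansets = scansets, records = records, truth = truth)
}
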