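#' Preprocessing parameters for the calibration window
#'
#' Bundles the spectral pretreatment settings applied, in fixed order, before
#' regression: window extraction, reference-peak normalization, and
#' multiplicative signal correction (MSC). The MSC reference is the mean of
#' the normalized, windowed calibration spectra and is frozen into the model
#' at fit time; prediction-time scans are always corrected against this
#' frozen reference.
#'
#' @param window_lo,window_hi Analysis window bounds in cm-1. The default
#'   1800-1300 cm-1 zone carries the main analyte and internal-standard bands
#'   while the excipient matrix contributes little there.
#' @param norm_wavenumber Wavenumber (cm-1) of the normalization anchor,
#'   mapped to the nearest grid point. Default 1697.6 cm-1, the strongest
#'   analyte band, which compensates the unstable absolute intensity of ATR
#'   contact.
#' @param msc_reference A [spectrum] on exactly the window grid, or `NULL`
#'   before fitting.
#' @return An object of class `preprocess_params`.
#' @export
preprocess_params <- function(window_lo = 1300, window_hi = 1800,
                              norm_wavenumber = 1697.6,
                              msc_reference = NULL) {
  if (!(window_lo < window_hi)) stop("window_lo must be < window_hi", call. = FALSE)
  if (norm_wavenumber < window_lo || norm_wavenumber > window_hi) {
    stop("norm_wavenumber must lie inside the window", call. = FALSE)
  }
  if (!is.null(msc_reference)) stopifnot(inherits(msc_reference, "spectrum"))
  structure(list(window_lo = window_lo, window_hi = window_hi,
                 norm_wavenumber = norm_wavenumber,
                 msc_reference = msc_reference),
            class = "preprocess_params")
}

#' Normalize a spectrum at a reference wavenumber
#'
#' Divides every absorbance value by the absorbance at the grid point nearest
#' `norm_wavenumber`, so the output equals exactly 1 at the anchor. Scans
#' whose anchor absorbance is non-positive or below `1e-6` are rejected as
#' degenerate (no analyte band).
#'
#' @param s A [spectrum].
#' @param norm_wavenumber Anchor wavenumber in cm-1.
#' @return The normalized [spectrum].
#' @export
normalize_at <- function(s, norm_wavenumber = 1697.6) {
  i <- nearest_index(s, norm_wavenumber)
  v <- s$absorbance[i]
  if (!is.finite(v) || v < 1e-6) {
    stop(sprintf(
      "degenerate spectrum: absorbance %g at anchor %g cm-1 (grid point %g)",
      v, norm_wavenumber, s$wavenumber[i]), call. = FALSE)
  }
  out <- s
  out$absorbance <- s$absorbance / v
  stopifnot(out$absorbance[i] == 1)
  out
}

#' Fit a multiplicative-signal-correction reference
#'
#' The MSC reference is the point-wise mean of the calibration spectra.
#'
#' @param calibration_spectra List of at least two [spectrum] objects on a
#'   common grid.
#' @return The mean [spectrum].
#' @export
msc_fit <- function(calibration_spectra) {
  if (!is.list(calibration_spectra) || length(calibration_spectra) < 2L) {
    stop("need at least two calibration spectra", call. = FALSE)
  }
  ref <- calibration_spectra[[1L]]
  for (i in seq_along(calibration_spectra)[-1L]) {
    if (!same_grid(ref, calibration_spectra[[i]])) {
      stop(sprintf("spectrum %d is on a different grid", i), call. = FALSE)
    }
  }
  A <- vapply(calibration_spectra, function(s) s$absorbance,
              numeric(length(ref$wavenumber)))
  spectrum(ref$wavenumber, rowMeans(A), label = "msc_reference")
}

#' Apply multiplicative signal correction
#'
#' Regresses the spectrum on the reference by ordinary least squares,
#' `s = a + b * ref + e`, and returns the corrected spectrum `(s - a) / b`.
#' MSC exactly inverts any affine distortion of the reference, and the
#' reference itself is a fixed point.
#'
#' @param s A [spectrum].
#' @param reference The MSC reference [spectrum] (non-constant, same grid).
#' @return The corrected [spectrum], with the fitted slope and intercept
#'   attached as attributes `msc_slope` and `msc_intercept`.
#' @export
msc_apply <- function(s, reference) {
  stopifnot(inherits(s, "spectrum"), inherits(reference, "spectrum"))
  if (!same_grid(s, reference)) {
    stop("spectrum and MSC reference are on different grids", call. = FALSE)
  }
  x <- reference$absorbance
  y <- s$absorbance
  mx <- mean(x)
  sxx <- sum((x - mx)^2)
  if (sxx == 0) stop("MSC reference is constant", call. = FALSE)
  b <- sum((x - mx) * (y - mean(y))) / sxx
  a <- mean(y) - b * mx
  if (abs(b) < 1e-8) {
    stop(sprintf("MSC failure: scan uncorrelated with reference (slope %g)", b),
         call. = FALSE)
  }
  out <- s
  out$absorbance <- (y - a) / b
  attr(out, "msc_slope") <- b
  attr(out, "msc_intercept") <- a
  out
}

#' Run the full pretreatment pipeline on one spectrum
#'
#' Applies, in fixed order: window extraction, anchor normalization, and
#' (when `p$msc_reference` is set) multiplicative signal correction against
#' the frozen reference. Deterministic: equal inputs give identical outputs.
#'
#' @param s A [spectrum] covering the window.
#' @param p A [preprocess_params] object.
#' @return The pre-treated [spectrum] on the window grid.
#' @export
preprocess_spectrum <- function(s, p) {
  stopifnot(inherits(p, "preprocess_params"))
  out <- extract_window(s, p$window_lo, p$window_hi)
  out <- normalize_at(out, p$norm_wavenumber)
  if (!is.null(p$msc_reference)) {
    out <- msc_apply(out, p$msc_reference)
  }
  out
}
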