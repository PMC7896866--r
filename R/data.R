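#' Published validation campaign for the sildenafil citrate assay
#'
#' Measured mixture records (weighed masses and found R values) from the
#' validation of the internal-standard ATR-FTIR assay of sildenafil citrate
#' in Siloflam tablets. Three tables are available:
#'
#' * `"accuracy"` — the recovery study: 6 replicate mixtures of stock
#'   powder (content 37.94% m/m) with paracetamol at each of three R levels
#'   (about 35, 50 and 65%), with the R value found by the calibration
#'   model. Columns: `level`, `replicate`, `m_p_mg`, `m_par_mg`, `r_found`.
#' * `"precision"` — 12 replicate determinations of the stock powder at the
#'   working level (~50% R) on two days by two analysts; day-1 rows
#'   (identical to the accuracy level-50 rows) are the repeatability set.
#'   Columns: `day`, `analyst`, `replicate`, `m_p_mg`, `m_par_mg`,
#'   `r_found`.
#' * `"application"` — 6 replicate determinations on tablet batch N531
#'   (content unknown a priori). Columns: `replicate`, `m_p_mg`,
#'   `m_par_mg`, `r_found`.
#'
#' The internal-standard purity is 0.997 and the stock content 0.3794
#' throughout (see [assay_constants]). Only masses and found R values are
#' recorded; the derived columns (recovered mass, recovery rate, content)
#' are recomputed at full precision by [recovery_summary] and
#' [content_summary].
#'
#' @param which One of `"accuracy"`, `"precision"`, `"application"`.
#' @return A data frame.
#' @export
assay_validation_data <- function(which = c("accuracy", "precision",
                                            "application")) {
  which <- match.arg(which)
  file <- switch(which,
                 accuracy = "sildenafil_accuracy.csv",
                 precision = "sildenafil_precision.csv",
                 application = "sildenafil_batch_n531.csv")
  path <- system.file("extdata", file, package = "irquant", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
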