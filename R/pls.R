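#' Calibration/validation split plan
#'
#' Describes the seeded, per-mixture random partition of repeated scans into
#' a calibration and a validation set. The default assigns 8 of the 10 scans
#' of each standard mixture to calibration and 2 to validation, so every
#' mixture contributes to both sets and the validation error stays sensitive
#' to preparation variability.
#'
#' @param seed Integer seed driving the partition.
#' @param n_cal,n_val Scans per mixture assigned to the calibration and
#'   validation sets.
#' @return An object of class `split_plan`.
#' @export
split_plan <- function(seed = 1L, n_cal = 8L, n_val = 2L) {
  stopifnot(n_cal >= 1L, n_val >= 1L)
  structure(list(seed = as.integer(seed), n_cal = as.integer(n_cal),
                 n_val = as.integer(n_val)),
            class = "split_plan")
}

# Evaluate `expr` with the RNG seeded to `seed`, restoring the caller's
# RNG state afterwards so library code does not disturb user simulations.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Split scan sets into calibration and validation spectra
#'
#' Performs the seeded per-mixture partition described by a [split_plan].
#' Each mixture's true mass ratio R is computed from its record via
#' [design_r] and carried along as the regression response.
#'
#' @param scansets List of [scanset] objects.
#' @param records Mixture manifest: a data frame with columns `mixture_id`,
#'   `m_p_mg`, `m_par_mg`, `p_par`, `c_s` (one row per scanset).
#' @param plan A [split_plan].
#' @return A list with elements `calibration` and `validation`, each a list
#'   with `spectra` (list of [spectrum]), `r` (true R, %), and `mixture_id`.
#' @export
split_calibration_validation <- function(scansets, records, plan = split_plan()) {
  stopifnot(inherits(plan, "split_plan"))
  total <- plan$n_cal + plan$n_val
  cal <- list(spectra = list(), r = numeric(0L), mixture_id = character(0L))
  val <- list(spectra = list(), r = numeric(0L), mixture_id = character(0L))
  with_seed(plan$seed, {
    for (ss in scansets) {
      n <- length(ss$spectra)
      if (n < total) {
        stop(sprintf("mixture '%s' has %d scans; plan needs %d",
                     ss$mixture_id, n, total), call. = FALSE)
      }
      row <- records[records$mixture_id == ss$mixture_id, , drop = FALSE]
      if (nrow(row) != 1L) {
        stop(sprintf("mixture '%s' not found (once) in records", ss$mixture_id),
             call. = FALSE)
      }
      r_true <- design_r(row)
      perm <- sample.int(n)
      ical <- perm[seq_len(plan$n_cal)]
      ival <- perm[plan$n_cal + seq_len(plan$n_val)]
      cal$spectra <- c(cal$spectra, ss$spectra[ical])
      cal$r <- c(cal$r, rep(r_true, plan$n_cal))
      cal$mixture_id <- c(cal$mixture_id, rep(ss$mixture_id, plan$n_cal))
      val$spectra <- c(val$spectra, ss$spectra[ival])
      val$r <- c(val$r, rep(r_true, plan$n_val))
      val$mixture_id <- c(val$mixture_id, rep(ss$mixture_id, plan$n_val))
    }
  })
  list(calibration = cal, validation = val)
}

#' NIPALS PLS-1 regression
#'
#' Fits a univariate partial-least-squares model by the NIPALS algorithm.
#' Per factor: weight `w = X'y / ||X'y||`, scores `t = X w`, x-loading
#' `p = X't / t't`, y-loading `q = y't / t't`, then X and y are deflated.
#' The regression vector is `b = W (P'W)^-1 q` on centered data. Both X and
#' y are mean-centered internally and the means stored. Deterministic.
#'
#' @param X Numeric matrix, one preprocessed spectrum per row.
#' @param y Numeric response (mass ratio R, %), one value per row of X.
#' @param k Number of latent factors, at most `min(nrow(X) - 1, ncol(X))`.
#' @return An object of class `pls1` with fields `x_mean`, `y_mean`,
#'   `weights` (p x k), `x_loadings` (p x k), `y_loadings` (length k),
#'   `coef` (regression vector), and `n_factors` (achieved factor count;
#'   less than `k`, with a warning, if the residual collapses early).
#' @export
nipals_pls1 <- function(X, y, k) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (n < 2L || length(y) != n) stop("X needs >= 2 rows matching y", call. = FALSE)
  if (stats::var(y) == 0) stop("zero-variance response", call. = FALSE)
  k <- as.integer(k)
  if (k < 1L || k > min(n - 1L, p)) {
    stop(sprintf("k must be in 1..%d", min(n - 1L, p)), call. = FALSE)
  }
  x_mean <- colMeans(X)
  y_mean <- mean(y)
  Xc <- sweep(X, 2L, x_mean, "-")
  yc <- y - y_mean

  W <- matrix(0, p, k); P <- matrix(0, p, k); q <- numeric(k)
  achieved <- 0L
  for (a in seq_len(k)) {
    w <- crossprod(Xc, yc)                       # p x 1
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) {
      warning(sprintf("residual collapsed after %d factors (requested %d)",
                      achieved, k), call. = FALSE)
      break
    }
    w <- w / nw
    t <- Xc %*% w
    tt <- sum(t^2)
    if (tt < 1e-24) {
      warning(sprintf("score collapse after %d factors (requested %d)",
                      achieved, k), call. = FALSE)
      break
    }
    pl <- crossprod(Xc, t) / tt
    ql <- sum(yc * t) / tt
    Xc <- Xc - t %*% t(pl)
    yc <- yc - ql * t[, 1L]
    W[, a] <- w; P[, a] <- pl; q[a] <- ql
    achieved <- a
  }
  if (achieved == 0L) stop("no PLS factor could be extracted", call. = FALSE)
  W <- W[, seq_len(achieved), drop = FALSE]
  P <- P[, seq_len(achieved), drop = FALSE]
  q <- q[seq_len(achieved)]
  coef <- W %*% solve(crossprod(P, W), q)
  structure(list(x_mean = x_mean, y_mean = y_mean, weights = W,
                 x_loadings = P, y_loadings = q, coef = as.numeric(coef),
                 n_factors = achieved),
            class = "pls1")
}

# Predict responses for a matrix of preprocessed spectra (rows).
predict_pls1 <- function(fit, X) {
  X <- if (is.matrix(X)) X else matrix(X, nrow = 1L)
  as.numeric(fit$y_mean + sweep(X, 2L, fit$x_mean, "-") %*% fit$coef)
}

#' Root-mean-square error
#'
#' @param pred,true Equal-length numeric vectors (R values, %).
#' @return `sqrt(mean((pred - true)^2))`, in R percentage-point units.
#' @export
rmse <- function(pred, true) {
  if (length(pred) != length(true) || length(pred) == 0L) {
    stop("pred and true must have equal nonzero length", call. = FALSE)
  }
  sqrt(mean((pred - true)^2))
}

#' Pearson correlation between predicted and true values
#'
#' @param pred,true Equal-length numeric vectors of length >= 3, neither
#'   constant.
#' @return Sample Pearson correlation coefficient in `[-1, 1]`.
#' @export
pearson_r <- function(pred, true) {
  if (length(pred) != length(true) || length(pred) < 3L) {
    stop("need equal lengths >= 3", call. = FALSE)
  }
  if (stats::sd(pred) == 0 || stats::sd(true) == 0) {
    stop("constant input has no defined correlation", call. = FALSE)
  }
  stats::cor(pred, true)
}

# Shared preparation for factor_scan and fit_calibration: stage-A preprocess
# (window + normalize), seeded split, MSC reference frozen from the
# calibration set, then MSC-corrected data matrices for both sets.
prepare_pls_data <- function(scansets, records, plan, params) {
  stageA <- lapply(scansets, function(ss) {
    lapply(ss$spectra, function(s) {
      normalize_at(extract_window(s, params$window_lo, params$window_hi),
                   params$norm_wavenumber)
    })
  })
  stageA_sets <- mapply(function(sp, ss) scanset(sp, ss$mixture_id),
                        stageA, scansets, SIMPLIFY = FALSE)
  split <- split_calibration_validation(stageA_sets, records, plan)
  msc_ref <- msc_fit(split$calibration$spectra)
  to_matrix <- function(spectra) {
    t(vapply(spectra,
             function(s) msc_apply(s, msc_ref)$absorbance,
             numeric(length(msc_ref$wavenumber))))
  }
  list(X_cal = to_matrix(split$calibration$spectra), y_cal = split$calibration$r,
       X_val = to_matrix(split$validation$spectra), y_val = split$validation$r,
       msc_ref = msc_ref, grid = msc_ref$wavenumber)
}

#' Scan calibration models over factor counts
#'
#' Fits PLS-1 models with 1..`k_max` factors on one fixed seeded split and
#' reports, per factor count: RMSEC and RMSEV, the correlation coefficients
#' r_c (calibration) and r_v (validation), and the mean relative prediction
#' error over validation spectra whose true R lies within `working_band`
#' percentage points of `working_level` (the analysis level of test
#' mixtures, about 50%). The balance of these diagnostics guards against
#' overfitting: RMSEC always falls with more factors, while a widening
#' RMSEV-RMSEC gap signals lost prediction power.
#'
#' @param scansets List of [scanset] objects (standard mixtures).
#' @param records Mixture manifest data frame (see
#'   [split_calibration_validation]).
#' @param plan A [split_plan].
#' @param k_max Largest factor count to try.
#' @param params A [preprocess_params] (its `msc_reference` is ignored; the
#'   reference is refit from the calibration split).
#' @param working_level,working_band Center and half-width (percentage
#'   points) of the working R band for the relative-error diagnostic.
#' @return A data frame with columns `k`, `rmsec`, `rmsev`, `r_c`, `r_v`,
#'   `rel_err_at_working` (`NA` if no validation spectrum falls in the band).
#' @export
factor_scan <- function(scansets, records, plan = split_plan(), k_max = 10L,
                        params = preprocess_params(),
                        working_level = 50, working_band = 5) {
  stopifnot(k_max >= 1L)
  d <- prepare_pls_data(scansets, records, plan, params)
  in_band <- abs(d$y_val - working_level) <= working_band
  rows <- lapply(seq_len(k_max), function(k) {
    fit <- suppressWarnings(nipals_pls1(d$X_cal, d$y_cal, k))
    pc <- predict_pls1(fit, d$X_cal)
    pv <- predict_pls1(fit, d$X_val)
    rel <- if (any(in_band)) {
      mean(abs(pv[in_band] - d$y_val[in_band]) / d$y_val[in_band] * 100)
    } else NA_real_
    data.frame(k = k, rmsec = rmse(pc, d$y_cal), rmsev = rmse(pv, d$y_val),
               r_c = pearson_r(pc, d$y_cal), r_v = pearson_r(pv, d$y_val),
               rel_err_at_working = rel)
  })
  do.call(rbind, rows)
}

#' Select the number of PLS factors
#'
#' Returns the smallest factor count whose calibration and validation
#' correlation coefficients both reach `r_threshold`. Choosing the first
#' qualifying count also keeps the RMSEV-RMSEC overfitting gap no larger
#' than that of any other qualifying count that could have been preferred.
#'
#' @param scan A data frame from [factor_scan].
#' @param r_threshold Correlation requirement for both sets (default 0.998).
#' @return The selected factor count `k`.
#' @export
select_factors <- function(scan, r_threshold = 0.998) {
  if (!is.data.frame(scan) || nrow(scan) == 0L) {
    stop("empty factor scan", call. = FALSE)
  }
  ok <- which(scan$r_c >= r_threshold & scan$r_v >= r_threshold)
  if (length(ok) == 0L) {
    stop(sprintf(
      "no factor count reaches r >= %g (best r_c = %.6f, best r_v = %.6f)",
      r_threshold, max(scan$r_c), max(scan$r_v)), call. = FALSE)
  }
  scan$k[min(ok)]
}

#' Fit the internal-standard calibration model
#'
#' End-to-end model construction from a calibration campaign: stage-A
#' preprocessing (window + anchor normalization), seeded calibration /
#' validation split, MSC reference frozen from the calibration spectra,
#' factor-count selection by [select_factors] (unless `n_factors` is given),
#' and the final NIPALS PLS-1 fit on the calibration set.
#'
#' @inheritParams factor_scan
#' @param n_factors Fixed factor count, bypassing automatic selection.
#' @param r_threshold Correlation threshold passed to [select_factors].
#' @return An object of class `ir_calibration` with the frozen
#'   [preprocess_params], the fitted `pls1` core, the selected `n_factors`,
#'   the full factor-scan table (`scan`) and the diagnostics row at the
#'   selected count (`diagnostics`).
#' @export
fit_calibration <- function(scansets, records, plan = split_plan(),
                            params = preprocess_params(), n_factors = NULL,
                            k_max = 10L, r_threshold = 0.998,
                            working_level = 50, working_band = 5) {
  scan <- factor_scan(scansets, records, plan, k_max = k_max, params = params,
                      working_level = working_level,
                      working_band = working_band)
  k <- if (is.null(n_factors)) select_factors(scan, r_threshold) else
    as.integer(n_factors)
  if (!k %in% scan$k) {
    stop(sprintf("n_factors = %d outside the scanned range 1..%d", k,
                 max(scan$k)), call. = FALSE)
  }
  d <- prepare_pls_data(scansets, records, plan, params)
  fit <- nipals_pls1(d$X_cal, d$y_cal, k)
  frozen <- preprocess_params(params$window_lo, params$window_hi,
                              params$norm_wavenumber,
                              msc_reference = d$msc_ref)
  structure(list(preprocess = frozen, fit = fit, n_factors = fit$n_factors,
                 grid = d$grid, scan = scan,
                 diagnostics = scan[scan$k == k, , drop = FALSE],
                 r_threshold = r_threshold, split_seed = plan$seed),
            class = "ir_calibration")
}

#' @export
print.ir_calibration <- function(x, ...) {
  d <- x$diagnostics
  cat(sprintf(paste0(
    "<ir_calibration> window %g-%g cm-1, anchor %g cm-1, %d factors\n",
    "  RMSEC %.4f  RMSEV %.4f  r_c %.5f  r_v %.5f\n"),
    x$preprocess$window_lo, x$preprocess$window_hi,
    x$preprocess$norm_wavenumber, x$n_factors,
    d$rmsec, d$rmsev, d$r_c, d$r_v))
  invisible(x)
}

#' Predict the mass ratio R for one scan
#'
#' Applies the model's frozen preprocessing (window, anchor normalization,
#' MSC against the stored reference) and the PLS regression vector.
#'
#' @param model An `ir_calibration` from [fit_calibration] or [load_model].
#' @param s A [spectrum] covering the model window on the model grid.
#' @return Predicted R in percent.
#' @export
predict_r <- function(model, s) {
  stopifnot(inherits(model, "ir_calibration"))
  if (max(s$wavenumber) < model$preprocess$window_hi - 1e-9 ||
      min(s$wavenumber) > model$preprocess$window_lo + 1e-9) {
    stop(sprintf(
      "window mismatch: spectrum %g-%g cm-1 does not cover the model window %g-%g",
      min(s$wavenumber), max(s$wavenumber),
      model$preprocess$window_lo, model$preprocess$window_hi), call. = FALSE)
  }
  p <- preprocess_spectrum(s, model$preprocess)
  if (length(p$wavenumber) != length(model$grid) ||
      any(abs(p$wavenumber - model$grid) > 1e-6)) {
    stop("window mismatch: spectrum grid does not match the model grid",
         call. = FALSE)
  }
  predict_pls1(model$fit, p$absorbance)
}

MODEL_SCHEMA <- "irquant/ir_calibration/1"

#' Save or load a calibration model
#'
#' The model is serialized losslessly (full double precision) to a
#' human-diffable versioned JSON file, including the preprocessing
#' parameters and the frozen MSC reference, so reloaded models give
#' bit-identical predictions.
#'
#' @param model An `ir_calibration` object.
#' @param path File path for the JSON model file.
#' @return `save_model` returns `path` invisibly; `load_model` returns the
#'   `ir_calibration` object.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "ir_calibration"))
  obj <- list(
    schema = MODEL_SCHEMA,
    preprocess = list(window_lo = model$preprocess$window_lo,
                      window_hi = model$preprocess$window_hi,
                      norm_wavenumber = model$preprocess$norm_wavenumber,
                      msc_wavenumber = model$preprocess$msc_reference$wavenumber,
                      msc_absorbance = model$preprocess$msc_reference$absorbance),
    fit = list(x_mean = model$fit$x_mean, y_mean = model$fit$y_mean,
               weights = model$fit$weights, x_loadings = model$fit$x_loadings,
               y_loadings = model$fit$y_loadings, coef = model$fit$coef,
               n_factors = model$fit$n_factors),
    grid = model$grid, scan = model$scan, diagnostics = model$diagnostics,
    r_threshold = model$r_threshold, split_seed = model$split_seed)
  # I(17) = 17 significant digits, enough to round-trip doubles exactly
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @param path File path of a model written by [save_model].
#' @export
load_model <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) {
                    stop(sprintf("cannot parse model file '%s': %s",
                                 path, conditionMessage(e)), call. = FALSE)
                  })
  if (!identical(obj$schema, MODEL_SCHEMA)) {
    stop(sprintf("model schema '%s' not supported (expected '%s')",
                 if (is.null(obj$schema)) "<missing>" else obj$schema,
                 MODEL_SCHEMA), call. = FALSE)
  }
  ref <- spectrum(obj$preprocess$msc_wavenumber, obj$preprocess$msc_absorbance,
                  label = "msc_reference")
  pp <- preprocess_params(obj$preprocess$window_lo, obj$preprocess$window_hi,
                          obj$preprocess$norm_wavenumber, msc_reference = ref)
  as_matrix <- function(m) {
    if (is.matrix(m)) m else matrix(m, ncol = 1L)
  }
  fit <- structure(list(x_mean = obj$fit$x_mean, y_mean = obj$fit$y_mean,
                        weights = as_matrix(obj$fit$weights),
                        x_loadings = as_matrix(obj$fit$x_loadings),
                        y_loadings = obj$fit$y_loadings, coef = obj$fit$coef,
                        n_factors = as.integer(obj$fit$n_factors)),
                   class = "pls1")
  structure(list(preprocess = pp, fit = fit, n_factors = fit$n_factors,
                 grid = obj$grid, scan = obj$scan,
                 diagnostics = obj$diagnostics,
                 r_threshold = obj$r_threshold,
                 split_seed = as.integer(obj$split_seed)),
            class = "ir_calibration")
}
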