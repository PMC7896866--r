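#' Default assay constants
#'
#' `STOCK_CONTENT` is the sildenafil citrate mass content (fraction) of the
#' homogenized stock tablet powder used to prepare working standard
#' mixtures, as assayed by HPLC (37.94% m/m). An alternative HPLC figure of
#' 37.64% was also reported for the same material; it is kept available as
#' `STOCK_CONTENT_ALT` and selectable wherever `c_s` is an argument, but
#' 0.3794 is the normative default. `PARACETAMOL_PURITY` is the certified
#' purity fraction of the internal standard.
#'
#' @format Numeric scalars.
#' @name assay_constants
NULL

#' @rdname assay_constants
#' @export
STOCK_CONTENT <- 0.3794

#' @rdname assay_constants
#' @export
STOCK_CONTENT_ALT <- 0.3764

#' @rdname assay_constants
#' @export
PARACETAMOL_PURITY <- 0.997

#' Construct a mixture record
#'
#' One row of the mixture manifest: the weighed masses and purities defining
#' a standard or test mixture of tablet powder and internal standard.
#'
#' @param mixture_id Identifier string.
#' @param m_p_mg Tablet-powder mass in mg (> 0).
#' @param m_par_mg Internal-standard (paracetamol) mass in mg (> 0).
#' @param p_par Internal-standard purity as a fraction in (0, 1].
#' @param c_s Analyte mass content of the powder as a fraction in (0, 1);
#'   known for standards, `NA` for unknowns.
#' @param role `"standard"` or `"test"`.
#' @param level_label Optional validation-level label (e.g. `"35"`).
#' @return A one-row data frame.
#' @export
mixture_record <- function(mixture_id, m_p_mg, m_par_mg,
                           p_par = PARACETAMOL_PURITY, c_s = NA_real_,
                           role = c("standard", "test"), level_label = "") {
  role <- match.arg(role)
  if (m_p_mg <= 0 || m_par_mg <= 0) stop("masses must be > 0", call. = FALSE)
  if (p_par <= 0 || p_par > 1) stop("p_par must be in (0, 1]", call. = FALSE)
  if (!is.na(c_s) && (c_s <= 0 || c_s >= 1)) {
    stop("c_s must be in (0, 1) when present", call. = FALSE)
  }
  data.frame(mixture_id = as.character(mixture_id), role = role,
             m_p_mg = m_p_mg, m_par_mg = m_par_mg, p_par = p_par, c_s = c_s,
             level_label = as.character(level_label),
             stringsAsFactors = FALSE)
}

#' Designed mass ratio R of a mixture
#'
#' R is the percentage of analyte mass over the total mass of analyte plus
#' pure internal standard:
#' `R = 100 * m_p * c_s / (m_p * c_s + m_par * p_par)`.
#'
#' @param m Mixture manifest (data frame with columns `m_p_mg`, `m_par_mg`,
#'   `p_par`, `c_s`); vectorized over rows.
#' @return R in percent, one value per row.
#' @export
design_r <- function(m) {
  if (any(is.na(m$c_s))) {
    stop("design_r requires a known analyte content c_s", call. = FALSE)
  }
  analyte <- m$m_p_mg * m$c_s
  standard <- m$m_par_mg * m$p_par
  100 * analyte / (analyte + standard)
}

#' Back-calculate analyte content from a found R value
#'
#' Inverts the internal-standard mass balance: given the found mass ratio R
#' of a test mixture, the analyte content of the original tablet powder is
#' `C (%) = 100 * [R / (100 - R)] * m_par * p_par / m_p`. This is the exact
#' algebraic inverse of [design_r]: `content_from_r(design_r(m), m)` equals
#' `100 * c_s` for any valid record.
#'
#' @param r Found R value(s) in percent, strictly inside (0, 100).
#' @param m Mixture manifest (columns `m_p_mg`, `m_par_mg`, `p_par`).
#' @return Mass content C in % m/m.
#' @export
content_from_r <- function(r, m) {
  if (any(!is.finite(r)) || any(r <= 0) || any(r >= 100)) {
    stop("R must lie strictly inside (0, 100)", call. = FALSE)
  }
  100 * (r / (100 - r)) * m$m_par_mg * m$p_par / m$m_p_mg
}

#' Analyte mass recovered in a mixture
#'
#' `[R / (100 - R)] * m_par * p_par`, the analyte mass (mg) implied by the
#' found R value and the weighed internal-standard mass.
#'
#' @param r Found R in percent, inside (0, 100).
#' @param m_par_mg Internal-standard mass in mg.
#' @param p_par Internal-standard purity fraction.
#' @return Recovered analyte mass in mg.
#' @export
recovered_mass <- function(r, m_par_mg, p_par = PARACETAMOL_PURITY) {
  if (any(!is.finite(r)) || any(r <= 0) || any(r >= 100)) {
    stop("R must lie strictly inside (0, 100)", call. = FALSE)
  }
  (r / (100 - r)) * m_par_mg * p_par
}

#' Recovery rate
#'
#' Recovered analyte mass as a percentage of the mass expected from the
#' weighed powder and its nominal content: `100 * recovered / (m_p * c_s)`.
#'
#' @param recovered Recovered analyte mass in mg.
#' @param m_p_mg Tablet-powder mass in mg (> 0).
#' @param c_s Nominal analyte content fraction (> 0).
#' @return Recovery rate in percent.
#' @export
recovery_rate <- function(recovered, m_p_mg, c_s = STOCK_CONTENT) {
  if (any(m_p_mg <= 0) || any(c_s <= 0)) {
    stop("m_p_mg and c_s must be > 0", call. = FALSE)
  }
  100 * recovered / (m_p_mg * c_s)
}

#' Relative standard deviation
#'
#' `100 * sd(x) / mean(x)` with the sample (n-1) standard deviation.
#'
#' @param values Numeric vector of length >= 2 with nonzero mean.
#' @return RSD in percent.
#' @export
rsd <- function(values) {
  if (length(values) < 2L) stop("RSD needs at least two values", call. = FALSE)
  m <- mean(values)
  if (m == 0) stop("RSD undefined for zero mean", call. = FALSE)
  100 * stats::sd(values) / m
}

#' Round half away from zero
#'
#' Presentation-layer rounding: exact halves round up in magnitude (so
#' 0.25 -> 0.3 at one decimal), unlike base R's round-half-even. All internal
#' arithmetic stays at full double precision; this is applied only when
#' reporting.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded values.
#' @export
round_half_up <- function(x, digits = 1L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

#' Quantify a test mixture against a calibration model
#'
#' Predicts R for every scan of the test mixture, averages the per-scan R
#' values (arithmetic mean), and back-calculates the analyte content of the
#' tablet powder via [content_from_r].
#'
#' @param model An `ir_calibration` model.
#' @param scans A [scanset] of the test mixture (conventionally 5 scans).
#' @param m A one-row mixture record with `role == "test"`.
#' @return An object of class `quant_result`: `r_per_scan`, `r_mean`,
#'   `r_sd`, `content` (% m/m) and the `mixture` record.
#' @export
quantify <- function(model, scans, m) {
  stopifnot(inherits(model, "ir_calibration"), inherits(scans, "scanset"))
  if (nrow(m) != 1L) stop("m must be a single mixture record", call. = FALSE)
  if (!identical(m$role, "test")) {
    stop("quantify expects a test-role mixture record", call. = FALSE)
  }
  if (length(scans$spectra) == 0L) stop("no scans to quantify", call. = FALSE)
  r <- vapply(seq_along(scans$spectra), function(i) {
    tryCatch(predict_r(model, scans$spectra[[i]]),
             error = function(e) {
               stop(sprintf("scan %d of mixture '%s' failed preprocessing: %s",
                            i, scans$mixture_id, conditionMessage(e)),
                    call. = FALSE)
             })
  }, numeric(1L))
  r_mean <- mean(r)
  structure(list(r_per_scan = r, r_mean = r_mean,
                 r_sd = if (length(r) > 1L) stats::sd(r) else NA_real_,
                 content = content_from_r(r_mean, m), mixture = m),
            class = "quant_result")
}

#' @export
print.quant_result <- function(x, ...) {
  cat(sprintf(
    "<quant_result> mixture '%s': mean R %.2f%% (n = %d scans), content %.1f%% m/m\n",
    x$mixture$mixture_id, x$r_mean, length(x$r_per_scan),
    round_half_up(x$content, 1L)))
  invisible(x)
}

#' Recovery arithmetic for an accuracy study
#'
#' Pure mass-balance arithmetic on a table of mixtures with found R values:
#' per replicate the recovered analyte mass and recovery rate, and per level
#' the mean recovery and RSD. All statistics are computed at full precision;
#' the rounded presentation columns (`_1dp`, `_2dp`) are added separately.
#' This is also the replay path for validation campaigns recorded as
#' (masses, found R) tables without spectra.
#'
#' @param df Data frame with columns `level`, `m_p_mg`, `m_par_mg`,
#'   `r_found`, and optionally `p_par` and `c_s` (defaulted from the assay
#'   constants).
#' @param p_par,c_s Defaults used where `df` lacks the columns.
#' @return A list with `replicates` (per-row table with `recovered_mg` and
#'   `recovery_pct`) and `levels` (per-level `mean_recovery`, `rsd`, and
#'   their 1-dp presentation values).
#' @export
recovery_summary <- function(df, p_par = PARACETAMOL_PURITY,
                             c_s = STOCK_CONTENT) {
  need <- c("level", "m_p_mg", "m_par_mg", "r_found")
  if (!all(need %in% names(df))) {
    stop(sprintf("df must have columns %s", paste(need, collapse = ", ")),
         call. = FALSE)
  }
  if (!"p_par" %in% names(df)) df$p_par <- p_par
  if (!"c_s" %in% names(df)) df$c_s <- c_s
  df$recovered_mg <- recovered_mass(df$r_found, df$m_par_mg, df$p_par)
  df$recovery_pct <- recovery_rate(df$recovered_mg, df$m_p_mg, df$c_s)
  df$recovered_mg_2dp <- round_half_up(df$recovered_mg, 2L)
  df$recovery_pct_1dp <- round_half_up(df$recovery_pct, 1L)
  lv <- split(df, df$level)
  levels <- do.call(rbind, lapply(lv, function(g) {
    data.frame(level = g$level[1L], n = nrow(g),
               mean_recovery = mean(g$recovery_pct),
               rsd = rsd(g$recovery_pct))
  }))
  levels$mean_recovery_1dp <- round_half_up(levels$mean_recovery, 1L)
  levels$rsd_1dp <- round_half_up(levels$rsd, 1L)
  rownames(levels) <- NULL
  list(replicates = df, levels = levels)
}

#' Content arithmetic for precision / application tables
#'
#' Applies [content_from_r] to every row of a (masses, found R) table and
#' summarizes mean content and RSD at full precision, with 1-dp presentation
#' values.
#'
#' @param df Data frame with columns `m_p_mg`, `m_par_mg`, `r_found` and
#'   optionally `p_par`.
#' @param p_par Default internal-standard purity where the column is absent.
#' @return A list with `replicates` (adds `content` and `content_1dp`) and
#'   scalars `mean_content`, `rsd`, `mean_content_1dp`, `rsd_1dp`.
#' @export
content_summary <- function(df, p_par = PARACETAMOL_PURITY) {
  need <- c("m_p_mg", "m_par_mg", "r_found")
  if (!all(need %in% names(df))) {
    stop(sprintf("df must have columns %s", paste(need, collapse = ", ")),
         call. = FALSE)
  }
  if (!"p_par" %in% names(df)) df$p_par <- p_par
  df$content <- content_from_r(df$r_found, df)
  df$content_1dp <- round_half_up(df$content, 1L)
  list(replicates = df,
       mean_content = mean(df$content), rsd = rsd(df$content),
       mean_content_1dp = round_half_up(mean(df$content), 1L),
       rsd_1dp = round_half_up(rsd(df$content), 1L))
}

#' Run the assay validation battery
#'
#' Quantifies every replicate mixture of a validation campaign against the
#' model and assembles the standard pharmaceutical-assay validation report:
#' per-level recovery (mean and RSD over >= 6 replicates at >= 3 R levels),
#' repeatability (>= 6 same-day replicates at the working level), and, when
#' a second day is present, intermediate precision over both days. Pass
#' flags use the conventional limits: mean recovery within
#' `recovery_limits` (default 98.0-102.0%) and RSD at most `rsd_limit`
#' (default 2.0%).
#'
#' @param model An `ir_calibration` model.
#' @param scansets Named-or-ordered list of [scanset]s, one per record row.
#' @param records Manifest data frame with columns `mixture_id`, `m_p_mg`,
#'   `m_par_mg`, `p_par`, `c_s`, `level_label`, and optionally `day`.
#' @param working_level Level label of the working (~50% R) level used for
#'   precision; defaults to the level whose label parses closest to 50.
#' @param recovery_limits Two-element vector of recovery acceptance bounds (%).
#' @param rsd_limit RSD acceptance bound (%).
#' @param min_levels,min_replicates Structural requirements for the study.
#' @return An object of class `validation_report`.
#' @export
validate_method <- function(model, scansets, records,
                            working_level = NULL,
                            recovery_limits = c(98, 102), rsd_limit = 2,
                            min_levels = 3L, min_replicates = 6L) {
  stopifnot(inherits(model, "ir_calibration"))
  ids <- vapply(scansets, function(s) s$mixture_id, character(1L))
  if (!all(records$mixture_id %in% ids)) {
    missing <- setdiff(records$mixture_id, ids)
    stop(sprintf("no scans for mixture(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (!"day" %in% names(records)) records$day <- 1L
  # Per-replicate quantitation: found R, recovered mass, recovery, content.
  found <- do.call(rbind, lapply(seq_len(nrow(records)), function(i) {
    row <- records[i, , drop = FALSE]
    ss <- scansets[[match(row$mixture_id, ids)]]
    qrow <- row
    qrow$role <- "test"   # quantified as an unknown against the model
    q <- quantify(model, ss, qrow)
    data.frame(mixture_id = row$mixture_id, level = row$level_label,
               day = row$day, m_p_mg = row$m_p_mg, m_par_mg = row$m_par_mg,
               p_par = row$p_par, c_s = row$c_s, r_found = q$r_mean,
               content = q$content, stringsAsFactors = FALSE)
  }))
  found$recovered_mg <- recovered_mass(found$r_found, found$m_par_mg,
                                       found$p_par)
  found$recovery_pct <- recovery_rate(found$recovered_mg, found$m_p_mg,
                                      found$c_s)

  # recovery is judged on the first day's replicates; later days exist only
  # for intermediate precision at the working level
  rec_set <- found[found$day == min(found$day), , drop = FALSE]
  lv_tab <- table(rec_set$level)
  if (length(lv_tab) < min_levels) {
    stop(sprintf("recovery study needs >= %d levels, found %d",
                 min_levels, length(lv_tab)), call. = FALSE)
  }
  short <- names(lv_tab)[lv_tab < min_replicates]
  if (length(short) > 0L) {
    stop(sprintf("level(s) %s have fewer than %d replicates",
                 paste(short, collapse = ", "), min_replicates), call. = FALSE)
  }
  recovery <- do.call(rbind, lapply(split(rec_set, rec_set$level), function(g) {
    data.frame(level = g$level[1L], n = nrow(g),
               mean_recovery = mean(g$recovery_pct), rsd = rsd(g$recovery_pct),
               pass_recovery = mean(g$recovery_pct) >= recovery_limits[1L] &&
                 mean(g$recovery_pct) <= recovery_limits[2L],
               pass_rsd = rsd(g$recovery_pct) <= rsd_limit)
  }))
  rownames(recovery) <- NULL

  if (is.null(working_level)) {
    num <- suppressWarnings(as.numeric(recovery$level))
    working_level <- recovery$level[which.min(abs(num - 50))]
  }
  wk <- found[found$level == working_level, , drop = FALSE]
  day1 <- wk[wk$day == min(wk$day), , drop = FALSE]
  if (nrow(day1) < min_replicates) {
    stop(sprintf("repeatability needs >= %d same-day replicates at level %s",
                 min_replicates, working_level), call. = FALSE)
  }
  repeatability <- list(n = nrow(day1), mean_content = mean(day1$content),
                        rsd = rsd(day1$content),
                        pass = rsd(day1$content) <= rsd_limit)
  intermediate <- NULL
  if (length(unique(wk$day)) > 1L) {
    intermediate <- list(n = nrow(wk), mean_content = mean(wk$content),
                         rsd = rsd(wk$content),
                         pass = rsd(wk$content) <= rsd_limit)
  }
  structure(list(replicates = found, recovery = recovery,
                 repeatability = repeatability, intermediate = intermediate,
                 working_level = working_level,
                 limits = list(recovery = recovery_limits, rsd = rsd_limit),
                 pass = all(recovery$pass_recovery) && all(recovery$pass_rsd) &&
                   repeatability$pass &&
                   (is.null(intermediate) || intermediate$pass)),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report>\n  Recovery:\n")
  for (i in seq_len(nrow(x$recovery))) {
    g <- x$recovery[i, ]
    cat(sprintf("    level %-4s n=%d  mean %.1f%%  RSD %.1f%%  [%s]\n",
                g$level, g$n, round_half_up(g$mean_recovery, 1L),
                round_half_up(g$rsd, 1L),
                if (g$pass_recovery && g$pass_rsd) "pass" else "FAIL"))
  }
  cat(sprintf("  Repeatability (n=%d): mean %.1f%% m/m, RSD %.1f%% [%s]\n",
              x$repeatability$n, round_half_up(x$repeatability$mean_content, 1L),
              round_half_up(x$repeatability$rsd, 1L),
              if (x$repeatability$pass) "pass" else "FAIL"))
  if (!is.null(x$intermediate)) {
    cat(sprintf("  Intermediate precision (n=%d): mean %.1f%% m/m, RSD %.1f%% [%s]\n",
                x$intermediate$n, round_half_up(x$intermediate$mean_content, 1L),
                round_half_up(x$intermediate$rsd, 1L),
                if (x$intermediate$pass) "pass" else "FAIL"))
  }
  cat(sprintf("  Overall: %s\n", if (x$pass) "pass" else "FAIL"))
  invisible(x)
}
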