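#' Construct an absorbance spectrum
#'
#' A `spectrum` is a single-beam absorbance curve sampled on an evenly spaced
#' wavenumber grid. The grid is stored in descending wavenumber order (the
#' instrument convention for mid-IR); constructors accept either order and
#' normalize. The grid must be strictly monotonic and evenly spaced to within
#' `1e-6` cm-1, and all absorbance values must be finite.
#'
#' @param wavenumber Numeric vector of wavenumbers in cm-1 (no duplicates).
#' @param absorbance Numeric vector of unitless absorbance values, one per
#'   grid point.
#' @param label Free-text label (mixture id, scan index).
#' @return An object of class `spectrum` with fields `wavenumber` (descending),
#'   `absorbance` and `label`.
#' @export
#' @examples
#' s <- spectrum(c(1800, 1796, 1792), c(0.1, 0.2, 0.15))
#' s$wavenumber
spectrum <- function(wavenumber, absorbance, label = "") {
  if (!is.numeric(wavenumber) || !is.numeric(absorbance)) {
    stop("wavenumber and absorbance must be numeric", call. = FALSE)
  }
  if (length(wavenumber) != length(absorbance)) {
    stop("wavenumber and absorbance must have the same length", call. = FALSE)
  }
  if (length(wavenumber) == 0L) {
    stop("empty spectrum", call. = FALSE)
  }
  if (!all(is.finite(wavenumber))) {
    stop("non-finite wavenumber values", call. = FALSE)
  }
  if (!all(is.finite(absorbance))) {
    stop("non-finite absorbance values", call. = FALSE)
  }
  if (anyDuplicated(wavenumber)) {
    dup <- wavenumber[duplicated(wavenumber)][1L]
    stop(sprintf("duplicate wavenumber %g cm-1", dup), call. = FALSE)
  }
  o <- order(wavenumber, decreasing = TRUE)
  w <- as.numeric(wavenumber[o])
  a <- as.numeric(absorbance[o])
  if (length(w) > 2L) {
    d <- diff(w)
    if (max(d) - min(d) > 1e-6) {
      stop("wavenumber grid is not evenly spaced (tolerance 1e-6 cm-1)",
           call. = FALSE)
    }
  }
  structure(list(wavenumber = w, absorbance = a, label = as.character(label)),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %d points, %g..%g cm-1%s\n",
              length(x$wavenumber),
              x$wavenumber[1L], x$wavenumber[length(x$wavenumber)],
              if (nzchar(x$label)) paste0(" [", x$label, "]") else ""))
  invisible(x)
}

#' @export
length.spectrum <- function(x) length(x$wavenumber)

# TRUE when two spectra are sampled on the same grid (within tol cm-1).
same_grid <- function(a, b, tol = 1e-6) {
  length(a$wavenumber) == length(b$wavenumber) &&
    all(abs(a$wavenumber - b$wavenumber) <= tol)
}

#' Group repeated scans of one mixture
#'
#' A `scanset` collects repeated independent scans (spectra) of a single
#' powder mixture. All member spectra must share one wavenumber grid.
#' Standard mixtures are conventionally scanned 10 times, test mixtures 5.
#'
#' @param spectra List of [spectrum] objects on a common grid.
#' @param mixture_id Identifier linking the scans to a mixture record.
#' @return An object of class `scanset`.
#' @export
scanset <- function(spectra, mixture_id) {
  if (!is.list(spectra) || length(spectra) == 0L) {
    stop("spectra must be a non-empty list", call. = FALSE)
  }
  ok <- vapply(spectra, inherits, logical(1L), what = "spectrum")
  if (!all(ok)) stop("all elements must be spectrum objects", call. = FALSE)
  for (i in seq_along(spectra)[-1L]) {
    if (!same_grid(spectra[[1L]], spectra[[i]])) {
      stop(sprintf("scan %d is not on the same grid as scan 1", i),
           call. = FALSE)
    }
  }
  structure(list(spectra = spectra, mixture_id = as.character(mixture_id)),
            class = "scanset")
}

#' @export
print.scanset <- function(x, ...) {
  cat(sprintf("<scanset> mixture '%s', %d scans, %d points\n",
              x$mixture_id, length(x$spectra),
              length(x$spectra[[1L]]$wavenumber)))
  invisible(x)
}

#' Read a spectrum from a two-column CSV file
#'
#' Expects a header row; the wavenumber and absorbance columns are located by
#' name (see `dialect`), falling back to the first two columns when the named
#' ones are absent. Rows are re-ordered to the canonical descending grid, so
#' ascending and descending files yield identical spectra.
#'
#' @param path Path to a CSV file.
#' @param dialect Named list mapping the canonical column roles to the file's
#'   column names; defaults to `wavenumber_cm-1` / `absorbance`.
#' @param label Label for the spectrum; defaults to the file name.
#' @return A [spectrum].
#' @export
read_spectrum_csv <- function(path,
                              dialect = list(wavenumber = "wavenumber_cm-1",
                                             absorbance = "absorbance"),
                              label = basename(path)) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("CSV must have at least two columns", call. = FALSE)
  wcol <- dialect$wavenumber
  acol <- dialect$absorbance
  if (is.null(wcol) || !wcol %in% names(df)) wcol <- names(df)[1L]
  if (is.null(acol) || !acol %in% names(df)) acol <- names(df)[2L]
  w <- suppressWarnings(as.numeric(df[[wcol]]))
  a <- suppressWarnings(as.numeric(df[[acol]]))
  bad <- which(!is.finite(w) | !is.finite(a))
  if (length(bad) > 0L) {
    # +1 for the header row, so the number matches the file line
    stop(sprintf("malformed numeric value at line %d of '%s'",
                 bad[1L] + 1L, path), call. = FALSE)
  }
  spectrum(w, a, label = label)
}

#' Write a spectrum to CSV
#'
#' Writes the canonical two-column format (`wavenumber_cm-1,absorbance`) with
#' full double precision, so read/write round-trips preserve values.
#'
#' @param s A [spectrum].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spectrum_csv <- function(s, path) {
  stopifnot(inherits(s, "spectrum"))
  lines <- c("wavenumber_cm-1,absorbance",
             paste(format(s$wavenumber, digits = 17, trim = TRUE,
                          scientific = FALSE),
                   format(s$absorbance, digits = 17, trim = TRUE),
                   sep = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Read a spectrum from a JCAMP-DX file
#'
#' Supports the JCAMP-DX 4.24 subset used for exchange of dispersive IR data:
#' AFFN-encoded `##XYDATA=(X++(Y..Y))` and `##XYPOINTS=(XY..XY)` blocks, with
#' `##XFACTOR`/`##YFACTOR` scaling and an `##NPOINTS` consistency check.
#' ASDF compression (SQZ/DIF/DUP) is rejected explicitly rather than
#' misparsed. A missing `##XUNITS` produces a warning and is assumed `1/CM`.
#'
#' @param path Path to a JCAMP-DX file.
#' @param label Label for the spectrum; defaults to the file name.
#' @return A [spectrum].
#' @export
read_spectrum_jcamp <- function(path, label = basename(path)) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\\$\\$.*$", "", lines)     # strip $$ comments ($$ to end)
  lines <- trimws(lines)

  hdr <- list(XFACTOR = 1, YFACTOR = 1, FIRSTX = NA_real_, LASTX = NA_real_,
              DELTAX = NA_real_, NPOINTS = NA_real_, XUNITS = NA_character_)
  mode <- NULL
  data_lines <- character(0L)
  for (ln in lines) {
    if (startsWith(ln, "##")) {
      if (!is.null(mode)) mode <- NULL      # any new record ends the block
      eq <- regexpr("=", ln, fixed = TRUE)
      if (eq < 0L) next
      key <- toupper(gsub("[- _/]", "", substr(ln, 3L, eq - 1L)))
      val <- trimws(substr(ln, eq + 1L, nchar(ln)))
      if (key %in% c("XFACTOR", "YFACTOR", "FIRSTX", "LASTX", "DELTAX",
                     "NPOINTS")) {
        hdr[[key]] <- suppressWarnings(as.numeric(val))
      } else if (key == "XUNITS") {
        hdr$XUNITS <- val
      } else if (key == "XYDATA") {
        if (!grepl("X\\+\\+\\(Y\\.\\.Y\\)", val)) {
          stop(sprintf("unsupported XYDATA variable list '%s'", val),
               call. = FALSE)
        }
        mode <- "xydata"
      } else if (key == "XYPOINTS") {
        mode <- "xypoints"
      } else if (key == "END") {
        break
      }
    } else if (!is.null(mode) && nzchar(ln)) {
      data_lines <- c(data_lines, ln)
      attr(data_lines, "mode") <- mode
    }
  }
  if (length(data_lines) == 0L) {
    stop("no XYDATA or XYPOINTS block found", call. = FALSE)
  }
  mode <- attr(data_lines, "mode")

  if (is.na(hdr$XUNITS)) {
    warning("##XUNITS missing; assuming 1/CM", call. = FALSE)
  } else if (!grepl("1\\s*/\\s*CM", toupper(hdr$XUNITS))) {
    warning(sprintf("XUNITS '%s' is not 1/CM; values used as-is", hdr$XUNITS),
            call. = FALSE)
  }
  # AFFN only: any letter besides an exponent marker signals ASDF compression
  stripped <- gsub("[eE][+-]?[0-9]+", "", data_lines)
  if (any(grepl("[A-DF-Za-df-z@%]", stripped))) {
    stop("ASDF-compressed (SQZ/DIF/DUP) JCAMP data is not supported",
         call. = FALSE)
  }

  tok <- function(x) {
    t <- unlist(strsplit(x, "[,;[:space:]]+"))
    as.numeric(t[nzchar(t)])
  }
  if (identical(mode, "xypoints")) {
    v <- tok(paste(data_lines, collapse = " "))
    if (length(v) %% 2L != 0L) stop("odd token count in XYPOINTS", call. = FALSE)
    x <- v[seq(1L, length(v), by = 2L)]
    y <- v[seq(2L, length(v), by = 2L)]
  } else {
    dx <- hdr$DELTAX
    if (is.na(dx)) {
      if (is.na(hdr$FIRSTX) || is.na(hdr$LASTX) || is.na(hdr$NPOINTS)) {
        stop("cannot determine X increment: need DELTAX or FIRSTX/LASTX/NPOINTS",
             call. = FALSE)
      }
      dx <- (hdr$LASTX - hdr$FIRSTX) / (hdr$NPOINTS - 1)
    }
    x <- numeric(0L); y <- numeric(0L)
    for (ln in data_lines) {
      v <- tok(ln)
      if (length(v) < 2L) stop("XYDATA line with no Y values", call. = FALSE)
      x <- c(x, v[1L] + dx * (seq_len(length(v) - 1L) - 1L))
      y <- c(y, v[-1L])
    }
  }
  if (!is.na(hdr$NPOINTS) && length(y) != hdr$NPOINTS) {
    stop(sprintf("NPOINTS=%d but %d data points found",
                 as.integer(hdr$NPOINTS), length(y)), call. = FALSE)
  }
  spectrum(x * hdr$XFACTOR, y * hdr$YFACTOR, label = label)
}

#' Extract an inclusive wavenumber window
#'
#' Returns the sub-spectrum with all grid points nu satisfying
#' `lo <= nu <= hi` (both ends inclusive). The input is left untouched.
#'
#' @param s A [spectrum].
#' @param lo,hi Window bounds in cm-1, `lo < hi`.
#' @return A [spectrum] restricted to the window.
#' @export
extract_window <- function(s, lo, hi) {
  stopifnot(inherits(s, "spectrum"))
  if (!(lo < hi)) stop("window requires lo < hi", call. = FALSE)
  keep <- s$wavenumber >= lo - 1e-9 & s$wavenumber <= hi + 1e-9
  if (!any(keep)) {
    stop(sprintf("window [%g, %g] cm-1 does not intersect the grid", lo, hi),
         call. = FALSE)
  }
  spectrum(s$wavenumber[keep], s$absorbance[keep], label = s$label)
}

#' Index of the grid point nearest a target wavenumber
#'
#' Ties (target exactly half-way between two grid points) are broken toward
#' the higher wavenumber. This supports anchoring operations such as
#' normalization at 1697.6 cm-1, which need not lie on a 4 cm-1 grid.
#'
#' @param s A [spectrum].
#' @param target Target wavenumber in cm-1.
#' @return Integer index into `s$wavenumber`.
#' @export
nearest_index <- function(s, target) {
  stopifnot(inherits(s, "spectrum"))
  d <- abs(s$wavenumber - target)
  cand <- which(d <= min(d) + 1e-12)
  # grid is descending, so the smallest index has the highest wavenumber
  cand[which.max(s$wavenumber[cand])]
}
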