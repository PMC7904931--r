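#' Excitation spectrum record
#'
#' A wavelength-indexed intensity trace.  The wavelength grid must be
#' strictly ascending and, for ratiometric use, cover the 420--520 nm window
#' read by [compute_rex()].
#'
#' @param wavelength_nm Strictly ascending numeric wavelength grid (nm).
#' @param intensity Numeric intensities (arbitrary units), same length.
#' @param meta A [sample_meta()] record.
#' @param require_ratio_range If `TRUE` (default) the grid must cover
#'   \[420, 520\] nm; disable for non-ratiometric traces.
#'
#' @return An object of class `spectrum`.
#' @export
spectrum <- function(wavelength_nm, intensity, meta,
                     require_ratio_range = TRUE) {
  wavelength_nm <- as.numeric(wavelength_nm)
  intensity <- as.numeric(intensity)
  if (length(wavelength_nm) != length(intensity)) {
    stopf("field 'intensity': length %d does not match 'wavelength_nm' length %d",
          length(intensity), length(wavelength_nm))
  }
  if (length(wavelength_nm) < 2L) {
    stopf("field 'wavelength_nm': need at least 2 points")
  }
  if (anyNA(wavelength_nm) || any(!is.finite(wavelength_nm))) {
    stopf("field 'wavelength_nm': values must be finite")
  }
  d <- diff(wavelength_nm)
  if (any(d <= 0)) {
    i <- which(d <= 0)[1]
    stopf("field 'wavelength_nm': grid not strictly ascending at point %d (%.6g then %.6g)",
          i + 1L, wavelength_nm[i], wavelength_nm[i + 1L])
  }
  if (anyNA(intensity) || any(!is.finite(intensity))) {
    stopf("field 'intensity': values must be finite")
  }
  if (require_ratio_range &&
      (min(wavelength_nm) > 420 || max(wavelength_nm) < 520)) {
    stopf("field 'wavelength_nm': range [%.6g, %.6g] does not cover ratio wavelengths 420-520 nm",
          min(wavelength_nm), max(wavelength_nm))
  }
  if (!inherits(meta, "sample_meta")) stopf("field 'meta': must be a sample_meta record")
  structure(list(wavelength_nm = wavelength_nm, intensity = intensity,
                 meta = meta),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %s: %d points, %.4g-%.4g nm%s\n",
              x$meta$sample_id, length(x$wavelength_nm),
              min(x$wavelength_nm), max(x$wavelength_nm),
              if (x$meta$is_blank) " [blank]" else ""))
  invisible(x)
}

#' Read an excitation spectrum file
#'
#' Parses the project spectrum dialect: a `#`-prefixed `key: value` metadata
#' header followed by a `wavelength_nm,intensity` CSV body.
#'
#' @param path File path.
#' @param require_ratio_range Passed to [spectrum()].
#' @return A [spectrum()] object.
#' @export
read_spectrum <- function(path, require_ratio_range = TRUE) {
  if (!file.exists(path)) stopf("%s: file does not exist", path)
  lines <- readLines(path, warn = FALSE)
  meta <- meta_from_header(parse_header(lines, path), path)
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (!length(body)) stopf("%s: no data rows", path)
  if (!grepl("^wavelength_nm\\s*,\\s*intensity$", trimws(body[1]))) {
    stopf("%s: line 1 of body: expected header 'wavelength_nm,intensity'", path)
  }
  rows <- strsplit(body[-1], ",", fixed = TRUE)
  bad <- which(vapply(rows, length, 0L) != 2L)
  if (length(bad)) stopf("%s: data line %d: expected 2 columns", path, bad[1])
  m <- matrix(suppressWarnings(as.numeric(unlist(rows))), ncol = 2, byrow = TRUE)
  if (anyNA(m)) {
    bad <- which(rowSums(is.na(m)) > 0)[1]
    stopf("%s: data line %d: non-numeric value '%s'", path, bad,
          paste(rows[[bad]], collapse = ","))
  }
  spectrum(m[, 1], m[, 2], meta, require_ratio_range = require_ratio_range)
}

#' Write an excitation spectrum file
#'
#' @param x A [spectrum()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(x, path) {
  stopifnot(inherits(x, "spectrum"))
  lines <- c(meta_header_lines(x$meta),
             "wavelength_nm,intensity",
             sprintf("%.15g,%.15g", x$wavelength_nm, x$intensity))
  writeLines(lines, path)
  invisible(path)
}
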