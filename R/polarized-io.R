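#' Polarized intensity reading set
#'
#' The four polarized emission intensity components of a steady-state
#' anisotropy measurement, repeated `n_repeats` times per sample (study
#' protocol: 7 repeats).  `I_XY` is the intensity with excitation polarizer
#' in orientation X and emission polarizer in orientation Y (V vertical,
#' H horizontal).
#'
#' @param I_VV,I_VH,I_HV,I_HH Numeric vectors of equal length (one value per
#'   repeat), non-negative.
#' @param meta A [sample_meta()] record.
#' @return An object of class `polarized_set`.
#' @export
polarized_set <- function(I_VV, I_VH, I_HV, I_HH, meta) {
  comp <- list(I_VV = as.numeric(I_VV), I_VH = as.numeric(I_VH),
               I_HV = as.numeric(I_HV), I_HH = as.numeric(I_HH))
  n <- length(comp$I_VV)
  if (n < 1L) stopf("field 'I_VV': need at least one repeat")
  for (nm in names(comp)) {
    v <- comp[[nm]]
    if (length(v) != n) {
      stopf("field '%s': length %d does not match I_VV length %d", nm, length(v), n)
    }
    if (anyNA(v) || any(!is.finite(v))) stopf("field '%s': values must be finite", nm)
    if (any(v < 0)) stopf("field '%s': negative intensity at repeat %d", nm, which(v < 0)[1])
  }
  if (!inherits(meta, "sample_meta")) stopf("field 'meta': must be a sample_meta record")
  structure(c(comp, list(n_repeats = n, meta = meta)), class = "polarized_set")
}

#' @export
print.polarized_set <- function(x, ...) {
  cat(sprintf("<polarized_set> %s: %d repeats%s\n", x$meta$sample_id,
              x$n_repeats, if (x$meta$is_blank) " [blank]" else ""))
  invisible(x)
}

#' Read a polarized reading set file
#'
#' Dialect: metadata header then `repeat,I_VV,I_VH,I_HV,I_HH` CSV body.
#'
#' @param path File path.
#' @return A [polarized_set()] object.
#' @export
read_polarized <- function(path) {
  if (!file.exists(path)) stopf("%s: file does not exist", path)
  lines <- readLines(path, warn = FALSE)
  meta <- meta_from_header(parse_header(lines, path), path)
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (!length(body)) stopf("%s: no data rows", path)
  if (!grepl("^repeat\\s*,\\s*I_VV\\s*,\\s*I_VH\\s*,\\s*I_HV\\s*,\\s*I_HH$",
             trimws(body[1]))) {
    stopf("%s: expected body header 'repeat,I_VV,I_VH,I_HV,I_HH'", path)
  }
  rows <- strsplit(body[-1], ",", fixed = TRUE)
  bad <- which(vapply(rows, length, 0L) != 5L)
  if (length(bad)) stopf("%s: data line %d: expected 5 columns", path, bad[1])
  m <- matrix(suppressWarnings(as.numeric(unlist(rows))), ncol = 5, byrow = TRUE)
  if (anyNA(m)) stopf("%s: non-numeric value on data line %d", path,
                      which(rowSums(is.na(m)) > 0)[1])
  polarized_set(m[, 2], m[, 3], m[, 4], m[, 5], meta)
}

#' Write a polarized reading set file
#'
#' @param x A [polarized_set()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_polarized <- function(x, path) {
  stopifnot(inherits(x, "polarized_set"))
  lines <- c(meta_header_lines(x$meta),
             "repeat,I_VV,I_VH,I_HV,I_HH",
             sprintf("%d,%.15g,%.15g,%.15g,%.15g", seq_len(x$n_repeats),
                     x$I_VV, x$I_VH, x$I_HV, x$I_HH))
  writeLines(lines, path)
  invisible(path)
}
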