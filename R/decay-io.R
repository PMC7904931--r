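#' TCSPC decay histogram
#'
#' Photon counts per channel from a single-photon-timing measurement,
#' together with the instrument response function (IRF) recorded on the same
#' channel grid.  The study acquisition used 0.055517 ns/channel with
#' 10,000--20,000 counts in the peak channel.
#'
#' @param counts Non-negative integer-valued counts per channel.
#' @param channel_width_ns Channel width in nanoseconds (> 0).
#' @param irf_counts Non-negative integer-valued IRF histogram on the same
#'   binning (same length, sum > 0).
#' @param meta A [sample_meta()] record.
#' @return An object of class `decay_histogram` with derived field
#'   `peak_counts = max(counts)`.
#' @export
decay_histogram <- function(counts, channel_width_ns, irf_counts, meta) {
  counts <- as.numeric(counts)
  irf_counts <- as.numeric(irf_counts)
  check_counts <- function(v, field) {
    if (anyNA(v) || any(!is.finite(v))) stopf("field '%s': values must be finite", field)
    if (any(v < 0)) stopf("field '%s': negative count at channel %d", field, which(v < 0)[1])
    if (any(v != round(v))) {
      stopf("field '%s': fractional count at channel %d", field, which(v != round(v))[1])
    }
  }
  check_counts(counts, "counts")
  check_counts(irf_counts, "irf_counts")
  if (length(irf_counts) != length(counts)) {
    stopf("field 'irf_counts': length %d does not match counts length %d (decay and IRF must share binning)",
          length(irf_counts), length(counts))
  }
  if (sum(irf_counts) <= 0) stopf("field 'irf_counts': IRF is all zeros, not normalizable")
  channel_width_ns <- as.numeric(channel_width_ns)
  if (!is.finite(channel_width_ns) || channel_width_ns <= 0) {
    stopf("field 'channel_width_ns': must be a positive number")
  }
  if (!inherits(meta, "sample_meta")) stopf("field 'meta': must be a sample_meta record")
  structure(list(counts = counts, channel_width_ns = channel_width_ns,
                 irf_counts = irf_counts, peak_counts = as.integer(max(counts)),
                 meta = meta),
            class = "decay_histogram")
}

#' @export
print.decay_histogram <- function(x, ...) {
  cat(sprintf("<decay_histogram> %s: %d channels x %.6g ns, peak %d counts\n",
              x$meta$sample_id, length(x$counts), x$channel_width_ns,
              x$peak_counts))
  invisible(x)
}

irf_companion_path <- function(path) sub("\\.csv$", ".irf.csv", path)

#' Read a TCSPC decay histogram
#'
#' Dialect: metadata header (including `channel_width_ns`) and a
#' `channel,counts` CSV body.  The IRF is read from a companion file
#' `<name>.irf.csv` (same body layout) unless `irf_path` is given.
#'
#' @param path Decay file path.
#' @param irf_path Optional explicit IRF file path.
#' @return A [decay_histogram()] object.
#' @export
read_decay <- function(path, irf_path = NULL) {
  if (!file.exists(path)) stopf("%s: file does not exist", path)
  if (is.null(irf_path)) irf_path <- irf_companion_path(path)
  if (!file.exists(irf_path)) {
    stopf("%s: no IRF: companion file %s does not exist", path, irf_path)
  }
  dec <- read_channel_table(path)
  irf <- read_channel_table(irf_path)
  width <- dec$header$channel_width_ns
  if (is.null(width)) stopf("%s: metadata header missing field 'channel_width_ns'", path)
  meta <- meta_from_header(dec$header, path)
  decay_histogram(dec$counts, as.numeric(width), irf$counts, meta)
}

read_channel_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  header <- parse_header(lines, path)
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (!length(body)) stopf("%s: no data rows", path)
  if (!grepl("^channel\\s*,\\s*counts$", trimws(body[1]))) {
    stopf("%s: expected body header 'channel,counts'", path)
  }
  rows <- strsplit(body[-1], ",", fixed = TRUE)
  bad <- which(vapply(rows, length, 0L) != 2L)
  if (length(bad)) stopf("%s: data line %d: expected 2 columns", path, bad[1])
  m <- matrix(suppressWarnings(as.numeric(unlist(rows))), ncol = 2, byrow = TRUE)
  if (anyNA(m)) stopf("%s: non-numeric value on data line %d", path,
                      which(rowSums(is.na(m)) > 0)[1])
  o <- order(m[, 1])
  list(header = header, channel = m[o, 1], counts = m[o, 2])
}

#' Write a TCSPC decay histogram (and its IRF companion)
#'
#' @param x A [decay_histogram()] object.
#' @param path Decay file path; the IRF goes to `<name>.irf.csv`.
#' @return `path`, invisibly.
#' @export
write_decay <- function(x, path) {
  stopifnot(inherits(x, "decay_histogram"))
  n <- length(x$counts)
  lines <- c(meta_header_lines(x$meta),
             sprintf("# channel_width_ns: %.15g", x$channel_width_ns),
             "channel,counts",
             sprintf("%d,%d", seq_len(n), as.integer(x$counts)))
  writeLines(lines, path)
  irf_lines <- c(sprintf("# channel_width_ns: %.15g", x$channel_width_ns),
                 "channel,counts",
                 sprintf("%d,%d", seq_len(n), as.integer(x$irf_counts)))
  writeLines(irf_lines, irf_companion_path(path))
  invisible(path)
}
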