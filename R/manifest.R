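#' Load a study manifest
#'
#' The manifest is a CSV with one row per measurement file and columns
#' `sample_id, kind, lipid_system, compound, replicate, probe,
#' compound_conc_uM, blank_id, is_blank, file`.  `kind` is one of
#' `spectrum`, `polarized`, `decay`.  Every non-blank spectrum or polarized
#' entry must reference an existing blank row of the same lipid system and
#' replicate; decay records carry no blank (TCSPC histograms are not
#' blank-subtracted).
#'
#' @param path Manifest CSV path.
#' @param check_files If `TRUE` (default), verify that each referenced file
#'   exists relative to the manifest's directory.
#' @return An object of class `manifest`: a data.frame of validated entries
#'   with attribute `dir` (the manifest directory) and a printed study
#'   summary via `print()`.
#' @export
load_manifest <- function(path, check_files = TRUE) {
  if (!file.exists(path)) stopf("%s: file does not exist", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stopf("%s: no entries", path)
  need <- c("sample_id", "kind", "lipid_system", "compound", "replicate",
            "probe", "blank_id", "file")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("%s: missing required column '%s'", path, miss[1])
  if (is.null(df$is_blank)) df$is_blank <- FALSE
  if (is.null(df$compound_conc_uM)) {
    df$compound_conc_uM <- ifelse(toupper(df$compound) == "CONTROL", 0, 50)
  }
  df$kind <- match_enum(df$kind, c("SPECTRUM", "POLARIZED", "DECAY"), "kind")
  df$kind <- tolower(df$kind)
  df$lipid_system <- match_enum(df$lipid_system, lipid_systems(), "lipid_system")
  df$compound <- match_enum(df$compound, compounds(), "compound")
  df$probe <- match_enum(df$probe, probes(), "probe")
  df$replicate <- as.integer(df$replicate)
  df$is_blank <- as.logical(df$is_blank)
  df$blank_id[is.na(df$blank_id) | !nzchar(df$blank_id)] <- NA_character_

  dup <- df$sample_id[duplicated(df$sample_id)]
  if (length(dup)) stopf("%s: duplicate sample_id '%s'", path, dup[1])

  # blank linkage: required for non-blank spectrum/polarized records
  needs_blank <- !df$is_blank & df$kind %in% c("spectrum", "polarized")
  if (any(needs_blank & is.na(df$blank_id))) {
    stopf("%s: sample '%s': field 'blank_id' is required for non-blank %s records",
          path, df$sample_id[which(needs_blank & is.na(df$blank_id))[1]],
          df$kind[which(needs_blank & is.na(df$blank_id))[1]])
  }
  has_blank <- which(!is.na(df$blank_id))
  for (i in has_blank) {
    j <- match(df$blank_id[i], df$sample_id)
    if (is.na(j)) {
      stopf("%s: sample '%s': blank_id '%s' does not match any row",
            path, df$sample_id[i], df$blank_id[i])
    }
    if (!df$is_blank[j]) {
      stopf("%s: sample '%s': blank_id '%s' points to a non-blank row",
            path, df$sample_id[i], df$blank_id[i])
    }
    if (df$lipid_system[j] != df$lipid_system[i] || df$replicate[j] != df$replicate[i]) {
      stopf("%s: sample '%s': blank '%s' has a different lipid system or replicate",
            path, df$sample_id[i], df$blank_id[i])
    }
  }

  dir <- dirname(normalizePath(path, mustWork = TRUE))
  if (check_files) {
    full <- file.path(dir, df$file)
    missing <- !file.exists(full)
    if (any(missing)) {
      stopf("%s: sample '%s': referenced file '%s' does not exist",
            path, df$sample_id[which(missing)[1]], df$file[which(missing)[1]])
    }
  }
  # canonical order: lipid system, compound (report order), replicate
  o <- order(match(df$lipid_system, lipid_systems()),
             match(df$compound, compounds()),
             df$replicate, df$is_blank, df$kind, df$sample_id)
  df <- df[o, , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("manifest", "data.frame"), dir = dir)
}

#' @export
print.manifest <- function(x, ...) {
  lab <- x[!x$is_blank, , drop = FALSE]
  cat(sprintf("<manifest> %d entries (%d labelled, %d blanks) in %s\n",
              nrow(x), nrow(lab), sum(x$is_blank), attr(x, "dir")))
  cat(sprintf("  design: %d lipid system(s) x %d compound(s) x %d replicate(s); kinds: %s\n",
              length(unique(lab$lipid_system)), length(unique(lab$compound)),
              max(lab$replicate),
              paste(sort(unique(lab$kind)), collapse = ", ")))
  invisible(x)
}

#' Write a study manifest
#'
#' @param df Data frame of manifest entries (see [load_manifest()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(df, path) {
  cols <- c("sample_id", "kind", "lipid_system", "compound", "replicate",
            "probe", "compound_conc_uM", "blank_id", "is_blank", "file")
  df <- as.data.frame(df)[, cols]
  write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Write a condition-level results table
#'
#' Writes a TSV with a fixed column order and deterministic row order
#' (lipid system, then compound in report order).  Values are written at
#' full stored precision; a read of the file reproduces them exactly up to
#' decimal representation.
#'
#' @param rows Data frame with at least `lipid_system` and `compound`
#'   columns; remaining columns are written as-is.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(rows, path) {
  rows <- as.data.frame(rows)
  if (nrow(rows)) {
    if (!all(c("lipid_system", "compound") %in% names(rows))) {
      stopf("field 'rows': need 'lipid_system' and 'compound' columns")
    }
    o <- order(match(rows$lipid_system, lipid_systems()),
               match(rows$compound, compounds()))
    rows <- rows[o, , drop = FALSE]
    front <- c("lipid_system", "compound")
    rows <- rows[, c(front, setdiff(names(rows), front)), drop = FALSE]
  }
  num <- vapply(rows, is.numeric, TRUE)
  out <- rows
  out[num] <- lapply(rows[num], function(v) sprintf("%.15g", v))
  write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read back a results table written by [write_results_table()]
#'
#' @param path TSV path.
#' @return A data frame.
#' @export
read_results_table <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
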