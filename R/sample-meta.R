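#' Sample metadata record
#'
#' Describes one measured sample: which liposome composition and compound it
#' belongs to, which probe labels it, its replicate index and, for labelled
#' samples, the id of the matching unlabelled blank.
#'
#' @param sample_id Unique token identifying the sample.
#' @param lipid_system One of [lipid_systems()] (case-insensitive).
#' @param compound One of [compounds()] (case-insensitive).
#' @param replicate Positive integer replicate index.
#' @param probe One of [probes()].
#' @param compound_conc_uM Final compound concentration in micromolar
#'   (study value 50; must be 0 for `CONTROL`).
#' @param blank_id Id of the matching blank sample, or `NA` for blanks and
#'   for record kinds that need no blank.
#' @param is_blank Logical; `TRUE` for unlabelled blank samples.
#'
#' @return An object of class `sample_meta` (a named list).
#' @export
sample_meta <- function(sample_id, lipid_system, compound = "CONTROL",
                        replicate = 1L, probe = "DI8ANEPPS",
                        compound_conc_uM = if (toupper(compound) == "CONTROL") 0 else 50,
                        blank_id = NA_character_, is_blank = FALSE) {
  if (!is.character(sample_id) || length(sample_id) != 1L || !nzchar(sample_id)) {
    stopf("field 'sample_id': must be a non-empty string")
  }
  lipid_system <- match_enum(lipid_system, lipid_systems(), "lipid_system")
  compound <- match_enum(compound, compounds(), "compound")
  probe <- match_enum(probe, probes(), "probe")
  replicate <- as.integer(replicate)
  if (is.na(replicate) || replicate < 1L) {
    stopf("field 'replicate': must be a positive integer")
  }
  compound_conc_uM <- as.numeric(compound_conc_uM)
  if (is.na(compound_conc_uM) || compound_conc_uM < 0) {
    stopf("field 'compound_conc_uM': must be a non-negative number")
  }
  if (compound == "CONTROL" && compound_conc_uM != 0) {
    stopf("field 'compound_conc_uM': CONTROL samples must have concentration 0")
  }
  structure(
    list(sample_id = sample_id, lipid_system = lipid_system,
         compound = compound, replicate = replicate, probe = probe,
         compound_conc_uM = compound_conc_uM,
         blank_id = if (is.na(blank_id) || !nzchar(blank_id)) NA_character_ else blank_id,
         is_blank = isTRUE(is_blank)),
    class = "sample_meta")
}

#' @export
print.sample_meta <- function(x, ...) {
  cat(sprintf("<sample_meta> %s  %s / %s  rep %d  probe %s%s%s\n",
              x$sample_id, x$lipid_system, x$compound, x$replicate, x$probe,
              if (x$is_blank) "  [blank]" else "",
              if (!is.na(x$blank_id)) paste0("  blank=", x$blank_id) else ""))
  invisible(x)
}

meta_header_lines <- function(meta) {
  c(sprintf("# sample_id: %s", meta$sample_id),
    sprintf("# lipid_system: %s", meta$lipid_system),
    sprintf("# compound: %s", meta$compound),
    sprintf("# replicate: %d", meta$replicate),
    sprintf("# probe: %s", meta$probe),
    sprintf("# compound_conc_uM: %.15g", meta$compound_conc_uM),
    sprintf("# blank_id: %s", if (is.na(meta$blank_id)) "" else meta$blank_id),
    sprintf("# is_blank: %s", if (meta$is_blank) "TRUE" else "FALSE"))
}

parse_header <- function(lines, path) {
  hdr <- grep("^#", lines, value = TRUE)
  kv <- regmatches(hdr, regexec("^#\\s*([A-Za-z0-9_.]+)\\s*:\\s*(.*)$", hdr))
  keys <- vapply(kv, function(m) if (length(m) == 3L) m[2] else NA_character_, "")
  vals <- vapply(kv, function(m) if (length(m) == 3L) trimws(m[3]) else NA_character_, "")
  ok <- !is.na(keys)
  setNames(as.list(vals[ok]), keys[ok])
}

meta_from_header <- function(h, path) {
  need <- c("sample_id", "lipid_system", "compound", "replicate", "probe")
  miss <- setdiff(need, names(h))
  if (length(miss)) {
    stopf("%s: metadata header missing field '%s'", path, miss[1])
  }
  sample_meta(sample_id = h$sample_id, lipid_system = h$lipid_system,
              compound = h$compound, replicate = as.integer(h$replicate),
              probe = h$probe,
              compound_conc_uM = if (!is.null(h$compound_conc_uM))
                as.numeric(h$compound_conc_uM)
              else if (toupper(h$compound) == "CONTROL") 0 else 50,
              blank_id = if (!is.null(h$blank_id) && nzchar(h$blank_id))
                h$blank_id else NA_character_,
              is_blank = identical(toupper(h$is_blank %||% "FALSE"), "TRUE"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
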