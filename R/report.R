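# End-to-end study analysis: manifest -> replicate-level readouts ->
# condition tables -> report bundle.

#' Analyze a complete study from its manifest
#'
#' Runs every measurement arm present in the manifest: blank-corrected
#' excitation ratios with condition aggregation and calibrated dipole
#' shifts; per-sample and per-condition anisotropies; reconvolution lifetime
#' fits with intensity-weighted mean lifetimes.
#'
#' @param manifest A [load_manifest()] result or a manifest CSV path.
#' @param slope A [rescaled_slope()] for the dipole calibration.
#' @param lifetime_components Number of decay components to fit, or
#'   `"auto"` for [select_model()].
#' @return A list of class `study_results` with replicate-level data frames
#'   (`rex_replicates`, `anisotropy_replicates`, `lifetime_replicates`) and
#'   condition tables (`rex`, `dipole`, `anisotropy`, `lifetime`).
#' @export
analyze_study <- function(manifest, slope = rescaled_slope(),
                          lifetime_components = 2L) {
  if (is.character(manifest)) manifest <- load_manifest(manifest)
  stopifnot(inherits(manifest, "manifest"))
  dir <- attr(manifest, "dir")
  out <- list(slope = slope)

  cond_order <- function(df) {
    df[order(match(df$lipid_system, lipid_systems()),
             match(df$compound, compounds())), , drop = FALSE]
  }

  spec_rows <- manifest[manifest$kind == "spectrum" & !manifest$is_blank, ]
  if (nrow(spec_rows)) {
    reps <- do.call(rbind, lapply(seq_len(nrow(spec_rows)), function(i) {
      row <- spec_rows[i, ]
      lab <- read_spectrum(file.path(dir, row$file))
      blk_file <- manifest$file[match(row$blank_id, manifest$sample_id)]
      blk <- read_spectrum(file.path(dir, blk_file))
      data.frame(sample_id = row$sample_id, lipid_system = row$lipid_system,
                 compound = row$compound, replicate = row$replicate,
                 rex = compute_rex(lab, blk), stringsAsFactors = FALSE)
    }))
    agg <- do.call(rbind, lapply(split(reps, paste(reps$lipid_system, reps$compound)),
                                 function(g) {
      r <- aggregate_rex(g$rex, g$lipid_system[1], g$compound[1])
      data.frame(lipid_system = r$lipid_system, compound = r$compound,
                 mean_rex = r$mean_rex, sd_rex = r$sd_rex, n = r$n,
                 stringsAsFactors = FALSE)
    }))
    rownames(agg) <- NULL
    out$rex_replicates <- reps
    out$rex <- cond_order(agg)
    if ("CONTROL" %in% agg$compound) {
      out$dipole <- dipole_table(agg, slope)
    }
  }

  pol_rows <- manifest[manifest$kind == "polarized" & !manifest$is_blank, ]
  if (nrow(pol_rows)) {
    reps <- do.call(rbind, lapply(seq_len(nrow(pol_rows)), function(i) {
      row <- pol_rows[i, ]
      set <- read_polarized(file.path(dir, row$file))
      blk <- if (!is.na(row$blank_id)) {
        read_polarized(file.path(dir, manifest$file[match(row$blank_id,
                                                          manifest$sample_id)]))
      }
      s <- aggregate_anisotropy(set, blk)
      data.frame(sample_id = row$sample_id, lipid_system = row$lipid_system,
                 compound = row$compound, replicate = row$replicate,
                 r = s$mean_r, G = s$G_mean, n_repeats = s$n_repeats_used,
                 stringsAsFactors = FALSE)
    }))
    agg <- do.call(rbind, lapply(split(reps, paste(reps$lipid_system, reps$compound)),
                                 function(g) {
      a <- condition_anisotropy(g$r, g$lipid_system[1], g$compound[1])
      data.frame(lipid_system = a$lipid_system, compound = a$compound,
                 mean_r = a$mean_r, sd_r = a$sd_r, G_mean = mean(g$G),
                 n = a$n_samples, stringsAsFactors = FALSE)
    }))
    rownames(agg) <- NULL
    out$anisotropy_replicates <- reps
    out$anisotropy <- cond_order(agg)
  }

  dec_rows <- manifest[manifest$kind == "decay" & !manifest$is_blank, ]
  if (nrow(dec_rows)) {
    reps <- do.call(rbind, lapply(seq_len(nrow(dec_rows)), function(i) {
      row <- dec_rows[i, ]
      h <- read_decay(file.path(dir, row$file))
      fit <- if (identical(lifetime_components, "auto")) select_model(h)
             else fit_reconvolution(h, lifetime_components)
      taus <- fit$model$taus_ns
      data.frame(sample_id = row$sample_id, lipid_system = row$lipid_system,
                 compound = row$compound, replicate = row$replicate,
                 mean_tau_ns = fit$mean_tau_ns,
                 n_components = fit$model$n_components,
                 tau_short_ns = taus[1], tau_long_ns = taus[length(taus)],
                 chi2_reduced = fit$diagnostics$chi2_reduced,
                 converged = fit$diagnostics$converged,
                 stringsAsFactors = FALSE)
    }))
    agg <- do.call(rbind, lapply(split(reps, paste(reps$lipid_system, reps$compound)),
                                 function(g) {
      data.frame(lipid_system = g$lipid_system[1], compound = g$compound[1],
                 mean_tau_ns = mean(g$mean_tau_ns),
                 sd_tau_ns = if (nrow(g) > 1L) sd(g$mean_tau_ns) else 0,
                 n = nrow(g), stringsAsFactors = FALSE)
    }))
    rownames(agg) <- NULL
    out$lifetime_replicates <- reps
    out$lifetime <- cond_order(agg)
  }
  structure(out, class = "study_results")
}

#' @export
print.study_results <- function(x, ...) {
  cat("<study_results>\n")
  for (nm in c("rex", "dipole", "anisotropy", "lifetime")) {
    if (!is.null(x[[nm]])) cat(sprintf("  $%s: %d condition rows\n", nm, nrow(x[[nm]])))
  }
  invisible(x)
}

# FNV-1a hash of a deparsed object; stable fingerprint for the run log
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 216613626
  for (b in bytes) {
    h <- (bitwXor(as.integer(h %% 2^30), as.integer(b)) * 16777619) %% 2^30
  }
  sprintf("%08x", as.integer(h))
}

#' Write the study report bundle
#'
#' Writes condition tables as TSV files under `out_dir`: the excitation
#' ratio table with Tukey significance codes vs. control, the
#' dipole-potential change table (long and report layouts), the anisotropy
#' and mean-lifetime tables, and a run log with the calibration settings and
#' a configuration fingerprint.  Regeneration from the same inputs is
#' byte-identical.
#'
#' @param results An [analyze_study()] result.
#' @param out_dir Output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
build_report <- function(results, out_dir) {
  stopifnot(inherits(results, "study_results"))
  if (is.null(results$rex) && is.null(results$anisotropy) &&
      is.null(results$lifetime)) {
    stopf("field 'results': no upstream tables to report")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  put <- function(df, name) {
    p <- file.path(out_dir, name)
    write_results_table(df, p)
    written[[name]] <<- p
  }
  if (!is.null(results$rex)) {
    rex <- results$rex
    rex$sig_vs_control <- ""
    for (ls in unique(rex$lipid_system)) {
      g <- results$rex_replicates[results$rex_replicates$lipid_system == ls, ]
      if (length(unique(g$compound)) < 2L || !"CONTROL" %in% g$compound) next
      cmp <- one_way_anova_tukey(g$rex, g$compound)$comparisons
      vs <- cmp[cmp$vs_control, ]
      other <- ifelse(vs$group_a == "CONTROL", vs$group_b, vs$group_a)
      i <- match(paste(ls, other), paste(rex$lipid_system, rex$compound))
      rex$sig_vs_control[i] <- vs$significance_code
    }
    rex$sig_vs_control[rex$compound == "CONTROL"] <- NA
    put(rex, "rex.tsv")
  }
  if (!is.null(results$dipole)) {
    put(results$dipole, "dipole_shifts.tsv")
    wide <- dipole_table(results$rex, results$slope, wide = TRUE)
    p <- file.path(out_dir, "dipole_shifts_wide.tsv")
    write.table(wide, p, sep = "\t", row.names = FALSE, quote = FALSE,
                fileEncoding = "UTF-8")
    written[["dipole_shifts_wide.tsv"]] <- p
  }
  if (!is.null(results$anisotropy)) put(results$anisotropy, "anisotropy.tsv")
  if (!is.null(results$lifetime)) put(results$lifetime, "mean_lifetime.tsv")
  log_lines <- c(
    "memfluor study report",
    sprintf("slope: k = %.6g mV/ratio, k_sd = %.6g (%s)",
            results$slope$k_mV_per_ratio, results$slope$k_sd,
            results$slope$provenance),
    sprintf("tables: %s", paste(names(written), collapse = ", ")),
    sprintf("config_hash: %s",
            config_hash(list(results$slope, names(results),
                             lapply(results[c("rex", "anisotropy", "lifetime")],
                                    function(d) if (!is.null(d)) dim(d))))))
  log_p <- file.path(out_dir, "run_log.txt")
  writeLines(log_lines, log_p)
  written[["run_log.txt"]] <- log_p
  invisible(written)
}
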