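# Whole-study forward simulation: the full condition grid of the liposome
# screen (3 lipid systems x 8 compounds x 3 replicates, three measurement
# arms), written to disk in the package file dialects with a ground-truth
# table for parameter-recovery tests.

#' Default compound effects on the dipole potential (mV)
#'
#' The per-condition dipole-potential shifts used as generator ground truth:
#' the study's reported values for the seven compounds in the three lipid
#' systems.  Rows are compounds, columns lipid systems.
#'
#' @return A data.frame with columns `compound`, `POPC`, `POPC_CHOL`,
#'   `POPC_CHOL_PSM`.
#' @export
default_delta_psi_table <- function() {
  data.frame(
    compound = c("PHLORETIN", "NOTHOFAGIN", "PHLORIZIN", "GENISTEIN",
                 "G8", "RESVERATROL", "GLCRESVERATROL"),
    POPC          = c(-103, -22, -72, -61, 4, -32, 5),
    POPC_CHOL     = c(-327, -25, -173, -127, -7, -76, -8),
    POPC_CHOL_PSM = c(-218, -24, -126, -62, -5, -80, -4),
    stringsAsFactors = FALSE)
}

#' Study design for the forward simulator
#'
#' Collects the condition grid and per-condition ground truths of the
#' simulated liposome screen.  The defaults are the study conditions:
#' triplicate independent samples, control excitation ratios of 2.03 (POPC),
#' 3.05 (POPC:Chol 1:1, the 1.5-fold cholesterol increase) and 2.20
#' (ternary); compound ratio shifts derived from the reported
#' dipole-potential changes through the 365 mV/ratio-unit slope; DPH-PC
#' anisotropies of 0.165 (POPC) and 0.247 (POPC:Chol) with a slightly more
#' fluid ternary mixture (0.240); and a bi-exponential DPH-PC decay with
#' 3 ns and 7 ns components in every system.
#'
#' @param lipid_systems,compounds Condition grid tokens.
#' @param n_replicates Independent samples per condition (default 3).
#' @param control_rex Named vector of control excitation ratios per system.
#' @param delta_psi_mV Compound dipole shifts (see
#'   [default_delta_psi_table()]); converted to ratio shifts via `slope_k`.
#' @param slope_k Calibration slope (mV per ratio unit) used to map
#'   dipole-shift truths onto ratio shifts.
#' @param anisotropy_r Named vector of control anisotropies per system.
#' @param anisotropy_sd Target across-sample anisotropy SD per system
#'   (drives the polarized noise level through [anisotropy_noise_cv()]).
#' @param g_factor Instrumental G factor.
#' @param n_repeats Polarized readings per sample (default 7).
#' @param lifetime_alphas,lifetime_taus_ns Decay ground truth shared by all
#'   conditions (mean lifetime was composition-independent).
#' @param shape A [spectrum_shape_config()] for the ratiometric arm.
#' @param polarized_scale Intensity scale of the polarized readings.
#' @param target_peak_counts TCSPC peak counts.
#' @param arms Subset of `c("dipole", "anisotropy", "lifetime")` to
#'   generate.
#' @return An object of class `study_design`.
#' @export
study_design <- function(lipid_systems = memfluor::lipid_systems(),
                         compounds = memfluor::compounds(),
                         n_replicates = 3L,
                         control_rex = c(POPC = 2.03, POPC_CHOL = 3.05,
                                         POPC_CHOL_PSM = 2.20),
                         delta_psi_mV = default_delta_psi_table(),
                         slope_k = 365,
                         anisotropy_r = c(POPC = 0.165, POPC_CHOL = 0.247,
                                          POPC_CHOL_PSM = 0.240),
                         anisotropy_sd = c(POPC = 0.002, POPC_CHOL = 0.007,
                                           POPC_CHOL_PSM = 0.007),
                         g_factor = 1.2,
                         n_repeats = 7L,
                         lifetime_alphas = c(0.5, 0.5),
                         lifetime_taus_ns = c(3, 7),
                         shape = spectrum_shape_config(),
                         polarized_scale = 1e5,
                         target_peak_counts = 15000L,
                         arms = c("dipole", "anisotropy", "lifetime")) {
  lipid_systems <- match_enum(lipid_systems, memfluor::lipid_systems(), "lipid_systems")
  compounds <- match_enum(compounds, memfluor::compounds(), "compounds")
  arms <- match.arg(arms, c("dipole", "anisotropy", "lifetime"), several.ok = TRUE)
  miss <- setdiff(lipid_systems, names(control_rex))
  if (length(miss)) stopf("field 'control_rex': no truth value for lipid system '%s'", miss[1])
  cmp <- setdiff(compounds, c("CONTROL", delta_psi_mV$compound))
  if (length(cmp)) stopf("field 'delta_psi_mV': no truth value for compound '%s'", cmp[1])
  miss <- setdiff(lipid_systems, names(anisotropy_r))
  if (length(miss) && "anisotropy" %in% arms) {
    stopf("field 'anisotropy_r': no truth value for lipid system '%s'", miss[1])
  }
  structure(list(lipid_systems = lipid_systems, compounds = compounds,
                 n_replicates = as.integer(n_replicates),
                 control_rex = control_rex, delta_psi_mV = delta_psi_mV,
                 slope_k = slope_k, anisotropy_r = anisotropy_r,
                 anisotropy_sd = anisotropy_sd, g_factor = g_factor,
                 n_repeats = as.integer(n_repeats),
                 lifetime_alphas = lifetime_alphas,
                 lifetime_taus_ns = lifetime_taus_ns,
                 shape = shape, polarized_scale = polarized_scale,
                 target_peak_counts = as.integer(target_peak_counts),
                 arms = arms),
            class = "study_design")
}

truth_rex_for <- function(design, ls, comp) {
  base <- design$control_rex[[ls]]
  if (comp == "CONTROL") return(base)
  row <- design$delta_psi_mV[design$delta_psi_mV$compound == comp, , drop = FALSE]
  if (!nrow(row)) stopf("field 'delta_psi_mV': no truth value for compound '%s'", comp)
  base + row[[ls]] / design$slope_k
}

#' Generate a complete synthetic study on disk
#'
#' Simulates every condition x replicate of the design for the requested
#' measurement arms, writes the files in the package dialects under `dir`,
#' and returns the manifest plus a ground-truth table keyed by sample id.
#' Fully reproducible: the same `(design, seed)` pair yields byte-identical
#' output.
#'
#' @param design A [study_design()].
#' @param dir Output directory (created if needed).
#' @param seed Integer seed; per-sample seeds are derived deterministically.
#' @return A list with `manifest_path`, `manifest` (a [load_manifest()]
#'   result), and `truth` (data.frame keyed by `sample_id`).
#' @export
generate_study <- function(design = study_design(), dir = tempfile("study"),
                           seed = 1L) {
  stopifnot(inherits(design, "study_design"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  truths <- list()
  idx <- 0L
  add_row <- function(meta, kind, file) {
    rows[[length(rows) + 1L]] <<- data.frame(
      sample_id = meta$sample_id, kind = kind,
      lipid_system = meta$lipid_system, compound = meta$compound,
      replicate = meta$replicate, probe = meta$probe,
      compound_conc_uM = meta$compound_conc_uM,
      blank_id = ifelse(is.na(meta$blank_id), "", meta$blank_id),
      is_blank = meta$is_blank, file = file, stringsAsFactors = FALSE)
  }
  add_truth <- function(sample_id, truth_rex = NA_real_, truth_r = NA_real_,
                        truth_G = NA_real_, truth_tau1_ns = NA_real_,
                        truth_tau2_ns = NA_real_, truth_mean_tau_ns = NA_real_) {
    truths[[length(truths) + 1L]] <<- data.frame(
      sample_id = sample_id, truth_rex = truth_rex, truth_r = truth_r,
      truth_G = truth_G, truth_tau1_ns = truth_tau1_ns,
      truth_tau2_ns = truth_tau2_ns, truth_mean_tau_ns = truth_mean_tau_ns,
      stringsAsFactors = FALSE)
  }

  for (ls in design$lipid_systems) {
    for (comp in design$compounds) {
      for (rep in seq_len(design$n_replicates)) {
        stem <- sprintf("%s_%s_%d", ls, comp, rep)
        if ("dipole" %in% design$arms) {
          idx <- idx + 1L
          tr <- truth_rex_for(design, ls, comp)
          meta <- sample_meta(paste0(stem, "_SPEC"), ls, comp, rep,
                              probe = "DI8ANEPPS")
          pair <- generate_excitation_pair(tr, design$shape, meta,
                                           seed = child_seed(seed, idx))
          f_lab <- sprintf("spec_%s.csv", stem)
          f_blk <- sprintf("spec_%s_blk.csv", stem)
          write_spectrum(pair$labelled, file.path(dir, f_lab))
          write_spectrum(pair$blank, file.path(dir, f_blk))
          add_row(pair$labelled$meta, "spectrum", f_lab)
          add_row(pair$blank$meta, "spectrum", f_blk)
          add_truth(pair$labelled$meta$sample_id, truth_rex = tr)
        }
        if ("anisotropy" %in% design$arms) {
          idx <- idx + 1L
          tr_r <- design$anisotropy_r[[ls]]
          cv <- anisotropy_noise_cv(tr_r, design$anisotropy_sd[[ls]],
                                    design$n_repeats)
          meta <- sample_meta(paste0(stem, "_POL"), ls, comp, rep,
                              probe = "DPHPC")
          sig <- generate_polarized_set(tr_r, design$g_factor,
                                        design$polarized_scale,
                                        design$n_repeats, cv, meta,
                                        seed = child_seed(seed, idx))
          # unpolarized background at 0.5% of the intensity scale, present in
          # the labelled readings and recorded in the blank file
          b0 <- 0.005 * design$polarized_scale
          idx <- idx + 1L
          blk <- with_seed(child_seed(seed, idx), {
            list(in_lab = matrix(b0 * lnorm_factors(4L * design$n_repeats, cv),
                                 ncol = 4),
                 in_file = matrix(b0 * lnorm_factors(4L * design$n_repeats, cv),
                                  ncol = 4))
          })
          bmeta <- sample_meta(paste0(stem, "_POL_BLK"), ls, comp, rep,
                               probe = "DPHPC", is_blank = TRUE)
          lmeta <- meta; lmeta$blank_id <- bmeta$sample_id
          lab <- polarized_set(sig$set$I_VV + blk$in_lab[, 1],
                               sig$set$I_VH + blk$in_lab[, 2],
                               sig$set$I_HV + blk$in_lab[, 3],
                               sig$set$I_HH + blk$in_lab[, 4], lmeta)
          blank <- polarized_set(blk$in_file[, 1], blk$in_file[, 2],
                                 blk$in_file[, 3], blk$in_file[, 4], bmeta)
          f_lab <- sprintf("pol_%s.csv", stem)
          f_blk <- sprintf("pol_%s_blk.csv", stem)
          write_polarized(lab, file.path(dir, f_lab))
          write_polarized(blank, file.path(dir, f_blk))
          add_row(lab$meta, "polarized", f_lab)
          add_row(blank$meta, "polarized", f_blk)
          add_truth(lab$meta$sample_id, truth_r = tr_r,
                    truth_G = design$g_factor)
        }
        if ("lifetime" %in% design$arms) {
          idx <- idx + 1L
          meta <- sample_meta(paste0(stem, "_DEC"), ls, comp, rep,
                              probe = "DPHPC")
          dec <- generate_decay(design$lifetime_alphas,
                                design$lifetime_taus_ns,
                                target_peak_counts = design$target_peak_counts,
                                meta = meta, seed = child_seed(seed, idx))
          f <- sprintf("dec_%s.csv", stem)
          write_decay(dec$histogram, file.path(dir, f))
          add_row(meta, "decay", f)
          add_truth(meta$sample_id,
                    truth_tau1_ns = dec$truth$truth_taus_ns[1],
                    truth_tau2_ns = dec$truth$truth_taus_ns[length(dec$truth$truth_taus_ns)],
                    truth_mean_tau_ns = sum(dec$truth$truth_alphas * dec$truth$truth_taus_ns^2) /
                      sum(dec$truth$truth_alphas * dec$truth$truth_taus_ns))
        }
      }
    }
  }
  manifest_df <- do.call(rbind, rows)
  manifest_path <- file.path(dir, "manifest.csv")
  write_manifest(manifest_df, manifest_path)
  truth <- do.call(rbind, truths)
  truth <- truth[order(truth$sample_id), , drop = FALSE]
  rownames(truth) <- NULL
  write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE, quote = FALSE)
  list(manifest_path = manifest_path,
       manifest = load_manifest(manifest_path),
       truth = truth)
}
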