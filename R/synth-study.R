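#' Synthetic study configuration
#'
#' Parameters of the synthetic study generator. The defaults reproduce the
#' emulated study design: 12 mutant and 14 wild-type specimens in the
#' analysis pool (plus a 23-specimen wild-type template pool split over two
#' clutches), 23 manual landmarks placed twice with digitization noise on
#' the order of one CT voxel (0.021 mm), three bilateral otolith pairs with
#' 8\% individual volume variation and a 25\% mutant asteriscus enlargement,
#' and smooth specimen deformations with a bilaterally symmetric individual
#' field, one-sided fluctuating asymmetry, localized mutant effect bumps at
#' twice the individual amplitude, and a 5\% mutant size effect.
#'
#' @param n_mutant,n_wildtype analysis-group sizes.
#' @param n_template_pool wild-type specimens notionally used for the atlas.
#' @param k_manual number of manual landmarks.
#' @param pseudo_spacing target pseudo-landmark spacing (mm); \code{NA}
#'   means tune to \code{pseudo_target}.
#' @param pseudo_target target pseudo-landmark count.
#' @param individual_sd amplitude sd (mm) of the symmetric individual
#'   deformation bumps.
#' @param n_individual_bumps,n_fa_bumps bump counts for the individual and
#'   fluctuating-asymmetry fields.
#' @param individual_size_sd log-scale sd of individual overall size
#'   (specimens of similar but not identical size).
#' @param symmetric_effect_size,asymmetric_effect_size mutant effect bump
#'   amplitudes (mm).
#' @param fa_noise_sd amplitude sd (mm) of the one-sided
#'   fluctuating-asymmetry bumps.
#' @param size_effect mutant relative size increase.
#' @param digitization_noise_sd manual landmark placement noise (mm).
#' @param otolith_volume_effect named per-otolith mutant volume multipliers.
#' @param otolith_cv coefficient of variation of individual otolith volume.
#' @param otolith_grid_size,otolith_spacing label-volume grid (voxels, mm).
#' @param seed study seed; all stage seeds derive from it.
#' @return an object of class \code{study_config}.
#' @export
study_config <- function(n_mutant = 12L, n_wildtype = 14L,
                         n_template_pool = 23L, k_manual = 23L,
                         pseudo_spacing = NA_real_, pseudo_target = 372L,
                         individual_sd = 0.02, n_individual_bumps = 6L,
                         n_fa_bumps = 4L, individual_size_sd = 0.02,
                         symmetric_effect_size = 0.04,
                         asymmetric_effect_size = 0.04,
                         fa_noise_sd = 0.008,
                         size_effect = 0.05,
                         digitization_noise_sd = 0.021,
                         otolith_volume_effect = c(lapillus = 1.10,
                                                   sagitta = 1.10,
                                                   asteriscus = 1.25),
                         otolith_cv = 0.08,
                         otolith_grid_size = 96L, otolith_spacing = 0.015,
                         seed = 1L) {
  cfg <- list(n_mutant = as.integer(n_mutant),
              n_wildtype = as.integer(n_wildtype),
              n_template_pool = as.integer(n_template_pool),
              k_manual = as.integer(k_manual),
              pseudo_spacing = pseudo_spacing,
              pseudo_target = as.integer(pseudo_target),
              individual_sd = individual_sd,
              n_individual_bumps = as.integer(n_individual_bumps),
              n_fa_bumps = as.integer(n_fa_bumps),
              individual_size_sd = individual_size_sd,
              symmetric_effect_size = symmetric_effect_size,
              asymmetric_effect_size = asymmetric_effect_size,
              fa_noise_sd = fa_noise_sd,
              size_effect = size_effect,
              digitization_noise_sd = digitization_noise_sd,
              otolith_volume_effect = otolith_volume_effect,
              otolith_cv = otolith_cv,
              otolith_grid_size = as.integer(otolith_grid_size),
              otolith_spacing = otolith_spacing,
              seed = as.integer(seed))
  if (cfg$n_mutant < 2 || cfg$n_wildtype < 2 || cfg$k_manual < 3)
    stop_cm("counts too small for a meaningful study")
  if (any(c(cfg$individual_sd, cfg$fa_noise_sd, cfg$digitization_noise_sd) < 0))
    stop_cm("noise standard deviations must be >= 0")
  structure(cfg, class = "study_config")
}

#' @export
print.study_config <- function(x, ...) {
  cat("Synthetic study configuration\n")
  cat(sprintf("  groups: %d mutant vs %d wildtype | %d manual landmarks | pLM target %d\n",
              x$n_mutant, x$n_wildtype, x$k_manual, x$pseudo_target))
  cat(sprintf("  fields: individual %.3g mm, FA %.3g mm, sym effect %.3g, asym effect %.3g, size %.3g\n",
              x$individual_sd, x$fa_noise_sd, x$symmetric_effect_size,
              x$asymmetric_effect_size, x$size_effect))
  cat(sprintf("  otoliths: CV %.2g, mutant effect %s | seed %d\n", x$otolith_cv,
              paste(sprintf("%s %.2f", names(x$otolith_volume_effect),
                            x$otolith_volume_effect), collapse = ", "),
              x$seed))
  invisible(x)
}

#' Generate the full synthetic study
#'
#' Assembles everything the analysis pipeline consumes: the symmetric
#' template mesh, per-specimen deformed meshes with recorded ground-truth
#' deformations, true manual-landmark positions with two noisy replicate
#' placements each, the otolith fixture, and a ground-truth ledger of every
#' injected effect. Deterministic given \code{config$seed}.
#'
#' @param config a [study_config()].
#' @param include_volumes generate the otolith label fixture (on by
#'   default; switch off for shape-only work).
#' @return an object of class \code{synthetic_study}.
#' @export
make_study <- function(config = study_config(), include_volumes = TRUE) {
  template <- make_template_mesh()
  manual_idx <- template_landmark_sites(template, config$k_manual)
  template_manual <- as_landmarks(template$vertices[manual_idx, , drop = FALSE],
                                  names = sprintf("LM_%d", seq_along(manual_idx)))
  n <- config$n_mutant + config$n_wildtype
  groups <- c(rep("mutant", config$n_mutant), rep("wildtype", config$n_wildtype))
  ids <- sprintf("%s_%02d", ifelse(groups == "mutant", "mut", "wt"), seq_len(n))
  specimens <- vector("list", n)
  manual_replicates <- vector("list", n)
  true_manual <- vector("list", n)
  for (i in seq_len(n)) {
    sp <- make_specimen(template, groups[i], config,
                        seed = substream_seed(config$seed, paste0("specimen_", i)))
    tm <- deform_points(sp, template_manual)
    reps <- make_manual_replicates(tm, config$digitization_noise_sd,
                                   seed = substream_seed(config$seed,
                                                         paste0("digitize_", i)))
    specimens[[i]] <- sp
    true_manual[[i]] <- tm
    manual_replicates[[i]] <- reps
  }
  names(specimens) <- names(true_manual) <- names(manual_replicates) <- ids
  otoliths <- if (include_volumes)
    make_otolith_fixture(config, groups,
                         seed = substream_seed(config$seed, "otoliths"))
  else NULL
  design <- data.frame(id = ids, group = groups,
                       clutch = "clutch_A", stringsAsFactors = FALSE)
  ledger <- list(seed = config$seed,
                 design = list(n_mutant = config$n_mutant,
                               n_wildtype = config$n_wildtype),
                 injected_effects = list(
                   symmetric_shape = config$symmetric_effect_size,
                   asymmetric_shape = config$asymmetric_effect_size,
                   size = config$size_effect,
                   otolith_volume = as.list(config$otolith_volume_effect)),
                 noise = list(individual_sd = config$individual_sd,
                              fa_noise_sd = config$fa_noise_sd,
                              digitization_noise_sd = config$digitization_noise_sd,
                              otolith_cv = config$otolith_cv))
  structure(list(config = config, template = template,
                 template_manual = template_manual, manual_idx = manual_idx,
                 design = design, specimens = specimens,
                 true_manual = true_manual,
                 manual_replicates = manual_replicates,
                 otoliths = otoliths, ground_truth = ledger),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("Synthetic study:", nrow(x$design), "specimens (",
      sum(x$design$group == "mutant"), "mutant /",
      sum(x$design$group == "wildtype"), "wildtype ) | seed",
      x$config$seed, "\n")
  cat("  template:", nrow(x$template$vertices), "vertices |",
      x$config$k_manual, "manual landmarks, 2 replicates each\n")
  if (!is.null(x$otoliths))
    cat("  otolith fixture:", paste(x$otoliths$grid_size, collapse = "x"),
        "grid,", nrow(x$otoliths$geometry), "labels\n")
  invisible(x)
}

#' Write a synthetic study to disk
#'
#' Standard-format export: template and specimen meshes as PLY (with region
#' labels), landmark replicates and true landmarks as FCSV, the design
#' table as CSV, the atlas otolith segmentation as NRRD, and the
#' ground-truth ledger as JSON. Per-specimen displacement fields are
#' regenerated on demand by [otolith_displacement_field()] and written only
#' when \code{write_fields = TRUE} (they dominate the disk footprint).
#'
#' @param study a [make_study()] result.
#' @param dir output directory (created if needed).
#' @param write_fields also write per-specimen displacement fields as NRRD.
#' @return \code{dir}, invisibly.
#' @export
write_study <- function(study, dir, write_fields = FALSE) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_mesh(study$template, file.path(dir, "template.ply"))
  write_fcsv(study$template_manual, file.path(dir, "template_landmarks.fcsv"))
  utils::write.csv(study$design, file.path(dir, "design.csv"), row.names = FALSE)
  for (id in study$design$id) {
    write_mesh(study$specimens[[id]]$mesh, file.path(dir, paste0(id, ".ply")))
    write_fcsv(study$true_manual[[id]], file.path(dir, paste0(id, "_true.fcsv")))
    write_fcsv(study$manual_replicates[[id]]$rep1,
               file.path(dir, paste0(id, "_rep1.fcsv")))
    write_fcsv(study$manual_replicates[[id]]$rep2,
               file.path(dir, paste0(id, "_rep2.fcsv")))
  }
  if (!is.null(study$otoliths)) {
    write_nrrd(study$otoliths$atlas_labels, file.path(dir, "atlas_otoliths.nrrd"))
    if (write_fields) {
      for (i in seq_len(nrow(study$design)))
        write_nrrd(otolith_displacement_field(study$otoliths, i),
                   file.path(dir, paste0(study$design$id[i], "_field.nrrd")))
    }
  }
  jsonlite::write_json(study$ground_truth,
                       file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
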