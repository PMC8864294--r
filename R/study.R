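#' Analysis configuration for the end-to-end study
#'
#' Validated options for [run_study()]. Unknown options are rejected.
#'
#' @param pseudo_target pseudo-landmark count aimed for after region
#'   filtering.
#' @param exclude_regions template region labels whose points are removed
#'   (deformation-prone structures).
#' @param n_permutations permutations for every permutation test.
#' @param sliding_mode \code{"bending_energy"}, \code{"procrustes_distance"},
#'   or \code{"off"}.
#' @param sliding_rounds sliding iterations.
#' @param target_points approximate downsampled cloud size for
#'   registration.
#' @param cpd_lambda,cpd_w,cpd_max_iter,cpd_tol deformable-registration
#'   controls; the kernel width defaults to twice the pseudo-landmark
#'   spacing.
#' @param project_transfer snap transferred points to the target surface.
#' @param n_pcs_tested leading PCs given per-axis group tests.
#' @param seed master seed; all stage seeds derive from it.
#' @return an object of class \code{analysis_config}.
#' @export
analysis_config <- function(pseudo_target = 372L,
                            exclude_regions = c("jaws", "pectoral_girdle"),
                            n_permutations = 999L,
                            sliding_mode = "bending_energy",
                            sliding_rounds = 3L,
                            target_points = 800L,
                            cpd_lambda = 2, cpd_w = 0.1,
                            cpd_max_iter = 60L, cpd_tol = 1e-6,
                            project_transfer = FALSE,
                            n_pcs_tested = 4L,
                            seed = 1L) {
  if (!sliding_mode %in% c("bending_energy", "procrustes_distance", "off"))
    stop_cm("unknown sliding mode: ", sliding_mode)
  structure(list(pseudo_target = as.integer(pseudo_target),
                 exclude_regions = as.character(exclude_regions),
                 n_permutations = as.integer(n_permutations),
                 sliding_mode = sliding_mode,
                 sliding_rounds = as.integer(sliding_rounds),
                 target_points = as.integer(target_points),
                 cpd_lambda = cpd_lambda, cpd_w = cpd_w,
                 cpd_max_iter = as.integer(cpd_max_iter), cpd_tol = cpd_tol,
                 project_transfer = isTRUE(project_transfer),
                 n_pcs_tested = as.integer(n_pcs_tested),
                 seed = as.integer(seed)),
            class = "analysis_config")
}

stage <- function(name, id = NULL, expr) {
  tryCatch(expr, error = function(e)
    stop_cm("stage '", name, "'",
            if (!is.null(id)) paste0(" (specimen ", id, ")"), " failed: ",
            conditionMessage(e)))
}

perm_entry <- function(test) {
  list(F = test$F, Z = test$Z, p = test$p,
       df = c(test$df_effect, test$df_residual),
       n_permutations = test$n_permutations, seed = test$seed)
}

#' Run the full pseudo-landmark study
#'
#' Executes the complete analysis on a synthetic (or equivalently
#' structured) study: symmetric pseudo-landmark generation on the template
#' with region filtering tuned to the target count; rigid (ICP) plus
#' deformable (CPD) landmark transfer to every specimen; generalized
#' Procrustes analysis with semilandmark sliding; bilateral-symmetry
#' decomposition; group Procrustes ANOVAs on the symmetric and asymmetric
#' components and on fluctuating-asymmetry scores; separate PCAs of both
#' components with per-PC group tests and heat-map displacement fields;
#' the manual-landmark validation battery (digitization error, method
#' ANOVA and disparity, normalized centroid size); and the otolith
#' label-propagation volume analysis. All randomness derives from
#' \code{config$seed}; a rerun with the same inputs is identical.
#'
#' @param study a [make_study()] result.
#' @param config an [analysis_config()].
#' @return an object of class \code{study_report}.
#' @export
run_study <- function(study, config = analysis_config()) {
  stopifnot(inherits(study, "synthetic_study"),
            inherits(config, "analysis_config"))
  template <- study$template
  groups <- factor(study$design$group, levels = c("mutant", "wildtype"))
  if (any(table(groups) < 2)) stop_cm("need at least 2 specimens per group")
  n <- nrow(study$design)
  ids <- study$design$id

  ## -- pseudo-landmarks: generate, filter, re-tune to hit the target
  plm <- stage("pseudo_landmarks", NULL, {
    gen <- generate_pseudo_landmarks(template, template$plane,
                                     target_count = config$pseudo_target,
                                     seed = substream_seed(config$seed, "plm"))
    if (length(config$exclude_regions)) {
      filt <- filter_points_by_region(gen, template, config$exclude_regions)
      rho <- nrow(filt$points) / nrow(gen$points)
      gen2 <- generate_pseudo_landmarks(template, template$plane,
                                        target_count = as.integer(round(config$pseudo_target / rho)),
                                        seed = substream_seed(config$seed, "plm"))
      filter_points_by_region(gen2, template, config$exclude_regions)
    } else gen
  })
  k_plm <- nrow(plm$points)

  ## -- transfer to every specimen
  vox <- auto_voxel_size(template$vertices, config$target_points)
  template_cloud <- if (is.null(vox)) template$vertices
                    else downsample_cloud(template$vertices, vox)
  beta <- 2 * plm$spacing
  transferred <- array(0, dim = c(k_plm, 3, n))
  transferred_manual <- vector("list", n)
  transfer_error <- numeric(n)
  for (i in seq_len(n)) {
    stage("transfer", ids[i], {
      mesh_i <- study$specimens[[i]]$mesh
      cloud_i <- if (is.null(vox)) mesh_i$vertices
                 else downsample_cloud(mesh_i$vertices, vox)
      icp <- rigid_align(template_cloud, cloud_i, allow_scaling = FALSE)
      cpd <- cpd_deformable(icp$aligned, cloud_i, beta = beta,
                            lambda = config$cpd_lambda, w = config$cpd_w,
                            max_iter = config$cpd_max_iter,
                            tol = config$cpd_tol)
      transferred[, , i] <- transfer_landmarks(plm$points, icp, cpd,
                                                target_mesh = mesh_i,
                                                project = config$project_transfer)
      transferred_manual[[i]] <- transfer_landmarks(study$template_manual,
                                                     icp, cpd,
                                                     target_mesh = mesh_i,
                                                     project = config$project_transfer)
      truth <- deform_points(study$specimens[[i]], plm$points)
      transfer_error[i] <- mean(landmark_distances(transferred[, , i], truth))
    })
  }

  ## -- sliding GPA and symmetry decomposition
  gpa_fit <- stage("gpa", NULL, {
    sl <- if (config$sliding_mode == "off") NULL
          else sliding_spec(seq_len(k_plm), mode = config$sliding_mode,
                            max_sliding_iterations = config$sliding_rounds)
    run_gpa(transferred, scale = TRUE, sliding = sl)
  })
  sym <- stage("symmetry", NULL,
               decompose_object_symmetry(gpa_fit$aligned, plm$map,
                                         scale = TRUE))

  ## -- group tests on the two components
  np <- config$n_permutations
  sym_test <- procrustes_anova(sym$symmetric, groups, np,
                               seed = substream_seed(config$seed, "sym_test"))
  asym_test <- procrustes_anova(sym$asymmetric, groups, np,
                                seed = substream_seed(config$seed, "asym_test"))
  fa <- fluctuating_asymmetry_scores(sym)
  fa_test <- welch_t_test(fa[groups == "mutant"], fa[groups == "wildtype"])

  ## -- PCAs, per-PC tests, heat-map fields
  pca_section <- function(arr, label) {
    pca <- shape_pca(arr)
    m <- min(config$n_pcs_tested, ncol(pca$scores))
    per_pc <- lapply(seq_len(m), function(j)
      perm_entry(procrustes_anova(pca$scores[, j], groups, np,
                                  seed = substream_seed(config$seed,
                                                        paste0(label, "_pc", j)))))
    names(per_pc) <- colnames(pca$scores)[seq_len(m)]
    fields <- lapply(1:2, function(j) pc_heatmap_field(pca, j, extent = 3))
    list(pca = pca, per_pc_tests = per_pc, heatmap_fields = fields)
  }
  sym_pca <- stage("pca", NULL, pca_section(sym$symmetric, "sym"))
  asym_pca <- stage("pca", NULL, pca_section(sym$asymmetric, "asym"))
  group_field <- function(arr) {
    mu_m <- apply(arr[, , groups == "mutant"], c(1, 2), mean)
    mu_w <- apply(arr[, , groups == "wildtype"], c(1, 2), mean)
    row_norms(mu_m - mu_w)
  }

  ## -- manual-landmark validation battery
  validation <- stage("validation", NULL, {
    k_man <- study$config$k_manual
    gold <- lapply(study$manual_replicates, `[[`, "gold")
    d_alp <- t(vapply(seq_len(n), function(i)
      landmark_distances(transferred_manual[[i]], gold[[i]]), numeric(k_man)))
    d_man <- t(vapply(seq_len(n), function(i) {
      (landmark_distances(study$manual_replicates[[i]]$rep1, gold[[i]]) +
         landmark_distances(study$manual_replicates[[i]]$rep2, gold[[i]])) / 2
    }, numeric(k_man)))
    method_anova <- one_way_anova(c(d_alp, d_man),
                                  rep(c("alpaca", "manual"),
                                      each = length(d_alp)),
                                  n_permutations = np,
                                  seed = substream_seed(config$seed, "err_anova"))
    per_lm <- lapply(seq_len(k_man), function(j)
      paired_signed_rank_test(d_alp[, j], d_man[, j]))
    joint <- c(gold, lapply(seq_len(n), function(i) transferred_manual[[i]]))
    method <- factor(rep(c("gold", "alpaca"), each = n))
    joint_gpa <- run_gpa(joint, scale = TRUE)
    method_shape <- procrustes_anova(joint_gpa$aligned, method, np,
                                     seed = substream_seed(config$seed, "method_shape"))
    method_disp <- morphological_disparity(joint_gpa$aligned, method, np,
                                           seed = substream_seed(config$seed, "method_disp"))
    ncs_gold <- vapply(gold, normalized_centroid_size, 0)
    ncs_alp <- vapply(transferred_manual, normalized_centroid_size, 0)
    list(digitization_error = list(alpaca = d_alp, manual = d_man),
         method_anova = method_anova,
         per_landmark_tests = per_lm,
         method_shape_test = perm_entry(method_shape),
         method_disparity = method_disp,
         ncs = list(gold = ncs_gold, alpaca = ncs_alp,
                    method_test = one_way_anova(c(ncs_gold, ncs_alp),
                                                rep(c("gold", "alpaca"), each = n),
                                                n_permutations = np,
                                                seed = substream_seed(config$seed, "ncs_method")),
                    group_test_gold = welch_t_test(ncs_gold[groups == "mutant"],
                                                   ncs_gold[groups == "wildtype"]),
                    group_test_alpaca = welch_t_test(ncs_alp[groups == "mutant"],
                                                     ncs_alp[groups == "wildtype"])))
  })

  ## -- otolith volume propagation
  otolith <- NULL
  if (!is.null(study$otoliths)) {
    fixture <- study$otoliths
    automated <- vector("list", n)
    for (i in seq_len(n)) {
      automated[[i]] <- stage("otolith_warp", ids[i], {
        fld <- otolith_displacement_field(fixture, i)
        label_volumes(warp_labels(fixture$atlas_labels, fld))
      })
    }
    names(automated) <- ids
    manual <- fixture$manual_volumes
    names(manual) <- ids
    otolith <- stage("otolith_stats", NULL,
                     compare_volume_tables(manual, automated, groups))
  }

  structure(list(
    design = study$design,
    pseudo_landmarks = list(count = k_plm, spacing = plm$spacing,
                            pairs = nrow(plm$map$pairs),
                            midline = length(plm$map$midline),
                            removed_regions = plm$removed_regions,
                            vertex_index = plm$vertex_index),
    transfer = list(mean_error = mean(transfer_error),
                    per_specimen_error = stats::setNames(transfer_error, ids),
                    spacing = plm$spacing),
    gpa = list(iterations = gpa_fit$iterations, converged = gpa_fit$converged,
               sliding_objective = gpa_fit$sliding_objective,
               centroid_sizes = stats::setNames(gpa_fit$centroid_sizes, ids)),
    symmetry = list(test_symmetric = perm_entry(sym_test),
                    test_asymmetric = perm_entry(asym_test),
                    fa_scores = stats::setNames(fa, ids),
                    fa_group_test = fa_test,
                    directional_asymmetry_norm =
                      sqrt(sum(sym$directional_asymmetry^2))),
    pca_symmetric = sym_pca, pca_asymmetric = asym_pca,
    group_fields = list(symmetric = group_field(sym$symmetric),
                        asymmetric = group_field(sym$asymmetric)),
    validation = validation,
    otolith = otolith,
    components = sym,
    provenance = list(config = unclass(config),
                      study_seed = study$config$seed,
                      groups = as.character(groups))),
    class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("Pseudo-landmark study report\n")
  cat(sprintf("  %d specimens | %d pseudo-landmarks (%d pairs, %d midline)\n",
              nrow(x$design), x$pseudo_landmarks$count,
              x$pseudo_landmarks$pairs, x$pseudo_landmarks$midline))
  cat(sprintf("  transfer error: %.4g mm (mean over specimens)\n",
              x$transfer$mean_error))
  st <- x$symmetry$test_symmetric; at <- x$symmetry$test_asymmetric
  cat(sprintf("  symmetric component:  F = %.3f, Z = %.3f, p = %.4g\n",
              st$F, st$Z, st$p))
  cat(sprintf("  asymmetric component: F = %.3f, Z = %.3f, p = %.4g\n",
              at$F, at$Z, at$p))
  cat(sprintf("  symmetric PCA: %s\n",
              paste(sprintf("%.1f%%",
                            100 * x$pca_symmetric$pca$variance_fractions[1:2]),
                    collapse = ", ")))
  cat(sprintf("  asymmetric PCA: %s\n",
              paste(sprintf("%.1f%%",
                            100 * x$pca_asymmetric$pca$variance_fractions[1:2]),
                    collapse = ", ")))
  if (!is.null(x$otolith)) {
    ov <- x$otolith$tests[1, ]
    cat(sprintf("  otolith manual vs automated: t = %.3f, p = %.4g\n",
                ov$t, ov$p))
  }
  invisible(x)
}

#' Write a study report to disk
#'
#' CSV tables (per-landmark fields, PCA scores, digitization errors,
#' otolith volumes) plus a JSON summary bundling every statistic with its
#' permutation count and seed. All writes are atomic.
#'
#' @param report a [run_study()] result.
#' @param dir output directory.
#' @return \code{dir}, invisibly.
#' @export
write_study_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wcsv <- function(df, name) {
    tmp <- tempfile(tmpdir = dir, fileext = ".tmp")
    utils::write.csv(df, tmp, row.names = FALSE)
    file.rename(tmp, file.path(dir, name))
  }
  wcsv(data.frame(specimen = names(report$transfer$per_specimen_error),
                  transfer_error_mm = report$transfer$per_specimen_error),
       "transfer_error.csv")
  wcsv(data.frame(landmark = seq_along(report$group_fields$symmetric),
                  symmetric = report$group_fields$symmetric,
                  asymmetric = report$group_fields$asymmetric),
       "group_difference_fields.csv")
  for (comp in c("pca_symmetric", "pca_asymmetric")) {
    sc <- report[[comp]]$pca$scores
    wcsv(data.frame(specimen = report$design$id, sc), paste0(comp, "_scores.csv"))
  }
  if (!is.null(report$otolith)) wcsv(report$otolith$tests, "otolith_tests.csv")
  summary <- list(
    pseudo_landmarks = report$pseudo_landmarks,
    transfer_mean_error = report$transfer$mean_error,
    symmetry = report$symmetry[c("test_symmetric", "test_asymmetric")],
    fa_group_test = report$symmetry$fa_group_test,
    pca_symmetric_variance = report$pca_symmetric$pca$variance_fractions,
    pca_asymmetric_variance = report$pca_asymmetric$pca$variance_fractions,
    per_pc_tests = list(symmetric = report$pca_symmetric$per_pc_tests,
                        asymmetric = report$pca_asymmetric$per_pc_tests),
    validation = list(method_anova = report$validation$method_anova,
                      method_shape_test = report$validation$method_shape_test,
                      ncs_group_gold = report$validation$ncs$group_test_gold,
                      ncs_group_alpaca = report$validation$ncs$group_test_alpaca),
    otolith_tests = if (!is.null(report$otolith)) report$otolith$tests,
    provenance = report$provenance)
  tmp <- tempfile(tmpdir = dir, fileext = ".tmp")
  jsonlite::write_json(summary, tmp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  file.rename(tmp, file.path(dir, "report.json"))
  invisible(dir)
}
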