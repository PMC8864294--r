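## Per-specimen synthetic deformations: smooth analytic displacement fields
## (sums of radially directed Gaussian bumps anchored on the template
## surface), composed of a bilaterally symmetric individual field, a
## one-sided fluctuating-asymmetry field, and -- for mutants -- localized
## symmetric and asymmetric group effects plus a global size effect.
## Because the fields are analytic, the ground-truth image of any template
## point is exact and cheap.

## Evaluate a bump field at points: u(p) = sum_b amp_b exp(-|p-c_b|^2/(2 s_b^2)) e(p),
## with e(p) the outward radial direction. Radial direction mirrors under
## x -> -x, so a mirrored bump pair with equal amplitudes yields an exactly
## symmetric field.
eval_bump_field <- function(points, bumps) {
  if (is.null(bumps) || nrow(bumps) == 0) return(matrix(0, nrow(points), 3))
  rn <- row_norms(points)
  rn[rn < 1e-12] <- 1
  e <- points / rn
  w <- rep(0, nrow(points))
  for (b in seq_len(nrow(bumps))) {
    d2 <- rowSums(sweep(points, 2, c(bumps$cx[b], bumps$cy[b], bumps$cz[b]))^2)
    w <- w + bumps$amp[b] * exp(-d2 / (2 * bumps$sigma[b]^2))
  }
  e * w
}

bump_row <- function(center, amp, sigma) {
  data.frame(cx = center[1], cy = center[2], cz = center[3],
             amp = amp, sigma = sigma)
}

mirror_bumps <- function(bumps) {
  m <- bumps
  m$cx <- -m$cx
  rbind(bumps, m)
}

## Fixed mutant-effect bump centers, anchored on template regions:
## symmetric effect on the anterior frontal + dorsal operculum, asymmetric
## effect on the posterior parietal + ventral operculum (one side).
mutant_effect_centers <- function(template) {
  v <- template$vertices; reg <- template$regions
  right <- v[, 1] > 0.05
  pick <- function(mask) colMeans(v[mask, , drop = FALSE])
  op <- reg == "operculum"
  zmed <- stats::median(v[op & right, 3])
  list(frontal = pick(reg == "frontal" & right),
       operculum_dorsal = pick(op & right & v[, 3] > zmed),
       parietal = pick(reg == "parietal" & right),
       operculum_ventral = pick(op & right & v[, 3] <= zmed))
}

#' Generate one synthetic specimen
#'
#' Deforms the template by a smooth analytic displacement field:
#' a bilaterally symmetric individual field (mirrored random bump pairs), a
#' one-sided fluctuating-asymmetry field, and for mutants localized
#' symmetric (frontal + dorsal opercular) and asymmetric (one-sided
#' parietal + ventral opercular) effect bumps plus a global scale factor.
#' Amplitudes large enough to fold the surface (detected by face-normal
#' flips against the template) raise an error.
#'
#' @param template a [make_template_mesh()] result.
#' @param group \code{"mutant"} or \code{"wildtype"}.
#' @param config a [study_config()].
#' @param seed integer seed for this specimen's random fields.
#' @return an object of class \code{cm_specimen}: \code{mesh},
#'   \code{group}, \code{bumps} (the full bump table), \code{scale},
#'   \code{seed}. Use [deform_points()] to map any template-space point
#'   through the specimen's ground-truth deformation.
#' @export
make_specimen <- function(template, group = c("wildtype", "mutant"),
                          config = study_config(), seed = 1L) {
  group <- match.arg(group)
  v <- template$vertices
  side_verts <- which(v[, 1] > 0.2)
  drawn <- with_seed(as.integer(seed), {
    size_mult <- exp(stats::rnorm(1, 0, config$individual_size_sd))
    ind <- do.call(rbind, lapply(seq_len(config$n_individual_bumps), function(b) {
      ctr <- v[sample(side_verts, 1), ]
      bump_row(ctr, stats::rnorm(1, 0, config$individual_sd),
               stats::runif(1, 0.5, 1.0))
    }))
    ind <- mirror_bumps(ind)
    fa <- do.call(rbind, lapply(seq_len(config$n_fa_bumps), function(b) {
      ctr <- v[sample(nrow(v), 1), ]
      bump_row(ctr, stats::rnorm(1, 0, config$fa_noise_sd),
               stats::runif(1, 0.4, 0.8))
    }))
    list(bumps = rbind(ind, fa), size_mult = size_mult)
  })
  bumps <- drawn$bumps
  scale <- drawn$size_mult
  if (group == "mutant") {
    ec <- mutant_effect_centers(template)
    if (config$symmetric_effect_size != 0) {
      sym <- rbind(bump_row(ec$frontal, config$symmetric_effect_size, 0.6),
                   bump_row(ec$operculum_dorsal, config$symmetric_effect_size, 0.6))
      bumps <- rbind(bumps, mirror_bumps(sym))
    }
    if (config$asymmetric_effect_size != 0) {
      ## purely antisymmetric: bump out on one side, in on the other, so no
      ## amplitude leaks into the symmetric component
      asym <- rbind(bump_row(ec$parietal, config$asymmetric_effect_size, 0.6),
                    bump_row(ec$operculum_ventral, config$asymmetric_effect_size, 0.6))
      asym_m <- asym; asym_m$cx <- -asym_m$cx; asym_m$amp <- -asym_m$amp
      bumps <- rbind(bumps, asym, asym_m)
    }
    scale <- scale * (1 + config$size_effect)
  }
  spec <- structure(list(group = group, bumps = bumps, scale = scale,
                         seed = as.integer(seed)),
                    class = "cm_specimen")
  new_v <- deform_points(spec, v)
  mesh <- cm_mesh(new_v, template$faces, regions = template$regions)
  if (any_normal_flips(template, mesh))
    stop_cm("deformation folds the surface; use smaller effect amplitudes")
  spec$mesh <- mesh
  spec
}

#' Map template-space points through a specimen's ground-truth deformation
#'
#' @param specimen a [make_specimen()] result.
#' @param points \code{n x 3} template-space coordinates.
#' @return the deformed \code{n x 3} coordinates.
#' @export
deform_points <- function(specimen, points) {
  stopifnot(inherits(specimen, "cm_specimen"))
  points <- as_landmarks(points)
  out <- (points + eval_bump_field(points, specimen$bumps)) * specimen$scale
  dimnames(out) <- dimnames(points)
  out
}

any_normal_flips <- function(template, mesh) {
  fn <- function(m) {
    f <- m$faces; v <- m$vertices
    e1 <- v[f[, 2], ] - v[f[, 1], ]; e2 <- v[f[, 3], ] - v[f[, 1], ]
    cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
          e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
          e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  }
  any(rowSums(fn(template) * fn(mesh)) < 0)
}

#' Replicate manual landmark placements
#'
#' Two independent isotropic Gaussian perturbations of the true landmark
#' positions, emulating a landmarker digitizing each specimen twice; their
#' coordinate-wise average is the synthetic gold standard.
#'
#' @param true_landmarks the specimen's true landmark configuration.
#' @param digitization_noise_sd isotropic noise standard deviation (mm).
#' @param seed integer seed.
#' @return list with elements \code{rep1}, \code{rep2} (configurations) and
#'   \code{gold} (their average).
#' @export
make_manual_replicates <- function(true_landmarks, digitization_noise_sd,
                                   seed = 1L) {
  lm <- as_landmarks(true_landmarks)
  if (digitization_noise_sd < 0) stop_cm("digitization noise sd must be >= 0")
  reps <- with_seed(as.integer(seed), {
    list(rep1 = lm + matrix(stats::rnorm(length(lm), 0, digitization_noise_sd),
                            nrow(lm), 3),
         rep2 = lm + matrix(stats::rnorm(length(lm), 0, digitization_noise_sd),
                            nrow(lm), 3))
  })
  reps$rep1 <- as_landmarks(reps$rep1, rownames(lm))
  reps$rep2 <- as_landmarks(reps$rep2, rownames(lm))
  reps$gold <- average_configurations(list(reps$rep1, reps$rep2))
  reps
}
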