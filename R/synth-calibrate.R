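## Landmark-level simulators for statistical calibration: cheap draws of
## whole studies directly in landmark space (no meshes), with the same
## covariance philosophy as the mesh generator -- individual biological
## variation is a low-rank random field over a fixed basis of smooth
## symmetric/asymmetric modes, plus isotropic digitization noise -- so
## type-I error and power of the downstream tests can be measured over
## hundreds of replicates.

random_rotation_matrix <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

## Symmetric/antisymmetric parts of a k x 3 perturbation under the
## canonical reflect-relabel operator.
split_symmetry <- function(P, map) {
  SP <- reflect_relabel_canonical(P, map)
  list(sym = (P + SP) / 2, asym = (P - SP) / 2)
}

unit_mode <- function(P) P / sqrt(sum(P^2))

#' Simulate a landmark-level two-group symmetry study
#'
#' Draws a study of raw landmark configurations with known symmetric and
#' asymmetric group effects: a fixed bilaterally symmetric base shape;
#' per-specimen individual variation as random loadings on \code{n_modes}
#' fixed symmetric modes (amplitude sd \code{individual_sd}) plus
#' fluctuating asymmetry on \code{n_modes} fixed asymmetric modes
#' (amplitude sd \code{fa_sd}); mutant group shifts of amplitude
#' \code{sym_effect} and \code{asym_effect} along one additional fixed
#' symmetric/asymmetric unit mode; isotropic digitization noise; and a
#' random rigid motion per specimen.
#'
#' @param n_mutant,n_wildtype group sizes.
#' @param k_pairs,k_midline bilateral pair and midline landmark counts.
#' @param individual_sd,fa_sd mode amplitude standard deviations.
#' @param sym_effect,asym_effect group-shift amplitudes (same units).
#' @param digit_sd isotropic noise sd.
#' @param n_modes modes per component.
#' @param seed integer seed.
#' @return list with \code{configs} (\code{k x 3 x n}), \code{groups}
#'   (factor), \code{map}, \code{truth} (the injected effect modes).
#' @export
simulate_symmetry_study <- function(n_mutant = 12L, n_wildtype = 14L,
                                    k_pairs = 46L, k_midline = 8L,
                                    individual_sd = 0.02, fa_sd = 0.008,
                                    sym_effect = 0, asym_effect = 0,
                                    digit_sd = 0.002, n_modes = 10L,
                                    seed = 1L) {
  k <- 2L * k_pairs + k_midline
  map <- bilateral_map(cbind(seq_len(k_pairs), k_pairs + seq_len(k_pairs)),
                       midline = if (k_midline > 0) 2L * k_pairs + seq_len(k_midline)
                                 else integer(0))
  n <- n_mutant + n_wildtype
  groups <- factor(c(rep("mutant", n_mutant), rep("wildtype", n_wildtype)),
                   levels = c("mutant", "wildtype"))
  out <- with_seed(substream_seed(seed, "base"), {
    right <- cbind(stats::runif(k_pairs, 0.2, 1.4),
                   stats::runif(k_pairs, -2.2, 2.2),
                   stats::runif(k_pairs, -1.0, 1.0))
    mid <- cbind(rep(0, k_midline), stats::runif(k_midline, -2.2, 2.2),
                 stats::runif(k_midline, -1.0, 1.0))
    base <- rbind(right, cbind(-right[, 1], right[, 2:3]), mid)
    modes_sym <- lapply(seq_len(n_modes), function(j)
      unit_mode(split_symmetry(matrix(stats::rnorm(3 * k), k, 3), map)$sym))
    modes_asym <- lapply(seq_len(n_modes), function(j)
      unit_mode(split_symmetry(matrix(stats::rnorm(3 * k), k, 3), map)$asym))
    dir_sym <- unit_mode(split_symmetry(matrix(stats::rnorm(3 * k), k, 3), map)$sym)
    dir_asym <- unit_mode(split_symmetry(matrix(stats::rnorm(3 * k), k, 3), map)$asym)
    list(base = base, modes_sym = modes_sym, modes_asym = modes_asym,
         dir_sym = dir_sym, dir_asym = dir_asym)
  })
  configs <- array(0, dim = c(k, 3, n))
  with_seed(substream_seed(seed, "specimens"), {
    for (i in seq_len(n)) {
      X <- out$base
      a <- stats::rnorm(n_modes, 0, individual_sd)
      b <- stats::rnorm(n_modes, 0, fa_sd)
      for (j in seq_len(n_modes))
        X <- X + a[j] * out$modes_sym[[j]] + b[j] * out$modes_asym[[j]]
      if (groups[i] == "mutant")
        X <- X + sym_effect * out$dir_sym + asym_effect * out$dir_asym
      X <- X + matrix(stats::rnorm(3 * k, 0, digit_sd), k, 3)
      X <- X %*% random_rotation_matrix() +
        matrix(stats::rnorm(3, 0, 1), k, 3, byrow = TRUE)
      configs[, , i] <- X
    }
  })
  list(configs = configs, groups = groups, map = map,
       truth = list(dir_sym = out$dir_sym, dir_asym = out$dir_asym,
                    sym_effect = sym_effect, asym_effect = asym_effect))
}

#' Simulate a null landmark sample (no group structure)
#'
#' Convenience wrapper over [simulate_symmetry_study()] with all group
#' effects at zero, for type-I error studies.
#'
#' @inheritParams simulate_symmetry_study
#' @return as [simulate_symmetry_study()].
#' @export
simulate_null_study <- function(n_mutant = 12L, n_wildtype = 14L,
                                k_pairs = 46L, k_midline = 8L,
                                individual_sd = 0.02, fa_sd = 0.008,
                                digit_sd = 0.002, seed = 1L) {
  simulate_symmetry_study(n_mutant, n_wildtype, k_pairs, k_midline,
                          individual_sd, fa_sd, sym_effect = 0,
                          asym_effect = 0, digit_sd = digit_sd, seed = seed)
}
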