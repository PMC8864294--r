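## Synthetic otolith fixture: six ellipsoidal labels (three bilateral pairs;
## the asteriscus pair largest) in a small isotropic grid, per-specimen true
## volumes with a multiplicative mutant effect, and per-specimen smooth
## displacement fields that carry the atlas segmentation into each
## specimen's space.

otolith_base_geometry <- function() {
  ## semi-axes (mm); asteriscus is the largest pair
  data.frame(
    name = c("lapillus_L", "lapillus_R", "sagitta_L", "sagitta_R",
             "asteriscus_L", "asteriscus_R"),
    otolith = rep(c("lapillus", "sagitta", "asteriscus"), each = 2),
    label = 1:6,
    cx = c(-0.33, 0.33, -0.35, 0.35, -0.32, 0.32),
    cy = c(0.12, 0.12, -0.02, -0.02, 0.05, 0.05),
    cz = c(0.42, 0.42, 0.02, 0.02, -0.40, -0.40),
    a = c(0.085, 0.085, 0.105, 0.105, 0.150, 0.150),
    b = c(0.070, 0.070, 0.075, 0.075, 0.120, 0.120),
    c = c(0.060, 0.060, 0.085, 0.085, 0.110, 0.110))
}

## Voxelize ellipsoids into a label grid; centers/semiaxes in a data frame.
voxelize_otoliths <- function(geom, grid_size, spacing, origin) {
  coords <- lapply(1:3, function(ax) origin[ax] + (seq_len(grid_size[ax]) - 1) * spacing[ax])
  grid <- array(0L, dim = grid_size)
  gx <- coords[[1]]; gy <- coords[[2]]; gz <- coords[[3]]
  for (r in seq_len(nrow(geom))) {
    xi <- which(abs(gx - geom$cx[r]) <= geom$a[r])
    yi <- which(abs(gy - geom$cy[r]) <= geom$b[r])
    zi <- which(abs(gz - geom$cz[r]) <= geom$c[r])
    if (!length(xi) || !length(yi) || !length(zi)) next
    sub <- expand.grid(x = gx[xi], y = gy[yi], z = gz[zi])
    inside <- ((sub$x - geom$cx[r]) / geom$a[r])^2 +
      ((sub$y - geom$cy[r]) / geom$b[r])^2 +
      ((sub$z - geom$cz[r]) / geom$c[r])^2 <= 1
    idx <- as.matrix(expand.grid(x = xi, y = yi, z = zi))[inside, , drop = FALSE]
    if (nrow(idx)) {
      lin <- (idx[, 3] - 1) * grid_size[1] * grid_size[2] +
        (idx[, 2] - 1) * grid_size[1] + idx[, 1]
      if (any(grid[lin] != 0L)) stop_cm("otolith labels overlap; widen separation")
      grid[lin] <- geom$label[r]
    }
  }
  grid
}

#' Synthetic otolith label fixture
#'
#' Builds the atlas otolith segmentation (six disjoint ellipsoidal labels:
#' bilateral lapillus, sagitta, and asteriscus pairs, spread along the
#' dorsoventral axis), draws per-specimen true otolith volumes (lognormal
#' individual variation of coefficient \code{otolith_cv}; mutant volumes
#' multiplied per-otolith by \code{otolith_volume_effect}), voxelizes each
#' specimen's "manual" segmentation, and records the per-specimen
#' deformation parameters from which [otolith_displacement_field()]
#' reconstructs the atlas-to-specimen displacement field on demand.
#'
#' @param config a [study_config()].
#' @param groups character vector of group labels per specimen.
#' @param seed integer seed.
#' @return an object of class \code{otolith_fixture}: \code{atlas_labels}
#'   (a [label_volume()]), \code{geometry} (atlas ellipsoid table),
#'   \code{specimen_geometry} (per-specimen ellipsoid tables),
#'   \code{manual_volumes} (per-specimen [label_volumes()] tables),
#'   \code{true_volumes} (analytic volumes, long data frame),
#'   \code{grid_size}, \code{spacing}, \code{origin}, \code{groups}.
#' @export
make_otolith_fixture <- function(config = study_config(), groups, seed = 1L) {
  geom <- otolith_base_geometry()
  gs <- rep(config$otolith_grid_size, 3)
  sp <- rep(config$otolith_spacing, 3)
  org <- -(gs - 1) * sp / 2
  atlas_grid <- voxelize_otoliths(geom, gs, sp, org)
  atlas_labels <- label_volume(atlas_grid, spacing = sp, origin = org)
  n <- length(groups)
  eff <- config$otolith_volume_effect
  spec_geoms <- vector("list", n)
  manual_volumes <- vector("list", n)
  true_rows <- list()
  for (i in seq_len(n)) {
    gi <- geom
    si <- with_seed(substream_seed(seed, paste0("otolith_", i)), {
      mult <- exp(stats::rnorm(nrow(geom), -config$otolith_cv^2 / 2,
                               config$otolith_cv))
      jit <- matrix(stats::rnorm(nrow(geom) * 3, 0, 0.01), ncol = 3)
      list(mult = mult, jit = jit)
    })
    if (groups[i] == "mutant") si$mult <- si$mult * eff[gi$otolith]
    s_lin <- si$mult^(1 / 3)
    gi$a <- gi$a * s_lin; gi$b <- gi$b * s_lin; gi$c <- gi$c * s_lin
    gi$cx <- gi$cx + si$jit[, 1]; gi$cy <- gi$cy + si$jit[, 2]
    gi$cz <- gi$cz + si$jit[, 3]
    spec_geoms[[i]] <- gi
    man_grid <- voxelize_otoliths(gi, gs, sp, org)
    manual_volumes[[i]] <- label_volumes(label_volume(man_grid, sp, org))
    true_rows[[i]] <- data.frame(specimen = i, label = gi$label,
                                 name = gi$name, otolith = gi$otolith,
                                 volume_mm3 = 4 / 3 * pi * gi$a * gi$b * gi$c)
  }
  structure(list(atlas_labels = atlas_labels, geometry = geom,
                 specimen_geometry = spec_geoms,
                 manual_volumes = manual_volumes,
                 true_volumes = do.call(rbind, true_rows),
                 grid_size = gs, spacing = sp, origin = org,
                 groups = groups, seed = as.integer(seed)),
            class = "otolith_fixture")
}

#' Displacement field carrying the atlas otoliths into one specimen
#'
#' Reconstructs the smooth per-specimen displacement field (subject space
#' to atlas space, the pull-back convention of [warp_labels()]): around
#' each otolith the map is locally an exact similarity taking the
#' specimen's ellipsoid back to the atlas ellipsoid, blended to zero away
#' from the otolith by a smooth window; displacement magnitudes are kept
#' small enough for positive Jacobian.
#'
#' @param fixture a [make_otolith_fixture()] result.
#' @param i specimen index.
#' @return a [displacement_field()] compatible with
#'   \code{fixture$atlas_labels}.
#' @export
otolith_displacement_field <- function(fixture, i) {
  gs <- fixture$grid_size; sp <- fixture$spacing; org <- fixture$origin
  gi <- fixture$specimen_geometry[[i]]
  g0 <- fixture$geometry
  coords <- lapply(1:3, function(ax) org[ax] + (seq_len(gs[ax]) - 1) * sp[ax])
  u <- array(0, dim = c(gs, 3))
  X <- array(rep(coords[[1]], times = gs[2] * gs[3]), dim = gs)
  Y <- array(rep(rep(coords[[2]], each = gs[1]), times = gs[3]), dim = gs)
  Z <- array(rep(coords[[3]], each = gs[1] * gs[2]), dim = gs)
  for (r in seq_len(nrow(gi))) {
    c_spec <- c(gi$cx[r], gi$cy[r], gi$cz[r])
    c_atlas <- c(g0$cx[r], g0$cy[r], g0$cz[r])
    s_lin <- gi$a[r] / g0$a[r]  # isotropic per-otolith scale
    R <- 1.25 * max(gi$a[r], gi$b[r], gi$c[r])
    tau <- 0.35 * R
    d <- sqrt((X - c_spec[1])^2 + (Y - c_spec[2])^2 + (Z - c_spec[3])^2)
    w <- ifelse(d <= R, 1, exp(-((d - R)^2) / (2 * tau^2)))
    ## atlas position for subject point x: c_atlas + (x - c_spec)/s_lin
    u[, , , 1] <- u[, , , 1] + w * (c_atlas[1] + (X - c_spec[1]) / s_lin - X)
    u[, , , 2] <- u[, , , 2] + w * (c_atlas[2] + (Y - c_spec[2]) / s_lin - Y)
    u[, , , 3] <- u[, , , 3] + w * (c_atlas[3] + (Z - c_spec[3]) / s_lin - Z)
  }
  displacement_field(u, spacing = sp, origin = org)
}

#' Simulate otolith volume tables only
#'
#' Fast path for power studies of the group comparison: draws per-specimen
#' true otolith volumes under the fixture's variation model without
#' voxelizing any grids.
#'
#' @param config a [study_config()].
#' @param groups character vector of group labels.
#' @param seed integer seed.
#' @return list of per-specimen volume tables (columns \code{label},
#'   \code{otolith}, \code{volume_mm3}), named \code{spec_<i>}.
#' @export
simulate_otolith_volumes <- function(config = study_config(), groups,
                                     seed = 1L) {
  geom <- otolith_base_geometry()
  base_vol <- 4 / 3 * pi * geom$a * geom$b * geom$c
  eff <- config$otolith_volume_effect
  out <- lapply(seq_along(groups), function(i) {
    mult <- with_seed(substream_seed(seed, paste0("otovol_", i)),
                      exp(stats::rnorm(nrow(geom), -config$otolith_cv^2 / 2,
                                       config$otolith_cv)))
    if (groups[i] == "mutant") mult <- mult * eff[geom$otolith]
    data.frame(label = geom$label, otolith = geom$otolith,
               volume_mm3 = base_vol * mult)
  })
  names(out) <- sprintf("spec_%d", seq_along(groups))
  out
}
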