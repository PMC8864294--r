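#' Label volume
#'
#' A 3D integer label grid with axis-aligned geometry: world coordinates of
#' the voxel center at (1-based) index \code{i} are
#' \code{origin + (i - 1) * spacing}.
#'
#' @param grid 3D integer array of labels (\code{>= 0}; 0 is background).
#' @param spacing per-axis voxel size (mm), all positive.
#' @param origin world coordinate of the first voxel center.
#' @return an object of class \code{label_volume}.
#' @export
label_volume <- function(grid, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(dim(grid)) != 3) stop_cm("grid must be a 3D array")
  if (any(grid < 0)) stop_cm("labels must be >= 0")
  spacing <- rep_len(as.numeric(spacing), 3)
  if (any(spacing <= 0)) stop_cm("spacing must be positive on all axes")
  storage.mode(grid) <- "integer"
  structure(list(grid = grid, spacing = spacing,
                 origin = rep_len(as.numeric(origin), 3)),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  cat("Label volume:", paste(dim(x$grid), collapse = " x "),
      "voxels | spacing", paste(signif(x$spacing, 4), collapse = " x "),
      "mm |", length(setdiff(unique(as.vector(x$grid)), 0L)), "labels\n")
  invisible(x)
}

#' Displacement field
#'
#' A voxel-wise 3-vector field (mm) on the same axis-aligned geometry as
#' [label_volume()]; dimension \code{nx x ny x nz x 3}.
#'
#' @param grid 4D numeric array, last dimension 3.
#' @param spacing,origin as in [label_volume()].
#' @return an object of class \code{displacement_field}.
#' @export
displacement_field <- function(grid, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(dim(grid)) != 4 || dim(grid)[4] != 3)
    stop_cm("grid must be an nx x ny x nz x 3 array")
  assert_finite(grid, "displacement values")
  spacing <- rep_len(as.numeric(spacing), 3)
  if (any(spacing <= 0)) stop_cm("spacing must be positive on all axes")
  structure(list(grid = grid, spacing = spacing,
                 origin = rep_len(as.numeric(origin), 3)),
            class = "displacement_field")
}

#' @export
print.displacement_field <- function(x, ...) {
  mags <- sqrt(x$grid[, , , 1]^2 + x$grid[, , , 2]^2 + x$grid[, , , 3]^2)
  cat("Displacement field:", paste(dim(x$grid)[1:3], collapse = " x "),
      "voxels | max |u| =", signif(max(mags), 4), "mm\n")
  invisible(x)
}

geometry_compatible <- function(a, b) {
  all(dim(a$grid)[1:3] == dim(b$grid)[1:3]) &&
    all(abs(a$spacing - b$spacing) < 1e-9) &&
    all(abs(a$origin - b$origin) < 1e-9)
}

#' Warp a label volume through a displacement field
#'
#' Pull-back (inverse-map) resampling with nearest-neighbor interpolation,
#' the convention used when label maps are resampled through a deformable
#' transform: for each output voxel center \code{x}, the output label is the
#' atlas label at the voxel nearest to \code{x + field(x)}. Mapped positions
#' outside the atlas grid become background (0). Continuous indices are
#' rounded to nearest with ties to even. Labels absent from the atlas are
#' never invented.
#'
#' @param atlas_labels a [label_volume()] in atlas space.
#' @param field a [displacement_field()] on the same geometry, pointing from
#'   output (subject) space into atlas space.
#' @return a [label_volume()] in subject space.
#' @export
warp_labels <- function(atlas_labels, field) {
  stopifnot(inherits(atlas_labels, "label_volume"),
            inherits(field, "displacement_field"))
  if (!geometry_compatible(atlas_labels, field))
    stop_cm("label volume and displacement field geometries do not match")
  dm <- dim(atlas_labels$grid)
  sp <- atlas_labels$spacing; or <- atlas_labels$origin
  idx <- arrayInd(seq_len(prod(dm)), dm)
  ## world position of each output voxel center, plus its displacement
  mapped_i <- (or[1] + (idx[, 1] - 1) * sp[1] + as.vector(field$grid[, , , 1]) - or[1]) / sp[1] + 1
  mapped_j <- (or[2] + (idx[, 2] - 1) * sp[2] + as.vector(field$grid[, , , 2]) - or[2]) / sp[2] + 1
  mapped_k <- (or[3] + (idx[, 3] - 1) * sp[3] + as.vector(field$grid[, , , 3]) - or[3]) / sp[3] + 1
  ii <- round(mapped_i); jj <- round(mapped_j); kk <- round(mapped_k)
  ok <- ii >= 1 & ii <= dm[1] & jj >= 1 & jj <= dm[2] & kk >= 1 & kk <= dm[3]
  out <- integer(prod(dm))
  lin <- (kk[ok] - 1) * dm[1] * dm[2] + (jj[ok] - 1) * dm[1] + ii[ok]
  out[ok] <- atlas_labels$grid[lin]
  label_volume(array(out, dm), spacing = sp, origin = or)
}

#' Per-label voxel counts and volumes
#'
#' @param labels a [label_volume()].
#' @return data frame with columns \code{label}, \code{voxels},
#'   \code{volume_mm3} (count times voxel volume); background (0) excluded.
#' @export
label_volumes <- function(labels) {
  stopifnot(inherits(labels, "label_volume"))
  tab <- table(labels$grid[labels$grid != 0L])
  vv <- prod(labels$spacing)
  data.frame(label = as.integer(names(tab)),
             voxels = as.integer(tab),
             volume_mm3 = as.integer(tab) * vv,
             row.names = NULL)
}

#' Numerically invert a displacement field
#'
#' Fixed-point iteration for the inverse of a small smooth displacement:
#' \code{v(x) = -u(x + v(x))}, with trilinear sampling of \code{u}. Used
#' for composition sanity checks of synthetic fields.
#'
#' @param field a [displacement_field()].
#' @param iterations fixed-point iterations.
#' @return a [displacement_field()] approximating the inverse map.
#' @export
invert_displacement_field <- function(field, iterations = 20L) {
  stopifnot(inherits(field, "displacement_field"))
  dm <- dim(field$grid)[1:3]
  sp <- field$spacing; or <- field$origin
  idx <- arrayInd(seq_len(prod(dm)), dm)
  pos <- cbind(or[1] + (idx[, 1] - 1) * sp[1],
               or[2] + (idx[, 2] - 1) * sp[2],
               or[3] + (idx[, 3] - 1) * sp[3])
  v <- matrix(0, nrow(pos), 3)
  for (it in seq_len(iterations)) {
    q <- pos + v
    v <- -sample_field_trilinear(field, q)
  }
  grid <- array(0, dim = c(dm, 3))
  for (c3 in 1:3) grid[, , , c3] <- array(v[, c3], dm)
  displacement_field(grid, spacing = sp, origin = or)
}

## Trilinear sampling of a displacement field at world positions (n x 3);
## clamped at the boundary.
sample_field_trilinear <- function(field, pos) {
  dm <- dim(field$grid)[1:3]
  sp <- field$spacing; or <- field$origin
  ci <- pmin(pmax((pos[, 1] - or[1]) / sp[1] + 1, 1), dm[1])
  cj <- pmin(pmax((pos[, 2] - or[2]) / sp[2] + 1, 1), dm[2])
  ck <- pmin(pmax((pos[, 3] - or[3]) / sp[3] + 1, 1), dm[3])
  i0 <- pmin(floor(ci), dm[1] - 1); j0 <- pmin(floor(cj), dm[2] - 1)
  k0 <- pmin(floor(ck), dm[3] - 1)
  fi <- ci - i0; fj <- cj - j0; fk <- ck - k0
  out <- matrix(0, nrow(pos), 3)
  n12 <- dm[1] * dm[2]
  base <- function(i, j, k) (k - 1) * n12 + (j - 1) * dm[1] + i
  for (c3 in 1:3) {
    g <- field$grid[, , , c3]
    out[, c3] <-
      g[base(i0, j0, k0)] * (1 - fi) * (1 - fj) * (1 - fk) +
      g[base(i0 + 1, j0, k0)] * fi * (1 - fj) * (1 - fk) +
      g[base(i0, j0 + 1, k0)] * (1 - fi) * fj * (1 - fk) +
      g[base(i0 + 1, j0 + 1, k0)] * fi * fj * (1 - fk) +
      g[base(i0, j0, k0 + 1)] * (1 - fi) * (1 - fj) * fk +
      g[base(i0 + 1, j0, k0 + 1)] * fi * (1 - fj) * fk +
      g[base(i0, j0 + 1, k0 + 1)] * (1 - fi) * fj * fk +
      g[base(i0 + 1, j0 + 1, k0 + 1)] * fi * fj * fk
  }
  out
}

#' Compare manual and atlas-propagated otolith volume tables
#'
#' The validation design for atlas-based segmentation: (a) an overall
#' manual-vs-automated Welch t-test pooled across labels, (b) per-label
#' manual-vs-automated Welch tests, and (c) per-label group (e.g. mutant vs
#' wild-type) Welch tests on the manual volumes.
#'
#' @param manual,automated named lists (one entry per specimen) of
#'   [label_volumes()]-style data frames with columns \code{label} and
#'   \code{volume_mm3}; specimen names and label vocabulary must match.
#' @param groups factor of group membership, one entry per specimen (same
#'   order as \code{manual}).
#' @param p_adjust multiple-testing correction applied to each family of
#'   per-label p-values (any [stats::p.adjust()] method); \code{"none"} by
#'   default.
#' @return an object of class \code{volume_report}: data frame \code{tests}
#'   with columns \code{comparison}, \code{label}, \code{t}, \code{df},
#'   \code{p}, and matrices of per-specimen volumes.
#' @export
compare_volume_tables <- function(manual, automated, groups,
                                  p_adjust = "none") {
  ids <- names(manual)
  if (is.null(ids) || is.null(names(automated)))
    stop_cm("manual and automated tables must be named by specimen id")
  missing_ids <- setdiff(ids, names(automated))
  if (length(missing_ids))
    stop_cm("specimens missing from automated tables: ",
            paste(missing_ids, collapse = ", "))
  automated <- automated[ids]
  labels <- sort(unique(manual[[1]]$label))
  vol_matrix <- function(tabs) {
    m <- vapply(tabs, function(tb) {
      v <- tb$volume_mm3[match(labels, tb$label)]
      v[is.na(v)] <- 0
      v
    }, numeric(length(labels)))
    t(m)  # specimens x labels
  }
  vm <- vol_matrix(manual); va <- vol_matrix(automated)
  colnames(vm) <- colnames(va) <- as.character(labels)
  groups <- droplevels(as.factor(groups))
  if (length(groups) != length(ids)) stop_cm("groups must have one entry per specimen")
  rows <- list()
  ov <- welch_t_test(as.vector(vm), as.vector(va))
  rows[[1]] <- data.frame(comparison = "manual_vs_automated", label = "all",
                          t = ov$statistic, df = ov$df, p = ov$p)
  for (lb in as.character(labels)) {
    tt <- welch_t_test(vm[, lb], va[, lb])
    rows[[length(rows) + 1]] <- data.frame(comparison = "manual_vs_automated",
                                           label = lb, t = tt$statistic,
                                           df = tt$df, p = tt$p)
  }
  lev <- levels(groups)
  for (lb in as.character(labels)) {
    tt <- welch_t_test(vm[groups == lev[1], lb], vm[groups == lev[2], lb])
    rows[[length(rows) + 1]] <- data.frame(
      comparison = paste0("group_", lev[1], "_vs_", lev[2], "_manual"),
      label = lb, t = tt$statistic, df = tt$df, p = tt$p)
  }
  tests <- do.call(rbind, rows)
  if (p_adjust != "none") {
    for (cmp in unique(tests$comparison)) {
      sel <- tests$comparison == cmp & tests$label != "all"
      tests$p[sel] <- stats::p.adjust(tests$p[sel], method = p_adjust)
    }
  }
  structure(list(tests = tests,
                 manual_volumes = vm, automated_volumes = va,
                 groups = groups, p_adjust = p_adjust),
            class = "volume_report")
}

#' @export
print.volume_report <- function(x, ...) {
  cat("Otolith volume comparisons\n")
  tab <- x$tests
  tab$t <- signif(tab$t, 4); tab$df <- signif(tab$df, 4); tab$p <- signif(tab$p, 4)
  print(tab, row.names = FALSE)
  invisible(x)
}
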