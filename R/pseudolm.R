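## Symmetric pseudo-landmark generation on a template mesh: surface points
## sampled on one side of the sagittal plane, mirrored across it and snapped
## back to the surface, plus points along the mesh-plane intersection, with
## the induced bilateral pairing.

## Farthest-point sampling over candidate points with a minimum-distance
## stopping radius. Deterministic given the seed (which picks the start).
farthest_point_sample <- function(pts, spacing, seed = 1L) {
  n <- nrow(pts)
  if (n == 0) return(integer(0))
  start <- with_seed(as.integer(seed), sample.int(n, 1))
  sel <- start
  mind <- sqrt(rowSums(sweep(pts, 2, pts[start, ])^2))
  repeat {
    i <- which.max(mind)
    if (mind[i] < spacing) break
    sel <- c(sel, i)
    di <- sqrt(rowSums(sweep(pts, 2, pts[i, ])^2))
    mind <- pmin(mind, di)
  }
  sel
}

## Signed distance of points to a plane.
plane_signed_distance <- function(points, plane) {
  as.vector((points - matrix(plane$origin, nrow(points), 3, byrow = TRUE)) %*%
              plane$normal)
}

#' Generate a symmetric pseudo-landmark set on a template mesh
#'
#' Samples surface points on one side of the symmetry plane by
#' farthest-point sampling at the given spacing, mirrors them across the
#' plane and snaps each mirror image to the nearest mesh vertex, and adds
#' midline points sampled from vertices on (or, failing that, projected
#' onto) the plane within a band of half-width \code{0.25 * spacing}. The
#' output carries the induced bilateral map and is a fixed point of
#' [reflect_relabel()] up to the mirror-snap error. A final symmetric
#' pruning pass enforces a minimum inter-point distance of
#' \code{0.5 * spacing}. If \code{target_count} is given, the spacing is
#' tuned by bisection until the final count is within 5\% of the target.
#'
#' @param mesh a [cm_mesh()] intersecting the plane.
#' @param plane a [symmetry_plane()]; default sagittal \code{x = 0}.
#' @param spacing target inter-point distance (mm); required unless
#'   \code{target_count} is given.
#' @param target_count optional desired number of points (both sides plus
#'   midline).
#' @param seed integer seed for the farthest-point start.
#' @return an object of class \code{pseudo_landmarks}: \code{points}
#'   (\code{k x 3}), \code{map} ([bilateral_map()]), \code{spacing},
#'   \code{plane}, \code{vertex_index} (nearest template vertex per point),
#'   \code{seed}, \code{removed_regions} (empty until filtering).
#' @export
generate_pseudo_landmarks <- function(mesh, plane = symmetry_plane(),
                                      spacing = NULL, target_count = NULL,
                                      seed = 1L) {
  stopifnot(inherits(mesh, "cm_mesh"))
  s <- plane_signed_distance(mesh$vertices, plane)
  if (min(s) > 0 || max(s) < 0) stop_cm("mesh does not intersect the symmetry plane")
  if (is.null(spacing) && is.null(target_count)) target_count <- 372L
  if (!is.null(target_count)) {
    diag_len <- bbox_diagonal(mesh$vertices)
    lo <- diag_len / 400; hi <- diag_len / 3
    best <- NULL
    for (it in 1:18) {
      mid <- sqrt(lo * hi)
      cand <- pseudo_lm_at_spacing(mesh, plane, mid, seed)
      k <- nrow(cand$points)
      if (is.null(best) ||
          abs(k - target_count) < abs(nrow(best$points) - target_count)) best <- cand
      if (abs(k - target_count) / target_count <= 0.02) break
      if (k > target_count) lo <- mid else hi <- mid
    }
    return(best)
  }
  if (spacing <= 0) stop_cm("spacing must be positive")
  pseudo_lm_at_spacing(mesh, plane, spacing, seed)
}

pseudo_lm_at_spacing <- function(mesh, plane, spacing, seed) {
  v <- mesh$vertices
  s <- plane_signed_distance(v, plane)
  band <- 0.25 * spacing
  tol_on <- 1e-9 * max(1, bbox_diagonal(v))
  side_idx <- which(s > band)
  if (length(side_idx) == 0) stop_cm("spacing too large: no off-plane vertices to sample")
  sel_side <- side_idx[farthest_point_sample(v[side_idx, , drop = FALSE],
                                             spacing, seed = seed)]
  ## mirror and snap to the nearest vertex on the far side
  mirrored <- reflect_points(v[sel_side, , drop = FALSE], plane)
  far_idx <- which(s < -band)
  if (length(far_idx) == 0) stop_cm("mesh has no vertices on the far side of the plane")
  snap <- far_idx[nearest_index(mirrored, v[far_idx, , drop = FALSE])]
  ## midline: exactly on-plane vertices when present, else band vertices
  ## projected onto the plane
  on_idx <- which(abs(s) <= tol_on)
  if (length(on_idx) > 0) {
    mid_pts <- v[on_idx, , drop = FALSE]
    mid_vidx <- on_idx
  } else {
    band_idx <- which(abs(s) <= band)
    mid_pts <- v[band_idx, , drop = FALSE] -
      plane_signed_distance(v[band_idx, , drop = FALSE], plane) %o% plane$normal
    mid_vidx <- band_idx
  }
  sel_mid <- integer(0)
  if (nrow(mid_pts) > 0)
    sel_mid <- farthest_point_sample(mid_pts, spacing,
                                     seed = substream_seed(seed, "midline"))
  n_s <- length(sel_side); n_m <- length(sel_mid)
  pts <- rbind(v[sel_side, , drop = FALSE],
               v[snap, , drop = FALSE],
               mid_pts[sel_mid, , drop = FALSE])
  vidx <- c(sel_side, snap, mid_vidx[sel_mid])
  keep <- prune_symmetric(pts, n_s, n_m, 0.5 * spacing)
  n_s2 <- sum(keep[seq_len(n_s)])
  n_m2 <- sum(keep[2 * n_s + seq_len(n_m)])
  pts <- pts[keep, , drop = FALSE]
  vidx <- vidx[keep]
  rownames(pts) <- c(sprintf("pLM_R%d", seq_len(n_s2)),
                     sprintf("pLM_L%d", seq_len(n_s2)),
                     if (n_m2 > 0) sprintf("pLM_M%d", seq_len(n_m2)))
  map <- bilateral_map(cbind(seq_len(n_s2), n_s2 + seq_len(n_s2)),
                       midline = if (n_m2 > 0) 2 * n_s2 + seq_len(n_m2)
                                 else integer(0))
  structure(list(points = as_landmarks(pts), map = map, spacing = spacing,
                 plane = plane, vertex_index = vidx, seed = as.integer(seed),
                 removed_regions = character(0)),
            class = "pseudo_landmarks")
}

## Drop points violating the minimum-distance rule while preserving the
## set's bilateral symmetry: midline offenders go singly, paired offenders
## go as a pair (later-sampled points dropped first).
prune_symmetric <- function(pts, n_s, n_m, min_dist) {
  n <- nrow(pts)
  keep <- rep(TRUE, n)
  partner <- c(n_s + seq_len(n_s), seq_len(n_s), rep(NA_integer_, n_m))
  d <- sqrt(cross_dist2(pts, pts))
  diag(d) <- Inf
  for (i in seq_len(n_s)) d[i, partner[i]] <- d[partner[i], i] <- Inf
  repeat {
    act <- which(keep)
    dd <- d[act, act, drop = FALSE]
    viol <- which(dd < min_dist, arr.ind = TRUE)
    if (nrow(viol) == 0) break
    i <- act[viol[1, 1]]; j <- act[viol[1, 2]]
    victim <- if (is.na(partner[max(i, j)])) max(i, j)
              else if (is.na(partner[min(i, j)])) min(i, j)
              else max(i, j)
    keep[victim] <- FALSE
    if (!is.na(partner[victim])) keep[partner[victim]] <- FALSE
  }
  keep
}

#' @export
print.pseudo_landmarks <- function(x, ...) {
  cat("Pseudo-landmark set:", nrow(x$points), "points (",
      nrow(x$map$pairs), "bilateral pairs,", length(x$map$midline),
      "midline ) | spacing", signif(x$spacing, 4), "mm\n")
  if (length(x$removed_regions))
    cat("  regions removed:", paste(x$removed_regions, collapse = ", "), "\n")
  invisible(x)
}

#' Remove pseudo-landmarks lying on excluded anatomical regions
#'
#' Drops every point whose nearest template vertex carries an excluded
#' region label, together with the bilateral partner of any dropped paired
#' point, so the set stays symmetric; the bilateral map is reindexed.
#'
#' @param set a [generate_pseudo_landmarks()] result.
#' @param region_labels per-vertex region labels of the template mesh
#'   (length = number of mesh vertices), or a [cm_mesh()] carrying
#'   \code{regions}.
#' @param excluded character vector of labels to remove.
#' @return the filtered \code{pseudo_landmarks} object.
#' @export
filter_points_by_region <- function(set, region_labels, excluded) {
  stopifnot(inherits(set, "pseudo_landmarks"))
  if (inherits(region_labels, "cm_mesh")) region_labels <- region_labels$regions
  region_labels <- as.character(region_labels)
  if (anyNA(region_labels)) stop_cm("region labels must cover all vertices")
  if (max(set$vertex_index) > length(region_labels))
    stop_cm("region labels must cover all vertices")
  excluded <- as.character(excluded)
  if (length(setdiff(unique(region_labels), excluded)) == 0)
    stop_cm("cannot exclude every region label")
  if (length(excluded) == 0) return(set)
  pt_region <- region_labels[set$vertex_index]
  drop <- pt_region %in% excluded
  ## symmetric closure: a dropped paired point takes its partner along
  pr <- set$map$pairs
  for (r in seq_len(nrow(pr))) {
    if (drop[pr[r, 1]] || drop[pr[r, 2]]) drop[pr[r, ]] <- TRUE
  }
  keep <- which(!drop)
  old2new <- match(seq_len(nrow(set$points)), keep)
  new_pairs <- pr[!is.na(old2new[pr[, 1]]), , drop = FALSE]
  new_pairs <- cbind(old2new[new_pairs[, 1]], old2new[new_pairs[, 2]])
  new_mid <- old2new[set$map$midline]
  new_mid <- new_mid[!is.na(new_mid)]
  set$points <- as_landmarks(set$points[keep, , drop = FALSE])
  set$vertex_index <- set$vertex_index[keep]
  set$map <- bilateral_map(new_pairs, midline = new_mid)
  set$removed_regions <- union(set$removed_regions, excluded)
  set
}
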