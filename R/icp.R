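## Rigid/similarity point-cloud registration (iterative closest point) and
## voxel-grid downsampling: the linear stage of template-to-specimen
## landmark transfer.

#' Voxel-grid downsampling of a point cloud
#'
#' One representative point (the centroid of the members) per occupied
#' voxel of a regular grid; deterministic for a given input.
#'
#' @param x a point matrix (\code{n x 3}) or a [cm_mesh()] (its vertices
#'   are used).
#' @param voxel_size edge length of the grid cells (mm), \code{> 0}.
#' @return a point matrix with at most \code{n} rows.
#' @export
downsample_cloud <- function(x, voxel_size) {
  pts <- if (inherits(x, "cm_mesh")) x$vertices else as_landmarks(x)
  if (nrow(pts) == 0) stop_cm("empty point cloud")
  if (voxel_size <= 0) stop_cm("voxel_size must be positive")
  mn <- apply(pts, 2, min)
  key <- floor(sweep(pts, 2, mn) / voxel_size)
  id <- paste(key[, 1], key[, 2], key[, 3])
  out <- rowsum(pts, id, reorder = TRUE)
  cnt <- as.vector(table(factor(id, levels = rownames(out))))
  out <- out / cnt
  rownames(out) <- NULL
  as_landmarks(out)
}

## Choose a voxel size so downsampling yields approximately target_points.
auto_voxel_size <- function(pts, target_points = 1000L) {
  if (nrow(pts) <= target_points) return(NULL)
  lo <- bbox_diagonal(pts) / 500; hi <- bbox_diagonal(pts) / 2
  for (it in 1:20) {
    mid <- sqrt(lo * hi)
    n <- nrow(downsample_cloud(pts, mid))
    if (abs(n - target_points) / target_points < 0.1) return(mid)
    if (n > target_points) lo <- mid else hi <- mid
  }
  mid
}

#' Similarity transform
#'
#' Rotation (proper), optional uniform scale, and translation; maps a point
#' row-vector \code{p} to \code{scale * p \%*\% rotation + translation}.
#'
#' @param rotation 3x3 proper rotation matrix.
#' @param scale positive scalar.
#' @param translation length-3 vector.
#' @return an object of class \code{similarity_transform}.
#' @export
similarity_transform <- function(rotation = diag(3), scale = 1,
                                 translation = c(0, 0, 0)) {
  structure(list(rotation = rotation, scale = scale,
                 translation = as.numeric(translation)),
            class = "similarity_transform")
}

#' Apply a similarity transform to points
#'
#' @param transform a [similarity_transform()].
#' @param points an \code{n x 3} matrix.
#' @return the transformed \code{n x 3} matrix.
#' @export
apply_transform <- function(transform, points) {
  points <- as_landmarks(points)
  out <- transform$scale * points %*% transform$rotation +
    matrix(transform$translation, nrow(points), 3, byrow = TRUE)
  dimnames(out) <- dimnames(points)
  out
}

#' @export
print.similarity_transform <- function(x, ...) {
  ang <- acos(pmin(pmax((sum(diag(x$rotation)) - 1) / 2, -1), 1)) * 180 / pi
  cat(sprintf("Similarity transform: rotation %.2f deg, scale %.6g, |t| = %.4g\n",
              ang, x$scale, sqrt(sum(x$translation^2))))
  invisible(x)
}

## Closed-form similarity fit (Horn/Umeyama) for matched point sets; proper
## rotation enforced.
fit_similarity <- function(source, target, allow_scaling = FALSE) {
  mu_s <- colMeans(source); mu_t <- colMeans(target)
  X <- sweep(source, 2, mu_s); Y <- sweep(target, 2, mu_t)
  R <- optimal_rotation(X, Y)
  s <- if (allow_scaling) sum((X %*% R) * Y) / sum(X * X) else 1
  similarity_transform(R, s, mu_t - s * as.numeric(mu_s %*% R))
}

#' Rigid (or similarity) alignment of point clouds by ICP
#'
#' Iterative closest point: alternates nearest-neighbor correspondence from
#' source to target with a closed-form rigid (optionally similarity) fit.
#' The matching cost (mean squared nearest-neighbor distance) is monotone
#' non-increasing within a run. Scaling defaults to off, the appropriate
#' choice when specimens are of similar size.
#'
#' Initialization works in two steps. A coarse pass (centroid shift, no
#' rotation) assumes the clouds are roughly pre-aligned — the usual
#' situation for specimens reconstructed in a common anatomical
#' orientation, and the only reliable way to pick among the four
#' 180-degree impostor alignments that bilaterally and fore-aft
#' pseudo-symmetric anatomy admits (feature-based global registration is
#' deliberately out of scope). The coarse result then only selects which of
#' the four canonical principal-axes relative orientations to start from,
#' and the final ICP runs from that canonical start. Because the canonical
#' start is a function of each cloud's own geometry, the final alignment is
#' equivariant under rigid motions of either cloud (exactly, as long as the
#' motion does not flip the discrete branch selection).
#'
#' @param source,target point matrices (\code{>= 3} points each) or
#'   [cm_mesh()] objects.
#' @param allow_scaling estimate a uniform scale factor.
#' @param max_iter iteration cap per start.
#' @param tol relative cost-change convergence tolerance.
#' @return an object of class \code{icp_fit}: the final
#'   \code{similarity_transform} plus \code{cost} (per-iteration costs of
#'   the winning start), \code{converged}, \code{aligned} (transformed
#'   source).
#' @export
rigid_align <- function(source, target, allow_scaling = FALSE,
                        max_iter = 50L, tol = 1e-8) {
  src <- if (inherits(source, "cm_mesh")) source$vertices else as_landmarks(source)
  tgt <- if (inherits(target, "cm_mesh")) target$vertices else as_landmarks(target)
  if (nrow(src) < 3 || nrow(tgt) < 3) stop_cm("ICP needs at least 3 points per cloud")
  mu_s <- colMeans(src); mu_t <- colMeans(tgt)
  icp_from <- function(cur0, tf0) {
    cur <- cur0; tf <- tf0
    costs <- numeric(0)
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      nn <- nearest_index(cur, tgt)
      step <- fit_similarity(src, tgt[nn, , drop = FALSE], allow_scaling)
      cur <- apply_transform(step, src)
      cost <- mean(rowSums((cur - tgt[nn, , drop = FALSE])^2))
      costs <- c(costs, cost)
      tf <- step
      if (it > 1 && abs(costs[it - 1] - cost) <= tol * max(cost, 1e-300)) {
        converged <- TRUE
        break
      }
    }
    c(tf, list(cost = costs, converged = converged, aligned = cur))
  }
  ## coarse pass: centroid shift only, to identify the symmetry branch
  coarse <- icp_from(sweep(src, 2, mu_s - mu_t),
                     similarity_transform(diag(3), 1, mu_t - mu_s))
  ## canonical principal-axes starts (all four proper sign combinations)
  Vs <- principal_axis_rotation(sweep(src, 2, mu_s))
  Vt <- principal_axis_rotation(sweep(tgt, 2, mu_t))
  flips <- list(c(1, 1, 1), c(-1, -1, 1), c(-1, 1, -1), c(1, -1, -1))
  R0s <- lapply(flips, function(fl) Vs %*% diag(fl) %*% t(Vt))
  pick <- which.min(vapply(R0s, function(R0)
    sum((R0 - coarse$rotation)^2), 0))
  R0 <- R0s[[pick]]
  best <- icp_from(sweep(src, 2, mu_s) %*% R0 +
                     matrix(mu_t, nrow(src), 3, byrow = TRUE),
                   similarity_transform(R0, 1, mu_t - as.numeric(mu_s %*% R0)))
  structure(best, class = c("icp_fit", "similarity_transform"))
}
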