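## Object-symmetry analysis: decompose superimposed shapes into symmetric and
## asymmetric components via the reflected-relabeled double of the sample.

## Mirror across x = 0 and relabel: the canonical in-shape-space reflection
## operator once the symmetry plane has been standardized to x = 0.
reflect_relabel_canonical <- function(X, map) {
  X[, 1] <- -X[, 1]
  X[relabel_permutation(map), , drop = FALSE]
}

## Best improper orthogonal Q minimizing || (P C) Q - C ||_F.
improper_opa_rotation <- function(Cperm, C) {
  M <- crossprod(Cperm, C)
  s <- svd(M)
  d <- -sign(det(s$u %*% t(s$v)))
  if (d == 0) d <- -1
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

## Rotate the joint-GPA frame so that the consensus' symmetry plane is x = 0,
## with a deterministic in-plane orientation and left/right sign convention.
## Returns the proper rotation (to be applied on the right of row-point
## matrices).
symmetry_frame_rotation <- function(C, map) {
  Q <- improper_opa_rotation(C[relabel_permutation(map), , drop = FALSE], C)
  e <- eigen((Q + t(Q)) / 2, symmetric = TRUE)
  w <- e$vectors[, which.min(e$values)]
  tb <- tangent_basis_from_normal(w)
  G <- cbind(w, tb$u, tb$v)
  C1 <- C %*% G
  ## symmetrized consensus in this frame
  Cs <- (C1 + reflect_relabel_canonical(C1, map)) / 2
  ## left/right sign: the first off-plane paired landmark gets x >= 0
  if (nrow(map$pairs) > 0) {
    xs <- Cs[map$pairs[, 1], 1]
    ref <- which(abs(xs) > 1e-8 * max(1, max(abs(Cs))))[1]
    if (!is.na(ref) && xs[ref] < 0) G <- G %*% diag(c(-1, 1, -1))
  }
  C1 <- C %*% G
  Cs <- (C1 + reflect_relabel_canonical(C1, map)) / 2
  ## in-plane principal axes (proper 2D rotation); the first axis sign is
  ## fixed by the third moment of the projected coordinates, which does not
  ## depend on the incoming frame
  A <- crossprod(Cs[, 2:3, drop = FALSE])
  e2 <- eigen(A, symmetric = TRUE)
  v1 <- e2$vectors[, 1]
  proj <- as.vector(Cs[, 2:3, drop = FALSE] %*% v1)
  s <- sum(proj^3)
  if (abs(s) < 1e-12 * max(abs(proj), 1e-300)^3) s <- proj[which.max(abs(proj))]
  if (s < 0) v1 <- -v1
  V2 <- cbind(v1, c(-v1[2], v1[1]))
  G %*% rbind(c(1, 0, 0), cbind(0, V2))
}

#' Bilateral object-symmetry decomposition
#'
#' Splits each configuration of a sample into a symmetric and an asymmetric
#' shape component. Each specimen is paired with its reflected-relabeled
#' copy, a joint GPA is run on all \code{2n} configurations, the shared
#' frame is rotated so the consensus symmetry plane is exactly \code{x = 0},
#' and each aligned specimen \code{a} is decomposed as
#' \code{symmetric = (a + S(a))/2}, \code{asymmetric = (a - S(a))/2}, where
#' \code{S} is reflection-relabeling in the standardized frame. By
#' construction \code{symmetric + asymmetric} reconstructs the aligned
#' specimen exactly, symmetric components are themselves plane-symmetric,
#' and the two components live in orthogonal subspaces.
#'
#' The mean of the asymmetric components is the directional asymmetry of the
#' sample; individual deviations from it are fluctuating asymmetry (see
#' [fluctuating_asymmetry_scores()]).
#'
#' @param configs list of landmark configurations or \code{k x 3 x n} array
#'   (raw or previously superimposed coordinates), \code{n >= 2}.
#' @param map a [bilateral_map()] covering all landmarks.
#' @param plane the [symmetry_plane()] of the raw coordinates (used only to
#'   build the reflected copies; the output frame is standardized to
#'   \code{x = 0}).
#' @param scale passed to the joint GPA; \code{TRUE} scales all copies to
#'   unit centroid size.
#' @param tol,max_iterations GPA controls.
#' @return an object of class \code{bilat_symmetry} with elements
#'   \code{aligned}, \code{symmetric}, \code{asymmetric} (\code{k x 3 x n}
#'   arrays), \code{directional_asymmetry} (\code{k x 3}),
#'   \code{consensus} (the symmetric consensus), \code{centroid_sizes},
#'   \code{map}, \code{scale}, \code{converged}.
#' @export
decompose_object_symmetry <- function(configs, map, plane = symmetry_plane(),
                                      scale = TRUE, tol = 1e-12,
                                      max_iterations = 200L) {
  arr <- as_landmark_array(configs)
  k <- dim(arr)[1]; n <- dim(arr)[3]
  if (n < 2) stop_cm("symmetry decomposition needs at least 2 specimens")
  if (!inherits(map, "bilateral_map")) stop_cm("map must be a bilateral_map")
  if (map$k != k) stop_cm("bilateral map does not cover all ", k, " landmarks")
  double <- array(0, dim = c(k, 3, 2L * n))
  cs <- numeric(n)
  for (i in seq_len(n)) {
    X <- arr[, , i]
    cs[i] <- centroid_size(X)
    if (cs[i] <= 0) stop_cm("degenerate configuration ", i)
    double[, , i] <- X
    double[, , n + i] <- reflect_relabel(X, map, plane)
  }
  for (j in seq_len(2L * n)) {
    Xj <- sweep(double[, , j], 2, colMeans(double[, , j]))
    if (scale) Xj <- Xj / sqrt(sum(Xj^2))
    double[, , j] <- Xj
  }
  fit <- gpa_iterate(double, tol = tol, max_iterations = max_iterations,
                     scale = scale)
  G <- symmetry_frame_rotation(fit$consensus, map)
  C1 <- fit$consensus %*% G
  Cs <- (C1 + reflect_relabel_canonical(C1, map)) / 2
  aligned <- array(0, dim = c(k, 3, n), dimnames = dimnames(arr))
  symmetric <- aligned; asymmetric <- aligned
  for (i in seq_len(n)) {
    a <- fit$arr[, , i] %*% G
    a <- a %*% optimal_rotation(a, Cs)
    b <- reflect_relabel_canonical(a, map)
    aligned[, , i] <- a
    symmetric[, , i] <- (a + b) / 2
    asymmetric[, , i] <- (a - b) / 2
  }
  da <- apply(asymmetric, c(1, 2), mean)
  dimnames(da) <- dimnames(arr)[1:2]
  structure(list(aligned = aligned, symmetric = symmetric,
                 asymmetric = asymmetric,
                 directional_asymmetry = da,
                 consensus = as_landmarks(Cs),
                 centroid_sizes = cs, map = map, scale = scale,
                 converged = fit$converged, n = n, k = k),
            class = "bilat_symmetry")
}

#' Fluctuating-asymmetry scores
#'
#' Per-specimen Procrustes norm of the deviation of the asymmetric component
#' from the sample's directional asymmetry: the individual degree of
#' fluctuating asymmetry.
#'
#' @param result a [decompose_object_symmetry()] result.
#' @return numeric vector of \code{n} non-negative scores.
#' @export
fluctuating_asymmetry_scores <- function(result) {
  stopifnot(inherits(result, "bilat_symmetry"))
  vapply(seq_len(result$n), function(i)
    sqrt(sum((result$asymmetric[, , i] - result$directional_asymmetry)^2)), 0)
}

#' Per-landmark asymmetry magnitudes
#'
#' Mean (across specimens) Euclidean magnitude of the asymmetric component at
#' each landmark; a scalar field suitable for surface heat maps.
#'
#' @param result a [decompose_object_symmetry()] result.
#' @return numeric vector of length \code{k}.
#' @export
asymmetry_field <- function(result) {
  stopifnot(inherits(result, "bilat_symmetry"))
  rowMeans(vapply(seq_len(result$n),
                  function(i) row_norms(result$asymmetric[, , i]),
                  numeric(result$k)))
}

#' @export
print.bilat_symmetry <- function(x, ...) {
  fa <- fluctuating_asymmetry_scores(x)
  cat("Bilateral object-symmetry decomposition\n")
  cat("  specimens:", x$n, "  landmarks:", x$k,
      "(", nrow(x$map$pairs), "pairs,", length(x$map$midline), "midline )\n")
  cat("  directional asymmetry norm:",
      signif(sqrt(sum(x$directional_asymmetry^2)), 4), "\n")
  cat("  fluctuating asymmetry: mean", signif(mean(fa), 4),
      " range [", signif(min(fa), 4), ",", signif(max(fa), 4), "]\n")
  invisible(x)
}
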