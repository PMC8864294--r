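#' Sliding semilandmark specification
#'
#' Controls the sliding step of [run_gpa()]. Surface semilandmarks carry no
#' point-to-point homology along the surface, so during superimposition they
#' are allowed to slide within their local tangent planes to minimize either
#' the thin-plate-spline bending energy against the consensus (the usual
#' choice for surface points) or the summed squared distance to the
#' consensus.
#'
#' @param semilandmark_indices integer indices (1-based) of landmarks allowed
#'   to slide.
#' @param mode \code{"bending_energy"} or \code{"procrustes_distance"}.
#' @param surface_neighbors number of nearest semilandmarks used to estimate
#'   a tangent plane when no surface normals are supplied; must be >= 3.
#' @param max_sliding_iterations number of slide-then-resuperimpose rounds.
#' @return an object of class \code{sliding_spec}.
#' @export
sliding_spec <- function(semilandmark_indices,
                         mode = c("bending_energy", "procrustes_distance"),
                         surface_neighbors = 8L,
                         max_sliding_iterations = 3L) {
  mode <- match.arg(mode)
  semilandmark_indices <- sort(unique(as.integer(semilandmark_indices)))
  if (surface_neighbors < 3) stop_cm("tangent estimation needs at least 3 neighbors")
  structure(list(semilandmark_indices = semilandmark_indices, mode = mode,
                 surface_neighbors = as.integer(surface_neighbors),
                 max_sliding_iterations = as.integer(max_sliding_iterations)),
            class = "sliding_spec")
}

## One plain GPA pass on a k x 3 x n array of centered (and, if scale, unit-CS)
## configurations. Returns aligned array, consensus and iteration info.
## With scale = TRUE each configuration is renormalized to unit centroid size
## every iteration (a no-op unless a sliding step changed sizes).
gpa_iterate <- function(arr, tol = 1e-10, max_iterations = 100L, scale = FALSE,
                        init_index = 1L) {
  n <- dim(arr)[3]
  consensus <- arr[, , init_index]
  ss_old <- Inf
  converged <- FALSE
  it <- 0L
  repeat {
    it <- it + 1L
    for (i in seq_len(n)) {
      Xi <- sweep(arr[, , i], 2, colMeans(arr[, , i]))
      if (scale) Xi <- Xi / sqrt(sum(Xi^2))
      R <- optimal_rotation(Xi, consensus)
      arr[, , i] <- Xi %*% R
    }
    consensus <- apply(arr, c(1, 2), mean)
    ss <- 0
    for (i in seq_len(n)) ss <- ss + sum((arr[, , i] - consensus)^2)
    if (is.finite(ss_old) && abs(ss_old - ss) <= tol * max(ss, .Machine$double.eps)) {
      converged <- TRUE
      break
    }
    if (it >= max_iterations) break
    ss_old <- ss
  }
  list(arr = arr, consensus = consensus, ss = ss, iterations = it,
       converged = converged)
}

## Deterministic orientation: rotate so the consensus principal axes align
## with the coordinate axes. Axis signs are fixed by the third moment of the
## projected coordinates (a rotation-invariant statistic of the shape, so
## the result does not depend on the incoming frame), falling back to the
## largest-magnitude projection when the moment vanishes.
principal_axis_rotation <- function(consensus) {
  e <- eigen(crossprod(consensus), symmetric = TRUE)
  V <- e$vectors
  for (j in 1:2) {
    proj <- as.vector(consensus %*% V[, j])
    s <- sum(proj^3)
    if (abs(s) < 1e-12 * max(abs(proj), 1e-300)^3)
      s <- proj[which.max(abs(proj))]
    if (s < 0) V[, j] <- -V[, j]
  }
  V[, 3] <- c(V[2, 1] * V[3, 2] - V[3, 1] * V[2, 2],
              V[3, 1] * V[1, 2] - V[1, 1] * V[3, 2],
              V[1, 1] * V[2, 2] - V[2, 1] * V[1, 2])
  V
}

#' Generalized Procrustes analysis
#'
#' Iterative superimposition of a sample of configurations: every
#' configuration is centered, optionally scaled to unit centroid size,
#' rotated to the running consensus, and the consensus re-estimated, until
#' the total Procrustes sum of squares stabilizes. If \code{sliding} is
#' given, a semilandmark sliding step is interleaved after each convergence
#' of the plain GPA and the GPA re-run, for
#' \code{sliding$max_sliding_iterations} rounds.
#'
#' @param configs a list of landmark configurations or a \code{k x 3 x n}
#'   array, \code{n >= 2}, all with positive centroid size.
#' @param scale if \code{TRUE} (default), configurations are scaled to unit
#'   centroid size (full Procrustes superimposition).
#' @param sliding optional [sliding_spec()].
#' @param surfaces optional per-specimen surface information for tangent
#'   planes during sliding: a list of \code{k x 3} unit normal matrices
#'   (rows for non-sliding landmarks are ignored). When \code{NULL}, tangent
#'   planes are estimated from the \code{surface_neighbors} nearest
#'   semilandmarks of the same specimen.
#' @param tol relative convergence tolerance on the total Procrustes sum of
#'   squares.
#' @param max_iterations iteration cap for each GPA pass.
#' @param n_inits number of consensus initializations tried (the first
#'   \code{n_inits} configurations each serve once); the fit with the
#'   lowest total Procrustes sum of squares is kept. The default single
#'   initialization is standard and sufficient for samples of similar
#'   shapes; heterogeneous samples can have local optima worth escaping.
#' @return an object of class \code{gpa} with elements \code{aligned}
#'   (\code{k x 3 x n} array), \code{consensus}, \code{centroid_sizes},
#'   \code{iterations}, \code{converged}, \code{scale}, \code{sliding},
#'   and \code{sliding_objective} (per-round objective values when sliding).
#' @export
run_gpa <- function(configs, scale = TRUE, sliding = NULL, surfaces = NULL,
                    tol = 1e-10, max_iterations = 100L, n_inits = 1L) {
  arr <- as_landmark_array(configs)
  k <- dim(arr)[1]; n <- dim(arr)[3]
  if (n < 2) stop_cm("GPA needs at least 2 configurations")
  if (k < 3) stop_cm("GPA needs k >= 3 landmarks")
  cs <- numeric(n)
  for (i in seq_len(n)) {
    cs[i] <- centroid_size(arr[, , i])
    if (cs[i] <= 0) stop_cm("degenerate configuration ", i, ": centroid size is zero")
    arr[, , i] <- sweep(arr[, , i], 2, colMeans(arr[, , i]))
    if (scale) arr[, , i] <- arr[, , i] / cs[i]
  }
  fit <- NULL
  for (init in seq_len(max(1L, min(n_inits, n)))) {
    cand <- gpa_iterate(arr, tol = tol, max_iterations = max_iterations,
                        scale = scale, init_index = init)
    if (is.null(fit) || cand$ss < fit$ss) fit <- cand
  }
  total_it <- fit$iterations
  objective <- numeric(0)
  if (!is.null(sliding) && length(sliding$semilandmark_indices) > 0) {
    if (!inherits(sliding, "sliding_spec")) stop_cm("sliding must be a sliding_spec")
    for (round in seq_len(sliding$max_sliding_iterations)) {
      fit$arr <- slide_pass(fit$arr, fit$consensus, sliding, surfaces)
      objective <- c(objective, sliding_objective(fit$arr, sliding))
      fit <- gpa_iterate(fit$arr, tol = tol, max_iterations = max_iterations,
                         scale = scale)
      total_it <- total_it + fit$iterations
    }
  }
  V <- principal_axis_rotation(fit$consensus)
  for (i in seq_len(n)) fit$arr[, , i] <- fit$arr[, , i] %*% V
  consensus <- fit$consensus %*% V
  dimnames(consensus) <- dimnames(arr)[1:2]
  structure(list(aligned = fit$arr, consensus = as_landmarks(consensus),
                 centroid_sizes = cs, iterations = total_it,
                 converged = fit$converged, scale = scale,
                 sliding = sliding, sliding_objective = objective,
                 n = n, k = k),
            class = "gpa")
}

## Total objective of the current alignment under a sliding spec: bending
## energy against the consensus, or total squared distance to the consensus.
sliding_objective <- function(arr, spec) {
  consensus <- apply(arr, c(1, 2), mean)
  n <- dim(arr)[3]
  if (spec$mode == "procrustes_distance") {
    s <- 0
    for (i in seq_len(n)) s <- s + sum((arr[, , i] - consensus)^2)
    return(s)
  }
  E <- bending_energy_matrix(consensus)
  s <- 0
  for (i in seq_len(n)) {
    R <- arr[, , i] - consensus
    s <- s + sum(R * (E %*% R))
  }
  s
}

#' Thin-plate-spline bending energy matrix
#'
#' The \code{k x k} bending energy matrix of a 3D thin-plate spline anchored
#' on the given reference configuration, using the kernel \code{U(r) = -r}:
#' the upper-left block of the inverse of the bordered TPS system matrix.
#'
#' @param reference a \code{k x 3} configuration (typically the consensus).
#' @return a symmetric \code{k x k} matrix, positive semidefinite on the
#'   subspace orthogonal to affine functions of the reference.
#' @export
bending_energy_matrix <- function(reference) {
  reference <- as_landmarks(reference)
  k <- nrow(reference)
  K <- -sqrt(cross_dist2(reference, reference))
  Q <- cbind(1, reference)
  L <- rbind(cbind(K, Q), cbind(t(Q), matrix(0, 4, 4)))
  Li <- solve(L)
  E <- Li[seq_len(k), seq_len(k), drop = FALSE]
  (E + t(E)) / 2
}

## Orthonormal tangent basis (two 3-vectors) perpendicular to a unit normal.
tangent_basis_from_normal <- function(nrm) {
  a <- if (abs(nrm[1]) <= abs(nrm[2]) && abs(nrm[1]) <= abs(nrm[3]))
    c(1, 0, 0) else if (abs(nrm[2]) <= abs(nrm[3])) c(0, 1, 0) else c(0, 0, 1)
  u <- c(nrm[2] * a[3] - nrm[3] * a[2],
         nrm[3] * a[1] - nrm[1] * a[3],
         nrm[1] * a[2] - nrm[2] * a[1])
  u <- u / sqrt(sum(u^2))
  v <- c(nrm[2] * u[3] - nrm[3] * u[2],
         nrm[3] * u[1] - nrm[1] * u[3],
         nrm[1] * u[2] - nrm[2] * u[1])
  list(u = u, v = v)
}

## Tangent bases for the sliding landmarks of one configuration. Either from
## supplied unit normals (k x 3) or by local plane fit to the nearest
## semilandmarks.
tangent_bases <- function(config, spec, normals = NULL) {
  idx <- spec$semilandmark_indices
  U <- matrix(0, length(idx), 3); V <- matrix(0, length(idx), 3)
  if (!is.null(normals)) {
    for (j in seq_along(idx)) {
      nrm <- normals[idx[j], ]
      nn <- sqrt(sum(nrm^2))
      if (nn < 1e-12) stop_cm("zero surface normal for sliding landmark ", idx[j])
      b <- tangent_basis_from_normal(nrm / nn)
      U[j, ] <- b$u; V[j, ] <- b$v
    }
    return(list(u = U, v = V))
  }
  semis <- config[idx, , drop = FALSE]
  if (nrow(semis) < spec$surface_neighbors + 1)
    stop_cm("not enough semilandmarks (", nrow(semis),
            ") for tangent estimation with ", spec$surface_neighbors, " neighbors")
  d2 <- cross_dist2(semis, semis)
  for (j in seq_along(idx)) {
    nb <- order(d2[j, ])[seq_len(spec$surface_neighbors + 1)]
    P <- semis[nb, , drop = FALSE]
    P <- sweep(P, 2, colMeans(P))
    e <- eigen(crossprod(P), symmetric = TRUE)
    b <- tangent_basis_from_normal(e$vectors[, 3])
    U[j, ] <- b$u; V[j, ] <- b$v
  }
  list(u = U, v = V)
}

## One sliding pass over all specimens against the current consensus.
slide_pass <- function(arr, consensus, spec, surfaces = NULL) {
  idx <- spec$semilandmark_indices
  k <- dim(arr)[1]; n <- dim(arr)[3]
  if (any(idx < 1 | idx > k)) stop_cm("semilandmark indices out of range")
  E <- if (spec$mode == "bending_energy") bending_energy_matrix(consensus) else diag(k)
  Ess <- E[idx, idx, drop = FALSE]
  for (i in seq_len(n)) {
    X <- arr[, , i]
    tb <- tangent_bases(X, spec, normals = if (!is.null(surfaces)) surfaces[[i]] else NULL)
    R <- X - consensus
    ER <- E %*% R
    g <- c(rowSums(tb$u * ER[idx, , drop = FALSE]),
           rowSums(tb$v * ER[idx, , drop = FALSE]))
    Guu <- tcrossprod(tb$u); Guv <- tb$u %*% t(tb$v); Gvv <- tcrossprod(tb$v)
    H <- rbind(cbind(Ess * Guu, Ess * Guv),
               cbind(Ess * t(Guv), Ess * Gvv))
    ridge <- 1e-10 * max(abs(diag(H)), 1e-12)
    t_par <- tryCatch(solve(H + ridge * diag(nrow(H)), -g),
                      error = function(e) rep(0, length(g)))
    m <- length(idx)
    disp <- t_par[seq_len(m)] * tb$u + t_par[m + seq_len(m)] * tb$v
    X[idx, ] <- X[idx, ] + disp
    arr[, , i] <- X
  }
  arr
}

#' Slide semilandmarks of a superimposed sample
#'
#' Applies one round of tangent-plane semilandmark sliding to an existing
#' [run_gpa()] result (each semilandmark of each specimen is displaced only
#' within its local tangent plane, minimizing the spec's objective against
#' the current consensus) and then re-runs the plain GPA. Usually invoked
#' through \code{run_gpa(..., sliding = )}; exposed for step-wise use.
#'
#' @param result a \code{gpa} object.
#' @param spec a [sliding_spec()].
#' @param surfaces optional per-specimen \code{k x 3} unit-normal matrices;
#'   see [run_gpa()].
#' @return an updated \code{gpa} object; \code{sliding_objective} gains one
#'   entry (objective value immediately after the sliding displacement).
#' @export
slide_semilandmarks <- function(result, spec, surfaces = NULL) {
  stopifnot(inherits(result, "gpa"), inherits(spec, "sliding_spec"))
  arr <- slide_pass(result$aligned, result$consensus, spec, surfaces)
  obj <- sliding_objective(arr, spec)
  fit <- gpa_iterate(arr, scale = result$scale)
  V <- principal_axis_rotation(fit$consensus)
  for (i in seq_len(dim(arr)[3])) fit$arr[, , i] <- fit$arr[, , i] %*% V
  result$aligned <- fit$arr
  result$consensus <- as_landmarks(fit$consensus %*% V)
  result$iterations <- result$iterations + fit$iterations
  result$converged <- fit$converged
  result$sliding <- spec
  result$sliding_objective <- c(result$sliding_objective, obj)
  result
}

#' @export
print.gpa <- function(x, ...) {
  cat("Generalized Procrustes analysis\n")
  cat("  specimens:", x$n, "  landmarks:", x$k,
      "  scaling:", if (x$scale) "on" else "off", "\n")
  cat("  iterations:", x$iterations,
      "  converged:", x$converged, "\n")
  if (!is.null(x$sliding))
    cat("  sliding:", length(x$sliding$semilandmark_indices), "semilandmarks, mode",
        x$sliding$mode, "(", x$sliding$max_sliding_iterations, "rounds )\n")
  invisible(x)
}

#' @export
summary.gpa <- function(object, ...) {
  d <- vapply(seq_len(object$n), function(i)
    sqrt(sum((object$aligned[, , i] - object$consensus)^2)), 0)
  cat("GPA summary:", object$n, "specimens,", object$k, "landmarks\n")
  cat("  centroid size: mean", signif(mean(object$centroid_sizes), 6),
      " range [", signif(min(object$centroid_sizes), 6), ",",
      signif(max(object$centroid_sizes), 6), "]\n")
  cat("  Procrustes distance to consensus: mean", signif(mean(d), 6),
      " max", signif(max(d), 6), "\n")
  invisible(list(distances = d, centroid_sizes = object$centroid_sizes))
}

#' @export
residuals.gpa <- function(object, ...) {
  sweep(object$aligned, c(1, 2), object$consensus)
}

#' Extract aligned coordinates
#'
#' @param object a \code{gpa} object.
#' @param ... unused.
#' @return the \code{k x 3 x n} array of superimposed coordinates.
#' @export
coef.gpa <- function(object, ...) object$aligned
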