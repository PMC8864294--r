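## Deformable point-set registration by coherent point drift (CPD): the
## source cloud is a Gaussian mixture whose centroids move coherently,
## displacement expressed as a Gaussian-kernel expansion over the source
## points. Supplies the non-rigid stage of template-to-specimen landmark
## transfer.

## Gaussian kernel matrix between point sets: G_ij = exp(-||a_i-b_j||^2/(2 beta^2)).
gaussian_kernel <- function(a, b, beta) {
  exp(-cross_dist2(a, b) / (2 * beta^2))
}

#' Fit a coherent-point-drift deformable registration
#'
#' Expectation-maximization over Gaussian-mixture correspondences between a
#' moving \code{source} cloud and a fixed \code{target} cloud. The fitted
#' map is \code{T(y) = y + G(y, source) \%*\% W} with Gaussian kernel width
#' \code{beta}; \code{lambda} penalizes non-smooth displacement and \code{w}
#' is the uniform outlier weight. \code{sigma2} (the mixture variance) is
#' driven down the EM iterations; the fit stops when its relative change
#' drops below \code{tol}, at \code{max_iter}, or when \code{sigma2}
#' collapses to the machine guard (flagged).
#'
#' @param source \code{m x 3} moving cloud (\code{m >= 4}), e.g. the
#'   rigidly aligned template cloud.
#' @param target \code{q x 3} fixed cloud (\code{q >= 4}).
#' @param beta Gaussian kernel width (mm), \code{> 0}.
#' @param lambda regularization weight, \code{> 0}.
#' @param w outlier weight in \code{[0, 1)}.
#' @param max_iter,tol EM controls.
#' @return an object of class \code{cpd_model}: \code{source_points},
#'   \code{weights} (\code{m x 3}), \code{beta}, \code{lambda}, \code{w},
#'   \code{sigma2} (final), \code{sigma2_path}, \code{iterations},
#'   \code{converged}, \code{collapsed}.
#' @export
cpd_deformable <- function(source, target, beta, lambda = 2, w = 0.1,
                           max_iter = 50L, tol = 1e-5) {
  Y <- as_landmarks(source); X <- as_landmarks(target)
  m <- nrow(Y); q <- nrow(X)
  if (m < 4 || q < 4) stop_cm("CPD needs at least 4 points per cloud")
  if (beta <= 0 || lambda <= 0) stop_cm("beta and lambda must be positive")
  if (w < 0 || w >= 1) stop_cm("outlier weight w must be in [0, 1)")
  D <- 3
  G <- gaussian_kernel(Y, Y, beta)
  W <- matrix(0, m, D)
  TY <- Y
  sigma2 <- sum(cross_dist2(X, Y)) / (D * m * q)
  ## variance floor relative to the target spread: below this the mixture
  ## is effectively a point match and further EM steps only lose numerical
  ## conditioning (the M-step ridge lambda*sigma^2 vanishes)
  floor2 <- 1e-9 * mean(rowSums(sweep(X, 2, colMeans(X))^2))
  sigma2_path <- numeric(0)
  converged <- FALSE; collapsed <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    ## E-step: posterior correspondence probabilities P (m x q)
    d2 <- cross_dist2(TY, X)
    num <- exp(-d2 / (2 * sigma2))
    c_out <- (2 * pi * sigma2)^(D / 2) * w / (1 - w) * m / q
    den <- colSums(num) + c_out
    P <- sweep(num, 2, den, "/")
    P1 <- rowSums(P)
    Np <- sum(P1)
    PX <- P %*% X
    ## M-step: smooth displacement weights
    dP1 <- pmax(P1, 1e-12)
    A <- G + lambda * sigma2 * diag(1 / dP1)
    B <- PX / dP1 - Y
    W <- solve(A, B)
    TY <- Y + G %*% W
    ## variance update
    xPx <- sum(colSums(P) * rowSums(X * X))
    trPXT <- sum(PX * TY)
    tTt <- sum(P1 * rowSums(TY * TY))
    sigma2_new <- max((xPx - 2 * trPXT + tTt) / (Np * D), 0)
    sigma2_path <- c(sigma2_path, sigma2_new)
    if (sigma2_new < floor2) {
      collapsed <- TRUE
      sigma2 <- max(sigma2_new, floor2)
      warning("CPD sigma^2 collapsed to the variance floor; stopping",
              call. = FALSE)
      break
    }
    if (abs(sigma2 - sigma2_new) <= tol * sigma2) {
      sigma2 <- sigma2_new
      converged <- TRUE
      break
    }
    sigma2 <- sigma2_new
  }
  structure(list(source_points = Y, weights = W, beta = beta,
                 lambda = lambda, w = w, sigma2 = sigma2,
                 sigma2_path = sigma2_path, iterations = it,
                 converged = converged, collapsed = collapsed,
                 registered = TY),
            class = "cpd_model")
}

#' @export
print.cpd_model <- function(x, ...) {
  cat("Coherent point drift (deformable)\n")
  cat(sprintf("  control points: %d | beta = %.4g mm | lambda = %.3g | w = %.2f\n",
              nrow(x$source_points), x$beta, x$lambda, x$w))
  cat(sprintf("  iterations: %d | final sigma^2 = %.4g | converged: %s%s\n",
              x$iterations, x$sigma2, x$converged,
              if (x$collapsed) " (variance collapsed)" else ""))
  invisible(x)
}

#' Evaluate the fitted deformable map at new points
#'
#' Applies the Gaussian-kernel displacement interpolant of a fitted
#' [cpd_deformable()] model; exact at the control points.
#'
#' @param object a \code{cpd_model}.
#' @param newpoints \code{n x 3} matrix of points in the model's (rigidly
#'   aligned) frame.
#' @param ... unused.
#' @return the deformed \code{n x 3} matrix.
#' @export
predict.cpd_model <- function(object, newpoints, ...) {
  pts <- as_landmarks(newpoints)
  pts + gaussian_kernel(pts, object$source_points, object$beta) %*% object$weights
}

#' Transfer template landmarks to a specimen
#'
#' Applies the rigid (ICP) transform and then the deformable (CPD) map to a
#' template landmark configuration, optionally snapping each transferred
#' point to the nearest vertex of the target mesh.
#'
#' @param template_landmarks a landmark configuration in template space.
#' @param rigid a [similarity_transform()] (or [rigid_align()] fit) from
#'   template space to the registration frame.
#' @param deformable a [cpd_deformable()] model fitted in that frame.
#' @param target_mesh optional [cm_mesh()] for surface projection.
#' @param project snap transferred points to the target surface
#'   (off by default: raw deformed points are returned).
#' @return the transferred landmark configuration.
#' @export
transfer_landmarks <- function(template_landmarks, rigid, deformable,
                               target_mesh = NULL, project = FALSE) {
  lm <- as_landmarks(template_landmarks)
  out <- apply_transform(rigid, lm)
  out <- predict(deformable, out)
  if (project) {
    if (is.null(target_mesh)) stop_cm("projection requires a target mesh")
    nn <- nearest_index(out, target_mesh$vertices)
    out <- target_mesh$vertices[nn, , drop = FALSE]
  }
  dimnames(out) <- dimnames(lm)
  as_landmarks(out)
}
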