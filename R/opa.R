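## Ordinary (pairwise) Procrustes superimposition and Procrustes distance.

## Optimal proper rotation R (3x3) minimizing ||X R - Y||_F for centered X, Y,
## with rows as points. Reflections are never returned: the determinant is
## forced to +1 via the Kabsch sign correction.
optimal_rotation <- function(X, Y) {
  M <- crossprod(X, Y)
  s <- svd(M)
  d <- sign(det(s$u %*% t(s$v)))
  if (d == 0) d <- 1
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

#' Superimpose one configuration onto another
#'
#' Least-squares rigid (optionally similarity) alignment of \code{source}
#' onto \code{target}: the returned rotation is always proper (no
#' reflection), and the residual sum of squares is the global minimum for
#' the allowed transformation class.
#'
#' @param source,target landmark configurations with equal \code{k >= 3} and
#'   positive centroid size.
#' @param allow_scaling if \code{TRUE}, a uniform scale factor is also
#'   estimated; otherwise scale is fixed at 1.
#' @return a list of class \code{opa_fit} with elements \code{aligned}
#'   (transformed source), \code{rotation} (3x3, det +1), \code{scale},
#'   \code{translation} (length 3), and \code{rss} (residual sum of squares).
#'   The transform maps a point row-vector \code{p} to
#'   \code{scale * (p - source_centroid) \%*\% rotation + target_centroid},
#'   i.e. \code{aligned = scale * centered_source \%*\% rotation + centroid(target)}.
#' @export
superimpose_pair <- function(source, target, allow_scaling = FALSE) {
  source <- as_landmarks(source); target <- as_landmarks(target)
  k <- nrow(source)
  if (nrow(target) != k) stop_cm("configurations must have equal k")
  if (k < 3) stop_cm("superimposition needs k >= 3 landmarks")
  cs_s <- centroid_size(source); cs_t <- centroid_size(target)
  if (cs_s <= 0 || cs_t <= 0) stop_cm("degenerate configuration: centroid size is zero")
  mu_s <- colMeans(source); mu_t <- colMeans(target)
  X <- sweep(source, 2, mu_s); Y <- sweep(target, 2, mu_t)
  R <- optimal_rotation(X, Y)
  s <- if (allow_scaling) sum((X %*% R) * Y) / sum(X * X) else 1
  aligned <- s * X %*% R + matrix(mu_t, k, 3, byrow = TRUE)
  dimnames(aligned) <- dimnames(source)
  structure(list(aligned = aligned, rotation = R, scale = s,
                 translation = as.numeric(mu_t - s * (mu_s %*% R)),
                 rss = sum((aligned - target)^2)),
            class = "opa_fit")
}

#' @export
print.opa_fit <- function(x, ...) {
  cat("Ordinary Procrustes fit: scale =", signif(x$scale, 6),
      " RSS =", format(x$rss, digits = 6), "\n")
  invisible(x)
}

#' Procrustes distance between two configurations
#'
#' The square root of the minimal summed squared coordinate differences after
#' centering, scaling both configurations to unit centroid size, and optimal
#' proper rotation (the partial Procrustes distance of shape space).
#' Symmetric in its arguments and zero for configurations of the same shape.
#'
#' @param a,b landmark configurations with equal \code{k} and positive
#'   centroid size.
#' @return a non-negative scalar.
#' @export
procrustes_distance <- function(a, b) {
  a <- as_landmarks(a); b <- as_landmarks(b)
  if (nrow(a) != nrow(b)) stop_cm("configurations must have equal k")
  cs_a <- centroid_size(a); cs_b <- centroid_size(b)
  if (cs_a <= 0 || cs_b <= 0) stop_cm("degenerate configuration: centroid size is zero")
  X <- sweep(a, 2, colMeans(a)) / cs_a
  Y <- sweep(b, 2, colMeans(b)) / cs_b
  R <- optimal_rotation(X, Y)
  sqrt(sum((X %*% R - Y)^2))
}
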