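#' Principal component analysis of shape
#'
#' Eigenanalysis (via singular value decomposition) of the covariance of
#' flattened, mean-centered shape coordinates. Axes with zero variance
#' (the similarity dimensions removed by superimposition, and anything
#' beyond \code{n - 1}) are dropped. The sign of each axis is fixed by
#' making its largest-magnitude loading positive, so results are
#' deterministic.
#'
#' @param coords a \code{k x 3 x n} array, list of configurations, or an
#'   \code{n x q} data matrix; \code{n >= 3}.
#' @return an object of class \code{shape_pca}: \code{scores}
#'   (\code{n x m}), \code{loadings} (\code{q x m}, unit columns),
#'   \code{variance_fractions} (length \code{m}, non-increasing, summing to
#'   1), \code{sdev}, \code{mean_shape} (\code{k x 3} when the input was
#'   configurations, else the mean row), \code{k}.
#' @export
shape_pca <- function(coords) {
  Y <- as_data_matrix(coords)
  n <- nrow(Y)
  if (n < 3) stop_cm("PCA needs at least 3 specimens")
  mu <- colMeans(Y)
  Yc <- sweep(Y, 2, mu)
  s <- svd(Yc)
  keep <- which(s$d > max(s$d) * 1e-8)
  if (length(keep) == 0) stop_cm("no variation in the data")
  d <- s$d[keep]
  U <- s$u[, keep, drop = FALSE]
  V <- s$v[, keep, drop = FALSE]
  for (j in seq_along(keep)) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) { V[, j] <- -V[, j]; U[, j] <- -U[, j] }
  }
  scores <- U * rep(d, each = n)
  colnames(scores) <- colnames(V) <- paste0("PC", seq_along(keep))
  k3 <- length(mu)
  mean_shape <- if (k3 %% 3 == 0)
    as_landmarks(matrix(mu, ncol = 3, byrow = FALSE,
                        dimnames = list(NULL, c("x", "y", "z"))))
  else mu
  structure(list(scores = scores, loadings = V,
                 variance_fractions = d^2 / sum(d^2),
                 sdev = d / sqrt(n - 1),
                 mean_shape = mean_shape, n = n, k = k3 / 3),
            class = "shape_pca")
}

#' @export
print.shape_pca <- function(x, ...) {
  m <- min(length(x$variance_fractions), 6)
  cat("Shape PCA:", x$n, "specimens,", ncol(x$loadings), "non-null axes\n")
  cat("  variance fractions:",
      paste0(colnames(x$scores)[1:m], " ",
             sprintf("%.1f%%", 100 * x$variance_fractions[1:m]),
             collapse = ", "),
      if (length(x$variance_fractions) > m) ", ..." else "", "\n")
  invisible(x)
}

#' @export
plot.shape_pca <- function(x, axes = c(1, 2), groups = NULL, ...) {
  a <- axes[1]; b <- axes[2]
  lab <- function(j) sprintf("PC%d (%.1f%%)", j, 100 * x$variance_fractions[j])
  col <- if (is.null(groups)) "black" else as.integer(as.factor(groups)) + 1L
  graphics::plot(x$scores[, a], x$scores[, b], col = col, pch = 19,
                 xlab = lab(a), ylab = lab(b), ...)
  graphics::abline(h = 0, v = 0, col = "grey80", lty = 3)
  if (!is.null(groups))
    graphics::legend("topright", legend = levels(as.factor(groups)),
                     col = seq_len(nlevels(as.factor(groups))) + 1L, pch = 19,
                     bty = "n")
  invisible(x)
}

#' Per-landmark displacement field along a principal component
#'
#' The shape at \code{extent} standard deviations along one PC axis, and the
#' per-landmark displacement vectors and magnitudes relative to the mean
#' shape: the scalar field rendered as a surface heat map.
#'
#' @param pca a [shape_pca()] result computed from configurations.
#' @param axis PC index (1-based), at most the number of retained axes.
#' @param extent position along the axis in units of the score standard
#'   deviation.
#' @return list with \code{displacement} (\code{k x 3}), \code{magnitude}
#'   (length \code{k}, \eqn{\ge 0}), \code{end_shape} (\code{k x 3}),
#'   \code{axis}, \code{extent}.
#' @export
pc_heatmap_field <- function(pca, axis = 1L, extent = 3) {
  stopifnot(inherits(pca, "shape_pca"))
  if (axis < 1 || axis > ncol(pca$loadings)) stop_cm("axis out of range")
  if (!is.matrix(pca$mean_shape)) stop_cm("pca was not computed from 3D configurations")
  sd_ax <- stats::sd(pca$scores[, axis])
  disp <- matrix(extent * sd_ax * pca$loadings[, axis], ncol = 3)
  colnames(disp) <- c("x", "y", "z")
  list(displacement = disp, magnitude = row_norms(disp),
       end_shape = as_landmarks(pca$mean_shape + disp),
       axis = as.integer(axis), extent = extent)
}
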