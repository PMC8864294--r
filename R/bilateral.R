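#' Symmetry plane
#'
#' A plane in 3D given by a point and a unit normal. The package convention
#' for synthetic data is the sagittal plane \code{x = 0} with normal
#' \code{(1, 0, 0)}, but all operations accept an arbitrary plane.
#'
#' @param origin numeric length-3 point on the plane.
#' @param normal numeric length-3 normal vector (will be normalized; must be
#'   non-zero).
#' @return an object of class \code{symmetry_plane}.
#' @export
symmetry_plane <- function(origin = c(0, 0, 0), normal = c(1, 0, 0)) {
  origin <- as.numeric(origin); normal <- as.numeric(normal)
  stopifnot(length(origin) == 3, length(normal) == 3)
  assert_finite(c(origin, normal), "plane parameters")
  nn <- sqrt(sum(normal^2))
  if (nn < 1e-12) stop_cm("plane normal must be non-zero")
  structure(list(origin = origin, normal = normal / nn),
            class = "symmetry_plane")
}

#' @export
print.symmetry_plane <- function(x, ...) {
  cat("Symmetry plane: origin (", paste(signif(x$origin, 4), collapse = ", "),
      "), normal (", paste(signif(x$normal, 4), collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Bilateral landmark map
#'
#' Pairing of left/right landmark indices plus midline indices, the side
#' structure required by object-symmetry analysis. \code{pairs} and
#' \code{midline} together must partition \code{1..k} with no repeats.
#'
#' @param pairs integer matrix with two columns (left, right) or a list of
#'   length-2 index vectors; 1-based.
#' @param midline integer vector of on-plane landmark indices (may be empty).
#' @param k total number of landmarks; inferred as the max index if missing.
#' @return an object of class \code{bilateral_map}.
#' @export
bilateral_map <- function(pairs, midline = integer(0), k = NULL) {
  if (is.list(pairs)) pairs <- do.call(rbind, lapply(pairs, as.integer))
  if (length(pairs) == 0) pairs <- matrix(integer(0), ncol = 2)
  pairs <- matrix(as.integer(pairs), ncol = 2)
  midline <- as.integer(midline)
  if (any(pairs[, 1] == pairs[, 2])) stop_cm("a landmark cannot be its own partner")
  all_idx <- c(pairs[, 1], pairs[, 2], midline)
  if (anyDuplicated(all_idx)) stop_cm("bilateral map indices must not repeat")
  k <- k %||% if (length(all_idx)) max(all_idx) else 0L
  if (length(all_idx) != k || (length(all_idx) && !setequal(all_idx, seq_len(k))))
    stop_cm("pairs and midline must partition 1..k")
  structure(list(pairs = pairs, midline = midline, k = as.integer(k)),
            class = "bilateral_map")
}

#' @export
print.bilateral_map <- function(x, ...) {
  cat("Bilateral map:", nrow(x$pairs), "pairs,", length(x$midline),
      "midline landmarks (k =", x$k, ")\n")
  invisible(x)
}

## Permutation that swaps left and right indices (midline fixed).
relabel_permutation <- function(map) {
  p <- seq_len(map$k)
  p[map$pairs[, 1]] <- map$pairs[, 2]
  p[map$pairs[, 2]] <- map$pairs[, 1]
  p
}

#' Mirror points across a plane
#'
#' Householder reflection of each point across an arbitrary plane.
#'
#' @param points a numeric \code{k x 3} matrix.
#' @param plane a [symmetry_plane()].
#' @return the mirrored \code{k x 3} matrix.
#' @export
reflect_points <- function(points, plane = symmetry_plane()) {
  points <- as_landmarks(points)
  n <- plane$normal
  d <- (points - matrix(plane$origin, nrow(points), 3, byrow = TRUE)) %*% n
  points - 2 * as.vector(d) %o% n
}

#' Reflect and relabel a configuration
#'
#' Mirrors every landmark across the symmetry plane and then swaps left and
#' right labels according to the bilateral map, so that the result is again a
#' configuration with the original labeling convention. Midline landmarks
#' keep their slot (mirrored in place). The operator is an involution:
#' applying it twice returns the input exactly.
#'
#' @param config a landmark configuration.
#' @param map a [bilateral_map()] covering all \code{k} landmarks.
#' @param plane a [symmetry_plane()].
#' @return the reflected-relabeled configuration.
#' @export
reflect_relabel <- function(config, map, plane = symmetry_plane()) {
  config <- as_landmarks(config)
  if (!inherits(map, "bilateral_map")) stop_cm("map must be a bilateral_map")
  if (map$k != nrow(config)) stop_cm("bilateral map does not match configuration size")
  mirrored <- reflect_points(config, plane)
  out <- mirrored[relabel_permutation(map), , drop = FALSE]
  dimnames(out) <- dimnames(config)
  out
}
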