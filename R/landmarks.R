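#' Landmark configurations
#'
#' A landmark configuration is a numeric \code{k x 3} matrix of ordered 3D
#' coordinates in millimetres, optionally with row names giving landmark
#' labels. \code{as_landmarks} validates and normalizes such an object; all
#' shape operations in the package accept anything it accepts.
#'
#' @param x a \code{k x 3} numeric matrix, or a data frame with columns
#'   \code{x}, \code{y}, \code{z}.
#' @param names optional character vector of landmark labels, length \code{k}.
#' @return a numeric \code{k x 3} matrix with columns \code{x}, \code{y},
#'   \code{z}.
#' @export
as_landmarks <- function(x, names = NULL) {
  if (is.data.frame(x)) {
    stopifnot(all(c("x", "y", "z") %in% base::names(x)))
    x <- as.matrix(x[, c("x", "y", "z")])
  }
  if (!is.matrix(x) || !is.numeric(x) || ncol(x) != 3)
    stop_cm("a landmark configuration must be a numeric k x 3 matrix")
  assert_finite(x, "landmark coordinates")
  colnames(x) <- c("x", "y", "z")
  if (!is.null(names)) {
    if (length(names) != nrow(x)) stop_cm("names must have length k")
    rownames(x) <- names
  }
  x
}

#' Centroid size of a landmark configuration
#'
#' The square root of the summed squared deviations of the landmarks from
#' their centroid; the standard size measure of geometric morphometrics.
#' Scales linearly under uniform scaling.
#'
#' @param config a landmark configuration (see [as_landmarks()]).
#' @return a non-negative scalar (mm).
#' @export
centroid_size <- function(config) {
  config <- as_landmarks(config)
  cen <- colMeans(config)
  sqrt(sum(sweep(config, 2, cen)^2))
}

#' Normalized centroid size
#'
#' Centroid size divided by the number of landmarks, which makes size
#' comparable across landmarking schemes with different point counts
#' (e.g. a 23-point manual scheme versus a dense pseudo-landmark set).
#'
#' @inheritParams centroid_size
#' @return a non-negative scalar.
#' @export
normalized_centroid_size <- function(config) {
  config <- as_landmarks(config)
  centroid_size(config) / nrow(config)
}

#' Per-landmark Euclidean distances between two configurations
#'
#' Used for digitization error: the distance between corresponding landmarks
#' of two placements of the same specimen (no superimposition is applied).
#'
#' @param a,b landmark configurations with equal \code{k} and the same
#'   landmark ordering.
#' @return numeric vector of length \code{k}, all \eqn{\ge 0} (mm).
#' @export
landmark_distances <- function(a, b) {
  a <- as_landmarks(a); b <- as_landmarks(b)
  if (nrow(a) != nrow(b)) stop_cm("configurations must have the same number of landmarks")
  row_norms(a - b)
}

#' Coordinate-wise average of landmark configurations
#'
#' Plain arithmetic mean with no superimposition; appropriate for replicate
#' digitizations of the same specimen in the same coordinate frame (the
#' gold-standard construction).
#'
#' @param configs a list of landmark configurations with equal \code{k}.
#' @return a single landmark configuration.
#' @export
average_configurations <- function(configs) {
  if (!is.list(configs) || length(configs) == 0)
    stop_cm("configs must be a non-empty list of configurations")
  configs <- lapply(configs, as_landmarks)
  k <- nrow(configs[[1]])
  if (!all(vapply(configs, nrow, 1L) == k))
    stop_cm("all configurations must have the same number of landmarks")
  out <- Reduce(`+`, configs) / length(configs)
  dimnames(out) <- dimnames(configs[[1]])
  out
}

## Canonicalize a sample of configurations to a k x 3 x n array.
as_landmark_array <- function(configs) {
  if (is.array(configs) && length(dim(configs)) == 3) {
    stopifnot(dim(configs)[2] == 3)
    assert_finite(configs)
    return(configs)
  }
  if (!is.list(configs) || length(configs) == 0)
    stop_cm("expected a list of configurations or a k x 3 x n array")
  configs <- lapply(configs, as_landmarks)
  k <- nrow(configs[[1]])
  if (!all(vapply(configs, nrow, 1L) == k))
    stop_cm("all configurations must have the same number of landmarks")
  arr <- array(unlist(configs, use.names = FALSE), dim = c(k, 3, length(configs)),
               dimnames = list(rownames(configs[[1]]), c("x", "y", "z"),
                               names(configs)))
  arr
}

array_to_list <- function(arr) {
  lapply(seq_len(dim(arr)[3]), function(i) arr[, , i])
}

## Flatten k x 3 x n array to n x 3k matrix (specimens in rows).
flatten_configs <- function(arr) {
  n <- dim(arr)[3]
  t(matrix(arr, nrow = dim(arr)[1] * 3, ncol = n))
}
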