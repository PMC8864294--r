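## Internal helpers shared across the package.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_cm <- function(...) stop(..., call. = FALSE)

#' @noRd
assert_finite <- function(x, what = "coordinates") {
  if (!all(is.finite(x))) stop_cm("non-finite ", what, " are not allowed")
  invisible(x)
}

## Derive a reproducible child seed from a parent seed and a stream name.
## The mixing is deliberately nonlinear (multiply + xor-shift rounds):
## linearly related seeds hand Mersenne-Twister correlated initial states,
## and draws taken early after seeding then correlate across replicates.
## Keeps results below 2^31 so they remain valid R integers.
substream_seed <- function(seed, stream) {
  u <- utf8ToInt(stream)
  h <- sum(u * seq_along(u))
  x <- (as.numeric(seed) %% 2147483647) + 1
  for (round in 1:3) {
    x <- (x * 48271 + h * 9973 + round * 7919) %% 2147483647
    xi <- as.integer(x)
    x <- as.numeric(bitwXor(xi, bitwShiftR(xi, 13))) %% 2147483647
  }
  as.integer(x %% 2147483562) + 1L
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  invisible(stats::runif(32))  # warm-up: decorrelates streams of related seeds
  expr
}

## Atomic text write: write to a temp file in the same directory, then rename.
atomic_write <- function(lines, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  writeLines(lines, tmp)
  file.rename(tmp, path)
  invisible(path)
}

## Row-wise Euclidean norms of a numeric matrix.
row_norms <- function(m) sqrt(rowSums(m * m))

## Pairwise squared distances between rows of a (na x 3) and b (nb x 3).
cross_dist2 <- function(a, b) {
  an <- rowSums(a * a)
  bn <- rowSums(b * b)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}

## Index of nearest row of b for each row of a (exact, dense; fine at desk scale).
nearest_index <- function(a, b, chunk = 2048L) {
  n <- nrow(a)
  out <- integer(n)
  i <- 1L
  while (i <= n) {
    j <- min(n, i + chunk - 1L)
    out[i:j] <- max.col(-cross_dist2(a[i:j, , drop = FALSE], b), ties.method = "first")
    i <- j + 1L
  }
  out
}
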