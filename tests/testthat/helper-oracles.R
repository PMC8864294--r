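# Independent oracles and small generators used across the test suite.
# The superimposition oracles parameterize rotation by unit quaternions and
# minimize numerically (multi-start BFGS) -- a code path fully independent
# of the SVD-based implementation they check.

quat_to_rotation <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         nrow = 3)
}

## Minimal RSS of ||s * Xc %*% R - Yc||^2 over proper rotations (and scale),
## after centering both configurations.
oracle_opa_rss <- function(X, Y, allow_scaling = FALSE, n_starts = 12) {
  Xc <- sweep(X, 2, colMeans(X))
  Yc <- sweep(Y, 2, colMeans(Y))
  obj <- function(par) {
    R <- quat_to_rotation(par[1:4])
    if (allow_scaling) {
      ## profile out the scale: for fixed R the optimum is closed form
      s <- max(0, sum((Xc %*% R) * Yc)) / sum(Xc^2)
    } else s <- 1
    sum((s * Xc %*% R - Yc)^2)
  }
  best <- Inf
  for (i in seq_len(n_starts)) {
    fit <- stats::optim(rnorm(4), obj, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-14))
    best <- min(best, fit$value)
  }
  best
}

## Minimal-RSS shape distance: both configurations centered and scaled to
## unit centroid size, rotation by quaternion search.
oracle_procrustes_distance <- function(X, Y, n_starts = 12) {
  Xs <- sweep(X, 2, colMeans(X)); Xs <- Xs / sqrt(sum(Xs^2))
  Ys <- sweep(Y, 2, colMeans(Y)); Ys <- Ys / sqrt(sum(Ys^2))
  sqrt(oracle_opa_rss(Xs, Ys, allow_scaling = FALSE, n_starts = n_starts))
}

## Joint GPA objective oracle: cyclic refinement of all rotations, each
## optimized by quaternion BFGS against the current consensus, from
## multiple random restarts; returns the best total Procrustes SS found.
oracle_gpa_ss <- function(configs, scale = TRUE, n_starts = 20) {
  n <- length(configs)
  prep <- lapply(configs, function(X) {
    Xc <- sweep(X, 2, colMeans(X))
    if (scale) Xc <- Xc / sqrt(sum(Xc^2))
    Xc
  })
  total_ss <- function(rots) {
    al <- lapply(seq_len(n), function(i) prep[[i]] %*% rots[[i]])
    cons <- Reduce(`+`, al) / n
    sum(vapply(al, function(a) sum((a - cons)^2), 0))
  }
  best <- Inf
  for (s in seq_len(n_starts)) {
    qs <- lapply(seq_len(n), function(i) rnorm(4))
    rots <- lapply(qs, quat_to_rotation)
    for (sweep_i in 1:15) {
      for (i in seq_len(n)) {
        cons <- Reduce(`+`, lapply(setdiff(seq_len(n), i), function(j)
          prep[[j]] %*% rots[[j]])) / n
        obj <- function(q) {
          al <- prep[[i]] %*% quat_to_rotation(q)
          cons_i <- cons + al / n
          sum((al - cons_i)^2) +
            sum(vapply(setdiff(seq_len(n), i), function(j)
              sum((prep[[j]] %*% rots[[j]] - cons_i)^2), 0))
        }
        fit <- stats::optim(qs[[i]], obj, method = "BFGS",
                            control = list(maxit = 200, reltol = 1e-13))
        qs[[i]] <- fit$par
        rots[[i]] <- quat_to_rotation(qs[[i]])
      }
    }
    best <- min(best, total_ss(rots))
  }
  best
}

random_config <- function(k = 6, scale = 1) {
  matrix(rnorm(k * 3), k, 3) * scale
}

random_proper_rotation <- function() {
  Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

## A bilaterally symmetric configuration plus its map, for symmetry tests.
symmetric_fixture <- function(k_pairs = 8, k_mid = 4, seed = 1) {
  set.seed(seed)
  right <- cbind(runif(k_pairs, 0.3, 1.5), rnorm(k_pairs), rnorm(k_pairs))
  mid <- cbind(rep(0, k_mid), rnorm(k_mid), rnorm(k_mid))
  base <- rbind(right, cbind(-right[, 1], right[, 2:3]), mid)
  map <- bilateral_map(cbind(seq_len(k_pairs), k_pairs + seq_len(k_pairs)),
                       midline = 2 * k_pairs + seq_len(k_mid))
  list(config = base, map = map)
}

## Total GPA sum of squares of a fitted gpa object.
gpa_total_ss <- function(g) {
  sum(vapply(seq_len(dim(g$aligned)[3]), function(i)
    sum((g$aligned[, , i] - g$consensus)^2), 0))
}
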