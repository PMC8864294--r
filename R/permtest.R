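## Permutation inference on shape data: Procrustes ANOVA by residual
## randomization and morphological disparity.

## Canonicalize shape input to an n x q data matrix (specimens in rows).
as_data_matrix <- function(coords) {
  if (is.array(coords) && length(dim(coords)) == 3) return(flatten_configs(as_landmark_array(coords)))
  if (is.list(coords)) return(flatten_configs(as_landmark_array(coords)))
  if (is.matrix(coords)) return(coords)
  if (is.numeric(coords)) return(matrix(coords, ncol = 1))
  stop_cm("coords must be a configuration array/list, a matrix, or a numeric vector")
}

## Number of distinct group-label assignments (multinomial coefficient),
## capped to avoid overflow.
n_distinct_assignments <- function(f, cap = 1e7) {
  tab <- table(f)
  v <- exp(lgamma(length(f) + 1) - sum(lgamma(tab + 1)))
  min(v, cap)
}

## All distinct two-group assignments as a list of factor vectors; only used
## when the count is small.
enumerate_assignments <- function(f) {
  lev <- levels(f)
  n <- length(f)
  if (length(lev) == 2) {
    n1 <- sum(f == lev[1])
    cmb <- utils::combn(n, n1)
    return(lapply(seq_len(ncol(cmb)), function(j) {
      g <- factor(rep(lev[2], n), levels = lev)
      g[cmb[, j]] <- lev[1]
      g
    }))
  }
  ## small-n general case: filter distinct assignments from all permutations
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  all_p <- perms(as.character(f))
  uniq <- unique(lapply(all_p, paste, collapse = "\r"))
  lapply(uniq, function(s) factor(strsplit(s, "\r", fixed = TRUE)[[1]], levels = lev))
}

## SS between groups from already-centered rows R (colSums(R) == 0).
ss_between <- function(R, f, n_g) {
  sums <- rowsum(R, f)
  sum(rowSums(sums * sums) / n_g)
}

#' Procrustes ANOVA by residual randomization
#'
#' Tests whether group mean shapes differ, using the distance-based sums of
#' squares of shape data and a permutation null obtained by randomizing the
#' residual vectors of the reduced (intercept-only) model. Reports the F
#' ratio, a standardized effect size Z computed from the log-F permutation
#' distribution, and the add-one permutation p-value. When the number of
#' distinct group assignments is at most \code{exhaustive_cap} the full
#' enumeration is used instead of random sampling and the p-value is exact.
#'
#' @param coords shape data: a \code{k x 3 x n} array, list of
#'   configurations, an \code{n x q} score matrix, or a numeric vector
#'   (one trait).
#' @param factor_ grouping factor (or coercible), \code{>= 2} levels.
#' @param n_permutations number of random permutations (ignored under
#'   enumeration).
#' @param seed integer seed for the permutation stream.
#' @param exhaustive \code{"auto"} (enumerate when feasible), \code{TRUE},
#'   or \code{FALSE}.
#' @param exhaustive_cap assignment-count threshold for automatic
#'   enumeration.
#' @return an object of class \code{perm_anova}: list with
#'   \code{statistic_name}, \code{observed} (SS between groups), \code{F},
#'   \code{Z}, \code{p}, \code{df_effect}, \code{df_residual},
#'   \code{n_permutations}, \code{seed}, \code{permutation_distribution}
#'   (null F values, observed first), \code{exhaustive}, \code{ss} table.
#' @export
procrustes_anova <- function(coords, factor_, n_permutations = 999L, seed = 1L,
                             exhaustive = "auto", exhaustive_cap = 10000) {
  Y <- as_data_matrix(coords)
  n <- nrow(Y)
  f <- droplevels(as.factor(factor_))
  if (length(f) != n) stop_cm("factor length does not match the number of specimens")
  if (nlevels(f) < 2) stop_cm("factor must have at least 2 levels")
  if (n < 3) stop_cm("need at least 3 specimens")
  gm <- colMeans(Y)
  R <- sweep(Y, 2, gm)
  ss_total <- sum(R * R)
  if (ss_total <= 0) stop_cm("total sum of squares is zero")
  n_g <- as.numeric(table(f))
  df_e <- nlevels(f) - 1L
  df_r <- n - nlevels(f)
  ss_e <- ss_between(R, f, n_g)
  ss_r <- ss_total - ss_e
  if (ss_r <= 0) stop_cm("zero residual sum of squares: F is undefined")
  f_stat <- function(sse) (sse / df_e) / ((ss_total - sse) / df_r)
  F_obs <- f_stat(ss_e)
  n_assign <- n_distinct_assignments(f)
  use_exh <- isTRUE(exhaustive) ||
    (identical(exhaustive, "auto") && n_assign <= exhaustive_cap)
  if (use_exh) {
    assigns <- enumerate_assignments(f)
    F_all <- vapply(assigns, function(g) f_stat(ss_between(R, g, n_g)), 0)
    slack <- 1e-9 * (abs(F_obs) + 1e-12)
    p <- mean(F_all >= F_obs - slack)
    dist <- F_all
    n_perm <- length(F_all) - 1L
  } else {
    n_perm <- as.integer(n_permutations)
    F_perm <- with_seed(as.integer(seed), {
      vapply(seq_len(n_perm), function(j) {
        f_stat(ss_between(R[sample.int(n), , drop = FALSE], f, n_g))
      }, 0)
    })
    slack <- 1e-9 * (abs(F_obs) + 1e-12)
    p <- (1 + sum(F_perm >= F_obs - slack)) / (n_perm + 1)
    dist <- c(F_obs, F_perm)
  }
  logd <- log(pmax(dist, .Machine$double.xmin))
  Z <- (log(max(F_obs, .Machine$double.xmin)) - mean(logd)) / stats::sd(logd)
  structure(list(statistic_name = "Procrustes ANOVA F",
                 observed = ss_e, F = F_obs, Z = Z, p = p,
                 df_effect = df_e, df_residual = df_r,
                 n_permutations = n_perm, seed = as.integer(seed),
                 permutation_distribution = dist, exhaustive = use_exh,
                 ss = c(effect = ss_e, residual = ss_r, total = ss_total)),
            class = "perm_anova")
}

#' @export
print.perm_anova <- function(x, ...) {
  cat(x$statistic_name, "\n")
  cat(sprintf("  SS(effect) = %.6g  SS(resid) = %.6g  df = %d, %d\n",
              x$ss[["effect"]], x$ss[["residual"]], x$df_effect, x$df_residual))
  cat(sprintf("  F = %.4f  Z = %.4f  p = %.4g  (%s%d permutations, seed %d)\n",
              x$F, x$Z, x$p, if (x$exhaustive) "exhaustive, " else "",
              x$n_permutations, x$seed))
  invisible(x)
}

#' Morphological disparity and its group comparison
#'
#' Procrustes variance of each group (mean squared distance of its members
#' from the group mean shape) and pairwise permutation tests of variance
#' differences, obtained by randomizing the residual vectors of the
#' group-mean model among specimens.
#'
#' @inheritParams procrustes_anova
#' @param groups grouping factor, every level with \code{>= 2} members.
#' @return an object of class \code{disparity}: list with
#'   \code{variances} (per group), \code{pairwise_difference},
#'   \code{pairwise_p} (matrices), \code{n_permutations}, \code{seed},
#'   \code{exhaustive}.
#' @export
morphological_disparity <- function(coords, groups, n_permutations = 999L,
                                    seed = 1L, exhaustive = "auto",
                                    exhaustive_cap = 10000) {
  Y <- as_data_matrix(coords)
  n <- nrow(Y)
  f <- droplevels(as.factor(groups))
  if (length(f) != n) stop_cm("groups length does not match the number of specimens")
  if (nlevels(f) < 2) stop_cm("need at least 2 groups")
  if (any(table(f) < 2)) stop_cm("every group needs at least 2 members")
  lev <- levels(f)
  n_g <- as.numeric(table(f))
  ## residual vectors of the reduced (grand-mean) model are the exchangeable
  ## units that get randomized; the variance statistic re-centers within
  ## whatever group a vector lands in, so group mean differences never
  ## masquerade as dispersion differences
  R <- sweep(Y, 2, colMeans(Y))
  pv_from <- function(Rm, g) {
    mg <- rowsum(Rm, g) / as.numeric(table(g))
    D <- Rm - mg[as.integer(g), , drop = FALSE]
    as.numeric(rowsum(rowSums(D * D), g) / as.numeric(table(g)))
  }
  pv_obs <- pv_from(R, f)
  names(pv_obs) <- lev
  n_assign <- n_distinct_assignments(f)
  use_exh <- isTRUE(exhaustive) ||
    (identical(exhaustive, "auto") && n_assign <= exhaustive_cap)
  nl <- length(lev)
  d_obs <- abs(outer(pv_obs, pv_obs, "-"))
  cnt <- matrix(0, nl, nl)
  if (use_exh) {
    assigns <- enumerate_assignments(f)
    for (g in assigns) {
      pv <- pv_from(R, g)
      d <- abs(outer(pv, pv, "-"))
      cnt <- cnt + (d >= d_obs - 1e-12 * (d_obs + 1e-12))
    }
    p <- cnt / length(assigns)
    n_perm <- length(assigns) - 1L
  } else {
    n_perm <- as.integer(n_permutations)
    with_seed(as.integer(seed), {
      for (j in seq_len(n_perm)) {
        pv <- pv_from(R[sample.int(n), , drop = FALSE], f)
        d <- abs(outer(pv, pv, "-"))
        cnt <- cnt + (d >= d_obs - 1e-12 * (d_obs + 1e-12))
      }
    })
    p <- (1 + cnt) / (n_perm + 1)
  }
  dimnames(p) <- dimnames(d_obs) <- list(lev, lev)
  diag(p) <- NA_real_
  structure(list(variances = pv_obs, pairwise_difference = d_obs,
                 pairwise_p = p, n_permutations = n_perm,
                 seed = as.integer(seed), exhaustive = use_exh),
            class = "disparity")
}

#' @export
print.disparity <- function(x, ...) {
  cat("Morphological disparity (Procrustes variance by group)\n")
  print(signif(x$variances, 6))
  cat("Pairwise |variance difference| p-values (",
      if (x$exhaustive) "exhaustive, " else "", x$n_permutations,
      " permutations):\n", sep = "")
  print(signif(x$pairwise_p, 4))
  invisible(x)
}
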