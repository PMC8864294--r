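## Classical univariate tests used by the validation analyses. Welch's t and
## the parametric one-way ANOVA delegate to stats; the paired signed-rank
## test is implemented here because an exact enumeration that tolerates ties
## is needed.

#' Welch two-sample t-test
#'
#' Welch's unequal-variance t statistic with Satterthwaite degrees of
#' freedom and a two-sided p-value. Degenerate inputs (zero variance in
#' both samples) give \code{t = 0, p = 1} when the means agree and an
#' error otherwise.
#'
#' @param a,b numeric samples, each of length \code{>= 2}.
#' @return list with \code{statistic} (t), \code{df}, \code{p},
#'   \code{means} (group means).
#' @export
welch_t_test <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2 || length(b) < 2) stop_cm("each sample needs at least 2 values")
  assert_finite(c(a, b), "sample values")
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0) {
    if (isTRUE(all.equal(mean(a), mean(b)))) {
      return(list(statistic = 0, df = length(a) + length(b) - 2, p = 1,
                  means = c(mean(a), mean(b)), degenerate = TRUE))
    }
    stop_cm("degenerate samples: zero variance with unequal means")
  }
  ht <- stats::t.test(a, b)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, means = unname(ht$estimate), degenerate = FALSE)
}

#' Paired signed-rank test
#'
#' Wilcoxon signed-rank test on paired differences. Zero differences are
#' dropped; ties in the absolute differences receive average ranks. For at
#' most \code{exact_max} non-zero pairs the null distribution is enumerated
#' over all sign assignments (exact even under ties); otherwise the normal
#' approximation with tie correction and continuity correction is used.
#'
#' @param x,y paired numeric samples of equal length \code{>= 2}.
#' @param exact_max largest number of non-zero pairs for exact enumeration.
#' @return list with \code{statistic} (V, the sum of ranks of positive
#'   differences), \code{p} (two-sided), \code{n_nonzero}, \code{exact}.
#' @export
paired_signed_rank_test <- function(x, y, exact_max = 15L) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y) || length(x) < 2)
    stop_cm("x and y must be paired samples of equal length >= 2")
  assert_finite(c(x, y), "sample values")
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stop_cm("no nonzero differences")
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  if (n <= exact_max) {
    ## all 2^n sign assignments; exact under ties
    stats_all <- numeric(2^n)
    for (mask in 0:(2^n - 1)) {
      sgn <- bitwAnd(bitwShiftR(mask, 0:(n - 1)), 1L) == 1L
      stats_all[mask + 1] <- sum(r[sgn])
    }
    mu <- sum(r) / 2
    p <- mean(abs(stats_all - mu) >= abs(V - mu) - 1e-12)
    return(list(statistic = V, p = p, n_nonzero = n, exact = TRUE))
  }
  mu <- n * (n + 1) / 4
  tie_tab <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie_tab^3 - tie_tab) / 48
  z <- (V - mu - sign(V - mu) * 0.5) / sqrt(sigma2)
  list(statistic = V, p = min(1, 2 * stats::pnorm(-abs(z))),
       n_nonzero = n, exact = FALSE)
}

#' One-way ANOVA with parametric and permutation p-values
#'
#' The classical F statistic for a single categorical factor, with the
#' parametric p-value from the F distribution (via [stats::aov()]) and a
#' permutation p-value obtained by shuffling group labels.
#'
#' @param values numeric response vector.
#' @param groups grouping factor, \code{>= 2} levels with \code{>= 2}
#'   members each.
#' @param n_permutations number of random permutations.
#' @param seed integer seed.
#' @param exhaustive see [procrustes_anova()].
#' @return list with \code{F}, \code{df} (length 2), \code{p_parametric},
#'   \code{p_permutation}, \code{n_permutations}, \code{seed}.
#' @export
one_way_anova <- function(values, groups, n_permutations = 999L, seed = 1L,
                          exhaustive = "auto") {
  values <- as.numeric(values)
  f <- droplevels(as.factor(groups))
  if (nlevels(f) < 2) stop_cm("need at least 2 groups")
  if (any(table(f) < 2)) stop_cm("every group needs at least 2 members")
  assert_finite(values, "response values")
  gm <- mean(values)
  ss_total <- sum((values - gm)^2)
  means <- tapply(values, f, mean)
  n_g <- as.numeric(table(f))
  ss_e <- sum(n_g * (means - gm)^2)
  ss_r <- ss_total - ss_e
  df <- c(nlevels(f) - 1L, length(values) - nlevels(f))
  if (ss_r <= 1e-300) {
    if (ss_e <= 1e-300)
      return(list(F = 0, df = df, p_parametric = 1, p_permutation = 1,
                  n_permutations = 0L, seed = as.integer(seed)))
    stop_cm("degenerate data: zero residual variance with group differences")
  }
  fit <- stats::aov(values ~ f)
  tab <- summary(fit)[[1]]
  F_obs <- tab[["F value"]][1]
  p_par <- tab[["Pr(>F)"]][1]
  pa <- procrustes_anova(matrix(values, ncol = 1), f,
                         n_permutations = n_permutations, seed = seed,
                         exhaustive = exhaustive)
  list(F = F_obs, df = df, p_parametric = p_par, p_permutation = pa$p,
       n_permutations = pa$n_permutations, seed = as.integer(seed))
}
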