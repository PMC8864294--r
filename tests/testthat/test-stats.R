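test_that("Welch t-test matches hand-computed values and conventions", {
  r <- welch_t_test(c(1, 2, 3), c(2, 3, 4))
  expect_equal(r$statistic, -1.224745, tolerance = 1e-6)
  expect_equal(r$df, 4.0, tolerance = 1e-9)
  ## identical samples
  same <- welch_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  ## antisymmetry in the arguments
  a <- rnorm(8); b <- rnorm(10, 1)
  r1 <- welch_t_test(a, b); r2 <- welch_t_test(b, a)
  expect_equal(r1$statistic, -r2$statistic)
  expect_equal(r1$p, r2$p)
  ## degenerate cases
  expect_equal(welch_t_test(c(2, 2, 2), c(2, 2))$p, 1)
  expect_error(welch_t_test(c(1, 1), c(2, 2)), "degenerate")
  expect_error(welch_t_test(1, c(1, 2)), "at least 2")
})

test_that("signed-rank test is exact by enumeration for small n", {
  ## constant shift: the most extreme sign pattern
  x <- c(1.2, 3.4, 0.5, 2.2, 5.1, 0.9)
  r <- paired_signed_rank_test(x + 1, x)
  expect_true(r$exact)
  expect_equal(r$p, 2 / 2^6)
  ## random pairs against an independent enumeration oracle
  set.seed(60)
  for (rep in 1:5) {
    a <- rnorm(6); b <- rnorm(6)
    r <- paired_signed_rank_test(a, b)
    d <- a - b
    rk <- rank(abs(d))
    V <- sum(rk[d > 0])
    signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), 6)))
    V_all <- apply(signs, 1, function(s) sum(rk[s]))
    mu <- sum(rk) / 2
    expect_equal(r$p, mean(abs(V_all - mu) >= abs(V - mu) - 1e-12))
    ## argument swap leaves the two-sided p unchanged
    expect_equal(paired_signed_rank_test(b, a)$p, r$p)
  }
  ## agreement with the stats implementation when it is exact (no ties)
  set.seed(61)
  a <- rnorm(10); b <- rnorm(10)
  expect_equal(paired_signed_rank_test(a, b)$p,
               stats::wilcox.test(a, b, paired = TRUE, exact = TRUE)$p.value,
               tolerance = 1e-12)
  expect_error(paired_signed_rank_test(c(1, 2), c(1, 2)), "no nonzero")
})

test_that("signed-rank normal approximation tracks the exact tail", {
  set.seed(62)
  a <- rnorm(25); b <- rnorm(25, 0.4)
  r <- paired_signed_rank_test(a, b)
  expect_false(r$exact)
  ref <- stats::wilcox.test(a, b, paired = TRUE, exact = FALSE,
                            correct = TRUE)$p.value
  expect_equal(r$p, ref, tolerance = 1e-9)
})

test_that("one-way ANOVA matches its algebraic identities and oracles", {
  ## identical group distributions
  v <- c(1, 2, 3, 1, 2, 3)
  g <- rep(c("a", "b"), each = 3)
  r <- one_way_anova(v, g, n_permutations = 99)
  expect_equal(r$F, 0)
  expect_equal(r$p_parametric, 1)
  ## F equals the square of the pooled-variance t for two groups
  set.seed(63)
  x <- rnorm(7); y <- rnorm(9, 0.8)
  r2 <- one_way_anova(c(x, y), rep(c("a", "b"), c(7, 9)),
                      n_permutations = 99, exhaustive = FALSE)
  tt <- stats::t.test(x, y, var.equal = TRUE)
  expect_equal(r2$F, unname(tt$statistic)^2, tolerance = 1e-9)
  expect_equal(r2$p_parametric, tt$p.value, tolerance = 1e-9)
  ## exhaustive permutation p equals the brute-force enumeration
  y6 <- rnorm(6)
  f6 <- factor(rep(c("a", "b"), each = 3))
  r3 <- one_way_anova(y6, f6, exhaustive = TRUE)
  gm <- mean(y6)
  fstat <- function(gg) {
    m <- tapply(y6, gg, mean)
    sum(3 * (m - gm)^2) / (sum((y6 - m[gg])^2) / 4)
  }
  F_all <- apply(combn(6, 3), 2, function(ix)
    fstat(factor(ifelse(1:6 %in% ix, "a", "b"))))
  expect_equal(r3$p_permutation, mean(F_all >= fstat(f6) - 1e-12))
  expect_error(one_way_anova(c(1, 1, 2, 2), c("a", "a", "b", "b")), "degenerate")
  expect_error(one_way_anova(c(1, 2, 3), c("a", "b", "b")), "at least 2 members")
})
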