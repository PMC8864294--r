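test_that("no between-group variation yields F = 0 and p = 1", {
  set.seed(50)
  A <- lapply(1:4, function(i) random_config(6))
  coords <- c(A, A)  # group B is an exact copy of group A
  f <- rep(c("a", "b"), each = 4)
  res <- procrustes_anova(coords, f, n_permutations = 199, seed = 1,
                          exhaustive = FALSE)
  expect_lt(res$F, 1e-20)
  expect_equal(res$p, 1)
})

test_that("small-sample permutation p equals exhaustive enumeration", {
  set.seed(51)
  y <- rnorm(6)
  f <- factor(rep(c("a", "b"), each = 3))
  res <- procrustes_anova(y, f, exhaustive = TRUE)
  expect_true(res$exhaustive)
  expect_equal(res$n_permutations, 19L)   # 20 distinct assignments
  ## independent brute-force oracle over all assignments
  gm <- mean(y)
  fstat <- function(g) {
    m <- tapply(y, g, mean)
    ssb <- sum(3 * (m - gm)^2)
    ssw <- sum((y - m[g])^2)
    (ssb / 1) / (ssw / 4)
  }
  cmb <- combn(6, 3)
  F_all <- apply(cmb, 2, function(ix) {
    g <- factor(ifelse(seq_len(6) %in% ix, "a", "b"))
    fstat(g)
  })
  expect_equal(res$p, mean(F_all >= fstat(f) - 1e-12))
  ## random-permutation mode approximates the same answer
  res_r <- procrustes_anova(y, f, n_permutations = 999, seed = 7,
                            exhaustive = FALSE)
  expect_lt(abs(res_r$p - res$p), 0.1)
})

test_that("permutation machinery is reproducible and never returns p = 0", {
  set.seed(52)
  Y <- matrix(rnorm(20 * 6), 20, 6)
  f <- rep(c("a", "b"), each = 10)
  r1 <- procrustes_anova(Y, f, n_permutations = 299, seed = 9, exhaustive = FALSE)
  r2 <- procrustes_anova(Y, f, n_permutations = 299, seed = 9, exhaustive = FALSE)
  expect_identical(r1$permutation_distribution, r2$permutation_distribution)
  expect_identical(r1$p, r2$p)
  expect_gte(r1$p, 1 / 300)
  expect_lte(r1$p, 1)
  r3 <- procrustes_anova(Y, f, n_permutations = 299, seed = 10, exhaustive = FALSE)
  expect_false(identical(r1$permutation_distribution, r3$permutation_distribution))
})

test_that("input validation of the shape ANOVA", {
  Y <- matrix(rnorm(12), 4, 3)
  expect_error(procrustes_anova(Y, rep("a", 4)), "at least 2 levels")
  expect_error(procrustes_anova(matrix(0, 4, 3), rep(c("a", "b"), 2)),
               "total sum of squares")
})

test_that("disparity measures within-group Procrustes variance", {
  set.seed(53)
  base <- random_config(8)
  ## zero spread in both groups
  cfgs <- c(lapply(1:3, function(i) base), lapply(1:3, function(i) 2 * base))
  f <- rep(c("a", "b"), each = 3)
  d <- morphological_disparity(cfgs, f, n_permutations = 99)
  expect_equal(unname(d$variances), c(0, 0))
  expect_equal(unname(d$pairwise_p[1, 2]), 1)
  ## doubling the spread around the mean quadruples the variance
  dev <- lapply(1:4, function(i) matrix(rnorm(24, 0, 0.1), 8, 3))
  ga <- lapply(dev, function(e) base + e)
  gb <- lapply(dev, function(e) base + 2 * e)
  Y <- craniomorph:::as_data_matrix(c(ga, gb))
  f2 <- rep(c("a", "b"), each = 4)
  d2 <- morphological_disparity(Y, f2, n_permutations = 99)
  expect_equal(unname(d2$variances["b"] / d2$variances["a"]), 4,
               tolerance = 1e-9)
  expect_error(morphological_disparity(Y, c(rep("a", 7), "b")), "at least 2 members")
})

test_that("disparity p-values match a brute-force enumeration on small data", {
  set.seed(54)
  y <- matrix(rnorm(12), 6, 2)
  f <- factor(rep(c("a", "b"), each = 3))
  d <- morphological_disparity(y, f, exhaustive = TRUE)
  expect_true(d$exhaustive)
  ## oracle: grand-mean residuals, within-group re-centered variance
  R <- sweep(y, 2, colMeans(y))
  pv <- function(g) {
    va <- colMeans(R[g == "a", , drop = FALSE])
    vb <- colMeans(R[g == "b", , drop = FALSE])
    abs(mean(rowSums(sweep(R[g == "a", , drop = FALSE], 2, va)^2)) -
          mean(rowSums(sweep(R[g == "b", , drop = FALSE], 2, vb)^2)))
  }
  obs <- pv(f)
  cmb <- combn(6, 3)
  d_all <- apply(cmb, 2, function(ix)
    pv(factor(ifelse(seq_len(6) %in% ix, "a", "b"))))
  expect_equal(unname(d$pairwise_p[1, 2]), mean(d_all >= obs - 1e-12))
})

test_that("the effect size Z can be negative for sub-null effects", {
  ## groups engineered to have nearly identical means: observed F falls in
  ## the lower tail of the permutation distribution
  set.seed(55)
  base <- rnorm(5)
  y <- c(base, base + 1e-4 * rnorm(5))
  f <- rep(c("a", "b"), each = 5)
  res <- procrustes_anova(y, f, n_permutations = 499, seed = 2,
                          exhaustive = FALSE)
  expect_lt(res$Z, 0)
})
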