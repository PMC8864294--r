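test_that("sliding leaves a sample of identical shapes untouched", {
  set.seed(30)
  base <- random_config(20)
  cfgs <- lapply(1:4, function(i) base)
  for (mode in c("bending_energy", "procrustes_distance")) {
    sl <- sliding_spec(1:20, mode = mode, max_sliding_iterations = 2)
    g <- run_gpa(cfgs, sliding = sl)
    for (i in 1:4)
      expect_lt(max(abs(g$aligned[, , i] - g$consensus)), 1e-9)
  }
})

test_that("procrustes-distance sliding projects a point onto its tangent plane target", {
  ## one sliding landmark whose tangent plane contains the consensus target:
  ## the slide is the exact in-plane projection, i.e. it reaches the target.
  base <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0), c(0.5, 0.5, 0))
  shifted <- base
  shifted[5, ] <- c(0.2, 0.8, 0)   # displaced within the z = 0 plane
  arr <- as_landmark_array(list(base, shifted))
  spec <- sliding_spec(5, mode = "procrustes_distance")
  normals <- lapply(1:2, function(i) matrix(rep(c(0, 0, 1), each = 5), 5, 3))
  consensus <- apply(arr, c(1, 2), mean)
  slid <- craniomorph:::slide_pass(arr, consensus, spec, normals)
  expect_equal(slid[5, , 2], consensus[5, ], tolerance = 1e-9)
  expect_equal(slid[5, , 1], consensus[5, ], tolerance = 1e-9)
  ## non-sliding landmarks untouched
  expect_equal(slid[1:4, , 2], arr[1:4, , 2])
})

test_that("sliding objective is non-increasing over rounds", {
  s <- simulate_symmetry_study(5, 5, k_pairs = 12, k_midline = 4,
                               individual_sd = 0.05, fa_sd = 0.02, seed = 31)
  sl_pd <- sliding_spec(1:28, mode = "procrustes_distance",
                        max_sliding_iterations = 5)
  g <- run_gpa(s$configs, sliding = sl_pd)
  obj <- g$sliding_objective
  expect_length(obj, 5)
  expect_true(all(diff(obj) <= 1e-6 * obj[-length(obj)] + 1e-12))
  sl_be <- sliding_spec(1:28, mode = "bending_energy",
                        max_sliding_iterations = 5)
  g2 <- run_gpa(s$configs, sliding = sl_be)
  obj2 <- g2$sliding_objective
  expect_true(all(diff(obj2) <= 1e-4 * obj2[-length(obj2)] + 1e-10))
})

test_that("sliding with an empty semilandmark set reproduces plain GPA", {
  set.seed(32)
  cfgs <- lapply(1:4, function(i) random_config(8))
  g_plain <- run_gpa(cfgs)
  g_empty <- run_gpa(cfgs, sliding = sliding_spec(integer(0)))
  expect_identical(g_plain$aligned, g_empty$aligned)
  expect_identical(g_plain$consensus, g_empty$consensus)
})

test_that("tangent estimation demands enough neighbors", {
  set.seed(33)
  cfgs <- lapply(1:3, function(i) random_config(5))
  sl <- sliding_spec(1:5, surface_neighbors = 8)
  expect_error(run_gpa(cfgs, sliding = sl), "not enough semilandmarks")
  expect_error(sliding_spec(1:5, surface_neighbors = 2), "at least 3")
})

test_that("bending energy matrix is symmetric and annihilates affine fields", {
  set.seed(34)
  ref <- random_config(12)
  E <- bending_energy_matrix(ref)
  expect_equal(E, t(E), tolerance = 1e-10)
  ## affine deformations of the reference have zero bending energy
  A <- matrix(rnorm(9), 3, 3)
  aff <- ref %*% A + matrix(rnorm(3), 12, 3, byrow = TRUE)
  expect_lt(abs(sum(aff * (E %*% aff))), 1e-8)
  ## and E is PSD on the non-affine complement
  ev <- eigen(E, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8)
})
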