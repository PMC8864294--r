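test_that("voxel downsampling is deterministic with the expected limits", {
  set.seed(90)
  pts <- random_config(200)
  big <- downsample_cloud(pts, 100)
  expect_equal(nrow(big), 1)
  expect_equal(as.numeric(big), colMeans(pts), tolerance = 1e-12)
  small <- downsample_cloud(pts, 0.5)
  expect_lte(nrow(small), 200)
  expect_identical(small, downsample_cloud(pts, 0.5))
  expect_error(downsample_cloud(pts, 0), "positive")
})

test_that("ICP recovers a known rigid motion and its cost never increases", {
  set.seed(91)
  src <- random_config(60)
  th <- 25 * pi / 180
  Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  tgt <- src %*% Rz + matrix(c(0.3, -0.2, 0.5), 60, 3, byrow = TRUE)
  fit <- rigid_align(src, tgt)
  expect_lt(sqrt(mean(rowSums((fit$aligned - tgt)^2))), 1e-6)
  expect_true(all(diff(fit$cost) <= 1e-12))
  ## similarity mode recovers a 1.3x scale
  fit_s <- rigid_align(src, 1.3 * src, allow_scaling = TRUE)
  expect_equal(fit_s$scale, 1.3, tolerance = 1e-6)
  expect_error(rigid_align(src[1:2, ], tgt), "at least 3")
})

test_that("the CPD kernel and self-registration behave as closed forms dictate", {
  ## two points at distance exactly beta
  a <- matrix(c(0, 0, 0, 2, 0, 0), 2, 3, byrow = TRUE)
  G <- craniomorph:::gaussian_kernel(a, a, beta = 2)
  expect_equal(G[1, 2], exp(-0.5), tolerance = 1e-12)
  expect_equal(diag(G), c(1, 1))
  ## identical clouds: no deformation needed
  set.seed(92)
  cloud <- random_config(50)
  fit <- cpd_deformable(cloud, cloud, beta = 1, w = 0)
  expect_lt(sqrt(mean(rowSums((fit$registered - cloud)^2))), 1e-8)
  expect_lt(max(abs(fit$weights)), 1e-6)
  expect_error(cpd_deformable(cloud[1:3, ], cloud, beta = 1), "at least 4")
  expect_error(cpd_deformable(cloud, cloud, beta = 1, w = 1), "outlier")
})

test_that("CPD recovers a smooth synthetic bump deformation", {
  set.seed(93)
  src <- random_config(150)
  bbox <- craniomorph:::bbox_diagonal(src)
  amp <- 0.02 * bbox
  u <- amp * exp(-rowSums(sweep(src, 2, c(0.3, 0, 0))^2) / (2 * 0.8^2))
  tgt <- src + cbind(u, 0.5 * u, -0.3 * u)
  fit <- cpd_deformable(src, tgt, beta = 1, lambda = 2, w = 0, max_iter = 80,
                        tol = 1e-8)
  rms <- sqrt(mean(rowSums((fit$registered - tgt)^2)))
  expect_lt(rms, 0.1 * amp)
  ## sigma^2 decreases along the EM path (numerical slack)
  expect_true(all(diff(fit$sigma2_path) <= 1e-12 + 1e-6 * fit$sigma2_path[-length(fit$sigma2_path)]))
})

test_that("landmark transfer is exact on identity and respects projection", {
  tpl <- make_template_mesh(n_theta = 19, n_phi = 32)
  ## registration clouds are density-equalized, as in the pipeline (CPD on
  ## a raw UV grid would chase the pole-ward density gradient)
  cloud <- downsample_cloud(tpl$vertices, 0.22)
  fit <- cpd_deformable(cloud, cloud, beta = 0.8, w = 0)
  lm <- tpl$vertices[seq(1, nrow(tpl$vertices), by = 40), ]
  moved <- transfer_landmarks(lm, similarity_transform(), fit)
  expect_lt(max(craniomorph:::row_norms(moved - lm)), 1e-6)
  ## projection lands on the surface
  proj <- transfer_landmarks(lm + 0.01, similarity_transform(), fit,
                             target_mesh = tpl, project = TRUE)
  nn <- craniomorph:::nearest_index(proj, tpl$vertices)
  expect_lt(max(craniomorph:::row_norms(proj - tpl$vertices[nn, ])), 1e-6)
})

test_that("strong regularization suppresses the deformable displacement", {
  set.seed(94)
  src <- random_config(80)
  tgt <- src + matrix(rnorm(240, 0, 0.05), 80, 3)
  d_small <- cpd_deformable(src, tgt, beta = 1, lambda = 1, w = 0)
  d_large <- cpd_deformable(src, tgt, beta = 1, lambda = 1e6, w = 0)
  disp <- function(f) max(craniomorph:::row_norms(f$registered - f$source_points))
  expect_lt(disp(d_large), 0.01 * disp(d_small))
})
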