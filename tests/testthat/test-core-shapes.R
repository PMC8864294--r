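test_that("centroid size follows its closed form and scales homogeneously", {
  sq <- matrix(c(1, 1, 0, 1, -1, 0, -1, -1, 0, -1, 1, 0), ncol = 3, byrow = TRUE)
  expect_equal(centroid_size(sq), sqrt(8), tolerance = 1e-12)
  expect_equal(normalized_centroid_size(sq), sqrt(8) / 4, tolerance = 1e-12)
  expect_equal(centroid_size(matrix(5, 7, 3)), 0)
  set.seed(11)
  X <- random_config(23)
  expect_equal(centroid_size(3.5 * X), 3.5 * centroid_size(X), tolerance = 1e-12)
  expect_equal(normalized_centroid_size(X), centroid_size(X) / 23)
  ## a 23-landmark configuration with CS 46 has normalized CS 2
  X46 <- X * (46 / centroid_size(X))
  expect_equal(normalized_centroid_size(X46), 2, tolerance = 1e-12)
  expect_error(centroid_size(matrix(c(1, NA, 0), 1, 3)), "non-finite")
})

test_that("per-landmark distances are symmetric, non-negative Euclidean norms", {
  set.seed(2)
  a <- random_config(9)
  expect_equal(landmark_distances(a, a), rep(0, 9))
  b <- a + matrix(c(3, 4, 0), 9, 3, byrow = TRUE)
  expect_equal(landmark_distances(a, b), rep(5, 9), tolerance = 1e-12)
  expect_equal(landmark_distances(a, b), landmark_distances(b, a))
  expect_error(landmark_distances(a, a[1:5, ]), "same number")
})

test_that("configuration averaging is coordinate-wise and order-invariant", {
  set.seed(3)
  a <- random_config(8)
  expect_equal(average_configurations(list(a, a)), as_landmarks(a))
  b <- a + matrix(c(2, 0, 0), 8, 3, byrow = TRUE)
  expect_equal(average_configurations(list(a, b)),
               as_landmarks(a + matrix(c(1, 0, 0), 8, 3, byrow = TRUE)))
  cc <- random_config(8)
  expect_equal(average_configurations(list(a, b, cc)),
               average_configurations(list(cc, a, b)))
  expect_error(average_configurations(list()), "non-empty")
})

test_that("reflect-relabel is an involution with the expected fixed points", {
  fx <- symmetric_fixture(6, 3, seed = 4)
  ## symmetric configuration: exact fixed point
  expect_equal(reflect_relabel(fx$config, fx$map), as_landmarks(fx$config),
               tolerance = 1e-12)
  ## involution on arbitrary configurations
  set.seed(5)
  for (rep in 1:5) {
    X <- random_config(15)
    map <- bilateral_map(cbind(1:6, 7:12), midline = 13:15)
    plane <- symmetry_plane(rnorm(3), rnorm(3))
    expect_equal(reflect_relabel(reflect_relabel(X, map, plane), map, plane),
                 as_landmarks(X), tolerance = 1e-12)
  }
  ## hand-worked single pair across x = 0
  X <- matrix(c(1, 0, 0, -1, 0, 0), 2, 3, byrow = TRUE)
  map1 <- bilateral_map(cbind(1, 2))
  expect_equal(reflect_relabel(X, map1), as_landmarks(X))
  ## commutes with uniform scaling about a point on the plane
  set.seed(6)
  Y <- random_config(12)
  map2 <- bilateral_map(cbind(1:5, 6:10), midline = 11:12)
  expect_equal(reflect_relabel(2.5 * Y, map2), 2.5 * reflect_relabel(Y, map2),
               tolerance = 1e-12)
})

test_that("bilateral map and plane validation reject malformed inputs", {
  expect_error(bilateral_map(cbind(1, 1)), "own partner")
  expect_error(bilateral_map(cbind(1, 2), midline = 2), "repeat")
  expect_error(bilateral_map(cbind(1, 2), midline = 4), "partition")
  expect_error(symmetry_plane(normal = c(0, 0, 0)), "non-zero")
  expect_equal(sum(symmetry_plane(normal = c(0, 0, 3))$normal^2), 1)
  fx <- symmetric_fixture(4, 2)
  wrong <- bilateral_map(cbind(1:2, 3:4), midline = 5:6)
  expect_error(reflect_relabel(fx$config, wrong), "does not match")
})
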