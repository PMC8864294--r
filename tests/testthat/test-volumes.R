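small_label_fixture <- function(dim3 = c(24, 24, 24), spacing = 0.1) {
  g <- array(0L, dim = dim3)
  g[8:12, 10:14, 9:13] <- 1L
  g[15:18, 6:9, 15:17] <- 2L
  label_volume(g, spacing = rep(spacing, 3))
}

zero_field_like <- function(lv) {
  displacement_field(array(0, dim = c(dim(lv$grid), 3)),
                     spacing = lv$spacing, origin = lv$origin)
}

test_that("label volumes count voxels and convert to mm^3", {
  g <- array(0L, dim = c(12, 12, 12))
  g[2:11, 2:11, 2:11] <- 3L
  lv <- label_volume(g, spacing = rep(0.021, 3))
  tab <- label_volumes(lv)
  expect_equal(tab$voxels, 1000L)
  expect_equal(tab$volume_mm3, 1000 * 0.021^3, tolerance = 1e-12)
  empty <- label_volumes(label_volume(array(0L, dim = c(4, 4, 4))))
  expect_equal(nrow(empty), 0)
  ## brute-force count oracle on random grids
  set.seed(100)
  for (rep in 1:3) {
    gr <- array(sample(0:4, 6^3, replace = TRUE), dim = c(6, 6, 6))
    tab2 <- label_volumes(label_volume(gr))
    for (r in seq_len(nrow(tab2))) {
      cnt <- 0L
      for (i in 1:6) for (j in 1:6) for (k in 1:6)
        if (gr[i, j, k] == tab2$label[r]) cnt <- cnt + 1L
      expect_equal(tab2$voxels[r], cnt)
    }
  }
})

test_that("warping with a zero field is the identity", {
  lv <- small_label_fixture()
  out <- warp_labels(lv, zero_field_like(lv))
  expect_identical(out$grid, lv$grid)
})

test_that("integer-voxel translation fields preserve label counts", {
  lv <- small_label_fixture()
  shift <- c(2L, -1L, 3L)  # voxels
  fld <- zero_field_like(lv)
  for (c3 in 1:3) fld$grid[, , , c3] <- shift[c3] * lv$spacing[c3]
  out <- warp_labels(lv, fld)
  t_in <- label_volumes(lv); t_out <- label_volumes(out)
  expect_equal(t_out$voxels, t_in$voxels)
  ## and the content is the shifted original
  expect_equal(out$grid[6, 11, 6], lv$grid[8, 10, 9])
})

test_that("a uniform expansion field reproduces the analytic volume ratio", {
  dim3 <- c(48, 48, 48)
  sp <- 0.05
  ctr <- (dim3 - 1) / 2 * sp
  g <- array(0L, dim = dim3)
  idx <- arrayInd(seq_len(prod(dim3)), dim3)
  pos <- sweep(idx - 1, 2, c(sp, sp, sp), "*")
  r <- sqrt(rowSums(sweep(pos, 2, ctr)^2))
  g[r <= 0.5] <- 1L
  lv <- label_volume(g, spacing = rep(sp, 3))
  ## pull-back expansion by 1.2: sample the atlas at x/1.2 (about the center)
  fld <- zero_field_like(lv)
  for (c3 in 1:3) {
    x <- array(rep(0, prod(dim3)), dim = dim3)
    x[] <- (pos[, c3] - ctr[c3]) * (1 / 1.2 - 1)
    fld$grid[, , , c3] <- x
  }
  out <- warp_labels(lv, fld)
  ratio <- label_volumes(out)$voxels / label_volumes(lv)$voxels
  expect_lt(abs(ratio - 1.2^3) / 1.2^3, 0.1)
  ## no labels invented anywhere
  expect_true(all(unique(as.vector(out$grid)) %in% c(0L, 1L)))
})

test_that("warping by a field and its numerical inverse recovers the labels", {
  cfg <- study_config(otolith_grid_size = 64L, otolith_spacing = 0.0225)
  fx <- make_otolith_fixture(cfg, c("mutant", "wildtype"), seed = 3)
  fld <- otolith_displacement_field(fx, 1)
  inv <- invert_displacement_field(fld)
  there <- warp_labels(fx$atlas_labels, fld)
  back <- warp_labels(there, inv)
  fg <- fx$atlas_labels$grid != 0L
  agree <- mean(back$grid[fg] == fx$atlas_labels$grid[fg])
  expect_gte(agree, 0.95)
})

test_that("volume-table comparison follows the validation design", {
  cfg <- study_config()
  groups <- c(rep("mutant", 3), rep("wildtype", 3))
  tabs <- simulate_otolith_volumes(cfg, groups, seed = 4)
  rep0 <- compare_volume_tables(tabs, tabs, groups)
  mv <- rep0$tests[rep0$tests$comparison == "manual_vs_automated", ]
  ## identical tables: all t = 0, p = 1; one overall row plus one per label
  expect_equal(nrow(mv), 6 + 1)
  expect_true(all(mv$t == 0))
  expect_true(all(mv$p == 1))
  expect_error(compare_volume_tables(tabs, tabs[1:4], groups), "missing")
  expect_error(compare_volume_tables(unname(tabs), tabs, groups), "named")
})

test_that("geometry mismatches are rejected", {
  lv <- small_label_fixture()
  bad <- displacement_field(array(0, dim = c(10, 10, 10, 3)),
                            spacing = lv$spacing)
  expect_error(warp_labels(lv, bad), "geometries")
})
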