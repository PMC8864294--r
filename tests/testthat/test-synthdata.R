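test_that("the synthetic template is watertight, symmetric, and fully labeled", {
  tpl <- make_template_mesh()
  expect_true(craniomorph:::is_watertight(tpl))
  v <- tpl$vertices
  mi <- tpl$mirror_index
  expect_equal(v[mi, ], cbind(-v[, 1], v[, 2], v[, 3]), tolerance = 0,
               ignore_attr = TRUE)
  expect_identical(tpl$regions[mi], tpl$regions)
  expect_false(anyNA(tpl$regions))
  expect_setequal(unique(tpl$regions),
                  c("cranium", "frontal", "parietal", "jaws", "operculum",
                    "pectoral_girdle"))
})

test_that("specimen generation honors its ground-truth contract", {
  tpl <- make_template_mesh(n_theta = 23, n_phi = 48)
  ## everything off: the specimen is the template
  cfg0 <- study_config(individual_sd = 0, fa_noise_sd = 0,
                       symmetric_effect_size = 0, asymmetric_effect_size = 0,
                       size_effect = 0, individual_size_sd = 0)
  sp0 <- make_specimen(tpl, "wildtype", cfg0, seed = 1)
  expect_equal(sp0$mesh$vertices, tpl$vertices, tolerance = 1e-12)
  ## pure size effect: centroid sizes scale exactly
  cfg_s <- study_config(individual_sd = 0, fa_noise_sd = 0,
                        symmetric_effect_size = 0, asymmetric_effect_size = 0,
                        size_effect = 0.1, individual_size_sd = 0)
  sp_s <- make_specimen(tpl, "mutant", cfg_s, seed = 2)
  lm <- tpl$vertices[template_landmark_sites(tpl, 23), ]
  expect_equal(centroid_size(deform_points(sp_s, lm)),
               1.1 * centroid_size(lm), tolerance = 1e-12)
  ## asymmetric-only mutants acquire asymmetry; wild types stay symmetric
  cfg_a <- study_config(individual_sd = 0, fa_noise_sd = 0,
                        symmetric_effect_size = 0,
                        asymmetric_effect_size = 0.05,
                        size_effect = 0, individual_size_sd = 0)
  plm <- generate_pseudo_landmarks(tpl, tpl$plane, spacing = 0.35, seed = 3)
  configs <- lapply(1:4, function(i)
    deform_points(make_specimen(tpl, c("mutant", "mutant", "wildtype",
                                       "wildtype")[i], cfg_a, seed = i),
                  plm$points))
  d <- decompose_object_symmetry(configs, plm$map)
  asym_norm <- vapply(1:4, function(i) sqrt(sum(d$asymmetric[, , i]^2)), 0)
  expect_gt(min(asym_norm[1:2]), 100 * max(asym_norm[3:4]))
})

test_that("manual replicates match the chi-distance oracle", {
  lm <- matrix(rnorm(69), 23, 3)
  r0 <- make_manual_replicates(lm, 0, seed = 1)
  expect_equal(r0$rep1, as_landmarks(lm))
  expect_equal(r0$gold, as_landmarks(lm))
  ## replicate spacing: |N(0, 2 sigma^2 I3)| has mean sigma*sqrt(2)*E|chi_3|
  sigma <- 0.05
  set.seed(110)
  mc <- mean(sqrt(rowSums(matrix(rnorm(3e4, 0, sigma * sqrt(2)), ncol = 3)^2)))
  big <- matrix(0, 0, 1)
  dists <- unlist(lapply(1:45, function(s) {
    r <- make_manual_replicates(lm, sigma, seed = s)
    landmark_distances(r$rep1, r$rep2)
  }))
  expect_equal(mean(dists), mc, tolerance = 0.02)
  ## determinism
  expect_identical(make_manual_replicates(lm, sigma, seed = 9),
                   make_manual_replicates(lm, sigma, seed = 9))
  expect_false(identical(make_manual_replicates(lm, sigma, seed = 9)$rep1,
                         make_manual_replicates(lm, sigma, seed = 10)$rep1))
})

test_that("otolith fixtures are disjoint, accurate, and effect-faithful", {
  cfg <- study_config(otolith_grid_size = 96L)
  fx <- make_otolith_fixture(cfg, c("mutant", "wildtype"), seed = 5)
  ## disjoint by construction (overlap raises); all six labels present
  expect_setequal(label_volumes(fx$atlas_labels)$label, 1:6)
  ## voxel-count volume close to the analytic ellipsoid volume
  atlas_tab <- label_volumes(fx$atlas_labels)
  an <- 4 / 3 * pi * fx$geometry$a * fx$geometry$b * fx$geometry$c
  expect_lt(max(abs(atlas_tab$volume_mm3 - an) / an), 0.03)
  ## volume effect multiplies mutant means
  groups <- c(rep("mutant", 40), rep("wildtype", 40))
  tabs <- simulate_otolith_volumes(cfg, groups, seed = 6)
  vol <- t(vapply(tabs, function(tb) tb$volume_mm3, numeric(6)))
  ratio <- colMeans(vol[1:40, ]) / colMeans(vol[41:80, ])
  expect_equal(unname(ratio[5:6]), c(1.25, 1.25), tolerance = 0.08)
  ## a unit effect leaves the groups exchangeable in expectation
  cfg1 <- study_config(otolith_volume_effect = c(lapillus = 1, sagitta = 1,
                                                 asteriscus = 1))
  tabs1 <- simulate_otolith_volumes(cfg1, groups, seed = 7)
  vol1 <- t(vapply(tabs1, function(tb) tb$volume_mm3, numeric(6)))
  ratio1 <- colMeans(vol1[1:40, ]) / colMeans(vol1[41:80, ])
  expect_lt(max(abs(ratio1 - 1)), 0.08)
})

test_that("the assembled study is reproducible and correctly sized", {
  cfg <- study_config(n_mutant = 3, n_wildtype = 3, otolith_grid_size = 48L, otolith_spacing = 0.03,
                      seed = 77)
  s1 <- make_study(cfg)
  s2 <- make_study(cfg)
  expect_identical(serialize(s1, NULL), serialize(s2, NULL))
  expect_equal(nrow(s1$design), 6)
  ## default design matches the emulated study
  cfg_d <- study_config()
  expect_equal(cfg_d$n_mutant + cfg_d$n_wildtype, 26L)
  expect_equal(cfg_d$k_manual, 23L)
  expect_equal(cfg_d$pseudo_target, 372L)
  ## ground-truth ledger records every injected effect
  expect_named(s1$ground_truth$injected_effects,
               c("symmetric_shape", "asymmetric_shape", "size",
                 "otolith_volume"))
})

test_that("study export writes the standard formats", {
  cfg <- study_config(n_mutant = 2, n_wildtype = 2, otolith_grid_size = 32L, otolith_spacing = 0.045,
                      seed = 8)
  st <- make_study(cfg)
  dir <- file.path(tempdir(), "study_export")
  write_study(st, dir)
  expect_true(file.exists(file.path(dir, "template.ply")))
  expect_true(file.exists(file.path(dir, "design.csv")))
  expect_true(file.exists(file.path(dir, "atlas_otoliths.nrrd")))
  expect_true(file.exists(file.path(dir, "ground_truth.json")))
  ids <- st$design$id
  expect_true(all(file.exists(file.path(dir, paste0(ids, ".ply")))))
  back <- read_mesh(file.path(dir, paste0(ids[1], ".ply")))
  expect_equal(back$vertices, st$specimens[[1]]$mesh$vertices,
               tolerance = 1e-15)
})
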