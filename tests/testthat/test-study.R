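# A reduced-size study keeps the end-to-end tests fast; the full-size
# default preset is exercised by the acceptance suite.
small_study <- function(seed = 5, ...) {
  make_study(study_config(n_mutant = 4, n_wildtype = 4,
                          otolith_grid_size = 48L, otolith_spacing = 0.03,
                          seed = seed, ...))
}
small_analysis <- function(seed = 5) {
  analysis_config(pseudo_target = 150L, n_permutations = 99L,
                  target_points = 500L, sliding_rounds = 2L,
                  n_pcs_tested = 2L, seed = seed)
}

test_that("the end-to-end study runs, reports every section, and is deterministic", {
  st <- small_study()
  r1 <- suppressWarnings(run_study(st, small_analysis()))
  expect_s3_class(r1, "study_report")
  ## structure: every statistical entry carries p, permutations, and seed
  for (tst in list(r1$symmetry$test_symmetric, r1$symmetry$test_asymmetric,
                   r1$validation$method_shape_test)) {
    expect_true(all(c("F", "Z", "p", "n_permutations", "seed") %in% names(tst)))
    expect_gte(tst$p, 1 / (tst$n_permutations + 1))
  }
  expect_equal(length(r1$transfer$per_specimen_error), 8)
  expect_equal(nrow(r1$otolith$tests), 1 + 6 + 6)
  ## per-landmark signed-rank table covers all manual landmarks
  expect_length(r1$validation$per_landmark_tests, st$config$k_manual)
  ## deterministic rerun, bit for bit
  r2 <- suppressWarnings(run_study(small_study(), small_analysis()))
  expect_identical(serialize(r1, NULL), serialize(r2, NULL))
})

test_that("stage failures name the stage and the offending specimen", {
  st <- small_study()
  st$specimens[[2]]$mesh$vertices[1, 1] <- NA_real_
  expect_error(suppressWarnings(run_study(st, small_analysis())),
               "transfer.*(mut_02|specimen)")
})

test_that("an asymmetric-only effect is detected in the asymmetric component only", {
  st <- make_study(study_config(n_mutant = 6, n_wildtype = 6,
                                symmetric_effect_size = 0, size_effect = 0,
                                asymmetric_effect_size = 0.06, seed = 31),
                   include_volumes = FALSE)
  cfgA <- analysis_config(pseudo_target = 200L, n_permutations = 199L,
                          target_points = 600L, seed = 31)
  r <- suppressWarnings(run_study(st, cfgA))
  expect_lt(r$symmetry$test_asymmetric$p, 0.05)
  expect_gt(r$symmetry$test_symmetric$p, 0.05)
  ## heat-map localization: the asymmetric group field peaks where the
  ## effect was injected (parietal/opercular bumps)
  fld <- r$group_fields$asymmetric
  expect_equal(length(fld), r$pseudo_landmarks$count)
  reg <- st$template$regions[r$pseudo_landmarks$vertex_index]
  top <- order(fld, decreasing = TRUE)[seq_len(ceiling(length(fld) / 10))]
  expect_gt(mean(reg[top] %in% c("parietal", "operculum")), 0.5)
})

test_that("report files are written atomically and completely", {
  st <- small_study(seed = 6)
  r <- suppressWarnings(run_study(st, small_analysis(seed = 6)))
  dir <- file.path(tempdir(), "report_out")
  write_study_report(r, dir)
  expect_true(file.exists(file.path(dir, "report.json")))
  expect_true(file.exists(file.path(dir, "transfer_error.csv")))
  expect_true(file.exists(file.path(dir, "group_difference_fields.csv")))
  expect_true(file.exists(file.path(dir, "otolith_tests.csv")))
  js <- jsonlite::read_json(file.path(dir, "report.json"))
  expect_true(!is.null(js$symmetry$test_symmetric$p))
  expect_true(!is.null(js$provenance$config$seed))
  ## no stray temp files left behind
  expect_length(list.files(dir, pattern = "\\.tmp$"), 0)
})
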