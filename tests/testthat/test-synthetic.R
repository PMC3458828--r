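test_that("identical seeds give bit-identical cohorts", {
  cfg <- simulation_config(n_regions = 20, n_patients = 5, n_controls = 5,
                           affected_edges = 10, seed = 123)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$features, b$features)
  expect_identical(a$truth, b$truth)
  c <- generate_cohort(simulation_config(n_regions = 20, n_patients = 5,
                                         n_controls = 5, affected_edges = 10,
                                         seed = 124))
  expect_false(identical(a$features, c$features))
})

test_that("a unit effect multiplier yields identical group populations", {
  cfg <- simulation_config(n_regions = 16, n_patients = 4, n_controls = 4,
                           effect_multiplier = 1, seed = 9)
  co <- generate_cohort(cfg)
  expect_equal(co$truth$mean_patient, co$truth$mean_control)
  expect_equal(attr(co$truth, "background"), 1)
})

test_that("affected edges get patient mean = multiplier x control mean", {
  cfg <- simulation_config(n_regions = 30, n_patients = 5, n_controls = 5,
                           affected_edges = 10, effect_multiplier = 1.8,
                           seed = 31)
  co <- generate_cohort(cfg)
  expect_equal(nrow(co$truth), 10)
  expect_equal(co$truth$mean_patient, 1.8 * co$truth$mean_control)
  # off-target edges share a solved background elevation
  expect_gt(attr(co$truth, "background"), 1)
})

test_that("invalid configurations are rejected with informative errors", {
  expect_error(simulation_config(n_patients = 1), "at least 2")
  expect_error(simulation_config(density = 0), "density")
  expect_error(simulation_config(effect_multiplier = -1), "positive")
  expect_error(simulation_config(affected_edges = cbind(3, 3)),
               "off-diagonal")
  # affected pair outside the sparse support is named
  cfg <- simulation_config(n_regions = 10, n_patients = 3, n_controls = 3,
                           density = 0.1,
                           affected_edges = cbind(c(1, 2), c(2, 3)),
                           seed = 77)
  expect_error(generate_cohort(cfg), "outside the template support")
  # density too low to place the requested number of edges
  cfg2 <- simulation_config(n_regions = 6, n_patients = 3, n_controls = 3,
                            density = 0.2, affected_edges = 10, seed = 1)
  expect_error(generate_cohort(cfg2), "density too low")
})

test_that("null cohorts give uniform edge-wise t-test p-values", {
  # independence across edges requires no shared per-subject scale factor;
  # edges clipped by the threshold for any subject are excluded because
  # their mixed discrete-continuous distribution is not the t-test's.
  cfg <- simulation_config(n_regions = 90, n_patients = 20, n_controls = 20,
                           affected_edges = 0, effect_multiplier = 1,
                           subject_scale_sd = 0, seed = 2024)
  co <- generate_cohort(cfg)
  keep <- colSums(co$features == 0) == 0
  expect_gte(sum(keep), 1000)
  p <- col_ttest(co$features[, keep], co$labels)$p
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("larger effect multipliers give larger affected-edge t statistics", {
  mean_t <- vapply(c(1.3, 2, 3.5), function(m) {
    cfg <- simulation_config(n_regions = 30, n_patients = 12,
                             n_controls = 12, affected_edges = 8,
                             effect_multiplier = m, seed = 55)
    co <- generate_cohort(cfg)
    mean(col_ttest(co$features, co$labels)$t[co$truth$feature])
  }, numeric(1))
  expect_true(all(diff(mean_t) > 0))
})

test_that("group mean nonzero strengths match the calibration targets", {
  cfg <- simulation_config(n_patients = 60, n_controls = 60, seed = 314)
  co <- generate_cohort(cfg)
  ms <- vapply(co$matrices, mean_nonzero_strength, numeric(1))
  for (g in c("patient", "control")) {
    target <- if (g == "patient") 0.0499 else 0.0412
    x <- ms[co$labels == g]
    se <- sd(x) / sqrt(length(x))
    expect_lt(abs(mean(x) - target), 3 * se)
  }
})

test_that("fiber counts follow the strength-scaled count law", {
  vc <- rep(10, 12)
  cfg <- simulation_config(n_regions = 12, n_patients = 25, n_controls = 25,
                           affected_edges = 0, effect_multiplier = 1,
                           emit_counts = TRUE, voxel_counts = vc,
                           samples_per_voxel = 5000, seed = 88)
  sim <- generate_fiber_counts(cfg)
  expect_length(sim$subjects, 50)

  # zero-strength edges never produce counts
  zero_edges <- sim$intended[[1]] == 0
  diag(zero_edges) <- FALSE
  expect_true(all(sim$subjects[[1]]$counts[zero_edges] == 0))

  # round trip: rebuilt strengths are unbiased for the intended ones
  diffs <- vapply(seq_along(sim$subjects), function(s) {
    rebuilt <- build_connectivity_matrix(sim$subjects[[s]], threshold = 0)
    mean(vectorize_matrix(rebuilt) - vectorize_matrix(sim$intended[[s]]))
  }, numeric(1))
  expect_lt(abs(mean(diffs)), 3 * sd(diffs) / sqrt(length(diffs)) + 1e-12)

  expect_error(generate_fiber_counts(
    simulation_config(emit_counts = TRUE, voxel_counts = c(-1, rep(10, 89)),
                      n_regions = 90, seed = 1)), "positive")
  expect_error(generate_fiber_counts(simulation_config(seed = 1)),
               "emit_counts")
})

test_that("written cohorts round-trip through the manifest", {
  dir <- withr::local_tempdir()
  cfg <- simulation_config(n_regions = 12, n_patients = 3, n_controls = 4,
                           affected_edges = 4, seed = 42)
  co <- generate_cohort(cfg)
  man <- write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "truth.csv")))
  back <- load_cohort(man)
  expect_equal(back$features, co$features, ignore_attr = TRUE)
})
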