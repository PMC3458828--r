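make_tiny_cohort <- function(seed = 501, sep = 4) {
  # 4 subjects, strong 2-vs-2 separation on a few edges
  set.seed(seed)
  mats <- lapply(1:4, function(s) {
    v <- runif(n_edges(8), 0.02, 0.05)
    if (s <= 2) v[1:3] <- v[1:3] + sep * 0.01
    devectorize_matrix(v, 8)
  })
  new_cohort(mats, c("patient", "patient", "control", "control"),
             validate = FALSE)
}

tiny_config <- function() {
  pipeline_config(n_features = 4, k_lle = 2, d_lle = 1, p_ceiling = NULL)
}

test_that("permutation p-values hit their boundary cases", {
  co <- make_tiny_cohort()
  pc <- tiny_config()
  pr <- permutation_test(co, pc, n_permutations = 30, seed = 1)
  expect_true(pr$p_value >= 1 / 31 && pr$p_value <= 1)
  # observed never below any null -> p = 1 exactly when all null >= observed
  fake <- structure(list(gr = -1), class = "cv_result")
  pr_low <- permutation_test(co, pc, n_permutations = 19, seed = 2,
                             observed = fake)
  expect_equal(pr_low$p_value, 1)
  fake_hi <- structure(list(gr = 101), class = "cv_result")
  pr_hi <- permutation_test(co, pc, n_permutations = 99, seed = 3,
                            observed = fake_hi)
  expect_equal(pr_hi$p_value, 1 / 100)
})

test_that("sampled permutation p matches the exhaustive enumeration oracle", {
  co <- make_tiny_cohort()
  pc <- tiny_config()
  obs <- run_loocv(co, pc)
  # enumerate all 6 distinct 2-vs-2 label assignments
  asg <- utils::combn(4, 2)
  null_grs <- apply(asg, 2, function(pat) {
    co2 <- co
    co2$labels <- factor(ifelse(seq_len(4) %in% pat, "patient", "control"),
                         levels = c("control", "patient"))
    run_loocv(co2, pc)$gr
  })
  p_star <- mean(null_grs >= obs$gr)     # probability under a random shuffle
  n <- 299
  pr <- permutation_test(co, pc, n_permutations = n, seed = 4,
                         observed = obs)
  expected <- (n * p_star + 1) / (n + 1)
  band <- 3 * sqrt(p_star * (1 - p_star) / n) + 1 / (n + 1)
  expect_lt(abs(pr$p_value - expected), band + 1e-12)
})

test_that("permutation runs are reproducible under a fixed seed", {
  co <- make_tiny_cohort()
  pc <- tiny_config()
  a <- permutation_test(co, pc, n_permutations = 20, seed = 9)
  b <- permutation_test(co, pc, n_permutations = 20, seed = 9)
  expect_identical(a$null_grs, b$null_grs)
  expect_identical(a$p_value, b$p_value)
})

test_that("consensus is the fold intersection with per-edge annotations", {
  cfg <- simulation_config(n_regions = 16, n_patients = 6, n_controls = 6,
                           affected_edges = 6, effect_multiplier = 6,
                           seed = 502)
  co <- suppressWarnings(generate_cohort(cfg))   # target overshoot warning
  cv <- run_loocv(co, pipeline_config(n_features = 8, k_lle = 5, d_lle = 3,
                                      p_ceiling = NULL))
  rep <- consensus_features(cv, co)
  manual <- sort(Reduce(intersect, lapply(cv$folds, `[[`, "selected")))
  expect_equal(rep$feature, manual)
  # mean p equals the hand-computed mean over folds
  if (nrow(rep) > 0) {
    f <- rep$feature[1]
    ps <- vapply(cv$folds, function(fd) fd$p_values[match(f, fd$selected)],
                 numeric(1))
    expect_equal(rep$mean_p[1], mean(ps))
  }
  # fold order cannot matter
  cv2 <- cv
  cv2$folds <- rev(cv2$folds)
  expect_equal(consensus_features(cv2, co)$feature, rep$feature)
})

test_that("degenerate consensus cases behave", {
  co <- make_tiny_cohort()
  cv <- run_loocv(co, tiny_config())
  # identical selections -> consensus equals that set
  cv_same <- cv
  for (i in seq_along(cv_same$folds)) {
    cv_same$folds[[i]]$selected <- c(2L, 5L, 9L)
    cv_same$folds[[i]]$p_values <- c(0.01, 0.02, 0.03)
  }
  expect_equal(consensus_features(cv_same, co)$feature, c(2L, 5L, 9L))
  # disjoint selections -> empty consensus is valid
  cv_disj <- cv
  for (i in seq_along(cv_disj$folds)) {
    cv_disj$folds[[i]]$selected <- i * 3L + 0:2
    cv_disj$folds[[i]]$p_values <- rep(0.5, 3)
  }
  empty <- consensus_features(cv_disj, co)
  expect_equal(nrow(empty), 0)
  expect_equal(sum(region_weights(empty)), 0)
})

test_that("region weights count incidences and satisfy the handshake identity", {
  rep_df <- structure(
    data.frame(feature = c(1L, 2L), region_a = c(1L, 1L),
               region_b = c(2L, 3L), label = c("a", "b"),
               network = NA, subnetwork = NA, mean_p = c(0.1, 0.2),
               direction = "increased"),
    class = c("consensus_report", "data.frame"), n_regions = 5L)
  w <- region_weights(rep_df)
  expect_equal(unname(w[1:3]), c(2, 1, 1))
  expect_equal(sum(w), 2 * nrow(rep_df))

  withr::local_seed(503)
  # handshake holds for arbitrary reports
  n <- 30
  rnd <- structure(
    data.frame(feature = seq_len(n),
               region_a = sample(1:20, n, TRUE),
               region_b = sample(21:40, n, TRUE), label = "x",
               network = NA, subnetwork = NA, mean_p = runif(n),
               direction = "increased"),
    class = c("consensus_report", "data.frame"), n_regions = 40L)
  expect_equal(sum(region_weights(rnd)), 2 * n)
})

test_that("atlas lookups annotate 90-region edges", {
  atlas <- region_atlas()
  expect_equal(nrow(atlas), 90)
  tax <- consensus_taxonomy()
  expect_equal(nrow(tax), 33)
  # a known cortical-limbic pair: left middle orbital frontal - left hippocampus
  i <- atlas$index[atlas$abbrev == "ORBmid" & atlas$hemisphere == "L"]
  j <- atlas$index[atlas$abbrev == "HIP" & atlas$hemisphere == "L"]
  ann <- annotate_edges(c(i, 1), c(j, 2))
  expect_equal(ann$network[1], "Cortical-Limbic")
  expect_equal(ann$subnetwork[1], "frontal-limbic")
  # unlisted pairs fall back to the lobe-pair tag
  expect_equal(ann$network[2], "frontal-frontal")
  expect_match(edge_labels(i, j), "ORBmid.L--HIP.L", fixed = TRUE)
})
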