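curve_measurements <- function(specimen_id, angles, offsets, round = 1L) {
  tibble::tibble(specimen_id = specimen_id,
                 image_id = paste0(specimen_id, "_", angles),
                 round = round, rotation_deg = angles, offset_mm = offsets)
}

test_that("sweep fields follow their definitions on a tiny curve", {
  sw <- analyze_sweeps(curve_measurements("A", c(-2, 0, 2), c(37, 38, 37.5)))
  expect_equal(sw$true_offset_mm, 38)
  expect_equal(sw$aligned_offset_mm, 38)
  expect_equal(sw$underestimation_mm, 0)
  expect_equal(sw$underestimation_pct, 0)
  expect_equal(sw$rotation_at_max_deg, 0)
  expect_false(sw$rotation_at_max_tied)
  expect_equal(sw$range_pm10_mm, 1)
})

test_that("noiseless simulated sweep matches the cosine closed form", {
  model <- femur_model(true_offset_mm = 40, offset_plane_deg = -6)
  grid <- seq(-10, 10, 2)
  meas <- dplyr::bind_rows(lapply(grid, function(th) {
    img <- project_femur(model, th, noise_sd_px = 0)
    tibble::tibble(specimen_id = "S01", image_id = img$landmarks$image_id[1],
                   round = 1L, rotation_deg = th,
                   offset_mm = measure_offset(img$landmarks)$offset_mm)
  }))
  sw <- analyze_sweeps(meas)
  expect_equal(sw$rotation_at_max_deg, -6)
  expect_equal(sw$true_offset_mm, 40, tolerance = 1e-6)
  expect_equal(sw$aligned_offset_mm, 40 * cos(6 * pi / 180), tolerance = 1e-6)
  expect_equal(sw$aligned_offset_mm, 39.781, tolerance = 1e-4)
})

test_that("ties at the maximum break towards small then internal rotation, and are flagged", {
  sw <- analyze_sweeps(curve_measurements("A", c(-2, 0, 2), c(38, 37, 38)))
  expect_equal(sw$rotation_at_max_deg, 2)
  expect_true(sw$rotation_at_max_tied)
  sw2 <- analyze_sweeps(curve_measurements("A", c(-4, 0, 4, 6), c(38, 37, 37.5, 38)))
  expect_equal(sw2$rotation_at_max_deg, -4)
})

test_that("a grid without neutral or with duplicate measurements is an error", {
  expect_error(analyze_sweeps(curve_measurements("A", c(-2, 2), c(37, 38))),
               "lacks 0")
  dup <- curve_measurements("A", c(-2, 0, 0), c(37, 38, 38))
  expect_error(analyze_sweeps(dup), "duplicate")
})

test_that("rounds are averaged before maximisation under mean_of_rounds", {
  two_rounds <- dplyr::bind_rows(
    curve_measurements("A", c(-2, 0, 2), c(40, 39, 36), round = 1L),
    curve_measurements("A", c(-2, 0, 2), c(36, 39, 40), round = 2L))
  avg <- analyze_sweeps(two_rounds, rounds_policy = "mean_of_rounds")
  expect_equal(avg$true_offset_mm, 39)
  expect_equal(avg$rotation_at_max_deg, 0)
  per <- analyze_sweeps(two_rounds, rounds_policy = "per_round")
  expect_equal(nrow(per), 2L)
  expect_equal(per$rotation_at_max_deg, c(-2, 2))
})

test_that("cohort summary reproduces hand-checkable statistics", {
  sw <- tibble::tibble(rotation_at_max_deg = c(5, 5, 5))
  s <- summarize_cohort(sw)
  expect_equal(s$mean, 5)
  expect_equal(s$sd, 0)
  expect_equal(s$median, 5)

  # published per-specimen rotation-at-maximum distribution
  rot <- tibble::tibble(rotation_at_max_deg = c(0, 0, -10, -10, -8, -6, -6,
                                                -6, -4, 2, 8))
  r <- summarize_cohort(rot)
  expect_equal(round(r$mean, 1), -3.6)
  expect_equal(round(r$sd, 1), 5.6)
  expect_equal(r$median, -6)
  expect_equal(c(r$min, r$max), c(-10, 8))
})

test_that("cohort underestimation is linear in the specimen means", {
  sw <- tibble::tibble(true_offset_mm = rep(38.2, 11),
                       aligned_offset_mm = rep(37.3, 11))
  s <- summarize_cohort(dplyr::mutate(
    sw, underestimation_mm = true_offset_mm - aligned_offset_mm))
  expect_equal(s$mean[s$metric == "underestimation_mm"], 0.9)
  expect_equal(round(s$mean[s$metric == "underestimation_pct_pooled"], 1), 2.4)

  # linearity on arbitrary sweeps: mean difference equals difference of means
  withr::with_seed(6, {
    rand <- tibble::tibble(true_offset_mm = runif(9, 30, 46))
    rand$aligned_offset_mm <- rand$true_offset_mm - runif(9, 0, 2)
    rand$underestimation_mm <- rand$true_offset_mm - rand$aligned_offset_mm
    s2 <- summarize_cohort(rand)
    expect_equal(s2$mean[s2$metric == "underestimation_mm"],
                 s2$mean[s2$metric == "true_offset_mm"] -
                   s2$mean[s2$metric == "aligned_offset_mm"])
  })
})

test_that("on noiseless cohorts the maximum falls at the grid point nearest theta0", {
  cfg <- cohort_config(n_specimens = 8, landmark_noise_sd_px = 0,
                       theta0_sd_deg = 3, n_rater_rounds = 1, seed = 77)
  sim <- simulate_cohort(cfg)
  sweeps <- analyze_sweeps(measure_offsets(sim$landmarks))
  truth <- dplyr::arrange(sim$specimens, specimen_id)
  inner <- seq(-10, 10, 2)
  nearest <- vapply(truth$theta0_deg, function(t0) {
    g <- cfg$angle_grid_deg
    g[which.max(abs(cos((g - t0) * pi / 180)))]
  }, numeric(1))
  keep <- abs(truth$theta0_deg) < 9  # away from grid-edge ambiguity
  expect_equal(sweeps$rotation_at_max_deg[keep], nearest[keep])
  expect_true(all(sweeps$aligned_offset_mm <= sweeps$true_offset_mm))
})

test_that("the cohort curve plot is a ggplot with one line per specimen", {
  sim <- simulate_cohort(cohort_config(n_specimens = 2, n_rater_rounds = 1,
                                       seed = 14))
  p <- plot_offset_curves(measure_offsets(sim$landmarks))
  expect_s3_class(p, "ggplot")
})
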