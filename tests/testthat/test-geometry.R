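test_that("total-least-squares line recovers exact collinear configurations", {
  v <- fit_line(cbind(rep(0, 5), 0:4))
  expect_equal(v$direction, c(0, 1))
  expect_equal(v$anchor, c(0, 0))
  expect_equal(v$rms_residual, 0)

  d <- fit_line(cbind(0:2, 0:2))
  expect_equal(d$direction, c(sqrt(2) / 2, sqrt(2) / 2))

  expect_error(fit_line(cbind(c(3, 3), c(7, 7))), "coincident")
})

test_that("line fit matches a brute-force grid oracle on noisy near-vertical points", {
  withr::with_seed(21, {
    for (i in 1:20) {
      pts <- cbind(3 + runif(5, -0.1, 0.1), seq(0, 8, 2) + rnorm(5, sd = 0.2))
      fit <- fit_line(pts)
      ss_fit <- line_ss_of_fit(pts, fit)
      ss_oracle <- oracle_line_ss(pts)
      expect_lte(ss_fit, ss_oracle + 1e-6)
    }
  })
})

test_that("bisector handles parallel, symmetric, and generic line pairs", {
  par <- bisect_lines(fit_line(cbind(0, 0:4)), fit_line(cbind(10, 0:4)))
  expect_equal(par$direction, c(0, 1))
  expect_equal(par$anchor[1], 5)

  a10 <- fit_line(cbind(sin(10 * pi / 180) * (0:4), cos(10 * pi / 180) * (0:4)))
  b10 <- fit_line(cbind(-sin(10 * pi / 180) * (0:4), cos(10 * pi / 180) * (0:4)))
  sym <- bisect_lines(a10, b10)
  expect_equal(sym$direction, c(0, 1))
  expect_equal(point_to_line_dist(c(0, 0), sym), 0, tolerance = 1e-12)

  # every point on a generic bisector is equidistant from the two lines
  withr::with_seed(8, {
    for (i in 1:10) {
      th1 <- runif(1, 0, pi); th2 <- runif(1, 0, pi)
      a <- fit_line(rbind(runif(2, -5, 5),
                          runif(2, -5, 5) + 3 * c(cos(th1), sin(th1))))
      b <- fit_line(rbind(runif(2, -5, 5),
                          runif(2, -5, 5) + 3 * c(cos(th2), sin(th2))))
      bis <- bisect_lines(a, b)
      for (t in c(-2, 0, 5)) {
        p <- bis$anchor + t * bis$direction
        expect_equal(point_to_line_dist(p, a), point_to_line_dist(p, b),
                     tolerance = 1e-9)
      }
    }
  })
})

test_that("circle fit is exact on exact circles and rejects collinear input", {
  unit <- fit_circle(cbind(c(1, 0, -1, 0), c(0, 1, 0, -1)))
  expect_equal(unit$center, c(0, 0), tolerance = 1e-12)
  expect_equal(unit$radius, 1, tolerance = 1e-12)
  expect_equal(unit$rms_residual, 0, tolerance = 1e-9)

  six <- fit_circle(circle_points(c(5, -3), 12, seq(0, 300, 60)))
  expect_equal(six$center, c(5, -3), tolerance = 1e-9)
  expect_equal(six$radius, 12, tolerance = 1e-9)

  expect_error(fit_circle(cbind(0:3, 2 * (0:3))), "collinear")
})

test_that("circle fit matches a direct Nelder-Mead oracle on noisy arcs", {
  withr::with_seed(33, {
    for (i in 1:20) {
      pts <- circle_points(runif(2, -20, 20), 40, seq(0, 300, 60),
                           radial_sd = 0.5)
      fit <- fit_circle(pts)
      oracle <- oracle_circle_fit(pts)
      ss_fit <- circle_geometric_ss(pts, fit$center[1], fit$center[2],
                                    fit$radius)
      expect_lte(ss_fit, oracle$value + 1e-8)
      expect_equal(fit$center, oracle$par[1:2], tolerance = 1e-3)
    }
  })
})

test_that("sphere calibration converts pixels to millimetres", {
  cal <- calibrate(circle_points(c(0, 0), 50, seq(0, 288, 72)))
  expect_equal(cal$mm_per_px, 0.254, tolerance = 1e-12)
  expect_equal(calibrate(circle_points(c(7, 9), 25.4, seq(0, 288, 72)))$mm_per_px,
               0.5, tolerance = 1e-12)
  # doubling all pixel coordinates halves the scale
  pts <- circle_points(c(10, -5), 80, seq(0, 300, 60))
  expect_equal(calibrate(2 * pts)$mm_per_px, calibrate(pts)$mm_per_px / 2,
               tolerance = 1e-12)
})

test_that("offset measurement on a hand-built symmetric image is exact and linear in scale", {
  ys <- seq(0, 80, 20)
  lm <- make_landmark_set(
    medial = cbind(rep(-10, 5), ys),
    lateral = cbind(rep(10, 5), ys),
    head = circle_points(c(25, -60), 15, seq(0, 300, 60)),
    sphere = circle_points(c(-80, 40), 12.7, seq(0, 288, 72)))  # mm_per_px 1
  m <- measure_offset(lm)
  expect_equal(m$offset_mm, 25, tolerance = 1e-9)
  expect_equal(m$calibration$mm_per_px, 1, tolerance = 1e-12)

  half <- measure_offset(lm, calibration = calibrate(
    circle_points(c(-80, 40), 25.4, seq(0, 288, 72))))
  expect_equal(half$offset_mm, 12.5, tolerance = 1e-9)

  expect_error(measure_offset(dplyr::filter(lm, role != "head")),
               "missing role 'head'")
})

test_that("offset is invariant to rigid motion and pixel rescaling of the whole image", {
  sim <- simulate_cohort(cohort_config(n_specimens = 2, n_rater_rounds = 1,
                                       seed = 17))
  base <- measure_offsets(sim$landmarks)

  rotate_df <- function(df, phi, dx, dy) {
    x <- df$x_px * cos(phi) - df$y_px * sin(phi) + dx
    y <- df$x_px * sin(phi) + df$y_px * cos(phi) + dy
    df$x_px <- x
    df$y_px <- y
    df
  }
  moved <- measure_offsets(rotate_df(sim$landmarks, 0.7, 123, -45))
  expect_equal(moved$offset_mm, base$offset_mm, tolerance = 1e-9)

  scaled <- sim$landmarks
  scaled$x_px <- scaled$x_px * 3.7
  scaled$y_px <- scaled$y_px * 3.7
  expect_equal(measure_offsets(scaled)$offset_mm, base$offset_mm,
               tolerance = 1e-9)
})

test_that("mirror-symmetric cortices put the shaft axis on the mirror line", {
  withr::with_seed(4, {
    for (i in 1:10) {
      x0 <- runif(1, -50, 50)
      medial <- cbind(x0 - runif(5, 5, 15), seq(0, 40, 10) + rnorm(5))
      lateral <- medial
      lateral[, 1] <- 2 * x0 - medial[, 1]  # mirror across x = x0
      axis <- bisect_lines(fit_line(medial), fit_line(lateral))
      expect_equal(abs(axis$direction[2]), 1, tolerance = 1e-9)
      expect_equal(point_to_line_dist(c(x0, 0), axis), 0, tolerance = 1e-9)
    }
  })
})
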