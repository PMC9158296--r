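# Independent brute-force oracles, kept deliberately separate from the
# package's fitting routines.

# Orthogonal-regression objective of a line given by normal angle psi and
# signed distance rho: residual_i = x_i cos(psi) + y_i sin(psi) - rho.
line_orthogonal_ss <- function(points, psi, rho) {
  sum((points[, 1] * cos(psi) + points[, 2] * sin(psi) - rho)^2)
}

# Best orthogonal line by exhaustive search over the normal angle; for each
# angle the optimal rho is the mean projection (closed form).
oracle_line_ss <- function(points, n_grid = 20000L) {
  psis <- seq(0, pi, length.out = n_grid)
  best <- Inf
  for (psi in psis) {
    proj <- points[, 1] * cos(psi) + points[, 2] * sin(psi)
    ss <- sum((proj - mean(proj))^2)
    if (ss < best) best <- ss
  }
  best
}

line_ss_of_fit <- function(points, line) {
  d <- (points[, 1] - line$anchor[1]) * line$direction[2] -
    (points[, 2] - line$anchor[2]) * line$direction[1]
  sum(d^2)
}

circle_geometric_ss <- function(points, cx, cy, r) {
  sum((sqrt((points[, 1] - cx)^2 + (points[, 2] - cy)^2) - r)^2)
}

# Direct Nelder-Mead minimisation of the geometric circle objective from a
# crude initial guess (centroid, mean distance to centroid).
oracle_circle_fit <- function(points) {
  ctr <- colMeans(points)
  r0 <- mean(sqrt((points[, 1] - ctr[1])^2 + (points[, 2] - ctr[2])^2))
  obj <- function(p) circle_geometric_ss(points, p[1], p[2], p[3])
  fit <- stats::optim(c(ctr, r0), obj, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-14))
  list(par = fit$par, value = fit$value)
}

# ICC(2,1) from the definition: two-way sums of squares computed by hand.
oracle_icc21 <- function(m) {
  n <- nrow(m)
  k <- ncol(m)
  gm <- mean(m)
  ssr <- k * sum((rowMeans(m) - gm)^2)
  ssc <- n * sum((colMeans(m) - gm)^2)
  sst <- sum((m - gm)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

point_to_line_dist <- function(p, line) {
  abs((p[1] - line$anchor[1]) * line$direction[2] -
        (p[2] - line$anchor[2]) * line$direction[1])
}

# Points on a circle, optionally with radial Gaussian noise.
circle_points <- function(center, radius, angles_deg, radial_sd = 0) {
  a <- angles_deg * pi / 180
  r <- radius + stats::rnorm(length(a), sd = radial_sd)
  cbind(center[1] + r * cos(a), center[2] + r * sin(a))
}

# A minimal valid one-image landmark tibble built around explicit geometry.
make_landmark_set <- function(medial, lateral, head, sphere,
                              specimen_id = "S01", image_id = "img1",
                              rotation_deg = 0, round = 1L) {
  stack <- function(m, role) {
    tibble::tibble(specimen_id = specimen_id, image_id = image_id,
                   rotation_deg = rotation_deg, role = role,
                   x_px = m[, 1], y_px = m[, 2], round = round)
  }
  dplyr::bind_rows(stack(medial, "medial_cortex"),
                   stack(lateral, "lateral_cortex"),
                   stack(head, "head"),
                   stack(sphere, "calibration"))
}
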