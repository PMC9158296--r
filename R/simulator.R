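#' Synthetic fluoroscopic projection of a parametric proximal femur
#'
#' @description
#' The simulator stands in for the cadaveric rig: a 3-D proximal femur is
#' rotated about its shaft axis and projected orthographically (parallel
#' beam) onto the image plane, emitting the same landmark roles a rater would
#' click. Orthographic projection is the idealisation that an in-plane
#' calibration sphere corrects for exactly, so magnification is uniform and
#' the cylinder silhouette half-width is constant in rotation.
#'
#' In the femur frame every feature sits at a cylindrical position
#' `(d, phi, z)` about the shaft axis; at actuator rotation `theta` (internal
#' rotation positive) its horizontal image coordinate is
#' `d * cos(theta - phi) / mm_per_px` from the projected shaft axis. The head
#' centre sits at distance `true_offset_mm` in the offset plane at azimuth
#' `offset_plane_deg` (`theta0`), so the noiseless projected offset follows
#' the cosine law `R * |cos(theta - theta0)|`: maximal when the offset plane
#' is parallel to the image plane, shrinking as the femur rotates away.
#'
#' `theta0` is the angular discrepancy between the line-aligned neutral
#' (rotation 0, where the two trochanteric radiographic lines superimpose)
#' and the rotation of true offset. The two trochanteric source points are
#' placed so their projections coincide horizontally at rotation 0 by
#' construction; their exact 3-D positions are free parameters of the model.
#'
#' @name simulator
NULL

deg2rad <- function(d) d * pi / 180

#' Parametric 3-D proximal femur
#'
#' @param true_offset_mm Perpendicular distance from the head centre to the
#'   shaft axis (3-D femoral offset), mm.
#' @param offset_plane_deg Angle `theta0` between the head-offset plane and
#'   the image plane at the line-aligned neutral; external rotation negative.
#' @param shaft_radius_mm,shaft_length_mm Shaft cylinder dimensions, mm.
#' @param head_radius_mm Femoral head radius, mm.
#' @param troch_posterior_d_mm,troch_posterior_az_deg Cylindrical position of
#'   the point producing the posterior radiographic line (most posterior
#'   aspect of the medial greater trochanter).
#' @param troch_anterior_az_deg Azimuth of the point producing the anterior
#'   line (anterior arc of the trochanteric fossa); its radial distance is
#'   derived so both lines superimpose at rotation 0.
#' @return A `femur_model` list.
#' @export
femur_model <- function(true_offset_mm = 38.2,
                        offset_plane_deg = -3.6,
                        shaft_radius_mm = 14,
                        shaft_length_mm = 120,
                        head_radius_mm = 22,
                        troch_posterior_d_mm = 28,
                        troch_posterior_az_deg = -35,
                        troch_anterior_az_deg = 50) {
  stopifnot(true_offset_mm > 0, shaft_radius_mm > 0, shaft_length_mm > 0,
            head_radius_mm > 0, troch_posterior_d_mm > 0)
  ca <- cos(deg2rad(troch_anterior_az_deg))
  if (abs(ca) < 1e-6) {
    stop("troch_anterior_az_deg too close to +/-90: alignment constraint degenerate",
         call. = FALSE)
  }
  # superimposition at rotation 0: d_a cos(az_a) = d_p cos(az_p)
  troch_anterior_d_mm <-
    troch_posterior_d_mm * cos(deg2rad(troch_posterior_az_deg)) / ca
  structure(
    list(true_offset_mm = true_offset_mm,
         offset_plane_deg = offset_plane_deg,
         shaft_radius_mm = shaft_radius_mm,
         shaft_length_mm = shaft_length_mm,
         head_radius_mm = head_radius_mm,
         troch_posterior_d_mm = troch_posterior_d_mm,
         troch_posterior_az_deg = troch_posterior_az_deg,
         troch_anterior_d_mm = troch_anterior_d_mm,
         troch_anterior_az_deg = troch_anterior_az_deg),
    class = "femur_model"
  )
}

# Noiseless projected landmark geometry for one image, in pixels.
# Returns plain vectors (role, x, y) plus ground-truth scalars; kept lean so
# simulate_cohort() can assemble large cohorts without per-image tibbles.
project_geometry <- function(model, rotation_deg, mm_per_px_true) {
  th <- deg2rad(rotation_deg)
  th0 <- deg2rad(model$offset_plane_deg)
  axis_x <- 200
  half_w <- model$shaft_radius_mm / mm_per_px_true
  # shaft silhouette: 5 points per border spread along the shaft
  ys <- seq(120, 120 + model$shaft_length_mm / mm_per_px_true / 2, length.out = 5L)
  head_dx <- model$true_offset_mm * cos(th - th0) / mm_per_px_true
  head_r <- model$head_radius_mm / mm_per_px_true
  head_c <- c(axis_x + head_dx, 60)
  ha <- deg2rad(seq(0, 300, by = 60))
  sphere_c <- c(60, 420)
  sphere_r <- 12.7 / mm_per_px_true
  sa <- deg2rad(seq(18, 306, by = 72))
  role <- c(rep("medial_cortex", 5L), rep("lateral_cortex", 5L),
            rep("head", 6L), rep("calibration", 5L))
  x <- c(rep(axis_x - half_w, 5L), rep(axis_x + half_w, 5L),
         head_c[1L] + head_r * cos(ha), sphere_c[1L] + sphere_r * cos(sa))
  y <- c(ys, ys, head_c[2L] + head_r * sin(ha), sphere_c[2L] + sphere_r * sin(sa))
  list(role = role, x = x, y = y,
       offset_noiseless_mm = model$true_offset_mm * abs(cos(th - th0)),
       troch_anterior_x_px = axis_x + model$troch_anterior_d_mm *
         cos(th - deg2rad(model$troch_anterior_az_deg)) / mm_per_px_true,
       troch_posterior_x_px = axis_x + model$troch_posterior_d_mm *
         cos(th - deg2rad(model$troch_posterior_az_deg)) / mm_per_px_true)
}

#' Project a femur model to a landmark table at one rotation
#'
#' Emits the canonical landmark counts (5 medial, 5 lateral cortex points on
#' the projected shaft silhouette, 6 head points, 5 calibration-sphere
#' points), each perturbed by isotropic Gaussian pixel noise. The current RNG
#' state fully determines the output; seed with [set.seed()] for
#' reproducibility.
#'
#' @param model A [femur_model()].
#' @param rotation_deg Actuator rotation, degrees (internal positive).
#' @param noise_sd_px Isotropic Gaussian landmark noise sd, pixels.
#' @param mm_per_px_true True image scale used to lay out the pixels.
#' @param specimen_id,image_id,round Identifiers stamped on the rows.
#' @return A list with `landmarks` (landmark tibble) and `truth` (tibble with
#'   the noiseless projected offset in mm and the horizontal projections of
#'   the two trochanteric source points in px).
#' @examples
#' set.seed(1)
#' img <- project_femur(femur_model(), rotation_deg = 0)
#' img$truth
#' @export
project_femur <- function(model, rotation_deg, noise_sd_px = 0,
                          mm_per_px_true = 0.25,
                          specimen_id = "S01", image_id = NULL, round = 1L) {
  stopifnot(inherits(model, "femur_model"))
  if (!is.numeric(noise_sd_px) || noise_sd_px < 0) {
    stop("noise_sd_px must be a nonnegative number", call. = FALSE)
  }
  stopifnot(mm_per_px_true > 0)
  if (is.null(image_id)) image_id <- sprintf("%s_ang%+g", specimen_id, rotation_deg)
  g <- project_geometry(model, rotation_deg, mm_per_px_true)
  np <- length(g$x)
  x <- g$x
  y <- g$y
  if (noise_sd_px > 0) {
    x <- x + stats::rnorm(np, sd = noise_sd_px)
    y <- y + stats::rnorm(np, sd = noise_sd_px)
  }
  list(
    landmarks = tibble::tibble(
      specimen_id = specimen_id, image_id = image_id,
      rotation_deg = as.numeric(rotation_deg), role = g$role,
      x_px = x, y_px = y, round = as.integer(round)),
    truth = tibble::tibble(
      specimen_id = specimen_id, image_id = image_id,
      rotation_deg = as.numeric(rotation_deg),
      offset_noiseless_mm = g$offset_noiseless_mm,
      troch_anterior_x_px = g$troch_anterior_x_px,
      troch_posterior_x_px = g$troch_posterior_x_px)
  )
}

#' Cohort simulation configuration
#'
#' Defaults reproduce the study design the package targets: 11 specimens,
#' true offsets drawn Normal(38.2, 4.9) mm truncated positive, offset-plane
#' angles `theta0` drawn Normal(-3.6, 5.6) degrees, a rotation grid of -30,
#' -10 to +10 in 2-degree steps, and +30 (13 radiographs), a 1-inch in-plane
#' calibration sphere at 0.25 mm/px, 0.5 px annotation noise, and three
#' rater rounds.
#'
#' @param n_specimens Number of simulated specimens.
#' @param offset_mean_mm,offset_sd_mm True-offset distribution, mm.
#' @param theta0_mean_deg,theta0_sd_deg Offset-plane angle distribution, deg.
#' @param angle_grid_deg Rotation grid; must contain 0.
#' @param landmark_noise_sd_px Annotation noise sd, px.
#' @param mm_per_px_true True image scale.
#' @param n_rater_rounds Independent re-annotation rounds per image.
#' @param seed Integer seed; per-specimen streams are derived from it so
#'   specimen i is reproducible independent of cohort size.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_specimens = 11L,
                          offset_mean_mm = 38.2, offset_sd_mm = 4.9,
                          theta0_mean_deg = -3.6, theta0_sd_deg = 5.6,
                          angle_grid_deg = c(-30, seq(-10, 10, by = 2), 30),
                          landmark_noise_sd_px = 0.5,
                          mm_per_px_true = 0.25,
                          n_rater_rounds = 3L,
                          seed = 1L) {
  stopifnot(n_specimens >= 1L, offset_sd_mm >= 0, theta0_sd_deg >= 0,
            landmark_noise_sd_px >= 0, mm_per_px_true > 0,
            n_rater_rounds >= 1L)
  if (!any(angle_grid_deg == 0)) {
    stop("angle_grid_deg must contain 0 (the aligned neutral)", call. = FALSE)
  }
  structure(
    list(n_specimens = as.integer(n_specimens),
         offset_mean_mm = offset_mean_mm, offset_sd_mm = offset_sd_mm,
         theta0_mean_deg = theta0_mean_deg, theta0_sd_deg = theta0_sd_deg,
         angle_grid_deg = as.numeric(angle_grid_deg),
         landmark_noise_sd_px = landmark_noise_sd_px,
         mm_per_px_true = mm_per_px_true,
         n_rater_rounds = as.integer(n_rater_rounds),
         seed = as.integer(seed)),
    class = "cohort_config"
  )
}

# Counter-based per-specimen seed: specimen i gets the same stream whatever
# the cohort size. Kept below 2^31.
specimen_seed <- function(seed, i) {
  as.integer((as.double(seed) * 48271 + i * 69621) %% 2147483563)
}

draw_truncated_normal <- function(n, mean, sd) {
  out <- stats::rnorm(n, mean, sd)
  while (any(out <= 0)) {
    k <- out <= 0
    out[k] <- stats::rnorm(sum(k), mean, sd)
  }
  out
}

#' Simulate a cohort of specimens across the rotation grid
#'
#' Per specimen, draws a true offset and an offset-plane angle, then projects
#' every grid rotation; each rater round re-noises the same noiseless
#' geometry independently, modelling repeated annotation of the same
#' radiograph. Fully deterministic under `config$seed`.
#'
#' @param config A [cohort_config()].
#' @return A list with `landmarks` (one landmark tibble for all specimens,
#'   angles and rounds), `specimens` (ground truth: `specimen_id`,
#'   `true_offset_mm`, `theta0_deg`), and `images` (per-image noiseless
#'   projected offset and trochanteric line positions).
#' @examples
#' sim <- simulate_cohort(cohort_config(n_specimens = 2, seed = 7))
#' sim$specimens
#' @export
simulate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  specimens <- vector("list", config$n_specimens)
  landmarks <- vector("list", config$n_specimens)
  images <- vector("list", config$n_specimens)
  for (i in seq_len(config$n_specimens)) {
    old_seed <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    set.seed(specimen_seed(config$seed, i))
    sid <- sprintf("S%02d", i)
    R <- draw_truncated_normal(1L, config$offset_mean_mm, config$offset_sd_mm)
    th0 <- stats::rnorm(1L, config$theta0_mean_deg, config$theta0_sd_deg)
    model <- femur_model(true_offset_mm = R, offset_plane_deg = th0)
    n_ang <- length(config$angle_grid_deg)
    n_rounds <- config$n_rater_rounds
    geoms <- lapply(config$angle_grid_deg, project_geometry,
                    model = model, mm_per_px_true = config$mm_per_px_true)
    np <- length(geoms[[1L]]$x)
    n_rows <- n_ang * n_rounds * np
    # one noiseless layout per angle, re-noised independently per round
    x0 <- rep(unlist(lapply(geoms, `[[`, "x")), times = n_rounds)
    y0 <- rep(unlist(lapply(geoms, `[[`, "y")), times = n_rounds)
    ord <- order(rep(seq_len(n_ang), each = np, times = n_rounds))
    if (config$landmark_noise_sd_px > 0) {
      x0 <- x0 + stats::rnorm(n_rows, sd = config$landmark_noise_sd_px)
      y0 <- y0 + stats::rnorm(n_rows, sd = config$landmark_noise_sd_px)
    }
    iids <- sprintf("%s_ang%+g", sid, config$angle_grid_deg)
    landmarks[[i]] <- tibble::tibble(
      specimen_id = sid,
      image_id = rep(rep(iids, each = np), times = n_rounds)[ord],
      rotation_deg = rep(rep(config$angle_grid_deg, each = np),
                         times = n_rounds)[ord],
      role = rep(geoms[[1L]]$role, times = n_ang * n_rounds),
      x_px = x0[ord], y_px = y0[ord],
      round = rep(rep(seq_len(n_rounds), each = n_ang * np))[ord])
    images[[i]] <- tibble::tibble(
      specimen_id = sid, image_id = iids,
      rotation_deg = config$angle_grid_deg,
      offset_noiseless_mm = vapply(geoms, `[[`, numeric(1L),
                                   "offset_noiseless_mm"),
      troch_anterior_x_px = vapply(geoms, `[[`, numeric(1L),
                                   "troch_anterior_x_px"),
      troch_posterior_x_px = vapply(geoms, `[[`, numeric(1L),
                                    "troch_posterior_x_px"))
    specimens[[i]] <- tibble::tibble(specimen_id = sid, true_offset_mm = R,
                                     theta0_deg = th0)
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }
  list(landmarks = dplyr::bind_rows(landmarks),
       specimens = dplyr::bind_rows(specimens),
       images = dplyr::bind_rows(images))
}
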