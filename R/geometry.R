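#' Geometric primitives for landmark-based offset measurement
#'
#' @description
#' The measurement chain for one radiograph is: total-least-squares lines
#' through the medial and lateral cortical landmarks, their acute-angle
#' bisector as the proximal shaft axis, a least-squares circle through the
#' head landmarks, a calibration-sphere circle converting pixels to
#' millimetres, and finally the perpendicular distance from the head centre
#' to the shaft axis.
#'
#' All fits operate on point *sets*: row order never matters.
#'
#' @name geometry
NULL

# ---- internal point handling ------------------------------------------------

# Accepts an n x 2 matrix, a data frame with x/y (or x_px/y_px) columns, or a
# list of length-2 points; returns an n x 2 numeric matrix.
as_point_matrix <- function(points) {
  if (is.matrix(points)) {
    m <- points
  } else if (is.data.frame(points)) {
    xs <- intersect(c("x_px", "x"), names(points))[1]
    ys <- intersect(c("y_px", "y"), names(points))[1]
    if (is.na(xs) || is.na(ys)) {
      stop("point data frame must have x/y or x_px/y_px columns", call. = FALSE)
    }
    m <- cbind(points[[xs]], points[[ys]])
  } else if (is.list(points)) {
    m <- do.call(rbind, lapply(points, as.numeric))
  } else {
    stop("cannot interpret `points` as 2-D coordinates", call. = FALSE)
  }
  m <- unname(as.matrix(m))
  storage.mode(m) <- "double"
  if (ncol(m) != 2L) stop("points must be 2-D", call. = FALSE)
  if (any(!is.finite(m))) stop("point coordinates must be finite", call. = FALSE)
  m
}

new_line2d <- function(anchor, direction, rms_residual = NA_real_) {
  structure(
    list(anchor = as.numeric(anchor), direction = as.numeric(direction),
         rms_residual = rms_residual),
    class = "line2d"
  )
}

#' @export
print.line2d <- function(x, ...) {
  cat(sprintf("<line2d> anchor (%.4g, %.4g), direction (%.6f, %.6f)\n",
              x$anchor[1], x$anchor[2], x$direction[1], x$direction[2]))
  invisible(x)
}

new_circle_fit <- function(center, radius, rms_residual) {
  structure(
    list(center = as.numeric(center), radius = as.numeric(radius),
         rms_residual = as.numeric(rms_residual)),
    class = "circle_fit"
  )
}

#' @export
print.circle_fit <- function(x, ...) {
  cat(sprintf("<circle_fit> center (%.4g, %.4g), radius %.6g, rms residual %.3g\n",
              x$center[1], x$center[2], x$radius, x$rms_residual))
  invisible(x)
}

# Canonical anchor: the point on the line closest to the origin, so that a
# line is represented uniquely regardless of which anchor it was built from.
canonicalize_line <- function(anchor, direction) {
  anchor - sum(anchor * direction) * direction
}

# Direction sign convention: the component of larger magnitude is positive;
# on a tie, positive y.
canonicalize_direction <- function(d) {
  flip <- if (abs(d[1]) > abs(d[2])) d[1] < 0 else d[2] < 0
  if (flip) -d else d
}

#' Fit a line to 2-D points by total least squares
#'
#' Orthogonal (total) least squares: the returned line is the first principal
#' axis through the centroid, minimising the sum of squared perpendicular
#' distances. Cortical borders are near-vertical on radiographs, where
#' ordinary y-on-x regression is ill-conditioned; orthogonal regression is
#' invariant to the image orientation.
#'
#' @param points At least 2 distinct points: an `n x 2` matrix or a data frame
#'   with `x_px`/`y_px` (or `x`/`y`) columns.
#' @return A `line2d` object: `anchor` (the point on the line closest to the
#'   origin), unit `direction` (sign-canonicalised so the larger-magnitude
#'   component is positive, ties broken towards positive y), and
#'   `rms_residual` in pixels.
#' @examples
#' fit_line(cbind(c(0, 0, 0), c(0, 1, 2)))
#' @export
fit_line <- function(points) {
  m <- as_point_matrix(points)
  if (nrow(m) < 2L) stop("fit_line needs at least 2 points", call. = FALSE)
  ctr <- colMeans(m)
  x <- sweep(m, 2L, ctr)
  scale <- max(abs(x))
  if (scale < 1e-12) {
    stop("degenerate geometry: all points coincident", call. = FALSE)
  }
  sv <- svd(x / scale, nu = 0L)
  d <- canonicalize_direction(sv$v[, 1L])
  resid <- x %*% c(-d[2L], d[1L])
  new_line2d(canonicalize_line(ctr, d), d, sqrt(mean(resid^2)))
}

#' Acute-angle bisector of two lines
#'
#' Direction is the normalised sum of the two unit directions after sign
#' harmonisation (the second direction is flipped when the dot product is
#' negative), i.e. the bisector of the acute angle between the cortices.
#' The anchor is the intersection point; for (near-)parallel lines —
#' `|sin(angle)| < 1e-6` — the anchor falls back to the midpoint of the two
#' canonical anchors, which is exact for parallel cortices.
#'
#' @param a,b `line2d` objects.
#' @return A `line2d`.
#' @examples
#' bisect_lines(fit_line(cbind(0, 0:4)), fit_line(cbind(10, 0:4)))
#' @export
bisect_lines <- function(a, b) {
  stopifnot(inherits(a, "line2d"), inherits(b, "line2d"))
  ua <- a$direction
  ub <- b$direction
  if (sum(ua * ub) < 0) ub <- -ub
  d <- ua + ub
  d <- canonicalize_direction(d / sqrt(sum(d^2)))
  cross <- ua[1L] * ub[2L] - ua[2L] * ub[1L]
  if (abs(cross) < 1e-6) {
    anchor <- (a$anchor + b$anchor) / 2
    d <- canonicalize_direction(ua)
  } else {
    # a$anchor + t * ua = b$anchor + s * ub  ->  solve for t by Cramer's rule
    rhs <- b$anchor - a$anchor
    t <- (rhs[1L] * ub[2L] - rhs[2L] * ub[1L]) / cross
    anchor <- a$anchor + t * ua
  }
  new_line2d(canonicalize_line(anchor, d), d)
}

#' Fit a circle to 2-D points
#'
#' Kasa algebraic least-squares fit (linear in the implicit circle
#' parameters) used as the initialiser, followed by Gauss-Newton refinement
#' of the geometric objective `sum((|p - c| - r)^2)`. With few points marked
#' over a partial arc — six clicks around a femoral head — the algebraic fit
#' is biased towards small radii, which the geometric refinement removes.
#'
#' @param points At least 3 non-collinear points (same forms as [fit_line()]).
#' @return A `circle_fit`: `center`, `radius` (pixels) and `rms_residual` of
#'   the geometric (radial) residuals.
#' @examples
#' fit_circle(cbind(c(1, 0, -1, 0), c(0, 1, 0, -1)))
#' @export
fit_circle <- function(points) {
  m <- as_point_matrix(points)
  n <- nrow(m)
  if (n < 3L) stop("fit_circle needs at least 3 points", call. = FALSE)
  ctr <- colMeans(m)
  xc <- sweep(m, 2L, ctr)
  sv <- svd(xc, nu = 0L)
  if (sv$d[2L] <= 1e-9 * max(sv$d[1L], 1e-300)) {
    stop("degenerate geometry: points are collinear", call. = FALSE)
  }
  # Kasa fit in centred coordinates: minimise ||A [uc, vc, w]' - b||
  A <- cbind(2 * xc, 1)
  b <- rowSums(xc^2)
  sol <- qr.solve(A, b)
  cen <- sol[1:2]
  r <- sqrt(sol[3L] + sum(cen^2))
  # Gauss-Newton on (cx, cy, r), normal-equation steps on the 3x3 system
  par <- c(cen, r)
  for (iter in seq_len(50L)) {
    dx <- xc[, 1L] - par[1L]
    dy <- xc[, 2L] - par[2L]
    di <- sqrt(dx^2 + dy^2)
    if (any(di < 1e-12)) break
    res <- di - par[3L]
    J <- cbind(-dx / di, -dy / di, -1)
    step <- tryCatch(solve(crossprod(J), -crossprod(J, res)),
                     error = function(e) NULL)
    if (is.null(step)) break
    par <- par + step
    if (max(abs(step)) < 1e-12 * max(1, par[3L])) break
  }
  dx <- xc[, 1L] - par[1L]
  dy <- xc[, 2L] - par[2L]
  res <- sqrt(dx^2 + dy^2) - par[3L]
  new_circle_fit(par[1:2] + ctr, par[3L], sqrt(mean(res^2)))
}

#' Pixel-to-millimetre calibration from a sphere of known diameter
#'
#' A radio-opaque sphere placed in the plane of the femur projects to a circle
#' whose fitted pixel radius converts pixel distances to millimetres:
#' `mm_per_px = sphere_diameter_mm / (2 * radius_px)`.
#'
#' @param sphere_points At least 3 points marked on the sphere's projected
#'   outline.
#' @param sphere_diameter_mm Physical sphere diameter; default 25.4 mm
#'   (1 inch).
#' @return A `calibration` object with `mm_per_px`, the underlying
#'   `sphere_fit` and `sphere_diameter_mm`.
#' @examples
#' calibrate(cbind(c(50, 0, -50, 0), c(0, 50, 0, -50)))  # mm_per_px = 0.254
#' @export
calibrate <- function(sphere_points, sphere_diameter_mm = 25.4) {
  stopifnot(is.numeric(sphere_diameter_mm), sphere_diameter_mm > 0)
  fit <- fit_circle(sphere_points)
  structure(
    list(mm_per_px = sphere_diameter_mm / (2 * fit$radius),
         sphere_fit = fit,
         sphere_diameter_mm = sphere_diameter_mm),
    class = "calibration"
  )
}

#' @export
print.calibration <- function(x, ...) {
  cat(sprintf("<calibration> %.6g mm/px (sphere %.4g mm, fitted radius %.6g px)\n",
              x$mm_per_px, x$sphere_diameter_mm, x$sphere_fit$radius))
  invisible(x)
}

point_line_distance <- function(p, line) {
  v <- p - line$anchor
  abs(v[1L] * line$direction[2L] - v[2L] * line$direction[1L])
}

# Lean internal core shared by measure_offset() and measure_offsets():
# takes role-split coordinate matrices, returns the fitted pieces.
measure_offset_core <- function(medial, lateral, head, calibration) {
  shaft_axis <- bisect_lines(fit_line(medial), fit_line(lateral))
  head_fit <- fit_circle(head)
  offset_px <- point_line_distance(head_fit$center, shaft_axis)
  list(shaft_axis = shaft_axis, head_fit = head_fit,
       offset_px = offset_px,
       offset_mm = offset_px * calibration$mm_per_px)
}

split_roles <- function(set) {
  split.data.frame(cbind(set$x_px, set$y_px), set$role)
}

#' Measure femoral offset on one annotated radiograph
#'
#' Builds the shaft axis as the bisector of the medial and lateral cortical
#' line fits, fits the head circle, and reports the perpendicular distance
#' from the head centre to the axis, converted to millimetres. The offset is
#' unsigned (a distance).
#'
#' @param set A landmark tibble for a single image (one row per point with
#'   `role`, `x_px`, `y_px`; see [read_landmarks()]).
#' @param calibration Optional `calibration` object; when `NULL` the set must
#'   contain `calibration`-role points from which the scale is fitted.
#' @return An `offset_measurement` object: identifiers, `shaft_axis`
#'   (`line2d`), `head_fit` (`circle_fit`), `calibration` and `offset_mm`.
#' @seealso [measure_offsets()] for the vectorised, tibble-returning version.
#' @export
measure_offset <- function(set, calibration = NULL) {
  stopifnot(is.data.frame(set))
  roles <- split_roles(set)
  for (role in c("medial_cortex", "lateral_cortex", "head")) {
    if (is.null(roles[[role]]) || nrow(roles[[role]]) == 0L) {
      stop(sprintf("missing role '%s' in landmark set", role), call. = FALSE)
    }
  }
  if (is.null(calibration)) {
    if (is.null(roles[["calibration"]])) {
      stop("no calibration points and no external calibration given",
           call. = FALSE)
    }
    calibration <- calibrate(roles[["calibration"]])
  }
  core <- measure_offset_core(roles$medial_cortex, roles$lateral_cortex,
                              roles$head, calibration)
  structure(
    list(specimen_id = set$specimen_id[1L], image_id = set$image_id[1L],
         rotation_deg = set$rotation_deg[1L],
         shaft_axis = core$shaft_axis, head_fit = core$head_fit,
         calibration = calibration, offset_mm = core$offset_mm),
    class = "offset_measurement"
  )
}

#' @export
print.offset_measurement <- function(x, ...) {
  cat(sprintf("<offset_measurement> %s/%s at %+g deg: offset %.4f mm\n",
              x$specimen_id, x$image_id, x$rotation_deg, x$offset_mm))
  invisible(x)
}

#' Measure femoral offset for every image in a landmark table
#'
#' Applies [measure_offset()] to each `(specimen_id, image_id, round)` group
#' of a landmark tibble and returns one row per image.
#'
#' @param landmarks Landmark tibble as returned by [read_landmarks()] or
#'   [simulate_cohort()].
#' @param calibration Optional shared `calibration`; by default each image is
#'   calibrated from its own sphere points.
#' @return A tibble with columns `specimen_id`, `image_id`, `round`,
#'   `rotation_deg`, `offset_mm`, `mm_per_px`, `head_rms_px` (head-circle
#'   geometric rms residual).
#' @examples
#' sim <- simulate_cohort(cohort_config(n_specimens = 2, seed = 1))
#' measure_offsets(sim$landmarks)
#' @export
measure_offsets <- function(landmarks, calibration = NULL) {
  stopifnot(is.data.frame(landmarks))
  if (is.null(landmarks$round)) landmarks$round <- 1L
  key <- paste(landmarks$specimen_id, landmarks$image_id, landmarks$round,
               sep = "\r")
  idx <- split(seq_len(nrow(landmarks)), key)
  n <- length(idx)
  specimen <- image <- character(n)
  round_ <- integer(n)
  rot <- off <- mpp <- hrms <- numeric(n)
  xs <- landmarks$x_px
  ys <- landmarks$y_px
  role <- landmarks$role
  for (g in seq_len(n)) {
    i <- idx[[g]]
    pts <- cbind(xs[i], ys[i])
    rl <- role[i]
    med <- pts[rl == "medial_cortex", , drop = FALSE]
    lat <- pts[rl == "lateral_cortex", , drop = FALSE]
    hd <- pts[rl == "head", , drop = FALSE]
    if (nrow(med) == 0L || nrow(lat) == 0L || nrow(hd) == 0L) {
      stop(sprintf("image %s is missing a required landmark role",
                   landmarks$image_id[i[1L]]), call. = FALSE)
    }
    cal <- calibration
    if (is.null(cal)) {
      sph <- pts[rl == "calibration", , drop = FALSE]
      if (nrow(sph) == 0L) {
        stop(sprintf("image %s has no calibration points and no external calibration",
                     landmarks$image_id[i[1L]]), call. = FALSE)
      }
      cal <- calibrate(sph)
    }
    core <- measure_offset_core(med, lat, hd, cal)
    specimen[g] <- landmarks$specimen_id[i[1L]]
    image[g] <- landmarks$image_id[i[1L]]
    round_[g] <- landmarks$round[i[1L]]
    rot[g] <- landmarks$rotation_deg[i[1L]]
    off[g] <- core$offset_mm
    mpp[g] <- cal$mm_per_px
    hrms[g] <- core$head_fit$rms_residual
  }
  tibble::tibble(specimen_id = specimen, image_id = image, round = round_,
                 rotation_deg = rot, offset_mm = off, mm_per_px = mpp,
                 head_rms_px = hrms) |>
    dplyr::arrange(.data$specimen_id, .data$rotation_deg, .data$round)
}
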