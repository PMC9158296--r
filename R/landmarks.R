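#' Landmark annotation tables
#'
#' A landmark table holds one row per annotated point on a radiograph:
#' `specimen_id`, `image_id`, `rotation_deg` (nominal actuator angle relative
#' to the radiographically aligned neutral, external rotation negative /
#' internal rotation positive), `role` (one of `medial_cortex`,
#' `lateral_cortex`, `head`, `calibration`), and continuous pixel coordinates
#' `x_px`, `y_px` (image convention: origin top-left, x rightward,
#' y downward — all downstream geometry uses distances only, so the
#' convention is documentation rather than computation). An optional `round`
#' column identifies the rater's measurement round (defaults to 1).
#'
#' @name landmarks
NULL

landmark_roles <- c("medial_cortex", "lateral_cortex", "head", "calibration")

# minimum points for a unique fit, per role
role_minima <- c(medial_cortex = 2L, lateral_cortex = 2L,
                 head = 3L, calibration = 3L)

landmark_columns <- c("specimen_id", "image_id", "rotation_deg", "role",
                      "x_px", "y_px")

validate_landmark_df <- function(df) {
  missing <- setdiff(landmark_columns, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("landmark schema error: missing column(s) %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (is.null(df$round)) df$round <- 1L
  df <- tibble::as_tibble(df[c(landmark_columns, "round")])
  df$specimen_id <- as.character(df$specimen_id)
  df$image_id <- as.character(df$image_id)
  df$rotation_deg <- as.numeric(df$rotation_deg)
  df$role <- as.character(df$role)
  df$x_px <- as.numeric(df$x_px)
  df$y_px <- as.numeric(df$y_px)
  df$round <- as.integer(df$round)
  if (nrow(df) == 0L) return(df)
  bad <- setdiff(unique(df$role), landmark_roles)
  if (length(bad) > 0L) {
    stop(sprintf("unknown landmark role(s): %s (expected %s)",
                 paste(bad, collapse = ", "),
                 paste(landmark_roles, collapse = ", ")), call. = FALSE)
  }
  if (any(!is.finite(df$x_px)) || any(!is.finite(df$y_px))) {
    stop("landmark coordinates must be finite", call. = FALSE)
  }
  counts <- dplyr::count(df, .data$specimen_id, .data$image_id, .data$round,
                         .data$role)
  counts$minimum <- role_minima[counts$role]
  short <- counts[counts$n < counts$minimum, ]
  if (nrow(short) > 0L) {
    stop(sprintf(
      "too few landmarks for a unique fit: specimen %s image %s role %s has %d point(s), needs >= %d",
      short$specimen_id[1L], short$image_id[1L], short$role[1L],
      short$n[1L], short$minimum[1L]), call. = FALSE)
  }
  rot <- dplyr::distinct(df, .data$specimen_id, .data$image_id,
                         .data$rotation_deg)
  dup <- rot[duplicated(rot[c("specimen_id", "image_id")]), ]
  if (nrow(dup) > 0L) {
    stop(sprintf("image %s/%s has inconsistent rotation_deg values",
                 dup$specimen_id[1L], dup$image_id[1L]), call. = FALSE)
  }
  df
}

#' Read landmark annotations from CSV or JSON
#'
#' CSV: header `specimen_id,image_id,rotation_deg,role,x_px,y_px` with an
#' optional `round` column, UTF-8, one point per row. JSON: a list of
#' image-level objects, each with the identifier fields and a `points`
#' object grouping `[x, y]` pairs by role. Both dialects round-trip with
#' [write_landmarks()] at full double precision.
#'
#' Validation errors name the offending column, role, or
#' specimen/image/role group; a file with a header and no rows yields an
#' empty table.
#'
#' @param path File path.
#' @param format `"csv"` or `"json"`; default guessed from the extension.
#' @return A landmark tibble (see [landmarks]), one row per point.
#' @export
read_landmarks <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  if (format == "csv") {
    # read numerics as text and convert with base strtod: bit-exact
    # round-trip at full double precision
    df <- readr::read_csv(path, show_col_types = FALSE,
                          col_types = readr::cols(.default = readr::col_character()))
    df <- as.data.frame(df)
    if (nrow(df) == 0L) {
      missing <- setdiff(landmark_columns, names(df))
      if (length(missing) > 0L) {
        stop(sprintf("landmark schema error: missing column(s) %s",
                     paste(missing, collapse = ", ")), call. = FALSE)
      }
    }
  } else {
    sets <- jsonlite::read_json(path, simplifyVector = FALSE)
    df <- purrr::map_dfr(sets, function(s) {
      for (field in c("specimen_id", "image_id", "rotation_deg", "points")) {
        if (is.null(s[[field]])) {
          stop(sprintf("landmark schema error: missing column(s) %s", field),
               call. = FALSE)
        }
      }
      purrr::imap_dfr(s$points, function(pts, role) {
        m <- do.call(rbind, lapply(pts, as.numeric))
        tibble::tibble(
          specimen_id = s$specimen_id, image_id = s$image_id,
          rotation_deg = as.numeric(s$rotation_deg), role = role,
          x_px = m[, 1L], y_px = m[, 2L],
          round = as.integer(s$round %||% 1L))
      })
    })
    if (nrow(df) == 0L) {
      df <- tibble::tibble(specimen_id = character(), image_id = character(),
                           rotation_deg = numeric(), role = character(),
                           x_px = numeric(), y_px = numeric(),
                           round = integer())
    }
  }
  validate_landmark_df(df)
}

#' Write landmark annotations to CSV or JSON
#'
#' Numeric fields are written at full round-trip precision (shortest
#' representation that restores the double exactly), so
#' `read_landmarks(write_landmarks(x))` reproduces `x` bit-exactly.
#'
#' @param landmarks Landmark tibble (validated before writing).
#' @param path Output file path.
#' @inheritParams read_landmarks
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(landmarks, path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  df <- validate_landmark_df(as.data.frame(landmarks))
  if (format == "csv") {
    readr::write_csv(df, path)
  } else {
    groups <- split(df, paste(df$specimen_id, df$image_id, df$round,
                              sep = "\r"))
    sets <- unname(lapply(groups, function(g) {
      list(specimen_id = g$specimen_id[1L], image_id = g$image_id[1L],
           rotation_deg = g$rotation_deg[1L], round = g$round[1L],
           points = lapply(split(g, g$role),
                           function(r) unname(Map(c, r$x_px, r$y_px))))
    }))
    jsonlite::write_json(sets, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
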