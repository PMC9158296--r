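#' Rotation-sweep analysis of per-image offset measurements
#'
#' @description
#' A rotation sweep summarises one specimen's offset-vs-rotation curve. The
#' *true* offset is the maximum measured offset over all imaged rotations
#' (the operational definition for a discrete grid), the *aligned* offset is
#' the value at rotation 0 (the line-aligned neutral), and the
#' underestimation is their difference — how much a measurement taken at the
#' radiographically aligned position falls short of the maximum.
#'
#' @name sweep
NULL

#' Per-specimen sweep statistics
#'
#' @param measurements Tibble of per-image offsets, as from
#'   [measure_offsets()]: columns `specimen_id`, `rotation_deg`, `offset_mm`
#'   and optionally `round`.
#' @param rounds_policy `"mean_of_rounds"` (default) averages the rounds of
#'   each image before maximisation; `"per_round"` analyses each round as a
#'   separate curve and returns one row per specimen-round.
#' @return A tibble with one row per specimen (or specimen-round), columns:
#'   `true_offset_mm` (curve maximum), `aligned_offset_mm` (at 0),
#'   `underestimation_mm`, `underestimation_pct` (of the true offset),
#'   `rotation_at_max_deg`, `rotation_at_max_tied` (TRUE when the maximum was
#'   attained at more than one grid angle), and `range_pm10_mm` (max minus
#'   min over rotations in \[-10, +10\] inclusive).
#'
#' @details Ties for the maximum are broken towards the angle of smallest
#'   magnitude, then towards internal (positive) rotation, and flagged.
#'   A grid without rotation 0 is an error: the aligned offset would be
#'   undefined. Duplicate (rotation, round) measurements are an error.
#' @examples
#' sim <- simulate_cohort(cohort_config(n_specimens = 2, seed = 3))
#' analyze_sweeps(measure_offsets(sim$landmarks))
#' @export
analyze_sweeps <- function(measurements,
                           rounds_policy = c("mean_of_rounds", "per_round")) {
  rounds_policy <- match.arg(rounds_policy)
  stopifnot(is.data.frame(measurements))
  df <- tibble::as_tibble(measurements)
  if (is.null(df$round)) df$round <- 1L
  for (col in c("specimen_id", "rotation_deg", "offset_mm")) {
    if (is.null(df[[col]])) {
      stop(sprintf("measurements must have a '%s' column", col), call. = FALSE)
    }
  }
  dup <- df |>
    dplyr::count(.data$specimen_id, .data$rotation_deg, .data$round) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(dup) > 0L) {
    stop(sprintf("duplicate measurement: specimen %s, rotation %g, round %d",
                 dup$specimen_id[1L], dup$rotation_deg[1L], dup$round[1L]),
         call. = FALSE)
  }
  if (rounds_policy == "mean_of_rounds") {
    curves <- df |>
      dplyr::summarise(offset_mm = mean(.data$offset_mm),
                       .by = c("specimen_id", "rotation_deg")) |>
      dplyr::mutate(round = NA_integer_)
  } else {
    curves <- df[c("specimen_id", "round", "rotation_deg", "offset_mm")]
  }
  curves |>
    dplyr::group_by(.data$specimen_id, .data$round) |>
    dplyr::group_modify(~ sweep_one(.x, .y$specimen_id)) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$specimen_id, .data$round)
}

sweep_one <- function(curve, specimen_id) {
  ang <- curve$rotation_deg
  off <- curve$offset_mm
  at0 <- which(ang == 0)
  if (length(at0) == 0L) {
    stop(sprintf("specimen %s: rotation grid lacks 0 deg, aligned offset undefined",
                 specimen_id), call. = FALSE)
  }
  true_off <- max(off)
  cand <- ang[off == true_off]
  tied <- length(cand) > 1L
  # smallest |angle| first, internal (positive) rotation breaks remaining ties
  cand <- cand[order(abs(cand), -cand)]
  aligned <- off[at0]
  in10 <- abs(ang) <= 10
  tibble::tibble(
    n_angles = length(ang),
    true_offset_mm = true_off,
    aligned_offset_mm = aligned,
    underestimation_mm = true_off - aligned,
    underestimation_pct = 100 * (true_off - aligned) / true_off,
    rotation_at_max_deg = cand[1L],
    rotation_at_max_tied = tied,
    range_pm10_mm = if (any(in10)) max(off[in10]) - min(off[in10]) else NA_real_
  )
}

sweep_metrics <- c("true_offset_mm", "aligned_offset_mm",
                   "underestimation_mm", "underestimation_pct",
                   "rotation_at_max_deg", "range_pm10_mm")

#' Cohort summary statistics over specimen sweeps
#'
#' For every sweep metric present in `sweeps`, reports mean, sample sd
#' (n - 1 denominator), median, min and max across specimens. When both the
#' true and aligned offsets are present, an extra row
#' `underestimation_pct_pooled` gives the underestimation of the *mean*
#' curve, `100 * (mean(true) - mean(aligned)) / mean(true)` — the ratio in
#' which a cohort-level "x mm, or y%" statement is usually quoted.
#'
#' @param sweeps Tibble as from [analyze_sweeps()]; any subset of the sweep
#'   metric columns is accepted.
#' @return A tibble with columns `metric`, `mean`, `sd`, `median`, `min`,
#'   `max`, `n`.
#' @export
summarize_cohort <- function(sweeps) {
  stopifnot(is.data.frame(sweeps))
  present <- intersect(sweep_metrics, names(sweeps))
  if (length(present) == 0L) {
    stop("sweeps contains no sweep metric columns", call. = FALSE)
  }
  n <- nrow(sweeps)
  rows <- purrr::map_dfr(present, function(m) {
    x <- sweeps[[m]]
    tibble::tibble(metric = m, mean = mean(x),
                   sd = if (n >= 2L) stats::sd(x) else NA_real_,
                   median = stats::median(x), min = min(x), max = max(x),
                   n = n)
  })
  if (all(c("true_offset_mm", "aligned_offset_mm") %in% present)) {
    pooled <- 100 * (mean(sweeps$true_offset_mm) - mean(sweeps$aligned_offset_mm)) /
      mean(sweeps$true_offset_mm)
    rows <- dplyr::bind_rows(rows, tibble::tibble(
      metric = "underestimation_pct_pooled", mean = pooled, sd = NA_real_,
      median = NA_real_, min = NA_real_, max = NA_real_, n = n))
  }
  rows
}

#' Distribution of the rotation of maximum offset across specimens
#'
#' @param sweeps Tibble with a `rotation_at_max_deg` column.
#' @return A count tibble (`rotation_at_max_deg`, `n`), ascending in angle.
#' @export
rotation_at_max_counts <- function(sweeps) {
  stopifnot(is.data.frame(sweeps), !is.null(sweeps$rotation_at_max_deg))
  sweeps |>
    dplyr::count(.data$rotation_at_max_deg) |>
    dplyr::arrange(.data$rotation_at_max_deg)
}

#' Offset-vs-rotation curves for a cohort
#'
#' One line per specimen (rounds averaged), with a dot at each specimen's
#' maximum — the discrete "true offset" — mirroring the usual presentation of
#' rotation-sweep results.
#'
#' @param measurements Tibble as from [measure_offsets()].
#' @return A ggplot object.
#' @export
plot_offset_curves <- function(measurements) {
  curves <- measurements |>
    dplyr::summarise(offset_mm = mean(.data$offset_mm),
                     .by = c("specimen_id", "rotation_deg"))
  maxima <- curves |>
    dplyr::slice_max(.data$offset_mm, n = 1L, by = "specimen_id",
                     with_ties = FALSE)
  ggplot2::ggplot(curves, ggplot2::aes(.data$rotation_deg, .data$offset_mm,
                                       group = .data$specimen_id,
                                       colour = .data$specimen_id)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::geom_point(data = maxima, size = 2) +
    ggplot2::labs(x = "rotation from aligned neutral (deg, ER < 0 < IR)",
                  y = "measured femoral offset (mm)",
                  colour = "specimen") +
    ggplot2::theme_minimal()
}
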