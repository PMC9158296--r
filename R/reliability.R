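#' Intrarater reliability via ICC(2,1)
#'
#' @description
#' Repeatability of the offset measurements across rater rounds is
#' quantified with the two-way random-effects, absolute-agreement,
#' single-measures intraclass correlation coefficient:
#'
#' \deqn{ICC(2,1) = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E + \frac{k}{n}(MS_C - MS_E)}}
#'
#' where \eqn{MS_R}, \eqn{MS_C}, \eqn{MS_E} are the subject, round and
#' residual mean squares of the two-way ANOVA, \eqn{n} subjects, \eqn{k}
#' rounds. Confidence intervals are nonparametric percentile bootstrap,
#' resampling *subjects* with replacement so a subject's rounds stay
#' paired.
#'
#' Interpretation bands: below 0.40 poor, 0.40 to 0.75 fair-to-good
#' (boundaries inclusive), above 0.75 excellent.
#'
#' @name reliability
NULL

icc_band <- function(icc) {
  if (icc < 0.40) "poor" else if (icc <= 0.75) "fair_to_good" else "excellent"
}

# Coerce a wide ratings input (matrix, or data frame possibly carrying a
# character subject-id first column) to an n x k numeric matrix.
as_ratings_matrix <- function(ratings) {
  if (is.data.frame(ratings)) {
    ischr <- vapply(ratings, is.character, logical(1L))
    m <- as.matrix(ratings[!ischr])
  } else {
    m <- as.matrix(ratings)
  }
  storage.mode(m) <- "double"
  if (anyNA(m)) stop("ratings table must have no missing cells", call. = FALSE)
  if (nrow(m) < 2L || ncol(m) < 2L) {
    stop("ratings table needs at least 2 subjects and 2 rounds", call. = FALSE)
  }
  m
}

#' Build a wide ratings table from per-image measurements
#'
#' Subjects are the individual offset measurements (specimen x image), one
#' column per rater round.
#'
#' @param measurements Tibble from [measure_offsets()] with a `round` column.
#' @return A wide tibble: `subject` plus one `round_<r>` column per round.
#' @export
ratings_matrix <- function(measurements) {
  stopifnot(is.data.frame(measurements), !is.null(measurements$round))
  measurements |>
    dplyr::mutate(subject = paste(.data$specimen_id, .data$image_id, sep = "/")) |>
    dplyr::select("subject", "round", "offset_mm") |>
    tidyr::pivot_wider(names_from = "round", values_from = "offset_mm",
                       names_prefix = "round_")
}

icc_point <- function(m) {
  n <- nrow(m)
  k <- ncol(m)
  if (max(m) - min(m) < 1e-12 * max(1, abs(m[1L]))) {
    # all cells equal: perfect (degenerate) agreement
    return(list(icc = 1, ms = c(rows = 0, cols = 0, error = 0),
                n = n, k = k, degenerate = TRUE))
  }
  long <- data.frame(
    value = as.vector(m),
    subject = factor(rep(seq_len(n), times = k)),
    round = factor(rep(seq_len(k), each = n)))
  fit <- stats::aov(value ~ subject + round, data = long)
  ms <- summary(fit)[[1L]][["Mean Sq"]]
  msr <- ms[1L]
  msc <- ms[2L]
  mse <- ms[3L]
  if (is.na(mse)) mse <- 0  # saturated fit with zero residual df cannot occur here
  icc <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  list(icc = icc, ms = c(rows = msr, cols = msc, error = mse),
       n = n, k = k, degenerate = FALSE)
}

new_icc_fit <- function(point, ci_low = NA_real_, ci_high = NA_real_,
                        n_boot = NA_integer_, seed = NA_integer_) {
  structure(
    list(icc = point$icc, band = icc_band(point$icc), ms = point$ms,
         n_subjects = point$n, k_rounds = point$k,
         degenerate = point$degenerate,
         ci_low = ci_low, ci_high = ci_high,
         n_boot = n_boot, seed = seed),
    class = "icc_fit"
  )
}

#' ICC(2,1) point estimate
#'
#' Two-way random-effects, absolute-agreement, single-measures intraclass
#' correlation. The mean squares come from [stats::aov()] on the
#' subject + round two-way layout. A table whose cells are all equal is a
#' degenerate perfect-agreement case, reported as ICC = 1 with
#' `degenerate = TRUE`; negative estimates are reported as computed, never
#' truncated at zero.
#'
#' @param ratings Wide table, rows = subjects, columns = rounds: a numeric
#'   matrix or a data frame (character id columns are dropped). No missing
#'   cells; at least 2 subjects and 2 rounds.
#' @return An `icc_fit` object (no confidence interval; see
#'   [icc_bootstrap()]).
#' @examples
#' icc21(cbind(c(35, 38, 41), c(35.2, 37.9, 41.1)))
#' @export
icc21 <- function(ratings) {
  new_icc_fit(icc_point(as_ratings_matrix(ratings)))
}

#' ICC(2,1) with percentile bootstrap confidence interval
#'
#' Resamples subject rows with replacement (keeping each subject's rounds
#' together), recomputes ICC(2,1) per replicate, and reports the 2.5 and
#' 97.5 percentiles. Deterministic under `seed`.
#'
#' @inheritParams icc21
#' @param n_boot Number of bootstrap replicates (at least 100).
#' @param seed Integer seed, required so reported intervals are reproducible.
#' @param conf_level Confidence level of the percentile interval.
#' @return An `icc_fit` with `ci_low`, `ci_high`, `n_boot`, `seed` filled in.
#' @examples
#' set.seed(1)
#' tab <- matrix(rnorm(30, 38, 5), 10, 3) + rnorm(30, sd = 0.3)
#' icc_bootstrap(tab, n_boot = 200, seed = 42)
#' @export
icc_bootstrap <- function(ratings, n_boot = 2000L, seed, conf_level = 0.95) {
  if (missing(seed)) stop("seed is required for reproducible intervals",
                          call. = FALSE)
  if (n_boot < 100L) stop("n_boot must be at least 100", call. = FALSE)
  m <- as_ratings_matrix(ratings)
  point <- icc_point(m)
  n <- nrow(m)
  reps <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_boot), function(b) {
      icc_point(m[sample.int(n, n, replace = TRUE), , drop = FALSE])$icc
    }, numeric(1L))
  })
  alpha <- (1 - conf_level) / 2
  ci <- unname(stats::quantile(reps, c(alpha, 1 - alpha)))
  fit <- new_icc_fit(point, ci_low = ci[1L], ci_high = ci[2L],
                     n_boot = as.integer(n_boot), seed = as.integer(seed))
  if (!is.na(fit$ci_low) && (fit$icc < fit$ci_low || fit$icc > fit$ci_high)) {
    fit$point_outside_ci <- TRUE
  }
  fit
}

#' @export
print.icc_fit <- function(x, ...) {
  cat(sprintf("ICC(2,1) = %.4f (%s agreement)\n", x$icc,
              gsub("_", " ", x$band)))
  if (!is.na(x$ci_low)) {
    cat(sprintf("  bootstrap 95%% CI [%.4f, %.4f]  (%d replicates, seed %d)\n",
                x$ci_low, x$ci_high, x$n_boot, x$seed))
  }
  cat(sprintf("  %d subjects x %d rounds; MS rows %.4g, cols %.4g, error %.4g%s\n",
              x$n_subjects, x$k_rounds, x$ms[["rows"]], x$ms[["cols"]],
              x$ms[["error"]], if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Tidy an ICC fit
#'
#' @param x An `icc_fit`.
#' @param ... Unused.
#' @return One-row tibble with `term`, `estimate`, `conf.low`, `conf.high`,
#'   `band`.
#' @method tidy icc_fit
#' @export
tidy.icc_fit <- function(x, ...) {
  tibble::tibble(term = "ICC(2,1)", estimate = x$icc,
                 conf.low = x$ci_low, conf.high = x$ci_high, band = x$band)
}

#' Glance at an ICC fit
#'
#' @inheritParams tidy.icc_fit
#' @return One-row tibble with the estimate, interval, variance-component
#'   mean squares, table dimensions and bootstrap settings.
#' @method glance icc_fit
#' @export
glance.icc_fit <- function(x, ...) {
  tibble::tibble(icc = x$icc, ci_low = x$ci_low, ci_high = x$ci_high,
                 band = x$band, ms_rows = x$ms[["rows"]],
                 ms_cols = x$ms[["cols"]], ms_error = x$ms[["error"]],
                 n_subjects = x$n_subjects, k_rounds = x$k_rounds,
                 n_boot = x$n_boot, degenerate = x$degenerate)
}
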