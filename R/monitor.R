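#' Assemble per-sample crystallization time series
#'
#' Collects crystallinity fits into a tidy table of A(t) and B(t) series,
#' one group of rows per tablet, sorted by time.
#'
#' @param fits Either a list of [fit_crystallinity()] objects or a data
#'   frame with columns `sample_id`, `temperature_C`, `time_h`, `A`, `B`
#'   (e.g. bound [glance()] rows).
#' @return A tibble sorted by `(sample_id, time_h)` with one row per
#'   (tablet, timepoint).
#' @export
build_series <- function(fits) {
  df <- if (is.data.frame(fits)) as_tibble(fits) else {
    dplyr::bind_rows(lapply(fits, glance))
  }
  need <- c("sample_id", "temperature_C", "time_h", "A", "B")
  if (!all(need %in% names(df))) {
    abort(sprintf("fits need columns %s.", paste(need, collapse = ", ")))
  }
  dup <- duplicated(df[c("sample_id", "time_h")])
  if (any(dup)) {
    d <- df[dup, ][1, ]
    abort(sprintf("duplicate timepoint for sample %s at %g h.", d$sample_id, d$time_h))
  }
  dplyr::arrange(df, .data$sample_id, .data$time_h)
}

#' Decimate a time series
#'
#' Keeps every `keep_every`-th timepoint of each tablet's series, starting
#' from the first. At the standard acquisition cadence of 3.5 min, the
#' default `keep_every = 4` yields the 14-min evaluation spacing used when
#' processing the full data volume is unnecessary.
#'
#' @param series A tibble from [build_series()].
#' @param keep_every Keep indices `1, 1+k, 1+2k, ...` (`k >= 1`).
#' @return The decimated tibble.
#' @export
decimate_series <- function(series, keep_every = 4) {
  if (keep_every < 1) abort("`keep_every` must be at least 1.")
  keep_every <- as.integer(keep_every)
  series |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::filter((dplyr::row_number() - 1L) %% keep_every == 0L) |>
    dplyr::ungroup()
}

#' Aggregate replicate tablets into mean +/- sd bands
#'
#' Pointwise mean and population standard deviation of A and B across the
#' replicate tablets of each storage temperature. Replicates are acquired
#' sequentially, so their timestamps may be staggered slightly; series are
#' aligned by timepoint rank and the alignment is verified against
#' `tolerance_min` rather than silently interpolated.
#'
#' @param series A tibble from [build_series()] (optionally decimated).
#' @param tolerance_min Maximum timestamp disagreement between aligned
#'   replicate points, in minutes (default 1).
#' @return A tibble with one row per (temperature, timepoint): `time_h`
#'   (mean across replicates), `A_mean`, `A_sd`, `B_mean`, `B_sd`,
#'   `n_replicates`.
#' @export
aggregate_replicates <- function(series, tolerance_min = 1) {
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  out <- series |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::mutate(.idx = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::group_by(.data$temperature_C, .data$.idx)
  spread <- out |>
    dplyr::summarise(spread_h = diff(range(.data$time_h)), .groups = "drop")
  if (any(spread$spread_h > tolerance_min / 60)) {
    abort(sprintf(
      "replicate time grids disagree by up to %.2f min (> %g min tolerance).",
      max(spread$spread_h) * 60, tolerance_min))
  }
  out |>
    dplyr::summarise(
      time_h = mean(.data$time_h),
      A_mean = mean(.data$A), A_sd = pop_sd(.data$A),
      B_mean = mean(.data$B), B_sd = pop_sd(.data$B),
      n_replicates = dplyr::n(), .groups = "drop") |>
    dplyr::select(-".idx") |>
    dplyr::arrange(.data$temperature_C, .data$time_h)
}

#' Time at which a polymorph coefficient peaks
#'
#' Applies a centered moving average (over complete windows only) to the
#' requested coefficient and returns the time of its global maximum, ties
#' broken toward the earliest time. Reading the beta-coefficient maximum off
#' a declared smoother makes the "time to peak beta content" reproducible
#' instead of a by-eye call.
#'
#' @param series A single tablet's series (columns `time_h` and the
#'   coefficient) or one temperature's aggregate (uses the `_mean` column).
#' @param coefficient `"B"` (default; the transient metastable form) or `"A"`.
#' @param smooth_window Moving-average window length in points (odd; default 5).
#' @return Peak time in hours.
#' @export
peak_time <- function(series, coefficient = "B", smooth_window = 5) {
  col <- if (coefficient %in% names(series)) coefficient else paste0(coefficient, "_mean")
  if (!col %in% names(series)) {
    abort(sprintf("series has no `%s` (or `%s_mean`) column.", coefficient, coefficient))
  }
  if ("sample_id" %in% names(series) && length(unique(series$sample_id)) > 1) {
    abort("`peak_time()` expects a single tablet's series; group or filter first.")
  }
  y <- series[[col]]
  t <- series$time_h
  if (length(y) < smooth_window) {
    abort(sprintf("need at least `smooth_window` = %d points.", smooth_window))
  }
  if (all(y == 0)) abort("coefficient is identically zero; no peak to locate.")
  sm <- stats::filter(y, rep(1 / smooth_window, smooth_window), sides = 2)
  valid <- !is.na(sm)
  t[valid][which.max(sm[valid])]
}

#' Plot aggregated crystallization kinetics
#'
#' A and B versus time per storage temperature with +/- 1 sd ribbons.
#'
#' @param aggregate A tibble from [aggregate_replicates()].
#' @return A ggplot object.
#' @export
plot_kinetics <- function(aggregate) {
  long <- aggregate |>
    tidyr::pivot_longer(cols = c("A_mean", "B_mean"), names_to = "coefficient",
                        values_to = "mean") |>
    dplyr::mutate(
      sd = ifelse(.data$coefficient == "A_mean", .data$A_sd, .data$B_sd),
      coefficient = ifelse(.data$coefficient == "A_mean",
                           "A (alpha form)", "B (beta form)"))
  ggplot2::ggplot(long, ggplot2::aes(.data$time_h, .data$mean,
                                     colour = .data$coefficient,
                                     fill = .data$coefficient)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         alpha = 0.25, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~temperature_C, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "Storage time (h)", y = "Fit coefficient (unitless)",
                  colour = NULL, fill = NULL)
}
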