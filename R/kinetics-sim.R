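#' Kinetics parameters for a synthetic aging study
#'
#' Amorphous nifedipine crystallizes sequentially: the disordered glass first
#' forms the metastable beta polymorph, which then converts to the stable
#' alpha polymorph. The generator models this as two consecutive first-order
#' steps, amorphous -> beta -> alpha, with rates `k1` and `k2` at the
#' 24 degC reference temperature, both multiplied by
#' `q10_factor^((T - 24)/10)` at storage temperature `T`.
#'
#' The defaults place the beta-coefficient maximum near 100 h at 24 degC,
#' near 29 h at 30 degC and near 10 h at 35 degC, reproducing the ordering
#' seen in accelerated-aging experiments (conversion is markedly faster at
#' higher storage temperature). The study protocol defaults mirror a
#' six-day monitoring run: 144 h, one acquisition per sample every 3.5 min,
#' five replicate tablets at each of three storage temperatures.
#'
#' @param k1_per_hour Amorphous -> beta rate at 24 degC (1/h).
#' @param k2_per_hour Beta -> alpha rate at 24 degC (1/h).
#' @param temperatures_C Storage temperatures of the study arms.
#' @param q10_factor Multiplicative rate increase per 10 degC.
#' @param duration_h Total monitoring time (h).
#' @param cadence_min Time between successive acquisitions of one sample (min).
#' @param n_replicates Tablets per storage temperature.
#' @return A validated list of class `kinetics_params`.
#' @export
kinetics_params <- function(k1_per_hour = 0.011, k2_per_hour = 0.009,
                            temperatures_C = c(24, 30, 35), q10_factor = 8,
                            duration_h = 144, cadence_min = 3.5,
                            n_replicates = 5) {
  p <- structure(
    list(k1_per_hour = k1_per_hour, k2_per_hour = k2_per_hour,
         temperatures_C = temperatures_C, q10_factor = q10_factor,
         duration_h = duration_h, cadence_min = cadence_min,
         n_replicates = as.integer(n_replicates)),
    class = "kinetics_params"
  )
  if (p$k1_per_hour <= 0 || p$k2_per_hour <= 0 || p$q10_factor <= 0) {
    abort("all kinetic rates and the Q10 factor must be positive.")
  }
  if (p$duration_h <= 0 || p$cadence_min <= 0) {
    abort("`duration_h` and `cadence_min` must be positive.")
  }
  if (p$n_replicates < 1) abort("`n_replicates` must be at least 1.")
  p
}

#' Closed-form sequential crystallization kinetics
#'
#' Solves the two-step first-order scheme
#' \deqn{x_a' = -k_1 x_a, \quad x_b' = k_1 x_a - k_2 x_b, \quad x_c' = k_2 x_b}
#' analytically from the all-amorphous initial state, at the rates implied by
#' the storage temperature. For `k1 != k2` the beta fraction is
#' \eqn{x_b(t) = k_1 (e^{-k_1 t} - e^{-k_2 t}) / (k_2 - k_1)}; the degenerate
#' `k1 == k2 == k` limit \eqn{x_b(t) = k t e^{-k t}} is used when the rates
#' coincide to within a relative `1e-9`, avoiding catastrophic cancellation.
#'
#' @param params A [kinetics_params()].
#' @param temperature_C Storage temperature; rates are scaled by
#'   `q10_factor^((temperature_C - 24)/10)`.
#' @param times_h Non-negative, increasing evaluation times in hours.
#' @return A tibble with columns `time_h`, `x_amorphous`, `x_beta`,
#'   `x_alpha`; each row sums to 1.
#' @export
#' @examples
#' simulate_kinetics(kinetics_params(), 30, c(0, 10, 50, 144))
simulate_kinetics <- function(params, temperature_C, times_h) {
  stopifnot(inherits(params, "kinetics_params"))
  if (any(times_h < 0)) abort("`times_h` must be non-negative.")
  if (is.unsorted(times_h, strictly = FALSE)) abort("`times_h` must be increasing.")

  scale <- params$q10_factor^((temperature_C - 24) / 10)
  k1 <- params$k1_per_hour * scale
  k2 <- params$k2_per_hour * scale

  xa <- exp(-k1 * times_h)
  if (abs(k1 - k2) <= 1e-9 * max(k1, k2)) {
    xb <- k1 * times_h * exp(-k1 * times_h)
  } else {
    xb <- k1 / (k2 - k1) * (exp(-k1 * times_h) - exp(-k2 * times_h))
  }
  xc <- 1 - xa - xb
  tibble(time_h = as.numeric(times_h), x_amorphous = xa, x_beta = xb,
         x_alpha = pmin(pmax(xc, 0), 1))
}

# Time at which the beta fraction is maximal (analytic argmax); used by the
# generator's documentation and tests.
beta_peak_time <- function(params, temperature_C) {
  scale <- params$q10_factor^((temperature_C - 24) / 10)
  k1 <- params$k1_per_hour * scale
  k2 <- params$k2_per_hour * scale
  if (abs(k1 - k2) <= 1e-9 * max(k1, k2)) 1 / k1 else log(k1 / k2) / (k1 - k2)
}
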