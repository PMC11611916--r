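#' Parameters of the synthetic reference pulse
#'
#' The synthetic instrument emits a single-cycle THz transient modeled as
#' the first derivative of a Gaussian, `A * (t - t0)/w * exp(1/2 - (t -
#' t0)^2 / (2 w^2))`, normalized so its extrema reach `amplitude_au`. With
#' the default 0.25 ps width the spectral amplitude peaks near 0.6 THz and
#' retains usable signal through 2 THz, matching the band over which tablet
#' optical constants are analyzed.
#'
#' Detector noise is additive white Gaussian noise on every raw
#' acquisition; `n_averages` raw scans are averaged into each stored
#' waveform, so the stored noise level is `noise_std_au / sqrt(n_averages)`.
#' The default mirrors the measurement protocol of averaging 100 scans.
#'
#' @param center_time_ps Pulse center; the first 5 ps of the record must be
#'   pre-pulse so the DC-offset estimate is signal-free.
#' @param width_ps Gaussian width parameter of the single-cycle pulse.
#' @param amplitude_au Peak amplitude.
#' @param time_window_ps Record length.
#' @param dt_ps Sampling interval.
#' @param noise_std_au Noise standard deviation per raw acquisition.
#' @param n_averages Raw acquisitions averaged per stored waveform.
#' @return A list of class `pulse_params`.
#' @export
pulse_params <- function(center_time_ps = 10, width_ps = 0.25,
                         amplitude_au = 1, time_window_ps = 40,
                         dt_ps = 0.05, noise_std_au = 0.01,
                         n_averages = 100) {
  p <- structure(
    list(center_time_ps = center_time_ps, width_ps = width_ps,
         amplitude_au = amplitude_au, time_window_ps = time_window_ps,
         dt_ps = dt_ps, noise_std_au = noise_std_au,
         n_averages = as.integer(n_averages)),
    class = "pulse_params"
  )
  if (p$dt_ps <= 0) abort("`dt_ps` must be positive.")
  if (p$time_window_ps <= p$center_time_ps) {
    abort("`time_window_ps` must extend beyond the pulse center.")
  }
  if (p$n_averages < 1) abort("`n_averages` must be at least 1.")
  if (p$noise_std_au < 0) abort("`noise_std_au` must be non-negative.")
  p
}

pulse_time_axis <- function(pulse) {
  seq(0, pulse$time_window_ps - pulse$dt_ps, by = pulse$dt_ps)
}

# Noiseless single-cycle field on the record's time axis.
pulse_field <- function(pulse, t = pulse_time_axis(pulse)) {
  u <- (t - pulse$center_time_ps) / pulse$width_ps
  pulse$amplitude_au * u * exp(0.5 - u^2 / 2)
}

# Two-sided FFT frequency axis in THz for n samples at dt ps.
fft_freqs <- function(n, dt_ps) {
  f <- (0:(n - 1)) / (n * dt_ps)
  nyq <- 1 / (2 * dt_ps)
  f[f >= nyq] <- f[f >= nyq] - 1 / dt_ps
  f
}

#' Mix the absorption spectrum of a partially crystallized tablet
#'
#' Forward model of the spectral signature at one timepoint: the
#' crystalline peak sums of the alpha and beta reference models weighted by
#' their phase fractions, on top of a quadratic background that relaxes
#' linearly (coefficient-wise) from the amorphous level towards a lower
#' crystalline level as the total crystalline fraction grows — the baseline
#' drop that accompanies the collapse of the glassy vibrational density of
#' states.
#'
#' @param fractions One-row data frame or named list/vector with
#'   `x_amorphous`, `x_beta`, `x_alpha` (each in `[0, 1]`, summing to 1
#'   within `1e-9`).
#' @param ref_alpha,ref_beta [reference_model()]s whose peak sums carry the
#'   crystalline signatures.
#' @param background_amorphous Quadratic coefficients `c(c0, c1, c2)` of the
#'   fully amorphous background (cm^-1, nu in THz).
#' @param freq_THz Positive, increasing frequency axis.
#' @param background_crystalline Background of a fully crystalline tablet;
#'   defaults to half the amorphous level.
#' @return A tibble with columns `freq_THz`, `alpha_cm1`.
#' @export
compose_absorption <- function(fractions, ref_alpha, ref_beta,
                               background_amorphous = c(0.5, 2, 3),
                               freq_THz,
                               background_crystalline = 0.5 * background_amorphous) {
  x <- as.list(fractions)
  xa <- x$x_amorphous; xb <- x$x_beta; xc <- x$x_alpha
  if (any(c(xa, xb, xc) < -1e-12) || abs(xa + xb + xc - 1) > 1e-9) {
    abort("phase fractions must lie in [0, 1] and sum to 1.")
  }
  if (any(freq_THz <= 0) || is.unsorted(freq_THz, strictly = TRUE)) {
    abort("`freq_THz` must be positive and strictly increasing.")
  }
  cryst <- xb + xc
  bg <- (1 - cryst) * background_amorphous + cryst * background_crystalline
  tibble(
    freq_THz = as.numeric(freq_THz),
    alpha_cm1 = xc * peak_sum(ref_alpha, freq_THz) +
      xb * peak_sum(ref_beta, freq_THz) +
      quad_eval(bg, freq_THz)
  )
}

# Frequency-domain slab transfer applied to a time-domain field.
# n_val, alpha_cm1 evaluated on the full two-sided FFT grid (absolute
# frequencies); the Fresnel amplitude factor 4n/(n+1)^2 is the exact
# reciprocal of the (n+1)^2/(4n) correction used in extraction, so a
# noiseless pair round-trips to machine precision.
apply_slab <- function(field, dt_ps, n_fun, alpha_fun, d_mm) {
  N <- length(field)
  f <- fft_freqs(N, dt_ps)
  fa <- abs(f)
  n <- n_fun(fa)
  a_mm <- alpha_fun(fa) / 10  # cm^-1 -> mm^-1
  if (any(n < 1)) abort("the slab model requires n(nu) >= 1.")
  if (any(a_mm < -1e-12)) abort("the slab model requires alpha(nu) >= 0.")
  H <- (4 * n / (n + 1)^2) * exp(-a_mm * d_mm / 2) *
    exp(-1i * 2 * pi * f * (n - 1) * d_mm / C_MM_PER_PS)
  Re(fft(fft(field) * H, inverse = TRUE)) / N
}

#' Synthesize a sample/reference waveform pair for a plano-parallel tablet
#'
#' Builds the reference transient from `pulse`, then constructs the sample
#' transient in the frequency domain by applying the slab transmission
#' model: the Fresnel transmission factor `4n/(n+1)^2`, Beer-Lambert
#' attenuation `exp(-alpha d / 2)` in field amplitude, and the propagation
#' delay phase `exp(-i 2 pi nu (n-1) d / c)`. Independent averaged detector
#' noise is added to each waveform.
#'
#' @param n_of_freq Function of frequency (THz) returning the refractive
#'   index (`>= 1`), or a single number.
#' @param alpha_of_freq Function of frequency (THz) returning the absorption
#'   coefficient in cm^-1 (`>= 0`), or a single number.
#' @param d_mm Tablet thickness in mm.
#' @param pulse A [pulse_params()].
#' @param seed Optional integer; when given, the pair is reproducible
#'   bit-for-bit and the caller's RNG state is untouched.
#' @param meta_sample,meta_reference Metadata for the two scans.
#' @return A list with elements `reference` and `sample`, both [waveform()]s.
#' @export
synthesize_waveform_pair <- function(n_of_freq, alpha_of_freq, d_mm,
                                     pulse = pulse_params(), seed = NULL,
                                     meta_sample = scan_meta(sample_id = "synthetic", thickness_mm = d_mm),
                                     meta_reference = scan_meta(sample_id = "synthetic_ref", role = "reference")) {
  if (d_mm <= 0) abort("`d_mm` must be positive.")
  n_fun <- as_freq_fun(n_of_freq)
  a_fun <- as_freq_fun(alpha_of_freq)

  t <- pulse_time_axis(pulse)
  n_max <- max(n_fun(seq(0, 1 / (2 * pulse$dt_ps), length.out = 257)))
  needed <- pulse$center_time_ps + (n_max - 1) * d_mm / C_MM_PER_PS + 6 * pulse$width_ps
  if (needed > pulse$time_window_ps) {
    abort(sprintf(
      "sample pulse is delayed beyond the record: time_window_ps must be at least %.2f ps.",
      needed))
  }

  ref_field <- pulse_field(pulse, t)
  smp_field <- apply_slab(ref_field, pulse$dt_ps, n_fun, a_fun, d_mm)

  noise_sd <- pulse$noise_std_au / sqrt(pulse$n_averages)
  draw <- function() {
    if (noise_sd > 0) rnorm(2 * length(t), sd = noise_sd) else numeric(2 * length(t))
  }
  eps <- if (is.null(seed)) draw() else with_preserved_seed(seed, draw())
  m <- length(t)

  meta_sample$n_averages <- pulse$n_averages
  meta_reference$n_averages <- pulse$n_averages
  list(
    reference = waveform(t, ref_field + eps[seq_len(m)], meta_reference),
    sample = waveform(t, smp_field + eps[m + seq_len(m)], meta_sample)
  )
}

as_freq_fun <- function(x) {
  if (is.function(x)) x else {
    val <- as.numeric(x)
    function(f) rep(val, length(f))
  }
}

# Evaluate `expr` under `seed` and restore the caller's RNG state.
with_preserved_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
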