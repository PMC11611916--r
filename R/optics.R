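#' Transfer function of a sample/reference spectrum pair
#'
#' Computes the complex transmission ratio of a tablet scan against its
#' nitrogen reference, restricted to the reliable analysis band: the
#' magnitude `|T(nu)| = |E_sample / E_reference|` and the processed phase
#' difference `delta_phi(nu)`.
#'
#' Phase processing: both one-sided phases are unwrapped from the lowest
#' in-band frequency upward, subtracted (reference minus sample, which is
#' positive for an optically delayed sample under the `exp(-i omega t)`
#' transform convention), and the whole curve is then shifted by the integer
#' multiple of `2 pi` nearest the intercept of a straight-line fit over the
#' band, so that the extrapolated phase passes through the origin. This
#' branch correction pins the physically meaningful branch that a pure
#' propagation delay `delta_phi = 2 pi nu dt` defines.
#'
#' @param sample,reference `thz_spectrum` objects on one frequency axis.
#' @param band_THz Analysis band `c(lo, hi)`; default 0.3-2.0 THz, inside
#'   which the synthetic instrument has usable dynamic range.
#' @param floor_rel Reference bins whose magnitude falls below `floor_rel`
#'   times the reference maximum are below the dynamic-range floor; hitting
#'   one inside the band is an error naming the frequency.
#' @return A tibble of class `thz_transfer` with columns `freq_THz`,
#'   `magnitude`, `delta_phi_rad`, restricted to the band.
#' @export
transfer_function <- function(sample, reference, band_THz = c(0.3, 2.0),
                              floor_rel = 1e-6) {
  stopifnot(inherits(sample, "thz_spectrum"), inherits(reference, "thz_spectrum"))
  if (nrow(sample) != nrow(reference) ||
      max(abs(sample$freq_THz - reference$freq_THz)) > 1e-9) {
    abort("sample and reference spectra must share one frequency axis.")
  }
  f <- sample$freq_THz
  if (band_THz[1] <= 0 || band_THz[2] > max(f) || band_THz[1] >= band_THz[2]) {
    abort("`band_THz` must be a positive interval inside the frequency axis.")
  }
  ib <- f >= band_THz[1] & f <= band_THz[2]
  ref_mag <- Mod(reference$field)
  weak <- ib & ref_mag < floor_rel * max(ref_mag)
  if (any(weak)) {
    abort(sprintf(
      "reference magnitude below the dynamic-range floor at %.4g THz; shrink the band.",
      f[which(weak)[1]]))
  }

  mag <- Mod(sample$field[ib] / reference$field[ib])
  phi_s <- signal::unwrap(Arg(sample$field[ib]))
  phi_r <- signal::unwrap(Arg(reference$field[ib]))
  dphi <- phi_r - phi_s
  fit <- lm(dphi ~ f[ib])
  dphi <- dphi - 2 * pi * round(coef(fit)[[1]] / (2 * pi))

  out <- tibble(freq_THz = f[ib], magnitude = mag, delta_phi_rad = dphi)
  attr(out, "band_THz") <- as.numeric(band_THz)
  attr(out, "meta") <- attr(sample, "meta")
  class(out) <- c("thz_transfer", class(out))
  out
}

#' Refractive index from the processed phase difference
#'
#' `n(nu) = 1 + c * delta_phi(nu) / (2 pi nu d)`, evaluated strictly inside
#' the band (the expression is singular at `nu = 0`).
#'
#' @param tf A [transfer_function()] result.
#' @param d_mm Tablet thickness in mm; defaults to the thickness carried in
#'   the scan metadata.
#' @return Numeric vector of refractive indices, one per in-band bin.
#' @export
refractive_index <- function(tf, d_mm = NULL) {
  stopifnot(inherits(tf, "thz_transfer"))
  d_mm <- d_mm %||% attr(tf, "meta")$thickness_mm
  if (is.null(d_mm) || is.na(d_mm) || d_mm <= 0) {
    abort("a positive tablet thickness `d_mm` is required.")
  }
  1 + C_MM_PER_PS * tf$delta_phi_rad / (2 * pi * tf$freq_THz * d_mm)
}

#' Absorption coefficient with Fresnel correction
#'
#' `alpha(nu) = -(2/d) * ln( ((n+1)^2 / (4 n)) * |T(nu)| )`, reported in
#' cm^-1. The `(n+1)^2/(4n)` factor removes the reflection loss of the two
#' tablet/air interfaces so that only bulk absorption remains.
#'
#' @param tf A [transfer_function()] result.
#' @param n Refractive index: a vector aligned with `tf` or a single value.
#' @param d_mm Tablet thickness in mm (default: from metadata).
#' @return A tibble of class `thz_absorption` with columns `freq_THz`,
#'   `alpha_cm1`.
#' @export
absorption_coefficient <- function(tf, n, d_mm = NULL) {
  stopifnot(inherits(tf, "thz_transfer"))
  d_mm <- d_mm %||% attr(tf, "meta")$thickness_mm
  if (is.null(d_mm) || is.na(d_mm) || d_mm <= 0) {
    abort("a positive tablet thickness `d_mm` is required.")
  }
  if (any(n <= 0)) abort("`n` must be positive within the band.")
  arg <- ((n + 1)^2 / (4 * n)) * tf$magnitude
  if (any(arg <= 0)) {
    abort(sprintf(
      "non-positive logarithm argument at %.4g THz: unphysical magnitude/Fresnel combination.",
      tf$freq_THz[which(arg <= 0)[1]]))
  }
  d_cm <- d_mm / 10
  out <- tibble(freq_THz = tf$freq_THz, alpha_cm1 = -(2 / d_cm) * log(arg))
  attr(out, "meta") <- attr(tf, "meta")
  attr(out, "band_THz") <- attr(tf, "band_THz")
  class(out) <- c("thz_absorption", class(out))
  out
}

#' Extract optical constants from a waveform pair
#'
#' The full per-scan chain: preprocessing (DC removal over the first
#' `head_ps`, Tukey windowing, zero-padded Fourier transform) of both scans,
#' transfer function over the band, refractive index, and
#' Fresnel-corrected absorption coefficient. Thickness is taken from the
#' sample scan's metadata.
#'
#' @param sample_wf,reference_wf [waveform()]s of the tablet and reference.
#' @param band_THz Analysis band (default 0.3-2.0 THz).
#' @param head_ps,tukey_alpha,pad_factor Preprocessing parameters, see
#'   [remove_dc()], [apply_window()], [to_spectrum()].
#' @return A tibble of class `thz_optical_constants` with columns
#'   `freq_THz`, `n`, `alpha_cm1`; metadata and processing parameters ride
#'   along as attributes.
#' @export
extract_optical_constants <- function(sample_wf, reference_wf,
                                      band_THz = c(0.3, 2.0), head_ps = 5.0,
                                      tukey_alpha = 0.1, pad_factor = 4) {
  meta <- wf_meta(sample_wf)
  if (is.na(meta$thickness_mm)) {
    abort(sprintf("sample scan %s has no thickness; cannot extract optical constants.",
                  meta$sample_id))
  }
  s_spec <- preprocess_waveform(sample_wf, head_ps, tukey_alpha, pad_factor)
  r_spec <- preprocess_waveform(reference_wf, head_ps, tukey_alpha, pad_factor)
  tf <- transfer_function(s_spec, r_spec, band_THz)
  n <- refractive_index(tf)
  ab <- absorption_coefficient(tf, n)
  out <- tibble(freq_THz = tf$freq_THz, n = n, alpha_cm1 = ab$alpha_cm1)
  attr(out, "meta") <- meta
  attr(out, "band_THz") <- as.numeric(band_THz)
  attr(out, "processing") <- list(head_ps = head_ps, tukey_alpha = tukey_alpha,
                                  pad_factor = pad_factor)
  class(out) <- c("thz_optical_constants", "thz_absorption", class(out))
  out
}

#' @export
autoplot.thz_absorption <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$freq_THz, .data$alpha_cm1)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Frequency (THz)",
                  y = expression(alpha ~ (cm^-1)),
                  title = attr(object, "meta")$sample_id)
}
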