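#' Reference spectral model of one crystalline polymorph
#'
#' Each crystalline form of nifedipine shows three phonon absorption peaks in
#' the low-THz range, each well described by a Gaussian line on top of a
#' monotonically rising quadratic background (dominated by scattering). A
#' reference model bundles the three peaks and the background for one form.
#'
#' The Gaussian width convention is the e-folding half-width as the mixture
#' model is written: each line is `G * exp(-((nu - nu0)/dnu)^2)`. This is
#' neither the standard-deviation sigma (`dnu = sqrt(2) * sigma`) nor the
#' FWHM (`FWHM = 2 * sqrt(log(2)) * dnu`); see [dnu_to_fwhm()].
#'
#' @param form `"alpha"` or `"beta"`.
#' @param peaks A data frame with columns `G_cm1` (amplitude, cm^-1, `>= 0`),
#'   `nu0_THz` (center) and `dnu_THz` (e-folding half-width, `> 0`); exactly
#'   three rows. Rows are stored sorted by center frequency.
#' @param background Quadratic background coefficients `c(c0, c1, c2)` of
#'   `c0 + c1*nu + c2*nu^2` (cm^-1 with `nu` in THz).
#' @param fit_band_THz Frequency band over which the model is valid.
#' @param residual_rms_cm1 Root-mean-square fit residual, when the model was
#'   fitted to a spectrum (`NA` for constructed models).
#' @return An object of class `reference_model`.
#' @seealso [fit_reference()], [nif_reference_alpha()]
#' @export
reference_model <- function(form, peaks, background = c(0, 0, 0),
                            fit_band_THz = c(0.5, 1.8),
                            residual_rms_cm1 = NA_real_) {
  form <- match.arg(form, c("alpha", "beta"))
  peaks <- as_tibble(peaks)
  need <- c("G_cm1", "nu0_THz", "dnu_THz")
  if (!all(need %in% names(peaks))) {
    abort(sprintf("`peaks` needs columns %s.", paste(need, collapse = ", ")))
  }
  if (nrow(peaks) != 3) {
    warn(sprintf("reference model for %s-form has %d peaks; the standard model uses exactly three.",
                 form, nrow(peaks)))
  }
  if (any(peaks$G_cm1 < 0) || any(peaks$dnu_THz <= 0)) {
    abort("peak amplitudes must be >= 0 and widths > 0.")
  }
  peaks <- dplyr::arrange(peaks[need], .data$nu0_THz)
  structure(
    list(form = form, peaks = peaks, background = as.numeric(background),
         fit_band_THz = as.numeric(fit_band_THz),
         residual_rms_cm1 = residual_rms_cm1),
    class = "reference_model"
  )
}

#' Built-in nifedipine reference models
#'
#' Reference models of the two crystalline forms at the literature peak
#' centers: 1.09, 1.20 and 1.36 THz for the stable alpha form, and three
#' weaker lines at 0.95, 1.25 and 1.50 THz for the metastable beta form.
#' Amplitudes and widths are the package defaults (alpha peaks 3-6 cm^-1,
#' beta peaks 1.5-2.5 cm^-1, widths 0.05-0.08 THz), chosen to reproduce the
#' alpha/beta intensity contrast of measured tablet spectra; they are
#' placeholders for instrument-specific values obtained with
#' [fit_reference()] on pure-form scans.
#'
#' @return A `reference_model`.
#' @export
nif_reference_alpha <- function() {
  reference_model("alpha", tibble(
    G_cm1 = c(4, 3, 6),
    nu0_THz = c(1.09, 1.20, 1.36),
    dnu_THz = c(0.05, 0.05, 0.08)
  ))
}

#' @rdname nif_reference_alpha
#' @export
nif_reference_beta <- function() {
  reference_model("beta", tibble(
    G_cm1 = c(1.5, 2.5, 2),
    nu0_THz = c(0.95, 1.25, 1.50),
    dnu_THz = c(0.06, 0.07, 0.08)
  ))
}

#' Evaluate a reference model
#'
#' `peak_sum()` evaluates only the Gaussian peak sum (the polymorph
#' signature); `predict()` adds the quadratic background.
#'
#' @param model A [reference_model()].
#' @param freq_THz Frequencies at which to evaluate.
#' @return Numeric vector of absorption values in cm^-1.
#' @export
peak_sum <- function(model, freq_THz) {
  stopifnot(inherits(model, "reference_model"))
  p <- model$peaks
  out <- numeric(length(freq_THz))
  for (i in seq_len(nrow(p))) {
    out <- out + p$G_cm1[i] * exp(-((freq_THz - p$nu0_THz[i]) / p$dnu_THz[i])^2)
  }
  out
}

#' @rdname peak_sum
#' @param object A [reference_model()].
#' @param ... Unused.
#' @export
predict.reference_model <- function(object, freq_THz, ...) {
  peak_sum(object, freq_THz) + quad_eval(object$background, freq_THz)
}

quad_eval <- function(coefs, x) coefs[1] + coefs[2] * x + coefs[3] * x^2

#' Gaussian width conversions
#'
#' Convert between the e-folding half-width `dnu` used throughout this
#' package and the full width at half maximum.
#'
#' @param dnu_THz,fwhm_THz Width values to convert.
#' @return Converted widths.
#' @export
dnu_to_fwhm <- function(dnu_THz) 2 * sqrt(log(2)) * dnu_THz

#' @rdname dnu_to_fwhm
#' @export
fwhm_to_dnu <- function(fwhm_THz) fwhm_THz / (2 * sqrt(log(2)))

#' @export
print.reference_model <- function(x, ...) {
  cat(sprintf("<reference_model> %s-form, band %.2f-%.2f THz, residual rms %s cm^-1\n",
              x$form, x$fit_band_THz[1], x$fit_band_THz[2],
              format(x$residual_rms_cm1, digits = 3)))
  print(x$peaks)
  cat(sprintf("background: %.4g + %.4g nu + %.4g nu^2 (cm^-1)\n",
              x$background[1], x$background[2], x$background[3]))
  invisible(x)
}

#' @export
tidy.reference_model <- function(x, ...) {
  dplyr::bind_rows(
    tibble(term = sprintf("peak%d_%s", rep(1:nrow(x$peaks), each = 3),
                          rep(c("G_cm1", "nu0_THz", "dnu_THz"), nrow(x$peaks))),
           estimate = as.numeric(t(as.matrix(x$peaks)))),
    tibble(term = c("c0", "c1", "c2"), estimate = x$background)
  )
}

#' @export
glance.reference_model <- function(x, ...) {
  tibble(form = x$form, n_peaks = nrow(x$peaks),
         band_lo_THz = x$fit_band_THz[1], band_hi_THz = x$fit_band_THz[2],
         residual_rms_cm1 = x$residual_rms_cm1)
}

#' Serialize a reference model to a human-readable parameter file
#'
#' @param model A [reference_model()].
#' @param path Destination (YAML).
#' @return `path`, invisibly; `read_reference_model()` returns the model.
#' @export
write_reference_model <- function(model, path) {
  stopifnot(inherits(model, "reference_model"))
  yaml::write_yaml(list(
    form = model$form,
    peaks = lapply(seq_len(nrow(model$peaks)), function(i) as.list(model$peaks[i, ])),
    background = as.list(setNames(model$background, c("c0", "c1", "c2"))),
    fit_band_THz = model$fit_band_THz,
    residual_rms_cm1 = if (is.na(model$residual_rms_cm1)) NULL else model$residual_rms_cm1
  ), path)
  invisible(path)
}

#' @rdname write_reference_model
#' @export
read_reference_model <- function(path) {
  y <- yaml::read_yaml(path)
  reference_model(
    form = y$form,
    peaks = dplyr::bind_rows(lapply(y$peaks, as_tibble)),
    background = unlist(y$background, use.names = FALSE),
    fit_band_THz = unlist(y$fit_band_THz),
    residual_rms_cm1 = y$residual_rms_cm1 %||% NA_real_
  )
}
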