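#' Fit a three-Gaussian-plus-quadratic reference model to a pure-form spectrum
#'
#' Nonlinear least squares of `sum_i G_i exp(-((nu - nu0_i)/dnu_i)^2) + c0 +
#' c1 nu + c2 nu^2` to an absorption spectrum of a pure crystalline form.
#' Initial peak positions and heights come from the `n_peaks` most prominent
#' local maxima of the quadratically detrended spectrum; bounds keep
#' amplitudes non-negative, widths in `[0.01, 0.5]` THz and centers inside
#' the band. A spectrum without enough prominent maxima is rejected with a
#' hint that it may be amorphous (disordered solids show only a monotonously
#' rising absorption, no peaks).
#'
#' @param spec A data frame with columns `freq_THz` and `alpha_cm1` (e.g.
#'   from [extract_optical_constants()]).
#' @param form `"alpha"` or `"beta"`.
#' @param n_peaks Number of Gaussian lines; the crystalline forms of
#'   nifedipine each show exactly three, other values are allowed but
#'   flagged with a warning.
#' @param band_THz Fit band; default 0.5-1.8 THz covers all six peaks of
#'   both forms.
#' @return A [reference_model()] with peaks sorted by center frequency and
#'   the residual RMS recorded.
#' @export
fit_reference <- function(spec, form = c("alpha", "beta"), n_peaks = 3,
                          band_THz = c(0.5, 1.8)) {
  form <- match.arg(form)
  ib <- spec$freq_THz >= band_THz[1] & spec$freq_THz <= band_THz[2]
  if (sum(ib) < 3 * n_peaks + 3) abort("spectrum does not cover the fit band densely enough.")
  f <- spec$freq_THz[ib]
  y <- spec$alpha_cm1[ib]

  detrend <- lm(y ~ f + I(f^2))
  r <- stats::resid(detrend)
  thr <- max(0.05, 0.2 * max(r))
  pk <- pracma::findpeaks(r, minpeakheight = thr, sortstr = TRUE)
  if (is.null(pk) || nrow(pk) < n_peaks) {
    abort(sprintf(
      "found %d prominent maxima but %d peaks requested; the spectrum may be amorphous (no crystalline peaks).",
      if (is.null(pk)) 0L else nrow(pk), n_peaks))
  }
  pk <- pk[seq_len(n_peaks), , drop = FALSE]

  # parameter vector: (G_1..k, nu0_1..k, dnu_1..k, c0, c1, c2)
  par0 <- c(pmax(pk[, 1], 0.1), f[pk[, 2]], rep(0.07, n_peaks), coef(detrend))
  lower <- c(rep(0, n_peaks), rep(band_THz[1], n_peaks), rep(0.01, n_peaks), rep(-Inf, 3))
  upper <- c(rep(Inf, n_peaks), rep(band_THz[2], n_peaks), rep(0.5, n_peaks), rep(Inf, 3))

  model_fn <- function(p) {
    G <- p[seq_len(n_peaks)]
    nu0 <- p[n_peaks + seq_len(n_peaks)]
    dnu <- p[2 * n_peaks + seq_len(n_peaks)]
    bg <- p[3 * n_peaks + 1:3]
    out <- quad_eval(bg, f)
    for (i in seq_len(n_peaks)) out <- out + G[i] * exp(-((f - nu0[i]) / dnu[i])^2)
    out
  }
  fit <- minpack.lm::nls.lm(
    par = par0, lower = lower, upper = upper,
    fn = function(p) y - model_fn(p),
    control = minpack.lm::nls.lm.control(maxiter = 500)
  )
  if (!fit$info %in% 1:4) {
    abort(sprintf("reference fit did not converge (code %d, residual rms %.3g cm^-1).",
                  fit$info, sqrt(mean(fit$fvec^2))))
  }
  p <- unname(fit$par)
  reference_model(
    form = form,
    peaks = tibble(G_cm1 = p[seq_len(n_peaks)],
                   nu0_THz = p[n_peaks + seq_len(n_peaks)],
                   dnu_THz = p[2 * n_peaks + seq_len(n_peaks)]),
    background = p[3 * n_peaks + 1:3],
    fit_band_THz = band_THz,
    residual_rms_cm1 = sqrt(mean(fit$fvec^2))
  )
}

#' Fit polymorph coefficients A and B to an absorption spectrum
#'
#' Decomposes a spectrum as
#' `f(nu) = A * P_alpha(nu) + B * P_beta(nu) + c0 + c1 nu + c2 nu^2`,
#' where `P_alpha` and `P_beta` are the fixed Gaussian peak sums of the two
#' reference models. Because every peak parameter is frozen at its
#' reference value, the model is linear in `(A, B, c0, c1, c2)` and is
#' solved as constrained linear least squares with `A, B >= 0` — no random
#' initialization, fully deterministic. The non-negativity constraint is
#' resolved exactly by enumerating the active sets of the two bounded
#' coefficients; the unconstrained solution is kept for diagnostics.
#'
#' `A = 1` (`B = 1`) corresponds to the peak intensity of the pure-form
#' reference spectrum; A and B are relative coefficients, not absolute mass
#' fractions.
#'
#' @param spec A data frame with `freq_THz`, `alpha_cm1`.
#' @param ref_alpha,ref_beta [reference_model()]s with frozen peak shapes.
#' @param band_THz Fit band (default 0.5-1.8 THz).
#' @return An object of class `crystallinity_fit` with elements `A`, `B`,
#'   `background`, `residual_rms_cm1`, `unconstrained` (the unbounded
#'   least-squares pair), and scan coordinates (`sample_id`, `time_h`,
#'   `temperature_C`) when the spectrum carries metadata.
#' @export
fit_crystallinity <- function(spec, ref_alpha, ref_beta, band_THz = c(0.5, 1.8)) {
  stopifnot(inherits(ref_alpha, "reference_model"), inherits(ref_beta, "reference_model"))
  ib <- spec$freq_THz >= band_THz[1] & spec$freq_THz <= band_THz[2]
  if (sum(ib) < 6) abort("spectrum does not cover the fit band.")
  f <- spec$freq_THz[ib]
  y <- spec$alpha_cm1[ib]
  X <- cbind(pa = peak_sum(ref_alpha, f), pb = peak_sum(ref_beta, f),
             c0 = 1, c1 = f, c2 = f^2)
  peak_scale <- c(max(ref_alpha$peaks$G_cm1), max(ref_beta$peaks$G_cm1))
  if (qr(X)$rank < ncol(X) ||
      max(X[, "pa"]) < 1e-6 * peak_scale[1] ||
      max(X[, "pb"]) < 1e-6 * peak_scale[2]) {
    abort("rank-deficient design: the band does not separate the model components.")
  }

  solve_ls <- function(cols) {
    beta <- rep(0, ncol(X))
    fit <- stats::lm.fit(X[, cols, drop = FALSE], y)
    beta[cols] <- fit$coefficients
    list(beta = beta, rss = sum(fit$residuals^2))
  }
  free <- solve_ls(1:5)
  best <- NULL
  # enumerate active sets of the two sign-constrained coefficients (exact
  # for this 2-constraint problem)
  for (active in list(integer(), 1L, 2L, c(1L, 2L))) {
    cols <- setdiff(1:5, active)
    cand <- solve_ls(cols)
    if (cand$beta[1] >= -1e-12 && cand$beta[2] >= -1e-12) {
      if (is.null(best) || cand$rss < best$rss) best <- cand
    }
  }
  beta <- pmax(best$beta, c(0, 0, -Inf, -Inf, -Inf))
  meta <- attr(spec, "meta")
  structure(
    list(A = beta[1], B = beta[2], background = beta[3:5],
         residual_rms_cm1 = sqrt(best$rss / length(y)),
         unconstrained = c(A = free$beta[1], B = free$beta[2]),
         band_THz = as.numeric(band_THz),
         sample_id = meta$sample_id %||% NA_character_,
         time_h = meta$time_h %||% NA_real_,
         temperature_C = meta$temperature_C %||% NA_real_),
    class = "crystallinity_fit"
  )
}

#' @export
print.crystallinity_fit <- function(x, ...) {
  cat(sprintf("<crystallinity_fit> A = %.4g, B = %.4g (residual rms %.3g cm^-1)\n",
              x$A, x$B, x$residual_rms_cm1))
  if (!is.na(x$sample_id)) {
    cat(sprintf("  %s | T = %s degC | t = %s h\n", x$sample_id,
                format(x$temperature_C), format(x$time_h)))
  }
  invisible(x)
}

#' @export
tidy.crystallinity_fit <- function(x, ...) {
  tibble(term = c("A", "B", "c0", "c1", "c2"),
         estimate = c(x$A, x$B, x$background))
}

#' @export
glance.crystallinity_fit <- function(x, ...) {
  tibble(sample_id = x$sample_id, temperature_C = x$temperature_C,
         time_h = x$time_h, A = x$A, B = x$B,
         residual_rms_cm1 = x$residual_rms_cm1)
}

#' Classify the solid-state form of a spectrum
#'
#' Labels a spectrum `"amorphous"` when both polymorph coefficients fall
#' below `tau` (an amorphous tablet shows only the featureless rising
#' background), `"mixed"` when the two coefficients are within a factor of
#' two of each other, and otherwise by the dominant coefficient.
#'
#' @param spec A spectrum data frame, or an existing [fit_crystallinity()]
#'   result.
#' @param ref_alpha,ref_beta Reference models (ignored when `spec` is
#'   already a fit).
#' @param tau Amorphous threshold on both coefficients (default 0.05).
#' @param mixed_ratio A/B ratio range labeled `"mixed"` (default 0.5-2).
#' @param band_THz Fit band forwarded to [fit_crystallinity()].
#' @return One of `"amorphous"`, `"alpha"`, `"beta"`, `"mixed"`.
#' @export
classify_form <- function(spec, ref_alpha = NULL, ref_beta = NULL, tau = 0.05,
                          mixed_ratio = c(0.5, 2), band_THz = c(0.5, 1.8)) {
  fit <- if (inherits(spec, "crystallinity_fit")) spec else {
    fit_crystallinity(spec, ref_alpha, ref_beta, band_THz)
  }
  if (fit$A < tau && fit$B < tau) return("amorphous")
  ratio <- fit$A / fit$B
  if (is.finite(ratio) && ratio >= mixed_ratio[1] && ratio <= mixed_ratio[2]) return("mixed")
  if (fit$A > fit$B) "alpha" else "beta"
}
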