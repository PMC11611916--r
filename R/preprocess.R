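#' Average repeated waveforms
#'
#' Pointwise arithmetic mean of raw acquisitions sharing one time axis and
#' sample id; the result's `n_averages` records the count, and additive
#' white detector noise shrinks by `1/sqrt(N)`.
#'
#' @param waveforms A list of [waveform()]s with identical time axes.
#' @return A single averaged [waveform()].
#' @export
average_waveforms <- function(waveforms) {
  if (length(waveforms) < 1) abort("need at least one waveform to average.")
  ref <- waveforms[[1]]
  for (wf in waveforms[-1]) {
    if (nrow(wf) != nrow(ref) || max(abs(wf$time_ps - ref$time_ps)) > 1e-9) {
      abort("all waveforms must share the same time axis.")
    }
    if (!identical(wf_meta(wf)$sample_id, wf_meta(ref)$sample_id)) {
      abort("refusing to average scans of different samples.")
    }
  }
  amp <- Reduce(`+`, lapply(waveforms, function(w) w$amplitude_au)) / length(waveforms)
  meta <- wf_meta(ref)
  meta$n_averages <- length(waveforms)
  wf_update(ref, amp, meta)
}

#' Remove the DC offset estimated from the pre-pulse head
#'
#' Subtracts the mean amplitude over the first `head_ps` picoseconds of the
#' record (a half-open interval `[t0, t0 + head_ps)` relative to the first
#' sample). The head of the record is pre-pulse by construction, so this
#' estimates the detector's DC offset without touching the transient.
#'
#' @param wf A [waveform()].
#' @param head_ps Length of the offset-estimation window (default 5 ps).
#' @return The offset-corrected [waveform()].
#' @export
remove_dc <- function(wf, head_ps = 5.0) {
  span <- wf$time_ps[nrow(wf)] - wf$time_ps[1]
  if (head_ps >= span) {
    abort(sprintf("`head_ps` (%g) must be shorter than the record (%g ps).", head_ps, span))
  }
  idx <- wf$time_ps < wf$time_ps[1] + head_ps
  wf_update(wf, wf$amplitude_au - mean(wf$amplitude_au[idx]))
}

#' Tukey (tapered-cosine) window
#'
#' @param n Window length.
#' @param alpha Taper fraction in `[0, 1]`: 0 gives a rectangular window,
#'   1 a Hann window.
#' @return Numeric vector of window values.
#' @export
tukey_window <- function(n, alpha = 0.1) {
  if (alpha < 0 || alpha > 1) abort("`alpha` must be in [0, 1].")
  if (alpha == 0) return(rep(1, n))
  x <- seq(0, 1, length.out = n)
  w <- rep(1, n)
  lo <- x < alpha / 2
  hi <- x > 1 - alpha / 2
  w[lo] <- 0.5 * (1 + cos(pi * (2 * x[lo] / alpha - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * (2 * x[hi] / alpha - 2 / alpha + 1)))
  w
}

#' Apply a Tukey window across the full record
#'
#' @param wf A [waveform()].
#' @param tukey_alpha Taper fraction, see [tukey_window()]. The default 0.1
#'   tapers only the outer 10% of the record, where the synthetic pulse
#'   carries no energy.
#' @return The windowed [waveform()].
#' @export
apply_window <- function(wf, tukey_alpha = 0.1) {
  wf_update(wf, wf$amplitude_au * tukey_window(nrow(wf), tukey_alpha))
}

#' Fourier-transform a waveform to a one-sided complex spectrum
#'
#' Zero-pads the record to `pad_factor` times the next power of two at or
#' above its length, applies an unnormalized forward DFT, and keeps the
#' one-sided half. The frequency axis is in THz (times in ps). The forward
#' transform carries no `1/N` factor; because sample and reference scans are
#' processed identically, any normalization cancels in the transfer
#' function. Under this convention time-domain energy satisfies
#' `sum(x^2) = (|X_0|^2 + 2 sum |X_k|^2 + |X_nyq|^2) / N_pad`
#' (see [spectrum_energy()]).
#'
#' @param wf A [waveform()] (typically DC-removed and windowed first).
#' @param pad_factor Zero-padding multiple (`>= 1`) of the next power of
#'   two; the default 4 gives a frequency sampling fine enough for stable
#'   Gaussian peak fitting.
#' @return A tibble of class `thz_spectrum` with columns `freq_THz` and
#'   `field` (complex); metadata and processing parameters are carried in
#'   attributes.
#' @export
to_spectrum <- function(wf, pad_factor = 4) {
  if (pad_factor < 1) abort("`pad_factor` must be >= 1.")
  dt <- wf_dt(wf)
  n <- nrow(wf)
  n_pad <- as.integer(round(pad_factor * 2^ceiling(log2(n))))
  x <- c(wf$amplitude_au, rep(0, n_pad - n))
  X <- fft(x)[seq_len(n_pad %/% 2 + 1)]
  out <- tibble(freq_THz = (0:(n_pad %/% 2)) / (n_pad * dt), field = X)
  attr(out, "meta") <- wf_meta(wf)
  attr(out, "processing") <- list(pad_factor = pad_factor, n_pad = n_pad,
                                  n_time = n, dt_ps = dt)
  class(out) <- c("thz_spectrum", class(out))
  out
}

#' Time-domain energy implied by a one-sided spectrum
#'
#' Companion of [to_spectrum()]'s normalization contract: returns
#' `(|X_0|^2 + 2 sum |X_k|^2 + |X_nyq|^2) / N_pad`, which equals
#' `sum(amplitude^2)` of the (padded) time record.
#'
#' @param spec A `thz_spectrum`.
#' @return Scalar energy in squared amplitude units.
#' @export
spectrum_energy <- function(spec) {
  stopifnot(inherits(spec, "thz_spectrum"))
  p <- attr(spec, "processing")
  mags2 <- Mod(spec$field)^2
  w <- c(1, rep(2, length(mags2) - 2), 1)
  sum(w * mags2) / p$n_pad
}

#' @export
print.thz_spectrum <- function(x, ...) {
  p <- attr(x, "processing")
  cat(sprintf("<thz_spectrum> %d one-sided bins, df = %.5g THz (pad %dx, N = %d)\n",
              nrow(x), x$freq_THz[2], p$pad_factor, p$n_time))
  invisible(x)
}

# Full preprocessing recipe used by the optics chain.
preprocess_waveform <- function(wf, head_ps = 5.0, tukey_alpha = 0.1, pad_factor = 4) {
  wf |> remove_dc(head_ps = head_ps) |> apply_window(tukey_alpha = tukey_alpha) |>
    to_spectrum(pad_factor = pad_factor)
}
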