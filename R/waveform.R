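#' Construct a THz time-domain waveform
#'
#' A waveform is the primary raw-data object: the electric-field transient of
#' a single THz pulse, uniformly sampled in time, together with the scan
#' metadata needed downstream (tablet thickness for the optics, storage
#' temperature and elapsed time for the kinetics).
#'
#' @param time_ps Numeric vector of sample times in picoseconds. Must be
#'   strictly increasing and uniformly spaced (relative tolerance `1e-9`),
#'   with at least 64 samples.
#' @param amplitude_au Numeric vector of field amplitudes (arbitrary units),
#'   same length as `time_ps`.
#' @param meta Scan metadata, see [scan_meta()].
#'
#' @return A tibble of class `thz_waveform` with columns `time_ps` and
#'   `amplitude_au`; metadata is attached as the `"meta"` attribute and
#'   accessible via [wf_meta()].
#' @seealso [read_waveform()], [write_waveform()], [scan_meta()]
#' @export
#' @examples
#' t <- seq(0, 20, by = 0.1)
#' wf <- waveform(t, exp(-(t - 10)^2), scan_meta(sample_id = "demo"))
#' wf_dt(wf)
waveform <- function(time_ps, amplitude_au, meta = scan_meta()) {
  if (length(time_ps) != length(amplitude_au)) {
    abort("`time_ps` and `amplitude_au` must have equal length.")
  }
  if (length(time_ps) < 64) {
    abort(sprintf("a waveform needs at least 64 samples, got %d.", length(time_ps)))
  }
  dt <- diff(time_ps)
  if (any(dt <= 0)) {
    abort("`time_ps` must be strictly increasing.")
  }
  if (max(abs(dt - dt[1])) > 1e-9 * max(abs(time_ps))) {
    abort("`time_ps` must be uniformly spaced (non-uniform time axis).")
  }
  out <- tibble(time_ps = as.numeric(time_ps), amplitude_au = as.numeric(amplitude_au))
  attr(out, "meta") <- validate_scan_meta(meta)
  class(out) <- c("thz_waveform", class(out))
  out
}

#' Scan metadata
#'
#' @param sample_id Identifier of the tablet (or reference slot).
#' @param role `"sample"` or `"reference"`.
#' @param thickness_mm Tablet thickness in mm; required for sample scans
#'   before optical constants can be extracted, `NA` for references.
#' @param temperature_C Storage temperature in degrees Celsius.
#' @param time_h Elapsed study time in hours (`>= 0`).
#' @param n_averages Number of raw acquisitions averaged into this waveform.
#' @return A named list of class `scan_meta`.
#' @export
scan_meta <- function(sample_id = NA_character_, role = "sample",
                      thickness_mm = NA_real_, temperature_C = NA_real_,
                      time_h = NA_real_, n_averages = 1L) {
  structure(
    list(sample_id = as.character(sample_id), role = role,
         thickness_mm = as.numeric(thickness_mm),
         temperature_C = as.numeric(temperature_C),
         time_h = as.numeric(time_h), n_averages = as.integer(n_averages)),
    class = "scan_meta"
  )
}

validate_scan_meta <- function(meta) {
  if (!inherits(meta, "scan_meta")) {
    meta <- do.call(scan_meta, as.list(meta))
  }
  if (!meta$role %in% c("sample", "reference")) {
    abort(sprintf("scan role must be 'sample' or 'reference', got '%s'.", meta$role))
  }
  if (!is.na(meta$thickness_mm) && meta$thickness_mm <= 0) {
    abort("`thickness_mm` must be positive.")
  }
  if (!is.na(meta$time_h) && meta$time_h < 0) {
    abort("`time_h` must be non-negative.")
  }
  meta
}

#' @export
print.thz_waveform <- function(x, ...) {
  m <- wf_meta(x)
  cat(sprintf("<thz_waveform> %d samples, dt = %.4g ps, span %.4g ps\n",
              nrow(x), wf_dt(x), diff(range(x$time_ps))))
  cat(sprintf("  id: %s | role: %s | d = %s mm | T = %s degC | t = %s h | averages: %d\n",
              m$sample_id, m$role, format(m$thickness_mm), format(m$temperature_C),
              format(m$time_h), m$n_averages))
  invisible(x)
}

#' Waveform accessors
#'
#' @param wf A [waveform()].
#' @return `wf_meta()` returns the [scan_meta()] list; `wf_dt()` the sampling
#'   interval in ps.
#' @export
wf_meta <- function(wf) attr(wf, "meta")

#' @rdname wf_meta
#' @export
wf_dt <- function(wf) wf$time_ps[2] - wf$time_ps[1]

# Rebuild a waveform with new amplitudes (and optionally new meta),
# preserving the time axis without re-validating it.
wf_update <- function(wf, amplitude_au, meta = wf_meta(wf)) {
  out <- tibble(time_ps = wf$time_ps, amplitude_au = amplitude_au)
  attr(out, "meta") <- meta
  class(out) <- c("thz_waveform", class(out))
  out
}

#' @export
autoplot.thz_waveform <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$time_ps, .data$amplitude_au)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time (ps)", y = "Field amplitude (a.u.)",
                  title = wf_meta(object)$sample_id)
}
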