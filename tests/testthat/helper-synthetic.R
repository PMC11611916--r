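# shared fixtures, built in code

quiet_pulse <- function(...) pulse_params(noise_std_au = 0, ...)

# a smooth test waveform with pre-pulse head
demo_waveform <- function(n = 400, dt = 0.05, id = "demo", thickness = 1.3) {
  t <- seq(0, by = dt, length.out = n)
  waveform(t, exp(-(t - 10)^2 / 0.5) * sin(2 * pi * 0.8 * t),
           scan_meta(sample_id = id, thickness_mm = thickness))
}

# noiseless dispersionless slab pair
slab_pair <- function(n0, alpha0_cm1, d_mm = 1.3, pulse = quiet_pulse()) {
  synthesize_waveform_pair(n0, alpha0_cm1, d_mm, pulse)
}

# absorption spectrum evaluated directly from reference models (no optics)
model_spectrum <- function(A, B, bg = c(1, 0.5, 2), band = c(0.5, 1.8), n = 600,
                           ref_a = nif_reference_alpha(), ref_b = nif_reference_beta()) {
  f <- seq(band[1], band[2], length.out = n)
  tibble::tibble(freq_THz = f,
                 alpha_cm1 = A * peak_sum(ref_a, f) + B * peak_sum(ref_b, f) +
                   bg[1] + bg[2] * f + bg[3] * f^2)
}
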