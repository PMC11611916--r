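spec_pair <- function(pair) {
  list(s = to_spectrum(apply_window(remove_dc(pair$sample))),
       r = to_spectrum(apply_window(remove_dc(pair$reference))))
}

test_that("identical spectra give unit magnitude and zero phase difference", {
  pair <- slab_pair(1.5, 3)
  sp <- spec_pair(pair)
  tf <- transfer_function(sp$r, sp$r)
  expect_equal(tf$magnitude, rep(1, nrow(tf)))
  expect_equal(tf$delta_phi_rad, rep(0, nrow(tf)), tolerance = 1e-9)

  half <- sp$r
  half$field <- 0.5 * half$field
  tf2 <- transfer_function(half, sp$r)
  expect_equal(tf2$magnitude, rep(0.5, nrow(tf2)))
  expect_equal(tf2$delta_phi_rad, rep(0, nrow(tf2)), tolerance = 1e-9)
})

test_that("a pure delay produces the linear phase 2 pi nu dt through the origin", {
  pair <- slab_pair(1.5, 0, d_mm = 1.0)  # delay (n-1)d/c = 1.6678 ps
  sp <- spec_pair(pair)
  tf <- transfer_function(sp$s, sp$r)
  dt_ps <- 0.5 / 0.299792458
  for (f0 in c(0.5, 1.5)) {
    i <- which.min(abs(tf$freq_THz - f0))
    expect_equal(tf$delta_phi_rad[i], 2 * pi * tf$freq_THz[i] * dt_ps,
                 tolerance = 1e-4)
  }
  # no 2*pi jumps between adjacent in-band bins
  expect_lt(max(abs(diff(tf$delta_phi_rad))), pi / 4)
})

test_that("refractive index inverts the phase relation algebraically", {
  pair <- slab_pair(1.5, 3)
  sp <- spec_pair(pair)
  tf <- transfer_function(sp$s, sp$r)
  # zero phase -> n = 1
  tf0 <- tf; tf0$delta_phi_rad <- rep(0, nrow(tf))
  expect_equal(refractive_index(tf0, 1.0), rep(1, nrow(tf)))
  # constructed phase for n0 = 1.5, d = 1 mm
  tfc <- tf
  tfc$delta_phi_rad <- 2 * pi * tf$freq_THz * 0.5 * 1.0 / 0.299792458
  expect_equal(refractive_index(tfc, 1.0), rep(1.5, nrow(tf)), tolerance = 1e-9)
})

test_that("absorption coefficient matches the hand-evaluated Fresnel-corrected form", {
  pair <- slab_pair(1.5, 0, d_mm = 1.0)
  sp <- spec_pair(pair)
  tf <- transfer_function(sp$s, sp$r)
  nb <- nrow(tf)

  tf1 <- tf; tf1$magnitude <- rep(1, nb)
  expect_equal(absorption_coefficient(tf1, rep(1, nb), 1)$alpha_cm1, rep(0, nb))

  # |T| equal to the Fresnel transmission alone -> alpha = 0 for any n
  for (n0 in c(1.2, 1.9)) {
    tf2 <- tf; tf2$magnitude <- rep(4 * n0 / (n0 + 1)^2, nb)
    expect_equal(absorption_coefficient(tf2, rep(n0, nb), 2.0)$alpha_cm1,
                 rep(0, nb), tolerance = 1e-12)
  }

  # hand case: n = 1.5, d = 1 mm, |T| = 0.96 exp(-0.05) -> alpha = 1 cm^-1
  tf3 <- tf; tf3$magnitude <- rep(0.96 * exp(-0.05), nb)
  expect_equal(absorption_coefficient(tf3, rep(1.5, nb), 1.0)$alpha_cm1,
               rep(1, nb), tolerance = 1e-6)

  tf4 <- tf; tf4$magnitude <- rep(0, nb)
  expect_error(absorption_coefficient(tf4, rep(1.5, nb), 1.0), "logarithm")
})

test_that("extraction recovers dispersionless slab constants across the grid", {
  for (n0 in c(1.2, 1.5, 2.0)) {
    for (a0 in c(0, 5, 20)) {
      pair <- slab_pair(n0, a0, d_mm = 1.3)
      oc <- extract_optical_constants(pair$sample, pair$reference)
      expect_lt(max(abs(oc$n - n0) / n0), 0.005)
      expect_lt(max(abs(oc$alpha_cm1 - a0)), 0.5)
    }
  }
})

test_that("thickness consistency: (n, alpha) are invariant to the slab thickness", {
  for (d in c(0.7, 1.4)) {
    pair <- slab_pair(1.7, 8, d_mm = d)
    oc <- extract_optical_constants(pair$sample, pair$reference)
    expect_equal(mean(oc$n), 1.7, tolerance = 1e-3)
    expect_equal(mean(oc$alpha_cm1), 8, tolerance = 0.05)
  }
})

test_that("a single-Gaussian absorption line survives the full chain", {
  afun <- function(f) 6 * exp(-((f - 1.1) / 0.07)^2) + 1
  pair <- synthesize_waveform_pair(1.7, afun, 1.3, quiet_pulse())
  oc <- extract_optical_constants(pair$sample, pair$reference)
  i <- which.max(oc$alpha_cm1)
  df <- oc$freq_THz[2] - oc$freq_THz[1]
  expect_equal(oc$freq_THz[i], 1.1, tolerance = df * 1.001)
})

test_that("extraction guards its inputs", {
  pair <- slab_pair(1.5, 3)
  no_thick <- pair$sample
  m <- wf_meta(no_thick); m$thickness_mm <- NA_real_
  attr(no_thick, "meta") <- m
  expect_error(extract_optical_constants(no_thick, pair$reference), "thickness")

  sp <- spec_pair(pair)
  expect_error(transfer_function(sp$s, sp$r, band_THz = c(0, 2)), "band")
  expect_error(transfer_function(sp$s, sp$r, band_THz = c(0.3, 11)), "band")
})

test_that("identical waveforms as sample and reference give n = 1, alpha = 0", {
  pair <- slab_pair(1.5, 3)
  wf <- pair$reference
  m <- wf_meta(wf); m$thickness_mm <- 1.3; m$role <- "sample"
  attr(wf, "meta") <- m
  oc <- extract_optical_constants(wf, pair$reference)
  expect_equal(oc$n, rep(1, nrow(oc)), tolerance = 1e-9)
  expect_equal(oc$alpha_cm1, rep(0, nrow(oc)), tolerance = 1e-9)
})
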