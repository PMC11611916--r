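test_that("averaging identical copies is the identity and averages pointwise", {
  wf <- demo_waveform()
  expect_equal(average_waveforms(list(wf, wf, wf))$amplitude_au, wf$amplitude_au)
  expect_equal(wf_meta(average_waveforms(list(wf, wf, wf)))$n_averages, 3L)

  w0 <- wf_update(wf, rep(0, nrow(wf)))
  w2 <- wf_update(wf, rep(2, nrow(wf)))
  expect_equal(average_waveforms(list(w0, w2))$amplitude_au, rep(1, nrow(wf)))
})

test_that("averaging 100 noisy copies reduces noise by about 1/sqrt(100)", {
  wf <- demo_waveform()
  set.seed(314)
  noisy <- lapply(1:100, function(i) wf_update(wf, wf$amplitude_au + rnorm(nrow(wf))))
  resid <- average_waveforms(noisy)$amplitude_au - wf$amplitude_au
  expect_equal(sd(resid), 0.1, tolerance = 0.2)
})

test_that("averaging refuses mismatched time axes or samples", {
  wf <- demo_waveform()
  other <- demo_waveform(n = 410)
  expect_error(average_waveforms(list(wf, other)), "time axis")
  expect_error(average_waveforms(list(wf, demo_waveform(id = "other"))),
               "different samples")
})

test_that("DC removal zeroes the first-5-ps mean", {
  wf <- demo_waveform()
  flat <- wf_update(wf, rep(0.3, nrow(wf)))
  expect_equal(remove_dc(flat)$amplitude_au, rep(0, nrow(wf)))

  out <- remove_dc(wf)
  head_idx <- out$time_ps < out$time_ps[1] + 5
  expect_lt(abs(mean(out$amplitude_au[head_idx])), 1e-12)

  # already zero-mean head: unchanged
  expect_equal(remove_dc(out)$amplitude_au, out$amplitude_au)
})

test_that("DC removal of a linear ramp subtracts the directly-summed head mean", {
  dt <- 0.1; a <- 0.7
  t <- seq(0, 20 - dt, by = dt)
  wf <- waveform(t, a * t, scan_meta(sample_id = "ramp", role = "reference"))
  # oracle: plain summation over the half-open [0, 5) ps head
  head_mean <- sum(a * t[t < 5]) / sum(t < 5)
  expect_equal(remove_dc(wf)$amplitude_au, a * t - head_mean, tolerance = 1e-12)
  expect_error(remove_dc(wf, head_ps = 25), "shorter than the record")
})

test_that("Tukey window limits: alpha 0 is rectangular, alpha 1 is Hann", {
  wf <- demo_waveform()
  expect_equal(apply_window(wf, 0)$amplitude_au, wf$amplitude_au)
  n <- nrow(wf)
  for (a in c(0.1, 0.5, 1)) {
    w <- tukey_window(n, a)
    expect_equal(w[c(1, n)], c(0, 0))
  }
  # Hann center value is exactly 1 (odd length puts a sample at the center)
  w <- tukey_window(401, 1)
  expect_equal(w[201], 1)
  expect_equal(w, 0.5 * (1 - cos(2 * pi * (0:400) / 400)), tolerance = 1e-12)
  expect_error(tukey_window(10, 1.5), "\\[0, 1\\]")
})

test_that("an impulse at t = 0 has a flat magnitude spectrum", {
  t <- seq(0, by = 0.05, length.out = 256)
  wf <- waveform(t, c(1, rep(0, 255)), scan_meta(role = "reference"))
  spec <- to_spectrum(wf)
  expect_lt(diff(range(Mod(spec$field))), 1e-9)
  expect_equal(spec$freq_THz[1], 0)
  expect_equal(nrow(spec), attr(spec, "processing")$n_pad / 2 + 1)
})

test_that("a pure cosine peaks at the bin nearest its frequency", {
  dt <- 0.05
  t <- seq(0, by = dt, length.out = 2048)
  wf <- waveform(t, cos(2 * pi * 1.0 * t) * tukey_window(2048, 0.5),
                 scan_meta(role = "reference"))
  spec <- to_spectrum(wf)
  f_peak <- spec$freq_THz[which.max(Mod(spec$field))]
  expect_equal(f_peak, 1.0, tolerance = spec$freq_THz[2] * 1.5)
})

test_that("Parseval holds under the declared normalization", {
  wf <- demo_waveform()
  spec <- to_spectrum(wf, pad_factor = 4)
  expect_equal(spectrum_energy(spec), sum(wf$amplitude_au^2), tolerance = 1e-9)
})

test_that("the transform is linear", {
  w1 <- demo_waveform()
  w2 <- wf_update(w1, sin(w1$time_ps))
  s1 <- to_spectrum(w1); s2 <- to_spectrum(w2)
  s12 <- to_spectrum(wf_update(w1, 2 * w1$amplitude_au - 3 * w2$amplitude_au))
  expect_equal(s12$field, 2 * s1$field - 3 * s2$field, tolerance = 1e-9)
})

test_that("padding refines sampling without moving the spectral envelope", {
  wf <- demo_waveform(n = 512)
  s4 <- to_spectrum(wf, pad_factor = 4)
  s8 <- to_spectrum(wf, pad_factor = 8)
  shared <- seq(1, nrow(s8), by = 2)  # every 2nd bin of the 8x grid is a 4x bin
  expect_equal(s8$freq_THz[shared], s4$freq_THz)
  m4 <- Mod(s4$field); m8 <- Mod(s8$field[shared])
  keep <- m4 > 0.01 * max(m4)
  expect_lt(max(abs(m8[keep] - m4[keep]) / m4[keep]), 0.005)
})
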