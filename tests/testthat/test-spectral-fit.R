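test_that("reference fitting recovers constructed Gaussian parameters to 0.1%", {
  truth <- tibble::tibble(G_cm1 = c(3.5, 2.8, 5.5),
                          nu0_THz = c(0.9, 1.15, 1.5),
                          dnu_THz = c(0.06, 0.05, 0.09))
  bg <- c(0.8, 1.5, 2.5)
  f <- seq(0.5, 1.8, length.out = 800)
  y <- bg[1] + bg[2] * f + bg[3] * f^2
  for (i in 1:3) y <- y + truth$G_cm1[i] * exp(-((f - truth$nu0_THz[i]) / truth$dnu_THz[i])^2)
  model <- fit_reference(tibble::tibble(freq_THz = f, alpha_cm1 = y), "alpha")
  expect_equal(model$peaks$G_cm1, truth$G_cm1, tolerance = 1e-3)
  expect_equal(model$peaks$nu0_THz, truth$nu0_THz, tolerance = 1e-3)
  expect_equal(model$peaks$dnu_THz, truth$dnu_THz, tolerance = 1e-3)
  expect_equal(model$background, bg, tolerance = 1e-3)
  expect_lt(model$residual_rms_cm1, 1e-6)
})

test_that("alpha-form spectra yield the literature peak centers", {
  spec <- model_spectrum(A = 1, B = 0)
  model <- fit_reference(spec, "alpha")
  expect_equal(model$peaks$nu0_THz, c(1.09, 1.20, 1.36), tolerance = 1e-3)
  spec_b <- model_spectrum(A = 0, B = 1)
  model_b <- fit_reference(spec_b, "beta")
  expect_equal(model_b$peaks$nu0_THz, c(0.95, 1.25, 1.50), tolerance = 1e-3)
})

test_that("a peakless monotone spectrum is flagged as possibly amorphous", {
  spec <- model_spectrum(A = 0, B = 0)
  expect_error(fit_reference(spec, "alpha"), "amorphous")
})

test_that("crystallinity fitting recovers construction coefficients exactly", {
  spec <- model_spectrum(A = 0.7, B = 0.3, bg = c(2, -0.5, 1.8))
  fit <- fit_crystallinity(spec, nif_reference_alpha(), nif_reference_beta())
  expect_equal(fit$A, 0.7, tolerance = 1e-6)
  expect_equal(fit$B, 0.3, tolerance = 1e-6)
  expect_equal(fit$background, c(2, -0.5, 1.8), tolerance = 1e-6)
})

test_that("pure backgrounds give A = B = 0 and pure forms give unit coefficients", {
  amorph <- model_spectrum(A = 0, B = 0)
  fit0 <- fit_crystallinity(amorph, nif_reference_alpha(), nif_reference_beta())
  expect_equal(fit0$A, 0, tolerance = 1e-9)
  expect_equal(fit0$B, 0, tolerance = 1e-9)

  pure_a <- model_spectrum(A = 1, B = 0)
  fit1 <- fit_crystallinity(pure_a, nif_reference_alpha(), nif_reference_beta())
  expect_equal(fit1$A, 1, tolerance = 1e-9)
  expect_equal(fit1$B, 0, tolerance = 1e-9)
})

test_that("the fit is linear in the spectrum for positive scalings", {
  ra <- nif_reference_alpha(); rb <- nif_reference_beta()
  base <- model_spectrum(A = 0.4, B = 0.6, bg = c(0, 0, 0))
  for (lambda in c(0.5, 2, 7)) {
    scaled <- base
    scaled$alpha_cm1 <- lambda * scaled$alpha_cm1
    fit <- fit_crystallinity(scaled, ra, rb)
    expect_equal(c(fit$A, fit$B), lambda * c(0.4, 0.6), tolerance = 1e-9)
  }
})

test_that("fitting never mutates the reference peak parameters", {
  ra <- nif_reference_alpha(); rb <- nif_reference_beta()
  before_a <- ra$peaks; before_b <- rb$peaks
  invisible(fit_crystallinity(model_spectrum(0.3, 0.5), ra, rb))
  expect_identical(ra$peaks, before_a)
  expect_identical(rb$peaks, before_b)
})

test_that("the constrained solve agrees with a brute-force grid search", {
  ra <- nif_reference_alpha(); rb <- nif_reference_beta()
  set.seed(99)
  f <- seq(0.5, 1.8, length.out = 400)
  Q <- cbind(1, f, f^2)
  pa <- peak_sum(ra, f); pb <- peak_sum(rb, f)
  for (i in 1:5) {
    ab <- runif(2, 0, 1.8)
    bg <- runif(3, -1, 3)
    y <- ab[1] * pa + ab[2] * pb + Q %*% bg
    spec <- tibble::tibble(freq_THz = f, alpha_cm1 = as.numeric(y))
    fit <- fit_crystallinity(spec, ra, rb)

    # oracle: profile out the background, scan (A, B) on a 0.01 grid
    grid <- seq(0, 2, by = 0.01)
    qr_q <- qr(Q)
    ry <- qr.resid(qr_q, as.numeric(y))
    rpa <- qr.resid(qr_q, pa); rpb <- qr.resid(qr_q, pb)
    rss <- outer(grid, grid, function(A, B) {
      sum(ry^2) - 2 * A * sum(ry * rpa) - 2 * B * sum(ry * rpb) +
        A^2 * sum(rpa^2) + B^2 * sum(rpb^2) + 2 * A * B * sum(rpa * rpb)
    })
    best <- arrayInd(which.min(rss), dim(rss))
    expect_lt(abs(fit$A - grid[best[1]]), 0.0101)  # within grid resolution
    expect_lt(abs(fit$B - grid[best[2]]), 0.0101)
  }
})

test_that("degenerate bands are rejected", {
  spec <- model_spectrum(0.5, 0.5)
  expect_error(
    fit_crystallinity(spec[spec$freq_THz > 1.75, ],
                      nif_reference_alpha(), nif_reference_beta(),
                      band_THz = c(1.75, 1.8)),
    "rank-deficient|cover the fit band")
})

test_that("form classification follows the coefficient rules", {
  ra <- nif_reference_alpha(); rb <- nif_reference_beta()
  expect_equal(classify_form(model_spectrum(0, 0), ra, rb), "amorphous")
  expect_equal(classify_form(model_spectrum(1, 0), ra, rb), "alpha")
  expect_equal(classify_form(model_spectrum(0, 1), ra, rb), "beta")
  expect_equal(classify_form(model_spectrum(0.4, 0.5), ra, rb), "mixed")
  expect_equal(classify_form(model_spectrum(0.9, 0.1), ra, rb), "alpha")
})

test_that("reference models serialize to a readable parameter file and back", {
  model <- fit_reference(model_spectrum(A = 1, B = 0), "alpha")
  path <- withr::local_tempfile(fileext = ".yml")
  write_reference_model(model, path)
  back <- read_reference_model(path)
  expect_equal(back$peaks, model$peaks, tolerance = 1e-9)
  expect_equal(back$background, model$background, tolerance = 1e-9)
  expect_equal(back$form, "alpha")
})
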