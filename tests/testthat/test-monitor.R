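fake_fits <- function(ids, temps, times, A, B) {
  tibble::tibble(sample_id = ids, temperature_C = temps, time_h = times,
                 A = A, B = B, residual_rms_cm1 = 0.1)
}

test_that("series assembly groups by sample and sorts by time", {
  fits <- fake_fits(rep("s1", 3), 24, c(2, 0, 1), 1:3 / 10, 3:1 / 10)
  s <- build_series(fits)
  expect_equal(s$time_h, c(0, 1, 2))

  many <- fake_fits(rep(sprintf("s%d", 1:5), each = 2), 24,
                    rep(c(0, 1), 5), 0.1, 0.2)
  expect_equal(length(unique(build_series(many)$sample_id)), 5)

  dup <- fake_fits(rep("s1", 2), 24, c(1, 1), 0.1, 0.2)
  expect_error(build_series(dup), "duplicate")
})

test_that("decimation keeps every k-th point and reproduces the 14-min interval", {
  s <- build_series(fake_fits(rep("s1", 8), 24, 0:7, 1:8, 8:1))
  d <- decimate_series(s, 4)
  expect_equal(d$time_h, c(0, 4))

  # study cadence 3.5 min, keep every 4th -> 14-min spacing
  cadence_h <- 3.5 / 60
  s2 <- build_series(fake_fits(rep("s1", 41), 24, (0:40) * cadence_h,
                               runif(41), runif(41)))
  d2 <- decimate_series(s2, 4)
  expect_equal(unique(round(diff(d2$time_h) * 60, 9)), 14)

  expect_equal(decimate_series(s2, 1), s2)
})

test_that("replicate aggregation gives pointwise mean and population sd", {
  five <- build_series(fake_fits(rep(sprintf("r%d", 1:5), each = 3), 30,
                                 rep(0:2, 5), 0.4, 0.6))
  agg <- aggregate_replicates(five)
  expect_equal(agg$A_sd, rep(0, 3))
  expect_equal(agg$B_sd, rep(0, 3))
  expect_equal(agg$n_replicates, rep(5L, 3))

  two <- build_series(fake_fits(rep(c("a", "b"), each = 3), 30,
                                rep(0:2, 2), 0.5, rep(c(0, 2), each = 3)))
  agg2 <- aggregate_replicates(two)
  expect_equal(agg2$B_mean, rep(1, 3))
  expect_equal(agg2$B_sd, rep(1, 3))  # population, not sample, sd
})

test_that("aggregation tolerates acquisition stagger up to the stated limit", {
  stag <- build_series(fake_fits(rep(c("a", "b"), each = 3), 30,
                                 c(0, 1, 2, 0.01, 1.01, 2.01), 0.5, 0.5))
  expect_equal(nrow(aggregate_replicates(stag)), 3)
  far <- build_series(fake_fits(rep(c("a", "b"), each = 3), 30,
                                c(0, 1, 2, 0.5, 1.5, 2.5), 0.5, 0.5))
  expect_error(aggregate_replicates(far), "tolerance")
})

test_that("aggregation is invariant to replicate order", {
  set.seed(8)
  fits <- fake_fits(rep(c("a", "b", "c"), each = 4), 30, rep(0:3, 3),
                    runif(12), runif(12))
  agg1 <- aggregate_replicates(build_series(fits))
  agg2 <- aggregate_replicates(build_series(fits[sample(12), ]))
  expect_equal(agg1, agg2)
})

test_that("peak time finds smoothed maxima with earliest-tie breaking", {
  tri <- tibble::tibble(sample_id = "s", time_h = 0:10,
                        B = c(0:5, 4:0))
  expect_equal(peak_time(tri), 5)

  plateau <- tibble::tibble(sample_id = "s", time_h = 0:10,
                            B = c(0, 1, 2, 3, 3, 3, 3, 3, 2, 1, 0))
  expect_equal(peak_time(plateau), 5)  # first smoothed maximum

  zero <- tibble::tibble(sample_id = "s", time_h = 0:10, B = rep(0, 11))
  expect_error(peak_time(zero), "no peak")
  expect_error(peak_time(tri[1:3, ]), "smooth_window")
})

test_that("peak time of noiseless equal-rate kinetics lands at 1/k", {
  k <- 0.05
  times <- seq(0, 48, by = 1)  # one decimated step = 1 h
  fr <- simulate_kinetics(kinetics_params(k1_per_hour = k, k2_per_hour = k), 24, times)
  series <- tibble::tibble(sample_id = "s", time_h = fr$time_h, B = fr$x_beta)
  expect_lte(abs(peak_time(series) - 20), 1)
})
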