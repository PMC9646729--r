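test_that("synthetic traces are deterministic rectangular waves with drift and noise", {
  tr <- synth_band_trace(35, duty = 10 / 35, n_periods = 4)
  expect_equal(length(tr$intensity), 140)
  expect_true(all(tr$intensity %in% c(0, 1)))
  # duty fraction: 10 of every 35 samples high
  expect_equal(sum(tr$intensity), 4 * 10)
  expect_equal(tr$source, "synthetic")

  t1 <- synth_band_trace(33, n_periods = 6, noise_sd = 0.3, seed = 4)
  t2 <- synth_band_trace(33, n_periods = 6, noise_sd = 0.3, seed = 4)
  expect_identical(t1$intensity, t2$intensity)
  t3 <- synth_band_trace(33, n_periods = 6, noise_sd = 0.3, seed = 5)
  expect_false(identical(t1$intensity, t3$intensity))
})

test_that("both estimators recover the true period of noiseless traces", {
  tr <- synth_band_trace(33, duty = 0.3, n_periods = 10)
  est <- fft_periodicity(tr, detrend = "none")
  expect_equal(est$period_nm, 33, tolerance = 33 / 330) # within one sample
  rs <- realspace_periodicity(tr)
  expect_equal(rs$period_nm, 33)
  expect_equal(rs$n_periods, 9)

  # drifted trace with linear detrend gives the same estimate
  trd <- synth_band_trace(33, duty = 0.3, n_periods = 10, drift = 0.01)
  estd <- fft_periodicity(trd, detrend = "linear")
  expect_equal(estd$period_nm, est$period_nm, tolerance = 0.01)

  # flat trace has no spectral peak
  expect_error(fft_periodicity(band_trace(rep(1, 64))), "noise floor")
  # single band cannot define a period
  one <- band_trace(c(rep(0, 10), rep(1, 5), rep(0, 10)))
  expect_error(realspace_periodicity(one), "fewer than 2")
})

test_that("estimators stay within 5% of truth at moderate noise", {
  for (sd in 1:10) {
    tr <- synth_band_trace(33, duty = 0.3, n_periods = 10,
                           noise_sd = 0.2, seed = sd) # SNR = 5
    expect_equal(fft_periodicity(tr, detrend = "none")$period_nm, 33,
                 tolerance = 0.05, info = paste("fft seed", sd))
    expect_equal(realspace_periodicity(tr)$period_nm, 33,
                 tolerance = 0.05, info = paste("realspace seed", sd))
  }
})

test_that("the two-sample equal-variance t-test matches the hand-computed fixture", {
  # hand computation with the pooled-variance formula:
  # g1 = (32.1, 32.5, 33.0), g2 = (33.8, 34.1, 34.6)
  # means 32.5333 / 34.1667, pooled s^2 = 0.18333, t = -4.671967, df = 4
  g1 <- c(32.1, 32.5, 33.0); g2 <- c(33.8, 34.1, 34.6)
  res <- compare_periods(g1, g2)
  expect_equal(res$t, -4.671967, tolerance = 1e-6)
  expect_equal(res$df, 4)
  expect_equal(res$p_value, 0.009504, tolerance = 1e-4)

  same <- compare_periods(c(32, 33, 34), c(32, 33, 34))
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)

  expect_error(compare_periods(32, c(33, 34)), "at least 2")
  expect_error(compare_periods(c(1, 1), c(1, 1)), "zero pooled variance")
})

test_that("band traces round-trip through CSV and reject non-uniform sampling", {
  tr <- synth_band_trace(20, n_periods = 3, noise_sd = 0.1, seed = 1)
  f <- tempfile(fileext = ".csv")
  write_band_trace(tr, f)
  back <- read_band_trace(f)
  expect_equal(back$intensity, tr$intensity)
  expect_equal(back$dx_nm, tr$dx_nm)

  bad <- data.frame(position_nm = c(0, 1, 3), intensity = c(1, 2, 3))
  f2 <- tempfile(fileext = ".csv")
  write.csv(bad, f2, row.names = FALSE)
  expect_error(read_band_trace(f2), "uniformly")
})
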