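test_that("spike vector strength matches closed-form oracles", {
  f <- 500
  # identical phases -> 1
  expect_equal(vs_spikes(c(0, 2, 5, 11) / f, f), 1)
  # antipodal pair -> 0
  expect_equal(vs_spikes(c(0, 1 / (2 * f)), f), 0, tolerance = 1e-12)
  # quarter-period pair -> |(1 + i)/2| = sqrt(2)/2
  expect_equal(vs_spikes(c(0, 1 / (4 * f)), f), sqrt(2) / 2)
  expect_error(vs_spikes(numeric(0), f), class = "cisync_empty_train")
})

test_that("charge-weighted vector strength matches its oracles", {
  expect_equal(vs_pulses(0.00123, 500, charges = 7), 1)  # single pulse
  # constant-rate unmodulated train, incommensurate rate, >= 100 pulses
  t <- (0:199) / 1317
  expect_lt(vs_pulses(t, 500, charges = rep(2, 200)), 0.05)
  # all-zero charge is undefined
  expect_error(vs_pulses(t, 500, charges = rep(0, 200)),
               class = "cisync_empty_train")
})

test_that("dense half-wave-rectified charge weighting converges to pi/4", {
  # continuous-limit oracle: |int_0^pi sin e^{i t}| / int_0^pi sin = pi/4
  f <- 500
  t <- seq(0, 1 / f, length.out = 2001)[-2001]
  q <- pmax(sin(2 * pi * f * t), 0)
  expect_equal(vs_pulses(t, f, charges = q), pi / 4, tolerance = 1e-4)
})

test_that("pulse VS reduces to spike VS for equal charges", {
  set.seed(101)
  t <- sort(runif(50, 0, 0.03))
  expect_equal(vs_pulses(t, 500, charges = rep(3.7, 50)), vs_spikes(t, 500))
})

test_that("VS magnitude is invariant to time shift and charge scale", {
  set.seed(102)
  t <- sort(runif(80, 0, 0.05))
  q <- runif(80, 0.1, 1)
  v0 <- vs_pulses(t, 440, charges = q)
  expect_equal(vs_pulses(t + 0.0123, 440, charges = q), v0)
  expect_equal(vs_pulses(t, 440, charges = 100 * q), v0)
  expect_equal(vs_spikes(t + 1, 440), vs_spikes(t, 440))
})

test_that("electrodogram VS defaults to the maximally excited channel", {
  eg <- schedule_carrier(hdcis_envelopes(ch500), 90000)
  best <- max_charge_channel(eg)
  expect_identical(best, which.min(abs(fb22$center_freqs - 500)))
  expect_equal(vs_pulses(eg, 500), vs_pulses(eg, 500, channel = best))
})

test_that("field-trace VS treats positive-phase samples as weighted events", {
  # single electrode, strong 500 Hz HDCIS channel: positive-phase weighting
  # of the field equals the charge-weighted pulse metric in the dense limit
  eg <- schedule_carrier(hdcis_envelopes(ch500), 90000)
  eg1 <- subset_electrodogram(eg, max_charge_channel(eg))
  ft <- spread(eg1, array_geometry(n_electrodes = 1), 0)
  tab <- vs_field(ft, 500)
  expect_s3_class(tab, "synchrony_table")
  expect_equal(tab$vs, vs_pulses(eg, 500), tolerance = 0.03)
})

test_that("ISI histograms separate first- from all-order statistics", {
  train <- (0:50) * 0.00205  # perfectly periodic at 2.05 ms
  h1 <- isi(train, "first")
  expect_identical(h1$n_intervals, length(train) - 1L)
  # all first-order mass sits in the 2.05 ms bin
  expect_identical(sum(h1$counts[abs(h1$mids_ms - 2.05) <= 0.11]),
                   h1$n_intervals)
  ha <- isi(train, "all", window_ms = 10)
  # all-order modes at every multiple of the period, nothing in between
  near_mode <- vapply(ha$mids_ms[ha$counts > 0], function(m)
    min(abs(m - 2.05 * (1:4))) <= 0.11, logical(1))
  expect_true(all(near_mode))
  for (k in 1:4)
    expect_gt(sum(ha$counts[abs(ha$mids_ms - 2.05 * k) <= 0.11]), 0)
  expect_identical(sum(ha$counts), ha$n_intervals)
  # fewer than two spikes -> empty histogram
  expect_identical(isi(c(0.01), "first")$n_intervals, 0L)
})

test_that("excitation profiles normalize charge and count spikes", {
  eg1 <- manual_electrodogram(c(10, 400), c(5, 5), c(1, 1))
  prof <- excitation_profile(eg1)
  expect_equal(sum(prof), 1)
  expect_equal(unname(prof[5]), 1)      # indicator for single-electrode input
  eg <- schedule_carrier(hdcis_envelopes(ch500), 90000)
  prof22 <- excitation_profile(eg)
  expect_equal(sum(prof22), 1)
  expect_identical(unname(which.max(prof22)),
                   which.min(abs(fb22$center_freqs - 500)))
})

test_that("metric tables write as tidy CSV", {
  tab <- synchrony_table(unit = 1:3, freq = 500, vs = c(0.1, 0.5, NA))
  expect_equal(vs_summary(tab), 0.5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_metric_csv(tab, path)
  expect_equal(read.csv(path)$vs, c(0.1, 0.5, NA))
  h <- isi(seq(0, 0.1, by = 0.002), "first")
  write_metric_csv(h, path)
  expect_identical(sum(read.csv(path)$count), h$n_intervals)
})
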