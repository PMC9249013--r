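test_that("CIS envelopes are smooth, non-negative and discard fine structure", {
  env <- cis_envelopes(ch500)
  expect_true(all(env >= 0))
  # a steady in-band sinusoid has a near-constant Hilbert magnitude after
  # 5 cycles (edge effects and any transient excluded)
  pure <- fake_channel_signals(matrix(sin(2 * pi * 500 * (0:2999) / FS),
                                      ncol = 1))
  seg <- cis_envelopes(pure)[1001:2500, 1]
  expect_lt((max(seg) - min(seg)) / mean(seg), 0.05)
  # zero signal -> zero envelope
  env0 <- cis_envelopes(fake_channel_signals(matrix(0, 500, 3)))
  expect_true(all(env0 == 0))
})

test_that("HDCIS envelopes are the half-wave rectified channel signals", {
  env <- hdcis_envelopes(ch500)
  y <- unclass(ch500)
  expect_true(all(env >= 0))
  expect_equal(unclass(env), pmax(y, 0))
  # envelope periodicity equals the tone period on the best channel
  best <- which.min(abs(fb22$center_freqs - 500))
  seg <- env[1001:3000, best]
  acf_lag <- function(k) cor(seg[-(1:k)], seg[1:(length(seg) - k)])
  expect_gt(acf_lag(200), 0.99)  # 200 samples = 2 ms = one 500 Hz period
})

test_that("carrier scheduling implements interleaved frame arithmetic", {
  env <- hdcis_envelopes(ch500)
  eg <- schedule_carrier(env, 90000)
  p <- eg$pulses
  expect_identical(nrow(p), 2700L)           # 30 ms at 90 kpps
  expect_equal(nrow(p) / 22 / 0.030, 90000 / 22, tolerance = 0.01)
  # per-channel inter-pulse interval = 22/90000 s on the 1 us grid
  t8 <- p$time_us[p$electrode == 8]
  expect_true(all(abs(diff(t8) - 22 / 90000 * 1e6) <= 1))
  expect_equal(mean(diff(t8)), 22 / 90000 * 1e6, tolerance = 1e-4)
  # onsets never collide across electrodes
  expect_false(any(duplicated(p$time_us)))
  # zero envelopes -> all amplitudes zero, same time grid
  eg0 <- schedule_carrier(hdcis_envelopes(
    fake_channel_signals(matrix(0, 3000, 22))), 90000)
  expect_true(all(eg0$pulses$amplitude == 0))
  expect_identical(eg0$pulses$time_us, p$time_us)
})

test_that("CIS pulse timing is independent of the input frequency", {
  t_of <- function(f) {
    w <- make_pure_tone(f, 0.03, FS)
    schedule_carrier(cis_envelopes(apply_filterbank(w, fb22)),
                     90000)$pulses$time_us
  }
  expect_identical(t_of(500), t_of(1234))
})

test_that("a frame too short for one biphasic pulse is rejected", {
  env <- hdcis_envelopes(fake_channel_signals(matrix(1, 1000, 2)))
  # 2 channels at 90 kpps: frame = 22.2 us < 58 us footprint
  expect_error(schedule_carrier(env, 90000), class = "cisync_frame_error")
  expect_error(hd_ace_select(hdcis_envelopes(
    fake_channel_signals(matrix(1, 1000, 22))), 90000, 1),
    class = "cisync_frame_error")
})

test_that("PDT fires one pulse per cycle of the driving fine structure", {
  eg <- pdt_encode(ch500)
  best <- which.min(abs(fb22$center_freqs - 500))
  n_best <- sum(eg$pulses$electrode == best)
  expect_lte(abs(n_best - 0.030 * 500), 2)  # ~15 peaks in 30 ms
  # monotonic signals have no interior maxima
  mono <- fake_channel_signals(matrix(seq_len(1000), ncol = 1))
  expect_identical(nrow(pdt_encode(mono)$pulses), 0L)
})

test_that("PDT collisions are resolved without simultaneous onsets", {
  y <- sin(2 * pi * 500 * (0:2999) / FS)
  two <- fake_channel_signals(cbind(y, y))  # identical peaks in both channels
  eg <- pdt_encode(two)
  expect_false(any(duplicated(eg$pulses$time_us)))
  # both channels kept all their peaks
  expect_equal(sum(eg$pulses$electrode == 1), sum(eg$pulses$electrode == 2))
  # plateau: first sample of a flat top is taken, once
  plat <- fake_channel_signals(matrix(c(0, 1, 2, 2, 2, 1, 0, 0), ncol = 1))
  pp <- pdt_encode(plat)
  expect_identical(nrow(pp$pulses), 1L)
  expect_equal(pp$pulses$time_us, round(2 / FS * 1e6))  # sample index 3, 0-based 2
})

test_that("HD-ACE selects the n largest envelopes per frame", {
  env <- hdcis_envelopes(ch500)
  eg <- hd_ace_select(env, 14400, 8)
  # per-electrode rate never exceeds total_rate / n_maxima
  dur_s <- eg$duration_us / 1e6
  per_el <- table(eg$pulses$electrode) / dur_s
  expect_lte(max(per_el), 14400 / 8 * 1.01)
  # constant envelopes -> a persistently selected electrode fires every frame
  const <- hdcis_envelopes(fake_channel_signals(
    matrix(rep(c(2, 2, 2, 2, 1, 1, 1, 1, 1, 1), each = 5000), ncol = 10)))
  eg2 <- hd_ace_select(const, 3500, 4)
  # per-electrode rate = 1 / frame duration = total_rate / n_maxima
  t1 <- eg2$pulses$time_us[eg2$pulses$electrode == 1]
  expect_equal(1e6 / stats::median(diff(t1)), 3500 / 4, tolerance = 0.002)
  expect_identical(sort(unique(eg2$pulses$electrode)), 1:4)  # tie -> low index
})

test_that("selecting all channels reproduces the plain carrier", {
  env <- hdcis_envelopes(ch500)
  eg_all <- hd_ace_select(env, 90000, 22)
  eg_car <- schedule_carrier(env, 90000)
  n <- min(nrow(eg_all$pulses), nrow(eg_car$pulses))
  expect_equal(eg_all$pulses[1:n, c("time_us", "electrode", "amplitude")],
               eg_car$pulses[1:n, c("time_us", "electrode", "amplitude")])
})

test_that("total charge equals the sum of amplitude x phase duration", {
  eg <- schedule_carrier(hdcis_envelopes(ch500), 90000)
  expect_equal(total_charge(eg), sum(eg$pulses$amplitude * 25))
  expect_equal(eg$pulses$charge, eg$pulses$amplitude * eg$params$phase_us)
})

test_that("pulse tables survive the CSV + sidecar round trip", {
  eg <- pdt_encode(ch500)
  path <- withr::local_tempfile(fileext = ".csv")
  write_pulse_table(eg, path)
  eg2 <- read_pulse_table(path)
  expect_equal(eg2$pulses$time_us, eg$pulses$time_us)
  expect_equal(eg2$pulses$amplitude, eg$pulses$amplitude)
  expect_equal(eg2$pulses$charge, eg$pulses$charge)
  expect_identical(eg2$strategy, "pdt")
  expect_equal(eg2$n_channels, 22)
  unlink(paste0(path, ".json"))
})
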