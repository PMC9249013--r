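test_that("an isolated pulse at threshold fires with probability one half", {
  p <- fiber_params(threshold_ma = 0.3)
  phat <- pulse_response_probability(p, i_eff = 0.3, n = 1e5, seed = 11)
  expect_lt(abs(phat - 0.5), 0.01)
})

test_that("a pulse at theta * (1 + 2 RS) fires with probability pnorm(2)", {
  p <- fiber_params(threshold_ma = 0.3, relative_spread = 0.06)
  i2 <- 0.3 * (1 + 2 * 0.06)
  phat <- pulse_response_probability(p, i_eff = i2, n = 1e5, seed = 12)
  expect_lt(abs(phat - pnorm(2)), 0.01)
})

test_that("firing probability is monotone in pulse amplitude", {
  p <- fiber_params(threshold_ma = 0.3)
  amps <- 0.3 * c(0.8, 0.95, 1, 1.05, 1.2)
  phats <- vapply(amps, function(a)
    pulse_response_probability(p, a, n = 2e4, seed = 13), numeric(1))
  expect_true(all(diff(phats) > 0))
})

test_that("simulate_fiber integrates an isolated pulse to its amplitude", {
  # trace with a single 0.3 mA biphasic pulse; by the chronaxie-derived
  # leaky-integrator normalization, I_eff at the end of the cathodic phase
  # equals the pulse amplitude, so firing probability is 1/2 at threshold
  eg <- manual_electrodogram(100, 1, 0.3, n_channels = 1, duration_us = 1000)
  ft <- spread(eg, array_geometry(n_electrodes = 1), 0, normalize = FALSE)
  p <- fiber_params(threshold_ma = 0.3, jitter_sd_us = 0)
  hits <- vapply(1:400, function(s)
    length(simulate_fiber(field_trace_at(ft, 1), p, seed = s)), numeric(1))
  expect_lt(abs(mean(hits) - 0.5), 0.08)  # 400 bernoulli trials
})

test_that("no interspike interval ever falls below the absolute refractory", {
  eg <- schedule_carrier(hdcis_envelopes(ch500), 90000)
  r <- simulate_population(eg, array_geometry(), seq(7, 13, by = 0.5),
                           thresholds_ma = c(0.1, 0.2, 0.4),
                           master_seed = 7, scale = 2)
  p <- fiber_params()
  for (s in r$spikes)
    if (length(s) > 1)
      expect_gt(min(diff(sort(s))) * 1e6, p$abs_refractory_us)
})

test_that("with no jitter a strong slow pulse train entrains 1:1", {
  # periodic suprathreshold pulses slower than refractory limits ->
  # deterministic periodic output at the pulse times
  times <- seq(100, 19000, by = 2000)
  eg <- manual_electrodogram(times, 1, 1, n_channels = 1,
                             duration_us = 20000)
  ft <- spread(eg, array_geometry(n_electrodes = 1), 0, normalize = FALSE)
  p <- fiber_params(threshold_ma = 0.3, jitter_sd_us = 0)
  s <- simulate_fiber(field_trace_at(ft, 1), p, seed = 5)
  expect_length(s, length(times))
  expect_equal(unique(round(diff(s * 1e6))), 2000)
})

test_that("closely spaced subthreshold pulses summate via leaky integration", {
  p <- fiber_params(threshold_ma = 0.3, jitter_sd_us = 0)
  geom1 <- array_geometry(n_electrodes = 1)
  fire_frac <- function(gap_us) {
    eg <- manual_electrodogram(c(100, 100 + gap_us), 1, 0.24,
                               n_channels = 1, duration_us = 5000)
    ft <- spread(eg, geom1, 0, normalize = FALSE)
    mean(vapply(1:300, function(s)
      length(simulate_fiber(field_trace_at(ft, 1), p, seed = s)) > 0,
      logical(1)))
  }
  # 0.24 mA = 0.8 theta alone is >3 RS below threshold (p ~ 4e-4); a second
  # pulse whose cathodic phase overlaps the first one's (12 us onset gap, as
  # on the 90 kpps carrier) integrates to nearly twice the amplitude
  expect_gt(fire_frac(12), fire_frac(2000) + 0.2)
})

test_that("population grids and seeding behave as documented", {
  expect_length(seq(0.1, 0.8, by = 0.05), 15)  # default threshold grid
  expect_length(seq(0, 30, by = 0.1), 301)     # rate-study position grid
  eg <- schedule_carrier(hdcis_envelopes(ch500), 90000)
  r1 <- simulate_population(eg, array_geometry(), c(9, 10),
                            thresholds_ma = c(0.2, 0.3), master_seed = 42)
  r2 <- simulate_population(eg, array_geometry(), c(9, 10),
                            thresholds_ma = c(0.2, 0.3), master_seed = 42)
  expect_identical(r1$spikes, r2$spikes)  # reproducible
  # enlarging the threshold grid must not reshuffle existing fibers
  r3 <- simulate_population(eg, array_geometry(), c(9, 10),
                            thresholds_ma = c(0.2, 0.3, 0.5),
                            master_seed = 42)
  expect_identical(r3$spikes[[1]], r1$spikes[[1]])
  expect_identical(r3$spikes[[4]], r1$spikes[[3]])
})

test_that("level calibration reaches the target rate and is monotone", {
  eg <- schedule_carrier(hdcis_envelopes(ch500), 90000)
  geom <- array_geometry()
  pos <- seq(4, 16, by = 0.25)
  s <- calibrate_level(eg, geom, pos, thresholds_ma = seq(0.1, 0.8, 0.1),
                       target_rate = 100, master_seed = 3)
  expect_gte(attr(s, "rate"), 90)
  expect_lte(attr(s, "rate"), 110)
  # doubling the scale never decreases the mean rate
  r_lo <- mean_rate(simulate_population(eg, geom, pos,
                                        seq(0.1, 0.8, 0.1), master_seed = 3,
                                        scale = as.numeric(s)))
  r_hi <- mean_rate(simulate_population(eg, geom, pos,
                                        seq(0.1, 0.8, 0.1), master_seed = 3,
                                        scale = 2 * as.numeric(s)))
  expect_gte(r_hi, r_lo)
})

test_that("HDCIS drives higher population synchrony than CIS at matched rate", {
  geom <- array_geometry()
  pos <- seq(4, 16, by = 0.25)
  thr <- seq(0.1, 0.8, 0.1)
  vs_of <- function(strategy) {
    eg <- encode_tone(tone500, strategy, experiment_config(), fb22)
    s <- calibrate_level(eg, geom, pos, thr, target_rate = 100,
                         master_seed = 2)
    r <- simulate_population(eg, geom, pos, thr, master_seed = 2,
                             scale = as.numeric(s))
    vs_summary(vs_raster(r, 500))
  }
  expect_gt(vs_of("hdcis"), vs_of("cis"))
})

test_that("spike rasters write as long-format CSV", {
  eg <- schedule_carrier(hdcis_envelopes(ch500), 90000)
  r <- simulate_population(eg, array_geometry(), c(9.5, 10),
                           thresholds_ma = c(0.15), master_seed = 1,
                           scale = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_spike_raster(r, path)
  df <- read.csv(path)
  expect_identical(names(df),
                   c("fiber_id", "position_mm", "threshold_ma",
                     "spike_time_s"))
  expect_identical(nrow(df), sum(lengths(r$spikes)))
})
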