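#' Point-process fiber parameters
#'
#' Single-fiber statistics of the stochastic threshold model of electrically
#' stimulated auditory-nerve fibers. Defaults are standard cat-fiber values
#' from the electrical-stimulation literature: relative spread 0.06, spike
#' latency jitter 85 us, chronaxie 276 us, absolute refractory period 332 us
#' and relative refractory time constant 411 us.
#'
#' The chronaxie sets the membrane integration time constant: for a leaky
#' integrator the strength-duration relation gives `tau = chronaxie / ln 2`.
#'
#' @param threshold_ma stochastic firing threshold theta, mA.
#' @param relative_spread RS, ratio of threshold SD to mean; sets the slope
#'   of the firing-probability curve.
#' @param jitter_sd_us SD of Gaussian spike-time jitter, us.
#' @param chronaxie_us chronaxie, us.
#' @param abs_refractory_us absolute refractory period, us.
#' @param rel_refractory_tau_us relative refractory decay constant, us.
#' @return An object of class `"fiber_params"`.
#' @export
fiber_params <- function(threshold_ma = 0.3, relative_spread = 0.06,
                         jitter_sd_us = 85, chronaxie_us = 276,
                         abs_refractory_us = 332,
                         rel_refractory_tau_us = 411) {
  stopifnot(threshold_ma > 0, relative_spread > 0, jitter_sd_us >= 0,
            chronaxie_us > 0, abs_refractory_us > 0,
            rel_refractory_tau_us > 0)
  structure(list(threshold_ma = threshold_ma,
                 relative_spread = relative_spread,
                 jitter_sd_us = jitter_sd_us, chronaxie_us = chronaxie_us,
                 abs_refractory_us = abs_refractory_us,
                 rel_refractory_tau_us = rel_refractory_tau_us),
            class = "fiber_params")
}

membrane_tau_us <- function(p) p$chronaxie_us / log(2)

## one-pole leaky integration on the 1 us grid, normalized so an isolated
## rectangular pulse of amplitude A and standard phase duration evaluates to
## exactly A at the end of its cathodic phase
leaky_integrate <- function(x, tau_us) {
  a <- exp(-1 / tau_us)
  as.numeric(signal::filter(1 - a, c(1, -a), x))
}

integration_gain <- function(p, params) {
  1 / (1 - exp(-params$phase_us / membrane_tau_us(p)))
}

## evaluation times: end of each pulse's cathodic phase
candidate_times_us <- function(pulse_times_us, params) {
  pulse_times_us + params$phase_us
}

#' Simulate one auditory-nerve fiber
#'
#' Cascade: (1) leaky temporal integration of the effective current with the
#' membrane time constant derived from the chronaxie, which makes closely
#' spaced pulses summate; (2) at each candidate event (a pulse arrival,
#' evaluated at the end of its cathodic phase) the spike probability is
#' `pnorm((I_eff - theta_eff) / (RS * theta))`; (3) `theta_eff` is infinite
#' within the absolute refractory period of the previous spike and decays
#' back as `theta * (1 + exp(-dt / tau_rel))` afterwards; (4) emitted spike
#' times carry Gaussian jitter. Spontaneous activity between pulses is not
#' modeled (electrically driven fibers only).
#'
#' @param trace a [field_trace()] (or one position of a [spread()] result via
#'   [field_trace_at()]).
#' @param p a [fiber_params()].
#' @param seed integer seed for this fiber's RNG stream.
#' @return Numeric vector of spike times in seconds.
#' @export
simulate_fiber <- function(trace, p = fiber_params(), seed = 1L) {
  stopifnot(inherits(trace, "field_trace"), inherits(p, "fiber_params"))
  tau <- membrane_tau_us(p)
  v <- leaky_integrate(trace$current, tau)
  ct <- candidate_times_us(trace$pulse_times_us, trace$params)
  ct <- ct[ct + 1 <= length(v)]
  ieff <- integration_gain(p, trace$params) * v[ct + 1]
  set.seed(seed)
  sim_fiber_cpp(ct, ieff, p$threshold_ma, p$relative_spread, p$jitter_sd_us,
                p$abs_refractory_us, p$rel_refractory_tau_us) / 1e6
}

#' Single-pulse firing probability, by simulation
#'
#' Monte-Carlo estimate of the probability that one isolated biphasic pulse
#' producing an effective current `i_eff` fires a fiber: candidates are
#' spaced far enough apart that refractory interactions are negligible, so
#' the estimate converges to `pnorm((i_eff - theta) / (RS * theta))`.
#'
#' @param p a [fiber_params()].
#' @param i_eff effective current at the candidate event, mA.
#' @param n number of trials.
#' @param seed RNG seed.
#' @param spacing_us spacing between trial pulses, us.
#' @return Estimated firing probability.
#' @export
pulse_response_probability <- function(p, i_eff, n = 1e5, seed = 1L,
                                       spacing_us = 1e4) {
  stopifnot(inherits(p, "fiber_params"))
  t_us <- seq_len(n) * spacing_us
  set.seed(seed)
  spikes <- sim_fiber_cpp(t_us, rep(i_eff, n), p$threshold_ma,
                          p$relative_spread, p$jitter_sd_us,
                          p$abs_refractory_us, p$rel_refractory_tau_us)
  length(spikes) / n
}

## deterministic per-fiber RNG stream id derived from (master, iter, pos, thr)
## so growing the population leaves existing fibers' streams unchanged
fiber_seed <- function(master_seed, pos_i, thr_i, iter = 1L) {
  s <- (abs(master_seed) %% 1e6) * 1000003 + iter * 100003 +
    pos_i * 211 + thr_i
  as.integer(s %% 2147483647)
}

## shared precomputation: leaky-integrated per-electrode waveforms sampled at
## candidate times, mixed by spread weights -> candidates x positions drive
population_drive <- function(eg, geom, positions_mm, p = fiber_params(),
                             norm_level = 1) {
  stopifnot(inherits(eg, "electrodogram"))
  W <- spread_weights(geom, positions_mm)
  E <- render_electrodogram(eg)
  scale <- 1
  if (nrow(eg$pulses) > 0) {
    pk <- field_peak(E, W)
    if (pk > 0) scale <- norm_level / pk
  }
  tau <- membrane_tau_us(p)
  V <- apply(E, 2, leaky_integrate, tau_us = tau)
  pt <- sort(unique(eg$pulses$time_us))
  ct <- candidate_times_us(pt, eg$params)
  ct <- ct[ct + 1 <= nrow(V)]
  drive <- integration_gain(p, eg$params) *
    (V[ct + 1, , drop = FALSE] %*% t(W)) * scale
  list(ct_us = ct, drive = drive, positions_mm = positions_mm,
       spread_scale = scale, duration_s = eg$duration_us / 1e6)
}

sim_population_drive <- function(pd, thresholds_ma, p, master_seed = 1L,
                                 scale = 1, iter = 1L) {
  npos <- length(pd$positions_mm)
  nthr <- length(thresholds_ma)
  spikes <- vector("list", npos * nthr)
  index <- data.frame(
    fiber = seq_len(npos * nthr),
    position_mm = rep(pd$positions_mm, each = nthr),
    threshold_ma = rep(thresholds_ma, times = npos))
  f <- 0L
  for (i in seq_len(npos)) {
    ieff <- pd$drive[, i] * scale
    for (j in seq_len(nthr)) {
      f <- f + 1L
      set.seed(fiber_seed(master_seed, i, j, iter))
      spikes[[f]] <- sim_fiber_cpp(
        pd$ct_us, ieff, thresholds_ma[j], p$relative_spread, p$jitter_sd_us,
        p$abs_refractory_us, p$rel_refractory_tau_us) / 1e6
    }
  }
  new_spike_raster(spikes, index, pd$duration_s)
}

new_spike_raster <- function(spikes, index, duration_s) {
  structure(list(spikes = spikes, index = index, duration_s = duration_s),
            class = "spike_raster")
}

#' @export
print.spike_raster <- function(x, ...) {
  n <- vapply(x$spikes, length, integer(1))
  cat(sprintf(
    "<spike_raster> %d fibers, %d spikes over %.1f ms (mean rate %.1f sp/s)\n",
    length(x$spikes), sum(n), x$duration_s * 1000,
    sum(n) / length(x$spikes) / x$duration_s))
  invisible(x)
}

#' Mean population firing rate
#'
#' @param r a `"spike_raster"`.
#' @return Spikes per second per fiber, averaged over the population.
#' @export
mean_rate <- function(r) {
  stopifnot(inherits(r, "spike_raster"))
  mean(vapply(r$spikes, length, integer(1))) / r$duration_s
}

#' Simulate a fiber population over positions and thresholds
#'
#' One fiber per (neural position, threshold) pair, each with an independent
#' RNG stream derived from `master_seed` (streams are keyed by position and
#' threshold index, so enlarging the population does not reshuffle existing
#' fibers). The default threshold grid is 0.1 to 0.8 mA in 0.05 mA steps
#' (15 values). The post-spread field is normalized to a 1 mA peak
#' (`norm_level`) and then multiplied by `scale` (see [calibrate_level()]).
#'
#' @param eg an `"electrodogram"`.
#' @param geom an [array_geometry()].
#' @param positions_mm neural positions, mm.
#' @param thresholds_ma threshold grid, mA.
#' @param p a [fiber_params()] (its `threshold_ma` is ignored in favor of the
#'   grid).
#' @param master_seed integer master seed.
#' @param scale global amplitude scale applied after normalization.
#' @param norm_level post-spread peak level, mA.
#' @return A `"spike_raster"`: per-fiber spike time vectors (seconds) plus an
#'   index data frame with `fiber`, `position_mm`, `threshold_ma`.
#' @export
simulate_population <- function(eg, geom = array_geometry(), positions_mm,
                                thresholds_ma = seq(0.1, 0.8, by = 0.05),
                                p = fiber_params(), master_seed = 1L,
                                scale = 1, norm_level = 1) {
  stopifnot(length(thresholds_ma) > 0)
  pd <- population_drive(eg, geom, positions_mm, p, norm_level)
  sim_population_drive(pd, thresholds_ma, p, master_seed, scale)
}

#' Calibrate stimulus level to a target population firing rate
#'
#' Bisection on a global amplitude scale (applied after the 1 mA post-spread
#' normalization) until the mean population firing rate is within `tol` of
#' `target_rate`. Deterministic given `master_seed`: every evaluation reuses
#' the same per-fiber RNG streams. Firing probability is monotone in the
#' stimulus scale, so bisection is well posed (up to simulation noise).
#'
#' @inheritParams simulate_population
#' @param target_rate target mean rate, spikes/s.
#' @param tol relative tolerance (0.1 = within 10%).
#' @param max_scale upper bound on the scale search.
#' @return The calibrated scale factor, with the achieved rate in attribute
#'   `"rate"`.
#' @export
calibrate_level <- function(eg, geom = array_geometry(), positions_mm,
                            thresholds_ma = seq(0.1, 0.8, by = 0.05),
                            p = fiber_params(), target_rate = 100,
                            master_seed = 1L, tol = 0.1, max_scale = 1e4,
                            norm_level = 1) {
  stopifnot(target_rate > 0)
  pd <- population_drive(eg, geom, positions_mm, p, norm_level)
  calibrate_drive(pd, thresholds_ma, p, target_rate, master_seed, tol,
                  max_scale)
}

#' Write a spike raster as long-format CSV
#'
#' Columns `fiber_id, position_mm, threshold_ma, spike_time_s` (for acoustic
#' rasters the third column holds the characteristic frequency instead).
#'
#' @param r a `"spike_raster"`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_spike_raster <- function(r, path) {
  stopifnot(inherits(r, "spike_raster"))
  n <- vapply(r$spikes, length, integer(1))
  df <- cbind(
    as.data.frame(lapply(r$index, rep, times = n)),
    data.frame(spike_time_s = if (sum(n)) unlist(r$spikes) else numeric(0)))
  names(df)[1] <- "fiber_id"
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
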