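#' Semitone-spaced frequency grid
#'
#' Frequencies `f_lo * 2^(k/12)` for all integer `k >= 0` with the result not
#' exceeding `f_hi` (a relative tolerance absorbs floating-point error at the
#' endpoint). 125-8000 Hz spans exactly six octaves (73 frequencies);
#' 55-1760 Hz spans five (61 frequencies, musical A1 to A6).
#'
#' @param f_lo,f_hi grid endpoints, Hz.
#' @return Numeric vector of frequencies.
#' @export
semitone_grid <- function(f_lo, f_hi) {
  k_max <- floor(12 * log2(f_hi / f_lo) + 1e-9)
  f_lo * 2^((0:k_max) / 12)
}

#' Experiment configuration
#'
#' Bundles everything that, together with the code version, determines an
#' experiment run. Defaults reproduce the headline study conditions: 30 ms
#' tones at 100 kHz, a 22-channel 125-8000 Hz filterbank, a 90,000 pps
#' carrier, 25/8 us biphasic pulses, inverse-law spread onto 201 neural
#' positions spanning 0-20 mm, thresholds 0.1-0.8 mA in 0.05 mA steps, and
#' stimulation levels calibrated so the population fires at ~100 spikes/s.
#'
#' @param duration_s stimulus duration, s.
#' @param sample_rate audio sample rate, Hz.
#' @param n_channels filterbank channels.
#' @param f_lo,f_hi filterbank range, Hz.
#' @param total_rate carrier rate, pulses/s.
#' @param strategies subset of `c("cis", "hdcis", "pdt")`.
#' @param pulse a [pulse_params()].
#' @param geometry an [array_geometry()].
#' @param positions_mm neural positions, mm.
#' @param thresholds_ma threshold grid, mA.
#' @param target_rate calibration target, spikes/s.
#' @param n_maxima channels per frame for HD-ACE (rate study).
#' @param master_seed integer master seed.
#' @return An object of class `"experiment_config"` (a named list).
#' @export
experiment_config <- function(duration_s = 0.030, sample_rate = 1e5,
                              n_channels = 22, f_lo = 125, f_hi = 8000,
                              total_rate = 90000,
                              strategies = c("cis", "hdcis", "pdt"),
                              pulse = pulse_params(),
                              geometry = array_geometry(),
                              positions_mm = seq(0, 20, by = 0.1),
                              thresholds_ma = seq(0.1, 0.8, by = 0.05),
                              target_rate = 100, n_maxima = 8,
                              master_seed = 1L) {
  strategies <- match.arg(strategies, c("cis", "hdcis", "pdt"),
                          several.ok = TRUE)
  structure(list(duration_s = duration_s, sample_rate = sample_rate,
                 n_channels = n_channels, f_lo = f_lo, f_hi = f_hi,
                 total_rate = total_rate, strategies = strategies,
                 pulse = pulse, geometry = geometry,
                 positions_mm = positions_mm, thresholds_ma = thresholds_ma,
                 target_rate = target_rate, n_maxima = n_maxima,
                 master_seed = as.integer(master_seed)),
            class = "experiment_config")
}

cfg_filterbank <- function(cfg) {
  design_filterbank(cfg$n_channels, cfg$f_lo, cfg$f_hi, cfg$sample_rate)
}

#' Encode a waveform with a named strategy
#'
#' Dispatch helper used by the experiment drivers: `"cis"` (Hilbert
#' envelopes on the interleaved carrier), `"hdcis"` (half-wave rectified
#' envelopes on the carrier), `"pdt"` (peak-derived timing) or `"hd_ace"`
#' (n-of-m selection over half-wave rectified envelopes).
#'
#' @param w a [waveform()].
#' @param strategy strategy name.
#' @param cfg an [experiment_config()].
#' @param fb optional pre-designed filterbank.
#' @return An `"electrodogram"`.
#' @export
encode_tone <- function(w, strategy, cfg = experiment_config(), fb = NULL) {
  if (is.null(fb)) fb <- cfg_filterbank(cfg)
  ch <- apply_filterbank(w, fb)
  strategy <- match.arg(strategy, c("cis", "hdcis", "pdt", "hd_ace"))
  eg <- switch(strategy,
               cis = schedule_carrier(cis_envelopes(ch), cfg$total_rate,
                                      cfg$pulse),
               hdcis = schedule_carrier(hdcis_envelopes(ch), cfg$total_rate,
                                        cfg$pulse),
               pdt = pdt_encode(ch, cfg$pulse),
               hd_ace = hd_ace_select(hdcis_envelopes(ch), cfg$total_rate,
                                      cfg$n_maxima, cfg$pulse))
  eg$strategy <- strategy
  eg
}

sweep_tones <- function(cfg, freqs, make_tone, stages) {
  fb <- cfg_filterbank(cfg)
  rows <- list()
  for (strategy in cfg$strategies) {
    for (f in freqs) {
      w <- make_tone(f)
      eg <- encode_tone(w, strategy, cfg, fb)
      if ("stimulation" %in% stages)
        rows[[length(rows) + 1]] <- data.frame(
          strategy = strategy, freq = f, stage = "stimulation",
          vs = vs_pulses(eg, f))
      if (any(c("spread", "neural") %in% stages)) {
        if ("spread" %in% stages) {
          ft <- spread(eg, cfg$geometry, cfg$positions_mm)
          rows[[length(rows) + 1]] <- data.frame(
            strategy = strategy, freq = f, stage = "spread",
            vs = vs_summary(vs_field(ft, f)))
        }
        if ("neural" %in% stages) {
          s <- calibrate_level(eg, cfg$geometry, cfg$positions_mm,
                               cfg$thresholds_ma,
                               target_rate = cfg$target_rate,
                               master_seed = cfg$master_seed)
          r <- simulate_population(eg, cfg$geometry, cfg$positions_mm,
                                   cfg$thresholds_ma,
                                   master_seed = cfg$master_seed,
                                   scale = as.numeric(s))
          rows[[length(rows) + 1]] <- data.frame(
            strategy = strategy, freq = f, stage = "neural",
            vs = vs_summary(vs_raster(r, f)))
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pure-tone synchrony sweep
#'
#' For each semitone-spaced frequency and each strategy, computes vector
#' strength at the tone frequency at up to three stages: the stimulation
#' pattern (max-charge channel), the post-spread field (max across
#' positions) and the modeled neural response (max across fibers, after
#' calibrating the level to the target rate). The neural stage is by far
#' the most expensive; restrict `freqs` when it is enabled.
#'
#' @param cfg an [experiment_config()].
#' @param freqs frequencies, Hz; default the full semitone grid.
#' @param stages subset of `c("stimulation", "spread", "neural")`.
#' @return A data frame with columns `strategy`, `freq`, `stage`, `vs`.
#' @export
sweep_pure <- function(cfg = experiment_config(),
                       freqs = semitone_grid(cfg$f_lo, cfg$f_hi),
                       stages = "stimulation") {
  stages <- match.arg(stages, c("stimulation", "spread", "neural"),
                      several.ok = TRUE)
  sweep_tones(cfg, freqs, function(f)
    make_pure_tone(f, cfg$duration_s, cfg$sample_rate), stages)
}

#' Complex-tone synchrony sweep
#'
#' As [sweep_pure()] but with harmonic complex tones (-6 dB/octave slope,
#' harmonics below 10 kHz) and vector strength evaluated at the fundamental.
#' The default grid spans musical notes A1 to A6 (55-1760 Hz).
#'
#' @inheritParams sweep_pure
#' @param f0s fundamental frequencies, Hz.
#' @return A data frame with columns `strategy`, `freq`, `stage`, `vs`.
#' @export
sweep_complex <- function(cfg = experiment_config(),
                          f0s = semitone_grid(55, 1760),
                          stages = "stimulation") {
  stages <- match.arg(stages, c("stimulation", "spread", "neural"),
                      several.ok = TRUE)
  sweep_tones(cfg, f0s, function(f)
    make_complex_tone(f, cfg$duration_s, cfg$sample_rate), stages)
}

#' Stimulation-rate study with HD-ACE
#'
#' Runs the n-of-m HD-ACE strategy at the three device classes studied:
#' 90,000 pps with 8 selected electrodes, 14,400 pps with 6, and 3,500 pps
#' with 4 (per-electrode rates 11,250 / 2,400 / 875 pps). Stimuli are five
#' cycles of a 500 Hz pure tone and five cycles of a 220 Hz complex tone;
#' fibers span 0-30 mm in 0.1 mm steps with thresholds 0.1-0.8 in 0.1
#' steps, and each condition is calibrated to the target rate.
#'
#' @param cfg an [experiment_config()]; its rate/maxima, positions and
#'   thresholds are overridden by the arguments below.
#' @param conditions data frame with columns `total_rate`, `n_maxima`.
#' @param positions_mm neural positions, mm.
#' @param thresholds_ma threshold grid.
#' @param tones named list of tone frequencies: `pure` (Hz) and `complex`
#'   (F0, Hz).
#' @param n_cycles number of stimulus cycles per tone.
#' @return A list with `vs` (data frame: `tone`, `total_rate`, `n_maxima`,
#'   `per_electrode_rate`, `vs`) and `rasters` (nested list of
#'   `"spike_raster"` objects).
#' @export
rate_study <- function(cfg = experiment_config(),
                       conditions = data.frame(
                         total_rate = c(90000, 14400, 3500),
                         n_maxima = c(8, 6, 4)),
                       positions_mm = seq(0, 30, by = 0.1),
                       thresholds_ma = seq(0.1, 0.8, by = 0.1),
                       tones = list(pure = 500, complex = 220),
                       n_cycles = 5) {
  fb <- cfg_filterbank(cfg)
  rows <- list()
  rasters <- list()
  for (tone in names(tones)) {
    f <- tones[[tone]]
    dur <- n_cycles / f
    w <- if (tone == "pure") make_pure_tone(f, dur, cfg$sample_rate)
         else make_complex_tone(f, dur, cfg$sample_rate)
    ch <- apply_filterbank(w, fb)
    env <- hdcis_envelopes(ch)
    for (k in seq_len(nrow(conditions))) {
      tr <- conditions$total_rate[k]
      nm <- conditions$n_maxima[k]
      eg <- hd_ace_select(env, tr, nm, cfg$pulse)
      s <- calibrate_level(eg, cfg$geometry, positions_mm, thresholds_ma,
                           target_rate = cfg$target_rate,
                           master_seed = cfg$master_seed)
      r <- simulate_population(eg, cfg$geometry, positions_mm, thresholds_ma,
                               master_seed = cfg$master_seed,
                               scale = as.numeric(s))
      rasters[[tone]][[as.character(tr)]] <- r
      rows[[length(rows) + 1]] <- data.frame(
        tone = tone, freq = f, total_rate = tr, n_maxima = nm,
        per_electrode_rate = tr / nm, vs = vs_summary(vs_raster(r, f)))
    }
  }
  vs <- do.call(rbind, rows)
  rownames(vs) <- NULL
  list(vs = vs, rasters = rasters)
}

#' Interspike-interval experiment
#'
#' Reproduces the single-electrode interval analysis: a 500 Hz tone is
#' encoded by each strategy, the maximally excited channel is retained as a
#' lone stimulating electrode, the level is calibrated to ~100 spikes/s for
#' a population of fibers flanking the electrode, and `n_iterations`
#' independent presentations are pooled into first- and all-order interval
#' histograms.
#'
#' @param cfg an [experiment_config()]; `duration_s` defaults here to
#'   100 ms via `duration_s`.
#' @param freq tone frequency, Hz.
#' @param duration_s stimulus duration per iteration, s.
#' @param n_iterations number of seeded presentations pooled.
#' @param positions_mm fiber positions relative to the electrode, mm.
#' @param thresholds_ma threshold grid.
#' @param bin_width_us histogram bin width, us.
#' @param window_ms all-order window, ms.
#' @return A named list per strategy, each with elements `first` and `all`
#'   ([isi()] histograms), `rate` (achieved spikes/s) and `scale`.
#' @export
isi_experiment <- function(cfg = experiment_config(),
                           freq = 500, duration_s = 0.100,
                           n_iterations = 100,
                           positions_mm = seq(-10, 10, by = 0.1),
                           thresholds_ma = seq(0.1, 0.8, by = 0.1),
                           bin_width_us = 100, window_ms = 20) {
  fb <- cfg_filterbank(cfg)
  w <- make_pure_tone(freq, duration_s, cfg$sample_rate)
  geom1 <- array_geometry(n_electrodes = 1, pitch_mm = cfg$geometry$pitch_mm,
                          array_to_nerve_mm = cfg$geometry$array_to_nerve_mm)
  out <- list()
  for (strategy in cfg$strategies) {
    eg <- encode_tone(w, strategy, cfg, fb)
    eg1 <- subset_electrodogram(eg, max_charge_channel(eg), renumber = TRUE)
    pd <- population_drive(eg1, geom1, positions_mm)
    p <- fiber_params()
    s <- calibrate_drive(pd, thresholds_ma, p, cfg$target_rate,
                         cfg$master_seed)
    trains <- list()
    total <- 0
    for (it in seq_len(n_iterations)) {
      r <- sim_population_drive(pd, thresholds_ma, p, cfg$master_seed,
                                as.numeric(s), iter = it)
      trains <- c(trains, r$spikes[vapply(r$spikes, length, integer(1)) > 1])
      total <- total + sum(vapply(r$spikes, length, integer(1)))
    }
    n_fibers <- length(positions_mm) * length(thresholds_ma)
    out[[strategy]] <- list(
      first = isi(trains, "first", bin_width_us, window_ms),
      all = isi(trains, "all", bin_width_us, window_ms),
      rate = total / n_iterations / n_fibers / duration_s,
      scale = as.numeric(s))
  }
  out
}

## bisection on a precomputed drive (shared by calibrate_level and the ISI
## experiment, which must reuse one drive across many iterations)
calibrate_drive <- function(pd, thresholds_ma, p, target_rate, master_seed,
                            tol = 0.1, max_scale = 1e4) {
  rate_at <- function(s)
    mean_rate(sim_population_drive(pd, thresholds_ma, p, master_seed, s))
  lo <- 0; hi <- 1
  r_hi <- rate_at(hi)
  while (r_hi < target_rate && hi < max_scale) {
    lo <- hi; hi <- hi * 2
    r_hi <- rate_at(hi)
  }
  if (r_hi < target_rate)
    stop(errorCondition(
      sprintf("target rate %g sp/s unreachable below scale %g", target_rate,
              max_scale),
      class = c("cisync_calibration_error", "error", "condition")))
  s <- hi; r <- r_hi
  for (k in 1:40) {
    if (abs(r - target_rate) <= tol * target_rate) break
    mid <- (lo + hi) / 2
    r <- rate_at(mid)
    if (r < target_rate) lo <- mid else hi <- mid
    s <- mid
  }
  if (abs(r - target_rate) > tol * target_rate)
    stop(errorCondition(
      sprintf("calibration did not converge: rate %.2f vs target %g", r,
              target_rate),
      class = c("cisync_calibration_error", "error", "condition")))
  structure(s, rate = r)
}
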