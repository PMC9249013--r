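#' Acoustic fiber model configuration
#'
#' Configuration for the simplified acoustic auditory-nerve stand-in used as
#' the normal-hearing comparison baseline. It is deliberately a reduced
#' cascade (band-pass tuning, rectification, phase-locking low-pass,
#' short-term adaptation, saturating rate mapping, dead-time Poisson
#' spiking), property-tested for the qualitative behaviors the comparisons
#' rely on, and is not a re-implementation of the full multi-stage
#' phenomenological periphery models used in physiology.
#'
#' @param n_fibers number of fibers; characteristic frequencies are
#'   log-spaced over `f_lo`..`f_hi` by the same designer as the implant
#'   filterbank.
#' @param f_lo,f_hi CF range, Hz.
#' @param ihc_lowpass_hz cutoff of the second-order low-pass that models the
#'   roll-off of inner-hair-cell phase locking; 3 kHz places the decline of
#'   synchrony in the physiological 2-4 kHz band.
#' @param spont_rate spontaneous rate, spikes/s (a low-spont fiber; fiber
#'   spontaneous-rate classes are not modeled).
#' @param refractory_us absolute dead time, us.
#' @param max_rate saturated driven rate, spikes/s.
#' @param half_sat drive (Pa) at which the rate mapping reaches half of
#'   `max_rate`; 0.02 Pa (~60 dB SPL peak) puts fibers into moderate
#'   saturation at the 65 dB SPL presentation level, as physiological
#'   rate-level functions do.
#' @param expansion expansive transduction exponent applied before the
#'   saturating map. The square law sharpens the within-cycle spiking window
#'   beyond the half-wave-rectified sine, which is what keeps phase locking
#'   near its physiological ~0.8 ceiling even for saturated fibers (a purely
#'   saturating half-wave window would cap vector strength at 2/pi).
#' @param adapt_tau_s time constant of short-term adaptation, s.
#' @param adapt_strength divisive adaptation strength (0 disables).
#' @return An object of class `"acoustic_config"`.
#' @export
acoustic_config <- function(n_fibers = 256, f_lo = 125, f_hi = 8000,
                            ihc_lowpass_hz = 3000, spont_rate = 1,
                            refractory_us = 750, max_rate = 300,
                            half_sat = 0.02, expansion = 2,
                            adapt_tau_s = 0.06, adapt_strength = 0.005) {
  structure(list(n_fibers = n_fibers, f_lo = f_lo, f_hi = f_hi,
                 ihc_lowpass_hz = ihc_lowpass_hz, spont_rate = spont_rate,
                 refractory_us = refractory_us, max_rate = max_rate,
                 half_sat = half_sat, expansion = expansion,
                 adapt_tau_s = adapt_tau_s, adapt_strength = adapt_strength),
            class = "acoustic_config")
}

## equivalent rectangular bandwidth of human auditory filters, Hz
erb_hz <- function(f) 24.7 * (4.37 * f / 1000 + 1)

#' Simulate the acoustic auditory-nerve baseline
#'
#' Per characteristic frequency: causal second-order band-pass at the CF with
#' an ERB-scale bandwidth, half-wave rectification, a second-order low-pass
#' modeling the phase-locking roll-off, divisive short-term adaptation, a
#' saturating drive-to-rate mapping, and inhomogeneous Poisson spiking with
#' an absolute dead time. Reproducible given `seed`.
#'
#' @param w an acoustically calibrated [waveform()].
#' @param cfg an [acoustic_config()].
#' @param seed integer master seed.
#' @return A `"spike_raster"` whose index columns are `fiber` and `cf_hz`.
#' @export
an_response <- function(w, cfg = acoustic_config(), seed = 1L) {
  stopifnot(inherits(w, "waveform"), inherits(cfg, "acoustic_config"))
  if (w$calibration != "acoustic_dbspl")
    stop(errorCondition(
      "acoustic fiber model requires an acoustic_dbspl-calibrated waveform",
      class = c("cisync_acoustic_input_error", "error", "condition")))
  fs <- w$sample_rate
  cfs <- design_filterbank(cfg$n_fibers, cfg$f_lo, cfg$f_hi,
                           fs)$center_freqs
  lp <- signal::butter(2, cfg$ihc_lowpass_hz / (fs / 2), type = "low")
  dt <- 1 / fs
  n <- length(w$samples)
  a_adapt <- exp(-dt / cfg$adapt_tau_s)
  dead_s <- cfg$refractory_us / 1e6
  spikes <- vector("list", cfg$n_fibers)
  for (i in seq_len(cfg$n_fibers)) {
    cf <- cfs[i]
    bw <- erb_hz(cf)
    ## 4-pole Butterworth band-pass, ERB-matched -3 dB bandwidth: skirt
    ## steepness comparable to the 4th-order gammatone standard, so that
    ## low-order harmonics of voiced F0s are resolved as in the cochlea
    bp <- signal::butter(2, c(max(cf - bw / 2, 1), min(cf + bw / 2,
                                                       fs / 2 * 0.999)) /
                           (fs / 2), type = "pass")
    y <- as.numeric(signal::filter(bp, w$samples))
    d <- pmax(y, 0)
    d <- pmax(as.numeric(signal::filter(lp, d)), 0)
    u <- (d / cfg$half_sat)^cfg$expansion
    driven <- cfg$max_rate * u / (u + 1)
    if (cfg$adapt_strength > 0) {
      m <- as.numeric(signal::filter(1 - a_adapt, c(1, -a_adapt), driven))
      driven <- driven / (1 + cfg$adapt_strength * m)
    }
    lambda <- cfg$spont_rate + driven
    set.seed(fiber_seed(seed, i, 1L))
    cand <- which(runif(n) < lambda * dt)
    t_cand <- (cand - 1) * dt
    keep <- numeric(0)
    last <- -Inf
    for (tc in t_cand) {
      if (tc - last >= dead_s) {
        keep <- c(keep, tc)
        last <- tc
      }
    }
    spikes[[i]] <- keep
  }
  new_spike_raster(spikes,
                   data.frame(fiber = seq_len(cfg$n_fibers), cf_hz = cfs),
                   n / fs)
}
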