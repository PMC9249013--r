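---
title: "Modeling neural synchrony under electric and acoustic stimulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling neural synchrony under electric and acoustic stimulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cisync)
```

## The question the pipeline answers

Auditory-nerve fibers phase-lock to the temporal fine structure of sound up
to a few kilohertz, and this synchrony is widely held to carry pitch.
Cochlear implants control stimulation timing with microsecond precision, yet
the most common sound-coding strategies discard fine structure in favor of
slow channel envelopes. `cisync` simulates the whole causal chain — tone,
filterbank, pulse coding, electrode current spread, stochastic nerve fibers —
so that the synchrony available to a listener can be compared across coding
strategies, across processing stages, and against a normal-hearing baseline.

Synchrony is quantified as vector strength at the analysis frequency $f$.
For spike trains,

$$\mathrm{VS}_{AN} = \Bigl|\tfrac{1}{N}\sum_{i=1}^{N} e^{j 2\pi f t_i}\Bigr|,$$

and for electrical stimulation patterns the analogous charge-weighted form

$$\mathrm{VS}_{CI} = \frac{\bigl|\sum_i q_i\, e^{j 2\pi f t_i}\bigr|}{\sum_i q_i},$$

where $q_i$ is the charge per phase of pulse $i$, a proxy for its spiking
probability. Both lie in $[0, 1]$; 1 is perfect phase locking.

## Stimuli

Pure tones are sine-phase sinusoids; harmonic complex tones sum sine-phase
harmonics $k f_0 < 10\,\mathrm{kHz}$ with amplitudes $\propto 1/k$
(−6 dB/octave, typical of natural harmonic sounds). Tones are 30 ms by
default, with **no onset ramp**: abrupt-onset hyper-synchronization of
electrically stimulated fibers is one of the behaviors under study, so
ramping it away would remove the phenomenon. Electric-side processing uses
peak-1 calibration; the acoustic model uses dB SPL re 20 µPa, applied to the
*summed* signal (the natural reading of a single presentation level; a
per-component convention would make complex-tone level grow with harmonic
count). The 100 kHz sample rate oversamples the 8 kHz top channel several
times over and divides the 1 µs pulse bookkeeping grid exactly.

## Filterbank

All strategies share a bank of 22 second-order (two-pole) recursive
band-pass filters with log-spaced center frequencies from 125 to 8000 Hz;
crossovers sit at the geometric means of adjacent centers and are the −3 dB
edges of both neighbors. Butterworth prototypes via the bilinear transform
are used: the stated order and −3 dB crossover placement pin the design down
up to the prototype family and digitization method, and Butterworth/bilinear
is the standard default for both. Filtering is **causal only**. The phase
delay of a constant-Q recursive bank decreases with center frequency, like
the cochlear traveling wave, and this inter-channel delay is precisely what
makes current spread smear temporal fine structure — zero-phase filtering
would assume that effect away.

## Pulse-coding strategies

All strategies emit charge-balanced biphasic pulses (25 µs phases, 8 µs
interphase gap, cathodic first) on a 1 µs grid.

* **CIS** extracts the Hilbert-magnitude envelope of each channel and
  modulates a fixed-rate interleaved carrier (90,000 pps total, so
  90000/22 ≈ 4091 pps per channel). The raw analytic-signal magnitude is
  used without a further envelope low-pass: the magnitude of a narrowband
  channel is already slow, and an extra smoothing stage is a vendor-specific
  detail that changes none of the studied contrasts (we verified it does not
  reduce the residual synchrony floor discussed under *Limitations*).
* **HDCIS** replaces the envelope by the half-wave rectified channel signal,
  which keeps within-cycle fine structure on the same carrier.
* **PDT** schedules one pulse per strict local maximum (positive value) of
  each channel's filtered signal, with amplitude equal to the peak value.
  Peaks are defined by a sign change of the first difference; a plateau
  contributes its first sample. When peaks of different channels land in
  the same microsecond slot, the later-detected pulse is delayed by one
  biphasic footprint (58 µs), preserving non-simultaneity with shifts that
  are negligible at fine-structure frequencies.
* **HD-ACE** applies frame-based n-of-m selection to the HDCIS envelopes:
  per frame the `n_maxima` largest instantaneous envelopes (ties to the
  lower channel) are pulsed in apex-to-base order, so each electrode fires
  at most `total_rate / n_maxima` times per second.

The interleave order (apex to base) is a reproducibility convention; at the
per-channel level it does not affect vector strength. Envelopes are sampled
at each pulse's onset slot. Note one physical subtlety: at 90,000 pps the
58 µs biphasic footprint exceeds the 11 µs onset slot, so the *waveforms* of
pulses on different electrodes overlap even though their onset slots never
collide; the current-spread stage superposes them linearly, which is how a
real high-rate interleaved system behaves at the tissue.

## Current spread

The electrode array is a straight line of 22 point sources, 0.75 mm apart,
running parallel to the nerve at 1 mm distance, the most basal electrode
perpendicular to the 0 mm neural location (the array spans 15.75 mm).
Electrode $e$ contributes to neural position $x$ with inverse-law weight
$a/\sqrt{a^2 + (x - x_e)^2}$, $a = 1$ mm, so the nearest point on the array
has unit weight; contributions superpose, and the resulting field is
rescaled per stimulus so its global peak is 1 mA. Voltage and effective
current are used interchangeably as a single drive unit — the distinction is
immaterial for a linear medium feeding a threshold model, and published
treatments of this geometry mix the two units as well.

## Point-process fiber model

Electrically driven fibers are simulated as a stochastic threshold cascade.
Candidate events are pulse arrivals; between-pulse spontaneous activity is
not modeled (fibers in an implanted, deafened ear are electrically driven).

1. The field is integrated by a leaky membrane with time constant
   $\tau = \mathrm{chronaxie}/\ln 2$ (the strength–duration relation of a
   leaky integrator), normalized so an isolated 25 µs pulse of amplitude $A$
   yields effective current $I_\mathrm{eff} = A$ at the end of its cathodic
   phase. Closely spaced pulses therefore summate.
2. At each candidate, the spike probability is
   $\Phi\bigl((I_\mathrm{eff} - \theta_\mathrm{eff})/(RS\cdot\theta)\bigr)$:
   a pulse exactly at threshold fires with probability 0.5, and one at
   $\theta(1 + 2RS)$ with probability $\Phi(2) \approx 0.977$.
3. Refractoriness: the proposed (jittered) spike time must clear the
   absolute refractory period of the previous spike; beyond it the
   threshold is elevated by a factor $1 + e^{-\Delta t/\tau_{rel}}$.
   Enforcing the absolute period on the *jittered* times guarantees that no
   emitted interspike interval is ever shorter than the absolute refractory
   period, which would not hold if jitter were applied after the fact.
4. Spike times carry Gaussian jitter (SD `jitter_sd_us`).

Defaults are standard cat-fiber statistics: RS = 0.06, jitter 85 µs,
chronaxie 276 µs, absolute refractory period 332 µs, relative refractory
time constant 411 µs; all overridable. Populations place one fiber per
(position, threshold) pair, thresholds 0.1–0.8 mA in 0.05 mA steps by
default (figure-specific drivers use 0.1 mA steps, matching the coarser
grids quoted for those analyses). Each fiber has its own RNG stream keyed
by position and threshold index, so enlarging a population never reshuffles
existing fibers. Stimulus level is set by `calibrate_level()`: bisection on
a global scale until the mean population rate is within 10% of the target
(100 spikes/s for the headline analyses).

## Acoustic baseline — a declared stand-in

The normal-hearing reference in the literature is a multi-stage
phenomenological periphery model validated on decades of physiology.
Re-implementing it bit-exactly is out of scope here; `an_response()` is a
deliberately simplified cascade that is *property-tested* for the behaviors
the electric/acoustic comparisons rely on, and its printed numbers should
not be read as replications of that model's values (e.g. its 0.88/0.90/0.97
vector-strength maxima).

Per fiber (256 CFs, log-spaced 125–8000 Hz by the same designer as the
filterbank): a causal 4-pole Butterworth band-pass at CF with ERB-scale
bandwidth (gammatone-like skirts, enough to resolve ~8–10 low harmonics),
half-wave rectification, a 2nd-order low-pass at 3 kHz placing the
phase-locking roll-off in the physiological 2–4 kHz band, divisive
short-term adaptation (τ = 60 ms), a square-law-expanded saturating rate
map, and dead-time (750 µs) Poisson spiking plus 1 spike/s of spontaneous
activity. The expansive square law before saturation matters: a purely
saturating half-wave window caps vector strength at $2/\pi \approx 0.64$,
whereas real fibers hold ~0.8 at low frequencies even when rate-saturated;
the square law restores that by narrowing the within-cycle spiking window.
Half-saturation at 0.02 Pa (~60 dB SPL peak) puts fibers into moderate
saturation at the 65 dB SPL presentation level, as physiological rate-level
functions do.

What the stand-in does **not** capture: middle-ear filtering, level-dependent
cochlear tuning, IHC-synapse vesicle dynamics, spontaneous-rate classes,
refractory recovery structure. Passing tests therefore show that the
*electric-side* results are compared against a baseline with the right
qualitative synchrony profile — not that they would match a specific
published periphery model number for number.

## Experiment drivers and problem sizes

* `sweep_pure()` / `sweep_complex()`: vector strength per strategy and stage
  over semitone grids (73 frequencies, 125–8000 Hz; 61 fundamentals, A1–A6).
  The stimulation stage runs the full grids in seconds. The spread and
  neural stages cost a current-spread rendering and a calibrated population
  simulation per point; the shipped analyses run them at representative
  frequencies (e.g. 500 Hz) over 201 positions x 15 thresholds.
* `isi_experiment()`: the interval analysis uses the maximally excited
  channel as a lone electrode (matching the single-electrode configuration
  of the corresponding figure), 201 positions flanking it (±10 mm, 0.1 mm
  steps) x 8 thresholds, level calibrated to ~100 spikes/s, 100 iterations
  of a 100 ms, 500 Hz tone, pooling on the order of $10^5$–$10^6$ intervals
  into 100 µs bins.
* `rate_study()`: HD-ACE at (90,000 pps, 8 maxima), (14,400, 6), (3,500, 4)
  — per-electrode rates 11,250 / 2,400 / 875 pps — on five cycles of a
  500 Hz pure tone and a 220 Hz complex tone, fibers 0–30 mm in 0.1 mm
  steps, thresholds 0.1–0.8 in 0.1 steps.

Every population result is reproducible from `master_seed`; per-fiber
streams are derived deterministically from it.

## Numerical choices and degenerate inputs

* Pulse times on a 1 µs grid; the carrier's 244.4 µs per-channel period is
  therefore realized as 244/245 µs steps whose mean is exact.
* Vector strength of an empty spike train (or an all-zero-charge pulse set)
  is *undefined* and raised as a typed error, never reported as 0.
* Vector strength is computed over the full stimulus by default; no onset
  window is excluded (an optional exclusion would be a sensitivity analysis,
  not the primary definition).
* Summary statistics over fiber populations are maxima across fibers, as in
  the source analyses; fibers with fewer than `min_spikes` (default 5)
  events are excluded from the maximum because a 1-spike train trivially has
  vector strength 1. The estimator $|\hat V|$ has an upward bias floor of
  about $1/\sqrt{N}$ for $N$ spikes, which is why the low-synchrony acoustic
  checks use long tones and explicit minimum spike counts.
* Ties in HD-ACE channel selection go to the lower (more apical) channel;
  PDT same-slot collisions delay the later-detected pulse by one footprint.
* An empty electrodogram spreads to a valid all-zero field and an empty
  spike raster.

## Known limitations

* **The CIS "near zero" claim has a measurement floor.** Over a 30 ms
  stimulus the charge train is a finite window, so the envelope's DC leaks
  into the vector-strength sum with a floor of roughly $|\mathrm{sinc}(fT)|$
  — about 0.05–0.07 below 200 Hz — and at 4000 Hz the tone lies within
  ~90 Hz of the 4090.9 pps per-channel carrier rate, whose finite-window
  Dirichlet kernel alone yields ≈ 0.09. CIS synchrony at the remaining ~92%
  of the semitone grid is below 0.05, and at frequencies commensurate with
  the analysis window (e.g. 500 Hz) it is below 0.01. These residuals are
  properties of the 30 ms analysis window, not encoded fine structure:
  they do not grow with stimulus level, and they persist for a constant
  envelope.
* The acoustic stand-in's absolute rates and vector-strength values are
  calibrated to qualitative physiology, not to a specific periphery model.
* No loudness mapping/compression to clinical current units; PDT amplitudes
  are raw peak values, so its low-rate channels would need per-channel gain
  in any clinical realization.
* FSP/FS4-style zero-crossing strategies are not simulated.

## Worked example

```{r example, eval = FALSE}
fb <- design_filterbank(22, 125, 8000, 1e5)
tone <- make_pure_tone(500, 0.030, 1e5)
ch <- apply_filterbank(tone, fb)

eg_hdcis <- schedule_carrier(hdcis_envelopes(ch), 90000)
eg_pdt <- pdt_encode(ch)
vs_pulses(eg_hdcis, 500)  # 0.786 (continuous-limit value pi/4 = 0.785)
vs_pulses(eg_pdt, 500)    # 0.999

cfg <- experiment_config()
ft <- spread(eg_hdcis, cfg$geometry, cfg$positions_mm)
vs_summary(vs_field(ft, 500))  # 0.515: current spread smears fine structure

s <- calibrate_level(eg_hdcis, cfg$geometry, cfg$positions_mm,
                     cfg$thresholds_ma, target_rate = 100, master_seed = 1)
r <- simulate_population(eg_hdcis, cfg$geometry, cfg$positions_mm,
                         cfg$thresholds_ma, master_seed = 1,
                         scale = as.numeric(s))
vs_summary(vs_raster(r, 500))  # 0.986: the nerve re-synchronizes the cue
```
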