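# cisync

Simulation of neural synchrony in the auditory nerve under electric
(cochlear-implant) and acoustic stimulation.

Cochlear implants can time their pulses with microsecond precision, but the
dominant sound-coding strategies modulate a fixed-rate pulse carrier with
slow channel envelopes, discarding the temporal fine structure that carries
musical and vocal pitch. `cisync` implements the full simulation chain needed
to ask how much fine-structure synchrony each strategy actually delivers to
the nerve:

```
tone  ->  22-channel log filterbank  ->  pulse coding (CIS | HDCIS | PDT | HD-ACE)
      ->  inverse-law current spread ->  stochastic point-process nerve fibers
      ->  synchrony metrics (vector strength, ISI histograms, excitation profiles)
```

Synchrony is quantified as **vector strength** at the analysis frequency
*f*. For spike trains, VS = |(1/N) Σ exp(j2πf tᵢ)|; for stimulation
patterns, the charge-weighted form VS = |Σ qᵢ exp(j2πf tᵢ)| / Σ qᵢ, with qᵢ
the charge per phase of pulse *i*. Both range from 0 (uniform phase) to 1
(perfect locking).

Strategies: **CIS** (Hilbert-magnitude envelopes on an interleaved 90 kpps
carrier — no fine structure), **HDCIS** (half-wave rectified channel signals
as "high-definition" envelopes — fine structure retained), **PDT** (one pulse
per local maximum of each channel's filtered signal), and **HD-ACE**
(frame-based n-of-m channel selection over HDCIS envelopes, for studying
reduced stimulation rates). A simplified, property-tested acoustic fiber
model provides the normal-hearing baseline.

## Worked example

```r
library(cisync)

fb   <- design_filterbank(22, 125, 8000, 1e5)   # 125-8000 Hz, 2nd order
tone <- make_pure_tone(500, 0.030, 1e5)          # 30 ms, sine phase, peak 1
ch   <- apply_filterbank(tone, fb)

eg <- schedule_carrier(hdcis_envelopes(ch), 90000)  # HDCIS on 90 kpps
vs_pulses(eg, 500)
#> [1] 0.786351
vs_pulses(pdt_encode(ch), 500)
#> [1] 0.9989671
vs_pulses(schedule_carrier(cis_envelopes(ch), 90000), 500)
#> [1] 0.009222831
```

CIS carries essentially no 500 Hz synchrony (0.009); HDCIS reaches 0.786 —
the continuous-limit value for half-wave rectified charge weighting is
π/4 ≈ 0.785 — and PDT is nearly perfect at 0.999, one precisely timed pulse
per cycle.

Following the cue through the tissue and the nerve:

```r
cfg <- experiment_config()   # 201 positions, thresholds 0.1-0.8 mA
ft  <- spread(eg, cfg$geometry, cfg$positions_mm)   # inverse-law, peak 1 mA
vs_summary(vs_field(ft, 500))
#> [1] 0.5152616
s <- calibrate_level(eg, cfg$geometry, cfg$positions_mm, cfg$thresholds_ma,
                     target_rate = 100, master_seed = 1)
r <- simulate_population(eg, cfg$geometry, cfg$positions_mm,
                         cfg$thresholds_ma, master_seed = 1,
                         scale = as.numeric(s))
vs_summary(vs_raster(r, 500))
#> [1] 0.9856242
```

Current spread smears fine structure across channels with different phase
delays (VS drops to 0.52), but the stochastic-threshold fibers synchronize
to the cycle-by-cycle charge accumulation and restore it (0.99).

Experiment drivers reproduce the full analyses: `sweep_pure()` /
`sweep_complex()` (semitone grids, per-stage synchrony tables),
`isi_experiment()` (calibrated first-/all-order interspike-interval
histograms — HDCIS and PDT show the 2 ms comb of a 500 Hz tone, CIS does
not), and `rate_study()` (HD-ACE at 90,000/14,400/3,500 pps with 8/6/4
selected electrodes). A thin CLI over the same functions lives in
`inst/cli/cisync.R` (subcommands `synth`, `encode`, `spread`, `metrics`,
`sweep`), exchanging data through the pulse-table CSV format. The methods
vignette (`vignettes/synchrony-modeling.Rmd`) documents the model, its
parameters and its limitations.

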