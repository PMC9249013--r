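# shared fixtures, built once per test run
FS <- 1e5

fb22 <- design_filterbank(22, 125, 8000, FS)

tone500 <- make_pure_tone(500, 0.030, FS)
ch500 <- apply_filterbank(tone500, fb22)

# synthetic channel signals for strategy edge cases
fake_channel_signals <- function(mat, sample_rate = FS) {
  structure(mat, class = "channel_signals", spec = NULL,
            sample_rate = sample_rate)
}

# electrodogram with hand-picked pulses, via the pulse-table interchange
manual_electrodogram <- function(time_us, electrode, amplitude,
                                 n_channels = 22,
                                 params = pulse_params(),
                                 duration_us = max(time_us) + 100) {
  path <- tempfile(fileext = ".csv")
  df <- data.frame(time_us = time_us, electrode = electrode,
                   amplitude_mA = amplitude, phase_us = params$phase_us,
                   gap_us = params$gap_us)
  write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(list(strategy = "manual", total_rate = NA,
                            n_channels = n_channels,
                            duration_us = duration_us, sample_rate = FS),
                       paste0(path, ".json"), auto_unbox = TRUE)
  on.exit(unlink(c(path, paste0(path, ".json"))))
  read_pulse_table(path)
}
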