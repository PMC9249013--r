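#' Sampled stimulus waveform
#'
#' Container for a sampled acoustic signal together with its sample rate and
#' calibration convention. Two calibrations are supported: `"electric_peak1"`
#' scales the signal to a peak absolute amplitude of exactly 1 (the convention
#' used before implant processing) and `"acoustic_dbspl"` scales the signal so
#' its RMS corresponds to `level` dB SPL re 20 uPa (the convention used by the
#' acoustic fiber model).
#'
#' @param samples numeric vector of amplitudes.
#' @param sample_rate sampling rate in Hz.
#' @param calibration `"electric_peak1"` or `"acoustic_dbspl"`.
#' @param level level in dB SPL (acoustic calibration only).
#' @param freq_or_f0 nominal frequency (pure tone) or fundamental (complex
#'   tone) in Hz, kept as metadata.
#' @return An object of class `"waveform"`.
#' @export
waveform <- function(samples, sample_rate,
                     calibration = c("electric_peak1", "acoustic_dbspl"),
                     level = NA_real_, freq_or_f0 = NA_real_) {
  calibration <- match.arg(calibration)
  samples <- as.numeric(samples)
  stopifnot(sample_rate > 0, length(samples) > 0)
  samples <- calibrate_samples(samples, calibration, level)
  structure(
    list(samples = samples, sample_rate = sample_rate,
         calibration = calibration, level = level, freq_or_f0 = freq_or_f0),
    class = "waveform")
}

calibrate_samples <- function(x, calibration, level) {
  if (calibration == "electric_peak1") {
    pk <- max(abs(x))
    if (pk > 0) x <- x / pk
  } else {
    if (is.na(level)) stop("acoustic calibration requires a level in dB SPL")
    target_rms <- 20e-6 * 10^(level / 20)  # Pa re 20 uPa
    r <- sqrt(mean(x^2))
    if (r > 0) x <- x * target_rms / r
  }
  x
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform> %d samples @ %g Hz (%.1f ms), calibration %s",
              length(x$samples), x$sample_rate,
              1000 * length(x$samples) / x$sample_rate, x$calibration))
  if (!is.na(x$freq_or_f0)) cat(sprintf(", f = %g Hz", x$freq_or_f0))
  if (x$calibration == "acoustic_dbspl") cat(sprintf(", %g dB SPL", x$level))
  cat("\n")
  invisible(x)
}

#' Generate a pure tone
#'
#' Sinusoid in sine phase (first sample exactly 0) with no onset or offset
#' ramp: abrupt onsets are a deliberately retained feature, since onset
#' hyper-synchronization of electrically stimulated fibers is one of the
#' phenomena the pipeline studies.
#'
#' @param freq tone frequency, Hz. Must be below the Nyquist frequency.
#' @param duration duration in seconds.
#' @param sample_rate sampling rate, Hz. The 100 kHz default comfortably
#'   oversamples the 8 kHz top analysis channel and divides the 1 us pulse
#'   grid cleanly.
#' @inheritParams waveform
#' @return A [waveform()].
#' @examples
#' w <- make_pure_tone(500, 0.03)
#' max(abs(w$samples)) # exactly 1 under electric calibration
#' @export
make_pure_tone <- function(freq, duration = 0.030, sample_rate = 1e5,
                           calibration = c("electric_peak1", "acoustic_dbspl"),
                           level = 65) {
  calibration <- match.arg(calibration)
  if (!(freq > 0) || !(duration > 0))
    stop("freq and duration must be positive")
  if (freq >= sample_rate / 2)
    stop(errorCondition(
      sprintf("tone frequency %g Hz is at or above Nyquist (%g Hz)",
              freq, sample_rate / 2),
      class = c("cisync_nyquist_error", "error", "condition")))
  n <- round(duration * sample_rate)
  t <- (seq_len(n) - 1) / sample_rate
  waveform(sin(2 * pi * freq * t), sample_rate, calibration,
           level = if (calibration == "acoustic_dbspl") level else NA_real_,
           freq_or_f0 = freq)
}

#' Generate a harmonic complex tone
#'
#' Sums integer harmonics `k * f0` for all `k` with `k * f0 < max_freq`
#' (strictly), each in sine phase, with amplitudes proportional to `1/k`
#' (a -6 dB/octave spectral slope, as typical of natural harmonic sounds).
#' Calibration is applied to the summed signal, not per component.
#'
#' @param f0 fundamental frequency, Hz.
#' @param max_freq exclusive upper frequency bound for harmonics, Hz.
#' @inheritParams make_pure_tone
#' @return A [waveform()]; the number of harmonics used is stored in the
#'   `n_harmonics` element.
#' @examples
#' w <- make_complex_tone(220, 0.03)
#' w$n_harmonics # 45: highest k with 220 k < 10000
#' @export
make_complex_tone <- function(f0, duration = 0.030, sample_rate = 1e5,
                              calibration = c("electric_peak1", "acoustic_dbspl"),
                              level = 65, max_freq = 10000) {
  calibration <- match.arg(calibration)
  if (!(f0 > 0) || !(duration > 0)) stop("f0 and duration must be positive")
  k_max <- ceiling(max_freq / f0) - 1  # largest k with k*f0 < max_freq
  if (k_max < 1)
    stop(errorCondition(
      sprintf("f0 = %g Hz leaves no harmonic below %g Hz", f0, max_freq),
      class = c("cisync_no_harmonics", "error", "condition")))
  n <- round(duration * sample_rate)
  t <- (seq_len(n) - 1) / sample_rate
  x <- numeric(n)
  for (k in seq_len(k_max)) x <- x + sin(2 * pi * k * f0 * t) / k
  w <- waveform(x, sample_rate, calibration,
                level = if (calibration == "acoustic_dbspl") level else NA_real_,
                freq_or_f0 = f0)
  w$n_harmonics <- k_max
  w
}

#' Write / read a waveform as CSV plus JSON sidecar
#'
#' The CSV holds a single `amplitude` column; `<path>.json` records the
#' sample rate, calibration, level and nominal frequency.
#'
#' @param w a [waveform()].
#' @param path CSV file path.
#' @return `write_waveform()` returns `path` invisibly; `read_waveform()`
#'   returns a [waveform()].
#' @export
write_waveform <- function(w, path) {
  stopifnot(inherits(w, "waveform"))
  write.csv(data.frame(amplitude = w$samples), path, row.names = FALSE)
  meta <- list(sample_rate = w$sample_rate, calibration = w$calibration,
               level = w$level, freq_or_f0 = w$freq_or_f0)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_waveform
#' @export
read_waveform <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  x <- read.csv(path)$amplitude
  waveform(x, meta$sample_rate, meta$calibration,
           level = if (is.null(meta$level)) NA_real_ else meta$level,
           freq_or_f0 = if (is.null(meta$freq_or_f0)) NA_real_ else meta$freq_or_f0)
}
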