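#' Design the logarithmic band-pass analysis filterbank
#'
#' Center frequencies are logarithmically spaced from `f_lo` to `f_hi`
#' (inclusive), so the ratio between adjacent centers is
#' `(f_hi/f_lo)^(1/(n_channels-1))`. The crossover between channels i and
#' i+1 is the geometric mean of their centers, and each channel is a
#' second-order (two-pole) Butterworth band-pass whose -3 dB edges sit at
#' its lower and upper crossovers, designed by bilinear transform. Edge
#' channels extend by the same half-ratio beyond their centers.
#'
#' The same designer builds both the 22-channel implant filterbank and the
#' 256-CF grid used by the acoustic fiber model.
#'
#' @param n_channels number of channels (>= 2).
#' @param f_lo,f_hi first and last center frequency, Hz.
#' @param sample_rate sampling rate the filters are designed for, Hz.
#' @return An object of class `"filterbank_spec"` with elements
#'   `center_freqs`, `crossover_freqs`, `edges_lo`, `edges_hi`, `order`,
#'   `sample_rate` and per-channel biquad coefficients `coef` (`b`, `a`).
#' @examples
#' fb <- design_filterbank(22, 125, 8000, 1e5)
#' fb$center_freqs[c(1, 22)]           # 125, 8000
#' fb$center_freqs[2] / fb$center_freqs[1] # 64^(1/21)
#' @export
design_filterbank <- function(n_channels = 22, f_lo = 125, f_hi = 8000,
                              sample_rate = 1e5) {
  stopifnot(n_channels >= 2, f_lo > 0)
  if (!(f_lo < f_hi) || !(f_hi < sample_rate / 2))
    stop(errorCondition("need f_lo < f_hi < sample_rate/2",
                        class = c("cisync_design_error", "error", "condition")))
  cf <- exp(seq(log(f_lo), log(f_hi), length.out = n_channels))
  ratio <- (f_hi / f_lo)^(1 / (n_channels - 1))
  crossover <- sqrt(cf[-n_channels] * cf[-1])
  edges_lo <- cf / sqrt(ratio)
  edges_hi <- cf * sqrt(ratio)
  # outer edges mirror the adjacent crossover in log frequency; for very
  # coarse banks this can pass Nyquist, so the top edge is clamped (the top
  # channel then simply extends to the usable band edge)
  edges_hi <- pmin(edges_hi, 0.95 * sample_rate / 2)
  if (any(edges_hi <= edges_lo))
    stop(errorCondition(
      sprintf("band edges infeasible at %g Hz sample rate", sample_rate),
      class = c("cisync_design_error", "error", "condition")))
  coef <- lapply(seq_len(n_channels), function(i) {
    flt <- signal::butter(1, c(edges_lo[i], edges_hi[i]) / (sample_rate / 2),
                          type = "pass")
    list(b = as.numeric(flt$b), a = as.numeric(flt$a))
  })
  structure(
    list(n_channels = n_channels, center_freqs = cf,
         crossover_freqs = crossover, edges_lo = edges_lo,
         edges_hi = edges_hi, order = 2L, impl = "causal_iir",
         sample_rate = sample_rate, coef = coef),
    class = "filterbank_spec")
}

#' @export
print.filterbank_spec <- function(x, ...) {
  cat(sprintf(
    "<filterbank_spec> %d second-order band-pass channels, %g-%g Hz @ %g Hz\n",
    x$n_channels, x$center_freqs[1], x$center_freqs[x$n_channels],
    x$sample_rate))
  invisible(x)
}

#' Apply the filterbank to a waveform
#'
#' Causal (forward-only) recursive filtering. Zero-phase filtering is
#' deliberately not offered: the per-channel phase delay, which decreases
#' with center frequency like the cochlear traveling wave, is itself a
#' studied property of the pipeline (it drives the temporal smearing seen
#' after current spread).
#'
#' @param w a [waveform()] or numeric vector.
#' @param spec a [design_filterbank()] spec matching the waveform's sample
#'   rate.
#' @return An object of class `"channel_signals"`: a samples-by-channels
#'   numeric matrix with the spec and sample rate attached as attributes.
#' @export
apply_filterbank <- function(w, spec) {
  stopifnot(inherits(spec, "filterbank_spec"))
  if (inherits(w, "waveform")) {
    if (!isTRUE(all.equal(w$sample_rate, spec$sample_rate)))
      stop(errorCondition(
        sprintf("waveform sample rate %g != filterbank design rate %g",
                w$sample_rate, spec$sample_rate),
        class = c("cisync_rate_mismatch", "error", "condition")))
    x <- w$samples
  } else {
    x <- as.numeric(w)
  }
  y <- vapply(spec$coef,
              function(cc) as.numeric(signal::filter(cc$b, cc$a, x)),
              numeric(length(x)))
  structure(y, class = "channel_signals", spec = spec,
            sample_rate = spec$sample_rate)
}

#' Filterbank frequency response
#'
#' Steady-state complex gain of one channel at given frequencies, from the
#' biquad coefficients.
#'
#' @param spec a [design_filterbank()] spec.
#' @param channel channel index.
#' @param freqs frequencies, Hz.
#' @return Complex gains; take `Mod()` for magnitude.
#' @export
filterbank_gain <- function(spec, channel, freqs) {
  cc <- spec$coef[[channel]]
  z <- exp(-2i * pi * freqs / spec$sample_rate)
  num <- outer(z, seq_along(cc$b) - 1, `^`) %*% cc$b
  den <- outer(z, seq_along(cc$a) - 1, `^`) %*% cc$a
  as.complex(num / den)
}

#' Serialize a filterbank spec to JSON
#'
#' @param spec a [design_filterbank()] spec.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_filterbank <- function(spec, path) {
  jsonlite::write_json(
    list(n_channels = spec$n_channels, center_freqs = spec$center_freqs,
         crossover_freqs = spec$crossover_freqs, edges_lo = spec$edges_lo,
         edges_hi = spec$edges_hi, order = spec$order,
         sample_rate = spec$sample_rate, coef = spec$coef),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
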