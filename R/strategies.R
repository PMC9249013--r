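#' Biphasic pulse parameters
#'
#' All strategies deliver charge-balanced biphasic pulses: a rectangular
#' cathodic phase, an interphase gap, then a symmetric anodic phase.
#' Defaults are 25 us phases with an 8 us gap, cathodic phase first.
#'
#' @param phase_us phase duration, microseconds.
#' @param gap_us interphase gap, microseconds.
#' @param polarity currently only `"cathodic_first"`.
#' @return An object of class `"pulse_params"`.
#' @export
pulse_params <- function(phase_us = 25, gap_us = 8,
                         polarity = "cathodic_first") {
  stopifnot(phase_us > 0, gap_us >= 0)
  polarity <- match.arg(polarity, "cathodic_first")
  structure(list(phase_us = phase_us, gap_us = gap_us, polarity = polarity),
            class = "pulse_params")
}

pulse_footprint_us <- function(params) 2 * params$phase_us + params$gap_us

## analytic-signal magnitude via FFT (one-sided spectrum doubling)
analytic_signal <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(stats::fft(x) * h, inverse = TRUE) / n
}

channel_env <- function(ch, fun) {
  stopifnot(inherits(ch, "channel_signals"))
  e <- apply(unclass(ch), 2, fun)
  structure(e, class = "channel_envelopes", spec = attr(ch, "spec"),
            sample_rate = attr(ch, "sample_rate"))
}

#' CIS envelopes: Hilbert magnitude
#'
#' The continuous-interleaved-sampling envelope is the magnitude of the
#' analytic signal of each channel: non-negative and free of within-cycle
#' fine structure. The raw magnitude is used without an additional envelope
#' low-pass.
#'
#' @param ch a [apply_filterbank()] result.
#' @return A `"channel_envelopes"` matrix (samples x channels).
#' @export
cis_envelopes <- function(ch) {
  channel_env(ch, function(y) Mod(analytic_signal(y)))
}

#' HDCIS envelopes: half-wave rectification
#'
#' The "high-definition" envelope is the half-wave rectified channel signal,
#' which retains the within-cycle temporal fine structure of the filtered
#' input.
#'
#' @inheritParams cis_envelopes
#' @return A `"channel_envelopes"` matrix (samples x channels).
#' @export
hdcis_envelopes <- function(ch) {
  channel_env(ch, function(y) pmax(y, 0))
}

new_electrodogram <- function(pulses, params, total_rate, strategy,
                              n_channels, duration_us, sample_rate) {
  pulses <- pulses[order(pulses$time_us), , drop = FALSE]
  rownames(pulses) <- NULL
  pulses$charge <- pulses$amplitude * params$phase_us
  structure(
    list(pulses = pulses, params = params, total_rate = total_rate,
         strategy = strategy, n_channels = n_channels,
         duration_us = duration_us, sample_rate = sample_rate),
    class = "electrodogram")
}

#' @export
print.electrodogram <- function(x, ...) {
  cat(sprintf(
    "<electrodogram> %s: %d pulses on %d electrodes over %.1f ms (%g pps total)\n",
    x$strategy, nrow(x$pulses), length(unique(x$pulses$electrode)),
    x$duration_us / 1000, round(x$total_rate, 1)))
  invisible(x)
}

env_at_us <- function(env, t_us, channel, sample_rate) {
  idx <- pmin(nrow(env), floor(t_us * sample_rate / 1e6) + 1)
  pmax(env[cbind(idx, channel)], 0)
}

#' Modulate an interleaved fixed-rate pulse carrier
#'
#' Channels are stimulated cyclically in a fixed apex-to-base rotation
#' (channel 1 = most apical). Pulse onsets sit on a 1 us grid at multiples
#' of `1/total_rate`; each pulse's amplitude is the channel envelope sampled
#' at the pulse onset time, and its charge is amplitude x phase duration.
#' The per-channel rate is `total_rate / n_channels`. A stimulation frame
#' (one pass through all channels) must be long enough to contain a biphasic
#' pulse footprint (2 x phase + gap); note that at high total rates the
#' footprint exceeds the per-pulse slot, so the physical phases of pulses on
#' different electrodes overlap even though their onset slots never do.
#'
#' @param env a `"channel_envelopes"` matrix.
#' @param total_rate total stimulation rate across channels, pulses/s.
#' @param params a [pulse_params()].
#' @return An `"electrodogram"`.
#' @examples
#' w <- make_pure_tone(500, 0.03)
#' fb <- design_filterbank(22, 125, 8000, 1e5)
#' eg <- schedule_carrier(hdcis_envelopes(apply_filterbank(w, fb)), 90000)
#' @export
schedule_carrier <- function(env, total_rate, params = pulse_params()) {
  stopifnot(inherits(env, "channel_envelopes"), total_rate > 0)
  nch <- ncol(env)
  fs <- attr(env, "sample_rate")
  duration_us <- nrow(env) / fs * 1e6
  frame_us <- nch * 1e6 / total_rate
  if (frame_us < pulse_footprint_us(params))
    stop(errorCondition(
      sprintf("frame of %.1f us cannot fit a %g us biphasic pulse",
              frame_us, pulse_footprint_us(params)),
      class = c("cisync_frame_error", "error", "condition")))
  k <- 0:(floor(duration_us * total_rate / 1e6) - 1)
  t_us <- round(k * 1e6 / total_rate)
  chan <- (k %% nch) + 1L
  amp <- env_at_us(env, t_us, chan, fs)
  new_electrodogram(
    data.frame(time_us = t_us, electrode = chan, amplitude = amp),
    params, total_rate, "carrier", nch, duration_us, fs)
}

## strict local maxima with positive value; a plateau contributes its first
## sample (run-length scan over the sign of the first difference)
find_peaks <- function(y) {
  d <- sign(diff(y))
  r <- rle(d)
  ends <- cumsum(r$lengths)
  pk <- integer(0)
  runs <- which(r$values == 1)
  for (j in runs) {
    nxt <- j + 1
    while (nxt <= length(r$values) && r$values[nxt] == 0) nxt <- nxt + 1
    if (nxt <= length(r$values) && r$values[nxt] == -1)
      pk <- c(pk, ends[j] + 1L)  # first sample at/after the rise
  }
  pk[y[pk] > 0]
}

#' Peak-derived timing (PDT) encoding
#'
#' One biphasic pulse is scheduled per strict local maximum (with positive
#' value) of each channel's filtered signal, with amplitude equal to the
#' signal value at the peak, so the pulse train follows the temporal fine
#' structure cycle by cycle. When peaks from different channels fall in the
#' same 1 us slot, the later-detected pulse is delayed by the biphasic
#' footprint so that stimulation remains non-simultaneous; at the fine
#' structure frequencies involved these shifts are negligible for vector
#' strength.
#'
#' @param ch a [apply_filterbank()] result.
#' @param params a [pulse_params()].
#' @return An `"electrodogram"` (its `total_rate` is the realized mean rate).
#' @export
pdt_encode <- function(ch, params = pulse_params()) {
  stopifnot(inherits(ch, "channel_signals"))
  fs <- attr(ch, "sample_rate")
  y <- unclass(ch)
  nch <- ncol(y)
  duration_us <- nrow(y) / fs * 1e6
  rows <- vector("list", nch)
  for (c in seq_len(nch)) {
    pk <- find_peaks(y[, c])
    if (length(pk))
      rows[[c]] <- data.frame(time_us = round((pk - 1) / fs * 1e6),
                              electrode = c, amplitude = y[pk, c])
  }
  pulses <- do.call(rbind, rows)
  if (is.null(pulses))
    pulses <- data.frame(time_us = numeric(0), electrode = integer(0),
                         amplitude = numeric(0))
  ## collision resolution: keep onsets unique on the 1 us grid
  pulses <- pulses[order(pulses$time_us, pulses$electrode), , drop = FALSE]
  foot <- pulse_footprint_us(params)
  used <- new.env(hash = TRUE)
  for (i in seq_len(nrow(pulses))) {
    t <- pulses$time_us[i]
    while (!is.null(used[[as.character(t)]])) t <- t + foot
    used[[as.character(t)]] <- TRUE
    pulses$time_us[i] <- t
  }
  new_electrodogram(pulses, params,
                    total_rate = nrow(pulses) / (duration_us / 1e6),
                    "pdt", nch, duration_us, fs)
}

#' HD-ACE n-of-m channel selection
#'
#' Frame-based n-of-m selection over high-definition (half-wave rectified)
#' envelopes, emulating Advanced Combinatorial Encoders. Each stimulation
#' frame lasts `n_maxima / total_rate` seconds; at the frame start the
#' `n_maxima` channels with the largest instantaneous envelope values are
#' selected (ties broken toward the lower channel index) and pulsed in
#' apex-to-base order at consecutive `1/total_rate` slots. Every electrode
#' can therefore fire at most once per frame, giving a per-electrode rate of
#' `total_rate / n_maxima`.
#'
#' @param env a `"channel_envelopes"` matrix.
#' @param total_rate total stimulation rate, pulses/s.
#' @param n_maxima number of channels selected per frame.
#' @param params a [pulse_params()].
#' @return An `"electrodogram"`.
#' @export
hd_ace_select <- function(env, total_rate, n_maxima,
                          params = pulse_params()) {
  stopifnot(inherits(env, "channel_envelopes"))
  nch <- ncol(env)
  stopifnot(n_maxima >= 1, n_maxima <= nch)
  fs <- attr(env, "sample_rate")
  duration_us <- nrow(env) / fs * 1e6
  frame_us <- n_maxima * 1e6 / total_rate
  if (frame_us < pulse_footprint_us(params))
    stop(errorCondition(
      sprintf("frame of %.1f us cannot fit a %g us biphasic pulse",
              frame_us, pulse_footprint_us(params)),
      class = c("cisync_frame_error", "error", "condition")))
  n_frames <- floor(duration_us / frame_us)
  rows <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    t0_us <- (f - 1) * frame_us
    idx <- pmin(nrow(env), floor(t0_us * fs / 1e6) + 1)
    vals <- pmax(env[idx, ], 0)
    sel <- sort(order(vals, seq_len(nch), decreasing = c(TRUE, FALSE),
                      method = "radix")[seq_len(n_maxima)])
    t_us <- round(t0_us + (seq_len(n_maxima) - 1) * 1e6 / total_rate)
    rows[[f]] <- data.frame(time_us = t_us, electrode = sel,
                            amplitude = env_at_us(env, t_us, sel, fs))
  }
  new_electrodogram(do.call(rbind, rows), params, total_rate, "hd_ace",
                    nch, duration_us, fs)
}

#' Total delivered charge of an electrodogram
#'
#' Bookkeeping identity: the sum over pulses of amplitude x phase duration.
#'
#' @param eg an `"electrodogram"`.
#' @return Total charge (mA x us, i.e. nC).
#' @export
total_charge <- function(eg) {
  stopifnot(inherits(eg, "electrodogram"))
  sum(eg$pulses$charge)
}

#' Restrict an electrodogram to selected electrodes
#'
#' Used e.g. to study single-electrode stimulation of the most strongly
#' driven channel. Electrodes can optionally be renumbered to 1..k for use
#' with a smaller [array_geometry()].
#'
#' @param eg an `"electrodogram"`.
#' @param electrodes electrode indices to keep.
#' @param renumber renumber kept electrodes consecutively from 1.
#' @return An `"electrodogram"`.
#' @export
subset_electrodogram <- function(eg, electrodes, renumber = TRUE) {
  stopifnot(inherits(eg, "electrodogram"))
  p <- eg$pulses[eg$pulses$electrode %in% electrodes, , drop = FALSE]
  nch <- eg$n_channels
  if (renumber) {
    p$electrode <- match(p$electrode, sort(unique(electrodes)))
    nch <- length(electrodes)
  }
  out <- new_electrodogram(p[, c("time_us", "electrode", "amplitude")],
                           eg$params, eg$total_rate, eg$strategy, nch,
                           eg$duration_us, eg$sample_rate)
  out
}

#' Write / read the pulse-table interchange CSV
#'
#' Columns `time_us, electrode, amplitude_mA, phase_us, gap_us`, plus a JSON
#' sidecar `<path>.json` holding the strategy tag, total rate, channel count
#' and duration. This is the interchange format between the encoding,
#' current-spread and metric stages (and the CLI).
#'
#' @param eg an `"electrodogram"`.
#' @param path CSV file path.
#' @return `write_pulse_table()` returns `path` invisibly;
#'   `read_pulse_table()` returns an `"electrodogram"`.
#' @export
write_pulse_table <- function(eg, path) {
  stopifnot(inherits(eg, "electrodogram"))
  df <- data.frame(time_us = eg$pulses$time_us,
                   electrode = eg$pulses$electrode,
                   amplitude_mA = eg$pulses$amplitude,
                   phase_us = eg$params$phase_us,
                   gap_us = eg$params$gap_us)
  write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(
    list(strategy = eg$strategy, total_rate = eg$total_rate,
         n_channels = eg$n_channels, duration_us = eg$duration_us,
         sample_rate = eg$sample_rate, polarity = eg$params$polarity),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_pulse_table
#' @export
read_pulse_table <- function(path) {
  df <- read.csv(path)
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path))
    jsonlite::read_json(meta_path, simplifyVector = TRUE) else list()
  params <- pulse_params(phase_us = df$phase_us[1], gap_us = df$gap_us[1])
  dur <- if (!is.null(meta$duration_us)) meta$duration_us
         else max(df$time_us) + pulse_footprint_us(params)
  new_electrodogram(
    data.frame(time_us = df$time_us, electrode = df$electrode,
               amplitude = df$amplitude_mA),
    params,
    total_rate = if (!is.null(meta$total_rate)) meta$total_rate
                 else nrow(df) / (dur / 1e6),
    strategy = if (!is.null(meta$strategy)) meta$strategy else "unknown",
    n_channels = if (!is.null(meta$n_channels)) meta$n_channels
                 else max(df$electrode),
    duration_us = dur,
    sample_rate = if (!is.null(meta$sample_rate)) meta$sample_rate else NA_real_)
}
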