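#' Vector strength of a spike train
#'
#' Magnitude of the mean unit phasor of event times at the analysis
#' frequency: `|mean(exp(2i pi f t))|`. 1 means perfect phase locking, 0 a
#' uniform phase distribution. An empty train has no defined phase
#' distribution and raises a distinct error rather than returning 0.
#'
#' @param times spike times, seconds.
#' @param f analysis frequency, Hz.
#' @return Vector strength in `[0, 1]`.
#' @examples
#' vs_spikes(c(0, 1/2000, 2/2000), 500) # sqrt(2)/2: phases 0, 1/4, 1/2 turn
#' @export
vs_spikes <- function(times, f) {
  if (length(times) < 1)
    stop(errorCondition("vector strength of an empty spike train is undefined",
                        class = c("cisync_empty_train", "error", "condition")))
  Mod(mean(exp(2i * pi * f * times)))
}

#' Charge-weighted vector strength of a pulse train
#'
#' `|sum(q exp(2i pi f t))| / sum(q)`: the stimulation-pattern analogue of
#' spike vector strength, with each pulse weighted by its charge per phase
#' (a proxy for its spiking probability). Invariant to scaling all charges
#' by a constant and, in magnitude, to global time shifts.
#'
#' Given an electrodogram, the vector strength is computed from the pulses
#' of a single channel: `channel` if supplied, otherwise the maximally
#' excited channel (the one receiving the greatest total charge).
#'
#' @param x pulse times in seconds, or an `"electrodogram"`.
#' @param f analysis frequency, Hz.
#' @param ... passed between methods.
#' @return Vector strength in `[0, 1]`.
#' @export
vs_pulses <- function(x, f, ...) UseMethod("vs_pulses")

#' @rdname vs_pulses
#' @param charges per-pulse charges (any unit; only ratios matter).
#' @export
vs_pulses.default <- function(x, f, charges, ...) {
  if (length(x) < 1 || sum(charges) <= 0)
    stop(errorCondition("charge-weighted vector strength needs positive total charge",
                        class = c("cisync_empty_train", "error", "condition")))
  Mod(sum(charges * exp(2i * pi * f * x))) / sum(charges)
}

#' @rdname vs_pulses
#' @param channel electrode whose pulses to analyze; `NULL` selects the
#'   max-charge channel.
#' @export
vs_pulses.electrodogram <- function(x, f, channel = NULL, ...) {
  p <- x$pulses
  if (is.null(channel)) channel <- max_charge_channel(x)
  p <- p[p$electrode == channel, , drop = FALSE]
  vs_pulses(p$time_us / 1e6, f, charges = p$charge)
}

#' Maximally excited channel of an electrodogram
#'
#' The electrode receiving the greatest total delivered charge.
#'
#' @param eg an `"electrodogram"`.
#' @return Electrode index.
#' @export
max_charge_channel <- function(eg) {
  stopifnot(inherits(eg, "electrodogram"))
  q <- tapply(eg$pulses$charge, eg$pulses$electrode, sum)
  as.integer(names(q)[which.max(q)])
}

#' Vector strength of post-spread field traces
#'
#' The continuous analogue of the charge-weighted pulse metric: every sample
#' of the positive (cathodic, excitatory) phase of the effective current is
#' treated as an event weighted by its amplitude. Computed per neural
#' position.
#'
#' @param ft a [spread()] result.
#' @param f analysis frequency, Hz.
#' @return A [synchrony_table()] with one row per position.
#' @export
vs_field <- function(ft, f) {
  stopifnot(inherits(ft, "field_traces"))
  n <- nrow(ft$current)
  ph <- exp(2i * pi * f * (0:(n - 1)) / 1e6)
  w <- pmax(ft$current, 0)
  num <- Mod(t(w) %*% ph)
  den <- colSums(w)
  vs <- ifelse(den > 0, as.numeric(num) / den, NA_real_)
  synchrony_table(unit = ft$positions_mm, freq = f, vs = vs)
}

#' Per-fiber vector strength of a spike raster
#'
#' Per-fiber vector strength at the analysis frequency, summarized (as in
#' the population analyses) by the maximum across fibers. Fibers with fewer
#' than `min_spikes` events give degenerate estimates (a single spike always
#' has vector strength 1) and are excluded from the summary; their rows are
#' kept with `NA`.
#'
#' @param r a `"spike_raster"`.
#' @param f analysis frequency, Hz.
#' @param min_spikes minimum spike count for a fiber to enter the summary.
#' @param pooled also compute the vector strength of all spikes pooled
#'   across fibers (stored in attribute `"pooled"`).
#' @return A [synchrony_table()] with one row per fiber; the summary
#'   attribute holds the max across qualifying fibers.
#' @export
vs_raster <- function(r, f, min_spikes = 5, pooled = FALSE) {
  stopifnot(inherits(r, "spike_raster"))
  vs <- vapply(r$spikes, function(s)
    if (length(s) >= min_spikes) vs_spikes(s, f) else NA_real_, numeric(1))
  tab <- synchrony_table(unit = r$index$fiber, freq = f, vs = vs)
  if (pooled) {
    all_spikes <- unlist(r$spikes)
    attr(tab, "pooled") <- if (length(all_spikes)) vs_spikes(all_spikes, f)
                           else NA_real_
  }
  tab
}

#' Synchrony table
#'
#' Rows of (unit, analysis frequency, vector strength) with the maximum
#' across units as the summary statistic, retrievable with
#' [vs_summary()].
#'
#' @param unit unit identifier (channel, position or fiber).
#' @param freq analysis frequency, Hz.
#' @param vs vector strength values in `[0, 1]` (NA allowed).
#' @return A data frame of class `"synchrony_table"`.
#' @export
synchrony_table <- function(unit, freq, vs) {
  stopifnot(all(is.na(vs) | (vs >= 0 & vs <= 1 + 1e-9)))
  structure(data.frame(unit = unit, freq = freq, vs = vs),
            class = c("synchrony_table", "data.frame"))
}

#' @rdname synchrony_table
#' @param tab a `"synchrony_table"`.
#' @export
vs_summary <- function(tab) {
  if (all(is.na(tab$vs))) NA_real_ else max(tab$vs, na.rm = TRUE)
}

#' Interspike-interval histogram
#'
#' First-order intervals are differences between consecutive spikes of a
#' fiber; all-order intervals are all ordered pairwise differences up to
#' `window_ms`. Intervals are pooled across the fibers of a raster (never
#' across fibers within a pair). Fewer than two spikes yield an empty
#' histogram.
#'
#' @param x a `"spike_raster"`, a list of spike-time vectors, or a single
#'   numeric spike train (seconds).
#' @param order `"first"` or `"all"`.
#' @param bin_width_us histogram bin width, us.
#' @param window_ms maximum interval retained, ms.
#' @return An object of class `"isi_histogram"`: `breaks_ms`, `mids_ms`,
#'   `counts`, `order`, `n_intervals`.
#' @export
isi <- function(x, order = c("first", "all"), bin_width_us = 100,
                window_ms = 20) {
  order <- match.arg(order)
  trains <- if (inherits(x, "spike_raster")) x$spikes
            else if (is.list(x)) x else list(as.numeric(x))
  ints <- lapply(trains, function(s) {
    s <- sort(s)
    if (length(s) < 2) return(numeric(0))
    if (order == "first") diff(s)
    else {
      out <- lapply(seq_len(length(s) - 1), function(i) {
        d <- s[(i + 1):length(s)] - s[i]
        d[d <= window_ms / 1000]
      })
      unlist(out)
    }
  })
  ints_ms <- unlist(ints) * 1000
  ints_ms <- ints_ms[ints_ms <= window_ms]
  breaks <- seq(0, window_ms, by = bin_width_us / 1000)
  counts <- if (length(ints_ms))
    graphics::hist(ints_ms, breaks = breaks, plot = FALSE)$counts
  else integer(length(breaks) - 1)
  structure(list(breaks_ms = breaks,
                 mids_ms = (breaks[-1] + breaks[-length(breaks)]) / 2,
                 counts = counts, order = order,
                 bin_width_us = bin_width_us,
                 n_intervals = length(ints_ms)),
            class = "isi_histogram")
}

#' @export
print.isi_histogram <- function(x, ...) {
  cat(sprintf("<isi_histogram> %s-order, %d intervals in %g us bins up to %g ms\n",
              x$order, x$n_intervals, x$bin_width_us,
              max(x$breaks_ms)))
  invisible(x)
}

#' Histogram count near a lag
#'
#' Mean count of the histogram bins within `halfwidth_ms` of `lag_ms`;
#' convenience for comb/periodicity checks.
#'
#' @param h an [isi()] histogram.
#' @param lag_ms center lag, ms.
#' @param halfwidth_ms half-width of the neighborhood, ms.
#' @return Mean bin count.
#' @export
isi_count_near <- function(h, lag_ms, halfwidth_ms = 0.2) {
  sel <- abs(h$mids_ms - lag_ms) <= halfwidth_ms
  mean(h$counts[sel])
}

#' Excitation profile
#'
#' For an electrodogram: the proportion of total charge delivered to each
#' electrode (sums to 1; all-zero for an empty pattern). For a spike
#' raster: each fiber's mean firing rate over the stimulus duration.
#'
#' @param x an `"electrodogram"` or `"spike_raster"`.
#' @return A named numeric vector (per electrode or per fiber).
#' @export
excitation_profile <- function(x) {
  if (inherits(x, "electrodogram")) {
    q <- numeric(x$n_channels)
    if (nrow(x$pulses) > 0) {
      agg <- tapply(x$pulses$charge, x$pulses$electrode, sum)
      q[as.integer(names(agg))] <- agg
    }
    tot <- sum(q)
    if (tot > 0) q <- q / tot
    names(q) <- seq_len(x$n_channels)
    q
  } else if (inherits(x, "spike_raster")) {
    r <- vapply(x$spikes, length, integer(1)) / x$duration_s
    names(r) <- x$index$fiber
    r
  } else stop("excitation_profile needs an electrodogram or spike_raster")
}

#' Write a synchrony table or ISI histogram as tidy CSV
#'
#' @param x a `"synchrony_table"` or `"isi_histogram"`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_metric_csv <- function(x, path) {
  if (inherits(x, "synchrony_table")) {
    write.csv(as.data.frame(x), path, row.names = FALSE)
  } else if (inherits(x, "isi_histogram")) {
    write.csv(data.frame(lag_ms = x$mids_ms, count = x$counts,
                         order = x$order), path, row.names = FALSE)
  } else stop("unsupported metric object")
  invisible(path)
}
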