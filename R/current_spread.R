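#' Electrode array geometry
#'
#' A straight array of point electrodes parallel to the modeled nerve, at a
#' perpendicular distance `array_to_nerve_mm` from it. The most basal
#' electrode (the highest-numbered one, carrying the highest-frequency
#' channel) sits perpendicular to the 0 mm neural location and electrodes
#' are spaced `pitch_mm` apart toward the apex, so electrode `e` lies at
#' `(n_electrodes - e) * pitch_mm` along the nerve axis. With the defaults
#' the 22-electrode array spans 15.75 mm.
#'
#' @param n_electrodes number of electrodes.
#' @param pitch_mm inter-electrode spacing, mm.
#' @param array_to_nerve_mm perpendicular array-to-nerve distance, mm.
#' @return An object of class `"array_geometry"` with an
#'   `electrode_positions_mm` element.
#' @export
array_geometry <- function(n_electrodes = 22, pitch_mm = 0.75,
                           array_to_nerve_mm = 1) {
  stopifnot(n_electrodes >= 1, pitch_mm > 0, array_to_nerve_mm > 0)
  structure(
    list(n_electrodes = n_electrodes, pitch_mm = pitch_mm,
         array_to_nerve_mm = array_to_nerve_mm,
         electrode_positions_mm = (n_electrodes - seq_len(n_electrodes)) *
           pitch_mm),
    class = "array_geometry")
}

#' Inverse-law spread weights
#'
#' The contribution of electrode `e` to neural position `x` scales as
#' `array_to_nerve / d(x, e)` with `d = sqrt(array_to_nerve^2 + (x - x_e)^2)`,
#' so a position directly opposite an electrode receives unit weight and the
#' weight decays monotonically and symmetrically with axial distance.
#'
#' @param geom an [array_geometry()].
#' @param positions_mm neural positions along the nerve axis, mm.
#' @return A positions-by-electrodes weight matrix.
#' @export
spread_weights <- function(geom, positions_mm) {
  stopifnot(inherits(geom, "array_geometry"), all(is.finite(positions_mm)))
  a <- geom$array_to_nerve_mm
  dx <- outer(positions_mm, geom$electrode_positions_mm, `-`)
  a / sqrt(a^2 + dx^2)
}

#' Render an electrodogram to per-electrode current waveforms
#'
#' Each pulse becomes a rectangular cathodic phase (rendered with positive
#' sign, the excitatory convention used throughout), the interphase gap, and
#' a rectangular anodic phase of opposite sign, on a 1 us time grid.
#' Overlapping pulses superpose linearly.
#'
#' @param eg an `"electrodogram"`.
#' @param duration_us grid length; defaults to the electrodogram duration
#'   extended by one pulse footprint.
#' @return A samples-by-electrodes matrix (1 us grid), in the amplitude unit
#'   of the electrodogram (mA).
#' @export
render_electrodogram <- function(eg, duration_us = NULL) {
  stopifnot(inherits(eg, "electrodogram"))
  params <- eg$params
  if (is.null(duration_us))
    duration_us <- ceiling(eg$duration_us + pulse_footprint_us(params))
  n <- as.integer(duration_us)
  ne <- eg$n_channels
  E <- matrix(0, n, ne)
  ph <- as.integer(params$phase_us)
  gap <- as.integer(params$gap_us)
  p <- eg$pulses
  for (i in seq_len(nrow(p))) {
    t0 <- as.integer(p$time_us[i]) + 1L  # 1-based grid bin
    a <- p$amplitude[i]
    e <- p$electrode[i]
    i1 <- t0:min(n, t0 + ph - 1L)
    E[i1, e] <- E[i1, e] + a
    t2 <- t0 + ph + gap
    if (t2 <= n) {
      i2 <- t2:min(n, t2 + ph - 1L)
      E[i2, e] <- E[i2, e] - a
    }
  }
  E
}

## global peak of |W E'| without materializing the full field matrix
field_peak <- function(E, W, chunk = 64L) {
  pk <- 0
  for (s in seq(1, nrow(W), by = chunk)) {
    rows <- s:min(nrow(W), s + chunk - 1L)
    pk <- max(pk, max(abs(E %*% t(W[rows, , drop = FALSE]))))
  }
  pk
}

#' Current spread: effective current at neural positions
#'
#' Sums the inverse-law-weighted contributions of all electrodes at each
#' neural position ([spread_weights()]), rendering pulses as rectangular
#' biphasic waveforms on a 1 us grid, then rescales the whole field so that
#' its global peak equals `norm_level` (1 mA by default, applied per
#' stimulus). An empty electrodogram yields a valid all-zero field.
#'
#' @param eg an `"electrodogram"`.
#' @param geom an [array_geometry()].
#' @param positions_mm neural positions, mm.
#' @param norm_level post-spread peak level, mA.
#' @param normalize set `FALSE` to keep the raw superposed field (the raw
#'   field is homogeneous of degree 1 in the pulse amplitudes).
#' @return An object of class `"field_traces"`: list with `current`
#'   (samples x positions matrix, 1 us grid), `positions_mm`, `scale` (the
#'   normalization factor applied), `pulse_times_us`, `params` and `geom`.
#' @export
spread <- function(eg, geom = array_geometry(), positions_mm,
                   norm_level = 1, normalize = TRUE) {
  stopifnot(inherits(eg, "electrodogram"), norm_level > 0)
  stopifnot(max(eg$pulses$electrode, 0) <= geom$n_electrodes)
  W <- spread_weights(geom, positions_mm)
  E <- render_electrodogram(eg)
  field <- E %*% t(W)
  scale <- 1
  if (normalize && nrow(eg$pulses) > 0) {
    pk <- max(abs(field))
    if (pk > 0) scale <- norm_level / pk
  }
  structure(
    list(current = field * scale, positions_mm = positions_mm, scale = scale,
         pulse_times_us = sort(unique(eg$pulses$time_us)),
         params = eg$params, geom = geom),
    class = "field_traces")
}

#' @export
print.field_traces <- function(x, ...) {
  cat(sprintf(
    "<field_traces> %d positions x %d us, peak %.3g mA\n",
    length(x$positions_mm), nrow(x$current), max(abs(x$current))))
  invisible(x)
}

#' Extract one position as a field trace
#'
#' @param ft a [spread()] result.
#' @param i position index.
#' @return An object of class `"field_trace"` (single position).
#' @export
field_trace_at <- function(ft, i) {
  stopifnot(inherits(ft, "field_traces"))
  field_trace(ft$current[, i], ft$pulse_times_us, ft$params,
              position_mm = ft$positions_mm[i])
}

#' Construct a single field trace directly
#'
#' Mostly useful for driving the fiber model with hand-built stimuli (e.g. an
#' isolated pulse) or with pulse tables loaded from disk.
#'
#' @param current effective current on the 1 us grid, mA.
#' @param pulse_times_us pulse onset times, us (the fiber model evaluates its
#'   membrane state at the end of each pulse's cathodic phase).
#' @param params the [pulse_params()] the trace was rendered with.
#' @param position_mm neural position label, mm.
#' @return An object of class `"field_trace"`.
#' @export
field_trace <- function(current, pulse_times_us, params = pulse_params(),
                        position_mm = 0) {
  structure(list(current = as.numeric(current),
                 pulse_times_us = sort(pulse_times_us), params = params,
                 position_mm = position_mm),
            class = "field_trace")
}

#' Write field traces as long-format CSV
#'
#' Columns `position_mm, time_us, current_mA`.
#'
#' @param ft a [spread()] result.
#' @param path output CSV path.
#' @param thin keep every `thin`-th time sample (the 1 us grid is dense).
#' @return `path`, invisibly.
#' @export
write_field_traces <- function(ft, path, thin = 1L) {
  stopifnot(inherits(ft, "field_traces"))
  keep <- seq(1, nrow(ft$current), by = thin)
  df <- data.frame(
    position_mm = rep(ft$positions_mm, each = length(keep)),
    time_us = rep(keep - 1L, times = length(ft$positions_mm)),
    current_mA = as.vector(ft$current[keep, ]))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
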