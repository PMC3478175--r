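#' Construct an event raster
#'
#' An event raster is the discrete intermediate of the pipeline: per-channel
#' event time-points ("digital units"), stored as a tibble with columns
#' `channel` (0-based electrode index) and `time_s` (seconds), sorted by
#' channel then time, carrying `n_channels` and `duration_s` as attributes.
#'
#' @param events A data frame with columns `channel` and `time_s`.
#' @param n_channels Number of electrodes (events may use only a subset).
#' @param duration_s Recording duration in seconds; all times must lie in
#'   `[0, duration_s)`.
#' @return A tibble of class `event_raster`.
#' @export
event_raster <- function(events, n_channels, duration_s) {
  events <- tibble::as_tibble(events)
  stopifnot(all(c("channel", "time_s") %in% names(events)))
  events <- dplyr::arrange(events[c("channel", "time_s")],
                           .data$channel, .data$time_s)
  if (nrow(events) > 0) {
    if (any(events$channel < 0) || any(events$channel >= n_channels))
      abort("event raster: channel indices must be in [0, n_channels)")
    if (any(events$time_s < 0) || any(events$time_s >= duration_s))
      abort("event raster: times must lie in [0, duration_s)")
  }
  structure(events,
            n_channels = as.integer(n_channels),
            duration_s = as.numeric(duration_s),
            class = c("event_raster", class(tibble::tibble())))
}

#' @export
print.event_raster <- function(x, ...) {
  cat(sprintf("<event_raster> %d events, %d channels, %.3g s\n",
              nrow(x), attr(x, "n_channels"), attr(x, "duration_s")))
  NextMethod()
}

raster_n_channels <- function(raster, n_channels = NULL) {
  n_channels %||% attr(raster, "n_channels") %||%
    (if (nrow(raster)) max(raster$channel) + 1L else
       abort("event raster: `n_channels` unknown; pass it explicitly"))
}

raster_duration <- function(raster, duration_s = NULL) {
  duration_s %||% attr(raster, "duration_s") %||%
    (if (nrow(raster)) max(raster$time_s) else
       abort("event raster: `duration_s` unknown; pass it explicitly"))
}
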