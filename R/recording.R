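#' Construct a multichannel recording
#'
#' A recording is a channel x time matrix of extracellular field potential
#' in microvolts plus its acquisition metadata: sampling rate, electrode
#' grid geometry and condition/session labels.
#'
#' @param samples Numeric matrix, channels in rows, samples in columns.
#' @param sampling_rate_hz Samples per second, `> 0`.
#' @param grid_shape Integer `c(rows, cols)` with `rows * cols == nrow(samples)`.
#'   Channel indices are 0-based row-major over this grid.
#' @param condition,session_id Labels.
#' @param provenance Optional list of generator/analysis configuration
#'   echoed through the pipeline.
#' @return A list of class `recording`.
#' @export
recording <- function(samples, sampling_rate_hz, grid_shape,
                      condition = "unlabeled", session_id = "s1",
                      provenance = list()) {
  if (!is.matrix(samples) || !is.numeric(samples))
    abort("recording: `samples` must be a numeric channel x time matrix")
  if (!is.numeric(sampling_rate_hz) || sampling_rate_hz <= 0)
    abort("recording: `sampling_rate_hz` must be > 0")
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 2L || prod(grid_shape) != nrow(samples))
    abort("recording: grid_shape rows x cols must equal the channel count")
  structure(
    list(samples = samples, sampling_rate_hz = sampling_rate_hz,
         grid_shape = grid_shape, condition = condition,
         session_id = session_id, provenance = provenance),
    class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf(
    "<recording> %d channels (%d x %d grid) x %d samples @ %g Hz (%.3g s)\n  condition: %s   session: %s\n",
    nrow(x$samples), x$grid_shape[1], x$grid_shape[2], ncol(x$samples),
    x$sampling_rate_hz, ncol(x$samples) / x$sampling_rate_hz,
    x$condition, x$session_id))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param x A [recording()].
#' @return Length in seconds.
#' @export
recording_duration <- function(x) {
  stopifnot(inherits(x, "recording"))
  ncol(x$samples) / x$sampling_rate_hz
}
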