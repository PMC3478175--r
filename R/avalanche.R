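#' Bin an event raster into frames
#'
#' Divides the session into consecutive frames of width `bin_ms`
#' (default 4 ms) aligned to `t = 0`, with half-open intervals
#' `[i * bin, (i + 1) * bin)`: an event exactly on a boundary belongs to
#' the later frame. A channel is active in a frame if it has at least one
#' event there; multiple events of one channel within a frame count once.
#'
#' @param raster An [event_raster()] (or a tibble with `channel`/`time_s`).
#' @param bin_ms Frame width in milliseconds.
#' @param n_channels,duration_s Overrides for rasters lacking metadata.
#' @return A tibble of class `frame_sequence` with columns `frame`
#'   (0-based) and `channel`, one row per active (frame, channel) pair,
#'   with attributes `bin_ms`, `n_frames`, `n_channels`.
#' @export
bin_raster <- function(raster, bin_ms = 4, n_channels = NULL, duration_s = NULL) {
  if (bin_ms <= 0) abort("invalid parameter: `bin_ms` must be > 0")
  n_ch <- raster_n_channels(raster, n_channels)
  dur <- raster_duration(raster, duration_s)
  n_frames <- as.integer(ceiling(dur * 1000 / bin_ms))
  frames <- tibble::tibble(
    frame = as.integer(floor(raster$time_s * 1000 / bin_ms)),
    channel = raster$channel)
  frames <- dplyr::arrange(dplyr::distinct(frames), .data$frame, .data$channel)
  structure(frames, bin_ms = bin_ms, n_frames = n_frames,
            n_channels = n_ch,
            class = c("frame_sequence", class(tibble::tibble())))
}

#' Extract avalanches from a frame sequence
#'
#' An avalanche is a maximal run of consecutive non-empty frames, bounded
#' by empty (blank) frames or by the sequence ends. Its size is the number
#' of active channels summed over its frames, so one channel active in two
#' consecutive frames contributes 2.
#'
#' @param frames A `frame_sequence` from [bin_raster()].
#' @param drop_boundary Drop avalanches touching the first or last frame
#'   of the sequence (default `FALSE`: kept).
#' @return A tibble of class `avalanche_set` with columns `start_frame`
#'   (0-based), `duration_frames`, `size`, carrying `n_frames` and
#'   `bin_ms` attributes.
#' @export
extract_avalanches <- function(frames, drop_boundary = FALSE) {
  n_frames <- attr(frames, "n_frames") %||%
    (if (nrow(frames)) max(frames$frame) + 1L else 0L)
  per_frame <- dplyr::count(tibble::as_tibble(frames), .data$frame, name = "n_active")
  per_frame <- dplyr::arrange(per_frame, .data$frame)
  if (nrow(per_frame) == 0) {
    av <- tibble::tibble(start_frame = integer(0),
                         duration_frames = integer(0), size = integer(0))
  } else {
    run <- cumsum(c(1L, diff(per_frame$frame) > 1L))
    av <- dplyr::summarise(
      dplyr::group_by(dplyr::mutate(per_frame, run = run), run),
      start_frame = dplyr::first(.data$frame),
      duration_frames = dplyr::last(.data$frame) - dplyr::first(.data$frame) + 1L,
      size = sum(.data$n_active), .groups = "drop")
    av <- dplyr::select(av, -"run")
    if (drop_boundary)
      av <- dplyr::filter(av, .data$start_frame > 0L,
                          .data$start_frame + .data$duration_frames < n_frames)
  }
  structure(av, n_frames = n_frames, bin_ms = attr(frames, "bin_ms"),
            class = c("avalanche_set", class(tibble::tibble())))
}

#' Avalanche size distribution
#'
#' Tabulates the occurrence count and probability of each observed
#' avalanche size. On log-log axes this distribution is the object the
#' power-law fit is applied to.
#'
#' @param avalanches An `avalanche_set` from [extract_avalanches()] (or
#'   any data frame with a `size` column, or a bare integer vector of
#'   sizes).
#' @return A tibble of class `size_distribution` with columns `size`,
#'   `count`, `probability` (summing to 1), and attribute `n_avalanches`.
#' @export
size_distribution <- function(avalanches) {
  sizes <- if (is.numeric(avalanches)) avalanches else avalanches$size
  if (length(sizes) == 0) abort("no avalanches: cannot build a size distribution")
  tab <- dplyr::count(tibble::tibble(size = as.integer(sizes)),
                      .data$size, name = "count")
  tab <- dplyr::mutate(dplyr::arrange(tab, .data$size),
                       probability = .data$count / sum(.data$count))
  structure(tab, n_avalanches = length(sizes),
            class = c("size_distribution", class(tibble::tibble())))
}
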