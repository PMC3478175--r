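#' Write / read a recording container
#'
#' A recording is stored as a raw float64 little-endian channel x time
#' matrix (`<path>.bin`, channel-major: each channel's samples are
#' contiguous) plus a JSON sidecar (`<path>.json`) carrying the sampling
#' rate, grid geometry, labels and any generator provenance including
#' seeds. The round trip is lossless.
#'
#' @param rec A [recording()].
#' @param path Base path without extension; `.bin` and `.json` are added.
#' @return `write_recording` returns `path` invisibly; `read_recording`
#'   returns a [recording()].
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "recording"))
  con <- file(paste0(path, ".bin"), "wb")
  on.exit(close(con))
  writeBin(as.vector(t(rec$samples)), con, size = 8, endian = "little")
  meta <- list(
    n_channels = nrow(rec$samples), n_samples = ncol(rec$samples),
    sampling_rate_hz = rec$sampling_rate_hz,
    grid_shape = rec$grid_shape, condition = rec$condition,
    session_id = rec$session_id, dtype = "float64", endian = "little",
    provenance = rec$provenance)
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  sidecar <- paste0(path, ".json")
  binfile <- paste0(path, ".bin")
  if (!file.exists(sidecar))
    abort(paste0("missing metadata: no JSON sidecar at ", sidecar))
  if (!file.exists(binfile))
    abort(paste0("corrupt container: no .bin file at ", binfile))
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (is.null(meta$sampling_rate_hz) || meta$sampling_rate_hz <= 0)
    abort("corrupt container: sampling_rate_hz must be > 0")
  n_val <- meta$n_channels * meta$n_samples
  if (file.info(binfile)$size != 8 * n_val)
    abort("corrupt container: .bin size does not match sidecar shape")
  con <- file(binfile, "rb")
  on.exit(close(con))
  vals <- readBin(con, numeric(), n = n_val, size = 8, endian = "little")
  samples <- matrix(vals, nrow = meta$n_channels, byrow = TRUE)
  recording(samples, meta$sampling_rate_hz, meta$grid_shape,
            condition = meta$condition %||% "unlabeled",
            session_id = meta$session_id %||% "s1",
            provenance = as.list(meta$provenance))
}

#' Write / read an event raster CSV
#'
#' Columns `channel_index` (0-based) and `time_s`; the channel count and
#' duration ride on a `#`-prefixed header line so the raster metadata
#' survives the round trip.
#'
#' @param raster An [event_raster()].
#' @param path CSV file path.
#' @param n_channels,duration_s Overrides when reading a bare CSV without
#'   the metadata header.
#' @return `write_raster` returns `path` invisibly; `read_raster` an
#'   [event_raster()].
#' @export
write_raster <- function(raster, path) {
  n_ch <- raster_n_channels(raster)
  dur <- raster_duration(raster)
  writeLines(sprintf("# n_channels=%d duration_s=%.17g", n_ch, dur), path)
  readr::write_csv(
    tibble::tibble(channel_index = raster$channel, time_s = raster$time_s),
    path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_raster
#' @export
read_raster <- function(path, n_channels = NULL, duration_s = NULL) {
  first <- readLines(path, n = 1L)
  if (startsWith(first, "#")) {
    m <- regmatches(first, regexec("n_channels=([0-9]+) duration_s=([0-9.eE+-]+)", first))[[1]]
    if (length(m) == 3) {
      n_channels <- n_channels %||% as.integer(m[[2]])
      duration_s <- duration_s %||% as.numeric(m[[3]])
    }
  }
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  if (!all(c("channel_index", "time_s") %in% names(df)))
    abort("read_raster: need columns channel_index, time_s")
  if (is.null(n_channels)) n_channels <- max(df$channel_index, 0L) + 1L
  if (is.null(duration_s)) duration_s <- if (nrow(df)) max(df$time_s) * (1 + 1e-12) else 0
  event_raster(tibble::tibble(channel = as.integer(df$channel_index),
                              time_s = df$time_s),
               n_channels = n_channels, duration_s = duration_s)
}

#' Write / read avalanche and distribution tables
#'
#' Plain CSV: avalanches as `start_frame,duration_frames,size`, size
#' distributions as `size,count,probability`.
#'
#' @param x An `avalanche_set` or `size_distribution` tibble.
#' @param path CSV file path.
#' @return The written path, invisibly.
#' @export
write_table_csv <- function(x, path) {
  readr::write_csv(tibble::as_tibble(x), path)
  invisible(path)
}

#' Write a power-law fit as JSON
#'
#' @param fit A `powerlaw_fit` from [fit_powerlaw()].
#' @param path JSON file path.
#' @return The path, invisibly.
#' @export
write_fit <- function(fit, path) {
  stopifnot(inherits(fit, "powerlaw_fit"))
  out <- fit[c("alpha", "intercept", "r_squared", "fit_min", "fit_max",
               "n_sizes_used", "n_avalanches", "accepted", "r2_threshold")]
  out$provenance <- fit$provenance
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Serialize / restore a pipeline configuration
#'
#' The full [pipeline_config()] round-trips losslessly through a single
#' JSON document.
#'
#' @param config A [pipeline_config()].
#' @param path JSON file path.
#' @return `write_pipeline_config` the path invisibly;
#'   `read_pipeline_config` a [pipeline_config()].
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  jsonlite::write_json(
    list(detection = unclass(config$detection), bin_ms = config$bin_ms,
         fit = unclass(config$fit), alpha_level = config$alpha_level,
         drop_boundary = config$drop_boundary, rng_seed = config$rng_seed),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  pipeline_config(
    detection = do.call(detection_config, x$detection),
    bin_ms = x$bin_ms,
    fit = do.call(fit_config, x$fit),
    alpha_level = x$alpha_level,
    drop_boundary = isTRUE(x$drop_boundary),
    rng_seed = x$rng_seed)
}
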