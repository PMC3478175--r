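#' Branching-process generator configuration
#'
#' Parameters of the electrode-grid branching process used to generate
#' ground-truth event rasters. Each active unit in one generative frame
#' spawns `Poisson(sigma)` offspring in the next frame; new cascades are
#' seeded by a Poisson process at `seed_rate`. `sigma` is the branching
#' parameter: `sigma = 1` is the critical point, `sigma < 1` subcritical.
#'
#' In `"unconstrained"` mode offspring are abstract events (the total
#' progeny of one cascade is then exactly Borel-distributed, see
#' [borel_pmf()]); in `"mapped"` mode every event lands on one of
#' `n_channels` electrodes and an electrode is active at most once per
#' frame, matching the per-channel-per-frame semantics of nLFP detection.
#'
#' @param sigma Branching parameter (expected offspring per active unit),
#'   `>= 0`. Values above 1.3 are rejected in unconstrained mode (runaway
#'   cascades).
#' @param seed_rate Cascade-initiation rate, events per second across the
#'   whole array. Default 20/s, i.e. 0.08 expected seeds per 4 ms frame.
#' @param n_channels Number of electrodes (default 32, a 4 x 8 grid).
#' @param bin_ms Generative time step in milliseconds (default 4).
#' @param duration_s Session length in seconds.
#' @param rng_seed Integer seed for all randomness in the simulation.
#' @param mode `"unconstrained"` or `"mapped"` (see Details).
#' @param max_avalanche_size Cap on single-cascade size in unconstrained
#'   mode; a cascade exceeding it is terminated and counted as truncated.
#'   Sizes at the head of the distribution are unaffected.
#'
#' @return A list of class `branching_config`.
#' @seealso [simulate_branching()]
#' @export
branching_config <- function(sigma,
                             seed_rate = 20,
                             n_channels = 32L,
                             bin_ms = 4,
                             duration_s = 60,
                             rng_seed = 1L,
                             mode = c("unconstrained", "mapped"),
                             max_avalanche_size = 1e4) {
  mode <- match.arg(mode)
  if (!is.numeric(sigma) || length(sigma) != 1L || is.na(sigma) || sigma < 0)
    abort("invalid parameter: `sigma` must be a single number >= 0")
  if (!is.numeric(seed_rate) || seed_rate <= 0)
    abort("invalid parameter: `seed_rate` must be > 0")
  if (!is.numeric(duration_s) || duration_s <= 0)
    abort("invalid parameter: `duration_s` must be > 0")
  if (!is.numeric(n_channels) || n_channels < 2)
    abort("invalid parameter: `n_channels` must be >= 2")
  if (!is.numeric(bin_ms) || bin_ms <= 0)
    abort("invalid parameter: `bin_ms` must be > 0")
  if (mode == "unconstrained" && sigma > 1.3)
    abort("supercritical runaway: `sigma` > 1.3 is rejected in unconstrained mode")
  structure(
    list(sigma = sigma, seed_rate = seed_rate,
         n_channels = as.integer(n_channels), bin_ms = bin_ms,
         duration_s = duration_s, rng_seed = as.integer(rng_seed),
         mode = mode, max_avalanche_size = max_avalanche_size),
    class = "branching_config"
  )
}

#' LFP rendering configuration
#'
#' Parameters used to turn a discrete event raster into a continuous
#' multichannel recording: each event becomes an inverted-Gaussian negative
#' deflection (an nLFP) added on top of independent 10-200 Hz band-limited
#' Gaussian noise.
#'
#' @param sampling_rate_hz Samples per second (default 40000, the standard
#'   acquisition rate for this kind of recording; analyses in the package's
#'   examples use 4000 Hz, which comfortably oversamples the 10-200 Hz band).
#' @param template_amplitude_uv Peak depth of the nLFP deflection in
#'   microvolts (positive number; the deflection is negative).
#' @param template_width_ms Full width of the deflection template in ms;
#'   the template is an inverted Gaussian truncated at `+/- width/2` with
#'   `sd = width/6`.
#' @param noise_sd_uv Standard deviation of the band-limited noise in
#'   microvolts after 10-200 Hz filtering (0 disables noise).
#' @param rng_seed Integer seed for the noise generator.
#'
#' @return A list of class `render_config`.
#' @seealso [render_lfp()]
#' @export
render_config <- function(sampling_rate_hz = 40000,
                          template_amplitude_uv = 80,
                          template_width_ms = 20,
                          noise_sd_uv = 10,
                          rng_seed = 1L) {
  if (!is.numeric(sampling_rate_hz) || sampling_rate_hz <= 0)
    abort("invalid parameter: `sampling_rate_hz` must be > 0")
  if (!is.numeric(template_amplitude_uv) || template_amplitude_uv <= 0)
    abort("invalid parameter: `template_amplitude_uv` must be > 0")
  if (!is.numeric(template_width_ms) || template_width_ms <= 0)
    abort("invalid parameter: `template_width_ms` must be > 0")
  if (!is.numeric(noise_sd_uv) || noise_sd_uv < 0)
    abort("invalid parameter: `noise_sd_uv` must be >= 0")
  structure(
    list(sampling_rate_hz = sampling_rate_hz,
         template_amplitude_uv = template_amplitude_uv,
         template_width_ms = template_width_ms,
         noise_sd_uv = noise_sd_uv,
         rng_seed = as.integer(rng_seed)),
    class = "render_config"
  )
}

#' nLFP detection configuration
#'
#' @param band_low_hz,band_high_hz Band-pass edges in Hz (default 10-200).
#' @param k_sd Threshold multiplier: an event is a crossing below
#'   `-k_sd * SD` of the filtered trace (default 4).
#' @param refractory_ms Minimum within-channel separation between events in
#'   ms (default 10, the template scale), so one deflection cannot yield
#'   several crossings.
#' @param sd_estimator `"robust"` (scaled median absolute deviation,
#'   resistant to contamination by the events themselves; default) or
#'   `"global"` (plain sample SD of the whole trace).
#' @param time_at Report events at the threshold `"crossing"` sample
#'   (default) or at the `"trough"` of the excursion, located as the
#'   depth-weighted centroid of the below-threshold excursion on a
#'   Gaussian-smoothed copy of the trace (robust to noise riding on the
#'   deflection).
#' @param trough_smooth_ms Gaussian smoothing SD (ms) used only for trough
#'   localization; default 3.3 ms, the timescale of a ~20 ms nLFP
#'   deflection.
#'
#' @return A list of class `detection_config`.
#' @seealso [detect_nlfp()]
#' @export
detection_config <- function(band_low_hz = 10,
                             band_high_hz = 200,
                             k_sd = 4,
                             refractory_ms = 10,
                             sd_estimator = c("robust", "global"),
                             time_at = c("crossing", "trough"),
                             trough_smooth_ms = 3.3) {
  sd_estimator <- match.arg(sd_estimator)
  time_at <- match.arg(time_at)
  if (!is.numeric(trough_smooth_ms) || trough_smooth_ms <= 0)
    abort("invalid parameter: `trough_smooth_ms` must be > 0")
  if (!is.numeric(band_low_hz) || !is.numeric(band_high_hz) ||
      band_low_hz <= 0 || band_high_hz <= band_low_hz)
    abort("invalid band: need 0 < band_low_hz < band_high_hz")
  if (!is.numeric(k_sd) || k_sd <= 0)
    abort("invalid threshold: `k_sd` must be > 0")
  if (!is.numeric(refractory_ms) || refractory_ms < 0)
    abort("invalid parameter: `refractory_ms` must be >= 0")
  structure(
    list(band_low_hz = band_low_hz, band_high_hz = band_high_hz,
         k_sd = k_sd, refractory_ms = refractory_ms,
         sd_estimator = sd_estimator, time_at = time_at,
         trough_smooth_ms = trough_smooth_ms),
    class = "detection_config"
  )
}

#' Power-law fit configuration
#'
#' @param fit_min,fit_max Avalanche-size range entering the straight-line
#'   fit (defaults 1 and 10).
#' @param r2_threshold Acceptance criterion on the coefficient of
#'   determination of the log-log fit (default 0.9).
#' @param zero_policy Sizes inside the range with zero observed count have
#'   no defined log-probability: `"skip"` (default) drops them, `"fail"`
#'   raises an error.
#'
#' @return A list of class `fit_config`.
#' @seealso [fit_powerlaw()]
#' @export
fit_config <- function(fit_min = 1L,
                       fit_max = 10L,
                       r2_threshold = 0.9,
                       zero_policy = c("skip", "fail")) {
  zero_policy <- match.arg(zero_policy)
  if (!is.numeric(fit_min) || fit_min < 1)
    abort("invalid parameter: `fit_min` must be >= 1")
  if (!is.numeric(fit_max) || fit_max <= fit_min)
    abort("invalid parameter: need fit_min < fit_max")
  if (!is.numeric(r2_threshold) || r2_threshold <= 0 || r2_threshold > 1)
    abort("invalid parameter: `r2_threshold` must be in (0, 1]")
  structure(
    list(fit_min = as.integer(fit_min), fit_max = as.integer(fit_max),
         r2_threshold = r2_threshold, zero_policy = zero_policy),
    class = "fit_config"
  )
}

#' Full pipeline configuration
#'
#' Bundles the per-stage configurations of the recording -> alpha pipeline.
#' The defaults reproduce the canonical analysis parameters: 10-200 Hz
#' band-pass, 4 x SD negative threshold, 4 ms frames, straight-line fit
#' over sizes 1-10 with R-squared acceptance at 0.9, and a 0.05
#' significance level for group comparisons.
#'
#' @param detection A [detection_config()].
#' @param bin_ms Frame width for avalanche binning in ms (default 4).
#' @param fit A [fit_config()].
#' @param alpha_level Significance level for group comparisons.
#' @param drop_boundary Drop avalanches touching the session boundary
#'   (default `FALSE`, they are kept).
#' @param rng_seed Optional integer seed recorded for provenance.
#'
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(detection = detection_config(),
                            bin_ms = 4,
                            fit = fit_config(),
                            alpha_level = 0.05,
                            drop_boundary = FALSE,
                            rng_seed = NULL) {
  stopifnot(inherits(detection, "detection_config"), inherits(fit, "fit_config"))
  if (!is.numeric(bin_ms) || bin_ms <= 0)
    abort("invalid parameter: `bin_ms` must be > 0")
  if (!is.numeric(alpha_level) || alpha_level <= 0 || alpha_level >= 1)
    abort("invalid parameter: `alpha_level` must be in (0, 1)")
  structure(
    list(detection = detection, bin_ms = bin_ms, fit = fit,
         alpha_level = alpha_level, drop_boundary = isTRUE(drop_boundary),
         rng_seed = if (!is.null(rng_seed)) as.integer(rng_seed)),
    class = "pipeline_config"
  )
}
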