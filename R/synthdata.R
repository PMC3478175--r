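#' Simulate an electrode-grid branching process
#'
#' Generates a ground-truth event raster from a discrete-time branching
#' process on the generative frame grid. Cascades are seeded by a Poisson
#' process at `config$seed_rate`; every event active in frame `t` spawns
#' `Poisson(sigma)` offspring events in frame `t + 1`. An avalanche is a
#' maximal run of consecutive non-empty frames, so cascade seeds arriving
#' while another cascade is still active merge into the same avalanche
#' (rare at the default seed rate).
#'
#' In `"mapped"` mode every event is placed on a uniformly random
#' electrode and electrodes are deduplicated within a frame (an electrode
#' is active or not), so at most `n_channels` events occupy one frame. In
#' `"unconstrained"` mode events are abstract: isolated cascades then have
#' exactly Borel-distributed total progeny ([borel_pmf()]), which the test
#' suite exploits as an analytic oracle. Raster channels are still drawn
#' uniformly so the raster can be rendered.
#'
#' Critical and near-critical cascades have heavy-tailed sizes; in
#' unconstrained mode a cascade reaching `config$max_avalanche_size`
#' events is terminated and reported with `truncated = TRUE`. The head of
#' the size distribution (the fitted range) is unaffected.
#'
#' @param config A [branching_config()].
#' @param return_raster Build the per-event raster (default `TRUE`). Set
#'   to `FALSE` for large oracle runs where only ground-truth avalanche
#'   sizes are needed.
#' @return A list of class `branching_sim` with elements `raster` (an
#'   [event_raster()], or `NULL`), `avalanches` (tibble: `start_frame`
#'   0-based, `duration_frames`, `size`, `truncated`) and `config`.
#' @examples
#' sim <- simulate_branching(branching_config(sigma = 0.5, duration_s = 20,
#'                                            rng_seed = 42))
#' mean(sim$avalanches$size)  # ~ 1 / (1 - sigma) = 2
#' @export
simulate_branching <- function(config, return_raster = TRUE) {
  stopifnot(inherits(config, "branching_config"))
  n_frames <- as.integer(ceiling(config$duration_s * 1000 / config$bin_ms))
  mu <- config$seed_rate * config$bin_ms / 1000
  mapped <- config$mode == "mapped"
  n_ch <- config$n_channels

  withr::with_seed(config$rng_seed, {
    # per-avalanche accumulators
    av_start <- integer(0); av_dur <- integer(0); av_size <- integer(0)
    av_trunc <- logical(0)
    ev_frame <- vector("list", 0); ev_chan <- vector("list", 0)
    frame <- 0L            # next frame to fill, 0-based
    active <- 0L           # event count in previous frame
    active_set <- integer(0)
    cur_start <- NA_integer_; cur_size <- 0L; cur_trunc <- FALSE
    chunk <- 4096L

    close_avalanche <- function(end_frame) {
      av_start[[length(av_start) + 1L]] <<- cur_start
      av_dur[[length(av_dur) + 1L]] <<- end_frame - cur_start
      av_size[[length(av_size) + 1L]] <<- cur_size
      av_trunc[[length(av_trunc) + 1L]] <<- cur_trunc
      cur_start <<- NA_integer_; cur_size <<- 0L; cur_trunc <<- FALSE
    }

    while (frame < n_frames) {
      if (active == 0L) {
        # vectorized scan of quiescent frames for the next seeded frame
        n_scan <- min(chunk, n_frames - frame)
        seeds <- rpois(n_scan, mu)
        hit <- which(seeds > 0L)
        if (length(hit) == 0L) { frame <- frame + n_scan; next }
        k <- hit[[1L]]
        frame <- frame + k            # frame index (0-based) = frame + k - 1
        n_new <- seeds[[k]]
        cur_start <- frame - 1L
      } else {
        n_new <- rpois(1L, config$sigma * active) + rpois(1L, mu)
        frame <- frame + 1L
      }
      this_frame <- frame - 1L
      if (n_new > 0L) {
        if (mapped) {
          set <- unique(sample.int(n_ch, n_new, replace = TRUE))
          active <- length(set)
          active_set <- set
        } else {
          active <- n_new
        }
        if (is.na(cur_start)) cur_start <- this_frame
        cur_size <- cur_size + active
        if (return_raster && active > 0L) {
          ev_frame[[length(ev_frame) + 1L]] <- rep.int(this_frame, active)
          ev_chan[[length(ev_chan) + 1L]] <-
            if (mapped) active_set - 1L else
              sample.int(n_ch, active, replace = TRUE) - 1L
        }
        if (!mapped && cur_size >= config$max_avalanche_size) {
          cur_trunc <- TRUE
          active <- 0L
          close_avalanche(frame)
        }
      } else {
        active <- 0L
        if (!is.na(cur_start)) close_avalanche(this_frame)
      }
    }
    if (!is.na(cur_start)) close_avalanche(n_frames)  # boundary avalanche

    avalanches <- tibble::tibble(
      start_frame = av_start, duration_frames = av_dur,
      size = av_size, truncated = av_trunc)
    raster <- NULL
    if (return_raster) {
      bin_s <- config$bin_ms / 1000
      raster <- event_raster(
        tibble::tibble(
          channel = unlist(ev_chan, use.names = FALSE) %||% integer(0),
          time_s  = (unlist(ev_frame, use.names = FALSE) %||% numeric(0) + 0.5) * bin_s),
        n_channels = n_ch,
        duration_s = n_frames * bin_s)
    }
    structure(list(raster = raster, avalanches = avalanches, config = config),
              class = "branching_sim")
  })
}

#' @export
print.branching_sim <- function(x, ...) {
  cat(sprintf(
    "<branching_sim> sigma=%.3g (%s), %d avalanches, %s events, %.3g s\n",
    x$config$sigma, x$config$mode, nrow(x$avalanches),
    if (is.null(x$raster)) "un-rastered" else format(nrow(x$raster)),
    x$config$duration_s))
  invisible(x)
}

#' Render an event raster into a continuous LFP recording
#'
#' Each event becomes a negative deflection (inverted Gaussian template of
#' peak depth `-template_amplitude_uv` and full width `template_width_ms`)
#' added at the event time on its channel, on top of independent 10-200 Hz
#' band-limited Gaussian noise rescaled to `noise_sd_uv`. Overlapping
#' templates sum; events whose template would extend past the recording
#' edge are clipped with a warning.
#'
#' @param raster An [event_raster()].
#' @param config A [render_config()].
#' @param grid_shape Electrode grid as `c(rows, cols)`; must multiply to
#'   the raster's channel count. Default lays channels on 4 rows.
#' @param condition,session_id Labels carried on the recording.
#' @return A [recording()].
#' @export
render_lfp <- function(raster, config = render_config(),
                       grid_shape = NULL,
                       condition = "unlabeled", session_id = "s1") {
  stopifnot(inherits(config, "render_config"))
  n_ch <- raster_n_channels(raster)
  duration_s <- raster_duration(raster)
  fs <- config$sampling_rate_hz
  n_samp <- as.integer(round(duration_s * fs))
  grid_shape <- grid_shape %||%
    (if (n_ch %% 4L == 0L) c(4L, n_ch %/% 4L) else c(1L, n_ch))
  if (prod(grid_shape) != n_ch)
    abort("render_lfp: grid_shape rows x cols must equal the channel count")

  # inverted-Gaussian nLFP template, truncated at +/- width/2
  hw <- max(1L, as.integer(round(config$template_width_ms / 2 / 1000 * fs)))
  tt <- (-hw):hw
  sd_samp <- config$template_width_ms / 6 / 1000 * fs
  template <- -config$template_amplitude_uv * exp(-0.5 * (tt / sd_samp)^2)

  samples <- matrix(0, nrow = n_ch, ncol = n_samp)
  clipped <- 0L
  withr::with_seed(config$rng_seed, {
    if (config$noise_sd_uv > 0) {
      for (ch in seq_len(n_ch)) {
        noise <- fft_bandpass(rnorm(n_samp), 10, 200, fs)
        samples[ch, ] <- noise * (config$noise_sd_uv / sd(noise))
      }
    }
  })
  if (nrow(raster)) {
    centers <- pmin(pmax(as.integer(round(raster$time_s * fs)) + 1L, 1L), n_samp)
    for (i in seq_len(nrow(raster))) {
      ch <- raster$channel[[i]] + 1L
      lo <- centers[[i]] - hw; hi <- centers[[i]] + hw
      tlo <- 1L; thi <- length(template)
      if (lo < 1L) { tlo <- 2L - lo; lo <- 1L; clipped <- clipped + 1L }
      if (hi > n_samp) { thi <- thi - (hi - n_samp); hi <- n_samp; clipped <- clipped + 1L }
      samples[ch, lo:hi] <- samples[ch, lo:hi] + template[tlo:thi]
    }
  }
  if (clipped > 0L)
    warn(sprintf("render_lfp: %d event template(s) clipped at the recording edge", clipped))
  recording(samples, sampling_rate_hz = fs, grid_shape = grid_shape,
            condition = condition, session_id = session_id,
            provenance = list(render = unclass(config)))
}

#' Generate a labeled multi-session synthetic study
#'
#' Builds the synthetic analogue of a multi-condition experiment:
#' `n_sessions` independent sessions per condition, each simulated with
#' [simulate_branching()] and (optionally) rendered with [render_lfp()].
#' Per-session seeds are derived deterministically from `master_seed`, so
#' the same master seed reproduces the study byte-for-byte.
#'
#' @param conditions Named list; each element is a list with components
#'   `branching` (a [branching_config()]) and `render` (a
#'   [render_config()]). The names are the condition labels.
#' @param n_sessions Sessions per condition, `>= 2`.
#' @param master_seed Integer master seed.
#' @param materialize If `TRUE` (default) return rendered [recording()]s;
#'   if `FALSE` return the design only (sessions are then simulated and
#'   rendered lazily by [run_study()], keeping one session in memory at a
#'   time).
#' @return A list of class `avalanche_study_design` with elements
#'   `design` (tibble: condition, session_id, branching_seed, render_seed),
#'   `conditions`, and — when materialized — `recordings` (list of
#'   [recording()]s in design order).
#' @export
make_study <- function(conditions, n_sessions = 6L, master_seed = 1L,
                       materialize = TRUE) {
  if (is.null(names(conditions)) || any(!nzchar(names(conditions))))
    abort("make_study: `conditions` must be a named list")
  if (n_sessions < 2) abort("make_study: `n_sessions` must be >= 2")
  for (cond in conditions) {
    stopifnot(inherits(cond$branching, "branching_config"),
              inherits(cond$render, "render_config"))
  }
  n_cond <- length(conditions)
  seeds <- withr::with_seed(as.integer(master_seed),
                            sample.int(.Machine$integer.max,
                                       2L * n_cond * n_sessions))
  design <- tidyr::expand_grid(condition = names(conditions),
                               session = seq_len(n_sessions))
  design <- dplyr::mutate(
    design,
    session_id = paste0(.data$condition, "_s", .data$session),
    branching_seed = seeds[seq_len(dplyr::n()) * 2L - 1L],
    render_seed = seeds[seq_len(dplyr::n()) * 2L])
  out <- structure(list(design = design, conditions = conditions,
                        master_seed = as.integer(master_seed),
                        recordings = NULL),
                   class = "avalanche_study_design")
  if (materialize)
    out$recordings <- purrr::map(seq_len(nrow(design)),
                                 function(i) realize_session(out, i))
  out
}

# Simulate + render one session of a study design.
realize_session <- function(study, i) {
  row <- study$design[i, ]
  cond <- study$conditions[[row$condition]]
  bc <- cond$branching; bc$rng_seed <- row$branching_seed
  rc <- cond$render; rc$rng_seed <- row$render_seed
  sim <- simulate_branching(bc)
  rec <- render_lfp(sim$raster, rc,
                    condition = row$condition, session_id = row$session_id)
  rec$provenance$branching <- unclass(bc)
  rec
}

#' @export
print.avalanche_study_design <- function(x, ...) {
  cat(sprintf("<avalanche_study_design> %d conditions x %d sessions (%s)\n",
              length(x$conditions), max(x$design$session),
              if (is.null(x$recordings)) "lazy" else "materialized"))
  print(x$design)
  invisible(x)
}
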