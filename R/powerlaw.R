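#' Fit the power-law exponent of an avalanche size distribution
#'
#' Ordinary least squares of `log10(probability)` on `log10(size)` over
#' the sizes in `[fit_min, fit_max]` with nonzero counts (defaults 1-10).
#' The slope is the avalanche exponent alpha; the fit is accepted as a
#' power law when the regression R-squared reaches `r2_threshold`
#' (default 0.9). Fitting normalized probabilities rather than raw counts
#' changes only the intercept, never alpha or R-squared.
#'
#' @param dist A [size_distribution()].
#' @param config A [fit_config()].
#' @return An object of class `powerlaw_fit`: a list with `alpha`,
#'   `intercept` (log10 probability at size 1), `r_squared`, `fit_min`,
#'   `fit_max`, `n_sizes_used`, `n_avalanches`, `accepted`,
#'   `r2_threshold` and the fitted `points` tibble. Supports [tidy()],
#'   [glance()] and [autoplot()].
#' @examples
#' d <- size_distribution(rep(1:10, times = round(1000 * (1:10)^-1.5)))
#' fit_powerlaw(d)  # recovers alpha = -1.5 exactly
#' @export
fit_powerlaw <- function(dist, config = fit_config()) {
  stopifnot(inherits(config, "fit_config"))
  pts <- dplyr::filter(tibble::as_tibble(dist),
                       .data$size >= config$fit_min,
                       .data$size <= config$fit_max,
                       .data$count > 0)
  if (config$zero_policy == "fail") {
    missing <- setdiff(seq(config$fit_min, config$fit_max), pts$size)
    if (length(missing))
      abort(sprintf("degenerate distribution: sizes %s have zero count in the fit range",
                    paste(missing, collapse = ", ")))
  }
  if (nrow(pts) < 2)
    abort("degenerate distribution: need >= 2 distinct sizes with nonzero count in the fit range")
  fit <- lm(log10(probability) ~ log10(size), data = pts)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((log10(pts$probability) - mean(log10(pts$probability)))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  structure(
    list(alpha = unname(coef(fit)[2]),
         intercept = unname(coef(fit)[1]),
         r_squared = r2,
         fit_min = config$fit_min, fit_max = config$fit_max,
         n_sizes_used = nrow(pts),
         n_avalanches = attr(dist, "n_avalanches") %||% sum(pts$count),
         accepted = r2 >= config$r2_threshold,
         r2_threshold = config$r2_threshold,
         points = pts,
         provenance = list(fit = unclass(config))),
    class = "powerlaw_fit")
}

#' @export
print.powerlaw_fit <- function(x, ...) {
  cat(sprintf(
    "<powerlaw_fit> alpha = %.4f  R^2 = %.4f  (%s at R^2 >= %.2g)\n  sizes %d-%d (%d used), %d avalanches\n",
    x$alpha, x$r_squared,
    if (x$accepted) "power law accepted" else "rejected", x$r2_threshold,
    x$fit_min, x$fit_max, x$n_sizes_used, x$n_avalanches))
  invisible(x)
}

#' Shuffle an event raster
#'
#' Destroys temporal structure while preserving every channel's event
#' count exactly: each event's time is redrawn independently and uniformly
#' over the session (no refractory is respected). Used to build surrogate
#' data: interdependent, temporally ordered events produce a power-law
#' size distribution, and shuffling collapses it toward the Poisson
#' expectation, which the R-squared acceptance criterion detects.
#'
#' @param raster An [event_raster()].
#' @param rng_seed Integer seed; identical seeds give identical surrogates.
#' @return A shuffled [event_raster()] with the same per-channel counts.
#' @export
shuffle_raster <- function(raster, rng_seed = 1L) {
  n_ch <- raster_n_channels(raster)
  dur <- raster_duration(raster)
  withr::with_seed(as.integer(rng_seed), {
    event_raster(
      tibble::tibble(channel = raster$channel,
                     time_s = runif(nrow(raster), 0, dur)),
      n_channels = n_ch, duration_s = dur)
  })
}

#' Shuffle-surrogate test of the power-law fit
#'
#' Generates `n_shuffles` surrogate rasters with [shuffle_raster()], runs
#' bin -> extract -> distribution -> fit on each, and returns all surrogate
#' fits for comparison with the original. A surrogate whose distribution
#' is degenerate is reported with `NA` statistics rather than aborting the
#' batch.
#'
#' @param raster An [event_raster()] (typically from [detect_nlfp()]).
#' @param bin_ms Frame width in ms (default 4).
#' @param config A [fit_config()].
#' @param n_shuffles Number of surrogates, `>= 1`.
#' @param rng_seed Master seed; per-surrogate seeds are derived from it.
#' @param drop_boundary Passed to [extract_avalanches()].
#' @return A tibble with one row per surrogate: `shuffle`, `seed`,
#'   `alpha`, `intercept`, `r_squared`, `accepted`, `n_avalanches`,
#'   `error` (NA unless that surrogate failed).
#' @export
shuffle_test <- function(raster, bin_ms = 4, config = fit_config(),
                         n_shuffles = 20L, rng_seed = 1L,
                         drop_boundary = FALSE) {
  if (!is.numeric(n_shuffles) || n_shuffles < 1)
    abort("invalid count: `n_shuffles` must be >= 1")
  seeds <- withr::with_seed(as.integer(rng_seed),
                            sample.int(.Machine$integer.max, n_shuffles))
  purrr::map_dfr(seq_len(n_shuffles), function(i) {
    res <- tryCatch({
      surr <- shuffle_raster(raster, seeds[[i]])
      fit <- fit_powerlaw(
        size_distribution(
          extract_avalanches(bin_raster(surr, bin_ms), drop_boundary)),
        config)
      tibble::tibble(alpha = fit$alpha, intercept = fit$intercept,
                     r_squared = fit$r_squared, accepted = fit$accepted,
                     n_avalanches = fit$n_avalanches, error = NA_character_)
    }, error = function(e) {
      tibble::tibble(alpha = NA_real_, intercept = NA_real_,
                     r_squared = NA_real_, accepted = NA,
                     n_avalanches = NA_integer_, error = conditionMessage(e))
    })
    dplyr::bind_cols(tibble::tibble(shuffle = i, seed = seeds[[i]]), res)
  })
}
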