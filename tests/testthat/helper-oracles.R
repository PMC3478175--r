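# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Brute-force avalanche extraction: scan a list of per-frame active-channel
# sets one frame at a time.
oracle_extract <- function(frame_sets) {
  out <- list()
  cur <- NULL
  for (i in seq_along(frame_sets)) {
    n_active <- length(frame_sets[[i]])
    if (n_active > 0) {
      if (is.null(cur)) cur <- list(start = i - 1L, dur = 0L, size = 0L)
      cur$dur <- cur$dur + 1L
      cur$size <- cur$size + n_active
    } else if (!is.null(cur)) {
      out[[length(out) + 1L]] <- cur
      cur <- NULL
    }
  }
  if (!is.null(cur)) out[[length(out) + 1L]] <- cur
  if (!length(out))
    return(tibble::tibble(start_frame = integer(0),
                          duration_frames = integer(0), size = integer(0)))
  tibble::tibble(start_frame = vapply(out, `[[`, integer(1), "start"),
                 duration_frames = vapply(out, `[[`, integer(1), "dur"),
                 size = vapply(out, `[[`, integer(1), "size"))
}

# Turn a list of per-frame active-channel sets into an event raster
# (events at frame centers).
raster_from_frame_sets <- function(frame_sets, n_channels, bin_ms = 4) {
  bin_s <- bin_ms / 1000
  ev <- purrr::imap_dfr(frame_sets, function(chs, i) {
    tibble::tibble(channel = as.integer(chs),
                   time_s = rep((i - 1 + 0.5) * bin_s, length(chs)))
  })
  event_raster(ev, n_channels = n_channels,
               duration_s = length(frame_sets) * bin_s)
}

# Closed-form OLS of y on x via explicit normal equations.
oracle_ols <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  yhat <- intercept + slope * x
  r2 <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  list(slope = slope, intercept = intercept, r_squared = r2)
}

# Closed-form pooled-variance two-sample t statistic.
oracle_student_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  t_stat <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  df <- na + nb - 2
  list(t = t_stat, df = df,
       p = 2 * stats::pt(-abs(t_stat), df))
}

# Recall within +/- tol_s and spurious fraction (detections with no true
# event within spur_tol_s) of a detected raster against ground truth.
match_rasters <- function(truth, detected, tol_s = 1e-3, spur_tol_s = 5e-3) {
  hits <- 0L; spurious <- 0L
  for (ch in unique(c(truth$channel, detected$channel))) {
    tt <- truth$time_s[truth$channel == ch]
    dd <- detected$time_s[detected$channel == ch]
    for (t1 in tt) if (length(dd) && min(abs(dd - t1)) <= tol_s) hits <- hits + 1L
    for (d1 in dd) if (!length(tt) || min(abs(tt - d1)) > spur_tol_s)
      spurious <- spurious + 1L
  }
  list(recall = hits / nrow(truth), spurious = spurious / nrow(detected),
       n_detected = nrow(detected))
}

# An exact power-law size distribution object (no sampling noise).
exact_powerlaw_dist <- function(exponent, sizes = 1:10) {
  p <- sizes^exponent / sum(sizes^exponent)
  structure(tibble::tibble(size = as.integer(sizes),
                           count = p * 1e6, probability = p),
            n_avalanches = 1e6,
            class = c("size_distribution", class(tibble::tibble())))
}

# Draw avalanche sizes directly from the Borel pmf (independent of the
# grid simulator).
sample_borel <- function(n, sigma, smax = 5000) {
  p <- borel_pmf(seq_len(smax), sigma)
  sample.int(smax, n, replace = TRUE, prob = p / sum(p))
}
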