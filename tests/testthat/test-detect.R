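test_that("band-pass response: DC removed, passband preserved, stopband cut", {
  for (fs in c(4000, 40000)) {
    t <- seq(0, 2, by = 1 / fs)[-1]
    # DC
    dc <- fft_bandpass(rep(5, length(t)), 10, 200, fs)
    expect_lt(max(abs(dc)), 5 * 1e-6)
    # 50 Hz sine at passband center: amplitude preserved within 5%
    s50 <- fft_bandpass(sin(2 * pi * 50 * t), 10, 200, fs)
    mid <- seq(round(length(t) * .25), round(length(t) * .75))
    expect_equal(max(abs(s50[mid])), 1, tolerance = 0.05)
    # 1 Hz sine: attenuated by >= 90%
    s1 <- fft_bandpass(sin(2 * pi * 1 * t), 10, 200, fs)
    expect_lt(max(abs(s1[mid])), 0.1)
  }
  expect_error(fft_bandpass(rnorm(100), 10, 600, 1000), "invalid band")
  expect_error(bandpass_recording(
    recording(matrix(0, 2, 100), 300, c(1, 2)),
    detection_config()), "invalid band")
})

test_that("noise SD estimators are calibrated and the robust one resists events", {
  set.seed(1)
  x <- rnorm(1e6, sd = 10)
  expect_equal(estimate_noise_sd(x, "global"), 10, tolerance = 0.01)
  expect_equal(estimate_noise_sd(x, "robust"), 10, tolerance = 0.01)
  expect_identical(estimate_noise_sd(rep(0, 100)), 0)
  expect_error(estimate_noise_sd(numeric(0)), "empty input")
  # 1% contamination with large troughs inflates the global estimate only
  xc <- x
  idx <- seq(1, 1e6, by = 100)
  xc[idx] <- xc[idx] - 200
  expect_equal(estimate_noise_sd(xc, "robust"), 10, tolerance = 0.05)
  expect_gt(estimate_noise_sd(xc, "global"), 15)
})

test_that("threshold crossings are detected at the constructed trough", {
  fs <- 1000
  n <- 10000
  set.seed(2)
  noise <- fft_bandpass(rnorm(n), 10, 200, fs)
  noise <- noise / sd(noise) * 5              # exact global SD 5
  trough <- -50 * exp(-0.5 * ((seq_len(n) - 5000) / 10)^2)  # depth 10 x SD
  rec <- recording(matrix(noise + trough, nrow = 1), fs, c(1, 1))
  cfg <- detection_config(k_sd = 4, sd_estimator = "global")
  raster <- detect_nlfp(rec, cfg, filtered = TRUE)
  expect_identical(nrow(raster), 1L)
  expect_equal(raster$time_s, 5.0, tolerance = 0.02)
  # trough timing lands on the deflection center
  raster_tr <- detect_nlfp(rec, detection_config(k_sd = 4, sd_estimator = "global",
                                                 time_at = "trough"),
                           filtered = TRUE)
  expect_equal(raster_tr$time_s, 5000 / fs, tolerance = 0.005)
  # all-zero recording -> empty raster
  zero <- recording(matrix(0, 2, 1000), fs, c(1, 2))
  expect_identical(nrow(detect_nlfp(zero, cfg, filtered = TRUE)), 0L)
})

test_that("detection count is monotonically non-increasing in k_sd", {
  set.seed(3)
  ev <- tibble::tibble(channel = sample(0:7, 100, TRUE),
                       time_s = sort(runif(100, 0.2, 19.8)))
  ra <- event_raster(ev, 8, 20)
  rec <- render_lfp(ra, render_config(sampling_rate_hz = 2000, rng_seed = 4),
                    grid_shape = c(2, 4))
  counts <- purrr::map_int(c(2, 3, 4, 5, 6), function(k)
    nrow(detect_nlfp(rec, detection_config(k_sd = k))))
  expect_true(all(diff(counts) <= 0))
})

test_that("refractory period merges crossings closer than its width", {
  fs <- 1000
  x <- rep(0, 3000)
  set.seed(4)
  base <- fft_bandpass(rnorm(3000), 10, 200, fs)
  base <- base / sd(base)                      # SD exactly 1
  two <- -20 * exp(-0.5 * ((seq_len(3000) - 1500) / 4)^2) +
         -20 * exp(-0.5 * ((seq_len(3000) - 1505) / 4)^2)
  rec <- recording(matrix(base + two, nrow = 1), fs, c(1, 1))
  n_with <- nrow(detect_nlfp(rec, detection_config(k_sd = 4, refractory_ms = 10,
                                                   sd_estimator = "global"),
                             filtered = TRUE))
  n_without <- nrow(detect_nlfp(rec, detection_config(k_sd = 4, refractory_ms = 0,
                                                      sd_estimator = "global"),
                                filtered = TRUE))
  expect_identical(n_with, 1L)
  expect_gte(n_without, n_with)
})

test_that("event times are strictly increasing per channel and in range", {
  sim <- simulate_branching(
    branching_config(sigma = 0.9, seed_rate = 20, duration_s = 30,
                     rng_seed = 5, mode = "mapped"))
  rec <- suppressWarnings(
    render_lfp(sim$raster, render_config(sampling_rate_hz = 2000, rng_seed = 6)))
  raster <- detect_nlfp(rec)
  expect_true(all(raster$time_s >= 0 & raster$time_s < attr(raster, "duration_s")))
  by_ch <- split(raster$time_s, raster$channel)
  expect_true(all(purrr::map_lgl(by_ch, function(v) all(diff(v) > 0))))
})
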