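test_that("config constructors validate their invariants", {
  expect_error(branching_config(sigma = -1), "invalid parameter")
  expect_error(branching_config(sigma = 1, seed_rate = 0), "invalid parameter")
  expect_error(branching_config(sigma = 1, duration_s = 0), "invalid parameter")
  expect_error(branching_config(sigma = 1, n_channels = 1), "invalid parameter")
  expect_error(branching_config(sigma = 1.4), "supercritical runaway")
  # mapped mode saturates on the grid, so high sigma is allowed there
  expect_s3_class(branching_config(sigma = 1.4, mode = "mapped"),
                  "branching_config")
  expect_error(render_config(sampling_rate_hz = 0), "invalid parameter")
  expect_error(render_config(template_amplitude_uv = -5), "invalid parameter")
})

test_that("without offspring every sparse-seeded avalanche is a single event", {
  sim <- simulate_branching(
    branching_config(sigma = 0, seed_rate = 0.5, duration_s = 200, rng_seed = 1))
  expect_gt(nrow(sim$avalanches), 50)
  expect_true(all(sim$avalanches$size == 1))
  expect_true(all(sim$avalanches$duration_frames == 1))
})

test_that("subcritical mean avalanche size matches total-progeny closed form", {
  # E[S] = 1 / (1 - sigma) for Poisson(sigma) offspring
  sim <- simulate_branching(
    branching_config(sigma = 0.5, seed_rate = 1, duration_s = 2e4, rng_seed = 2),
    return_raster = FALSE)
  expect_gt(nrow(sim$avalanches), 1e4)
  expect_equal(mean(sim$avalanches$size), 2, tolerance = 0.03)
})

test_that("simulator size law converges to the Borel pmf", {
  sim <- simulate_branching(
    branching_config(sigma = 0.6, seed_rate = 1, duration_s = 2.2e4, rng_seed = 3),
    return_raster = FALSE)
  emp <- table(sim$avalanches$size) / nrow(sim$avalanches)
  s <- as.integer(names(emp))
  dev_large <- max(abs(as.numeric(emp) - borel_pmf(s, 0.6)))
  # Kolmogorov-Smirnov distance shrinks with sample size
  ks_of <- function(sizes) {
    smax <- 200
    emp_cdf <- cumsum(tabulate(pmin(sizes, smax), smax)) / length(sizes)
    max(abs(emp_cdf - cumsum(borel_pmf(1:smax, 0.6))))
  }
  small <- simulate_branching(
    branching_config(sigma = 0.6, seed_rate = 1, duration_s = 1e3, rng_seed = 3),
    return_raster = FALSE)
  expect_lt(dev_large, 0.01)
  expect_lt(ks_of(sim$avalanches$size), ks_of(small$avalanches$size))
})

test_that("identical seeds give identical simulations, rasters and studies", {
  cfg <- branching_config(sigma = 0.9, seed_rate = 20, duration_s = 20,
                          rng_seed = 11, mode = "mapped")
  s1 <- simulate_branching(cfg)
  s2 <- simulate_branching(cfg)
  expect_identical(s1$avalanches, s2$avalanches)
  expect_identical(as.data.frame(s1$raster), as.data.frame(s2$raster))

  conds <- list(
    a = list(branching = branching_config(sigma = 0.8, duration_s = 5, mode = "mapped"),
             render = render_config(sampling_rate_hz = 1000, noise_sd_uv = 5)),
    b = list(branching = branching_config(sigma = 0.9, duration_s = 5, mode = "mapped"),
             render = render_config(sampling_rate_hz = 1000, noise_sd_uv = 5)))
  st1 <- suppressWarnings(make_study(conds, n_sessions = 2, master_seed = 42))
  st2 <- suppressWarnings(make_study(conds, n_sessions = 2, master_seed = 42))
  expect_length(st1$recordings, 4)
  expect_identical(purrr::map_chr(st1$recordings, "condition"),
                   c("a", "a", "b", "b"))
  expect_identical(st1$recordings[[3]]$samples, st2$recordings[[3]]$samples)
  # lazy realization reproduces the materialized recordings
  lazy <- make_study(conds, n_sessions = 2, master_seed = 42, materialize = FALSE)
  expect_identical(suppressWarnings(avalanchr:::realize_session(lazy, 2))$samples,
                   st1$recordings[[2]]$samples)
})

test_that("mapped-mode ground truth equals extraction from its own raster", {
  sim <- simulate_branching(
    branching_config(sigma = 0.8, seed_rate = 20, duration_s = 60,
                     rng_seed = 5, mode = "mapped"))
  got <- extract_avalanches(bin_raster(sim$raster, 4))
  expect_identical(got$start_frame, sim$avalanches$start_frame)
  expect_identical(got$size, as.integer(sim$avalanches$size))
})

test_that("mapped and unconstrained modes agree when collisions are rare", {
  # low activity on a large grid: dedup almost never triggers
  m <- simulate_branching(
    branching_config(sigma = 0.5, seed_rate = 1, duration_s = 5e3,
                     rng_seed = 6, mode = "mapped", n_channels = 64),
    return_raster = FALSE)
  u <- simulate_branching(
    branching_config(sigma = 0.5, seed_rate = 1, duration_s = 5e3, rng_seed = 7),
    return_raster = FALSE)
  expect_equal(mean(m$avalanches$size), mean(u$avalanches$size), tolerance = 0.05)
})

test_that("render_lfp constructs deflections as specified", {
  # empty raster, no noise -> all-zero recording
  empty <- event_raster(tibble::tibble(channel = integer(0), time_s = numeric(0)),
                        n_channels = 4, duration_s = 1)
  rec0 <- render_lfp(empty, render_config(sampling_rate_hz = 1000, noise_sd_uv = 0))
  expect_true(all(rec0$samples == 0))
  expect_identical(dim(rec0$samples), c(4L, 1000L))

  # single event, no noise -> exactly one trough of the template depth
  one <- event_raster(tibble::tibble(channel = 1L, time_s = 0.5),
                      n_channels = 4, duration_s = 1)
  rec1 <- render_lfp(one, render_config(sampling_rate_hz = 1000,
                                        template_amplitude_uv = 80, noise_sd_uv = 0))
  expect_equal(min(rec1$samples[2, ]), -80)
  expect_equal((which.min(rec1$samples[2, ]) - 1) / 1000, 0.5)
  expect_true(all(rec1$samples[-2, ] == 0))

  # an event at the very edge is clipped with a warning
  edge <- event_raster(tibble::tibble(channel = 0L, time_s = 0.001),
                       n_channels = 4, duration_s = 1)
  expect_warning(render_lfp(edge, render_config(sampling_rate_hz = 1000,
                                                noise_sd_uv = 0)),
                 "clipped")
})
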