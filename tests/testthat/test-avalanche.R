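test_that("binning uses half-open 4 ms frames aligned to t = 0", {
  ra <- event_raster(
    tibble::tibble(channel = c(0L, 1L, 2L), time_s = c(0.0005, 0.0039, 0.004)),
    n_channels = 3, duration_s = 0.02)
  fr <- bin_raster(ra, 4)
  expect_identical(attr(fr, "n_frames"), 5L)
  expect_identical(fr$frame[fr$channel == 0L], 0L)
  expect_identical(fr$frame[fr$channel == 1L], 0L)
  # boundary event at exactly 4 ms falls in frame 1
  expect_identical(fr$frame[fr$channel == 2L], 1L)
  # duplicate events of one channel in one frame count once
  ra2 <- event_raster(tibble::tibble(channel = c(0L, 0L, 0L),
                                     time_s = c(0.001, 0.002, 0.003)),
                      n_channels = 2, duration_s = 0.008)
  expect_identical(nrow(bin_raster(ra2, 4)), 1L)
  # empty raster -> no active frames
  empty <- event_raster(tibble::tibble(channel = integer(0), time_s = numeric(0)),
                        n_channels = 2, duration_s = 0.1)
  expect_identical(nrow(bin_raster(empty, 4)), 0L)
})

test_that("avalanche extraction matches the worked example and edge cases", {
  # frame active-sets [{A,B}, {C}, {}, {D}, {}]
  sets <- list(c(0L, 1L), 2L, integer(0), 3L, integer(0))
  av <- extract_avalanches(bin_raster(raster_from_frame_sets(sets, 4), 4))
  expect_identical(av$start_frame, c(0L, 3L))
  expect_identical(av$duration_frames, c(2L, 1L))
  expect_identical(av$size, c(3L, 1L))
  # all frames empty -> zero avalanches
  none <- extract_avalanches(bin_raster(
    raster_from_frame_sets(list(integer(0), integer(0)), 2), 4))
  expect_identical(nrow(none), 0L)
  # all frames non-empty -> one avalanche spanning the sequence
  full <- extract_avalanches(bin_raster(
    raster_from_frame_sets(list(0L, 1L, 0L), 2), 4))
  expect_identical(nrow(full), 1L)
  expect_identical(full$duration_frames, 3L)
  # boundary avalanches can be dropped on request
  dropped <- extract_avalanches(bin_raster(
    raster_from_frame_sets(list(0L, integer(0), 1L, integer(0)), 2), 4),
    drop_boundary = TRUE)
  expect_identical(nrow(dropped), 1L)
  expect_identical(dropped$start_frame, 2L)
})

test_that("extraction equals the brute-force frame-scan oracle on random inputs", {
  set.seed(10)
  for (rep in 1:200) {
    n_frames <- sample(1:30, 1)
    n_ch <- sample(2:6, 1)
    sets <- purrr::map(seq_len(n_frames), function(i) {
      k <- sample(0:n_ch, 1, prob = c(0.5, rep(0.5 / n_ch, n_ch)))
      sort(sample(0:(n_ch - 1), k))
    })
    got <- extract_avalanches(bin_raster(raster_from_frame_sets(sets, n_ch), 4))
    want <- oracle_extract(sets)
    expect_identical(got$start_frame, want$start_frame)
    expect_identical(got$duration_frames, want$duration_frames)
    expect_identical(got$size, want$size)
    # conservation: sizes sum to the number of active (channel, frame) pairs
    expect_identical(sum(got$size), sum(lengths(sets)))
  }
})

test_that("avalanche statistics are invariant under channel relabeling", {
  set.seed(11)
  sets <- purrr::map(1:50, function(i) {
    k <- sample(0:4, 1)
    sort(sample(0:7, k))
  })
  perm <- sample(0:7)
  sets_perm <- purrr::map(sets, function(s) sort(perm[s + 1L]))
  a <- extract_avalanches(bin_raster(raster_from_frame_sets(sets, 8), 4))
  b <- extract_avalanches(bin_raster(raster_from_frame_sets(sets_perm, 8), 4))
  expect_identical(a$size, b$size)
  expect_identical(a$start_frame, b$start_frame)
})

test_that("size distribution normalizes correctly", {
  d <- size_distribution(c(1L, 1L, 2L))
  expect_equal(d$probability[d$size == 1], 2 / 3)
  expect_equal(d$probability[d$size == 2], 1 / 3)
  expect_identical(attr(d, "n_avalanches"), 3L)
  set.seed(12)
  d2 <- size_distribution(sample(1:20, 500, TRUE))
  expect_equal(sum(d2$probability), 1, tolerance = 1e-12)
  expect_true(all(d2$size >= 1))
  expect_error(size_distribution(integer(0)), "no avalanches")
})

test_that("critical-run size-1 probability approaches the Borel value", {
  sim <- simulate_branching(
    branching_config(sigma = 1, seed_rate = 2, duration_s = 1.2e4, rng_seed = 13),
    return_raster = FALSE)
  expect_gt(nrow(sim$avalanches), 2e4)
  d <- size_distribution(sim$avalanches)
  expect_equal(d$probability[d$size == 1], exp(-1), tolerance = 0.04)
})
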