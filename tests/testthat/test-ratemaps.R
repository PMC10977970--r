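# Rate maps, spatial information, open-arena grid identification.

test_that("linear rate map recovers rates from spikes and occupancy", {
  tr <- short_trace(5)
  expect_equal(max(linear_rate_map(numeric(0), tr)$rates, na.rm = TRUE), 0)
  # one spike per 1 cm bin at 10 cm/s: dwell 0.1 s per bin -> 10 Hz everywhere
  spike_times <- tr$time_s[match(unique(floor(tr$cum_dist_cm)),
                                 floor(tr$cum_dist_cm))]
  map <- linear_rate_map(spike_times, tr)
  expect_equal(unname(as.vector(map$rates_unsmoothed)),
               rep(10, 1000), tolerance = 1e-9)
  expect_error(linear_rate_map(1, tr[0, ]), "empty")
})

test_that("rate-map mass is conserved and smoothing preserves trial means", {
  cfg <- sim_config(n_trials = 10, grid_spacing_cm = 50, mode = "anchored",
                    seed = 20)
  tr <- short_trace(10)
  sp <- draw_spikes(grid_pdf(cfg), tr, 0.1, seed = 21)
  map <- linear_rate_map(sp, tr)
  expect_equal(sum(map$rates_unsmoothed * map$occupancy_s, na.rm = TRUE),
               length(sp))
  # reflective padding keeps the convolution mass: per-trial mean preserved
  for (t in c(1, 5, 10)) {
    expect_equal(mean(map$rates[t, ]), mean(map$rates_unsmoothed[t, ]),
                 tolerance = 0.01)
  }
})

test_that("spatial information matches closed forms", {
  two_bins <- mock_linear_map(matrix(c(2, 0), 1, 2))
  expect_equal(spatial_information(two_bins), 1)
  unif <- mock_linear_map(matrix(3, 4, 10))
  expect_equal(spatial_information(unif), 0)
  m <- mock_linear_map(matrix(c(1, 2, 3, 0, 1, 5), 2, 3))
  expect_equal(spatial_information(mock_linear_map(2 * m$rates)),
               2 * spatial_information(m))
  expect_gte(spatial_information(m), 0)
  expect_error(spatial_information(c(1, 2), occupancy_s = c(0, 0)), "occupancy")
})

test_that("epoch trial counts are equalised by random subsetting", {
  labels <- c(rep("TA", 30), rep("TI", 10))
  sub <- equalise_epoch_trials(labels, seed = 1)
  expect_length(sub$TA, 10L)
  expect_length(sub$TI, 10L)
  expect_true(all(labels[sub$TA] == "TA"))
  eq <- equalise_epoch_trials(c("TA", "TI", "TA", "TI"))
  expect_equal(eq$TA, c(1L, 3L))
  expect_identical(equalise_epoch_trials(labels, seed = 5),
                   equalise_epoch_trials(labels, seed = 5))
  expect_error(equalise_epoch_trials(rep("TA", 5)), "non-empty")
})

test_that("autocorrelogram is 1 at zero lag, symmetric, and shows the hex ring", {
  hex <- hex_rate_map()
  ac <- rate_map_autocorr(hex)
  c0 <- (dim(ac) + 1) / 2
  expect_equal(ac[c0[1], c0[2]], 1)
  flipped <- ac[rev(seq_len(nrow(ac))), rev(seq_len(ncol(ac)))]
  expect_equal(unclass(ac), unclass(flipped))
  # binarised autocorrelogram: six fields nearest the centre form a ring of
  # roughly equal radii (one lattice spacing)
  b <- !is.na(ac) & ac >= 0.2 * max(ac, na.rm = TRUE)
  cent <- gridtask:::binary_local_maxima(b)
  expect_gt(nrow(cent), 7)
  d <- sqrt((cent[, 1] - c0[1])^2 + (cent[, 2] - c0[2])^2)
  ring <- sort(d)[2:7]  # exclude the centre
  expect_lt(diff(range(ring)) / mean(ring), 0.15)
  # nearest autocorrelogram fields sit one lattice spacing from the centre
  expect_equal(mean(ring) * 2.5, 40, tolerance = 0.05)
})

test_that("grid score is positive for hexagonal maps and undefined below 8 maxima", {
  hex <- hex_rate_map()
  expect_gt(grid_score(rate_map_autocorr(hex)), 0.5)
  # 12-fold ring: rotation by 30 and 60 degrees both map fields onto fields,
  # so rotated correlations are all equal and the score is ~0
  n <- 81; c0 <- (n + 1) / 2
  ring12 <- matrix(0, n, n)
  for (a in seq(0, 330, by = 30)) {
    cx <- c0 + 20 * cos(a * pi / 180); cy <- c0 + 20 * sin(a * pi / 180)
    ring12 <- ring12 + exp(-((row(ring12) - cx)^2 + (col(ring12) - cy)^2) / 8)
  }
  ring12[c0, c0] <- max(ring12) * 1.2
  expect_lt(abs(grid_score(ring12)), 0.12)
  gs <- grid_score(matrix(exp(-((row(diag(41)) - 21)^2 +
                                  (col(diag(41)) - 21)^2) / 20), 41, 41))
  expect_true(is.na(gs))
  expect_match(attr(gs, "reason"), "maxima")
})

test_that("grid score is invariant to rate-map scaling", {
  hex <- hex_rate_map()
  expect_equal(grid_score(rate_map_autocorr(hex)),
               grid_score(rate_map_autocorr(hex * 7.3)), tolerance = 1e-9)
})

test_that("shuffle classification separates grid cells from noise cells", {
  oa <- open_arena_fixture()
  call <- open_field_shuffle_call(oa$grid_spikes, oa$positions,
                                  n_shuffles = 100, seed = 2)
  expect_true(call$is_grid)
  expect_gt(call$grid_score, call$shuffle_p99_grid)
  expect_gt(call$stability_r, call$shuffle_p99_stability)
  noise <- open_field_shuffle_call(oa$noise_spikes, oa$positions,
                                   n_shuffles = 100, seed = 3)
  expect_false(noise$is_grid)
  expect_error(open_field_shuffle_call(oa$grid_spikes, oa$positions,
                                       n_shuffles = 1), "at least 2")
  expect_warning(open_field_shuffle_call(oa$grid_spikes, oa$positions,
                                         n_shuffles = 10, seed = 4),
                 "fewer than 100")
})
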