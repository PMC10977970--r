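# Simulator: kinematics, firing PDFs, mode alternation, spike draws,
# stopping behaviour.

test_that("constant-speed trace has the expected duration, sampling and types", {
  tr <- default_trace()
  # 100 trials x 200 cm at 10 cm/s sampled at 1000 Hz
  expect_equal(nrow(tr), 2000000L)
  expect_equal(max(tr$time_s) + 1e-3, 2000)
  expect_true(all(diff(tr$time_s) > 0))
  expect_true(all(tr$pos_cm >= 0 & tr$pos_cm < 200))
  expect_equal(tr$cum_dist_cm, (tr$trial_number - 1) * 200 + tr$pos_cm)
  expect_true(!is.unsorted(tr$trial_number))

  tr1 <- make_position_trace(sim_config(n_trials = 1, speed_cm_s = 200, seed = 1))
  expect_equal(max(tr1$time_s) + 1e-3, 1)

  tr6 <- make_position_trace(sim_config(n_trials = 6, speed_cm_s = 200,
                                        sample_rate_hz = 10,
                                        trial_block_pattern = "BBN", seed = 1))
  expect_equal(tr6$trial_type[match(1:6, tr6$trial_number)],
               c("beaconed", "beaconed", "non_beaconed",
                 "beaconed", "beaconed", "non_beaconed"))
  expect_error(sim_config(speed_cm_s = 0), "positive")
  expect_error(sim_config(n_trials = 0), "at least 1")
  expect_error(sim_config(trial_block_pattern = ""), "non-empty")
})

test_that("anchored grid PDF is trial-invariant with the expected field count", {
  cfg <- sim_config(grid_spacing_cm = 50, mode = "anchored", n_trials = 10, seed = 2)
  pdf <- grid_pdf(cfg)
  expect_true(all(pdf$density >= 0 & pdf$density <= 1))
  for (t in 2:10) expect_equal(pdf$density[t, ], pdf$density[1, ])
  expect_length(find_peaks(pdf$density[1, ]), 4L)  # floor(200 / 50)
  expect_equal(pdf$true_label_per_trial, rep("TA", 10))
  expect_error(grid_pdf(sim_config(), mode = "place"), "anchored")
})

test_that("independent grid PDF advances its phase by track mod spacing", {
  cfg <- sim_config(grid_spacing_cm = 60, mode = "independent", n_trials = 8, seed = 3)
  pdf <- grid_pdf(cfg)
  flat <- as.vector(t(pdf$density))
  pk <- find_peaks(flat)
  # constant inter-field interval of exactly lambda in cumulative distance
  expect_true(all(diff(pk) == 60))
  # within-track phase advances by 200 mod 60 = 20 cm per trial
  p1 <- find_peaks(pdf$density[1, ])[1]
  p2 <- find_peaks(pdf$density[2, ])[1]
  expect_equal((p1 - p2) %% 60, 20)
})

test_that("non-grid PDFs match their definitions", {
  cfg <- sim_config(n_trials = 5, seed = 4)
  pl <- nongrid_pdf("place", cfg)
  expect_equal(unname(apply(pl$density, 1, which.max)), rep(100L, 5))
  rp <- nongrid_pdf("ramp", cfg)
  expect_lt(rp$density[1, 1], 0.01)
  expect_equal(which.max(rp$density[1, ]), 200L)
  nz <- nongrid_pdf("noise", cfg)
  expect_equal(diff(range(nz$density)), 0)
  sf <- nongrid_pdf("shuffled_field", cfg)
  # field shuffle permutes the place PDF bins
  expect_equal(sort(as.vector(sf$density)),
               sort(as.vector(pl$density) / max(pl$density)))
  expect_error(nongrid_pdf("theta", cfg))
})

test_that("mode alternation follows the switching scheme", {
  cfg <- sim_config(n_trials = 50, grid_spacing_cm = 70, seed = 5)
  a <- grid_pdf(cfg, "anchored"); b <- grid_pdf(cfg, "independent")
  keep <- alternate_modes(a, b, "blocks", switch_prob = 0, seed = 6)
  expect_length(unique(keep$true_label_per_trial), 1L)
  flip <- alternate_modes(a, b, "blocks", switch_prob = 1, seed = 6)
  expect_true(all(flip$true_label_per_trial[-1] != flip$true_label_per_trial[-50]))
  # merged density rows come from the PDF named by the label
  lab <- flip$true_label_per_trial
  expect_equal(flip$density[lab == "TA", ], a$density[lab == "TA", ])
  expect_equal(flip$density[lab == "TI", ], b$density[lab == "TI", ])
  cfg_big <- sim_config(n_trials = 10000, grid_spacing_cm = 70, seed = 5)
  big <- alternate_modes(grid_pdf(cfg_big, "anchored"),
                         grid_pdf(cfg_big, "independent"),
                         "blocks", switch_prob = 0.1, seed = 7)
  sw <- mean(big$true_label_per_trial[-1] != big$true_label_per_trial[-10000])
  se <- sqrt(0.1 * 0.9 / 9999)
  expect_lt(abs(sw - 0.1), 3 * se)
  cfg2 <- sim_config(n_trials = 20, seed = 5)
  expect_error(alternate_modes(grid_pdf(cfg2, "anchored"), b, "blocks"),
               "trial counts")
})

test_that("spike draws are Bernoulli with rate p_max * density", {
  tr <- short_trace(10)
  cfg <- sim_config(n_trials = 10, seed = 8)
  zero <- nongrid_pdf("noise", cfg); zero$density[] <- 0
  expect_length(draw_spikes(zero, tr, 0.1, seed = 1), 0L)
  unif <- nongrid_pdf("noise", cfg)  # density == 1 everywhere
  sp <- draw_spikes(unif, tr, 0.1, seed = 2)
  rate <- length(sp) / (nrow(tr) / 1000)
  se_rate <- sqrt(0.1 * 0.9 / nrow(tr)) * 1000
  expect_lt(abs(rate - 100), 3 * se_rate)
  expect_identical(draw_spikes(unif, tr, 0.1, seed = 3),
                   draw_spikes(unif, tr, 0.1, seed = 3))
  expect_error(draw_spikes(unif, tr, 0), "p_max_spike")
})

test_that("expected spikes per trial equal p_max times summed density", {
  tr <- default_trace()
  cfg <- sim_config(grid_spacing_cm = 80, mode = "anchored", seed = 9)
  pdf <- grid_pdf(cfg)
  sp <- draw_spikes(pdf, tr, 0.1, seed = 10)
  counts <- tabulate(findInterval(sp, seq(0, 2000, by = 20)), nbins = 100)
  # each 1 cm bin is visited for 100 samples at these defaults
  expected <- 0.1 * rowSums(pdf$density) * 100
  se <- sd(counts) / sqrt(100)
  expect_lt(abs(mean(counts) - mean(expected)), 4 * se)
})

test_that("stopping behaviour follows the stop policy", {
  tr <- short_trace(10)
  forced <- stop_policy(p_stop_base = 0, p_stop_rz = 1)
  beh <- simulate_behaviour(tr, forced, seed = 11)
  in_zone <- beh$stops$pos_cm >= 60 & beh$stops$pos_cm < 80
  expect_equal(sort(unique(beh$stops$trial_number[in_zone])), 1:10)
  expect_error(stop_policy(p_stop_rz = 1.5), "\\[0, 1\\]")

  none <- simulate_behaviour(tr, stop_policy(p_stop_base = 0, p_stop_rz = 0),
                             seed = 12)
  expect_equal(nrow(none$stops), 0L)
  out <- classify_outcomes(speed_profile(tr, speed = none$speed_cm_s),
                           none$stops)
  expect_true(all(is.na(out$label) | out$label %in% c("run", "unclassified")))
})

test_that("uniform stop policy yields uniform stop positions", {
  cfg <- sim_config(n_trials = 300, seed = 13)
  tr <- make_position_trace(cfg)
  unif <- stop_policy(p_stop_base = 0.2, p_stop_rz = 0.2, stop_duration_s = 0)
  beh <- simulate_behaviour(tr, unif, seed = 14)
  pos <- beh$stops$pos_cm
  expect_gt(length(pos), 10000)
  ks <- suppressWarnings(ks.test(pos[seq_len(10000)], "punif", 0, 200))
  expect_gt(ks$p.value, 0.01)
})

test_that("sessions are reproducible under a fixed seed", {
  cfg <- sim_config(n_trials = 5, grid_spacing_cm = 60,
                    mode = "alternating_blocks", seed = 99)
  s1 <- simulate_session(cfg)
  s2 <- simulate_session(cfg)
  expect_identical(s1$spikes, s2$spikes)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$behaviour$stops, s2$behaviour$stops)
})
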