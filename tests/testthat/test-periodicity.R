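# Spatial periodograms, field shuffle, false alarm thresholds and the
# TA / TI / aperiodic classification.

test_that("flattening serialises trials in order and round-trips", {
  m <- matrix(seq_len(600), 3, 200, byrow = TRUE)
  sig <- flatten_rate_signal(m)
  expect_length(sig, 600L)
  # bin (trial t, position p) maps to index (t-1)*200 + p
  expect_equal(sig[(2 - 1) * 200 + 57], m[2, 57])
  expect_equal(unflatten_rate_signal(sig, 200), m)
})

test_that("periodogram power agrees with a direct least-squares fit", {
  set.seed(1)
  x <- (1:600 - 0.5) / 200
  y <- 2 + sin(2 * pi * 4 * x + 0.7) + rnorm(600, 0, 0.3)
  pg <- lomb_scargle_windows(y)
  for (f in c(0.5, 1.37, 2.86, 4.0)) {
    fit <- lm(y ~ cos(2 * pi * f * x) + sin(2 * pi * f * x))
    i <- which.min(abs(pg$freqs - f))
    expect_equal(pg$power[1, i], summary(fit)$r.squared, tolerance = 1e-10)
  }
  # pure 50 cm period -> peak at 4 oscillations per trial
  pure <- sin(2 * pi * seq(0.5, 1999.5) / 50)
  avg <- average_periodogram(lomb_scargle_windows(pure))
  expect_equal(avg$freqs[which.max(avg$power)], 4, tolerance = 0.011)
  # constant signal -> no power anywhere
  expect_equal(max(lomb_scargle_windows(rep(3, 600))$power), 0)
  expect_lte(max(pg$freqs), 5)
  expect_error(lomb_scargle_windows(rep(1, 599)), "shorter")
})

test_that("averaging periodograms is an element-wise mean", {
  set.seed(2)
  sig <- rnorm(1200)
  pg <- lomb_scargle_windows(sig)
  avg <- average_periodogram(pg)
  expect_equal(avg$power, colMeans(pg$power))
  same <- average_periodogram(list(pg$power[1, ], pg$power[1, ]),
                              freqs = pg$freqs)
  expect_equal(same$power, pg$power[1, ])
  mid <- average_periodogram(list(pg$power[1, ], pg$power[2, ]),
                             freqs = pg$freqs)
  expect_equal(mid$power, (pg$power[1, ] + pg$power[2, ]) / 2)
  expect_error(average_periodogram(list(1:10, 1:9), freqs = 1:10), "mismatch")
})

test_that("field detection segments bumps between troughs", {
  x <- seq(0.5, 199.5)
  bump <- exp(-(x - 100)^2 / 50)
  f1 <- detect_fields(bump)
  expect_length(f1$fields, 1L)
  # two bumps 15 cm apart merge under the 20 cm minimum peak distance
  two <- exp(-(x - 90)^2 / 18) + exp(-(x - 105)^2 / 18)
  expect_length(detect_fields(two)$peaks, 1L)
  # anchored grid, spacing 50, 10 trials: 4 fields per trial
  cfg <- sim_config(grid_spacing_cm = 50, mode = "anchored", n_trials = 10,
                    seed = 30)
  tr <- short_trace(10)
  map <- linear_rate_map(draw_spikes(grid_pdf(cfg), tr, 0.1, seed = 31), tr)
  fs <- detect_fields(flatten_rate_signal(map, smoothed = FALSE))
  expect_length(fs$fields, 40L)
  expect_length(detect_fields(rep(0, 400))$fields, 0L)
})

test_that("field shuffle is a permutation preserving field interiors", {
  cfg <- sim_config(grid_spacing_cm = 50, mode = "anchored", n_trials = 10,
                    seed = 30)
  tr <- short_trace(10)
  raw <- flatten_rate_signal(
    linear_rate_map(draw_spikes(grid_pdf(cfg), tr, 0.1, seed = 31), tr),
    smoothed = FALSE)
  fs <- detect_fields(raw)
  sh <- field_shuffle(raw, fs, seed = 32)
  expect_equal(sort(sh), sort(raw))
  # each field's internal order survives somewhere in the shuffled signal
  fld <- raw[fs$fields[[1]][1]:fs$fields[[1]][2]]
  hits <- vapply(seq_len(length(sh) - length(fld) + 1),
                 function(i) all(sh[i:(i + length(fld) - 1)] == fld),
                 logical(1))
  expect_true(any(hits))
  # with no fields the output is still a permutation
  flatsig <- rep(c(0, 0.01), 200)
  fs0 <- detect_fields(rep(0, 400))
  expect_equal(sort(field_shuffle(flatsig, fs0, seed = 1)), sort(flatsig))
})

test_that("false alarm thresholds are positive, scale-free and shrink with averaging", {
  cfg <- sim_config(grid_spacing_cm = 70, mode = "anchored", n_trials = 40,
                    seed = 33)
  tr <- make_position_trace(cfg)
  map <- linear_rate_map(draw_spikes(grid_pdf(cfg), tr, 0.1, seed = 34), tr)
  thr1 <- false_alarm_threshold(map, n_shuffles = 120, scope = "single", seed = 35)
  expect_gt(thr1$threshold_power, 0)
  # standard normalisation is scale-invariant: doubling rates changes nothing
  map2 <- map
  map2$rates <- 2 * map$rates
  map2$rates_unsmoothed <- 2 * map$rates_unsmoothed
  thr2 <- false_alarm_threshold(map2, n_shuffles = 120, scope = "single", seed = 35)
  expect_equal(thr2$threshold_power, thr1$threshold_power, tolerance = 1e-9)
  # averaging 200 periodograms shrinks shuffled peaks relative to single windows
  thr_roll <- false_alarm_threshold(map, n_shuffles = 120,
                                    scope = "rolling_adjusted", seed = 35)
  expect_lt(thr_roll$threshold_power, thr1$threshold_power)
  expect_warning(false_alarm_threshold(map, n_shuffles = 20, scope = "single",
                                       seed = 1), "fewer than 100")
})

test_that("session classification applies the threshold and integer rule", {
  freqs <- frequency_grid()
  mk <- function(peak_f, peak_p) {
    power <- rep(0.01, length(freqs))
    power[which.min(abs(freqs - peak_f))] <- peak_p
    structure(list(freqs = freqs, power = power), class = "periodogram_avg")
  }
  expect_equal(classify_session(mk(4.00, 0.5), threshold = 0.2)$label, "TA")
  expect_equal(classify_session(mk(3.40, 0.5), threshold = 0.2)$label, "TI")
  expect_equal(classify_session(mk(4.00, 0.1), threshold = 0.2)$label, "aperiodic")
  # below 0.5 oscillations/trial the nearest positive integer is 1
  expect_equal(classify_session(mk(0.30, 0.5), threshold = 0.2)$label, "TI")
  expect_equal(classify_session(mk(2.96, 0.5), threshold = 0.2)$label, "TA")
  expect_equal(classify_session(mk(2.96, 0.5), NULL)$label, "TA")
  expect_error(classify_session(list(freqs = numeric(0), power = numeric(0))),
               "empty")
})

test_that("rolling classification tracks a mid-session mode switch", {
  # deterministic rate signal: anchored spacing 50 for 30 trials, then
  # independent spacing 70 for 30 trials
  cfgA <- sim_config(grid_spacing_cm = 50, mode = "anchored", n_trials = 30,
                     seed = 40)
  cfgB <- sim_config(grid_spacing_cm = 70, mode = "independent", n_trials = 30,
                     seed = 40)
  sig <- c(as.vector(t(grid_pdf(cfgA)$density)),
           as.vector(t(grid_pdf(cfgB)$density)))
  pg <- lomb_scargle_windows(sig)
  rc <- rolling_classify(pg, NULL, window = 200)
  expect_true(all(rc$label %in% c("TA", "TI")))
  # homogeneous stretches are labelled purely
  expect_true(all(rc$label[rc$midpoint_trial < 25] == "TA"))
  expect_true(all(rc$label[rc$midpoint_trial > 35] == "TI"))
  # the switch is located within half a window (5 trials) of trial 30
  first_ti <- min(rc$midpoint_trial[rc$label == "TI"])
  expect_lt(abs(first_ti - 30), 5)
  expect_error(rolling_classify(lomb_scargle_windows(sig[1:700]), NULL, 200),
               "fewer periodograms")
})

test_that("window midpoints are assigned to the nearest trial with majority vote", {
  r <- assign_trials(c("TA", "TI", "TI"), c(10.4, 10.6, 10.5), 12)
  expect_equal(r$label[10], "TA")
  expect_equal(r$label[11], "TI")
  maj <- assign_trials(c("TA", "TA", "TI"), c(5.1, 4.9, 5.2), 6)
  expect_equal(maj$label[5], "TA")
  expect_true(all(table(maj$trial_number) == 1))
  # trials without windows inherit the nearest label and are flagged
  expect_true(maj$imputed[1])
  expect_equal(maj$label[1], maj$label[5])
  expect_error(assign_trials("TA", c(1, 2), 3), "length mismatch")
})

test_that("silent cells are classified aperiodic by convention", {
  tr <- short_trace(20)
  g <- classify_grid_code(numeric(0), tr, mode = "rolling",
                          use_field_shuffle = FALSE)
  expect_equal(g$session$label, "aperiodic")
  expect_true(all(g$raster$label == "aperiodic"))
  expect_equal(nrow(g$raster), 20L)
})

test_that("gridcode objects print, summarise and plot", {
  cfg <- sim_config(grid_spacing_cm = 50, mode = "anchored", n_trials = 20,
                    seed = 44)
  tr <- short_trace(20)
  sp <- draw_spikes(grid_pdf(cfg), tr, 0.1, seed = 45)
  g <- classify_grid_code(sp, tr, mode = "rolling", use_field_shuffle = FALSE)
  expect_s3_class(g, "gridcode")
  expect_equal(g$session$label, "TA")
  expect_output(print(g), "session label: TA")
  s <- summary(g)
  expect_output(print(s), "Spatial info")
  pdf_file <- tempfile(fileext = ".pdf")
  grDevices::pdf(pdf_file)
  expect_silent(plot(g))
  grDevices::dev.off()
  expect_true(file.exists(pdf_file))
  unlink(pdf_file)
})
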