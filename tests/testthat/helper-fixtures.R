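# Shared fixtures, memoised so expensive simulations run once per suite.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, force(expr), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# default-scale kinematic trace (100 trials, 2e6 samples), shared widely
default_trace <- function() {
  fixture("default_trace", make_position_trace(sim_config(seed = 1)))
}

# short 20-trial trace for cheap tests
short_trace <- function(n_trials = 20) {
  fixture(paste0("short_trace_", n_trials),
          make_position_trace(sim_config(n_trials = n_trials, seed = 1)))
}

# a smooth open-arena random walk plus a hexagonal-lattice grid cell
open_arena_fixture <- function() {
  fixture("open_arena", {
    set.seed(10)
    nt <- 15000; dt <- 0.04
    vx <- vy <- numeric(nt); x <- y <- numeric(nt); x[1] <- y[1] <- 50
    for (i in 2:nt) {
      vx[i] <- 0.9 * vx[i - 1] + rnorm(1, 0, 4)
      vy[i] <- 0.9 * vy[i - 1] + rnorm(1, 0, 4)
      x[i] <- x[i - 1] + vx[i] * dt; y[i] <- y[i - 1] + vy[i] * dt
      if (x[i] < 0 || x[i] > 99.9) { vx[i] <- -vx[i]; x[i] <- min(max(x[i], 0), 99.9) }
      if (y[i] < 0 || y[i] > 99.9) { vy[i] <- -vy[i]; y[i] <- min(max(y[i], 0), 99.9) }
    }
    pos <- data.frame(time_s = (seq_len(nt) - 1) * dt, x_cm = x, y_cm = y)
    lam <- 40; k <- 4 * pi / (sqrt(3) * lam)
    g <- sapply(c(0, pi / 3, 2 * pi / 3),
                function(a) cos(k * (cos(a) * x + sin(a) * y)))
    rate <- pmax(rowSums(g), 0) / 3
    grid_spikes <- pos$time_s[runif(nt) < 0.6 * rate]
    noise_spikes <- pos$time_s[runif(nt) < 0.1]
    list(positions = pos, grid_spikes = grid_spikes,
         noise_spikes = noise_spikes, spacing_cm = lam)
  })
}

# ideal noiseless hexagonal rate map on a square grid (values >= 0)
hex_rate_map <- function(n = 40, bin_cm = 2.5, spacing_cm = 40) {
  k <- 4 * pi / (sqrt(3) * spacing_cm)
  xy <- expand.grid(x = (seq_len(n) - 0.5) * bin_cm,
                    y = (seq_len(n) - 0.5) * bin_cm)
  g <- sapply(c(0, pi / 3, 2 * pi / 3),
              function(a) cos(k * (cos(a) * xy$x + sin(a) * xy$y)))
  matrix(pmax(rowSums(g), 0), n, n)
}

# minimal hand-built linear_rate_map for closed-form tests
mock_linear_map <- function(rates, occupancy = NULL) {
  occupancy <- if (is.null(occupancy)) matrix(1, nrow(rates), ncol(rates)) else occupancy
  structure(list(rates = rates, rates_unsmoothed = rates,
                 occupancy_s = occupancy,
                 visited = occupancy > 0, n_spikes = NA_integer_,
                 smoothing_sd_cm = 0, track_length_cm = ncol(rates)),
            class = "linear_rate_map")
}
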