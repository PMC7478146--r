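# Shared fixtures, built once per test session.
#
# mini montage: 32 channels, 60 mm sphere, 15 mm grid (~100 voxels) for
# fast algebraic tests. full montage: the package's default desk-scale
# study conditions (64 channels, 80 mm sphere, 10 mm grid, ~1400 voxels)
# for localization suites.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, builder(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

mini_montage <- function() memo("mini", function() {
  sensors <- make_sensor_array(32, array_radius = 100)
  model <- sphere_head_model(c(0, 0, 0), 60)
  grid <- make_source_grid(60, 15)
  lf <- compute_leadfield(grid, sensors, model)
  lf3 <- compute_leadfield(grid, sensors, model, rank_mode = "full3")
  list(sensors = sensors, model = model, grid = grid, lf = lf, lf3 = lf3)
})

full_montage <- function() memo("full", function() {
  sensors <- make_sensor_array(64)
  model <- sphere_head_model(c(0, 0, 0), 80)
  grid <- make_source_grid(80, 10)
  lf <- compute_leadfield(grid, sensors, model)
  list(sensors = sensors, model = model, grid = grid, lf = lf)
})

# deep inside voxels, away from center and surface, for source placement
deep_voxels <- function(m, rmin = 15, rmax = 0.7 * m$model$radius) {
  ic <- inside_coords(m$grid)
  r <- sqrt(rowSums(ic^2))
  which(r >= rmin & r <= rmax)
}

# single-source simulation on a montage; returns sim list
simulate_one_source <- function(m, voxel, kind = "evoked", seed = 1,
                                snr = NULL, sensor_white = 1e-18, ...) {
  ic <- inside_coords(m$grid)
  tb <- tangential_basis(ic[voxel, ], c(0, 0, 0))
  noise <- if (is.null(snr)) list(sensor_white = sensor_white)
           else list(target_snr = snr)
  cfg <- sim_config(list(sim_source(ic[voxel, ], tb[1, ], kind, ...)),
                    n_channels = length(m$sensors$channel_id),
                    sphere_radius = m$model$radius,
                    grid_spacing = m$grid$spacing,
                    noise = noise, n_trials = 15, sfreq = 200,
                    epoch_span = c(-300, 700), seed = seed)
  simulate_epochs(cfg, sensors = m$sensors, model = m$model, grid = m$grid)
}

random_spd <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  A <- matrix(rnorm(n * n), n)
  crossprod(A) / n + diag(0.1, n)
}

# --- shared simulation fixtures used across test files ---

two_dipole_sim <- function(m, seed = 3, snr = 10) {
  ic <- inside_coords(m$grid)
  v1 <- megsource:::nearest_inside_voxel(m$grid, c(35, 20, 30))
  v2 <- megsource:::nearest_inside_voxel(m$grid, c(-30, -25, 25))
  tb1 <- tangential_basis(ic[v1, ], c(0, 0, 0))
  tb2 <- tangential_basis(ic[v2, ], c(0, 0, 0))
  cfg <- sim_config(list(
    sim_source(ic[v1, ], tb1[1, ], "evoked", freq = 10, amplitude = 20,
               onset = 50, offset = 450),
    sim_source(ic[v2, ], tb2[1, ], "evoked", freq = 17, amplitude = 20,
               onset = 100, offset = 500)),
    noise = list(target_snr = snr), n_trials = 20, sfreq = 200,
    epoch_span = c(-200, 600), seed = seed)
  sim <- simulate_epochs(cfg, sensors = m$sensors, model = m$model,
                         grid = m$grid)
  list(sim = sim, v1 = v1, v2 = v2)
}

dssp_sim <- function(with_interference, seed = 5) {
  m <- full_montage()
  ic <- inside_coords(m$grid)
  v1 <- megsource:::nearest_inside_voxel(m$grid, c(35, 20, 30))
  tb <- tangential_basis(ic[v1, ], c(0, 0, 0))
  sources <- list(sim_source(ic[v1, ], tb[1, ], "evoked", freq = 10,
                             amplitude = 20, onset = 50, offset = 450))
  if (with_interference)
    sources <- c(sources, list(sim_source(c(400, 300, 0), c(0, 0, 1),
                                          "interference", freq = 60,
                                          amplitude = 5e4)))
  cfg <- sim_config(sources, noise = list(sensor_white = 2e-14),
                    n_trials = 10, sfreq = 200, epoch_span = c(-200, 600),
                    seed = seed)
  simulate_epochs(cfg, sensors = m$sensors, model = m$model, grid = m$grid)
}

as_chan_time <- function(a) matrix(aperm(a, c(2, 3, 1)), dim(a)[2],
                                   dim(a)[3] * dim(a)[1])

tf_fixture <- function() memo("tf_fixture", function() {
  m <- full_montage()
  ic <- inside_coords(m$grid)
  v1 <- megsource:::nearest_inside_voxel(m$grid, c(35, 20, 30))
  tb1 <- tangential_basis(ic[v1, ], c(0, 0, 0))
  cfg <- sim_config(list(sim_source(ic[v1, ], tb1[1, ], "induced", freq = 10,
                                    amplitude = 30, onset = 300,
                                    offset = 800)),
                    noise = list(target_snr = 10), n_trials = 20, sfreq = 200,
                    epoch_span = c(-1000, 1500), seed = 11)
  sim <- simulate_epochs(cfg, sensors = m$sensors, model = m$model,
                         grid = m$grid)
  wins <- make_windows(c(0, 900), 250, 50)
  spec <- tf_spec(bands = list(c(8, 12), c(18, 30)), active_windows = wins,
                  control_window = c(-800, -300))
  tf <- tf_reconstruct(sim$rec, m$lf, spec, method = "lcmv_scalar", reg = 0.05)
  list(m = m, sim = sim, v1 = v1, wins = wins, spec = spec, tf = tf)
})

band_noise_segments <- function(nseg, n, sfreq = 200, f0 = 10, seed = 2) {
  set.seed(seed)
  t <- (0:(n - 1)) / sfreq
  x <- matrix(0, nseg, n)
  for (s in seq_len(nseg))
    x[s, ] <- sin(2 * pi * f0 * t + runif(1, 0, 2 * pi)) + 0.1 * rnorm(n)
  x
}

stats_grid <- function() memo("stats_grid", function() make_source_grid(40, 10))

demo_config <- function(out_dir) {
  list(seed = 42,
       out_dir = out_dir,
       simulate = list(n_channels = 32, array_radius = 100,
                       sphere_radius = 60, grid_spacing = 15,
                       n_trials = 8, sfreq = 200, epoch_span = c(-300, 700),
                       noise = list(target_snr = 10),
                       sources = list(list(pos = c(20, 10, 25),
                                           orientation = c(0, 1, 0),
                                           kind = "evoked", freq = 10,
                                           amplitude = 20, onset = 0,
                                           offset = 500))),
       filter = list(band = c(2, 45)),
       evoked = list(method = "champagne", control_window = c(-300, 0)),
       export = list(what = "evoked_map"))
}
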