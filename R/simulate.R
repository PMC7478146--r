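#' Quasi-uniform sensor array on a spherical cap
#'
#' Emulates an axial-gradiometer MEG helmet (CTF-style geometry at
#' configurable scale): `n_channels` coils placed by a golden-angle spiral
#' on the upper cap of a sphere of `array_radius`, radially oriented, with
#' a fixed gradiometer baseline.
#'
#' @param n_channels number of channels (>= 8).
#' @param array_radius helmet radius, mm.
#' @param cap_fraction fraction of the sphere's polar angle covered
#'   (default 0.45: from the vertex down to ~81 degrees).
#' @param baseline axial gradiometer baseline, mm (default 50).
#' @param coil_type `"axial_gradiometer"` (default) or `"magnetometer"`.
#' @return A [sensor_array()].
#' @export
make_sensor_array <- function(n_channels, array_radius = 120,
                              cap_fraction = 0.45, baseline = 50,
                              coil_type = "axial_gradiometer") {
  if (n_channels < 8) stop_mg("need at least 8 channels")
  i <- seq_len(n_channels)
  zmin <- cos(pi * cap_fraction)
  z <- 1 - (1 - zmin) * (i - 0.5) / n_channels
  phi <- i * pi * (3 - sqrt(5))              # golden angle
  s <- sqrt(pmax(1 - z^2, 0))
  dirs <- cbind(s * cos(phi), s * sin(phi), z)
  sensor_array(sprintf("MEG%03d", i), dirs * array_radius, dirs,
               coil_type, if (coil_type == "magnetometer") 0 else baseline)
}

#' Spherical source grid
#'
#' Regular lattice covering a sphere, inside voxels those at least
#' `margin` mm below the surface (near-surface dipoles have near-singular
#' tangential gains and are excluded by default).
#'
#' @param radius sphere radius, mm.
#' @param spacing lattice spacing, mm.
#' @param center sphere center, mm (default origin).
#' @param margin surface margin, mm (default one voxel spacing).
#' @return A [source_grid()].
#' @export
make_source_grid <- function(radius = 80, spacing = 10, center = c(0, 0, 0),
                             margin = spacing) {
  m <- floor(radius / spacing)
  ax <- spacing * (-m:m)
  shape <- rep(2L * m + 1L, 3)
  pts <- as.matrix(expand.grid(x = ax, y = ax, z = ax))
  r <- sqrt(rowSums(pts^2))
  # the sphere-center voxel is excluded: its tangential plane is undefined
  # and gains there are near-singular
  inside <- r <= radius - margin & r >= 1
  source_grid(origin = center + c(ax[1], ax[1], ax[1]), spacing = spacing,
              shape = shape, inside_mask = inside)
}

#' Simulation configuration
#'
#' Defines the montage, head model, grid, dipole sources, noise and trial
#' structure of a synthetic MEG session. Defaults describe the package's
#' desk-scale study conditions: 64 axial gradiometers over an 80 mm
#' sphere, 10 mm grid, 1200 Hz decimated to `sfreq`.
#'
#' @param sources list of source descriptions, each from [sim_source()].
#' @param n_channels,array_radius,sphere_radius,grid_spacing montage and
#'   model geometry (mm).
#' @param noise list: `sensor_white` (tesla, per-sample white noise SD) or
#'   `target_snr` (power SNR of the summed brain-source signal in its
#'   active windows; overrides `sensor_white`).
#' @param n_trials,sfreq,epoch_span trials, sampling rate (Hz), epoch span
#'   (ms).
#' @param seed mandatory RNG seed; identical configs reproduce
#'   bit-identical data.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(sources, n_channels = 64, array_radius = 120,
                       sphere_radius = 80, grid_spacing = 10,
                       noise = list(sensor_white = 2e-14), n_trials = 20,
                       sfreq = 300, epoch_span = c(-500, 1000), seed) {
  if (missing(seed)) stop_mg("a seed is mandatory in sim_config")
  structure(list(sources = sources, n_channels = n_channels,
                 array_radius = array_radius, sphere_radius = sphere_radius,
                 grid_spacing = grid_spacing, noise = noise,
                 n_trials = n_trials, sfreq = sfreq,
                 epoch_span = as.numeric(epoch_span), seed = as.integer(seed)),
            class = "sim_config")
}

#' One simulated dipole source
#'
#' @param pos mm position. Brain sources (`evoked`/`induced`) must lie
#'   strictly inside the sphere, at least 1 mm from its center and one
#'   grid spacing below the surface; `interference` sources must lie
#'   outside (>= 1.5x sphere radius from center).
#' @param orientation moment direction (unit-normalized internally).
#' @param kind `"evoked"` (phase-locked Gaussian-windowed sinusoid,
#'   identical in every trial), `"induced"` (band-limited oscillation with
#'   per-trial random phase, amplitude raised in the window — cancels in
#'   the trial average) or `"interference"` (continuous external dipole,
#'   infinite-medium field).
#' @param freq oscillation frequency, Hz.
#' @param amplitude moment amplitude, nA*m.
#' @param onset,offset active window, ms.
#' @param condition restrict the source to trials of this condition label
#'   (default all trials).
#' @return list describing the source.
#' @export
sim_source <- function(pos, orientation, kind = c("evoked", "induced",
                                                  "interference"),
                       freq = 10, amplitude = 20, onset = 0, offset = 500,
                       condition = NULL) {
  kind <- match.arg(kind)
  o <- as.numeric(orientation); o <- o / vnorm(o)
  list(pos = as.numeric(pos), orientation = o, kind = kind, freq = freq,
       amplitude = amplitude, onset = onset, offset = offset,
       condition = condition)
}

# cosine-ramped rectangular envelope; ramps kept long (100 ms default) so
# the induced tone stays narrowband rather than splattering transient
# energy into higher bands
window_envelope <- function(times, onset, offset,
                            ramp_ms = min(100, (offset - onset) / 4)) {
  env <- numeric(length(times))
  inw <- times >= onset & times <= offset
  env[inw] <- 1
  up <- times >= onset & times < onset + ramp_ms
  env[up] <- 0.5 - 0.5 * cos(pi * (times[up] - onset) / ramp_ms)
  dn <- times > offset - ramp_ms & times <= offset
  env[dn] <- 0.5 - 0.5 * cos(pi * (offset - times[dn]) / ramp_ms)
  env
}

#' Simulate an epoched MEG recording with known ground truth
#'
#' Projects each configured dipole through the spherical-conductor forward
#' model (infinite-medium field for external interference sources), adds
#' white sensor noise, and records the per-source sensor-space components,
#' true voxels and achieved SNR.
#'
#' @param cfg a [sim_config()].
#' @param sensors,model,grid,lf optionally precomputed montage, head
#'   model, grid and lead field (built from the config when NULL; pass
#'   them when simulating many sessions on one montage).
#' @param conditions optional character vector of per-trial condition
#'   labels (default all `"trial"`).
#' @return list with `rec` (an [epoched_recording()]), `truth` (per-source
#'   true voxel index, per-trial waveforms, sensor components, achieved
#'   SNR, noise SD) and the montage objects used.
#' @export
simulate_epochs <- function(cfg, sensors = NULL, model = NULL, grid = NULL,
                            lf = NULL, conditions = NULL) {
  set.seed(cfg$seed)
  sensors <- sensors %||% make_sensor_array(cfg$n_channels, cfg$array_radius)
  model <- model %||% sphere_head_model(c(0, 0, 0), cfg$sphere_radius)
  grid <- grid %||% make_source_grid(cfg$sphere_radius, cfg$grid_spacing)
  nt <- cfg$n_trials; nc <- n_channels(sensors)
  times <- seq(cfg$epoch_span[1], cfg$epoch_span[2], by = 1000 / cfg$sfreq)
  ns <- length(times)
  conditions <- conditions %||% rep("trial", nt)
  inf_field <- function(dp, m, obs, centers) {
    out <- point_field_infinite(dp, m, obs)
    if (is.null(dim(out))) out <- matrix(out, 1, 3)
    out
  }
  truth <- list(sources = list(), noise_sd = NA_real_, seed = cfg$seed)
  signal <- array(0, c(nt, nc, ns))
  active_mask <- rep(FALSE, ns)
  brain_signal <- array(0, c(nt, nc, ns))
  for (si in seq_along(cfg$sources)) {
    src <- cfg$sources[[si]]
    r <- vnorm(src$pos)
    if (src$kind == "interference") {
      if (r < 1.5 * cfg$sphere_radius)
        stop_mg("interference source %d must lie >= 1.5x sphere radius from center", si)
      g <- all_channel_gains(src$pos, src$orientation, sensors, model,
                             field_fun = inf_field)
    } else {
      if (r >= cfg$sphere_radius - cfg$grid_spacing || r < 1)
        stop_mg("source %d at %g mm from center: brain sources must sit in [1, radius - spacing) mm", si, r)
      g <- all_channel_gains(src$pos, src$orientation, sensors, model)
    }
    amp <- src$amplitude * 1e-9
    wf <- matrix(0, nt, ns)
    on_trials <- if (is.null(src$condition)) seq_len(nt)
                 else which(conditions == src$condition)
    for (tr in on_trials) {
      wf[tr, ] <- switch(src$kind,
        evoked = {
          mid <- (src$onset + src$offset) / 2
          sdv <- (src$offset - src$onset) / 6
          amp * exp(-(times - mid)^2 / (2 * sdv^2)) *
            sin(2 * pi * src$freq * (times - src$onset) / 1000)
        },
        induced = {
          phase <- stats::runif(1, 0, 2 * pi)
          jitter <- stats::runif(1, 0.8, 1.2)
          amp * jitter * window_envelope(times, src$onset, src$offset) *
            sin(2 * pi * src$freq * times / 1000 + phase)
        },
        interference = {
          phase <- stats::runif(1, 0, 2 * pi)
          amp * sin(2 * pi * src$freq * times / 1000 + phase)
        })
    }
    comp <- array(0, c(nt, nc, ns))
    for (tr in seq_len(nt)) comp[tr, , ] <- outer(g, wf[tr, ])
    signal <- signal + comp
    if (src$kind != "interference") {
      brain_signal <- brain_signal + comp
      active_mask <- active_mask | (times >= src$onset & times <= src$offset)
    }
    truth$sources[[si]] <- list(
      kind = src$kind, pos = src$pos,
      voxel = if (src$kind != "interference") nearest_inside_voxel(grid, src$pos)
              else NA_integer_,
      waveforms = wf, component = comp, gain = g)
  }
  sigma <- cfg$noise$sensor_white %||% 0
  if (!is.null(cfg$noise$target_snr)) {
    sig_pow <- mean(brain_signal[, , active_mask]^2)
    sigma <- sqrt(sig_pow / cfg$noise$target_snr)
  }
  noise <- array(stats::rnorm(nt * nc * ns, sd = sigma), c(nt, nc, ns))
  data <- signal + noise
  if (any(active_mask) && sigma > 0)
    truth$snr_achieved <- mean(brain_signal[, , active_mask]^2) / sigma^2
  truth$noise_sd <- sigma
  rec <- epoched_recording(data, cfg$sfreq, times, conditions)
  list(rec = rec, truth = truth, sensors = sensors, model = model,
       grid = grid, lf = lf)
}

#' Simulate a multi-subject stack of source maps
#'
#' Null voxels are zero-mean Gaussian noise; effect voxels receive a
#' per-subject shift drawn from `N(shift, between_sd^2)` (the same draw
#' for every voxel of the effect set within a subject). Feeds the group
#' statistics tests at desk scale.
#'
#' @param grid a [source_grid()].
#' @param n_subjects number of subjects (>= 2).
#' @param effect list: `voxels` (inside-voxel indices, may be empty for a
#'   pure null), `shift` (mean effect), `between_sd` (between-subject SD
#'   of the effect).
#' @param noise_sd SD of the null voxel noise (default 1).
#' @param seed RNG seed.
#' @return list with `maps` (subjects x voxels matrix) and `truth`.
#' @export
simulate_group <- function(grid, n_subjects, effect = list(voxels = integer(),
                                                           shift = 0,
                                                           between_sd = 0),
                           noise_sd = 1, seed) {
  if (n_subjects < 2) stop_mg("need at least 2 subjects")
  nv <- n_inside(grid)
  if (length(effect$voxels) && (min(effect$voxels) < 1 ||
                                max(effect$voxels) > nv))
    stop_mg("effect voxels outside the grid (1..%d)", nv)
  set.seed(seed)
  maps <- matrix(stats::rnorm(n_subjects * nv, sd = noise_sd), n_subjects, nv)
  if (length(effect$voxels)) {
    shifts <- stats::rnorm(n_subjects, mean = effect$shift,
                           sd = effect$between_sd %||% 0)
    maps[, effect$voxels] <- maps[, effect$voxels] + shifts
  }
  list(maps = maps,
       truth = list(effect_voxels = effect$voxels,
                    shifts = if (length(effect$voxels)) shifts else numeric(),
                    noise_sd = noise_sd, seed = seed))
}
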