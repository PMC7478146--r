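.known_stage_keys <- c("seed", "out_dir", "simulate", "filter", "evoked",
                       "tfbeam", "fc", "stats", "export")

#' Validate a pipeline run configuration
#'
#' Schema-checks a config (list, or path to a YAML/JSON file) before any
#' computation: unknown top-level keys are rejected and band edges are
#' checked against Nyquist, so malformed runs fail fast with the offending
#' field named.
#'
#' @param config list or file path.
#' @return the validated config list, invisibly on error-free.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop_mg("config file not found: %s", config)
    config <- if (grepl("\\.json$", config, ignore.case = TRUE))
      jsonlite::fromJSON(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  unknown <- setdiff(names(config), .known_stage_keys)
  if (length(unknown))
    stop_mg("unknown config key(s): %s", paste(unknown, collapse = ", "))
  if (is.null(config$seed)) stop_mg("config$seed is required")
  sfreq <- config$simulate$sfreq %||% 300
  check_band <- function(band, where) {
    if (is.null(band)) return()
    hi <- band[2]
    if (is.finite(hi) && hi >= sfreq / 2)
      stop_mg("%s band [%g, %g] Hz: upper edge at or above Nyquist (%g Hz)",
              where, band[1], band[2], sfreq / 2)
  }
  check_band(config$filter$band, "filter")
  if (!is.null(config$tfbeam$bands))
    for (b in seq_along(config$tfbeam$bands))
      check_band(as.numeric(config$tfbeam$bands[[b]]), sprintf("tfbeam[%d]", b))
  check_band(config$fc$band, "fc")
  config
}

config_sources <- function(spec_list) {
  lapply(spec_list, function(s)
    sim_source(pos = as.numeric(s$pos),
               orientation = as.numeric(s$orientation %||% c(0, 1, 0)),
               kind = s$kind %||% "evoked", freq = s$freq %||% 10,
               amplitude = s$amplitude %||% 20, onset = s$onset %||% 0,
               offset = s$offset %||% 500, condition = s$condition))
}

#' Run a configured analysis pipeline
#'
#' Executes the requested stages in dependency order (simulate -> filter
#' -> evoked / tfbeam / fc / stats -> export), saving every produced
#' object as a container stamped with the config hash. Re-running an
#' identical config reproduces hash-identical payloads.
#'
#' @param config list or YAML/JSON path (see [validate_config()]).
#' @param out_dir output directory (default `config$out_dir`, else a
#'   tempdir).
#' @return list with `artifacts` (named file paths), `hashes` (md5 of each
#'   artifact's payload), and the in-memory results.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  config <- validate_config(config)
  out_dir <- out_dir %||% config$out_dir %||% tempfile("megsource_run_")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  # hash over the analysis content only: io locations must not change results
  cfg_hash <- md5_of(config[setdiff(names(config), "out_dir")])
  artifacts <- character(0); hashes <- character(0); results <- list()
  put <- function(obj, name) {
    path <- file.path(out_dir, paste0(name, ".rds"))
    if (inherits(obj, "source_estimate"))
      obj$provenance <- c(obj$provenance, list(config_hash = cfg_hash))
    save_container(obj, path)
    artifacts[[name]] <<- path
    hashes[[name]] <<- md5_of(unclass(obj))
    results[[name]] <<- obj
  }

  sim <- NULL
  if (!is.null(config$simulate)) {
    sc <- config$simulate
    cfg <- sim_config(sources = config_sources(sc$sources),
                      n_channels = sc$n_channels %||% 64,
                      array_radius = sc$array_radius %||% 120,
                      sphere_radius = sc$sphere_radius %||% 80,
                      grid_spacing = sc$grid_spacing %||% 10,
                      noise = sc$noise %||% list(sensor_white = 2e-14),
                      n_trials = sc$n_trials %||% 20,
                      sfreq = sc$sfreq %||% 300,
                      epoch_span = sc$epoch_span %||% c(-500, 1000),
                      seed = config$seed)
    sim <- simulate_epochs(cfg)
    sim$lf <- compute_leadfield(sim$grid, sim$sensors, sim$model)
    put(sim$rec, "recording")
  }
  rec <- sim$rec
  if (!is.null(config$filter) && !is.null(rec)) {
    fs <- filter_spec(as.numeric(config$filter$band),
                      family = config$filter$family %||% "Butterworth",
                      order = config$filter$order)
    rec <- apply_filter(rec, fs)
    put(rec, "recording_filtered")
  }
  if (!is.null(config$evoked) && !is.null(sim)) {
    ev <- config$evoked
    ctl <- as.numeric(ev$control_window %||% c(rec$times[1], 0))
    ncov <- estimate_covariance(rec, ctl)
    est <- switch(ev$method %||% "champagne",
      champagne = champagne(sim$lf, rec, regularize(ncov, "relative",
                                                    0.05)$matrix)$estimate,
      lcmv_vector = ,
      lcmv_scalar = {
        cov <- regularize(estimate_covariance(rec), "relative",
                          ev$reg %||% 0.05)
        filt <- if ((ev$method %||% "") == "lcmv_scalar")
          lcmv_scalar(sim$lf, cov) else lcmv_vector(sim$lf, cov)
        noise_normalized_power(filt, cov,
                               regularize(ncov, "relative", 0.05)$matrix)
      },
      sloreta = {
        filt <- min_norm(sim$lf, lambda = ev$lambda %||% 1e-6)
        avg <- apply(rec$data, c(2, 3), mean)
        source_estimate(sloreta_power(filt, sim$lf, avg), "power_active",
                        sim$grid, method = "sloreta")
      },
      stop_mg("unknown evoked method '%s'", ev$method))
    put(est, "evoked_map")
  }
  if (!is.null(config$tfbeam) && !is.null(sim)) {
    tb <- config$tfbeam
    wins <- make_windows(as.numeric(tb$active_span),
                         tb$window_length %||% 250, tb$window_overlap %||% 50)
    spec <- tf_spec(bands = lapply(tb$bands, as.numeric),
                    active_windows = wins,
                    control_window = as.numeric(tb$control_window),
                    weight_source = tb$weight_source %||% "combined")
    tf <- tf_reconstruct(rec, sim$lf, spec, method = tb$method %||% "lcmv_scalar",
                         reg = tb$reg %||% 0.05)
    put(tf_as_estimate(tf, "pseudoF"), "tf_pseudoF")
    results$tf <- tf
  }
  if (!is.null(config$fc) && !is.null(sim)) {
    fcc <- config$fc
    cov <- regularize(estimate_covariance(rec), "relative", fcc$reg %||% 0.05)
    filt <- lcmv_scalar(sim$lf, cov)
    tcs <- project_sources(filt, rec)
    spec <- fc_spec(fcc$metric %||% "imcoh", as.numeric(fcc$band),
                    seed = fcc$seed %||% list(type = "global"))
    put(seed_map(tcs, rec$sfreq, spec, sim$grid), "fc_map")
  }
  if (!is.null(config$stats)) {
    st <- config$stats
    grid <- sim$grid %||% make_source_grid(config$simulate$sphere_radius %||% 80,
                                           config$simulate$grid_spacing %||% 10)
    grp <- simulate_group(grid, st$n_subjects %||% 10,
                          effect = list(voxels = st$effect_voxels %||% integer(),
                                        shift = st$effect_shift %||% 0,
                                        between_sd = st$effect_between_sd %||% 0),
                          seed = config$seed + 1)
    sm <- snpm_test(group_sample(grp$maps, st$design %||% "one_sample"),
                    grid,
                    scheme = permutation_scheme(st$n_subjects %||% 10,
                                                st$max_permutations %||% 4096,
                                                seed = config$seed),
                    fwhm_mm = st$fwhm_mm %||% 20)
    put(sm, "stat_map")
  }
  if (!is.null(config$export)) {
    what <- config$export$what %||% "evoked_map"
    if (!is.null(results[[what]])) {
      path <- file.path(out_dir, paste0(what, ".nii.gz"))
      export_nifti(results[[what]], config$export$window %||% 1L,
                   config$export$band %||% 1L, path)
      artifacts[["nifti"]] <- path
    }
  }
  list(artifacts = artifacts, hashes = hashes, results = results,
       config_hash = cfg_hash, out_dir = out_dir)
}
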