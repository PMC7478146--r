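#' Sensor array geometry
#'
#' Describes an MEG sensor montage in head-frame coordinates: one row per
#' channel with a coil position (mm), a unit orientation vector, the coil
#' type, and, for axial gradiometers, the baseline (separation between the
#' pickup and compensation coils, mm).
#'
#' @param channel_id character vector of unique channel names.
#' @param position numeric n x 3 matrix, coil positions in mm (head frame,
#'   RAS).
#' @param orientation numeric n x 3 matrix of unit vectors (coil normal;
#'   for axial gradiometers also the axis along which the second coil sits).
#' @param coil_type character vector, each `"magnetometer"` or
#'   `"axial_gradiometer"`.
#' @param baseline numeric vector of gradiometer baselines in mm; must be 0
#'   for magnetometers and > 0 for gradiometers. A scalar is recycled.
#' @return An object of class `sensor_array`.
#' @export
sensor_array <- function(channel_id, position, orientation, coil_type,
                         baseline) {
  n <- length(channel_id)
  position <- as.matrix(position); orientation <- as.matrix(orientation)
  if (anyDuplicated(channel_id))
    stop_mg("channel ids must be unique")
  if (!identical(dim(position), c(n, 3L)) ||
      !identical(dim(orientation), c(n, 3L)))
    stop_mg("position and orientation must be %d x 3 matrices", n)
  if (any(abs(rownorms(orientation) - 1) > 1e-9))
    stop_mg("orientations must be unit-norm (tolerance 1e-9)")
  coil_type <- rep_len(coil_type, n)
  if (!all(coil_type %in% c("magnetometer", "axial_gradiometer")))
    stop_mg("coil_type must be 'magnetometer' or 'axial_gradiometer'")
  baseline <- rep_len(as.numeric(baseline), n)
  grad <- coil_type == "axial_gradiometer"
  if (any(baseline[grad] <= 0) || any(baseline[!grad] != 0))
    stop_mg("baseline must be > 0 exactly for axial gradiometers and 0 otherwise")
  structure(list(channel_id = as.character(channel_id), position = position,
                 orientation = orientation, coil_type = coil_type,
                 baseline = baseline),
            class = "sensor_array")
}

#' @export
print.sensor_array <- function(x, ...) {
  cat(sprintf("<sensor_array> %d channels (%s)\n", length(x$channel_id),
              paste(unique(x$coil_type), collapse = ", ")))
  invisible(x)
}

n_channels <- function(sensors) length(sensors$channel_id)

#' Epoched multi-channel recording
#'
#' @param data numeric array, trials x channels x samples, in tesla.
#' @param sfreq sampling rate in Hz.
#' @param times numeric vector of sample times in ms (0 = event onset);
#'   must be uniform and strictly increasing.
#' @param condition character vector of per-trial condition labels.
#' @return An object of class `epoched_recording`.
#' @export
epoched_recording <- function(data, sfreq, times, condition = NULL) {
  data <- unclass(data)
  if (length(dim(data)) != 3L)
    stop_mg("data must be a trials x channels x samples array")
  if (!is_scalar_num(sfreq) || sfreq <= 0) stop_mg("sfreq must be > 0")
  if (length(times) != dim(data)[3])
    stop_mg("length(times) (%d) must equal samples (%d)", length(times),
            dim(data)[3])
  if (length(times) > 1) {
    dt <- diff(times)
    if (any(dt <= 0) || (max(dt) - min(dt)) > 1e-9 * max(abs(dt)))
      stop_mg("times must be strictly increasing and uniform")
  }
  condition <- condition %||% rep("trial", dim(data)[1])
  if (length(condition) != dim(data)[1])
    stop_mg("one condition label per trial required")
  structure(list(data = data, sfreq = sfreq, times = as.numeric(times),
                 condition = as.character(condition)),
            class = "epoched_recording")
}

#' @export
print.epoched_recording <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoched_recording> %d trials x %d channels x %d samples @ %g Hz, t = [%g, %g] ms\n",
              d[1], d[2], d[3], x$sfreq, min(x$times), max(x$times)))
  invisible(x)
}

#' Regular volumetric source grid
#'
#' A full rectangular lattice of candidate source locations with an
#' inside-brain mask. Lattice order is x-fastest (R array order); lattice
#' indices are 0-based in the NIfTI affine convention.
#'
#' @param origin mm coordinate of lattice index (0,0,0).
#' @param spacing lattice spacing in mm (isotropic).
#' @param shape integer 3-vector of lattice extents.
#' @param inside_mask logical vector over all `prod(shape)` lattice points.
#' @return An object of class `source_grid`. `$voxel_coords` holds the mm
#'   coordinates of every lattice point; `$inside_idx` the indices of inside
#'   voxels (the rows of every per-voxel result array in this package).
#' @export
source_grid <- function(origin, spacing, shape, inside_mask) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L)) stop_mg("shape must be 3 positive extents")
  if (!is_scalar_num(spacing) || spacing <= 0) stop_mg("spacing must be > 0")
  np <- prod(shape)
  if (length(inside_mask) != np)
    stop_mg("inside_mask must have one entry per lattice point (%d)", np)
  if (!any(inside_mask)) stop_mg("at least one voxel must be inside")
  idx <- as.matrix(expand.grid(i = 0:(shape[1] - 1), j = 0:(shape[2] - 1),
                               k = 0:(shape[3] - 1)))
  coords <- sweep(idx * spacing, 2, as.numeric(origin), `+`)
  colnames(coords) <- c("x", "y", "z")
  structure(list(origin = as.numeric(origin), spacing = spacing,
                 shape = shape, inside_mask = as.logical(inside_mask),
                 voxel_coords = coords,
                 inside_idx = which(inside_mask)),
            class = "source_grid")
}

#' @export
print.source_grid <- function(x, ...) {
  cat(sprintf("<source_grid> %s lattice, %g mm spacing, %d/%d voxels inside\n",
              paste(x$shape, collapse = "x"), x$spacing,
              sum(x$inside_mask), length(x$inside_mask)))
  invisible(x)
}

n_inside <- function(grid) length(grid$inside_idx)

#' Coordinates of the inside voxels of a grid
#' @param grid a [source_grid()].
#' @return numeric matrix, inside-voxels x 3, mm.
#' @export
inside_coords <- function(grid) grid$voxel_coords[grid$inside_idx, , drop = FALSE]

# nearest inside voxel (index into inside ordering) for an mm position
nearest_inside_voxel <- function(grid, pos) {
  ic <- inside_coords(grid)
  d2 <- rowSums(sweep(ic, 2, pos)^2)
  which.min(d2)
}

#' Volumetric source-space result container
#'
#' Holds voxel-wise values (power, pseudo-F, connectivity, statistic or a
#' time course) over time windows and frequency bands, together with the
#' grid they live on and a provenance snapshot.
#'
#' @param values numeric array, inside-voxels x windows x bands (a matrix or
#'   vector is promoted).
#' @param kind one of `"power_active"`, `"power_control"`, `"pseudoF"`,
#'   `"timecourse"`, `"connectivity"`, `"statistic"`.
#' @param grid the [source_grid()] the voxel axis refers to.
#' @param windows numeric windows x 2 matrix of (start, end) ms pairs.
#' @param bands numeric bands x 2 matrix of (lo, hi) Hz pairs.
#' @param method character label of the generating method.
#' @param provenance list of free-form provenance metadata.
#' @return An object of class `source_estimate`.
#' @export
source_estimate <- function(values, kind, grid, windows = NULL, bands = NULL,
                            method = "unspecified", provenance = list()) {
  kinds <- c("power_active", "power_control", "pseudoF", "timecourse",
             "connectivity", "statistic")
  if (!kind %in% kinds)
    stop_mg("kind must be one of: %s", paste(kinds, collapse = ", "))
  if (is.null(dim(values))) values <- array(values, c(length(values), 1L, 1L))
  if (length(dim(values)) == 2L) values <- array(values, c(dim(values), 1L))
  windows <- windows %||% matrix(c(-Inf, Inf), 1L)
  bands <- bands %||% matrix(c(0, Inf), 1L)
  windows <- matrix(as.numeric(windows), ncol = 2L)
  bands <- matrix(as.numeric(bands), ncol = 2L)
  if (dim(values)[1] != n_inside(grid))
    stop_mg("values has %d voxels but grid has %d inside", dim(values)[1],
            n_inside(grid))
  if (dim(values)[2] != nrow(windows) || dim(values)[3] != nrow(bands))
    stop_mg("values shape (%s) inconsistent with %d windows x %d bands",
            paste(dim(values), collapse = "x"), nrow(windows), nrow(bands))
  if (any(windows[, 2] <= windows[, 1]))
    stop_mg("windows must be non-degenerate (end > start)")
  structure(list(values = values, kind = kind, grid = grid,
                 windows = windows, bands = bands, method = method,
                 provenance = provenance),
            class = "source_estimate")
}

#' @export
print.source_estimate <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<source_estimate> kind=%s method=%s: %d voxels x %d windows x %d bands\n",
              x$kind, x$method, d[1], d[2], d[3]))
  invisible(x)
}

#' Group statistical map
#'
#' Result of a nonparametric permutation test: a pseudo-t map with
#' uncorrected, FWER- and FDR-corrected p-values and (optionally) a
#' cluster-level correction.
#'
#' @param pseudo_t,p_uncorrected,p_fwer,p_fdr numeric arrays of identical
#'   voxels x windows x bands shape; p-values in (0, 1].
#' @param clusters list of cluster records (voxel indices, size, corrected p).
#' @param n_subjects,n_permutations integers.
#' @param test character test label.
#' @param grid,windows,bands as in [source_estimate()].
#' @return An object of class `stat_map`.
#' @export
stat_map <- function(pseudo_t, p_uncorrected, p_fwer, p_fdr,
                     clusters = list(), n_subjects, n_permutations,
                     test = "one_sample", grid = NULL, windows = NULL,
                     bands = NULL) {
  shp <- dim(pseudo_t)
  for (p in list(p_uncorrected, p_fwer, p_fdr)) {
    if (!identical(dim(p), shp)) stop_mg("p arrays must match pseudo_t shape")
    ok <- is.na(p) | (p > 0 & p <= 1)
    if (!all(ok)) stop_mg("p-values must lie in (0, 1]")
  }
  bad <- !is.na(p_fwer) & !is.na(p_uncorrected) & (p_fwer < p_uncorrected - 1e-12)
  if (any(bad)) stop_mg("p_fwer must dominate p_uncorrected elementwise")
  if (grepl("sign", test) && n_permutations > 2^n_subjects)
    stop_mg("at most 2^N sign-flip permutations exist")
  structure(list(pseudo_t = pseudo_t, p_uncorrected = p_uncorrected,
                 p_fwer = p_fwer, p_fdr = p_fdr, clusters = clusters,
                 n_subjects = n_subjects, n_permutations = n_permutations,
                 test = test, grid = grid, windows = windows, bands = bands),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  cat(sprintf("<stat_map> %s, N=%d, %d permutations, min FWER p = %.4g, %d clusters\n",
              x$test, x$n_subjects, x$n_permutations,
              suppressWarnings(min(x$p_fwer, na.rm = TRUE)),
              length(x$clusters)))
  invisible(x)
}
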