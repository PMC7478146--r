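MU0_OVER_4PI <- 1e-7  # T·m / (A·m)

#' Spherical conductor head model
#'
#' Either a single sphere center shared by all channels, or a per-channel
#' ("multisphere", CTF localSpheres style) table of centers. The radius is
#' used only for grid construction and inside tests: the MEG field of a
#' current dipole in a spherically symmetric conductor does not depend on
#' the sphere radius.
#'
#' @param center numeric length-3 mm vector, or an n-channels x 3 matrix of
#'   per-channel centers (rownames = channel ids recommended).
#' @param radius sphere radius in mm (> 0).
#' @return An object of class `sphere_head_model`.
#' @export
sphere_head_model <- function(center, radius) {
  if (!is_scalar_num(radius) || radius <= 0) stop_mg("radius must be > 0")
  if (is.matrix(center)) {
    if (ncol(center) != 3L) stop_mg("per-channel centers must be n x 3")
    type <- "multisphere"
  } else {
    center <- as.numeric(center)
    if (length(center) != 3L) stop_mg("center must be a 3-vector")
    type <- "single"
  }
  structure(list(center = center, radius = radius, type = type),
            class = "sphere_head_model")
}

# per-channel center matrix for a model
model_centers <- function(model, n) {
  if (model$type == "single")
    matrix(model$center, n, 3, byrow = TRUE)
  else {
    if (nrow(model$center) != n)
      stop_mg("multisphere model has %d centers for %d channels",
              nrow(model$center), n)
    model$center
  }
}

# Magnetic field of a current dipole inside a spherically symmetric
# conductor, evaluated at external points. Closed-form gradient formulation:
#   a = r - rq, F = a (R a + R^2 - rq.r)
#   grad F = (a^2/R + a.r/a + 2a + 2R) r - (a + 2R + a.r/a) rq
#   B = mu0/(4 pi F^2) (F (Q x rq) - (Q x rq . r) grad F)
# with r, rq relative to the sphere center. Radius-free and numerically
# stable away from F -> 0 (observation approaching the dipole's ray).
# `obs` is n x 3 (mm); `centers` a 3-vector or n x 3 matrix (mm);
# returns n x 3 tesla for a moment in A·m.
sarvas_field <- function(dipole_pos, moment, obs, centers) {
  obs <- matrix(obs, ncol = 3L)
  n <- nrow(obs)
  if (!is.matrix(centers)) centers <- matrix(centers, n, 3, byrow = TRUE)
  # work in metres
  r <- (obs - centers) * 1e-3
  rq <- (matrix(dipole_pos, n, 3, byrow = TRUE) - centers) * 1e-3
  a_v <- r - rq
  a <- sqrt(rowSums(a_v^2))
  if (any(a < 1e-12)) stop_mg("observation point coincides with the dipole")
  R <- sqrt(rowSums(r^2))
  if (any(R <= sqrt(rowSums(rq^2)) + 1e-12))
    stop_mg("observation point not outside the dipole's radius (inside sphere?)")
  rq_dot_r <- rowSums(rq * r)
  a_dot_r <- rowSums(a_v * r)
  F_ <- a * (R * a + R^2 - rq_dot_r)
  cF1 <- a^2 / R + a_dot_r / a + 2 * a + 2 * R
  cF2 <- a + 2 * R + a_dot_r / a
  gradF <- cF1 * r - cF2 * rq
  # Q x rq per row
  Q <- matrix(moment, n, 3, byrow = TRUE)
  qxrq <- cbind(Q[, 2] * rq[, 3] - Q[, 3] * rq[, 2],
                Q[, 3] * rq[, 1] - Q[, 1] * rq[, 3],
                Q[, 1] * rq[, 2] - Q[, 2] * rq[, 1])
  qxrq_dot_r <- rowSums(qxrq * r)
  (MU0_OVER_4PI / F_^2) * (F_ * qxrq - qxrq_dot_r * gradF)
}

#' Field of a current dipole in a conducting sphere
#'
#' Magnetic field (tesla) at a point outside the conductor produced by a
#' current dipole inside it. The result is independent of the sphere
#' radius, exactly linear in the moment, and exactly zero for radially
#' oriented dipoles (the silent sources of spherical conductors).
#'
#' @param dipole_pos dipole location, mm head frame.
#' @param moment dipole moment, A·m 3-vector.
#' @param obs_point observation point, mm.
#' @param center sphere center, mm.
#' @return tesla 3-vector.
#' @export
point_field_sphere <- function(dipole_pos, moment, obs_point, center) {
  drop(sarvas_field(as.numeric(dipole_pos), as.numeric(moment),
                    matrix(as.numeric(obs_point), 1, 3), as.numeric(center)))
}

#' Infinite-medium current dipole field
#'
#' Biot–Savart field mu0/4pi (Q x (r - rq)) / |r - rq|^3 of a current
#' dipole in free space. Used as the physical model for external
#' interference sources (outside any conductor) and as the reference whose
#' radial component the spherical-conductor field must reproduce (volume
#' currents contribute no radial field).
#'
#' @inheritParams point_field_sphere
#' @return tesla 3-vector (or n x 3 matrix for matrix `obs_point`).
#' @export
point_field_infinite <- function(dipole_pos, moment, obs_point) {
  obs <- matrix(obs_point, ncol = 3L)
  n <- nrow(obs)
  d <- (obs - matrix(dipole_pos, n, 3, byrow = TRUE)) * 1e-3
  dn <- sqrt(rowSums(d^2))
  if (any(dn < 1e-12)) stop_mg("observation point coincides with the dipole")
  Q <- matrix(moment, n, 3, byrow = TRUE)
  qxd <- cbind(Q[, 2] * d[, 3] - Q[, 3] * d[, 2],
               Q[, 3] * d[, 1] - Q[, 1] * d[, 3],
               Q[, 1] * d[, 2] - Q[, 2] * d[, 1])
  out <- MU0_OVER_4PI * qxd / dn^3
  if (nrow(out) == 1L) drop(out) else out
}

# scalar outputs of all channels for one dipole; sensor coil integration:
# magnetometer = B(pos) . orientation; axial gradiometer = first-order
# difference of that projection over the baseline along the coil axis.
all_channel_gains <- function(dipole_pos, moment, sensors, model,
                              field_fun = sarvas_field) {
  n <- n_channels(sensors)
  centers <- model_centers(model, n)
  B1 <- field_fun(dipole_pos, moment, sensors$position, centers)
  out <- rowSums(B1 * sensors$orientation)
  grad <- sensors$coil_type == "axial_gradiometer"
  if (any(grad)) {
    pos2 <- sensors$position[grad, , drop = FALSE] +
      sensors$baseline[grad] * sensors$orientation[grad, , drop = FALSE]
    B2 <- field_fun(dipole_pos, moment, pos2,
                    centers[grad, , drop = FALSE])
    out[grad] <- out[grad] -
      rowSums(B2 * sensors$orientation[grad, , drop = FALSE])
  }
  out
}

#' Single-channel gain of a dipole
#'
#' Output (tesla) of one sensor for a dipole with the given moment:
#' field projected on the coil orientation for magnetometers; the
#' difference of the projections at the pickup coil and at the coil
#' displaced by `baseline` along the orientation for axial gradiometers.
#'
#' @param dipole_pos,moment dipole location (mm) and moment (A·m).
#' @param sensors a [sensor_array()].
#' @param channel channel index or id.
#' @param model a [sphere_head_model()].
#' @return scalar tesla.
#' @export
channel_gain <- function(dipole_pos, moment, sensors, channel, model) {
  i <- if (is.character(channel)) match(channel, sensors$channel_id)
       else as.integer(channel)
  if (is.na(i) || i < 1 || i > n_channels(sensors))
    stop_mg("unknown channel")
  sub <- sensor_array(sensors$channel_id[i],
                      sensors$position[i, , drop = FALSE],
                      sensors$orientation[i, , drop = FALSE],
                      sensors$coil_type[i], sensors$baseline[i])
  m <- model
  if (model$type == "multisphere")
    m <- sphere_head_model(model$center[i, , drop = FALSE], model$radius)
  all_channel_gains(dipole_pos, moment, sub, m)
}

#' Deterministic tangential basis at a voxel
#'
#' Right-handed orthonormal pair spanning the plane tangential to the
#' sphere at the voxel: `e1 = normalize(z x rhat)` unless `|z x rhat| <
#' 1e-8` (voxel on the vertical axis), in which case `e1 = x`;
#' `e2 = rhat x e1`.
#'
#' @param voxel,center mm 3-vectors; `voxel != center`.
#' @return 2 x 3 matrix with rows e1, e2.
#' @export
tangential_basis <- function(voxel, center) {
  r <- as.numeric(voxel) - as.numeric(center)
  rn <- vnorm(r)
  if (rn < 1e-12) stop_mg("voxel coincides with the sphere center")
  rhat <- r / rn
  zxr <- c(-rhat[2], rhat[1], 0)          # z x rhat
  if (vnorm(zxr) < 1e-8) {
    e1 <- c(1, 0, 0)
  } else {
    e1 <- zxr / vnorm(zxr)
  }
  e2 <- c(rhat[2] * e1[3] - rhat[3] * e1[2],
          rhat[3] * e1[1] - rhat[1] * e1[3],
          rhat[1] * e1[2] - rhat[2] * e1[1])   # rhat x e1
  rbind(e1 = e1, e2 = e2)
}

#' Compute the lead-field grid
#'
#' Per-voxel gain matrices linking unit dipoles at every inside voxel of
#' the grid to all sensors. In `full3` mode the three columns are the
#' gains of unit dipoles along x, y, z (the radial combination of which is
#' numerically zero in a spherical conductor); in `tangential2` mode the
#' two columns correspond to the deterministic [tangential_basis()], which
#' spans all observable source orientations.
#'
#' @param grid a [source_grid()]; all inside voxels must lie strictly
#'   inside the sphere(s).
#' @param sensors a [sensor_array()].
#' @param model a [sphere_head_model()].
#' @param rank_mode `"tangential2"` (default) or `"full3"`.
#' @return An object of class `leadfield_grid` with `$gain` (inside-voxels
#'   x channels x k, tesla per A·m), `$basis` (tangential2 only), and the
#'   grid/model references.
#' @export
compute_leadfield <- function(grid, sensors, model,
                              rank_mode = c("tangential2", "full3")) {
  rank_mode <- match.arg(rank_mode)
  nv <- n_inside(grid)
  nc <- n_channels(sensors)
  coords <- inside_coords(grid)
  centers <- model_centers(model, nc)
  # inside-sphere check against every channel's sphere
  for (v in seq_len(nv)) {
    d <- sqrt(rowSums(sweep(centers, 2, coords[v, ])^2))
    if (any(d >= model$radius))
      stop_mg("voxel %d at (%s) mm lies outside a model sphere (radius %g)",
              v, paste(round(coords[v, ], 1), collapse = ", "), model$radius)
  }
  k <- if (rank_mode == "full3") 3L else 2L
  gain <- array(0, c(nv, nc, k))
  basis <- if (rank_mode == "tangential2") array(0, c(nv, 3L, 2L))
  ident <- diag(3)
  ctr_ref <- if (model$type == "single") model$center else colMeans(model$center)
  for (v in seq_len(nv)) {
    if (rank_mode == "full3") {
      for (j in 1:3)
        gain[v, , j] <- all_channel_gains(coords[v, ], ident[j, ], sensors, model)
    } else {
      tb <- tangential_basis(coords[v, ], ctr_ref)
      basis[v, , ] <- t(tb)
      for (j in 1:2)
        gain[v, , j] <- all_channel_gains(coords[v, ], tb[j, ], sensors, model)
    }
  }
  structure(list(gain = gain, grid = grid, rank_mode = rank_mode,
                 basis = basis, sensors = sensors, model = model),
            class = "leadfield_grid")
}

#' @export
print.leadfield_grid <- function(x, ...) {
  d <- dim(x$gain)
  cat(sprintf("<leadfield_grid> %d voxels x %d channels x %d (%s)\n",
              d[1], d[2], d[3], x$rank_mode))
  invisible(x)
}

# channels x k gain block of one voxel
voxel_gain <- function(lf, v) matrix(lf$gain[v, , ], dim(lf$gain)[2], dim(lf$gain)[3])

# horizontally stacked lead field: channels x (k * voxels)
stacked_gain <- function(lf) {
  d <- dim(lf$gain)
  # gain[v, c, k] -> L[, (v-1)*k + k'] = gain[v, , k']
  L <- aperm(lf$gain, c(2, 3, 1))
  dim(L) <- c(d[2], d[3] * d[1])
  L
}
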