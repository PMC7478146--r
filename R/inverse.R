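new_spatial_filter <- function(weights, method, lf, orientation = NULL,
                               flagged = NULL, extra = list()) {
  d <- dim(weights)
  structure(c(list(weights = weights, method = method, lf = lf,
                   orientation = orientation,
                   flagged = flagged %||% rep(FALSE, d[1]),
                   n_orient = d[3]),
              extra),
            class = "spatial_filter")
}

#' @export
print.spatial_filter <- function(x, ...) {
  d <- dim(x$weights)
  cat(sprintf("<spatial_filter> %s: %d voxels x %d channels x %d orientations (%d flagged)\n",
              x$method, d[1], d[2], d[3], sum(x$flagged)))
  invisible(x)
}

# channels x k weight block of one voxel
voxel_weights <- function(filt, v)
  matrix(filt$weights[v, , ], dim(filt$weights)[2], dim(filt$weights)[3])

#' LCMV vector beamformer
#'
#' Linearly constrained minimum-variance spatial filter with a full
#' orientation block per voxel: `W_v = R^-1 L_v (L_v' R^-1 L_v)^-1`, the
#' unit-gain (`W_v' L_v = I`) minimum-output-variance solution. Adaptive:
#' `R` is the (regularized) data covariance.
#'
#' @param lf a [leadfield_grid()].
#' @param cov a `covariance` (regularized so that it is invertible) or a
#'   plain SPD matrix.
#' @return A `spatial_filter`. Voxels where `L_v' R^-1 L_v` is singular are
#'   flagged and carry NaN weights.
#' @export
lcmv_vector <- function(lf, cov) {
  R <- if (is.matrix(cov)) cov else cov$matrix
  Ri <- sym_inv(R, "data covariance")
  d <- dim(lf$gain)
  W <- array(NA_real_, d)
  flagged <- rep(FALSE, d[1])
  for (v in seq_len(d[1])) {
    L <- voxel_gain(lf, v)
    RiL <- Ri %*% L
    A <- crossprod(L, RiL)
    Ai <- tryCatch(solve(A), error = function(e) NULL)
    if (is.null(Ai) || !all(is.finite(Ai))) { flagged[v] <- TRUE; next }
    W[v, , ] <- RiL %*% Ai
  }
  new_spatial_filter(W, "lcmv_vector", lf, flagged = flagged,
                     extra = list(cov = R))
}

#' LCMV scalar beamformer (SAM-style)
#'
#' One optimized orientation per voxel: the generalized eigenvector for
#' the extremal eigenvalue of `(L'R^-1 L, L'R^-2 L)`, which maximizes
#' noise-normalized output power. Weights are
#' `R^-1 L eta / (eta' L' R^-1 L eta)` (unit gain along `eta`).
#'
#' @inheritParams lcmv_vector
#' @return A `spatial_filter` with one orientation column; `$orientation`
#'   holds the optimizing unit 3-vector per voxel.
#' @export
lcmv_scalar <- function(lf, cov) {
  R <- if (is.matrix(cov)) cov else cov$matrix
  Ri <- sym_inv(R, "data covariance")
  Ri2 <- Ri %*% Ri
  d <- dim(lf$gain)
  W <- array(NA_real_, c(d[1], d[2], 1L))
  orient <- matrix(NA_real_, d[1], 3L)
  flagged <- rep(FALSE, d[1])
  for (v in seq_len(d[1])) {
    L <- voxel_gain(lf, v)
    A <- crossprod(L, Ri %*% L)
    B <- crossprod(L, Ri2 %*% L)
    # generalized symmetric eigenproblem via Cholesky whitening of B
    U <- tryCatch(chol((B + t(B)) / 2), error = function(e) NULL)
    if (is.null(U)) { flagged[v] <- TRUE; next }
    Uinv <- backsolve(U, diag(ncol(U)))
    S <- crossprod(Uinv, A %*% Uinv)
    e <- eigen((S + t(S)) / 2, symmetric = TRUE)
    eta <- Uinv %*% e$vectors[, 1]
    eta <- eta / vnorm(eta)
    denom <- drop(crossprod(eta, A %*% eta))
    if (!is.finite(denom) || denom <= 0) { flagged[v] <- TRUE; next }
    W[v, , 1] <- (Ri %*% (L %*% eta)) / denom
    orient[v, ] <- if (lf$rank_mode == "tangential2")
      drop(matrix(lf$basis[v, , ], 3, 2) %*% eta) else drop(eta)
  }
  new_spatial_filter(W, "lcmv_scalar", lf, orientation = orient,
                     flagged = flagged, extra = list(cov = R))
}

#' Eigenspace projection of beamformer weights
#'
#' Projects each voxel's weights onto the dominant (signal) eigenvector
#' subspace of the data covariance, reducing the noise sensitivity of the
#' reconstructed time courses.
#'
#' @param filt a `spatial_filter`.
#' @param cov data covariance (`covariance` or matrix).
#' @param signal_dim number of signal-subspace dimensions, `1 <= signal_dim
#'   <= channels` (equal to channels leaves the weights unchanged).
#' @return The projected `spatial_filter`.
#' @export
eigenspace_project <- function(filt, cov, signal_dim) {
  R <- if (is.matrix(cov)) cov else cov$matrix
  nc <- nrow(R)
  if (signal_dim < 1 || signal_dim > nc)
    stop_mg("signal_dim must be in [1, %d]", nc)
  Es <- eigen((R + t(R)) / 2, symmetric = TRUE)$vectors[, seq_len(signal_dim),
                                                        drop = FALSE]
  d <- dim(filt$weights)
  out <- filt
  for (v in seq_len(d[1])) {
    if (filt$flagged[v]) next
    Wv <- voxel_weights(filt, v)
    out$weights[v, , ] <- Es %*% crossprod(Es, Wv)
  }
  out$method <- paste0("eigenspace_", filt$method)
  out
}

#' Minimum-norm inverse operator
#'
#' Tikhonov-regularized minimum-norm solution: with `L` the horizontally
#' stacked lead fields, `W = L' (L L' + lambda C_n)^-1`, applied voxel-wise.
#'
#' @param lf a [leadfield_grid()].
#' @param noise_cov channels x channels noise covariance (default identity,
#'   scaled to the mean lead-field power so `lambda` is dimensionless).
#' @param lambda nonnegative regularization parameter.
#' @return A `spatial_filter` (method `"min_norm"`).
#' @export
min_norm <- function(lf, noise_cov = NULL, lambda = 1e-8) {
  if (lambda < 0) stop_mg("lambda must be >= 0")
  L <- stacked_gain(lf)
  nc <- nrow(L)
  Cn <- noise_cov %||% diag(mean(rowSums(L^2)), nc)
  if (is.list(Cn)) Cn <- Cn$matrix
  G <- tcrossprod(L) + lambda * Cn
  Gi <- tryCatch(sym_inv(G, "gram matrix"), error = function(e)
    stop_mg("L L' + lambda C_n is singular; increase lambda (> 0)"))
  Wfull <- crossprod(L, Gi)       # (k V) x channels
  d <- dim(lf$gain)
  W <- array(0, d)
  for (v in seq_len(d[1]))
    W[v, , ] <- t(Wfull[(v - 1) * d[3] + seq_len(d[3]), , drop = FALSE])
  new_spatial_filter(W, "min_norm", lf,
                     extra = list(noise_cov = Cn, lambda = lambda))
}

#' dSPM noise normalization factors
#'
#' Per-voxel divisor `sqrt(trace(W_v' C_n W_v))`: dividing minimum-norm
#' amplitudes by it (powers by its square) makes pure-noise input give an
#' expected normalized power of `n_orient` at every voxel.
#'
#' @param filt a minimum-norm `spatial_filter`.
#' @param noise_cov noise covariance matrix (defaults to the one stored in
#'   the filter).
#' @return numeric vector of per-voxel divisors; zero divisors are NaN
#'   (flagged).
#' @export
dspm_normalize <- function(filt, noise_cov = NULL) {
  Cn <- noise_cov %||% filt$noise_cov
  if (is.list(Cn)) Cn <- Cn$matrix
  d <- dim(filt$weights)
  out <- numeric(d[1])
  for (v in seq_len(d[1])) {
    Wv <- voxel_weights(filt, v)
    out[v] <- sqrt(sum(diag(crossprod(Wv, Cn %*% Wv))))
  }
  out[out == 0] <- NaN
  out
}

#' sLORETA standardization matrices
#'
#' Per-voxel resolution block `R_v = W_v' L_v` of a minimum-norm filter;
#' the standardized source power of an estimate `s_v` is
#' `s_v' R_v^-1 s_v`. For noiseless single sources this standardization
#' has zero localization error.
#'
#' @param filt a minimum-norm `spatial_filter`.
#' @param lf the [leadfield_grid()] the filter was built from.
#' @return list with `R` (voxels x k x k array) and logical `flagged`
#'   (singular blocks).
#' @export
sloreta_standardize <- function(filt, lf) {
  d <- dim(filt$weights)
  R <- array(NA_real_, c(d[1], d[3], d[3]))
  flagged <- rep(FALSE, d[1])
  for (v in seq_len(d[1])) {
    Rv <- crossprod(voxel_weights(filt, v), voxel_gain(lf, v))
    Rv <- (Rv + t(Rv)) / 2
    R[v, , ] <- Rv
    ev <- eigen(Rv, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= .Machine$double.eps * max(abs(ev)) * d[3])
      flagged[v] <- TRUE
  }
  list(R = R, flagged = flagged)
}

#' sLORETA standardized power map
#'
#' Applies a minimum-norm filter to a sensor vector (or channels x time
#' matrix, in which case powers are averaged over time) and standardizes
#' each voxel's power by its resolution block.
#'
#' @param filt minimum-norm `spatial_filter`.
#' @param lf the matching [leadfield_grid()].
#' @param y sensor vector (channels) or channels x time matrix.
#' @param std optional precomputed [sloreta_standardize()] result.
#' @return numeric per-voxel standardized power (NaN at flagged voxels).
#' @export
sloreta_power <- function(filt, lf, y, std = NULL) {
  std <- std %||% sloreta_standardize(filt, lf)
  y <- as.matrix(y)
  d <- dim(filt$weights)
  out <- rep(NaN, d[1])
  for (v in seq_len(d[1])) {
    if (std$flagged[v]) next
    s <- crossprod(voxel_weights(filt, v), y)    # k x T
    Rv <- matrix(std$R[v, , ], d[3], d[3])
    out[v] <- mean(colSums(s * solve(Rv, s)))
  }
  out
}

#' Virtual sensor: reconstructed source time course at one voxel
#'
#' @param filt a `spatial_filter`.
#' @param rec an [epoched_recording()].
#' @param voxel inside-voxel index.
#' @param average average across trials first? (default TRUE)
#' @return orientations x samples matrix (average) or an orientations x
#'   samples x trials array. Units A·m for unit-gain filters.
#' @export
virtual_sensor <- function(filt, rec, voxel, average = TRUE) {
  if (filt$flagged[voxel]) stop_mg("voxel %d is flagged (singular)", voxel)
  Wv <- voxel_weights(filt, voxel)
  d <- dim(rec$data)
  if (average) {
    avg <- apply(rec$data, c(2, 3), mean)
    crossprod(Wv, avg)
  } else {
    out <- array(0, c(ncol(Wv), d[3], d[1]))
    for (tr in seq_len(d[1]))
      out[, , tr] <- crossprod(Wv, matrix(rec$data[tr, , ], d[2], d[3]))
    out
  }
}

#' Source power map (optionally noise-normalized, "pseudo-Z")
#'
#' Per-voxel output power `trace(W_v' C W_v)`; when a noise covariance is
#' supplied the map is divided by the projected noise power
#' `trace(W_v' C_n W_v)`, which removes the depth bias of unnormalized
#' beamformer power.
#'
#' @param filt a `spatial_filter`.
#' @param cov data covariance (`covariance` or matrix).
#' @param noise_cov optional noise covariance for normalization.
#' @return A [source_estimate()] (kind `"power_active"`); flagged voxels
#'   are NaN.
#' @export
noise_normalized_power <- function(filt, cov, noise_cov = NULL) {
  C <- if (is.matrix(cov)) cov else cov$matrix
  Cn <- noise_cov
  if (is.list(Cn)) Cn <- Cn$matrix
  d <- dim(filt$weights)
  p <- rep(NaN, d[1])
  for (v in seq_len(d[1])) {
    if (filt$flagged[v]) next
    Wv <- voxel_weights(filt, v)
    p[v] <- sum(diag(crossprod(Wv, C %*% Wv)))
    if (!is.null(Cn)) {
      np <- sum(diag(crossprod(Wv, Cn %*% Wv)))
      p[v] <- if (np > 0) p[v] / np else NaN
    }
  }
  method <- if (is.null(Cn)) paste0(filt$method, "_power")
            else paste0(filt$method, "_pseudoZ")
  source_estimate(p, "power_active", filt$lf$grid, method = method)
}

#' Peak voxel of a per-voxel map
#'
#' Argmax over inside voxels with NaN (flagged) entries excluded; ties are
#' broken deterministically in favour of the lowest voxel index.
#' @param x numeric per-voxel vector or a [source_estimate()] (first
#'   window/band slice).
#' @return integer inside-voxel index.
#' @export
peak_voxel <- function(x) {
  if (inherits(x, "source_estimate")) x <- x$values[, 1, 1]
  ok <- which(is.finite(x))
  if (!length(ok)) stop_mg("no finite voxel values")
  ok[which.max(x[ok])]
}
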