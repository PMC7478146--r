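toy_lf <- function(nv = 10, nc = 16, k = 2, seed = 1) {
  set.seed(seed)
  grid <- source_grid(c(0, 0, 0), 10, c(nv, 1, 1), rep(TRUE, nv))
  structure(list(gain = array(rnorm(nv * nc * k), c(nv, nc, k)),
                 grid = grid, rank_mode = "tangential2", basis = NULL,
                 sensors = NULL, model = NULL),
            class = "leadfield_grid")
}

test_that("LCMV unit-gain constraint holds on random SPD covariances", {
  m <- mini_montage()
  nv <- n_inside(m$grid)
  k <- dim(m$lf$gain)[3]
  set.seed(31)
  for (i in 1:20) {
    R <- random_spd(length(m$sensors$channel_id)) * 1e-26
    filt <- lcmv_vector(m$lf, R)
    for (v in sample(nv, 5)) {
      WtL <- crossprod(megsource:::voxel_weights(filt, v),
                       megsource:::voxel_gain(m$lf, v))
      expect_lt(max(abs(WtL - diag(k))), 1e-8)
    }
  }
  # identity covariance reduces to the pseudoinverse transpose
  filt_i <- lcmv_vector(m$lf, diag(length(m$sensors$channel_id)))
  v <- 7
  L <- megsource:::voxel_gain(m$lf, v)
  expect_equal(megsource:::voxel_weights(filt_i, v),
               L %*% solve(crossprod(L)), tolerance = 1e-8)
})

test_that("scalar beamformer orientation matches a brute-force search", {
  m <- mini_montage()
  set.seed(32)
  R <- random_spd(length(m$sensors$channel_id)) * 1e-26
  filt <- lcmv_scalar(m$lf, R)
  Ri <- solve(R); Ri2 <- Ri %*% Ri
  for (v in c(3, 20, 50)) {
    L <- megsource:::voxel_gain(m$lf, v)
    A <- crossprod(L, Ri %*% L); B <- crossprod(L, Ri2 %*% L)
    # 1-degree grid over tangential angles
    angs <- seq(0, pi, by = pi / 180)
    crit <- vapply(angs, function(a) {
      e <- c(cos(a), sin(a))
      drop(crossprod(e, A %*% e) / crossprod(e, B %*% e))
    }, numeric(1))
    best <- c(cos(angs[which.max(crit)]), sin(angs[which.max(crit)]))
    eta3 <- filt$orientation[v, ]
    best3 <- drop(matrix(m$lf$basis[v, , ], 3, 2) %*% best)
    expect_gt(abs(sum(eta3 * best3)), cos(2 * pi / 180))  # within 2 degrees
    # optimality: scalar output power >= any tested fixed orientation
    w_pow <- function(e) {
      w <- (Ri %*% (L %*% e)) / drop(crossprod(e, A %*% e))
      drop(crossprod(w, R %*% w)) /
        drop(crossprod(w, w))               # noise-normalized
    }
    eta2 <- drop(crossprod(matrix(m$lf$basis[v, , ], 3, 2), eta3))
    expect_gte(w_pow(eta2) + 1e-9, max(vapply(angs[seq(1, 181, 20)],
      function(a) w_pow(c(cos(a), sin(a))), numeric(1))))
  }
})

test_that("scalar beamformer recovers the true source orientation at high SNR", {
  m <- full_montage()
  vset <- deep_voxels(m)
  set.seed(33)
  v <- vset[17]
  sim <- simulate_one_source(m, v, "evoked", seed = 2, snr = 100,
                             freq = 10, amplitude = 20, onset = 0,
                             offset = 500)
  cov <- regularize(estimate_covariance(sim$rec, c(0, 500)), "relative", 0.01)
  filt <- lcmv_scalar(m$lf, cov)
  true_orient <- tangential_basis(inside_coords(m$grid)[v, ], c(0, 0, 0))[1, ]
  ang <- acos(min(abs(sum(filt$orientation[v, ] * true_orient)), 1)) * 180 / pi
  expect_lt(ang, 5)
})

test_that("eigenspace projection: completeness, span, and denoising", {
  m <- mini_montage()
  nc <- length(m$sensors$channel_id)
  set.seed(34)
  R <- random_spd(nc) * 1e-26
  filt <- lcmv_vector(m$lf, R)
  # full signal space leaves weights unchanged
  full <- eigenspace_project(filt, R, nc)
  expect_equal(full$weights, filt$weights, tolerance = 1e-10)
  expect_error(eigenspace_project(filt, R, 0), "signal_dim")
  # projected weights lie in span(E_s)
  proj <- eigenspace_project(filt, R, 3)
  Es <- eigen(R, symmetric = TRUE)$vectors[, 1:3]
  for (v in c(1, 11)) {
    W <- megsource:::voxel_weights(proj, v)
    resid <- W - Es %*% crossprod(Es, W)
    expect_lt(max(abs(resid)), 1e-10 * max(abs(filt$weights)))
  }
  # rank-1 signal + noise: dim-1 projection keeps the source time course
  mf <- full_montage()
  v <- deep_voxels(mf)[40]
  sim <- simulate_one_source(mf, v, "evoked", seed = 3, snr = 5,
                             freq = 8, amplitude = 20, onset = 0, offset = 500)
  cov <- regularize(estimate_covariance(sim$rec), "relative", 0.05)
  filt <- eigenspace_project(lcmv_scalar(mf$lf, cov), cov, 1)
  tc <- drop(virtual_sensor(filt, sim$rec, v))
  truth <- colMeans(sim$truth$sources[[1]]$waveforms)
  expect_gt(abs(cor(tc, truth)), 0.99)
})

test_that("minimum norm equals the closed-form Tikhonov oracle", {
  lf <- toy_lf(nv = 10, nc = 16, k = 2, seed = 41)
  L <- megsource:::stacked_gain(lf)
  nc <- nrow(L)
  lambda <- 0.5
  filt <- min_norm(lf, noise_cov = diag(nc), lambda = lambda)
  set.seed(42)
  y <- rnorm(nc)
  # independent least-squares oracle: (L'L + lambda I)^-1 L' y
  s_oracle <- solve(crossprod(L) + lambda * diag(ncol(L)), crossprod(L, y))
  s_filt <- as.numeric(vapply(seq_len(10), function(v)
    drop(crossprod(megsource:::voxel_weights(filt, v), y)), numeric(2)))
  expect_equal(s_filt, as.numeric(s_oracle), tolerance = 1e-10)
  # weights shrink as 1/lambda
  f1 <- min_norm(lf, noise_cov = diag(nc), lambda = 1e3)
  f2 <- min_norm(lf, noise_cov = diag(nc), lambda = 1e4)
  expect_equal(sum(abs(f1$weights)) / sum(abs(f2$weights)), 10,
               tolerance = 0.2)
  # near-noiseless single source: data fit residual < 1%
  s_true <- numeric(20); s_true[7] <- 1
  y0 <- drop(L %*% s_true)
  f0 <- min_norm(lf, noise_cov = diag(nc), lambda = 1e-8)
  s_hat <- as.numeric(vapply(seq_len(10), function(v)
    drop(crossprod(megsource:::voxel_weights(f0, v), y0)), numeric(2)))
  expect_lt(sqrt(sum((drop(L %*% s_hat) - y0)^2)) / sqrt(sum(y0^2)), 0.01)
})

test_that("dSPM normalization: unit case, homogeneity, noise calibration", {
  lf <- toy_lf(nv = 8, nc = 12, k = 2, seed = 51)
  nc <- 12
  # single unit row divisor
  f <- min_norm(lf, noise_cov = diag(nc), lambda = 0.1)
  unit <- f
  unit$weights[1, , ] <- 0
  unit$weights[1, 1, 1] <- 1
  expect_equal(dspm_normalize(unit, diag(nc))[1], 1)
  # divisor is invariant to data scale; normalized power scales with data^2
  div <- dspm_normalize(f, diag(nc))
  expect_true(all(is.finite(div)))
  set.seed(52)
  y <- rnorm(nc)
  pow <- vapply(seq_len(8), function(v)
    sum(crossprod(megsource:::voxel_weights(f, v), y)^2), numeric(1))
  expect_equal((pow * 100) / div^2, sum_pow_10 <- vapply(seq_len(8),
    function(v) sum(crossprod(megsource:::voxel_weights(f, v), 10 * y)^2),
    numeric(1)) / div^2, tolerance = 1e-10)
  # Monte-Carlo: white-noise input gives normalized power ~ 1 per component
  nT <- 20000
  Y <- matrix(rnorm(nc * nT), nc)
  npow <- vapply(seq_len(8), function(v)
    mean(colSums(crossprod(megsource:::voxel_weights(f, v), Y)^2)), numeric(1)) /
    div^2
  expect_true(all(abs(npow - 1) < 0.1))
})

test_that("sLORETA: resolution blocks PSD, exact toy, zero localization error", {
  # two orthonormal lead fields, lambda = 0: standardized power is exact
  grid2 <- source_grid(c(0, 0, 0), 10, c(2, 1, 1), c(TRUE, TRUE))
  lf2 <- structure(list(gain = array(c(1, 0, 0, 1), c(2, 2, 1)), grid = grid2,
                        rank_mode = "tangential2", basis = NULL),
                   class = "leadfield_grid")
  f2 <- min_norm(lf2, noise_cov = diag(2), lambda = 0)
  p <- sloreta_power(f2, lf2, c(3, 0))
  expect_equal(p[1], 9, tolerance = 1e-10)
  expect_equal(p[2], 0, tolerance = 1e-10)

  m <- full_montage()
  filt <- min_norm(m$lf, lambda = 1e-8)
  std <- sloreta_standardize(filt, m$lf)
  for (v in c(5, 100, 600)) {
    Rv <- matrix(std$R[v, , ], 2, 2)
    expect_equal(Rv, t(Rv), tolerance = 1e-12)
    expect_gt(min(eigen(Rv, symmetric = TRUE, only.values = TRUE)$values), 0)
  }
  # zero localization error on noiseless single sources
  vset <- deep_voxels(m, rmin = 12, rmax = 60)
  set.seed(61)
  ic <- inside_coords(m$grid)
  for (v in sample(vset, 12)) {
    tb <- tangential_basis(ic[v, ], c(0, 0, 0))
    ang <- runif(1, 0, 2 * pi)
    mom <- cos(ang) * tb[1, ] + sin(ang) * tb[2, ]
    y <- megsource:::all_channel_gains(ic[v, ], mom * 1e-8, m$sensors, m$model)
    expect_identical(peak_voxel(sloreta_power(filt, m$lf, y, std)), v)
  }
})

test_that("virtual sensor: unit gain, linearity, evoked peak latency", {
  m <- full_montage()
  v <- deep_voxels(m)[25]
  # 8.6 Hz: incommensurate with the Gaussian envelope midpoint, so the
  # true waveform has a unique global peak (a 10 Hz tone peaks twice,
  # symmetrically, and the argmax tie-break is noise-driven)
  sim <- simulate_one_source(m, v, "evoked", seed = 4, sensor_white = 1e-18,
                             freq = 8.6, amplitude = 20, onset = 0,
                             offset = 500)
  cov <- regularize(estimate_covariance(sim$rec, c(0, 500)), "relative", 1e-8)
  filt <- lcmv_vector(m$lf, cov)
  # unit gain: filter applied to its own voxel's forward field recovers the
  # source amplitude in the tangential basis
  L <- megsource:::voxel_gain(m$lf, v)
  e1 <- c(1, 0)
  rec1 <- drop(crossprod(megsource:::voxel_weights(filt, v), L %*% e1))
  expect_equal(rec1, e1, tolerance = 1e-6)
  # peak latency within one sample of the true source peak
  tc <- virtual_sensor(filt, sim$rec, v)
  amp <- sqrt(colSums(tc^2))
  truth <- colMeans(abs(sim$truth$sources[[1]]$waveforms))
  expect_lte(abs(which.max(amp) - which.max(truth)), 1)
  # linearity in the data
  rec2 <- sim$rec; rec2$data <- 2 * rec2$data
  expect_equal(virtual_sensor(filt, rec2, v), 2 * tc, tolerance = 1e-12)
  filt$flagged[v] <- TRUE
  expect_error(virtual_sensor(filt, sim$rec, v), "flagged")
})

test_that("power maps: normalization identity, quadratic scaling, localization", {
  m <- full_montage()
  v <- deep_voxels(m)[55]
  sim <- simulate_one_source(m, v, "evoked", seed = 5, snr = 10,
                             freq = 10, amplitude = 20, onset = 0,
                             offset = 500)
  cov <- regularize(estimate_covariance(sim$rec, c(0, 500)), "relative", 0.05)
  ncov <- regularize(estimate_covariance(sim$rec, c(-300, 0)), "relative", 0.05)
  filt <- lcmv_vector(m$lf, cov)
  # cov == noise_cov  =>  normalized power = 1 everywhere
  same <- noise_normalized_power(filt, cov, cov)
  expect_equal(range(same$values), c(1, 1), tolerance = 1e-8)
  # power scales quadratically with source amplitude
  p1 <- noise_normalized_power(filt, cov$matrix)
  p4 <- noise_normalized_power(filt, 4 * cov$matrix)
  expect_equal(p4$values, 4 * p1$values, tolerance = 1e-10)
  # noise-normalized map peaks at the true voxel
  pz <- noise_normalized_power(filt, cov, ncov)
  expect_identical(peak_voxel(pz), v)
})
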