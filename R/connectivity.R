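#' Functional connectivity specification
#'
#' @param metric one of `"imcoh"` (imaginary coherence), `"msc"`
#'   (magnitude-squared coherence), `"pli"` (phase lag index), `"aec"`
#'   (amplitude envelope correlation), `"glc"` (general lagged coherence).
#' @param band (lo, hi) Hz analysis band.
#' @param seed `list(type = "voxel", index = i)`,
#'   `list(type = "roi", index = <voxel indices>)`, or
#'   `list(type = "global")`.
#' @param segment_length spectral segment length in samples (>= 8; only
#'   used in resting mode — task mode treats each epoch as one segment).
#' @param segment_overlap overlap fraction in `[0, 1)` for resting mode.
#' @param mode `"task_epochs"` or `"resting_continuous"`.
#' @param roi_average `"timecourse"` (metric of the mean ROI time course;
#'   default) or `"metric"` (mean of per-voxel metrics).
#' @param global_average `"fisher_z"` (default) or `"raw"`.
#' @return An object of class `fc_spec`.
#' @export
fc_spec <- function(metric = c("imcoh", "msc", "pli", "aec", "glc"),
                    band, seed = list(type = "global"),
                    segment_length = 256L, segment_overlap = 0.5,
                    mode = c("task_epochs", "resting_continuous"),
                    roi_average = c("timecourse", "metric"),
                    global_average = c("fisher_z", "raw")) {
  metric <- match.arg(metric)
  mode <- match.arg(mode)
  if (segment_length < 8) stop_mg("segment_length must be >= 8 samples")
  if (segment_overlap < 0 || segment_overlap >= 1)
    stop_mg("segment_overlap must lie in [0, 1)")
  structure(list(metric = metric, band = as.numeric(band), seed = seed,
                 segment_length = as.integer(segment_length),
                 segment_overlap = segment_overlap, mode = mode,
                 roi_average = match.arg(roi_average),
                 global_average = match.arg(global_average)),
            class = "fc_spec")
}

#' Project sensor data through a spatial filter
#'
#' Linear combination of the sensor data with each voxel's weights,
#' producing source-space time courses. Scalar (one-orientation) filters
#' project directly; vector filters are first reduced to their dominant
#' orientation (`reduce = "svd"`, the leading left singular vector of the
#' voxel's orientation-resolved time course) or rejected
#' (`reduce = "none"`).
#'
#' @param filt a `spatial_filter`.
#' @param rec an [epoched_recording()].
#' @param reduce `"none"` (error on vector filters) or `"svd"`.
#' @return voxels x trials x samples array.
#' @export
project_sources <- function(filt, rec, reduce = c("none", "svd")) {
  reduce <- match.arg(reduce)
  d <- dim(rec$data)
  dw <- dim(filt$weights)
  nv <- dw[1]
  if (dw[3] > 1 && reduce == "none")
    stop_mg("vector filter: choose a reduction policy (reduce = \"svd\") or use a scalar method")
  out <- array(0, c(nv, d[1], d[3]))
  Y <- matrix(aperm(rec$data, c(2, 3, 1)), d[2], d[3] * d[1])
  for (v in seq_len(nv)) {
    if (filt$flagged[v]) { out[v, , ] <- NaN; next }
    S <- crossprod(voxel_weights(filt, v), Y)    # k x (samples*trials)
    if (nrow(S) > 1) {
      u1 <- svd(S, nu = 1, nv = 0)$u[, 1]
      S <- matrix(colSums(u1 * S), 1)
    }
    out[v, , ] <- t(matrix(S, d[3], d[1]))
  }
  out
}

# Split a time course set into spectral segments.
# x: trials x samples matrix. Returns samples x segments matrix.
spectral_segments <- function(x, spec) {
  x <- as.matrix(x)
  if (spec$mode == "task_epochs") {
    t(x)                                      # one segment per epoch
  } else {
    v <- as.numeric(t(x))
    len <- spec$segment_length
    step <- max(1L, as.integer(round(len * (1 - spec$segment_overlap))))
    starts <- seq(1L, length(v) - len + 1L, by = step)
    vapply(starts, function(s) v[s:(s + len - 1L)], numeric(len))
  }
}

# Per-segment band-averaged auto/cross spectra with a Hann taper.
# segs_*: samples x segments. Returns list(sxy = complex per segment,
# sxx, syy = numeric per segment).
segment_band_spectra <- function(segs_x, segs_y, sfreq, band) {
  n <- nrow(segs_x)
  taper <- 0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1))
  freqs <- (seq_len(n) - 1) * sfreq / n
  bins <- which(freqs >= band[1] & freqs <= band[2] & freqs <= sfreq / 2)
  if (!length(bins))
    stop_mg("band [%g, %g] Hz contains no frequency bins at this segment length",
            band[1], band[2])
  X <- stats::mvfft(segs_x * taper)
  Y <- stats::mvfft(segs_y * taper)
  list(sxy = colMeans(matrix(X[bins, , drop = FALSE] *
                             Conj(Y[bins, , drop = FALSE]), length(bins))),
       sxx = colMeans(matrix(abs(X[bins, , drop = FALSE])^2, length(bins))),
       syy = colMeans(matrix(abs(Y[bins, , drop = FALSE])^2, length(bins))),
       n_segments = ncol(segs_x))
}

#' Averaged cross-spectrum of two time courses
#'
#' Welch-style segment-averaged band cross-spectrum. In task mode each
#' epoch is one segment; in resting mode sliding (overlapping) segments
#' are cut from the continuous record. Hermitian by construction:
#' `S_xy = Conj(S_yx)`.
#'
#' @param x,y trials x samples matrices (or vectors) of two source time
#'   courses.
#' @param sfreq sampling rate, Hz.
#' @param band (lo, hi) Hz band to average over.
#' @param spec an [fc_spec()] controlling segmentation.
#' @return list with complex `sxy` and real `sxx`, `syy` (band-and-segment
#'   averaged), per-segment values (`sxy_seg`, ...) and `n_segments`.
#' @export
cross_spectra <- function(x, y, sfreq, band, spec = fc_spec("imcoh", band)) {
  if (is.null(dim(x))) x <- matrix(x, 1)
  if (is.null(dim(y))) y <- matrix(y, 1)
  sx <- spectral_segments(x, spec)
  sy <- spectral_segments(y, spec)
  if (ncol(sx) < 2) stop_mg("need >= 2 segments for coherence estimates")
  ss <- segment_band_spectra(sx, sy, sfreq, band)
  list(sxy = mean(ss$sxy), sxx = mean(ss$sxx), syy = mean(ss$syy),
       sxy_seg = ss$sxy, sxx_seg = ss$sxx, syy_seg = ss$syy,
       n_segments = ss$n_segments)
}

#' Bivariate connectivity metric from cross-spectra
#'
#' * `imcoh`: `|Im(S_xy / sqrt(S_xx S_yy))|` — insensitive to zero-lag
#'   (volume-conduction) mixing.
#' * `msc`: `|S_xy|^2 / (S_xx S_yy)`.
#' * `pli`: `|mean_seg sign(Im(S_xy^seg))|`.
#' * `glc`: `Im(S_xy)^2 / (S_xx S_yy - Re(S_xy)^2)` (NaN when the
#'   denominator is nonpositive).
#'
#' `aec` has no spectral form here; see [aec_metric()].
#'
#' @param cs a [cross_spectra()] result.
#' @param metric `"imcoh"`, `"msc"`, `"pli"` or `"glc"`.
#' @return scalar in `[0, 1]`.
#' @export
fc_metric <- function(cs, metric = c("imcoh", "msc", "pli", "glc")) {
  metric <- match.arg(metric)
  switch(metric,
    imcoh = abs(Im(cs$sxy / sqrt(cs$sxx * cs$syy))),
    msc = Mod(cs$sxy)^2 / (cs$sxx * cs$syy),
    pli = abs(mean(sign(Im(cs$sxy_seg)))),
    glc = {
      den <- cs$sxx * cs$syy - Re(cs$sxy)^2
      if (den <= 0) NaN else Im(cs$sxy)^2 / den
    })
}

# analytic signal via FFT (Marple): zero negative frequencies, double
# positive ones
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) { h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2 }
  else { h[1] <- 1; h[2:((n + 1) / 2)] <- 2 }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Amplitude envelope correlation
#'
#' Pearson correlation of the band-limited analytic-signal envelopes of
#' two source time courses (plain variant, no leakage orthogonalization).
#' Envelopes are computed per trial and pooled.
#'
#' @param x,y trials x samples matrices (or vectors).
#' @param sfreq sampling rate, Hz.
#' @param band (lo, hi) Hz.
#' @return scalar in `[-1, 1]`.
#' @export
aec_metric <- function(x, y, sfreq, band) {
  if (is.null(dim(x))) x <- matrix(x, 1)
  if (is.null(dim(y))) y <- matrix(y, 1)
  filt <- design_filter(filter_spec(band), sfreq)
  env <- function(m) {
    out <- matrix(0, nrow(m), ncol(m))
    for (tr in seq_len(nrow(m)))
      out[tr, ] <- Mod(analytic_signal(apply_filter_1d(filt, m[tr, ], TRUE)))
    as.numeric(t(out))
  }
  stats::cor(env(x), env(y))
}

# metric between two tcs given a spec (dispatch spectral vs envelope path)
pairwise_fc <- function(x, y, sfreq, spec) {
  if (spec$metric == "aec") return(aec_metric(x, y, sfreq, spec$band))
  cs <- cross_spectra(x, y, sfreq, spec$band, spec)
  fc_metric(cs, spec$metric)
}

fisher_mean <- function(vals, how) {
  vals <- vals[is.finite(vals)]
  if (!length(vals)) return(NaN)
  if (how == "raw") return(mean(vals))
  eps <- 1e-7
  tanh(mean(atanh(pmin(pmax(vals, -1 + eps), 1 - eps))))
}

#' Seed-based or global connectivity map
#'
#' Voxel seed: metric between the seed time course and every target voxel.
#' ROI seed: metric of the averaged ROI time course (default) or the mean
#' of per-voxel metrics. Global: per-voxel mean of the metric over all
#' other voxels (self-connections excluded), Fisher-z averaged by default.
#'
#' @param tcs voxels x trials x samples array from [project_sources()].
#' @param sfreq sampling rate, Hz.
#' @param spec an [fc_spec()].
#' @param grid the [source_grid()] the voxel axis refers to.
#' @return A [source_estimate()] (kind `"connectivity"`); provenance
#'   records the metric, band and segment count.
#' @export
seed_map <- function(tcs, sfreq, spec, grid) {
  nv <- dim(tcs)[1]
  tc <- function(v) matrix(tcs[v, , ], dim(tcs)[2], dim(tcs)[3])
  seed <- spec$seed
  vals <- rep(NaN, nv)
  if (seed$type == "voxel") {
    sx <- tc(seed$index)
    for (v in seq_len(nv))
      vals[v] <- if (v == seed$index) NA else pairwise_fc(sx, tc(v), sfreq, spec)
  } else if (seed$type == "roi") {
    if (!length(seed$index)) stop_mg("empty ROI seed")
    if (spec$roi_average == "timecourse") {
      sx <- apply(tcs[seed$index, , , drop = FALSE], c(2, 3), mean)
      for (v in seq_len(nv))
        vals[v] <- if (v %in% seed$index) NA
                   else pairwise_fc(sx, tc(v), sfreq, spec)
    } else {
      for (v in seq_len(nv)) {
        if (v %in% seed$index) next
        m <- vapply(seed$index, function(s)
          pairwise_fc(tc(s), tc(v), sfreq, spec), numeric(1))
        vals[v] <- fisher_mean(m, spec$global_average)
      }
    }
  } else if (seed$type == "global") {
    pair <- matrix(NA_real_, nv, nv)
    for (i in seq_len(nv - 1))
      for (j in (i + 1):nv) {
        m <- pairwise_fc(tc(i), tc(j), sfreq, spec)
        pair[i, j] <- m; pair[j, i] <- m
      }
    for (v in seq_len(nv))
      vals[v] <- fisher_mean(pair[v, -v], spec$global_average)
  } else stop_mg("unknown seed type '%s'", seed$type)
  n_seg <- if (spec$mode == "task_epochs") dim(tcs)[2] else NA_integer_
  source_estimate(vals, "connectivity", grid,
                  bands = matrix(spec$band, 1),
                  method = paste0("fc_", spec$metric),
                  provenance = list(metric = spec$metric, band = spec$band,
                                    n_segments = n_seg,
                                    seed = seed$type))
}
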