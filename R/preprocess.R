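#' Digital filter specification
#'
#' @param band (lo, hi) Hz pair. `lo = 0` gives a lowpass at `hi`;
#'   `hi = Inf` a highpass at `lo`; otherwise a bandpass.
#' @param family `"Butterworth"` (default, order 4) or `"FIR"`
#'   (windowed-sinc, Hamming window).
#' @param order filter order (>= 1). Defaults: 4 for Butterworth; for FIR a
#'   3.3/transition-width heuristic at application time when `NULL`.
#' @param zero_phase apply forward-backward (no group delay)? Default TRUE.
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(band, family = c("Butterworth", "FIR"), order = NULL,
                        zero_phase = TRUE) {
  family <- match.arg(family)
  band <- as.numeric(band)
  if (length(band) != 2L || band[1] < 0 || band[2] <= band[1])
    stop_mg("band must be (lo, hi) with 0 <= lo < hi")
  if (is.null(order)) order <- if (family == "Butterworth") 4L else NA_integer_
  if (!is.na(order) && order < 1) stop_mg("order must be >= 1")
  structure(list(band = band, family = family, order = order,
                 zero_phase = zero_phase),
            class = "filter_spec")
}

# build a signal-package filter object for a sampling rate
design_filter <- function(spec, sfreq) {
  nyq <- sfreq / 2
  lo <- spec$band[1]; hi <- spec$band[2]
  if (lo >= nyq) stop_mg("band edge %g Hz is at or above Nyquist (%g Hz)", lo, nyq)
  if (is.finite(hi) && hi >= nyq)
    stop_mg("band edge %g Hz is at or above Nyquist (%g Hz)", hi, nyq)
  type <- if (lo == 0) "low" else if (!is.finite(hi)) "high" else "pass"
  W <- switch(type, low = hi / nyq, high = lo / nyq, pass = c(lo, hi) / nyq)
  if (spec$family == "Butterworth") {
    signal::butter(spec$order, W, type = type)
  } else {
    ord <- spec$order
    if (is.na(ord)) {
      # 3.3 / transition-width heuristic (Hamming); transition = 25% of the
      # lower band edge (or of hi for lowpass), floor 2 Hz
      trans <- max(0.25 * (if (lo > 0) lo else hi), 2) / sfreq
      ord <- max(8L, 2L * ceiling(3.3 / trans / 2))
    }
    if (ord %% 2 == 1) ord <- ord + 1L  # even order so bandpass/highpass valid
    signal::fir1(ord, W, type = type)
  }
}

# apply a designed filter to one numeric vector
apply_filter_1d <- function(filt, x, zero_phase) {
  if (zero_phase) as.numeric(signal::filtfilt(filt, x))
  else as.numeric(signal::filter(filt, x))
}

#' Filter an epoched recording
#'
#' Applies the specified filter independently to every trial and channel.
#' Zero-phase (forward-backward) application doubles the effective order
#' and removes group delay.
#'
#' @param rec an [epoched_recording()].
#' @param spec a [filter_spec()].
#' @return A filtered [epoched_recording()] of identical shape.
#' @export
apply_filter <- function(rec, spec) {
  filt <- design_filter(spec, rec$sfreq)
  d <- dim(rec$data)
  out <- rec$data
  for (tr in seq_len(d[1]))
    for (ch in seq_len(d[2]))
      out[tr, ch, ] <- apply_filter_1d(filt, rec$data[tr, ch, ], spec$zero_phase)
  epoched_recording(out, rec$sfreq, rec$times, rec$condition)
}

# sample indices whose times fall in [start, end] ms
window_samples <- function(times, window) {
  idx <- which(times >= window[1] & times <= window[2])
  idx
}

#' Per-channel RMS over a time window
#'
#' Root mean square of each channel over all trials and all samples in the
#' window, the standard sensor-quality map inspected before source
#' analysis.
#'
#' @param rec an [epoched_recording()].
#' @param window (start, end) ms pair.
#' @return named numeric vector (tesla), one value per channel.
#' @export
rms_map <- function(rec, window = range(rec$times)) {
  idx <- window_samples(rec$times, window)
  if (length(idx) == 0) stop_mg("window [%g, %g] ms contains no samples",
                                window[1], window[2])
  x <- rec$data[, , idx, drop = FALSE]
  out <- sqrt(apply(x^2, 2, mean))
  names(out) <- attr(rec, "channel_id") %||% NULL
  out
}

#' Estimate the sensor covariance in a window
#'
#' Sample covariance of the per-epoch demeaned channel signals, pooling all
#' samples of the selected trials inside the window.
#'
#' @param rec an [epoched_recording()].
#' @param window (start, end) ms pair.
#' @param trials optional integer subset of trials (default all).
#' @return An object of class `covariance` with `$matrix` (channels x
#'   channels, tesla^2), `$window`, `$n_samples_used`, `$regularization`
#'   (0) and `$rank_deficient` (TRUE when fewer pooled samples than
#'   channels — a recorded warning flag, not an error).
#' @export
estimate_covariance <- function(rec, window = range(rec$times), trials = NULL) {
  idx <- window_samples(rec$times, window)
  trials <- trials %||% seq_len(dim(rec$data)[1])
  n_used <- length(idx) * length(trials)
  if (n_used < 2) stop_mg("need at least 2 samples x trials in the window")
  nc <- dim(rec$data)[2]
  acc <- matrix(0, nc, nc)
  for (tr in trials) {
    seg <- matrix(rec$data[tr, , idx], nc, length(idx))
    seg <- seg - rowMeans(seg)
    acc <- acc + tcrossprod(seg)
  }
  mat <- acc / (n_used - 1)
  mat <- (mat + t(mat)) / 2
  structure(list(matrix = mat, window = as.numeric(window),
                 n_samples_used = n_used, regularization = 0,
                 rank_deficient = n_used < nc),
            class = "covariance")
}

#' Regularize a covariance matrix
#'
#' Adds a ridge `lambda * I`: `lambda = value` in absolute mode, `value *
#' mean(diag)` in relative mode (the conventional way of stating MEG
#' covariance regularization, scale-free in sensor units).
#'
#' @param cov a `covariance` (from [estimate_covariance()]) or a plain
#'   matrix.
#' @param mode `"relative"` or `"absolute"`.
#' @param value nonnegative regularization amount.
#' @return A regularized `covariance`.
#' @export
regularize <- function(cov, mode = c("relative", "absolute"), value) {
  mode <- match.arg(mode)
  if (!is_scalar_num(value) || value < 0) stop_mg("value must be >= 0")
  if (is.matrix(cov))
    cov <- structure(list(matrix = cov, window = c(NA, NA),
                          n_samples_used = NA, regularization = 0,
                          rank_deficient = FALSE), class = "covariance")
  lambda <- if (mode == "absolute") value else value * mean(diag(cov$matrix))
  out <- cov
  if (lambda > 0) out$matrix <- cov$matrix + diag(lambda, nrow(cov$matrix))
  out$regularization <- cov$regularization + lambda
  out
}
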