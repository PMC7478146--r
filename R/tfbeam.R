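#' Sliding analysis windows
#'
#' Generates windows of the given length stepping by `length - overlap`
#' ms across the span. With `partial = "drop"` (default) a final window
#' that would overrun the span is dropped; with `"truncate"` it is kept
#' and clipped to the span end.
#'
#' @param epoch_span (start, end) ms pair.
#' @param length window length, ms.
#' @param overlap overlap between consecutive windows, ms
#'   (`0 <= overlap < length`).
#' @param partial `"drop"` or `"truncate"`.
#' @return windows x 2 matrix of (start, end) ms pairs.
#' @export
make_windows <- function(epoch_span, length, overlap = 0,
                         partial = c("drop", "truncate")) {
  partial <- match.arg(partial)
  span <- as.numeric(epoch_span)
  if (length <= overlap || overlap < 0)
    stop_mg("need length > overlap >= 0")
  if (length > span[2] - span[1])
    stop_mg("window length %g ms exceeds the span (%g ms)", length,
            span[2] - span[1])
  step <- length - overlap
  starts <- seq(span[1], span[2], by = step)
  full <- starts + length <= span[2] + 1e-9
  out <- cbind(start = starts[full], end = starts[full] + length)
  if (partial == "truncate") {
    part <- which(!full & starts < span[2] - 1e-9)
    if (length(part))
      out <- rbind(out, cbind(start = starts[part[1]], end = span[2]))
  }
  out
}

#' Time-frequency analysis specification
#'
#' @param bands list of (lo, hi) Hz pairs (or a bands x 2 matrix).
#' @param active_windows windows x 2 ms matrix (see [make_windows()]).
#' @param control_window (start, end) ms pair; must be disjoint from the
#'   active windows unless `condition_contrast` names two trial conditions
#'   (in which case the control powers come from the control condition's
#'   trials over the same windows).
#' @param filter_family,filter_order passed to [filter_spec()] per band.
#' @param weight_source `"combined"` (weights from the pooled
#'   active+control covariance; default) or `"active_only"`.
#' @param condition_contrast optional `c(active_label, control_label)`.
#' @param min_samples minimum pooled samples for a window; below it the
#'   window is flagged NaN.
#' @param allow_overlap permit overlapping frequency bands (e.g. a
#'   broadband tile alongside its sub-bands)? Default FALSE.
#' @return An object of class `tf_spec`.
#' @export
tf_spec <- function(bands, active_windows, control_window,
                    filter_family = "Butterworth", filter_order = 4L,
                    weight_source = c("combined", "active_only"),
                    condition_contrast = NULL, min_samples = 32L,
                    allow_overlap = FALSE) {
  weight_source <- match.arg(weight_source)
  if (is.list(bands)) bands <- do.call(rbind, bands)
  bands <- matrix(as.numeric(bands), ncol = 2)
  if (any(bands[, 1] < 0 | bands[, 2] <= bands[, 1]))
    stop_mg("each band must satisfy 0 <= lo < hi")
  if (!allow_overlap && nrow(bands) > 1) {
    for (i in seq_len(nrow(bands) - 1))
      for (j in (i + 1):nrow(bands))
        if (bands[i, 1] < bands[j, 2] && bands[j, 1] < bands[i, 2])
          stop_mg("bands %d and %d overlap; set allow_overlap = TRUE if intended",
                  i, j)
  }
  active_windows <- matrix(as.numeric(active_windows), ncol = 2)
  control_window <- as.numeric(control_window)
  if (is.null(condition_contrast)) {
    overlaps <- active_windows[, 1] < control_window[2] &
      active_windows[, 2] > control_window[1]
    if (any(overlaps))
      stop_mg("control window overlaps active window(s) %s; use a condition contrast for identical windows",
              paste(which(overlaps), collapse = ", "))
  }
  structure(list(bands = bands, active_windows = active_windows,
                 control_window = control_window,
                 filter_family = filter_family, filter_order = filter_order,
                 weight_source = weight_source,
                 condition_contrast = condition_contrast,
                 min_samples = as.integer(min_samples)),
            class = "tf_spec")
}

#' Pseudo-F contrast of active vs control power
#'
#' `F = (P_active - P_control) / P_control`: 0 for no change, scale-free
#' under common rescaling. `dB = TRUE` returns the display variant
#' `10 log10(P_active / P_control)`.
#'
#' @param power_active,power_control nonnegative arrays of equal shape.
#' @param dB return decibels instead of the ratio-minus-one form?
#' @return array of the same shape; `NaN` where `power_control == 0`.
#' @export
pseudo_f <- function(power_active, power_control, dB = FALSE) {
  if (!identical(dim(power_active) %||% length(power_active),
                 dim(power_control) %||% length(power_control)))
    stop_mg("power arrays must have identical shape")
  out <- if (dB) 10 * log10(power_active / power_control)
         else (power_active - power_control) / power_control
  out[!is.na(power_control) & power_control == 0] <- NaN
  out
}

# half the filter's effective impulse-response length (samples): smallest
# m such that the energy of the (zero-phase) impulse response outside
# [-m, m] is below 1%.
edge_trim_samples <- function(spec_filter, sfreq, n = 1024L) {
  filt <- design_filter(spec_filter, sfreq)
  x <- numeric(2 * n); x[n] <- 1
  h <- apply_filter_1d(filt, x, zero_phase = TRUE)
  e <- h^2 / sum(h^2)
  off <- abs(seq_along(e) - n)
  ord <- order(off)                 # cumulative energy by increasing |offset|
  ce <- cumsum(e[ord])
  m <- off[ord][which(ce >= 0.99)[1]]
  max(m, 1L)
}

#' Time-frequency source reconstruction (filter bank -> windowed
#' covariances -> power maps)
#'
#' The induced-activity pipeline, in three steps per frequency band:
#' (1) all trials are bandpass filtered (zero-phase) and the epoch edges
#' trimmed by half the filter's effective impulse response; (2) spatial
#' filter weights are computed from the pooled active+control covariance
#' (default) in that band; (3) for every active window the windowed
#' covariance `C_w` gives `P_active[v,w,b] = trace(W_v' C_w W_v)`, and the
#' control window (or the control condition over the same windows) gives
#' `P_control`. The pseudo-F contrast is assembled alongside.
#'
#' @param rec an [epoched_recording()].
#' @param lf a [leadfield_grid()].
#' @param spec a [tf_spec()].
#' @param method `"lcmv_scalar"`, `"lcmv_vector"`, `"min_norm"` or
#'   `"sloreta"`.
#' @param reg relative covariance regularization for beamformer weights.
#' @param band_subset,window_subset optional index vectors restricting the
#'   computation to a tile of bands/windows (for batched runs assembled
#'   with [assemble_outputs()]); other tiles are left NA.
#' @return A `tf_result`: list of [source_estimate()]-shaped arrays
#'   `power_active`, `power_control`, `pseudoF` (voxels x windows x
#'   bands), the spec, grid, and a logical `filled` windows x bands tile
#'   matrix, plus the per-band edge trim (ms).
#' @export
tf_reconstruct <- function(rec, lf, spec, method = "lcmv_scalar", reg = 0.05,
                           band_subset = NULL, window_subset = NULL) {
  stopifnot(inherits(spec, "tf_spec"))
  methods_ok <- c("lcmv_scalar", "lcmv_vector", "min_norm", "sloreta")
  if (!method %in% methods_ok)
    stop_mg("method must be one of: %s", paste(methods_ok, collapse = ", "))
  nb <- nrow(spec$bands); nw <- nrow(spec$active_windows)
  band_subset <- band_subset %||% seq_len(nb)
  window_subset <- window_subset %||% seq_len(nw)
  nv <- n_inside(lf$grid)
  pa <- array(NA_real_, c(nv, nw, nb))
  pc <- array(NA_real_, c(nv, nw, nb))
  filled <- matrix(FALSE, nw, nb)
  trims <- numeric(nb)
  contrast <- !is.null(spec$condition_contrast)
  if (contrast) {
    act_tr <- which(rec$condition == spec$condition_contrast[1])
    ctl_tr <- which(rec$condition == spec$condition_contrast[2])
    if (!length(act_tr) || !length(ctl_tr))
      stop_mg("condition labels %s not found in the recording",
              paste(spec$condition_contrast, collapse = "/"))
  } else {
    act_tr <- ctl_tr <- seq_len(dim(rec$data)[1])
  }
  for (b in band_subset) {
    fs <- filter_spec(spec$bands[b, ], family = spec$filter_family,
                      order = spec$filter_order)
    fb <- apply_filter(rec, fs)
    trim <- edge_trim_samples(fs, rec$sfreq)
    trims[b] <- trim / rec$sfreq * 1000
    keep <- seq_len(dim(fb$data)[3])
    keep <- keep[keep > trim & keep <= length(keep) - trim]
    times_b <- fb$times[keep]
    window_cov <- function(win, tr_set) {
      idx <- which(times_b >= win[1] & times_b <= win[2])
      if (length(idx) * length(tr_set) < spec$min_samples) return(NULL)
      cov_of(fb, keep[idx], tr_set)
    }
    cov_of <- function(fb, sample_idx, tr_set) {
      nc <- dim(fb$data)[2]
      acc <- matrix(0, nc, nc); n <- 0
      for (tr in tr_set) {
        seg <- matrix(fb$data[tr, , sample_idx], nc, length(sample_idx))
        seg <- seg - rowMeans(seg)
        acc <- acc + tcrossprod(seg); n <- n + length(sample_idx)
      }
      list(matrix = acc / max(n - 1, 1), n = n)
    }
    # weights covariance: pooled over all active windows + control
    wins <- spec$active_windows[window_subset, , drop = FALSE]
    pool_idx <- sort(unique(unlist(lapply(seq_len(nrow(wins)), function(w)
      which(times_b >= wins[w, 1] & times_b <= wins[w, 2])))))
    if (!contrast) {
      ctl_idx <- which(times_b >= spec$control_window[1] &
                       times_b <= spec$control_window[2])
      if (spec$weight_source == "combined")
        pool_idx <- sort(unique(c(pool_idx, ctl_idx)))
    }
    Cw <- cov_of(fb, keep[pool_idx],
                 if (contrast) sort(c(act_tr, ctl_tr)) else act_tr)
    Creg <- regularize(structure(list(matrix = Cw$matrix, window = c(NA, NA),
                                      n_samples_used = Cw$n,
                                      regularization = 0,
                                      rank_deficient = FALSE),
                                 class = "covariance"),
                       "relative", reg)
    filt <- switch(method,
      lcmv_scalar = lcmv_scalar(lf, Creg),
      lcmv_vector = lcmv_vector(lf, Creg),
      min_norm = min_norm(lf, lambda = reg * mean(diag(Creg$matrix)) /
                            mean(rowSums(stacked_gain(lf)^2))),
      sloreta = min_norm(lf, lambda = reg * mean(diag(Creg$matrix)) /
                           mean(rowSums(stacked_gain(lf)^2))))
    std <- if (method == "sloreta") sloreta_standardize(filt, lf)
    power_of <- function(cv) {
      p <- rep(NaN, nv)
      for (v in seq_len(nv)) {
        if (filt$flagged[v]) next
        Wv <- voxel_weights(filt, v)
        pv <- crossprod(Wv, cv %*% Wv)
        if (method == "sloreta") {
          if (std$flagged[v]) next
          Rv <- matrix(std$R[v, , ], dim(filt$weights)[3], dim(filt$weights)[3])
          pv <- solve(Rv, pv)
        }
        p[v] <- sum(diag(as.matrix(pv)))
      }
      p
    }
    if (!contrast) {
      ctl_cov <- window_cov(spec$control_window, ctl_tr)
      p_ctl <- if (is.null(ctl_cov)) rep(NaN, nv) else power_of(ctl_cov$matrix)
    }
    for (w in window_subset) {
      a_cov <- window_cov(spec$active_windows[w, ], act_tr)
      if (contrast) {
        c_cov <- window_cov(spec$active_windows[w, ], ctl_tr)
        p_ctl <- if (is.null(c_cov)) rep(NaN, nv) else power_of(c_cov$matrix)
      }
      pa[, w, b] <- if (is.null(a_cov)) NaN else power_of(a_cov$matrix)
      pc[, w, b] <- p_ctl
      filled[w, b] <- TRUE
    }
  }
  structure(list(power_active = pa, power_control = pc,
                 pseudoF = pseudo_f(pa, pc), spec = spec, grid = lf$grid,
                 method = method, filled = filled, edge_trim_ms = trims),
            class = "tf_result")
}

#' @export
print.tf_result <- function(x, ...) {
  d <- dim(x$power_active)
  cat(sprintf("<tf_result> %s: %d voxels x %d windows x %d bands (%d/%d tiles filled)\n",
              x$method, d[1], d[2], d[3], sum(x$filled), length(x$filled)))
  invisible(x)
}

#' Assemble batched time-frequency tiles into one result
#'
#' Merges partial `tf_result`s produced with `band_subset`/`window_subset`
#' tiles into a single consolidated result. Tiles must share the grid and
#' spec, be disjoint, and jointly cover every window x band cell.
#'
#' @param parts list of `tf_result` objects.
#' @return A complete `tf_result`, bit-identical to a single-pass run.
#' @export
assemble_outputs <- function(parts) {
  if (!length(parts)) stop_mg("no partial results supplied")
  ref <- parts[[1]]
  out <- ref
  out$filled[] <- FALSE
  for (p in parts) {
    if (!identical(dim(p$power_active), dim(ref$power_active)) ||
        !identical(p$spec$bands, ref$spec$bands))
      stop_mg("partial results disagree on grid or spec")
    both <- p$filled & out$filled
    if (any(both)) {
      same <- vapply(which(both), function(i) {
        w <- (i - 1) %% nrow(p$filled) + 1; b <- (i - 1) %/% nrow(p$filled) + 1
        identical(p$power_active[, w, b], out$power_active[, w, b])
      }, logical(1))
      if (!all(same)) stop_mg("overlapping tiles with conflicting values")
    }
    for (i in which(p$filled)) {
      w <- (i - 1) %% nrow(p$filled) + 1; b <- (i - 1) %/% nrow(p$filled) + 1
      out$power_active[, w, b] <- p$power_active[, w, b]
      out$power_control[, w, b] <- p$power_control[, w, b]
      out$pseudoF[, w, b] <- p$pseudoF[, w, b]
      out$filled[w, b] <- TRUE
      if (p$edge_trim_ms[b] > 0) out$edge_trim_ms[b] <- p$edge_trim_ms[b]
    }
  }
  if (!all(out$filled)) {
    gaps <- which(!out$filled, arr.ind = TRUE)
    stop_mg("missing tiles: %s",
            paste(sprintf("(window %d, band %d)", gaps[, 1], gaps[, 2]),
                  collapse = ", "))
  }
  out
}

#' Convert a tf_result layer to a source_estimate
#'
#' @param tf a `tf_result`.
#' @param what `"pseudoF"`, `"power_active"` or `"power_control"`.
#' @return A [source_estimate()].
#' @export
tf_as_estimate <- function(tf, what = c("pseudoF", "power_active",
                                        "power_control")) {
  what <- match.arg(what)
  kind <- if (what == "pseudoF") "pseudoF" else what
  source_estimate(tf[[what]], kind, tf$grid,
                  windows = tf$spec$active_windows, bands = tf$spec$bands,
                  method = tf$method,
                  provenance = list(edge_trim_ms = tf$edge_trim_ms))
}
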