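#' Dual signal subspace projection (DSSP) interference suppression
#'
#' Separates brain activity from external interference using two
#' complementary descriptions of the data. The spatial "inside-brain"
#' subspace is spanned by the top `spatial_dim` left singular vectors of
#' the stacked lead-field matrix; projecting the data onto it and onto its
#' complement yields two data matrices whose temporal row spaces are
#' compared via principal angles. Temporal directions common to both (high
#' principal correlation) can only come from interference that reaches the
#' sensors both "through" and "around" the brain subspace; the data are
#' projected onto the orthogonal complement of that common temporal
#' subspace.
#'
#' Epochs are concatenated along time for subspace estimation, cleaned
#' jointly and re-split.
#'
#' @param rec an [epoched_recording()].
#' @param lf a [leadfield_grid()] covering the inside-brain grid.
#' @param spatial_dim dimension of the spatial (inside-brain) subspace;
#'   must be < channels.
#' @param n_interference number of interference temporal dimensions to
#'   remove, or `"auto"` to take every principal correlation above
#'   `threshold`.
#' @param threshold principal-correlation cutoff for `"auto"` (default
#'   0.9).
#' @return list with `cleaned` (an [epoched_recording()]) and `report`
#'   (principal correlations, removed dimension, temporal interference
#'   basis `projector` as a time x n matrix, relative power change).
#' @export
dssp_clean <- function(rec, lf, spatial_dim = 40L,
                       n_interference = "auto", threshold = 0.9) {
  d <- dim(rec$data)
  nc <- d[2]
  if (spatial_dim >= nc)
    stop_mg("spatial_dim (%d) must be smaller than the channel count (%d)",
            spatial_dim, nc)
  # channels x time (epochs concatenated)
  Y <- matrix(aperm(rec$data, c(2, 3, 1)), nc, d[1] * d[3])
  L <- stacked_gain(lf)
  Us <- svd(L, nu = spatial_dim, nv = 0)$u
  Yin <- Us %*% (t(Us) %*% Y)
  Yout <- Y - Yin
  V1 <- orth_basis(t(Yin))    # time x r1
  V2 <- orth_basis(t(Yout))   # time x r2
  r <- min(ncol(V1), ncol(V2))
  s <- svd(crossprod(V1, V2))
  corr <- s$d[seq_len(r)]
  n_int <- if (identical(n_interference, "auto")) sum(corr > threshold)
           else as.integer(n_interference)
  if (n_int >= r && n_int > 0)
    stop_mg("n_interference (%d) must be below the smaller subspace rank (%d)",
            n_int, r)
  rel_change <- 0
  P <- matrix(0, nrow(V1), 0)
  cleaned <- rec
  if (n_int > 0) {
    P <- V1 %*% s$u[, seq_len(n_int), drop = FALSE]  # orthonormal, time x n
    Yc <- Y - (Y %*% P) %*% t(P)
    rel_change <- sqrt(sum((Yc - Y)^2) / sum(Y^2))
    arr <- array(Yc, c(nc, d[3], d[1]))
    cleaned <- epoched_recording(aperm(arr, c(3, 1, 2)), rec$sfreq, rec$times,
                                 rec$condition)
  }
  list(cleaned = cleaned,
       report = list(principal_correlations = corr, removed_dim = n_int,
                     spatial_dim = spatial_dim, threshold = threshold,
                     projector = P, relative_change = rel_change))
}
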