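#' Group sample of source maps
#'
#' @param maps numeric array subjects x voxels (x windows x bands); 2-D and
#'   3-D inputs are promoted. For the `"paired"` design pass per-subject
#'   condition differences.
#' @param design `"one_sample"`, `"paired"`, `"two_sample"` or
#'   `"correlation"`.
#' @param group factor/character of group labels (two_sample design).
#' @param covariate per-subject scalar (correlation design).
#' @return An object of class `group_sample`.
#' @export
group_sample <- function(maps, design = c("one_sample", "paired",
                                          "two_sample", "correlation"),
                         group = NULL, covariate = NULL) {
  design <- match.arg(design)
  maps <- unclass(maps)
  if (length(dim(maps)) == 2L) dim(maps) <- c(dim(maps), 1L, 1L)
  if (length(dim(maps)) == 3L) dim(maps) <- c(dim(maps), 1L)
  n <- dim(maps)[1]
  if (n < 2) stop_mg("need at least 2 subjects")
  if (n < 5) warn_mg("only %d subjects; permutation inference is coarse below 5", n)
  if (design == "two_sample") {
    if (is.null(group) || length(group) != n)
      stop_mg("two_sample design needs one group label per subject")
    if (length(unique(group)) != 2) stop_mg("exactly two groups required")
  }
  if (design == "correlation" && (is.null(covariate) || length(covariate) != n))
    stop_mg("correlation design needs one covariate value per subject")
  structure(list(maps = maps, design = design, group = group,
                 covariate = covariate, n_subjects = n),
            class = "group_sample")
}

#' Permutation scheme
#'
#' Full enumeration of the `2^N` sign flips when `N <= enumerate_limit`,
#' otherwise `max_permutations` distinct random sign vectors; the identity
#' permutation is always included (first row), so attainable p-values are
#' bounded below by `1/count`.
#'
#' @param n_subjects N.
#' @param max_permutations cap when not enumerating (default 4096).
#' @param seed RNG seed for the sampled case.
#' @param enumerate_limit enumerate fully up to this N (default 12).
#' @return An object of class `permutation_scheme` with the `signs`
#'   (count x N) matrix.
#' @export
permutation_scheme <- function(n_subjects, max_permutations = 4096L,
                               seed = 1L, enumerate_limit = 12L) {
  n <- as.integer(n_subjects)
  enumerate <- n <= enumerate_limit
  if (enumerate) {
    signs <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))
    dimnames(signs) <- NULL
    id <- which(rowSums(signs) == n)
    signs <- rbind(signs[id, ], signs[-id, ])
  } else {
    set.seed(seed)
    seen <- new.env(hash = TRUE)
    signs <- matrix(1, 1, n)
    assign(paste(rep(1, n), collapse = ""), TRUE, envir = seen)
    while (nrow(signs) < max_permutations) {
      s <- sample(c(1, -1), n, replace = TRUE)
      key <- paste(s, collapse = "")
      if (!exists(key, envir = seen)) {
        assign(key, TRUE, envir = seen)
        signs <- rbind(signs, s)
      }
    }
    dimnames(signs) <- NULL
  }
  structure(list(n_subjects = n, count = nrow(signs), enumerate = enumerate,
                 seed = seed, signs = signs),
            class = "permutation_scheme")
}

# mask-renormalized Gaussian smoothing operator over inside voxels:
# row-stochastic V x V matrix (identity for fwhm 0)
smoothing_matrix <- function(grid, fwhm_mm) {
  nv <- n_inside(grid)
  if (fwhm_mm == 0) return(NULL)
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2)))
  xy <- inside_coords(grid)
  d2 <- as.matrix(stats::dist(xy))^2
  K <- exp(-d2 / (2 * sigma^2))
  K / rowSums(K)
}

#' Smooth a voxelwise variance map
#'
#' 3-D Gaussian smoothing on the grid lattice with the kernel renormalized
#' over inside voxels (so a constant field is preserved exactly despite the
#' mask). `fwhm_mm = 0` returns the input unchanged.
#'
#' @param var_map nonnegative per-voxel vector (or perms x voxels matrix,
#'   smoothed row-wise).
#' @param grid the [source_grid()].
#' @param fwhm_mm kernel full width at half maximum, mm (the conventional
#'   "2 cm" kernel is `fwhm_mm = 20`).
#' @param S optional precomputed smoothing operator (internal reuse).
#' @return smoothed map, same shape.
#' @export
smooth_variance <- function(var_map, grid, fwhm_mm = 20, S = NULL) {
  if (any(var_map < 0, na.rm = TRUE)) stop_mg("variances must be nonnegative")
  if (fwhm_mm == 0 && is.null(S)) return(var_map)
  S <- S %||% smoothing_matrix(grid, fwhm_mm)
  if (is.null(S)) return(var_map)
  if (is.matrix(var_map)) var_map %*% t(S) else as.numeric(S %*% var_map)
}

#' Pseudo-t statistic with smoothed variance
#'
#' `t~ = mean / sqrt(smoothed_var / N)` per voxel. `0/0` is defined as 0;
#' a zero smoothed variance with nonzero mean flags the voxel (NaN). With
#' `smoothed_var` equal to the raw sample variance this is the textbook
#' one-sample t statistic.
#'
#' @param maps subjects x voxels matrix.
#' @param smoothed_var per-voxel smoothed variance.
#' @return per-voxel pseudo-t vector.
#' @export
pseudo_t <- function(maps, smoothed_var) {
  n <- nrow(maps)
  if (n < 2) stop_mg("need at least 2 subjects")
  m <- colMeans(maps)
  tt <- m / sqrt(smoothed_var / n)
  tt[smoothed_var == 0 & m == 0] <- 0
  tt[smoothed_var == 0 & m != 0] <- NaN
  tt
}

# 6-connectivity neighbour list of inside voxels (indices in inside order)
grid_neighbours <- function(grid) {
  shp <- grid$shape
  lin <- grid$inside_idx
  pos <- match(seq_len(prod(shp)), lin)   # lattice -> inside index or NA
  k <- (lin - 1) %/% (shp[1] * shp[2])
  j <- ((lin - 1) %/% shp[1]) %% shp[2]
  i <- (lin - 1) %% shp[1]
  nb <- vector("list", length(lin))
  off <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
               c(0, 0, 1), c(0, 0, -1))
  for (v in seq_along(lin)) {
    ii <- i[v] + off[, 1]; jj <- j[v] + off[, 2]; kk <- k[v] + off[, 3]
    ok <- ii >= 0 & ii < shp[1] & jj >= 0 & jj < shp[2] & kk >= 0 & kk < shp[3]
    cand <- pos[ii[ok] + jj[ok] * shp[1] + kk[ok] * shp[1] * shp[2] + 1]
    nb[[v]] <- cand[!is.na(cand)]
  }
  nb
}

# connected components of a logical inside-voxel mask under 6-connectivity
connected_clusters <- function(supra, nb) {
  lab <- integer(length(supra))
  cur <- 0L
  for (v in which(supra)) {
    if (lab[v]) next
    cur <- cur + 1L
    queue <- v; lab[v] <- cur
    while (length(queue)) {
      u <- queue[[1]]; queue <- queue[-1]
      for (w in nb[[u]]) if (supra[w] && !lab[w]) { lab[w] <- cur; queue <- c(queue, w) }
    }
  }
  lab
}

# maximum cluster statistic of a thresholded map: "mass" = sum of
# exceedances (statistic - threshold) over the cluster (continuous, so the
# permutation test is near-exact); "size" = voxel count
max_cluster_stat <- function(vals, threshold, nb, stat = "mass") {
  supra <- is.finite(vals) & vals > threshold
  if (!any(supra)) return(0)
  lab <- connected_clusters(supra, nb)
  per <- if (stat == "mass") {
    as.numeric(rowsum(vals[supra] - threshold, lab[supra]))
  } else tabulate(lab[lab > 0])
  max(per)
}

#' Nonparametric permutation test on a group of source maps
#'
#' For one-sample/paired designs, the polarity of each subject's map is
#' flipped according to every sign vector of the scheme; for each
#' permutation the pseudo-t (variance re-smoothed inside the permutation)
#' is recomputed and its maximum over voxels and time windows recorded per
#' frequency band. FWER-corrected p-values come from the position of each
#' observed value in that max distribution; uncorrected p-values from each
#' voxel's own permutation distribution; FDR from a Benjamini–Hochberg
#' step-up over all voxels x windows within a band. Two-sided by default
#' (maxima of `|t~|`). Two-sample designs permute group labels;
#' correlation designs permute the covariate (Pearson by default).
#'
#' @param sample a [group_sample()].
#' @param grid the [source_grid()] of the maps.
#' @param scheme a [permutation_scheme()] (default: built from the sample).
#' @param fwhm_mm variance-smoothing kernel FWHM (default 20 mm).
#' @param tail `"two"` (default) or `"pos"` (signed one-sided).
#' @param cluster_threshold optional primary pseudo-t threshold enabling
#'   the spatial cluster correction (6-connectivity, null distribution of
#'   the maximum cluster size over the same permutations).
#' @param cor_method `"pearson"` or `"spearman"` (correlation design).
#' @return A [stat_map()].
#' @export
snpm_test <- function(sample, grid, scheme = NULL, fwhm_mm = 20,
                      tail = c("two", "pos"), cluster_threshold = NULL,
                      cluster_stat = c("mass", "size"),
                      cor_method = c("pearson", "spearman")) {
  tail <- match.arg(tail)
  cluster_stat <- match.arg(cluster_stat)
  cor_method <- match.arg(cor_method)
  stopifnot(inherits(sample, "group_sample"))
  n <- sample$n_subjects
  scheme <- scheme %||% permutation_scheme(n)
  if (scheme$count < 20)
    warn_mg("only %d permutations; minimum attainable p is %.3f",
            scheme$count, 1 / scheme$count)
  d <- dim(sample$maps)
  nv <- d[2]; nw <- d[3]; nb_bands <- d[4]
  if (nv != n_inside(grid)) stop_mg("maps do not match the grid")
  S <- smoothing_matrix(grid, fwhm_mm)
  nb <- if (!is.null(cluster_threshold)) grid_neighbours(grid)
  P <- scheme$count
  score <- function(tt) if (tail == "two") abs(tt) else tt

  t_obs <- array(NA_real_, c(nv, nw, nb_bands))
  p_unc <- array(NA_real_, c(nv, nw, nb_bands))
  p_fwer <- array(NA_real_, c(nv, nw, nb_bands))
  p_fdr <- array(NA_real_, c(nv, nw, nb_bands))
  clusters <- list()

  perm_stats <- function(X, perm_idx) {
    # X: subjects x (nv*nw) for one band; returns P x (nv*nw) statistics
    switch(sample$design,
      one_sample = ,
      paired = {
        sgn <- scheme$signs
        means <- sgn %*% X / n
        SS <- matrix(colSums(X^2), P, ncol(X), byrow = TRUE)
        vars <- pmax((SS - n * means^2) / (n - 1), 0)
        if (!is.null(S)) {
          dim(vars) <- c(P, nv, nw)
          for (w in seq_len(nw)) vars[, , w] <- vars[, , w] %*% t(S)
          dim(vars) <- c(P, nv * nw)
        }
        tt <- means / sqrt(vars / n)
        tt[vars == 0 & means == 0] <- 0
        tt[vars == 0 & means != 0] <- NaN    # flagged: no variance estimate
        tt
      },
      two_sample = {
        g <- as.integer(factor(sample$group))
        out <- matrix(NA_real_, P, ncol(X))
        for (p in seq_len(P)) {
          gp <- g[perm_idx[p, ]]
          i1 <- gp == 1; i2 <- gp == 2
          n1 <- sum(i1); n2 <- sum(i2)
          m1 <- colMeans(X[i1, , drop = FALSE])
          m2 <- colMeans(X[i2, , drop = FALSE])
          v1 <- apply(X[i1, , drop = FALSE], 2, stats::var)
          v2 <- apply(X[i2, , drop = FALSE], 2, stats::var)
          vp <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
          if (!is.null(S)) {
            dim(vp) <- c(nv, nw)
            vp <- as.numeric(apply(vp, 2, function(col) S %*% col))
          }
          out[p, ] <- (m1 - m2) / sqrt(vp * (1 / n1 + 1 / n2))
        }
        out
      },
      correlation = {
        out <- matrix(NA_real_, P, ncol(X))
        cv <- sample$covariate
        if (cor_method == "spearman") { X <- apply(X, 2, rank); cv <- rank(cv) }
        for (p in seq_len(P))
          out[p, ] <- suppressWarnings(stats::cor(cv[perm_idx[p, ]], X))
        out
      })
  }

  perm_idx <- NULL
  if (sample$design %in% c("two_sample", "correlation")) {
    set.seed(scheme$seed)
    perm_idx <- rbind(seq_len(n),
                      t(replicate(P - 1, sample.int(n))))
  }

  for (b in seq_len(nb_bands)) {
    X <- matrix(sample$maps[, , , b], n, nv * nw)
    tt <- perm_stats(X, perm_idx)
    sc <- score(tt)
    obs <- sc[1, ]
    maxima <- apply(sc, 1, function(r) max(r[is.finite(r)], -Inf))
    p_f <- vapply(obs, function(o)
      if (!is.finite(o)) NA_real_ else mean(maxima >= o - 1e-12), numeric(1))
    p_u <- colMeans(sweep(sc, 2, obs - 1e-12, `>=`), na.rm = TRUE)
    t_obs[, , b] <- tt[1, ]
    p_unc[, , b] <- p_u
    p_fwer[, , b] <- pmax(p_f, p_u)   # max-stat p dominates by construction
    p_fdr[, , b] <- fdr_correct(p_u)
    if (!is.null(cluster_threshold)) {
      null_max <- vapply(seq_len(P), function(p) {
        m <- 0
        scp <- matrix(sc[p, ], nv, nw)
        for (w in seq_len(nw))
          m <- max(m, max_cluster_stat(scp[, w], cluster_threshold, nb,
                                       cluster_stat))
        m
      }, numeric(1))
      obs_sc <- matrix(obs, nv, nw)
      for (w in seq_len(nw)) {
        supra <- is.finite(obs_sc[, w]) & obs_sc[, w] > cluster_threshold
        if (!any(supra)) next
        lab <- connected_clusters(supra, nb)
        for (cl in seq_len(max(lab))) {
          vox <- which(lab == cl)
          mass <- sum(obs_sc[vox, w] - cluster_threshold)
          stat <- if (cluster_stat == "mass") mass else length(vox)
          clusters[[length(clusters) + 1]] <-
            list(voxels = vox, window = w, band = b, size = length(vox),
                 mass = mass,
                 p_corrected = mean(null_max >= stat - 1e-12))
        }
      }
    }
  }
  test_name <- paste0(sample$design,
                      if (sample$design %in% c("one_sample", "paired"))
                        "_signflip" else "")
  stat_map(t_obs, p_unc, p_fwer, p_fdr, clusters, n, P, test_name,
           grid = grid)
}

#' Benjamini–Hochberg FDR adjustment
#'
#' Monotone step-up adjustment; the family is all voxels x windows within
#' one frequency band (pass one band's p-values at a time).
#'
#' @param p_uncorrected numeric vector/array of p-values in (0, 1].
#' @return adjusted p-values, same shape, elementwise >= input.
#' @export
fdr_correct <- function(p_uncorrected) {
  shp <- dim(p_uncorrected)
  out <- stats::p.adjust(as.numeric(p_uncorrected), method = "BH")
  if (!is.null(shp)) dim(out) <- shp
  out
}

#' Spatial clusters of a suprathreshold map
#'
#' Groups suprathreshold inside voxels by face-wise (6-)connectivity.
#' Exposed for descriptive use; corrected cluster p-values come from
#' [snpm_test()] with `cluster_threshold` set.
#'
#' @param values per-voxel statistic vector.
#' @param grid the [source_grid()].
#' @param threshold primary threshold (> 0); voxels strictly above it
#'   enter clusters.
#' @return list of clusters (voxel indices and size), possibly empty.
#' @export
cluster_correct <- function(values, grid, threshold) {
  if (threshold <= 0) stop_mg("threshold must be > 0")
  nb <- grid_neighbours(grid)
  supra <- is.finite(values) & values > threshold
  if (!any(supra)) return(list())
  lab <- connected_clusters(supra, nb)
  lapply(seq_len(max(lab)), function(cl)
    list(voxels = which(lab == cl), size = sum(lab == cl)))
}

#' Grand mean of a group sample
#'
#' @param sample a [group_sample()] (or subjects x voxels matrix).
#' @param grid the [source_grid()].
#' @return A [source_estimate()] of the voxelwise mean across subjects.
#' @export
grand_mean <- function(sample, grid) {
  maps <- if (inherits(sample, "group_sample")) sample$maps else sample
  if (length(dim(maps)) == 2L) dim(maps) <- c(dim(maps), 1L, 1L)
  m <- apply(maps, c(2, 3, 4), mean)
  source_estimate(m, "statistic", grid, method = "grand_mean")
}
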