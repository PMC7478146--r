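test_that("variance smoothing preserves constants and has the stated width", {
  grid <- stats_grid()
  nv <- n_inside(grid)
  const <- rep(3.7, nv)
  expect_equal(smooth_variance(const, grid, 20), const, tolerance = 1e-12)
  expect_identical(smooth_variance(const, grid, 0), const)
  expect_error(smooth_variance(c(-1, rep(1, nv - 1)), grid, 20),
               "nonnegative")
  # single-voxel impulse spreads with the requested FWHM
  ctr <- megsource:::nearest_inside_voxel(grid, c(0, 0, 0))
  imp <- rep(0, nv); imp[ctr] <- 1
  sm <- smooth_variance(imp, grid, 20)
  ic <- inside_coords(grid)
  d <- sqrt(rowSums(sweep(ic, 2, ic[ctr, ])^2))
  # profile should fall to half its peak near fwhm/2 = 10 mm
  prof <- sm / sm[ctr]
  half_reached <- d[which(prof >= 0.5)]
  expect_lte(max(half_reached), 10 + grid$spacing / 2)
  expect_gte(max(half_reached), 10 - grid$spacing / 2)
})

test_that("pseudo-t matches the textbook t statistic when unsmoothed", {
  set.seed(91)
  X <- matrix(rnorm(8 * 30), 8)
  tt <- pseudo_t(X, apply(X, 2, var))
  oracle <- apply(X, 2, function(col) unname(t.test(col)$statistic))
  expect_equal(tt, oracle, tolerance = 1e-12)
  # degenerate cases
  expect_equal(pseudo_t(matrix(0, 5, 3), rep(0, 3)), rep(0, 3))
  v <- 0.25
  expect_equal(pseudo_t(matrix(1, 5, 2), rep(v, 2)),
               rep(1 / sqrt(v / 5), 2))
  expect_true(is.nan(pseudo_t(matrix(1, 5, 1), 0)))
  expect_error(pseudo_t(matrix(1, 1, 2), c(1, 1)), "at least 2")
})

test_that("sign-flip enumeration is exact and exchangeable", {
  sch <- permutation_scheme(5)
  expect_equal(sch$count, 32L)
  expect_true(sch$enumerate)
  # identity first and exactly once
  expect_equal(sch$signs[1, ], rep(1, 5))
  expect_equal(sum(apply(sch$signs, 1, function(r) all(r == 1))), 1)
  expect_equal(nrow(unique(sch$signs)), 32)
  # sampled scheme keeps the identity and draws distinct vectors
  sch2 <- permutation_scheme(20, max_permutations = 128, seed = 2)
  expect_equal(sch2$count, 128L)
  expect_equal(sch2$signs[1, ], rep(1, 20))
  expect_equal(nrow(unique(sch2$signs)), 128)

  grid <- stats_grid()
  grp <- simulate_group(grid, 5, seed = 1)
  suppressWarnings({
    sm <- snpm_test(group_sample(grp$maps), grid, permutation_scheme(5),
                    fwhm_mm = 20)
    # permuting subject order leaves every output unchanged
    sm_perm <- snpm_test(group_sample(grp$maps[c(3, 1, 5, 2, 4), ]), grid,
                         permutation_scheme(5), fwhm_mm = 20)
  })
  expect_equal(sm$pseudo_t, sm_perm$pseudo_t, tolerance = 1e-12)
  expect_equal(sm$p_fwer, sm_perm$p_fwer)
  expect_equal(sm$n_permutations, 32)
  # minimum attainable p: 1/32 one-sided; two-sided pairs s with -s so 2/32
  suppressWarnings(
    smp <- snpm_test(group_sample(grp$maps), grid, permutation_scheme(5),
                     fwhm_mm = 0, tail = "pos"))
  expect_equal(min(smp$p_uncorrected), 1 / 32)
  expect_equal(min(sm$p_uncorrected), 2 / 32)
  # p-value dominance invariant on a produced map
  expect_true(all(sm$p_fwer >= sm$p_uncorrected - 1e-12))
})

test_that("null maps give calibrated FWER and cluster error rates", {
  grid <- stats_grid()
  sch <- permutation_scheme(8)
  rej <- rej_cl <- logical(150)
  for (r in seq_len(150)) {
    grp <- simulate_group(grid, 8, seed = 7000 + r)
    sm <- snpm_test(group_sample(grp$maps), grid, sch, fwhm_mm = 20,
                    cluster_threshold = 2.365)
    rej[r] <- min(sm$p_fwer) <= 0.05
    pc <- vapply(sm$clusters, `[[`, numeric(1), "p_corrected")
    rej_cl[r] <- length(pc) > 0 && min(pc) <= 0.05
  }
  # nominal 0.05; 150 replicates give a generous binomial envelope
  expect_gte(mean(rej), 0.01); expect_lte(mean(rej), 0.10)
  expect_gte(mean(rej_cl), 0.01); expect_lte(mean(rej_cl), 0.10)
})

test_that("a strong localized effect is detected with FWER control", {
  grid <- stats_grid()
  sch <- permutation_scheme(10, max_permutations = 1024)
  v <- megsource:::nearest_inside_voxel(grid, c(20, 0, 10))
  hits <- 0
  for (r in 1:10) {
    grp <- simulate_group(grid, 10,
                          effect = list(voxels = v, shift = 2,
                                        between_sd = 0.3),
                          seed = 300 + r)
    sm <- snpm_test(group_sample(grp$maps), grid, sch, fwhm_mm = 20)
    hits <- hits + (sm$p_fwer[v, 1, 1] <= 0.05)
  }
  expect_gte(hits, 9)
})

test_that("FDR adjustment follows the Benjamini-Hochberg step-up", {
  expect_equal(fdr_correct(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_correct(rep(0.2, 5)), rep(0.2, 5))
  set.seed(13)
  p <- runif(50)
  expect_true(all(fdr_correct(p) >= p))
  shaped <- fdr_correct(array(p[1:24], c(4, 3, 2)))
  expect_equal(dim(shaped), c(4, 3, 2))
})

test_that("cluster grouping respects the lattice connectivity", {
  grid <- stats_grid()
  nv <- n_inside(grid)
  ic <- inside_coords(grid)
  vals <- rep(0, nv)
  a <- megsource:::nearest_inside_voxel(grid, c(0, 0, 10))
  vals[a] <- 5
  cl <- cluster_correct(vals, grid, 2)
  expect_length(cl, 1)
  expect_equal(cl[[1]]$size, 1)
  # face-adjacent neighbour joins the cluster
  b <- megsource:::nearest_inside_voxel(grid, ic[a, ] + c(grid$spacing, 0, 0))
  vals[b] <- 5
  cl2 <- cluster_correct(vals, grid, 2)
  expect_length(cl2, 1)
  expect_equal(cl2[[1]]$size, 2)
  # diagonal neighbour does not (6-connectivity)
  vals[b] <- 0
  dgn <- megsource:::nearest_inside_voxel(grid, ic[a, ] +
                                            c(grid$spacing, grid$spacing, 0))
  vals[dgn] <- 5
  expect_length(cluster_correct(vals, grid, 2), 2)
  expect_error(cluster_correct(vals, grid, 0), "> 0")
  expect_length(cluster_correct(rep(0, nv), grid, 2), 0)
})

test_that("two-sample and correlation designs permute the right labels", {
  grid <- stats_grid()
  nv <- n_inside(grid)
  set.seed(55)
  maps <- matrix(rnorm(12 * nv), 12)
  v <- 11
  maps[7:12, v] <- maps[7:12, v] + 3
  gs <- group_sample(maps, "two_sample", group = rep(c("a", "b"), each = 6))
  sm <- snpm_test(gs, grid,
                  permutation_scheme(12, max_permutations = 256,
                                     enumerate_limit = 0),
                  fwhm_mm = 0)
  expect_equal(which.min(sm$p_uncorrected[, 1, 1]), v)
  # correlation design: covariate equal to the subject means of one voxel
  maps2 <- matrix(rnorm(10 * nv), 10)
  cov_var <- maps2[, 5]
  gs2 <- group_sample(maps2, "correlation", covariate = cov_var)
  sm2 <- snpm_test(gs2, grid,
                   permutation_scheme(10, max_permutations = 512,
                                      enumerate_limit = 0),
                   fwhm_mm = 0)
  expect_equal(which.max(abs(sm2$pseudo_t[, 1, 1])), 5)
  expect_equal(min(sm2$p_uncorrected), sm2$p_uncorrected[5, 1, 1])
})

test_that("grand mean reduces to the arithmetic mean", {
  grid <- stats_grid()
  nv <- n_inside(grid)
  one <- matrix(rnorm(nv), 1)
  expect_equal(grand_mean(one, grid)$values[, 1, 1], one[1, ])
  two <- rbind(rep(1, nv), rep(-1, nv))
  expect_equal(grand_mean(two, grid)$values[, 1, 1], rep(0, nv))
  set.seed(14)
  X <- matrix(rnorm(6 * nv), 6)
  expect_equal(grand_mean(X, grid)$values[, 1, 1], colMeans(X))
})
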