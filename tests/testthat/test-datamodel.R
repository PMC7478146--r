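test_that("containers round-trip every domain type losslessly", {
  set.seed(42)
  tmp <- withr::local_tempdir()
  rec <- epoched_recording(array(rnorm(3 * 4 * 10), c(3, 4, 10)), 100,
                           seq(0, 90, by = 10), c("a", "a", "b"))
  p <- file.path(tmp, "rec.rds")
  save_container(rec, p)
  back <- load_container(p)
  expect_identical(back$data, rec$data)
  expect_identical(back$times, rec$times)
  expect_identical(back$condition, rec$condition)

  grid <- make_source_grid(40, 20)
  # randomized metadata round-trips (windows x bands layouts)
  for (i in 1:5) {
    nw <- sample(1:10, 1); nb <- sample(1:5, 1)
    est <- source_estimate(array(rnorm(n_inside(grid) * nw * nb),
                                 c(n_inside(grid), nw, nb)),
                           "pseudoF", grid,
                           windows = cbind(seq_len(nw) * 100,
                                           seq_len(nw) * 100 + 50),
                           bands = cbind(seq_len(nb) * 10,
                                         seq_len(nb) * 10 + 5),
                           method = "test",
                           provenance = list(run = i))
    save_container(est, p)
    back <- load_container(p)
    expect_identical(back$values, est$values)
    expect_identical(back$windows, est$windows)
    expect_identical(back$bands, est$bands)
    expect_identical(back$provenance, est$provenance)
  }
})

test_that("corrupt or unknown containers fail loudly", {
  tmp <- withr::local_tempdir()
  p <- file.path(tmp, "bad.rds")
  saveRDS(list(container_version = 99L, class = "epoched_recording",
               object = list()), p)
  expect_error(load_container(p), "unknown container version")
  saveRDS(list(no_version = TRUE), p)
  expect_error(load_container(p), "version")
  # shape corruption: times no longer matches samples
  rec <- epoched_recording(array(0, c(2, 3, 5)), 100, seq(0, 40, 10))
  payload <- list(container_version = 1L, class = "epoched_recording",
                  object = unclass(rec))
  payload$object$times <- payload$object$times[-1]
  saveRDS(payload, p)
  expect_error(load_container(p), "samples")
  expect_error(load_container(file.path(tmp, "missing.rds")), "not found")
})

test_that("NIfTI export places values by the grid affine and keeps NaN outside", {
  grid <- make_source_grid(40, 20)
  tmp <- withr::local_tempdir()
  aff <- grid_affine(grid)
  # affine at index (0,0,0) is the lattice origin
  expect_equal(drop(aff %*% c(0, 0, 0, 1))[1:3], grid$origin)
  # affine consistency over all inside voxels
  idx <- which(grid$inside_mask)
  ijk <- cbind((idx - 1) %% grid$shape[1],
               ((idx - 1) %/% grid$shape[1]) %% grid$shape[2],
               (idx - 1) %/% (grid$shape[1] * grid$shape[2]))
  mm <- t(aff %*% t(cbind(ijk, 1)))[, 1:3]
  expect_lt(max(abs(mm - grid$voxel_coords[idx, ])), 1e-6)

  # single-voxel placement
  vals <- rep(0, n_inside(grid)); vals[5] <- 7
  est <- source_estimate(vals, "power_active", grid)
  f <- file.path(tmp, "map.nii.gz")
  export_nifti(est, 1, 1, f)
  img <- RNifti::readNifti(f)
  target_mm <- inside_coords(grid)[5, ]
  ijk5 <- drop(solve(aff) %*% c(target_mm, 1))[1:3]
  expect_equal(img[ijk5[1] + 1, ijk5[2] + 1, ijk5[3] + 1], 7)
  # outside voxels are NaN
  expect_true(all(is.na(as.array(img)[!array(grid$inside_mask, grid$shape)])))

  # full random map round-trip
  set.seed(1)
  vals <- rnorm(n_inside(grid))
  est <- source_estimate(vals, "power_active", grid)
  export_nifti(est, 1, 1, f)
  img <- RNifti::readNifti(f)
  expect_equal(as.array(img)[grid$inside_idx], vals, tolerance = 1e-6)
  expect_error(export_nifti(est, 2, 1, f), "out of range")
})

test_that("pointer files are validated on read", {
  tmp <- withr::local_tempdir()
  # 39 subjects, one condition
  files <- file.path(tmp, sprintf("s%02d.rds", 1:39))
  grid <- make_source_grid(40, 20)
  for (f in files)
    save_container(source_estimate(rnorm(n_inside(grid)), "pseudoF", grid), f)
  tsv <- file.path(tmp, "pointer.tsv")
  df <- data.frame(path = basename(files), subject_id = sprintf("S%02d", 1:39),
                   group = "ctl", condition = "face")
  write.table(df, tsv, sep = "\t", row.names = FALSE, quote = FALSE)
  pf <- read_pointer(tsv)
  expect_s3_class(pf, "pointer_file")
  expect_equal(nrow(pf), 39)

  # empty file
  write.table(df[0, ], tsv, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(read_pointer(tsv), "no entries")

  # missing referenced path is named
  df2 <- df[1:3, ]; df2$path[2] <- "gone.rds"
  write.table(df2, tsv, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(read_pointer(tsv), "gone.rds")

  # duplicate (subject, condition)
  df3 <- df[c(1, 1, 2), ]
  write.table(df3, tsv, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(read_pointer(tsv), "duplicate")

  # JSON alternative
  js <- file.path(tmp, "pointer.json")
  jsonlite::write_json(df[1:4, ], js)
  expect_equal(nrow(read_pointer(js)), 4)
})

test_that("domain type invariants are enforced", {
  expect_error(sensor_array(c("a", "a"), matrix(0, 2, 3),
                            matrix(c(1, 0, 0, 1, 0, 0), 2, byrow = TRUE),
                            "magnetometer", 0), "unique")
  expect_error(sensor_array("a", matrix(1, 1, 3), matrix(c(2, 0, 0), 1),
                            "magnetometer", 0), "unit-norm")
  expect_error(sensor_array("a", matrix(1, 1, 3), matrix(c(1, 0, 0), 1),
                            "axial_gradiometer", 0), "baseline")
  expect_error(epoched_recording(array(0, c(2, 3, 4)), 100, c(0, 10, 25, 30)),
               "uniform")
  expect_error(source_grid(c(0, 0, 0), 10, c(2, 2, 2), rep(FALSE, 8)),
               "at least one voxel")
  grid <- make_source_grid(40, 20)
  expect_error(source_estimate(rnorm(n_inside(grid)), "power_active", grid,
                               windows = matrix(c(100, 100), 1)),
               "non-degenerate")
  # stat_map p-value dominance invariant
  shp <- c(4, 1, 1)
  ok_p <- array(0.5, shp)
  expect_error(stat_map(array(1, shp), ok_p, array(0.2, shp), ok_p,
                        n_subjects = 8, n_permutations = 256),
               "dominate")
  expect_error(stat_map(array(1, shp), ok_p, array(0, shp), ok_p,
                        n_subjects = 8, n_permutations = 256),
               "0, 1")
})
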