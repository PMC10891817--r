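test_that("volume construction enforces geometry invariants", {
  expect_error(volume3d(array(0, c(4, 4, 4)), spacing = c(1, 0, 1)), "positive")
  expect_error(volume3d(array(0, c(4, 4, 4)), direction = diag(3) * 2),
               "orthonormal")
  expect_error(volume3d(matrix(0, 4, 4)), "3D")
})

test_that("index/physical mappings invert each other with direction cosines", {
  D <- o_rot_zyx(30, 15, -40)
  v <- volume3d(array(0, c(8, 9, 10)), c(0.7, 1.1, 2.0), c(5, -3, 2), D)
  idx <- rbind(c(0, 0, 0), c(3.5, 2.25, 7), c(7, 8, 9))
  p <- index_to_physical(v, idx)
  expect_equal(physical_to_index(v, p), idx, tolerance = 1e-9)
  expect_equal(p[1, ], v$origin)
})

test_that("NRRD round-trips bit-for-bit in all encodings", {
  set.seed(5)
  v <- volume3d(array(rnorm(4 * 5 * 6), c(4, 5, 6)), c(0.5, 0.5, 0.5),
                c(-1, 2, 3), o_rot_zyx(10, 5, 2), modality = "CT")
  for (enc in c("raw", "gzip", "ascii")) {
    f <- tempfile(fileext = ".nrrd")
    write_nrrd(v, f, encoding = enc)
    r <- read_nrrd(f, modality = "CT")
    expect_identical(r$data, v$data)
    expect_equal(r$spacing, v$spacing, tolerance = 1e-14)
    expect_equal(r$origin, v$origin, tolerance = 1e-14)
    expect_equal(r$direction, v$direction, tolerance = 1e-14)
  }
})

test_that("NRRD header geometry is honoured, including RAS conversion", {
  f <- tempfile(fileext = ".nrrd")
  v <- volume3d(array(1:27, c(3, 3, 3)), c(0.5, 0.5, 0.5))
  write_nrrd(v, f)
  expect_equal(read_nrrd(f)$spacing, c(0.5, 0.5, 0.5))
  # hand-written RAS-space header: directions/origin flip to LPS on read
  con <- file(f, "wb")
  writeLines(c("NRRD0004", "type: double", "dimension: 3",
               "space: right-anterior-superior", "sizes: 2 2 2",
               "space directions: (1,0,0) (0,1,0) (0,0,1)",
               "endian: little", "encoding: raw",
               "space origin: (10,-5,3)", ""), con)
  writeBin(as.numeric(1:8), con, size = 8, endian = "little")
  close(con)
  r <- read_nrrd(f)
  expect_equal(r$origin, c(-10, 5, 3))
  expect_equal(r$direction, diag(c(-1, -1, 1)))
})

test_that("NIfTI round-trips and RAS headers land in LPS correctly", {
  set.seed(6)
  v <- volume3d(array(rnorm(120), c(4, 5, 6)), c(1.25, 0.8, 2.0),
                c(4, -7, 1.5), diag(3))
  f <- tempfile(fileext = ".nii")
  write_nifti_volume(v, f)
  r <- read_nifti_volume(f)
  expect_equal(r$data, v$data, tolerance = 1e-12)
  expect_equal(r$spacing, v$spacing, tolerance = 1e-6)
  expect_equal(r$origin, v$origin, tolerance = 1e-6)
  expect_equal(r$direction, v$direction, tolerance = 1e-6)
  # a bright voxel's physical position agrees between a landmark given in
  # RAS (as NIfTI/Slicer would report it) and the LPS volume read back
  v2 <- volume3d(array(0, c(10, 10, 10)), c(1, 1, 1), c(0, 0, 0))
  v2$data[4, 6, 8] <- 100
  write_nifti_volume(v2, f)
  r2 <- read_nifti_volume(f)
  idx <- which(r2$data == 100, arr.ind = TRUE) - 1
  p_lps <- index_to_physical(r2, idx)
  ras_landmark <- c(-3, -5, 7)   # same anatomical point quoted in RAS
  expect_equal(as.numeric(p_lps), c(-ras_landmark[1], -ras_landmark[2],
                                    ras_landmark[3]))
})

test_that("4D input is routed to the time-series reader with a clear error", {
  f <- tempfile(fileext = ".nii")
  RNifti::writeNifti(RNifti::asNifti(array(0, c(3, 3, 3, 4))), f)
  expect_error(read_nifti_volume(f), "time-series")
  expect_error(read_volume(tempfile(fileext = ".nrrd")), "not found")
  expect_error(read_volume(tempfile(), format = "DICOM_DIR"), "not supported")
})

test_that("time series round-trips through per-frame files plus manifest", {
  frames <- lapply(1:3, function(i)
    volume3d(array(i * 1.5, c(3, 4, 5)), c(1, 1, 2), c(0, 0, 0)))
  ts <- time_series_volume(frames, phase = c(0, 0.1, 0.2), source = "ECG_GATED")
  d <- tempfile("ts_")
  m <- write_time_series(ts, d)
  r <- read_time_series(m)
  expect_equal(length(r$frames), 3L)
  expect_identical(r$frames[[2]]$data, frames[[2]]$data)
  expect_equal(r$phase, c(0, 0.1, 0.2))
  expect_identical(r$source, "ECG_GATED")
  # gated series demand known, strictly increasing phases
  expect_error(time_series_volume(frames, c(0, 0.2, 0.1), source = "ECG_GATED"),
               "increasing")
  expect_error(time_series_volume(frames, NULL, source = "ECG_GATED"), "phases")
})

test_that("resampling a constant volume returns that constant", {
  v <- volume3d(array(7.5, c(10, 10, 10)), c(1, 1, 1))
  r <- resample_volume(v, c(0.6, 0.9, 1.7), method = "linear")
  expect_equal(r$spacing, c(0.6, 0.9, 1.7))
  expect_true(all(abs(r$data - 7.5) < 1e-12))
})

test_that("linear resampling reproduces a linear intensity ramp", {
  v <- o_ramp_volume(coef = c(2, -1, 0.5), const = 7)
  r <- resample_volume(v, c(0.55, 0.7, 0.9), method = "linear")
  idx <- o_grid_idx(dim(r$data))
  p <- index_to_physical(r, idx)
  expected <- p %*% c(2, -1, 0.5) + 7
  # interior only: clamp-to-edge flattens the ramp at the boundary
  ok <- p[, 1] < max(p[, 1]) - 1 & p[, 2] < max(p[, 2]) - 1.2 &
        p[, 3] < max(p[, 3]) - 1.5
  expect_lt(max(abs(as.numeric(r$data)[ok] - expected[ok])), 1e-6)
})

test_that("resampling covers the extent, respects range, is identity at same spacing", {
  set.seed(9)
  v <- volume3d(array(runif(20 * 18 * 12, 0, 100), c(20, 18, 12)),
                c(0.47, 0.47, 1.0), c(-3, 1, 2))
  r <- resample_volume(v, c(0.342, 0.342, 0.37), method = "linear")
  expect_equal(r$spacing, c(0.342, 0.342, 0.37))
  expect_gte((dim(r$data)[1] - 1) * r$spacing[1], (20 - 1) * 0.47)
  expect_gte(min(r$data), min(v$data))
  expect_lte(max(r$data), max(v$data))
  same <- resample_volume(v, v$spacing, method = "linear")
  expect_equal(dim(same$data), dim(v$data))
  expect_lt(max(abs(same$data - v$data)), 1e-6)
  expect_error(resample_volume(v, c(0, 1, 1)), "positive")
})

test_that("cubic resampling also reproduces smooth ramps", {
  v <- o_ramp_volume()
  r <- resample_volume(v, c(0.5, 0.6, 0.8), method = "bspline")
  idx <- o_grid_idx(dim(r$data))
  p <- index_to_physical(r, idx)
  expected <- p %*% c(2, -1, 0.5) + 7
  ok <- p[, 1] > 1 & p[, 1] < max(p[, 1]) - 2 & p[, 2] > 3 &
        p[, 2] < max(p[, 2]) - 2.5 & p[, 3] > 6.5 & p[, 3] < max(p[, 3]) - 3
  expect_lt(max(abs(as.numeric(r$data)[ok] - expected[ok])), 1e-6)
})

test_that("centering is idempotent and preserves pairwise distances", {
  v <- volume3d(array(0, c(100, 100, 100)), c(1, 1, 1), c(0, 0, 0))
  c1 <- center_volume(v)
  expect_equal(c1$origin, c(-49.5, -49.5, -49.5))
  expect_equal(center_volume(c1)$origin, c1$origin)
  # distances between voxel centres are translation-invariant
  idx <- rbind(c(0, 0, 0), c(10, 20, 30), c(99, 99, 99))
  d0 <- dist(index_to_physical(v, idx))
  d1 <- dist(index_to_physical(c1, idx))
  expect_equal(as.numeric(d0), as.numeric(d1))
  # an already centred volume is unchanged
  expect_equal(center_volume(c1)$origin, c1$origin)
})

test_that("mirroring is an involution on voxel-column planes and preserves histograms", {
  set.seed(10)
  v <- volume3d(array(sample(0:5, 9 * 8 * 7, TRUE), c(9, 8, 7)), c(1, 1, 1),
                c(-4, 0, 0))
  m <- mirror_volume(v, plane_position = 0)  # x = 0 is the central column
  expect_identical(mirror_volume(m, 0)$data, v$data)
  expect_equal(table(m$data), table(v$data))
  sym <- v
  sym$data <- (v$data + v$data[9:1, , ]) / 2  # symmetric about x = 0
  expect_equal(mirror_volume(sym, 0)$data, sym$data)
  expect_error(mirror_volume(v, plane_position = 50), "outside")
})

test_that("a mirrored blob lands at the reflected centroid", {
  v <- volume3d(array(0, c(41, 21, 21)), c(1, 1, 1), c(-20, -10, -10))
  idx <- o_grid_idx(dim(v$data))
  p <- index_to_physical(v, idx)
  v$data <- array(exp(-(rowSums(sweep(p, 2, c(12, 0, 0))^2)) / 8), dim(v$data))
  m <- mirror_volume(v, plane_position = 0)
  centroid <- function(vol) {
    w <- as.numeric(vol$data)
    colSums(p * w) / sum(w)
  }
  expect_equal(centroid(v)[1], 12, tolerance = 0.5)
  expect_equal(centroid(m)[1], -12, tolerance = 0.5)
})

test_that("resample_through_transform relocates structures by the transform", {
  v <- volume3d(array(0, c(30, 30, 30)), c(1, 1, 1), c(-14.5, -14.5, -14.5))
  idx <- o_grid_idx(dim(v$data))
  p <- index_to_physical(v, idx)
  v$data <- array(as.numeric(rowSums(sweep(p, 2, c(-4, 0, 0))^2) < 16),
                  dim(v$data))
  t <- rigid_transform(diag(3), c(6, 2, -3))
  out <- resample_through_transform(v, v, t, method = "linear")
  w <- as.numeric(out$data)
  ctr <- colSums(p * w) / sum(w)
  expect_equal(ctr, c(-4, 0, 0) + c(6, 2, -3), tolerance = 0.5)
  # identity on itself is the identity to interpolation accuracy
  same <- resample_through_transform(v, v, rigid_identity(), "linear")
  expect_lt(max(abs(same$data - v$data)), 1e-6)
  expect_warning(resample_through_transform(
    v, v, rigid_transform(diag(3), c(500, 0, 0)), "linear"), "overlap")
})
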