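# a reduced-grid phantom spec used throughout the suite; geometry ratios and
# phase structure match the full defaults, grids are smaller for speed
o_small_cardiac <- function(seed = 1L, noise_sd = 0.3,
                            true_transform = rigid_from_params(
                              c(25, -12, 40, 6, -4, 9))) {
  cardiac_phantom_spec(ct_shape = c(48L, 48L, 24L),
                       ct_spacing = c(1.2, 1.2, 2.2),
                       us_shape = c(40L, 40L, 40L),
                       us_spacing = c(1.1, 1.1, 0.8),
                       true_transform = true_transform,
                       noise_sd = noise_sd, seed = seed)
}

test_that("phantom generation is bit-identical across runs with one seed", {
  a <- make_cardiac_pair(o_small_cardiac(seed = 4))
  b <- make_cardiac_pair(o_small_cardiac(seed = 4))
  expect_identical(a$ct$frames[[3]]$data, b$ct$frames[[3]]$data)
  expect_identical(a$us$frames[[7]]$data, b$us$frames[[7]]$data)
  expect_identical(a$truth$landmarks_ct[[1]]$points,
                   b$truth$landmarks_ct[[1]]$points)
  c <- make_cardiac_pair(o_small_cardiac(seed = 5))
  expect_false(identical(a$us$frames[[7]]$data, c$us$frames[[7]]$data))
})

test_that("phantom structure matches its spec", {
  ph <- make_cardiac_pair(o_small_cardiac())
  expect_equal(length(ph$ct$frames), 10L)
  expect_identical(ph$ct$source, "ECG_GATED")
  expect_equal(ph$ct$phase, seq(0, 0.9, 0.1))
  expect_identical(ph$us$source, "FREE_RUNNING")
  expect_null(ph$us$phase)                      # unknown to consumers
  expect_gte(length(ph$truth$landmarks_ct[[1]]), 12L)
})

test_that("US landmark truth is the CT truth through the inverse transform", {
  ph <- make_cardiac_pair(o_small_cardiac())
  tt <- ph$truth$true_transform
  for (j in c(1, 10, 20)) {
    p <- ph$truth$us_frame_phases[j]
    # CT-space landmarks at that exact phase
    idx_ct <- which(abs(ph$truth$ct_phases - p) < 1e-9)
    mapped <- rt_apply(tt, ph$truth$landmarks_us[[j]]$points)
    if (length(idx_ct) == 1) {
      expect_lt(max(abs(mapped - ph$truth$landmarks_ct[[idx_ct]]$points)), 1e-9)
    } else {
      # generic phase: mapping back must land on the annulus ring radius
      a <- sqrt(sum(mapped[1, 1:2]^2))
      expect_lt(abs(mapped[1, 3]), 1e-9)
      expect_gt(a, 10)
    }
  }
})

test_that("rendered annulus pulsation matches the configured amplitude", {
  spec <- o_small_cardiac(noise_sd = 0)
  ph <- make_cardiac_pair(spec)
  # measure ring diameter on the rendered frame: bright voxels at z ~ 0
  measure <- function(v) {
    idx <- which(v$data > 200, arr.ind = TRUE) - 1
    p <- index_to_physical(v, idx)
    ring <- abs(p[, 3]) < 2
    2 * mean(sqrt(p[ring, 1]^2 + p[ring, 2]^2))
  }
  d_open <- measure(ph$ct$frames[[1]])            # phase 0, fully open
  d_mid <- measure(ph$ct$frames[[6]])             # phase 0.5, minimum
  amp <- spec$annulus_pulsation_amplitude * spec$annulus_diameter_mean
  expect_equal(d_open - d_mid, amp, tolerance = max(spec$ct_spacing))
})

test_that("noiseless identity-pose US agrees with CT inside the cone", {
  spec <- cardiac_phantom_spec(ct_shape = c(48L, 48L, 48L),
                               ct_spacing = c(1.2, 1.2, 1.2),
                               us_shape = c(40L, 40L, 40L),
                               us_spacing = c(1.1, 1.1, 0.8),
                               true_transform = rigid_identity(),
                               noise_sd = 0, seed = 1L)
  ph <- make_cardiac_pair(spec)
  # compare the US frame nearest to phase 0 with the CT frame at phase 0
  j <- which.min(pmin(ph$truth$us_frame_phases, 1 - ph$truth$us_frame_phases))
  us <- ph$us$frames[[j]]
  ct <- ph$ct$frames[[1]]
  idx <- o_grid_idx(dim(us$data))
  p <- index_to_physical(us, idx)
  ct_vals <- sample_volume_at(ct, p, "linear")
  us_vals <- as.numeric(us$data)
  inside <- us_vals > 0
  # whole cone: strong agreement despite partial-volume mismatch at the
  # sharp structure boundaries
  expect_gt(cor(ct_vals[inside], us_vals[inside]), 0.9)
  # away from structure edges (uniform 2-voxel neighbourhood in the
  # rendering) the same scene must agree almost perfectly: any pose error
  # would shift region labels and destroy this
  u <- us$data
  uniform <- array(TRUE, dim(u))
  dm <- dim(u)
  for (s in list(c(2, 0, 0), c(-2, 0, 0), c(0, 2, 0), c(0, -2, 0),
                 c(0, 0, 2), c(0, 0, -2), c(1, 0, 0), c(-1, 0, 0),
                 c(0, 1, 0), c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))) {
    sh <- u[pmin(pmax(1:dm[1] + s[1], 1), dm[1]),
            pmin(pmax(1:dm[2] + s[2], 1), dm[2]),
            pmin(pmax(1:dm[3] + s[3], 1), dm[3])]
    uniform <- uniform & (sh == u)
  }
  core <- inside & as.numeric(uniform) > 0
  expect_gt(sum(core), 1000)
  expect_gt(cor(ct_vals[core], us_vals[core]), 0.99)
})

test_that("speckle degrades but preserves the cone-zero background", {
  ph <- make_cardiac_pair(o_small_cardiac(noise_sd = 0.3))
  us <- ph$us$frames[[1]]$data
  expect_true(any(us == 0))            # cropped cone corners
  expect_true(all(us >= 0))
})

test_that("jaw phantom symmetry, defect bookkeeping and determinism hold", {
  sym_spec <- jaw_phantom_spec(asymmetry_transform = rigid_identity(),
                               defect_radius_mm = 0)
  sym <- make_jaw_phantom(sym_spec)
  # even x-extent with centred origin puts the mirror plane between columns:
  # voxel-exact mirror symmetry of the rendered scene
  expect_equal(sym$ct$data, sym$ct$data[dim(sym$ct$data)[1]:1, , ])
  # bone mask at stated thresholds equals the rendered bone voxel count
  thr <- sym$truth$bone_thresholds
  mask <- threshold_segment(sym$ct, thr[1], thr[2])
  expect_equal(sum(mask$mask), sum(sym$ct$data == 1200))
  # no defect: phantom equals its own pre-defect rendering
  expect_equal(sum(mask$mask), sum(sym$truth$pre_defect_mask$mask))

  asym <- make_jaw_phantom(jaw_phantom_spec())
  mask_a <- threshold_segment(asym$ct, thr[1], thr[2])
  rep <- mask_overlap_report(mask_a, asym$truth$pre_defect_mask)
  expect_lt(rep$dice, 1)
  # bone lost to the defect lies on the defect (+x / LEFT) side only
  lost <- asym$truth$pre_defect_mask$mask & !mask_a$mask
  idx <- which(lost, arr.ind = TRUE) - 1
  p <- index_to_physical(asym$ct, idx)
  in_defect <- sqrt(rowSums(sweep(p, 2, c(24, 10, 14))^2)) < 11 + 1e-9
  near_defect_or_asym <- p[, 1] > 0 | !in_defect
  expect_true(all(p[in_defect, 1] > 0))
  again <- make_jaw_phantom(jaw_phantom_spec())
  expect_identical(asym$ct$data, again$ct$data)
})

test_that("jaw truth landmarks sit on bone in original and mirrored volumes", {
  ph <- make_jaw_phantom(jaw_phantom_spec())
  expect_gte(length(ph$truth$landmarks_original), 6L)
  v_orig <- sample_volume_at(ph$ct, ph$truth$landmarks_original$points,
                             "nearest")
  expect_true(all(v_orig == 1200))
  mirrored <- mirror_volume(ph$ct, plane_position = 0)
  v_mirr <- sample_volume_at(mirrored, ph$truth$landmarks_mirrored$points,
                             "nearest")
  expect_true(all(v_mirr == 1200))
})
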