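#' Specification of the synthetic 4D cardiac CT/US phantom pair
#'
#' The phantom renders a mitral-valve-like scene from additive geometric
#' primitives: a torus annulus in the valve plane whose diameter pulses
#' sinusoidally over the cardiac cycle, two ellipsoidal chamber shells
#' (atrium/ventricle analogues) filled with contrast-intensity blood pool,
#' and a tube outflow-tract analogue. The CT series is ECG-gated at
#' \code{n_ct_phases} known phase fractions; the US series is free-running
#' on an independent frame grid spanning more than one cycle, rendered from
#' the same scene through \code{true_transform} (the synthetic gold
#' standard), cropped to a probe cone and degraded with multiplicative
#' speckle and a mild blur.
#'
#' Geometry defaults follow typical acquisitions: CT spacing
#' 0.47 x 0.47 x 1.00 mm, US spacing 0.50 x 0.50 x 0.27 mm. The annulus mean
#' diameter (35 mm) and pulsation (15%) are configuration defaults
#' representative of the mitral annulus.
#'
#' @param annulus_diameter_mean mean annulus diameter, mm.
#' @param annulus_pulsation_amplitude peak-to-peak diameter modulation as a
#'   fraction of the mean, in (0,1).
#' @param n_ct_phases number of gated CT phases (default 10).
#' @param n_us_frames number of US frames (must span > 1 cycle).
#' @param us_cycle_span US frames per cardiac cycle.
#' @param us_phase0 cardiac phase of the first US frame (unknown to
#'   consumers; stored only in the truth record).
#' @param ct_spacing,us_spacing voxel spacings, mm.
#' @param ct_shape,us_shape grid sizes (voxels).
#' @param true_transform \code{\link{rigid_transform}} mapping US physical
#'   coordinates into CT space (the arbitrary probe pose).
#' @param us_cone_half_angle probe cone half-angle, degrees.
#' @param noise_sd SD of the unit-mean multiplicative speckle factor
#'   (0 disables speckle and blur).
#' @param seed RNG seed for the speckle.
#' @return Object of class \code{cardiac_phantom_spec}.
#' @export
cardiac_phantom_spec <- function(annulus_diameter_mean = 35,
                                 annulus_pulsation_amplitude = 0.15,
                                 n_ct_phases = 10L,
                                 n_us_frames = 28L,
                                 us_cycle_span = 16L,
                                 us_phase0 = 0.37,
                                 ct_spacing = c(0.47, 0.47, 1.00),
                                 us_spacing = c(0.50, 0.50, 0.27),
                                 ct_shape = c(96L, 96L, 48L),
                                 us_shape = c(80L, 80L, 96L),
                                 true_transform =
                                   rigid_from_params(c(25, -12, 40, 6, -4, 9)),
                                 us_cone_half_angle = 35,
                                 noise_sd = 0.3,
                                 seed = 1L) {
  stopifnot(n_ct_phases >= 2,
            annulus_pulsation_amplitude > 0, annulus_pulsation_amplitude < 1,
            all(ct_spacing > 0), all(us_spacing > 0),
            n_us_frames > us_cycle_span)
  structure(list(annulus_diameter_mean = annulus_diameter_mean,
                 annulus_pulsation_amplitude = annulus_pulsation_amplitude,
                 n_ct_phases = as.integer(n_ct_phases),
                 n_us_frames = as.integer(n_us_frames),
                 us_cycle_span = as.integer(us_cycle_span),
                 us_phase0 = us_phase0,
                 ct_spacing = ct_spacing, us_spacing = us_spacing,
                 ct_shape = as.integer(ct_shape), us_shape = as.integer(us_shape),
                 true_transform = true_transform,
                 us_cone_half_angle = us_cone_half_angle,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "cardiac_phantom_spec")
}

# annulus diameter at cardiac phase p (fully open at p = 0)
.annulus_diameter <- function(spec, p) {
  spec$annulus_diameter_mean *
    (1 + spec$annulus_pulsation_amplitude / 2 * cos(2 * pi * p))
}

# scene intensity at CT-space points (n x 3), at cardiac phase p
.cardiac_scene <- function(pts, p, spec) {
  a <- .annulus_diameter(spec, p) / 2
  x <- pts[, 1]; y <- pts[, 2]; z <- pts[, 3]
  out <- rep(30, nrow(pts))                       # soft-tissue background
  # chamber blood pools (contrast) and 2 mm walls
  e_at <- sqrt((x / 16)^2 + (y / 16)^2 + ((z - 15) / 14)^2)
  e_ve <- sqrt((x / 18)^2 + (y / 18)^2 + ((z + 18) / 16)^2)
  out[e_at < 1] <- 80
  out[e_ve < 1] <- 80
  out[abs(e_at - 1) < 0.12] <- 120
  out[abs(e_ve - 1) < 0.12] <- 120
  # outflow-tract tube (radius 5 mm, 2 mm wall) along a tilted axis
  ax <- c(0.5, 0, 0.8660254); p0 <- c(12, 0, 2)
  rel <- cbind(x - p0[1], y - p0[2], z - p0[3])
  s <- rel %*% ax
  rad <- sqrt(rowSums((rel - s %*% t(ax))^2))
  tube <- s >= 0 & s <= 25 & abs(rad - 5) < 1
  out[tube] <- 180
  # annulus torus (minor radius 2.5 mm), brightest structure
  ring <- sqrt((sqrt(x^2 + y^2) - a)^2 + z^2)
  out[ring < 2.5] <- 250
  out
}

# truth landmark positions in CT space at phase p: annulus ring points,
# trigone analogues, outflow and chamber reference points
.cardiac_truth_landmarks <- function(spec, p) {
  a <- .annulus_diameter(spec, p) / 2
  ang <- (0:7) * pi / 4
  ring <- cbind(a * cos(ang), a * sin(ang), 0)
  extra <- rbind(c(a * cos(1.92), a * sin(1.92), 2.5),   # trigone analogue 1
                 c(a * cos(4.36), a * sin(4.36), 2.5),   # trigone analogue 2
                 c(12, 0, 2) + 10 * c(0.5, 0, 0.8660254),# outflow tract
                 c(0, 10, 14),                           # atrium wall
                 c(0, 0, -20))                           # ventricle apex
  pts <- rbind(ring, extra)
  labels <- c(paste0("annulus_", 1:8), "trigone_1", "trigone_2",
              "outflow", "atrium", "apex")
  landmark_set(pts, labels, space = "ct")
}

.smooth3 <- function(arr) {
  # separable (0.25, 0.5, 0.25) smoothing with edge replication
  for (axis in 1:3) {
    d <- dim(arr)
    lo <- hi <- arr
    n <- d[axis]
    idx_lo <- c(1, seq_len(n - 1)); idx_hi <- c(seq_len(n - 1) + 1, n)
    if (axis == 1) { lo <- arr[idx_lo, , , drop = FALSE]
                     hi <- arr[idx_hi, , , drop = FALSE] }
    if (axis == 2) { lo <- arr[, idx_lo, , drop = FALSE]
                     hi <- arr[, idx_hi, , drop = FALSE] }
    if (axis == 3) { lo <- arr[, , idx_lo, drop = FALSE]
                     hi <- arr[, , idx_hi, drop = FALSE] }
    arr <- 0.5 * arr + 0.25 * (lo + hi)
  }
  arr
}

#' Generate a paired synthetic 4D cardiac CT and US acquisition
#'
#' Renders the gated CT series at phases 0, 1/n, ..., (n-1)/n and the
#' free-running US series at uniformly spaced phases starting from the
#' (consumer-unknown) offset \code{us_phase0}, through the ground-truth
#' probe pose. The truth record carries everything validation needs: the
#' true US-to-CT transform (the synthetic gold standard), the per-frame US
#' phases, and >= 12 labelled anatomical landmark positions per CT phase and
#' per US frame (US positions are the CT positions mapped through the
#' inverse true transform, by construction).
#'
#' @param spec a \code{\link{cardiac_phantom_spec}}.
#' @return List with elements \code{ct} and \code{us}
#'   (\code{\link{time_series_volume}}s) and \code{truth} (list with
#'   \code{true_transform}, \code{us_frame_phases}, \code{ct_phases},
#'   \code{landmarks_ct}, \code{landmarks_us}).
#' @export
make_cardiac_pair <- function(spec = cardiac_phantom_spec()) {
  stopifnot(inherits(spec, "cardiac_phantom_spec"))
  ct_phases <- (seq_len(spec$n_ct_phases) - 1) / spec$n_ct_phases

  centered_origin <- function(shape, spacing) -(shape - 1) / 2 * spacing
  ct_origin <- centered_origin(spec$ct_shape, spec$ct_spacing)
  ct_proto <- volume3d(array(0, spec$ct_shape), spec$ct_spacing, ct_origin,
                       modality = "CT")
  ct_pts <- index_to_physical(ct_proto, .grid_index_matrix(spec$ct_shape))
  ct_frames <- lapply(ct_phases, function(p)
    volume3d(array(.cardiac_scene(ct_pts, p, spec), spec$ct_shape),
             spec$ct_spacing, ct_origin, modality = "CT"))
  ct <- time_series_volume(ct_frames, ct_phases, source = "ECG_GATED")

  us_phases <- spec$us_phase0 + (seq_len(spec$n_us_frames) - 1) / spec$us_cycle_span
  us_origin <- centered_origin(spec$us_shape, spec$us_spacing)
  us_proto <- volume3d(array(0, spec$us_shape), spec$us_spacing, us_origin,
                       modality = "US")
  us_pts <- index_to_physical(us_proto, .grid_index_matrix(spec$us_shape))
  scene_pts <- rt_apply(spec$true_transform, us_pts)
  # probe cone: apex 5 mm above the top of the US volume, axis -z
  apex_z <- max(us_pts[, 3]) + 5
  rel_z <- apex_z - us_pts[, 3]
  rad <- sqrt(us_pts[, 1]^2 + us_pts[, 2]^2)
  in_cone <- rad <= rel_z * tan(spec$us_cone_half_angle * pi / 180)

  us_frames <- withr::with_seed(spec$seed, lapply(us_phases, function(p) {
    vals <- .cardiac_scene(scene_pts, p %% 1, spec)
    vals[!in_cone] <- 0
    arr <- array(vals, spec$us_shape)
    if (spec$noise_sd > 0) {
      arr <- .smooth3(arr)
      # Rayleigh-derived multiplicative speckle, rescaled to mean 1 and the
      # requested relative SD
      ray <- sqrt(-2 * log(stats::runif(length(arr))))
      f <- 1 + spec$noise_sd * (ray - sqrt(pi / 2)) / sqrt(2 - pi / 2)
      arr <- arr * pmax(f, 0)
    }
    volume3d(arr, spec$us_spacing, us_origin, modality = "US")
  }))
  us <- time_series_volume(us_frames, phase = NULL, source = "FREE_RUNNING")

  t_inv <- rt_inverse(spec$true_transform)
  landmarks_ct <- lapply(ct_phases, function(p) .cardiac_truth_landmarks(spec, p))
  landmarks_us <- lapply(us_phases, function(p) {
    lm <- .cardiac_truth_landmarks(spec, p %% 1)
    apply_transform(t_inv, lm, space = "us")
  })
  list(ct = ct, us = us,
       truth = list(true_transform = spec$true_transform,
                    ct_phases = ct_phases,
                    us_frame_phases = us_phases %% 1,
                    landmarks_ct = landmarks_ct,
                    landmarks_us = landmarks_us))
}
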