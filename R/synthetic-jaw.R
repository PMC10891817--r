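#' Specification of the synthetic asymmetric jaw phantom
#'
#' Renders a U-shaped mandible analogue (a half-torus body in the axial
#' plane with two vertical rami) inside a soft-tissue background. To emulate
#' anatomic asymmetry, the whole healthy half of the scene is rigidly
#' displaced by \code{asymmetry_transform} relative to perfect mirror
#' symmetry; a spherical defect region on the other (defect) side is then
#' replaced by tumour-intensity voxels. The truth record stores the intact
#' pre-defect bone mask (rendered before carving, with no asymmetry on the
#' defect side) and landmark positions on defect-side structures outside the
#' defect, together with their positions as seen in the mirrored volume --
#' exactly the inputs the mirror-reconstruction pipeline needs.
#'
#' @param shape grid size in voxels.
#' @param spacing voxel spacing, mm.
#' @param bone_intensity,soft_intensity,tumour_intensity rendered intensity
#'   levels (bone must be separable from the others by thresholding).
#' @param asymmetry_transform \code{\link{rigid_transform}} applied to the
#'   healthy half (identity gives a perfectly symmetric phantom).
#' @param defect_center,defect_radius_mm spherical defect region (LPS mm) on
#'   the defect side; \code{defect_radius_mm = 0} disables the defect.
#' @param defect_side \code{"LEFT"} (+x) or \code{"RIGHT"} (-x).
#' @param seed reserved for future stochastic texture; kept for
#'   reproducibility bookkeeping.
#' @return Object of class \code{jaw_phantom_spec}.
#' @export
jaw_phantom_spec <- function(shape = c(80L, 72L, 56L),
                             spacing = c(1.2, 1.2, 1.2),
                             bone_intensity = 1200,
                             soft_intensity = 60,
                             tumour_intensity = 300,
                             asymmetry_transform =
                               rigid_from_params(c(0, 4, 0, 2.5, -1.5, 1.0)),
                             defect_center = c(24, 10, 14),
                             defect_radius_mm = 11,
                             defect_side = c("LEFT", "RIGHT"),
                             seed = 1L) {
  defect_side <- match.arg(defect_side)
  stopifnot(all(spacing > 0), defect_radius_mm >= 0)
  sgn <- if (defect_side == "LEFT") 1 else -1
  if (defect_radius_mm > 0 && sgn * defect_center[1] <= defect_radius_mm / 2)
    stop("jaw_phantom_spec: defect region must lie on the ", defect_side,
         " side of the mid-sagittal plane")
  structure(list(shape = as.integer(shape), spacing = spacing,
                 bone_intensity = bone_intensity,
                 soft_intensity = soft_intensity,
                 tumour_intensity = tumour_intensity,
                 asymmetry_transform = asymmetry_transform,
                 defect_center = as.numeric(defect_center),
                 defect_radius_mm = defect_radius_mm,
                 defect_side = defect_side, seed = as.integer(seed)),
            class = "jaw_phantom_spec")
}

# symmetric mandible scene: bone intensity where the point lies within the
# body half-torus or either ramus; soft tissue elsewhere
.jaw_scene_symmetric <- function(pts, spec) {
  x <- pts[, 1]; y <- pts[, 2]; z <- pts[, 3]
  bone <- rep(FALSE, nrow(pts))
  # body: half-torus in the z = 0 plane, open toward +y, major radius 28 mm,
  # minor radius 5 mm, centred at y = 8
  ring <- sqrt((sqrt(x^2 + (y - 8)^2) - 28)^2 + z^2)
  bone <- bone | (ring < 5 & y < 8)
  # rami: vertical capsules rising from the posterior ends of the body
  for (sx in c(-1, 1)) {
    cx <- sx * 28; cy <- 8
    rad <- sqrt((x - cx)^2 + (y - cy)^2)
    bone <- bone | (rad < 5 & z >= 0 & z <= 26)
    # condyle knob on top of each ramus
    bone <- bone | (sqrt((x - cx)^2 + (y - cy)^2 + (z - 26)^2) < 6.5)
  }
  ifelse(bone, spec$bone_intensity, spec$soft_intensity)
}

#' Generate the asymmetric jaw phantom with a recoverable defect
#'
#' The defect-side half of the scene is rendered in its ideal symmetric
#' pose; the healthy half is rendered through \code{asymmetry_transform}
#' (points on the healthy side sample the symmetric scene at the
#' inverse-transformed position). The defect sphere is then filled with
#' tumour intensity. Truth landmarks are placed on defect-side bone
#' structures outside the defect; their mirrored-volume counterparts are the
#' same anatomical features as they appear after mirroring the displaced
#' healthy half, computed analytically.
#'
#' @param spec a \code{\link{jaw_phantom_spec}}.
#' @return List with \code{ct} (a \code{\link{volume3d}} centred on the
#'   mid-sagittal plane x = 0) and \code{truth}: \code{pre_defect_mask}
#'   (\code{\link{segmentation_mask}} of the intact symmetric bone),
#'   \code{asymmetry_transform}, \code{landmarks_original},
#'   \code{landmarks_mirrored}, \code{bone_thresholds} and
#'   \code{defect_side}.
#' @export
make_jaw_phantom <- function(spec = jaw_phantom_spec()) {
  stopifnot(inherits(spec, "jaw_phantom_spec"))
  origin <- -(spec$shape - 1) / 2 * spec$spacing
  proto <- volume3d(array(0, spec$shape), spec$spacing, origin, modality = "CT")
  pts <- index_to_physical(proto, .grid_index_matrix(spec$shape))
  sgn <- if (spec$defect_side == "LEFT") 1 else -1

  # healthy half displaced by the asymmetry transform
  healthy <- sgn * pts[, 1] < 0
  pts_sample <- pts
  inv_asym <- rt_inverse(spec$asymmetry_transform)
  pts_sample[healthy, ] <- rt_apply(inv_asym, pts[healthy, , drop = FALSE])
  vals <- .jaw_scene_symmetric(pts_sample, spec)

  # intact symmetric rendering -> pre-defect ground-truth bone mask
  vals_sym <- .jaw_scene_symmetric(pts, spec)
  # halfway between soft tissue/tumour and bone, robust to interpolation
  thresholds <- c((spec$soft_intensity + spec$bone_intensity) / 2,
                  2 * spec$bone_intensity)
  pre_defect <- volume3d(array(vals_sym, spec$shape), spec$spacing, origin,
                         modality = "CT")
  pre_defect_mask <- threshold_segment(pre_defect, thresholds[1], thresholds[2])

  if (spec$defect_radius_mm > 0) {
    d <- sweep(pts, 2, spec$defect_center)
    in_defect <- sqrt(rowSums(d^2)) < spec$defect_radius_mm
    vals[in_defect] <- spec$tumour_intensity
  }
  ct <- volume3d(array(vals, spec$shape), spec$spacing, origin, modality = "CT")

  # truth landmarks: defect-side features outside the defect sphere
  lm <- rbind(c(sgn * 10, -18.5, 0),    # body, anterior
              c(sgn * 20, -12, 0),      # body, lateral
              c(sgn * 26, 0, 0),        # body, posterior
              c(sgn * 15, -16, 4),      # body, superior margin
              c(sgn * 24, -6, -4),      # body, inferior margin
              c(sgn * 5, -20.5, 0),     # near-symphysis
              c(sgn * 27, 4, 2))        # body/ramus junction
  labels <- c("body_ant", "body_lat", "body_post", "body_sup", "body_inf",
              "symphysis", "gonion")
  if (spec$defect_radius_mm > 0) {
    dd <- sqrt(rowSums(sweep(lm, 2, spec$defect_center)^2))
    keep <- dd > spec$defect_radius_mm + 2
    lm <- lm[keep, , drop = FALSE]; labels <- labels[keep]
  }
  landmarks_original <- landmark_set(lm, labels, space = "ct")
  # the same features in the mirrored volume: the healthy-side homologue
  # M(p) was displaced to A(M(p)), and mirroring maps it to M(A(M(p)))
  mirror_x <- function(p) { p[, 1] <- -p[, 1]; p }
  lm_mirr <- mirror_x(rt_apply(spec$asymmetry_transform, mirror_x(lm)))
  landmarks_mirrored <- landmark_set(lm_mirr, labels, space = "ct_mirrored")

  list(ct = ct,
       truth = list(pre_defect_mask = pre_defect_mask,
                    asymmetry_transform = spec$asymmetry_transform,
                    landmarks_original = landmarks_original,
                    landmarks_mirrored = landmarks_mirrored,
                    bone_thresholds = thresholds,
                    defect_side = spec$defect_side))
}
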