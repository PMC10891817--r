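#' Binary segmentation mask tied to a volume's geometry
#'
#' Produced by intensity-band thresholding; the mask is true exactly where
#' \code{lower <= intensity <= upper}. Geometry (spacing, origin, direction)
#' is copied from the source volume so masks can be compared in physical
#' space.
#'
#' @param mask 3D logical array.
#' @param geometry a \code{\link{volume3d}} supplying the geometry.
#' @param lower,upper the thresholds that produced the mask.
#' @param label free-text label.
#' @return Object of class \code{segmentation_mask}.
#' @export
segmentation_mask <- function(mask, geometry, lower = NA_real_,
                              upper = NA_real_, label = "") {
  mask <- array(as.logical(mask), dim(mask))
  stopifnot(length(dim(mask)) == 3L, inherits(geometry, "volume3d"),
            identical(dim(mask), dim(geometry$data)))
  structure(list(mask = mask, spacing = geometry$spacing,
                 origin = geometry$origin, direction = geometry$direction,
                 lower = lower, upper = upper, label = label),
            class = "segmentation_mask")
}

#' @export
print.segmentation_mask <- function(x, ...) {
  cat(sprintf("segmentation_mask '%s': %d voxels in [%g, %g]\n",
              x$label, sum(x$mask), x$lower, x$upper))
  invisible(x)
}

# label connected foreground components (26-neighbourhood), iterative BFS
.largest_component_26 <- function(mask) {
  dm <- dim(mask)
  nb <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  nb <- nb[rowSums(abs(nb)) > 0, ]
  offs <- nb[, 1] + dm[1] * nb[, 2] + dm[1] * dm[2] * nb[, 3]
  fg <- which(mask)
  if (!length(fg)) return(mask)
  comp <- integer(length(mask))  # 0 = unvisited
  ncomp <- 0L
  sizes <- integer(0)
  coord_ok <- function(lin, src_lin) {
    # reject neighbours that wrapped across the i or j faces
    di <- ((lin - 1L) %% dm[1]) - ((src_lin - 1L) %% dm[1])
    dj <- (((lin - 1L) %/% dm[1]) %% dm[2]) - (((src_lin - 1L) %/% dm[1]) %% dm[2])
    abs(di) <= 1L & abs(dj) <= 1L
  }
  for (s in fg) {
    if (comp[s] != 0L) next
    ncomp <- ncomp + 1L
    comp[s] <- ncomp
    frontier <- s
    size <- 1L
    while (length(frontier)) {
      cand <- rep(frontier, each = nrow(nb)) + rep(offs, times = length(frontier))
      src <- rep(frontier, each = nrow(nb))
      ok <- cand >= 1L & cand <= length(mask)
      cand <- cand[ok]; src <- src[ok]
      ok <- coord_ok(cand, src)
      cand <- unique(cand[ok])
      cand <- cand[mask[cand] & comp[cand] == 0L]
      comp[cand] <- ncomp
      size <- size + length(cand)
      frontier <- cand
    }
    sizes[ncomp] <- size
  }
  keep <- which.max(sizes)
  array(comp == keep, dm)
}

#' Threshold-segment a volume into a binary mask
#'
#' Marks voxels with \code{lower <= intensity <= upper}. Optionally keeps
#' only the largest 26-connected component. An empty result raises a
#' warning (count 0), not an error.
#'
#' @param v a \code{\link{volume3d}}.
#' @param lower,upper inclusive intensity band, \code{lower <= upper}.
#' @param largest_component keep only the largest 26-connected component.
#' @param label label stored on the mask.
#' @return A \code{\link{segmentation_mask}}.
#' @export
threshold_segment <- function(v, lower, upper, largest_component = FALSE,
                              label = "") {
  stopifnot(inherits(v, "volume3d"))
  if (lower > upper) stop("threshold_segment: lower > upper")
  m <- v$data >= lower & v$data <= upper
  if (!any(m)) warning("threshold_segment: empty mask (0 voxels in band)")
  else if (largest_component) m <- .largest_component_26(m)
  segmentation_mask(array(m, dim(v$data)), v, lower, upper, label)
}

.mask_geometry_equal <- function(a, b) {
  identical(dim(a$mask), dim(b$mask)) &&
    max(abs(a$spacing - b$spacing)) < 1e-9 &&
    max(abs(a$origin - b$origin)) < 1e-9 &&
    max(abs(a$direction - b$direction)) < 1e-9
}

# physical coordinates of surface voxels (foreground with a 6-neighbour
# background or grid boundary)
.surface_points <- function(m) {
  dm <- dim(m$mask)
  pad <- array(FALSE, dm + 2L)
  pad[2:(dm[1] + 1), 2:(dm[2] + 1), 2:(dm[3] + 1)] <- m$mask
  core <- pad[2:(dm[1] + 1), 2:(dm[2] + 1), 2:(dm[3] + 1)]
  all_nb <- pad[1:dm[1], 2:(dm[2] + 1), 2:(dm[3] + 1)] &
            pad[3:(dm[1] + 2), 2:(dm[2] + 1), 2:(dm[3] + 1)] &
            pad[2:(dm[1] + 1), 1:dm[2], 2:(dm[3] + 1)] &
            pad[2:(dm[1] + 1), 3:(dm[2] + 2), 2:(dm[3] + 1)] &
            pad[2:(dm[1] + 1), 2:(dm[2] + 1), 1:dm[3]] &
            pad[2:(dm[1] + 1), 2:(dm[2] + 1), 3:(dm[3] + 2)]
  surf <- which(core & !all_nb, arr.ind = TRUE) - 1L
  v <- volume3d(array(0, dm), m$spacing, m$origin, m$direction)
  index_to_physical(v, surf)
}

# for each row of a, distance to the nearest row of b (mm), chunked
.nn_dist <- function(a, b, chunk = 512L) {
  out <- numeric(nrow(a))
  bb <- rowSums(b^2)
  for (s in seq(1, nrow(a), by = chunk)) {
    e <- min(s + chunk - 1L, nrow(a))
    blk <- a[s:e, , drop = FALSE]
    d2 <- outer(rowSums(blk^2), bb, "+") - 2 * blk %*% t(b)
    out[s:e] <- sqrt(pmax(apply(d2, 1, min), 0))
  }
  out
}

#' Overlap and surface-distance report between two masks
#'
#' Dice coefficient \eqn{2|A \cap B| / (|A| + |B|)} plus percentiles of the
#' symmetric surface distance, computed by exhaustive nearest-surface-voxel
#' search in physical space (distances pooled over both directions).
#'
#' @param a,b \code{\link{segmentation_mask}}s on the same geometry.
#' @param percentiles surface-distance percentiles to report.
#' @return List with \code{dice}, \code{surface_distance_percentiles} (named
#'   vector, mm) and the voxel counts.
#' @export
mask_overlap_report <- function(a, b, percentiles = c(0.5, 0.9, 0.95, 1.0)) {
  stopifnot(inherits(a, "segmentation_mask"), inherits(b, "segmentation_mask"))
  if (!.mask_geometry_equal(a, b))
    stop("mask_overlap_report: masks have different geometry")
  na <- sum(a$mask); nb <- sum(b$mask)
  dice <- if (na + nb == 0) NA_real_ else 2 * sum(a$mask & b$mask) / (na + nb)
  sd_pct <- rep(NA_real_, length(percentiles))
  if (na > 0 && nb > 0) {
    sa <- .surface_points(a); sb <- .surface_points(b)
    d <- c(.nn_dist(sa, sb), .nn_dist(sb, sa))
    sd_pct <- stats::quantile(d, percentiles, type = 7, names = FALSE)
  }
  list(dice = dice,
       surface_distance_percentiles = stats::setNames(sd_pct,
                                                      paste0("p", percentiles * 100)),
       n_voxels_a = na, n_voxels_b = nb)
}

#' Reconstruct a unilateral jaw defect by mirroring and local registration
#'
#' The pipeline: (1) mirror the CT across the mid-sagittal plane so the
#' healthy side overlays the defect side; (2) fit a rigid "local" transform
#' from landmarks placed on structures adjacent to the defect but unaffected
#' by it (mirrored-volume placements as moving, original-volume placements
#' as fixed); (3) resample the mirrored volume through that transform onto
#' the original grid; (4) re-segment the registered volume with the SAME
#' bone thresholds used for the original (asserted), restricted to the
#' defect side of the mirroring plane.
#'
#' @param ct the original CT \code{\link{volume3d}}.
#' @param bone_thresholds length-2 \code{c(lower, upper)} intensity band for
#'   bone; no default -- thresholds are a required, dataset-specific input.
#' @param defect_side \code{"LEFT"} (+x in LPS) or \code{"RIGHT"}.
#' @param landmarks_original \code{\link{landmark_set}} placed on the
#'   original volume near the defect (fixed side of the fit).
#' @param landmarks_mirrored matching \code{landmark_set} locating the same
#'   features in the mirrored volume (moving side); may be placed fresh on
#'   the mirrored volume or derived from contralateral originals.
#' @param plane_position mirroring-plane x (mm); defaults to the volume's
#'   bounding-box centre x.
#' @param mirror_method interpolation for the mirroring step.
#' @return List of class \code{reconstruction_result}: \code{mirrored},
#'   \code{registered_mirrored} (volumes), \code{local_transform},
#'   \code{reconstructed_mask}, \code{bone_thresholds}.
#' @export
reconstruct_unilateral <- function(ct, bone_thresholds, defect_side,
                                   landmarks_original, landmarks_mirrored,
                                   plane_position = NULL,
                                   mirror_method = "nearest") {
  stopifnot(inherits(ct, "volume3d"), length(bone_thresholds) == 2L)
  defect_side <- match.arg(defect_side, c("LEFT", "RIGHT"))
  if (is.null(plane_position)) plane_position <- volume_center(ct)[1]
  sgn <- if (defect_side == "LEFT") 1 else -1
  xr <- range(index_to_physical(ct, rbind(c(0, 0, 0), dim(ct$data) - 1))[, 1])
  if (sgn * plane_position >= sgn * (if (sgn > 0) xr[2] else xr[1]))
    stop("reconstruct_unilateral: defect side ", defect_side,
         " is inconsistent with mirroring plane at x = ", plane_position)

  mirrored <- mirror_volume(ct, plane_position, method = mirror_method)
  pairing <- landmark_pairing(fixed = landmarks_original,
                              moving = landmarks_mirrored)
  local_transform <- fit_rigid(pairing)
  registered <- resample_through_transform(mirrored, ct, local_transform,
                                           method = "linear")
  # re-segmentation with bit-identical thresholds (asserted)
  mask <- threshold_segment(registered, bone_thresholds[1], bone_thresholds[2],
                            label = "reconstructed")
  stopifnot(identical(c(mask$lower, mask$upper), as.numeric(bone_thresholds)))
  # restrict to the defect side of the mirroring plane
  pts_x <- index_to_physical(ct, .grid_index_matrix(dim(ct$data)))[, 1]
  side <- array(sgn * (pts_x - plane_position) > 0, dim(ct$data))
  mask$mask <- mask$mask & side
  structure(list(mirrored = mirrored, registered_mirrored = registered,
                 local_transform = local_transform,
                 reconstructed_mask = mask,
                 bone_thresholds = as.numeric(bone_thresholds)),
            class = "reconstruction_result")
}
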