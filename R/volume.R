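#' 3D scalar image volume with physical geometry
#'
#' The unit every pipeline stage operates on: a 3D intensity array plus the
#' physical geometry mapping voxel indices to LPS millimetre coordinates,
#' \deqn{p = origin + D \, (s \odot i)}
#' with 0-based index \eqn{i}, per-axis spacing \eqn{s} (mm) and orthonormal
#' direction matrix \eqn{D}. All physical coordinates in the package are LPS
#' (the DICOM/ITK convention); NIfTI's RAS headers are converted at the I/O
#' boundary.
#'
#' @param data 3D numeric array (fastest-varying index first).
#' @param spacing per-axis voxel size in mm, all > 0.
#' @param origin physical LPS position of voxel (0,0,0), mm.
#' @param direction 3x3 orthonormal direction-cosine matrix (columns are the
#'   physical directions of the voxel axes); determinant +1 or -1 within
#'   1e-9 accepted on construction, internal operations keep det = +1.
#' @param modality one of \code{"CT"}, \code{"US"}, \code{"OTHER"}.
#' @return Object of class \code{volume3d}.
#' @examples
#' v <- volume3d(array(0, c(10, 10, 10)), spacing = c(1, 1, 1))
#' dim(v$data); v$spacing
#' @export
volume3d <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                     direction = diag(3), modality = "OTHER") {
  data <- as.array(data)
  if (length(dim(data)) != 3L) stop("volume3d: data must be a 3D array")
  spacing <- unname(as.numeric(spacing)); origin <- unname(as.numeric(origin))
  direction <- unname(as.matrix(direction))
  stopifnot(length(spacing) == 3L, length(origin) == 3L,
            all(dim(direction) == c(3L, 3L)))
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("volume3d: all spacing components must be positive")
  if (max(abs(crossprod(direction) - diag(3))) > 1e-9)
    stop("volume3d: direction matrix not orthonormal within 1e-9")
  if (abs(abs(det(direction)) - 1) > 1e-9)
    stop("volume3d: direction determinant must be +1 or -1 within 1e-9")
  modality <- match.arg(modality, c("CT", "US", "OTHER"))
  structure(list(data = data, spacing = spacing, origin = origin,
                 direction = direction, modality = modality),
            class = "volume3d")
}

#' @export
print.volume3d <- function(x, ...) {
  cat(sprintf("volume3d [%s]: %s voxels, spacing %s mm, origin (%s) LPS\n",
              x$modality, paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing, digits = 4), collapse = "x"),
              paste(format(x$origin, digits = 4), collapse = ", ")))
  invisible(x)
}

#' Map 0-based voxel indices to physical LPS coordinates
#'
#' @param v a \code{volume3d}.
#' @param idx n x 3 matrix (or length-3 vector) of 0-based voxel indices;
#'   fractional indices are allowed.
#' @return n x 3 matrix of LPS coordinates in mm.
#' @export
index_to_physical <- function(v, idx) {
  one <- is.null(dim(idx))
  idx <- matrix(as.numeric(idx), ncol = 3L)
  p <- sweep(idx, 2, v$spacing, "*") %*% t(v$direction) +
    matrix(v$origin, nrow(idx), 3L, byrow = TRUE)
  if (one) p[1, ] else p
}

#' Map physical LPS coordinates to (fractional) 0-based voxel indices
#'
#' @param v a \code{volume3d}.
#' @param pts n x 3 matrix (or length-3 vector) of LPS coordinates in mm.
#' @return n x 3 matrix of continuous 0-based indices.
#' @export
physical_to_index <- function(v, pts) {
  one <- is.null(dim(pts))
  pts <- matrix(as.numeric(pts), ncol = 3L)
  rel <- sweep(pts, 2, v$origin) %*% v$direction  # D orthonormal: D^-1 = D^T
  idx <- sweep(rel, 2, v$spacing, "/")
  if (one) idx[1, ] else idx
}

#' Physical centre of a volume's bounding box (voxel-centre extent)
#' @param v a \code{volume3d}.
#' @return LPS coordinate (mm) of the centre of the voxel-centre bounding box.
#' @export
volume_center <- function(v) {
  index_to_physical(v, (dim(v$data) - 1) / 2)
}

#' Translate a volume so its physical centre sits at the origin
#'
#' Only the origin changes; voxel data, spacing and direction are untouched,
#' so all pairwise physical distances are preserved. Centering is idempotent.
#'
#' @param v a \code{volume3d}.
#' @return The centred \code{volume3d}.
#' @examples
#' v <- volume3d(array(0, c(100, 100, 100)))
#' center_volume(v)$origin  # (-49.5, -49.5, -49.5)
#' @export
center_volume <- function(v) {
  v$origin <- v$origin - volume_center(v)
  v
}
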