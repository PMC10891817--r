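#' Rigid (rotation + translation) spatial transforms
#'
#' A rigid transform maps physical LPS coordinates of a *moving* space into a
#' *fixed* space as \eqn{p \mapsto R p + t}, with \eqn{R} a proper rotation
#' (orthonormal, det = +1) and \eqn{t} a translation in mm. The 6-parameter
#' view uses intrinsic Z-Y-X Euler angles in degrees followed by the
#' translation in mm: \code{(rz, ry, rx, tx, ty, tz)}.
#'
#' @param rotation 3x3 proper rotation matrix.
#' @param translation length-3 numeric translation (mm).
#' @return An object of class \code{rigid_transform}.
#' @examples
#' t <- rigid_transform(diag(3), c(1, 2, 3))
#' transform_params(t)
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  stopifnot(all(dim(rotation) == c(3L, 3L)), length(translation) == 3L)
  if (!all(is.finite(rotation)) || !all(is.finite(translation)))
    stop("rigid_transform: non-finite entries")
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9)
    stop("rigid_transform: rotation matrix is not orthonormal within 1e-9")
  if (abs(det(rotation) - 1) > 1e-9)
    stop("rigid_transform: rotation determinant is not +1 (reflections are not rigid)")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  p <- transform_params(x)
  cat("rigid_transform (moving -> fixed, LPS)\n")
  cat(sprintf("  rotation ZYX (deg): %.4f %.4f %.4f\n", p[1], p[2], p[3]))
  cat(sprintf("  translation (mm):   %.4f %.4f %.4f\n", p[4], p[5], p[6]))
  invisible(x)
}

#' Identity rigid transform
#' @export
rigid_identity <- function() rigid_transform(diag(3), c(0, 0, 0))

#' Invert a rigid transform
#'
#' @param t a \code{rigid_transform}.
#' @return The inverse transform: if \code{t} maps moving to fixed, the
#'   result maps fixed to moving.
#' @export
rt_inverse <- function(t) {
  rigid_transform(t(t$rotation), -crossprod(t$rotation, t$translation)[, 1])
}

#' Compose rigid transforms (a after b)
#'
#' @param a,b \code{rigid_transform}s; the result applies \code{b} first.
#' @export
rt_compose <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' Apply a rigid transform to raw point coordinates
#'
#' @param t a \code{rigid_transform}.
#' @param pts n x 3 matrix of LPS coordinates (mm); a length-3 vector is
#'   treated as one point.
#' @return Matrix of transformed coordinates with the same shape.
#' @export
rt_apply <- function(t, pts) {
  one <- is.null(dim(pts))
  pts <- matrix(as.numeric(pts), ncol = 3L)
  out <- pts %*% t(t$rotation) +
    matrix(t$translation, nrow(pts), 3L, byrow = TRUE)
  if (one) out[1, ] else out
}

rot_x <- function(deg) {
  a <- deg * pi / 180
  matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
}
rot_y <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
}
rot_z <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

#' Build a rigid transform from its 6-parameter vector
#'
#' Parameters are \code{(rz, ry, rx, tx, ty, tz)}: intrinsic Z-Y-X Euler
#' angles in degrees (the rotation is \code{Rz(rz) Ry(ry) Rx(rx)}), then the
#' translation in mm.
#'
#' @param params numeric length 6.
#' @export
rigid_from_params <- function(params) {
  stopifnot(length(params) == 6L)
  rigid_transform(rot_z(params[1]) %*% rot_y(params[2]) %*% rot_x(params[3]),
                  params[4:6])
}

#' Extract the 6-parameter vector of a rigid transform
#'
#' Deterministic intrinsic Z-Y-X Euler extraction; angles in degrees,
#' translations in mm, ordered \code{(rz, ry, rx, tx, ty, tz)}. Near gimbal
#' lock (|ry| within ~1e-6 degrees of 90) the canonical branch \code{rx = 0}
#' is chosen and a warning is raised.
#'
#' @param t a \code{rigid_transform}.
#' @return Named numeric vector of length 6.
#' @export
transform_params <- function(t) {
  R <- t$rotation
  sy <- -R[3, 1]
  sy <- max(-1, min(1, sy))
  ry <- asin(sy)
  if (abs(abs(sy) - 1) < 1e-12) {
    # gimbal lock: rz and rx are not separable; put all roll into rz
    warning("transform_params: pitch at +/-90 degrees (gimbal lock); rx set to 0")
    rz <- atan2(-R[1, 2], R[2, 2])
    rx <- 0
  } else {
    rz <- atan2(R[2, 1], R[1, 1])
    rx <- atan2(R[3, 2], R[3, 3])
  }
  c(rz = rz * 180 / pi, ry = ry * 180 / pi, rx = rx * 180 / pi,
    tx = t$translation[1], ty = t$translation[2], tz = t$translation[3])
}

#' Write a rigid transform as a 4x4 homogeneous matrix text file
#'
#' Plain text: comment header stating the moving-to-fixed direction and LPS
#' frame, then four rows of four numbers.
#'
#' @param t a \code{rigid_transform}.
#' @param path output file path.
#' @export
write_transform_matrix <- function(t, path) {
  m <- rbind(cbind(t$rotation, t$translation), c(0, 0, 0, 1))
  lines <- c("# rigid transform, maps moving -> fixed, LPS coordinates (mm)",
             "# 4x4 homogeneous matrix, row per line",
             apply(m, 1, function(r) paste(formatC(r, format = "g", digits = 17),
                                           collapse = " ")))
  writeLines(lines, path)
  invisible(path)
}

#' Read a rigid transform from a 4x4 matrix text file
#' @param path file written by \code{\link{write_transform_matrix}} (or any
#'   plain 4x4 matrix text with optional \code{#} comment lines).
#' @export
read_transform_matrix <- function(path) {
  if (!file.exists(path)) stop("transform file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 4) stop("expected 4 matrix rows in ", path)
  m <- do.call(rbind, lapply(lines[1:4], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
  if (!all(dim(m) == c(4, 4)) || any(!is.finite(m)))
    stop("malformed 4x4 transform matrix in ", path)
  rigid_transform(m[1:3, 1:3], m[1:3, 4])
}

#' Write a rigid transform in ITK transform-file text format
#'
#' Emits an \code{AffineTransform_double_3_3} record (rotation row-major,
#' then translation; zero fixed center). The transform maps moving to fixed
#' in LPS, which is also ITK's native frame.
#'
#' @param t a \code{rigid_transform}.
#' @param path output path (conventionally \code{.tfm}).
#' @export
write_transform_itk <- function(t, path) {
  pars <- c(t(t$rotation), t$translation)
  writeLines(c("#Insight Transform File V1.0",
               "#Transform 0",
               "Transform: AffineTransform_double_3_3",
               paste("Parameters:", paste(formatC(pars, format = "g", digits = 17),
                                          collapse = " ")),
               "FixedParameters: 0 0 0"), path)
  invisible(path)
}

#' Read an ITK-style transform text file
#' @param path \code{.tfm}-style text file holding one affine/rigid record.
#' @export
read_transform_itk <- function(path) {
  if (!file.exists(path)) stop("transform file not found: ", path)
  lines <- readLines(path)
  pl <- grep("^Parameters:", lines, value = TRUE)
  if (length(pl) < 1) stop("no Parameters line in ", path)
  pars <- as.numeric(strsplit(trimws(sub("^Parameters:", "", pl[1])), "\\s+")[[1]])
  if (length(pars) != 12) stop("expected 12 parameters in ", path)
  R <- matrix(pars[1:9], 3, 3, byrow = TRUE)
  tr <- pars[10:12]
  fl <- grep("^FixedParameters:", lines, value = TRUE)
  if (length(fl) >= 1) {
    ctr <- as.numeric(strsplit(trimws(sub("^FixedParameters:", "", fl[1])), "\\s+")[[1]])
    if (length(ctr) == 3 && any(ctr != 0))
      tr <- tr + ctr - as.numeric(R %*% ctr)
  }
  rigid_transform(R, tr)
}
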