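#' Closed-form least-squares rigid registration of paired landmarks
#'
#' Finds the rigid transform (rotation + translation, no scaling, no
#' reflection) minimizing the sum of squared residuals
#' \deqn{\sum_i \| R\,m_i + t - f_i \|^2}
#' over the paired moving points \eqn{m_i} and fixed points \eqn{f_i}, by the
#' singular-value decomposition of the centred cross-covariance (the
#' classical absolute-orientation / Kabsch solution). When the unconstrained
#' optimum would be a reflection, the sign of the smallest singular direction
#' is flipped so the returned rotation is always proper (det = +1).
#'
#' The returned transform maps moving-space coordinates into fixed space;
#' use \code{\link{rt_inverse}} for the opposite direction.
#'
#' @param pairing a \code{\link{landmark_pairing}} with n >= 3 pairs whose
#'   moving points are not all collinear.
#' @return A \code{\link{rigid_transform}} (moving -> fixed).
#' @examples
#' fx <- landmark_set(rbind(c(1, 2, 3), c(2, 2, 3), c(1, 3, 3), c(1, 2, 4)))
#' mv <- landmark_set(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)))
#' fit_rigid(landmark_pairing(fx, mv))  # pure translation (1,2,3)
#' @export
fit_rigid <- function(pairing) {
  stopifnot(inherits(pairing, "landmark_pairing"))
  f <- pairing$fixed$points
  m <- pairing$moving$points
  n <- nrow(f)
  fc <- colMeans(f)
  mc <- colMeans(m)
  fm <- sweep(f, 2, fc)
  mm <- sweep(m, 2, mc)
  # collinear moving points leave a free rotation about the common axis
  sv_m <- svd(mm, nu = 0, nv = 0)$d
  scale <- max(sv_m[1], .Machine$double.eps)
  if (sv_m[2] / scale < 1e-9)
    stop("fit_rigid: degenerate configuration (moving points collinear); ",
         "the least-squares rotation is not unique")
  H <- crossprod(mm, fm)             # 3x3 cross-covariance (moving x fixed)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  if (d == 0) d <- 1
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  rigid_transform(R, fc - as.numeric(R %*% mc))
}

#' Root-mean-square residual of a rigid fit on its own pairing
#'
#' Convenience wrapper equal to \code{fre(fit_rigid(pairing), pairing)}.
#'
#' @param pairing a \code{landmark_pairing}.
#' @return FRE in mm.
#' @export
fit_rigid_fre <- function(pairing) {
  fre(fit_rigid(pairing), pairing)
}
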