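#' Registration error metrics
#'
#' Three complementary error measures score a trial registration:
#' \itemize{
#'   \item \code{rmse1}: RMS difference between the 6 rigid parameters of the
#'     trial transform and of the gold-standard transform, reported
#'     separately for the three rotation angles (degrees) and the three
#'     translations (mm). It compares the transforms themselves, independent
#'     of any landmark set.
#'   \item \code{fre} (fiducial registration error): RMS Euclidean residual
#'     of the registered landmark pairs, in mm.
#'   \item \code{rmse2}: RMS distance between the moving landmarks mapped by
#'     the trial transform and the same landmarks mapped by the gold
#'     standard, in mm -- how differently the two transforms act on the
#'     anatomy of interest.
#' }
#' @name error_metrics
NULL

#' RMS parameter difference between a trial and a gold-standard transform
#'
#' Both transforms are parameterized under the package's single documented
#' convention (intrinsic Z-Y-X Euler angles in degrees, translations in mm;
#' see \code{\link{transform_params}}). Rotation and translation components
#' are reported separately, never summed, because their units differ.
#' Rotation-angle differences are wrapped into (-180, 180] before squaring.
#'
#' @param eval_t trial \code{rigid_transform}.
#' @param gs_t gold-standard \code{rigid_transform}.
#' @return Named numeric \code{c(rot=..., trans=...)} (degrees, mm).
#' @export
rmse1 <- function(eval_t, gs_t) {
  p1 <- transform_params(eval_t)
  p2 <- transform_params(gs_t)
  dr <- (p1[1:3] - p2[1:3] + 180) %% 360 - 180
  dt <- p1[4:6] - p2[4:6]
  c(rot = sqrt(mean(dr^2)), trans = sqrt(mean(dt^2)))
}

#' Fiducial registration error of a transform on a landmark pairing
#'
#' \deqn{FRE = \sqrt{ \frac{1}{n} \sum_i \| T(m_i) - f_i \|^2 }}
#' the root-mean-square Euclidean residual (mm) between the transformed
#' moving landmarks and their fixed counterparts.
#'
#' @param t a \code{rigid_transform} (moving -> fixed).
#' @param pairing a \code{landmark_pairing}.
#' @return FRE in mm.
#' @export
fre <- function(t, pairing) {
  stopifnot(inherits(pairing, "landmark_pairing"))
  if (pairing$n < 1) stop("fre: empty pairing")
  res <- rt_apply(t, pairing$moving$points) - pairing$fixed$points
  sqrt(mean(rowSums(res^2)))
}

#' Gold-standard reference for scoring trial registrations
#'
#' Bundles the reference transform with the "GS fiducials": the moving-volume
#' landmarks mapped by that transform. The fiducials are computed on
#' construction so the invariant
#' \code{gs_fiducials == apply_transform(transform, moving_landmarks)}
#' holds by construction.
#'
#' @param transform the reference \code{rigid_transform} (moving -> fixed).
#' @param moving_landmarks \code{landmark_set} on the moving volume.
#' @return Object of class \code{gold_standard}.
#' @export
gold_standard <- function(transform, moving_landmarks) {
  stopifnot(inherits(transform, "rigid_transform"),
            inherits(moving_landmarks, "landmark_set"))
  structure(list(transform = transform,
                 moving_landmarks = moving_landmarks,
                 gs_fiducials = apply_transform(transform, moving_landmarks,
                                                space = "fixed")),
            class = "gold_standard")
}

#' RMS distance between trial-transformed and gold-standard fiducials
#'
#' \deqn{RMSE2 = \sqrt{ \frac{1}{n} \sum_i \| tf_i - gsf_i \|^2 }}
#' where \eqn{tf_i} are the moving landmarks mapped by the trial transform
#' and \eqn{gsf_i} the same landmarks mapped by the gold standard.
#'
#' @param t trial \code{rigid_transform} (moving -> fixed).
#' @param moving_landmarks moving-volume \code{landmark_set}; must match the
#'   gold standard's landmarks in length and labels.
#' @param gs a \code{\link{gold_standard}}.
#' @return RMSE2 in mm.
#' @export
rmse2 <- function(t, moving_landmarks, gs) {
  stopifnot(inherits(gs, "gold_standard"),
            inherits(moving_landmarks, "landmark_set"))
  if (!identical(moving_landmarks$labels, gs$gs_fiducials$labels))
    stop("rmse2: landmark labels/length do not match the gold standard")
  tf <- rt_apply(t, moving_landmarks$points)
  d <- tf - gs$gs_fiducials$points
  sqrt(mean(rowSums(d^2)))
}
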