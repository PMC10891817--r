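#' Observer landmark-placement model
#'
#' Emulates a human observer clicking fiducials on the two volumes: each
#' placement is the true position plus i.i.d. per-coordinate Gaussian noise
#' of standard deviation \code{sigma_mm}, optionally inflated with the
#' landmark index as \eqn{\sigma_k = \sigma (1 + \gamma k)} (k = 0-based
#' index) to emulate the observation that later landmarks, placed on less
#' evident anatomy, are localized less accurately. A constant per-observer
#' bias can be added.
#'
#' @param sigma_mm per-coordinate localization SD in mm (>= 0). The
#'   corresponding fiducial localization error is \eqn{FLE^2 = 3\sigma^2}.
#' @param index_inflation gamma >= 0 in \eqn{\sigma_k = \sigma(1+\gamma k)}.
#' @param bias_mm length-3 constant offset (mm) added to every placement.
#' @param seed base RNG seed for reproducible placements.
#' @return Object of class \code{observer_spec}.
#' @export
observer_spec <- function(sigma_mm = 1, index_inflation = 0,
                          bias_mm = c(0, 0, 0), seed = 1L) {
  stopifnot(sigma_mm >= 0, index_inflation >= 0, length(bias_mm) == 3L)
  structure(list(sigma_mm = sigma_mm, index_inflation = index_inflation,
                 bias_mm = as.numeric(bias_mm), seed = as.integer(seed)),
            class = "observer_spec")
}

# deterministic sub-seed for a (trial, user) placement stream; stays < 2^31
.placement_seed <- function(seed, trial, user) {
  uid <- if (is.character(user)) sum(utf8ToInt(user)) else as.integer(user)
  (as.integer(seed) %% 1000003L) * 1009L + (as.integer(trial) %% 9973L) * 97L +
    (uid %% 997L) + 1L
}

#' Simulate observer placement of paired landmarks
#'
#' Takes the first \code{n} truth positions (prefix order) and perturbs each
#' independently per point and per volume with the observer's noise model.
#' Placements are deterministic given \code{(observer$seed, trial, user)} and
#' prefix-nested across \code{n}: the noise for landmark k does not change as
#' n grows, so N-sweeps over the same trial share the first N placements.
#'
#' @param fixed_truth n_max x 3 matrix (or \code{landmark_set}) of true
#'   positions in the fixed volume.
#' @param moving_truth matching truth in the moving volume.
#' @param observer an \code{\link{observer_spec}}.
#' @param n number of pairs to place (<= available truth landmarks).
#' @param trial trial index (part of the RNG stream identity).
#' @param user user id, character or integer (part of the stream identity).
#' @return A \code{\link{landmark_pairing}} of the noisy placements.
#' @export
place_landmarks <- function(fixed_truth, moving_truth, observer, n,
                            trial = 1L, user = 1L) {
  fx <- if (inherits(fixed_truth, "landmark_set")) fixed_truth$points else
    matrix(as.numeric(fixed_truth), ncol = 3L)
  mv <- if (inherits(moving_truth, "landmark_set")) moving_truth$points else
    matrix(as.numeric(moving_truth), ncol = 3L)
  n_max <- nrow(fx)
  stopifnot(nrow(mv) == n_max)
  if (n > n_max) stop("place_landmarks: n = ", n, " exceeds the ", n_max,
                      " available truth landmarks")
  labels <- if (inherits(fixed_truth, "landmark_set")) fixed_truth$labels else
    paste0("F", seq_len(n_max))
  # draw noise for ALL landmarks in a private RNG stream, then take a prefix
  noise <- withr::with_seed(.placement_seed(observer$seed, trial, user), {
    sd_k <- observer$sigma_mm * (1 + observer$index_inflation * (seq_len(n_max) - 1))
    list(fixed = matrix(stats::rnorm(3 * n_max, sd = rep(sd_k, 3)), n_max, 3),
         moving = matrix(stats::rnorm(3 * n_max, sd = rep(sd_k, 3)), n_max, 3))
  })
  bias <- matrix(observer$bias_mm, n_max, 3, byrow = TRUE)
  keep <- seq_len(n)
  landmark_pairing(
    landmark_set((fx + noise$fixed + bias)[keep, , drop = FALSE],
                 labels[keep], "fixed"),
    landmark_set((mv + noise$moving + bias)[keep, , drop = FALSE],
                 labels[keep], "moving"))
}
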