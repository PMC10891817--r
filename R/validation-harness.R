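#' Validation protocol for the landmark-count reproducibility study
#'
#' Encodes the registration validation protocol: the landmark count N is
#' swept from \code{n_min} to \code{n_max}, each (user, N) cell is repeated
#' over \code{trials} independent placements, and records at the chosen N
#' are checked against the acceptance bounds (RMSE2 <= \code{rmse_bound},
#' FRE <= \code{fre_bound}, both inclusive). Defaults follow the cardiac
#' study: N in 3..12, 10 trials, two users, chosen N = 10, bounds 15 mm and
#' 8 mm.
#'
#' @param n_min,n_max landmark-count sweep range.
#' @param trials repeated registration trials per (user, N).
#' @param users character vector of observer ids.
#' @param chosen_n the landmark count used operationally.
#' @param rmse_bound,fre_bound acceptance bounds in mm.
#' @return Object of class \code{validation_protocol}.
#' @export
validation_protocol <- function(n_min = 3L, n_max = 12L, trials = 10L,
                                users = c("user1", "user2"), chosen_n = 10L,
                                rmse_bound = 15, fre_bound = 8) {
  n_min <- as.integer(n_min); n_max <- as.integer(n_max)
  chosen_n <- as.integer(chosen_n); trials <- as.integer(trials)
  if (!(3L <= n_min && n_min <= chosen_n && chosen_n <= n_max))
    stop("validation_protocol: need 3 <= n_min <= chosen_n <= n_max")
  if (trials < 1L) stop("validation_protocol: trials >= 1 required")
  if (rmse_bound <= 0 || fre_bound <= 0)
    stop("validation_protocol: bounds must be positive")
  structure(list(n_min = n_min, n_max = n_max, trials = trials,
                 users = as.character(users), chosen_n = chosen_n,
                 rmse_bound = rmse_bound, fre_bound = fre_bound),
            class = "validation_protocol")
}

#' Sweep landmark count over repeated observer trials
#'
#' For each (user, trial) a full set of \code{n_max} noisy landmark
#' placements is simulated (or taken from recorded files); for each N in
#' [\code{n_min}, \code{n_max}] the rigid registration is fit on the FIRST N
#' pairs -- prefix nesting, so landmark k's placement is identical across N
#' within a trial -- and all three metrics are computed against the gold
#' standard. Fully reproducible given the observer seeds.
#'
#' @param fixed_truth,moving_truth truth landmark positions (n_max x 3 or
#'   \code{landmark_set}) in the fixed and moving volumes.
#' @param gs a \code{\link{gold_standard}} built on the moving truth
#'   landmarks (or on the recorded moving landmarks).
#' @param protocol a \code{\link{validation_protocol}}.
#' @param observers named list mapping each user id to an
#'   \code{\link{observer_spec}}; a single spec is recycled for all users.
#' @param recorded optional recorded placements instead of the observer
#'   model: a list indexed \code{recorded[[user]][[trial]]} of
#'   \code{landmark_pairing}s with at least n_max pairs.
#' @param patient patient id tag for the records.
#' @return Data frame of metric records with columns \code{patient, user,
#'   trial, n_landmarks, rmse1_rot, rmse1_trans, fre, rmse2}.
#' @export
run_sweep <- function(fixed_truth, moving_truth, gs, protocol,
                      observers = NULL, recorded = NULL, patient = "P1") {
  stopifnot(inherits(protocol, "validation_protocol"),
            inherits(gs, "gold_standard"))
  if (is.null(observers) && is.null(recorded))
    stop("run_sweep: need an observer model or recorded landmark placements")
  if (inherits(observers, "observer_spec"))
    observers <- stats::setNames(rep(list(observers), length(protocol$users)),
                                 protocol$users)
  ns <- protocol$n_min:protocol$n_max
  recs <- vector("list", length(protocol$users) * protocol$trials * length(ns))
  k <- 0L
  for (user in protocol$users) {
    for (trial in seq_len(protocol$trials)) {
      if (!is.null(recorded)) {
        full <- recorded[[user]][[trial]]
        if (is.null(full) || full$n < protocol$n_max)
          stop("run_sweep: fewer than n_max recorded landmarks for user ",
               user, ", trial ", trial)
      } else {
        full <- place_landmarks(fixed_truth, moving_truth, observers[[user]],
                                n = protocol$n_max, trial = trial, user = user)
      }
      for (n in ns) {
        pairing <- landmark_pairing(lm_head(full$fixed, n),
                                    lm_head(full$moving, n))
        t_fit <- fit_rigid(pairing)
        r1 <- rmse1(t_fit, gs$transform)
        k <- k + 1L
        recs[[k]] <- data.frame(
          patient = patient, user = user, trial = trial, n_landmarks = n,
          rmse1_rot = r1[["rot"]], rmse1_trans = r1[["trans"]],
          fre = fre(t_fit, pairing),
          rmse2 = rmse2(t_fit, gs$moving_landmarks, gs))
      }
    }
  }
  do.call(rbind, recs)
}

#' Mean/SD metric curves versus landmark count
#'
#' Averages each metric over the trials, per (patient, user, N), mirroring
#' the per-N trend curves of the reproducibility study.
#'
#' @param records data frame from \code{\link{run_sweep}}.
#' @return Data frame with one row per (patient, user, n_landmarks) and
#'   mean/sd columns for each metric.
#' @export
aggregate_curves <- function(records) {
  metrics <- c("rmse1_rot", "rmse1_trans", "fre", "rmse2")
  by <- list(patient = records$patient, user = records$user,
             n_landmarks = records$n_landmarks)
  means <- stats::aggregate(records[metrics], by, mean)
  sds <- stats::aggregate(records[metrics], by, stats::sd)
  names(means)[match(metrics, names(means))] <- paste0(metrics, "_mean")
  names(sds)[match(metrics, names(sds))] <- paste0(metrics, "_sd")
  out <- merge(means, sds, by = c("patient", "user", "n_landmarks"))
  out[order(out$patient, out$user, out$n_landmarks), , drop = FALSE]
}

#' Select the optimal landmark count from aggregated curves
#'
#' The optimum trades accuracy against placement effort: the smallest N
#' whose mean RMSE2 (pooled over patients and users) lies within
#' \code{tolerance} (relative) of the minimum mean RMSE2 over the sweep.
#' Ties break toward smaller N. A constant curve therefore yields
#' \code{n_min}.
#'
#' @param curves data frame from \code{\link{aggregate_curves}}.
#' @param protocol a \code{\link{validation_protocol}}.
#' @param tolerance relative closeness to the minimum (default 0.05).
#' @return The selected N (integer).
#' @export
select_optimal_n <- function(curves, protocol, tolerance = 0.05) {
  pooled <- stats::aggregate(list(rmse2 = curves$rmse2_mean),
                             list(n_landmarks = curves$n_landmarks), mean)
  pooled <- pooled[order(pooled$n_landmarks), ]
  lo <- min(pooled$rmse2)
  ok <- pooled$rmse2 <= lo * (1 + tolerance) + 1e-12
  as.integer(min(pooled$n_landmarks[ok]))
}

#' Check all records at the chosen N against the acceptance bounds
#'
#' Passes iff every record at \code{protocol$chosen_n} has
#' \code{rmse2 <= rmse_bound} and \code{fre <= fre_bound}; both comparisons
#' are inclusive. Offending records are returned for inspection.
#'
#' @param records data frame from \code{\link{run_sweep}}.
#' @param protocol a \code{\link{validation_protocol}}.
#' @return List \code{list(pass = logical, offenders = data.frame)}.
#' @export
check_bounds <- function(records, protocol) {
  at <- records[records$n_landmarks == protocol$chosen_n, , drop = FALSE]
  if (!nrow(at)) stop("check_bounds: no records at chosen N = ",
                      protocol$chosen_n)
  bad <- at$rmse2 > protocol$rmse_bound | at$fre > protocol$fre_bound
  list(pass = !any(bad), offenders = at[bad, , drop = FALSE])
}

#' Five-number boxplot summaries at the chosen landmark count
#'
#' Min, Q1, median, Q3, max per (patient, user) at \code{chosen_n}, with
#' quantiles by linear interpolation of order statistics (R type 7), plus
#' the count of points flagged as outliers by the 1.5 IQR rule.
#'
#' @param records data frame from \code{\link{run_sweep}}.
#' @param chosen_n landmark count to summarize at.
#' @param metric which metric column to summarize (default \code{"fre"}).
#' @return Data frame with columns patient, user, min, q1, median, q3, max,
#'   n_outliers.
#' @export
boxplot_summary <- function(records, chosen_n, metric = "fre") {
  at <- records[records$n_landmarks == chosen_n, , drop = FALSE]
  if (!nrow(at)) stop("boxplot_summary: no records at N = ", chosen_n)
  groups <- split(at[[metric]], list(at$patient, at$user), drop = TRUE)
  out <- do.call(rbind, lapply(names(groups), function(g) {
    x <- groups[[g]]
    q <- stats::quantile(x, c(0, 0.25, 0.5, 0.75, 1), type = 7, names = FALSE)
    iqr <- q[4] - q[2]
    key <- strsplit(g, ".", fixed = TRUE)[[1]]
    data.frame(patient = key[1], user = paste(key[-1], collapse = "."),
               min = q[1], q1 = q[2], median = q[3], q3 = q[4], max = q[5],
               n_outliers = sum(x < q[2] - 1.5 * iqr | x > q[4] + 1.5 * iqr))
  }))
  rownames(out) <- NULL
  out
}
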