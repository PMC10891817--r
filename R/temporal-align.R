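#' Temporal alignment of gated CT and free-running US series
#'
#' The contrast CT is ECG-gated at 10 known phase fractions of the cardiac
#' cycle; the 4D US runs free, unsynchronized with the ECG, over one or more
#' cycles. Temporal registration first delimits one full cardiac cycle in
#' the US series (between two "fully open" valve states) and then matches
#' each CT phase to the US frame at the same relative position in that
#' cycle.
#' @name temporal_align
NULL

#' A selected cardiac cycle within a US frame sequence
#'
#' @param start_frame,end_frame 0-based frame indices delimiting one full
#'   cycle, \code{start_frame < end_frame}.
#' @param n_frames total number of US frames (for bounds checking), or
#'   \code{NULL} to skip the upper-bound check.
#' @param criterion free-text description of the delimiting criterion.
#' @return Object of class \code{cycle_selection}.
#' @export
cycle_selection <- function(start_frame, end_frame, n_frames = NULL,
                            criterion = "user-specified") {
  start_frame <- as.integer(start_frame); end_frame <- as.integer(end_frame)
  if (start_frame < 0 || start_frame >= end_frame)
    stop("cycle_selection: need 0 <= start_frame < end_frame")
  if (!is.null(n_frames) && end_frame >= n_frames)
    stop("cycle_selection: end_frame ", end_frame,
         " out of range for ", n_frames, " frames")
  structure(list(start_frame = start_frame, end_frame = end_frame,
                 criterion = criterion), class = "cycle_selection")
}

# first pair of consecutive local maxima separated by a valley at least
# min_drop below both peaks (the valve closing between two fully-open
# states); boundary samples count as maxima
.find_cycle_peaks <- function(x, min_drop) {
  n <- length(x)
  left <- c(-Inf, x[-n]); right <- c(x[-1], -Inf)
  cand <- which(x >= left & x >= right & (x > left | x > right))
  if (length(cand) >= 2) {
    for (k in seq_len(length(cand) - 1)) {
      a <- cand[k]; b <- cand[k + 1]
      valley <- min(x[a:b])
      if (x[a] - valley >= min_drop && x[b] - valley >= min_drop)
        return(c(a, b))
    }
  }
  NULL
}

#' Delimit one cardiac cycle in a US series from a valve-openness signal
#'
#' The openness signal is any per-frame scalar proxy for leaflet opening
#' (e.g. the mean intensity in a user-chosen ROI box, see
#' \code{\link{openness_signal}}); a cycle runs between two consecutive
#' "fully open" states: the first pair of consecutive local maxima whose
#' intervening valley (the valve closing) drops at least
#' \code{prominence_frac} of the signal range below both maxima. Explicit
#' \code{start}/\code{end} indices mirror the interactive visual selection
#' and bypass peak detection.
#'
#' @param us a \code{\link{time_series_volume}} (or an integer giving the
#'   frame count) used for bounds checking.
#' @param openness numeric per-frame signal; required unless \code{start}
#'   and \code{end} are given.
#' @param start,end optional user-supplied 0-based frame indices.
#' @param prominence_frac minimum depth of the valley between the two
#'   delimiting maxima, as a fraction of the signal range (default 0.25).
#' @return A \code{\link{cycle_selection}}.
#' @examples
#' s <- sin(pi * (0:40) / 10)^2  # two exact periods, maxima at 5,15,25,35
#' select_cycle(41L, s)
#' @export
select_cycle <- function(us, openness = NULL, start = NULL, end = NULL,
                         prominence_frac = 0.25) {
  n <- if (inherits(us, "time_series_volume")) length(us$frames) else as.integer(us)
  if (!is.null(start) && !is.null(end))
    return(cycle_selection(start, end, n, criterion = "user-specified"))
  if (is.null(openness)) stop("select_cycle: need an openness signal or ",
                              "explicit start/end indices")
  if (length(openness) != n)
    stop("select_cycle: openness must have one value per frame")
  rng <- diff(range(openness))
  if (rng <= 0) stop("select_cycle: fewer than 2 'fully open' maxima in the ",
                     "openness signal; cannot delimit a cycle")
  peaks <- .find_cycle_peaks(openness, min_drop = prominence_frac * rng)
  if (is.null(peaks))
    stop("select_cycle: fewer than 2 'fully open' maxima in the openness ",
         "signal; cannot delimit a cycle")
  cycle_selection(peaks[1] - 1L, peaks[2] - 1L, n,
                  criterion = "fully-open to fully-open (automatic)")
}

#' Mean-intensity openness proxy inside an ROI box
#'
#' A simple automatic stand-in for visual assessment of valve opening: the
#' mean intensity within a fixed voxel box, per frame. With a contrast-filled
#' orifice the mean tracks the leaflet opening.
#'
#' @param ts a \code{\link{time_series_volume}}.
#' @param roi_min,roi_max 1-based inclusive voxel index corners of the box.
#' @return Numeric vector, one value per frame.
#' @export
openness_signal <- function(ts, roi_min, roi_max) {
  stopifnot(inherits(ts, "time_series_volume"))
  vapply(ts$frames, function(f)
    mean(f$data[roi_min[1]:roi_max[1], roi_min[2]:roi_max[2],
                roi_min[3]:roi_max[3]]), numeric(1))
}

#' Match each gated CT phase to its US frame within the selected cycle
#'
#' Assuming uniform phase spacing across the selected US cycle (no ECG is
#' available for the US), CT phase fraction \eqn{p} maps to
#' \code{start_frame + round(p * (end_frame - start_frame))}, with R's
#' round-half-even rounding. The mapping is deterministic and monotone in
#' \eqn{p}.
#'
#' @param ct an ECG-gated \code{\link{time_series_volume}} with known
#'   phases, or a numeric vector of phase fractions.
#' @param cycle a \code{\link{cycle_selection}}.
#' @return Data frame with columns \code{ct_phase_index} (0-based),
#'   \code{ct_phase_fraction} and \code{us_frame_index} (0-based).
#' @examples
#' match_phases(seq(0, 0.9, by = 0.1), cycle_selection(5, 24))
#' @export
match_phases <- function(ct, cycle) {
  stopifnot(inherits(cycle, "cycle_selection"))
  if (inherits(ct, "time_series_volume")) {
    if (ct$source != "ECG_GATED" || is.null(ct$phase))
      stop("match_phases: CT series must be ECG-gated with known phases")
    phases <- ct$phase
  } else phases <- as.numeric(ct)
  if (anyNA(phases)) stop("match_phases: unknown CT phases")
  span <- cycle$end_frame - cycle$start_frame
  data.frame(ct_phase_index = seq_along(phases) - 1L,
             ct_phase_fraction = phases,
             us_frame_index = cycle$start_frame + as.integer(round(phases * span)))
}

#' Extract the CT/US volume pair at a given cardiac phase
#'
#' @param ct gated CT \code{\link{time_series_volume}}.
#' @param us free-running US \code{\link{time_series_volume}}.
#' @param matches match table from \code{\link{match_phases}}.
#' @param phase_fraction requested gated phase (e.g. 0.9 for end-diastole).
#' @return List \code{list(ct = volume3d, us = volume3d)}.
#' @export
extract_matched_pair <- function(ct, us, matches, phase_fraction) {
  row <- which(abs(matches$ct_phase_fraction - phase_fraction) < 1e-9)
  if (length(row) != 1)
    stop("extract_matched_pair: phase ", phase_fraction,
         " is not one of the gated CT phases")
  list(ct = ct$frames[[matches$ct_phase_index[row] + 1L]],
       us = us$frames[[matches$us_frame_index[row] + 1L]])
}
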