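#' Ordered sets of labelled fiducial landmarks
#'
#' A landmark set holds ordered 3D physical-space points (LPS, mm) with
#' unique per-point labels and a frame-of-reference tag naming the volume the
#' points were placed on.
#'
#' @param points n x 3 numeric matrix of LPS coordinates in mm.
#' @param labels character vector of unique labels, one per point; defaults
#'   to \code{F1..Fn}.
#' @param space frame-of-reference tag (volume identifier).
#' @return Object of class \code{landmark_set}.
#' @examples
#' landmark_set(rbind(c(0, 0, 0), c(10, 0, 0)), c("apex", "annulus"))
#' @export
landmark_set <- function(points, labels = NULL, space = "unknown") {
  points <- matrix(as.numeric(points), ncol = 3L)
  if (!all(is.finite(points))) stop("landmark_set: coordinates must be finite")
  n <- nrow(points)
  if (is.null(labels)) labels <- paste0("F", seq_len(n))
  labels <- as.character(labels)
  if (length(labels) != n) stop("landmark_set: one label per point required")
  if (anyDuplicated(labels)) stop("landmark_set: labels must be unique")
  structure(list(points = points, labels = labels, space = as.character(space)),
            class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("landmark_set: %d points in space '%s' (LPS mm)\n",
              nrow(x$points), x$space))
  invisible(x)
}

#' @export
length.landmark_set <- function(x) nrow(x$points)

#' Take the first n landmarks of a set
#' @param x a \code{landmark_set}.
#' @param n prefix length.
#' @export
lm_head <- function(x, n) {
  stopifnot(n >= 1, n <= nrow(x$points))
  landmark_set(x$points[seq_len(n), , drop = FALSE], x$labels[seq_len(n)], x$space)
}

#' Paired fixed/moving landmark correspondence
#'
#' Pairs the i-th fixed point with the i-th moving point. Labels must match
#' pairwise and at least 3 pairs are required, the minimum for a rigid fit.
#'
#' @param fixed,moving \code{landmark_set}s of equal length with matching
#'   labels.
#' @return Object of class \code{landmark_pairing}.
#' @export
landmark_pairing <- function(fixed, moving) {
  stopifnot(inherits(fixed, "landmark_set"), inherits(moving, "landmark_set"))
  n <- nrow(fixed$points)
  if (nrow(moving$points) != n)
    stop("landmark_pairing: fixed and moving sets differ in length")
  if (n < 3) stop("landmark_pairing: at least 3 pairs required")
  if (!identical(fixed$labels, moving$labels))
    stop("landmark_pairing: corresponding labels must match")
  structure(list(fixed = fixed, moving = moving, n = n),
            class = "landmark_pairing")
}

#' Apply a rigid transform to a landmark set
#'
#' Maps each point \eqn{p \mapsto R p + t}; labels and ordering preserved.
#'
#' @param t a \code{rigid_transform}.
#' @param lms a \code{landmark_set}.
#' @param space optional new frame-of-reference tag for the result.
#' @export
apply_transform <- function(t, lms, space = lms$space) {
  stopifnot(inherits(t, "rigid_transform"), inherits(lms, "landmark_set"))
  landmark_set(rt_apply(t, lms$points), lms$labels, space)
}

## ---- file formats ----------------------------------------------------------

#' Read landmarks from a Slicer FCSV fiducial file
#'
#' Handles both RAS and LPS coordinate-system headers; RAS coordinates are
#' converted to the package's LPS convention (x and y negated).
#'
#' @param path an \code{.fcsv} file.
#' @param space frame-of-reference tag to attach.
#' @return A \code{landmark_set} (LPS mm).
#' @export
read_fcsv <- function(path, space = basename(path)) {
  if (!file.exists(path)) stop("fcsv file not found: ", path)
  lines <- readLines(path)
  hdr <- lines[grepl("^#", lines)]
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  ras <- TRUE  # legacy Slicer default
  cs <- grep("CoordinateSystem", hdr, value = TRUE)
  if (length(cs)) {
    val <- trimws(sub(".*=", "", cs[1]))
    ras <- val %in% c("RAS", "0")
  }
  if (!length(body)) stop("fcsv file has no landmark rows: ", path)
  rows <- strsplit(body, ",")
  pts <- t(vapply(rows, function(r) as.numeric(r[2:4]), numeric(3)))
  labels <- vapply(rows, function(r) if (length(r) >= 12) r[12] else r[1],
                   character(1))
  if (any(!nzchar(labels))) labels <- paste0("F", seq_along(labels))
  if (ras) pts[, 1:2] <- -pts[, 1:2]
  landmark_set(pts, labels, space)
}

#' Write landmarks as a Slicer FCSV fiducial file
#'
#' Writes LPS coordinates with an explicit \code{CoordinateSystem = LPS}
#' header so round-trips are exact.
#'
#' @param lms a \code{landmark_set}.
#' @param path output \code{.fcsv} path.
#' @export
write_fcsv <- function(lms, path) {
  n <- nrow(lms$points)
  rows <- vapply(seq_len(n), function(i)
    paste(c(sprintf("vtkMRMLMarkupsFiducialNode_%d", i - 1),
            formatC(lms$points[i, ], format = "g", digits = 17),
            "0", "0", "0", "1", "1", "1", "0",
            lms$labels[i], "", ""), collapse = ","), character(1))
  writeLines(c("# Markups fiducial file version = 4.11",
               "# CoordinateSystem = LPS",
               "# columns = id,x,y,z,ow,ox,oy,oz,vis,sel,lock,label,desc,associatedNodeID",
               rows), path)
  invisible(path)
}

#' Read landmarks from a Slicer markups JSON file
#' @param path a \code{.mrk.json} markups file.
#' @param space frame-of-reference tag to attach.
#' @export
read_markups_json <- function(path, space = basename(path)) {
  if (!file.exists(path)) stop("markups file not found: ", path)
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(j$markups) || !length(j$markups))
    stop("no markups in ", path)
  mk <- j$markups[[1]]
  cs <- if (!is.null(mk$coordinateSystem)) mk$coordinateSystem else "LPS"
  cps <- mk$controlPoints
  if (is.null(cps) || !length(cps)) stop("no control points in ", path)
  pts <- t(vapply(cps, function(p) as.numeric(unlist(p$position)), numeric(3)))
  labels <- vapply(seq_along(cps), function(i) {
    lb <- cps[[i]]$label
    if (is.null(lb) || !nzchar(lb)) paste0("F", i) else lb
  }, character(1))
  if (identical(cs, "RAS")) pts[, 1:2] <- -pts[, 1:2]
  landmark_set(pts, labels, space)
}

#' Write landmarks as a Slicer markups JSON file
#' @param lms a \code{landmark_set}.
#' @param path output \code{.mrk.json} path.
#' @export
write_markups_json <- function(lms, path) {
  cps <- lapply(seq_len(nrow(lms$points)), function(i)
    list(id = as.character(i), label = lms$labels[i],
         position = as.numeric(lms$points[i, ])))
  jsonlite::write_json(
    list(markups = list(list(type = "Fiducial", coordinateSystem = "LPS",
                             controlPoints = cps))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read landmarks from a plain CSV (label,x,y,z in LPS mm)
#' @param path CSV with header \code{label,x,y,z}.
#' @param space frame-of-reference tag to attach.
#' @export
read_landmarks_csv <- function(path, space = basename(path)) {
  if (!file.exists(path)) stop("landmark csv not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "x", "y", "z")
  if (!all(need %in% names(d))) stop("landmark csv needs columns label,x,y,z")
  landmark_set(as.matrix(d[, c("x", "y", "z")]), d$label, space)
}

#' Write landmarks as a plain CSV (label,x,y,z in LPS mm)
#' @param lms a \code{landmark_set}.
#' @param path output CSV path.
#' @export
write_landmarks_csv <- function(lms, path) {
  d <- data.frame(label = lms$labels, x = lms$points[, 1],
                  y = lms$points[, 2], z = lms$points[, 3])
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
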