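#' Volume file I/O
#'
#' Volumes are read and written in NRRD (attached or detached header; raw,
#' gzip or ascii encodings) and NIfTI-1 (via RNifti). Geometry is always
#' taken from the file header, never guessed, and converted to the package's
#' LPS convention: NIfTI headers and RAS-space NRRDs have their first two
#' physical axes negated on read, and are written back the same way.
#' @name volume_io
NULL

.nrrd_types <- list(
  "uchar" = list(what = "integer", size = 1, signed = FALSE),
  "unsigned char" = list(what = "integer", size = 1, signed = FALSE),
  "uint8" = list(what = "integer", size = 1, signed = FALSE),
  "short" = list(what = "integer", size = 2, signed = TRUE),
  "signed short" = list(what = "integer", size = 2, signed = TRUE),
  "int16" = list(what = "integer", size = 2, signed = TRUE),
  "ushort" = list(what = "integer", size = 2, signed = FALSE),
  "unsigned short" = list(what = "integer", size = 2, signed = FALSE),
  "uint16" = list(what = "integer", size = 2, signed = FALSE),
  "int" = list(what = "integer", size = 4, signed = TRUE),
  "signed int" = list(what = "integer", size = 4, signed = TRUE),
  "int32" = list(what = "integer", size = 4, signed = TRUE),
  "float" = list(what = "double", size = 4, signed = TRUE),
  "double" = list(what = "double", size = 8, signed = TRUE))

.parse_nrrd_vec <- function(s) {
  s <- gsub("[()]", "", trimws(s))
  as.numeric(strsplit(s, ",")[[1]])
}

#' Read a volume from a NRRD file
#'
#' Supports NRRD0001-0005 magic, attached and detached (\code{.nhdr} +
#' \code{data file:}) headers, \code{raw}, \code{gzip} and \code{ascii}
#' encodings, and the \code{left-posterior-superior} /
#' \code{right-anterior-superior} space tags (RAS converted to LPS).
#'
#' @param path a \code{.nrrd} or \code{.nhdr} file.
#' @param modality modality tag for the returned volume.
#' @return A \code{\link{volume3d}}.
#' @export
read_nrrd <- function(path, modality = "OTHER") {
  if (!file.exists(path)) stop("NRRD file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  magic <- readLines(con, n = 1, warn = FALSE)
  if (!grepl("^NRRD000[1-5]", magic)) stop("not a NRRD file: ", path)
  fields <- list()
  repeat {
    line <- readLines(con, n = 1, warn = FALSE)
    if (length(line) == 0 || !nzchar(line)) break
    if (grepl("^#", line)) next
    kv <- regmatches(line, regexpr(":=?", line), invert = TRUE)[[1]]
    if (length(kv) >= 2)
      fields[[tolower(trimws(kv[1]))]] <- trimws(paste(kv[-1], collapse = ":"))
  }
  dimn <- as.integer(fields[["dimension"]])
  if (is.na(dimn)) stop("NRRD header missing dimension: ", path)
  if (dimn == 4L)
    stop("4D NRRD passed where a 3D volume was expected; ",
         "use the time-series reader (read_time_series) instead")
  if (dimn != 3L) stop("only 3D NRRD volumes are supported, got dimension ", dimn)
  sizes <- as.integer(strsplit(fields[["sizes"]], "\\s+")[[1]])
  type <- .nrrd_types[[tolower(fields[["type"]])]]
  if (is.null(type)) stop("unsupported NRRD type: ", fields[["type"]])
  encoding <- tolower(fields[["encoding"]])
  endian <- if (!is.null(fields[["endian"]])) fields[["endian"]] else "little"
  n <- prod(sizes)

  data_con <- con
  if (!is.null(fields[["data file"]])) {
    dpath <- file.path(dirname(path), fields[["data file"]])
    if (!file.exists(dpath)) stop("detached NRRD data file not found: ", dpath)
    data_con <- file(dpath, "rb")
    on.exit(close(data_con), add = TRUE)
  }
  vals <- switch(encoding,
    raw = readBin(data_con, type$what, n = n, size = type$size,
                  signed = type$signed, endian = endian),
    gzip = , gz = {
      comp <- readBin(data_con, "raw", n = file.size(path) + 16)
      raw <- memDecompress(comp, type = "gzip")
      readBin(raw, type$what, n = n, size = type$size,
              signed = type$signed, endian = endian)
    },
    ascii = , txt = , text = scan(data_con, what = double(), n = n, quiet = TRUE),
    stop("unsupported NRRD encoding: ", encoding))
  if (length(vals) != n) stop("NRRD data truncated: ", path)

  spacing <- c(1, 1, 1); direction <- diag(3); origin <- c(0, 0, 0)
  space <- if (!is.null(fields[["space"]])) tolower(fields[["space"]]) else
    "left-posterior-superior"
  if (!is.null(fields[["space directions"]])) {
    toks <- regmatches(fields[["space directions"]],
                       gregexpr("\\(([^)]*)\\)", fields[["space directions"]]))[[1]]
    if (length(toks) != 3) stop("expected 3 space direction vectors in ", path)
    M <- vapply(toks, .parse_nrrd_vec, numeric(3))  # columns = axis vectors
    spacing <- sqrt(colSums(M^2))
    direction <- sweep(M, 2, spacing, "/")
  } else if (!is.null(fields[["spacings"]])) {
    spacing <- as.numeric(strsplit(fields[["spacings"]], "\\s+")[[1]])
  }
  if (!is.null(fields[["space origin"]]))
    origin <- .parse_nrrd_vec(fields[["space origin"]])
  if (space %in% c("right-anterior-superior", "ras")) {
    direction[1:2, ] <- -direction[1:2, ]
    origin[1:2] <- -origin[1:2]
  } else if (!space %in% c("left-posterior-superior", "lps"))
    stop("unsupported NRRD space: ", space)
  volume3d(array(vals, sizes), spacing, origin, direction, modality)
}

#' Write a volume as a NRRD file
#'
#' Writes NRRD0004 with LPS space tags. Encoding \code{"raw"} (little-endian
#' doubles, the default), \code{"gzip"} or \code{"ascii"}.
#'
#' @param v a \code{\link{volume3d}}.
#' @param path output \code{.nrrd} path.
#' @param encoding one of \code{"raw"}, \code{"gzip"}, \code{"ascii"}.
#' @export
write_nrrd <- function(v, path, encoding = c("raw", "gzip", "ascii")) {
  encoding <- match.arg(encoding)
  stopifnot(inherits(v, "volume3d"))
  M <- v$direction %*% diag(v$spacing)
  fmt_vec <- function(x) sprintf("(%s)", paste(formatC(x, format = "g", digits = 17),
                                               collapse = ","))
  hdr <- c("NRRD0004",
           "type: double",
           "dimension: 3",
           "space: left-posterior-superior",
           paste("sizes:", paste(dim(v$data), collapse = " ")),
           paste("space directions:", fmt_vec(M[, 1]), fmt_vec(M[, 2]), fmt_vec(M[, 3])),
           "kinds: domain domain domain",
           "endian: little",
           paste0("encoding: ", if (encoding == "ascii") "ascii" else encoding),
           paste("space origin:", fmt_vec(v$origin)))
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeLines(c(hdr, ""), con, sep = "\n")
  vals <- as.numeric(v$data)
  if (encoding == "raw") {
    writeBin(vals, con, size = 8, endian = "little")
  } else if (encoding == "gzip") {
    raw <- writeBin(vals, raw(), size = 8, endian = "little")
    writeBin(memCompress(raw, type = "gzip"), con)
  } else {
    writeLines(paste(formatC(vals, format = "g", digits = 17), collapse = " "), con)
  }
  invisible(path)
}

.lps_flip <- diag(c(-1, -1, 1))

#' Read a volume from a NIfTI-1 file
#'
#' The NIfTI sform/qform affine (RAS) is converted to the package's LPS
#' convention. A non-orthonormal direction (shear in the affine) beyond 1e-6
#' is an error.
#'
#' @param path a \code{.nii} or \code{.nii.gz} file.
#' @param modality modality tag for the returned volume.
#' @return A \code{\link{volume3d}} in LPS.
#' @export
read_nifti_volume <- function(path, modality = "OTHER") {
  if (!file.exists(path)) stop("NIfTI file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4] > 1L)
    stop("4D NIfTI passed where a 3D volume was expected; ",
         "use the time-series reader instead")
  aff <- structure(RNifti::xform(img), dim = c(4, 4))  # voxel (0-based) -> RAS mm
  A <- .lps_flip %*% aff[1:3, , drop = FALSE]          # -> LPS mm
  spacing <- sqrt(colSums(A[, 1:3]^2))
  direction <- sweep(A[, 1:3], 2, spacing, "/")
  if (max(abs(crossprod(direction) - diag(3))) > 1e-6)
    stop("NIfTI affine has shear (non-orthonormal direction): ", path)
  arr <- array(as.vector(img), d[1:3])  # strip nifti attributes
  volume3d(arr, spacing, A[, 4], direction, modality)
}

#' Write a volume as a NIfTI-1 file
#'
#' LPS geometry is converted back to a RAS sform/qform.
#'
#' @param v a \code{\link{volume3d}}.
#' @param path output \code{.nii} or \code{.nii.gz} path.
#' @export
write_nifti_volume <- function(v, path) {
  stopifnot(inherits(v, "volume3d"))
  A_lps <- cbind(v$direction %*% diag(v$spacing), v$origin)
  A_ras <- rbind(.lps_flip %*% A_lps, c(0, 0, 0, 1))
  img <- RNifti::asNifti(v$data)
  RNifti::pixdim(img) <- v$spacing  # sform scaling is carried by pixdim
  img <- RNifti::`sform<-`(img, structure(A_ras, code = 2L))
  img <- RNifti::`qform<-`(img, structure(A_ras, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a 3D volume, dispatching on format
#'
#' @param path file path (or directory for DICOM).
#' @param format \code{"NRRD"}, \code{"NIFTI"} or \code{"DICOM_DIR"};
#'   guessed from the extension when \code{NULL}.
#' @param modality modality tag for the returned volume.
#' @return A \code{\link{volume3d}}.
#' @export
read_volume <- function(path, format = NULL, modality = "OTHER") {
  if (is.null(format)) {
    format <- if (dir.exists(path)) "DICOM_DIR"
      else if (grepl("\\.(nrrd|nhdr)$", path, ignore.case = TRUE)) "NRRD"
      else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) "NIFTI"
      else stop("cannot guess volume format from path: ", path)
  }
  switch(format,
    NRRD = read_nrrd(path, modality),
    NIFTI = read_nifti_volume(path, modality),
    DICOM_DIR = stop("DICOM series reading is not supported in this build; ",
                     "convert the series to NRRD or NIfTI first"),
    stop("unknown volume format: ", format))
}

#' Write a 3D volume, dispatching on extension
#' @param v a \code{\link{volume3d}}.
#' @param path output path ending in \code{.nrrd}, \code{.nii} or
#'   \code{.nii.gz}.
#' @param ... passed to the format-specific writer.
#' @export
write_volume <- function(v, path, ...) {
  if (grepl("\\.(nrrd|nhdr)$", path, ignore.case = TRUE)) write_nrrd(v, path, ...)
  else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) write_nifti_volume(v, path)
  else stop("cannot guess volume format from path: ", path)
}

## ---- 4D time series --------------------------------------------------------

#' Ordered time series of volumes with cardiac-phase annotations
#'
#' All frames must share grid shape, spacing, origin and direction. For
#' ECG-gated series (the 10-phase CT) the per-frame phase fractions must be
#' known and strictly increasing in [0,1); free-running series (the 4D US)
#' may have unknown phases.
#'
#' @param frames list of \code{\link{volume3d}} objects.
#' @param phase numeric vector of per-frame cardiac-phase fractions in
#'   [0, 1), or \code{NULL} when unknown.
#' @param source \code{"ECG_GATED"} or \code{"FREE_RUNNING"}.
#' @return Object of class \code{time_series_volume}.
#' @export
time_series_volume <- function(frames, phase = NULL,
                               source = c("FREE_RUNNING", "ECG_GATED")) {
  source <- match.arg(source)
  stopifnot(is.list(frames), length(frames) >= 1)
  ref <- frames[[1]]
  for (f in frames) {
    stopifnot(inherits(f, "volume3d"))
    if (!identical(dim(f$data), dim(ref$data)) ||
        max(abs(f$spacing - ref$spacing)) > 1e-9 ||
        max(abs(f$origin - ref$origin)) > 1e-9 ||
        max(abs(f$direction - ref$direction)) > 1e-9)
      stop("time_series_volume: all frames must share grid shape, spacing, ",
           "origin and direction")
  }
  if (source == "ECG_GATED") {
    if (is.null(phase) || anyNA(phase))
      stop("time_series_volume: ECG-gated series require known phases")
    if (length(phase) != length(frames))
      stop("time_series_volume: one phase per frame required")
    if (any(phase < 0 | phase >= 1) || any(diff(phase) <= 0))
      stop("time_series_volume: gated phases must be strictly increasing in [0,1)")
  } else if (!is.null(phase) && length(phase) != length(frames))
    stop("time_series_volume: one phase per frame required")
  structure(list(frames = frames, phase = phase, source = source),
            class = "time_series_volume")
}

#' @export
print.time_series_volume <- function(x, ...) {
  cat(sprintf("time_series_volume [%s]: %d frames of %s voxels\n",
              x$source, length(x$frames), paste(dim(x$frames[[1]]$data),
                                                collapse = "x")))
  invisible(x)
}

#' @export
length.time_series_volume <- function(x) length(x$frames)

#' Write a time series as per-frame volume files plus a JSON manifest
#'
#' 4D data are stored as a directory of 3D files and a sidecar manifest
#' (\code{manifest.json}) listing frame paths, phases and the source tag.
#'
#' @param ts a \code{\link{time_series_volume}}.
#' @param dir output directory (created if needed).
#' @param prefix frame-file prefix.
#' @param format \code{"NRRD"} or \code{"NIFTI"}.
#' @param ... passed to the frame writer (e.g. \code{encoding}).
#' @return Path to the manifest file.
#' @export
write_time_series <- function(ts, dir, prefix = "frame", format = c("NRRD", "NIFTI"),
                              ...) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (format == "NRRD") ".nrrd" else ".nii"
  paths <- sprintf("%s_%03d%s", prefix, seq_along(ts$frames) - 1L, ext)
  for (i in seq_along(ts$frames))
    write_volume(ts$frames[[i]], file.path(dir, paths[i]), ...)
  manifest <- list(frames = paths,
                   phase = if (is.null(ts$phase)) NULL else as.numeric(ts$phase),
                   source = ts$source)
  mpath <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(mpath)
}

#' Read a time series from a manifest JSON
#'
#' @param manifest_path path to a \code{manifest.json} written by
#'   \code{\link{write_time_series}} (frame paths resolved relative to it).
#' @param modality modality tag for the frames.
#' @return A \code{\link{time_series_volume}}.
#' @export
read_time_series <- function(manifest_path, modality = "OTHER") {
  if (!file.exists(manifest_path)) stop("manifest not found: ", manifest_path)
  m <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  if (is.null(m$frames) || !length(m$frames)) stop("manifest lists no frames")
  frames <- lapply(file.path(dirname(manifest_path), m$frames), read_volume,
                   modality = modality)
  phase <- if (is.null(m$phase) || all(is.na(m$phase))) NULL else as.numeric(m$phase)
  time_series_volume(frames, phase,
                     source = if (identical(m$source, "ECG_GATED")) "ECG_GATED"
                              else "FREE_RUNNING")
}
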