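# TRK (TrackVis) and TCK (MRtrix) streamline readers and writers.
#
# TCK stores points directly in world (RAS) mm. TRK stores points in
# "voxmm" space (voxel index times voxel size, corner-of-voxel origin);
# reading applies the header's voxel-to-RAS affine after shifting by half a
# voxel so that returned coordinates are world mm, matching the TCK path.

#' Read streamlines from a TCK or TRK file
#'
#' @param path file path; format inferred from the extension unless given.
#' @param format `"tck"`, `"trk"`, or `NULL` to infer.
#' @return list of n x 3 coordinate matrices in world mm (RAS).
#' @export
read_streamlines <- function(path, format = NULL) {
  if (is.null(format))
    format <- tolower(tools::file_ext(path))
  switch(format,
         tck = read_tck(path),
         trk = read_trk(path)$streamlines,
         stop("unknown streamline format: ", format))
}

#' @rdname read_streamlines
#' @export
read_tck <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!identical(magic, "mrtrix tracks"))
    stop("not a TCK file (missing 'mrtrix tracks' magic)")
  fields <- list()
  offset <- NA_integer_
  repeat {
    ln <- readLines(con, n = 1L)
    if (!length(ln)) stop("unterminated TCK header")
    if (identical(trimws(ln), "END")) break
    kv <- regmatches(ln, regexpr(":", ln), invert = TRUE)[[1L]]
    if (length(kv) == 2L) fields[[trimws(kv[1L])]] <- trimws(kv[2L])
  }
  dt <- fields[["datatype"]]
  if (is.null(dt) || !dt %in% c("Float32LE", "Float32BE"))
    stop("unsupported TCK datatype: ", dt)
  endian <- if (dt == "Float32LE") "little" else "big"
  off_field <- fields[["file"]]
  if (is.null(off_field)) stop("TCK header missing 'file' field")
  offset <- as.integer(sub("^\\.\\s+", "", off_field))
  seek(con, where = offset, origin = "start")
  raw_n <- (file.size(path) - offset) / 4L
  vals <- readBin(con, "numeric", n = raw_n, size = 4L, endian = endian)
  pts <- matrix(vals, ncol = 3L, byrow = TRUE)
  streamlines <- list()
  cur_start <- 1L
  for (i in seq_len(nrow(pts))) {
    if (all(is.nan(pts[i, ])) || all(is.infinite(pts[i, ]))) {
      if (i > cur_start)
        streamlines[[length(streamlines) + 1L]] <-
          pts[cur_start:(i - 1L), , drop = FALSE]
      cur_start <- i + 1L
      if (all(is.infinite(pts[i, ]))) break
    }
  }
  if (!length(streamlines)) stop("TCK file contains no streamlines")
  streamlines
}

#' Write streamlines to a TCK file
#'
#' @param streamlines list of n x 3 matrices, world mm.
#' @param path output path.
#' @export
write_tck <- function(streamlines, path) {
  header <- c("mrtrix tracks",
              "datatype: Float32LE",
              sprintf("count: %d", length(streamlines)))
  # reserve room for the 'file: . <offset>' line, then END
  stub <- paste(c(header, "file: . 0000000000", "END"), collapse = "\n")
  offset <- nchar(stub, type = "bytes") + 1L  # trailing newline
  header <- c(header, sprintf("file: . %010d", offset), "END")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(header, con, sep = "\n")
  for (s in streamlines) {
    writeBin(as.numeric(t(s)), con, size = 4L, endian = "little")
    writeBin(rep(NaN, 3L), con, size = 4L, endian = "little")
  }
  writeBin(rep(Inf, 3L), con, size = 4L, endian = "little")
  invisible(path)
}

# ---------------------------------------------------------------------------
# TRK

#' Read a TRK (TrackVis) streamline file
#'
#' Applies the header's voxel-to-RAS affine (with the half-voxel,
#' corner-origin convention of the format) so that returned points are in
#' world mm, consistent with [read_tck()].
#'
#' @param path file path.
#' @return list with `streamlines` (world-mm matrices), `voxel_size`,
#'   `dim`, `vox_to_ras`, and per-streamline `scalars`/`properties` when
#'   present.
#' @export
read_trk <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 6L)
  if (!identical(magic[1:5], charToRaw("TRACK"))) stop("not a TRK file")
  dim3 <- readBin(con, "integer", 3L, size = 2L, endian = "little")
  voxel_size <- readBin(con, "numeric", 3L, size = 4L, endian = "little")
  origin <- readBin(con, "numeric", 3L, size = 4L, endian = "little")
  n_scalars <- readBin(con, "integer", 1L, size = 2L, endian = "little")
  invisible(readBin(con, "raw", 200L))  # scalar names
  n_props <- readBin(con, "integer", 1L, size = 2L, endian = "little")
  invisible(readBin(con, "raw", 200L))  # property names
  M <- matrix(readBin(con, "numeric", 16L, size = 4L, endian = "little"),
              4L, 4L, byrow = TRUE)
  invisible(readBin(con, "raw", 444L))
  invisible(readBin(con, "raw", 4L))    # voxel_order
  invisible(readBin(con, "raw", 4L))    # pad2
  invisible(readBin(con, "numeric", 6L, size = 4L))  # image orientation
  invisible(readBin(con, "raw", 2L))    # pad1
  invisible(readBin(con, "raw", 6L))    # invert/swap flags
  n_count <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  version <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  hdr_size <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (hdr_size != 1000L) stop("TRK header size mismatch (unsupported version?)")
  if (M[4L, 4L] == 0) M <- diag(4)  # version-1 files carry no affine
  streamlines <- list()
  scalars <- list()
  properties <- list()
  repeat {
    npts <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (!length(npts)) break
    vals <- readBin(con, "numeric", npts * (3L + n_scalars), size = 4L,
                    endian = "little")
    rec <- matrix(vals, ncol = 3L + n_scalars, byrow = TRUE)
    props <- if (n_props > 0L)
      readBin(con, "numeric", n_props, size = 4L, endian = "little")
    else numeric(0)
    voxmm <- rec[, 1:3, drop = FALSE]
    vox <- sweep(voxmm, 2L, voxel_size, `/`) - 0.5
    world <- cbind(vox, 1) %*% t(M)
    streamlines[[length(streamlines) + 1L]] <- world[, 1:3, drop = FALSE]
    if (n_scalars > 0L)
      scalars[[length(scalars) + 1L]] <- rec[, -(1:3), drop = FALSE]
    if (n_props > 0L)
      properties[[length(properties) + 1L]] <- props
  }
  if (!length(streamlines)) stop("TRK file contains no streamlines")
  if (n_count > 0L && length(streamlines) != n_count)
    warning(sprintf("TRK header declares %d streamlines, found %d",
                    n_count, length(streamlines)))
  list(streamlines = streamlines, voxel_size = voxel_size, dim = dim3,
       vox_to_ras = M, version = version,
       scalars = if (n_scalars > 0L) scalars else NULL,
       properties = if (n_props > 0L) properties else NULL)
}

#' Write a TRK (TrackVis) streamline file
#'
#' Points are given in world mm and converted to the format's voxmm space
#' through the inverse of `vox_to_ras`.
#'
#' @param streamlines list of n x 3 world-mm matrices.
#' @param path output path.
#' @param voxel_size length-3 voxel size (mm).
#' @param dim length-3 voxel grid dimensions.
#' @param vox_to_ras 4 x 4 voxel-to-RAS affine (default scaled identity).
#' @export
write_trk <- function(streamlines, path, voxel_size = c(1, 1, 1),
                      dim = c(100L, 100L, 100L), vox_to_ras = NULL) {
  if (is.null(vox_to_ras)) {
    vox_to_ras <- diag(c(voxel_size, 1))
  }
  Minv <- solve(vox_to_ras)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("TRACK", con, nchars = 5L, eos = NULL)
  writeBin(as.raw(0L), con)
  writeBin(as.integer(dim), con, size = 2L, endian = "little")
  writeBin(as.numeric(voxel_size), con, size = 4L, endian = "little")
  writeBin(numeric(3L), con, size = 4L, endian = "little")  # origin
  writeBin(0L, con, size = 2L, endian = "little")           # n_scalars
  writeBin(raw(200L), con)
  writeBin(0L, con, size = 2L, endian = "little")           # n_properties
  writeBin(raw(200L), con)
  writeBin(as.numeric(t(vox_to_ras)), con, size = 4L, endian = "little")
  writeBin(raw(444L), con)
  writeChar("LPS", con, nchars = 3L, eos = NULL); writeBin(as.raw(0L), con)
  writeBin(raw(4L), con)                                    # pad2
  writeBin(as.numeric(c(1, 0, 0, 0, 1, 0)), con, size = 4L, endian = "little")
  writeBin(raw(2L), con)                                    # pad1
  writeBin(raw(6L), con)                                    # invert/swap
  writeBin(as.integer(length(streamlines)), con, size = 4L, endian = "little")
  writeBin(2L, con, size = 4L, endian = "little")           # version
  writeBin(1000L, con, size = 4L, endian = "little")        # hdr_size
  for (s in streamlines) {
    world <- cbind(as.matrix(s), 1)
    vox <- world %*% t(Minv)
    voxmm <- sweep(vox[, 1:3, drop = FALSE] + 0.5, 2L, voxel_size, `*`)
    writeBin(as.integer(nrow(voxmm)), con, size = 4L, endian = "little")
    writeBin(as.numeric(t(voxmm)), con, size = 4L, endian = "little")
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# Tract label manifests

#' Read a tract-label manifest and assemble a tract set
#'
#' The manifest maps streamline files to tract abbreviations, as a CSV with
#' columns `file,tract` or a JSON object `{"file": "tract", ...}`. Paths are
#' resolved relative to the manifest.
#'
#' @param path manifest path (.csv or .json).
#' @param step resampling step in mm applied to every streamline.
#' @return a `tract_set`.
#' @export
read_tract_manifest <- function(path, step = 1.0) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    m <- jsonlite::read_json(path, simplifyVector = TRUE)
    files <- names(m)
    labels <- unname(unlist(m))
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    files <- df$file
    labels <- df$tract
  }
  base <- dirname(path)
  out <- list()
  for (i in seq_along(files)) {
    fp <- if (file.exists(files[i])) files[i] else file.path(base, files[i])
    sls <- read_streamlines(fp)
    fibers <- lapply(sls, resample_streamline, step = step)
    lab <- labels[i]
    out[[lab]] <- c(out[[lab]], fibers)
  }
  tract_set(out)
}
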