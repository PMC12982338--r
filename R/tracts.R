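# Streamline ingestion, beam-chain resampling, tract bookkeeping, fiber
# direction canonicalization and per-element material-axis assignment.

#' Construct a tract set
#'
#' A tract set maps tract abbreviations (e.g. `CC_B`, `TR_P_L`, `SLF3_R`) to
#' lists of fibers; a fiber is a numeric matrix of ordered beam-node
#' coordinates (mm, world space), implying beam elements between consecutive
#' nodes.
#'
#' @param tracts named list; each entry a list of n x 3 coordinate matrices.
#' @return object of class `tract_set`.
#' @export
tract_set <- function(tracts) {
  if (is.null(names(tracts)) || any(!nzchar(names(tracts))))
    stop("every tract must carry a non-empty abbreviation")
  if (anyDuplicated(names(tracts))) stop("tract abbreviations must be unique")
  tracts <- lapply(tracts, function(fl) lapply(fl, function(f) {
    f <- as.matrix(f)
    storage.mode(f) <- "double"
    if (ncol(f) != 3L || nrow(f) < 2L)
      stop("each fiber needs >= 2 nodes with 3 coordinates")
    seg <- sqrt(rowSums(diff(f)^2))
    if (any(seg <= 0)) stop("fiber with zero-length beam element")
    f
  }))
  structure(tracts, class = "tract_set")
}

#' @export
print.tract_set <- function(x, ...) {
  nf <- vapply(x, length, integer(1))
  nb <- vapply(x, function(fl) sum(vapply(fl, nrow, integer(1)) - 1L), integer(1))
  cat(sprintf("<tract_set> %d tract(s), %d fiber(s), %d beam element(s)\n",
              length(x), sum(nf), sum(nb)))
  invisible(x)
}

#' Fiber and beam counts of a tract set
#'
#' @param tracts a `tract_set`.
#' @return data frame with per-tract `n_fibers` and `n_beams`.
#' @export
tract_counts <- function(tracts) {
  data.frame(
    tract = names(tracts),
    n_fibers = vapply(tracts, length, integer(1)),
    n_beams = vapply(tracts, function(fl)
      sum(vapply(fl, nrow, integer(1)) - 1L), integer(1)),
    row.names = NULL)
}

# ---------------------------------------------------------------------------
# Resampling

# Interpolate a polyline at given arc lengths.
.interp_arc <- function(points, s_targets) {
  seg <- sqrt(rowSums(diff(points)^2))
  cs <- c(0, cumsum(seg))
  out <- matrix(0, length(s_targets), 3L)
  for (d in 1:3) out[, d] <- stats::approx(cs, points[, d], xout = s_targets,
                                           rule = 2)$y
  out
}

#' Resample a streamline into a beam chain
#'
#' Arc-length resampling at a fixed step (1.0 mm by default, the tracking
#' step of the source tractography). Beam nodes sit at multiples of `step`
#' along the polyline; a trailing remainder shorter than `step / 2` is
#' merged into the last beam, a longer one is kept as a short final beam.
#' Both endpoints are always preserved. Streamlines shorter than `step`
#' collapse to a single beam between the endpoints.
#'
#' @param points n x 3 streamline coordinates (mm).
#' @param step resampling step in mm (> 0).
#' @return resampled coordinate matrix (a fiber).
#' @export
resample_streamline <- function(points, step = 1.0) {
  stopifnot(step > 0)
  points <- as.matrix(points)
  if (nrow(points) < 2L) stop("streamline needs >= 2 points")
  L <- sum(sqrt(rowSums(diff(points)^2)))
  if (L <= step) return(points[c(1L, nrow(points)), , drop = FALSE])
  n_full <- floor(L / step)
  r <- L - n_full * step
  if (r < step / 2) {
    # merge remainder into the previous beam (also covers r == 0, where the
    # final sample already coincides with the endpoint)
    s <- c(seq(0, (n_full - 1L) * step, by = step), L)
  } else {
    s <- c(seq(0, n_full * step, by = step), L)
  }
  .interp_arc(points, s)
}

#' Resample every streamline of a bundle
#'
#' @param streamlines list of coordinate matrices.
#' @param step resampling step (mm).
#' @param label tract abbreviation for the resulting bundle.
#' @return a single-tract `tract_set`.
#' @export
resample_bundle <- function(streamlines, step = 1.0, label = "bundle") {
  fibers <- lapply(streamlines, resample_streamline, step = step)
  tract_set(stats::setNames(list(fibers), label))
}

# ---------------------------------------------------------------------------
# Direction canonicalization

#' Canonicalize a fiber direction vector
#'
#' Fiber start/end is arbitrary, so antipodal direction vectors must be
#' collapsed to one representative before averaging, or opposite traversals
#' cancel. The sign rule keeps `v` when the product of its three components
#' is non-negative and returns `-v` otherwise. In `"strict"` mode a zero
#' product leaves `v` untouched; the default `"robust"` mode adds a
#' first-nonzero-component-positive tie-break so that axis-aligned vectors
#' (which have zero product) also collapse antipodally.
#'
#' @param v length-3 non-zero vector, or an n x 3 matrix of vectors.
#' @param mode `"robust"` (default) or `"strict"`.
#' @return canonicalized vector(s), same shape as the input.
#' @export
canonicalize_direction <- function(v, mode = c("robust", "strict")) {
  mode <- match.arg(mode)
  single <- is.null(dim(v))
  m <- if (single) matrix(v, ncol = 3L) else as.matrix(v)
  if (any(!is.finite(m))) stop("direction vectors must be finite")
  if (any(rowSums(m != 0) == 0L)) stop("zero direction vector")
  p <- m[, 1L] * m[, 2L] * m[, 3L]
  flip <- p < 0
  if (mode == "robust") {
    zero <- p == 0
    if (any(zero)) {
      first_sign <- function(row) {
        nz <- row[row != 0]
        nz[1L]
      }
      fs <- apply(m[zero, , drop = FALSE], 1L, first_sign)
      flip[zero] <- fs < 0
    }
  }
  m[flip, ] <- -m[flip, , drop = FALSE]
  if (single) as.numeric(m) else m
}

# ---------------------------------------------------------------------------
# Material axes

# Beam segment midpoints, unit directions and lengths of a tract set.
beam_segments <- function(tracts) {
  mids <- list(); dirs <- list(); lens <- list()
  tract_lab <- list(); fiber_id <- list()
  fid <- 0L
  for (tr in names(tracts)) {
    for (f in tracts[[tr]]) {
      fid <- fid + 1L
      d <- diff(f)
      len <- sqrt(rowSums(d^2))
      mids[[length(mids) + 1L]] <- (f[-1L, , drop = FALSE] + f[-nrow(f), , drop = FALSE]) / 2
      dirs[[length(dirs) + 1L]] <- d / len
      lens[[length(lens) + 1L]] <- len
      tract_lab[[length(tract_lab) + 1L]] <- rep(tr, length(len))
      fiber_id[[length(fiber_id) + 1L]] <- rep(fid, length(len))
    }
  }
  list(midpoints = do.call(rbind, mids), directions = do.call(rbind, dirs),
       lengths = unlist(lens), tract = unlist(tract_lab),
       fiber = unlist(fiber_id))
}

#' Assign per-element material axes from embedded fibers
#'
#' For each solid element, collects the unit direction vectors of the beam
#' elements whose midpoint lies inside it, canonicalizes their signs (so
#' opposite fiber traversals do not cancel), averages and renormalizes. The
#' mean fiber direction becomes the element's material axis for a
#' transversely isotropic constitutive description. Elements traversed by no
#' beam are flagged absent; elements whose canonicalized directions still
#' cancel (mean norm below `degenerate_tol`) are flagged degenerate and a
#' warning record is kept.
#'
#' @param mesh a `hex_mesh`.
#' @param tracts a `tract_set` in the same coordinate frame as the mesh.
#' @param mode sign-unification mode, see [canonicalize_direction()].
#' @param length_weighted weight each beam direction by its segment length
#'   (default FALSE: unweighted average).
#' @param degenerate_tol mean-vector norm below which an element is flagged
#'   degenerate.
#' @return object of class `material_axis_field`: list with `axes`
#'   (n_elem x 3, unit rows or NA), `present`, `degenerate` (logicals) and
#'   `n_segments` per element.
#' @export
assign_material_axes <- function(mesh, tracts, mode = c("robust", "strict"),
                                 length_weighted = FALSE,
                                 degenerate_tol = 1e-8) {
  mode <- match.arg(mode)
  seg <- beam_segments(tracts)
  loc <- locate_points(mesh, seg$midpoints)
  dirs <- canonicalize_direction(seg$directions, mode = mode)
  n_elem <- nrow(mesh$elements)
  acc <- matrix(0, n_elem, 3L)
  cnt <- integer(n_elem)
  w <- if (length_weighted) seg$lengths else rep(1, length(seg$lengths))
  inside <- !is.na(loc$element)
  for (i in which(inside)) {
    e <- loc$element[i]
    acc[e, ] <- acc[e, ] + w[i] * dirs[i, ]
    cnt[e] <- cnt[e] + 1L
  }
  present <- cnt > 0L
  nrm <- sqrt(rowSums(acc^2))
  wsum <- rep(0, n_elem)
  for (i in which(inside)) wsum[loc$element[i]] <- wsum[loc$element[i]] + w[i]
  mean_norm <- ifelse(present, nrm / pmax(wsum, .Machine$double.xmin), 0)
  degenerate <- present & mean_norm < degenerate_tol
  axes <- matrix(NA_real_, n_elem, 3L)
  ok <- present & !degenerate
  axes[ok, ] <- acc[ok, , drop = FALSE] / nrm[ok]
  if (any(degenerate))
    warning(sprintf("%d element(s) with mutually cancelling fiber directions flagged degenerate",
                    sum(degenerate)))
  structure(list(axes = axes, present = present, degenerate = degenerate,
                 n_segments = cnt, mode = mode,
                 length_weighted = length_weighted),
            class = "material_axis_field")
}

#' @export
print.material_axis_field <- function(x, ...) {
  cat(sprintf("<material_axis_field> %d elements: %d with axis, %d absent, %d degenerate\n",
              length(x$present), sum(x$present & !x$degenerate),
              sum(!x$present), sum(x$degenerate)))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Affine transforms

#' Apply an affine transform to every fiber of a tract set
#'
#' @param tracts a `tract_set`.
#' @param matrix4 4 x 4 affine matrix acting on homogeneous coordinates.
#' @return transformed `tract_set`.
#' @export
affine_transform_tracts <- function(tracts, matrix4) {
  matrix4 <- as.matrix(matrix4)
  stopifnot(all(dim(matrix4) == c(4L, 4L)))
  A <- matrix4[1:3, 1:3]
  b <- matrix4[1:3, 4L]
  out <- lapply(tracts, function(fl) lapply(fl, function(f)
    sweep(f %*% t(A), 2L, b, `+`)))
  tract_set(out)
}

# ---------------------------------------------------------------------------
# LS-DYNA keyword export of material axes

# Orthonormal completion: given unit axis a, choose d = component of global z
# orthogonal to a (global y fallback when a is nearly parallel to z).
.ortho_completion <- function(a) {
  z <- c(0, 0, 1)
  d <- z - sum(z * a) * a
  if (sqrt(sum(d^2)) < 1e-6) {
    y <- c(0, 1, 0)
    d <- y - sum(y * a) * a
  }
  d / sqrt(sum(d^2))
}

#' Write per-element material axes as *ELEMENT_SOLID_ORTHO keyword cards
#'
#' Emits, for every element that carries a material axis, the standard
#' four-card block: element/part ids, the 8 node ids (1-based), the fiber
#' axis `a`, and an in-plane vector `d` completing the orthotropic frame.
#' Elements without an axis are skipped and counted.
#'
#' @param field a `material_axis_field`.
#' @param mesh the `hex_mesh` the field was computed on.
#' @param path output file path.
#' @return invisibly, a list with `n_written` and `n_skipped`.
#' @export
export_solid_ortho <- function(field, mesh, path) {
  ok <- which(field$present & !field$degenerate)
  part_ids <- as.integer(factor(mesh$part_labels))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("*KEYWORD", con)
  writeLines("*ELEMENT_SOLID_ORTHO", con)
  fmt_i <- function(x) formatC(x, width = 8L)
  fmt_f <- function(x) formatC(x, width = 16L, digits = 8L, format = "e")
  for (e in ok) {
    a <- field$axes[e, ]
    d <- .ortho_completion(a)
    writeLines(paste0(fmt_i(e), fmt_i(part_ids[e])), con)
    writeLines(paste0(paste(fmt_i(mesh$elements[e, ]), collapse = "")), con)
    writeLines(paste0(fmt_f(a[1L]), fmt_f(a[2L]), fmt_f(a[3L])), con)
    writeLines(paste0(fmt_f(d[1L]), fmt_f(d[2L]), fmt_f(d[3L])), con)
  }
  writeLines("*END", con)
  invisible(list(n_written = length(ok),
                 n_skipped = nrow(mesh$elements) - length(ok)))
}

#' Read back *ELEMENT_SOLID_ORTHO cards
#'
#' Minimal reader for the fixed-width cards written by
#' [export_solid_ortho()]; returns element ids with their `a` and `d`
#' vectors. Intended for round-trip checks and downstream tooling.
#'
#' @param path keyword file path.
#' @return data frame with `element`, `part`, `a1..a3`, `d1..d3`.
#' @export
read_solid_ortho <- function(path) {
  lines <- readLines(path)
  start <- which(trimws(lines) == "*ELEMENT_SOLID_ORTHO")
  if (!length(start)) stop("no *ELEMENT_SOLID_ORTHO block found")
  i <- start[1L] + 1L
  recs <- list()
  while (i + 3L <= length(lines) && !startsWith(trimws(lines[i]), "*")) {
    ids <- scan(text = lines[i], quiet = TRUE)
    av <- scan(text = lines[i + 2L], quiet = TRUE)
    dv <- scan(text = lines[i + 3L], quiet = TRUE)
    recs[[length(recs) + 1L]] <- c(ids[1L], ids[2L], av, dv)
    i <- i + 4L
  }
  out <- as.data.frame(do.call(rbind, recs))
  names(out) <- c("element", "part", "a1", "a2", "a3", "d1", "d2", "d3")
  out
}
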