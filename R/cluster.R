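# Marker-cluster strain (constant-strain tetrahedra over tracked markers)
# and CORA correlation-method scoring of paired time histories.

#' Define a marker cluster
#'
#' A cluster of tracked markers (e.g. neutral density targets in a cadaver
#' head) triangulated into tetrahedra; strain is estimated per tetrahedron
#' and averaged. Individual tetrahedra can be excluded (e.g. when one marker
#' of a sub-cluster was not recorded).
#'
#' @param marker_coords m x 3 reference coordinates (mm); row names or
#'   `marker_ids` name the markers.
#' @param tets t x 4 matrix of marker indices (rows of `marker_coords`).
#' @param exclude integer indices of tetrahedra to skip in the average.
#' @param marker_ids optional marker id vector.
#' @return object of class `cluster_definition`.
#' @export
cluster_definition <- function(marker_coords, tets, exclude = integer(0),
                               marker_ids = NULL) {
  marker_coords <- as.matrix(marker_coords)
  tets <- as.matrix(tets)
  storage.mode(tets) <- "integer"
  stopifnot(ncol(marker_coords) == 3L, ncol(tets) == 4L)
  if (any(tets < 1L | tets > nrow(marker_coords)))
    stop("tetrahedron references a missing marker")
  if (is.null(marker_ids)) marker_ids <- seq_len(nrow(marker_coords))
  exclude <- as.integer(exclude)
  if (any(exclude < 1L | exclude > nrow(tets)))
    stop("excluded tetrahedron index out of range")
  # reference edge matrices and volumes
  vols <- numeric(nrow(tets))
  for (k in seq_len(nrow(tets))) {
    X <- marker_coords[tets[k, ], ]
    D <- t(X[2:4, ]) - X[1L, ]
    vols[k] <- det(D) / 6
    if (abs(vols[k]) < 1e-12)
      stop(sprintf("tetrahedron %d has (near-)zero reference volume", k))
  }
  structure(list(marker_coords = marker_coords, tets = tets,
                 exclude = exclude, marker_ids = marker_ids,
                 ref_volumes = vols),
            class = "cluster_definition")
}

#' Cluster strain history from marker displacements
#'
#' Per tetrahedron and time step, the deformation gradient of the
#' constant-strain tetrahedron is formed from the four marker motions
#' (exact for affine fields), the Green-Lagrange tensor follows, and the
#' cluster values are the means over included tetrahedra of the maximum
#' principal strain and of the maximum shear strain `(E1 - E3) / 2`.
#'
#' @param cluster a `cluster_definition`.
#' @param times time vector (s).
#' @param marker_disp array `[time, marker, 3]` of marker displacements (mm).
#' @return object of class `cluster_strain_history`: `times`, `mps`,
#'   `max_shear` (cluster means), and per-tet histories.
#' @export
cluster_strain <- function(cluster, times, marker_disp) {
  marker_disp <- as.array(marker_disp)
  d <- dim(marker_disp)
  if (length(d) != 3L || d[1L] != length(times) ||
      d[2L] != nrow(cluster$marker_coords) || d[3L] != 3L)
    stop("marker_disp must be [time, marker, 3] matching the cluster")
  include <- setdiff(seq_len(nrow(cluster$tets)), cluster$exclude)
  if (!length(include)) stop("all tetrahedra excluded")
  nt <- length(times)
  tet_mps <- matrix(0, nt, length(include))
  tet_shear <- matrix(0, nt, length(include))
  Dref_inv <- lapply(include, function(k) {
    X <- cluster$marker_coords[cluster$tets[k, ], ]
    solve(t(X[2:4, ]) - X[1L, ])
  })
  for (t in seq_len(nt)) {
    cur <- cluster$marker_coords + matrix(marker_disp[t, , ], ncol = 3L)
    for (j in seq_along(include)) {
      k <- include[j]
      Xc <- cur[cluster$tets[k, ], ]
      Dcur <- t(Xc[2:4, ]) - Xc[1L, ]
      Fm <- Dcur %*% Dref_inv[[j]]
      ev <- principal_strains(green_lagrange(Fm))
      tet_mps[t, j] <- ev[1L]
      tet_shear[t, j] <- (ev[1L] - ev[3L]) / 2
    }
  }
  structure(list(times = times, mps = rowMeans(tet_mps),
                 max_shear = rowMeans(tet_shear),
                 tet_mps = tet_mps, tet_shear = tet_shear,
                 included = include),
            class = "cluster_strain_history")
}

# ---------------------------------------------------------------------------
# CORA correlation-method scoring

#' CORA configuration
#'
#' Parameters of the correlation sub-method. The published analyses this
#' mirrors cite an "optimized setting" without printing the constants, so
#' every constant here is explicit and configurable; the defaults follow the
#' public CORA manual's correlation method (shape from the maximal
#' normalized cross-correlation over an allowed shift window, raised to a
#' power; phase linear in the shift magnitude; size from the ratio of curve
#' L2 magnitudes, min over max).
#'
#' @param w_shape,w_size,w_phase sub-rating weights (normalized internally).
#' @param k_shape,k_size exponents applied to the shape and size ratings.
#' @param max_shift_frac allowed phase shift as a fraction of the evaluation
#'   interval length.
#' @param eval_interval `"full"` (whole common time base) or `"active"`
#'   (from first to last time the reference exceeds
#'   `interval_threshold * max|reference|`).
#' @param interval_threshold activity threshold for `eval_interval = "active"`.
#' @return list of class `cora_config`.
#' @export
cora_config <- function(w_shape = 0.5, w_size = 0.25, w_phase = 0.25,
                        k_shape = 1, k_size = 1, max_shift_frac = 0.2,
                        eval_interval = c("full", "active"),
                        interval_threshold = 0.05) {
  eval_interval <- match.arg(eval_interval)
  stopifnot(w_shape >= 0, w_size >= 0, w_phase >= 0,
            w_shape + w_size + w_phase > 0,
            k_shape > 0, k_size > 0,
            max_shift_frac >= 0, max_shift_frac < 1)
  structure(list(w_shape = w_shape, w_size = w_size, w_phase = w_phase,
                 k_shape = k_shape, k_size = k_size,
                 max_shift_frac = max_shift_frac,
                 eval_interval = eval_interval,
                 interval_threshold = interval_threshold),
            class = "cora_config")
}

# normalized cross-correlation of ref with test shifted by m samples
.xcorr_at <- function(ref, test, m) {
  n <- length(ref)
  if (m >= 0) {
    a <- ref[1:(n - m)]; b <- test[(1 + m):n]
  } else {
    a <- ref[(1 - m):n]; b <- test[1:(n + m)]
  }
  den <- sqrt(sum(a^2) * sum(b^2))
  if (den == 0) return(0)
  sum(a * b) / den
}

#' CORA score of a reference/test time-history pair
#'
#' Correlation method only (no corridor rating). Both curves must share a
#' time base or are linearly resampled onto the coarser common grid over the
#' overlapping interval.
#'
#' @param reference,test numeric curves, or two-column matrices
#'   `(time, value)`.
#' @param times shared time vector when `reference`/`test` are plain values.
#' @param config a [cora_config()].
#' @return object of class `cora_result`: `shape`, `size`, `phase`, `total`
#'   in `[0, 1]`, `label`, `shift` (optimal shift in samples), and the
#'   configuration used.
#' @export
cora_score <- function(reference, test, times = NULL, config = cora_config()) {
  pair <- .common_grid(reference, test, times)
  ref <- pair$ref; tst <- pair$test
  n <- length(ref)
  if (n < 3L) stop("need at least 3 samples on the common grid")
  # evaluation interval
  if (config$eval_interval == "active") {
    act <- which(abs(ref) > config$interval_threshold * max(abs(ref)))
    if (length(act) >= 3L) {
      ref <- ref[act[1L]:act[length(act)]]
      tst <- tst[act[1L]:act[length(act)]]
      n <- length(ref)
    }
  }
  if (all(ref == 0)) stop("all-zero reference on the evaluation interval; score undefined")
  m_max <- floor(config$max_shift_frac * n)
  shifts <- seq.int(-m_max, m_max)
  cc <- vapply(shifts, function(m) .xcorr_at(ref, tst, m), numeric(1))
  best <- max(cc)
  # among (numerically) tied maxima prefer the smallest |shift|
  tied <- which(cc >= best - 1e-12)
  m_star <- shifts[tied[which.min(abs(shifts[tied]))]]
  shape <- max(0, best)^config$k_shape
  phase <- if (m_max == 0L) 1 else max(0, 1 - abs(m_star) / m_max)
  l2r <- sqrt(sum(ref^2)); l2t <- sqrt(sum(tst^2))
  size <- if (max(l2r, l2t) == 0) 0 else
    (min(l2r, l2t) / max(l2r, l2t))^config$k_size
  wsum <- config$w_shape + config$w_size + config$w_phase
  total <- (config$w_shape * shape + config$w_size * size +
              config$w_phase * phase) / wsum
  total <- min(1, max(0, total))
  structure(list(shape = shape, size = size, phase = phase, total = total,
                 label = cora_rating(total), shift = m_star, n = n,
                 config = config),
            class = "cora_result")
}

#' @export
print.cora_result <- function(x, ...) {
  cat(sprintf("<cora_result> total %.3f (%s): shape %.3f, size %.3f, phase %.3f\n",
              x$total, x$label, x$shape, x$size, x$phase))
  invisible(x)
}

# Bring two curves onto a shared grid. Curves may be plain vectors on a
# shared `times`, or (time, value) matrices resampled by linear
# interpolation onto the coarser grid over the overlapping time range.
.common_grid <- function(reference, test, times) {
  as_tv <- function(x) {
    if (!is.null(dim(x))) list(t = x[, 1L], y = x[, 2L]) else NULL
  }
  r <- as_tv(reference); s <- as_tv(test)
  if (is.null(r) && is.null(s)) {
    ref <- as.numeric(reference); tst <- as.numeric(test)
    if (length(ref) != length(tst))
      stop("curves on a shared grid must have equal length")
    return(list(ref = ref, test = tst, times = times))
  }
  if (is.null(r) || is.null(s))
    stop("give both curves as (time, value) matrices or both as vectors")
  t0 <- max(min(r$t), min(s$t)); t1 <- min(max(r$t), max(s$t))
  if (t1 <= t0) stop("curves have no overlapping time range")
  dt <- max(stats::median(diff(r$t)), stats::median(diff(s$t)))
  grid <- seq(t0, t1, by = dt)
  list(ref = stats::approx(r$t, r$y, grid)$y,
       test = stats::approx(s$t, s$y, grid)$y, times = grid)
}

#' Sliding-scale rating of a CORA score
#'
#' Bands: Unacceptable `[0, 0.26)`, Marginal `[0.26, 0.44)`, Fair
#' `[0.44, 0.65)`, Good `[0.65, 0.86)`, Excellent `[0.86, 1]`. A score on a
#' shared edge belongs to the upper band.
#'
#' @param score numeric in `[0, 1]` (vectorized).
#' @return character rating label(s).
#' @export
cora_rating <- function(score) {
  if (any(score < 0 | score > 1)) stop("CORA score must lie in [0, 1]")
  breaks <- c(0.26, 0.44, 0.65, 0.86)
  labels <- c("Unacceptable", "Marginal", "Fair", "Good", "Excellent")
  labels[1L + rowSums(outer(score, breaks, `>=`))]
}

#' Multi-channel validation report
#'
#' Scores each reference/test pair (e.g. marker displacement channels, or
#' cluster MPS and maximum shear histories) and averages the totals, the
#' standard summary of a validation campaign.
#'
#' @param pairs named list; each entry a list with `reference` and `test`
#'   (vectors on `times`, or (time, value) matrices).
#' @param times shared time vector for plain-vector pairs.
#' @param config a [cora_config()].
#' @return list with `table` (per-channel sub-ratings, totals, labels),
#'   `mean_total` and `mean_label`.
#' @export
validation_report <- function(pairs, times = NULL, config = cora_config()) {
  stopifnot(length(pairs) > 0L)
  if (is.null(names(pairs))) names(pairs) <- paste0("channel_", seq_along(pairs))
  rows <- lapply(names(pairs), function(nm) {
    r <- cora_score(pairs[[nm]]$reference, pairs[[nm]]$test, times, config)
    data.frame(channel = nm, shape = r$shape, size = r$size, phase = r$phase,
               total = r$total, label = r$label)
  })
  tab <- do.call(rbind, rows)
  mt <- mean(tab$total)
  list(table = tab, mean_total = mt, mean_label = cora_rating(mt))
}
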