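# Synthetic fixture generators with known ground truth: box meshes, fiber
# bundles, deformation histories with closed-form strain oracles, marker
# cluster fixtures and paired CORA curves. Everything is deterministic under
# a fixed seed.

#' Haversine amplitude pulse
#'
#' The canonical smooth, zero-start amplitude shape of impact biomechanics:
#' `a(t) = peak * sin^2(pi t / duration)` for `t` in `[0, duration]`, zero
#' after.
#'
#' @param t time(s), seconds.
#' @param peak peak amplitude, reached at `duration / 2`.
#' @param duration pulse duration, seconds.
#' @return amplitude value(s).
#' @export
haversine_pulse <- function(t, peak, duration) {
  a <- peak * sin(pi * pmin(pmax(t, 0), duration) / duration)^2
  a[t < 0 | t > duration] <- 0
  a
}

#' Structured box mesh
#'
#' @param nx,ny,nz element counts per direction (>= 1).
#' @param spacing element edge length, mm.
#' @param origin corner of the box.
#' @param part part label for every element.
#' @return a `hex_mesh` with `(nx+1)(ny+1)(nz+1)` nodes and `nx ny nz`
#'   elements.
#' @export
make_box_mesh <- function(nx, ny, nz, spacing = 1.0, origin = c(0, 0, 0),
                          part = "parenchyma") {
  stopifnot(nx >= 1L, ny >= 1L, nz >= 1L, spacing > 0)
  xs <- origin[1L] + spacing * 0:nx
  ys <- origin[2L] + spacing * 0:ny
  zs <- origin[3L] + spacing * 0:nz
  coords <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  nid <- function(i, j, k) 1L + i + (nx + 1L) * (j + (ny + 1L) * k)
  elems <- matrix(0L, nx * ny * nz, 8L)
  e <- 0L
  for (k in 0:(nz - 1L)) for (j in 0:(ny - 1L)) for (i in 0:(nx - 1L)) {
    e <- e + 1L
    elems[e, ] <- c(nid(i, j, k), nid(i + 1L, j, k),
                    nid(i + 1L, j + 1L, k), nid(i, j + 1L, k),
                    nid(i, j, k + 1L), nid(i + 1L, j, k + 1L),
                    nid(i + 1L, j + 1L, k + 1L), nid(i, j + 1L, k + 1L))
  }
  hex_mesh(coords, elems, rep(part, nrow(elems)))
}

#' Randomly perturbed box mesh
#'
#' Interior nodes jittered by a fraction of the spacing; boundary nodes kept
#' so the domain stays a box. Useful for exercising the inverse mapping on
#' non-trivial (but non-degenerate) element shapes.
#'
#' @param nx,ny,nz,spacing,origin,part as in [make_box_mesh()].
#' @param jitter maximum node perturbation as a fraction of `spacing`
#'   (keep below ~0.3 for guaranteed positive Jacobians).
#' @param seed RNG seed.
#' @return a `hex_mesh`.
#' @export
make_perturbed_mesh <- function(nx, ny, nz, spacing = 1.0, jitter = 0.15,
                                origin = c(0, 0, 0), part = "parenchyma",
                                seed = 1L) {
  m <- make_box_mesh(nx, ny, nz, spacing, origin, part)
  lo <- origin
  hi <- origin + spacing * c(nx, ny, nz)
  interior <- apply(m$node_coords, 1L, function(p)
    all(p > lo + spacing / 4) && all(p < hi - spacing / 4))
  set.seed(seed)
  pert <- matrix(stats::runif(sum(interior) * 3L, -jitter, jitter) * spacing,
                 ncol = 3L)
  m$node_coords[interior, ] <- m$node_coords[interior, ] + pert
  hex_mesh(m$node_coords, m$elements, m$part_labels)
}

#' Synthetic fiber bundle
#'
#' Generates a labelled bundle of parallel fibers along a straight line,
#' circular arc or helix, resampled at the requested beam step, with
#' optional lateral jitter of each fiber's offset. Deterministic under a
#' fixed seed.
#'
#' @param kind `"straight"`, `"arc"` or `"helix"`.
#' @param n_fibers number of fibers (>= 1).
#' @param label tract abbreviation.
#' @param start start point (straight) / centre (arc, helix).
#' @param direction unit direction (straight) / axis (helix).
#' @param length fiber length, mm (straight).
#' @param radius arc / helix radius, mm.
#' @param angle arc angular span, radians.
#' @param pitch helix advance per turn, mm.
#' @param turns helix turns.
#' @param spread lateral extent of the bundle cross-section, mm.
#' @param jitter random lateral offset magnitude per fiber, mm.
#' @param step resampling step, mm.
#' @param seed RNG seed.
#' @param bbox optional 2 x 3 matrix (rows lo, hi); fibers leaving it raise
#'   an error.
#' @return a single-tract `tract_set`.
#' @export
make_bundle <- function(kind = c("straight", "arc", "helix"), n_fibers = 10L,
                        label = "BUNDLE", start = c(0, 0, 0),
                        direction = c(1, 0, 0), length = 10, radius = 10,
                        angle = pi, pitch = 5, turns = 2, spread = 0.5,
                        jitter = 0, step = 1.0, seed = 1L, bbox = NULL) {
  kind <- match.arg(kind)
  stopifnot(n_fibers >= 1L)
  set.seed(seed)
  direction <- direction / sqrt(sum(direction^2))
  # two unit vectors orthogonal to the main direction, for lateral offsets
  ref <- if (abs(direction[3L]) < 0.9) c(0, 0, 1) else c(0, 1, 0)
  e1 <- ref - sum(ref * direction) * direction
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(direction[2L] * e1[3L] - direction[3L] * e1[2L],
          direction[3L] * e1[1L] - direction[1L] * e1[3L],
          direction[1L] * e1[2L] - direction[2L] * e1[1L])
  offsets <- matrix(stats::runif(n_fibers * 2L, -spread / 2, spread / 2),
                    ncol = 2L)
  if (n_fibers == 1L) offsets[] <- 0
  if (jitter > 0)
    offsets <- offsets + matrix(stats::runif(n_fibers * 2L, -jitter, jitter),
                                ncol = 2L)
  centers <- sweep(offsets[, 1L, drop = FALSE] %*% rbind(e1) +
                     offsets[, 2L, drop = FALSE] %*% rbind(e2),
                   2L, start, `+`)
  n_samp <- 200L
  fibers <- lapply(seq_len(n_fibers), function(i) {
    c0 <- centers[i, ]
    pts <- switch(kind,
      straight = {
        s <- seq(0, length, length.out = max(2L, ceiling(length / step) + 1L))
        sweep(outer(s, direction), 2L, c0, `+`)
      },
      arc = {
        th <- seq(0, angle, length.out = n_samp)
        cbind(c0[1L] + radius * cos(th), c0[2L] + radius * sin(th),
              rep(c0[3L], n_samp))
      },
      helix = {
        th <- seq(0, 2 * pi * turns, length.out = n_samp * max(1, turns))
        cbind(c0[1L] + radius * cos(th), c0[2L] + radius * sin(th),
              c0[3L] + pitch * th / (2 * pi))
      })
    resample_streamline(pts, step = step)
  })
  if (!is.null(bbox)) {
    all_pts <- do.call(rbind, fibers)
    lo <- bbox[1L, ]; hi <- bbox[2L, ]
    if (any(sweep(all_pts, 2L, lo, `<`)) || any(sweep(all_pts, 2L, hi, `>`)))
      stop("bundle geometry exits the stated bounding box")
  }
  tract_set(stats::setNames(list(fibers), label))
}

# ---------------------------------------------------------------------------
# Deformation histories

#' Deformation specification
#'
#' Describes a closed-form displacement field whose amplitude follows a
#' haversine pulse, so histories start at zero and peak mid-pulse.
#'
#' Kinds and their fields at amplitude `a`:
#' * `affine`: `u(X) = a (M - I) X` for a target matrix `M`, i.e.
#'   `F = I + a (M - I)` everywhere.
#' * `simple_shear`: `u_x = a X_y` (shear plane normal y), `F` the unit
#'   shear with parameter `gamma = a`.
#' * `rigid_rotation`: rotation by angle `a` about `axis` through `center`,
#'   plus translation `a * translation`.
#' * `twist`: rotation about the z axis whose angle varies linearly along z,
#'   `theta(X) = a (X_z - center_z)`; inhomogeneous, so no closed-form
#'   element strain — oracles use dense finite differences of the field.
#'
#' @param kind deformation kind.
#' @param peak peak amplitude (matrix blend fraction, shear gamma, rotation
#'   angle in radians, or twist rate in rad/mm).
#' @param duration pulse duration, s.
#' @param matrix target matrix `M` (affine kind).
#' @param axis rotation axis (rigid_rotation).
#' @param center rotation/twist centre.
#' @param translation additional translation at unit amplitude.
#' @return list of class `deformation_spec`.
#' @export
deformation_spec <- function(kind = c("affine", "simple_shear",
                                      "rigid_rotation", "twist"),
                             peak = 0.2, duration = 0.01, matrix = NULL,
                             axis = c(0, 0, 1), center = c(0, 0, 0),
                             translation = c(0, 0, 0)) {
  kind <- match.arg(kind)
  if (kind == "affine" && is.null(matrix))
    stop("affine deformation needs a target matrix")
  structure(list(kind = kind, peak = peak, duration = duration,
                 matrix = matrix, axis = axis / sqrt(sum(axis^2)),
                 center = center, translation = translation),
            class = "deformation_spec")
}

# Rodrigues rotation matrix
.rot_axis_angle <- function(axis, theta) {
  K <- matrix(c(0, axis[3L], -axis[2L],
                -axis[3L], 0, axis[1L],
                axis[2L], -axis[1L], 0), 3L, 3L)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

# displacement field u(X; a) for a spec at amplitude a; X is n x 3
.displacement_field <- function(spec, X, a) {
  switch(spec$kind,
    affine = a * (X %*% t(spec$matrix - diag(3))),
    simple_shear = cbind(a * X[, 2L], 0 * X[, 2L], 0 * X[, 2L]),
    rigid_rotation = {
      R <- .rot_axis_angle(spec$axis, a)
      Xc <- sweep(X, 2L, spec$center)
      sweep(Xc %*% t(R) - Xc, 2L, a * spec$translation, `+`)
    },
    twist = {
      th <- a * (X[, 3L] - spec$center[3L])
      xc <- X[, 1L] - spec$center[1L]
      yc <- X[, 2L] - spec$center[2L]
      cbind(xc * cos(th) - yc * sin(th) - xc,
            xc * sin(th) + yc * cos(th) - yc,
            0 * th)
    })
}

# closed-form deformation gradient at amplitude a (homogeneous kinds only)
.field_F <- function(spec, a) {
  switch(spec$kind,
    affine = diag(3) + a * (spec$matrix - diag(3)),
    simple_shear = matrix(c(1, 0, 0, a, 1, 0, 0, 0, 1), 3L, 3L),
    rigid_rotation = .rot_axis_angle(spec$axis, a),
    stop("no closed-form deformation gradient for kind ", spec$kind))
}

#' Displacement history of a deformation field over a mesh
#'
#' Samples the closed-form field of a [deformation_spec()] at the mesh nodes
#' over a time grid; returns the history together with oracle functions:
#' `F_at(t)` and `E_at(t)` for homogeneous kinds (exact), and
#' `F_num(X, t)` (dense central finite differences of the displacement
#' field, step `1e-6` of the domain scale) for every kind, including twist.
#'
#' @param mesh a `hex_mesh`.
#' @param spec a `deformation_spec`.
#' @param times time grid, s (default 21 steps over the pulse).
#' @return list with `history` (a `displacement_history`), `oracle` (list of
#'   functions), and `spec`.
#' @export
make_history <- function(mesh, spec, times = NULL) {
  if (is.null(times)) times <- seq(0, spec$duration, length.out = 21L)
  amp <- haversine_pulse(times, spec$peak, spec$duration)
  X <- mesh$node_coords
  nt <- length(times)
  U <- array(0, c(nt, nrow(X), 3L))
  for (t in seq_len(nt)) U[t, , ] <- .displacement_field(spec, X, amp[t])
  hist <- displacement_history(times, U, mesh)
  homog <- spec$kind %in% c("affine", "simple_shear", "rigid_rotation")
  scale <- max(apply(X, 2L, function(v) diff(range(v))), 1)
  h_fd <- 1e-6 * scale
  F_num <- function(Xq, t) {
    a <- haversine_pulse(t, spec$peak, spec$duration)
    Fm <- diag(3)
    for (d in 1:3) {
      ei <- numeric(3L); ei[d] <- h_fd
      up <- .displacement_field(spec, matrix(Xq + ei, ncol = 3L), a)
      um <- .displacement_field(spec, matrix(Xq - ei, ncol = 3L), a)
      Fm[, d] <- Fm[, d] + as.numeric(up - um) / (2 * h_fd)
    }
    Fm
  }
  oracle <- list(
    amplitude = function(t) haversine_pulse(t, spec$peak, spec$duration),
    F_num = F_num)
  if (homog) {
    oracle$F_at <- function(t)
      .field_F(spec, haversine_pulse(t, spec$peak, spec$duration))
    oracle$E_at <- function(t) green_lagrange(oracle$F_at(t))
    oracle$axonal_green_at <- function(t, axis)
      as.numeric(axis %*% oracle$E_at(t) %*% axis)
  }
  list(history = hist, oracle = oracle, spec = spec)
}

# ---------------------------------------------------------------------------
# Cluster fixtures and CORA pairs

#' Marker-cluster fixture
#'
#' Seven markers (a centre and the six vertices of an octahedron) joined
#' into eight tetrahedra (centre + each octahedron face), moved through the
#' closed-form field of a [deformation_spec()]. For homogeneous kinds every
#' tetrahedron sees the exact field strain, giving an analytic oracle.
#'
#' @param spec a `deformation_spec`.
#' @param times time grid, s.
#' @param center cluster centre, mm.
#' @param size centre-to-vertex distance, mm.
#' @param exclude tetrahedra to exclude from the cluster average.
#' @return list with `cluster` (a `cluster_definition`), `times`,
#'   `marker_disp` (`[time, marker, 3]`), and `oracle` (for homogeneous
#'   kinds: exact `mps_at(t)` and `max_shear_at(t)`).
#' @export
make_cluster_fixture <- function(spec, times = NULL, center = c(0, 0, 0),
                                 size = 5, exclude = integer(0)) {
  if (is.null(times)) times <- seq(0, spec$duration, length.out = 21L)
  markers <- rbind(center,
                   center + c(size, 0, 0), center - c(size, 0, 0),
                   center + c(0, size, 0), center - c(0, size, 0),
                   center + c(0, 0, size), center - c(0, 0, size))
  # octahedron faces (vertex indices into rows 2..7), each + centre (1)
  v <- list(px = 2L, mx = 3L, py = 4L, my = 5L, pz = 6L, mz = 7L)
  faces <- rbind(c(v$px, v$py, v$pz), c(v$py, v$mx, v$pz),
                 c(v$mx, v$my, v$pz), c(v$my, v$px, v$pz),
                 c(v$py, v$px, v$mz), c(v$mx, v$py, v$mz),
                 c(v$my, v$mx, v$mz), c(v$px, v$my, v$mz))
  tets <- cbind(1L, faces)
  cl <- cluster_definition(markers, tets, exclude = exclude)
  nt <- length(times)
  amp <- haversine_pulse(times, spec$peak, spec$duration)
  disp <- array(0, c(nt, nrow(markers), 3L))
  for (t in seq_len(nt))
    disp[t, , ] <- .displacement_field(spec, markers, amp[t])
  oracle <- NULL
  if (spec$kind %in% c("affine", "simple_shear", "rigid_rotation")) {
    oracle <- list(
      mps_at = function(t) {
        ev <- principal_strains(green_lagrange(
          .field_F(spec, haversine_pulse(t, spec$peak, spec$duration))))
        ev[1L]
      },
      max_shear_at = function(t) {
        ev <- principal_strains(green_lagrange(
          .field_F(spec, haversine_pulse(t, spec$peak, spec$duration))))
        (ev[1L] - ev[3L]) / 2
      })
  }
  list(cluster = cl, times = times, marker_disp = disp, oracle = oracle)
}

#' Paired reference/test curves for CORA exercises
#'
#' The reference is a haversine pulse; the test is the reference modified by
#' the requested degradation.
#'
#' @param kind `"identical"`, `"scaled"`, `"shifted"` or `"noisy"`.
#' @param n samples.
#' @param duration pulse duration, s.
#' @param peak pulse peak.
#' @param scale multiplicative factor (scaled kind).
#' @param shift_frac shift as a fraction of the record length (shifted kind).
#' @param noise_sd additive Gaussian noise SD (noisy kind).
#' @param seed RNG seed (noisy kind).
#' @return list with `times`, `reference`, `test`.
#' @export
make_cora_pair <- function(kind = c("identical", "scaled", "shifted", "noisy"),
                           n = 201L, duration = 0.05, peak = 1.0,
                           scale = 2.0, shift_frac = 0.1, noise_sd = 0.05,
                           seed = 1L) {
  kind <- match.arg(kind)
  times <- seq(0, duration, length.out = n)
  ref <- haversine_pulse(times, peak, duration / 2)
  test <- switch(kind,
    identical = ref,
    scaled = scale * ref,
    shifted = {
      m <- round(shift_frac * n)
      c(rep(0, m), ref)[seq_len(n)]
    },
    noisy = {
      set.seed(seed)
      ref + stats::rnorm(n, 0, noise_sd)
    })
  list(times = times, reference = ref, test = test)
}
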