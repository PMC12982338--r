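# Hexahedral mesh kinematics: trilinear interpolation, point location,
# deformation gradient and Green-Lagrange strain post-processing.

# Corner sign pattern of the reference trilinear hexahedron, one row per
# node, following the usual VTK / LS-DYNA ordering (bottom face counter-
# clockwise, then top face).
.hex_signs <- matrix(c(
  -1, -1, -1,
   1, -1, -1,
   1,  1, -1,
  -1,  1, -1,
  -1, -1,  1,
   1, -1,  1,
   1,  1,  1,
  -1,  1,  1), ncol = 3, byrow = TRUE)

#' Construct a hexahedral mesh
#'
#' Bundles node coordinates (mm) and 8-node trilinear element connectivity
#' into a validated mesh object. Node and element indices are 0-based in
#' external files and 1-based internally (R convention); constructors take
#' 1-based indices into the rows of `node_coords`.
#'
#' @param node_coords numeric matrix, one row per node, columns x/y/z in mm.
#' @param elements integer matrix, one row per element, 8 columns of node
#'   indices (rows of `node_coords`) in trilinear corner order.
#' @param part_labels character vector, one non-empty label per element.
#' @param node_ids optional external node ids (defaults to `1:n`).
#' @param validate check connectivity and centroid Jacobians (default TRUE).
#'
#' @return An object of class `hex_mesh` with fields `node_coords`,
#'   `elements`, `part_labels`, `node_ids`.
#' @export
hex_mesh <- function(node_coords, elements, part_labels = NULL,
                     node_ids = NULL, validate = TRUE) {
  node_coords <- as.matrix(node_coords)
  storage.mode(node_coords) <- "double"
  dimnames(node_coords) <- NULL
  elements <- as.matrix(elements)
  storage.mode(elements) <- "integer"
  dimnames(elements) <- NULL
  if (ncol(node_coords) != 3L) stop("node_coords must have 3 columns")
  if (ncol(elements) != 8L) stop("elements must have 8 columns")
  n_nodes <- nrow(node_coords)
  n_elem <- nrow(elements)
  if (is.null(part_labels)) part_labels <- rep("default", n_elem)
  part_labels <- as.character(part_labels)
  if (length(part_labels) != n_elem) stop("one part label per element required")
  if (is.null(node_ids)) node_ids <- seq_len(n_nodes)
  if (validate) {
    if (any(is.na(elements)) || any(elements < 1L) || any(elements > n_nodes))
      stop("element connectivity references missing nodes")
    if (any(apply(elements, 1L, anyDuplicated) > 0L))
      stop("element with repeated nodes")
    if (any(!nzchar(part_labels))) stop("part labels must be non-empty")
  }
  m <- structure(list(node_coords = node_coords, elements = elements,
                      part_labels = part_labels, node_ids = node_ids),
                 class = "hex_mesh")
  if (validate) {
    detj <- centroid_jacobians(m)
    if (any(detj <= 0))
      stop("element(s) with non-positive centroid Jacobian: ",
           paste(utils::head(which(detj <= 0), 5L), collapse = ", "))
  }
  m
}

#' @export
print.hex_mesh <- function(x, ...) {
  cat(sprintf("<hex_mesh> %d nodes, %d hexahedral elements, %d part(s)\n",
              nrow(x$node_coords), nrow(x$elements),
              length(unique(x$part_labels))))
  invisible(x)
}

#' Trilinear shape functions and natural-coordinate gradients
#'
#' Evaluates the 8 trilinear basis functions and their gradients with
#' respect to the natural coordinates at a point `xi` of the reference cube
#' `[-1, 1]^3`.
#'
#' @param xi numeric length-3 natural coordinate.
#' @return list with `N` (length-8 weights, summing to 1) and `dN`
#'   (8 x 3 matrix of gradients, columns summing to 0).
#' @export
hex_shape <- function(xi) {
  stopifnot(length(xi) == 3L, all(is.finite(xi)))
  s <- .hex_signs
  a <- 1 + s[, 1L] * xi[1L]
  b <- 1 + s[, 2L] * xi[2L]
  c3 <- 1 + s[, 3L] * xi[3L]
  N <- a * b * c3 / 8
  dN <- cbind(s[, 1L] * b * c3, a * s[, 2L] * c3, a * b * s[, 3L]) / 8
  list(N = N, dN = dN)
}

# Shape weights for many points at once: xi is n x 3, returns n x 8.
.hex_shape_batch <- function(xi) {
  s <- .hex_signs
  out <- matrix(0, nrow(xi), 8L)
  for (k in 1:8) {
    out[, k] <- (1 + s[k, 1L] * xi[, 1L]) *
      (1 + s[k, 2L] * xi[, 2L]) * (1 + s[k, 3L] * xi[, 3L]) / 8
  }
  out
}

# Centroid Jacobian determinant of every element.
centroid_jacobians <- function(mesh) {
  sh <- hex_shape(c(0, 0, 0))
  vapply(seq_len(nrow(mesh$elements)), function(e) {
    X <- mesh$node_coords[mesh$elements[e, ], , drop = FALSE]
    det(t(X) %*% sh$dN)
  }, numeric(1))
}

#' Element volumes by Gauss quadrature
#'
#' 2x2x2 Gauss integration of the Jacobian determinant, exact for the
#' trilinear map.
#'
#' @param mesh a `hex_mesh`.
#' @return numeric vector of element volumes (mm^3).
#' @export
element_volumes <- function(mesh) {
  g <- 1 / sqrt(3)
  gp <- as.matrix(expand.grid(c(-g, g), c(-g, g), c(-g, g)))
  dNs <- lapply(seq_len(8L), function(i) hex_shape(gp[i, ])$dN)
  vapply(seq_len(nrow(mesh$elements)), function(e) {
    X <- t(mesh$node_coords[mesh$elements[e, ], , drop = FALSE])
    sum(vapply(dNs, function(dN) det(X %*% dN), numeric(1)))
  }, numeric(1))
}

# ---------------------------------------------------------------------------
# Point location (inverse isoparametric mapping)

# Axis-aligned bounding-box grid over elements, cached on the mesh object's
# environment-free attribute slot. Cell size ~ median element bbox edge.
.mesh_grid <- function(mesh, pad = 0) {
  g <- attr(mesh, ".bbox_grid")
  if (!is.null(g) && identical(g$pad, pad)) return(g)
  nc <- mesh$node_coords
  el <- mesh$elements
  n_elem <- nrow(el)
  lo <- hi <- matrix(0, n_elem, 3L)
  for (d in 1:3) {
    xd <- matrix(nc[el, d], n_elem, 8L)
    lo[, d] <- apply(xd, 1L, min) - pad
    hi[, d] <- apply(xd, 1L, max) + pad
  }
  dom_lo <- apply(lo, 2L, min)
  dom_hi <- apply(hi, 2L, max)
  cell <- pmax(apply(hi - lo, 2L, stats::median), 1e-9)
  ncell <- pmax(1L, pmin(64L, ceiling((dom_hi - dom_lo) / cell)))
  cell <- (dom_hi - dom_lo) / ncell
  cell[cell <= 0] <- 1
  idx <- function(p, d) pmin(ncell[d] - 1L, pmax(0L, floor((p - dom_lo[d]) / cell[d])))
  key_of <- function(i, j, k) 1 + i + ncell[1L] * (j + ncell[2L] * k)
  buckets <- vector("list", prod(ncell))
  for (e in seq_len(n_elem)) {
    i0 <- idx(lo[e, 1L], 1L); i1 <- idx(hi[e, 1L], 1L)
    j0 <- idx(lo[e, 2L], 2L); j1 <- idx(hi[e, 2L], 2L)
    k0 <- idx(lo[e, 3L], 3L); k1 <- idx(hi[e, 3L], 3L)
    for (k in k0:k1) for (j in j0:j1) for (i in i0:i1) {
      key <- key_of(i, j, k)
      buckets[[key]] <- c(buckets[[key]], e)
    }
  }
  list(buckets = buckets, dom_lo = dom_lo, cell = cell, ncell = ncell,
       lo = lo, hi = hi, idx = idx, key_of = key_of, pad = pad)
}

# Newton inversion of the trilinear map for one element and a batch of
# points (n x 3). Returns n x 3 xi; does not test containment.
.invert_trilinear <- function(X, pts, tol = 1e-10, maxit = 50L) {
  n <- nrow(pts)
  xi <- matrix(0, n, 3L)
  active <- rep(TRUE, n)
  for (it in seq_len(maxit)) {
    ia <- which(active)
    if (!length(ia)) break
    sh <- .hex_shape_batch(xi[ia, , drop = FALSE])
    cur <- sh %*% X                      # mapped positions
    r <- cur - pts[ia, , drop = FALSE]   # residual
    conv <- rowSums(abs(r)) < tol
    # Jacobian J = dx/dxi per point; assemble the 9 entries vectorised.
    s <- .hex_signs
    x1 <- xi[ia, 1L]; x2 <- xi[ia, 2L]; x3 <- xi[ia, 3L]
    J <- array(0, c(length(ia), 3L, 3L))
    for (k in 1:8) {
      a <- 1 + s[k, 1L] * x1; b <- 1 + s[k, 2L] * x2; c3 <- 1 + s[k, 3L] * x3
      g1 <- s[k, 1L] * b * c3 / 8
      g2 <- a * s[k, 2L] * c3 / 8
      g3 <- a * b * s[k, 3L] / 8
      for (d in 1:3) {
        J[, d, 1L] <- J[, d, 1L] + X[k, d] * g1
        J[, d, 2L] <- J[, d, 2L] + X[k, d] * g2
        J[, d, 3L] <- J[, d, 3L] + X[k, d] * g3
      }
    }
    # Cramer's rule, vectorised over points.
    a11 <- J[, 1, 1]; a12 <- J[, 1, 2]; a13 <- J[, 1, 3]
    a21 <- J[, 2, 1]; a22 <- J[, 2, 2]; a23 <- J[, 2, 3]
    a31 <- J[, 3, 1]; a32 <- J[, 3, 2]; a33 <- J[, 3, 3]
    det <- a11 * (a22 * a33 - a23 * a32) -
           a12 * (a21 * a33 - a23 * a31) +
           a13 * (a21 * a32 - a22 * a31)
    bad <- abs(det) < 1e-300
    det[bad] <- NA_real_
    b1 <- r[, 1L]; b2 <- r[, 2L]; b3 <- r[, 3L]
    d1 <- (b1 * (a22 * a33 - a23 * a32) -
           a12 * (b2 * a33 - a23 * b3) +
           a13 * (b2 * a32 - a22 * b3)) / det
    d2 <- (a11 * (b2 * a33 - a23 * b3) -
           b1 * (a21 * a33 - a23 * a31) +
           a13 * (a21 * b3 - b2 * a31)) / det
    d3 <- (a11 * (a22 * b3 - b2 * a32) -
           a12 * (a21 * b3 - b2 * a31) +
           b1 * (a21 * a32 - a22 * a31)) / det
    step <- cbind(d1, d2, d3)
    step[!is.finite(step)] <- 0
    xi[ia, ] <- xi[ia, , drop = FALSE] - step
    active[ia[conv]] <- FALSE
  }
  xi
}

#' Locate points in a hexahedral mesh
#'
#' Finds, for each query point, the element containing it and the natural
#' coordinates `xi` inside that element, by Newton inversion of the
#' trilinear map starting from the element centre. Candidate elements are
#' pre-filtered with an axis-aligned bounding-box grid. Points on shared
#' faces are assigned to the containing element with the lowest index.
#'
#' @param mesh a `hex_mesh`.
#' @param points numeric matrix (n x 3) or length-3 vector, mm.
#' @param tol containment tolerance in natural coordinates (each `xi`
#'   component may exceed 1 by at most `tol`).
#' @param newton_tol convergence tolerance of the Newton solve.
#' @return data frame with columns `element` (1-based index, `NA` when the
#'   point is outside every element) and `xi1`, `xi2`, `xi3`.
#' @export
locate_points <- function(mesh, points, tol = 1e-8, newton_tol = 1e-10) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3L)
  points <- as.matrix(points)
  n <- nrow(points)
  grid <- .mesh_grid(mesh)
  element <- rep(NA_integer_, n)
  xi_out <- matrix(NA_real_, n, 3L)
  # candidate element list per point
  ci <- grid$idx(points[, 1L], 1L)
  cj <- grid$idx(points[, 2L], 2L)
  ck <- grid$idx(points[, 3L], 3L)
  keys <- grid$key_of(ci, cj, ck)
  # group points by candidate element so each element inverts one batch
  cand_e <- vector("list", n)
  for (p in seq_len(n)) {
    es <- grid$buckets[[keys[p]]]
    if (is.null(es)) next
    inb <- points[p, 1L] >= grid$lo[es, 1L] - 1e-9 & points[p, 1L] <= grid$hi[es, 1L] + 1e-9 &
           points[p, 2L] >= grid$lo[es, 2L] - 1e-9 & points[p, 2L] <= grid$hi[es, 2L] + 1e-9 &
           points[p, 3L] >= grid$lo[es, 3L] - 1e-9 & points[p, 3L] <= grid$hi[es, 3L] + 1e-9
    cand_e[[p]] <- sort(es[inb])
  }
  by_elem <- split(rep(seq_len(n), lengths(cand_e)), unlist(cand_e))
  for (ename in names(by_elem)) {
    e <- as.integer(ename)
    pts_idx <- by_elem[[ename]]
    # keep lowest-element-index assignment: skip points already claimed by
    # a lower-index element (names are processed in increasing order below)
    pts_idx <- pts_idx[is.na(element[pts_idx]) | element[pts_idx] > e]
    if (!length(pts_idx)) next
    X <- mesh$node_coords[mesh$elements[e, ], , drop = FALSE]
    xi <- .invert_trilinear(X, points[pts_idx, , drop = FALSE], tol = newton_tol)
    # a claim needs both containment and a converged forward-map residual
    # (Newton can stall inside a badly shaped element for exterior points)
    res <- .hex_shape_batch(xi) %*% X - points[pts_idx, , drop = FALSE]
    ok <- apply(abs(xi) <= 1 + tol, 1L, all) &
      rowSums(abs(res)) < 1e-7 * max(1, max(abs(X)))
    if (any(ok)) {
      hit <- pts_idx[ok]
      take <- is.na(element[hit]) | element[hit] > e
      hit <- hit[take]
      element[hit] <- e
      xi_out[hit, ] <- xi[ok, , drop = FALSE][take, , drop = FALSE]
    }
  }
  data.frame(element = element, xi1 = xi_out[, 1L], xi2 = xi_out[, 2L],
             xi3 = xi_out[, 3L])
}

#' @rdname locate_points
#' @param point a single length-3 point (mm).
#' @return `locate_point()` returns a list with `element` and `xi`, or
#'   raises an error naming the nearest element when the point is outside
#'   the mesh.
#' @export
locate_point <- function(mesh, point, tol = 1e-8, newton_tol = 1e-10) {
  res <- locate_points(mesh, matrix(point, ncol = 3L), tol, newton_tol)
  if (is.na(res$element[1L])) {
    near <- nearest_element_point(mesh, point)
    stop(sprintf(
      "point (%g, %g, %g) lies outside the mesh; nearest element %d at distance %.6g mm",
      point[1L], point[2L], point[3L], near$element, near$distance))
  }
  list(element = res$element[1L],
       xi = c(res$xi1[1L], res$xi2[1L], res$xi3[1L]))
}

# Nearest point on the mesh to an exterior query: Newton solve on bbox-near
# candidate elements with xi clamped to the reference cube.
nearest_element_point <- function(mesh, point, n_candidates = 8L) {
  grid <- .mesh_grid(mesh)
  ctr <- (grid$lo + grid$hi) / 2
  d2 <- rowSums((sweep(ctr, 2L, point))^2)
  cand <- order(d2)[seq_len(min(n_candidates, nrow(grid$lo)))]
  best <- list(element = NA_integer_, distance = Inf, xi = NULL, point = NULL)
  for (e in cand) {
    X <- mesh$node_coords[mesh$elements[e, ], , drop = FALSE]
    xi <- .invert_trilinear(X, matrix(point, ncol = 3L))
    xi[] <- pmin(1, pmax(-1, xi))
    p_on <- as.numeric(.hex_shape_batch(xi) %*% X)
    d <- sqrt(sum((p_on - point)^2))
    if (d < best$distance ||
        (abs(d - best$distance) < 1e-12 && e < best$element)) {
      best <- list(element = e, distance = d, xi = as.numeric(xi), point = p_on)
    }
  }
  best
}

#' Map natural coordinates back to physical space
#'
#' @param mesh a `hex_mesh`.
#' @param element element index (1-based).
#' @param xi length-3 natural coordinate.
#' @return length-3 physical point (mm).
#' @export
forward_map <- function(mesh, element, xi) {
  X <- mesh$node_coords[mesh$elements[element, ], , drop = FALSE]
  as.numeric(hex_shape(xi)$N %*% X)
}

# ---------------------------------------------------------------------------
# Displacement histories

#' Nodal displacement history
#'
#' @param times strictly increasing time vector, seconds.
#' @param displacements numeric array `[time, node, 3]`, mm.
#' @param mesh optional mesh for node-count validation.
#' @return object of class `displacement_history`.
#' @export
displacement_history <- function(times, displacements, mesh = NULL) {
  times <- as.numeric(times)
  if (length(times) < 1L || any(diff(times) <= 0))
    stop("times must be non-empty and strictly increasing")
  displacements <- as.array(displacements)
  d <- dim(displacements)
  if (length(d) != 3L || d[1L] != length(times) || d[3L] != 3L)
    stop("displacements must be a [time, node, 3] array matching times")
  if (!is.null(mesh) && d[2L] != nrow(mesh$node_coords))
    stop("displacement node count does not match the mesh")
  structure(list(times = times, displacements = displacements),
            class = "displacement_history")
}

#' @export
print.displacement_history <- function(x, ...) {
  cat(sprintf("<displacement_history> %d time steps (%.4g-%.4g s), %d nodes\n",
              length(x$times), min(x$times), max(x$times),
              dim(x$displacements)[2L]))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Deformation gradient and strain

#' Deformation gradient of an element at one time step
#'
#' Computes `F = I + du/dX` from the nodal displacements via the
#' isoparametric map, evaluated at natural coordinate `xi` (element
#' centroid by default).
#'
#' @param mesh a `hex_mesh`.
#' @param disp a `displacement_history`.
#' @param element element index.
#' @param time_index time step index.
#' @param xi evaluation point in natural coordinates (default centroid).
#' @return 3 x 3 deformation gradient.
#' @export
deformation_gradient <- function(mesh, disp, element, time_index,
                                 xi = c(0, 0, 0)) {
  X <- mesh$node_coords[mesh$elements[element, ], , drop = FALSE]
  U <- matrix(disp$displacements[time_index, mesh$elements[element, ], ],
              ncol = 3L)
  sh <- hex_shape(xi)
  J <- t(X) %*% sh$dN                     # dX/dxi
  if (abs(det(J)) < 1e-300)
    stop(sprintf("element %d has a singular Jacobian at the evaluation point",
                 element))
  B <- sh$dN %*% solve(J)                 # dN/dX, 8 x 3
  diag(3) + t(U) %*% B
}

#' Green-Lagrange strain tensor from a deformation gradient
#'
#' `E = (F'F - I) / 2`, symmetrised to machine precision.
#'
#' @param F 3 x 3 deformation gradient.
#' @return symmetric 3 x 3 strain tensor.
#' @export
green_lagrange <- function(F) {
  E <- (t(F) %*% F - diag(3)) / 2
  (E + t(E)) / 2
}

#' Principal strains of a symmetric strain tensor
#'
#' @param E symmetric 3 x 3 tensor.
#' @return length-3 eigenvalues in descending order (E1 >= E2 >= E3).
#' @export
principal_strains <- function(E) {
  sort(eigen((E + t(E)) / 2, symmetric = TRUE, only.values = TRUE)$values,
       decreasing = TRUE)
}

#' Element strain histories
#'
#' Evaluates the Green-Lagrange tensor of every requested element at every
#' time step, at a single natural-coordinate evaluation point (centroid by
#' default) or averaged over the 2x2x2 Gauss points.
#'
#' @param mesh a `hex_mesh`.
#' @param disp a `displacement_history`.
#' @param elements element indices (default all).
#' @param eval_rule `"centroid"` (single point) or `"gauss"` (mean of the
#'   8 Gauss-point tensors).
#' @return object of class `strain_tensor_history`: list with `times`,
#'   `elements`, `E` (array `[time, element, 3, 3]`) and `mps` (matrix
#'   `[time, element]` of maximum principal strains).
#' @export
element_strain_history <- function(mesh, disp,
                                   elements = seq_len(nrow(mesh$elements)),
                                   eval_rule = c("centroid", "gauss")) {
  eval_rule <- match.arg(eval_rule)
  if (eval_rule == "centroid") {
    pts <- matrix(0, 1L, 3L)
  } else {
    g <- 1 / sqrt(3)
    pts <- as.matrix(expand.grid(c(-g, g), c(-g, g), c(-g, g)))
  }
  nt <- length(disp$times)
  ne <- length(elements)
  Earr <- array(0, c(nt, ne, 3L, 3L))
  mps <- matrix(0, nt, ne)
  shapes <- lapply(seq_len(nrow(pts)), function(i) hex_shape(pts[i, ]))
  for (j in seq_len(ne)) {
    e <- elements[j]
    conn <- mesh$elements[e, ]
    X <- mesh$node_coords[conn, , drop = FALSE]
    Bs <- lapply(shapes, function(sh) {
      J <- t(X) %*% sh$dN
      if (abs(det(J)) < 1e-300)
        stop(sprintf("element %d has a singular Jacobian", e))
      sh$dN %*% solve(J)
    })
    for (t in seq_len(nt)) {
      U <- matrix(disp$displacements[t, conn, ], ncol = 3L)
      Eacc <- matrix(0, 3L, 3L)
      for (B in Bs) {
        Fm <- diag(3) + t(U) %*% B
        Eacc <- Eacc + green_lagrange(Fm)
      }
      E <- Eacc / length(Bs)
      Earr[t, j, , ] <- E
      mps[t, j] <- principal_strains(E)[1L]
    }
  }
  structure(list(times = disp$times, elements = elements, E = Earr,
                 mps = mps, eval_rule = eval_rule),
            class = "strain_tensor_history")
}

#' Peak maximum principal strain per element
#'
#' @param strain_hist a `strain_tensor_history`.
#' @return numeric vector, one peak MPS per element (max over time).
#' @export
peak_mps <- function(strain_hist) {
  apply(strain_hist$mps, 2L, max)
}

#' @export
print.strain_tensor_history <- function(x, ...) {
  cat(sprintf(
    "<strain_tensor_history> %d time steps x %d elements (%s rule); peak MPS %.4g\n",
    length(x$times), length(x$elements), x$eval_rule, max(x$mps)))
  invisible(x)
}
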