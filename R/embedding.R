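# Beam-in-solid embedding and axonal strain tracking.
#
# Embedded beams are pure kinematic trackers (the null-beam convention:
# negligible density and cross-section, no force feedback): every beam node
# follows the trilinearly interpolated displacement of its host solid
# element, and the axial strain of each beam element is the axonal strain.

#' Embed fibers into a hexahedral mesh
#'
#' Maps every beam node of every fiber to a host element and natural
#' coordinates. Nodes that fall outside the mesh but within `snap_tol` mm of
#' the boundary are snapped to the nearest element surface (counted and
#' recorded); a fiber with any node farther out is dropped and recorded,
#' never silently.
#'
#' @param mesh a `hex_mesh`.
#' @param tracts a `tract_set` in the mesh coordinate frame.
#' @param snap_tol boundary snap tolerance, mm.
#' @return object of class `embedded_fiber_set`: beam-node table (host
#'   element, xi, interpolation weights), beam-element table (node pair,
#'   reference length, tract, fiber), reference node positions, and an
#'   embedding summary (`n_fibers`, `n_beams`, `n_dropped`, `n_snapped`).
#' @export
embed_fibers <- function(mesh, tracts, snap_tol = 0.5) {
  fibers <- list()
  labels <- character(0)
  for (tr in names(tracts)) {
    for (f in tracts[[tr]]) {
      fibers[[length(fibers) + 1L]] <- f
      labels <- c(labels, tr)
    }
  }
  n_fib <- length(fibers)
  all_pts <- do.call(rbind, fibers)
  fib_of_pt <- rep(seq_len(n_fib), vapply(fibers, nrow, integer(1)))
  loc <- locate_points(mesh, all_pts)
  outside <- which(is.na(loc$element))
  n_snapped <- 0L
  drop_fiber <- rep(FALSE, n_fib)
  for (i in outside) {
    near <- nearest_element_point(mesh, all_pts[i, ])
    if (near$distance <= snap_tol) {
      loc$element[i] <- near$element
      loc[i, c("xi1", "xi2", "xi3")] <- near$xi
      n_snapped <- n_snapped + 1L
    } else {
      drop_fiber[fib_of_pt[i]] <- TRUE
    }
  }
  keep_pt <- !drop_fiber[fib_of_pt]
  kept_fibers <- which(!drop_fiber)
  if (!length(kept_fibers)) stop("every fiber fell outside the mesh")
  # renumber beam nodes over kept points
  node_map <- cumsum(keep_pt)
  nodes <- data.frame(
    element = loc$element[keep_pt],
    xi1 = loc$xi1[keep_pt], xi2 = loc$xi2[keep_pt], xi3 = loc$xi3[keep_pt])
  ref_pos <- all_pts[keep_pt, , drop = FALSE]
  # beams: consecutive node pairs within each kept fiber
  beams <- list()
  pt_offset <- c(0L, cumsum(vapply(fibers, nrow, integer(1))))
  for (fi in kept_fibers) {
    idx <- (pt_offset[fi] + 1L):pt_offset[fi + 1L]
    new_idx <- node_map[idx]
    n <- length(new_idx)
    beams[[length(beams) + 1L]] <- data.frame(
      node0 = new_idx[-n], node1 = new_idx[-1L],
      tract = labels[fi], fiber = fi)
  }
  beams <- do.call(rbind, beams)
  d <- ref_pos[beams$node1, , drop = FALSE] - ref_pos[beams$node0, , drop = FALSE]
  beams$ref_length <- sqrt(rowSums(d^2))
  if (any(beams$ref_length <= 0)) stop("beam element with zero reference length")
  # interpolation weights: per beam node, the host's 8 mesh nodes + weights
  W_idx <- mesh$elements[nodes$element, , drop = FALSE]
  W_val <- .hex_shape_batch(as.matrix(nodes[, c("xi1", "xi2", "xi3")]))
  W <- Matrix::sparseMatrix(
    i = rep(seq_len(nrow(nodes)), 8L),
    j = as.integer(W_idx),
    x = as.numeric(W_val),
    dims = c(nrow(nodes), nrow(mesh$node_coords)))
  structure(list(
    nodes = nodes, beams = beams, ref_positions = ref_pos, weights = W,
    n_mesh_nodes = nrow(mesh$node_coords),
    summary = list(n_fibers = length(kept_fibers), n_beams = nrow(beams),
                   n_dropped = sum(drop_fiber), n_snapped = n_snapped,
                   dropped_fibers = which(drop_fiber))),
    class = "embedded_fiber_set")
}

#' @export
print.embedded_fiber_set <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<embedded_fiber_set> %d fibers, %d beam elements (%d dropped, %d nodes snapped)\n",
              s$n_fibers, s$n_beams, s$n_dropped, s$n_snapped))
  invisible(x)
}

#' Dynamic axonal strain from an embedded fiber set
#'
#' At each time step, each beam node's current position is its reference
#' position plus the trilinearly interpolated nodal displacement of its host
#' element; the stretch of each beam element is current length over
#' reference length and the axonal strain follows the chosen measure:
#' `green` (axial Green-Lagrange, `(lambda^2 - 1)/2`, default),
#' `engineering` (`lambda - 1`), or `logarithmic` (`log(lambda)`).
#'
#' @param emb an `embedded_fiber_set`.
#' @param disp a `displacement_history` on the same mesh.
#' @param measure strain measure tag.
#' @return object of class `axonal_strain_history`: `times`, `strain`
#'   (matrix `[time, beam]`), `peaks` (per-beam max over time), beam table
#'   with tract labels, and the measure tag.
#' @export
axonal_strain_dynamic <- function(emb, disp,
                                  measure = c("green", "engineering",
                                              "logarithmic")) {
  measure <- match.arg(measure)
  if (dim(disp$displacements)[2L] != emb$n_mesh_nodes)
    stop("displacement history node count does not match the embedding")
  nt <- length(disp$times)
  nb <- nrow(emb$beams)
  strain <- matrix(0, nt, nb)
  i0 <- emb$beams$node0
  i1 <- emb$beams$node1
  for (t in seq_len(nt)) {
    U <- matrix(disp$displacements[t, , ], ncol = 3L)
    u_beam <- as.matrix(emb$weights %*% U)
    cur <- emb$ref_positions + u_beam
    len <- sqrt(rowSums((cur[i1, , drop = FALSE] - cur[i0, , drop = FALSE])^2))
    if (any(len <= 0))
      stop(sprintf("non-positive beam length at time step %d (invalid kinematics)", t))
    lam <- len / emb$beams$ref_length
    strain[t, ] <- switch(measure,
                          green = (lam^2 - 1) / 2,
                          engineering = lam - 1,
                          logarithmic = log(lam))
  }
  structure(list(times = disp$times, strain = strain,
                 peaks = apply(strain, 2L, max), beams = emb$beams,
                 measure = measure),
            class = "axonal_strain_history")
}

#' @export
print.axonal_strain_history <- function(x, ...) {
  cat(sprintf("<axonal_strain_history> %d time steps x %d beams (%s measure); peak %.4g\n",
              length(x$times), ncol(x$strain), x$measure, max(x$peaks)))
  invisible(x)
}

#' Static axonal strain by tensor projection
#'
#' The post-processing alternative to dynamic tracking: projects a solid
#' element's Green-Lagrange tensor onto a fixed fiber axis. For the `green`
#' measure this is `a' E a`; `engineering` returns the corresponding stretch
#' minus one, `sqrt(1 + 2 a'Ea) - 1`; `logarithmic` returns
#' `log(1 + 2 a'Ea) / 2`. Under a homogeneous (affine) deformation this
#' equals the dynamic value exactly; under inhomogeneous fields the two may
#' differ because the fixed axis cannot follow element-scale rotation of the
#' fiber.
#'
#' @param E symmetric 3 x 3 Green-Lagrange tensor.
#' @param axis unit fiber direction.
#' @param measure strain measure tag.
#' @return scalar axonal strain.
#' @export
axonal_strain_static <- function(E, axis,
                                 measure = c("green", "engineering",
                                             "logarithmic")) {
  measure <- match.arg(measure)
  nrm <- sqrt(sum(axis^2))
  if (abs(nrm - 1) > 1e-8) stop("axis must be a unit vector")
  q <- as.numeric(axis %*% E %*% axis)
  if (measure == "green") return(q)
  lam2 <- 1 + 2 * q
  if (lam2 <= 0) stop("strain tensor implies non-positive stretch along the axis")
  if (measure == "engineering") sqrt(lam2) - 1 else log(lam2) / 2
}

#' Per-beam peak table with tract labels
#'
#' @param hist an `axonal_strain_history`.
#' @return data frame with `beam`, `tract`, `fiber`, `peak`.
#' @export
beam_peaks <- function(hist) {
  data.frame(beam = seq_len(ncol(hist$strain)), tract = hist$beams$tract,
             fiber = hist$beams$fiber, peak = hist$peaks)
}

# ---------------------------------------------------------------------------
# Embedding table I/O

#' Export / import an embedding table as CSV
#'
#' Columns: `beam_node`, `element` (1-based), `xi1..xi3`, `x/y/z` reference
#' position.
#'
#' @param emb an `embedded_fiber_set`.
#' @param path CSV path.
#' @export
write_embedding_csv <- function(emb, path) {
  df <- data.frame(beam_node = seq_len(nrow(emb$nodes)),
                   element = emb$nodes$element,
                   xi1 = emb$nodes$xi1, xi2 = emb$nodes$xi2,
                   xi3 = emb$nodes$xi3,
                   x = emb$ref_positions[, 1L],
                   y = emb$ref_positions[, 2L],
                   z = emb$ref_positions[, 3L])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_embedding_csv
#' @param path CSV path written by [write_embedding_csv()].
#' @return data frame of the table.
#' @export
read_embedding_csv <- function(path) {
  utils::read.csv(path)
}
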