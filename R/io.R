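# Mesh and displacement-history readers/writers: CSV dialect and legacy
# ASCII VTK unstructured grids (hexahedron cells).

#' Read / write a mesh in the CSV dialect
#'
#' `nodes.csv`: columns `id,x,y,z` (mm). `elements.csv`: columns
#' `id,n1..n8,part` with 1-based node ids.
#'
#' @param nodes_path,elements_path CSV paths.
#' @return a `hex_mesh`.
#' @export
read_mesh_csv <- function(nodes_path, elements_path) {
  nd <- utils::read.csv(nodes_path)
  el <- utils::read.csv(elements_path, stringsAsFactors = FALSE)
  need_n <- c("id", "x", "y", "z")
  need_e <- c("id", paste0("n", 1:8), "part")
  if (!all(need_n %in% names(nd))) stop("nodes.csv needs columns id,x,y,z")
  if (!all(need_e %in% names(el))) stop("elements.csv needs columns id,n1..n8,part")
  id_to_row <- stats::setNames(seq_len(nrow(nd)), nd$id)
  conn <- matrix(id_to_row[as.character(as.matrix(el[, paste0("n", 1:8)]))],
                 nrow(el), 8L)
  if (any(is.na(conn))) stop("element references an undefined node id")
  hex_mesh(as.matrix(nd[, c("x", "y", "z")]), conn, el$part, node_ids = nd$id)
}

#' @rdname read_mesh_csv
#' @param mesh a `hex_mesh`.
#' @export
write_mesh_csv <- function(mesh, nodes_path, elements_path) {
  nd <- data.frame(id = mesh$node_ids, x = mesh$node_coords[, 1L],
                   y = mesh$node_coords[, 2L], z = mesh$node_coords[, 3L])
  conn <- matrix(mesh$node_ids[mesh$elements], nrow(mesh$elements), 8L)
  el <- data.frame(id = seq_len(nrow(mesh$elements)))
  for (k in 1:8) el[[paste0("n", k)]] <- conn[, k]
  el$part <- mesh$part_labels
  utils::write.csv(nd, nodes_path, row.names = FALSE)
  utils::write.csv(el, elements_path, row.names = FALSE)
  invisible(c(nodes_path, elements_path))
}

#' Read a legacy ASCII VTK unstructured grid of hexahedra
#'
#' Supports `DATASET UNSTRUCTURED_GRID` with `POINTS`, `CELLS` and
#' `CELL_TYPES` (type 12, VTK_HEXAHEDRON; 0-based connectivity). An optional
#' `CELL_DATA` string/scalar field named `part` is used for part labels.
#'
#' @param path .vtk file path.
#' @return a `hex_mesh`.
#' @export
read_mesh_vtk <- function(path) {
  lines <- readLines(path)
  toks <- function(s) strsplit(trimws(s), "\\s+")[[1L]]
  i_pts <- grep("^POINTS", lines)
  if (!length(i_pts)) stop("VTK file has no POINTS section")
  n_pts <- as.integer(toks(lines[i_pts[1L]])[2L])
  vals <- numeric(0)
  i <- i_pts[1L] + 1L
  while (length(vals) < 3L * n_pts) {
    vals <- c(vals, as.numeric(toks(lines[i])))
    i <- i + 1L
  }
  coords <- matrix(vals[seq_len(3L * n_pts)], ncol = 3L, byrow = TRUE)
  i_cells <- grep("^CELLS", lines)
  if (!length(i_cells)) stop("VTK file has no CELLS section")
  hdr <- toks(lines[i_cells[1L]])
  n_cells <- as.integer(hdr[2L])
  ints <- integer(0)
  i <- i_cells[1L] + 1L
  while (length(ints) < as.integer(hdr[3L])) {
    ints <- c(ints, as.integer(toks(lines[i])))
    i <- i + 1L
  }
  conn <- matrix(0L, n_cells, 8L)
  p <- 1L
  for (c0 in seq_len(n_cells)) {
    np <- ints[p]
    if (np != 8L) stop("non-hexahedral cell in VTK file")
    conn[c0, ] <- ints[(p + 1L):(p + 8L)] + 1L
    p <- p + np + 1L
  }
  i_types <- grep("^CELL_TYPES", lines)
  if (length(i_types)) {
    tys <- integer(0)
    i <- i_types[1L] + 1L
    while (length(tys) < n_cells) {
      tys <- c(tys, as.integer(toks(lines[i])))
      i <- i + 1L
    }
    if (any(tys != 12L)) stop("VTK cells must all be hexahedra (type 12)")
  }
  parts <- rep("default", n_cells)
  i_part <- grep("^SCALARS part|^FIELD", lines)
  i_cd <- grep("^CELL_DATA", lines)
  if (length(i_cd) && length(i_part)) {
    j <- i_part[i_part > i_cd[1L]][1L]
    if (!is.na(j)) {
      j <- j + if (startsWith(lines[j], "SCALARS")) 2L else 1L
      pv <- character(0)
      while (length(pv) < n_cells && j <= length(lines)) {
        pv <- c(pv, toks(lines[j]))
        j <- j + 1L
      }
      parts <- pv[seq_len(n_cells)]
    }
  }
  hex_mesh(coords, conn, parts)
}

#' Write a legacy ASCII VTK unstructured grid
#'
#' @param mesh a `hex_mesh`.
#' @param path output .vtk path.
#' @export
write_mesh_vtk <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  n_pts <- nrow(mesh$node_coords)
  n_cells <- nrow(mesh$elements)
  writeLines(c("# vtk DataFile Version 3.0", "hexahedral mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", n_pts)), con)
  utils::write.table(format(mesh$node_coords, digits = 17, trim = TRUE,
                            scientific = FALSE),
                     con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  writeLines(sprintf("CELLS %d %d", n_cells, 9L * n_cells), con)
  utils::write.table(cbind(8L, mesh$elements - 1L), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  writeLines(sprintf("CELL_TYPES %d", n_cells), con)
  writeLines(as.character(rep(12L, n_cells)), con)
  writeLines(sprintf("CELL_DATA %d", n_cells), con)
  writeLines(c("SCALARS part int 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(as.integer(factor(mesh$part_labels))), con)
  invisible(path)
}

#' Read / write a displacement history as long CSV
#'
#' Columns `time,node,ux,uy,uz`; `node` is the 1-based node index, `time` in
#' the unit given by `time_unit` (converted to seconds on read).
#'
#' @param path CSV path.
#' @param mesh optional `hex_mesh` for node-count validation.
#' @param time_unit `"s"` (default) or `"ms"`.
#' @return a `displacement_history`.
#' @export
read_displacements_csv <- function(path, mesh = NULL,
                                   time_unit = c("s", "ms")) {
  time_unit <- match.arg(time_unit)
  df <- utils::read.csv(path)
  need <- c("time", "node", "ux", "uy", "uz")
  if (!all(need %in% names(df)))
    stop("displacement CSV needs columns time,node,ux,uy,uz")
  if (time_unit == "ms") df$time <- df$time / 1000
  times <- sort(unique(df$time))
  nodes <- sort(unique(df$node))
  n_nodes <- if (is.null(mesh)) max(nodes) else nrow(mesh$node_coords)
  U <- array(0, c(length(times), n_nodes, 3L))
  ti <- match(df$time, times)
  U[cbind(ti, df$node, 1L)] <- df$ux
  U[cbind(ti, df$node, 2L)] <- df$uy
  U[cbind(ti, df$node, 3L)] <- df$uz
  displacement_history(times, U, mesh)
}

#' @rdname read_displacements_csv
#' @param disp a `displacement_history`.
#' @export
write_displacements_csv <- function(disp, path) {
  nt <- length(disp$times)
  nn <- dim(disp$displacements)[2L]
  df <- data.frame(
    time = rep(disp$times, each = nn),
    node = rep(seq_len(nn), nt),
    ux = as.numeric(t(disp$displacements[, , 1L, drop = TRUE])),
    uy = as.numeric(t(disp$displacements[, , 2L, drop = TRUE])),
    uz = as.numeric(t(disp$displacements[, , 3L, drop = TRUE])))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read / write marker displacement histories as long CSV
#'
#' Columns `time,marker,ux,uy,uz`.
#'
#' @param path CSV path.
#' @param time_unit `"s"` or `"ms"`.
#' @return list with `times` and `disp` (`[time, marker, 3]`).
#' @export
read_marker_csv <- function(path, time_unit = c("s", "ms")) {
  time_unit <- match.arg(time_unit)
  df <- utils::read.csv(path)
  need <- c("time", "marker", "ux", "uy", "uz")
  if (!all(need %in% names(df)))
    stop("marker CSV needs columns time,marker,ux,uy,uz")
  if (time_unit == "ms") df$time <- df$time / 1000
  times <- sort(unique(df$time))
  markers <- sort(unique(df$marker))
  U <- array(0, c(length(times), length(markers), 3L))
  ti <- match(df$time, times)
  mi <- match(df$marker, markers)
  U[cbind(ti, mi, 1L)] <- df$ux
  U[cbind(ti, mi, 2L)] <- df$uy
  U[cbind(ti, mi, 3L)] <- df$uz
  list(times = times, disp = U, markers = markers)
}

#' Read a cluster definition from JSON
#'
#' Schema: `{"markers": [[x,y,z], ...], "tets": [[i,j,k,l], ...],
#' "exclude": [...]}` with 1-based marker indices.
#'
#' @param path JSON path.
#' @return a `cluster_definition`.
#' @export
read_cluster_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  to_mat <- function(x, nc) {
    if (is.matrix(x)) x else matrix(unlist(x), ncol = nc, byrow = TRUE)
  }
  cluster_definition(
    marker_coords = to_mat(j$markers, 3L),
    tets = to_mat(j$tets, 4L),
    exclude = if (is.null(j$exclude)) integer(0) else as.integer(j$exclude))
}
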