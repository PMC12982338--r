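# End-to-end orchestration: configuration, the embed -> strain -> metrics
# chain, named synthetic scenarios, and pinned-format report output.

#' Run configuration
#'
#' Validated parameter bundle for [run_pipeline()]. Paths may be omitted
#' when the corresponding object is passed directly. Every output carries
#' the configuration in its metadata.
#'
#' @param mesh_nodes,mesh_elements CSV mesh paths (or `mesh_vtk` for a
#'   legacy VTK file).
#' @param mesh_vtk legacy VTK mesh path.
#' @param displacements long-CSV displacement path.
#' @param tract_manifest tract-label manifest path (see
#'   [read_tract_manifest()]).
#' @param output_dir directory for report files.
#' @param step resampling step, mm (> 0).
#' @param eps_thresh fiber damage threshold (> 0).
#' @param csdm_threshold CSDM MPS threshold (> 0).
#' @param strain_measure `"green"`, `"engineering"` or `"logarithmic"`.
#' @param csdm_mode `"volume"` or `"count"`.
#' @param snap_tol boundary snap tolerance, mm (>= 0).
#' @param eval_rule solid strain evaluation rule (`"centroid"`/`"gauss"`).
#' @param parts optional part-label filter for the global metrics.
#' @param time_unit displacement file time unit (`"s"`/`"ms"`).
#' @param seed RNG seed recorded in metadata.
#' @return list of class `run_config`.
#' @export
run_config <- function(mesh_nodes = NULL, mesh_elements = NULL,
                       mesh_vtk = NULL, displacements = NULL,
                       tract_manifest = NULL, output_dir = NULL,
                       step = 1.0, eps_thresh = 0.10, csdm_threshold = 0.25,
                       strain_measure = c("green", "engineering",
                                          "logarithmic"),
                       csdm_mode = c("volume", "count"), snap_tol = 0.5,
                       eval_rule = c("centroid", "gauss"), parts = NULL,
                       time_unit = c("s", "ms"), seed = 1L) {
  strain_measure <- match.arg(strain_measure)
  csdm_mode <- match.arg(csdm_mode)
  eval_rule <- match.arg(eval_rule)
  time_unit <- match.arg(time_unit)
  stopifnot(step > 0, eps_thresh > 0, csdm_threshold > 0, snap_tol >= 0)
  structure(list(mesh_nodes = mesh_nodes, mesh_elements = mesh_elements,
                 mesh_vtk = mesh_vtk, displacements = displacements,
                 tract_manifest = tract_manifest, output_dir = output_dir,
                 step = step, eps_thresh = eps_thresh,
                 csdm_threshold = csdm_threshold,
                 strain_measure = strain_measure, csdm_mode = csdm_mode,
                 snap_tol = snap_tol, eval_rule = eval_rule, parts = parts,
                 time_unit = time_unit, seed = as.integer(seed)),
            class = "run_config")
}

#' Load a run configuration from YAML
#'
#' @param path YAML file whose keys match the [run_config()] arguments.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(y), known)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  do.call(run_config, y)
}

# pinned number formatting so repeated runs are byte-identical
.fmt_num <- function(x) formatC(x, digits = 12, format = "g")

#' Run the full embed -> strain -> metrics pipeline
#'
#' Reads (or accepts) a mesh, a displacement history and a tract set; embeds
#' the fibers, computes dynamic axonal strain and solid strain histories,
#' derives the per-tract metric table and the global metrics, and (when
#' `output_dir` is set) writes the embedding table, per-beam peak summary,
#' metric tables and a metadata record. On any failure, partial outputs in
#' `output_dir` are removed before the error propagates.
#'
#' @param config a `run_config`.
#' @param mesh,disp,tracts optional in-memory objects overriding the
#'   configured paths.
#' @return list with `tract_metrics`, `global_metrics`, `embedding_summary`,
#'   `axonal` (strain history), `solid` (strain history), `metadata`.
#' @export
run_pipeline <- function(config, mesh = NULL, disp = NULL, tracts = NULL) {
  stopifnot(inherits(config, "run_config"))
  outputs <- character(0)
  cleanup <- function() if (length(outputs)) unlink(outputs)
  tryCatch({
    if (is.null(mesh)) {
      mesh <- if (!is.null(config$mesh_vtk)) read_mesh_vtk(config$mesh_vtk)
      else if (!is.null(config$mesh_nodes))
        read_mesh_csv(config$mesh_nodes, config$mesh_elements)
      else stop("no mesh given (mesh_vtk / mesh_nodes+mesh_elements / mesh object)")
    }
    if (is.null(disp)) {
      if (is.null(config$displacements)) stop("no displacement history given")
      disp <- read_displacements_csv(config$displacements, mesh,
                                     config$time_unit)
    }
    if (is.null(tracts)) {
      if (is.null(config$tract_manifest)) stop("no tract set given")
      tracts <- read_tract_manifest(config$tract_manifest, config$step)
    }
    emb <- embed_fibers(mesh, tracts, snap_tol = config$snap_tol)
    ax <- axonal_strain_dynamic(emb, disp, measure = config$strain_measure)
    solid <- element_strain_history(mesh, disp, eval_rule = config$eval_rule)
    tm <- tract_metrics(ax, eps_thresh = config$eps_thresh)
    gm <- global_metrics(mesh, solid, csdm_threshold = config$csdm_threshold,
                         parts = config$parts, csdm_mode = config$csdm_mode)
    meta <- list(tool = "axtract",
                 version = as.character(utils::packageVersion("axtract")),
                 config = unclass(config),
                 n_fibers = emb$summary$n_fibers,
                 n_beams = emb$summary$n_beams,
                 n_dropped_fibers = emb$summary$n_dropped,
                 n_snapped_nodes = emb$summary$n_snapped)
    if (!is.null(config$output_dir)) {
      dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
      fp <- function(f) file.path(config$output_dir, f)
      outputs <- c(fp("embedding.csv"), fp("beam_peaks.csv"),
                    fp("tract_metrics.csv"), fp("global_metrics.json"),
                    fp("metadata.json"))
      write_embedding_csv(emb, fp("embedding.csv"))
      pk <- beam_peaks(ax)
      pk$peak <- .fmt_num(pk$peak)
      utils::write.csv(pk, fp("beam_peaks.csv"), row.names = FALSE)
      tm_out <- tm
      for (cn in c("phi", "axs95")) tm_out[[cn]] <- .fmt_num(tm_out[[cn]])
      utils::write.csv(tm_out, fp("tract_metrics.csv"), row.names = FALSE)
      jsonlite::write_json(c(gm, list(metadata = meta)),
                           fp("global_metrics.json"), auto_unbox = TRUE,
                           digits = NA, pretty = TRUE)
      jsonlite::write_json(meta, fp("metadata.json"), auto_unbox = TRUE,
                           digits = NA, pretty = TRUE)
    }
    list(tract_metrics = tm, global_metrics = gm,
         embedding_summary = emb$summary, axonal = ax, solid = solid,
         metadata = meta)
  }, error = function(e) {
    cleanup()
    stop(e)
  })
}

#' Materialize a named synthetic scenario
#'
#' `"shear_box"`: a box mesh under a haversine simple-shear pulse with a
#' diagonal fiber bundle aligned with the stretched direction of the shear
#' (so that increasing the shear peak drives the bundle's susceptibility
#' index through the damage threshold). `"twist_box"`: the same box and
#' bundle under an inhomogeneous twist, where dynamic and projected static
#' axonal strain genuinely differ.
#'
#' @param name scenario name.
#' @param peak deformation peak amplitude (shear gamma or twist rate).
#' @param n number of box elements per edge.
#' @param n_fibers bundle fiber count.
#' @param n_times time steps over the pulse.
#' @param seed RNG seed.
#' @return list with `mesh`, `tracts`, `history` (a
#'   `displacement_history`), `oracle`, `spec`.
#' @export
synth_scenario <- function(name = c("shear_box", "twist_box"), peak = 0.3,
                           n = 5L, n_fibers = 20L, n_times = 11L,
                           seed = 1L) {
  name <- match.arg(name)
  size <- 10
  spacing <- size / n
  mesh <- make_box_mesh(n, n, n, spacing = spacing)
  # bundle along (1,1,0)/sqrt(2): the direction stretched by u_x = gamma * y
  dirv <- c(1, 1, 0) / sqrt(2)
  tracts <- make_bundle("straight", n_fibers = n_fibers, label = "CC_B",
                        start = c(1.5, 1.5, size / 2), direction = dirv,
                        length = size - 3, spread = 1.0, seed = seed,
                        bbox = rbind(c(0, 0, 0), c(size, size, size)))
  spec <- switch(name,
    shear_box = deformation_spec("simple_shear", peak = peak,
                                 duration = 0.01),
    twist_box = deformation_spec("twist", peak = peak, duration = 0.01,
                                 center = c(size / 2, size / 2, 0)))
  mh <- make_history(mesh, spec, seq(0, spec$duration,
                                     length.out = n_times))
  list(mesh = mesh, tracts = tracts, history = mh$history,
       oracle = mh$oracle, spec = spec)
}
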