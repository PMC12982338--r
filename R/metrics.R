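# Tract-level and global injury metrics.
#
# The tract-wise susceptibility index phi is a two-level statistic: per
# fiber, the fraction of its beam elements whose peak axonal strain exceeds
# a threshold (the fiber damage weight w); per tract, the mean of w over the
# tract's fibers. Averaging fiber fractions is NOT the same as pooling all
# beams of the tract whenever fiber lengths differ, and the two-level
# structure is deliberate.

#' Fiber damage weight
#'
#' Fraction of a fiber's beam elements whose peak axonal strain strictly
#' exceeds the threshold (0.10 by default, the established optimum for
#' axonal functional impairment).
#'
#' @param peaks per-beam peak strains of one fiber.
#' @param eps_thresh strain threshold (> 0).
#' @param strict count only strictly exceeding beams (default TRUE).
#' @return list with `w`, `n_beams`, `n_exceed`.
#' @export
fiber_weight <- function(peaks, eps_thresh = 0.10, strict = TRUE) {
  if (!length(peaks)) stop("fiber with no beam elements")
  stopifnot(eps_thresh > 0)
  n_exceed <- if (strict) sum(peaks > eps_thresh) else sum(peaks >= eps_thresh)
  list(w = n_exceed / length(peaks), n_beams = length(peaks),
       n_exceed = n_exceed)
}

#' Tract-wise injury susceptibility index
#'
#' Mean of the fiber damage weights over the fibers of one tract.
#'
#' @param weights numeric vector of fiber weights `w`, or a list of
#'   [fiber_weight()] results.
#' @return scalar in `[0, 1]`, or `NA` for an empty tract.
#' @export
phi_tract <- function(weights) {
  if (is.list(weights)) weights <- vapply(weights, `[[`, numeric(1), "w")
  if (!length(weights)) return(NA_real_)
  mean(weights)
}

# Linear-interpolation percentile between closest ranks on sorted data
# (position p * (n - 1)); identical to stats::quantile type 7, written out
# because the convention matters downstream and differs across tools.
.percentile_linear <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  if (n == 1L) return(x)
  h <- p * (n - 1)
  lo <- floor(h)
  x[lo + 1L] + (h - lo) * (x[pmin(lo + 2L, n)] - x[lo + 1L])
}

#' 95th-percentile peak axonal strain of a tract (AxS95)
#'
#' The 95th percentile of per-beam peak axonal strains, used instead of the
#' maximum to limit the influence of numerical instability in a few beams.
#' Linear interpolation between closest ranks.
#'
#' @param peaks per-beam peak strains of one tract (or, with
#'   `pooled = TRUE`, the pooled time-by-beam samples).
#' @param prob percentile (default 0.95).
#' @return scalar.
#' @export
axs95 <- function(peaks, prob = 0.95) {
  if (!length(peaks)) stop("tract with no beam elements")
  .percentile_linear(as.numeric(peaks), prob)
}

#' 95th-percentile peak maximum principal strain (MPS95)
#'
#' @param peak_mps per-element peak MPS over the element set of interest.
#' @param prob percentile (default 0.95).
#' @return scalar.
#' @export
mps95 <- function(peak_mps, prob = 0.95) {
  if (!length(peak_mps)) stop("empty element set")
  .percentile_linear(as.numeric(peak_mps), prob)
}

#' Cumulative strain damage measure (CSDM)
#'
#' Fraction of the element set whose peak MPS strictly exceeds the threshold
#' (0.25 by default), volume-weighted by default; `mode = "count"` uses the
#' plain element fraction.
#'
#' @param peak_mps per-element peak MPS.
#' @param volumes per-element volumes (required for volume mode).
#' @param threshold MPS threshold.
#' @param mode `"volume"` (default) or `"count"`.
#' @param strict strictly-exceeding convention (default TRUE).
#' @return fraction in `[0, 1]`.
#' @export
csdm <- function(peak_mps, volumes = NULL, threshold = 0.25,
                 mode = c("volume", "count"), strict = TRUE) {
  mode <- match.arg(mode)
  if (!length(peak_mps)) stop("empty element set")
  over <- if (strict) peak_mps > threshold else peak_mps >= threshold
  if (mode == "count") return(mean(over))
  if (is.null(volumes)) stop("volume mode requires per-element volumes")
  if (length(volumes) != length(peak_mps))
    stop("volumes and peak_mps lengths differ")
  if (any(volumes <= 0)) stop("volumes must be positive")
  sum(volumes[over]) / sum(volumes)
}

#' Per-tract injury metric table
#'
#' Computes the susceptibility index phi and AxS95 for every tract of an
#' axonal strain history.
#'
#' @param hist an `axonal_strain_history`.
#' @param eps_thresh fiber-weight threshold.
#' @param prob AxS95 percentile.
#' @return data frame: `tract`, `phi`, `axs95`, `n_fibers`, `n_beams`.
#' @export
tract_metrics <- function(hist, eps_thresh = 0.10, prob = 0.95) {
  df <- beam_peaks(hist)
  tr_names <- unique(df$tract)
  rows <- lapply(tr_names, function(tr) {
    sub <- df[df$tract == tr, ]
    ws <- vapply(split(sub$peak, sub$fiber),
                 function(p) fiber_weight(p, eps_thresh)$w, numeric(1))
    data.frame(tract = tr, phi = phi_tract(ws),
               axs95 = axs95(sub$peak, prob),
               n_fibers = length(ws), n_beams = nrow(sub))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Global injury metrics of a solid strain history
#'
#' MPS95 and CSDM over a named element set (all elements by default, or a
#' part-label filter).
#'
#' @param mesh a `hex_mesh`.
#' @param strain_hist a `strain_tensor_history` over all mesh elements.
#' @param csdm_threshold CSDM threshold (default 0.25).
#' @param parts optional character vector of part labels defining the
#'   element set (default: all elements provided).
#' @param csdm_mode `"volume"` or `"count"`.
#' @return list with `mps95`, `csdm`, `threshold`, `element_set`, `n_elements`.
#' @export
global_metrics <- function(mesh, strain_hist, csdm_threshold = 0.25,
                           parts = NULL, csdm_mode = c("volume", "count")) {
  csdm_mode <- match.arg(csdm_mode)
  pk <- peak_mps(strain_hist)
  vols <- element_volumes(mesh)[strain_hist$elements]
  labs <- mesh$part_labels[strain_hist$elements]
  if (!is.null(parts)) {
    keep <- labs %in% parts
    if (!any(keep)) stop("no elements match the requested part labels")
    pk <- pk[keep]; vols <- vols[keep]
  }
  list(mps95 = mps95(pk),
       csdm = csdm(pk, vols, csdm_threshold, mode = csdm_mode),
       threshold = csdm_threshold,
       element_set = if (is.null(parts)) "all" else paste(parts, collapse = "+"),
       n_elements = length(pk))
}
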