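# Case-level outcome statistics: top-five-tract representative values,
# rank correlations with exact small-sample permutation p-values, and the
# rotation-axis contribution analysis.

#' Mean of the top five tract values
#'
#' Representative per-case summary of a per-tract metric table: the mean of
#' the five largest values. Ties at the fifth rank are broken by tract-name
#' lexicographic order for determinism.
#'
#' @param values named numeric vector of per-tract metric values.
#' @param k number of top tracts (default 5).
#' @param lenient with fewer than `k` defined values, average what is there
#'   instead of erroring.
#' @return scalar mean of the `k` largest values.
#' @export
top5_mean <- function(values, k = 5L, lenient = FALSE) {
  if (!length(values)) stop("empty metric table")
  values <- values[!is.na(values)]
  if (length(values) < k) {
    if (!lenient)
      stop(sprintf("fewer than %d defined tract values (have %d)", k,
                   length(values)))
    k <- length(values)
    if (!k) stop("no defined tract values")
  }
  nm <- names(values)
  if (is.null(nm)) nm <- sprintf("tract_%06d", seq_along(values))
  ord <- order(-values, nm)
  mean(values[ord[seq_len(k)]])
}

# all permutations of 1..n (n! x n matrix), plain recursion
.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (k in seq_len(n)) {
    rows <- r + seq_len(nrow(sub))
    out[rows, 1L] <- k
    rest <- seq_len(n)[-k]
    out[rows, -1L] <- matrix(rest[sub], nrow(sub), n - 1L)
    r <- r + nrow(sub)
  }
  out
}

#' Rank correlation with exact permutation p-value
#'
#' Spearman's rho on average-ranked ties and Kendall's tau-b between an
#' ordinal outcome vector and a metric vector. The two-sided p-value for rho
#' is computed by exhaustive enumeration of all `n!` permutations of the
#' metric values when `n <= exact_n_max` (40320 permutations at n = 8), and
#' falls back to the asymptotic t approximation above that.
#'
#' @param outcomes ordinal outcome codes (numeric).
#' @param values metric values, same length, `n >= 3`.
#' @param exact_n_max largest n for exhaustive permutation (default 9).
#' @return list with `rho`, `tau`, `p_value`, `p_method`, `n`; all `NA` with
#'   `reason` when either vector is constant.
#' @export
rank_correlation <- function(outcomes, values, exact_n_max = 9L) {
  outcomes <- as.numeric(outcomes)
  values <- as.numeric(values)
  n <- length(outcomes)
  if (length(values) != n) stop("outcomes and values must have equal length")
  if (n < 3L) stop("need at least 3 cases")
  if (length(unique(outcomes)) < 2L || length(unique(values)) < 2L) {
    return(list(rho = NA_real_, tau = NA_real_, p_value = NA_real_,
                p_method = "none", n = n,
                reason = "constant outcomes or values; correlation undefined"))
  }
  rx <- rank(outcomes)
  ry <- rank(values)
  rho <- stats::cor(rx, ry)
  tau <- stats::cor(outcomes, values, method = "kendall")
  if (n <= exact_n_max) {
    perms <- .permutations(n)
    # Pearson correlation of fixed rx with permuted ry, vectorized:
    # rho_perm = (S_perm - n*mx*my) / (n * sx * sy) with S_perm = sum(rx * ry[perm])
    ry_perm <- matrix(ry[perms], nrow(perms), n)
    S <- as.numeric(ry_perm %*% rx)
    mx <- mean(rx); my <- mean(ry)
    sx <- sqrt(sum((rx - mx)^2)); sy <- sqrt(sum((ry - my)^2))
    rho_perm <- (S - n * mx * my) / (sx * sy)
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
    method <- "exact_permutation"
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    method <- "asymptotic_t"
  }
  list(rho = rho, tau = tau, p_value = p, p_method = method, n = n)
}

#' Rotation-axis contribution analysis
#'
#' Correlates, per tract, the case-wise metric values with the case-wise
#' peak angular accelerations about the X, Y and Z axes, and normalizes the
#' absolute correlation magnitudes so each tract's three contributions sum
#' to 1. Tracts whose metric is constant across cases (e.g. zero everywhere)
#' are reported as missing rows, since no correlation can be computed.
#'
#' @param metrics cases x tracts numeric matrix (column names = tract
#'   abbreviations).
#' @param peaks cases x 3 matrix of peak angular accelerations about X, Y, Z
#'   (rad/s^2).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return data frame: `tract`, `x`, `y`, `z` (non-negative, summing to 1
#'   per present row), `missing`.
#' @export
axis_contribution <- function(metrics, peaks,
                              method = c("pearson", "spearman")) {
  method <- match.arg(method)
  metrics <- as.matrix(metrics)
  peaks <- as.matrix(peaks)
  if (nrow(metrics) != nrow(peaks)) stop("metrics and peaks case counts differ")
  if (nrow(metrics) < 3L) stop("need at least 3 cases")
  if (ncol(peaks) != 3L) stop("peaks must have 3 axis columns")
  tr <- colnames(metrics)
  if (is.null(tr)) tr <- paste0("tract_", seq_len(ncol(metrics)))
  rows <- lapply(seq_len(ncol(metrics)), function(j) {
    m <- metrics[, j]
    if (length(unique(m)) < 2L)
      return(data.frame(tract = tr[j], x = NA_real_, y = NA_real_,
                        z = NA_real_, missing = TRUE))
    r <- abs(vapply(1:3, function(a)
      stats::cor(m, peaks[, a], method = method), numeric(1)))
    s <- sum(r)
    if (!is.finite(s) || s == 0)
      return(data.frame(tract = tr[j], x = NA_real_, y = NA_real_,
                        z = NA_real_, missing = TRUE))
    r <- r / s
    data.frame(tract = tr[j], x = r[1L], y = r[2L], z = r[3L],
               missing = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "method") <- method
  attr(out, "negatives") <- "absolute value before normalization"
  out
}

#' Read a case manifest
#'
#' CSV with columns `case_id`, `outcome` (ordinal code 0/1/2) and optionally
#' `ax_peak_x`, `ax_peak_y`, `ax_peak_z` (peak angular accelerations,
#' rad/s^2). A bundled manifest with the ordinal outcome coding of the eight
#' reconstructed impact cases ships at
#' `system.file("extdata", "case_outcomes.csv", package = "axtract")`; the
#' outcome of any case can be edited for sensitivity re-analysis.
#'
#' @param path CSV path.
#' @return data frame.
#' @export
read_case_manifest <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("case_id", "outcome") %in% names(df)))
    stop("case manifest needs case_id and outcome columns")
  if (!all(df$outcome %in% 0:2))
    stop("outcome codes must be 0, 1 or 2")
  df
}
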