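#' Sakoe-Chiba band constraint
#'
#' The band width is declared in original-visit units and converted to the
#' interpolated grid when trajectories are interpolated (a width of one visit
#' allows warping to the previous, same or next visit). `mode = "forward"`
#' is the one-sided (asymmetric) band used for directed alignment: the
#' source series may only lead, never lag, the target.
#'
#' @param width_visits Non-negative band half-width in visit steps
#'   (`Inf` for an unconstrained alignment); default 1.
#' @param mode `"symmetric"` or `"forward"`.
#' @return An object of class `band_constraint`.
#' @export
band_constraint <- function(width_visits = 1, mode = c("symmetric", "forward")) {
  mode <- match.arg(mode)
  if (length(width_visits) != 1 || is.na(width_visits) || width_visits < 0) {
    stop("'width_visits' must be a single non-negative number")
  }
  structure(list(width_visits = width_visits, mode = mode),
            class = "band_constraint")
}

band_cells <- function(band, cells_per_visit) {
  if (is.infinite(band$width_visits)) return(-1L)
  as.integer(round(band$width_visits * cells_per_visit))
}

#' Linear trajectory interpolation
#'
#' Inserts `k` equidistant values between consecutive points, so a length-`n`
#' trajectory becomes length `n + (n - 1) * k` (six visits with the default
#' `k = 5` give 31 points); original values are preserved at stride `k + 1`.
#'
#' @param x Numeric trajectory (length >= 2, finite).
#' @param k Number of values to insert between neighbours (default 5).
#' @return Numeric vector of length `length(x) + (length(x) - 1) * k`.
#' @export
#' @examples
#' interpolate_trajectory(c(0, 3), k = 5)
interpolate_trajectory <- function(x, k = 5) {
  if (k < 0) stop("'k' must be >= 0")
  n <- length(x)
  if (n < 2) stop("trajectory needs at least 2 points")
  if (!all(is.finite(x))) stop("trajectory values must be finite")
  if (k == 0) return(as.numeric(x))
  stats::approx(seq_len(n), x, n = n + (n - 1L) * k)$y
}

#' Local cost matrix between two equal-length trajectories
#'
#' Element `(i, j)` is the local distance between `a[i]` and `b[j]` on the
#' univariate score scale: absolute difference by default, squared
#' difference as an option.
#'
#' @param a,b Equal-length finite numeric trajectories.
#' @param metric `"absolute"` or `"squared"`.
#' @return A `length(a) x length(b)` matrix of non-negative local costs.
#' @export
local_cost_matrix <- function(a, b, metric = c("absolute", "squared")) {
  metric <- match.arg(metric)
  if (length(a) != length(b)) stop("length mismatch between trajectories")
  if (!all(is.finite(a)) || !all(is.finite(b))) stop("values must be finite")
  m <- abs(outer(a, b, "-"))
  if (metric == "squared") m <- m^2
  m
}

dtw_engine <- function(a, b, band, cells_per_visit, metric, forward,
                       want_path = TRUE) {
  if (length(a) != length(b)) stop("length mismatch between trajectories")
  if (length(a) < 2) stop("trajectories need at least 2 points")
  if (!all(is.finite(a)) || !all(is.finite(b))) stop("values must be finite")
  width <- band_cells(band, cells_per_visit)
  res <- cpp_dtw(as.numeric(a), as.numeric(b), width, forward,
                 metric == "squared", want_path)
  if (!res$feasible) {
    stop("infeasible band: no complete warping path within the constraint")
  }
  normalizer <- length(a) + length(b)
  structure(
    list(distance = res$raw_cost / normalizer,
         raw_cost = res$raw_cost,
         path = res$path,
         normalizer = normalizer),
    class = "alignment_result")
}

#' Band-constrained DTW distance (symmetric2 step pattern)
#'
#' Computes the optimal warping path by dynamic programming with the
#' symmetric2 step pattern: `D(i, j) = min(D(i-1, j-1) + 2 c(i, j),
#' D(i-1, j) + c(i, j), D(i, j-1) + c(i, j))`, `D(1, 1) = c(1, 1)`, cells
#' outside the Sakoe-Chiba band excluded. The reported `distance` is the
#' cumulative cost normalized by `N + M`. Ties among equal-cost paths are
#' broken toward the diagonal step, so the reported path is deterministic.
#'
#' @param a,b Equal-length numeric trajectories.
#' @param band A [band_constraint()] (symmetric mode).
#' @param cells_per_visit Grid cells per visit step: 1 for raw trajectories,
#'   `k + 1` for trajectories interpolated with [interpolate_trajectory()].
#' @param metric Local distance, `"absolute"` (default) or `"squared"`.
#' @return An `alignment_result` with `distance`, `raw_cost`, `path`
#'   (two-column index matrix from `(1, 1)` to `(N, M)`) and `normalizer`.
#' @export
#' @examples
#' dtw_distance(c(0, 2), c(0, 0), band_constraint(Inf))$distance
dtw_distance <- function(a, b, band = band_constraint(1),
                         cells_per_visit = 1,
                         metric = c("absolute", "squared")) {
  metric <- match.arg(metric)
  if (!inherits(band, "band_constraint")) stop("'band' must be a band_constraint")
  if (band$mode != "symmetric") {
    stop("dtw_distance needs a symmetric band; see directed_dtw_distance")
  }
  dtw_engine(a, b, band, cells_per_visit, metric, forward = FALSE)
}

#' Directed DTW distance with a forward-only band
#'
#' Same symmetric2 recursion as [dtw_distance()] but restricted to cells with
#' `0 <= j - i <= width`, so the source trajectory `a` may only lead (never
#' lag) the target `b`. `d(a -> b)` and `d(b -> a)` generally differ; a small
#' `d(a -> b)` indicates that `a`'s fluctuations precede `b`'s.
#'
#' @inheritParams dtw_distance
#' @param band A [band_constraint()]; its mode is coerced to `"forward"`.
#' @return An `alignment_result`; see [dtw_distance()].
#' @export
directed_dtw_distance <- function(a, b, band = band_constraint(1, "forward"),
                                  cells_per_visit = 1,
                                  metric = c("absolute", "squared")) {
  metric <- match.arg(metric)
  if (!inherits(band, "band_constraint")) stop("'band' must be a band_constraint")
  dtw_engine(a, b, band, cells_per_visit, metric, forward = TRUE)
}

#' Per-patient all-pairs DTW distance matrices
#'
#' For one complete patient, interpolates every symptom trajectory and
#' computes (i) the symmetric matrix of band-constrained DTW distances and
#' (ii) the directed matrix where entry `(i, j)` is the forward-only
#' distance from symptom `i` to symptom `j`. Diagonals are exactly 0.
#'
#' @param panel A complete `symptom_panel` (see [filter_complete()]).
#' @param patient_id Patient identifier.
#' @param band_width Band half-width in visit units (default 1).
#' @param k Interpolation density per visit gap (default 5).
#' @param metric Local distance (see [dtw_distance()]).
#' @param scale If `TRUE`, z-scale each symptom trajectory within the
#'   patient before alignment (constant trajectories are left at 0).
#' @return An object of class `patient_dtw`: list with `patient_id`,
#'   `symmetric`, `directed` (both `S x S`, dimnamed) and `params`.
#' @export
patient_matrices <- function(panel, patient_id, band_width = 1, k = 5,
                             metric = c("absolute", "squared"),
                             scale = FALSE) {
  metric <- match.arg(metric)
  if (!all(panel$observed[patient_id, ])) {
    stop("patient ", patient_id,
         " has unobserved visits; apply filter_complete() first")
  }
  sc <- panel_scores(panel, patient_id)  # symptoms x visits
  traj <- t(apply(sc, 1, interpolate_trajectory, k = k))
  if (scale) {
    traj <- t(apply(traj, 1, function(x) {
      s <- stats::sd(x)
      if (s < .Machine$double.eps) rep(0, length(x)) else (x - mean(x)) / s
    }))
  }
  width <- band_cells(band_constraint(band_width), k + 1)
  sym <- cpp_all_pairs(traj, width, FALSE, metric == "squared")
  dir <- cpp_all_pairs(traj, width, TRUE, metric == "squared")
  if (any(!is.finite(sym)) || any(!is.finite(dir))) {
    stop("infeasible band: no complete warping path within the constraint")
  }
  syms <- panel_symptoms(panel)
  dimnames(sym) <- dimnames(dir) <- list(syms, syms)
  structure(
    list(patient_id = patient_id, symmetric = sym, directed = dir,
         params = list(band_width = band_width, k = k, metric = metric,
                       step_pattern = "symmetric2", scale = scale)),
    class = "patient_dtw")
}

#' @export
print.patient_dtw <- function(x, ...) {
  cat(sprintf("patient_dtw: %s, %d symptoms (band %g visit, k = %d, %s)\n",
              x$patient_id, nrow(x$symmetric), x$params$band_width,
              x$params$k, x$params$metric))
  invisible(x)
}

#' All-patients DTW distance matrices
#'
#' Applies [patient_matrices()] to every patient of a complete panel.
#'
#' @inheritParams patient_matrices
#' @return Named list of `patient_dtw` objects, one per patient.
#' @export
cohort_matrices <- function(panel, band_width = 1, k = 5,
                            metric = c("absolute", "squared"),
                            scale = FALSE) {
  metric <- match.arg(metric)
  if (!all(panel$observed)) {
    stop("panel has incomplete patients; apply filter_complete() first")
  }
  pats <- panel_patients(panel)
  out <- lapply(pats, function(p) {
    patient_matrices(panel, p, band_width = band_width, k = k,
                     metric = metric, scale = scale)
  })
  names(out) <- pats
  out
}

#' Write per-patient matrices and a parameter manifest
#'
#' Serializes each patient's symmetric and directed matrix as labelled
#' square CSVs plus a JSON manifest of the alignment parameters.
#'
#' @param matrices Output of [cohort_matrices()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
write_matrices <- function(matrices, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (m in matrices) {
    utils::write.csv(m$symmetric,
                     file.path(dir, paste0(m$patient_id, "_symmetric.csv")))
    utils::write.csv(m$directed,
                     file.path(dir, paste0(m$patient_id, "_directed.csv")))
  }
  manifest <- c(matrices[[1]]$params,
                list(n_patients = length(matrices),
                     patients = vapply(matrices, `[[`, "", "patient_id")))
  path <- file.path(dir, "dtw_manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
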