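#' Random 1:1 split of a patient list
#'
#' Uniformly random partition into disjoint halves of sizes `floor(n/2)` and
#' `ceiling(n/2)` (155 patients split 77/78); seeded and reproducible.
#'
#' @param patients Vector of patient identifiers (length >= 4).
#' @param seed Integer seed.
#' @return List with elements `a` and `b`.
#' @export
split_half <- function(patients, seed = 1) {
  n <- length(patients)
  if (n < 4) stop("need at least 4 patients to split")
  perm <- withr::with_seed(seed, sample(patients))
  n_a <- n %/% 2
  list(a = perm[seq_len(n_a)], b = perm[(n_a + 1):n])
}

#' Tucker congruence coefficient between two weight matrices
#'
#' `phi = sum(a b) / sqrt(sum(a^2) sum(b^2))` over the vectorized
#' off-diagonal entries; 1 for identical (or positively proportional)
#' patterns, invariant to positive rescaling of either matrix.
#'
#' @param A,B Same-shape matrices with identical node ordering.
#' @return Scalar in \[-1, 1\].
#' @export
congruence_coefficient <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (!identical(dim(A), dim(B))) stop("matrices must have the same shape")
  off <- row(A) != col(A)
  a <- A[off]; b <- B[off]
  na <- sum(a * a); nb <- sum(b * b)
  if (na < 1e-24 || nb < 1e-24) {
    stop("congruence undefined: an input matrix is zero off-diagonal")
  }
  sum(a * b) / sqrt(na * nb)
}

#' Procrustes alignment of two node configurations
#'
#' Orthogonal rotation/reflection, scaling and translation of configuration
#' `B` minimizing the sum of squared coordinate differences to `A` (used to
#' overlay split-half network layouts for visual comparison).
#'
#' @param config_a Target coordinate matrix (nodes x dimensions).
#' @param config_b Configuration to align (same nodes and dimension).
#' @return List with `aligned` (transformed `config_b`), `residual` (sum of
#'   squared differences after alignment) and the fitted `rotation`,
#'   `scale`, `translation`.
#' @export
procrustes_align <- function(config_a, config_b) {
  A <- as.matrix(config_a); B <- as.matrix(config_b)
  if (!identical(dim(A), dim(B))) {
    stop("configurations must share node set and dimension")
  }
  if (all(apply(B, 2, stats::sd) < 1e-12) ||
      all(apply(A, 2, stats::sd) < 1e-12)) {
    stop("degenerate configuration: all nodes coincident")
  }
  fit <- vegan::procrustes(A, B, scale = TRUE, symmetric = FALSE)
  # Yrot lives in the centered-target space; shift back by the target mean
  aligned <- sweep(fit$Yrot, 2, fit$xmean, "+")
  dimnames(aligned) <- dimnames(A)
  list(aligned = aligned,
       residual = sum((A - aligned)^2),
       rotation = fit$rotation,
       scale = fit$scale,
       translation = drop(fit$translation))
}

#' Split-half stability of the group directed network
#'
#' Repeatedly splits the cohort into random halves, runs the DTW ->
#' aggregation -> network stage on each half independently, and computes the
#' Tucker congruence between the two halves' edge-weight matrices. Per-
#' patient distance matrices depend only on the patient, so they are
#' computed once and reused across splits.
#'
#' @param panel A complete `symptom_panel`.
#' @param n_splits Number of random re-splits (default 200).
#' @param seed Integer seed governing all splits.
#' @param band_width,k,metric Alignment parameters (see
#'   [patient_matrices()]).
#' @param transform Distance-to-weight transform (see
#'   [distance_to_similarity()]).
#' @param matrices Optional precomputed [cohort_matrices()] result.
#' @return A `stability_report`: `n_splits`, `values` (congruence per
#'   split), `median`, `p25`, `p95`, `sizes`.
#' @export
stability_run <- function(panel, n_splits = 200, seed = 1, band_width = 1,
                          k = 5, metric = "absolute", transform = "max",
                          matrices = NULL) {
  if (is.null(matrices)) {
    matrices <- cohort_matrices(panel, band_width = band_width, k = k,
                                metric = metric)
  }
  pats <- names(matrices)
  n <- length(pats)
  if (n < 4) stop("need at least 4 patients")
  half_weights <- function(ids) {
    distance_to_similarity(aggregate_directed(matrices[ids]),
                           transform = transform)
  }
  values <- numeric(n_splits)
  withr::with_seed(seed, {
    for (s in seq_len(n_splits)) {
      perm <- sample(pats)
      n_a <- n %/% 2
      wa <- half_weights(perm[seq_len(n_a)])
      wb <- half_weights(perm[(n_a + 1):n])
      values[s] <- congruence_coefficient(wa, wb)
    }
  })
  structure(
    list(n_splits = n_splits,
         values = values,
         median = stats::median(values),
         p25 = unname(stats::quantile(values, 0.25)),
         p95 = unname(stats::quantile(values, 0.95)),
         sizes = c(n %/% 2, n - n %/% 2),
         seed = seed),
    class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf(
    "stability_report: %d splits (%d/%d); median congruence %.3f (p25 %.3f, p95 %.3f)\n",
    x$n_splits, x$sizes[1], x$sizes[2], x$median, x$p25, x$p95))
  invisible(x)
}

#' Serialize a stability report to JSON
#'
#' @param report A [stability_run()] result.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_stability <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
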