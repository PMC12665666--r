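#' Double-centered, eigenvalue-normalized cross-product matrix
#'
#' Transforms one symmetric distance matrix into the cross-product form used
#' by Distatis: `S = -1/2 J D J` with `J = I - 11'/n` (the classical MDS
#' double-centering), then divides by the leading eigenvalue so every
#' patient contributes on the same scale (first eigenvalue 1). An all-zero
#' input returns the zero matrix (normalization skipped by convention).
#'
#' @param D Symmetric non-negative distance matrix with zero diagonal.
#' @return The normalized cross-product matrix (dimnames preserved).
#' @export
to_crossproduct <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) != ncol(D)) stop("distance matrix must be square")
  if (max(abs(D - t(D))) > 1e-8) stop("distance matrix must be symmetric")
  if (any(D < 0)) stop("distance matrix must be non-negative")
  if (max(abs(diag(D))) > 1e-8) stop("distance matrix must have zero diagonal")
  n <- nrow(D)
  # double-centering: S = -1/2 (D - r 1' - 1 c' + m)
  S <- -0.5 * (D - outer(rowMeans(D), rep(1, n)) -
                 outer(rep(1, n), colMeans(D)) + mean(D))
  S <- (S + t(S)) / 2
  if (max(abs(S)) < 1e-12) return(S * 0)
  l1 <- eigen(S, symmetric = TRUE, only.values = TRUE)$values[1]
  if (l1 <= 1e-12) stop("degenerate distance matrix: leading eigenvalue <= 0")
  S / l1
}

#' RV coefficient between two cross-product matrices
#'
#' `RV(A, B) = trace(A B) / sqrt(trace(A A) trace(B B))`; for symmetric
#' matrices this is the cosine between the vectorized matrices.
#'
#' @param A,B Symmetric matrices of identical dimension.
#' @return A scalar in \[-1, 1\] (1 for proportional matrices).
#' @export
rv_coefficient <- function(A, B) {
  if (!identical(dim(A), dim(B))) stop("matrices must have identical shape")
  na <- sum(A * A)
  nb <- sum(B * B)
  if (na < 1e-24 || nb < 1e-24) stop("RV undefined for an all-zero matrix")
  sum(A * B) / sqrt(na * nb)
}

rv_matrix <- function(crossproducts) {
  V <- vapply(crossproducts, as.vector,
              numeric(length(crossproducts[[1]])))
  norms <- sqrt(colSums(V * V))
  if (any(norms < 1e-12)) stop("degenerate all-zero cross-product matrix")
  C <- crossprod(V) / outer(norms, norms)
  (C + t(C)) / 2
}

weights_from_rv <- function(C) {
  e <- eigen(C, symmetric = TRUE)
  v <- e$vectors[, 1]
  if (sum(v) < 0) v <- -v
  if (any(v < -1e-8)) {
    stop("first eigenvector of the RV matrix has mixed signs")
  }
  v[v < 0] <- 0
  v / sum(v)
}

#' Patient congruence weights
#'
#' Builds the K x K matrix of RV coefficients between patients'
#' cross-product matrices and returns its (rescaled) first eigenvector:
#' patients whose temporal structure agrees with the group consensus
#' receive larger weight. Weights are non-negative and sum to 1.
#'
#' @param crossproducts List of K >= 2 cross-product matrices
#'   (see [to_crossproduct()]).
#' @return Numeric weight vector of length K (names preserved).
#' @export
congruence_weights <- function(crossproducts) {
  if (length(crossproducts) < 2) stop("need at least 2 cross-products")
  w <- weights_from_rv(rv_matrix(crossproducts))
  names(w) <- names(crossproducts)
  w
}

#' Distatis compromise: weighted group cross-product and its eigenstructure
#'
#' The compromise is the congruence-weighted sum of the patients'
#' cross-product matrices. Its eigendecomposition yields the compromise
#' factors: factor scores are eigenvectors scaled by the square root of
#' their eigenvalues, and each positive eigenvalue's share of the positive
#' eigenvalue mass is its variance explained. Symptom coordinates on the
#' first few factors (3 by default) summarize average temporal similarity.
#'
#' @param crossproducts List of cross-product matrices.
#' @param weights Optional weight vector; computed with
#'   [congruence_weights()] when omitted.
#' @param n_factors Number of factors retained for downstream use.
#' @return An object of class `distatis_compromise`: `weights`,
#'   `compromise`, `eigenvalues` (non-increasing), `factor_scores`
#'   (symptoms x positive factors), `variance_explained`, `n_factors`.
#' @export
distatis_compromise <- function(crossproducts, weights = NULL, n_factors = 3) {
  if (is.null(weights)) weights <- congruence_weights(crossproducts)
  if (length(weights) != length(crossproducts)) {
    stop("one weight per cross-product required")
  }
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-8) {
    stop("weights must be non-negative and sum to 1")
  }
  S <- Reduce(`+`, Map(`*`, crossproducts, weights))
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  lambda <- e$values
  pos <- which(lambda > 1e-12 * max(abs(lambda), 1e-300))
  V <- e$vectors[, pos, drop = FALSE]
  # canonical sign: largest-magnitude loading positive
  for (f in seq_len(ncol(V))) {
    i <- which.max(abs(V[, f]))
    if (V[i, f] < 0) V[, f] <- -V[, f]
  }
  F_sc <- V %*% diag(sqrt(lambda[pos]), length(pos))
  rownames(F_sc) <- rownames(S)
  colnames(F_sc) <- paste0("F", seq_len(ncol(F_sc)))
  ve <- lambda[pos] / sum(lambda[pos])
  structure(
    list(weights = weights, compromise = S, eigenvalues = lambda,
         eigenvectors = V, factor_scores = F_sc,
         variance_explained = ve,
         n_factors = min(n_factors, ncol(F_sc))),
    class = "distatis_compromise")
}

#' @export
print.distatis_compromise <- function(x, ...) {
  ve <- round(100 * x$variance_explained[seq_len(x$n_factors)], 1)
  cat(sprintf(
    "distatis_compromise: %d symptoms, %d patients; first %d factors explain %s%% \n",
    nrow(x$compromise), length(x$weights), x$n_factors,
    paste(ve, collapse = "% / ")))
  invisible(x)
}

#' Retained factor scores of a compromise
#'
#' @param x A `distatis_compromise`.
#' @param n_factors How many factors; defaults to the retained number.
#' @return Symptoms x factors coordinate matrix.
#' @export
factor_scores <- function(x, n_factors = x$n_factors) {
  x$factor_scores[, seq_len(n_factors), drop = FALSE]
}

#' Bootstrap confidence envelopes for the compromise configuration
#'
#' Resamples patients with replacement `B` times; each replicate's
#' congruence weights and compromise are recomputed and the replicate
#' configuration is projected onto the fixed reference eigenbasis
#' (`S_b V Lambda^{-1/2}`), avoiding rotation/reflection indeterminacy.
#' Per-symptom, per-factor percentile intervals are returned.
#'
#' @param crossproducts List of cross-product matrices.
#' @param B Number of bootstrap replicates (default 500).
#' @param seed Integer seed; envelopes are reproducible bit-for-bit.
#' @param reference Optional precomputed [distatis_compromise()].
#' @param n_factors Factors to envelope (default: reference's retained).
#' @param level Interval coverage (default 0.95).
#' @return A `distatis_boot` list: `lower`/`upper` (symptoms x factors),
#'   `replicates` (symptoms x factors x B), `B`, `seed`, `level`.
#' @export
bootstrap_envelopes <- function(crossproducts, B = 500, seed = 1,
                                reference = NULL,
                                n_factors = NULL, level = 0.95) {
  if (B < 1) stop("'B' must be >= 1")
  if (is.null(reference)) reference <- distatis_compromise(crossproducts)
  if (is.null(n_factors)) n_factors <- reference$n_factors
  K <- length(crossproducts)
  C <- rv_matrix(crossproducts)
  lam <- reference$eigenvalues[seq_len(n_factors)]
  proj <- reference$eigenvectors[, seq_len(n_factors), drop = FALSE] %*%
    diag(1 / sqrt(lam), n_factors)
  n_sym <- nrow(reference$compromise)
  reps <- array(NA_real_, dim = c(n_sym, n_factors, B),
                dimnames = list(rownames(reference$compromise),
                                paste0("F", seq_len(n_factors)), NULL))
  withr::with_seed(seed, {
    for (b in seq_len(B)) {
      idx <- sample.int(K, K, replace = TRUE)
      w <- weights_from_rv(C[idx, idx, drop = FALSE])
      Sb <- Reduce(`+`, Map(`*`, crossproducts[idx], w))
      reps[, , b] <- Sb %*% proj
    }
  })
  alpha <- (1 - level) / 2
  lower <- apply(reps, c(1, 2), stats::quantile, probs = alpha, names = FALSE)
  upper <- apply(reps, c(1, 2), stats::quantile, probs = 1 - alpha,
                 names = FALSE)
  structure(list(lower = lower, upper = upper, replicates = reps,
                 B = B, seed = seed, level = level),
            class = "distatis_boot")
}
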