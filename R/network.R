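#' Average the per-patient directed distance matrices
#'
#' Element-wise arithmetic mean of the cohort's directed DTW distance
#' matrices, summarizing directional symptom dynamics at group level.
#'
#' @param matrices List of [patient_matrices()] results, or of plain
#'   directed matrices with identical dimnames.
#' @return The mean directed distance matrix.
#' @export
aggregate_directed <- function(matrices) {
  if (!length(matrices)) stop("need at least one patient matrix")
  mats <- lapply(matrices, function(m) {
    if (inherits(m, "patient_dtw")) m$directed else as.matrix(m)
  })
  ref <- dimnames(mats[[1]])
  ok <- vapply(mats, function(m) identical(dimnames(m), ref), logical(1))
  if (!all(ok)) stop("mismatched symptom catalogues across patients")
  Reduce(`+`, mats) / length(mats)
}

#' Directed distance to edge-weight transform
#'
#' Edges should be strong where the directed distance from source to target
#' is small (the source plausibly leads the target). The default transform
#' is `w[i, j] = max_offdiag(D) - D[i, j]`; the alternative is the
#' reciprocal `1 / (1 + D)`. Diagonals are 0 under both.
#'
#' @param D Non-negative directed distance matrix with zero diagonal.
#' @param transform `"max"` (default) or `"reciprocal"`.
#' @return Non-negative weight matrix, zero diagonal, dimnames preserved.
#' @export
distance_to_similarity <- function(D, transform = c("max", "reciprocal")) {
  transform <- match.arg(transform)
  D <- as.matrix(D)
  if (any(D < 0)) stop("distances must be non-negative")
  off <- row(D) != col(D)
  W <- if (transform == "max") max(D[off]) - D else 1 / (1 + D)
  W[!off] <- 0
  W
}

#' Build a weighted directed symptom network
#'
#' @param weights Non-negative weight matrix with zero diagonal;
#'   `weights[i, j]` is the strength of the directed edge i -> j.
#' @param clusters Optional named cluster labels for the nodes.
#' @return A `symptom_network`: `weights`, `out_strength` (row sums),
#'   `in_strength` (column sums), `clusters`.
#' @export
symptom_network <- function(weights, clusters = NULL) {
  weights <- as.matrix(weights)
  if (nrow(weights) != ncol(weights)) stop("weight matrix must be square")
  if (any(weights < 0)) stop("weights must be non-negative")
  if (max(abs(diag(weights))) > 0) stop("diagonal must be zero")
  if (!is.null(clusters)) {
    if (!setequal(names(clusters), rownames(weights))) {
      stop("cluster labels do not match the nodes")
    }
    clusters <- clusters[rownames(weights)]
  }
  structure(list(weights = weights,
                 out_strength = rowSums(weights),
                 in_strength = colSums(weights),
                 clusters = clusters),
            class = "symptom_network")
}

#' @export
print.symptom_network <- function(x, ...) {
  cat(sprintf("symptom_network: %d nodes, total edge mass %.3f\n",
              nrow(x$weights), sum(x$weights)))
  invisible(x)
}

#' In- and out-strength centralities
#'
#' Out-strength (row sum) is high for symptoms whose fluctuations typically
#' precede changes in others (drivers); in-strength (column sum) is high for
#' symptoms that follow (consequences).
#'
#' @param network A [symptom_network()].
#' @return Data frame `symptom, out_strength, in_strength, out_rank,
#'   in_rank` (rank 1 = strongest).
#' @export
strength_centralities <- function(network) {
  data.frame(
    symptom = rownames(network$weights),
    out_strength = unname(network$out_strength),
    in_strength = unname(network$in_strength),
    out_rank = rank(-network$out_strength, ties.method = "min"),
    in_rank = rank(-network$in_strength, ties.method = "min"),
    row.names = NULL)
}

#' Collapse a symptom network to cluster level
#'
#' The weight between two distinct clusters is the mean of the member-pair
#' edge weights (direction preserved); within-cluster blocks are excluded,
#' so the cluster-level diagonal is zero.
#'
#' @param network A [symptom_network()].
#' @param labels Named cluster labels partitioning the nodes.
#' @return A `symptom_network` over the clusters.
#' @export
cluster_level_network <- function(network, labels) {
  nodes <- rownames(network$weights)
  if (!setequal(names(labels), nodes)) {
    stop("cluster labels do not match the network nodes")
  }
  labels <- labels[nodes]
  cl <- sort(unique(labels))
  W <- matrix(0, length(cl), length(cl),
              dimnames = list(as.character(cl), as.character(cl)))
  for (a in seq_along(cl)) {
    for (b in seq_along(cl)) {
      if (a == b) next
      ia <- which(labels == cl[a])
      ib <- which(labels == cl[b])
      W[a, b] <- mean(network$weights[ia, ib, drop = FALSE])
    }
  }
  symptom_network(W)
}

#' Export a symptom network
#'
#' Writes a GraphML file, an edge-list CSV (`source, target, weight`) and
#' the centrality table; node attributes carry cluster labels when present.
#'
#' @param network A [symptom_network()].
#' @param dir Output directory.
#' @param name File-name stem (default `"network"`).
#' @param top_q Optional fraction in (0, 1\]; keep only the strongest
#'   `top_q` fraction of edges in the export (visualization aid only —
#'   centralities are always computed on the full network).
#' @return Invisibly, the written paths.
#' @export
write_network <- function(network, dir, name = "network", top_q = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  W <- network$weights
  if (!is.null(top_q)) {
    stopifnot(top_q > 0, top_q <= 1)
    off <- W[row(W) != col(W)]
    thr <- stats::quantile(off, probs = 1 - top_q)
    W[W < thr] <- 0
  }
  g <- igraph::graph_from_adjacency_matrix(W, mode = "directed",
                                           weighted = TRUE, diag = FALSE)
  if (!is.null(network$clusters)) {
    igraph::V(g)$cluster <- as.character(network$clusters[rownames(W)])
  }
  p1 <- file.path(dir, paste0(name, ".graphml"))
  igraph::write_graph(g, p1, format = "graphml")
  el <- which(W > 0, arr.ind = TRUE)
  edges <- data.frame(source = rownames(W)[el[, 1]],
                      target = colnames(W)[el[, 2]],
                      weight = W[el])
  edges <- edges[order(edges$source, edges$target), ]
  p2 <- file.path(dir, paste0(name, "_edges.csv"))
  utils::write.csv(edges, p2, row.names = FALSE)
  p3 <- file.path(dir, paste0(name, "_centralities.csv"))
  utils::write.csv(strength_centralities(network), p3, row.names = FALSE)
  invisible(c(p1, p2, p3))
}
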