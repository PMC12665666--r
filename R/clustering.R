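#' Ward.D2 linkage on factor-space coordinates
#'
#' Agglomerative clustering of symptoms placed in compromise-factor space,
#' merging the pair of clusters that minimizes the Ward.D2 criterion
#' (squared Euclidean distances; merge heights on the distance scale).
#'
#' @param points Numeric matrix of coordinates (rows = symptoms, rownames
#'   required for labelled output).
#' @return An [stats::hclust] tree.
#' @export
ward_linkage <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 2) stop("need at least 2 points to cluster")
  stats::hclust(stats::dist(points), method = "ward.D2")
}

sse_for_labels <- function(points, labels) {
  sum(vapply(split(seq_len(nrow(points)), labels), function(idx) {
    ctr <- colMeans(points[idx, , drop = FALSE])
    sum(sweep(points[idx, , drop = FALSE], 2, ctr)^2)
  }, numeric(1)))
}

#' Within-cluster SSE curve over candidate cluster counts
#'
#' @param points Coordinate matrix used to build `linkage`.
#' @param linkage A [ward_linkage()] tree.
#' @param k_max Largest candidate k (default 10).
#' @return Named numeric vector `SSE(k)` for `k = 1..k_max` (non-increasing).
#' @export
sse_curve <- function(points, linkage, k_max = 10) {
  points <- as.matrix(points)
  k_max <- min(k_max, nrow(points))
  sse <- vapply(seq_len(k_max), function(k) {
    sse_for_labels(points, stats::cutree(linkage, k = k))
  }, numeric(1))
  names(sse) <- seq_len(k_max)
  sse
}

#' Elbow criterion for the number of clusters
#'
#' Operationalizes "maximal curvature change" as the discrete second
#' difference of the SSE curve normalized by the local curve level:
#' returns the interior `k` maximizing
#' `(SSE(k-1) - 2 SSE(k) + SSE(k+1)) / SSE(k)`. The normalization makes
#' the criterion scale-free, which matters for agglomerative SSE curves:
#' their merge costs grow with cluster size, so the *raw* second
#' difference peaks at k = 2 on almost any hierarchical data, whereas the
#' relative curvature peaks where the decay rate collapses -- the knee.
#' Ties go to the smallest k (with a warning), and a non-monotone curve
#' warns but proceeds.
#'
#' @param sse Numeric SSE (or eigenvalue scree) curve over `k = 1..k_max`,
#'   `k_max >= 3`.
#' @return The selected integer k.
#' @export
#' @examples
#' elbow_k(c(100, 60, 25, 23, 22))  # 3
elbow_k <- function(sse) {
  K <- length(sse)
  if (K < 3) stop("elbow needs a curve over at least 3 candidate k")
  scale <- max(abs(sse), 1e-300)
  if (any(diff(sse) > 1e-8 * scale)) {
    warning("SSE curve is not non-increasing; elbow may be unreliable")
  }
  interior <- 2:(K - 1)
  d2 <- sse[interior - 1] - 2 * sse[interior] + sse[interior + 1]
  rel <- d2 / pmax(sse[interior], 1e-12 * scale)
  rel[!is.finite(rel)] <- -Inf
  best <- max(rel)
  hits <- interior[rel >= best - 1e-10 * max(abs(best), 1)]
  if (length(hits) > 1) {
    warning("tied elbow candidates (", paste(hits, collapse = ", "),
            "); returning the smallest")
  }
  as.integer(hits[1])
}

#' Cut a linkage tree into k clusters
#'
#' @param linkage An [stats::hclust] tree.
#' @param k Number of clusters, `1 <= k <= n`.
#' @return Named integer label vector.
#' @export
cut_tree <- function(linkage, k) {
  n <- length(linkage$order)
  if (k < 1 || k > n) stop("'k' must be between 1 and ", n)
  stats::cutree(linkage, k = k)
}

#' Cluster symptoms in compromise-factor space
#'
#' Runs Ward.D2 linkage on the retained factor scores, evaluates the
#' within-cluster SSE over `1..k_max`, selects k with [elbow_k()] (unless a
#' fixed `k` is given) and cuts the tree.
#'
#' @param points Symptom coordinates (typically [factor_scores()] of a
#'   [distatis_compromise()]).
#' @param k_max Largest candidate cluster count (default 10).
#' @param k Optional fixed cluster count overriding the elbow.
#' @return A `cluster_solution`: `linkage`, `k`, `labels`, `sse_curve`.
#' @export
cluster_symptoms <- function(points, k_max = 10, k = NULL) {
  points <- as.matrix(points)
  linkage <- ward_linkage(points)
  curve <- sse_curve(points, linkage, k_max)
  if (is.null(k)) k <- elbow_k(curve)
  labels <- cut_tree(linkage, k)
  structure(list(linkage = linkage, k = k, labels = labels,
                 sse_curve = curve),
            class = "cluster_solution")
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat(sprintf("cluster_solution: %d symptoms in %d clusters (sizes %s)\n",
              length(x$labels), x$k,
              paste(table(x$labels), collapse = ", ")))
  invisible(x)
}

#' Serialize a cluster solution
#'
#' Writes the merge table (standard linkage-matrix layout), a Newick string
#' of the dendrogram, and the symptom-to-cluster label table.
#'
#' @param solution A [cluster_symptoms()] result.
#' @param dir Output directory.
#' @return Invisibly, the written file paths.
#' @export
write_clusters <- function(solution, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  hc <- solution$linkage
  merge_tab <- data.frame(merge1 = hc$merge[, 1], merge2 = hc$merge[, 2],
                          height = hc$height)
  p1 <- file.path(dir, "linkage.csv")
  utils::write.csv(merge_tab, p1, row.names = FALSE)
  p2 <- file.path(dir, "dendrogram.nwk")
  ape::write.tree(ape::as.phylo(hc), p2)
  lab <- data.frame(symptom_id = names(solution$labels),
                    cluster_id = unname(solution$labels),
                    cluster_name = paste0("cluster_",
                                          unname(solution$labels)))
  p3 <- file.path(dir, "labels.csv")
  utils::write.csv(lab, p3, row.names = FALSE)
  p4 <- file.path(dir, "sse_curve.csv")
  utils::write.csv(data.frame(k = as.integer(names(solution$sse_curve)),
                              sse = unname(solution$sse_curve)),
                   p4, row.names = FALSE)
  invisible(c(p1, p2, p3, p4))
}
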