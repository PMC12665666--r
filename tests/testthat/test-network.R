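named_mat <- function(x, n = NULL) {
  m <- if (is.matrix(x)) x else matrix(x, n, n, byrow = TRUE)
  dimnames(m) <- list(paste0("S", seq_len(nrow(m))),
                      paste0("S", seq_len(nrow(m))))
  m
}

test_that("directed matrices aggregate by element-wise mean", {
  M <- named_mat(c(0, 1, 2, 0), 2)
  expect_equal(aggregate_directed(list(M)), M)
  expect_equal(aggregate_directed(list(M, 3 * M)), 2 * M)
  M2 <- named_mat(c(0, 4, 6, 0), 2)
  expect_equal(aggregate_directed(list(M, M2)),
               aggregate_directed(list(M2, M)))
  bad <- M2
  rownames(bad) <- c("X1", "X2")
  expect_error(aggregate_directed(list(M, bad)), "mismatched")
})

test_that("distance-to-similarity reverses the ordering under both
          transforms", {
  D <- named_mat(c(0, 1, 3, 0), 2)
  expect_equal(unname(distance_to_similarity(D)),
               matrix(c(0, 0, 2, 0), 2))
  Dc <- named_mat(c(0, 2, 2, 0), 2)
  expect_true(all(distance_to_similarity(Dc) == 0))
  set.seed(1)
  D3 <- named_mat(matrix(runif(16, 0, 3), 4))
  diag(D3) <- 0
  off <- row(D3) != col(D3)
  for (tr in c("max", "reciprocal")) {
    W <- distance_to_similarity(D3, tr)
    expect_equal(order(W[off]), rev(order(D3[off])))
    expect_equal(diag(W), setNames(rep(0, 4), rownames(D3)))
  }
})

test_that("strength centralities are row and column sums", {
  W <- named_mat(c(0, 2, 1,
                   0, 0, 4,
                   3, 0, 0), 3)
  net <- symptom_network(W)
  expect_equal(unname(net$out_strength), c(3, 4, 3))
  expect_equal(unname(net$in_strength), c(3, 2, 5))
  tab <- strength_centralities(net)
  expect_equal(tab$out_strength, c(3, 4, 3))
  expect_equal(tab$in_strength, c(3, 2, 5))
  # conservation of edge mass
  expect_equal(sum(net$in_strength), sum(net$out_strength))
  # symmetric weights give in = out
  Ws <- W + t(W)
  nets <- symptom_network(Ws)
  expect_equal(nets$in_strength, nets$out_strength)
})

test_that("cluster-level collapse averages between-cluster blocks", {
  W <- named_mat(c(0, 2, 1,
                   0, 0, 4,
                   3, 0, 0), 3)
  net <- symptom_network(W)
  singletons <- setNames(1:3, rownames(W))
  cl <- cluster_level_network(net, singletons)
  expect_equal(unname(cl$weights), unname(W))
  # two clusters with uniform inter-block weight w
  W2 <- named_mat(matrix(0, 4, 4))
  W2[1:2, 3:4] <- 0.7
  W2[3:4, 1:2] <- 0.2
  lab <- setNames(c(1, 1, 2, 2), rownames(W2))
  cl2 <- cluster_level_network(symptom_network(W2), lab)
  expect_equal(unname(cl2$weights), matrix(c(0, 0.2, 0.7, 0), 2))
  expect_error(cluster_level_network(net, setNames(1:3, c("a", "b", "c"))),
               "labels")
})

test_that("consistent relabeling permutes every output", {
  set.seed(3)
  W <- named_mat(matrix(runif(25, 0, 2), 5))
  diag(W) <- 0
  net <- symptom_network(W)
  perm <- c(4, 2, 5, 1, 3)
  net_p <- symptom_network(W[perm, perm])
  expect_equal(unname(net_p$out_strength), unname(net$out_strength[perm]))
  expect_equal(unname(net_p$in_strength), unname(net$in_strength[perm]))
})

test_that("network exports write graphml, edges and centralities", {
  set.seed(4)
  W <- named_mat(matrix(runif(16, 0, 1), 4))
  diag(W) <- 0
  net <- symptom_network(W, clusters = setNames(c(1, 1, 2, 2), rownames(W)))
  dir <- file.path(tempdir(), "net")
  paths <- write_network(net, dir)
  expect_true(all(file.exists(paths)))
  g <- igraph::read_graph(file.path(dir, "network.graphml"),
                          format = "graphml")
  expect_equal(igraph::gorder(g), 4)
  expect_equal(igraph::ecount(g), 12)
})
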