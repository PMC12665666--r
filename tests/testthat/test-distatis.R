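random_distance <- function(n, seed) {
  set.seed(seed)
  x <- matrix(runif(n * 3, 0, 4), n)
  D <- as.matrix(dist(x))
  dimnames(D) <- list(paste0("S", 1:n), paste0("S", 1:n))
  D
}

test_that("cross-product transform is the double-centering of classical MDS", {
  D0 <- matrix(0, 4, 4)
  expect_equal(to_crossproduct(D0), D0)

  D <- random_distance(6, 1)
  S <- to_crossproduct(D)
  # double-centering: rows and columns sum to zero (scaling is scalar)
  expect_equal(rowSums(S), setNames(rep(0, 6), rownames(D)))
  expect_equal(colSums(S), setNames(rep(0, 6), rownames(D)))
  # leading eigenvalue normalized to 1
  expect_equal(eigen(S, symmetric = TRUE, only.values = TRUE)$values[1], 1)

  # squared distances of collinear points reproduce their Gram matrix
  x <- c(0, 1, 3)
  xc <- x - mean(x)
  Dsq <- outer(x, x, function(u, v) (u - v)^2)
  expect_equal(to_crossproduct(Dsq), outer(xc, xc) / sum(xc^2))
})

test_that("invalid distance matrices are rejected", {
  D <- random_distance(4, 2)
  A <- D; A[1, 2] <- A[1, 2] + 1
  expect_error(to_crossproduct(A), "symmetric")
  B <- D; B[1, 2] <- B[2, 1] <- -1
  expect_error(to_crossproduct(B), "non-negative")
  C <- D; diag(C) <- 1
  expect_error(to_crossproduct(C), "diagonal")
})

test_that("congruence weights are uniform for identical inputs and
          downweight an outlier", {
  S <- to_crossproduct(random_distance(5, 3))
  expect_equal(rv_coefficient(S, S), 1)
  w <- congruence_weights(list(S, S, S, S))
  expect_equal(w, rep(0.25, 4))

  S2 <- to_crossproduct(random_distance(5, 4))
  S3 <- to_crossproduct(random_distance(5, 5))
  w3 <- congruence_weights(list(a = S, b = S, c = 0.5 * S2 + 0.5 * S3))
  expect_equal(names(which.min(w3)), "c")
  expect_equal(sum(w3), 1)
  expect_true(all(w3 >= 0))
})

test_that("compromise of identical inputs is the common matrix with its own
          eigen-coordinates", {
  S <- to_crossproduct(random_distance(6, 6))
  comp <- distatis_compromise(list(S, S, S))
  expect_equal(comp$compromise, S)
  e <- eigen(S, symmetric = TRUE)
  pos <- e$values > 1e-12
  expect_equal(abs(comp$factor_scores),
               abs(e$vectors[, pos] %*% diag(sqrt(e$values[pos]))),
               ignore_attr = TRUE)
  expect_true(all(diff(comp$variance_explained) <= 1e-12))
  expect_equal(sum(comp$variance_explained), 1)
})

test_that("factor-space distances reconstruct compromise-implied distances", {
  cps <- lapply(7:9, function(s) to_crossproduct(random_distance(5, s)))
  comp <- distatis_compromise(cps)
  F_all <- comp$factor_scores
  implied <- outer(diag(comp$compromise), diag(comp$compromise), "+") -
    2 * comp$compromise
  expect_equal(as.matrix(dist(F_all))^2, implied,
               ignore_attr = TRUE, tolerance = 1e-6)
})

test_that("patient order does not matter", {
  cps <- lapply(10:13, function(s) to_crossproduct(random_distance(5, s)))
  names(cps) <- paste0("P", 1:4)
  c1 <- distatis_compromise(cps)
  perm <- c(3, 1, 4, 2)
  c2 <- distatis_compromise(cps[perm])
  expect_equal(c2$compromise, c1$compromise)
  expect_equal(c2$weights, c1$weights[perm])
  expect_equal(c2$factor_scores, c1$factor_scores)
})

test_that("bootstrap envelopes are zero-width for identical patients and
          reproducible under a fixed seed", {
  S <- to_crossproduct(random_distance(5, 20))
  cps <- list(S, S, S, S, S)
  env <- bootstrap_envelopes(cps, B = 30, seed = 99)
  expect_equal(env$lower, env$upper, tolerance = 1e-12)

  cps2 <- lapply(21:26, function(s) to_crossproduct(random_distance(5, s)))
  e1 <- bootstrap_envelopes(cps2, B = 40, seed = 123)
  e2 <- bootstrap_envelopes(cps2, B = 40, seed = 123)
  expect_identical(e1$lower, e2$lower)
  expect_identical(e1$upper, e2$upper)
  e3 <- bootstrap_envelopes(cps2, B = 40, seed = 124)
  expect_false(identical(e1$lower, e3$lower))
  expect_true(all(e1$upper >= e1$lower))
})
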