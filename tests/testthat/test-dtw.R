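test_that("interpolation inserts equidistant points and keeps originals", {
  expect_equal(interpolate_trajectory(c(0, 3), k = 5),
               c(0, 0.5, 1, 1.5, 2, 2.5, 3))
  x <- c(2, 0, 4, 1, 3, 2)
  expect_equal(interpolate_trajectory(x, k = 0), x)
  y <- interpolate_trajectory(x, k = 5)
  expect_length(y, 31)
  expect_equal(y[seq(1, 31, by = 6)], x)
  expect_error(interpolate_trajectory(x, k = -1), ">= 0")
})

test_that("local cost matrix is the pairwise absolute difference", {
  expect_equal(local_cost_matrix(c(0, 1), c(1, 0)),
               matrix(c(1, 0, 0, 1), 2, 2))
  x <- c(1, 2, 3)
  expect_equal(diag(local_cost_matrix(x, x)), c(0, 0, 0))
  expect_equal(local_cost_matrix(2, 5), matrix(3, 1, 1))
  expect_error(local_cost_matrix(1:3, 1:4), "length mismatch")
})

test_that("DP distance matches the enumeration oracle on frozen examples", {
  # oracle-computed: best path (1,1)->(1,2)->(2,2) costs 0 + 0 + 2 = 2
  r <- dtw_distance(c(0, 2), c(0, 0), band_constraint(Inf))
  expect_identical(r$raw_cost, enum_dtw(c(0, 2), c(0, 0)))
  expect_equal(r$raw_cost, 2)
  expect_equal(r$distance, 0.5)
  expect_equal(r$normalizer, 4)
})

test_that("DP equals brute-force path enumeration on random instances", {
  set.seed(42)
  for (i in 1:60) {
    n <- sample(4:8, 1)
    a <- sample(0:4, n, replace = TRUE)
    b <- sample(0:4, n, replace = TRUE)
    w <- sample(c(0:(n - 1), Inf), 1)
    got <- dtw_distance(a, b, band_constraint(w))$raw_cost
    expect_equal(got, enum_dtw(a, b, width = w), tolerance = 1e-12)
  }
})

test_that("undirected DTW is a symmetric non-negative identity-of-
          indiscernibles measure", {
  set.seed(7)
  for (i in 1:25) {
    n <- sample(4:8, 1)
    a <- runif(n, 0, 4)
    b <- runif(n, 0, 4)
    band <- band_constraint(sample(1:(n - 1), 1))
    expect_equal(dtw_distance(a, a, band)$distance, 0)
    expect_gte(dtw_distance(a, b, band)$distance, 0)
    expect_equal(dtw_distance(a, b, band)$distance,
                 dtw_distance(b, a, band)$distance)
  }
  # zero iff identical (integer-valued scores)
  a <- c(0, 1, 2, 1)
  b <- c(0, 1, 2, 2)
  expect_gt(dtw_distance(a, b, band_constraint(1))$distance, 0)
})

test_that("widening the band never increases the distance and the full
          band reaches the unconstrained optimum", {
  set.seed(11)
  for (i in 1:20) {
    n <- sample(5:8, 1)
    a <- runif(n, 0, 4)
    b <- runif(n, 0, 4)
    d <- vapply(0:(n - 1), function(w) {
      dtw_distance(a, b, band_constraint(w))$distance
    }, numeric(1))
    expect_true(all(diff(d) <= 1e-12))
    expect_equal(d[n], dtw_distance(a, b, band_constraint(Inf))$distance)
  }
})

test_that("warping paths are admissible and tie-broken deterministically", {
  set.seed(3)
  for (i in 1:10) {
    n <- sample(4:7, 1)
    a <- sample(0:4, n, replace = TRUE)
    b <- sample(0:4, n, replace = TRUE)
    r <- dtw_distance(a, b, band_constraint(Inf))
    p <- r$path
    expect_equal(p[1, ], c(1, 1))
    expect_equal(p[nrow(p), ], c(n, n))
    steps <- diff(p)
    expect_true(all(steps >= 0 & steps <= 1))
    expect_true(all(rowSums(steps) >= 1))
    # path cost re-derives the reported raw cost
    w <- ifelse(rowSums(steps) == 2, 2, 1)
    costs <- abs(a[p[, 1]] - b[p[, 2]])
    expect_equal(costs[1] + sum(w * costs[-1]), r$raw_cost)
  }
})

test_that("directed DTW detects which series leads", {
  a <- c(0, 3, 0, 0, 0, 0)
  b <- c(0, 0, 3, 0, 0, 0)
  expect_equal(directed_dtw_distance(a, a)$distance, 0)
  d_ab <- directed_dtw_distance(a, b)$distance
  d_ba <- directed_dtw_distance(b, a)$distance
  expect_lt(d_ab, d_ba)
  # the gap reverses sign when the arguments swap
  expect_equal(d_ab - d_ba, -(d_ba - d_ab))
})

test_that("directed DP matches the forward-constrained enumeration oracle", {
  set.seed(17)
  for (i in 1:40) {
    n <- sample(4:6, 1)
    a <- sample(0:4, n, replace = TRUE)
    b <- sample(0:4, n, replace = TRUE)
    w <- sample(c(0:(n - 1), Inf), 1)
    got <- directed_dtw_distance(a, b, band_constraint(w, "forward"))$raw_cost
    expect_equal(got, enum_dtw(a, b, width = w, forward = TRUE),
                 tolerance = 1e-12)
  }
})

test_that("per-patient matrices have the documented structure", {
  cfg <- simulation_config(n_patients = 2, seed = 5)
  panel <- generate_panel(cfg)$panel
  pm <- patient_matrices(panel, "P001")
  expect_equal(dim(pm$symmetric), c(32, 32))
  expect_equal(dim(pm$directed), c(32, 32))
  expect_equal(pm$symmetric, t(pm$symmetric))
  expect_equal(diag(pm$symmetric), setNames(rep(0, 32), panel_symptoms(panel)))
  expect_equal(diag(pm$directed), setNames(rep(0, 32), panel_symptoms(panel)))
  expect_true(all(pm$symmetric >= 0) && all(pm$directed >= 0))
  expect_equal(sum(upper.tri(pm$symmetric)), 496)

  # a duplicated trajectory gives zero distance in both matrices
  sc <- panel$scores
  sc[, "S02", ] <- sc[, "S01", ]
  dup <- symptom_panel(sc, panel$observed, panel$symptoms)
  pm2 <- patient_matrices(dup, "P001")
  expect_equal(pm2$symmetric["S01", "S02"], 0)
  expect_equal(pm2$directed["S01", "S02"], 0)
  expect_equal(pm2$directed["S02", "S01"], 0)
})

test_that("band width declared in visits converts to interpolated cells", {
  cfg <- simulation_config(n_patients = 1, seed = 9)
  panel <- generate_panel(cfg)$panel
  pm <- patient_matrices(panel, "P001", band_width = 1, k = 5)
  t1 <- interpolate_trajectory(panel$scores["P001", "S01", ], 5)
  t2 <- interpolate_trajectory(panel$scores["P001", "S07", ], 5)
  manual <- dtw_distance(t1, t2, band_constraint(1), cells_per_visit = 6)
  expect_equal(pm$symmetric["S01", "S07"], manual$distance)
  manual_dir <- directed_dtw_distance(t1, t2, band_constraint(1, "forward"),
                                      cells_per_visit = 6)
  expect_equal(pm$directed["S01", "S07"], manual_dir$distance)
})

test_that("incomplete patients are rejected with a pointer to the filter", {
  cfg <- simulation_config(n_patients = 6, seed = 4, n_complete = 3)
  panel <- generate_panel(cfg)$panel
  bad <- panel_patients(panel)[rowSums(panel$observed) < 6][1]
  expect_error(patient_matrices(panel, bad), "filter_complete")
  expect_error(cohort_matrices(panel), "filter_complete")
})
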