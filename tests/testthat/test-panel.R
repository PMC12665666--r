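test_that("item scores are the mean of the three ratings", {
  expect_equal(score_item(TRUE, 3, 2, 4), 3)
  expect_equal(score_item(TRUE, 1, 1, 0), 2 / 3)
  expect_equal(score_item(FALSE), 0)
  # vectorized, mixed presence
  expect_equal(score_item(c(TRUE, FALSE, TRUE), c(4, NA, 2), c(4, NA, 3),
                          c(4, NA, 1)),
               c(4, 0, 2))
})

test_that("rating validation names the offending field", {
  expect_error(score_item(TRUE, 5, 2, 2), "frequency")
  expect_error(score_item(TRUE, 2, 0, 2), "severity")
  expect_error(score_item(TRUE, 2, 2, 5), "distress")
  expect_error(score_item(FALSE, 2, NA, NA), "non-endorsed")
  expect_error(score_item(TRUE, NA, 2, 2), "missing")
})

make_long <- function() {
  g <- expand.grid(symptom_id = c("S01", "S02"), visit_index = 0:5,
                   patient_id = "P1", stringsAsFactors = FALSE)
  g$score <- round((seq_len(nrow(g)) %% 5) * 0.8, 3)
  g
}

test_that("long and wide layouts produce identical panels", {
  long <- make_long()
  p_long <- read_panel(long, "long", symptoms = toy_catalogue(2))
  expect_equal(dim(p_long$scores), c(1, 2, 6))
  expect_equal(sum(!is.na(p_long$scores)), 12)

  wide <- write_panel(p_long, layout = "wide")
  p_wide <- read_panel(wide, "wide", symptoms = toy_catalogue(2))
  expect_equal(p_wide$scores, p_long$scores)
  expect_equal(p_wide$observed, p_long$observed)
})

test_that("panel round-trips through both serialized layouts", {
  cfg <- simulation_config(n_patients = 4, seed = 2,
                           missing_visit_prob = 0.2)
  panel <- generate_panel(cfg)$panel
  for (layout in c("long", "wide")) {
    path <- file.path(tempdir(), paste0("panel_", layout, ".csv"))
    write_panel(panel, path, layout = layout)
    back <- read_panel(path, layout)
    expect_equal(back$scores, panel$scores)
    expect_equal(unname(back$observed), unname(panel$observed))
  }
})

test_that("malformed tables are rejected", {
  long <- make_long()
  expect_error(read_panel(rbind(long, long[1, ]), "long",
                          symptoms = toy_catalogue(2)), "duplicate")
  bad <- long
  bad$symptom_id[1] <- "S99"
  expect_error(read_panel(bad, "long", symptoms = toy_catalogue(2)),
               "S99.*catalogue|catalogue.*S99")
  bad <- long
  bad$visit_index[1] <- 7
  expect_error(read_panel(bad, "long", symptoms = toy_catalogue(2)),
               "visit")
})

test_that("symptoms without rows at an observed visit score zero", {
  long <- make_long()
  long <- long[!(long$symptom_id == "S02" & long$visit_index == 3), ]
  p <- read_panel(long, "long", symptoms = toy_catalogue(2))
  expect_true(p$observed[1, 4])
  expect_equal(p$scores["P1", "S02", 4], 0)
})

test_that("completeness filter keeps exactly the fully observed patients", {
  mk <- function(...) matrix(1, 2, 6)
  obs <- rbind(rep(TRUE, 6), rep(TRUE, 6), c(rep(TRUE, 5), FALSE))
  rownames(obs) <- c("A", "B", "C")
  sc <- list(A = mk(), B = mk(), C = mk())
  sc$C[, 6] <- NA
  panel <- toy_panel(sc, obs)
  kept <- filter_complete(panel)
  expect_equal(panel_patients(kept), c("A", "B"))
  # idempotent
  expect_equal(filter_complete(kept), kept)
  # identity when all complete
  all_ok <- toy_panel(list(A = mk(), B = mk()))
  expect_equal(filter_complete(all_ok), all_ok)
  # explicit error when nothing survives
  none <- toy_panel(list(C = sc$C), obs["C", , drop = FALSE])
  expect_error(filter_complete(none), "no complete cases")
})

test_that("panel validation enforces the score range and mask consistency", {
  bad <- matrix(5, 2, 6)
  expect_error(toy_panel(list(A = bad)), "\\[0, 4\\]")
  sc <- matrix(1, 2, 6)
  sc[1, 2] <- NA
  obs <- matrix(TRUE, 1, 6, dimnames = list("A", NULL))
  expect_error(toy_panel(list(A = sc), obs), "observed")
})
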