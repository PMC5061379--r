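test_that("fold increase divides by the same-plate cell-control median", {
  expect_equal(fold_increase(300, c(100, 100, 120)), 3)
  expect_equal(fold_increase(100, c(100, 100, 120)), 1)   # value = median
  expect_equal(fold_increase(c(50, 200), c(100, 100)), c(0.5, 2))
  expect_error(fold_increase(10, c(NA, NA)), "no non-missing")
  expect_error(fold_increase(10, c(0, 0)), "must be > 0")
})

test_that("viability is anchored at the control medians", {
  v <- viability(150, hyamine_values = c(50, 50),
                 cell_control_values = c(250, 250))
  expect_equal(v$percent, 50)
  expect_equal(v$fraction, 0.5)
  expect_equal(viability(50, c(50, 50), c(250, 250))$percent, 0)    # Hyamine
  expect_equal(viability(250, c(50, 50), c(250, 250))$percent, 100) # cell ctrl
  # below the Hyamine median: negative, reported not clipped
  expect_lt(viability(20, c(50, 50), c(250, 250))$percent, 0)
  expect_error(viability(10, c(5, 5), c(5, 5)), "degenerate")
})

test_that("normalized fold increase guards the viability floor but keeps the raw ratio", {
  expect_equal(normalized_fold_increase(2, 1)$normalized_fold_increase, 2)
  expect_equal(normalized_fold_increase(2, 0.5)$normalized_fold_increase, 4)
  low <- normalized_fold_increase(2, 0.05)
  expect_true(is.na(low$normalized_fold_increase))
  expect_equal(low$normalized_fold_increase_raw, 40)
})

test_that("score_plate reproduces the noiseless null and hit propagation", {
  layout <- plate_layout(96)
  sim <- simulate_plate(plate_sim_spec(layout = layout, cv = 0, seed = 1))
  scores <- score_plate(layout, sim$immunostain, sim$viability)
  test_rows <- scores$role == "test"
  expect_true(all(scores$fold_increase[test_rows] == 1))
  expect_true(all(scores$viability_percent[test_rows] == 100))
  expect_true(all(scores$normalized_fold_increase[test_rows] == 1))
})

test_that("normalization identities hold exactly on stochastic plates", {
  for (seed in 1:3) {
    sim <- simulate_plate(plate_sim_spec(384, cv = 0.1, seed = seed))
    scores <- score_plate(sim$layout, sim$immunostain, sim$viability)
    cc_med_stain <- attr(scores, "cell_control_median_stain")
    expect_equal(fold_increase(cc_med_stain,
                               scores$stain_value[scores$role == "cell_control"]),
                 1)
    cc_med_v <- attr(scores, "cell_control_median_viab")
    hy_med_v <- attr(scores, "hyamine_median_viab")
    hy <- scores$viab_value[scores$role == "viability_control"]
    cc <- scores$viab_value[scores$role == "cell_control"]
    expect_equal(viability(cc_med_v, hy, cc)$percent, 100)
    expect_equal(viability(hy_med_v, hy, cc)$percent, 0)
  }
})

test_that("fold increase is scale-invariant and normalization is plate-local", {
  sim <- simulate_plate(plate_sim_spec(96, cv = 0.08, seed = 9))
  scores <- score_plate(sim$layout, sim$immunostain, sim$viability)
  scaled <- sim$immunostain; scaled$value <- scaled$value * 7
  scores7 <- score_plate(sim$layout, scaled, sim$viability)
  expect_equal(scores7$fold_increase, scores$fold_increase)
  # permuting wells within the plate permutes scores identically
  perm <- sample(nrow(sim$immunostain))
  shuffled <- sim$immunostain[perm, ]
  scores_p <- score_plate(sim$layout, shuffled, sim$viability)
  expect_equal(scores_p$fold_increase, scores$fold_increase)
})

test_that("wells missing a read are flagged and excluded from control medians", {
  layout <- plate_layout(96)
  sim <- simulate_plate(plate_sim_spec(layout = layout, cv = 0, seed = 2))
  drop_well <- layout$well[layout$role == "test"][1]
  stain <- sim$immunostain[sim$immunostain$well != drop_well, ]
  expect_message(scores <- score_plate(layout, stain, sim$viability),
                 "flagged")
  row <- scores[scores$well == drop_well, ]
  expect_true(is.na(row$fold_increase))
  expect_equal(row$flag, "missing_stain")
  # every other well scores as before
  others <- scores$well != drop_well
  ref <- score_plate(layout, sim$immunostain, sim$viability)
  expect_equal(scores$fold_increase[others], ref$fold_increase[others])
})
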