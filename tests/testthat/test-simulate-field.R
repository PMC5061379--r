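test_that("noiseless painting is exact: compartment means equal nominal intensities", {
  spec <- image_sim_spec(field_shape = c(96, 96), n_cells = 3, seed = 11)
  sim <- simulate_field(spec)
  expect_equal(sim$truth$mean_pm, rep(spec$intensity_pm, 3))
  expect_equal(sim$truth$mean_perinuclear, rep(spec$intensity_perinuclear, 3))
  # total is the area-weighted mix of the painted compartments
  t <- sim$truth
  a_cyto <- t$area_total - t$area_pm - t$area_perinuclear
  mix <- (t$area_pm * spec$intensity_pm +
            t$area_perinuclear * spec$intensity_perinuclear +
            a_cyto * spec$intensity_cytoplasm) / t$area_total
  expect_equal(t$mean_total, mix)
  # and the painted image agrees with the recorded truth inside each mask
  pm_px <- sim$field$target[sim$cell_labels > 0 &
                              sim$field$target == spec$intensity_pm]
  expect_gt(length(pm_px), 0)
})

test_that("different seeds move cell centers but not ground-truth means", {
  spec1 <- image_sim_spec(field_shape = c(128, 128), n_cells = 4, seed = 1)
  spec2 <- image_sim_spec(field_shape = c(128, 128), n_cells = 4, seed = 2)
  s1 <- simulate_field(spec1); s2 <- simulate_field(spec2)
  expect_false(identical(s1$truth[, c("row", "col")],
                         s2$truth[, c("row", "col")]))
  expect_equal(s1$truth$mean_pm, s2$truth$mean_pm)
  expect_equal(s1$truth$mean_perinuclear, s2$truth$mean_perinuclear)
  expect_equal(s1$truth$mean_total, s2$truth$mean_total)
})

test_that("placement never overlaps and never silently drops cells", {
  spec <- image_sim_spec(field_shape = c(256, 256), n_cells = 50,
                         nucleus_radius = 4, cell_radius = 7, seed = 5)
  sim <- simulate_field(spec)
  expect_equal(nrow(sim$truth), 50)
  d <- as.matrix(dist(sim$truth[, c("row", "col")]))
  diag(d) <- Inf
  expect_true(all(d >= 2 * spec$cell_radius + 1))
  # no painted cell touches the field border
  border <- c(sim$cell_labels[1, ], sim$cell_labels[256, ],
              sim$cell_labels[, 1], sim$cell_labels[, 256])
  expect_true(all(border == 0))
})

test_that("an impossible placement raises a named error", {
  spec <- image_sim_spec(field_shape = c(48, 48), n_cells = 40,
                         nucleus_radius = 4, cell_radius = 7, seed = 1)
  expect_error(simulate_field(spec), "non-overlapping")
})

test_that("simulation is bit-reproducible and noise leaves ground truth unchanged", {
  spec <- image_sim_spec(field_shape = c(96, 96), n_cells = 3, noise_sd = 25,
                         seed = 42)
  a <- simulate_field(spec); b <- simulate_field(spec)
  expect_identical(a$field$target, b$field$target)
  quiet <- image_sim_spec(field_shape = c(96, 96), n_cells = 3, noise_sd = 0,
                          seed = 42)
  q <- simulate_field(quiet)
  expect_identical(a$truth, q$truth)
  expect_identical(a$cell_labels, q$cell_labels)
  expect_false(identical(a$field$target, q$field$target))
  expect_true(all(a$field$target >= 0))  # additive noise clipped at zero
})

test_that("spec invariants are enforced at construction", {
  expect_error(image_sim_spec(nucleus_radius = 5, cell_radius = 5), "exceed")
  expect_error(image_sim_spec(intensity_pm = -1), ">= 0")
  expect_error(image_sim_spec(noise_sd = -1), ">= 0")
})

test_that("fields round-trip through 16-bit multi-page TIFF exactly", {
  sim <- simulate_field(image_sim_spec(field_shape = c(64, 64), n_cells = 1,
                                       seed = 9))
  path <- withr::local_tempfile(fileext = ".tif")
  write_field_tiff(sim$field, path)
  back <- read_field_tiff(path, well_id = "A01")
  expect_equal(back$nuclear, sim$field$nuclear)
  expect_equal(back$target, sim$field$target)
})

test_that("a well of fields is reproducible from one seed and fields differ", {
  spec <- image_sim_spec(field_shape = c(96, 96), n_cells = 2, seed = 3)
  w1 <- simulate_image_well(spec, "B02", n_fields = 3)
  w2 <- simulate_image_well(spec, "B02", n_fields = 3)
  expect_identical(lapply(w1, `[[`, "truth"), lapply(w2, `[[`, "truth"))
  expect_false(identical(w1[[1]]$truth$row, w1[[2]]$truth$row))
  expect_equal(vapply(w1, function(f) f$field$field_index, integer(1)), 0:2)
})
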