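test_that("noiseless synthetic compartments are recovered exactly", {
  spec <- image_sim_spec(field_shape = c(160, 160), n_cells = 5,
                         intensity_pm = 500, intensity_perinuclear = 300,
                         intensity_cytoplasm = 100, seed = 17)
  sim <- simulate_field(spec)
  masks <- segmentation_masks(sim$nucleus_labels, sim$cell_labels)
  rec <- measure_cells(sim$field, masks)
  expect_equal(nrow(rec), 5)
  expect_equal(rec$mean_pm, sim$truth$mean_pm)
  expect_equal(rec$mean_perinuclear, sim$truth$mean_perinuclear)
  expect_equal(rec$mean_total, sim$truth$mean_total)
  expect_equal(rec$area_total, sim$truth$area_total)
  expect_equal(rec$integrated_total, rec$mean_total * rec$area_total)
})

test_that("a uniform target channel gives every compartment the same mean", {
  sim <- simulate_field(image_sim_spec(field_shape = c(96, 96), n_cells = 2,
                                       seed = 4))
  f <- sim$field
  f$target <- matrix(42, 96, 96)
  masks <- segmentation_masks(sim$nucleus_labels, sim$cell_labels)
  rec <- measure_cells(f, masks)
  expect_true(all(rec$mean_pm == 42 & rec$mean_perinuclear == 42 &
                    rec$mean_total == 42))
})

test_that("a field with zero cells yields an empty record table", {
  empty <- matrix(0L, 30, 30)
  masks <- segmentation_masks(empty, empty)
  rec <- measure_cells(as_field(matrix(5, 30, 30)), masks)
  expect_equal(nrow(rec), 0)
})

test_that("cells touching the field border are excluded and counted", {
  cell <- matrix(0L, 20, 20)
  cell[1:6, 1:6] <- 1L          # touches border
  cell[10:15, 10:15] <- 2L
  nuc <- matrix(0L, 20, 20); nuc[3:4, 3:4] <- 1L; nuc[12:13, 12:13] <- 2L
  masks <- segmentation_masks(nuc, cell)
  expect_message(rec <- measure_cells(as_field(matrix(1, 20, 20)), masks),
                 "border")
  expect_equal(rec$cell_id, 2L)
  expect_equal(attr(rec, "n_border_excluded"), 1L)
  rec_all <- measure_cells(as_field(matrix(1, 20, 20)), masks,
                           exclude_border = FALSE)
  expect_equal(rec_all$cell_id, c(1L, 2L))
})

test_that("an empty compartment is reported missing, never zero", {
  # nucleus fills the whole cell: the perinuclear ring is empty
  cell <- matrix(0L, 12, 12); cell[4:7, 4:7] <- 1L
  masks <- segmentation_masks(cell, cell)
  rec <- measure_cells(as_field(matrix(10, 12, 12)), masks)
  expect_true(is.na(rec$mean_perinuclear))
  expect_equal(rec$area_perinuclear, 0L)
  expect_equal(rec$mean_total, 10)
})

test_that("well summaries pool cells with equal weight, not field means", {
  a <- data.frame(mean_pm = 100, mean_perinuclear = 100, mean_total = 100)
  b <- data.frame(mean_pm = c(200, 200), mean_perinuclear = c(200, 200),
                  mean_total = c(200, 200))
  s <- summarize_well(list(a, b), "C03")
  expect_equal(s$mean_total, 500 / 3)       # 166.67, not 175
  expect_equal(s$n_cells, 3)
  # single field: equals that field's cell mean
  expect_equal(summarize_well(b, "C03")$mean_total, 200)
  # duplicated fields: same mean, doubled count
  dup <- summarize_well(list(b, b), "C03")
  expect_equal(dup$mean_total, 200)
  expect_equal(dup$n_cells, 4)
})

test_that("missing compartment means are excluded from pooling; empty wells are NA", {
  recs <- data.frame(mean_pm = c(10, NA, 30),
                     mean_perinuclear = c(NA, NA, NA),
                     mean_total = c(1, 2, 3))
  s <- summarize_well(recs, "D04")
  expect_equal(s$mean_pm, 20)
  expect_true(is.na(s$mean_perinuclear))
  none <- summarize_well(recs[0, ], "D05")
  expect_equal(none$n_cells, 0)
  expect_true(is.na(none$mean_total))
})

test_that("measured means converge to painted values under noise", {
  spec <- image_sim_spec(field_shape = c(200, 200), n_cells = 8,
                         noise_sd = 40, seed = 23)
  sim <- simulate_field(spec)
  masks <- segmentation_masks(sim$nucleus_labels, sim$cell_labels)
  rec <- measure_cells(sim$field, masks)
  s <- summarize_well(rec, "E05")
  # tolerance 3 * sd / sqrt(total compartment pixels)
  tol <- function(area) 3 * spec$noise_sd / sqrt(sum(area))
  expect_lt(abs(s$mean_pm - spec$intensity_pm), tol(rec$area_pm))
  expect_lt(abs(s$mean_perinuclear - spec$intensity_perinuclear),
            tol(rec$area_perinuclear))
})

test_that("quantify_well chains segmentation and measurement over fields", {
  spec <- image_sim_spec(field_shape = c(128, 128), n_cells = 4, seed = 19)
  fields <- lapply(simulate_image_well(spec, "F06", n_fields = 2), `[[`,
                   "field")
  s <- quantify_well(fields, "F06")
  expect_equal(s$n_cells, 8)
  expect_equal(s$mean_pm, spec$intensity_pm)
  expect_equal(s$mean_perinuclear, spec$intensity_perinuclear)
})
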