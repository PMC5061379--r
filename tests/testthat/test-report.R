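simulate_screen_scores <- function(n_plates = 2, cv = 0.07, hit_ids = numeric(0),
                                   seed = 1, plate_format = 96) {
  tabs <- lapply(seq_len(n_plates), function(p) {
    layout <- plate_layout(plate_format, plate_id = sprintf("plate%02d", p))
    sim <- simulate_plate(plate_sim_spec(layout = layout, cv = cv,
                                         hit_ids = hit_ids,
                                         seed = seed + p - 1))
    list(scores = as.data.frame(score_plate(layout, sim$immunostain,
                                            sim$viability)),
         truth = sim$truth)
  })
  list(scores = do.call(rbind, lapply(tabs, `[[`, "scores")),
       truth = do.call(rbind, lapply(tabs, `[[`, "truth")))
}

test_that("an end-to-end noiseless screen recovers exactly the spiked hits", {
  layout <- plate_layout(384)
  cpds <- layout$compound_id[layout$role == "test"]
  spiked <- setNames(rep(3, 4), cpds[c(10, 80, 200, 311)])
  sc <- simulate_screen_scores(n_plates = 1, cv = 0, hit_ids = spiked,
                               plate_format = 384)
  report <- screen_report(sc$scores)
  ht <- report$hits$normalized_fold_increase$table
  expect_setequal(ht$compound_id[ht$is_hit], names(spiked))
  # zero-variance but separated controls are the perfect-assay limit: z = 1
  expect_identical(report$zfactors$z, 1)
  expect_identical(report$zfactors$error, "")
  # truly degenerate controls (no separation) become a per-plate error entry
  broken <- sc$scores
  broken$stain_value[broken$role == "positive_control"] <-
    broken$stain_value[broken$role == "cell_control"][1]
  broken$stain_value[broken$role == "cell_control"] <-
    broken$stain_value[broken$role == "cell_control"][1]
  rep2 <- screen_report(broken)
  expect_match(rep2$zfactors$error, "undefined separation")
  expect_true(is.na(rep2$zfactors$z))
  expect_null(rep2$z_aggregate)
})

test_that("a stochastic two-plate screen reports Z mean +/- SEM and is seed-stable", {
  sc <- simulate_screen_scores(n_plates = 2, cv = 0.07, seed = 5)
  r1 <- screen_report(sc$scores)
  r2 <- screen_report(simulate_screen_scores(n_plates = 2, cv = 0.07,
                                             seed = 5)$scores)
  expect_equal(r1$zfactors$z, r2$zfactors$z)
  expect_equal(r1$z_aggregate$mean, mean(r1$zfactors$z))
  expect_equal(r1$z_aggregate$sem,
               sd(r1$zfactors$z) / sqrt(nrow(r1$zfactors)))
  expect_equal(r1$z_aggregate$n, 2)
})

test_that("requesting a readout absent from the scores is a named error", {
  sc <- simulate_screen_scores(n_plates = 1)
  expect_error(screen_report(sc$scores, readouts = "mean_pm"), "mean_pm")
})

test_that("screen reports serialize and re-read losslessly", {
  sc <- simulate_screen_scores(n_plates = 2, cv = 0.07, seed = 8)
  report <- screen_report(sc$scores, metadata = list(seed = 8))
  d <- withr::local_tempdir()
  write_screen_report(report, d)
  expect_true(all(file.exists(file.path(d, c(
    "report.json", "zfactors.tsv",
    "hits_fold_increase.tsv", "hits_normalized_fold_increase.tsv")))))
  back <- read_screen_report(d)
  expect_equal(back$zfactors$z, report$zfactors$z)
  expect_equal(back$z_aggregate$mean, report$z_aggregate$mean)
  for (r in names(report$hits)) {
    expect_equal(back$hits[[r]]$threshold, report$hits[[r]]$threshold)
    expect_equal(back$hits[[r]]$table$is_hit, report$hits[[r]]$table$is_hit)
  }
  expect_equal(back$metadata$seed, 8)
})

test_that("imaging-arm well summaries feed the same report machinery", {
  layout <- plate_layout(96)
  wells <- layout$well[layout$role %in% c("test", "positive_control",
                                          "cell_control")][1:30]
  withr::local_seed(44)
  scores <- data.frame(
    plate_id = "imgplate", well = wells,
    role = layout$role[match(wells, layout$well)],
    compound_id = layout$compound_id[match(wells, layout$well)],
    mean_pm = rnorm(30, 100, 5), mean_total = rnorm(30, 200, 5)
  )
  scores$mean_total[scores$role == "positive_control"] <- rnorm(
    sum(scores$role == "positive_control"), 400, 5)
  report <- screen_report(scores, readouts = c("mean_pm", "mean_total"),
                          z_value_col = "mean_total")
  expect_gt(report$zfactors$z, 0)
  expect_named(report$hits, c("mean_pm", "mean_total"))
})
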