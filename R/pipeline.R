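#' Run the simulated screen end to end
#'
#' Chains the two arms from one configuration: simulates `n_plates`
#' 384- or 96-well plates (with any configured spiked hits), scores every
#' plate against its in-plate controls, and assembles the [screen_report()];
#' optionally simulates and quantifies a few imaging wells as well. All
#' intermediate tables, the report directory and a run manifest (package
#' version, config hash, seeds) are written under `config$out_dir`.
#' Deterministic for a fixed `config$seed`: plate `p` uses seed
#' `seed + p - 1`, the imaging arm `seed + 10000 + well index`.
#'
#' @param config A `run_config` from [load_config()].
#' @param quiet Suppress progress messages.
#' @return The `screen_report`, invisibly, with the stacked score table as
#'   `attr(, "scores")` and the truth tables as `attr(, "truth")`.
#' @export
#' @examples
#' \donttest{
#' cfg <- load_config(overrides = list(plate_format = 96,
#'                                     out_dir = tempfile()))
#' rep <- run_pipeline(cfg, quiet = TRUE)
#' }
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message(...)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  hit_ids <- unlist(config$hit_ids)
  all_scores <- list(); all_truth <- list()
  for (p in seq_len(config$n_plates)) {
    pid <- sprintf("plate%02d", p)
    layout <- plate_layout(config$plate_format, plate_id = pid)
    spec <- plate_sim_spec(layout = layout, cv = config$cv,
                           hit_ids = hit_ids,
                           seed = config$seed + p - 1L)
    sim <- simulate_plate(spec)
    scores <- score_plate(layout, sim$immunostain, sim$viability,
                          viability_floor = config$viability_floor,
                          plate_id = pid)
    write_scores_tsv(scores, file.path(config$out_dir,
                                       paste0("scores_", pid, ".tsv")))
    write_layout_csv(layout, file.path(config$out_dir,
                                       paste0("layout_", pid, ".csv")))
    all_scores[[p]] <- scores
    all_truth[[p]] <- cbind(plate_id = pid, sim$truth)
    say("scored ", pid, " (", sum(layout$role == "test"), " test wells)")
  }
  scores <- do.call(rbind, lapply(all_scores, as.data.frame))
  truth <- do.call(rbind, all_truth)

  image_summaries <- NULL
  if (config$image_wells > 0) {
    image_summaries <- do.call(rbind, lapply(seq_len(config$image_wells),
                                             function(w) {
      wid <- well_ids(config$plate_format)[w]
      spec <- image_sim_spec(n_cells = config$image_n_cells,
                             seed = config$seed + 10000L + w)
      fields <- lapply(simulate_image_well(spec, well_id = wid,
                                           n_fields = config$fields_per_well),
                       `[[`, "field")
      quantify_well(fields, wid,
                    nuclear_threshold = config$nuclear_threshold,
                    cyto_threshold = config$cyto_threshold,
                    pm_width = config$pm_width,
                    perinuclear_width = config$perinuclear_width,
                    min_nucleus_area = config$min_nucleus_area)
    }))
    utils::write.table(image_summaries,
                       file.path(config$out_dir, "well_summaries.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    say("quantified ", config$image_wells, " imaging well(s)")
  }

  cfg_file <- file.path(config$out_dir, "config.yaml")
  save_config(config, cfg_file)
  # hash the configuration minus its I/O paths, so identical analyses hash
  # identically wherever their outputs land
  hash_file <- tempfile(fileext = ".yaml")
  save_config(config[setdiff(names(config), "out_dir")], hash_file)
  report <- screen_report(scores, k = config$k,
                          metadata = list(seed = config$seed,
                                          config_hash = unname(tools::md5sum(hash_file)),
                                          viability_floor = config$viability_floor))
  write_screen_report(report, file.path(config$out_dir, "report"))
  jsonlite::write_json(report$metadata,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  say("report written to ", file.path(config$out_dir, "report"))

  attr(report, "scores") <- scores
  attr(report, "truth") <- truth
  if (!is.null(image_summaries)) attr(report, "image_summaries") <- image_summaries
  invisible(report)
}
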