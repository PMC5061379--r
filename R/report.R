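#' Screen-level report: per-plate Z factors and hit tables
#'
#' Bundles quality control and hit calling for a whole screen. `scores` is a
#' stacked table of per-well results across plates — either plate-arm
#' [score_plate()] outputs or imaging-arm well summaries joined to a layout —
#' with columns `plate_id`, `well`, `role`, `compound_id`, the readout
#' columns to call hits on, and a raw-value column for the Z factor. Per
#' plate, the Z factor contrasts the designated positive and negative roles;
#' a plate whose controls are degenerate (e.g. zero separation) is reported
#' as an error entry rather than a number. Hits are called per readout over
#' test wells only.
#'
#' @param scores Data frame as described above (stack per-plate tables with
#'   `rbind`).
#' @param readouts Character vector of score columns to call hits on
#'   (default the plate-arm readouts).
#' @param k SD multiplier for [call_hits()].
#' @param z_value_col Column holding the raw values used for the Z factor
#'   (default `"stain_value"`; use e.g. `"mean_total"` for the imaging arm).
#' @param z_roles Length-2 named character vector mapping `pos`/`neg` to
#'   layout roles.
#' @param metadata Optional named list (seeds, thresholds, ...) stored in
#'   the report.
#' @return An object of class `screen_report`: list with `zfactors` (data
#'   frame: `plate_id`, `mu_pos`, `mu_neg`, `sd_pos`, `sd_neg`, `z`,
#'   `error`), `z_aggregate` (from [aggregate_z()], or `NULL` when no plate
#'   yielded a Z), `hits` (named list of [call_hits()] results) and
#'   `metadata` (includes package version and `k`).
#' @export
screen_report <- function(scores,
                          readouts = c("fold_increase",
                                       "normalized_fold_increase"),
                          k = 3,
                          z_value_col = "stain_value",
                          z_roles = c(pos = "positive_control",
                                      neg = "cell_control"),
                          metadata = list()) {
  need <- c("plate_id", "well", "role", "compound_id", z_value_col)
  .check(all(need %in% names(scores)),
         "scores is missing column(s): %s",
         paste(setdiff(need, names(scores)), collapse = ", "))
  missing_readouts <- setdiff(readouts, names(scores))
  .check(length(missing_readouts) == 0,
         "requested readout(s) absent from scores: %s",
         paste(missing_readouts, collapse = ", "))

  zrows <- lapply(unique(scores$plate_id), function(pid) {
    p <- scores[scores$plate_id == pid, ]
    pos <- p[[z_value_col]][p$role == z_roles[["pos"]]]
    neg <- p[[z_value_col]][p$role == z_roles[["neg"]]]
    res <- tryCatch(z_factor(pos, neg, plate_id = pid), error = identity)
    if (inherits(res, "error")) {
      data.frame(plate_id = pid, mu_pos = NA_real_, mu_neg = NA_real_,
                 sd_pos = NA_real_, sd_neg = NA_real_, z = NA_real_,
                 error = conditionMessage(res))
    } else {
      data.frame(plate_id = pid, mu_pos = res$mu_pos, mu_neg = res$mu_neg,
                 sd_pos = res$sd_pos, sd_neg = res$sd_neg, z = res$z,
                 error = "")
    }
  })
  zfactors <- do.call(rbind, zrows)
  z_aggregate <- if (any(!is.na(zfactors$z))) aggregate_z(zfactors$z) else NULL

  test <- scores[scores$role == "test", ]
  hits <- setNames(lapply(readouts, function(r) {
    call_hits(setNames(test[[r]], test$compound_id), k = k, readout_name = r)
  }), readouts)

  metadata <- c(metadata,
                list(k = k, z_value_col = z_value_col,
                     package_version = as.character(packageVersion("cftrscreen")),
                     n_plates = nrow(zfactors), n_test_wells = nrow(test)))
  structure(list(zfactors = zfactors, z_aggregate = z_aggregate,
                 hits = hits, metadata = metadata),
            class = "screen_report")
}

#' @export
print.screen_report <- function(x, ...) {
  cat("Screen report:", x$metadata$n_plates, "plate(s),",
      x$metadata$n_test_wells, "test wells\n")
  if (!is.null(x$z_aggregate)) {
    cat(sprintf("Z factor: %.3f +/- %s (mean +/- SEM, n = %d)\n",
                x$z_aggregate$mean,
                if (is.na(x$z_aggregate$sem)) "NA"
                else sprintf("%.3f", x$z_aggregate$sem),
                x$z_aggregate$n))
  }
  for (h in x$hits) {
    cat(sprintf("  %s: %d hit(s) above mean + %g SD\n",
                h$readout_name, sum(h$table$is_hit), h$k))
  }
  invisible(x)
}

#' Serialize a screen report to a directory
#'
#' Writes `report.json` (machine-readable, full precision), one
#' `hits_<readout>.tsv` per readout, and `zfactors.tsv`.
#' `read_screen_report` restores the report from `report.json` losslessly.
#'
#' @param report A `screen_report`.
#' @param dir Output directory (created if needed).
#' @return `dir` (write) or a `screen_report` (read), invisibly for write.
#' @export
write_screen_report <- function(report, dir) {
  stopifnot(inherits(report, "screen_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ser <- list(
    zfactors = report$zfactors,
    z_aggregate = report$z_aggregate,
    hits = lapply(report$hits, unclass),
    metadata = report$metadata
  )
  jsonlite::write_json(ser, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       dataframe = "columns")
  utils::write.table(report$zfactors, file.path(dir, "zfactors.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  for (h in report$hits) {
    utils::write.table(h$table,
                       file.path(dir, paste0("hits_", h$readout_name, ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}

#' @rdname write_screen_report
#' @export
read_screen_report <- function(dir) {
  path <- file.path(dir, "report.json")
  .check(file.exists(path), "no report.json under %s", dir)
  ser <- jsonlite::read_json(path, simplifyVector = TRUE)
  ser$zfactors <- as.data.frame(ser$zfactors)
  if (is.null(ser$zfactors$error)) ser$zfactors$error <- ""
  ser$hits <- lapply(ser$hits, function(h) {
    h$table <- as.data.frame(h$table)
    structure(h, class = "hit_table")
  })
  structure(list(zfactors = ser$zfactors, z_aggregate = ser$z_aggregate,
                 hits = ser$hits, metadata = ser$metadata),
            class = "screen_report")
}
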