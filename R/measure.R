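# Mean of target intensities per label over a label matrix; NA where a label
# has no pixels.
.label_means <- function(target, labels, ids) {
  vals <- tapply(target[labels > 0], labels[labels > 0], mean)
  m <- match(as.character(ids), names(vals))
  out <- rep(NA_real_, length(ids))
  out[!is.na(m)] <- as.numeric(vals[m[!is.na(m)]])
  out
}

.label_areas <- function(labels, ids) {
  areas <- tabulate(labels[labels > 0], nbins = max(ids, 0L))
  if (!length(ids)) return(integer(0))
  areas[ids]
}

#' Per-cell compartment measurements
#'
#' For every segmented cell, computes the arithmetic mean of the target
#' channel over the plasma-membrane ring, perinuclear ring, and whole cell
#' mask, with pixel areas. Cells touching the field border are excluded
#' (their PM ring is truncated by the edge) and counted in
#' `attr(, "n_border_excluded")`. An empty compartment yields a missing
#' mean — never zero. The integrated (summed) whole-cell intensity and the
#' PM/perinuclear ring overlap area are reported as auxiliary columns.
#'
#' @param field A `field_image` whose `target` channel is measured.
#' @param masks A [segmentation_masks()] derived from this field.
#' @param exclude_border Drop cells whose mask touches the field border
#'   (default `TRUE`).
#' @return Data frame with one row per retained cell: `cell_id`, `mean_pm`,
#'   `mean_perinuclear`, `mean_total`, `area_pm`, `area_perinuclear`,
#'   `area_total`, `integrated_total`, `overlap_pm_perinuclear`.
#' @export
measure_cells <- function(field, masks, exclude_border = TRUE) {
  stopifnot(inherits(masks, "segmentation_masks"))
  target <- if (inherits(field, "field_image")) field$target else field
  .check(is.matrix(target) && all(dim(target) == dim(masks$cell_labels)),
         "target channel and masks must have the same shape")

  cl <- masks$cell_labels
  ids <- sort(unique(cl[cl > 0]))
  empty <- data.frame(cell_id = integer(), mean_pm = numeric(),
                      mean_perinuclear = numeric(), mean_total = numeric(),
                      area_pm = integer(), area_perinuclear = integer(),
                      area_total = integer(), integrated_total = numeric(),
                      overlap_pm_perinuclear = integer())
  if (!length(ids)) {
    attr(empty, "n_border_excluded") <- 0L
    return(empty)
  }

  n_border <- 0L
  if (exclude_border) {
    nr <- nrow(cl); nc <- ncol(cl)
    border_labels <- unique(c(cl[1, ], cl[nr, ], cl[, 1], cl[, nc]))
    border_labels <- border_labels[border_labels > 0]
    n_border <- length(border_labels)
    if (n_border > 0) {
      message(n_border, " cell(s) touching the field border excluded")
      ids <- setdiff(ids, border_labels)
    }
  }
  if (!length(ids)) {
    attr(empty, "n_border_excluded") <- n_border
    return(empty)
  }

  overlap <- masks$pm_labels
  overlap[masks$pm_labels != masks$perinuclear_labels] <- 0L
  sums <- tapply(target[cl > 0], cl[cl > 0], sum)
  integrated <- as.numeric(sums[match(as.character(ids), names(sums))])

  rec <- data.frame(
    cell_id = ids,
    mean_pm = .label_means(target, masks$pm_labels, ids),
    mean_perinuclear = .label_means(target, masks$perinuclear_labels, ids),
    mean_total = .label_means(target, cl, ids),
    area_pm = .label_areas(masks$pm_labels, ids),
    area_perinuclear = .label_areas(masks$perinuclear_labels, ids),
    area_total = .label_areas(cl, ids),
    integrated_total = integrated,
    overlap_pm_perinuclear = .label_areas(overlap, ids)
  )
  attr(rec, "n_border_excluded") <- n_border
  rec
}

#' Pool per-cell records into a per-well summary
#'
#' Pools every cell across all fields of a well with equal weight (a mean of
#' the cell-level means, not a mean of field means) — each measurement is
#' the mean fluorescence over all cells imaged in the well's fields. Cells
#' with a missing compartment mean are excluded from that compartment's
#' pooled mean only.
#'
#' @param records A data frame of cell records (from [measure_cells()]) or a
#'   list of such data frames, one per field.
#' @param well_id Well identifier for the summary row.
#' @return One-row data frame: `well_id`, `n_cells`, `mean_pm`,
#'   `mean_perinuclear`, `mean_total`. Means are missing when `n_cells` is
#'   zero.
#' @export
#' @examples
#' a <- data.frame(mean_pm = 100, mean_perinuclear = 100, mean_total = 100)
#' b <- data.frame(mean_pm = c(200, 200), mean_perinuclear = c(200, 200),
#'                 mean_total = c(200, 200))
#' summarize_well(list(a, b), "B02")  # pooled mean 166.67, not 175
summarize_well <- function(records, well_id = NA_character_) {
  if (is.data.frame(records)) records <- list(records)
  .check(length(records) >= 1, "at least one field of records required")
  pooled <- do.call(rbind, lapply(records, function(r) {
    r[, c("mean_pm", "mean_perinuclear", "mean_total"), drop = FALSE]
  }))
  n <- nrow(pooled)
  pool_mean <- function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  data.frame(
    well_id = well_id,
    n_cells = n,
    mean_pm = if (n == 0) NA_real_ else pool_mean(pooled$mean_pm),
    mean_perinuclear = if (n == 0) NA_real_ else pool_mean(pooled$mean_perinuclear),
    mean_total = if (n == 0) NA_real_ else pool_mean(pooled$mean_total)
  )
}

#' Quantify one well's fields end to end
#'
#' Convenience wrapper chaining [segment_nuclei()], [segment_cells()],
#' [segmentation_masks()], [measure_cells()] and [summarize_well()] over the
#' fields of a well.
#'
#' @param fields List of `field_image` objects belonging to one well.
#' @param well_id Well identifier; defaults to the first field's.
#' @param nuclear_threshold,cyto_threshold Thresholds (AFU or `"auto"`).
#' @param pm_width,perinuclear_width Ring widths in pixels.
#' @param min_nucleus_area Minimum nucleus area in pixels.
#' @return A [summarize_well()] row; the per-field cell records are attached
#'   as `attr(, "records")`.
#' @export
quantify_well <- function(fields, well_id = NULL,
                          nuclear_threshold = "auto", cyto_threshold = "auto",
                          pm_width = 2L, perinuclear_width = 5L,
                          min_nucleus_area = 10L) {
  .check(length(fields) >= 1, "at least one field required")
  if (is.null(well_id)) well_id <- fields[[1]]$well_id
  records <- lapply(fields, function(f) {
    nuc <- segment_nuclei(f, nuclear_threshold, min_area = min_nucleus_area)
    cells <- segment_cells(f, nuc, cyto_threshold)
    measure_cells(f, segmentation_masks(nuc, cells, pm_width, perinuclear_width))
  })
  out <- summarize_well(records, well_id)
  attr(out, "records") <- records
  out
}
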