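# Median over non-missing values; NA when none.
.ctrl_median <- function(values) {
  v <- values[!is.na(values)]
  if (!length(v)) return(NA_real_)
  median(v)
}

#' Fold increase over the cell-control median
#'
#' `fold increase = DataValue / median(cell controls)`, the immunostain
#' normalization of the screen: each well is expressed relative to the
#' median of the same plate's DMSO cell-control wells.
#'
#' @param value Well value(s) in AFU; vectorized.
#' @param cell_control_values Cell-control well values from the same plate.
#' @param plate_id Used in error messages.
#' @return Dimensionless fold increase(s).
#' @export
#' @examples
#' fold_increase(300, c(100, 100, 120))  # 3
fold_increase <- function(value, cell_control_values, plate_id = "plate") {
  med <- .ctrl_median(cell_control_values)
  .check(!is.na(med), "no non-missing cell-control values on %s", plate_id)
  .check(med > 0, "cell-control median on %s is %s (must be > 0)",
         plate_id, format(med))
  value / med
}

#' Percent viability anchored on control medians
#'
#' `% viability = 100 * (DataValue - median Hyamine) /
#' (median cell control - median Hyamine)`: the viability-control (Hyamine,
#' killed) median anchors 0% and the cell-control median anchors 100%.
#' Values below the Hyamine median yield negative viability, reported as is.
#'
#' @param value Viability-read value(s) in AFU; vectorized.
#' @param hyamine_values Viability-control well values (same plate).
#' @param cell_control_values Cell-control well values (same plate).
#' @param plate_id Used in error messages.
#' @return Data frame with columns `percent` and `fraction`
#'   (`fraction = percent / 100`).
#' @export
#' @examples
#' viability(150, hyamine_values = c(50, 50), cell_control_values = c(250, 250))
viability <- function(value, hyamine_values, cell_control_values,
                      plate_id = "plate") {
  med_hy <- .ctrl_median(hyamine_values)
  med_cc <- .ctrl_median(cell_control_values)
  .check(!is.na(med_hy) && !is.na(med_cc),
         "missing control medians for viability on %s", plate_id)
  .check(med_cc != med_hy,
         "degenerate viability anchors on %s: cell-control and Hyamine medians are both %s",
         plate_id, format(med_cc))
  pct <- 100 * (value - med_hy) / (med_cc - med_hy)
  data.frame(percent = pct, fraction = pct / 100)
}

#' Viability-normalized fold increase
#'
#' `normalized fold increase = fold increase / viability` (fractional
#' viability), correcting the immunostain signal for relative cell number.
#' Wells at or below the viability floor are flagged missing — dividing by
#' near-zero viability amplifies dead-well noise without bound — while the
#' raw ratio is always retained.
#'
#' @param fold Fold increase(s).
#' @param viability_fraction Fractional viability (percent / 100).
#' @param floor Minimum viability fraction for a reportable score
#'   (default 0.1).
#' @return Data frame with columns `normalized_fold_increase` (missing below
#'   the floor) and `normalized_fold_increase_raw` (unguarded ratio).
#' @export
#' @examples
#' normalized_fold_increase(2, 0.5)   # 4
#' normalized_fold_increase(2, 0.05)  # flagged, raw ratio 40
normalized_fold_increase <- function(fold, viability_fraction, floor = 0.1) {
  .check(floor >= 0, "viability floor must be >= 0")
  raw <- ifelse(viability_fraction > 0, fold / viability_fraction, NA_real_)
  nfi <- ifelse(!is.na(viability_fraction) & viability_fraction > floor,
                raw, NA_real_)
  data.frame(normalized_fold_increase = nfi,
             normalized_fold_increase_raw = raw)
}

#' Score every well of a plate from its two reads
#'
#' Applies [fold_increase()] to the immunostain read and [viability()] to
#' the viability read, well by well, using the same plate's control medians,
#' and combines them into [normalized_fold_increase()]. Control wells are
#' scored too (for QC); wells missing from either read are flagged and
#' excluded from the control medians.
#'
#' @param layout A `plate_layout` data frame (see [plate_layout()]).
#' @param immunostain,viability_read `plate_read` data frames
#'   (`well`, `value`).
#' @param viability_floor Passed to [normalized_fold_increase()].
#' @param plate_id Plate identifier; defaults to the layout's.
#' @return A `well_scores` data frame: layout columns plus `stain_value`,
#'   `viab_value`, `fold_increase`, `viability_percent`,
#'   `viability_fraction`, `normalized_fold_increase`,
#'   `normalized_fold_increase_raw`, `flag` (`""`, `"missing_stain"`,
#'   `"missing_viability"` or both). Control medians are attached as
#'   attributes.
#' @export
score_plate <- function(layout, immunostain, viability_read,
                        viability_floor = 0.1, plate_id = NULL) {
  layout <- .validate_layout(layout)
  if (is.null(plate_id)) {
    plate_id <- attr(layout, "plate_id")
    if (is.null(plate_id)) plate_id <- "plate"
  }
  pick <- function(read, kind) {
    .check(all(c("well", "value") %in% names(read)),
           "%s read needs columns well,value", kind)
    read$well <- normalize_well(read$well)
    extra <- setdiff(read$well, layout$well)
    .check(length(extra) == 0, "%s read has wells not in layout: %s",
           kind, paste(extra, collapse = ", "))
    read$value[match(layout$well, read$well)]
  }
  stain <- pick(immunostain, "immunostain")
  viab <- pick(viability_read, "viability")

  flag <- paste0(ifelse(is.na(stain), "missing_stain", ""),
                 ifelse(is.na(stain) & is.na(viab), "+", ""),
                 ifelse(is.na(viab), "missing_viability", ""))
  if (any(nzchar(flag))) {
    message(sum(nzchar(flag)), " well(s) flagged with missing reads on ",
            plate_id)
  }

  cc <- layout$role == "cell_control"
  hy <- layout$role == "viability_control"
  fi <- fold_increase(stain, stain[cc], plate_id)
  vb <- viability(viab, viab[hy], viab[cc], plate_id)
  nf <- normalized_fold_increase(fi, vb$fraction, viability_floor)

  scores <- data.frame(
    plate_id = plate_id, well = layout$well, role = layout$role,
    compound_id = layout$compound_id, concentration = layout$concentration,
    stain_value = stain, viab_value = viab,
    fold_increase = fi,
    viability_percent = vb$percent, viability_fraction = vb$fraction,
    normalized_fold_increase = nf$normalized_fold_increase,
    normalized_fold_increase_raw = nf$normalized_fold_increase_raw,
    flag = flag
  )
  attr(scores, "cell_control_median_stain") <- .ctrl_median(stain[cc])
  attr(scores, "cell_control_median_viab") <- .ctrl_median(viab[cc])
  attr(scores, "hyamine_median_viab") <- .ctrl_median(viab[hy])
  attr(scores, "viability_floor") <- viability_floor
  class(scores) <- c("well_scores", "data.frame")
  scores
}

#' Write well scores as TSV
#'
#' @param scores A `well_scores` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scores_tsv <- function(scores, path) {
  utils::write.table(scores, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
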