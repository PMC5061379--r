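#' Default multiwell screening layout
#'
#' Builds the control/test layout used throughout the package: the first
#' column holds DMSO cell controls, the second the positive control (ALLN in
#' the screen this emulates), the last-but-one column the viability control
#' (Hyamine), and the last column additional cell controls; every remaining
#' well is a test compound at a single concentration. A 384-well plate thus
#' carries 320 test wells.
#'
#' @param plate_format 96 or 384.
#' @param plate_id Plate identifier.
#' @param concentration Test-compound concentration recorded in the layout
#'   (default 25, the micromolar screening concentration).
#' @param compound_prefix Prefix for generated compound IDs.
#' @return A `plate_layout` data frame with columns `well`, `role`
#'   (`cell_control`, `positive_control`, `viability_control`, `test`),
#'   `compound_id` and `concentration`.
#' @export
#' @examples
#' table(plate_layout(96)$role)
plate_layout <- function(plate_format = 384, plate_id = "plate1",
                         concentration = 25,
                         compound_prefix = "CPD") {
  d <- .plate_dims(plate_format)
  wells <- well_ids(plate_format)
  col_no <- as.integer(substring(wells, 2))
  role <- rep("test", length(wells))
  role[col_no == 1L] <- "cell_control"
  role[col_no == 2L] <- "positive_control"
  role[col_no == d["cols"] - 1L] <- "viability_control"
  role[col_no == d["cols"]] <- "cell_control"
  layout <- data.frame(well = wells, role = role,
                       compound_id = NA_character_,
                       concentration = NA_real_)
  n_test <- sum(role == "test")
  layout$compound_id[role == "test"] <-
    sprintf("%s%04d", compound_prefix, seq_len(n_test))
  layout$concentration[role == "test"] <- concentration
  attr(layout, "plate_id") <- plate_id
  attr(layout, "plate_format") <- as.integer(plate_format)
  class(layout) <- c("plate_layout", "data.frame")
  layout
}

.validate_layout <- function(layout) {
  .check(all(c("well", "role", "compound_id") %in% names(layout)),
         "layout needs columns well, role, compound_id")
  layout$well <- normalize_well(layout$well)
  .check(!anyDuplicated(layout$well), "layout wells must be unique")
  for (r in c("cell_control", "positive_control", "viability_control")) {
    n <- sum(layout$role == r)
    .check(n >= 2, "layout must contain >= 2 wells with role '%s' (has %d)",
           r, n)
  }
  .check(all(!is.na(layout$compound_id[layout$role == "test"])),
         "every test well needs a compound_id")
  layout
}

#' Specification for a simulated screening plate
#'
#' Defines the distributional ground truth for one plate: per-role means for
#' the immunostain and viability (alamarBlue-style) reads, a common
#' coefficient of variation, and the compounds spiked as true hits. Each
#' well's value is drawn as `mean * (1 + cv * Z)` with standard normal `Z`,
#' clipped at zero; `cv = 0` is the exact noiseless limit.
#'
#' Defaults emulate a robust corrector screen: the positive control sits at
#' three times the cell-control immunostain and `cv = 0.07`, giving a
#' Z-factor window in the 0.5–0.65 range; the viability read for living
#' wells is centred at 4e6 AFU (the plate-development stopping point of the
#' emulated protocol), with the viability control far below it.
#'
#' @param plate_format 96 or 384; ignored when `layout` is supplied.
#' @param layout A `plate_layout`; defaults to [plate_layout()] for the
#'   format.
#' @param mu_cell_control Immunostain mean of cell-control and unspiked test
#'   wells (AFU).
#' @param mu_positive Immunostain mean of positive-control wells (AFU).
#' @param mu_viability_control Viability-read mean of viability-control
#'   (killed) wells (AFU).
#' @param mu_alive Viability-read mean of living wells (AFU).
#' @param stain_death_factor Immunostain mean of killed wells as a fraction
#'   of `mu_cell_control`.
#' @param cv Coefficient of variation applied to every draw; must be >= 0.
#' @param hit_ids Named numeric vector: compound ID -> immunostain effect
#'   multiplier (> 0) for spiked hits.
#' @param seed Integer seed; one seed drives both reads.
#' @return An object of class `plate_sim_spec`.
#' @seealso [simulate_plate()]
#' @export
plate_sim_spec <- function(plate_format = 384, layout = NULL,
                           mu_cell_control = 5000,
                           mu_positive = 15000,
                           mu_viability_control = 2e5,
                           mu_alive = 4e6,
                           stain_death_factor = 0.2,
                           cv = 0.07,
                           hit_ids = numeric(0),
                           seed = 1L) {
  if (is.null(layout)) layout <- plate_layout(plate_format)
  layout <- .validate_layout(layout)
  .check(cv >= 0, "cv must be >= 0")
  .check(all(c(mu_cell_control, mu_positive, mu_viability_control,
               mu_alive) > 0), "all role means must be > 0")
  .check(stain_death_factor > 0, "stain_death_factor must be > 0")
  if (length(hit_ids)) {
    .check(!is.null(names(hit_ids)) && all(nzchar(names(hit_ids))),
           "hit_ids must be a named numeric vector (compound_id -> multiplier)")
    .check(all(hit_ids > 0), "effect multipliers must be > 0")
    missing_ids <- setdiff(names(hit_ids), layout$compound_id)
    .check(length(missing_ids) == 0, "hit_ids not in layout: %s",
           paste(missing_ids, collapse = ", "))
  }
  structure(list(layout = layout,
                 mu_cell_control = mu_cell_control,
                 mu_positive = mu_positive,
                 mu_viability_control = mu_viability_control,
                 mu_alive = mu_alive,
                 stain_death_factor = stain_death_factor,
                 cv = cv, hit_ids = hit_ids, seed = as.integer(seed)),
            class = "plate_sim_spec")
}

#' Simulate immunostain and viability reads for one plate
#'
#' Draws both plate reads from the role-dependent means of the spec and
#' returns them with the per-well truth table recording which wells were
#' spiked. Reproducible for a fixed seed.
#'
#' @param spec A [plate_sim_spec()].
#' @return A list with `immunostain` and `viability` (`plate_read` data
#'   frames: columns `well`, `value`), `truth` (data frame: `well`,
#'   `compound_id`, `role`, `multiplier`, `is_hit`) and `layout`.
#' @export
#' @examples
#' sim <- simulate_plate(plate_sim_spec(96, cv = 0, seed = 7))
#' head(sim$immunostain)
simulate_plate <- function(spec) {
  stopifnot(inherits(spec, "plate_sim_spec"))
  layout <- spec$layout
  n <- nrow(layout)

  mult <- rep(1, n)
  if (length(spec$hit_ids)) {
    idx <- match(names(spec$hit_ids), layout$compound_id)
    mult[idx] <- unname(spec$hit_ids)
  }

  stain_mu <- vapply(seq_len(n), function(i) {
    switch(layout$role[i],
           cell_control = spec$mu_cell_control,
           positive_control = spec$mu_positive,
           viability_control = spec$mu_cell_control * spec$stain_death_factor,
           test = spec$mu_cell_control * mult[i])
  }, numeric(1))
  viab_mu <- ifelse(layout$role == "viability_control",
                    spec$mu_viability_control, spec$mu_alive)

  set.seed(spec$seed)
  draw <- function(mu) {
    if (spec$cv == 0) return(mu)
    pmax(mu * (1 + spec$cv * rnorm(length(mu))), 0)
  }
  stain <- draw(stain_mu)
  viab <- draw(viab_mu)

  plate_id <- attr(layout, "plate_id")
  mk_read <- function(values, kind) {
    rd <- data.frame(well = layout$well, value = values)
    attr(rd, "plate_id") <- plate_id
    attr(rd, "read_kind") <- kind
    class(rd) <- c("plate_read", "data.frame")
    rd
  }
  truth <- data.frame(well = layout$well, compound_id = layout$compound_id,
                      role = layout$role, multiplier = mult,
                      is_hit = layout$role == "test" & mult != 1)
  list(immunostain = mk_read(stain, "immunostain"),
       viability = mk_read(viab, "viability"),
       truth = truth, layout = layout)
}

#' Plate CSV input/output
#'
#' Plate reads travel as long-format CSV with columns `well,value`; layouts
#' as `well,role,compound_id,concentration`. Well IDs are normalized
#' (`"A1"` -> `"A01"`) on read.
#'
#' @param read A `plate_read` data frame.
#' @param path CSV path.
#' @param read_kind,plate_id Metadata attached on read.
#' @return The written path (invisibly) or the parsed object.
#' @export
write_plate_csv <- function(read, path) {
  write.csv(read[, c("well", "value")], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_plate_csv
#' @export
read_plate_csv <- function(path, read_kind = NA_character_,
                           plate_id = NA_character_) {
  .check(file.exists(path), "plate read file not found: %s", path)
  rd <- read.csv(path, stringsAsFactors = FALSE)
  .check(all(c("well", "value") %in% names(rd)),
         "%s must have columns well,value", path)
  rd$well <- normalize_well(rd$well)
  attr(rd, "plate_id") <- plate_id
  attr(rd, "read_kind") <- read_kind
  class(rd) <- c("plate_read", "data.frame")
  rd
}

#' @rdname write_plate_csv
#' @param layout A `plate_layout` data frame.
#' @export
write_layout_csv <- function(layout, path) {
  write.csv(layout[, c("well", "role", "compound_id", "concentration")],
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_plate_csv
#' @export
read_layout_csv <- function(path, plate_id = NA_character_) {
  .check(file.exists(path), "layout file not found: %s", path)
  layout <- read.csv(path, stringsAsFactors = FALSE)
  layout <- .validate_layout(layout)
  attr(layout, "plate_id") <- plate_id
  class(layout) <- c("plate_layout", "data.frame")
  layout
}
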