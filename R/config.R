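#' Default pipeline configuration
#'
#' All tunable parameters of the end-to-end run, with the protocol's printed
#' values as defaults: 2 px plasma-membrane ring, 5 px perinuclear ring,
#' nine imaging fields per well, hit threshold at 3 SD.
#'
#' @return Named list of defaults (see [load_config()] for the keys).
#' @export
default_config <- function() {
  list(
    nuclear_threshold = "auto",   # AFU or "auto" (Otsu)
    cyto_threshold = "auto",      # AFU or "auto"
    pm_width = 2L,                # px, plasma-membrane ring
    perinuclear_width = 5L,       # px, perinuclear ring
    fields_per_well = 9L,
    min_nucleus_area = 10L,       # px
    viability_floor = 0.1,        # fraction
    k = 3,                        # SD multiplier for hit calling
    seed = 1L,
    plate_format = 384L,
    n_plates = 1L,
    hit_ids = list(),             # compound_id -> multiplier
    cv = 0.07,
    image_wells = 0L,             # imaging-arm demo wells to simulate
    image_n_cells = 20L,
    out_dir = "cftrscreen-run"
  )
}

.validate_config <- function(config) {
  num_pos <- function(key, strict = TRUE) {
    v <- config[[key]]
    .check(is.numeric(v) && length(v) == 1 && (if (strict) v > 0 else v >= 0),
           "config key '%s' must be a %s number (got %s)",
           key, if (strict) "positive" else "non-negative",
           paste(format(v), collapse = ","))
  }
  for (key in c("pm_width", "perinuclear_width", "fields_per_well",
                "n_plates", "image_n_cells")) num_pos(key)
  for (key in c("min_nucleus_area", "viability_floor", "seed", "cv",
                "image_wells")) num_pos(key, strict = FALSE)
  num_pos("k")
  .check(config$plate_format %in% c(96L, 384L),
         "config key 'plate_format' must be 96 or 384")
  for (key in c("nuclear_threshold", "cyto_threshold")) {
    v <- config[[key]]
    .check(identical(v, "auto") || (is.numeric(v) && length(v) == 1),
           "config key '%s' must be a number or \"auto\"", key)
  }
  if (length(config$hit_ids)) {
    .check(!is.null(names(config$hit_ids)) &&
             all(unlist(config$hit_ids) > 0),
           "config key 'hit_ids' must map compound IDs to positive multipliers")
  }
  config
}

#' Load and validate a run configuration
#'
#' Reads a YAML file of configuration keys, overlays it on
#' [default_config()], and validates every value. Unknown keys are an
#' error (listed by name), so typos never silently fall back to defaults.
#' An empty or absent file yields the full defaults.
#'
#' @param path Path to a YAML config file, or `NULL` for pure defaults.
#' @param overrides Named list applied after the file (e.g. command-line
#'   style overrides); validated identically.
#' @return Validated configuration list of class `run_config`.
#' @export
#' @examples
#' cfg <- load_config()
#' cfg$pm_width
load_config <- function(path = NULL, overrides = list()) {
  config <- default_config()
  if (!is.null(path)) {
    .check(file.exists(path), "config file not found: %s", path)
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
    unknown <- setdiff(names(user), names(config))
    .check(length(unknown) == 0, "unknown config key(s): %s",
           paste(unknown, collapse = ", "))
    config[names(user)] <- user
  }
  if (length(overrides)) {
    unknown <- setdiff(names(overrides), names(config))
    .check(length(unknown) == 0, "unknown override key(s): %s",
           paste(unknown, collapse = ", "))
    config[names(overrides)] <- overrides
  }
  for (key in c("pm_width", "perinuclear_width", "fields_per_well",
                "min_nucleus_area", "seed", "plate_format", "n_plates",
                "image_wells", "image_n_cells")) {
    if (is.numeric(config[[key]])) config[[key]] <- as.integer(config[[key]])
  }
  config <- .validate_config(config)
  class(config) <- c("run_config", "list")
  config
}

#' @rdname load_config
#' @param config A `run_config`.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
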