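#' Specification for a simulated microscopy field
#'
#' Describes one synthetic two-channel field: a nuclear/DNA-stain channel
#' (bright nuclear disks over a dim cytoplasmic stain, as with DRAQ5) and a
#' target immunofluorescence channel painted per cell compartment. Cells are
#' rendered as concentric regions — nucleus, perinuclear band, cytoplasm and
#' plasma-membrane (PM) band — whose geometry matches the analysis ring ROIs
#' by construction, so that noiseless recovery tests are exact.
#'
#' Intensities are in arbitrary fluorescence units (AFU) and should stay
#' within the 16-bit range `[0, 65535]` if fields are written to TIFF.
#'
#' @param field_shape Integer `(rows, cols)` of the field in pixels.
#' @param n_cells Number of cells to place.
#' @param nucleus_radius,cell_radius Euclidean disk radii in pixels;
#'   `cell_radius > nucleus_radius > 0`. The defaults (4, 14) leave the
#'   perinuclear band clear of the PM band, so every compartment's painted
#'   mean equals its nominal intensity; smaller cells are allowed and simply
#'   produce overlapping rings, which the measurement stage reports.
#' @param intensity_pm,intensity_perinuclear,intensity_cytoplasm,intensity_background
#'   Target-channel intensities (AFU) for the PM band, perinuclear band,
#'   remaining cell interior (including the nucleus footprint) and
#'   background.
#' @param noise_sd Standard deviation of additive Gaussian noise (AFU) on the
#'   target channel, clipped at zero. Noise never alters the ground truth.
#' @param seed Integer seed. Placement uses `seed`; pixel noise uses a
#'   documented sub-seed (`seed + 500009`), so changing `noise_sd` or adding
#'   noise never changes cell placement.
#' @param pm_width,perinuclear_width Ring widths in pixels (Chebyshev
#'   metric), matching the analysis defaults of 2 and 5.
#' @param nuclear_stain_nucleus,nuclear_stain_cytoplasm,nuclear_stain_background
#'   Nuclear-channel intensities (AFU): high-contrast nuclei, low-contrast
#'   cytoplasmic staining, background.
#' @return An object of class `image_sim_spec`.
#' @seealso [simulate_field()]
#' @export
image_sim_spec <- function(field_shape = c(256L, 256L),
                           n_cells = 20L,
                           nucleus_radius = 4,
                           cell_radius = 14,
                           intensity_pm = 500,
                           intensity_perinuclear = 300,
                           intensity_cytoplasm = 100,
                           intensity_background = 20,
                           noise_sd = 0,
                           seed = 1L,
                           pm_width = 2L,
                           perinuclear_width = 5L,
                           nuclear_stain_nucleus = 4000,
                           nuclear_stain_cytoplasm = 400,
                           nuclear_stain_background = 10) {
  .check(length(field_shape) == 2 && all(field_shape >= 8),
         "field_shape must be (rows, cols), each >= 8")
  .check(n_cells >= 0, "n_cells must be >= 0")
  .check(nucleus_radius > 0, "nucleus_radius must be > 0")
  .check(cell_radius > nucleus_radius,
         "cell_radius (%s) must exceed nucleus_radius (%s)",
         cell_radius, nucleus_radius)
  ints <- c(intensity_pm, intensity_perinuclear, intensity_cytoplasm,
            intensity_background, nuclear_stain_nucleus,
            nuclear_stain_cytoplasm, nuclear_stain_background)
  .check(all(ints >= 0), "all intensities must be >= 0")
  .check(noise_sd >= 0, "noise_sd must be >= 0")
  .check(pm_width >= 1 && perinuclear_width >= 1, "ring widths must be >= 1")
  structure(list(
    field_shape = as.integer(field_shape), n_cells = as.integer(n_cells),
    nucleus_radius = nucleus_radius, cell_radius = cell_radius,
    intensity_pm = intensity_pm, intensity_perinuclear = intensity_perinuclear,
    intensity_cytoplasm = intensity_cytoplasm,
    intensity_background = intensity_background,
    noise_sd = noise_sd, seed = as.integer(seed),
    pm_width = as.integer(pm_width),
    perinuclear_width = as.integer(perinuclear_width),
    nuclear_stain_nucleus = nuclear_stain_nucleus,
    nuclear_stain_cytoplasm = nuclear_stain_cytoplasm,
    nuclear_stain_background = nuclear_stain_background
  ), class = "image_sim_spec")
}

# Dart-throwing placement: centers at least min_sep apart, disks clear of the
# field border by >= 1 px. Errors (never silently drops cells) when the field
# cannot host n_cells.
.place_cells <- function(spec) {
  if (spec$n_cells == 0L) {
    return(data.frame(cell_id = integer(), row = numeric(), col = numeric()))
  }
  r <- spec$cell_radius
  nr <- spec$field_shape[1]; nc <- spec$field_shape[2]
  lo <- ceiling(r) + 2; hi_r <- nr - ceiling(r) - 1; hi_c <- nc - ceiling(r) - 1
  .check(hi_r >= lo && hi_c >= lo,
         "field %dx%d too small for cells of radius %s", nr, nc, r)
  # +2 keeps masks from touching even diagonally, so labels never merge
  min_sep <- 2 * r + 2
  centers <- matrix(NA_real_, spec$n_cells, 2)
  max_tries <- 2000L * spec$n_cells
  placed <- 0L; tries <- 0L
  while (placed < spec$n_cells && tries < max_tries) {
    tries <- tries + 1L
    # integer centers: every disk then has the same pixelation, so painted
    # areas and means are identical across seeds
    cand <- c(sample(lo:hi_r, 1), sample(lo:hi_c, 1))
    if (placed > 0L) {
      d2 <- (centers[seq_len(placed), 1] - cand[1])^2 +
            (centers[seq_len(placed), 2] - cand[2])^2
      if (any(d2 < min_sep^2)) next
    }
    placed <- placed + 1L
    centers[placed, ] <- cand
  }
  .check(placed == spec$n_cells,
         paste0("could not place %d non-overlapping cells of radius %s on a ",
                "%dx%d field (placed %d; centers must be >= %s px apart and ",
                "clear of the border)"),
         spec$n_cells, r, nr, nc, placed, min_sep)
  data.frame(cell_id = seq_len(spec$n_cells),
             row = centers[, 1], col = centers[, 2])
}

#' Simulate a two-channel field with known per-compartment ground truth
#'
#' Places non-overlapping disk-shaped cells, paints the nuclear and target
#' channels compartment by compartment, and records the exact masks and mean
#' intensities used — the ground truth against which the imaging pipeline is
#' validated. Ground-truth means are computed from the noiseless painted
#' image, so painting order (cytoplasm, then perinuclear band, then PM band)
#' is accounted for even when rings overlap in small cells.
#'
#' @param spec An [image_sim_spec()].
#' @param well_id,field_index Identifiers carried into the returned field.
#' @return A list with components:
#'   \describe{
#'     \item{field}{A `field_image`: list with `nuclear`, `target` matrices
#'       (AFU), `well_id`, `field_index`.}
#'     \item{truth}{Data frame of per-cell ground truth: painted compartment
#'       means and pixel areas, plus cell centers.}
#'     \item{nucleus_labels, cell_labels}{Integer label matrices of the
#'       painted geometry (0 = background).}
#'   }
#' @export
#' @examples
#' sim <- simulate_field(image_sim_spec(field_shape = c(64, 64), n_cells = 3))
#' sim$truth
simulate_field <- function(spec, well_id = "A01", field_index = 0L) {
  stopifnot(inherits(spec, "image_sim_spec"))
  nr <- spec$field_shape[1]; nc <- spec$field_shape[2]

  set.seed(spec$seed)
  centers <- .place_cells(spec)

  target <- matrix(spec$intensity_background, nr, nc)
  nuclear <- matrix(spec$nuclear_stain_background, nr, nc)
  nucleus_labels <- matrix(0L, nr, nc)
  cell_labels <- matrix(0L, nr, nc)

  rows <- row(target); cols <- col(target)
  masks <- vector("list", spec$n_cells)
  for (i in seq_len(spec$n_cells)) {
    d2 <- (rows - centers$row[i])^2 + (cols - centers$col[i])^2
    cell <- d2 <= spec$cell_radius^2
    nuc <- d2 <= spec$nucleus_radius^2
    peri <- cell & !nuc & .cheb_dilate(nuc, spec$perinuclear_width)
    pm <- cell & !.cheb_erode(cell, spec$pm_width)

    nuclear[cell] <- spec$nuclear_stain_cytoplasm
    nuclear[nuc] <- spec$nuclear_stain_nucleus
    target[cell] <- spec$intensity_cytoplasm
    target[peri] <- spec$intensity_perinuclear
    target[pm] <- spec$intensity_pm

    cell_labels[cell] <- i
    nucleus_labels[nuc] <- i
    masks[[i]] <- list(cell = cell, nucleus = nuc, peri = peri, pm = pm)
  }

  truth <- do.call(rbind, lapply(seq_len(spec$n_cells), function(i) {
    m <- masks[[i]]
    data.frame(
      cell_id = i, row = centers$row[i], col = centers$col[i],
      mean_pm = mean(target[m$pm]),
      mean_perinuclear = mean(target[m$peri]),
      mean_total = mean(target[m$cell]),
      area_pm = sum(m$pm), area_perinuclear = sum(m$peri),
      area_total = sum(m$cell)
    )
  }))
  if (is.null(truth)) {
    truth <- data.frame(cell_id = integer(), row = numeric(), col = numeric(),
                        mean_pm = numeric(), mean_perinuclear = numeric(),
                        mean_total = numeric(), area_pm = integer(),
                        area_perinuclear = integer(), area_total = integer())
  }

  if (spec$noise_sd > 0) {
    set.seed(spec$seed + 500009L)
    target <- pmax(target + rnorm(length(target), 0, spec$noise_sd), 0)
  }

  field <- structure(list(nuclear = nuclear, target = target,
                          well_id = well_id,
                          field_index = as.integer(field_index)),
                     class = "field_image")
  list(field = field, truth = truth,
       nucleus_labels = nucleus_labels, cell_labels = cell_labels)
}

#' Simulate all fields of one imaging well
#'
#' Generates `n_fields` independent fields for a well (the screening protocol
#' images nine fields per well), sub-seeding each field as
#' `spec$seed + field_index` so a well is reproducible from one seed.
#'
#' @param spec An [image_sim_spec()]; its `seed` anchors the well.
#' @param well_id Well identifier.
#' @param n_fields Number of fields (default 9).
#' @return List of [simulate_field()] results, one per field.
#' @export
simulate_image_well <- function(spec, well_id = "A01", n_fields = 9L) {
  .check(n_fields >= 1, "n_fields must be >= 1")
  lapply(seq_len(n_fields) - 1L, function(fi) {
    fspec <- spec
    fspec$seed <- spec$seed + fi
    simulate_field(fspec, well_id = well_id, field_index = fi)
  })
}

#' Read or write a field as multi-page 16-bit TIFF
#'
#' Page 0 holds the nuclear channel, page 1 the target channel, stored as
#' 16-bit unsigned integers; intensities are rounded and clipped to
#' `[0, 65535]`.
#'
#' @param field A `field_image`.
#' @param path Output TIFF path.
#' @return `write_field_tiff` returns `path` invisibly; `read_field_tiff`
#'   returns a `field_image`.
#' @export
write_field_tiff <- function(field, path) {
  stopifnot(inherits(field, "field_image"))
  enc <- function(m) {
    m <- round(m)
    if (any(m > 65535)) warning("intensities above 65535 clipped in ", path)
    pmin(pmax(m, 0), 65535) / 65535
  }
  tiff::writeTIFF(list(enc(field$nuclear), enc(field$target)), path,
                  bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_field_tiff
#' @param well_id,field_index Identifiers attached to the field on read.
#' @export
read_field_tiff <- function(path, well_id = NA_character_, field_index = 0L) {
  pages <- tiff::readTIFF(path, all = TRUE)
  .check(length(pages) >= 2,
         "expected a 2-page TIFF (nuclear, target) at %s", path)
  dec <- function(p) round(p * 65535)
  structure(list(nuclear = dec(pages[[1]]), target = dec(pages[[2]]),
                 well_id = well_id, field_index = as.integer(field_index)),
            class = "field_image")
}
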