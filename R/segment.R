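# Otsu threshold on an intensity matrix, optionally restricted to a pixel
# subset (used to find the dim cytoplasmic stain below the nuclear peak).
.auto_threshold <- function(x, subset = NULL) {
  v <- if (is.null(subset)) as.vector(x) else x[subset]
  mx <- max(v)
  if (mx <= 0) return(Inf)             # nothing above background
  thr01 <- EBImage::otsu(EBImage::Image(matrix(v / mx, ncol = 1)),
                         range = c(0, 1), levels = 256L)
  thr01 * mx
}

# Relabel a label matrix to consecutive 1..k preserving first-appearance order.
.relabel <- function(labels) {
  ids <- sort(unique(labels[labels > 0]))
  if (!length(ids)) return(labels)
  map <- integer(max(ids)); map[ids] <- seq_along(ids)
  out <- labels
  out[out > 0] <- map[out[out > 0]]
  out
}

#' Segment nuclei from the nuclear channel by intensity threshold
#'
#' High-contrast nuclear staining is thresholded (fixed value or Otsu
#' `"auto"`), connected components are labeled (4-connectivity), and
#' components below a minimum area are discarded as noise specks. An
#' all-background image yields an empty labeling; a threshold at or below the
#' channel minimum (all pixels foreground) is an error.
#'
#' @param field A `field_image` (or a plain matrix taken as the nuclear
#'   channel).
#' @param threshold Intensity threshold in AFU, or `"auto"` for Otsu's
#'   method on the channel histogram. Pixels with intensity `>= threshold`
#'   are foreground.
#' @param min_area Minimum component area in pixels (default 10).
#' @return Integer label matrix, 0 = background, labels 1..k.
#' @export
#' @examples
#' m <- matrix(0, 16, 16); m[2:6, 2:6] <- 100; m[10:14, 10:14] <- 100
#' table(segment_nuclei(m, threshold = 50))
segment_nuclei <- function(field, threshold = "auto", min_area = 10L) {
  ch <- if (inherits(field, "field_image")) field$nuclear else field
  .check(is.matrix(ch) && length(ch) > 0, "nuclear channel must be a matrix")
  if (identical(threshold, "auto")) threshold <- .auto_threshold(ch)
  .check(is.numeric(threshold), "threshold must be numeric or 'auto'")
  fg <- ch >= threshold
  if (!any(fg)) return(matrix(0L, nrow(ch), ncol(ch)))
  .check(!all(fg),
         "threshold %s is at or below the channel minimum: all pixels foreground",
         format(threshold))
  labels <- EBImage::bwlabel(fg)
  labels <- matrix(as.integer(labels), nrow(ch), ncol(ch))
  if (min_area > 0) {
    areas <- tabulate(labels[labels > 0])
    drop <- which(areas < min_area)
    if (length(drop)) labels[labels %in% drop] <- 0L
  }
  .relabel(labels)
}

# Multi-source BFS over the foreground: each unlabeled foreground pixel takes
# the label of the geodesically nearest seed (8-neighbour steps); ties at the
# same distance go to the lower label. Pure R, vectorized over wavefronts.
.assign_to_seeds <- function(fg, seeds) {
  labels <- seeds
  labels[!fg] <- 0L
  active <- any(labels > 0)
  repeat {
    if (!active) break
    best <- matrix(Inf, nrow(fg), ncol(fg))
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0L && dj == 0L) next
      nb <- .shift_mat(labels, di, dj, 0L)
      cand <- nb > 0 & labels == 0L & fg & nb < best
      best[cand] <- nb[cand]
    }
    grow <- is.finite(best)
    if (!any(grow)) break
    labels[grow] <- as.integer(best[grow])
  }
  labels
}

#' Associate cytoplasm with each nucleus to form cell masks
#'
#' The cytoplasmic foreground (low-contrast staining at or above
#' `cyto_threshold`, plus all nucleus pixels) is partitioned among the
#' nucleus seeds: every foreground pixel joins the nucleus it can reach by
#' the shortest path within the foreground (8-neighbour steps, ties to the
#' lower label). Cell labels therefore equal their nucleus labels and nuclei
#' are always contained in their cells. Foreground pixels with no reachable
#' nucleus remain background; their count is reported via
#' `attr(, "n_orphan")` and a message.
#'
#' @param field A `field_image` (or matrix taken as the nuclear channel,
#'   whose dim cytoplasmic staining defines cell extent).
#' @param nucleus_labels Label matrix from [segment_nuclei()].
#' @param cyto_threshold Intensity threshold in AFU, or `"auto"` (Otsu on
#'   the pixels outside nuclei, i.e. on the background/cytoplasm mixture).
#' @return Integer cell-label matrix matching `nucleus_labels` labels.
#' @export
segment_cells <- function(field, nucleus_labels, cyto_threshold = "auto") {
  ch <- if (inherits(field, "field_image")) field$nuclear else field
  .check(is.matrix(ch) && all(dim(ch) == dim(nucleus_labels)),
         "nuclear channel and nucleus_labels must have the same shape")
  if (identical(cyto_threshold, "auto")) {
    cyto_threshold <- .auto_threshold(ch, subset = nucleus_labels == 0L)
  }
  fg <- (ch >= cyto_threshold) | nucleus_labels > 0L
  labels <- .assign_to_seeds(fg, nucleus_labels)
  n_orphan <- sum(fg & labels == 0L)
  if (n_orphan > 0) {
    message(n_orphan,
            " cytoplasmic foreground pixel(s) had no reachable nucleus seed",
            " and were left as background")
  }
  attr(labels, "n_orphan") <- n_orphan
  labels
}

#' Ring regions of interest around cell margins and nuclei
#'
#' `derive_pm_roi` extracts the plasma-membrane ROI: for each cell, the band
#' of its pixels within `width` of the nearest non-cell pixel (Chebyshev
#' metric, so `width = 2` means two erosion steps with a 3x3 element, the "2
#' pixel wide" cell-margin region of the screening protocol). Pixels beyond
#' the field border count as non-cell, so cells at the edge still carry a
#' ring there.
#'
#' `derive_perinuclear_roi` extracts the perinuclear ROI: pixels outside the
#' nucleus, inside the cell, within `width` of the nucleus (default 5, the
#' "5 pixel wide" band around the nuclear mask used as an ER proxy). The
#' ring is clipped by the cell mask and may overlap the PM ring in small
#' cells; the overlap is reported by [measure_cells()], not forbidden.
#'
#' @param cell_labels,nucleus_labels Integer label matrices; the two label
#'   sets must match for the perinuclear ROI.
#' @param width Ring width in pixels; must be >= 1.
#' @return Integer label matrix of the rings (label = owning cell).
#' @export
#' @examples
#' cell <- matrix(0L, 14, 14); cell[3:12, 3:12] <- 1L
#' sum(derive_pm_roi(cell, 2) == 1L)  # 100 - 36 interior = 64
derive_pm_roi <- function(cell_labels, width = 2L) {
  .check(is.numeric(width) && width >= 1, "width must be a positive integer")
  width <- as.integer(width)
  out <- matrix(0L, nrow(cell_labels), ncol(cell_labels))
  for (l in sort(unique(cell_labels[cell_labels > 0]))) {
    m <- cell_labels == l
    ring <- m & !.cheb_erode(m, width)
    out[ring] <- l
  }
  out
}

#' @rdname derive_pm_roi
#' @export
derive_perinuclear_roi <- function(nucleus_labels, cell_labels, width = 5L) {
  .check(is.numeric(width) && width >= 1, "width must be a positive integer")
  width <- as.integer(width)
  nuc_ids <- sort(unique(nucleus_labels[nucleus_labels > 0]))
  cell_ids <- sort(unique(cell_labels[cell_labels > 0]))
  .check(identical(nuc_ids, cell_ids),
         "nucleus and cell label sets differ (nuclei: %s; cells: %s)",
         paste(nuc_ids, collapse = ","), paste(cell_ids, collapse = ","))
  .check(all(cell_labels[nucleus_labels > 0] ==
               nucleus_labels[nucleus_labels > 0]),
         "every nucleus must lie inside its cell mask")
  out <- matrix(0L, nrow(cell_labels), ncol(cell_labels))
  for (l in nuc_ids) {
    nuc <- nucleus_labels == l
    ring <- (cell_labels == l) & !nuc & .cheb_dilate(nuc, width)
    out[ring] <- l
  }
  out
}

#' Bundle segmentation products with validated invariants
#'
#' Checks that every nucleus has exactly one matching cell containing it,
#' then derives the PM and perinuclear ring ROIs at the requested widths.
#'
#' @param nucleus_labels,cell_labels Label matrices with matching label sets.
#' @param pm_width,perinuclear_width Ring widths in pixels (defaults 2
#'   and 5).
#' @return An object of class `segmentation_masks` holding the four label
#'   matrices and the widths.
#' @export
segmentation_masks <- function(nucleus_labels, cell_labels,
                               pm_width = 2L, perinuclear_width = 5L) {
  .check(all(dim(nucleus_labels) == dim(cell_labels)),
         "label matrices must have the same shape")
  peri <- derive_perinuclear_roi(nucleus_labels, cell_labels,
                                 perinuclear_width)  # validates containment
  pm <- derive_pm_roi(cell_labels, pm_width)
  structure(list(nucleus_labels = nucleus_labels, cell_labels = cell_labels,
                 pm_labels = pm, perinuclear_labels = peri,
                 pm_width = as.integer(pm_width),
                 perinuclear_width = as.integer(perinuclear_width)),
            class = "segmentation_masks")
}
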