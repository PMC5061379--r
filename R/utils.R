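#' @keywords internal
"_PACKAGE"

#' @importFrom stats median rnorm sd setNames
#' @importFrom utils read.csv write.csv packageVersion
NULL

# Row letters for multiwell plates, extended past Z for completeness.
.plate_dims <- function(plate_format) {
  switch(as.character(plate_format),
    "96"  = c(rows = 8L,  cols = 12L),
    "384" = c(rows = 16L, cols = 24L),
    stop("unsupported plate format: ", plate_format, " (expected 96 or 384)")
  )
}

#' Well identifiers for a plate format
#'
#' Returns zero-padded well IDs in row-major order, `"A01"` .. `"P24"` for
#' 384-well plates and `"A01"` .. `"H12"` for 96-well plates.
#'
#' @param plate_format 96 or 384.
#' @return Character vector of well IDs.
#' @export
#' @examples
#' head(well_ids(96))
well_ids <- function(plate_format = 384) {
  d <- .plate_dims(plate_format)
  rows <- LETTERS[seq_len(d["rows"])]
  as.vector(t(outer(rows, sprintf("%02d", seq_len(d["cols"])), paste0)))
}

#' Normalize a well identifier
#'
#' Accepts `"A1"` or `"A01"` style IDs (any case) and returns the canonical
#' zero-padded form, e.g. `"A01"`.
#'
#' @param well Character vector of well IDs.
#' @return Character vector of canonical IDs.
#' @export
#' @examples
#' normalize_well(c("a1", "P24", "B09"))
normalize_well <- function(well) {
  well <- toupper(trimws(as.character(well)))
  ok <- grepl("^[A-Z][0-9]{1,2}$", well)
  if (!all(ok | is.na(well))) {
    stop("malformed well ID(s): ", paste(well[!ok & !is.na(well)], collapse = ", "))
  }
  row <- substr(well, 1, 1)
  col <- as.integer(substring(well, 2))
  ifelse(is.na(well), NA_character_, sprintf("%s%02d", row, col))
}

# Stop unless `cond`; msg built sprintf-style.
.check <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) stop(sprintf(fmt, ...), call. = FALSE)
  invisible(TRUE)
}

# Shift a matrix by (di, dj), filling vacated cells with `fill`.
.shift_mat <- function(m, di, dj, fill) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  src_i <- seq_len(nr) - di; src_j <- seq_len(nc) - dj
  ok_i <- src_i >= 1L & src_i <= nr
  ok_j <- src_j >= 1L & src_j <= nc
  out[ok_i, ok_j] <- m[src_i[ok_i], src_j[ok_j]]
  out
}

# One Chebyshev (8-neighbour) erosion step; outside the image is background.
.erode1 <- function(mask) {
  out <- mask
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0L && dj == 0L) next
    out <- out & .shift_mat(mask, di, dj, FALSE)
  }
  out
}

# One Chebyshev dilation step; outside the image is background.
.dilate1 <- function(mask) {
  out <- mask
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0L && dj == 0L) next
    out <- out | .shift_mat(mask, di, dj, FALSE)
  }
  out
}

# Erode/dilate a logical mask by `w` Chebyshev steps (3x3 box, iterated).
# Iterating a unit box w times equals a single (2w+1)x(2w+1) box, i.e. the
# set of pixels at Chebyshev distance <= w.
.cheb_erode <- function(mask, w) {
  for (i in seq_len(w)) mask <- .erode1(mask)
  mask
}

.cheb_dilate <- function(mask, w) {
  for (i in seq_len(w)) mask <- .dilate1(mask)
  mask
}
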