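# Independent brute-force oracles for the geometric operations, written
# directly from the definitions (one-shot neighbourhood scans and scalar
# BFS), deliberately not sharing code with the package's iterated-morphology
# implementation.

# Value of m at (i+di, j+dj), with positions outside the matrix reading as
# `outside`.
.at <- function(m, i, j, outside) {
  nr <- nrow(m); nc <- ncol(m)
  if (i < 1 || i > nr || j < 1 || j > nc) outside else m[i, j]
}

# Per-pixel scan: is any position within Chebyshev distance w of (i, j)
# background for this mask? Outside the image counts as background.
oracle_ring_pixel <- function(mask, i, j, w) {
  for (di in -w:w) for (dj in -w:w) {
    if (!.at(mask, i + di, j + dj, FALSE)) return(TRUE)
  }
  FALSE
}

# PM ring by direct definition: cell pixels whose Chebyshev distance to the
# nearest non-cell pixel is <= w. Fully per-pixel; use on small masks.
oracle_pm_ring_slow <- function(cell_labels, w) {
  out <- matrix(0L, nrow(cell_labels), ncol(cell_labels))
  for (i in seq_len(nrow(cell_labels))) for (j in seq_len(ncol(cell_labels))) {
    l <- cell_labels[i, j]
    if (l > 0 && oracle_ring_pixel(cell_labels == l, i, j, w)) out[i, j] <- l
  }
  out
}

# Same definition evaluated as a one-shot (2w+1)^2 neighbourhood union,
# vectorized with explicit index arithmetic (no iterated morphology).
oracle_pm_ring <- function(cell_labels, w) {
  nr <- nrow(cell_labels); nc <- ncol(cell_labels)
  out <- matrix(0L, nr, nc)
  for (l in sort(unique(cell_labels[cell_labels > 0]))) {
    bg <- cell_labels != l
    near_bg <- matrix(FALSE, nr, nc)
    for (di in -w:w) for (dj in -w:w) {
      shifted <- matrix(TRUE, nr, nc)  # outside the image = background
      si <- seq_len(nr) + di; sj <- seq_len(nc) + dj
      oi <- si >= 1 & si <= nr; oj <- sj >= 1 & sj <= nc
      shifted[oi, oj] <- bg[si[oi], sj[oj]]
      near_bg <- near_bg | shifted
    }
    out[(cell_labels == l) & near_bg] <- l
  }
  out
}

# Perinuclear ring by direct definition: pixels of cell l, outside its
# nucleus, with some nucleus-l pixel within Chebyshev distance w.
oracle_peri_ring <- function(nucleus_labels, cell_labels, w) {
  nr <- nrow(cell_labels); nc <- ncol(cell_labels)
  out <- matrix(0L, nr, nc)
  for (l in sort(unique(cell_labels[cell_labels > 0]))) {
    nuc <- nucleus_labels == l
    near_nuc <- matrix(FALSE, nr, nc)
    for (di in -w:w) for (dj in -w:w) {
      shifted <- matrix(FALSE, nr, nc)
      si <- seq_len(nr) + di; sj <- seq_len(nc) + dj
      oi <- si >= 1 & si <= nr; oj <- sj >= 1 & sj <= nc
      shifted[oi, oj] <- nuc[si[oi], sj[oj]]
      near_nuc <- near_nuc | shifted
    }
    out[(cell_labels == l) & !nuc & near_nuc] <- l
  }
  out
}

# Scalar queue BFS: geodesic Chebyshev distance within `fg` from a seed set.
oracle_geodesic_dist <- function(fg, seed_mask) {
  dist <- matrix(Inf, nrow(fg), ncol(fg))
  q <- which(seed_mask & fg)
  dist[q] <- 0
  nr <- nrow(fg)
  while (length(q)) {
    nq <- integer(0)
    for (p in q) {
      i <- (p - 1) %% nr + 1; j <- (p - 1) %/% nr + 1
      for (di in -1:1) for (dj in -1:1) {
        ii <- i + di; jj <- j + dj
        if (ii < 1 || ii > nr || jj < 1 || jj > ncol(fg)) next
        if (fg[ii, jj] && dist[ii, jj] > dist[i, j] + 1) {
          dist[ii, jj] <- dist[i, j] + 1
          nq <- c(nq, (jj - 1) * nr + ii)
        }
      }
    }
    q <- unique(nq)
  }
  dist
}

# Nearest-seed assignment of the foreground: per-seed geodesic distance
# maps, argmin per pixel, ties to the lower label, unreachable -> 0.
oracle_assign_seeds <- function(fg, seeds) {
  ids <- sort(unique(seeds[seeds > 0]))
  dists <- lapply(ids, function(l) oracle_geodesic_dist(fg, seeds == l))
  out <- matrix(0L, nrow(fg), ncol(fg))
  for (p in which(fg)) {
    dv <- vapply(dists, function(d) d[p], numeric(1))
    if (all(is.infinite(dv))) next
    out[p] <- ids[which.min(dv)]  # which.min takes the first (lowest) label
  }
  out
}

# Random connected blobs with a nucleus inside each: random-walk visited
# sets started at well-spread centers. Returns nucleus and cell label
# matrices (labels match; nuclei non-empty and contained by construction).
random_blob_labels <- function(nr = 64, nc = 64, n_blobs = 3, walk_len = 120,
                               nucleus_len = 8) {
  cells <- matrix(0L, nr, nc)
  nuclei <- matrix(0L, nr, nc)
  centers <- cbind(sample(5:(nr - 4), n_blobs), sample(5:(nc - 4), n_blobs))
  for (l in seq_len(n_blobs)) {
    i <- centers[l, 1]; j <- centers[l, 2]
    visited <- matrix(FALSE, nr, nc)
    path_i <- integer(walk_len); path_j <- integer(walk_len)
    for (s in seq_len(walk_len)) {
      visited[i, j] <- TRUE
      path_i[s] <- i; path_j[s] <- j
      i <- min(max(i + sample(-1:1, 1), 2L), nr - 1L)
      j <- min(max(j + sample(-1:1, 1), 2L), nc - 1L)
    }
    claim <- visited & cells == 0L
    if (!any(claim)) next
    # keep only the connected component containing the walk start, so the
    # claimed region stays connected even where another blob overlapped
    comp <- oracle_geodesic_dist(claim, {
      s0 <- matrix(FALSE, nr, nc)
      start_idx <- which(claim)[1]
      s0[start_idx] <- TRUE
      s0
    })
    claim <- is.finite(comp)
    cells[claim] <- l
    first_on <- which(claim[cbind(path_i, path_j)])[seq_len(nucleus_len)]
    first_on <- first_on[!is.na(first_on)]
    nuclei[cbind(path_i[first_on], path_j[first_on])] <- l
  }
  # drop labels whose blob vanished entirely
  keep <- intersect(sort(unique(cells[cells > 0])),
                    sort(unique(nuclei[nuclei > 0])))
  cells[!cells %in% keep] <- 0L
  nuclei[!nuclei %in% keep] <- 0L
  list(nuclei = nuclei, cells = cells)
}

# A field-like object from plain matrices.
as_field <- function(nuclear, target = nuclear, well_id = "A01",
                     field_index = 0L) {
  structure(list(nuclear = nuclear, target = target, well_id = well_id,
                 field_index = as.integer(field_index)),
            class = "field_image")
}
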