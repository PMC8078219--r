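#' Membrane ring geometry
#'
#' The membrane signal of a cell is measured in an annulus ("ring") around its
#' nucleus: the ring starts `inner_margin` pixels outside the nucleus boundary
#' and is `thickness` pixels wide. Dilation is Euclidean (a pixel is inside
#' the dilation by radius r iff its distance to the nearest nucleus pixel is
#' <= r). The defaults (1 px margin, 3 px width) place a 3-pixel-wide band
#' over the plasma membrane of typical lymphocytes at confocal resolution.
#'
#' @param inner_margin Pixels between the nucleus boundary and the ring's
#'   inner edge (>= 0).
#' @param thickness Ring width in pixels (>= 1).
#' @return An object of class `ring_spec`.
#' @export
ring_spec <- function(inner_margin = 1, thickness = 3) {
  if (inner_margin < 0 || thickness < 1)
    stop_histocyto("inner_margin must be >= 0 and thickness >= 1", "argument_error")
  structure(list(inner_margin = inner_margin, thickness = thickness),
            class = "ring_spec")
}

#' Read a labeled-nucleus TIFF volume
#'
#' @param path Multi-page TIFF of integer nucleus labels (0 = background,
#'   k = nucleus of cell k); one page per optical slice.
#' @return Integer array `[y, x, slice]`.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop_histocyto(paste0("label image not found: ", path), "io_error")
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0L, dim = c(nrow(pages[[1]]), ncol(pages[[1]]), length(pages)))
  for (s in seq_along(pages)) arr[, , s] <- pages[[s]]
  storage.mode(arr) <- "integer"
  arr
}

#' Central optical section of each nucleus
#'
#' For each labeled nucleus, the slice on which its cross-sectional pixel area
#' is largest; ties are broken toward the lowest slice index. All 2D
#' measurements of a cell are taken on this slice.
#'
#' @param labels Integer array `[y, x, slice]` of nucleus labels.
#' @return Named integer vector mapping label id to central slice.
#' @export
central_slice <- function(labels) {
  if (length(dim(labels)) == 2) dim(labels) <- c(dim(labels), 1)
  d <- dim(labels)
  nmax <- max(labels, 0L)
  if (nmax == 0) return(stats::setNames(integer(0), character(0)))
  counts <- matrix(0L, nmax, d[3])
  for (s in seq_len(d[3])) counts[, s] <- tabulate(labels[, , s], nbins = nmax)
  ids <- which(rowSums(counts) > 0)
  stats::setNames(apply(counts[ids, , drop = FALSE], 1, which.max), ids)
}

# Bounding window of a logical mask, padded and clipped to the matrix.
.mask_window <- function(mask, pad) {
  idx <- which(mask, arr.ind = TRUE)
  list(r0 = max(1, min(idx[, 1]) - pad), r1 = min(nrow(mask), max(idx[, 1]) + pad),
       c0 = max(1, min(idx[, 2]) - pad), c1 = min(ncol(mask), max(idx[, 2]) + pad))
}

#' Build the membrane ring of one cell
#'
#' The ring is the Euclidean annulus `inner_margin < d <= inner_margin +
#' thickness` around the cell's nucleus cross-section on the given slice,
#' where `d` is the distance to the nearest nucleus pixel. In dense tissue the
#' annuli of adjacent cells can overlap; contested pixels are assigned to the
#' cell whose nucleus is nearest (ties to the lower cell id), so no pixel is
#' counted in two rings. The outer boundary of the (unrestricted) annulus is
#' traced into the cell's contour polygon — the shape saved to roi.zip and
#' used for morphology.
#'
#' @param labels Integer array `[y, x, slice]` of nucleus labels.
#' @param coi_id Cell id; must be present on `slice`.
#' @param slice 1-based slice index.
#' @param spec A [ring_spec].
#' @return List with `pixels` (2-column matrix of 1-based `(row, col)` ring
#'   pixel positions after territory exclusion), `polygon` (a [roi_polygon]
#'   in 0-based image coordinates) and `degenerate` (`TRUE` when the ring is
#'   empty after exclusion; intensities then become `NA`).
#' @export
membrane_ring <- function(labels, coi_id, slice, spec = ring_spec()) {
  if (length(dim(labels)) == 2) dim(labels) <- c(dim(labels), 1)
  page <- labels[, , slice]
  own <- page == coi_id
  if (!any(own))
    stop_histocyto(paste0("cell ", coi_id, " has no pixels on slice ", slice),
                   "argument_error")
  R <- spec$inner_margin + spec$thickness
  w <- .mask_window(own, pad = 2 * R + 2)
  win <- page[w$r0:w$r1, w$c0:w$c1, drop = FALSE]
  win_own <- win == coi_id
  dn <- EBImage::distmap(1 - win_own)
  ring <- dn > spec$inner_margin & dn <= R
  outer <- dn <= R
  # territory: a contested pixel belongs to the nearest nucleus (lower id wins ties)
  others <- sort(setdiff(unique(as.vector(win)), c(0L, coi_id)))
  if (length(others) && any(ring)) {
    d_min <- matrix(Inf, nrow(win), ncol(win))
    owner <- matrix(NA_integer_, nrow(win), ncol(win))
    for (o in others) {
      d_o <- EBImage::distmap(1 - (win == o))
      upd <- d_o < d_min
      d_min[upd] <- d_o[upd]
      owner[upd] <- o
    }
    keep <- dn < d_min | (dn == d_min & coi_id < owner)
    keep[is.na(keep)] <- TRUE
    ring <- ring & keep
  }
  idx <- which(ring, arr.ind = TRUE)
  degenerate <- nrow(idx) == 0
  if (degenerate)
    warn_histocyto(paste0("degenerate ring for cell ", coi_id,
                          ": empty after territory exclusion"),
                   "degenerate_ring_warning")
  pixels <- cbind(row = idx[, 1] + w$r0 - 1L, col = idx[, 2] + w$c0 - 1L)
  polygon <- .trace_polygon(outer, coi_id, slice, row_off = w$r0, col_off = w$c0)
  list(pixels = pixels, polygon = polygon, degenerate = degenerate)
}

# Trace the largest closed contour of a mask into a roi_polygon.
# ocontour returns 0-based (row, col) pairs; image coordinates are
# x = col (0-based), y = row (0-based).
.trace_polygon <- function(mask, coi_id, slice, row_off = 1L, col_off = 1L) {
  oc <- EBImage::ocontour(mask)
  if (length(oc) == 0) stop_histocyto("cannot trace an empty mask", "argument_error")
  cont <- oc[[which.max(vapply(oc, nrow, numeric(1)))]]
  x <- cont[, 2] + (col_off - 1L)
  y <- cont[, 1] + (row_off - 1L)
  if (length(x) < 3) {  # degenerate 1-2 pixel mask: use its pixel square
    x <- c(x[1], x[1] + 1, x[1] + 1, x[1])
    y <- c(y[1], y[1], y[1] + 1, y[1] + 1)
  }
  roi_polygon(coi_id, slice, cbind(x = x, y = y))
}

#' Mean channel intensities within a ring
#'
#' Per-channel mean of the pixel values at the ring positions on the given
#' slice. 16-bit data are rescaled linearly from \[0, 65535\] to \[0, 255\]
#' first, so intensities are comparable across images. The mean (rather than
#' median or integrated density) is used as the ring statistic.
#'
#' @param stack An [image_stack].
#' @param ring Result of [membrane_ring()], or a 2-column `(row, col)` matrix.
#' @param slice 1-based slice index.
#' @return Named numeric vector (one mean per channel, named by the legend
#'   labels), all `NA` for an empty ring.
#' @export
measure_coi <- function(stack, ring, slice) {
  stopifnot(inherits(stack, "image_stack"))
  px <- if (is.list(ring)) ring$pixels else ring
  labels <- unclass(stack$legend)
  out <- stats::setNames(rep(NA_real_, stack$n_channels), labels)
  if (is.null(px) || nrow(px) == 0) return(out)
  rescale <- if (stack$bit_depth == 16) 255 / 65535 else 1
  for (ch in seq_len(stack$n_channels)) {
    out[ch] <- mean(stack$pixels[cbind(px[, 1], px[, 2], ch, slice)]) * rescale
  }
  out
}

#' Morphology of a contour polygon
#'
#' Area by the shoelace formula (pixels^2), circularity `4*pi*area/perimeter^2`
#' (1 for a perfect circle, clamped to <= 1) and solidity `area / convex hull
#' area` (1 for convex shapes).
#'
#' @param polygon A [roi_polygon] or a 2-column vertex matrix (>= 3 vertices).
#' @return Named numeric vector `c(area, circularity, solidity)`.
#' @export
morphology <- function(polygon) {
  v <- if (inherits(polygon, "roi_polygon")) polygon$vertices else as.matrix(polygon)
  if (is.null(dim(v)) || ncol(v) != 2 || nrow(v) < 3)
    stop_histocyto("morphology needs a polygon with >= 3 vertices", "argument_error")
  x <- v[, 1]; y <- v[, 2]
  shoelace <- function(x, y) {
    xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
    abs(sum(x * yn - xn * y)) / 2
  }
  area <- shoelace(x, y)
  per <- sum(sqrt(diff(c(x, x[1]))^2 + diff(c(y, y[1]))^2))
  circ <- if (per > 0) min(1, 4 * pi * area / per^2) else 0
  h <- grDevices::chull(x, y)
  hull_area <- shoelace(x[h], y[h])
  sol <- if (hull_area > 0) min(1, area / hull_area) else 1
  c(area = area, circularity = circ, solidity = sol)
}

#' Measure every cell of a labeled nucleus volume
#'
#' The native measurement stage: for each nucleus label, pick the central
#' slice (largest cross-section), build the membrane ring there, measure the
#' per-channel ring means and the outer-polygon morphology, and record the
#' nucleus centroid. This replaces the ImageJ-macro measurement step of a
#' Fiji-based segmentation pipeline; nucleus detection itself is an input.
#'
#' @param stack An [image_stack].
#' @param labels Integer array `[y, x, slice]` of nucleus labels with the same
#'   y/x/slice geometry as `stack`.
#' @param spec A [ring_spec].
#' @return List with `table` (a [coi_table] with columns `coi_id`, one
#'   intensity column per channel, `x`, `y` (0-based centroid of the nucleus
#'   cross-section on the central slice), `z` (central slice), `area`,
#'   `circularity`, `solidity`) and `rois` (a [roi_set] of outer polygons).
#' @export
run_measurement <- function(stack, labels, spec = ring_spec()) {
  stopifnot(inherits(stack, "image_stack"))
  if (length(dim(labels)) == 2) dim(labels) <- c(dim(labels), 1)
  d <- dim(labels)
  if (d[1] != stack$height || d[2] != stack$width || d[3] != stack$n_slices)
    stop_histocyto(paste0("label geometry ", d[1], "x", d[2], "x", d[3],
                          " does not match image ", stack$height, "x",
                          stack$width, "x", stack$n_slices), "dimension_error")
  centers <- central_slice(labels)
  ids <- as.integer(names(centers))
  labs <- unclass(stack$legend)
  n <- length(ids)
  inten <- matrix(NA_real_, n, stack$n_channels, dimnames = list(NULL, labs))
  geom <- matrix(NA_real_, n, 6,
                 dimnames = list(NULL, c("x", "y", "z", "area", "circularity", "solidity")))
  rois <- vector("list", n)
  for (i in seq_len(n)) {
    id <- ids[i]; s <- centers[[i]]
    ring <- membrane_ring(labels, id, s, spec)
    inten[i, ] <- measure_coi(stack, ring, s)
    npx <- which(labels[, , s] == id, arr.ind = TRUE)
    m <- morphology(ring$polygon)
    geom[i, ] <- c(mean(npx[, 2]) - 1, mean(npx[, 1]) - 1, s, m)
    rois[[i]] <- ring$polygon
  }
  df <- data.frame(coi_id = ids)
  if (n == 0) {
    inten <- matrix(numeric(0), 0, stack$n_channels, dimnames = list(NULL, labs))
    geom <- matrix(numeric(0), 0, 6,
                   dimnames = list(NULL, c("x", "y", "z", "area", "circularity", "solidity")))
  }
  df <- cbind(df, as.data.frame(inten), as.data.frame(geom))
  list(table = coi_table(df, channels = labs),
       rois = roi_set(rois))
}
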