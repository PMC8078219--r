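#' Density-based tissue-region detection (DBSCAN)
#'
#' Standard DBSCAN over 2D cell centroids with Euclidean distance: a core
#' point has at least `min_pts` neighbors within `eps` (itself included);
#' clusters are the sets of core points connected through eps-reachability
#' plus their border points; everything else is noise. Border points reachable
#' from several clusters are assigned to the cluster discovered first when
#' processing points in ascending order, which makes the labeling independent
#' of input ordering.
#'
#' @param points Two-column matrix/data.frame of (x, y) centroids.
#' @param eps Neighborhood radius in pixels (> 0). The default (50 px) is an
#'   arbitrary starting point; `eps` should be tuned to roughly twice the
#'   typical cell spacing inside the regions of interest.
#' @param min_pts Minimum neighborhood size for a core point (>= 1), self
#'   included. Default 5.
#' @param ids Optional cell ids parallel to `points` (default row numbers).
#' @return An object of class `region_labeling`: list with `eps`, `min_pts`,
#'   `ids`, `cluster` (integer cluster id per point, 0-based; -1 = noise) and
#'   `flag` (1 when the point belongs to any cluster, 0 otherwise).
#' @export
dbscan_regions <- function(points, eps = 50, min_pts = 5, ids = NULL) {
  if (!is.numeric(eps) || eps <= 0) stop_histocyto("eps must be > 0", "argument_error")
  if (!is_count(min_pts)) stop_histocyto("min_pts must be a positive integer", "argument_error")
  pts <- as.matrix(points)
  n <- nrow(pts) %||% 0
  if (is.null(ids)) ids <- seq_len(n)
  if (n == 0)
    return(structure(list(eps = eps, min_pts = min_pts, ids = integer(0),
                          cluster = integer(0), flag = integer(0)),
                     class = "region_labeling"))
  ord <- order(ids)
  pts <- pts[ord, , drop = FALSE]; ids <- ids[ord]
  D <- as.matrix(stats::dist(pts[, 1:2, drop = FALSE]))
  nb <- lapply(seq_len(n), function(i) which(D[i, ] <= eps))
  core <- vapply(nb, length, integer(1)) >= min_pts
  cluster <- rep(-1L, n)
  next_id <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || cluster[i] >= 0) next
    cluster[i] <- next_id
    queue <- nb[[i]]
    while (length(queue)) {
      j <- queue[1]; queue <- queue[-1]
      if (cluster[j] < 0) {
        cluster[j] <- next_id
        if (core[j]) queue <- c(queue, nb[[j]][cluster[nb[[j]]] < 0])
      }
    }
    next_id <- next_id + 1L
  }
  structure(list(eps = eps, min_pts = min_pts, ids = ids,
                 cluster = cluster, flag = as.integer(cluster >= 0)),
            class = "region_labeling")
}

#' @export
print.region_labeling <- function(x, ...) {
  k <- length(unique(x$cluster[x$cluster >= 0]))
  cat("<region_labeling> ", length(x$ids), " point(s), ", k, " cluster(s), ",
      sum(x$cluster < 0), " noise; eps=", x$eps, ", min_pts=", x$min_pts,
      "\n", sep = "")
  invisible(x)
}

#' Write DBSCAN membership into the region flag column
#'
#' Sets the table's `ROI_DBSCAN` column to 1 for cells inside any density
#' region and 0 otherwise.
#'
#' @param table A [coi_table].
#' @param labeling A `region_labeling` from [dbscan_regions()] covering every
#'   id of `table`.
#' @return The updated [coi_table].
#' @export
assign_region_flag <- function(table, labeling) {
  stopifnot(inherits(table, "coi_table"), inherits(labeling, "region_labeling"))
  m <- match(table$coi_id, labeling$ids)
  if (anyNA(m))
    stop_histocyto(paste0("labeling does not cover table ids: ",
                          paste(table$coi_id[is.na(m)], collapse = ",")),
                   "integrity_error")
  table$ROI_DBSCAN <- labeling$flag[m]
  table
}

#' Flag cell contacts with a partner-cell mask
#'
#' A cell interacts (flag 1) when its outer contour polygon, dilated by
#' `contact_dist` pixels (Euclidean), overlaps at least one partner-positive
#' pixel on the cell's own optical slice. Equivalently: some partner pixel
#' lies within `contact_dist` of the filled polygon.
#'
#' @param rois A [roi_set] of cell contours.
#' @param partner_mask Logical/0-1 array `[y, x, slice]` (or matrix for a
#'   single slice) marking partner-cell pixels, in the same geometry as the
#'   image the contours live in.
#' @param contact_dist Contact distance in pixels (>= 0).
#' @return Named integer vector (0/1) keyed by cell id.
#' @export
detect_interactions <- function(rois, partner_mask, contact_dist = 2) {
  stopifnot(inherits(rois, "roi_set"))
  if (length(dim(partner_mask)) == 2) dim(partner_mask) <- c(dim(partner_mask), 1)
  if (contact_dist < 0) stop_histocyto("contact_dist must be >= 0", "argument_error")
  d <- dim(partner_mask)
  out <- stats::setNames(integer(length(rois)), names(rois))
  for (k in seq_along(rois)) {
    r <- rois[[k]]
    if (r$slice > d[3])
      stop_histocyto(paste0("cell ", r$coi_id, " lies on slice ", r$slice,
                            " but the partner mask has ", d[3], " slice(s)"),
                     "dimension_error")
    pad <- ceiling(contact_dist) + 1L
    # polygon vertices are 0-based; rows/cols are 1-based
    r0 <- max(1, min(r$vertices[, 2]) + 1 - pad)
    r1 <- min(d[1], max(r$vertices[, 2]) + 1 + pad)
    c0 <- max(1, min(r$vertices[, 1]) + 1 - pad)
    c1 <- min(d[2], max(r$vertices[, 1]) + 1 + pad)
    win_mask <- rasterize_polygon(r$vertices, r0, r1, c0, c1)
    dpoly <- EBImage::distmap(1 - win_mask)
    partner <- partner_mask[r0:r1, c0:c1, r$slice] > 0
    out[k] <- as.integer(any(partner & dpoly <= contact_dist))
  }
  out
}

# Fill a polygon (0-based x/y vertices) on the 1-based window [r0:r1, c0:c1];
# boundary pixels are included.
rasterize_polygon <- function(vertices, r0, r1, c0, c1) {
  rows <- r0:r1; cols <- c0:c1
  px <- rep(cols - 1, each = length(rows))   # x of every window pixel
  py <- rep(rows - 1, times = length(cols))  # y
  inside <- point_in_polygon(px, py, vertices[, 1], vertices[, 2])
  matrix(as.numeric(inside), nrow = length(rows), ncol = length(cols))
}

#' Point-in-polygon test (boundary inclusive)
#'
#' Vectorized crossing-number (ray casting) test; points lying exactly on a
#' polygon edge or vertex count as inside. Used by lasso gates, region
#' selections and polygon rasterization.
#'
#' @param px,py Coordinates of the query points.
#' @param vx,vy Polygon vertex coordinates (>= 3 vertices, closed implicitly).
#' @param tol Tolerance for the on-edge test.
#' @return Logical vector.
#' @export
point_in_polygon <- function(px, py, vx, vy, tol = 1e-9) {
  n <- length(vx)
  if (n < 3) stop_histocyto("polygon needs >= 3 vertices", "argument_error")
  inside <- rep(FALSE, length(px))
  on_edge <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    x1 <- vx[j]; y1 <- vy[j]; x2 <- vx[i]; y2 <- vy[i]
    # on-segment: collinear and within the segment's bounding box
    cross <- (x2 - x1) * (py - y1) - (y2 - y1) * (px - x1)
    seg_len2 <- (x2 - x1)^2 + (y2 - y1)^2
    col_ok <- abs(cross) <= tol * max(1, sqrt(seg_len2))
    within <- px >= pmin(x1, x2) - tol & px <= pmax(x1, x2) + tol &
      py >= pmin(y1, y2) - tol & py <= pmax(y1, y2) + tol
    on_edge <- on_edge | (col_ok & within)
    # crossing number (half-open rule avoids double-counting vertices)
    crosses <- ((y1 > py) != (y2 > py)) &
      (px < (x2 - x1) * (py - y1) / (y2 - y1) + x1)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside | on_edge
}

#' Cells inside an image region ("Image to Plot")
#'
#' Returns the ids of cells whose centroid lies inside (or on the boundary of)
#' a region polygon drawn on the image, optionally restricted to one optical
#' slice. The returned subset is what gets displayed on a linked
#' two-parameter scatterplot.
#'
#' @param table A [coi_table] with `x`/`y` columns in the coordinates of the
#'   image as loaded.
#' @param region Two-column vertex matrix (x, y) or a [roi_polygon].
#' @param slice_filter Optional slice index; when given, only cells whose
#'   `z` (rounded) equals it are considered.
#' @return Integer vector of cell ids, in table order.
#' @export
cells_in_region <- function(table, region, slice_filter = NULL) {
  stopifnot(inherits(table, "coi_table"))
  v <- if (inherits(region, "roi_polygon")) region$vertices else as.matrix(region)
  if (is.null(dim(v)) || ncol(v) != 2 || nrow(v) < 3)
    stop_histocyto("region must be a polygon with >= 3 vertices", "argument_error")
  if (!all(c("x", "y") %in% names(table)))
    stop_histocyto("table needs x and y columns", "argument_error")
  keep <- point_in_polygon(table$x, table$y, v[, 1], v[, 2])
  if (!is.null(slice_filter)) {
    if (!"z" %in% names(table))
      stop_histocyto("slice_filter requires a z column", "argument_error")
    keep <- keep & round(table$z) == slice_filter
  }
  table$coi_id[keep]
}
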