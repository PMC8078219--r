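#' Synthetic tissue-scene specification
#'
#' Describes a simulated multi-channel z-stack of membrane-stained cells with
#' known ground truth, structured like the canonical analysis scenario: a
#' 6-channel, 12-slice image of 176 proliferative cells split into T, B and
#' uncharacterized populations, half of them packed into one dense
#' proliferation region, a fraction of them in contact with phagocyte blobs
#' painted on a dedicated partner channel.
#'
#' Geometry is chosen so that the planted truth is recoverable by
#' construction: nuclei are spheres (radius 4-5 px, slice spacing 2 px) whose
#' largest cross-section sits exactly on an integer slice; membranes are
#' painted as annuli covering the measurement ring; cells keep enough mutual
#' clearance that rings never overlap foreign paint; dense-region members sit
#' on a jittered grid (spacing 26 px) so DBSCAN with `eps` = twice the
#' spacing separates them from sparse cells (which keep at least `eps` + a
#' margin of clearance); phagocyte blobs are planted overlapping their
#' target's contour and clear of every other cell.
#'
#' @param n_cells Total cell count.
#' @param image_size `(X, Y)` pixel size (at most 1024 on the larger side, so
#'   bundle coordinates are already in display space).
#' @param n_slices Optical sections.
#' @param legend A [coi_legend] naming the channels.
#' @param populations List of populations, each
#'   `list(label =, fraction =, membrane = <named per-channel means>, sd =)`;
#'   fractions are normalized to sum to 1.
#' @param nuclear Named vector of nuclear-channel intensities painted inside
#'   nuclei.
#' @param nucleus_radius Range (px) of nucleus sphere radii.
#' @param slice_spacing Axial distance between slices, in pixel units.
#' @param cluster `list(fraction =, spacing =, jitter =, clearance =)` for the
#'   planted dense region.
#' @param contacts `list(fraction =, blob_radius =, partner_channel =,
#'   value =, threshold =, contact_dist =)` for planted phagocyte contacts.
#' @param noise_sd Gaussian pixel noise SD (0 disables noise).
#' @param ring A [ring_spec] used when measuring the bundle.
#' @param paint_outer Outer radius (px from the nucleus) of the painted
#'   membrane annulus; must be >= `inner_margin + thickness` of `ring`.
#' @param report_channels Channel labels whose intensities go into
#'   results.csv (the canonical table reports the T and B channels only,
#'   giving 10 parameter columns).
#' @param seed Integer seed; identical seeds give byte-identical bundles.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(n_cells = 176,
                       image_size = c(X = 1024, Y = 768),
                       n_slices = 12,
                       legend = coi_legend(c("Ki67", "LB", "LT", "Phago", "CD69", "DAPI")),
                       populations = list(
                         list(label = "T", fraction = 70 / 176,
                              membrane = c(Ki67 = 0, LB = 30, LT = 180, Phago = 0,
                                           CD69 = 60, DAPI = 0), sd = 10),
                         list(label = "B", fraction = 70 / 176,
                              membrane = c(Ki67 = 0, LB = 180, LT = 30, Phago = 0,
                                           CD69 = 0, DAPI = 0), sd = 10),
                         list(label = "neg", fraction = 36 / 176,
                              membrane = c(Ki67 = 0, LB = 30, LT = 30, Phago = 0,
                                           CD69 = 0, DAPI = 0), sd = 10)),
                       nuclear = c(Ki67 = 200, DAPI = 220),
                       nucleus_radius = c(4, 5),
                       slice_spacing = 2,
                       cluster = list(fraction = 0.5, spacing = 26, jitter = 1,
                                      clearance = 56),
                       contacts = list(fraction = 0.3, blob_radius = 2,
                                       partner_channel = "Phago", value = 200,
                                       threshold = 80, contact_dist = 2),
                       noise_sd = 5,
                       ring = ring_spec(1, 3),
                       paint_outer = 6,
                       report_channels = c("LB", "LT"),
                       seed = 1) {
  stopifnot(inherits(legend, "coi_legend"), inherits(ring, "ring_spec"))
  if (n_cells < 0) stop_histocyto("n_cells must be >= 0", "argument_error")
  if (max(image_size) > 1024)
    stop_histocyto("image_size must stay within the 1024-px display bound",
                   "argument_error")
  for (p in populations) {
    if (any(p$membrane < 0 | p$membrane > 255))
      stop_histocyto("membrane intensities must lie in [0,255]", "argument_error")
    if (!setequal(names(p$membrane), unclass(legend)))
      stop_histocyto("population membrane vectors must name every channel",
                     "argument_error")
  }
  if (paint_outer < ring$inner_margin + ring$thickness)
    stop_histocyto("paint_outer must cover the measurement ring", "argument_error")
  fr <- vapply(populations, `[[`, numeric(1), "fraction")
  for (i in seq_along(populations)) populations[[i]]$fraction <- fr[i] / sum(fr)
  structure(list(
    n_cells = as.integer(n_cells), image_size = image_size,
    n_slices = as.integer(n_slices), legend = legend,
    populations = populations, nuclear = nuclear,
    nucleus_radius = nucleus_radius, slice_spacing = slice_spacing,
    cluster = cluster, contacts = contacts, noise_sd = noise_sd,
    ring = ring, paint_outer = paint_outer,
    report_channels = report_channels, seed = as.integer(seed)
  ), class = "scene_spec")
}

#' @export
print.scene_spec <- function(x, ...) {
  cat("<scene_spec> ", x$n_cells, " cell(s), ", x$image_size[1], "x",
      x$image_size[2], " px, ", x$n_slices, " slice(s), ",
      length(x$legend), " channel(s), seed ", x$seed, "\n", sep = "")
  invisible(x)
}

# Pixel positions (1-based row/col) of the disc of radius r around the
# continuous 0-based center (cx, cy), restricted to the image.
.disc_pixels <- function(cx, cy, r, W, H) {
  if (r <= 0) return(cbind(row = integer(0), col = integer(0)))
  c0 <- max(1, floor(cx - r) + 1); c1 <- min(W, ceiling(cx + r) + 1)
  r0 <- max(1, floor(cy - r) + 1); r1 <- min(H, ceiling(cy + r) + 1)
  if (c1 < c0 || r1 < r0) return(cbind(row = integer(0), col = integer(0)))
  cols <- c0:c1; rows <- r0:r1
  g <- expand.grid(row = rows, col = cols)
  keep <- (g$col - 1 - cx)^2 + (g$row - 1 - cy)^2 <= r^2
  cbind(row = g$row[keep], col = g$col[keep])
}

.place_cluster <- function(n_in, spacing, jitter, image_size) {
  if (n_in == 0) return(list(pts = matrix(numeric(0), 0, 2), radius = 0,
                             center = c(0, 0)))
  K <- ceiling(sqrt(n_in)) + 3
  g <- expand.grid(i = -K:K, j = -K:K)
  d <- sqrt((g$i * spacing)^2 + (g$j * spacing)^2)
  ord <- order(d, g$i, g$j)
  if (length(ord) < n_in)
    stop_histocyto("cannot pack the dense region: too many cluster cells",
                   "packing_error")
  sel <- ord[seq_len(n_in)]
  R <- max(d[sel])
  center <- c(R + 22, R + 22)
  if (any(center + R + 16 > image_size))
    stop_histocyto(paste0("cannot pack the dense region (radius ", round(R),
                          " px) into the image; reduce counts or spacing"),
                   "packing_error")
  pts <- cbind(center[1] + g$i[sel] * spacing, center[2] + g$j[sel] * spacing)
  pts <- pts + matrix(stats::runif(2 * n_in, -jitter, jitter), ncol = 2)
  list(pts = pts, radius = R + jitter, center = center)
}

.place_sparse <- function(n_out, taken, min_dist, excl_center, excl_radius,
                          image_size, margin = 16) {
  pts <- matrix(numeric(0), 0, 2)
  for (k in seq_len(n_out)) {
    ok <- FALSE
    for (try in seq_len(1000)) {
      p <- c(stats::runif(1, margin, image_size[1] - 1 - margin),
             stats::runif(1, margin, image_size[2] - 1 - margin))
      if (sqrt(sum((p - excl_center)^2)) < excl_radius) next
      all_pts <- rbind(taken, pts)
      if (nrow(all_pts) &&
          min(sqrt((all_pts[, 1] - p[1])^2 + (all_pts[, 2] - p[2])^2)) < min_dist)
        next
      ok <- TRUE
      break
    }
    if (!ok)
      stop_histocyto("cannot place all sparse cells; reduce counts or spacing",
                     "packing_error")
    pts <- rbind(pts, p)
  }
  pts
}

#' Generate a complete synthetic bundle with ground truth
#'
#' Draws the scene of a [scene_spec] (one pseudo-random stream, consumed in
#' the fixed order placement, radii/slices, intensities, contacts, noise),
#' paints image and nucleus-label volumes, runs the native measurement stage
#' plus the region/interaction flagging on them, and writes the four-file
#' bundle `image.tif`, `roi.zip`, `results.csv`, `legend.csv` together with
#' `labels.tif` (the nucleus label volume) and `ground_truth.csv` (planted
#' population, position, region membership, contact flag and painted membrane
#' intensities per cell).
#'
#' @param spec A [scene_spec].
#' @param dir Output directory (created if missing).
#' @return Invisibly, a list with `dir`, the file `paths`, the measured
#'   `table` ([coi_table]), `rois` ([roi_set]), the `truth` data frame and
#'   the `spec`.
#' @export
generate_bundle <- function(spec, dir) {
  stopifnot(inherits(spec, "scene_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(spec$seed)
  W <- as.integer(spec$image_size[1]); H <- as.integer(spec$image_size[2])
  nch <- length(spec$legend); nsl <- spec$n_slices
  labs <- unclass(spec$legend)
  n <- spec$n_cells

  ## 1. placement -------------------------------------------------------
  n_in <- round((spec$cluster$fraction %||% 0) * n)
  cl <- .place_cluster(n_in, spec$cluster$spacing, spec$cluster$jitter,
                       c(W, H))
  sparse <- .place_sparse(n - n_in, cl$pts, spec$cluster$clearance %||% 56,
                          cl$center, cl$radius + (spec$cluster$clearance %||% 56),
                          c(W, H))
  pos <- rbind(cl$pts, sparse)
  in_cluster <- c(rep(1L, n_in), rep(0L, n - n_in))

  ## 2. radii, central slices, populations ------------------------------
  radius <- if (n) stats::runif(n, spec$nucleus_radius[1], spec$nucleus_radius[2]) else numeric(0)
  dz <- spec$slice_spacing
  span <- ceiling(max(spec$nucleus_radius) / dz)
  if (nsl < 2 * span + 1)
    stop_histocyto("not enough slices to hold the nucleus spheres", "argument_error")
  zc <- if (n) sample((1 + span):(nsl - span), n, replace = TRUE) else integer(0)
  pop_labels <- vapply(spec$populations, `[[`, character(1), "label")
  pop_counts <- round(vapply(spec$populations, `[[`, numeric(1), "fraction") * n)
  while (sum(pop_counts) < n) pop_counts[1] <- pop_counts[1] + 1
  while (sum(pop_counts) > n) pop_counts[which.max(pop_counts)] <- max(pop_counts) - 1
  pop <- if (n) sample(rep(pop_labels, pop_counts)) else character(0)

  ## 3. per-cell membrane intensities -----------------------------------
  memb <- matrix(0, n, nch, dimnames = list(NULL, labs))
  for (i in seq_len(n)) {
    p <- spec$populations[[match(pop[i], pop_labels)]]
    memb[i, ] <- round(clamp(stats::rnorm(nch, p$membrane[labs], p$sd), 0, 255))
  }

  ## 4. contacts --------------------------------------------------------
  n_contact <- round((spec$contacts$fraction %||% 0) * n)
  contact <- rep(0L, n)
  blob <- matrix(numeric(0), 0, 3)  # (x, y, slice)
  blob_r <- spec$contacts$blob_radius %||% 2
  ring_total <- spec$ring$inner_margin + spec$ring$thickness
  if (n_contact > 0) {
    cand <- sample(n)
    for (i in cand) {
      if (sum(contact) >= n_contact) break
      placed <- FALSE
      for (try in seq_len(16)) {
        ang <- stats::runif(1, 0, 2 * pi)
        dc <- radius[i] + ring_total + blob_r - 1
        bc <- pos[i, ] + dc * c(cos(ang), sin(ang))
        if (any(bc < blob_r + 1) || bc[1] > W - 2 - blob_r || bc[2] > H - 2 - blob_r) next
        others <- pos[-i, , drop = FALSE]
        if (nrow(others) &&
            min(sqrt((others[, 1] - bc[1])^2 + (others[, 2] - bc[2])^2)) <
            max(spec$nucleus_radius) + ring_total + blob_r +
            (spec$contacts$contact_dist %||% 2) + 2) next
        blob <- rbind(blob, c(bc, zc[i]))
        contact[i] <- 1L
        placed <- TRUE
        break
      }
    }
  }

  ## 5. paint volumes ---------------------------------------------------
  img <- array(0, dim = c(H, W, nch, nsl))
  lab <- array(0L, dim = c(H, W, nsl))
  nuc_idx <- match(names(spec$nuclear), labs)
  for (i in seq_len(n)) {
    for (t in seq_len(nsl)) {
      rt2 <- radius[i]^2 - ((t - zc[i]) * dz)^2
      if (rt2 <= 0) next
      px <- .disc_pixels(pos[i, 1], pos[i, 2], sqrt(rt2), W, H)
      lab[cbind(px[, 1], px[, 2], t)] <- i
      for (k in seq_along(nuc_idx))
        img[cbind(px[, 1], px[, 2], nuc_idx[k], t)] <- spec$nuclear[k]
    }
    # membrane annulus on the central slice, from the rasterized nucleus
    pad <- ceiling(radius[i]) + spec$paint_outer + 2
    r0 <- max(1, floor(pos[i, 2]) - pad); r1 <- min(H, ceiling(pos[i, 2]) + pad)
    c0 <- max(1, floor(pos[i, 1]) - pad); c1 <- min(W, ceiling(pos[i, 1]) + pad)
    win_own <- lab[r0:r1, c0:c1, zc[i]] == i
    dn <- EBImage::distmap(1 - win_own)
    ann <- which(dn > 0 & dn <= spec$paint_outer, arr.ind = TRUE)
    for (ch in seq_len(nch)) {
      if (memb[i, ch] > 0)
        img[cbind(ann[, 1] + r0 - 1L, ann[, 2] + c0 - 1L, ch, zc[i])] <- memb[i, ch]
    }
  }
  partner_ch <- match(spec$contacts$partner_channel %||% "Phago", labs)
  if (nrow(blob) && !is.na(partner_ch)) {
    for (b in seq_len(nrow(blob))) {
      px <- .disc_pixels(blob[b, 1], blob[b, 2], blob_r, W, H)
      img[cbind(px[, 1], px[, 2], partner_ch, blob[b, 3])] <- spec$contacts$value %||% 200
    }
  }

  ## 6. noise -----------------------------------------------------------
  if (spec$noise_sd > 0) {
    for (s in seq_len(nsl)) for (ch in seq_len(nch)) {
      img[, , ch, s] <- clamp(round(img[, , ch, s] +
                                      stats::rnorm(H * W, 0, spec$noise_sd)), 0, 255)
    }
  }

  ## 7. measure + flags -------------------------------------------------
  stack <- image_stack(img, spec$legend, bit_depth = 8)
  meas <- run_measurement(stack, lab, spec$ring)
  table <- meas$table; rois <- meas$rois
  if (n > 0) {
    mask <- if (!is.na(partner_ch)) {
      stack$pixels[, , partner_ch, , drop = TRUE] > (spec$contacts$threshold %||% 80)
    } else array(FALSE, dim = c(H, W, nsl))
    if (length(dim(mask)) == 2) dim(mask) <- c(H, W, 1)
    table$interaction <- as.integer(
      detect_interactions(rois, mask, spec$contacts$contact_dist %||% 2))
    labeling <- dbscan_regions(cbind(table$x, table$y),
                               eps = 2 * spec$cluster$spacing,
                               min_pts = 5, ids = table$coi_id)
    table <- assign_region_flag(table, labeling)
  } else {
    table$interaction <- integer(0)
    table$ROI_DBSCAN <- integer(0)
  }
  drop_ch <- setdiff(labs, spec$report_channels)
  out_tab <- as.data.frame(table)[, setdiff(names(table), drop_ch), drop = FALSE]
  out_tab <- coi_table(out_tab, channels = intersect(spec$report_channels, names(out_tab)))

  ## 8. write bundle ----------------------------------------------------
  paths <- list(
    image = file.path(dir, "image.tif"),
    labels = file.path(dir, "labels.tif"),
    rois = file.path(dir, "roi.zip"),
    results = file.path(dir, "results.csv"),
    legend = file.path(dir, "legend.csv"),
    truth = file.path(dir, "ground_truth.csv"))
  write_stack(stack, paths$image)
  lab_arr <- array(as.numeric(lab), dim = c(H, W, 1, nsl))
  write_stack(lab_arr, paths$labels, bit_depth = 16)
  suppressWarnings(write_roi_archive(rois, paths$rois))
  write_results(out_tab, paths$results)
  write_legend(spec$legend, paths$legend)
  truth <- data.frame(
    coi_id = seq_len(n),
    population = pop,
    x_true = if (n) pos[, 1] else numeric(0),
    y_true = if (n) pos[, 2] else numeric(0),
    radius = radius, central_slice = zc,
    in_cluster = in_cluster, contact = contact)
  if (n) truth <- cbind(truth, stats::setNames(as.data.frame(memb),
                                               paste0("paint_", labs)))
  utils::write.csv(truth, paths$truth, row.names = FALSE)
  invisible(list(dir = dir, paths = paths, table = out_tab, rois = rois,
                 truth = truth, spec = spec))
}

#' Score pipeline recovery of a synthetic bundle's planted truth
#'
#' Re-runs the full pipeline from the files on disk — load the stack and
#' labels, measure rings and morphology, threshold the partner channel and
#' flag contacts, run DBSCAN region detection, then the canonical
#' filter/quadrant/symbol-class gating — and scores every stage against the
#' generator's ground truth.
#'
#' @param dir Bundle directory written by [generate_bundle()].
#' @param spec The [scene_spec] the bundle was generated with (supplies ring
#'   geometry, DBSCAN and contact parameters).
#' @param quadrant_thresholds `(x, y)` intensity thresholds for the T/B
#'   quadrant split; default halfway between the planted positive and
#'   negative membrane levels of the first two populations.
#' @return A list of class `e2e_report`: recovery percentages for T/B
#'   identity, region membership and contact flags, intensity-recovery
#'   errors on the reported channels, and the underlying tables.
#' @export
end_to_end_check <- function(dir, spec, quadrant_thresholds = NULL) {
  stopifnot(inherits(spec, "scene_spec"))
  legend <- read_legend(file.path(dir, "legend.csv"))
  stack <- load_stack(file.path(dir, "image.tif"), legend)
  labels <- read_labels(file.path(dir, "labels.tif"))
  truth <- utils::read.csv(file.path(dir, "ground_truth.csv"))
  labs <- unclass(legend)

  meas <- run_measurement(stack, labels, spec$ring)
  table <- meas$table
  partner_ch <- match(spec$contacts$partner_channel %||% "Phago", labs)
  mask <- stack$pixels[, , partner_ch, , drop = TRUE] > (spec$contacts$threshold %||% 80)
  if (length(dim(mask)) == 2) dim(mask) <- c(dim(mask), 1)
  table$interaction <- as.integer(
    detect_interactions(meas$rois, mask, spec$contacts$contact_dist %||% 2))
  labeling <- dbscan_regions(cbind(table$x, table$y),
                             eps = 2 * spec$cluster$spacing, min_pts = 5,
                             ids = table$coi_id)
  table <- assign_region_flag(table, labeling)

  m <- match(table$coi_id, truth$coi_id)
  truth <- truth[m, , drop = FALSE]

  # canonical gating: filter on the region flag, quadrant-split T vs B
  xp <- spec$report_channels[2] %||% "LT"; yp <- spec$report_channels[1] %||% "LB"
  if (is.null(quadrant_thresholds)) {
    hi <- max(vapply(spec$populations, function(p) p$membrane[[xp]], numeric(1)))
    lo <- min(vapply(spec$populations, function(p) p$membrane[[xp]], numeric(1)))
    quadrant_thresholds <- rep((hi + lo) / 2, 2)
  }
  filtered <- apply_filter(table, filter_spec("ROI_DBSCAN", c(1, 1)))
  quads_all <- quadrant_split(table, table$coi_id, xp, yp,
                              quadrant_thresholds[1], quadrant_thresholds[2])
  assigned <- rep("neg", nrow(table))
  assigned[table$coi_id %in% quads_all$LR$members] <- "T"
  assigned[table$coi_id %in% quads_all$UL$members] <- "B"
  assigned[table$coi_id %in% quads_all$UR$members] <- "TB"
  truth_class <- ifelse(truth$population %in% c("T", "B"), truth$population, "neg")
  shapes <- classify_shapes(table, table$coi_id,
                            shape_rule("interaction", 1, c("triangle", "circle")))

  pct <- function(x) 100 * mean(x)
  paint_cols <- paste0("paint_", spec$report_channels)
  err <- abs(as.matrix(as.data.frame(table)[, spec$report_channels, drop = FALSE]) -
               as.matrix(truth[, paint_cols, drop = FALSE]))
  structure(list(
    n = nrow(table),
    identity_pct = pct(assigned == truth_class),
    region_pct = pct(table$ROI_DBSCAN == truth$in_cluster),
    contact_pct = pct(table$interaction == truth$contact),
    shape_consistent = all((shapes[as.character(table$coi_id)] == "circle") ==
                             (table$interaction == 1)),
    intensity_mean_err = mean(err), intensity_max_err = max(err),
    n_filtered = length(filtered),
    quadrant_counts = vapply(quads_all, function(q) length(q$members), integer(1)),
    table = table, truth = truth
  ), class = "e2e_report")
}

#' @export
print.e2e_report <- function(x, ...) {
  cat("<e2e_report> ", x$n, " cell(s)\n", sep = "")
  cat(sprintf("  T/B identity recovery : %.2f%%\n", x$identity_pct))
  cat(sprintf("  region membership     : %.2f%%\n", x$region_pct))
  cat(sprintf("  contact flags         : %.2f%%\n", x$contact_pct))
  cat(sprintf("  intensity mean |err|  : %.3f (max %.3f)\n",
              x$intensity_mean_err, x$intensity_max_err))
  cat("  quadrant counts       : ",
      paste(names(x$quadrant_counts), x$quadrant_counts, sep = "=", collapse = " "),
      "\n", sep = "")
  invisible(x)
}
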