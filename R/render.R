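#' Overlay display options
#'
#' @param slice 1-based slice to display.
#' @param channels Channel indices to compose.
#' @param gain Brightness factor.
#' @param thickness Contour stroke thickness in pixels (>= 1); 1 draws the
#'   bare polygon-boundary raster.
#' @param show_ids Draw each cell's id next to its contour.
#' @param color Contour (and id text) color for the rendered population.
#' @return An object of class `overlay_spec`.
#' @export
overlay_spec <- function(slice, channels, gain = 1, thickness = 1,
                         show_ids = FALSE, color = "magenta") {
  if (thickness < 1) stop_histocyto("thickness must be >= 1", "argument_error")
  structure(list(slice = slice, channels = channels, gain = gain,
                 thickness = as.integer(thickness), show_ids = show_ids,
                 color = color), class = "overlay_spec")
}

# Midpoint (Bresenham) raster of the segment (x0,y0)-(x1,y1), inclusive.
bresenham <- function(x0, y0, x1, y1) {
  dx <- abs(x1 - x0); dy <- abs(y1 - y0)
  sx <- sign(x1 - x0); sy <- sign(y1 - y0)
  n <- max(dx, dy) + 1
  xs <- integer(n); ys <- integer(n)
  err <- dx - dy
  x <- x0; y <- y0
  for (i in seq_len(n)) {
    xs[i] <- x; ys[i] <- y
    if (x == x1 && y == y1) { xs <- xs[1:i]; ys <- ys[1:i]; break }
    e2 <- 2 * err
    if (e2 > -dy) { err <- err - dy; x <- x + sx }
    if (e2 < dx) { err <- err + dx; y <- y + sy }
  }
  cbind(x = xs, y = ys)
}

# Closed-contour raster of a polygon (0-based integer vertices).
.stroke_pixels <- function(vertices, thickness) {
  n <- nrow(vertices)
  segs <- lapply(seq_len(n), function(i) {
    j <- if (i == n) 1L else i + 1L
    bresenham(vertices[i, 1], vertices[i, 2], vertices[j, 1], vertices[j, 2])
  })
  px <- unique(do.call(rbind, segs))
  if (thickness > 1) {
    lo <- -((thickness - 1L) %/% 2L); hi <- thickness %/% 2L
    off <- expand.grid(dx = lo:hi, dy = lo:hi)
    px <- unique(do.call(rbind, lapply(seq_len(nrow(off)), function(k)
      cbind(x = px[, 1] + off$dx[k], y = px[, 2] + off$dy[k]))))
  }
  px
}

# 3x5 bitmap digit font, one string of 15 bits per digit (row-major).
.digit_font <- c(
  "0" = "111101101101111", "1" = "010110010010111", "2" = "111001111100111",
  "3" = "111001111001111", "4" = "101101111001001", "5" = "111100111001111",
  "6" = "111100111101111", "7" = "111001010010010", "8" = "111101111101111",
  "9" = "111101111001111")

# Pixels (0-based x,y) of the decimal digits of `number` with top-left anchor.
.text_pixels <- function(number, x0, y0) {
  digits <- strsplit(as.character(number), "")[[1]]
  out <- NULL
  for (d in digits) {
    bits <- as.integer(strsplit(.digit_font[[d]], "")[[1]])
    on <- which(bits == 1) - 1L
    out <- rbind(out, cbind(x = x0 + on %% 3L, y = y0 + on %/% 3L))
    x0 <- x0 + 4L
  }
  out
}

# Paint 0-based (x, y) pixels of an rgb image with an RGB triple in [0,255].
.paint <- function(img, px, rgb255) {
  h <- dim(img)[1]; w <- dim(img)[2]
  keep <- px[, 1] >= 0 & px[, 1] < w & px[, 2] >= 0 & px[, 2] < h
  px <- px[keep, , drop = FALSE]
  for (k in 1:3) img[cbind(px[, 2] + 1L, px[, 1] + 1L, k)] <- rgb255[k]
  img
}

#' Render selected cells back into the image
#'
#' Composes the display image for a slice and strokes the contours of the
#' selected cells on it — the "Plot to Image" view. Only contours whose slice
#' equals the displayed slice are drawn; cells without a contour are skipped
#' with a warning. With `show_ids`, the cell id is drawn with a built-in
#' bitmap font just right of the contour's bounding box (labels are placed
#' deterministically and not deconflicted). All pixels farther from a drawn
#' contour than the stroke (plus label boxes) are bit-identical to the plain
#' composed image.
#'
#' @param stack An [image_stack].
#' @param rois A [roi_set].
#' @param members Ids of the cells to highlight (e.g. a gate result's
#'   members).
#' @param spec An [overlay_spec].
#' @param base Optional `rgb_image` to draw on (to layer several populations
#'   in different colors); defaults to the freshly composed channel image.
#' @return An `rgb_image`.
#' @export
overlay_selection <- function(stack, rois, members, spec, base = NULL) {
  stopifnot(inherits(stack, "image_stack"), inherits(rois, "roi_set"),
            inherits(spec, "overlay_spec"))
  img <- base %||% compose(stack, spec$slice, spec$channels, spec$gain)
  rgb255 <- grDevices::col2rgb(spec$color)[, 1]
  for (id in members) {
    r <- unclass(rois)[[as.character(id)]]
    if (is.null(r)) {
      warn_histocyto(paste0("no ROI for cell ", id, "; skipped"), "missing_roi_warning")
      next
    }
    if (r$slice != spec$slice) next
    img <- .paint(img, .stroke_pixels(r$vertices, spec$thickness), rgb255)
    if (isTRUE(spec$show_ids))
      img <- .paint(img, .text_pixels(r$coi_id, r$bounds["right"] + 3L,
                                      r$bounds["top"]), rgb255)
  }
  img
}

#' Crop one cell for annotation
#'
#' Cuts the cell's bounding box (plus a margin) out of the composed channel
#' image and magnifies it by nearest-neighbor pixel replication — the per-cell
#' view used when reviewing and correcting annotations.
#'
#' @param stack An [image_stack].
#' @param roi The cell's [roi_polygon]; must lie within the image.
#' @param magnification Factor >= 1; both output dimensions scale by it.
#' @param spec Optional [overlay_spec] (slice/channels/gain); defaults to the
#'   cell's own slice with all channels at gain 1.
#' @param margin Padding in pixels around the bounding box (clipped at the
#'   image border).
#' @return An `rgb_image`.
#' @export
crop_cell <- function(stack, roi, magnification = 1, spec = NULL, margin = 2) {
  stopifnot(inherits(stack, "image_stack"), inherits(roi, "roi_polygon"))
  if (magnification < 1)
    stop_histocyto("magnification must be >= 1", "argument_error")
  b <- roi$bounds
  if (b["left"] < 0 || b["top"] < 0 || b["right"] >= stack$width ||
      b["bottom"] >= stack$height)
    stop_histocyto("ROI lies outside the image", "bounds_error")
  spec <- spec %||% overlay_spec(roi$slice, seq_len(stack$n_channels), gain = 1)
  img <- compose(stack, spec$slice, spec$channels, spec$gain)
  r0 <- max(1, b["top"] + 1 - margin); r1 <- min(stack$height, b["bottom"] + 1 + margin)
  c0 <- max(1, b["left"] + 1 - margin); c1 <- min(stack$width, b["right"] + 1 + margin)
  crop <- unclass(img)[r0:r1, c0:c1, , drop = FALSE]
  if (magnification > 1) {
    oh <- round(nrow(crop) * magnification); ow <- round(ncol(crop) * magnification)
    ri <- clamp(floor((seq_len(oh) - 0.5) / magnification) + 1, 1, nrow(crop))
    ci <- clamp(floor((seq_len(ow) - 0.5) / magnification) + 1, 1, ncol(crop))
    crop <- crop[ri, ci, , drop = FALSE]
  }
  structure(crop, class = "rgb_image",
            provenance = list(slice = spec$slice, channels = spec$channels,
                              gain = spec$gain))
}
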