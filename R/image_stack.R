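#' Multi-channel, multi-slice image stack
#'
#' Container for the pixel data of a tissue-section image: an array indexed
#' `[y, x, channel, slice]` holding 8- or 16-bit grayscale values, together
#' with the channel legend, the resize factor applied on load and the original
#' (pre-resize) dimensions.
#'
#' @param pixels Numeric array `[y, x, channel, slice]` (a matrix or 3D array
#'   is promoted by treating missing channel/slice dimensions as length 1).
#' @param legend A [coi_legend]; its length must equal the channel dimension.
#' @param bit_depth 8 or 16.
#' @param scale Resize factor applied on load (1 when no resize happened).
#' @param original_size Pre-resize `(X, Y)` size in pixels.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(pixels, legend, bit_depth = 8, scale = 1,
                        original_size = NULL) {
  stopifnot(inherits(legend, "coi_legend"))
  d <- dim(pixels)
  if (length(d) == 2) dim(pixels) <- c(d, 1, 1)
  if (length(dim(pixels)) == 3) dim(pixels) <- c(dim(pixels), 1)
  d <- dim(pixels)
  if (d[3] != length(legend))
    stop_histocyto(paste0("channel count (", d[3], ") does not match legend size (",
                          length(legend), ")"), "mismatch_error")
  if (!bit_depth %in% c(8, 16))
    stop_histocyto("unsupported bit depth (expected 8 or 16)", "format_error")
  structure(list(
    pixels = pixels,
    n_slices = d[4], n_channels = d[3],
    width = d[2], height = d[1],
    legend = legend, bit_depth = bit_depth, scale = scale,
    original_size = original_size %||% c(X = d[2], Y = d[1])
  ), class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  cat("<image_stack> ", x$width, "x", x$height, " px, ", x$n_channels,
      " channel(s), ", x$n_slices, " slice(s), ", x$bit_depth, "-bit",
      if (x$scale < 1) paste0(" (resized by ", signif(x$scale, 4), " from ",
                              x$original_size[1], "x", x$original_size[2], ")"),
      "\n", sep = "")
  invisible(x)
}

# Overlap-weight matrix for exact area-average resampling of one axis:
# output pixel j averages the input interval [ (j-1)*r, j*r ), r = n_in/n_out.
.resize_weights <- function(n_in, n_out) {
  r <- n_in / n_out
  W <- matrix(0, n_out, n_in)
  for (j in seq_len(n_out)) {
    lo <- (j - 1) * r; hi <- j * r
    i <- (floor(lo) + 1):min(ceiling(hi), n_in)
    W[j, i] <- (pmin(hi, i) - pmax(lo, i - 1)) / r
  }
  W
}

# Area-average resize of a single 2D plane to new_h x new_w.
resize_area <- function(mat, new_h, new_w) {
  Wy <- .resize_weights(nrow(mat), new_h)
  Wx <- .resize_weights(ncol(mat), new_w)
  Wy %*% mat %*% t(Wx)
}

#' Load a multi-channel TIFF stack
#'
#' Reads a multi-page grayscale TIFF and applies the automatic resize rule:
#' an image whose larger dimension exceeds 1024 pixels is scaled down
#' proportionally so that the larger dimension becomes 1024 (a 2048 x 1536
#' image is stored as 1024 x 768). Resampling is area-averaging, which
#' preserves mean-intensity statistics; target dimensions are rounded half-up.
#'
#' @param path Path to the TIFF file.
#' @param legend A [coi_legend]; the page count must be a multiple of its
#'   length.
#' @param channel_order `"slice_major"` (pages cycle through the channels of
#'   slice 1, then slice 2, ...) or `"channel_major"` (all slices of channel 1
#'   first). The default matches Fiji's default hyperstack export order.
#' @return An [image_stack]. Pixel values are kept on the native 8- or 16-bit
#'   scale; resized values are rounded to the nearest integer.
#' @export
load_stack <- function(path, legend, channel_order = c("slice_major", "channel_major")) {
  channel_order <- match.arg(channel_order)
  stopifnot(inherits(legend, "coi_legend"))
  if (!file.exists(path)) stop_histocyto(paste0("image not found: ", path), "io_error")
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (any(vapply(pages, function(p) length(dim(p)) != 2, logical(1))))
    stop_histocyto("expected single-sample (grayscale) TIFF pages", "format_error")
  n_ch <- length(legend)
  if (length(pages) %% n_ch != 0)
    stop_histocyto(paste0("page count (", length(pages),
                          ") is not a multiple of the legend's channel count (",
                          n_ch, ")"), "mismatch_error")
  n_sl <- length(pages) %/% n_ch
  maxval <- max(vapply(pages, max, numeric(1)), 0)
  bit_depth <- if (maxval > 255) 16 else 8
  H <- nrow(pages[[1]]); W <- ncol(pages[[1]])
  scale <- min(1, 1024 / max(W, H))
  if (scale < 1) {
    new_h <- floor(H * scale + 0.5); new_w <- floor(W * scale + 0.5)
    pages <- lapply(pages, function(p) round(resize_area(p, new_h, new_w)))
  }
  h <- nrow(pages[[1]]); w <- ncol(pages[[1]])
  a <- array(0, dim = c(h, w, n_ch, n_sl))
  for (p in seq_along(pages)) {
    if (channel_order == "slice_major") {
      s <- (p - 1) %/% n_ch + 1; c <- (p - 1) %% n_ch + 1
    } else {
      c <- (p - 1) %/% n_sl + 1; s <- (p - 1) %% n_sl + 1
    }
    a[, , c, s] <- pages[[p]]
  }
  image_stack(a, legend, bit_depth = bit_depth, scale = scale,
              original_size = c(X = W, Y = H))
}

#' Write an image stack to a multi-page TIFF
#'
#' Pages are written slice-major (the channels of slice 1, then slice 2, ...),
#' the order [load_stack()] expects by default.
#'
#' @param stack An [image_stack] (or a bare `[y, x, channel, slice]` array
#'   plus `bit_depth`).
#' @param path Output path.
#' @param bit_depth Used only when `stack` is a bare array.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, bit_depth = 8) {
  if (inherits(stack, "image_stack")) {
    pixels <- stack$pixels; bit_depth <- stack$bit_depth
  } else {
    pixels <- stack
    if (length(dim(pixels)) == 2) dim(pixels) <- c(dim(pixels), 1, 1)
    if (length(dim(pixels)) == 3) dim(pixels) <- c(dim(pixels), 1)
  }
  maxv <- if (bit_depth == 8) 255 else 65535
  d <- dim(pixels)
  pages <- vector("list", d[3] * d[4])
  p <- 1
  for (s in seq_len(d[4])) for (c in seq_len(d[3])) {
    pages[[p]] <- pixels[, , c, s] / maxv
    p <- p + 1
  }
  tiff::writeTIFF(pages, path, bits.per.sample = bit_depth)
  invisible(path)
}

#' Rescale ROI and table geometry to follow an image resize
#'
#' When [load_stack()] shrinks an image, contours and centroid/area columns
#' measured on the original image must follow: vertices and `x`/`y` are
#' multiplied by the scale factor (and rounded, for vertices), areas by its
#' square. The original `x`, `y` and `area` values are kept in the table
#' attribute `original_geometry` so they can be exported unchanged.
#'
#' @param rois A [roi_set] (or `NULL`).
#' @param table A [coi_table] (or `NULL`).
#' @param scale Resize factor in (0, 1].
#' @return List with elements `rois` and `table`.
#' @export
rescale_geometry <- function(rois, table, scale) {
  if (!is.numeric(scale) || length(scale) != 1 || scale <= 0 || scale > 1)
    stop_histocyto("scale must be a single value in (0, 1]", "argument_error")
  if (scale == 1) return(list(rois = rois, table = table))
  if (!is.null(rois)) {
    rois <- roi_set(lapply(unclass(rois), function(r)
      roi_polygon(r$coi_id, r$slice, round(r$vertices * scale))))
  }
  if (!is.null(table)) {
    keep <- intersect(c("coi_id", "x", "y", "area"), names(table))
    orig <- as.data.frame(table)[, keep, drop = FALSE]
    if ("x" %in% names(table)) table$x <- table$x * scale
    if ("y" %in% names(table)) table$y <- table$y * scale
    if ("area" %in% names(table)) table$area <- table$area * scale^2
    attr(table, "original_geometry") <- orig
  }
  list(rois = rois, table = table)
}

.default_channel_colors <- c("red", "green", "blue", "magenta", "yellow", "cyan")

#' Compose a display image from selected channels
#'
#' Each selected channel is mapped to its display color (default: a fixed
#' red/green/blue/magenta/yellow/cyan cycle keyed by channel index), the
#' colored channels are summed, multiplied by the brightness gain and clipped
#' to \[0, 255\]. 16-bit data are first rescaled linearly from \[0, 65535\] to
#' \[0, 255\].
#'
#' @param stack An [image_stack].
#' @param slice 1-based slice index.
#' @param channels Vector of 1-based channel indices (non-empty).
#' @param gain Brightness factor >= 0.
#' @param colors Optional character vector of display colors, one per entry of
#'   `channels`; defaults to the fixed cycle keyed by channel index.
#' @return An `rgb_image`: array `[y, x, 3]` of values in \[0, 255\], with a
#'   `provenance` attribute recording slice, channels and gain.
#' @export
compose <- function(stack, slice, channels, gain = 1, colors = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  if (length(channels) == 0)
    stop_histocyto("at least one channel must be selected", "argument_error")
  if (!is_count(slice) || slice > stack$n_slices)
    stop_histocyto("slice out of range", "argument_error")
  if (any(channels < 1 | channels > stack$n_channels))
    stop_histocyto("channel index out of range", "argument_error")
  if (!is.numeric(gain) || length(gain) != 1 || gain < 0)
    stop_histocyto("gain must be a single value >= 0", "argument_error")
  if (is.null(colors))
    colors <- .default_channel_colors[(channels - 1) %% 6 + 1]
  if (length(colors) != length(channels))
    stop_histocyto("colors must match channels in length", "argument_error")
  rescale <- if (stack$bit_depth == 16) 255 / 65535 else 1
  out <- array(0, dim = c(stack$height, stack$width, 3))
  for (i in seq_along(channels)) {
    rgb <- grDevices::col2rgb(colors[i])[, 1] / 255
    v <- stack$pixels[, , channels[i], slice] * rescale
    for (k in 1:3) if (rgb[k] > 0) out[, , k] <- out[, , k] + v * rgb[k]
  }
  out <- clamp(out * gain, 0, 255)
  structure(out, class = "rgb_image",
            provenance = list(slice = slice, channels = channels, gain = gain))
}

#' @export
print.rgb_image <- function(x, ...) {
  p <- attr(x, "provenance")
  cat("<rgb_image> ", dim(x)[2], "x", dim(x)[1], " px", sep = "")
  if (!is.null(p))
    cat(" (slice ", p$slice, ", channel(s) ", paste(p$channels, collapse = ","),
        ", gain ", p$gain, ")", sep = "")
  cat("\n")
  invisible(x)
}

#' Export an rgb_image to PNG
#'
#' @param img An `rgb_image` (values in \[0, 255\]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rgb <- function(img, path) {
  png::writePNG(unclass(img) / 255, path)
  invisible(path)
}
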