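#' Per-cell contour polygon (ImageJ ROI)
#'
#' A `roi_polygon` is a closed 2D contour for one cell, in the pixel
#' coordinates of the image as loaded (0-based, origin at the top-left corner,
#' `x` = column, `y` = row).
#'
#' @param coi_id Positive integer cell id (may be `NA` until the polygon is
#'   placed into a [roi_set]).
#' @param slice 1-based optical-section index the contour belongs to.
#' @param vertices Two-column matrix of (x, y) vertex coordinates; at least 3
#'   vertices. Sub-pixel coordinates are rounded to integers.
#' @return An object of class `roi_polygon` with fields `coi_id`, `slice`,
#'   `vertices` and `bounds` (`top`, `left`, `bottom`, `right`).
#' @export
roi_polygon <- function(coi_id, slice, vertices) {
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2 || nrow(vertices) < 3)
    stop_histocyto("a roi_polygon needs a two-column matrix of >= 3 vertices",
                   "argument_error")
  storage.mode(vertices) <- "double"
  vertices <- round(vertices)
  colnames(vertices) <- c("x", "y")
  if (!is_count(slice)) stop_histocyto("slice must be a positive integer", "argument_error")
  bounds <- c(top = min(vertices[, 2]), left = min(vertices[, 1]),
              bottom = max(vertices[, 2]), right = max(vertices[, 1]))
  structure(list(coi_id = coi_id, slice = as.integer(slice),
                 vertices = vertices, bounds = bounds),
            class = "roi_polygon")
}

#' @export
print.roi_polygon <- function(x, ...) {
  cat("<roi_polygon> id ", x$coi_id, ", slice ", x$slice, ", ",
      nrow(x$vertices), " vertices, bounds [x ", x$bounds["left"], "..",
      x$bounds["right"], ", y ", x$bounds["top"], "..", x$bounds["bottom"],
      "]\n", sep = "")
  invisible(x)
}

#' Set of per-cell contours keyed by cell id
#'
#' @param rois List of [roi_polygon] objects, each with a non-missing
#'   `coi_id`; exactly one polygon per cell (for 3D segmentations, the one on
#'   the cell's central slice).
#' @return An object of class `roi_set`: a list keyed by `coi_id`, sorted by id.
#' @export
roi_set <- function(rois = list()) {
  ids <- vapply(rois, function(r) as.numeric(r$coi_id), numeric(1))
  if (anyNA(ids)) stop_histocyto("all polygons in a roi_set need a coi_id", "argument_error")
  if (anyDuplicated(ids))
    stop_histocyto(paste0("duplicate coi_id in roi_set: ",
                          paste(unique(ids[duplicated(ids)]), collapse = ", ")),
                   "integrity_error")
  ord <- order(ids)
  structure(stats::setNames(rois[ord], as.character(ids[ord])), class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  cat("<roi_set> ", length(x), " polygon(s)", sep = "")
  if (length(x)) cat(", ids ", names(x)[1], "..", names(x)[length(x)], sep = "")
  cat("\n")
  invisible(x)
}

#' @export
`[.roi_set` <- function(x, i) {
  out <- unclass(x)[i]
  structure(out, class = "roi_set")
}

# ImageJ ROI type codes (byte at offset 6 of the header)
.roi_type_names <- c("polygon", "rect", "oval", "line", "freeline", "polyline",
                     "noRoi", "freehand", "traced", "angle", "point")

int16be <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "big")
int32be <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "big")

#' Decode an ImageJ .roi byte block into a polygon
#'
#' Implements the ImageJ/Fiji binary ROI layout: the 4-byte magic `Iout`, a
#' 64-byte big-endian header carrying the type code, integer bounding box,
#' vertex count and stack position, followed by the vertex coordinates as
#' signed 16-bit offsets relative to the bounding box's top-left corner.
#' Only outline types (polygon, freehand, traced) are accepted.
#'
#' @param payload Raw vector with the contents of one `.roi` file.
#' @return A [roi_polygon] (with `coi_id = NA`; archives key polygons by their
#'   entry names). The slice is taken from the header's position field when
#'   set, else 1.
#' @export
decode_roi <- function(payload) {
  payload <- as.raw(payload)
  if (length(payload) < 64 || rawToChar(payload[1:4]) != "Iout")
    stop_histocyto("not an ImageJ ROI: missing 'Iout' magic", "format_error")
  rd16 <- function(off) readBin(payload[(off + 1):(off + 2)], "integer",
                                size = 2, endian = "big")
  type <- as.integer(payload[7])
  if (!type %in% c(0L, 7L, 8L)) {
    nm <- if (type + 1 <= length(.roi_type_names)) .roi_type_names[type + 1] else "unknown"
    stop_histocyto(paste0("unsupported ROI type code ", type, " (", nm,
                          "); only polygon/freehand/traced outlines are supported"),
                   "unsupported_type_error")
  }
  top <- rd16(8); left <- rd16(10)
  n <- rd16(16)
  if (n < 0) n <- n + 65536  # stored as unsigned short
  if (length(payload) < 64 + 4 * n)
    stop_histocyto("truncated ROI: coordinate block shorter than header count",
                   "format_error")
  pos <- readBin(payload[57:60], "integer", size = 4, endian = "big")
  xs <- readBin(payload[65:(64 + 2 * n)], "integer", size = 2, n = n, endian = "big")
  ys <- readBin(payload[(65 + 2 * n):(64 + 4 * n)], "integer", size = 2, n = n,
                endian = "big")
  roi_polygon(NA_integer_, slice = if (pos > 0) pos else 1L,
              vertices = cbind(x = left + xs, y = top + ys))
}

#' Encode a polygon as an ImageJ .roi byte block
#'
#' Inverse of [decode_roi()]: writes a version-227 polygon-type ROI whose
#' position field carries the slice. The block is readable by ImageJ/Fiji and
#' by [decode_roi()].
#'
#' @param roi A [roi_polygon].
#' @return Raw vector with the `.roi` file contents.
#' @export
encode_roi <- function(roi) {
  stopifnot(inherits(roi, "roi_polygon"))
  v <- roi$vertices
  left <- min(v[, 1]); top <- min(v[, 2])
  right <- max(v[, 1]); bottom <- max(v[, 2])
  xr <- v[, 1] - left; yr <- v[, 2] - top
  if (max(xr, yr) > 32767)
    stop_histocyto("polygon extent exceeds the signed-16-bit relative range (32767 px)",
                   "overflow_error")
  if (left < -32768 || top < -32768 || right > 32767 || bottom > 32767)
    stop_histocyto("polygon bounds exceed the 16-bit coordinate range", "overflow_error")
  header <- c(
    charToRaw("Iout"),
    int16be(227),                # version
    as.raw(c(0, 0)),             # type = 0 (polygon), unused byte
    int16be(top), int16be(left), int16be(bottom), int16be(right),
    int16be(nrow(v)),
    raw(16),                     # x1,y1,x2,y2 floats (unused)
    raw(22),                     # stroke/fill/subtype/options/... (unused)
    int32be(roi$slice),          # position
    int32be(0)                   # header2 offset
  )
  stopifnot(length(header) == 64)
  c(header, int16be(xr), int16be(yr))
}

.roi_entry_name <- function(id) sprintf("%04d.roi", id)

#' Read a roi.zip archive of per-cell contours
#'
#' Entry names are parsed for the cell id: `0042.roi` style names map directly;
#' Fiji's `nnnn-yyyy-xxxx.roi` position-based names are accepted, taking the
#' first field as the slice (when the ROI's own position field is unset) and
#' assigning ids by entry order with a warning. Entries that fail to decode are
#' reported in a warning, never silently dropped.
#'
#' @param path Path to the zip archive.
#' @return A [roi_set].
#' @export
read_roi_archive <- function(path) {
  if (!file.exists(path)) stop_histocyto(paste0("archive not found: ", path), "io_error")
  entries <- zip_read(path)
  if (length(entries) == 0) {
    warn_histocyto("ROI archive is empty", "empty_archive_warning")
    return(roi_set())
  }
  rois <- list()
  failed <- character(0)
  for (i in seq_along(entries)) {
    nm <- names(entries)[i]
    base <- sub("\\.roi$", "", basename(nm), ignore.case = TRUE)
    r <- tryCatch(decode_roi(entries[[i]]), error = function(e) e)
    if (inherits(r, "error")) {
      failed <- c(failed, paste0(nm, " (", conditionMessage(r), ")"))
      next
    }
    if (grepl("^[0-9]+$", base)) {
      r$coi_id <- as.integer(base)
    } else if (grepl("^[0-9]{3,5}-[0-9]{3,5}-[0-9]{3,5}$", base)) {
      fields <- as.integer(strsplit(base, "-")[[1]])
      if (r$slice == 1L && fields[1] >= 1) r$slice <- fields[1]
      r$coi_id <- i
      warn_histocyto(paste0("position-style entry name '", nm,
                            "': assigning coi_id ", i, " by entry order"),
                     "entry_name_warning")
    } else {
      grp <- regmatches(base, regexpr("[0-9]+", base))
      r$coi_id <- if (length(grp)) as.integer(grp) else i
      if (!length(grp))
        warn_histocyto(paste0("no id in entry name '", nm,
                              "': assigning coi_id ", i, " by entry order"),
                       "entry_name_warning")
    }
    rois[[length(rois) + 1L]] <- r
  }
  if (length(failed))
    warn_histocyto(paste0("failed to decode ", length(failed), " ROI entr",
                          if (length(failed) == 1) "y" else "ies", ": ",
                          paste(failed, collapse = "; ")),
                   "decode_warning")
  roi_set(rois)
}

#' Write a roi.zip archive
#'
#' One `.roi` entry per cell, named by the zero-padded cell id (`0042.roi`),
#' with the ROI position field set to the cell's slice.
#'
#' @param set A [roi_set].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_roi_archive <- function(set, path) {
  stopifnot(inherits(set, "roi_set"))
  if (length(set) == 0)
    warn_histocyto("writing an empty ROI archive", "empty_archive_warning")
  entries <- lapply(set, encode_roi)
  names(entries) <- vapply(set, function(r) .roi_entry_name(r$coi_id), character(1))
  ok <- tryCatch({ zip_write(entries, path); TRUE }, error = function(e) FALSE)
  if (!ok) stop_histocyto(paste0("cannot write archive to: ", path), "io_error")
  invisible(path)
}

#' Check that a roi_set and a coi_table describe the same cells
#'
#' @param set A [roi_set].
#' @param table A [coi_table].
#' @return `TRUE` invisibly; warns (does not stop) when the id sets differ.
#' @export
check_roi_table_consistency <- function(set, table) {
  ids_r <- as.integer(names(set))
  ids_t <- as.integer(table$coi_id)
  miss_r <- setdiff(ids_t, ids_r)
  miss_t <- setdiff(ids_r, ids_t)
  if (length(miss_r) || length(miss_t))
    warn_histocyto(paste0(
      "roi_set / coi_table id mismatch",
      if (length(miss_r)) paste0("; missing ROIs for: ", paste(miss_r, collapse = ",")),
      if (length(miss_t)) paste0("; ROIs without table rows: ", paste(miss_t, collapse = ","))),
      "consistency_warning")
  invisible(TRUE)
}
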