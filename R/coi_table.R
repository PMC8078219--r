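#' Table of Cells Of Interest (COI)
#'
#' A `coi_table` is a data frame with one row per segmented cell. The canonical
#' columns are `coi_id` (unique positive integer), one intensity column per
#' labeled channel (arbitrary units bounded by \[0, 255\]), the centroid
#' coordinates `x`, `y` (pixels of the image as loaded) and `z` (the cell's
#' central optical section), the morphology columns `area` (pixels^2),
#' `circularity` (\[0, 1\]) and `solidity` ((0, 1\]), and the binary flags
#' `interaction` (contact with a partner cell) and `ROI_DBSCAN` (membership of
#' a density-defined tissue region). Any further numeric columns are carried
#' along untouched. Only `coi_id` plus at least two numeric parameter columns
#' are mandatory: two parameters are the minimum needed to build a scatterplot.
#'
#' @param df A data frame.
#' @param channels Character vector naming the intensity columns of `df`
#'   (typically the legend labels present in the table).
#' @return `df` with class `coi_table` and attribute `channels`.
#' @export
coi_table <- function(df, channels = character(0)) {
  stopifnot(is.data.frame(df))
  df <- as.data.frame(df, check.names = FALSE)
  rownames(df) <- NULL
  if (!"coi_id" %in% names(df))
    stop_histocyto("coi_table requires a coi_id column", "format_error")
  channels <- intersect(channels, names(df))
  out <- structure(df, channels = channels, class = c("coi_table", "data.frame"))
  validate_coi_table(out)
  out
}

#' @export
print.coi_table <- function(x, ...) {
  cat("<coi_table> ", nrow(x), " cell(s), ",
      ncol(x) - 1L, " parameter column(s)", sep = "")
  ch <- attr(x, "channels")
  if (length(ch)) cat("; channels: ", paste(ch, collapse = ", "), sep = "")
  cat("\n")
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("... ", nrow(x) - 10, " more row(s)\n", sep = "")
  invisible(x)
}

#' Channel intensity column names of a coi_table
#' @param table A [coi_table].
#' @return Character vector of intensity column names.
#' @export
coi_channels <- function(table) attr(table, "channels") %||% character(0)

#' Validate a coi_table
#'
#' Checks uniqueness of `coi_id`, the \[0, 255\] bound on every channel
#' intensity (reporting offending rows and columns), the ranges of the
#' morphology columns, and that at least two numeric parameter columns exist.
#'
#' @param table A [coi_table].
#' @return `TRUE` invisibly; stops with a classed error otherwise.
#' @export
validate_coi_table <- function(table) {
  df <- as.data.frame(table)
  id <- df$coi_id
  if (anyNA(id) || any(id != round(id)) || any(id < 1))
    stop_histocyto("coi_id must be positive integers", "validation_error")
  if (anyDuplicated(id))
    stop_histocyto(
      paste0("duplicate coi_id: ",
             paste(unique(id[duplicated(id)]), collapse = ", ")),
      "integrity_error")
  num_cols <- names(df)[vapply(df, is.numeric, logical(1))]
  if (length(setdiff(num_cols, "coi_id")) < 2 && nrow(df) > 0)
    stop_histocyto("a coi_table needs at least two numeric parameter columns",
                   "format_error")
  bad <- character(0)
  for (ch in coi_channels(table)) {
    v <- df[[ch]]
    idx <- which(!is.na(v) & (v < 0 | v > 255))
    if (length(idx))
      bad <- c(bad, paste0("column '", ch, "' row(s) ",
                           paste(idx, collapse = ","), " outside [0,255]"))
  }
  if (length(bad))
    stop_histocyto(paste0("intensity out of range: ", paste(bad, collapse = "; ")),
                   "validation_error")
  if ("circularity" %in% names(df)) {
    v <- df$circularity
    if (any(!is.na(v) & (v < 0 | v > 1)))
      stop_histocyto("circularity outside [0,1]", "validation_error")
  }
  if ("solidity" %in% names(df)) {
    v <- df$solidity
    if (any(!is.na(v) & (v <= 0 | v > 1)))
      stop_histocyto("solidity outside (0,1]", "validation_error")
  }
  if ("area" %in% names(df)) {
    v <- df$area
    if (any(!is.na(v) & v <= 0))
      stop_histocyto("area must be positive", "validation_error")
  }
  invisible(TRUE)
}

# Canonical names for common Fiji "Results" headers. Matching is
# case-insensitive; the results format in the wild never fixes header names.
.column_synonyms <- c(
  "id" = "coi_id", "coi_id" = "coi_id", "coi" = "coi_id", "label" = "coi_id",
  "x" = "x", "xm" = "x", "y" = "y", "ym" = "y", "z" = "z",
  "slice" = "slice",
  "area" = "area",
  "circ." = "circularity", "circ" = "circularity", "circularity" = "circularity",
  "solidity" = "solidity",
  "interaction" = "interaction",
  "roi_dbscan" = "ROI_DBSCAN", "region" = "ROI_DBSCAN"
)

#' Read a segmentation results CSV
#'
#' Parses the per-cell results table produced by a segmentation pipeline.
#' Column names are matched case-insensitively against common synonyms
#' (`X`/`XM`, `Circ.`/`circularity`, ...); when a legend is given, columns whose
#' names match legend labels become the channel intensity columns and are
#' validated against the \[0, 255\] intensity range. A leading unnamed column
#' (the Fiji row index) is used as `coi_id` when no explicit id column exists.
#'
#' @param path Path to the results CSV (one header row, comma separated).
#' @param legend Optional [coi_legend]; enables channel-column matching.
#' @return A [coi_table].
#' @export
read_results <- function(path, legend = NULL) {
  if (!file.exists(path)) stop_histocyto(paste0("results file not found: ", path), "io_error")
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0 || !nzchar(first))
    stop_histocyto("results file has no header row", "format_error")
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  nms <- names(df)
  # unnamed leading Fiji index column
  has_id <- any(tolower(nms) %in% names(.column_synonyms)[.column_synonyms == "coi_id"])
  if (nzchar(nms[1]) == FALSE || nms[1] == " ") {
    nms[1] <- if (has_id) "fiji_index" else "coi_id"
  }
  canon <- .column_synonyms[tolower(nms)]
  nms <- ifelse(is.na(canon), nms, canon)
  channels <- character(0)
  if (!is.null(legend)) {
    stopifnot(inherits(legend, "coi_legend"))
    m <- match(tolower(nms), tolower(unclass(legend)))
    nms <- ifelse(is.na(m), nms, unclass(legend)[m])
    channels <- unclass(legend)[stats::na.omit(m)]
  }
  if (anyDuplicated(nms))
    stop_histocyto(paste0("duplicate column after name matching: ",
                          paste(unique(nms[duplicated(nms)]), collapse = ", ")),
                   "format_error")
  names(df) <- nms
  if (!"coi_id" %in% nms)
    stop_histocyto("no id column found (expected ID/coi_id or unnamed index)",
                   "format_error")
  coi_table(df, channels = channels)
}

#' Write a segmentation results CSV
#'
#' Writes a [coi_table] so that [read_results()] with the same legend parses it
#' back to an identical table (column order preserved).
#'
#' @param table A [coi_table].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(table, path) {
  stopifnot(inherits(table, "coi_table"))
  validate_coi_table(table)
  df <- as.data.frame(table)
  for (cl in names(df)) {  # 17 significant digits: doubles round-trip exactly
    if (is.double(df[[cl]]))
      df[[cl]] <- ifelse(is.na(df[[cl]]), NA, sprintf("%.17g", df[[cl]]))
  }
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop_histocyto(paste0("cannot write results to: ", path), "io_error")
  invisible(path)
}
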