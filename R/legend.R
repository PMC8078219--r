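#' Channel legend
#'
#' A legend maps the image's channels (headers `Ch1`, `Ch2`, ...) to the
#' biological labels used as intensity column names in the results table
#' (e.g. `Ch3` -> `"LT"` for the T-cell staining channel).
#'
#' @param labels Character vector of channel labels, in channel order.
#' @return An object of class `coi_legend`: a named character vector whose
#'   names are `Ch1..ChN`.
#' @examples
#' legend <- coi_legend(c("Ki67", "LB", "LT"))
#' names(legend)
#' @export
coi_legend <- function(labels) {
  labels <- as.character(labels)
  if (length(labels) < 1) stop_histocyto("legend needs at least one channel", "format_error")
  if (anyNA(labels) || any(!nzchar(labels)))
    stop_histocyto("legend labels must be non-empty strings", "format_error")
  structure(labels, names = paste0("Ch", seq_along(labels)), class = "coi_legend")
}

#' @export
print.coi_legend <- function(x, ...) {
  cat("<coi_legend> ", length(x), " channel(s)\n", sep = "")
  for (i in seq_along(x)) cat("  ", names(x)[i], " -> ", x[[i]], "\n", sep = "")
  invisible(x)
}

#' Read a channel legend CSV
#'
#' The legend file has one header row `Ch1,Ch2,...,ChN` (consecutive from 1)
#' and one data row with the channel labels.
#'
#' @param path Path to the legend CSV.
#' @return A [coi_legend] object.
#' @export
read_legend <- function(path) {
  if (!file.exists(path)) stop_histocyto(paste0("legend file not found: ", path), "io_error")
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  hdr <- names(df)
  if (!all(grepl("^Ch[0-9]+$", hdr)))
    stop_histocyto("legend headers must be Ch1..ChN", "format_error")
  idx <- as.integer(sub("^Ch", "", hdr))
  if (!identical(idx, seq_along(idx)))
    stop_histocyto(
      paste0("legend headers must be consecutive Ch1..ChN, got: ",
             paste(hdr, collapse = ",")), "format_error")
  if (nrow(df) < 1) stop_histocyto("legend file has no label row", "format_error")
  coi_legend(as.character(df[1, ]))
}

#' Write a channel legend CSV
#'
#' @param legend A [coi_legend].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_legend <- function(legend, path) {
  stopifnot(inherits(legend, "coi_legend"))
  df <- as.data.frame(as.list(unclass(legend)), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
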