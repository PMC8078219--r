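#' Data filter over one or two parameters
#'
#' The pre-gating filter: keep only cells whose parameter values lie inside
#' closed intervals — one parameter (histogram range) or two (rectangle on a
#' scatterplot). Typically used to discard badly segmented cells (aberrant
#' area) or to restrict the analysis to a subpopulation (e.g. cells with the
#' region flag set to 1).
#'
#' @param params Character vector of 1 or 2 column names.
#' @param bounds Numeric vector `c(lo, hi)` (one parameter) or a 2-row list /
#'   2x2 matrix with one `c(lo, hi)` pair per parameter.
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(params, bounds) {
  params <- as.character(params)
  if (!length(params) %in% 1:2)
    stop_histocyto("a filter uses one or two parameters", "argument_error")
  if (is.numeric(bounds) && length(bounds) == 2) bounds <- list(bounds)
  if (is.matrix(bounds)) bounds <- lapply(seq_len(nrow(bounds)), function(i) bounds[i, ])
  if (length(bounds) != length(params))
    stop_histocyto("one (lo, hi) pair per parameter is required", "argument_error")
  for (b in bounds) {
    if (length(b) != 2 || anyNA(b) || b[1] > b[2])
      stop_histocyto("each bound must be c(lo, hi) with lo <= hi", "argument_error")
  }
  structure(list(mode = if (length(params) == 1) "range" else "rectangle",
                 params = params, bounds = lapply(bounds, as.numeric)),
            class = "filter_spec")
}

#' Apply a filter to a COI table
#'
#' @param table A [coi_table].
#' @param spec A [filter_spec].
#' @return Ids of the cells inside every closed bound, in table order.
#' @export
apply_filter <- function(table, spec) {
  stopifnot(inherits(table, "coi_table"), inherits(spec, "filter_spec"))
  keep <- rep(TRUE, nrow(table))
  for (i in seq_along(spec$params)) {
    p <- spec$params[i]
    if (!p %in% names(table))
      stop_histocyto(paste0("unknown filter column: ", p), "argument_error")
    b <- spec$bounds[[i]]
    keep <- keep & !is.na(table[[p]]) & table[[p]] >= b[1] & table[[p]] <= b[2]
  }
  table$coi_id[keep]
}

#' Scatterplot gates
#'
#' A gate selects cells on a two-parameter scatterplot. Three kinds exist,
#' mirroring the selection tools of interactive histo-cytometry:
#' `gate_rectangle()` (closed intervals on both axes), `gate_lasso()`
#' (arbitrary polygon, boundary inclusive) and `gate_quadrant()` (two
#' thresholds splitting the plane into four populations — see
#' [quadrant_split()]). The boundary convention is uniform: a cell exactly on
#' a gate edge or at a threshold belongs to the gate / upper-right side.
#'
#' @param x_param,y_param Column names of the two plotted parameters.
#' @param x0,x1,y0,y1 Rectangle bounds (`x0 <= x1`, `y0 <= y1`, non-degenerate).
#' @param vertices Two-column matrix of lasso vertices (>= 3).
#' @param x_thr,y_thr Quadrant thresholds.
#' @param name Gate label.
#' @return An object of class `gate`.
#' @name gates
NULL

#' @rdname gates
#' @export
gate_rectangle <- function(x_param, y_param, x0, x1, y0, y1, name = "rectangle") {
  if (x0 > x1 || y0 > y1 || (x0 == x1 && y0 == y1))
    stop_histocyto("degenerate rectangle gate", "argument_error")
  structure(list(kind = "rectangle", x_param = x_param, y_param = y_param,
                 geometry = list(x0 = x0, x1 = x1, y0 = y0, y1 = y1),
                 name = name), class = "gate")
}

#' @rdname gates
#' @export
gate_lasso <- function(x_param, y_param, vertices, name = "lasso") {
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2 || nrow(vertices) < 3)
    stop_histocyto("a lasso gate needs >= 3 vertices", "argument_error")
  structure(list(kind = "lasso", x_param = x_param, y_param = y_param,
                 geometry = list(vertices = vertices), name = name),
            class = "gate")
}

#' @rdname gates
#' @export
gate_quadrant <- function(x_param, y_param, x_thr, y_thr, name = "quadrant") {
  if (!is.finite(x_thr) || !is.finite(y_thr))
    stop_histocyto("quadrant thresholds must be finite", "argument_error")
  structure(list(kind = "quadrant", x_param = x_param, y_param = y_param,
                 geometry = list(x_thr = x_thr, y_thr = y_thr), name = name),
            class = "gate")
}

#' @export
print.gate <- function(x, ...) {
  g <- x$geometry
  desc <- switch(x$kind,
    rectangle = paste0("[", g$x0, ",", g$x1, "] x [", g$y0, ",", g$y1, "]"),
    lasso = paste0(nrow(g$vertices), " vertices"),
    quadrant = paste0("thresholds (", g$x_thr, ", ", g$y_thr, ")"))
  cat("<gate> '", x$name, "' ", x$kind, " on (", x$x_param, ", ", x$y_param,
      "): ", desc, "\n", sep = "")
  invisible(x)
}

.gate_members <- function(table, ids, gate) {
  sub <- table[table$coi_id %in% ids, , drop = FALSE]
  for (p in c(gate$x_param, gate$y_param))
    if (!p %in% names(table))
      stop_histocyto(paste0("unknown gate column: ", p), "argument_error")
  gx <- sub[[gate$x_param]]; gy <- sub[[gate$y_param]]
  g <- gate$geometry
  keep <- switch(gate$kind,
    rectangle = gx >= g$x0 & gx <= g$x1 & gy >= g$y0 & gy <= g$y1,
    lasso = point_in_polygon(gx, gy, g$vertices[, 1], g$vertices[, 2]),
    quadrant = stop_histocyto(
      "use quadrant_split() for quadrant gates (they produce four populations)",
      "argument_error"))
  sub$coi_id[keep & !is.na(keep)]
}

#' Apply a gate (or a union of gates) to a filtered set
#'
#' Single mode: one gate, members in table order. Multiple-selection mode
#' (a list of gates): the union of the member sets, duplicates removed, ids
#' ascending — a cell selected by any lasso/rectangle is selected.
#'
#' @param table A [coi_table].
#' @param ids Filtered id subset (see [apply_filter()]); must be a subset of
#'   the table ids.
#' @param gate A `gate`, or a list of gates for multiple-selection mode.
#' @param name Name for the combined result (multiple mode).
#' @return An object of class `gate_result`: list with `name`, `members` and
#'   `provenance`.
#' @export
apply_gate <- function(table, ids, gate, name = NULL) {
  stopifnot(inherits(table, "coi_table"))
  if (!all(ids %in% table$coi_id))
    stop_histocyto("ids must be a subset of the table's coi_id", "argument_error")
  if (inherits(gate, "gate")) {
    members <- .gate_members(table, ids, gate)
    return(structure(list(name = name %||% gate$name, members = members,
                          provenance = list(filtered = ids, gates = list(gate))),
                     class = "gate_result"))
  }
  if (!is.list(gate) || !all(vapply(gate, inherits, logical(1), "gate")))
    stop_histocyto("gate must be a gate or a list of gates", "argument_error")
  members <- sort(unique(unlist(lapply(gate, function(g) .gate_members(table, ids, g)))))
  structure(list(name = name %||% "union", members = as.integer(members),
                 provenance = list(filtered = ids, gates = gate)),
            class = "gate_result")
}

#' @export
print.gate_result <- function(x, ...) {
  cat("<gate_result> '", x$name, "': ", length(x$members), " cell(s)\n", sep = "")
  invisible(x)
}

#' Quadrant split of a scatterplot
#'
#' Partitions the filtered cells into the four quadrant populations defined by
#' two thresholds: LL (`x < x_thr, y < y_thr`), LR (`x >= x_thr, y < y_thr`),
#' UL (`x < x_thr, y >= y_thr`) and UR (`x >= x_thr, y >= y_thr`). Every
#' filtered cell lands in exactly one quadrant; a cell exactly at the
#' threshold goes to the at-or-above side. In the canonical use (T-cell
#' intensity on x, B-cell intensity on y) LR are the T cells, UL the B cells
#' and LL the uncharacterized cells.
#'
#' @param table A [coi_table].
#' @param ids Filtered id subset.
#' @param x_param,y_param Column names.
#' @param x_thr,y_thr Finite thresholds.
#' @return Named list of four `gate_result`s: `LL`, `LR`, `UL`, `UR`.
#' @export
quadrant_split <- function(table, ids, x_param, y_param, x_thr, y_thr) {
  stopifnot(inherits(table, "coi_table"))
  if (!is.finite(x_thr) || !is.finite(y_thr))
    stop_histocyto("quadrant thresholds must be finite", "argument_error")
  for (p in c(x_param, y_param))
    if (!p %in% names(table))
      stop_histocyto(paste0("unknown gate column: ", p), "argument_error")
  sub <- table[table$coi_id %in% ids, , drop = FALSE]
  gx <- sub[[x_param]]; gy <- sub[[y_param]]
  right <- gx >= x_thr; upper <- gy >= y_thr
  mk <- function(keep, nm) {
    structure(list(name = nm, members = sub$coi_id[keep],
                   provenance = list(filtered = ids,
                                     gates = list(gate_quadrant(x_param, y_param,
                                                                x_thr, y_thr, nm)))),
              class = "gate_result")
  }
  list(LL = mk(!right & !upper, "LL"), LR = mk(right & !upper, "LR"),
       UL = mk(!right & upper, "UL"), UR = mk(right & upper, "UR"))
}

#' Third-parameter symbol class rule
#'
#' On a two-parameter scatterplot a third parameter can be shown through the
#' symbol shape: cells at or above a user threshold get the second marker
#' class. The canonical use flags phagocyte-interacting cells (interaction
#' column, threshold 1 -> circles) among non-interacting ones (triangles).
#'
#' @param param Column name of the third parameter.
#' @param threshold Threshold value.
#' @param classes Length-2 character vector: marker labels for below /
#'   at-or-above threshold.
#' @return An object of class `shape_rule`.
#' @export
shape_rule <- function(param, threshold, classes = c("triangle", "circle")) {
  if (length(classes) != 2)
    stop_histocyto("exactly two symbol classes are required", "argument_error")
  structure(list(param = param, threshold = threshold,
                 classes = as.character(classes)), class = "shape_rule")
}

#' Classify cells by a shape rule
#'
#' @param table A [coi_table].
#' @param ids Id subset to classify.
#' @param rule A [shape_rule].
#' @return Named character vector mapping id to class label.
#' @export
classify_shapes <- function(table, ids, rule) {
  stopifnot(inherits(table, "coi_table"), inherits(rule, "shape_rule"))
  if (!rule$param %in% names(table))
    stop_histocyto(paste0("unknown column: ", rule$param), "argument_error")
  sub <- table[table$coi_id %in% ids, , drop = FALSE]
  cls <- ifelse(sub[[rule$param]] >= rule$threshold, rule$classes[2], rule$classes[1])
  stats::setNames(cls, sub$coi_id)
}

#' Summary statistics of gated populations
#'
#' For each gated population: the cell count, the percentage of the filtered
#' parent set, and per-column mean/median/min/max; plus the full per-cell
#' rows (the downloadable table). Over the four quadrant populations the
#' percentages sum to 100 up to rounding. Empty populations keep a zero row.
#'
#' @param table A [coi_table].
#' @param results A `gate_result` or list of them.
#' @param parent Ids of the filtered parent set (defaults to the provenance
#'   of the first result, else all table ids).
#' @return An object of class `population_stats`: list with `summary` (one
#'   row per population x column) , `counts` (population, n, percent) and
#'   `members` (per-cell rows with a `population` column).
#' @export
population_stats <- function(table, results, parent = NULL) {
  stopifnot(inherits(table, "coi_table"))
  if (inherits(results, "gate_result")) results <- list(results)
  stopifnot(all(vapply(results, inherits, logical(1), "gate_result")))
  parent <- parent %||% results[[1]]$provenance$filtered %||% table$coi_id
  num_cols <- setdiff(names(table)[vapply(as.data.frame(table), is.numeric, logical(1))],
                      "coi_id")
  counts <- data.frame(population = vapply(results, `[[`, character(1), "name"),
                       n = vapply(results, function(r) length(r$members), integer(1)))
  counts$percent <- if (length(parent)) 100 * counts$n / length(parent) else 0
  summ <- do.call(rbind, lapply(results, function(r) {
    sub <- as.data.frame(table)[table$coi_id %in% r$members, , drop = FALSE]
    do.call(rbind, lapply(num_cols, function(cl) {
      v <- sub[[cl]]
      data.frame(population = r$name, column = cl,
                 mean = if (nrow(sub)) mean(v, na.rm = TRUE) else NA_real_,
                 median = if (nrow(sub)) stats::median(v, na.rm = TRUE) else NA_real_,
                 min = if (nrow(sub)) suppressWarnings(min(v, na.rm = TRUE)) else NA_real_,
                 max = if (nrow(sub)) suppressWarnings(max(v, na.rm = TRUE)) else NA_real_)
    }))
  }))
  members <- do.call(rbind, lapply(results, function(r) {
    sub <- as.data.frame(table)[table$coi_id %in% r$members, , drop = FALSE]
    if (nrow(sub)) cbind(population = r$name, sub) else NULL
  }))
  structure(list(counts = counts, summary = summ,
                 members = members %||% data.frame()),
            class = "population_stats")
}

#' @export
print.population_stats <- function(x, ...) {
  cat("<population_stats>\n")
  print(x$counts, row.names = FALSE)
  invisible(x)
}

#' Export population statistics as CSV
#'
#' Two machine-parseable files: `<prefix>_summary.csv` (population block:
#' counts, percentages and per-column summaries) and `<prefix>_cells.csv`
#' (one row per gated cell).
#'
#' @param stats A `population_stats`.
#' @param prefix Output path prefix.
#' @return Character vector of the two paths, invisibly.
#' @export
export_stats <- function(stats, prefix) {
  stopifnot(inherits(stats, "population_stats"))
  p1 <- paste0(prefix, "_summary.csv")
  p2 <- paste0(prefix, "_cells.csv")
  summ <- merge(stats$counts, stats$summary, by = "population", sort = FALSE)
  utils::write.csv(summ, p1, row.names = FALSE)
  utils::write.csv(stats$members, p2, row.names = FALSE)
  invisible(c(p1, p2))
}

.gate_schema_version <- 1L

#' Save and load gate sets
#'
#' Gates, filters and shape rules persist as JSON with a `schema_version`
#' field; geometry is stored in data units (not pixels), so saved gates
#' transfer across images of the same staining panel. Loading a file written
#' by a newer schema fails explicitly rather than misparsing.
#'
#' @param path JSON file path.
#' @param gates List of [gates] objects.
#' @param filters List of [filter_spec] objects.
#' @param shape_rules List of [shape_rule] objects.
#' @return `save_gates()`: `path` invisibly. `load_gates()`: list with
#'   `gates`, `filters`, `shape_rules`.
#' @export
save_gates <- function(path, gates = list(), filters = list(), shape_rules = list()) {
  ser_gate <- function(g) {
    geo <- g$geometry
    if (g$kind == "lasso") geo <- list(vertices = unname(apply(geo$vertices, 1, as.numeric, simplify = FALSE)))
    list(kind = g$kind, x_param = g$x_param, y_param = g$y_param,
         geometry = geo, name = g$name)
  }
  obj <- list(
    schema_version = .gate_schema_version,
    gates = lapply(gates, ser_gate),
    filters = lapply(filters, function(f) list(params = f$params, bounds = f$bounds)),
    shape_rules = lapply(shape_rules, function(r)
      list(param = r$param, threshold = r$threshold, classes = r$classes))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_gates
#' @export
load_gates <- function(path) {
  if (!file.exists(path)) stop_histocyto(paste0("gate file not found: ", path), "io_error")
  obj <- jsonlite::read_json(path)
  ver <- obj$schema_version
  if (is.null(ver)) stop_histocyto("gate file has no schema_version", "parse_error")
  if (ver > .gate_schema_version)
    stop_histocyto(paste0("gate file schema_version ", ver,
                          " is newer than supported version ", .gate_schema_version),
                   "schema_version_error")
  de_gate <- function(g) {
    geo <- g$geometry
    switch(g$kind,
      rectangle = gate_rectangle(g$x_param, g$y_param, geo$x0, geo$x1, geo$y0,
                                 geo$y1, name = g$name),
      lasso = gate_lasso(g$x_param, g$y_param,
                         do.call(rbind, lapply(geo$vertices, unlist)),
                         name = g$name),
      quadrant = gate_quadrant(g$x_param, g$y_param, geo$x_thr, geo$y_thr,
                               name = g$name),
      stop_histocyto(paste0("unknown gate kind: ", g$kind), "parse_error"))
  }
  list(
    gates = lapply(obj$gates, de_gate),
    filters = lapply(obj$filters, function(f)
      filter_spec(unlist(f$params), lapply(f$bounds, unlist))),
    shape_rules = lapply(obj$shape_rules, function(r)
      shape_rule(r$param, r$threshold, unlist(r$classes)))
  )
}

#' Annotation edits
#'
#' Manual corrections of per-cell values (e.g. fixing a cell identity after
#' visual inspection of its crop). Edits are applied in order; conflicting
#' edits to the same cell and column resolve last-wins with a logged warning.
#' Applying an edit and then its inverse restores the original table.
#'
#' @param table A [coi_table].
#' @param edits Data frame with columns `coi_id`, `column`, `new_value`, or a
#'   list of such records.
#' @return List with `table` (edited [coi_table]) and `log` (audit data frame
#'   with `coi_id`, `column`, `old_value`, `new_value`, `timestamp`).
#' @export
annotate <- function(table, edits) {
  stopifnot(inherits(table, "coi_table"))
  if (is.list(edits) && !is.data.frame(edits))
    edits <- do.call(rbind, lapply(edits, as.data.frame))
  if (is.null(edits) || nrow(edits) == 0)
    return(list(table = table, log = data.frame(
      coi_id = integer(0), column = character(0), old_value = numeric(0),
      new_value = numeric(0), timestamp = character(0))))
  stopifnot(all(c("coi_id", "column", "new_value") %in% names(edits)))
  key <- paste(edits$coi_id, edits$column)
  if (anyDuplicated(key))
    warn_histocyto(paste0("conflicting edits (last wins) for: ",
                          paste(unique(key[duplicated(key)]), collapse = "; ")),
                   "edit_conflict_warning")
  log <- vector("list", nrow(edits))
  for (i in seq_len(nrow(edits))) {
    id <- edits$coi_id[i]; cl <- as.character(edits$column[i])
    if (!cl %in% names(table))
      stop_histocyto(paste0("unknown column in edit: ", cl), "argument_error")
    row <- which(table$coi_id == id)
    if (length(row) != 1)
      stop_histocyto(paste0("unknown coi_id in edit: ", id), "argument_error")
    old <- table[[cl]][row]
    table[[cl]][row] <- edits$new_value[i]
    log[[i]] <- data.frame(coi_id = id, column = cl, old_value = old,
                           new_value = edits$new_value[i],
                           timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  }
  validate_coi_table(table)
  list(table = table, log = do.call(rbind, log))
}
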