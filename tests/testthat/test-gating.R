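clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

test_that("filters keep exactly the rows inside their closed bounds", {
  set.seed(20)
  tab <- random_coi_table(200)
  all_ids <- apply_filter(tab, filter_spec("area", range(tab$area)))
  expect_identical(all_ids, tab$coi_id)

  tab$ROI_DBSCAN <- sample(0:1, 200, TRUE)
  keep <- apply_filter(tab, filter_spec("ROI_DBSCAN", c(1, 1)))
  expect_identical(keep, tab$coi_id[tab$ROI_DBSCAN == 1])

  # two-parameter rectangle vs brute-force row scan
  for (k in 1:20) {
    bx <- sort(runif(2, 0, 255)); by <- sort(runif(2, 0, 500))
    got <- apply_filter(tab, filter_spec(c("LT", "area"), list(bx, by)))
    ora <- tab$coi_id[tab$LT >= bx[1] & tab$LT <= bx[2] &
                        tab$area >= by[1] & tab$area <= by[2]]
    expect_identical(got, ora)
  }
  expect_error(apply_filter(tab, filter_spec("nope", c(0, 1))),
               class = "argument_error")
  expect_error(filter_spec("a", c(2, 1)), class = "argument_error")
})

test_that("rectangle and lasso gates agree with per-row oracles", {
  set.seed(21)
  tab <- random_coi_table(300)
  ids <- tab$coi_id
  for (k in 1:20) {
    x0 <- runif(1, 0, 200); x1 <- x0 + runif(1, 1, 55)
    y0 <- runif(1, 0, 200); y1 <- y0 + runif(1, 1, 55)
    g <- gate_rectangle("LT", "LB", x0, x1, y0, y1)
    got <- apply_gate(tab, ids, g)$members
    ora <- ids[tab$LT >= x0 & tab$LT <= x1 & tab$LB >= y0 & tab$LB <= y1]
    expect_identical(got, ora)

    v <- random_polygon(cx = runif(1, 50, 200), cy = runif(1, 50, 200),
                        rmin = 20, rmax = 120)
    gl <- gate_lasso("LT", "LB", v)
    gotl <- apply_gate(tab, ids, gl)$members
    oral <- ids[oracle_point_in_polygon(tab$LT, tab$LB, v[, 1], v[, 2])]
    expect_identical(gotl, oral)
  }
  big <- gate_lasso("LT", "LB", cbind(c(-1, 300, 300, -1), c(-1, -1, 300, 300)))
  expect_identical(apply_gate(tab, ids, big)$members, ids)
})

test_that("multiple-selection mode unions member sets ascending", {
  tab <- random_coi_table(100)
  g1 <- gate_rectangle("LT", "LB", 0, 50, 0, 300)
  g2 <- gate_rectangle("LT", "LB", 200, 255, 0, 300)
  u <- apply_gate(tab, tab$coi_id, list(g1, g2), name = "both")
  m1 <- apply_gate(tab, tab$coi_id, g1)$members
  m2 <- apply_gate(tab, tab$coi_id, g2)$members
  expect_length(intersect(m1, m2), 0)
  expect_identical(u$members, sort(as.integer(union(m1, m2))))
})

test_that("gating a filtered set equals intersecting with the filter", {
  set.seed(22)
  tab <- random_coi_table(400)
  for (k in 1:10) {
    f <- filter_spec("area", sort(runif(2, 10, 400)))
    ids <- apply_filter(tab, f)
    v <- random_polygon(cx = 120, cy = 120, rmin = 30, rmax = 140)
    g <- gate_lasso("LT", "LB", v)
    on_filtered <- apply_gate(tab, ids, g)$members
    on_full <- apply_gate(tab, tab$coi_id, g)$members
    expect_identical(on_filtered, intersect(on_full, ids))
  }
})

test_that("quadrants partition the filtered set with at-threshold going upper-right", {
  set.seed(23)
  for (k in 1:20) {
    tab <- random_coi_table(sample(1:300, 1))
    ids <- sort(sample(tab$coi_id, sample(seq_len(nrow(tab)), 1)))
    xt <- runif(1, 0, 255); yt <- runif(1, 0, 255)
    q <- quadrant_split(tab, ids, "LT", "LB", xt, yt)
    members <- c(q$LL$members, q$LR$members, q$UL$members, q$UR$members)
    expect_setequal(members, ids)
    expect_equal(length(members), length(ids))  # exactly one quadrant each
  }
  tab <- coi_table(data.frame(coi_id = 1L, LT = 100, LB = 50), channels = c("LT", "LB"))
  q <- quadrant_split(tab, 1L, "LT", "LB", 100, 50)
  expect_identical(q$UR$members, 1L)  # point exactly at both thresholds
  q2 <- quadrant_split(tab, 1L, "LT", "LB", -1, -1)
  expect_identical(q2$UR$members, 1L)  # thresholds below the data minimum
})

test_that("shape classes split at-or-above the threshold, order-invariant", {
  tab <- random_coi_table(50)
  tab$interaction <- rep(c(1, 0), 25)
  cls <- classify_shapes(tab, tab$coi_id, shape_rule("interaction", 1))
  expect_identical(unname(cls == "circle"), tab$interaction == 1)
  cls2 <- classify_shapes(tab, rev(tab$coi_id), shape_rule("interaction", 1))
  expect_identical(cls2[names(cls)], cls)
  all_low <- classify_shapes(tab, tab$coi_id, shape_rule("LT", 300))
  expect_true(all(all_low == "triangle"))
  expect_error(classify_shapes(tab, tab$coi_id, shape_rule("nope", 1)),
               class = "argument_error")
})

test_that("population statistics match an independent recomputation", {
  set.seed(24)
  tab <- random_coi_table(150)
  ids <- tab$coi_id
  q <- quadrant_split(tab, ids, "LT", "LB", 128, 128)
  st <- population_stats(tab, q, parent = ids)
  expect_equal(sum(st$counts$percent), 100, tolerance = 1e-9)
  for (nm in names(q)) {
    sub <- as.data.frame(tab)[tab$coi_id %in% q[[nm]]$members, ]
    if (nrow(sub)) {
      row <- st$summary[st$summary$population == nm & st$summary$column == "LT", ]
      expect_equal(row$mean, sum(sub$LT) / nrow(sub))
      s <- sort(sub$LT); n2 <- length(s)
      med <- if (n2 %% 2 == 1) s[(n2 + 1) / 2] else (s[n2 / 2] + s[n2 / 2 + 1]) / 2
      expect_equal(row$median, med)
      expect_equal(row$min, min(sub$LT)); expect_equal(row$max, max(sub$LT))
    }
  }
  one <- apply_gate(tab, ids, gate_lasso("LT", "LB",
                                         cbind(c(-1, 300, 300, -1), c(-1, -1, 300, 300))))
  st1 <- population_stats(tab, one, parent = ids)
  expect_equal(st1$counts$n, nrow(tab))
  expect_equal(st1$counts$percent, 100)

  empty <- apply_gate(tab, ids, gate_rectangle("LT", "LB", 400, 500, 400, 500))
  st0 <- population_stats(tab, empty, parent = ids)
  expect_equal(st0$counts$n, 0)        # zero row present, not dropped
  expect_true(all(is.na(st0$summary$mean)))

  paths <- export_stats(st, withr::local_tempfile())
  expect_true(all(file.exists(paths)))
  expect_equal(nrow(read.csv(paths[1])), nrow(st$summary))
})

test_that("gate sets survive the JSON round trip and refuse newer schemas", {
  gates <- list(gate_rectangle("LT", "LB", 0, 100, 5, 50, name = "r1"),
                gate_lasso("LT", "LB", cbind(c(0, 10, 5), c(0, 0, 9)), name = "l1"),
                gate_quadrant("LT", "LB", 100, 100, name = "q1"))
  filters <- list(filter_spec(c("area", "LT"), list(c(10, 50), c(0, 255))))
  rules <- list(shape_rule("interaction", 1))
  f <- withr::local_tempfile(fileext = ".json")
  save_gates(f, gates, filters, rules)
  back <- load_gates(f)
  expect_equal(back$gates, gates)
  expect_equal(back$filters, filters)
  expect_equal(back$shape_rules, rules)

  f2 <- withr::local_tempfile(fileext = ".json")
  writeLines('{"schema_version":1,"gates":[{"kind":"rectangle","x_param":"A",
    "y_param":"B","geometry":{"x0":0,"x1":1,"y0":0,"y1":2},"name":"g"}],
    "filters":[],"shape_rules":[]}', f2)
  mini <- load_gates(f2)
  expect_length(mini$gates, 1)
  expect_equal(mini$gates[[1]]$geometry$y1, 2)

  f3 <- withr::local_tempfile(fileext = ".json")
  writeLines('{"schema_version": 99, "gates": []}', f3)
  expect_error(load_gates(f3), class = "schema_version_error")
})

test_that("annotation edits apply in order, revert cleanly and update stats", {
  tab <- random_coi_table(30)
  orig <- tab$LT[tab$coi_id == 7]
  ed <- annotate(tab, data.frame(coi_id = 7, column = "LT", new_value = 200))
  expect_equal(ed$table$LT[ed$table$coi_id == 7], 200)
  back <- annotate(ed$table, data.frame(coi_id = 7, column = "LT", new_value = orig))
  expect_tables_equal(back$table, tab)

  ids <- tab$coi_id
  before <- population_stats(tab, apply_gate(tab, ids, gate_rectangle(
    "LT", "LB", 0, 255, 0, 255)), parent = ids)
  after <- population_stats(ed$table, apply_gate(ed$table, ids, gate_rectangle(
    "LT", "LB", 0, 255, 0, 255)), parent = ids)
  d <- (200 - orig) / nrow(tab)
  row_b <- before$summary[before$summary$column == "LT", "mean"]
  row_a <- after$summary[after$summary$column == "LT", "mean"]
  expect_equal(row_a - row_b, d)

  expect_warning(
    conf <- annotate(tab, data.frame(coi_id = c(3, 3), column = "LT",
                                     new_value = c(10, 20))),
    class = "edit_conflict_warning")
  expect_equal(conf$table$LT[conf$table$coi_id == 3], 20)  # last wins
  expect_equal(nrow(conf$log), 2)

  noop <- annotate(tab, data.frame())
  expect_tables_equal(noop$table, tab)
})

test_that("well-separated planted mixtures are recovered by midpoint quadrants", {
  set.seed(25)
  for (k in 1:5) {
    n <- 400
    truth <- sample(c("T", "B"), n, TRUE)
    sdv <- runif(1, 2, 10)
    sep <- 4 * sdv * runif(1, 1.2, 3)
    lo <- 50
    lt <- rnorm(n, ifelse(truth == "T", lo + sep, lo), sdv)
    lb <- rnorm(n, ifelse(truth == "B", lo + sep, lo), sdv)
    tab <- coi_table(data.frame(coi_id = 1:n, LT = clamp(lt, 0, 255),
                                LB = clamp(lb, 0, 255)), channels = c("LT", "LB"))
    q <- quadrant_split(tab, tab$coi_id, "LT", "LB", lo + sep / 2, lo + sep / 2)
    called <- rep(NA_character_, n)
    called[tab$coi_id %in% q$LR$members] <- "T"
    called[tab$coi_id %in% q$UL$members] <- "B"
    expect_gte(mean(!is.na(called) & called == truth), 0.99)
  }
})
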