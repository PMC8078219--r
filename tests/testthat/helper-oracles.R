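# Independent reference implementations used to cross-check the package.
# These deliberately use different algorithms from the implementation under
# test (set fixed points instead of BFS, per-point scalar ray casting, ...).

# Brute-force DBSCAN: core points from the full distance matrix, clusters as
# the fixed point of reachability closure over core points, borders attached
# to the first cluster in ascending point order.
oracle_dbscan <- function(pts, eps, min_pts) {
  n <- nrow(pts)
  if (n == 0) return(integer(0))
  D <- as.matrix(stats::dist(pts))
  nbmat <- D <= eps
  core <- rowSums(nbmat) >= min_pts
  cluster <- rep(-1L, n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || cluster[i] >= 0) next
    members <- i
    repeat {  # closure: add every core point eps-reachable from the set
      reach <- which(core & cluster < 0 &
                       apply(nbmat[, members, drop = FALSE], 1, any))
      reach <- setdiff(reach, members)
      if (!length(reach)) break
      members <- c(members, reach)
    }
    cluster[members] <- cid
    cid <- cid + 1L
  }
  for (i in seq_len(n)) {  # borders: earliest-discovered cluster that reaches them
    if (cluster[i] >= 0 || core[i]) next
    cores_near <- which(core & nbmat[i, ])
    if (length(cores_near)) cluster[i] <- min(cluster[cores_near])
  }
  cluster
}

# Scalar even-odd ray casting with explicit on-segment handling.
oracle_point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  one <- function(x, y) {
    inside <- FALSE
    j <- n
    for (i in seq_len(n)) {
      x1 <- vx[j]; y1 <- vy[j]; x2 <- vx[i]; y2 <- vy[i]
      d <- abs((x2 - x1) * (y - y1) - (y2 - y1) * (x - x1))
      if (d < 1e-9 && x >= min(x1, x2) - 1e-9 && x <= max(x1, x2) + 1e-9 &&
          y >= min(y1, y2) - 1e-9 && y <= max(y1, y2) + 1e-9) return(TRUE)
      if ((y1 > y) != (y2 > y) && x < (x2 - x1) * (y - y1) / (y2 - y1) + x1)
        inside <- !inside
      j <- i
    }
    inside
  }
  mapply(one, px, py)
}

random_polygon <- function(n_vertices = NULL, cx = 0, cy = 0, rmin = 3, rmax = 40) {
  k <- n_vertices %||% sample(3:24, 1)
  ang <- sort(stats::runif(k, 0, 2 * pi))
  r <- stats::runif(k, rmin, rmax)
  cbind(x = round(cx + r * cos(ang)), y = round(cy + r * sin(ang)))
}

random_coi_table <- function(n, channels = c("LB", "LT")) {
  df <- data.frame(coi_id = seq_len(n))
  for (ch in channels) df[[ch]] <- round(stats::runif(n, 0, 255), 3)
  df$x <- round(stats::runif(n, 0, 500), 2)
  df$y <- round(stats::runif(n, 0, 500), 2)
  df$area <- round(stats::runif(n, 10, 400), 2)
  coi_table(df, channels = channels)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Numeric-normalizing table comparison (CSV round trips can turn integer-valued
# doubles into integers).
expect_tables_equal <- function(a, b) {
  a <- as.data.frame(a); b <- as.data.frame(b)
  expect_identical(names(a), names(b))
  for (cl in names(a)) {
    va <- a[[cl]]; vb <- b[[cl]]
    if (is.numeric(va)) {
      expect_equal(as.numeric(va), as.numeric(vb), tolerance = 0)
    } else {
      expect_identical(as.character(va), as.character(vb))
    }
  }
}
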