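test_that("dbscan_regions matches the reachability-closure oracle", {
  set.seed(10)
  for (k in 1:30) {
    n <- sample(5:60, 1)
    pts <- cbind(runif(n, 0, 100), runif(n, 0, 100))
    eps <- runif(1, 5, 25)
    min_pts <- sample(1:6, 1)
    got <- dbscan_regions(pts, eps, min_pts)
    ora <- oracle_dbscan(pts, eps, min_pts)
    expect_identical(got$cluster, ora)
    expect_identical(got$flag, as.integer(ora >= 0))
  }
})

test_that("dbscan separates well-separated blobs and flags isolated noise", {
  set.seed(11)
  eps <- 5
  blob <- function(cx, cy) cbind(runif(30, cx, cx + eps), runif(30, cy, cy + eps))
  pts <- rbind(blob(0, 0), blob(10 * eps, 0))
  lab <- dbscan_regions(pts, eps, 4)
  expect_equal(length(unique(lab$cluster)), 2)
  expect_true(all(lab$cluster >= 0))
  expect_equal(sort(unique(lab$cluster)), c(0, 1))

  single <- dbscan_regions(cbind(c(0, 100), c(0, 100)), eps = 1, min_pts = 2)
  expect_identical(single$cluster, c(-1L, -1L))

  same <- dbscan_regions(matrix(5, nrow = 7, ncol = 2), eps = 1, min_pts = 7)
  expect_true(all(same$cluster == 0L))

  empty <- dbscan_regions(matrix(numeric(0), 0, 2), 5, 3)
  expect_length(empty$cluster, 0)
})

test_that("region flags are invariant under point reordering", {
  set.seed(12)
  n <- 50
  pts <- cbind(runif(n, 0, 60), runif(n, 0, 60))
  ids <- 1:n
  base <- dbscan_regions(pts, 8, 4, ids = ids)
  perm <- sample(n)
  shuf <- dbscan_regions(pts[perm, ], 8, 4, ids = ids[perm])
  expect_identical(shuf$flag[match(ids, shuf$ids)], base$flag[match(ids, base$ids)])
})

test_that("assign_region_flag writes ROI_DBSCAN and checks id coverage", {
  tab <- random_coi_table(20)
  lab <- dbscan_regions(cbind(tab$x, tab$y), eps = 1e-6, min_pts = 2,
                        ids = tab$coi_id)
  out <- assign_region_flag(tab, lab)
  expect_true(all(out$ROI_DBSCAN == 0))  # all-noise labeling -> all flags 0

  lab2 <- dbscan_regions(cbind(tab$x, tab$y)[1:10, ], 50, 2, ids = tab$coi_id[1:10])
  expect_error(assign_region_flag(tab, lab2), class = "integrity_error")
})

test_that("planted dense-region membership is recovered from a bundle", {
  dir <- withr::local_tempdir()
  sp <- small_scene(n = 20, seed = 13, noise_sd = 0, contacts_fraction = 0)
  b <- generate_bundle(sp, dir)
  expect_identical(b$table$ROI_DBSCAN[match(b$truth$coi_id, b$table$coi_id)],
                   b$truth$in_cluster)
})

test_that("contact flags follow dilation-overlap semantics and are monotone", {
  sq <- function(x0, y0, s) roi_polygon(1L, 1L,
    cbind(x = c(x0, x0 + s, x0 + s, x0), y = c(y0, y0, y0 + s, y0 + s)))
  rois <- roi_set(list(sq(10, 10, 6)))
  mask <- matrix(0, 40, 40)
  mask[12, 19] <- 1  # x = 18 (0-based): 2 px right of the polygon edge x = 16
  expect_equal(unname(detect_interactions(rois, mask, contact_dist = 0)), 0L)
  expect_equal(unname(detect_interactions(rois, mask, contact_dist = 2)), 1L)
  mask2 <- matrix(0, 40, 40)
  mask2[12, 15] <- 1  # inside the polygon: contact at distance 0
  expect_equal(unname(detect_interactions(rois, mask2, contact_dist = 0)), 1L)
  # monotone: flags only turn 0 -> 1 as contact_dist grows
  set.seed(14)
  mask3 <- matrix(rbinom(40 * 40, 1, 0.01), 40, 40)
  prev <- 0L
  for (cd in c(0, 1, 2, 4, 8)) {
    cur <- unname(detect_interactions(rois, mask3, cd))
    expect_gte(cur, prev)
    prev <- cur
  }
  # slice out of range
  r2 <- roi_set(list(roi_polygon(1L, 3L, sq(10, 10, 6)$vertices)))
  expect_error(detect_interactions(r2, mask, 1), class = "dimension_error")
})

test_that("cells_in_region agrees with the scalar ray-casting oracle", {
  set.seed(15)
  tab <- random_coi_table(120)
  for (k in 1:15) {
    v <- random_polygon(cx = runif(1, 100, 400), cy = runif(1, 100, 400),
                        rmin = 30, rmax = 200)
    got <- cells_in_region(tab, v)
    ora <- tab$coi_id[oracle_point_in_polygon(tab$x, tab$y, v[, 1], v[, 2])]
    expect_identical(got, ora)
    # invariant under vertex rotation
    rot <- rbind(v[-1, , drop = FALSE], v[1, , drop = FALSE])
    expect_identical(sort(cells_in_region(tab, rot)), sort(got))
  }
  whole <- cbind(x = c(-1, 600, 600, -1), y = c(-1, -1, 600, 600))
  expect_identical(cells_in_region(tab, whole), tab$coi_id)
  tiny <- cbind(x = c(-10, -9, -9), y = c(-10, -10, -9))
  expect_length(cells_in_region(tab, tiny), 0)
})

test_that("points exactly on a region edge are inside", {
  tab <- coi_table(data.frame(coi_id = 1:2, LT = c(1, 2), LB = c(1, 2),
                              x = c(50, 50), y = c(10, 30)), channels = c("LT", "LB"))
  v <- cbind(x = c(0, 50, 50, 0), y = c(0, 0, 20, 20))
  expect_identical(cells_in_region(tab, v), 1L)
})
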