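# Paint a (possibly truncated) sphere of nucleus `id` into a label volume.
paint_sphere <- function(lab, id, cx, cy, cs, r, dz = 1) {
  for (t in seq_len(dim(lab)[3])) {
    rt2 <- r^2 - ((t - cs) * dz)^2
    if (rt2 <= 0) next
    for (row in seq_len(dim(lab)[1])) for (col in seq_len(dim(lab)[2])) {
      if ((col - 1 - cx)^2 + (row - 1 - cy)^2 <= rt2) lab[row, col, t] <- id
    }
  }
  lab
}

test_that("central_slice picks the largest cross-section, ties to the lower slice", {
  lab <- array(0L, dim = c(24, 24, 9))
  lab <- paint_sphere(lab, 1L, 11, 11, 5, 4.5)  # spans slices 1..9, max at 5
  cs <- central_slice(lab)
  # brute-force per-slice pixel counts
  counts <- vapply(1:9, function(s) sum(lab[, , s] == 1L), integer(1))
  expect_equal(unname(cs["1"]), which.max(counts))
  expect_equal(unname(cs["1"]), 5L)

  lab2 <- array(0L, dim = c(10, 10, 6))
  lab2[4:6, 4:6, 2] <- 1L                      # single-slice nucleus
  expect_equal(unname(central_slice(lab2)["1"]), 2L)

  lab3 <- array(0L, dim = c(10, 10, 6))
  lab3[4:6, 4:6, 4] <- 1L                      # equal areas on slices 4 and 5
  lab3[4:6, 4:6, 5] <- 1L
  expect_equal(unname(central_slice(lab3)["1"]), 4L)
})

test_that("reversing the z-axis mirrors the central slice (up to ties)", {
  set.seed(8)
  n_sl <- 9
  lab <- array(0L, dim = c(60, 60, n_sl))
  for (i in 1:4)
    lab <- paint_sphere(lab, i, 8 + 14 * (i - 1), 30, sample(3:7, 1), runif(1, 2.5, 4.5))
  fwd <- central_slice(lab)
  rev <- central_slice(lab[, , n_sl:1])
  for (id in names(fwd)) {
    counts <- vapply(1:n_sl, function(s) sum(lab[, , s] == as.integer(id)),
                     integer(1))
    # mirrored slice has the same (maximal) cross-section area ...
    expect_equal(counts[n_sl + 1L - rev[[id]]], counts[fwd[[id]]])
    # ... and when the maximum is unique the mapping is exactly s -> n+1-s
    if (sum(counts == max(counts)) == 1)
      expect_equal(rev[[id]], n_sl + 1L - fwd[[id]])
  }
})

test_that("the ring of a disk nucleus is the expected annulus", {
  lab <- array(0L, dim = c(40, 40, 1))
  lab <- paint_sphere(lab, 1L, 20, 20, 1, 5)
  ring <- membrane_ring(lab, 1L, 1L, ring_spec(inner_margin = 1, thickness = 3))
  # annulus between radii 6 and 9: area pi*(9^2-6^2)
  expect_equal(nrow(ring$pixels), pi * (81 - 36), tolerance = 0.15)
  d <- sqrt((ring$pixels[, 2] - 1 - 20)^2 + (ring$pixels[, 1] - 1 - 20)^2)
  expect_true(all(d > 5.9 & d <= 9.1))

  shell <- membrane_ring(lab, 1L, 1L, ring_spec(inner_margin = 0, thickness = 1))
  ds <- sqrt((shell$pixels[, 2] - 1 - 20)^2 + (shell$pixels[, 1] - 1 - 20)^2)
  expect_true(all(ds > 5 & ds <= 6.1))  # one-pixel boundary shell
})

test_that("rings of adjacent nuclei never overlap", {
  lab <- array(0L, dim = c(40, 60, 1))
  lab <- paint_sphere(lab, 1L, 24, 20, 1, 5)
  lab <- paint_sphere(lab, 2L, 36, 20, 1, 5)   # centers 12 px apart
  r1 <- membrane_ring(lab, 1L, 1L)
  r2 <- membrane_ring(lab, 2L, 1L)
  k1 <- paste(r1$pixels[, 1], r1$pixels[, 2])
  k2 <- paste(r2$pixels[, 1], r2$pixels[, 2])
  expect_length(intersect(k1, k2), 0)
})

test_that("ring means recover uniform and painted membrane values", {
  lab <- array(0L, dim = c(40, 40, 1))
  lab <- paint_sphere(lab, 1L, 20, 20, 1, 5)
  st <- uniform_stack(c(42, 7), h = 40, w = 40)
  ring <- membrane_ring(lab, 1L, 1L)
  m <- measure_coi(st, ring, 1L)
  expect_equal(unname(m), c(42, 7))
  # empty ring propagates NA
  m2 <- measure_coi(st, cbind(row = integer(0), col = integer(0)), 1L)
  expect_true(all(is.na(m2)))
})

test_that("morphology: shoelace area, circularity and solidity behave analytically", {
  sq <- cbind(x = c(0, 10, 10, 0), y = c(0, 0, 10, 10))
  m <- morphology(sq)
  expect_equal(unname(m["area"]), 100)
  expect_equal(unname(m["solidity"]), 1)
  expect_equal(unname(m["circularity"]), pi / 4, tolerance = 1e-10)

  th <- seq(0, 2 * pi, length.out = 65)[-65]
  circ64 <- cbind(x = 100 * cos(th), y = 100 * sin(th))
  expect_gte(morphology(circ64)["circularity"], 0.97)

  expect_error(morphology(cbind(x = c(0, 1), y = c(0, 1))), class = "argument_error")

  # scale laws: area ~ f^2, circularity and solidity invariant
  set.seed(9)
  for (k in 1:10) {
    v <- random_polygon(cx = 0, cy = 0, rmin = 10, rmax = 50)
    f <- runif(1, 0.5, 3)
    m1 <- morphology(v); m2 <- morphology(v * f)
    expect_equal(unname(m2["area"]), unname(m1["area"]) * f^2, tolerance = 1e-9)
    expect_equal(unname(m2["circularity"]), unname(m1["circularity"]), tolerance = 1e-9)
    expect_equal(unname(m2["solidity"]), unname(m1["solidity"]), tolerance = 1e-9)
  }
})

test_that("run_measurement pairs one record with one ROI for every nucleus", {
  dir <- withr::local_tempdir()
  b <- generate_bundle(measure_scene(n = 12, seed = 21, image = c(X = 400, Y = 400)), dir)
  lab <- read_labels(b$paths$labels)
  st <- load_stack(b$paths$image, read_legend(b$paths$legend))
  out <- run_measurement(st, lab)
  expect_equal(nrow(out$table), 12)
  expect_length(out$rois, 12)
  expect_setequal(out$table$coi_id, 1:12)

  empty <- run_measurement(st, array(0L, dim = dim(lab)))
  expect_equal(nrow(empty$table), 0)
  expect_length(empty$rois, 0)

  bad <- array(0L, dim = c(10, 10, 2))
  expect_error(run_measurement(st, bad), class = "dimension_error")
})

test_that("noise-free measurement recovers painted membrane values exactly", {
  dir <- withr::local_tempdir()
  sp <- measure_scene(n = 10, noise_sd = 0, sd = 0, seed = 31,
                      image = c(X = 360, Y = 360))
  b <- generate_bundle(sp, dir)
  truth <- b$truth
  for (ch in c("LB", "LT")) {
    expect_identical(unname(b$table[[ch]][match(truth$coi_id, b$table$coi_id)]),
                     as.numeric(truth[[paste0("paint_", ch)]]))
  }
})
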