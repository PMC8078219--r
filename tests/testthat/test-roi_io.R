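# Helper assembling .roi bytes field by field, following the published
# ImageJ RoiDecoder layout, independent of the package's encoder.
build_roi_bytes <- function(type = 0L, top = 10L, left = 10L, bottom = 14L,
                            right = 15L, xs = c(0L, 5L, 2L), ys = c(0L, 0L, 4L),
                            position = 0L, magic = "Iout") {
  be2 <- function(v) writeBin(as.integer(v), raw(), size = 2, endian = "big")
  be4 <- function(v) writeBin(as.integer(v), raw(), size = 4, endian = "big")
  hdr <- c(charToRaw(magic), be2(218), as.raw(c(type, 0)),
           be2(top), be2(left), be2(bottom), be2(right), be2(length(xs)),
           raw(38), be4(position), be4(0))
  stopifnot(length(hdr) == 64)
  c(hdr, be2(xs), be2(ys))
}

test_that("decode reconstructs absolute vertices from a hand-assembled block", {
  p <- decode_roi(build_roi_bytes())
  expect_s3_class(p, "roi_polygon")
  expect_equal(unname(p$vertices), cbind(c(10, 15, 12), c(10, 10, 14)))
  expect_equal(p$slice, 1L)  # position unset -> slice 1
  p2 <- decode_roi(build_roi_bytes(position = 7L))
  expect_equal(p2$slice, 7L)
})

test_that("wrong magic and unsupported ROI types are refused by name", {
  expect_error(decode_roi(build_roi_bytes(magic = "Xout")), class = "format_error")
  err <- tryCatch(decode_roi(build_roi_bytes(type = 2L)), error = function(e) e)
  expect_s3_class(err, "unsupported_type_error")
  expect_match(conditionMessage(err), "oval")
  expect_error(decode_roi(build_roi_bytes(type = 10L)),
               class = "unsupported_type_error")
  # freehand (7) and traced (8) outlines are accepted
  expect_s3_class(decode_roi(build_roi_bytes(type = 7L)), "roi_polygon")
  expect_s3_class(decode_roi(build_roi_bytes(type = 8L)), "roi_polygon")
})

test_that("encode emits the documented byte layout", {
  r <- roi_polygon(1L, 3L, cbind(x = c(0, 1, 1, 0), y = c(0, 0, 1, 1)))
  b <- encode_roi(r)
  expect_identical(rawToChar(b[1:4]), "Iout")
  rd16 <- function(off) readBin(b[(off + 1):(off + 2)], "integer", size = 2,
                                endian = "big")
  expect_identical(as.integer(b[7]), 0L)            # polygon type
  expect_equal(c(rd16(8), rd16(10), rd16(12), rd16(14)), c(0, 0, 1, 1))
  expect_equal(rd16(16), 4)                         # vertex count
  expect_equal(readBin(b[57:60], "integer", size = 4, endian = "big"), 3)
})

test_that("decode(encode(.)) is the identity over random polygons", {
  set.seed(1)
  for (k in 1:200) {
    v <- random_polygon(cx = sample(0:3000, 1), cy = sample(0:3000, 1))
    r <- roi_polygon(k, sample(1:12, 1), v)
    d <- decode_roi(encode_roi(r))
    expect_identical(unname(d$vertices), unname(r$vertices))
    expect_identical(d$slice, r$slice)
    expect_identical(unname(d$bounds), unname(r$bounds))
  }
})

test_that("relative extents beyond the signed-16-bit range overflow loudly", {
  v <- cbind(x = c(0, 40000, 0), y = c(0, 0, 10))
  expect_error(encode_roi(roi_polygon(1L, 1L, v)), class = "overflow_error")
})

test_that("roi archives round-trip with slices preserved per entry", {
  set.seed(2)
  rois <- lapply(1:30, function(i)
    roi_polygon(i, slice = (i - 1) %% 12 + 1,
                random_polygon(cx = 100 + 40 * (i %% 6), cy = 100 + 40 * (i %/% 6))))
  s <- roi_set(rois)
  f <- withr::local_tempfile(fileext = ".zip")
  write_roi_archive(s, f)
  back <- read_roi_archive(f)
  expect_length(back, 30)
  for (i in 1:30) {
    expect_identical(back[[as.character(i)]]$vertices, s[[as.character(i)]]$vertices)
    expect_identical(back[[as.character(i)]]$slice, s[[as.character(i)]]$slice)
  }
})

test_that("a corrupt entry is reported and the rest of the archive survives", {
  rois <- lapply(1:4, function(i) roi_polygon(i, 1L, random_polygon(cx = 50, cy = 50)))
  entries <- lapply(rois, encode_roi)
  names(entries) <- sprintf("%04d.roi", 1:4)
  entries[["0003.roi"]] <- charToRaw("garbage-not-a-roi")
  f <- withr::local_tempfile(fileext = ".zip")
  histocyto:::zip_write(entries, f)
  expect_warning(back <- read_roi_archive(f), class = "decode_warning")
  expect_length(back, 3)
  expect_false("3" %in% names(back))
})

test_that("empty archives warn on both ends; duplicates are an error", {
  f <- withr::local_tempfile(fileext = ".zip")
  expect_warning(write_roi_archive(roi_set(), f), class = "empty_archive_warning")
  expect_warning(back <- read_roi_archive(f), class = "empty_archive_warning")
  expect_length(back, 0)

  r <- roi_polygon(5L, 1L, random_polygon(cx = 20, cy = 20))
  entries <- list(encode_roi(r), encode_roi(r))
  names(entries) <- c("0005.roi", "cell-0005.roi")
  f2 <- withr::local_tempfile(fileext = ".zip")
  histocyto:::zip_write(entries, f2)
  expect_error(read_roi_archive(f2), class = "integrity_error")
})

test_that("Fiji position-style entry names are accepted", {
  r <- roi_polygon(1L, 1L, random_polygon(cx = 30, cy = 30))
  entries <- list(`0004-0120-0200.roi` = encode_roi(roi_polygon(1L, 1L, r$vertices)))
  f <- withr::local_tempfile(fileext = ".zip")
  histocyto:::zip_write(entries, f)
  expect_warning(back <- read_roi_archive(f), class = "entry_name_warning")
  expect_equal(back[[1]]$slice, 4L)  # slice taken from the name's first field
})

test_that("the internal zip container is readable by an external unzip", {
  skip_if(Sys.which("unzip") == "")
  entries <- list(`a.roi` = as.raw(1:10), `b.roi` = charToRaw("hello"))
  f <- withr::local_tempfile(fileext = ".zip")
  histocyto:::zip_write(entries, f)
  out <- system2("unzip", c("-t", shQuote(f)), stdout = TRUE)
  expect_true(any(grepl("No errors detected", out)))
})
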