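make_random_stack <- function(seed, T = 3, H = 5, W = 4, bits = 16) {
  set.seed(seed)
  frame_stack(array(sample(0:(2^bits - 1), T * H * W, replace = TRUE),
                    c(T, H, W)),
              container_bits = bits)
}

test_that("write_stack / read_stack round-trip is bit-exact", {
  fs <- make_random_stack(11)
  path <- withr::local_tempfile(fileext = ".tif")
  write_stack(fs, path)
  back <- read_stack(path)
  expect_equal(back$frames, fs$frames, ignore_attr = TRUE)
  expect_equal(back$container_bits, 16L)

  # degenerate 1x1x1 stack
  one <- frame_stack(array(7L, c(1, 1, 1)), container_bits = 8)
  write_stack(one, path)
  expect_equal(read_stack(path)$frames[1, 1, 1], 7)
})

test_that("page order is preserved as time order", {
  arr <- array(0L, c(4, 3, 3))
  for (t in 1:4) arr[t, , ] <- t * 10L
  path <- withr::local_tempfile(fileext = ".tif")
  write_stack(frame_stack(arr, container_bits = 8), path)
  back <- read_stack(path)
  expect_equal(back$frames[, 1, 1], c(10, 20, 30, 40))
})

test_that("full 16-bit range and zero stacks read with correct depth", {
  path <- withr::local_tempfile(fileext = ".tif")
  hot <- frame_stack(array(c(0L, 65535L, 1L, 2L), c(1, 2, 2)),
                     container_bits = 16)
  write_stack(hot, path)
  back <- read_stack(path)
  expect_equal(back$container_bits, 16L)
  expect_equal(max(back$frames), 65535)

  write_stack(frame_stack(array(0L, c(3, 4, 4)), container_bits = 8), path)
  z <- read_stack(path)
  expect_equal(n_frames(z), 3L)
  expect_equal(z$container_bits, 8L)
  expect_true(all(z$frames == 0))
})

test_that("multi-band stacks round-trip", {
  set.seed(3)
  fs <- frame_stack(array(sample(0:255, 2 * 4 * 4 * 3, replace = TRUE),
                          c(2, 4, 4, 3)), container_bits = 8)
  path <- withr::local_tempfile(fileext = ".tif")
  write_stack(fs, path)
  back <- read_stack(path)
  expect_equal(back$band_count, 3L)
  expect_equal(back$frames, fs$frames, ignore_attr = TRUE)
})

test_that("unreadable input is rejected with an informative error", {
  expect_error(read_stack("no/such/file.tif"), "cannot read")
  bad <- withr::local_tempfile(fileext = ".tif")
  writeLines("not a tiff", bad)
  expect_error(read_stack(bad), "unreadable TIFF")
})

test_that("extract_roi slices half-open windows without clipping", {
  fs <- make_random_stack(5, T = 2, H = 100, W = 100, bits = 8)
  # identity on the full frame
  full <- extract_roi(fs, roi(0, 0, 100, 100))
  expect_equal(full$frames, fs$frames)
  # 21x21 default window
  sub <- extract_roi(fs, roi(0, 0))
  expect_equal(dim(sub$frames), c(2L, 21L, 21L))
  expect_equal(sub$container_bits, fs$container_bits)
  # one pixel past the right edge fails loudly
  expect_error(extract_roi(fs, roi(0, 80, 21, 21)), "exceeds frame bounds")
  # commutes with frame indexing
  r <- roi(10, 30, 7, 9)
  sub2 <- extract_roi(fs, r)
  expect_equal(get_frame(sub2, 2), get_frame(fs, 2)[11:17, 31:39])
})

test_that("ROI config files load from YAML and JSON", {
  recs <- list(
    list(name = "bg", role = "background", row0 = 0, col0 = 40),
    list(name = "emb", role = "embryo", row0 = 5, col0 = 5,
         height = 10, width = 12))
  ypath <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(recs, ypath)
  jpath <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(recs, jpath, auto_unbox = TRUE)
  for (p in c(ypath, jpath)) {
    rois <- read_roi_file(p)
    expect_length(rois, 2L)
    expect_equal(rois[[1]]$role, "background")
    expect_equal(rois[[1]]$height, 21L)  # default sampling window
    expect_equal(rois[[2]]$width, 12L)
  }
  expect_error(read_roi_file("missing.yaml"), "not found")
})
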