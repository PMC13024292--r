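test_that("label_mask_sequence validates its invariants", {
  frames <- list(matrix(0:3, 2, 2), matrix(c(0L, 1L, 2L, 3L), 2, 2))
  seq <- label_mask_sequence(frames)
  expect_s3_class(seq, "label_mask_sequence")
  expect_equal(unname(seq$label_map), c("C0", "C1", "C2"))

  expect_error(label_mask_sequence(list(matrix(0L, 2, 2), matrix(0L, 3, 2))),
               class = "spinetrack_dimension_error")
  expect_error(label_mask_sequence(list(matrix(0.5, 2, 2))),
               class = "spinetrack_format_error")
  expect_error(
    label_mask_sequence(frames, label_map = c("1" = "C0")),
    class = "spinetrack_format_error")
})

test_that("TIFF stack round trip is bit-exact, 8- and 16-bit, both endians read", {
  set.seed(42)
  frames <- lapply(1:4, function(i)
    matrix(sample.int(9, 15 * 11, TRUE) - 1L, 15, 11))
  f <- withr::local_tempfile(fileext = ".tif")
  spinetrack:::write_tiff_stack(frames, f, bits = 16L)
  expect_identical(spinetrack:::read_tiff_stack(f), frames)
  spinetrack:::write_tiff_stack(frames, f, bits = 8L)
  expect_identical(spinetrack:::read_tiff_stack(f), frames)
  # values above the 8-bit range are refused
  expect_error(spinetrack:::write_tiff_stack(list(matrix(300L, 2, 2)), f,
                                             bits = 8L),
               class = "spinetrack_format_error")
})

test_that("PNG round trip is bit-exact and frame order is preserved", {
  set.seed(43)
  m <- matrix(sample.int(5000, 20 * 13, TRUE) - 1L, 20, 13)
  f <- withr::local_tempfile(fileext = ".png")
  spinetrack:::write_png_gray(m, f, bits = 16L)
  expect_identical(spinetrack:::read_png_gray(f), m)
  m8 <- matrix(sample.int(256, 12 * 12, TRUE) - 1L, 12, 12)
  spinetrack:::write_png_gray(m8, f, bits = 8L)
  expect_identical(spinetrack:::read_png_gray(f), m8)
})

test_that("mask sequence round trips through TIFF stack and PNG directory", {
  set.seed(44)
  frames <- lapply(1:5, function(i)
    matrix(sample(0:8, 30 * 30, TRUE), 30, 30))
  meta <- recording_meta("rt", pixel_spacing_mm = 0.2, width_px = 30,
                         height_px = 30, quality_flag = "low",
                         segment_quality = c("C4-C5" = "low"))
  seq <- label_mask_sequence(frames, meta = meta)

  tif <- withr::local_tempfile(fileext = ".tif")
  write_mask_sequence(seq, tif)
  back <- read_mask_sequence(tif)
  expect_identical(back$frames, seq$frames)
  expect_identical(back$label_map, seq$label_map)
  expect_equal(back$meta$pixel_spacing_mm, 0.2)
  expect_equal(back$meta$quality_flag, "low")
  expect_equal(back$meta$segment_quality, c("C4-C5" = "low"))

  dirp <- withr::local_tempdir()
  pngdir <- file.path(dirp, "frames")
  write_mask_sequence(seq, pngdir)
  back2 <- read_mask_sequence(pngdir)
  expect_identical(back2$frames, seq$frames)
  expect_identical(back2$meta$recording_id, "rt")
})

test_that("read_mask_sequence enforces the >= 2 frame precondition", {
  f <- withr::local_tempfile(fileext = ".tif")
  spinetrack:::write_tiff_stack(list(matrix(1L, 4, 4)), f)
  expect_error(read_mask_sequence(f), class = "spinetrack_insufficient_data")
  expect_error(read_mask_sequence(file.path(tempdir(), "nope-xyz")),
               class = "spinetrack_io_error")
})

test_that("an all-zero frame loads and downstream marks it missing", {
  frames <- list(square_mask(), matrix(0L, 32L, 32L), square_mask())
  seq <- label_mask_sequence(frames, label_map = c("1" = "C4"))
  tmpl <- as_mean_shape(square_mask(), "C4")
  tr <- track_vertebra(seq, tmpl)
  expect_equal(tr$missing_frames, 2L)
  expect_true(is.na(tr$theta_deg[2]))
})

test_that("write_trace_table emits long format with empty cells for missing", {
  tr1 <- rotation_trace("C4", theta_deg = c(0, 1, NA, 2),
                        dtheta_deg = c(0, 1, NA, NA),
                        fit_overlap = c(1, 1, NA, 1), missing_frames = 3L)
  tr2 <- segment_trace("C4", "C5", dtheta_rel_deg = c(0, 0.5, 0.5, 0),
                       dtheta_rel_smoothed_deg = c(0, 0.4, 0.4, 0),
                       srom_deg = 1)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_trace_table(list(tr1, tr2), f)
  tab <- read.delim(f, na.strings = "")
  expect_equal(nrow(tab), 8L)            # two traces x four frames
  expect_true(is.na(tab$theta_deg[3]))   # empty cell, not zero
  raw <- readLines(f)
  expect_false(grepl("NA", raw[4]))

  # empty list -> header-only file
  write_trace_table(list(), f)
  expect_equal(nrow(read.delim(f)), 0L)

  # mixed frame counts -> consistency error
  tr3 <- rotation_trace("C5", 0, 0, 1)
  expect_error(write_trace_table(list(tr1, tr3), f),
               class = "spinetrack_consistency_error")

  # traces written then re-read reconstruct the same series
  write_trace_table(list(tr1, tr2), f)
  back <- spinetrack:::read_trace_table(f)
  expect_equal(back[["C4"]]$theta_deg, tr1$theta_deg)
  expect_equal(back[["C4-C5"]]$dtheta_rel_deg, tr2$dtheta_rel_deg)
})

test_that("writing a non-sequence errors", {
  expect_error(write_mask_sequence(list(), tempfile()),
               class = "spinetrack_format_error")
})

test_that("rotation_trace rejects deltas beyond the 90 degree window", {
  expect_error(rotation_trace("C4", c(0, 95), c(0, 95), c(1, 1)),
               class = "spinetrack_trace_error")
})
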