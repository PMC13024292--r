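test_that("phantom truth bookkeeping: programmed excursions are analytic", {
  cfg <- small_phantom_config(n_frames = 40, seed = 21)
  rec <- generate_phantom(cfg)
  sroms <- vapply(rec$truth_segment, `[[`, 0, "srom_deg")
  expect_equal(unname(sroms[c("C4-C5", "C5-C6", "C6-C7")]), c(10, 8, 6))
  # truth_segment derives from truth_theta by differencing
  for (seg in names(rec$truth_segment)) {
    parts <- strsplit(seg, "-")[[1]]
    rel <- rec$truth_theta[, parts[1]] - rec$truth_theta[, parts[2]]
    expect_equal(rec$truth_segment[[seg]]$dtheta_rel,
                 c(0, diff(rel)), tolerance = 1e-12)
  }
  # cumulative C4-C7 truth at the last frame equals the configured sum
  c47 <- c("C4-C5", "C5-C6", "C6-C7")
  total <- sum(vapply(rec$truth_segment[c47], function(s)
    sum(s$dtheta_rel), 0))
  expect_equal(total, 24, tolerance = 1e-9)
})

test_that("same seed reproduces the stack bit-exactly", {
  cfg <- small_phantom_config(n_frames = 6, size = 256, seed = 22,
                              jitter_px = 2)
  r1 <- generate_phantom(cfg)
  r2 <- generate_phantom(cfg)
  expect_identical(r1$masks$frames, r2$masks$frames)
  r3 <- generate_phantom(small_phantom_config(n_frames = 6, size = 256,
                                              seed = 23, jitter_px = 2))
  expect_false(identical(r1$masks$frames, r3$masks$frames))
})

test_that("clean masks are consistent with the analytic poses", {
  cfg <- small_phantom_config(n_frames = 5, size = 320, seed = 24)
  rec <- generate_phantom(cfg)
  # re-rasterizing from truth poses reproduces the masks bit-exactly:
  # generate() is deterministic given the config
  rec2 <- generate_phantom(cfg)
  expect_identical(rec$masks$frames, rec2$masks$frames)
  # every vertebra present in every frame, labels 1..8
  for (f in rec$masks$frames)
    expect_setequal(unique(as.vector(f)), 0:8)
})

test_that("degrade is the identity at jitter 0 and never touches truth", {
  cfg <- small_phantom_config(n_frames = 4, size = 256, seed = 25)
  rec <- generate_phantom(cfg)
  deg <- degrade_phantom(rec, jitter_px = 0, seed = 1)
  expect_identical(deg$masks$frames, rec$masks$frames)
  deg2 <- degrade_phantom(rec, jitter_px = 2, seed = 1)
  expect_identical(deg2$truth_theta, rec$truth_theta)
  expect_identical(deg2$truth_segment, rec$truth_segment)
  expect_false(identical(deg2$masks$frames, rec$masks$frames))
})

test_that("jitter lowers mask fidelity monotonically (fixed seeds)", {
  cfg <- small_phantom_config(n_frames = 3, size = 320, seed = 26)
  rec <- generate_phantom(cfg)
  lab <- spinetrack:::label_of(rec$masks, "C4")
  dice_at <- vapply(c(1, 2, 3), function(j) {
    deg <- degrade_phantom(rec, jitter_px = j, seed = 5)
    mean(vapply(seq_along(rec$masks$frames), function(t)
      dsc(rec$masks$frames[[t]] == lab, deg$masks$frames[[t]] == lab), 0))
  }, 0)
  expect_true(all(dice_at < 1))
  expect_true(all(diff(dice_at) < 0))
})

test_that("occlusion band with dropout 1 empties the covered labels", {
  cfg <- small_phantom_config(n_frames = 3, size = 320, seed = 27)
  rec <- generate_phantom(cfg)
  # C7 sits at the bottom of the chain: cover the lower quarter
  deg <- degrade_phantom(rec, occlusion = list(rows = c(0.72, 1.0),
                                               dropout = 1.0), seed = 2)
  lab <- spinetrack:::label_of(rec$masks, "C7")
  H <- nrow(rec$masks$frames[[1]])
  band <- round(0.72 * H):H
  for (t in seq_along(deg$masks$frames))
    expect_equal(sum(deg$masks$frames[[t]][band, ] == lab), 0)
  expect_identical(deg$truth_theta, rec$truth_theta)
})

test_that("whole-label dropout produces missing frames downstream", {
  cfg <- small_phantom_config(n_frames = 12, size = 256, seed = 28,
                              dropout_prob = 0.4)
  rec <- generate_phantom(cfg)
  present <- vapply(rec$masks$frames, function(f) any(f == 5L), TRUE)
  expect_true(any(!present))   # with p = 0.4 over 12 frames this is certain
})

test_that("config validation", {
  expect_error(phantom_config(global_sweep_deg = 10),
               class = "spinetrack_config_error")   # contributions sum to 40
  expect_error(phantom_config(n_frames = 1), class = "spinetrack_config_error")
  bad <- spinetrack:::default_contributions(40)
  bad$peak[1] <- 1.2
  expect_error(phantom_config(segment_contributions = bad),
               class = "spinetrack_config_error")
})

test_that("infeasible geometry raises a generation error", {
  sc <- spinetrack:::default_contributions(40)
  # grotesquely large excursion concentrated on one segment collides the chain
  sc$excursion_deg <- c(0, 0, 0, 0, 0, 0, 40)
  sc$peak <- c(0.5, 0.5, 0.5, 0.5, 0.5, 0.5, 0.5)
  cfg <- phantom_config(n_frames = 10, image_size = c(256L, 256L),
                        segment_contributions = sc, seed = 29)
  expect_error(generate_phantom(cfg), class = "spinetrack_generation_error")
})

test_that("phantom_intensity renders a seeded grayscale sequence", {
  rec <- generate_phantom(small_phantom_config(n_frames = 3, size = 128,
                                               seed = 30))
  g1 <- phantom_intensity(rec, seed = 4)
  g2 <- phantom_intensity(rec, seed = 4)
  expect_identical(g1$frames, g2$frames)
  expect_s3_class(g1, "grayscale_sequence")
  expect_true(mean(g1$frames[[1]][rec$masks$frames[[1]] != 0]) >
              mean(g1$frames[[1]][rec$masks$frames[[1]] == 0]))
})
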