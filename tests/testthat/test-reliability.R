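test_that("icc_3_1 equals 1 for identical and shifted raters", {
  x <- c(1, 2, 3, 5, 4, 6)
  expect_equal(icc_3_1(x, x)$icc, 1)
  expect_equal(icc_3_1(x, x + 5)$icc, 1)   # consistency ignores offsets
})

test_that("icc_3_1 matches the brute-force ANOVA oracle (frozen value)", {
  x <- c(1, 2, 3, 4, 5, 6)
  y <- c(1, 3, 2, 4, 6, 5)
  r <- icc_3_1(x, y)
  # frozen from the two-way ANOVA mean squares: (MS_R - MS_E)/(MS_R + MS_E)
  expect_equal(r$icc, 0.885714285714286, tolerance = 1e-12)
  expect_equal(r$icc, icc31_aov_oracle(x, y), tolerance = 1e-12)
  expect_lte(r$ci_low, r$icc)
  expect_gte(r$ci_high, r$icc)
})

test_that("icc_3_1 equals the aov oracle on 200 random tables", {
  set.seed(2024)
  for (i in 1:200) {
    n <- sample(3:20, 1)
    x <- rnorm(n)
    y <- 0.7 * x + rnorm(n, sd = 0.5)
    expect_equal(icc_3_1(x, y)$icc, icc31_aov_oracle(x, y), tolerance = 1e-9)
  }
})

test_that("icc_3_1 invariances and degenerate cases", {
  set.seed(31)
  x <- rnorm(12); y <- x + rnorm(12, sd = 0.3)
  base <- icc_3_1(x, y)$icc
  # common affine transform of both raters
  expect_equal(icc_3_1(2.5 * x - 7, 2.5 * y - 7)$icc, base, tolerance = 1e-9)
  # rater-specific additive shifts
  expect_equal(icc_3_1(x + 3, y - 2)$icc, base, tolerance = 1e-9)
  # missing frames dropped pairwise
  xm <- x; xm[3] <- NA
  expect_equal(icc_3_1(xm, y)$icc, icc_3_1(x[-3], y[-3])$icc)
  expect_error(icc_3_1(1:2, 2:3), class = "spinetrack_insufficient_data")
  expect_warning(r <- icc_3_1(rep(1, 5), rep(2, 5)),
                 class = "spinetrack_degenerate_icc")
  expect_true(is.na(r$icc))
})

# build paired pred/gt segment-trace batches with controlled noise
mk_batch <- function(n_rec = 4, n_frames = 60, noise = 0.2, seed = 1) {
  set.seed(seed)
  u <- (seq_len(n_frames) - 1) / (n_frames - 1)
  segs <- c("C4-C5" = 0.7, "C5-C6" = 0.4, "C6-C7" = 0.2)
  amps <- c(9, 7, 5)
  pred <- list(); gt <- list()
  for (r in seq_len(n_rec)) {
    ps <- list(); gs <- list()
    for (i in seq_along(segs)) {
      w <- min(0.2, segs[i], 1 - segs[i])
      phi <- amps[i] * spinetrack:::rcos_cdf((u - segs[i]) / w)
      d <- c(0, diff(phi))
      dn <- d + rnorm(n_frames, sd = noise)
      parts <- strsplit(names(segs)[i], "-")[[1]]
      gsm <- smooth_trace(d, 3); psm <- smooth_trace(dn, 3)
      gs[[names(segs)[i]]] <- segment_trace(parts[1], parts[2], d, gsm,
                                            srom_deg = spinetrack:::srom_of(gsm))
      ps[[names(segs)[i]]] <- segment_trace(parts[1], parts[2], dn, psm,
                                            srom_deg = spinetrack:::srom_of(psm))
    }
    pred[[paste0("rec", r)]] <- ps
    gt[[paste0("rec", r)]] <- gs
  }
  list(pred = pred, gt = gt)
}

test_that("segment_icc_table: identical traces give ICC 1 across recordings", {
  b <- mk_batch(n_rec = 5, noise = 0)
  rep <- segment_icc_table(b$gt, b$gt)
  expect_true(all(rep$per_segment$icc_mean == 1))
  expect_true(all(rep$per_segment$n == 5))
})

test_that("higher noise gives lower mean ICC", {
  lo <- mk_batch(n_rec = 4, noise = 0.2, seed = 5)
  hi <- mk_batch(n_rec = 4, noise = 1.0, seed = 5)
  r_lo <- segment_icc_table(lo$pred, lo$gt)
  r_hi <- segment_icc_table(hi$pred, hi$gt)
  expect_true(all(r_hi$per_segment$icc_mean < r_lo$per_segment$icc_mean))
})

test_that("low-sROM filter drops exactly the under-threshold segments", {
  b <- mk_batch(n_rec = 3, noise = 0.1, seed = 6)
  # C6-C7 amp 5 > 4; shrink its gt sROM below 4 in every recording
  for (r in names(b$gt)) {
    tr <- b$gt[[r]][["C6-C7"]]
    tr$srom_deg <- 3.5
    b$gt[[r]][["C6-C7"]] <- tr
  }
  rep <- segment_icc_table(b$pred, b$gt, filters = "low_srom")
  expect_false("C6-C7" %in% rep$per_segment$segment)
  expect_equal(nrow(rep$dropped), 3L)
  expect_true(all(rep$dropped$reason == "low_srom"))
})

test_that("low-quality filter uses recording and segment flags", {
  b <- mk_batch(n_rec = 3, noise = 0.1, seed = 7)
  quality <- list(
    rec1 = list(quality_flag = "low", segment_quality = NULL),
    rec2 = list(quality_flag = "normal",
                segment_quality = c("C4-C5" = "low")),
    rec3 = list(quality_flag = "normal", segment_quality = NULL))
  rep <- segment_icc_table(b$pred, b$gt, filters = "low_quality",
                           quality = quality)
  # rec1 contributes nothing; rec2 loses C4-C5
  expect_equal(sum(rep$per_recording$recording == "rec1"), 0L)
  expect_equal(rep$per_segment$n[rep$per_segment$segment == "C4-C5"], 1L)
  expect_equal(rep$per_segment$n[rep$per_segment$segment == "C5-C6"], 2L)
})

test_that("unmatched keys error with the offending names", {
  b <- mk_batch(n_rec = 2)
  expect_error(segment_icc_table(b$pred[1], b$gt),
               class = "spinetrack_unmatched_keys")
})

test_that("metric_icc_correlation signs and degeneracy", {
  set.seed(77)
  n_rec <- 6
  b <- mk_batch(n_rec = n_rec, noise = 0.01, seed = 8)
  pred <- list(); gt <- b$gt
  metrics <- list()
  # per-recording noise drives both metric degradation and ICC loss
  noises <- seq(0.05, 1.2, length.out = n_rec)
  for (r in seq_len(n_rec)) {
    nb <- mk_batch(n_rec = 1, noise = noises[r], seed = 100 + r)
    pred[[paste0("rec", r)]] <- nb$pred[[1]]
    gt[[paste0("rec", r)]] <- nb$gt[[1]]
    # synthetic per-frame metric values: DSC decreasing in noise
    dscs <- pmin(1, pmax(0, 0.97 - 0.3 * noises[r] +
                              rnorm(20, sd = 0.01)))
    ious <- dscs / (2 - dscs)
    metrics[[paste0("rec", r)]] <- list(list(
      per_frame = data.frame(frame = 1:20, dsc = dscs, iou = ious,
                             hd95 = 2 + 10 * noises[r] + abs(rnorm(20)))))
  }
  rep <- segment_icc_table(pred, gt)
  tab <- metric_icc_correlation(rep, metrics)
  expect_equal(nrow(tab), 9L)
  r_dsc_mean <- tab$r[tab$metric == "dsc" & tab$statistic == "mean"]
  expect_gt(r_dsc_mean, 0)
  r_hd95_mean <- tab$r[tab$metric == "hd95" & tab$statistic == "mean"]
  expect_lt(r_hd95_mean, 0)
  expect_true(all(abs(tab$r) <= 1))

  # identical metrics across recordings -> NA correlations with warnings
  # (one per metric-statistic pair)
  same <- lapply(metrics, function(m) metrics[[1]])
  warns <- testthat::capture_warnings(tab2 <- metric_icc_correlation(rep, same))
  expect_true(length(warns) >= 9)
  expect_true(all(is.na(tab2$r[tab2$metric == "dsc"])))

  expect_error(metric_icc_correlation(rep, metrics[1:2]),
               class = "spinetrack_insufficient_data")
})
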