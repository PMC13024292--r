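# Reliability statistics: agreement between predicted and reference
# segmental rotation traces.
#
# The agreement measure is ICC(3,1): the single-rater intraclass
# correlation from a two-way mixed-effects model under the *consistency*
# definition, which scores similarity of the rotational patterns rather
# than absolute agreement -- a constant offset between raters does not
# lower it. Values above 0.6 are conventionally acceptable, above 0.8
# excellent.

#' ICC(3,1): two-way mixed-effects, consistency, single rater
#'
#' For an n x 2 table (frames x raters) the two-way ANOVA decomposition
#' gives row (target) and residual mean squares, and
#' `ICC = (MS_R - MS_E) / (MS_R + (k - 1) MS_E)` with k = 2 raters. The 95%
#' confidence interval is the standard F-based interval.
#'
#' @param x,y paired numeric series (the two raters); frames missing in
#'   either are dropped.
#' @param conf confidence level of the interval.
#' @return An object of class `icc_result` with `icc`, `ci_low`, `ci_high`,
#'   `n_frames`, acceptability flags (`acceptable` > 0.6, `excellent` >
#'   0.8) and the model tag.
#' @export
icc_3_1 <- function(x, y, conf = 0.95) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3)
    st_stop("ICC needs at least 3 complete pairs (got %d)",
            "insufficient_data", n)
  k <- 2
  tab <- cbind(x, y)
  grand <- mean(tab)
  rowm <- rowMeans(tab)
  colm <- colMeans(tab)
  ss_rows <- k * sum((rowm - grand)^2)
  # residuals computed directly (not by subtracting sums of squares, which
  # loses all precision when the raters agree up to an offset)
  resid <- sweep(sweep(tab, 1, rowm), 2, colm) + grand
  ss_err <- sum(resid^2)
  ms_r <- ss_rows / (n - 1)
  ms_e <- ss_err / ((n - 1) * (k - 1))
  scale <- mean(abs(tab - grand)) + .Machine$double.eps
  if (ms_r <= (1e-12 * scale)^2) {
    st_warn("zero between-frame variance: ICC undefined", "degenerate_icc")
    icc <- NA_real_
    ci <- c(NA_real_, NA_real_)
  } else if (ms_e <= (1e-12 * scale)^2) {
    icc <- 1
    ci <- c(1, 1)
  } else {
    icc <- (ms_r - ms_e) / (ms_r + (k - 1) * ms_e)
    alpha <- 1 - conf
    f <- ms_r / ms_e
    df1 <- n - 1
    df2 <- (n - 1) * (k - 1)
    fl <- f / qf(1 - alpha / 2, df1, df2)
    fu <- f * qf(1 - alpha / 2, df2, df1)
    ci <- c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
  }
  structure(list(icc = icc, ci_low = ci[1], ci_high = ci[2],
                 n_frames = n,
                 acceptable = if (is.na(icc)) NA else icc > 0.6,
                 excellent = if (is.na(icc)) NA else icc > 0.8,
                 model = "ICC(3,1) consistency"),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("<icc_result> %s: %.3f (95%% CI %.3f-%.3f), n = %d\n",
              x$model, x$icc, x$ci_low, x$ci_high, x$n_frames))
  invisible(x)
}

# series used for agreement: smoothed per-frame relative rotation, or its
# cumulative version
icc_series <- function(trace, cumulative = FALSE) {
  sm <- trace$dtheta_rel_smoothed_deg
  if (!cumulative) return(sm)
  cum <- cumsum(fill_na_linear(sm))
  cum[is.na(sm)] <- NA_real_
  cum
}

#' Per-segment ICC table across recordings
#'
#' For every matched (recording, segment) pair, computes the ICC(3,1)
#' between the predicted and reference smoothed relative-rotation series,
#' then summarises each segment as mean and (min-max) range across
#' recordings. Sensitivity filters drop (recording, segment) pairs before
#' summarising:
#' * `"low_srom"`: reference sROM strictly below `srom_threshold` degrees;
#' * `"low_quality"`: the recording (or that segment, via
#'   `meta$segment_quality`) is flagged `"low"` in `quality`.
#'
#' @param pred,gt named lists (one element per recording) of named lists of
#'   [segment_trace()] (one per segment); keys must match.
#' @param filters character subset of `c("low_srom", "low_quality")`.
#' @param quality optional named list (per recording) with elements
#'   `quality_flag` and `segment_quality` (as in [recording_meta()]).
#' @param srom_threshold threshold for the low-sROM filter, degrees.
#' @param cumulative compare cumulative instead of per-frame series.
#' @param conf confidence level for the per-recording intervals.
#' @return An object of class `reliability_report`: `per_recording` (data
#'   frame recording/segment/icc/ci/n), `per_segment` (summary data frame),
#'   `filters_applied`, `dropped`.
#' @export
segment_icc_table <- function(pred, gt, filters = character(),
                              quality = NULL, srom_threshold = 4,
                              cumulative = FALSE, conf = 0.95) {
  bad <- union(setdiff(names(pred), names(gt)), setdiff(names(gt), names(pred)))
  if (length(bad))
    st_stop("recordings not matched between pred and gt: %s",
            "unmatched_keys", paste(bad, collapse = ", "))
  if (length(filters))
    filters <- match.arg(filters, c("low_srom", "low_quality"),
                         several.ok = TRUE)
  rows <- list()
  dropped <- list()
  for (rec in names(pred)) {
    psegs <- pred[[rec]]; gsegs <- gt[[rec]]
    names(psegs) <- vapply(psegs, `[[`, "", "segment")
    names(gsegs) <- vapply(gsegs, `[[`, "", "segment")
    badseg <- union(setdiff(names(psegs), names(gsegs)),
                    setdiff(names(gsegs), names(psegs)))
    if (length(badseg))
      st_stop("segments not matched in recording %s: %s",
              "unmatched_keys", rec, paste(badseg, collapse = ", "))
    for (seg in names(psegs)) {
      drop_reason <- NULL
      if ("low_srom" %in% filters) {
        srom <- gsegs[[seg]]$srom_deg
        if (is.na(srom)) srom <- segmental_rom(gsegs[[seg]])
        if (srom < srom_threshold) drop_reason <- "low_srom"
      }
      if (is.null(drop_reason) && "low_quality" %in% filters &&
          !is.null(quality) && rec %in% names(quality)) {
        q <- quality[[rec]]
        seg_q <- q$segment_quality
        if (identical(q$quality_flag, "low") ||
            (!is.null(seg_q) && identical(unname(seg_q[seg]), "low")))
          drop_reason <- "low_quality"
      }
      if (!is.null(drop_reason)) {
        dropped[[length(dropped) + 1L]] <-
          data.frame(recording = rec, segment = seg, reason = drop_reason)
        next
      }
      r <- icc_3_1(icc_series(psegs[[seg]], cumulative),
                   icc_series(gsegs[[seg]], cumulative), conf = conf)
      rows[[length(rows) + 1L]] <-
        data.frame(recording = rec, segment = seg, icc = r$icc,
                   ci_low = r$ci_low, ci_high = r$ci_high,
                   n_frames = r$n_frames)
    }
  }
  per_rec <- if (length(rows)) do.call(rbind, rows)
             else data.frame(recording = character(), segment = character(),
                             icc = numeric(), ci_low = numeric(),
                             ci_high = numeric(), n_frames = integer())
  per_seg <- do.call(rbind, lapply(split(per_rec, per_rec$segment),
    function(d) data.frame(segment = d$segment[1],
                           icc_mean = mean(d$icc, na.rm = TRUE),
                           icc_min = suppressWarnings(min(d$icc, na.rm = TRUE)),
                           icc_max = suppressWarnings(max(d$icc, na.rm = TRUE)),
                           n = sum(!is.na(d$icc)), row.names = NULL)))
  if (!is.null(per_seg) && nrow(per_seg))
    per_seg <- per_seg[order(vapply(per_seg$segment, seg_level, 0)), ]
  structure(list(per_recording = per_rec, per_segment = per_seg,
                 filters_applied = filters,
                 dropped = if (length(dropped)) do.call(rbind, dropped)
                           else data.frame(recording = character(),
                                           segment = character(),
                                           reason = character())),
            class = "reliability_report")
}

#' @export
print.reliability_report <- function(x, ...) {
  cat(sprintf("<reliability_report> filters: %s; %d (recording, segment) pairs, %d dropped\n",
              if (length(x$filters_applied))
                paste(x$filters_applied, collapse = "+") else "none",
              nrow(x$per_recording), nrow(x$dropped)))
  if (!is.null(x$per_segment) && nrow(x$per_segment)) {
    for (i in seq_len(nrow(x$per_segment)))
      cat(sprintf("  %s: %.3f (%.3f-%.3f), n = %d\n",
                  x$per_segment$segment[i], x$per_segment$icc_mean[i],
                  x$per_segment$icc_min[i], x$per_segment$icc_max[i],
                  x$per_segment$n[i]))
  }
  invisible(x)
}

#' Correlation of segmentation metrics with per-recording ICC
#'
#' Pearson correlation of the per-recording mean ICC with the mean, median
#' and SD of each segmentation metric (DSC, IoU, HD95) pooled over that
#' recording's vertebrae and frames. Two-sided p-values are reported but
#' never used for filtering.
#'
#' @param report a [segment_icc_table()] result.
#' @param metrics named list (per recording) of [evaluate_sequence()]
#'   results.
#' @return data frame with columns metric, statistic, r, p, n.
#' @export
metric_icc_correlation <- function(report, metrics) {
  icc_by_rec <- tapply(report$per_recording$icc,
                       report$per_recording$recording,
                       mean, na.rm = TRUE)
  recs <- intersect(names(icc_by_rec), names(metrics))
  if (length(recs) < 3)
    st_stop("need at least 3 recordings with both ICC and metrics (got %d)",
            "insufficient_data", length(recs))
  pooled <- function(rec, metric)
    unlist(lapply(metrics[[rec]], function(r) r$per_frame[[metric]]))
  out <- list()
  for (metric in c("dsc", "iou", "hd95")) {
    stats_tab <- vapply(recs, function(rec) {
      v <- pooled(rec, metric)
      c(mean = mean(v), median = median(v), sd = sd(v))
    }, c(mean = 0, median = 0, sd = 0))
    for (statn in c("mean", "median", "sd")) {
      xs <- stats_tab[statn, ]
      ys <- as.numeric(icc_by_rec[recs])
      if (sd(xs) == 0 || sd(ys) == 0) {
        st_warn("constant column for %s %s: correlation undefined",
                "degenerate_correlation", metric, statn)
        r <- NA_real_; p <- NA_real_
      } else {
        ct <- cor.test(xs, ys)
        r <- unname(ct$estimate); p <- ct$p.value
      }
      out[[length(out) + 1L]] <-
        data.frame(metric = metric, statistic = statn, r = r, p = p,
                   n = length(recs))
    }
  }
  do.call(rbind, out)
}
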