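# Segmentation evaluation: Dice similarity coefficient, intersection over
# union (Jaccard), and the symmetric 95th-percentile Hausdorff distance
# between mask boundaries, plus per-vertebra aggregation across the frames
# of a recording.
#
# Acceptability thresholds used by the flags: DSC >= 0.8 (stricter than the
# usual 0.7, to protect downstream rotation accuracy), IoU >= 0.7, and
# HD95 < 16 mm (about one vertebral body diameter).

as_binary <- function(m) {
  b <- m != 0
  storage.mode(b) <- "integer"
  b
}

check_pair <- function(a, b) {
  if (!all(dim(a) == dim(b)))
    st_stop("masks have different dimensions", "dimension_error")
}

#' Dice similarity coefficient
#'
#' `2 |A intersect B| / (|A| + |B|)` over the nonzero pixels of two masks.
#'
#' @param a,b binary masks (any nonzero pixel counts as foreground).
#' @return value in \[0, 1\]; `NA` with a warning if both masks are empty.
#' @export
dsc <- function(a, b) {
  check_pair(a, b)
  na <- sum(a != 0); nb <- sum(b != 0)
  if (na + nb == 0) {
    st_warn("both masks empty: DSC undefined", "empty_mask")
    return(NA_real_)
  }
  2 * sum(a != 0 & b != 0) / (na + nb)
}

#' Intersection over union (Jaccard index)
#'
#' `|A intersect B| / |A union B|`.
#'
#' @inheritParams dsc
#' @return value in \[0, 1\]; `NA` with a warning if both masks are empty.
#' @export
iou <- function(a, b) {
  check_pair(a, b)
  un <- sum(a != 0 | b != 0)
  if (un == 0) {
    st_warn("both masks empty: IoU undefined", "empty_mask")
    return(NA_real_)
  }
  sum(a != 0 & b != 0) / un
}

# 8-connected outer boundary: mask pixels with a 4-neighbour outside.
boundary_mask <- function(m) cpp_boundary(as_binary(m))

# linear-interpolation percentile of a sorted-or-not vector (quantile type 7)
pctl <- function(x, p) as.numeric(quantile(x, p, type = 7, names = FALSE))

#' 95th-percentile Hausdorff distance between mask boundaries
#'
#' Symmetric robust Hausdorff distance: the larger of the two directed 95th
#' percentiles of Euclidean distances from each boundary pixel of one mask
#' to the nearest boundary pixel of the other. Distances are computed with
#' an exact Euclidean distance transform; the percentile uses linear
#' interpolation between order statistics.
#'
#' @inheritParams dsc
#' @param spacing optional pixel spacing in mm/px; when given the result is
#'   in mm, otherwise in pixels.
#' @return nonnegative distance; `NA` with a warning if either mask is empty.
#' @export
hd95 <- function(a, b, spacing = NULL) {
  check_pair(a, b)
  if (sum(a != 0) == 0 || sum(b != 0) == 0) {
    st_warn("empty mask: HD95 undefined", "empty_mask")
    return(NA_real_)
  }
  ba <- boundary_mask(a); bb <- boundary_mask(b)
  dt_a <- cpp_edt(ba); dt_b <- cpp_edt(bb)
  d_ab <- dt_b[ba == 1L]   # boundary of A -> nearest boundary pixel of B
  d_ba <- dt_a[bb == 1L]
  out <- max(pctl(d_ab, 0.95), pctl(d_ba, 0.95))
  if (!is.null(spacing)) out * spacing else out
}

new_seg_metrics_result <- function(vertebra, per_frame, excluded, unit) {
  mean_sd <- function(x) c(mean = mean(x), sd = if (length(x) > 1) sd(x) else 0)
  ms <- list(dsc = mean_sd(per_frame$dsc), iou = mean_sd(per_frame$iou),
             hd95 = mean_sd(per_frame$hd95))
  flags <- c(dsc_ok = unname(ms$dsc["mean"] >= 0.8),
             iou_ok = unname(ms$iou["mean"] >= 0.7),
             hd95_ok = if (unit == "mm") unname(ms$hd95["mean"] < 16) else NA)
  structure(list(vertebra = vertebra, per_frame = per_frame,
                 mean_sd = ms, flags = flags,
                 excluded_frames = excluded, hd95_unit = unit),
            class = "seg_metrics_result")
}

#' @export
print.seg_metrics_result <- function(x, ...) {
  cat(sprintf(
    "<seg_metrics_result> %s over %d frames (%d excluded): DSC %.3f+-%.3f, IoU %.3f+-%.3f, HD95 %.2f+-%.2f %s\n",
    x$vertebra, nrow(x$per_frame), length(x$excluded_frames),
    x$mean_sd$dsc["mean"], x$mean_sd$dsc["sd"],
    x$mean_sd$iou["mean"], x$mean_sd$iou["sd"],
    x$mean_sd$hd95["mean"], x$mean_sd$hd95["sd"], x$hd95_unit))
  invisible(x)
}

#' Evaluate a predicted mask sequence against ground truth
#'
#' Computes per-frame DSC, IoU and HD95 for every vertebra label and
#' aggregates mean and SD across frames. Frames in which either mask is
#' empty for a vertebra are excluded from the aggregation and listed in the
#' result. HD95 is reported in mm when the prediction's metadata carries a
#' pixel spacing, otherwise in px (and the `hd95_ok` flag is `NA`).
#'
#' @param pred,gt [label_mask_sequence()] objects with equal frame counts,
#'   dimensions and a shared label map.
#' @param spacing optional mm/px override of `pred$meta$pixel_spacing_mm`.
#' @return list of `seg_metrics_result`, one per vertebra name.
#' @export
evaluate_sequence <- function(pred, gt, spacing = NULL) {
  if (n_frames(pred) != n_frames(gt))
    st_stop("pred and gt have different frame counts", "consistency_error")
  if (!all(dim(pred$frames[[1]]) == dim(gt$frames[[1]])))
    st_stop("pred and gt have different dimensions", "dimension_error")
  if (is.null(spacing)) spacing <- pred$meta$pixel_spacing_mm
  unit <- if (is.null(spacing)) "px" else "mm"
  vertebrae <- union(pred$label_map, gt$label_map)
  out <- list()
  for (v in vertebrae) {
    if (!(v %in% pred$label_map) || !(v %in% gt$label_map)) {
      st_warn("vertebra %s present in only one of pred/gt; skipped",
              "label_mismatch", v)
      next
    }
    lp <- label_of(pred, v); lg <- label_of(gt, v)
    res <- data.frame(frame = integer(), dsc = numeric(), iou = numeric(),
                      hd95 = numeric())
    excluded <- integer()
    for (f in seq_len(n_frames(pred))) {
      a <- pred$frames[[f]] == lp
      b <- gt$frames[[f]] == lg
      if (!any(a) || !any(b)) {
        excluded <- c(excluded, f)
        next
      }
      storage.mode(a) <- "integer"; storage.mode(b) <- "integer"
      i_cnt <- sum(a == 1L & b == 1L)
      na <- sum(a); nb <- sum(b)
      res <- rbind(res, data.frame(
        frame = f,
        dsc = 2 * i_cnt / (na + nb),
        iou = i_cnt / (na + nb - i_cnt),
        hd95 = hd95(a, b, spacing)))
    }
    if (nrow(res) == 0) {
      st_warn("vertebra %s empty in every frame pair; skipped",
              "label_mismatch", v)
      next
    }
    out[[v]] <- new_seg_metrics_result(v, res, excluded, unit)
  }
  out
}

#' Per-vertebra metric table (mean +- SD)
#'
#' Formats a list of `seg_metrics_result` as a data frame with one row per
#' vertebra, mirroring the usual reporting layout of per-structure
#' segmentation studies.
#'
#' @param results list returned by [evaluate_sequence()].
#' @return data frame with columns vertebra, dsc, iou, hd95 and their SDs,
#'   n_frames, hd95_unit.
#' @export
metrics_table <- function(results) {
  do.call(rbind, lapply(results, function(r) data.frame(
    vertebra = r$vertebra,
    dsc_mean = unname(r$mean_sd$dsc["mean"]), dsc_sd = unname(r$mean_sd$dsc["sd"]),
    iou_mean = unname(r$mean_sd$iou["mean"]), iou_sd = unname(r$mean_sd$iou["sd"]),
    hd95_mean = unname(r$mean_sd$hd95["mean"]), hd95_sd = unname(r$mean_sd$hd95["sd"]),
    hd95_unit = r$hd95_unit,
    n_frames = nrow(r$per_frame), n_excluded = length(r$excluded_frames),
    dsc_ok = unname(r$flags["dsc_ok"]), iou_ok = unname(r$flags["iou_ok"]),
    hd95_ok = unname(r$flags["hd95_ok"]),
    row.names = NULL)))
}
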