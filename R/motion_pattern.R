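# Motion-pattern analysis: segmental range of motion, the cumulative
# C4-C7 rotation axis, per-segment motion-pattern curves, and the sequence
# of segmental contribution (SSC) -- the order in which motion segments
# reach their maximum contribution during the extension movement.

required_c4c7 <- c("C4-C5", "C5-C6", "C6-C7")

#' Segmental range of motion
#'
#' The angular excursion of one motion segment: max minus min of the
#' cumulative smoothed relative-rotation series. Missing frames are
#' linearly interpolated for the cumulation.
#'
#' @param trace a [segment_trace()].
#' @return sROM in degrees (nonnegative).
#' @export
segmental_rom <- function(trace) {
  sm <- trace$dtheta_rel_smoothed_deg
  if (sum(!is.na(sm)) < 2)
    st_stop("segment %s has fewer than 2 non-missing frames",
            "insufficient_data", trace$segment)
  srom_of(sm)
}

#' Filter out segments with low range of motion
#'
#' Segments whose sROM is strictly below `threshold_deg` (default 4
#' degrees) are excluded; a segment at exactly the threshold is retained.
#' Small excursions put the true frame-to-frame motion on the order of the
#' segmentation noise, which makes derived rotations unreliable -- hence
#' the sensitivity filter.
#'
#' @param traces list of [segment_trace()].
#' @param threshold_deg exclusion threshold in degrees.
#' @return list with `retained` and `excluded` (both lists of traces) and
#'   `reasons` (data frame of segment, srom_deg, retained).
#' @export
low_srom_filter <- function(traces, threshold_deg = 4) {
  if (length(traces) == 0)
    return(list(retained = list(), excluded = list(),
                reasons = data.frame(segment = character(),
                                     srom_deg = numeric(),
                                     retained = logical())))
  sroms <- vapply(traces, function(tr) {
    if (is.na(tr$srom_deg)) segmental_rom(tr) else tr$srom_deg
  }, 0)
  keep <- sroms >= threshold_deg
  list(retained = traces[keep], excluded = traces[!keep],
       reasons = data.frame(
         segment = vapply(traces, `[[`, "", "segment"),
         srom_deg = sroms, retained = keep, row.names = NULL))
}

#' Build a motion pattern from segment traces
#'
#' The x-axis is the cumulative smoothed rotation of C4 to C7 (sum of the
#' C4-C5, C5-C6 and C6-C7 smoothed relative rotations, cumulated within the
#' analyzed frame interval and zeroed at its first frame). Each segment's
#' curve plots its smoothed per-frame rotation against that axis. The SSC
#' orders the segments by the x-position at which each reaches its maximum
#' contribution (the extremum in the direction of motion); segments peaking
#' within one frame of each other are ordered cranial-first and flagged as
#' ties.
#'
#' @param traces list of [segment_trace()]; must include C4-C5, C5-C6 and
#'   C6-C7 (other segments are carried along for plotting).
#' @param extension_phase integer frame interval `c(first, last)` to
#'   analyze; default the full recording.
#' @return An object of class `motion_pattern`.
#' @export
build_pattern <- function(traces, extension_phase = NULL) {
  segs <- vapply(traces, `[[`, "", "segment")
  names(traces) <- segs
  missing <- setdiff(required_c4c7, segs)
  if (length(missing))
    st_stop("missing required segment(s): %s", "missing_segment",
            paste(missing, collapse = ", "))
  nf <- length(traces[[1]]$dtheta_rel_deg)
  for (tr in traces)
    if (length(tr$dtheta_rel_deg) != nf)
      st_stop("segment traces have mixed frame counts", "consistency_error")
  if (is.null(extension_phase)) extension_phase <- c(1L, nf)
  a <- extension_phase[1]; b <- extension_phase[2]
  if (a >= b || a < 1 || b > nf)
    st_stop("invalid extension phase [%s, %s] for %d frames",
            "config_error", a, b, nf)
  frames <- a:b
  sm <- lapply(traces, function(tr)
    fill_na_linear(tr$dtheta_rel_smoothed_deg)[frames])
  csum <- sm[["C4-C5"]] + sm[["C5-C6"]] + sm[["C6-C7"]]
  cum <- cumsum(csum)
  cum <- cum - cum[1]                      # zero at the first analyzed frame
  direction <- sign(cum[length(cum)] - cum[1])
  if (direction == 0) direction <- 1
  peak_frame <- vapply(sm, function(y)
    if (direction > 0) which.max(y) else which.min(y), 1L)
  peak_x <- cum[peak_frame]
  ord <- order(peak_x, vapply(names(sm), seg_level, 0))
  ties <- character()
  px <- peak_frame[ord]
  for (i in seq_len(length(ord) - 1))
    if (abs(px[i + 1] - px[i]) <= 1)
      ties <- c(ties, names(sm)[ord[i]], names(sm)[ord[i + 1]])
  structure(list(segments = traces,
                 frames = frames,
                 cumulative_c4c7_deg = cum,
                 curves = lapply(sm, function(y)
                   data.frame(x = cum, y = y)),
                 ssc = names(sm)[ord],
                 ssc_peak_x = peak_x[ord],
                 ssc_ties = unique(ties),
                 extension_phase = c(a, b)),
            class = "motion_pattern")
}

# anatomical level of a segment name ("C4-C5" -> 4); used for tie-breaks
seg_level <- function(segment) as.numeric(sub("^C(\\d+).*", "\\1", segment))

#' @export
print.motion_pattern <- function(x, ...) {
  cat(sprintf("<motion_pattern> frames %d-%d, cumulative C4-C7 excursion %.2f deg\n",
              x$extension_phase[1], x$extension_phase[2],
              max(x$cumulative_c4c7_deg) - min(x$cumulative_c4c7_deg)))
  cat("  SSC:", paste(x$ssc, collapse = " -> "), "\n")
  if (length(x$ssc_ties))
    cat("  ties:", paste(x$ssc_ties, collapse = ", "), "\n")
  invisible(x)
}

#' Plot-ready motion-pattern table (and optional figure)
#'
#' @param p a [build_pattern()] result.
#' @param plot_file optional PNG path; when given and the device is
#'   available, the motion-pattern curves are rendered there.
#' @return long-format data frame (segment, frame, x, y).
#' @export
pattern_plot_data <- function(p, plot_file = NULL) {
  tab <- do.call(rbind, lapply(names(p$curves), function(s)
    data.frame(segment = s, frame = p$frames,
               x = p$curves[[s]]$x, y = p$curves[[s]]$y,
               row.names = NULL)))
  if (!is.null(plot_file) && isTRUE(capabilities("png"))) {
    grDevices::png(plot_file, width = 900, height = 600)
    on.exit(grDevices::dev.off())
    cols <- seq_along(p$curves)
    xr <- range(tab$x); yr <- range(tab$y)
    plot(NA, xlim = xr, ylim = yr,
         xlab = "cumulative C4-C7 rotation (deg)",
         ylab = "segmental rotation per frame (deg)",
         main = "Motion pattern")
    for (i in seq_along(p$curves))
      lines(p$curves[[i]]$x, p$curves[[i]]$y, col = cols[i], lwd = 2)
    legend("topright", legend = names(p$curves), col = cols, lwd = 2)
  }
  tab
}
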