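#' Recording metadata
#'
#' Acquisition metadata for one dynamic X-ray recording. The defaults match
#' the common clinical acquisition for cervical flexion--extension studies:
#' 1024 x 1024 px at 15 frames per second.
#'
#' @param recording_id character scalar identifying the recording.
#' @param frame_rate_hz frames per second (> 0); default 15.
#' @param pixel_spacing_mm physical pixel size in mm/px, or `NULL` if
#'   unknown. When `NULL`, HD95 values derived from this recording are
#'   reported in pixels and flagged as such.
#' @param width_px,height_px image dimensions in pixels.
#' @param quality_flag `"normal"` or `"low"`: visual acquisition-quality
#'   rating of the whole recording.
#' @param segment_quality optional named character vector mapping motion
#'   segment names (e.g. `"C4-C5"`) to `"normal"`/`"low"`.
#' @return An object of class `recording_meta`.
#' @export
recording_meta <- function(recording_id = "rec", frame_rate_hz = 15,
                           pixel_spacing_mm = NULL,
                           width_px = 1024L, height_px = 1024L,
                           quality_flag = c("normal", "low"),
                           segment_quality = NULL) {
  quality_flag <- match.arg(quality_flag)
  if (!is.numeric(frame_rate_hz) || length(frame_rate_hz) != 1 ||
      frame_rate_hz <= 0)
    st_stop("frame_rate_hz must be a positive number", "meta_error")
  if (!is.null(pixel_spacing_mm) &&
      (!is.numeric(pixel_spacing_mm) || pixel_spacing_mm <= 0))
    st_stop("pixel_spacing_mm must be positive or NULL", "meta_error")
  if (width_px <= 0 || height_px <= 0)
    st_stop("image dimensions must be positive", "meta_error")
  if (!is.null(segment_quality)) {
    if (is.null(names(segment_quality)) ||
        !all(segment_quality %in% c("normal", "low")))
      st_stop("segment_quality must be a named vector of 'normal'/'low'",
              "meta_error")
  }
  structure(
    list(recording_id = as.character(recording_id),
         frame_rate_hz = as.numeric(frame_rate_hz),
         pixel_spacing_mm = if (is.null(pixel_spacing_mm)) NULL
                            else as.numeric(pixel_spacing_mm),
         width_px = as.integer(width_px), height_px = as.integer(height_px),
         quality_flag = quality_flag, segment_quality = segment_quality),
    class = "recording_meta")
}

#' @export
print.recording_meta <- function(x, ...) {
  cat(sprintf("<recording_meta> %s: %dx%d px @ %g fps, spacing %s, quality %s\n",
              x$recording_id, x$width_px, x$height_px, x$frame_rate_hz,
              if (is.null(x$pixel_spacing_mm)) "unknown"
              else sprintf("%g mm/px", x$pixel_spacing_mm),
              x$quality_flag))
  invisible(x)
}

# default label map: integer label i -> "C<i-1>" (1 = C0 ... 8 = C7)
default_label_map <- function(labels) {
  labels <- sort(unique(as.integer(labels)))
  setNames(paste0("C", labels - 1L), labels)
}

#' Label-mask sequence
#'
#' The pipeline's main input: one integer label image per frame (0 =
#' background) plus a map from integer label to vertebra name (`"C0"` ...
#' `"C7"`), in acquisition order.
#'
#' @param frames list of integer matrices, all the same size.
#' @param label_map named character vector mapping integer labels (names) to
#'   vertebra names; defaults to label `i` -> `C(i-1)` for the labels present.
#' @param meta a [recording_meta()]; dimensions default from the frames.
#' @return An object of class `label_mask_sequence`.
#' @export
label_mask_sequence <- function(frames, label_map = NULL, meta = NULL) {
  if (!is.list(frames) || length(frames) == 0)
    st_stop("frames must be a non-empty list of integer matrices",
            "format_error")
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    st_stop("all frames must share identical dimensions", "dimension_error")
  frames <- lapply(frames, function(f) {
    if (!is.numeric(f)) st_stop("frames must be numeric", "format_error")
    if (!is.integer(f)) {
      if (any(f != round(f))) st_stop("non-integer pixel data", "format_error")
      storage.mode(f) <- "integer"
    }
    f
  })
  present <- sort(unique(unlist(lapply(frames, function(f)
    unique(f[f != 0L])))))
  if (is.null(label_map)) {
    label_map <- default_label_map(if (length(present)) present else 1L)
  } else {
    label_map <- setNames(as.character(label_map), names(label_map))
    missing <- setdiff(present, as.integer(names(label_map)))
    if (length(missing))
      st_stop("labels present but not in label_map: %s",
              "format_error", paste(missing, collapse = ", "))
  }
  if (is.null(meta))
    meta <- recording_meta(width_px = dims[2, 1], height_px = dims[1, 1])
  structure(list(meta = meta, frames = frames, label_map = label_map),
            class = "label_mask_sequence")
}

#' @export
print.label_mask_sequence <- function(x, ...) {
  cat(sprintf("<label_mask_sequence> %d frames of %dx%d px; vertebrae: %s\n",
              length(x$frames), nrow(x$frames[[1]]), ncol(x$frames[[1]]),
              paste(x$label_map, collapse = " ")))
  invisible(x)
}

n_frames <- function(seq) length(seq$frames)

# integer label for a vertebra name
label_of <- function(seq, vertebra) {
  idx <- which(seq$label_map == vertebra)
  if (length(idx) != 1)
    st_stop("vertebra '%s' not in label map", "label_error", vertebra)
  as.integer(names(seq$label_map)[idx])
}

# binary mask of one vertebra in one frame
mask_of <- function(seq, vertebra, frame) {
  lab <- label_of(seq, vertebra)
  m <- seq$frames[[frame]] == lab
  storage.mode(m) <- "integer"
  m
}

# centroid (x = col, y = row) of a binary mask; NULL if empty
mask_centroid <- function(mask) {
  idx <- which(mask != 0)
  if (length(idx) == 0) return(NULL)
  h <- nrow(mask)
  c(x = mean(((idx - 1) %/% h) + 1), y = mean(((idx - 1) %% h) + 1))
}

#' Per-frame rotation trace of one vertebra
#'
#' Holds the absolute fitted angle `theta_deg` per frame, the frame-to-frame
#' delta `dtheta_deg` (zero at the first frame by convention), the overlap of
#' the accepted template fit, and bookkeeping for frames where the vertebra
#' was absent.
#'
#' @param vertebra vertebra name.
#' @param theta_deg,dtheta_deg numeric vectors (NA at missing frames).
#' @param fit_overlap per-frame overlap of the accepted fit.
#' @param missing_frames integer indices (1-based) of frames with no mask.
#' @param low_confidence integer indices of frames whose best overlap fell
#'   below the confidence floor.
#' @return An object of class `rotation_trace`.
#' @export
rotation_trace <- function(vertebra, theta_deg, dtheta_deg, fit_overlap,
                           missing_frames = integer(),
                           low_confidence = integer()) {
  stopifnot(length(theta_deg) == length(dtheta_deg),
            length(theta_deg) == length(fit_overlap))
  ok <- !is.na(dtheta_deg)
  if (any(abs(dtheta_deg[ok]) > 90 + 1e-9))
    st_stop("frame-to-frame rotation exceeds the 90 degree window",
            "trace_error")
  structure(list(vertebra = vertebra, theta_deg = as.numeric(theta_deg),
                 dtheta_deg = as.numeric(dtheta_deg),
                 fit_overlap = as.numeric(fit_overlap),
                 missing_frames = as.integer(missing_frames),
                 low_confidence = as.integer(low_confidence)),
            class = "rotation_trace")
}

#' @export
print.rotation_trace <- function(x, ...) {
  cat(sprintf("<rotation_trace> %s: %d frames, %d missing, theta range [%.2f, %.2f] deg\n",
              x$vertebra, length(x$theta_deg), length(x$missing_frames),
              suppressWarnings(min(x$theta_deg, na.rm = TRUE)),
              suppressWarnings(max(x$theta_deg, na.rm = TRUE))))
  invisible(x)
}

#' Segmental (inter-vertebral) rotation trace
#'
#' Relative rotation between an adjacent vertebra pair: per-frame
#' `dtheta_rel_deg` (difference of the two vertebrae's per-frame deltas), its
#' Gaussian-smoothed version, and the segmental range of motion `srom_deg`
#' (max minus min of the cumulative smoothed series).
#'
#' Usually constructed via [relative_rotation()].
#'
#' @param upper,lower vertebra names (cranial, caudal).
#' @param dtheta_rel_deg per-frame relative rotation in degrees.
#' @param dtheta_rel_smoothed_deg Gaussian-smoothed series.
#' @param sigma smoothing width in frames.
#' @param srom_deg segmental range of motion in degrees.
#' @param missing_frames frame indices missing in either parent trace.
#' @return An object of class `segment_trace`.
#' @export
segment_trace <- function(upper, lower, dtheta_rel_deg,
                          dtheta_rel_smoothed_deg, sigma = 3,
                          srom_deg = NA_real_, missing_frames = integer()) {
  stopifnot(length(dtheta_rel_deg) == length(dtheta_rel_smoothed_deg))
  if (!is.na(srom_deg) && srom_deg < 0)
    st_stop("srom_deg must be nonnegative", "trace_error")
  structure(list(upper = upper, lower = lower, segment = paste0(upper, "-", lower),
                 dtheta_rel_deg = as.numeric(dtheta_rel_deg),
                 dtheta_rel_smoothed_deg = as.numeric(dtheta_rel_smoothed_deg),
                 sigma = sigma, srom_deg = srom_deg,
                 missing_frames = as.integer(missing_frames)),
            class = "segment_trace")
}

#' @export
print.segment_trace <- function(x, ...) {
  cat(sprintf("<segment_trace> %s: %d frames, sROM %.2f deg (sigma %g)\n",
              x$segment, length(x$dtheta_rel_deg), x$srom_deg, x$sigma))
  invisible(x)
}
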