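# Recording-level I/O: mask stacks (multi-page TIFF or a directory of PNG
# frames), a plain-text metadata sidecar, and long-format trace tables.

sidecar_path <- function(path) {
  if (dir.exists(path)) file.path(path, "recording.meta")
  else paste0(file_path_sans_ext(path), ".meta")
}

write_sidecar <- function(meta, label_map, path) {
  lines <- c(
    paste0("recording_id: ", meta$recording_id),
    paste0("frame_rate_hz: ", format(meta$frame_rate_hz, digits = 15)),
    if (!is.null(meta$pixel_spacing_mm))
      paste0("pixel_spacing_mm: ", format(meta$pixel_spacing_mm, digits = 15)),
    paste0("width_px: ", meta$width_px),
    paste0("height_px: ", meta$height_px),
    paste0("quality_flag: ", meta$quality_flag),
    if (!is.null(meta$segment_quality))
      paste0("segment_quality: ",
             paste(names(meta$segment_quality), meta$segment_quality,
                   sep = "=", collapse = ",")),
    paste0("label_map: ",
           paste(names(label_map), label_map, sep = "=", collapse = ","))
  )
  writeLines(lines, path)
}

read_sidecar <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  kv <- regmatches(lines, regexec("^([^:]+):\\s*(.*)$", lines))
  vals <- setNames(vapply(kv, `[`, "", 3), trimws(vapply(kv, `[`, "", 2)))
  parse_map <- function(s) {
    parts <- strsplit(strsplit(s, ",")[[1]], "=")
    setNames(vapply(parts, `[`, "", 2), vapply(parts, `[`, "", 1))
  }
  meta <- recording_meta(
    recording_id = if (!is.na(vals["recording_id"])) vals[["recording_id"]] else "rec",
    frame_rate_hz = if (!is.na(vals["frame_rate_hz"]))
      as.numeric(vals[["frame_rate_hz"]]) else 15,
    pixel_spacing_mm = if (!is.na(vals["pixel_spacing_mm"]))
      as.numeric(vals[["pixel_spacing_mm"]]) else NULL,
    width_px = if (!is.na(vals["width_px"])) as.integer(vals[["width_px"]]) else 1L,
    height_px = if (!is.na(vals["height_px"])) as.integer(vals[["height_px"]]) else 1L,
    quality_flag = if (!is.na(vals["quality_flag"])) vals[["quality_flag"]] else "normal",
    segment_quality = if (!is.na(vals["segment_quality"]))
      parse_map(vals[["segment_quality"]]) else NULL
  )
  label_map <- if (!is.na(vals["label_map"])) parse_map(vals[["label_map"]]) else NULL
  list(meta = meta, label_map = label_map)
}

#' Read a label-mask stack from disk
#'
#' Accepts either a multi-page TIFF stack (the canonical format written by
#' [write_mask_sequence()]) or a directory of lexicographically ordered PNG
#' files, one frame per file. A plain-text metadata sidecar
#' (`<stem>.meta` next to the TIFF, or `recording.meta` inside the
#' directory) is read when present.
#'
#' @param path path to a `.tif`/`.tiff` stack or a directory of `.png` files.
#' @param label_map optional named character vector (integer label ->
#'   vertebra name); overrides the sidecar and the `C(i-1)` default.
#' @return A [label_mask_sequence()].
#' @export
read_mask_sequence <- function(path, label_map = NULL) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
    if (length(files) == 0)
      st_stop("no PNG frames found in %s", "format_error", path)
    frames <- lapply(files, read_png_gray)
  } else if (file.exists(path)) {
    frames <- read_tiff_stack(path)
  } else {
    st_stop("path does not exist: %s", "io_error", path)
  }
  if (length(frames) < 2)
    st_stop("a recording needs at least 2 frames (got %d)",
            "insufficient_data", length(frames))
  meta <- NULL
  sc <- sidecar_path(path)
  if (file.exists(sc)) {
    info <- read_sidecar(sc)
    meta <- info$meta
    meta$width_px <- ncol(frames[[1]])
    meta$height_px <- nrow(frames[[1]])
    if (is.null(label_map)) label_map <- info$label_map
  }
  label_mask_sequence(frames, label_map = label_map, meta = meta)
}

#' Write a label-mask stack to disk
#'
#' Writes the canonical lossless representation: a multi-page 16-bit
#' unsigned TIFF stack when `path` ends in `.tif`/`.tiff`, otherwise a
#' directory of numbered 16-bit PNG frames. The recording metadata and label
#' map go to a plain-text sidecar so that [read_mask_sequence()] inverts the
#' write bit-exactly.
#'
#' @param seq a [label_mask_sequence()].
#' @param path output stack path or directory.
#' @return `path`, invisibly.
#' @export
write_mask_sequence <- function(seq, path) {
  if (!inherits(seq, "label_mask_sequence"))
    st_stop("seq must be a label_mask_sequence", "format_error")
  ext <- tolower(file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    write_tiff_stack(seq$frames, path, bits = 16L)
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    for (i in seq_along(seq$frames))
      write_png_gray(seq$frames[[i]],
                     file.path(path, sprintf("frame_%05d.png", i)),
                     bits = 16L)
  }
  write_sidecar(seq$meta, seq$label_map, sidecar_path(path))
  invisible(path)
}

#' Write rotation/segment traces as a long-format TSV table
#'
#' One row per frame per trace, with empty cells (not zeros) for missing
#' frames. Rotation traces fill the `theta_deg`/`dtheta_deg`/`fit_overlap`
#' columns, segment traces the `dtheta_rel_deg`/`dtheta_rel_smoothed_deg`
#' columns.
#'
#' @param traces list of [rotation_trace()] and/or [segment_trace()] objects
#'   sharing one frame count.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trace_table <- function(traces, path) {
  cols <- c("frame", "name", "kind", "theta_deg", "dtheta_deg", "fit_overlap",
            "dtheta_rel_deg", "dtheta_rel_smoothed_deg")
  rows <- lapply(traces, function(tr) {
    if (inherits(tr, "rotation_trace")) {
      nf <- length(tr$theta_deg)
      data.frame(frame = seq_len(nf), name = tr$vertebra, kind = "vertebra",
                 theta_deg = tr$theta_deg, dtheta_deg = tr$dtheta_deg,
                 fit_overlap = tr$fit_overlap,
                 dtheta_rel_deg = NA_real_,
                 dtheta_rel_smoothed_deg = NA_real_)
    } else if (inherits(tr, "segment_trace")) {
      nf <- length(tr$dtheta_rel_deg)
      data.frame(frame = seq_len(nf), name = tr$segment, kind = "segment",
                 theta_deg = NA_real_, dtheta_deg = NA_real_,
                 fit_overlap = NA_real_,
                 dtheta_rel_deg = tr$dtheta_rel_deg,
                 dtheta_rel_smoothed_deg = tr$dtheta_rel_smoothed_deg)
    } else {
      st_stop("traces must be rotation_trace or segment_trace objects",
              "format_error")
    }
  })
  if (length(rows)) {
    nfs <- vapply(rows, nrow, 1L)
    if (length(unique(nfs)) > 1)
      st_stop("traces have mixed frame counts: %s", "consistency_error",
              paste(unique(nfs), collapse = ", "))
    tab <- do.call(rbind, rows)
  } else {
    tab <- as.data.frame(setNames(rep(list(logical(0)), length(cols)), cols))
  }
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

# Inverse of write_trace_table (CLI plumbing).
read_trace_table <- function(path) {
  tab <- read.delim(path, sep = "\t", na.strings = "",
                    stringsAsFactors = FALSE)
  out <- list()
  for (nm in unique(tab$name)) {
    sub <- tab[tab$name == nm, ]
    sub <- sub[order(sub$frame), ]
    if (sub$kind[1] == "vertebra") {
      out[[nm]] <- rotation_trace(nm, sub$theta_deg, sub$dtheta_deg,
                                  sub$fit_overlap,
                                  missing_frames = sub$frame[is.na(sub$theta_deg)])
    } else {
      parts <- strsplit(nm, "-")[[1]]
      sm <- sub$dtheta_rel_smoothed_deg
      srom <- if (all(is.na(sm))) NA_real_ else {
        cum <- cumsum(ifelse(is.na(sm), 0, sm))
        max(cum) - min(cum)
      }
      out[[nm]] <- segment_trace(parts[1], parts[2], sub$dtheta_rel_deg,
                                 sm, srom_deg = srom,
                                 missing_frames = sub$frame[is.na(sub$dtheta_rel_deg)])
    }
  }
  out
}
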