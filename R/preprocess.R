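# Contrast preprocessing of grayscale frame stacks.
#
# Dynamic radiographs often contain large background areas (air, collimator
# borders) whose pixels would dominate a plain histogram equalization, so
# equalization is computed from, and applied to, a patient mask only.
# Recordings whose collimators defeat threshold-based masking are instead
# histogram-matched to a caller-chosen reference frame.

#' Grayscale frame sequence
#'
#' @param frames list of integer matrices, all the same size.
#' @param meta a [recording_meta()]; defaults from the frame dimensions.
#' @param range_max top of the stated intensity range (255 for 8-bit data,
#'   65535 for 16-bit); defaults to 255 unless a pixel exceeds it.
#' @return An object of class `grayscale_sequence`.
#' @export
grayscale_sequence <- function(frames, meta = NULL, range_max = NULL) {
  if (!is.list(frames) || length(frames) == 0)
    st_stop("frames must be a non-empty list", "format_error")
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    st_stop("all frames must share identical dimensions", "dimension_error")
  frames <- lapply(frames, function(f) { storage.mode(f) <- "integer"; f })
  if (is.null(range_max)) {
    mx <- max(vapply(frames, max, 1L))
    range_max <- if (mx <= 255L) 255L else 65535L
  }
  if (is.null(meta))
    meta <- recording_meta(width_px = dims[2, 1], height_px = dims[1, 1])
  structure(list(meta = meta, frames = frames,
                 range_max = as.integer(range_max)),
            class = "grayscale_sequence")
}

#' Otsu threshold of an intensity image
#'
#' Classic between-class-variance maximisation on a binned histogram.
#' Returns the threshold value; pixels strictly above it are foreground.
#'
#' @param x numeric vector or matrix of intensities.
#' @param nbins number of histogram bins (256 covers 8-bit data exactly).
#' @return threshold on the intensity scale of `x`.
#' @export
otsu_threshold <- function(x, nbins = 256L) {
  v <- as.numeric(x)
  lo <- min(v); hi <- max(v)
  if (hi == lo) return(lo)
  bin <- pmin(nbins, floor((v - lo) / (hi - lo) * nbins) + 1L)
  h <- tabulate(bin, nbins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mids <- lo + (seq_len(nbins) - 0.5) / nbins * (hi - lo)
  mu <- cumsum(p * mids)
  mu_t <- mu[nbins]
  denom <- omega * (1 - omega)
  sigma_b <- ifelse(denom > 0, (mu_t * omega - mu)^2 / denom, 0)
  k <- which.max(sigma_b)
  lo + k / nbins * (hi - lo)
}

fill_holes <- function(mask) {
  # background components not touching the image border are holes
  inv <- 1L - mask
  lab <- cpp_label_components(inv, 4L)
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  hole <- inv == 1L & !(lab %in% setdiff(border, 0L))
  out <- mask
  out[hole] <- 1L
  out
}

#' Patient mask of a radiograph frame
#'
#' Binary mask isolating the patient region: threshold (Otsu by default, or
#' a fixed value), keep the largest connected foreground component, fill its
#' holes. Air background and black collimator borders fall below the
#' threshold and are excluded.
#'
#' @param frame integer matrix of intensities.
#' @param threshold `"otsu"` or a fixed numeric threshold; pixels strictly
#'   above the threshold are foreground.
#' @return integer 0/1 matrix of the same size. An all-background frame
#'   yields a zero mask with a warning.
#' @export
patient_mask <- function(frame, threshold = "otsu") {
  if (length(frame) == 0) st_stop("frame is empty", "format_error")
  if (max(frame) == min(frame)) {
    if (max(frame) == 0) {
      st_warn("all-background frame: returning an empty patient mask",
              "empty_mask")
      return(matrix(0L, nrow(frame), ncol(frame)))
    }
    return(matrix(1L, nrow(frame), ncol(frame)))  # uniform: nothing to exclude
  }
  thr <- if (identical(threshold, "otsu")) otsu_threshold(frame)
         else as.numeric(threshold)
  fg <- frame > thr
  storage.mode(fg) <- "integer"
  if (!any(fg == 1L)) {
    st_warn("threshold removed every pixel: returning an empty patient mask",
            "empty_mask")
    return(fg)
  }
  lab <- cpp_label_components(fg, 8L)
  counts <- tabulate(lab[lab > 0L])
  keep <- which.max(counts)
  out <- matrix(0L, nrow(frame), ncol(frame))
  out[lab == keep] <- 1L
  fill_holes(out)
}

# cumulative histogram of values within a mask, on nbins bins over [0, range_max]
masked_cdf <- function(values, range_max, nbins) {
  bin <- pmin(nbins, floor(values / (range_max + 1) * nbins) + 1L)
  h <- tabulate(bin, nbins)
  cumsum(h) / sum(h)
}

hist_nbins <- function(range_max) if (range_max <= 255L) 256L else 1024L

#' Histogram equalization restricted to a mask
#'
#' The intensity CDF is computed from pixels inside the mask only and the
#' equalizing map `v -> round(cdf(v) * range_max)` is applied to those
#' pixels only; pixels outside the mask are returned bit-identical.
#'
#' @param frame integer matrix of intensities.
#' @param mask 0/1 matrix of the same size.
#' @param range_max top of the intensity range (default 255 unless a pixel
#'   exceeds it).
#' @return equalized frame, same dimensions and range.
#' @export
equalize_within_mask <- function(frame, mask, range_max = NULL) {
  if (!all(dim(frame) == dim(mask)))
    st_stop("mask and frame dimensions differ", "dimension_error")
  if (is.null(range_max))
    range_max <- if (max(frame) <= 255L) 255L else 65535L
  inside <- mask != 0
  if (!any(inside)) {
    st_warn("empty mask: frame returned unchanged", "empty_mask")
    return(frame)
  }
  nbins <- hist_nbins(range_max)
  cdf <- masked_cdf(as.numeric(frame[inside]), range_max, nbins)
  bin <- pmin(nbins, floor(as.numeric(frame[inside]) / (range_max + 1) * nbins) + 1L)
  out <- frame
  out[inside] <- as.integer(round(cdf[bin] * range_max))
  out
}

# Monotone lookup mapping the CDF of `values` onto the reference CDF.
# Returns a length-nbins table: input bin -> output intensity.
matching_lut <- function(cdf_in, cdf_ref, range_max, nbins) {
  # smallest reference level whose CDF reaches the input mass
  ref_levels <- (seq_len(nbins) - 0.5) / nbins * (range_max + 1)
  idx <- findInterval(cdf_in, cdf_ref, left.open = TRUE) + 1L
  idx <- pmin(idx, nbins)
  pmin(range_max, pmax(0, round(ref_levels[idx])))
}

#' Histogram matching to a reference frame
#'
#' Maps each frame's intensity CDF onto the CDF of `reference` via the usual
#' monotone quantile lookup. Used instead of masked equalization when
#' collimators defeat threshold-based patient masking.
#'
#' @param x a [grayscale_sequence()] or a single integer matrix.
#' @param reference integer matrix; must not be constant.
#' @return object of the same kind as `x` with matched intensities.
#' @export
match_to_reference <- function(x, reference) {
  if (length(reference) == 0 || max(reference) == min(reference))
    st_stop("reference image is constant; histogram matching is degenerate",
            "degenerate_reference")
  single <- is.matrix(x)
  frames <- if (single) list(x) else x$frames
  range_max <- if (single) {
    if (max(x, reference) <= 255L) 255L else 65535L
  } else x$range_max
  nbins <- hist_nbins(range_max)
  cdf_ref <- masked_cdf(as.numeric(reference), range_max, nbins)
  out <- lapply(frames, function(f) {
    cdf_in <- masked_cdf(as.numeric(f), range_max, nbins)
    lut <- matching_lut(cdf_in, cdf_ref, range_max, nbins)
    bin <- pmin(nbins, floor(as.numeric(f) / (range_max + 1) * nbins) + 1L)
    matrix(as.integer(lut[bin]), nrow(f), ncol(f))
  })
  if (single) out[[1]]
  else grayscale_sequence(out, meta = x$meta, range_max = range_max)
}

#' Masked histogram equalization of a whole sequence
#'
#' Convenience wrapper applying [patient_mask()] + [equalize_within_mask()]
#' to every frame, either with a per-frame mapping (default) or one global
#' mapping pooled over all frames.
#'
#' @param seq a [grayscale_sequence()].
#' @param threshold passed to [patient_mask()].
#' @param global if `TRUE`, one equalizing map is computed from all frames'
#'   masked pixels and applied to every frame.
#' @return an equalized [grayscale_sequence()].
#' @export
equalize_sequence <- function(seq, threshold = "otsu", global = FALSE) {
  masks <- lapply(seq$frames, patient_mask, threshold = threshold)
  if (!global) {
    out <- Map(function(f, m) equalize_within_mask(f, m, seq$range_max),
               seq$frames, masks)
  } else {
    nbins <- hist_nbins(seq$range_max)
    vals <- unlist(Map(function(f, m) as.numeric(f[m != 0]),
                       seq$frames, masks))
    if (length(vals) == 0) {
      st_warn("all patient masks empty: sequence returned unchanged",
              "empty_mask")
      return(seq)
    }
    cdf <- masked_cdf(vals, seq$range_max, nbins)
    out <- Map(function(f, m) {
      inside <- m != 0
      if (!any(inside)) return(f)
      bin <- pmin(nbins,
                  floor(as.numeric(f[inside]) / (seq$range_max + 1) * nbins) + 1L)
      f[inside] <- as.integer(round(cdf[bin] * seq$range_max))
      f
    }, seq$frames, masks)
  }
  grayscale_sequence(out, meta = seq$meta, range_max = seq$range_max)
}
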