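# Per-frame vertebral rotation by rigid template fitting.
#
# The mean shape of a vertebra is translated to the centroid of the
# per-frame mask and rotated to maximise overlap. The admissible angles are
# restricted to a +-90 degree window around the previous frame's accepted
# angle, which prevents the half-turn flips that near-symmetric vertebral
# bodies would otherwise allow. The maximisation is a coarse grid scan
# followed by golden-section refinement; the rasterization of a rotated
# template is bilinear sampling thresholded at 0.5, so the whole procedure
# is deterministic.

#' Fit configuration for rotation tracking
#'
#' @param angle_window_deg half-width of the admissible angle window around
#'   the previous frame's angle (default 90).
#' @param coarse_step_deg step of the coarse grid scan in degrees.
#' @param refine_tol_deg termination tolerance of the golden-section
#'   refinement.
#' @param overlap_criterion `"dice"` (default) or `"intersection"` (the
#'   fraction of template pixels covered by the mask).
#' @param sigma_frames Gaussian smoothing width for rotation series, in
#'   frames.
#' @param overlap_floor fits whose overlap falls below this value are
#'   flagged low-confidence.
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(angle_window_deg = 90, coarse_step_deg = 1,
                       refine_tol_deg = 0.01,
                       overlap_criterion = c("dice", "intersection"),
                       sigma_frames = 3, overlap_floor = 0.5) {
  overlap_criterion <- match.arg(overlap_criterion)
  if (coarse_step_deg <= 0 || coarse_step_deg > angle_window_deg)
    st_stop("need 0 < coarse_step_deg <= angle_window_deg", "config_error")
  if (refine_tol_deg <= 0) st_stop("refine_tol_deg must be > 0", "config_error")
  structure(list(angle_window_deg = angle_window_deg,
                 coarse_step_deg = coarse_step_deg,
                 refine_tol_deg = refine_tol_deg,
                 overlap_criterion = overlap_criterion,
                 sigma_frames = sigma_frames,
                 overlap_floor = overlap_floor),
            class = "fit_config")
}

crit_code <- function(cfg) if (cfg$overlap_criterion == "intersection") 1L else 0L

# template foreground pixel offsets from the centroid, columns (x, y)
template_points <- function(template, centroid) {
  idx <- which(template != 0)
  h <- nrow(template)
  cbind(((idx - 1) %/% h) + 1 - centroid[1], ((idx - 1) %% h) + 1 - centroid[2])
}

#' Fit the rotation of a mean shape to one mask
#'
#' Places the template centroid at the mask centroid and searches the angle
#' maximising the overlap between the rotated template and the mask, within
#' `prev_angle_deg` +- `cfg$angle_window_deg`. A coarse grid scan (fast
#' nearest-pixel surrogate of the objective) locates the basin;
#' golden-section refinement of a smooth partial-volume overlap polishes it
#' to `cfg$refine_tol_deg`. The returned `overlap` is the Dice (or
#' intersection fraction) of the rasterized rotated template
#' (bilinear sampling, 0.5 threshold) against the mask.
#'
#' @param template a [build_mean_shape()] result (or [as_mean_shape()]).
#' @param mask binary mask of the vertebra in one frame.
#' @param prev_angle_deg centre of the admissible angle window.
#' @param cfg a [fit_config()].
#' @return list with `angle_deg`, `overlap`, `low_confidence`, `missing`.
#' @export
fit_angle <- function(template, mask, prev_angle_deg = 0, cfg = fit_config()) {
  mask <- as_binary(mask)
  mc <- mask_centroid(mask)
  if (is.null(mc))
    return(list(angle_deg = NA_real_, overlap = NA_real_,
                low_confidence = FALSE, missing = TRUE))
  mask_count <- sum(mask)
  crit <- crit_code(cfg)
  tm <- template$template_num
  tc <- template$centroid
  pts <- template$fg_pts
  w <- cfg$angle_window_deg
  coarse <- seq(prev_angle_deg - w, prev_angle_deg + w,
                by = cfg$coarse_step_deg)
  sc <- vapply(coarse, function(a)
    cpp_overlap_nn(pts, mask, mc[1], mc[2], a, mask_count, crit), 0)
  # the surrogate can plateau on crisp shapes: take the tied maximisers,
  # centre the pick on the one nearest the previous angle, and bracket the
  # whole plateau for refinement
  tied <- which(sc >= max(sc) - 1e-12)
  a0 <- coarse[tied[which.min(abs(coarse[tied] - prev_angle_deg))]]
  plateau <- range(coarse[tied])
  # refinement objective: soft (partial-volume) Dice -- same optimum
  # location as the rasterized Dice but smooth in the angle, so the
  # golden-section search is not limited by pixel-flip quantization
  f <- function(a) cpp_overlap_soft(tm, tc[1], tc[2], mask, mc[1], mc[2],
                                    a, mask_count, crit)
  lo <- max(prev_angle_deg - w, plateau[1] - cfg$coarse_step_deg)
  hi <- min(prev_angle_deg + w, plateau[2] + cfg$coarse_step_deg)
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  c1 <- b - gr * (b - a); d1 <- a + gr * (b - a)
  fc <- f(c1); fd <- f(d1)
  while (b - a > cfg$refine_tol_deg) {
    if (fc >= fd) {
      b <- d1; d1 <- c1; fd <- fc
      c1 <- b - gr * (b - a); fc <- f(c1)
    } else {
      a <- c1; c1 <- d1; fc <- fd
      d1 <- a + gr * (b - a); fd <- f(d1)
    }
  }
  best_a <- (a + b) / 2
  # guard: the refined point must not be worse than the coarse optimum
  if (f(a0) > f(best_a)) best_a <- a0
  # reported overlap: Dice of the rasterized (bilinear + 0.5 threshold)
  # rotated template against the mask
  best_f <- cpp_overlap_bilinear(tm, tc[1], tc[2], mask, mc[1], mc[2],
                                 best_a, mask_count, crit)
  list(angle_deg = best_a, overlap = best_f,
       low_confidence = best_f < cfg$overlap_floor, missing = FALSE)
}

#' Track a vertebra's rotation across a recording
#'
#' Fits [fit_angle()] frame by frame: frame 1 is fitted around angle 0, each
#' later frame around the previous accepted angle, so no frame-to-frame jump
#' can exceed the window. Frames in which the vertebra is absent are
#' recorded as missing; the last accepted angle carries over as the window
#' centre for the next fitted frame. The per-frame delta `dtheta_deg` is the
#' difference of consecutive fitted angles, zero by convention at the first
#' frame, and `NA` just after a gap.
#'
#' @param seq a [label_mask_sequence()].
#' @param template a mean shape of one vertebra in `seq`.
#' @param cfg a [fit_config()].
#' @return A [rotation_trace()].
#' @export
track_vertebra <- function(seq, template, cfg = fit_config()) {
  nf <- n_frames(seq)
  vertebra <- template$vertebra
  lab <- label_of(seq, vertebra)
  theta <- rep(NA_real_, nf)
  overlap <- rep(NA_real_, nf)
  missing <- integer()
  lowc <- integer()
  prev <- 0
  for (t in seq_len(nf)) {
    m <- seq$frames[[t]] == lab
    storage.mode(m) <- "integer"
    fit <- fit_angle(template, m, prev_angle_deg = prev, cfg = cfg)
    if (fit$missing) {
      missing <- c(missing, t)
      next
    }
    theta[t] <- fit$angle_deg
    overlap[t] <- fit$overlap
    if (fit$low_confidence) lowc <- c(lowc, t)
    prev <- fit$angle_deg
  }
  if (all(is.na(theta)))
    st_stop("vertebra %s absent in every frame: no trace", "no_trace",
            vertebra)
  dtheta <- c(0, diff(theta))
  if (is.na(theta[1])) dtheta[1] <- NA_real_
  dtheta[which(is.na(theta))] <- NA_real_
  rotation_trace(vertebra, theta, dtheta, overlap,
                 missing_frames = missing, low_confidence = lowc)
}

#' Relative rotation between two vertebrae (one motion segment)
#'
#' Per-frame difference of the two vertebrae's rotation deltas; frames
#' missing in either trace are missing in the output. The smoothed series
#' (Gaussian, `sigma` frames) and the segmental range of motion (max minus
#' min of the cumulative smoothed series) are computed on construction.
#'
#' @param upper,lower [rotation_trace()] of the cranial and caudal vertebra.
#' @param sigma Gaussian smoothing width in frames (default 3).
#' @return A [segment_trace()].
#' @export
relative_rotation <- function(upper, lower, sigma = 3) {
  if (length(upper$dtheta_deg) != length(lower$dtheta_deg))
    st_stop("traces have different frame counts", "consistency_error")
  rel <- upper$dtheta_deg - lower$dtheta_deg
  miss <- which(is.na(rel))
  sm <- smooth_trace(rel, sigma)
  srom <- srom_of(sm)
  segment_trace(upper$vertebra, lower$vertebra, rel, sm, sigma = sigma,
                srom_deg = srom, missing_frames = miss)
}

fill_na_linear <- function(x) {
  ok <- which(!is.na(x))
  if (length(ok) == 0) st_stop("all values missing", "all_missing")
  if (length(ok) == length(x)) return(x)
  if (length(ok) == 1) return(rep(x[ok], length(x)))
  stats::approx(ok, x[ok], xout = seq_along(x), rule = 2)$y
}

# sROM of a (possibly NA-flagged) smoothed delta series
srom_of <- function(sm) {
  if (all(is.na(sm))) return(NA_real_)
  cum <- cumsum(fill_na_linear(sm))
  max(cum) - min(cum)
}

#' Gaussian smoothing of a rotation time series
#'
#' Discrete Gaussian convolution (kernel truncated at 4 sigma, normalised to
#' unit sum) with symmetric reflective boundary handling. Missing values are
#' linearly interpolated before filtering and re-flagged as missing after.
#'
#' @param series numeric vector (may contain `NA`).
#' @param sigma_frames kernel width in frames (> 0).
#' @return smoothed vector of the same length, `NA` where the input was.
#' @export
smooth_trace <- function(series, sigma_frames = 3) {
  if (sigma_frames <= 0) st_stop("sigma_frames must be > 0", "config_error")
  n <- length(series)
  if (n == 0) st_stop("empty series", "all_missing")
  was_na <- is.na(series)
  if (all(was_na)) st_stop("all values missing", "all_missing")
  x <- fill_na_linear(series)
  r <- ceiling(4 * sigma_frames)
  k <- exp(-((-r:r)^2) / (2 * sigma_frames^2))
  k <- k / sum(k)
  # symmetric (half-sample) reflection indices for 1-r .. n+r
  reflect <- function(i) {
    while (any(bad <- i < 1 | i > n)) {
      i[i < 1] <- 1 - i[i < 1]
      i[i > n] <- 2 * n + 1 - i[i > n]
    }
    i
  }
  xp <- x[reflect((1 - r):(n + r))]
  out <- vapply(seq_len(n), function(t) sum(k * xp[t:(t + 2 * r)]), 0)
  out[was_na] <- NA_real_
  out
}
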