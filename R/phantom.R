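# Synthetic articulated phantom recordings.
#
# An eight-vertebra chain (C0 skull base at the top, C7 at the bottom) of
# rounded rectangles is stacked along a mildly lordotic spine. During the
# recording the chain performs one fluent extension sweep: each motion
# segment's rotation follows a raised-cosine bump in sweep progress, with a
# configurable excursion (degrees) and peak position (fraction of the
# sweep), and the per-segment rotations sum to the global sweep. Vertebra
# poses follow by forward kinematics and are rasterized to integer labels.
# The analytic ground-truth angle trajectories are stored alongside, so
# every downstream stage can be validated against known kinematics.
# Optional degradations emulate what spoils real recordings: boundary
# jitter (segmentation noise), an occlusion band (shoulder overprojection)
# and whole-label dropout.

default_contributions <- function(global_sweep_deg = 40) {
  d <- data.frame(
    segment = c("C0-C1", "C1-C2", "C2-C3", "C3-C4", "C4-C5", "C5-C6", "C6-C7"),
    excursion_deg = c(2, 3, 5, 6, 10, 8, 6),
    peak = c(0.95, 0.90, 0.75, 0.65, 0.80, 0.50, 0.20))
  if (abs(sum(d$excursion_deg) - global_sweep_deg) > 1e-9)
    st_stop("default contributions sum to %g, not %g", "config_error",
            sum(d$excursion_deg), global_sweep_deg)
  d
}

#' Phantom recording configuration
#'
#' Defaults emulate a typical clinical acquisition: a 1024 x 1024 px,
#' 15 fps recording of a ~10 s extension sweep (150 frames) with a total
#' excursion of 40 degrees distributed over the seven motion segments
#' (C4-C5: 10, C5-C6: 8, C6-C7: 6 degrees peaking at 0.8/0.5/0.2 of the
#' sweep; the remaining 16 degrees spread over C0-C1 .. C3-C4, including a
#' deliberately low-motion C1-C2 segment of 3 degrees for exercising the
#' sROM filter).
#'
#' @param n_frames number of frames (default 150).
#' @param image_size `c(height, width)` in px.
#' @param global_sweep_deg total extension excursion; must equal the sum of
#'   the segment excursions.
#' @param segment_contributions data frame with columns `segment`,
#'   `excursion_deg`, `peak` (peak position in \[0, 1\] of the sweep).
#' @param bump_width half-width of the raised-cosine contribution bump in
#'   sweep-progress units; clamped per segment so its support stays inside
#'   the sweep (keeping the programmed excursion exact).
#' @param jitter_px boundary-noise amplitude in px.
#' @param occlusion optional `list(rows = c(top, bottom), dropout = p)`:
#'   fractions of image height delimiting an occlusion band, and the
#'   per-frame-per-label probability that label pixels inside it are
#'   deleted.
#' @param dropout_prob per-frame per-label probability of deleting the
#'   whole label.
#' @param seed integer seed; fixed seed implies bit-reproducible output.
#' @param frame_rate_hz,pixel_spacing_mm recording metadata.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(n_frames = 150L, image_size = c(1024L, 1024L),
                           global_sweep_deg = 40,
                           segment_contributions = NULL,
                           bump_width = 0.35,
                           jitter_px = 0, occlusion = NULL,
                           dropout_prob = 0, seed = 1L,
                           frame_rate_hz = 15, pixel_spacing_mm = 0.2) {
  if (is.null(segment_contributions))
    segment_contributions <- default_contributions(global_sweep_deg)
  sc <- segment_contributions
  if (!all(c("segment", "excursion_deg", "peak") %in% names(sc)))
    st_stop("segment_contributions needs segment/excursion_deg/peak columns",
            "config_error")
  if (abs(sum(sc$excursion_deg) - global_sweep_deg) > 1e-9)
    st_stop("segment excursions sum to %g but global_sweep_deg is %g",
            "config_error", sum(sc$excursion_deg), global_sweep_deg)
  if (any(sc$peak <= 0 | sc$peak >= 1))
    st_stop("peak positions must lie strictly inside (0, 1)", "config_error")
  if (n_frames < 2) st_stop("n_frames must be >= 2", "config_error")
  if (length(image_size) == 1) image_size <- rep(image_size, 2)
  structure(list(n_frames = as.integer(n_frames),
                 image_size = as.integer(image_size),
                 global_sweep_deg = global_sweep_deg,
                 segment_contributions = sc,
                 bump_width = bump_width,
                 jitter_px = jitter_px, occlusion = occlusion,
                 dropout_prob = dropout_prob, seed = as.integer(seed),
                 frame_rate_hz = frame_rate_hz,
                 pixel_spacing_mm = pixel_spacing_mm),
            class = "phantom_config")
}

# cumulative raised-cosine bump: 0 below z = -1, 1 above z = 1
rcos_cdf <- function(z) {
  out <- ifelse(z <= -1, 0, ifelse(z >= 1, 1, (z + 1) / 2 + sin(pi * z) / (2 * pi)))
  out
}

# per-level rounded-rectangle geometry, scaled to the image
phantom_geometry <- function(image_size) {
  s <- min(image_size)
  lev <- 0:7
  list(half_w = s * (0.045 + 0.003 * lev),
       half_h = s * (0.027 + 0.001 * lev),
       corner = 0.4 * s * (0.027 + 0.001 * lev),
       gap = 0.022 * s,
       base_x = 0.5 * image_size[2],
       base_y = 0.80 * image_size[1],
       base_angle = 2.0 * (3.5 - lev))    # mild static lordosis, cancels in deltas
}

# analytic truth: per-frame segment angles and per-vertebra absolute angles
phantom_truth <- function(config) {
  n <- config$n_frames
  sc <- config$segment_contributions
  tt <- (seq_len(n) - 1) / (n - 1)
  u <- 3 * tt^2 - 2 * tt^3                       # smooth sweep progress
  phi <- sapply(seq_len(nrow(sc)), function(i) {
    w <- min(config$bump_width, sc$peak[i], 1 - sc$peak[i])
    sc$excursion_deg[i] * rcos_cdf((u - sc$peak[i]) / w)
  })
  colnames(phi) <- sc$segment
  geom <- phantom_geometry(config$image_size)
  # vertebra i accumulates every segment below it (C7 is the fixed base)
  dyn <- matrix(0, n, 8)
  colnames(dyn) <- paste0("C", 0:7)
  for (i in 0:6) {
    below <- which(seg_level(sc$segment) >= i)   # segments Ci-Ci+1 .. C6-C7
    dyn[, i + 1] <- rowSums(phi[, below, drop = FALSE])
  }
  theta <- sweep(dyn, 2, -geom$base_angle)       # add static base angles
  list(u = u, phi = phi, theta = theta, geom = geom)
}

# rasterize one rounded rectangle into `frame`, label `lab`; errors if it
# would overlap an existing label
raster_rrect <- function(frame, cx, cy, angle_deg, hw, hh, r, lab) {
  H <- nrow(frame); W <- ncol(frame)
  rad <- sqrt(hw^2 + hh^2) + 1
  x0 <- max(1L, floor(cx - rad)); x1 <- min(W, ceiling(cx + rad))
  y0 <- max(1L, floor(cy - rad)); y1 <- min(H, ceiling(cy + rad))
  xs <- x0:x1; ys <- y0:y1
  px <- rep(xs, each = length(ys)) - cx
  py <- rep(ys, times = length(xs)) - cy
  a <- angle_deg * pi / 180
  lx <- cos(a) * px + sin(a) * py                # inverse rotation
  ly <- -sin(a) * px + cos(a) * py
  qx <- abs(lx) - (hw - r)
  qy <- abs(ly) - (hh - r)
  inside <- abs(lx) <= hw & abs(ly) <= hh &
    (qx <= 0 | qy <= 0 | (qx^2 + qy^2) <= r^2)
  sub <- frame[ys, xs, drop = FALSE]
  if (any(sub[inside] != 0L))
    st_stop("vertebra polygons overlap after kinematics: config infeasible",
            "generation_error")
  sub[inside] <- lab
  frame[ys, xs] <- sub
  frame
}

#' Generate a synthetic phantom recording
#'
#' Rasterizes the articulated chain at every frame and packages the label
#' stack together with the analytic ground-truth kinematics. Degradations
#' requested in the config (jitter, occlusion, dropout) are applied by
#' [degrade_phantom()] with the config's seed; the truth fields always
#' describe the clean kinematics.
#'
#' @param config a [phantom_config()].
#' @return An object of class `phantom_recording` with elements `masks`
#'   (a [label_mask_sequence()]), `truth_theta` (frames x vertebrae matrix
#'   of absolute angles), `truth_segment` (list per segment: `phi`,
#'   `dtheta_rel`, `srom_deg`, `peak`), and `config`.
#' @export
generate_phantom <- function(config = phantom_config()) {
  truth <- phantom_truth(config)
  n <- config$n_frames
  H <- config$image_size[1]; W <- config$image_size[2]
  geom <- truth$geom
  frames <- vector("list", n)
  for (t in seq_len(n)) {
    fr <- matrix(0L, H, W)
    # chain positions by forward kinematics, C7 anchored at the base
    cx <- geom$base_x; cy <- geom$base_y
    th <- truth$theta[t, ]
    pos <- matrix(0, 8, 2)
    pos[8, ] <- c(cx, cy)
    for (i in 7:1) {                     # place C6 ... C0 upwards
      pitch <- geom$half_h[i] + geom$half_h[i + 1] + geom$gap
      mid <- (th[i] + th[i + 1]) / 2 * pi / 180
      pos[i, 1] <- pos[i + 1, 1] + sin(mid) * pitch
      pos[i, 2] <- pos[i + 1, 2] - cos(mid) * pitch
    }
    for (i in 1:8)
      fr <- raster_rrect(fr, pos[i, 1], pos[i, 2], th[i],
                         geom$half_w[i], geom$half_h[i], geom$corner[i],
                         lab = i)
    frames[[t]] <- fr
  }
  meta <- recording_meta(recording_id = sprintf("phantom-seed%d", config$seed),
                         frame_rate_hz = config$frame_rate_hz,
                         pixel_spacing_mm = config$pixel_spacing_mm,
                         width_px = W, height_px = H)
  masks <- label_mask_sequence(frames,
                               label_map = setNames(paste0("C", 0:7), 1:8),
                               meta = meta)
  segs <- lapply(seq_len(ncol(truth$phi)), function(i) {
    phi <- truth$phi[, i]
    list(segment = colnames(truth$phi)[i], phi = phi,
         dtheta_rel = c(0, diff(phi)),
         srom_deg = max(phi) - min(phi),
         peak = config$segment_contributions$peak[i])
  })
  names(segs) <- colnames(truth$phi)
  rec <- structure(list(masks = masks, truth_theta = truth$theta,
                        truth_segment = segs, config = config,
                        degradations = list()),
                   class = "phantom_recording")
  if (config$jitter_px > 0 || !is.null(config$occlusion) ||
      config$dropout_prob > 0)
    rec <- degrade_phantom(rec, jitter_px = config$jitter_px,
                           occlusion = config$occlusion,
                           dropout_prob = config$dropout_prob,
                           seed = config$seed)
  rec
}

#' @export
print.phantom_recording <- function(x, ...) {
  cat(sprintf("<phantom_recording> %d frames %dx%d, sweep %g deg over %d segments, seed %d\n",
              x$config$n_frames, x$config$image_size[1], x$config$image_size[2],
              x$config$global_sweep_deg, nrow(x$config$segment_contributions),
              x$config$seed))
  if (length(x$degradations))
    cat("  degradations:", paste(names(x$degradations), collapse = ", "), "\n")
  invisible(x)
}

#' Degrade a phantom recording
#'
#' Applies boundary jitter (random erosion/dilation of each label within
#' `jitter_px` of its boundary), an occlusion band (probabilistic deletion
#' of label pixels inside a horizontal band, emulating shoulder
#' overprojection) and whole-label dropout -- without touching the
#' ground-truth fields. All randomness derives from `seed`.
#'
#' @param rec a [generate_phantom()] result (clean or already degraded).
#' @param jitter_px boundary-noise amplitude in px (0 = identity).
#' @param occlusion `list(rows = c(top, bottom), dropout = p)` with rows as
#'   fractions of image height, or `NULL`.
#' @param dropout_prob per-frame per-label whole-label deletion probability.
#' @param seed integer seed.
#' @return a `phantom_recording` with degraded masks.
#' @export
degrade_phantom <- function(rec, jitter_px = 0, occlusion = NULL,
                            dropout_prob = 0, seed = rec$config$seed) {
  frames <- rec$masks$frames
  H <- nrow(frames[[1]]); W <- ncol(frames[[1]])
  labs <- sort(as.integer(names(rec$masks$label_map)))
  with_seed(seed, {
    for (t in seq_along(frames)) {
      fr <- frames[[t]]
      for (lab in labs) {
        has <- any(fr == lab)
        if (!has) next
        if (dropout_prob > 0 && stats::runif(1) < dropout_prob) {
          fr[fr == lab] <- 0L
          next
        }
        if (jitter_px > 0) {
          m <- fr == lab
          rows <- range(which(rowSums(m) > 0))
          cols <- range(which(colSums(m) > 0))
          pad <- ceiling(jitter_px) + 1L
          r0 <- max(1L, rows[1] - pad); r1 <- min(H, rows[2] + pad)
          c0 <- max(1L, cols[1] - pad); c1 <- min(W, cols[2] + pad)
          sub <- m[r0:r1, c0:c1, drop = FALSE]
          storage.mode(sub) <- "integer"
          d <- cpp_edt(cpp_boundary(sub))
          band <- which(d <= jitter_px)
          frsub <- fr[r0:r1, c0:c1, drop = FALSE]
          free <- frsub == 0L | frsub == lab    # never clobber other labels
          flips <- stats::runif(length(band)) < 0.5
          grow <- band[flips]
          grow <- grow[free[grow]]
          shrink <- band[!flips]
          shrink <- shrink[frsub[shrink] == lab]
          frsub[shrink] <- 0L
          frsub[grow] <- lab
          fr[r0:r1, c0:c1] <- frsub
        }
        if (!is.null(occlusion)) {
          band_rows <- pmax(1L, pmin(H, round(occlusion$rows * H)))
          if (stats::runif(1) < occlusion$dropout) {
            sel <- matrix(FALSE, H, W)
            sel[band_rows[1]:band_rows[2], ] <- TRUE
            fr[sel & fr == lab] <- 0L
          }
        }
      }
      frames[[t]] <- fr
    }
  })
  rec$masks <- label_mask_sequence(frames, label_map = rec$masks$label_map,
                                   meta = rec$masks$meta)
  rec$degradations <- c(rec$degradations,
                        setNames(list(list(jitter_px = jitter_px,
                                           occlusion = occlusion,
                                           dropout_prob = dropout_prob,
                                           seed = seed)),
                                 sprintf("degrade_%d", length(rec$degradations) + 1L)))
  rec
}

#' Flat-shaded intensity rendering of a phantom recording
#'
#' Minimal grayscale rendering (background/bone levels plus Gaussian
#' noise) for exercising the preprocessing operators; not a physical X-ray
#' simulation.
#'
#' @param rec a `phantom_recording`.
#' @param bg,fg background and bone intensity levels (0-255).
#' @param noise_sd Gaussian noise SD in gray levels.
#' @param seed integer seed.
#' @return a [grayscale_sequence()].
#' @export
phantom_intensity <- function(rec, bg = 30, fg = 200, noise_sd = 5,
                              seed = rec$config$seed) {
  with_seed(seed, {
    frames <- lapply(rec$masks$frames, function(fr) {
      v <- ifelse(fr != 0L, fg, bg) +
        round(stats::rnorm(length(fr), 0, noise_sd))
      matrix(as.integer(pmax(0, pmin(255, v))), nrow(fr), ncol(fr))
    })
  })
  grayscale_sequence(frames, meta = rec$masks$meta, range_max = 255L)
}

# predicted-vs-truth segment traces of one phantom: tracks every vertebra
# C1..C7 present, builds segment traces, and pairs them with the analytic
# truth smoothed the same way. Used by tests and the pipeline examples.
phantom_segment_traces <- function(rec, cfg = fit_config(),
                                   vertebrae = paste0("C", 1:7),
                                   min_frames = 3L) {
  shapes <- lapply(vertebrae, function(v)
    build_mean_shape(rec$masks, v, cfg = cfg, min_frames = min_frames))
  names(shapes) <- vertebrae
  tracks <- lapply(shapes, function(s) track_vertebra(rec$masks, s, cfg))
  pred <- list()
  truth <- list()
  for (i in seq_len(length(vertebrae) - 1)) {
    up <- vertebrae[i]; lo <- vertebrae[i + 1]
    seg <- paste0(up, "-", lo)
    pred[[seg]] <- relative_rotation(tracks[[up]], tracks[[lo]],
                                     sigma = cfg$sigma_frames)
    ts <- rec$truth_segment[[seg]]
    sm <- smooth_trace(ts$dtheta_rel, cfg$sigma_frames)
    truth[[seg]] <- segment_trace(up, lo, ts$dtheta_rel, sm,
                                  sigma = cfg$sigma_frames,
                                  srom_deg = srom_of(sm))
  }
  list(shapes = shapes, tracks = tracks, pred = pred, truth = truth)
}
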