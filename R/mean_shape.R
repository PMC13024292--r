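# Per-recording rigid mean shape of a vertebra.
#
# Vertebrae are rigid, but frame-wise segmentations of them are not: noise,
# occlusion and model uncertainty perturb the outline from frame to frame.
# Averaging all frames of one recording into a single binary template
# enforces anatomical consistency; the template is what the rotation
# tracker fits. Construction alternates angle fitting and aligned
# averaging:
#   (i)   per-frame angles start at 0;
#   (ii)  each frame's mask is resampled into a common local window with its
#         centroid at the window centre, de-rotated by its current angle;
#   (iii) the aligned masks are averaged and thresholded at 0.5 (largest
#         connected component kept) to give a provisional template;
#   (iv)  each frame's angle is re-fitted to that template;
#   (v)   repeat (ii)-(iv) until the mean fit overlap changes by less than
#         `tol` or `max_iter` is reached.
# The skull base (C0) is excluded by default: its visibility is too
# inconsistent for a rigid template to be meaningful.

finish_mean_shape <- function(vertebra, tmpl, n_used, convergence, converged,
                              angles, soft = NULL) {
  tm <- tmpl
  storage.mode(tm) <- "double"
  # the real-valued aligned average (when available) is what fit_angle
  # samples: unlike the thresholded binary it has no coherent
  # re-rasterization jaggedness, which would bias fitted angles by several
  # tenths of a degree. The centroid is the mass centre of whichever field
  # is fitted, so rotation does not leak into translation.
  field <- if (is.null(soft)) tm else soft
  tot <- sum(field)
  h <- nrow(field)
  idx <- seq_along(field)
  cen <- c(x = sum((((idx - 1) %/% h) + 1) * field) / tot,
           y = sum((((idx - 1) %% h) + 1) * field) / tot)
  structure(list(vertebra = vertebra, template = tmpl,
                 template_num = field,
                 template_bin = tm,
                 centroid = c(cen["x"], cen["y"]),
                 reference_angle_deg = 0,
                 n_frames_used = n_used,
                 convergence = convergence, converged = converged,
                 frame_angles = angles,
                 fg_pts = template_points(tmpl, cen)),
            class = "mean_shape")
}

#' Wrap a binary mask as a mean shape
#'
#' Advanced constructor: treat a single binary mask as a rigid template (its
#' centroid becomes the local origin and its pose the zero-angle reference).
#' Mainly useful for testing the tracker against shapes of known pose.
#'
#' @param mask binary matrix (nonzero = foreground).
#' @param vertebra vertebra name to attach.
#' @return An object of class `mean_shape`.
#' @export
as_mean_shape <- function(mask, vertebra = "C4") {
  m <- as_binary(mask)
  if (!any(m == 1L)) st_stop("template mask is empty", "format_error")
  finish_mean_shape(vertebra, m, 1L, numeric(), TRUE, numeric())
}

#' @export
print.mean_shape <- function(x, ...) {
  cat(sprintf("<mean_shape> %s: %d px template from %d frames, %s after %d iteration(s)\n",
              x$vertebra, sum(x$template), x$n_frames_used,
              if (x$converged) "converged" else "NOT converged",
              length(x$convergence)))
  invisible(x)
}

#' Build the mean shape of a vertebra from a recording
#'
#' Iterative aligned averaging of all frames in which the vertebra is
#' present (see the package vignette for the procedure). Fails with an
#' `insufficient_frames` error when the vertebra is present in fewer than
#' `min_frames` frames, and returns the best iterate with a warning and
#' `converged = FALSE` when the alternation does not settle within
#' `max_iter` iterations -- mirroring the occasional recording on which mean
#' shape construction fails in practice.
#'
#' @param seq a [label_mask_sequence()].
#' @param vertebra vertebra name; `"C0"` is refused unless `allow_c0`.
#' @param cfg a [fit_config()] used for the per-frame angle refits.
#' @param min_frames minimum number of frames with a nonempty mask.
#' @param tol convergence tolerance on the change of mean fit overlap.
#' @param max_iter maximum number of fit/average alternations.
#' @param allow_c0 set `TRUE` to override the skull-base exclusion.
#' @return An object of class `mean_shape`.
#' @export
build_mean_shape <- function(seq, vertebra, cfg = fit_config(),
                             min_frames = 3L, tol = 1e-3, max_iter = 10L,
                             allow_c0 = FALSE) {
  if (identical(vertebra, "C0") && !allow_c0)
    st_stop(paste("C0 (skull base) is excluded from mean-shape construction;",
                  "use allow_c0 = TRUE to override"), "c0_excluded")
  lab <- label_of(seq, vertebra)
  crops <- list()
  cents <- list()
  for (t in seq_len(n_frames(seq))) {
    m <- seq$frames[[t]] == lab
    if (!any(m)) next
    storage.mode(m) <- "integer"
    # crop to the bounding box (+2 px) to keep resampling cheap
    rows <- range(which(rowSums(m) > 0))
    cols <- range(which(colSums(m) > 0))
    r0 <- max(1L, rows[1] - 2L); r1 <- min(nrow(m), rows[2] + 2L)
    c0 <- max(1L, cols[1] - 2L); c1 <- min(ncol(m), cols[2] + 2L)
    crop <- m[r0:r1, c0:c1, drop = FALSE]
    cen <- mask_centroid(crop)
    crops[[length(crops) + 1L]] <- crop
    cents[[length(cents) + 1L]] <- cen
  }
  n <- length(crops)
  if (n < min_frames)
    st_stop("vertebra %s present in only %d frame(s); %d required",
            "insufficient_frames", vertebra, n, min_frames)
  # common local window sized to the largest centroid-to-pixel radius
  rad <- 0
  for (i in seq_len(n)) {
    idx <- which(crops[[i]] != 0)
    h <- nrow(crops[[i]])
    dx <- ((idx - 1) %/% h) + 1 - cents[[i]]["x"]
    dy <- ((idx - 1) %% h) + 1 - cents[[i]]["y"]
    rad <- max(rad, sqrt(max(dx^2 + dy^2)))
  }
  W <- 2L * as.integer(ceiling(rad + 3)) + 1L
  oc <- (W + 1) / 2
  angles <- rep(0, n)
  convergence <- numeric()
  best <- NULL
  best_ov <- -Inf
  tmpl <- NULL
  for (it in seq_len(max_iter)) {
    acc <- matrix(0, W, W)
    for (i in seq_len(n))
      acc <- acc + cpp_sample_aligned(crops[[i]], cents[[i]]["x"],
                                      cents[[i]]["y"], angles[i],
                                      W, W, oc, oc)
    tmpl <- matrix(as.integer(acc / n >= 0.5), W, W)
    if (!any(tmpl == 1L))
      st_stop("mean shape for %s degenerated to an empty template",
              "convergence_failure", vertebra)
    comp <- cpp_label_components(tmpl, 8L)
    keep <- which.max(tabulate(comp[comp > 0L]))
    tmpl[comp != keep] <- 0L
    soft <- acc / n
    shape <- finish_mean_shape(vertebra, tmpl, n, convergence, TRUE, angles,
                               soft = soft)
    # (iv) refit each frame against the provisional template; after the
    # first pass the per-frame angle is already near its basin, so the
    # refit window narrows to +-15 degrees for speed
    wnd <- if (it == 1L) cfg$angle_window_deg else min(cfg$angle_window_deg, 15)
    cfg_it <- cfg
    cfg_it$angle_window_deg <- wnd
    cfg_it$coarse_step_deg <- min(cfg$coarse_step_deg, wnd)
    ovs <- numeric(n)
    for (i in seq_len(n)) {
      fit <- fit_angle(shape, crops[[i]], prev_angle_deg = angles[i],
                       cfg = cfg_it)
      angles[i] <- fit$angle_deg
      ovs[i] <- fit$overlap
    }
    # re-anchor the rotational gauge: nothing else pins the template's
    # orientation, so without this the alternation can drift a few degrees
    angles <- angles - mean(angles)
    convergence <- c(convergence, mean(ovs))
    if (mean(ovs) > best_ov) {
      best_ov <- mean(ovs)
      best <- list(tmpl = tmpl, angles = angles, soft = soft)
    }
    if (it >= 2 &&
        abs(convergence[it] - convergence[it - 1]) < tol) {
      return(finish_mean_shape(vertebra, tmpl, n, convergence, TRUE, angles,
                               soft = soft))
    }
  }
  st_warn("mean shape for %s did not converge in %d iterations; returning best iterate",
          "convergence_failure", vertebra, max_iter)
  finish_mean_shape(vertebra, best$tmpl, n, convergence, FALSE, best$angles,
                    soft = best$soft)
}

#' Per-frame overlap of a mean shape with its recording
#'
#' Diagnostic for how consistently the rigid template explains each frame:
#' the best-fit overlap (Dice by default) of the template against the
#' vertebra's mask in every frame. `NA` where the vertebra is absent.
#'
#' @param shape a [build_mean_shape()] result.
#' @param seq the [label_mask_sequence()] to score against.
#' @param vertebra vertebra name (defaults to the shape's own).
#' @param cfg a [fit_config()].
#' @return numeric vector, one overlap per frame.
#' @export
mean_shape_overlap <- function(shape, seq, vertebra = shape$vertebra,
                               cfg = fit_config()) {
  lab <- label_of(seq, vertebra)
  prev <- 0
  vapply(seq_len(n_frames(seq)), function(t) {
    m <- seq$frames[[t]] == lab
    storage.mode(m) <- "integer"
    fit <- fit_angle(shape, m, prev_angle_deg = prev, cfg = cfg)
    if (fit$missing) return(NA_real_)
    prev <<- fit$angle_deg
    fit$overlap
  }, 0)
}
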