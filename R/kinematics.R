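#' Fill short marker gaps by cubic-spline interpolation
#'
#' Gaps of at most \code{max_gap} consecutive frames are filled per marker
#' and per axis with a natural cubic spline through the valid samples;
#' longer gaps (and gaps at the trajectory ends) are left invalid.
#'
#' @param markers a \code{\link{marker_trajectory_set}}.
#' @param max_gap longest gap (frames) that is filled; default 10.
#' @return A \code{\link{marker_trajectory_set}} with gaps filled.
#' @export
fill_gaps <- function(markers, max_gap = 10) {
  pos <- markers$positions
  mask <- markers$valid_mask
  nfr <- nrow(mask)
  for (j in seq_len(ncol(mask))) {
    v <- mask[, j]
    if (all(v) || sum(v) < 4L) next
    r <- rle(!v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      if (r$lengths[k] > max_gap) next
      if (starts[k] == 1L || ends[k] == nfr) next  # edge gap: cannot bracket
      idx <- starts[k]:ends[k]
      for (ax in 1:3) {
        sp <- stats::spline(which(v), pos[v, j, ax], xout = idx,
                            method = "natural")
        pos[idx, j, ax] <- sp$y
      }
      mask[idx, j] <- TRUE
    }
  }
  marker_trajectory_set(markers$labels, pos, markers$rate, mask)
}

#' Per-frame rigid bone poses from a marker cluster
#'
#' For every capture frame, estimates the rigid transform taking the
#' neutral-position surface landmarks (imaging frame) to that frame's
#' marker positions (lab frame) by SVD registration
#' (\code{\link{estimate_rigid_transform}}). Frames with fewer than 3
#' valid shared markers are flagged invalid. Short marker gaps are filled
#' first (see \code{\link{fill_gaps}}).
#'
#' @param markers a \code{\link{marker_trajectory_set}}.
#' @param neutral named matrix of the same segment's surface landmarks at
#'   the neutral position (rownames are labels; mm, imaging frame).
#' @param fill fill short gaps before fitting (default TRUE).
#' @param max_gap see \code{\link{fill_gaps}}.
#' @return Object of class \code{frame_transform_series}: list with
#'   \code{transforms} (list of \code{\link{rigid_transform}} or NULL),
#'   \code{residual_rms} (mm, NA when invalid), \code{valid} (logical),
#'   and \code{rate} (Hz).
#' @export
fit_frame_transforms <- function(markers, neutral, fill = TRUE,
                                 max_gap = 10) {
  neutral <- as_landmarks(neutral)
  shared <- intersect(markers$labels, rownames(neutral))
  if (length(shared) < 3L) {
    stop("need at least 3 marker labels shared with the neutral set ",
         "(found ", length(shared), ")", call. = FALSE)
  }
  if (fill) markers <- fill_gaps(markers, max_gap)
  jidx <- match(shared, markers$labels)
  P0 <- neutral[shared, , drop = FALSE]
  nfr <- n_frames(markers)
  transforms <- vector("list", nfr)
  residual <- rep(NA_real_, nfr)
  valid <- rep(FALSE, nfr)
  for (i in seq_len(nfr)) {
    ok <- markers$valid_mask[i, jidx]
    if (sum(ok) < 3L) next
    Q <- matrix(markers$positions[i, jidx[ok], ], sum(ok), 3)
    tf <- tryCatch(
      estimate_rigid_transform(P0[ok, , drop = FALSE], Q),
      error = function(e) NULL)
    if (is.null(tf)) next
    transforms[[i]] <- tf
    residual[i] <- attr(tf, "residual_rms")
    valid[i] <- TRUE
  }
  if (!any(valid)) stop("all frames invalid: no pose could be fitted",
                        call. = FALSE)
  structure(list(transforms = transforms, residual_rms = residual,
                 valid = valid, rate = markers$rate),
            class = "frame_transform_series")
}

#' @export
print.frame_transform_series <- function(x, ...) {
  cat(sprintf(
    "Frame transforms: %d frames (%d valid), median residual %.3g mm\n",
    length(x$valid), sum(x$valid),
    stats::median(x$residual_rms, na.rm = TRUE)))
  invisible(x)
}

#' Bone-landmark trajectories in the lab frame
#'
#' Applies each frame's fitted transform to the imaging-frame bone
#' landmark set: \code{B = R A + t} per frame. Invalid frames yield NA.
#'
#' @param series a \code{\link{fit_frame_transforms}} result.
#' @param bone_landmarks N x 3 matrix (imaging frame, mm).
#' @return frames x N x 3 array of lab-frame positions (mm).
#' @export
bone_landmark_trajectories <- function(series, bone_landmarks) {
  A <- as_points3(bone_landmarks, "bone_landmarks")
  nfr <- length(series$valid)
  out <- array(NA_real_, c(nfr, nrow(A), 3))
  for (i in seq_len(nfr)) {
    if (!series$valid[i]) next
    out[i, , ] <- apply_transform(series$transforms[[i]], A)
  }
  dimnames(out) <- list(NULL, rownames(A), c("x", "y", "z"))
  out
}

#' Detect gait events from vertical ground reaction force
#'
#' Heel strike is an upward crossing of the force threshold, toe off a
#' downward crossing. Crossings closer together than \code{debounce_s}
#' are merged (oscillation around the threshold). The gait cycle runs
#' heel-strike to next ipsilateral heel-strike.
#'
#' @param grf a \code{\link{grf_record}}.
#' @param threshold force threshold in N (default 10).
#' @param debounce_s crossings closer than this (s) are merged; default
#'   0.05.
#' @return Object of class \code{gait_events}: list with
#'   \code{heel_strikes} and \code{toe_offs} (frame indices) and
#'   \code{rate}.
#' @export
detect_gait_events <- function(grf, threshold = 10, debounce_s = 0.05) {
  f <- vertical_force(grf)
  above <- f >= threshold
  up <- which(!above[-length(above)] & above[-1]) + 1L
  down <- which(above[-length(above)] & !above[-1]) + 1L
  ev <- rbind(data.frame(frame = up,
                         type = rep("heel_strike", length(up))),
              data.frame(frame = down, type = rep("toe_off", length(down))))
  ev <- ev[order(ev$frame), , drop = FALSE]
  # debounce: an adjacent event pair closer than the window is an
  # oscillation around the threshold -- both events annihilate.
  # Smallest gaps are removed first.
  min_gap <- debounce_s * grf$rate
  while (nrow(ev) > 1L) {
    gaps <- diff(ev$frame)
    if (all(gaps >= min_gap)) break
    k <- which.min(gaps)
    ev <- ev[-c(k, k + 1L), , drop = FALSE]
  }
  if (nrow(ev) == 0L) {
    warning("no threshold crossings found: empty gait events")
  }
  structure(list(heel_strikes = ev$frame[ev$type == "heel_strike"],
                 toe_offs = ev$frame[ev$type == "toe_off"],
                 rate = grf$rate),
            class = "gait_events")
}

#' @export
print.gait_events <- function(x, ...) {
  cat(sprintf("Gait events: %d heel strikes, %d toe offs @ %g Hz\n",
              length(x$heel_strikes), length(x$toe_offs), x$rate))
  invisible(x)
}

#' Write gait events to CSV
#' @param events a \code{gait_events} object.
#' @param path output CSV path.
#' @export
write_events <- function(events, path) {
  df <- rbind(data.frame(frame = events$heel_strikes, type = "heel_strike"),
              data.frame(frame = events$toe_offs, type = "toe_off"))
  utils::write.csv(df[order(df$frame), ], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Time-normalize a per-frame series to the gait cycle
#'
#' Linearly interpolates a scalar series onto \code{q} equally spaced
#' gait-cycle percentages between one heel strike and the next; the
#' endpoints map exactly to the two heel strikes.
#'
#' @param series numeric per-frame values (NA allowed outside the cycle;
#'   NA inside the cycle is linearly bridged if \code{na_policy} is
#'   \code{"interpolate"}, rejected if \code{"error"}).
#' @param cycle integer length-2: (heel strike frame, next ipsilateral
#'   heel strike frame).
#' @param q node count (default 101: 0%, 1%, ..., 100%).
#' @param na_policy \code{"interpolate"} or \code{"error"}.
#' @return Object of class \code{normalized_curve}: list with
#'   \code{values} (length q) and \code{percent}.
#' @export
normalize_to_cycle <- function(series, cycle, q = 101,
                               na_policy = c("interpolate", "error")) {
  na_policy <- match.arg(na_policy)
  cycle <- as.numeric(cycle)
  if (length(cycle) != 2L || diff(cycle) < 1) {
    stop("cycle must span at least 2 frames", call. = FALSE)
  }
  frames <- seq(cycle[1], cycle[2])
  y <- series[frames]
  if (anyNA(y)) {
    if (na_policy == "error") stop("series has gaps inside the cycle",
                                   call. = FALSE)
    ok <- !is.na(y)
    if (sum(ok) < 2L) stop("too few valid samples in cycle", call. = FALSE)
    y <- stats::approx(frames[ok], y[ok], xout = frames, rule = 2)$y
  }
  pct <- seq(0, 100, length.out = q)
  xout <- cycle[1] + pct / 100 * (cycle[2] - cycle[1])
  vals <- stats::approx(frames, y, xout = xout)$y
  structure(list(values = vals, percent = pct), class = "normalized_curve")
}

#' @export
print.normalized_curve <- function(x, ...) {
  cat(sprintf("Normalized curve: %d nodes, range %.3f..%.3f\n",
              length(x$values), min(x$values), max(x$values)))
  invisible(x)
}
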