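#' Triangulated icosphere
#'
#' Subdivided icosahedron with vertices projected onto the sphere.
#'
#' @param radius sphere radius in mm.
#' @param subdivisions subdivision depth (0 = icosahedron; 2 gives 162
#'   vertices).
#' @param center length-3 centre (mm).
#' @return List: \code{vertices}, \code{faces}.
#' @export
icosphere <- function(radius = 50, subdivisions = 2, center = c(0, 0, 0)) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    mids <- new.env()
    nv <- nrow(v)
    newf <- matrix(0L, 0, 3)
    get_mid <- function(a, b) {
      k <- edge_key(a, b)
      if (!is.null(mids[[k]])) return(mids[[k]])
      m <- (v[a, ] + v[b, ]) / 2
      m <- m / sqrt(sum(m^2))
      v <<- rbind(v, m)
      mids[[k]] <- nrow(v)
      nrow(v)
    }
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; c_ <- f[i, 3]
      ab <- get_mid(a, b); bc <- get_mid(b, c_); ca <- get_mid(c_, a)
      newf <- rbind(newf, c(a, ab, ca), c(b, bc, ab), c(c_, ca, bc),
                    c(ab, bc, ca))
    }
    f <- newf
  }
  list(vertices = unname(sweep(v * radius, 2, center, "+")), faces = f)
}

#' Sphere-phantom specification
#'
#' Parameters of the in-silico validation phantom: a sphere standing in
#' for the bone carries 5 bone landmarks on its surface, each paired with
#' a surface landmark raised outward along the local normal by a
#' group-specific offset (simulating unequal soft-tissue thickness). The
#' rigid assembly is driven along a commanded motion: a 300 mm slide
#' along an oblique track axis over 990 frames, or a 90 degree rotation
#' about a fixed axis through the mount point over 1435 frames, at
#' 100 Hz.
#'
#' @param radius sphere radius mm (default 50).
#' @param offsets_mm 5 distinct surface-to-bone offsets mm (default
#'   5, 8, 11, 14, 17).
#' @param motion "slide" or "rotation".
#' @param slide_mm commanded slide distance (default 300).
#' @param slide_axis oblique track direction (normalized; default not
#'   parallel to the ground).
#' @param rotation_deg commanded rotation (default 90).
#' @param rotation_axis rotation axis (default z, the pan axis).
#' @param mount point on the rotation axis (default below the sphere).
#' @param frames frame count (default 990 for slide, 1435 for rotation).
#' @param rate Hz (default 100).
#' @param noise_sd isotropic Gaussian marker noise SD in mm (default 0).
#' @param seed RNG seed for landmark placement and noise.
#' @return List of class \code{phantom_spec}.
#' @export
phantom_spec <- function(radius = 50, offsets_mm = c(5, 8, 11, 14, 17),
                         motion = c("slide", "rotation"), slide_mm = 300,
                         slide_axis = c(2, 1, 2), rotation_deg = 90,
                         rotation_axis = c(0, 0, 1), mount = NULL,
                         frames = NULL, rate = 100, noise_sd = 0,
                         seed = 1) {
  motion <- match.arg(motion)
  if (any(offsets_mm <= 0)) stop("offsets must be positive", call. = FALSE)
  if (anyDuplicated(offsets_mm)) {
    stop("offsets must be distinct across groups", call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (is.null(frames)) frames <- if (motion == "slide") 990L else 1435L
  if (frames < 2) stop("frames must be >= 2", call. = FALSE)
  if (is.null(mount)) mount <- c(0, 0, -(radius + 20))
  if (sqrt(sum(slide_axis^2)) == 0) stop("zero-length slide axis",
                                         call. = FALSE)
  if (sqrt(sum(rotation_axis^2)) == 0) stop("zero rotation axis",
                                            call. = FALSE)
  structure(list(radius = radius, offsets_mm = offsets_mm, motion = motion,
                 slide_mm = slide_mm,
                 slide_axis = slide_axis / sqrt(sum(slide_axis^2)),
                 rotation_deg = rotation_deg,
                 rotation_axis = rotation_axis /
                   sqrt(sum(rotation_axis^2)),
                 mount = mount, frames = as.integer(frames), rate = rate,
                 noise_sd = noise_sd, seed = seed),
            class = "phantom_spec")
}

#' Build the sphere phantom
#'
#' Triangulated sphere with 5 bone-landmark / surface-landmark pairs:
#' bone points on the sphere surface at seeded random directions (spread
#' over both sides), surface points offset outward along the local
#' normal by each group's height. Deterministic for a fixed seed.
#'
#' @param spec a \code{\link{phantom_spec}}.
#' @return A \code{\link{bone_model}} whose ROI \code{"sphere_surface"}
#'   is the whole sphere; bone landmarks \code{b1..b5}, surface
#'   landmarks \code{s1..s5}.
#' @export
build_phantom <- function(spec) {
  set.seed(spec$seed)
  ng <- length(spec$offsets_mm)
  # seeded random directions, alternating hemispheres, kept well apart
  dirs <- matrix(0, ng, 3)
  for (i in seq_len(ng)) {
    repeat {
      u <- stats::rnorm(3)
      u <- u / sqrt(sum(u^2))
      u[1] <- abs(u[1]) * (if (i %% 2 == 0) -1 else 1)
      cosang <- dirs[seq_len(i - 1), , drop = FALSE] %*% u
      if (i == 1 || min(acos(pmax(-1, pmin(1, cosang)))) > 0.5) break
    }
    dirs[i, ] <- u
  }
  b <- dirs * spec$radius
  s <- dirs * (spec$radius + spec$offsets_mm)
  rownames(b) <- paste0("b", seq_len(ng))
  rownames(s) <- paste0("s", seq_len(ng))
  mesh <- icosphere(spec$radius, 2)
  bone_model(mesh$vertices, mesh$faces, b, s,
             rois = list(sphere_surface = seq_len(nrow(mesh$vertices))))
}

# Shared machinery: given per-frame truth transforms, produce marker set
# (noisy surface landmarks) and truth trajectories.
phantom_capture <- function(spec, model, transforms) {
  nfr <- spec$frames
  s0 <- model$surface_landmarks
  b0 <- model$bone_landmarks
  ns <- nrow(s0)
  surf <- array(NA_real_, c(nfr, ns, 3))
  bone <- array(NA_real_, c(nfr, nrow(b0), 3))
  for (i in seq_len(nfr)) {
    surf[i, , ] <- apply_transform(transforms[[i]], s0)
    bone[i, , ] <- apply_transform(transforms[[i]], b0)
  }
  dimnames(surf) <- list(NULL, rownames(s0), NULL)
  dimnames(bone) <- list(NULL, rownames(b0), NULL)
  pos <- surf
  if (spec$noise_sd > 0) {
    pos <- pos + array(stats::rnorm(length(pos), sd = spec$noise_sd),
                       dim(pos))
  }
  markers <- marker_trajectory_set(rownames(s0), pos, spec$rate)
  truth <- structure(list(transforms = transforms, bone_traj = bone,
                          surface_traj = surf),
                     class = "phantom_truth")
  list(markers = markers, truth = truth)
}

#' Simulate the phantom slide motion
#'
#' Constant-speed translation of the whole rigid assembly by the
#' commanded distance along the oblique track axis. Marker noise
#' (seeded) is added to the surface markers only; the ground truth is
#' exact.
#'
#' @param spec a \code{\link{phantom_spec}} with \code{motion = "slide"}.
#' @return List: \code{markers} (\code{marker_trajectory_set}),
#'   \code{truth} (\code{phantom_truth}), \code{model}
#'   (\code{bone_model}).
#' @export
simulate_slide <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"), spec$motion == "slide")
  model <- build_phantom(spec)       # also seeds the RNG
  u <- spec$slide_axis
  transforms <- lapply(seq_len(spec$frames), function(i) {
    d <- spec$slide_mm * (i - 1) / (spec$frames - 1)
    rigid_transform(diag(3), u * d, validate = FALSE)
  })
  out <- phantom_capture(spec, model, transforms)
  out$model <- model
  out
}

#' Simulate the phantom rotation motion
#'
#' Constant-rate rotation about the fixed axis through the mount point
#' by the commanded angle (the pan-tilt stage of the validation
#' protocol).
#'
#' @param spec a \code{\link{phantom_spec}} with
#'   \code{motion = "rotation"}.
#' @return As \code{\link{simulate_slide}}.
#' @export
simulate_rotation <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"), spec$motion == "rotation")
  model <- build_phantom(spec)
  m <- spec$mount
  transforms <- lapply(seq_len(spec$frames), function(i) {
    ang <- spec$rotation_deg * (i - 1) / (spec$frames - 1)
    R <- rotation_about_axis(spec$rotation_axis, ang)
    rigid_transform(R, as.numeric(m - R %*% m), validate = FALSE)
  })
  out <- phantom_capture(spec, model, transforms)
  out$model <- model
  out
}

#' Add a soft-tissue-artifact-like perturbation to markers
#'
#' Smooth sinusoidal per-marker, per-axis displacement of amplitude
#' \code{amplitude} mm at the given frequency, with seeded random
#' phases. Breaks the rigid-cluster assumption to probe registration
#' sensitivity; amplitude 0 is the identity.
#'
#' @param markers a \code{\link{marker_trajectory_set}}.
#' @param amplitude per-axis amplitude in mm (>= 0); peak displacement
#'   magnitude is at most \code{amplitude * sqrt(3)}.
#' @param frequency Hz (default 1).
#' @param seed RNG seed for the phases.
#' @return Perturbed \code{\link{marker_trajectory_set}}.
#' @export
add_sta_perturbation <- function(markers, amplitude, frequency = 1,
                                 seed = 1) {
  stopifnot(amplitude >= 0)
  if (amplitude == 0) return(markers)
  set.seed(seed)
  nfr <- n_frames(markers)
  tt <- (seq_len(nfr) - 1) / markers$rate
  pos <- markers$positions
  for (j in seq_len(length(markers$labels))) {
    for (ax in 1:3) {
      phase <- stats::runif(1, 0, 2 * pi)
      pos[, j, ax] <- pos[, j, ax] +
        amplitude * sin(2 * pi * frequency * tt + phase)
    }
  }
  marker_trajectory_set(markers$labels, pos, markers$rate,
                        markers$valid_mask)
}

# Periodic IFS excursion waveform (mm about the neutral gap): maximum
# near 30% of the cycle (mid-stance), minimum near 65% (initial swing).
ifs_waveform <- function(pct, amp = 1, shift = 0) {
  x <- c(0, 15, 30, 45, 65, 85, 100)
  y <- c(0, 4, 8, 2, -8, -2, 0)
  f <- stats::splinefun(x, y, method = "periodic")
  amp * f((pct - shift) %% 100)
}

# Smooth effect window: raised-cosine bump on [lo, hi], peak 1.
effect_bump <- function(pct, lo = 40, hi = 80) {
  w <- numeric(length(pct))
  inside <- pct >= lo & pct <= hi
  w[inside] <- 0.5 * (1 - cos(2 * pi * (pct[inside] - lo) / (hi - lo)))
  w
}

#' Sample cohort IFS curves (healthy vs affected)
#'
#' Draws gait-normalized IFS waveforms for two cohorts from the
#' generator's waveform family: neutral gap 30 mm, excursion peaking in
#' mid-stance and dipping in initial swing, per-subject amplitude and
#' phase variability plus smooth additive noise. The affected cohort's
#' IFS is reduced by \code{effect_mm} (raised-cosine window over
#' 40-80% of the cycle, peak amplitude \code{effect_mm}).
#'
#' @param n_healthy,n_affected cohort sizes (default 18 and 12 hips).
#' @param effect_mm peak between-cohort IFS reduction in mm (default 6).
#' @param noise_sd between-subject smooth curve noise SD in mm
#'   (default 2).
#' @param q nodes (default 101).
#' @param neutral_mm neutral IFS in mm (default 30).
#' @param seed RNG seed.
#' @return List: \code{healthy}, \code{affected} (subjects x q
#'   matrices), \code{effect_window} = c(40, 80), \code{percent}.
#' @export
simulate_ifs_cohorts <- function(n_healthy = 18, n_affected = 12,
                                 effect_mm = 6, noise_sd = 2, q = 101,
                                 neutral_mm = 30, seed = 1) {
  set.seed(seed)
  pct <- seq(0, 100, length.out = q)
  draw <- function(n, effect) {
    out <- matrix(0, n, q)
    for (i in seq_len(n)) {
      amp <- stats::rnorm(1, 1, 0.08)
      shift <- stats::rnorm(1, 0, 2)
      base <- neutral_mm + ifs_waveform(pct, amp, shift) -
        effect * effect_bump(pct)
      noise <- noise_sd * smooth_gaussian_curves(1, q, fwhm = 20)
      out[i, ] <- base + noise
    }
    out
  }
  healthy <- draw(n_healthy, 0)
  affected <- draw(n_affected, effect_mm)
  if (min(affected) < 0 || min(healthy) < 0) {
    stop("effect/noise too large: generated IFS would be negative",
         call. = FALSE)
  }
  list(healthy = healthy, affected = affected,
       effect_window = c(40, 80), percent = pct)
}

#' Simulate a gait-like two-body scene
#'
#' Builds two schematic rigid bodies -- a pelvis block carrying a
#' spherical ischial prominence and a femur shaft carrying a spherical
#' lesser-trochanter prominence -- and drives them through smooth
#' periodic pose profiles over complete gait cycles so that the true
#' inter-prominence gap follows the cohort waveform family (neutral
#' 30 mm, maximum in mid-stance, minimum in initial swing). Both
#' prominences are spheres and all rotations are taken about the
#' prominence centres, so the commanded gap is exact up to mesh
#' discretization. A synthetic vertical GRF with a stance plateau
#' crosses the 10 N event threshold at each cycle boundary.
#'
#' @param cycle_s gait-cycle duration in s (default 1.1).
#' @param rate capture rate Hz (default 100).
#' @param n_cycles complete cycles (default 2).
#' @param effect_mm IFS reduction applied to the affected subject's
#'   waveform (default 0).
#' @param noise_sd marker noise SD mm (default 0).
#' @param seed RNG seed.
#' @return List: \code{pelvis}, \code{femur} (bone models with ROIs
#'   \code{ischial_tuberosity_lateral_cortex} and
#'   \code{lesser_trochanter_medial_cortex}), \code{markers}
#'   (pelvis+femur clusters in one set), \code{grf}, \code{events}
#'   (true heel-strike frames), \code{pelvis_truth}, \code{femur_truth}
#'   (per-frame transforms), \code{truth_ifs} (per-frame commanded gap,
#'   mm), \code{cycle} (first heel-strike pair), \code{rate}.
#' @export
simulate_gait_scene <- function(cycle_s = 1.1, rate = 100, n_cycles = 2,
                                effect_mm = 0, noise_sd = 0, seed = 1) {
  set.seed(seed)
  r_prom <- 10
  neutral <- 30
  cpelvis <- c(0, 0, 0)
  cfemur <- c(neutral + 2 * r_prom, 0, 0)
  pelvis <- make_prominence_body(cpelvis, r_prom, side = -1,
                                 roi = "ischial_tuberosity_lateral_cortex")
  femur <- make_prominence_body(cfemur, r_prom, side = +1,
                                roi = "lesser_trochanter_medial_cortex")
  fpc <- round(cycle_s * rate)              # frames per cycle
  nfr <- n_cycles * fpc + 1
  tt <- seq_len(nfr) - 1
  pct <- (tt %% fpc) / fpc * 100
  w <- ifs_waveform(pct) - effect_mm * effect_bump(pct)
  if (any(neutral + w <= 0)) {
    stop("effect too large: commanded IFS would be non-positive",
         call. = FALSE)
  }
  sway <- cbind(3 * sin(2 * pi * tt / fpc), 2 * cos(2 * pi * tt / fpc),
                1.5 * sin(4 * pi * tt / fpc))
  pelvis_tfs <- lapply(seq_len(nfr), function(i) {
    R <- rotation_about_axis(c(0, 0, 1), 2 * sin(2 * pi * tt[i] / fpc))
    # rotate about the prominence centre so the spherical ROI is invariant
    rigid_transform(R, as.numeric(cpelvis - R %*% cpelvis) + sway[i, ],
                    validate = FALSE)
  })
  femur_tfs <- lapply(seq_len(nfr), function(i) {
    R <- rotation_about_axis(c(0, 1, 0), 10 * sin(2 * pi * tt[i] / fpc))
    rigid_transform(R, as.numeric(cfemur - R %*% cfemur) + sway[i, ] +
                      c(w[i], 0, 0), validate = FALSE)
  })
  mk <- function(model, tfs, labels) {
    s0 <- model$surface_landmarks[labels, , drop = FALSE]
    pos <- array(NA_real_, c(nfr, length(labels), 3))
    for (i in seq_len(nfr)) pos[i, , ] <- apply_transform(tfs[[i]], s0)
    pos
  }
  plab <- rownames(pelvis$surface_landmarks)
  flab <- rownames(femur$surface_landmarks)
  pos <- array(NA_real_, c(nfr, length(plab) + length(flab), 3))
  pos[, seq_along(plab), ] <- mk(pelvis, pelvis_tfs, plab)
  pos[, length(plab) + seq_along(flab), ] <- mk(femur, femur_tfs, flab)
  if (noise_sd > 0) {
    pos <- pos + array(stats::rnorm(length(pos), sd = noise_sd), dim(pos))
  }
  markers <- marker_trajectory_set(c(plab, flab), pos, rate)
  # stance-plateau GRF: rises through 10 N at each heel strike
  f <- numeric(nfr)
  hs <- 1 + (0:(n_cycles)) * fpc
  stance <- round(0.6 * fpc)
  for (h in hs[hs <= nfr]) {
    idx <- h:min(h + stance, nfr)
    ph <- (idx - h) / stance
    f[idx] <- pmax(f[idx], 600 * sin(pi * ph))
  }
  grf <- grf_record(f, rate)
  list(pelvis = pelvis, femur = femur, markers = markers, grf = grf,
       events = hs[hs <= nfr], pelvis_truth = pelvis_tfs,
       femur_truth = femur_tfs, truth_ifs = neutral + w,
       cycle = c(hs[1], hs[2]), rate = rate)
}

# Schematic bone: a block plus a spherical prominence whose vertices form
# the cortical ROI. side = -1 puts the block on -x (pelvis), +1 on +x
# (femur shaft).
make_prominence_body <- function(center, r_prom, side, roi) {
  sph <- icosphere(r_prom, 2, center)
  x0 <- center[1] + side * (r_prom + 5)
  x1 <- x0 + side * 40
  bx <- sort(c(x0, x1))
  box_v <- as.matrix(expand.grid(bx, center[2] + c(-15, 15),
                                 center[3] + c(-40, 20)))
  colnames(box_v) <- NULL
  box_f <- rbind(c(1, 3, 4), c(1, 4, 2), c(5, 8, 7), c(5, 6, 8),
                 c(1, 2, 6), c(1, 6, 5), c(3, 8, 4), c(3, 7, 8),
                 c(1, 5, 7), c(1, 7, 3), c(2, 4, 8), c(2, 8, 6))
  nv <- nrow(sph$vertices)
  vertices <- rbind(sph$vertices, box_v)
  faces <- rbind(sph$faces, box_f + nv)
  # three well-spread skin markers on the block
  sl <- rbind(box_v[1, ] + c(0, 2, 5), box_v[4, ] + c(0, -3, 2),
              box_v[6, ] + c(0, 1, -4))
  rownames(sl) <- paste0(roi_prefix(roi), c("_m1", "_m2", "_m3"))
  bl <- rbind(center, center + c(0, 0, r_prom))
  rownames(bl) <- paste0(roi_prefix(roi), c("_prom_centre", "_prom_top"))
  rois <- stats::setNames(list(seq_len(nv)), roi)
  bone_model(vertices, faces, bl, sl, rois)
}

roi_prefix <- function(roi) {
  if (grepl("^ischial", roi)) "pelvis" else "femur"
}

#' Write a phantom dataset to files
#'
#' Emits the marker TSV (or TRC), mesh STL, landmark and ROI JSON
#' consumed by the pipeline, plus a \code{truth/} directory with the
#' ground-truth transforms CSV and (when present) bone-landmark
#' trajectories.
#'
#' @param sim result of \code{\link{simulate_slide}} or
#'   \code{\link{simulate_rotation}}.
#' @param dir output directory (created).
#' @param dialect marker format, "tsv" or "trc".
#' @return \code{dir}, invisibly.
#' @export
write_phantom_dataset <- function(sim, dir, dialect = "tsv") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "truth"), showWarnings = FALSE)
  write_markers(sim$markers, file.path(dir, paste0("markers.", dialect)),
                dialect)
  write_mesh(sim$model, file.path(dir, "phantom.stl"))
  write_landmarks(sim$model$bone_landmarks, sim$model$surface_landmarks,
                  file.path(dir, "landmarks.json"))
  write_rois(sim$model$rois, file.path(dir, "rois.json"))
  write_transforms(sim$truth$transforms,
                   file.path(dir, "truth", "transforms.csv"))
  invisible(dir)
}
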