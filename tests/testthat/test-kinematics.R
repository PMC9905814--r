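# Rigid cluster of 6 markers driven through a commanded motion.
make_cluster_motion <- function(nfr = 40, seed = 2, motion = NULL) {
  set.seed(seed)
  neutral <- matrix(stats::rnorm(18, sd = 60), 6, 3)
  rownames(neutral) <- paste0("m", 1:6)
  if (is.null(motion)) {
    motion <- lapply(seq_len(nfr), function(i) {
      ang <- 45 * sin(2 * pi * i / nfr)
      R <- rotation_about_axis(c(1, 2, 0.5), ang)
      rigid_transform(R, c(3 * i, -i, 0.5 * i), validate = FALSE)
    })
  }
  pos <- array(NA_real_, c(nfr, 6, 3))
  for (i in seq_len(nfr)) {
    pos[i, , ] <- apply_transform(motion[[i]], neutral)
  }
  list(neutral = neutral,
       markers = marker_trajectory_set(rownames(neutral), pos, 100),
       motion = motion)
}

test_that("a static trial yields identity transforms with zero residual", {
  cm <- make_cluster_motion(motion = rep(list(rigid_transform()), 15),
                            nfr = 15)
  series <- fit_frame_transforms(cm$markers, cm$neutral)
  expect_true(all(series$valid))
  expect_lt(max(series$residual_rms), 1e-9)
  for (tf in series$transforms) {
    expect_lt(geodesic_precise_deg(tf$rotation, diag(3)), 1e-9)
    expect_lt(max(abs(tf$translation)), 1e-9)
  }
})

test_that("noiseless rigid cluster motion is recovered exactly, any geometry", {
  for (seed in c(2, 5, 9)) {
    cm <- make_cluster_motion(seed = seed)
    series <- fit_frame_transforms(cm$markers, cm$neutral)
    bt <- bone_landmark_trajectories(series, cm$neutral)
    for (i in seq_along(cm$motion)) {
      expect_lt(geodesic_precise_deg(series$transforms[[i]]$rotation,
                                     cm$motion[[i]]$rotation), 1e-9)
      truth <- apply_transform(cm$motion[[i]], cm$neutral)
      expect_lt(max(abs(bt[i, , ] - truth)), 1e-9)
    }
  }
})

test_that("a frame with one gapped marker is still fitted from the rest", {
  cm <- make_cluster_motion(nfr = 12)
  cm$markers$positions[5, 3, ] <- NA_real_
  cm$markers$valid_mask[5, 3] <- FALSE
  series <- fit_frame_transforms(cm$markers, cm$neutral, fill = FALSE)
  expect_true(series$valid[5])
  expect_lt(geodesic_precise_deg(series$transforms[[5]]$rotation,
                                 cm$motion[[5]]$rotation), 1e-9)
})

test_that("short gaps are spline-filled, long gaps invalidate only themselves", {
  cm <- make_cluster_motion(nfr = 60)
  cm$markers$positions[20:24, 2, ] <- NA_real_
  cm$markers$valid_mask[20:24, 2] <- FALSE
  filled <- fill_gaps(cm$markers, max_gap = 10)
  expect_true(all(filled$valid_mask[20:24, 2]))
  # smooth motion: spline error stays small
  truth <- t(vapply(20:24, function(i) {
    apply_transform(cm$motion[[i]], cm$neutral)[2, ]
  }, numeric(3)))
  expect_lt(max(abs(filled$positions[20:24, 2, ] - truth)), 0.5)
  cm$markers$valid_mask[30:45, 2] <- FALSE
  filled2 <- fill_gaps(cm$markers, max_gap = 10)
  expect_false(any(filled2$valid_mask[30:45, 2]))
})

test_that("registration residual is invariant to a global rigid motion", {
  set.seed(31)
  cm <- make_cluster_motion(nfr = 10)
  noisy <- cm$markers
  noisy$positions <- noisy$positions +
    array(stats::rnorm(length(noisy$positions), sd = 0.5),
          dim(noisy$positions))
  s1 <- fit_frame_transforms(noisy, cm$neutral)
  g <- rigid_transform(random_rotation(), c(500, -200, 100))
  moved <- noisy
  for (i in seq_len(10)) {
    moved$positions[i, , ] <- apply_transform(g, moved$positions[i, , ])
  }
  neutral_moved <- apply_transform(g, cm$neutral)
  rownames(neutral_moved) <- rownames(cm$neutral)
  s2 <- fit_frame_transforms(moved, neutral_moved)
  expect_equal(s1$residual_rms, s2$residual_rms, tolerance = 1e-8)
})

test_that("fit_frame_transforms needs 3 shared labels", {
  cm <- make_cluster_motion(nfr = 5)
  neutral <- cm$neutral[1:2, , drop = FALSE]
  expect_error(fit_frame_transforms(cm$markers, neutral), "at least 3")
})

test_that("gait events come from threshold crossings with debouncing", {
  f <- numeric(300)
  f[50:150] <- seq(0, 600, length.out = 101)   # rises through 10 N after 50
  f[150:200] <- seq(600, 0, length.out = 51)
  g <- grf_record(f, 100)
  ev <- detect_gait_events(g, threshold = 10)
  expect_equal(length(ev$heel_strikes), 1L)
  expect_equal(length(ev$toe_offs), 1L)
  hs <- ev$heel_strikes[1]
  expect_true(hs >= 51 && hs <= 53)
  expect_true(ev$toe_offs[1] >= 198)

  expect_warning(detect_gait_events(grf_record(rep(0, 100), 100)),
                 "no threshold crossings")

  # oscillation around the threshold within the debounce window is merged
  f2 <- numeric(400)
  f2[100:250] <- 300
  f2[103] <- 5          # brief dip: spurious crossing pair
  g2 <- grf_record(f2, 100)
  ev2 <- detect_gait_events(g2, threshold = 10)
  expect_equal(length(ev2$heel_strikes), 1L)
  expect_equal(length(ev2$toe_offs), 1L)

  # two stance bumps define one complete cycle
  f3 <- numeric(500)
  f3[100:200] <- 300
  f3[320:420] <- 300
  ev3 <- detect_gait_events(grf_record(f3, 100), threshold = 10)
  expect_equal(length(ev3$heel_strikes), 2L)
  expect_equal(diff(ev3$heel_strikes), 220)
})

test_that("event frames scale proportionally with sampling rate", {
  f <- numeric(300)
  f[100:200] <- 300
  ev1 <- detect_gait_events(grf_record(f, 100))
  f2 <- rep(f, each = 2)
  ev2 <- detect_gait_events(grf_record(f2, 200))
  expect_equal(ev2$heel_strikes[1], 2 * ev1$heel_strikes[1] - 1,
               tolerance = 1)
  # additive offsets below threshold do not change events
  ev3 <- detect_gait_events(grf_record(f + 5, 100))
  expect_equal(ev3$heel_strikes, ev1$heel_strikes)
})

test_that("cycle normalization is exact for constant and linear series", {
  s <- rep(7, 100)
  nc <- normalize_to_cycle(s, c(10, 90))
  expect_equal(length(nc$values), 101)
  expect_equal(nc$values, rep(7, 101))

  lin <- seq(0, 99)
  nl <- normalize_to_cycle(lin, c(11, 91))
  expect_equal(nl$values, seq(10, 90, length.out = 101), tolerance = 1e-12)
  expect_equal(nl$values[1], lin[11])
  expect_equal(nl$values[101], lin[91])
  expect_error(normalize_to_cycle(lin, c(5, 5)), "at least 2")
})

test_that("normalizing a downsampled cycle refines to the original", {
  x <- seq(0, 1, length.out = 991)
  s <- 30 + 8 * sin(2 * pi * x) + 3 * cos(4 * pi * x)
  full <- normalize_to_cycle(s, c(1, 991))
  coarse_idx <- seq(1, 991, by = 10)
  coarse <- normalize_to_cycle(s[coarse_idx], c(1, 100))
  # linear-interpolation error bound ~ max|f''| h^2 / 8 on the coarse grid
  expect_lt(max(abs(full$values - coarse$values)), 0.02)
})
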