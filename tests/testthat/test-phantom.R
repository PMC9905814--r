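test_that("phantom construction places landmark pairs at their offsets", {
  spec <- phantom_spec(seed = 3)
  model <- build_phantom(spec)
  b <- model$bone_landmarks
  s <- model$surface_landmarks
  expect_equal(nrow(b), 5)
  # bone points on the sphere, surface points raised by the group offset
  expect_equal(unname(sqrt(rowSums(b^2))), rep(50, 5), tolerance = 1e-9)
  expect_equal(unname(sqrt(rowSums((s - b)^2))), c(5, 8, 11, 14, 17),
               tolerance = 1e-9)
  # landmark directions spread over both sides of the sphere
  expect_true(any(b[, 1] > 0) && any(b[, 1] < 0))
  # deterministic under a fixed seed
  model2 <- build_phantom(phantom_spec(seed = 3))
  expect_identical(model$bone_landmarks, model2$bone_landmarks)
  expect_identical(model$vertices, model2$vertices)
  expect_error(phantom_spec(offsets_mm = c(0, 1, 2, 3, 4)), "positive")
  expect_error(phantom_spec(offsets_mm = c(5, 5, 6, 7, 8)), "distinct")
})

test_that("noiseless slide moves every landmark by the commanded 300 mm", {
  sim <- simulate_slide(phantom_spec(motion = "slide", seed = 1))
  expect_equal(n_frames <- dim(sim$truth$bone_traj)[1], 990)
  net <- sqrt(rowSums((sim$truth$bone_traj[990, , ] -
                         sim$truth$bone_traj[1, , ])^2))
  expect_equal(unname(net), rep(300, 5), tolerance = 1e-9)
  # ground-truth rotation stays the identity
  for (i in c(1, 495, 990)) {
    expect_equal(sim$truth$transforms[[i]]$rotation, diag(3))
  }
  # markers equal the true surface trajectories when noise-free
  expect_equal(sim$markers$positions,
               unname(sim$truth$surface_traj), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("slide marker noise has the commanded standard deviation", {
  sim <- simulate_slide(phantom_spec(motion = "slide", noise_sd = 0.2,
                                     seed = 8))
  dev <- sim$markers$positions - unname(sim$truth$surface_traj)
  expect_equal(stats::sd(dev), 0.2, tolerance = 0.02)  # +/- 10%
})

test_that("noiseless rotation spans 90 degrees with a fixed mount point", {
  spec <- phantom_spec(motion = "rotation", seed = 1)
  sim <- simulate_rotation(spec)
  expect_equal(dim(sim$truth$bone_traj)[1], 1435)
  ang <- rotation_angle_deg(sim$truth$transforms[[1]]$rotation,
                            sim$truth$transforms[[1435]]$rotation)
  expect_equal(ang, 90, tolerance = 1e-9)
  # the mount point never moves
  mount_traj <- t(vapply(sim$truth$transforms, function(tf) {
    apply_transform(tf, spec$mount)
  }, numeric(3)))
  expect_lt(max(abs(sweep(mount_traj, 2, spec$mount))), 1e-9)
})

test_that("full pipeline on the noiseless phantom is exact end to end", {
  for (motion in c("slide", "rotation")) {
    spec <- phantom_spec(motion = motion, seed = 2,
                         frames = if (motion == "slide") 50 else 60)
    sim <- if (motion == "slide") simulate_slide(spec) else
      simulate_rotation(spec)
    series <- fit_frame_transforms(sim$markers,
                                   sim$model$surface_landmarks)
    bt <- bone_landmark_trajectories(series, sim$model$bone_landmarks)
    expect_lt(max(abs(bt - unname(sim$truth$bone_traj))), 1e-9)
  }
})

test_that("generated marker files re-read to identical trajectories", {
  sim <- simulate_slide(phantom_spec(motion = "slide", frames = 20,
                                     noise_sd = 0.3, seed = 5))
  dir <- withr::local_tempdir()
  write_phantom_dataset(sim, dir)
  back <- read_markers(file.path(dir, "markers.tsv"), "tsv")
  expect_lt(max(abs(back$positions - sim$markers$positions)), 1e-6)
  expect_true(file.exists(file.path(dir, "truth", "transforms.csv")))
  model <- read_bone_model(file.path(dir, "phantom.stl"),
                           file.path(dir, "landmarks.json"),
                           file.path(dir, "rois.json"))
  expect_equal(model$bone_landmarks, sim$model$bone_landmarks,
               tolerance = 1e-9)
})

test_that("phantom RMSE scales linearly with injected marker noise", {
  sds <- c(0.1, 0.2, 0.5, 1.0)
  rmse <- vapply(sds, function(s) {
    sim <- simulate_slide(phantom_spec(motion = "slide", frames = 300,
                                       noise_sd = s, seed = 21))
    series <- fit_frame_transforms(sim$markers,
                                   sim$model$surface_landmarks)
    bt <- bone_landmark_trajectories(series, sim$model$bone_landmarks)
    rmse_distance(bt, unname(sim$truth$bone_traj))
  }, 0)
  fit <- lfm(sds, rmse)
  expect_gt(fit$r2, 0.99)
  expect_gt(fit$a1, 0)
})

test_that("soft-tissue-artifact perturbation behaves as documented", {
  sim <- simulate_slide(phantom_spec(motion = "slide", frames = 100,
                                     seed = 6))
  same <- add_sta_perturbation(sim$markers, 0)
  expect_identical(same$positions, sim$markers$positions)
  pert <- add_sta_perturbation(sim$markers, 1.5, frequency = 2, seed = 9)
  disp <- sqrt(apply((pert$positions - sim$markers$positions)^2, c(1, 2),
                     sum))
  expect_lte(max(disp), 1.5 * sqrt(3) + 1e-9)
  expect_gt(max(disp), 0.5)
  # registration residual grows monotonically with amplitude
  res <- vapply(c(0, 0.5, 1, 2), function(a) {
    m <- add_sta_perturbation(sim$markers, a, seed = 9)
    mean(fit_frame_transforms(m, sim$model$surface_landmarks)$residual_rms)
  }, 0)
  expect_true(all(diff(res) > 0))
})

test_that("cohort sampler produces positive curves with the commanded effect", {
  co <- simulate_ifs_cohorts(n_healthy = 18, n_affected = 12,
                             effect_mm = 6, noise_sd = 2, seed = 31)
  expect_equal(dim(co$healthy), c(18, 101))
  expect_equal(dim(co$affected), c(12, 101))
  expect_true(all(co$healthy > 0) && all(co$affected > 0))
  # effect localized to the 40-80% window
  gap <- colMeans(co$healthy) - colMeans(co$affected)
  inwin <- co$percent >= 50 & co$percent <= 70
  outwin <- co$percent <= 20
  expect_gt(mean(gap[inwin]), mean(gap[outwin]) + 2)
  expect_error(simulate_ifs_cohorts(effect_mm = 60, seed = 1), "negative")
})

test_that("gait scene GRF crosses the 10 N threshold at cycle boundaries", {
  sc <- simulate_gait_scene(seed = 2)
  ev <- detect_gait_events(sc$grf, threshold = 10)
  expect_gte(length(ev$heel_strikes), 2)
  expect_lt(max(abs(ev$heel_strikes[1:2] - sc$events[1:2])), 3)
  # commanded IFS stays positive and periodic
  expect_true(all(sc$truth_ifs > 0))
  expect_error(simulate_gait_scene(effect_mm = 100), "non-positive")
})
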