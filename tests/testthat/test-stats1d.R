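test_that("two-sample t curve matches scalar t.test at every node", {
  set.seed(11)
  y1 <- smooth_gaussian_curves(8, 31, 8) + 1
  y2 <- smooth_gaussian_curves(10, 31, 8)
  tc <- t_curve_two_sample(y1, y2)
  expect_equal(tc$df, 16)
  for (j in c(1, 7, 16, 31)) {
    ref <- stats::t.test(y1[, j], y2[, j], var.equal = TRUE)$statistic
    expect_equal(tc$t[j], unname(ref), tolerance = 1e-12)
  }
  # identical groups give the zero curve
  tc0 <- t_curve_two_sample(y1, y1)
  expect_equal(tc0$t, rep(0, 31))
  # location invariance
  tc_shift <- t_curve_two_sample(y1 + 5, y2 + 5)
  expect_equal(tc_shift$t, tc$t, tolerance = 1e-9)
  expect_error(t_curve_two_sample(y1[1, , drop = FALSE], y2), "n >= 2")
})

test_that("paired t curve equals one-sample t on differences", {
  set.seed(12)
  y1 <- smooth_gaussian_curves(9, 25, 6) + 0.5
  y2 <- smooth_gaussian_curves(9, 25, 6)
  tc <- t_curve_paired(y1, y2)
  expect_equal(tc$df, 8)
  d <- y1 - y2
  for (j in c(1, 13, 25)) {
    ref <- stats::t.test(d[, j])$statistic
    expect_equal(tc$t[j], unname(ref), tolerance = 1e-12)
    ref2 <- stats::t.test(y1[, j], y2[, j], paired = TRUE)$statistic
    expect_equal(tc$t[j], unname(ref2), tolerance = 1e-12)
  }
  expect_equal(t_curve_paired(y1, y1)$t, rep(0, 25))
  # sign flip of all differences negates the curve
  expect_equal(t_curve_paired(y2, y1)$t, -tc$t, tolerance = 1e-12)
  expect_error(t_curve_paired(y1, y2[1:5, ]), "matching dimensions")
})

test_that("the K2 normality test reproduces frozen reference values", {
  # references computed once with an independent implementation of the
  # same published omnibus test
  x <- c(0.1, -1.2, 0.5, 2.3, -0.7, 1.1, 0.0, -0.4, 0.9, -1.6, 0.3,
         0.8, -0.2, 1.9, -1.1, 0.6, 0.25, -0.85, 1.45, -0.35)
  r <- dagostino_k2(x)
  expect_equal(r$statistic, 0.34069386423712905, tolerance = 1e-10)
  expect_equal(r$p_value, 0.8433721729408805, tolerance = 1e-10)
  r3 <- dagostino_k2(x^3)
  expect_equal(r3$statistic, 24.61624301316285, tolerance = 1e-10)
  expect_equal(r3$p_value, 4.514927148868007e-06, tolerance = 1e-8)
  expect_error(dagostino_k2(stats::rnorm(5)), "n >= 8")
})

test_that("normality gate selects SPM for Gaussian and SnPM for heavy tails", {
  set.seed(9)
  spm_n <- 0
  snpm_t2 <- 0
  nrep <- 40
  for (s in seq_len(nrep)) {
    y <- smooth_gaussian_curves(20, 101, 15)
    if (normality_gate(y[1:10, ], y[11:20, ])$method == "SPM") {
      spm_n <- spm_n + 1
    }
    yh <- matrix(stats::rt(20 * 101, df = 2), 20)
    if (normality_gate(yh[1:10, ], yh[11:20, ])$method == "SnPM") {
      snpm_t2 <- snpm_t2 + 1
    }
  }
  expect_gte(spm_n / nrep, 0.9)
  expect_gte(snpm_t2 / nrep, 0.9)
  # too-small samples default to SnPM with a warning
  y <- smooth_gaussian_curves(4, 21, 5)
  expect_warning(g <- normality_gate(y[1:2, ], y[3:4, ]), "SnPM")
  expect_equal(g$method, "SnPM")
})

test_that("RFT threshold has the right limits and monotonicity", {
  # perfectly smooth residuals: threshold is the pointwise quantile
  expect_equal(rft_threshold(28, q = 101, fwhm = Inf, alpha = 0.05),
               stats::qt(0.975, 28), tolerance = 1e-9)
  th <- vapply(c(5, 10, 20, 50), function(f) {
    rft_threshold(28, q = 101, fwhm = f, alpha = 0.05)
  }, 0)
  expect_true(all(diff(th) < 0))       # smoother field -> lower threshold
  ta <- vapply(c(0.01, 0.05, 0.1), function(a) {
    rft_threshold(28, q = 101, fwhm = 15, alpha = a)
  }, 0)
  expect_true(all(diff(ta) < 0))       # larger alpha -> lower threshold
  expect_gt(rft_threshold(28, q = 101, fwhm = 15), stats::qt(0.975, 28))
})

test_that("RFT threshold controls the FWER in Gaussian null simulation", {
  set.seed(5)
  nrep <- 500
  rej <- 0
  for (s in seq_len(nrep)) {
    y <- smooth_gaussian_curves(30, 101, 15)
    tc <- t_curve_two_sample(y[1:15, ], y[16:30, ])
    thr <- rft_threshold(tc$df, residuals = tc$residuals, alpha = 0.05)
    if (max(abs(tc$t)) > thr) rej <- rej + 1
  }
  expect_gte(rej / nrep, 0.03)
  expect_lte(rej / nrep, 0.07)
})

test_that("estimated FWHM tracks the generating smoothness", {
  set.seed(30)
  for (f in c(8, 15, 25)) {
    est <- mean(vapply(1:20, function(i) {
      estimate_fwhm(smooth_gaussian_curves(20, 101, f))
    }, 0))
    expect_equal(est, f, tolerance = 0.2)
  }
})

test_that("paired SnPM with n = 5 enumerates all 32 sign flips exactly", {
  set.seed(17)
  y1 <- smooth_gaussian_curves(5, 21, 5) + 0.8
  y2 <- smooth_gaussian_curves(5, 21, 5)
  sn <- snpm_threshold(y1, y2, paired = TRUE, n_perm = 10000)
  expect_true(sn$exhaustive)
  expect_equal(sn$n_perm, 32L)
  ref <- enum_signflip_max_t(y1 - y2)
  expect_equal(sort(sn$perm_max), sort(ref), tolerance = 1e-10)
  expect_equal(sn$threshold, sort(ref)[ceiling(0.95 * 32)],
               tolerance = 1e-10)
})

test_that("SnPM is deterministic under a fixed seed", {
  set.seed(3)
  y1 <- smooth_gaussian_curves(12, 101, 15)
  y2 <- smooth_gaussian_curves(18, 101, 15)
  a <- snpm_threshold(y1, y2, n_perm = 500, seed = 42)
  b <- snpm_threshold(y1, y2, n_perm = 500, seed = 42)
  expect_identical(a$threshold, b$threshold)
  expect_identical(a$perm_max, b$perm_max)
  expect_error(snpm_threshold(y1[1:2, ], y2[1:2, ], paired = TRUE),
               "fewer than 20")
})

test_that("cluster endpoints are linearly interpolated to 2 decimals", {
  q <- 101
  pct <- seq(0, 100)
  t_curve <- rep(0, q)
  # triangular curve crossing exactly at nodes 40% and 60%
  t_curve[41:61] <- 2 + 1.5 * (1 - abs(seq(-1, 1, length.out = 21)))
  t_curve[41] <- 2; t_curve[61] <- 2
  cl <- spm_clusters(t_curve, threshold = 2, percent = pct)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$start_pct, 40.00)
  expect_equal(cl$end_pct, 60.00)
  # hand interpolation: 1.9 at 40%, 2.1 at 41%, threshold 2 -> 40.50
  t2 <- rep(0, q)
  t2[41] <- 1.9
  t2[42:50] <- 2.1
  t2[51] <- 1.9
  cl2 <- spm_clusters(t2, threshold = 2, percent = pct)
  expect_equal(cl2$start_pct, 40.50)
  expect_equal(cl2$end_pct, 49.50)
  # below threshold everywhere -> empty
  expect_equal(nrow(spm_clusters(rep(1, q), 2, pct)), 0L)
})

test_that("cluster sets mirror when the curve is node-reversed", {
  set.seed(23)
  y1 <- smooth_gaussian_curves(10, 101, 12) +
    matrix(2 * exp(-((0:100) - 30)^2 / 100), 10, 101, byrow = TRUE)
  y2 <- smooth_gaussian_curves(10, 101, 12)
  tc <- t_curve_two_sample(y1, y2)
  cl <- spm_clusters(tc$t, 3, seq(0, 100))
  clr <- spm_clusters(rev(tc$t), 3, seq(0, 100))
  expect_equal(nrow(cl), nrow(clr))
  if (nrow(cl)) {
    expect_equal(sort(100 - clr$end_pct), sort(cl$start_pct),
                 tolerance = 1e-9)
    expect_equal(sort(100 - clr$start_pct), sort(cl$end_pct),
                 tolerance = 1e-9)
  }
})

test_that("spm_compare end-to-end: detects a known effect, none under null", {
  set.seed(41)
  eff <- matrix(3 * exp(-((0:100) - 50)^2 / 200), 14, 101, byrow = TRUE)
  y1 <- smooth_gaussian_curves(14, 101, 15) + eff
  y2 <- smooth_gaussian_curves(14, 101, 15)
  res <- spm_compare(y1, y2, method = "SnPM", n_perm = 1000, seed = 2)
  expect_s3_class(res, "spm1d_result")
  expect_gt(nrow(res$clusters), 0)
  expect_true(any(res$clusters$start_pct < 50 & res$clusters$end_pct > 50))
  expect_true(all(res$clusters$p <= res$alpha))
  # identical groups -> no clusters (both methods)
  base <- smooth_gaussian_curves(14, 101, 15)
  for (m in c("SPM", "SnPM")) {
    r0 <- spm_compare(base + 0.001 * matrix(stats::rnorm(14 * 101), 14),
                      base, method = m, n_perm = 200, seed = 1)
    expect_equal(nrow(r0$clusters), 0)
  }
  expect_error(spm_compare(y1, y2, alpha = 1.2), "alpha")
  # serialization round-trip
  path <- withr::local_tempfile(fileext = ".json")
  write_spm_result(res, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$threshold, res$threshold, tolerance = 1e-9)
  expect_equal(nrow(back$clusters), nrow(res$clusters))
})

test_that("t curves are invariant to common affine rescaling", {
  set.seed(51)
  y1 <- smooth_gaussian_curves(8, 41, 10) + 2
  y2 <- smooth_gaussian_curves(8, 41, 10)
  t0 <- t_curve_two_sample(y1, y2)$t
  t1 <- t_curve_two_sample(3 * y1 + 7, 3 * y2 + 7)$t
  expect_equal(t1, t0, tolerance = 1e-9)
  # paired: adding a subject-level constant changes nothing
  cvec <- stats::rnorm(8, sd = 10)
  tp0 <- t_curve_paired(y1, y2)$t
  tp1 <- t_curve_paired(y1 + cvec, y2 + cvec)$t
  expect_equal(tp1, tp0, tolerance = 1e-9)
})
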