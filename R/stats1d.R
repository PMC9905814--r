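#' Pointwise two-sample t curve
#'
#' Pooled-variance independent-samples t statistic at each gait-cycle
#' node; df = n1 + n2 - 2. Nodes with zero pooled variance yield NaN and
#' are flagged.
#'
#' @param y1,y2 subjects x nodes matrices (equal node counts).
#' @return List: \code{t} (length-Q), \code{df}, \code{zero_variance}
#'   (logical per node), \code{residuals} (group-centred, stacked).
#' @export
t_curve_two_sample <- function(y1, y2) {
  y1 <- as.matrix(y1); y2 <- as.matrix(y2)
  if (ncol(y1) != ncol(y2)) stop("node counts differ", call. = FALSE)
  n1 <- nrow(y1); n2 <- nrow(y2)
  if (n1 < 2L || n2 < 2L) stop("each group needs n >= 2", call. = FALSE)
  m1 <- colMeans(y1); m2 <- colMeans(y2)
  ss1 <- colSums(sweep(y1, 2, m1)^2)
  ss2 <- colSums(sweep(y2, 2, m2)^2)
  df <- n1 + n2 - 2
  sp2 <- (ss1 + ss2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  zero <- se == 0
  tval <- (m1 - m2) / se
  tval[zero & m1 == m2] <- 0
  list(t = tval, df = df, zero_variance = zero,
       residuals = rbind(sweep(y1, 2, m1), sweep(y2, 2, m2)))
}

#' Pointwise paired t curve
#'
#' Nodewise paired-samples t statistic (equivalently a one-sample t on
#' the row-wise differences); df = n - 1.
#'
#' @param y1,y2 matched subjects x nodes matrices (same row order).
#' @return Same structure as \code{\link{t_curve_two_sample}}.
#' @export
t_curve_paired <- function(y1, y2) {
  y1 <- as.matrix(y1); y2 <- as.matrix(y2)
  if (!all(dim(y1) == dim(y2))) {
    stop("paired groups must have matching dimensions", call. = FALSE)
  }
  n <- nrow(y1)
  if (n < 2L) stop("need n >= 2 pairs", call. = FALSE)
  d <- y1 - y2
  md <- colMeans(d)
  sdd <- sqrt(colSums(sweep(d, 2, md)^2) / (n - 1))
  se <- sdd / sqrt(n)
  zero <- se == 0
  tval <- md / se
  tval[zero & md == 0] <- 0
  list(t = tval, df = n - 1, zero_variance = zero,
       residuals = sweep(d, 2, md))
}

#' D'Agostino-Pearson K-squared normality test
#'
#' Omnibus test combining the transformed sample skewness and kurtosis
#' z-scores: K2 = Z1(skew)^2 + Z2(kurt)^2 ~ chi-squared(2) under
#' normality. Requires n >= 8.
#'
#' @param x numeric sample.
#' @return List: \code{statistic}, \code{p_value}.
#' @export
dagostino_k2 <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 8L) stop("K2 test needs n >= 8", call. = FALSE)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  m3 <- mean((x - m)^3)
  m4 <- mean((x - m)^4)
  g1 <- m3 / m2^1.5
  b2 <- m4 / m2^2
  # skewness z (D'Agostino 1970 transform)
  y <- g1 * sqrt(((n + 1) * (n + 3)) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(0.5 * log(w2))
  a <- sqrt(2 / (w2 - 1))
  z1 <- delta * log(y / a + sqrt((y / a)^2 + 1))
  # kurtosis z (Anscombe & Glynn 1983 transform)
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (b2 - eb2) / sqrt(vb2)
  sb <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  aa <- 6 + 8 / sb * (2 / sb + sqrt(1 + 4 / sb^2))
  z2 <- ((1 - 2 / (9 * aa)) -
           ((1 - 2 / aa) / (1 + xk * sqrt(2 / (aa - 4))))^(1 / 3)) /
    sqrt(2 / (9 * aa))
  k2 <- z1^2 + z2^2
  list(statistic = k2, p_value = stats::pchisq(k2, 2, lower.tail = FALSE))
}

#' Choose SPM or SnPM by a nodewise normality gate
#'
#' Runs the D'Agostino-Pearson K2 test on the model residuals at every
#' node; the parametric SPM path is used only when no node rejects
#' normality. The per-node level is Sidak-corrected for the number of
#' nodes, so that under normality the gate selects SPM with probability
#' of about 1 - alpha regardless of Q. Samples too small for the K2 test
#' (n < 8) default to SnPM with a warning.
#'
#' @param y1,y2 subjects x nodes matrices.
#' @param paired logical.
#' @param alpha family-wise gate level (default 0.05).
#' @return List: \code{method} ("SPM" or "SnPM"), \code{min_p},
#'   \code{alpha_node}.
#' @export
normality_gate <- function(y1, y2, paired = FALSE, alpha = 0.05) {
  res <- if (paired) t_curve_paired(y1, y2)$residuals else
    t_curve_two_sample(y1, y2)$residuals
  q <- ncol(res)
  if (nrow(res) < 8L) {
    warning("sample too small for the K2 normality test; using SnPM")
    return(list(method = "SnPM", min_p = NA_real_, alpha_node = NA_real_))
  }
  alpha_node <- 1 - (1 - alpha)^(1 / q)
  pv <- vapply(seq_len(q), function(j) {
    r <- res[, j]
    if (stats::sd(r) == 0) return(1)
    dagostino_k2(r)$p_value
  }, 0)
  method <- if (any(pv < alpha_node)) "SnPM" else "SPM"
  list(method = method, min_p = min(pv), alpha_node = alpha_node)
}

#' Field smoothness (FWHM) from residuals
#'
#' Estimates the smoothness of the residual field in nodes, from the
#' gradients of the variance-normalized residuals, for the
#' random-field-theory threshold.
#'
#' @param residuals observations x nodes matrix.
#' @return FWHM in node units (Inf for perfectly smooth residuals).
#' @export
estimate_fwhm <- function(residuals) {
  r <- as.matrix(residuals)
  q <- ncol(r)
  ssq <- colSums(r^2)
  if (all(ssq == 0)) return(Inf)
  # central-difference gradient along nodes, one-sided at the ends
  g <- r
  g[, 2:(q - 1)] <- (r[, 3:q] - r[, 1:(q - 2)]) / 2
  g[, 1] <- r[, 2] - r[, 1]
  g[, q] <- r[, q] - r[, q - 1]
  v <- colSums(g^2) / (ssq + .Machine$double.eps)
  rpn <- sqrt(v / (4 * log(2)))   # resels per node
  if (mean(rpn) == 0) return(Inf)
  1 / mean(rpn)
}

# 1D Euler-characteristic density for a t field at height u.
ec1_t <- function(u, df) {
  sqrt(4 * log(2)) / (2 * pi) * (1 + u^2 / df)^(-(df - 1) / 2)
}

# Tail of P(max |T| > u) under the EC approximation (two-sided when
# two_sided, via doubling).
rft_tail <- function(u, df, resels, two_sided = TRUE) {
  p <- stats::pt(u, df, lower.tail = FALSE) + resels * ec1_t(u, df)
  min(1, if (two_sided) 2 * p else p)
}

#' Random-field-theory critical threshold for a 1D t field
#'
#' Solves P(max T > t*) = alpha with the one-dimensional
#' Euler-characteristic approximation for t fields,
#' P ~ P(T > u) + (L / FWHM) (sqrt(4 ln 2) / 2 pi)
#' (1 + u^2 / df)^(-(df - 1) / 2), where L = Q - 1 node intervals and the
#' FWHM is estimated from the residuals. Thresholds are two-sided by
#' default (the tail is doubled), matching direction-agnostic p-values.
#'
#' @param df degrees of freedom.
#' @param residuals observations x nodes residual matrix (used to
#'   estimate FWHM), or NULL if \code{fwhm} is given.
#' @param q node count (default taken from residuals).
#' @param alpha test level (default 0.05).
#' @param fwhm override smoothness in nodes.
#' @param two_sided double the tail (default TRUE).
#' @return Critical t*.
#' @export
rft_threshold <- function(df, residuals = NULL, q = NULL, alpha = 0.05,
                          fwhm = NULL, two_sided = TRUE) {
  if (is.null(fwhm)) {
    if (is.null(residuals)) stop("need residuals or fwhm", call. = FALSE)
    fwhm <- estimate_fwhm(residuals)
    if (is.null(q)) q <- ncol(residuals)
  }
  if (is.null(q)) stop("need node count q", call. = FALSE)
  if (!is.finite(fwhm) || fwhm <= 0) {
    if (is.infinite(fwhm)) {
      return(stats::qt(1 - if (two_sided) alpha / 2 else alpha, df))
    }
    stop("non-finite FWHM estimate", call. = FALSE)
  }
  resels <- (q - 1) / fwhm
  f <- function(u) rft_tail(u, df, resels, two_sided) - alpha
  stats::uniroot(f, c(stats::qt(1 - alpha, df) * 0.5, 100),
                 tol = 1e-10)$root
}

# Permutation max-|t| distribution. Returns list(max_t, exhaustive, B).
# Row 1 of the permutation scheme is always the identity labelling.
perm_max_t <- function(y1, y2, paired, n_perm, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (paired) {
    d <- as.matrix(y1) - as.matrix(y2)
    n <- nrow(d)
    n_distinct <- 2^n
    if (n_distinct < 20) {
      stop("fewer than 20 distinct permutations: alpha = 0.05 unreachable",
           call. = FALSE)
    }
    exhaustive <- n_distinct <= n_perm
    S <- if (exhaustive) {
      as.matrix(expand.grid(rep(list(c(1, -1)), n)))
    } else {
      rbind(rep(1, n),
            matrix(sample(c(1, -1), (n_perm - 1) * n, replace = TRUE),
                   n_perm - 1, n))
    }
    B <- nrow(S)
    ms <- (S %*% d) / n
    ssd <- matrix(colSums(d^2), B, ncol(d), byrow = TRUE)
    vs <- (ssd - n * ms^2) / (n - 1)
    tm <- ms / sqrt(vs / n)
    tm[!is.finite(tm)] <- 0
  } else {
    y <- rbind(as.matrix(y1), as.matrix(y2))
    n1 <- nrow(y1); n2 <- nrow(y2); n <- n1 + n2
    n_distinct <- choose(n, n1)
    if (n_distinct < 20) {
      stop("fewer than 20 distinct permutations: alpha = 0.05 unreachable",
           call. = FALSE)
    }
    exhaustive <- n_distinct <= n_perm
    G <- if (exhaustive) {
      combos <- utils::combn(n, n1)
      t(apply(combos, 2, function(ix) {
        g <- rep(0, n); g[ix] <- 1; g
      }))
    } else {
      rbind(c(rep(1, n1), rep(0, n2)),
            t(vapply(seq_len(n_perm - 1), function(i) {
              g <- rep(0, n); g[sample.int(n, n1)] <- 1; g
            }, numeric(n))))
    }
    if (exhaustive) {
      # put the identity labelling first
      id <- c(rep(1, n1), rep(0, n2))
      k <- which(apply(G, 1, function(g) all(g == id)))[1]
      G <- rbind(G[k, , drop = FALSE], G[-k, , drop = FALSE])
    }
    B <- nrow(G)
    S <- colSums(y); SS <- colSums(y^2)
    S1 <- G %*% y; SS1 <- G %*% y^2
    m1 <- S1 / n1
    m2 <- sweep(-S1, 2, S, "+") / n2
    ss1 <- SS1 - n1 * m1^2
    ss2 <- sweep(-SS1, 2, SS, "+") - n2 * m2^2
    sp2 <- (ss1 + ss2) / (n1 + n2 - 2)
    tm <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    tm[!is.finite(tm)] <- 0
  }
  list(max_t = apply(abs(tm), 1, max), exhaustive = exhaustive, B = B)
}

#' SnPM critical threshold by max-statistic permutation
#'
#' The critical t* is the (1 - alpha) empirical quantile of the
#' max-over-nodes |t| statistic across group-label permutations
#' (independent design) or pair sign-flips (paired design). Permutations
#' are enumerated exhaustively when the design admits no more than
#' \code{n_perm} distinct relabellings; otherwise \code{n_perm} random
#' relabellings (always including the observed one) are used.
#'
#' @param y1,y2 subjects x nodes matrices.
#' @param paired logical design flag.
#' @param alpha test level (default 0.05).
#' @param n_perm permutation budget (default 10000).
#' @param seed RNG seed for non-exhaustive sampling.
#' @return List: \code{threshold}, \code{perm_max} (max-|t| distribution),
#'   \code{exhaustive}, \code{n_perm}.
#' @export
snpm_threshold <- function(y1, y2, paired = FALSE, alpha = 0.05,
                           n_perm = 10000, seed = NULL) {
  pm <- perm_max_t(y1, y2, paired, n_perm, seed)
  srt <- sort(pm$max_t)
  k <- ceiling((1 - alpha) * pm$B)
  list(threshold = srt[k], perm_max = pm$max_t,
       exhaustive = pm$exhaustive, n_perm = pm$B)
}

#' Supra-threshold clusters with interpolated endpoints
#'
#' Maximal runs of nodes where |t| exceeds the critical threshold.
#' Cluster endpoints are linearly interpolated between the bracketing
#' nodes (reported as percent of the gait cycle, rounded to 2 decimals).
#' Cluster p-values: under SnPM, the fraction of the permutation max-|t|
#' distribution at or above the cluster maximum; under SPM, the
#' Euler-characteristic tail evaluated at the cluster maximum.
#'
#' @param t_curve numeric t statistic series.
#' @param threshold critical t*.
#' @param percent node percentages (default 0..100 equally spaced).
#' @param perm_max permutation max-|t| distribution (SnPM p-values).
#' @param df,fwhm t-field parameters (SPM p-values).
#' @param two_sided cluster on |t| (default TRUE).
#' @return data.frame: start_pct, end_pct, max_t, p.
#' @export
spm_clusters <- function(t_curve, threshold, percent = NULL,
                         perm_max = NULL, df = NULL, fwhm = NULL,
                         two_sided = TRUE) {
  stopifnot(is.finite(threshold))
  q <- length(t_curve)
  if (is.null(percent)) percent <- seq(0, 100, length.out = q)
  tt <- if (two_sided) abs(t_curve) else t_curve
  above <- tt > threshold
  if (!any(above)) {
    return(data.frame(start_pct = numeric(0), end_pct = numeric(0),
                      max_t = numeric(0), p = numeric(0)))
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- lapply(which(r$values), function(k) {
    i0 <- starts[k]; i1 <- ends[k]
    sp <- if (i0 == 1L) percent[1] else {
      fr <- (threshold - tt[i0 - 1]) / (tt[i0] - tt[i0 - 1])
      percent[i0 - 1] + fr * (percent[i0] - percent[i0 - 1])
    }
    ep <- if (i1 == q) percent[q] else {
      fr <- (tt[i1] - threshold) / (tt[i1] - tt[i1 + 1])
      percent[i1] + fr * (percent[i1 + 1] - percent[i1])
    }
    mx <- max(tt[i0:i1])
    p <- if (!is.null(perm_max)) {
      mean(perm_max >= mx)
    } else if (!is.null(df) && !is.null(fwhm)) {
      resels <- if (is.finite(fwhm)) (q - 1) / fwhm else 0
      rft_tail(mx, df, resels, two_sided)
    } else NA_real_
    data.frame(start_pct = round(sp, 2), end_pct = round(ep, 2),
               max_t = mx, p = p)
  })
  do.call(rbind, out)
}

#' Compare two groups of gait-normalized curves (SPM/SnPM)
#'
#' Full one-dimensional inference on waveform samples: pointwise t curve
#' (independent or paired), method selection by the normality gate (or
#' forced), field-wise critical threshold at the chosen level
#' (random-field theory for SPM, max-statistic permutation for SnPM),
#' and supra-threshold clusters with interpolated endpoints and
#' p-values. Tests are two-sided on |t|; the signed t curve is kept for
#' plotting.
#'
#' @param y1,y2 subjects x nodes matrices (same node count; same subject
#'   order when paired).
#' @param paired paired design (default FALSE: independent groups).
#' @param alpha test level in (0, 1) (default 0.05).
#' @param method "auto" (normality gate), "SPM" or "SnPM".
#' @param n_perm permutation budget for SnPM (default 10000).
#' @param seed RNG seed for SnPM sampling.
#' @return Object of class \code{spm1d_result}: \code{t_curve},
#'   \code{df}, \code{threshold}, \code{clusters}, \code{method},
#'   \code{alpha}, \code{fwhm}, \code{n_perm}, \code{seed},
#'   \code{percent}.
#' @export
spm_compare <- function(y1, y2, paired = FALSE, alpha = 0.05,
                        method = c("auto", "SPM", "SnPM"),
                        n_perm = 10000, seed = NULL) {
  method <- match.arg(method)
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1) {
    stop("alpha must be in (0, 1)", call. = FALSE)
  }
  tc <- if (paired) t_curve_paired(y1, y2) else t_curve_two_sample(y1, y2)
  if (method == "auto") {
    method <- normality_gate(y1, y2, paired, alpha)$method
  }
  fwhm <- estimate_fwhm(tc$residuals)
  percent <- seq(0, 100, length.out = length(tc$t))
  if (method == "SPM") {
    thr <- rft_threshold(tc$df, q = length(tc$t), alpha = alpha,
                         fwhm = fwhm)
    cl <- spm_clusters(tc$t, thr, percent, df = tc$df, fwhm = fwhm)
    pm <- NULL
    nb <- NA_integer_
  } else {
    sn <- snpm_threshold(y1, y2, paired, alpha, n_perm, seed)
    thr <- sn$threshold
    cl <- spm_clusters(tc$t, thr, percent, perm_max = sn$perm_max)
    pm <- sn$perm_max
    nb <- sn$n_perm
  }
  structure(list(t_curve = tc$t, df = tc$df, threshold = thr,
                 clusters = cl, method = method, alpha = alpha,
                 fwhm = fwhm, n_perm = nb, seed = seed,
                 percent = percent, perm_max = pm),
            class = "spm1d_result")
}

#' @export
print.spm1d_result <- function(x, ...) {
  cat(sprintf("%s{t}: df = %g, alpha = %g, critical |t*| = %.3f\n",
              x$method, x$df, x$alpha, x$threshold))
  if (nrow(x$clusters) == 0) {
    cat("  no supra-threshold clusters\n")
  } else {
    for (i in seq_len(nrow(x$clusters))) {
      cat(sprintf("  cluster %d: %.2f%%-%.2f%% of the gait cycle (p = %.3f)\n",
                  i, x$clusters$start_pct[i], x$clusters$end_pct[i],
                  x$clusters$p[i]))
    }
  }
  invisible(x)
}

#' Serialize an SPM/SnPM result
#'
#' JSON with the t curve, threshold, clusters, method, alpha and seed;
#' optionally a CSV of the t curve.
#'
#' @param result an \code{spm1d_result}.
#' @param path JSON output path.
#' @param csv_path optional CSV path (percent, t).
#' @export
write_spm_result <- function(result, path, csv_path = NULL) {
  obj <- list(method = result$method, alpha = result$alpha,
              df = result$df, threshold = result$threshold,
              fwhm = result$fwhm, n_perm = result$n_perm,
              seed = result$seed, percent = result$percent,
              t_curve = result$t_curve, clusters = result$clusters)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  if (!is.null(csv_path)) {
    utils::write.csv(data.frame(percent = result$percent,
                                t = result$t_curve),
                     csv_path, row.names = FALSE)
  }
  invisible(path)
}

#' Empirical family-wise error rate of the SnPM threshold under the null
#'
#' Monte-Carlo calibration: simulates datasets of two groups drawn from
#' the same smooth Gaussian curve distribution, runs the SnPM
#' max-statistic test on each, and reports the fraction with any
#' supra-threshold cluster.
#'
#' @param n_sim number of simulated datasets.
#' @param n1,n2 group sizes.
#' @param q nodes per curve (default 101).
#' @param fwhm smoothness of the simulated curves in nodes (default 15).
#' @param alpha test level (default 0.05).
#' @param n_perm permutations per dataset (default 1000).
#' @param seed RNG seed.
#' @return List: \code{fwer}, \code{n_sim}, \code{rejections}.
#' @export
snpm_fwer_null <- function(n_sim, n1, n2, q = 101, fwhm = 15,
                           alpha = 0.05, n_perm = 1000, seed = 1) {
  set.seed(seed)
  rej <- logical(n_sim)
  for (s in seq_len(n_sim)) {
    y <- smooth_gaussian_curves(n1 + n2, q, fwhm)
    y1 <- y[seq_len(n1), , drop = FALSE]
    y2 <- y[n1 + seq_len(n2), , drop = FALSE]
    sn <- snpm_threshold(y1, y2, paired = FALSE, alpha = alpha,
                         n_perm = n_perm)
    obs <- max(abs(t_curve_two_sample(y1, y2)$t))
    rej[s] <- obs > sn$threshold
  }
  list(fwer = mean(rej), n_sim = n_sim, rejections = sum(rej))
}

#' Smooth Gaussian random curves
#'
#' Zero-mean unit-variance Gaussian curves with approximately Gaussian
#' autocorrelation of the given FWHM (white noise convolved with a
#' Gaussian kernel, variance renormalized). The standard null model for
#' 1D random-field simulations.
#'
#' @param n number of curves.
#' @param q nodes per curve (default 101).
#' @param fwhm smoothness in nodes (default 15).
#' @return n x q matrix.
#' @export
smooth_gaussian_curves <- function(n, q = 101, fwhm = 15) {
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  half <- ceiling(3 * sigma)
  kern <- stats::dnorm(seq(-half, half), sd = sigma)
  kern <- kern / sqrt(sum(kern^2))   # unit output variance
  w <- matrix(stats::rnorm(n * (q + 2 * half)), n)
  out <- matrix(0, n, q)
  for (i in seq_len(n)) {
    out[i, ] <- stats::convolve(w[i, ], kern, type = "filter")
  }
  out
}
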