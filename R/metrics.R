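#' Root-mean-square trajectory error (mm)
#'
#' RMSE of the Euclidean distance between corresponding landmark
#' positions, pooled over frames and landmarks:
#' \code{sqrt(mean(||calc - ref||^2))}.
#'
#' @param calculated,reference frames x landmarks x 3 arrays (or N x 3
#'   matrices) in mm, same shape.
#' @param na.rm drop frames with missing values (default TRUE).
#' @return RMSE in mm.
#' @export
rmse_distance <- function(calculated, reference, na.rm = TRUE) {
  calculated <- as_traj_array(calculated)
  reference <- as_traj_array(reference)
  if (!all(dim(calculated) == dim(reference))) {
    stop("trajectory arrays must have the same shape", call. = FALSE)
  }
  err2 <- apply((calculated - reference)^2, c(1, 2), sum)
  sqrt(mean(err2, na.rm = na.rm))
}

as_traj_array <- function(x) {
  if (length(dim(x)) == 2L) {
    x <- array(as.matrix(x), c(nrow(x), 1, 3))
  }
  if (length(dim(x)) != 3L || dim(x)[3] != 3L) {
    stop("expected frames x landmarks x 3 trajectories", call. = FALSE)
  }
  x
}

#' Root-mean-square orientation error (degrees)
#'
#' RMSE of the geodesic misorientation between corresponding rotations:
#' \code{sqrt(mean(angle(est_i, ref_i)^2))} with angles from
#' \code{\link{rotation_angle_deg}}.
#'
#' @param estimated,reference lists of rotation matrices (or rigid
#'   transforms) of equal length.
#' @return RMSE in degrees.
#' @export
rmse_angle <- function(estimated, reference) {
  if (length(estimated) != length(reference)) {
    stop("rotation series must have equal length", call. = FALSE)
  }
  ang <- mapply(rotation_angle_deg, estimated, reference)
  sqrt(mean(ang^2))
}

#' Coefficient of multiple correlation for repeated waveforms
#'
#' Between-session waveform-similarity statistic used for gait-curve
#' reliability. With \code{G} repetitions of \code{F} frames,
#' \deqn{CMC = \sqrt{1 - \frac{\sum_g\sum_f (Y_{gf}-\bar Y_f)^2 / (F(G-1))}
#'   {\sum_g\sum_f (Y_{gf}-\bar Y)^2 / (FG-1)}}}
#' where \eqn{\bar Y_f} is the frame-wise mean and \eqn{\bar Y} the grand
#' mean. Values near 1 indicate near-identical repetitions; the statistic
#' is undefined (returned as 0 with \code{degenerate = TRUE}) when the
#' within-repetition variance ratio exceeds 1, e.g. for flat waveforms at
#' different levels.
#'
#' @param waveforms G x F matrix: repetitions in rows.
#' @return List: \code{cmc} in [0, 1], \code{degenerate} flag.
#' @export
cmc <- function(waveforms) {
  y <- as.matrix(waveforms)
  G <- nrow(y); F_ <- ncol(y)
  if (G < 2L) stop("CMC needs at least 2 repetitions", call. = FALSE)
  if (F_ < 2L) stop("CMC needs at least 2 frames", call. = FALSE)
  ybar_f <- colMeans(y)
  ybar <- mean(y)
  num <- sum(sweep(y, 2, ybar_f)^2) / (F_ * (G - 1))
  den <- sum((y - ybar)^2) / (F_ * G - 1)
  if (den <= 0 || num / den > 1) {
    return(list(cmc = 0, degenerate = TRUE))
  }
  list(cmc = sqrt(1 - num / den), degenerate = FALSE)
}

#' Linear fit method (LFM) validity of one waveform against another
#'
#' Ordinary least squares \code{test = a1 * reference + a0}; R-squared is
#' the squared Pearson correlation. Used to quantify agreement of a
#' computed trajectory with a gold-standard one.
#'
#' @param reference,test numeric waveforms of equal length (>= 3);
#'   reference must not be constant.
#' @return List: \code{a1} slope, \code{a0} intercept, \code{r2}.
#' @export
lfm <- function(reference, test) {
  if (length(reference) != length(test)) {
    stop("waveforms must have equal length", call. = FALSE)
  }
  if (length(reference) < 3L) stop("need at least 3 samples", call. = FALSE)
  if (stats::sd(reference) == 0) {
    stop("reference waveform is constant", call. = FALSE)
  }
  fit <- stats::lm.fit(cbind(1, reference), test)
  r <- stats::cor(reference, test)
  list(a1 = unname(fit$coefficients[2]), a0 = unname(fit$coefficients[1]),
       r2 = r^2)
}

#' Per-group error summary with pooled total
#'
#' For each group of per-frame scalar errors: mean, SD, normal-theory 95%
#' confidence interval of the mean (mean +/- 1.96 SD / sqrt(n)) and RMSE.
#' The "Total" row pools all frames of all groups (not an average of the
#' group statistics), so the pooled RMSE of equally sized groups with
#' RMSEs r_i equals sqrt(mean(r_i^2)).
#'
#' @param errors named list of numeric vectors (one per group, each with
#'   >= 1 frame).
#' @return data.frame with columns group, n, mean, sd, ci_lower,
#'   ci_upper, rmse; last row is "Total".
#' @export
summarize_groups <- function(errors) {
  if (!length(errors)) stop("no groups supplied", call. = FALSE)
  if (is.null(names(errors))) names(errors) <- seq_along(errors)
  one <- function(x, nm) {
    x <- as.numeric(x)
    if (!length(x)) stop("empty group '", nm, "'", call. = FALSE)
    m <- mean(x)
    s <- if (length(x) > 1) stats::sd(x) else 0
    half <- 1.96 * s / sqrt(length(x))
    data.frame(group = nm, n = length(x), mean = m, sd = s,
               ci_lower = m - half, ci_upper = m + half,
               rmse = sqrt(mean(x^2)))
  }
  rows <- Map(one, errors, names(errors))
  pooled <- one(unlist(errors, use.names = FALSE), "Total")
  out <- do.call(rbind, c(rows, list(pooled)))
  rownames(out) <- NULL
  out
}

#' Phantom validation report
#'
#' Bundles the validation arithmetic for a phantom run: per-group and
#' pooled distance (mm) and angle (degree) error summaries, per-axis CMC
#' reliability between two sessions, per-axis linear-fit validity against
#' the gold standard, and pooled trajectory RMSE.
#'
#' @param dist_errors named list of per-frame distance errors (mm) per
#'   landmark group.
#' @param angle_errors named list of per-frame angle errors (degrees) per
#'   group (optional).
#' @param day1,day2 optional frames x landmarks x 3 trajectory arrays
#'   from two sessions (between-day reliability; CMC per axis).
#' @param calculated,reference optional trajectory arrays for validity
#'   (LFM R-squared per axis + pooled RMSE).
#' @return List of class \code{validation_report} with elements
#'   \code{distance}, \code{angle} (summary tables),
#'   \code{reliability} (per-axis CMC + degenerate flags, trajectory
#'   RMSE), \code{validity} (per-axis a1/a0/R2, trajectory RMSE).
#' @export
validation_report <- function(dist_errors, angle_errors = NULL,
                              day1 = NULL, day2 = NULL,
                              calculated = NULL, reference = NULL) {
  rep_ <- list(distance = summarize_groups(dist_errors))
  if (!is.null(angle_errors)) rep_$angle <- summarize_groups(angle_errors)
  axes <- c("x", "y", "z")
  if (!is.null(day1) && !is.null(day2)) {
    day1 <- as_traj_array(day1); day2 <- as_traj_array(day2)
    per_axis <- lapply(1:3, function(ax) {
      cmc(rbind(as.vector(day1[, , ax]), as.vector(day2[, , ax])))
    })
    rep_$reliability <- list(
      cmc = stats::setNames(vapply(per_axis, `[[`, 0, "cmc"), axes),
      degenerate = stats::setNames(vapply(per_axis, `[[`, TRUE,
                                          "degenerate"), axes),
      rmse_mm = rmse_distance(day1, day2))
  }
  if (!is.null(calculated) && !is.null(reference)) {
    calculated <- as_traj_array(calculated)
    reference <- as_traj_array(reference)
    per_axis <- lapply(1:3, function(ax) {
      lfm(as.vector(reference[, , ax]), as.vector(calculated[, , ax]))
    })
    rep_$validity <- list(
      r2 = stats::setNames(vapply(per_axis, `[[`, 0, "r2"), axes),
      a1 = stats::setNames(vapply(per_axis, `[[`, 0, "a1"), axes),
      a0 = stats::setNames(vapply(per_axis, `[[`, 0, "a0"), axes),
      rmse_mm = rmse_distance(calculated, reference))
  }
  structure(rep_, class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Validation report\n-- distance error (mm)\n")
  print(x$distance, digits = 4)
  if (!is.null(x$angle)) {
    cat("-- angle error (deg)\n")
    print(x$angle, digits = 4)
  }
  if (!is.null(x$reliability)) {
    cat(sprintf("-- reliability: CMC x/y/z = %s; RMSE %.4g mm\n",
                paste(round(x$reliability$cmc, 4), collapse = "/"),
                x$reliability$rmse_mm))
  }
  if (!is.null(x$validity)) {
    cat(sprintf("-- validity: R2 x/y/z = %s; RMSE %.4g mm\n",
                paste(round(x$validity$r2, 4), collapse = "/"),
                x$validity$rmse_mm))
  }
  invisible(x)
}

#' Serialize a validation report to JSON
#' @param report a \code{validation_report}.
#' @param path output path.
#' @export
write_validation_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  invisible(path)
}
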