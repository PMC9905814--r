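#' Rigid transform (rotation + translation)
#'
#' A rigid body transform mapping imaging-frame coordinates to lab-frame
#' coordinates: \code{B = R A + t}, with \code{R} a proper 3x3 rotation
#' matrix and \code{t} a translation in mm.
#'
#' @param rotation 3x3 proper orthogonal matrix.
#' @param translation numeric length-3 vector (mm).
#' @param validate check orthonormality and determinant (default TRUE).
#' @return An object of class \code{rigid_transform} with elements
#'   \code{rotation} and \code{translation}.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0),
                            validate = TRUE) {
  rotation <- matrix(as.numeric(rotation), 3, 3)
  translation <- as.numeric(translation)
  if (length(translation) != 3L) {
    stop("translation must have length 3", call. = FALSE)
  }
  if (validate) {
    if (any(!is.finite(rotation)) || any(!is.finite(translation))) {
      stop("rigid_transform: non-finite entries", call. = FALSE)
    }
    if (max(abs(crossprod(rotation) - diag(3))) > 1e-9) {
      stop("rotation is not orthonormal (R'R != I)", call. = FALSE)
    }
    if (abs(det(rotation) - 1) > 1e-9) {
      stop("rotation is not proper (det != +1)", call. = FALSE)
    }
  }
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("Rigid transform\n  rotation:\n")
  print(round(x$rotation, 6))
  cat("  translation (mm):", paste(round(x$translation, 6), collapse = ", "),
      "\n")
  invisible(x)
}

#' Landmark correspondence between imaging and lab frames
#'
#' Paired point sets defining a rigid registration problem: \code{source}
#' are landmark coordinates in the imaging (neutral) frame, \code{target}
#' the same physical landmarks observed in the lab frame, both in mm and
#' in the same row order.
#'
#' @param source N x 3 numeric matrix (imaging frame, mm).
#' @param target N x 3 numeric matrix (lab frame, mm).
#' @return An object of class \code{landmark_correspondence}.
#' @export
landmark_correspondence <- function(source, target) {
  source <- as_points3(source, "source")
  target <- as_points3(target, "target")
  if (nrow(source) != nrow(target)) {
    stop("source and target must have the same number of points",
         call. = FALSE)
  }
  if (nrow(source) < 3L) {
    stop("at least 3 point pairs are required", call. = FALSE)
  }
  if (any(!is.finite(source)) || any(!is.finite(target))) {
    stop("landmark coordinates must be finite", call. = FALSE)
  }
  if (is_collinear(source)) {
    stop("source points are collinear: rotation is under-determined",
         call. = FALSE)
  }
  structure(list(source = source, target = target,
                 n_points = nrow(source)),
            class = "landmark_correspondence")
}

as_points3 <- function(x, what = "points") {
  x <- as.matrix(x)
  if (is.null(dim(x)) || ncol(x) != 3L) {
    stop(sprintf("%s must be an N x 3 matrix", what), call. = FALSE)
  }
  storage.mode(x) <- "double"
  x
}

# Collinearity test: ratio of 2nd to 1st singular value of the centred set.
is_collinear <- function(pts, tol = 1e-6) {
  pc <- sweep(pts, 2, colMeans(pts))
  s <- svd(pc, nu = 0, nv = 0)$d
  s[1] == 0 || (s[2] / s[1]) < tol
}

#' Estimate the rigid transform aligning corresponded point sets
#'
#' Closed-form least-squares rigid registration (Kabsch/SVD). Centroids of
#' the two sets are removed, the 3x3 cross-covariance \code{H = P' Q''} is
#' decomposed by SVD, and the rotation is \code{R = V U'} with the
#' determinant correction that guarantees a proper rotation (the column of
#' \code{V} paired with the smallest singular value is negated when
#' \code{det(V U') < 0}). The translation is \code{t = -R muP + muQ}.
#' The result minimizes \code{sum ||R p_i + t - q_i||^2} over proper
#' rotations.
#'
#' @param corr a \code{\link{landmark_correspondence}}, or an N x 3 source
#'   matrix if \code{target} is given.
#' @param target optional N x 3 target matrix (alternative calling form).
#' @return A \code{\link{rigid_transform}} with an extra attribute
#'   \code{residual_rms}, the root-mean-square residual in mm.
#' @export
estimate_rigid_transform <- function(corr, target = NULL) {
  if (!inherits(corr, "landmark_correspondence")) {
    corr <- landmark_correspondence(corr, target)
  }
  P <- corr$source
  Q <- corr$target
  muP <- colMeans(P)
  muQ <- colMeans(Q)
  Pc <- sweep(P, 2, muP)
  Qc <- sweep(Q, 2, muQ)
  H <- crossprod(Pc, Qc)          # 3x3 cross-covariance P' Q''
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d < 0) {
    sv$v[, 3] <- -sv$v[, 3]       # smallest singular value is last
  }
  R <- sv$v %*% t(sv$u)
  t <- as.numeric(-R %*% muP + muQ)
  tf <- rigid_transform(R, t, validate = FALSE)
  res <- apply_transform(tf, P) - Q
  attr(tf, "residual_rms") <- sqrt(mean(rowSums(res^2)))
  tf
}

#' Apply a rigid transform to a point set
#'
#' Computes \code{B = R A + t} for every row of \code{points}.
#'
#' @param tf a \code{\link{rigid_transform}}.
#' @param points N x 3 matrix (or length-3 vector) in mm.
#' @return N x 3 matrix of transformed points.
#' @export
apply_transform <- function(tf, points) {
  stopifnot(inherits(tf, "rigid_transform"))
  vec <- is.null(dim(points))
  if (vec) points <- matrix(points, 1, 3)
  points <- as_points3(points)
  out <- points %*% t(tf$rotation)
  out <- sweep(out, 2, tf$translation, "+")
  if (vec) out[1, ] else out
}

#' Compose and invert rigid transforms
#'
#' \code{compose_transforms(tf1, tf2)} is the transform equivalent to
#' applying \code{tf2} first, then \code{tf1}. \code{invert_transform(tf)}
#' satisfies \code{compose_transforms(tf, invert_transform(tf)) = identity}.
#'
#' @param tf1,tf2,tf rigid transforms.
#' @return A \code{\link{rigid_transform}}.
#' @export
compose_transforms <- function(tf1, tf2) {
  stopifnot(inherits(tf1, "rigid_transform"), inherits(tf2, "rigid_transform"))
  rigid_transform(tf1$rotation %*% tf2$rotation,
                  as.numeric(tf1$rotation %*% tf2$translation) +
                    tf1$translation,
                  validate = FALSE)
}

#' @rdname compose_transforms
#' @export
invert_transform <- function(tf) {
  stopifnot(inherits(tf, "rigid_transform"))
  Rt <- t(tf$rotation)
  rigid_transform(Rt, as.numeric(-Rt %*% tf$translation), validate = FALSE)
}

#' Geodesic misorientation between two rotations
#'
#' The rotation angle of \code{r1' r2}: \code{acos((trace(r1' r2) - 1)/2)}
#' in degrees, the canonical distance between two orientations, in
#' [0, 180].
#'
#' @param r1,r2 3x3 proper rotation matrices (or rigid transforms, whose
#'   rotation part is used).
#' @return Angle in degrees.
#' @export
rotation_angle_deg <- function(r1, r2 = diag(3)) {
  if (inherits(r1, "rigid_transform")) r1 <- r1$rotation
  if (inherits(r2, "rigid_transform")) r2 <- r2$rotation
  check_rotation(r1)
  check_rotation(r2)
  ctheta <- (sum(diag(crossprod(r1, r2))) - 1) / 2
  # acos((tr - 1)/2), computed through ||r1 - r2||_F = 2 sqrt(2) sin(th/2)
  # when the angle is small (acos loses ~8 digits near 0)
  if (ctheta > 0.5) {
    s <- sqrt(sum((r1 - r2)^2)) / (2 * sqrt(2))
    2 * asin(min(1, s)) * 180 / pi
  } else {
    acos(min(1, max(-1, ctheta))) * 180 / pi
  }
}

check_rotation <- function(R, tol = 1e-6) {
  R <- as.matrix(R)
  if (!all(dim(R) == c(3L, 3L)) ||
      max(abs(crossprod(R) - diag(3))) > tol || abs(det(R) - 1) > tol) {
    stop("input is not a proper 3x3 rotation matrix", call. = FALSE)
  }
  invisible(R)
}

#' Rotation about an axis
#'
#' Axis-angle rotation matrix (Rodrigues formula). Used by the phantom
#' generator and convenient for constructing test motions.
#'
#' @param axis length-3 axis (normalized internally; must be non-zero).
#' @param angle_deg rotation angle in degrees.
#' @return 3x3 rotation matrix.
#' @export
rotation_about_axis <- function(axis, angle_deg) {
  axis <- as.numeric(axis)
  n <- sqrt(sum(axis^2))
  if (n == 0) stop("rotation axis must be non-zero", call. = FALSE)
  u <- axis / n
  th <- angle_deg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Write / read per-frame transforms as CSV
#'
#' One row per frame: frame index, the nine rotation entries in row-major
#' order, and the three translation components in mm.
#'
#' @param transforms list of \code{\link{rigid_transform}} (NULL entries
#'   allowed for invalid frames; written as NA).
#' @param path output CSV path.
#' @export
write_transforms <- function(transforms, path) {
  rows <- lapply(seq_along(transforms), function(i) {
    tf <- transforms[[i]]
    if (is.null(tf)) return(c(i, rep(NA_real_, 12)))
    c(i, as.numeric(t(tf$rotation)), tf$translation)
  })
  m <- do.call(rbind, rows)
  colnames(m) <- c("frame", paste0("r", rep(1:3, each = 3), rep(1:3, 3)),
                   "tx", "ty", "tz")
  utils::write.csv(as.data.frame(m), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_transforms
#' @return \code{read_transforms}: a list of rigid transforms (NULL for
#'   frames stored as NA).
#' @export
read_transforms <- function(path) {
  df <- utils::read.csv(path)
  lapply(seq_len(nrow(df)), function(i) {
    v <- as.numeric(df[i, -1])
    if (any(is.na(v))) return(NULL)
    rigid_transform(matrix(v[1:9], 3, 3, byrow = TRUE), v[10:12])
  })
}
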