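# Closest point on triangles for a set of (point, triangle) pairs.
# P: n x 3 points; A, B, C: n x 3 matching triangle corners (one triangle
# per row). Returns list(dist, closest). Vectorized Ericson-style region
# classification.
closest_point_triangle <- function(P, A, B, C) {
  ab <- B - A; ac <- C - A; ap <- P - A
  d1 <- rowSums(ab * ap); d2 <- rowSums(ac * ap)
  n <- nrow(P)
  closest <- matrix(NA_real_, n, 3)
  done <- rep(FALSE, n)

  m <- !done & d1 <= 0 & d2 <= 0                     # vertex A
  closest[m, ] <- A[m, , drop = FALSE]; done <- done | m

  bp <- P - B
  d3 <- rowSums(ab * bp); d4 <- rowSums(ac * bp)
  m <- !done & d3 >= 0 & d4 <= d3                    # vertex B
  closest[m, ] <- B[m, , drop = FALSE]; done <- done | m

  vc <- d1 * d4 - d3 * d2
  m <- !done & vc <= 0 & d1 >= 0 & d3 <= 0           # edge AB
  if (any(m)) {
    t_ <- d1[m] / (d1[m] - d3[m])
    closest[m, ] <- A[m, , drop = FALSE] + t_ * ab[m, , drop = FALSE]
  }
  done <- done | m

  cp <- P - C
  d5 <- rowSums(ab * cp); d6 <- rowSums(ac * cp)
  m <- !done & d6 >= 0 & d5 <= d6                    # vertex C
  closest[m, ] <- C[m, , drop = FALSE]; done <- done | m

  vb <- d5 * d2 - d1 * d6
  m <- !done & vb <= 0 & d2 >= 0 & d6 <= 0           # edge AC
  if (any(m)) {
    t_ <- d2[m] / (d2[m] - d6[m])
    closest[m, ] <- A[m, , drop = FALSE] + t_ * ac[m, , drop = FALSE]
  }
  done <- done | m

  va <- d3 * d6 - d5 * d4
  m <- !done & va <= 0 & (d4 - d3) >= 0 & (d5 - d6) >= 0  # edge BC
  if (any(m)) {
    t_ <- (d4[m] - d3[m]) / ((d4[m] - d3[m]) + (d5[m] - d6[m]))
    closest[m, ] <- B[m, , drop = FALSE] +
      t_ * (C[m, , drop = FALSE] - B[m, , drop = FALSE])
  }
  done <- done | m

  if (any(!done)) {                                  # interior
    i <- !done
    denom <- 1 / (va[i] + vb[i] + vc[i])
    v <- vb[i] * denom; w <- vc[i] * denom
    closest[i, ] <- A[i, , drop = FALSE] + v * ab[i, , drop = FALSE] +
      w * ac[i, , drop = FALSE]
  }
  d <- sqrt(rowSums((P - closest)^2))
  list(dist = d, closest = closest)
}

# Faces whose three vertices all lie in the ROI index set.
roi_faces <- function(model, roi_name) {
  idx <- model$rois[[roi_name]]
  if (is.null(idx)) stop("unknown ROI '", roi_name, "'", call. = FALSE)
  f <- model$faces
  inroi <- matrix(f %in% idx, nrow(f), 3)
  f[rowSums(inroi) == 3L, , drop = FALSE]
}

# Minimum over points x triangle set, with conservative bounding-sphere
# pruning against an upper bound; exact (pruning only removes pairs whose
# lower bound exceeds a realized distance).
min_points_tris <- function(pts, V, faces, upper) {
  if (nrow(faces) == 0L || nrow(pts) == 0L) {
    return(list(dist = Inf, p = NULL, q = NULL))
  }
  A <- V[faces[, 1], , drop = FALSE]
  B <- V[faces[, 2], , drop = FALSE]
  C <- V[faces[, 3], , drop = FALSE]
  ctr <- (A + B + C) / 3
  rad <- sqrt(pmax(rowSums((A - ctr)^2), rowSums((B - ctr)^2),
                   rowSums((C - ctr)^2)))
  # pairwise lower bound: |p - centre| - radius
  d2 <- outer(rowSums(pts^2), rowSums(ctr^2), "+") -
    2 * tcrossprod(pts, ctr)
  lb <- sqrt(pmax(d2, 0)) - rep(rad, each = nrow(pts))
  keep <- which(lb <= upper + 1e-12)
  if (!length(keep)) return(list(dist = Inf, p = NULL, q = NULL))
  ip <- ((keep - 1) %% nrow(pts)) + 1
  it <- ((keep - 1) %/% nrow(pts)) + 1
  res <- closest_point_triangle(pts[ip, , drop = FALSE],
                                A[it, , drop = FALSE],
                                B[it, , drop = FALSE],
                                C[it, , drop = FALSE])
  k <- which.min(res$dist)
  list(dist = res$dist[k], p = pts[ip[k], ], q = res$closest[k, ])
}

# Segment-triangle intersection (Moller-Trumbore), vectorized over pairs.
# O, D: n x 3 segment origin and direction (D = end - origin);
# A, B, C: n x 3 triangles. Returns logical vector.
segments_hit_triangles <- function(O, D, A, B, C) {
  e1 <- B - A; e2 <- C - A
  pv <- cbind(D[, 2] * e2[, 3] - D[, 3] * e2[, 2],
              D[, 3] * e2[, 1] - D[, 1] * e2[, 3],
              D[, 1] * e2[, 2] - D[, 2] * e2[, 1])
  det <- rowSums(e1 * pv)
  ok <- abs(det) > 1e-14
  tv <- O - A
  u <- rowSums(tv * pv) / det
  qv <- cbind(tv[, 2] * e1[, 3] - tv[, 3] * e1[, 2],
              tv[, 3] * e1[, 1] - tv[, 1] * e1[, 3],
              tv[, 1] * e1[, 2] - tv[, 2] * e1[, 1])
  v <- rowSums(D * qv) / det
  t_ <- rowSums(e2 * qv) / det
  ok & u >= 0 & v >= 0 & (u + v) <= 1 & t_ >= 0 & t_ <= 1
}

# Do the two posed ROI surfaces intersect? Tests edges of the smaller
# face set against the other set's triangles (bounding-sphere pruned).
surfaces_intersect <- function(Va, Fa, Vb, Fb) {
  if (nrow(Fa) == 0L || nrow(Fb) == 0L) return(FALSE)
  edges <- unique(rbind(Fa[, 1:2, drop = FALSE], Fa[, 2:3, drop = FALSE],
                        Fa[, c(3, 1), drop = FALSE]))
  O <- Va[edges[, 1], , drop = FALSE]
  E <- Va[edges[, 2], , drop = FALSE]
  A <- Vb[Fb[, 1], , drop = FALSE]
  B <- Vb[Fb[, 2], , drop = FALSE]
  C <- Vb[Fb[, 3], , drop = FALSE]
  ne <- nrow(edges); nt <- nrow(Fb)
  ie <- rep(seq_len(ne), times = nt)
  it <- rep(seq_len(nt), each = ne)
  any(segments_hit_triangles(O[ie, , drop = FALSE],
                             E[ie, , drop = FALSE] - O[ie, , drop = FALSE],
                             A[it, , drop = FALSE], B[it, , drop = FALSE],
                             C[it, , drop = FALSE]))
}

#' Minimum distance between two posed cortical surfaces
#'
#' Shortest Euclidean distance between the posed region-of-interest
#' surfaces of two bone models, the geometric core of the ischiofemoral
#' space measurement. The ROI surface is the set of mesh faces whose three
#' vertices all belong to the ROI; the distance is the symmetrized minimum
#' of ROI-vertex-to-ROI-triangle distances (point-to-point when a side has
#' no complete face). Candidate pairs are pruned with conservative
#' per-triangle bounding spheres, so the result equals the brute-force
#' all-pairs minimum exactly. Intersecting surfaces are reported as
#' distance 0 with \code{intersecting = TRUE}.
#'
#' @param model_a,model_b \code{\link{bone_model}} objects.
#' @param roi_a,roi_b ROI names in the respective models.
#' @param tf_a,tf_b \code{\link{rigid_transform}} poses (imaging -> lab).
#' @param check_intersection run the edge-through-triangle test that
#'   catches interpenetration not visible to vertex sampling (default
#'   TRUE; disable to obtain the raw point-to-triangle minimum).
#' @return List: \code{distance} (mm), \code{witness_a}, \code{witness_b}
#'   (the realizing points, lab frame), \code{intersecting}.
#' @export
min_distance <- function(model_a, roi_a, tf_a = rigid_transform(),
                         model_b, roi_b, tf_b = rigid_transform(),
                         check_intersection = TRUE) {
  ia <- model_a$rois[[roi_a]]
  ib <- model_b$rois[[roi_b]]
  if (is.null(ia)) stop("unknown ROI '", roi_a, "' in model_a", call. = FALSE)
  if (is.null(ib)) stop("unknown ROI '", roi_b, "' in model_b", call. = FALSE)
  Va <- apply_transform(tf_a, model_a$vertices)
  Vb <- apply_transform(tf_b, model_b$vertices)
  Fa <- roi_faces(model_a, roi_a)
  Fb <- roi_faces(model_b, roi_b)
  Pa <- Va[ia, , drop = FALSE]
  Pb <- Vb[ib, , drop = FALSE]
  # upper bound from vertex-vertex minimum (also the point-point fallback)
  d2 <- outer(rowSums(Pa^2), rowSums(Pb^2), "+") - 2 * tcrossprod(Pa, Pb)
  kvv <- arrayInd(which.min(d2), dim(d2))
  best <- list(dist = sqrt(max(min(d2), 0)),
               p = Pa[kvv[1], ], q = Pb[kvv[2], ])
  r1 <- min_points_tris(Pa, Vb, Fb, best$dist)
  if (r1$dist < best$dist) best <- r1
  r2 <- min_points_tris(Pb, Va, Fa, best$dist)
  if (r2$dist < best$dist) best <- list(dist = r2$dist, p = r2$q, q = r2$p)
  inter <- FALSE
  if (best$dist <= 1e-12) {
    inter <- TRUE
  } else if (check_intersection && nrow(Fa) && nrow(Fb)) {
    va <- Va[unique(as.vector(Fa)), , drop = FALSE]
    vb <- Vb[unique(as.vector(Fb)), , drop = FALSE]
    boxes_overlap <- all(apply(va, 2, min) <= apply(vb, 2, max)) &&
      all(apply(vb, 2, min) <= apply(va, 2, max))
    if (boxes_overlap) inter <- surfaces_intersect(Va, Fa, Vb, Fb)
  }
  if (inter) best$dist <- 0
  list(distance = best$dist, witness_a = best$p, witness_b = best$q,
       intersecting = inter)
}

#' Dynamic bone-to-bone distance series (IFS)
#'
#' Per-frame minimum distance between two posed cortical ROIs (pelvis
#' ischial tuberosity vs femoral lesser trochanter for the ischiofemoral
#' space), optionally time-normalized to one gait cycle.
#'
#' @param pelvis,femur \code{\link{bone_model}} objects.
#' @param pelvis_tfs,femur_tfs \code{\link{fit_frame_transforms}} results
#'   covering the same frames.
#' @param rois length-2 character: ROI name in pelvis, ROI name in femur.
#' @param cycle optional length-2 heel-strike frame pair for
#'   normalization.
#' @param q node count for the normalized curve (default 101).
#' @return Object of class \code{ifs_curve}: \code{distance_mm} per frame
#'   (NA when either pose is invalid), \code{witness_a}/\code{witness_b}
#'   arrays, \code{valid}, \code{rate}, and when \code{cycle} is given,
#'   \code{normalized} (a \code{normalized_curve}) plus \code{argmax_pct}
#'   and \code{argmin_pct}.
#' @export
ifs_series <- function(pelvis, femur, pelvis_tfs, femur_tfs, rois,
                       cycle = NULL, q = 101) {
  stopifnot(length(rois) == 2L)
  nfr <- length(pelvis_tfs$valid)
  if (length(femur_tfs$valid) != nfr) {
    stop("transform series must cover the same frames", call. = FALSE)
  }
  valid <- pelvis_tfs$valid & femur_tfs$valid
  if (!any(valid)) stop("no overlapping valid frames", call. = FALSE)
  dist <- rep(NA_real_, nfr)
  wa <- wb <- matrix(NA_real_, nfr, 3)
  for (i in which(valid)) {
    r <- min_distance(pelvis, rois[1], pelvis_tfs$transforms[[i]],
                      femur, rois[2], femur_tfs$transforms[[i]])
    dist[i] <- r$distance
    wa[i, ] <- r$witness_a
    wb[i, ] <- r$witness_b
  }
  out <- list(distance_mm = dist, witness_a = wa, witness_b = wb,
              valid = valid, rate = pelvis_tfs$rate)
  if (!is.null(cycle)) {
    nc <- normalize_to_cycle(dist, cycle, q)
    out$normalized <- nc
    out$argmax_pct <- nc$percent[which.max(nc$values)]
    out$argmin_pct <- nc$percent[which.min(nc$values)]
  }
  structure(out, class = "ifs_curve")
}

#' @export
print.ifs_curve <- function(x, ...) {
  cat(sprintf("IFS series: %d frames (%d valid), range %.2f..%.2f mm\n",
              length(x$distance_mm), sum(x$valid),
              min(x$distance_mm, na.rm = TRUE),
              max(x$distance_mm, na.rm = TRUE)))
  if (!is.null(x$normalized)) {
    cat(sprintf("  normalized: max at %.0f%%, min at %.0f%% of cycle\n",
                x$argmax_pct, x$argmin_pct))
  }
  invisible(x)
}

#' Write an IFS series to CSV
#'
#' Columns: frame, time_s, distance_mm, witness coordinates (both bones).
#'
#' @param ifs an \code{ifs_curve}.
#' @param path output CSV path.
#' @export
write_ifs <- function(ifs, path) {
  nfr <- length(ifs$distance_mm)
  df <- data.frame(frame = seq_len(nfr),
                   time_s = (seq_len(nfr) - 1) / ifs$rate,
                   distance_mm = ifs$distance_mm,
                   ax = ifs$witness_a[, 1], ay = ifs$witness_a[, 2],
                   az = ifs$witness_a[, 3],
                   bx = ifs$witness_b[, 1], by = ifs$witness_b[, 2],
                   bz = ifs$witness_b[, 3])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
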