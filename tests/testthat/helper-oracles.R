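# Independent oracles used to cross-check the package implementations.
# Each is deliberately coded from a different algorithm than the code it
# checks.

# Horn's closed-form absolute orientation via the unit quaternion that
# maximises q' N q (largest eigenvector of the 4x4 profile matrix).
horn_orientation <- function(P, Q) {
  muP <- colMeans(P); muQ <- colMeans(Q)
  Pc <- sweep(P, 2, muP); Qc <- sweep(Q, 2, muQ)
  S <- crossprod(Pc, Qc)   # sum p_i q_i'
  Sxx <- S[1, 1]; Sxy <- S[1, 2]; Sxz <- S[1, 3]
  Syx <- S[2, 1]; Syy <- S[2, 2]; Syz <- S[2, 3]
  Szx <- S[3, 1]; Szy <- S[3, 2]; Szz <- S[3, 3]
  N <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,       Szx - Sxz,       Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz, Sxy + Syx,       Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,       -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx,       Szx + Sxz,       Syz + Szy,       -Sxx - Syy + Szz),
    4, 4, byrow = TRUE)
  q <- eigen(N, symmetric = TRUE)$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    w^2 + x^2 - y^2 - z^2, 2 * (x * y - w * z),   2 * (x * z + w * y),
    2 * (x * y + w * z),   w^2 - x^2 + y^2 - z^2, 2 * (y * z - w * x),
    2 * (x * z - w * y),   2 * (y * z + w * x),   w^2 - x^2 - y^2 + z^2),
    3, 3, byrow = TRUE)
  list(rotation = R, translation = as.numeric(muQ - R %*% muP))
}

# Random proper rotation from a random axis and angle.
random_rotation <- function() {
  ax <- stats::rnorm(3)
  rotation_about_axis(ax, stats::runif(1, 0, 180))
}

# Geodesic angle through the Frobenius norm, accurate for tiny angles.
geodesic_precise_deg <- function(r1, r2) {
  s <- sqrt(sum((r1 - r2)^2)) / (2 * sqrt(2))
  2 * asin(min(1, s)) * 180 / pi
}

# Point-to-triangle distance by unconstrained projection followed by
# explicit clamping to the three edges (different algorithm from the
# region classification in the package).
pt_tri_dist_ref <- function(p, a, b, c) {
  e0 <- b - a; e1 <- c - a
  M <- rbind(c(sum(e0 * e0), sum(e0 * e1)), c(sum(e0 * e1), sum(e1 * e1)))
  rhs <- c(sum(e0 * (p - a)), sum(e1 * (p - a)))
  st <- tryCatch(solve(M, rhs), error = function(e) c(-1, -1))
  cand <- list()
  if (all(st >= 0) && sum(st) <= 1) {
    cand[[1]] <- a + st[1] * e0 + st[2] * e1
  }
  seg <- function(p, u, v) {
    d <- v - u
    t_ <- sum((p - u) * d) / sum(d * d)
    u + max(0, min(1, t_)) * d
  }
  cand <- c(cand, list(seg(p, a, b), seg(p, b, c), seg(p, c, a)))
  min(vapply(cand, function(x) sqrt(sum((p - x)^2)), 0))
}

# Brute-force symmetric minimum distance between two posed ROI surfaces:
# every ROI vertex of one model against every ROI face of the other, no
# pruning.
brute_min_distance <- function(ma, roi_a, tfa, mb, roi_b, tfb) {
  Va <- apply_transform(tfa, ma$vertices)
  Vb <- apply_transform(tfb, mb$vertices)
  faces_in <- function(model, roi) {
    idx <- model$rois[[roi]]
    f <- model$faces
    f[rowSums(matrix(f %in% idx, nrow(f), 3)) == 3L, , drop = FALSE]
  }
  Fa <- faces_in(ma, roi_a); Fb <- faces_in(mb, roi_b)
  Pa <- Va[ma$rois[[roi_a]], , drop = FALSE]
  Pb <- Vb[mb$rois[[roi_b]], , drop = FALSE]
  best <- Inf
  for (i in seq_len(nrow(Pa))) {
    for (k in seq_len(nrow(Fb))) {
      best <- min(best, pt_tri_dist_ref(Pa[i, ], Vb[Fb[k, 1], ],
                                        Vb[Fb[k, 2], ], Vb[Fb[k, 3], ]))
    }
  }
  for (i in seq_len(nrow(Pb))) {
    for (k in seq_len(nrow(Fa))) {
      best <- min(best, pt_tri_dist_ref(Pb[i, ], Va[Fa[k, 1], ],
                                        Va[Fa[k, 2], ], Va[Fa[k, 3], ]))
    }
  }
  if (!nrow(Fa) && !nrow(Fb)) {
    d2 <- outer(rowSums(Pa^2), rowSums(Pb^2), "+") - 2 * tcrossprod(Pa, Pb)
    best <- sqrt(max(0, min(d2)))
  }
  best
}

# Small random blobby mesh: an icosphere with seeded radial perturbation
# (remains a valid closed triangulation).
random_blob_mesh <- function(radius = 10, center = c(0, 0, 0),
                             bump = 0.25) {
  m <- icosphere(1, 1, c(0, 0, 0))      # 42 vertices, 80 faces
  r <- radius * (1 + stats::runif(nrow(m$vertices), -bump, bump))
  v <- m$vertices * r
  bone_model(sweep(v, 2, center, "+"), m$faces,
             rois = list(all = seq_len(nrow(v))))
}

# Direct textbook CMC (loops, no matrix shortcuts).
cmc_ref <- function(y) {
  G <- nrow(y); F_ <- ncol(y)
  ybar_f <- colMeans(y); ybar <- mean(y)
  num <- 0
  for (g in 1:G) for (f in 1:F_) num <- num + (y[g, f] - ybar_f[f])^2
  num <- num / (F_ * (G - 1))
  den <- 0
  for (g in 1:G) for (f in 1:F_) den <- den + (y[g, f] - ybar)^2
  den <- den / (F_ * G - 1)
  sqrt(1 - num / den)
}

# Hand enumeration of the paired sign-flip max-|t| distribution, with the
# nodewise t computed through stats::t.test.
enum_signflip_max_t <- function(d) {
  n <- nrow(d)
  signs <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))
  apply(signs, 1, function(s) {
    ds <- d * s
    max(abs(vapply(seq_len(ncol(d)), function(j) {
      unname(stats::t.test(ds[, j])$statistic)
    }, 0)))
  })
}
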