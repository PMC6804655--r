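#' Affine transform (rotation, translation, independent scale)
#'
#' Parameterized as three Euler angles (degrees, applied as Rz Ry Rx), a
#' translation vector (mm) and three independent scale factors, optionally
#' about a center point: `x' = T + C + R S (x - C)`.
#'
#' @param rotation length-3 angles in degrees.
#' @param translation length-3 mm.
#' @param scale length-3 positive factors.
#' @param center rotation/scale center, mm.
#' @export
affine_transform <- function(rotation = c(0, 0, 0),
                             translation = c(0, 0, 0),
                             scale = c(1, 1, 1),
                             center = c(0, 0, 0)) {
  scale <- rep_len(scale, 3)
  if (any(scale <= 0)) stop("affine_transform: scale factors must be positive")
  r <- rotation * pi / 180
  Rx <- rbind(c(1, 0, 0), c(0, cos(r[1]), -sin(r[1])), c(0, sin(r[1]), cos(r[1])))
  Ry <- rbind(c(cos(r[2]), 0, sin(r[2])), c(0, 1, 0), c(-sin(r[2]), 0, cos(r[2])))
  Rz <- rbind(c(cos(r[3]), -sin(r[3]), 0), c(sin(r[3]), cos(r[3]), 0), c(0, 0, 1))
  A <- Rz %*% Ry %*% Rx %*% diag(scale)
  M <- diag(4)
  M[1:3, 1:3] <- A
  M[1:3, 4] <- translation + center - A %*% center
  structure(list(matrix = M, rotation = rotation, translation = translation,
                 scale = scale, center = center),
            class = "affine_transform")
}

#' @export
print.affine_transform <- function(x, ...) {
  cat("<affine_transform> rot(deg) [", paste(signif(x$rotation, 4), collapse = ", "),
      "] trans(mm) [", paste(signif(x$translation, 4), collapse = ", "),
      "] scale [", paste(signif(x$scale, 4), collapse = ", "), "]\n", sep = "")
  invisible(x)
}

#' Invert an affine transform
#' @param t an [affine_transform()].
#' @return an `affine_transform` whose matrix is the inverse; the stored
#'   scale components are reciprocals (used for radius rescaling).
#' @export
inverse_transform <- function(t) {
  out <- structure(list(matrix = solve(t$matrix), rotation = -t$rotation,
                        translation = NA, scale = 1 / t$scale,
                        center = t$center),
                   class = "affine_transform")
  out$translation <- out$matrix[1:3, 4]
  out
}

#' Map mm points through an affine transform
#' @param pts n x 3 matrix.
#' @param t an [affine_transform()].
#' @export
transform_points <- function(pts, t) {
  pts <- rbind(pts)
  sweep(pts %*% t(t$matrix[1:3, 1:3]), 2, t$matrix[1:3, 4], "+")
}

#' Transform a surface mesh
#'
#' Vertices are mapped through the transform; faces are unchanged. Vertex
#' radii, when present, are multiplied by the mean of the three scale
#' factors (the convention for anisotropic scaling).
#'
#' @param mesh a `surface_mesh`.
#' @param t an [affine_transform()].
#' @export
transform_mesh <- function(mesh, t) {
  mesh$vertices <- transform_points(mesh$vertices, t)
  if (!is.null(mesh$vertex_radius))
    mesh$vertex_radius <- mesh$vertex_radius * mean(t$scale)
  mesh
}

#' Resample a moving volume through a transform into a fixed grid
#'
#' The transform maps moving-space mm coordinates to fixed-space mm
#' coordinates; each fixed voxel center is pulled back through the inverse
#' and sampled trilinearly.
#'
#' @param moving a `seeg_volume`.
#' @param t an [affine_transform()] (moving to fixed).
#' @param grid fixed grid spec.
#' @param outside value for unmapped voxels (`NA` marks no-overlap).
#' @export
resample_volume <- function(moving, t, grid, outside = 0) {
  fixed_pts <- voxel_centers(empty_volume(grid))
  src <- transform_points(fixed_pts, inverse_transform(t))
  vals <- cpp_trilinear(as.numeric(moving$data), dim(moving$data),
                        moving$voxdim, moving$origin, src,
                        if (is.na(outside)) NA_real_ else outside)
  new_volume(array(as.numeric(vals), grid$dim), grid$voxdim, grid$origin)
}

#' Normalized mutual information between two volumes
#'
#' `NMI = (H(A) + H(B)) / H(A, B)` over the voxels where both images are
#' defined, from a joint histogram with `bins` bins per axis. Invariant to
#' bijective intensity remapping at the histogram level; equals its maximum
#' for identical images and approaches 1 for independent ones.
#'
#' @param fixed,moving `seeg_volume`s on the same grid (resample first);
#'   `NA` voxels in either are excluded.
#' @param bins histogram bins per axis (>= 2).
#' @export
normalized_mutual_information <- function(fixed, moving, bins = 64) {
  stopifnot(bins >= 2)
  a <- as.numeric(fixed$data); b <- as.numeric(moving$data)
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) stop("normalized_mutual_information: empty overlap")
  a <- a[ok]; b <- b[ok]
  cut_idx <- function(x) {
    r <- range(x)
    if (r[2] <= r[1]) return(rep(1L, length(x)))
    pmin(pmax(floor((x - r[1]) / (r[2] - r[1]) * bins) + 1L, 1L), bins)
  }
  ia <- cut_idx(a); ib <- cut_idx(b)
  joint <- tabulate(ia + bins * (ib - 1L), nbins = bins * bins)
  pj <- joint / sum(joint)
  pa <- tabulate(ia, nbins = bins) / length(ia)
  pb <- tabulate(ib, nbins = bins) / length(ib)
  ent <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  hj <- ent(pj)
  if (hj <= 0) return(2)  # both images constant: perfectly matched
  (ent(pa) + ent(pb)) / hj
}

# intensity moments: weighted centroid and covariance of the positive part
volume_moments <- function(vol) {
  w <- pmax(as.numeric(vol$data), 0)
  pts <- voxel_centers(vol)
  sw <- sum(w)
  ctr <- colSums(pts * w) / sw
  cen <- sweep(pts, 2, ctr)
  C <- crossprod(cen * sqrt(w)) / sw
  list(centroid = ctr, cov = C)
}

# closed-form moments initializer: aligns principal axes and centroids of
# the two images (rotation by Procrustes of eigenvectors with sign fixing,
# isotropic scale from the covariance determinants)
moments_init <- function(fixed, moving, center) {
  mf <- volume_moments(fixed)
  mm <- volume_moments(moving)
  ef <- eigen(mf$cov, symmetric = TRUE)
  em <- eigen(mm$cov, symmetric = TRUE)
  Em <- em$vectors
  for (k in 1:3) if (sum(ef$vectors[, k] * Em[, k]) < 0) Em[, k] <- -Em[, k]
  R0 <- ef$vectors %*% t(Em)
  if (det(R0) < 0) { Em[, 3] <- -Em[, 3]; R0 <- ef$vectors %*% t(Em) }
  # Euler angles of R0 under the Rz Ry Rx convention
  ry <- asin(pmin(pmax(-R0[3, 1], -1), 1))
  rx <- atan2(R0[3, 2], R0[3, 3])
  rz <- atan2(R0[2, 1], R0[1, 1])
  rot <- c(rx, ry, rz) * 180 / pi
  s0 <- (det(mf$cov) / det(mm$cov))^(1 / 6)
  scale <- rep(max(min(s0, 1.2), 0.8), 3)
  # translation so the moving centroid maps onto the fixed one
  A <- R0 %*% diag(scale)
  trans <- mf$centroid - center - as.numeric(A %*% (mm$centroid - center))
  affine_transform(rotation = rot, translation = trans, scale = scale,
                   center = center)
}

# recover rotation/translation/scale parameters from a 4x4 matrix (small
# shear discarded via polar decomposition)
params_from_matrix <- function(M, center) {
  A <- M[1:3, 1:3]
  e <- eigen(crossprod(A), symmetric = TRUE)
  P <- e$vectors %*% diag(sqrt(pmax(e$values, 1e-12))) %*% t(e$vectors)
  R <- A %*% solve(P)
  ry <- asin(pmin(pmax(-R[3, 1], -1), 1))
  rx <- atan2(R[3, 2], R[3, 3])
  rz <- atan2(R[2, 1], R[1, 1])
  affine_transform(rotation = c(rx, ry, rz) * 180 / pi,
                   translation = M[1:3, 4] - center +
                     as.numeric(A %*% center),
                   scale = pmin(pmax(diag(P), 0.8), 1.25), center = center)
}

# iterated moments alignment: apply the current estimate, re-estimate the
# residual from intensity moments, compose; converges to moments-consistent
# alignment even under anisotropic scale (where one-shot principal-axes
# Procrustes is biased)
moments_init_iter <- function(fixed, moving, center, iters = 3) {
  t <- moments_init(fixed, moving, center)
  g <- vol_grid(fixed)
  for (k in seq_len(iters - 1)) {
    mov2 <- resample_volume(moving, t, g)
    dt <- moments_init(fixed, mov2, center)
    t <- params_from_matrix(dt$matrix %*% t$matrix, center)
  }
  t
}

# sampled NMI objective: fixed voxel centers on a stride, pulled back
# through the candidate transform and trilinearly sampled in the moving
# image; histograms over the valid overlap
make_nmi_objective <- function(fixed, moving, stride, bins, center) {
  d <- dim(fixed$data)
  ix <- seq(1, d[1], by = stride); iy <- seq(1, d[2], by = stride)
  iz <- seq(1, d[3], by = stride)
  sel <- as.matrix(expand.grid(ix, iy, iz))
  fpts <- sweep(sweep(sel - 1, 2, fixed$voxdim, "*"), 2, fixed$origin, "+")
  fvals <- fixed$data[sel]
  fr <- range(fvals)
  fbin <- if (fr[2] > fr[1])
    pmin(pmax(floor((fvals - fr[1]) / (fr[2] - fr[1]) * bins) + 1L, 1L), bins)
  else rep(1L, length(fvals))
  mdat <- as.numeric(moving$data); mdim <- dim(moving$data)
  function(par) {
    t <- affine_transform(rotation = par[1:3], translation = par[4:6],
                          scale = exp(par[7:9]), center = center)
    Minv <- solve(t$matrix)
    src <- sweep(fpts %*% t(Minv[1:3, 1:3]), 2, Minv[1:3, 4], "+")
    mv <- as.numeric(cpp_trilinear(mdat, mdim, moving$voxdim, moving$origin,
                                   src, NA_real_))
    ok <- !is.na(mv)
    if (sum(ok) < 100) return(1)   # essentially no overlap
    mvo <- mv[ok]
    mr <- range(mvo)
    if (mr[2] <= mr[1]) return(-2)
    # partial-volume (linear) binning of the moving intensities keeps the
    # objective smooth in the transform parameters; hard bins create
    # plateaus that trap the simplex
    b <- (mvo - mr[1]) / (mr[2] - mr[1]) * bins + 0.5
    b0 <- pmin(pmax(floor(b), 1), bins)
    b1 <- pmin(b0 + 1, bins)
    w1 <- pmin(pmax(b - b0, 0), 1)
    w0 <- 1 - w1
    fb <- fbin[ok]
    acc <- rowsum(c(w0, w1), c(fb + bins * (b0 - 1), fb + bins * (b1 - 1)))
    joint <- numeric(bins * bins)
    joint[as.integer(rownames(acc))] <- acc
    pj <- joint / sum(joint)
    pa <- tabulate(fb, nbins = bins) / sum(ok)
    accb <- rowsum(c(w0, w1), c(b0, b1))
    pb <- numeric(bins)
    pb[as.integer(rownames(accb))] <- accb
    pb <- pb / sum(pb)
    ent <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
    hj <- ent(pj)
    if (hj <= 0) return(-2)
    -(ent(pa) + ent(pb)) / hj
  }
}

#' Affine registration by normalized mutual information
#'
#' Two-level multi-resolution search (coarse grid first, then full
#' resolution) with derivative-free Nelder-Mead over 9 parameters (3
#' rotations, 3 translations, 3 log-scales), multi-started from the initial
#' transform plus seeded perturbations. Deterministic given `seed` and
#' `init`.
#'
#' @param fixed,moving `seeg_volume`s.
#' @param init initial [affine_transform()] (default identity about the
#'   fixed-volume center).
#' @param bins histogram bins.
#' @param n_starts number of coarse-level starts (1 = init only).
#' @param seed integer seed for the perturbed starts.
#' @return an `affine_transform`; attribute `"nmi"` holds the attained
#'   score, and attribute `"improved"` is `FALSE` (with a warning) when no
#'   start improved on the initial transform.
#' @export
register_affine_nmi <- function(fixed, moving, init = NULL, bins = 64,
                                n_starts = 4, seed = 1) {
  ctr <- fixed$origin + (dim(fixed$data) - 1) * fixed$voxdim / 2
  user_init <- !is.null(init)
  if (is.null(init)) init <- affine_transform(center = ctr)
  p0 <- c(init$rotation, init$translation, log(init$scale))
  # closed-form moments start (principal-axes alignment) unless the caller
  # supplied an explicit initial transform
  p_mom <- if (user_init) p0 else {
    m <- moments_init_iter(fixed, moving, ctr)
    c(m$rotation, m$translation, log(m$scale))
  }

  # both levels sample the full-resolution images; the coarse level just
  # uses a sparser voxel stride and fewer bins (downsampled pyramids can
  # displace the NMI optimum under small scale changes)
  obj2 <- make_nmi_objective(fixed, moving, stride = 4, bins = 32,
                             center = ctr)
  obj1 <- make_nmi_objective(fixed, moving, stride = 3, bins = bins,
                             center = ctr)
  obj_fine <- make_nmi_objective(fixed, moving, stride = 2, bins = bins,
                                 center = ctr)

  # stage 1: rotation + translation + isotropic scale (7 parameters; the
  # isotropic axis is the diagonal of the scale valley, so the simplex can
  # follow it), multi-started across the plausible misalignment envelope
  starts <- list(c(p0[1:6], mean(p0[7:9])),
                 c(p_mom[1:6], mean(p_mom[7:9])))
  with_seed(seed, {
    if (n_starts > 2)
      for (s in seq_len(n_starts - 2))
        starts[[s + 2]] <- starts[[2]] + c(runif(3, -2, 2), runif(3, -2, 2),
                                           runif(1, -0.02, 0.02))
  })
  best <- NULL; best_val <- Inf
  for (p in starts) {
    fit <- optim(p, function(p7) obj2(c(p7[1:6], rep(p7[7], 3))),
                 method = "Nelder-Mead",
                 control = list(maxit = 300,
                                parscale = c(rep(2, 6), 0.02),
                                reltol = 1e-8))
    if (fit$value < best_val) {
      best_val <- fit$value
      best <- c(fit$par[1:6], rep(fit$par[7], 3))
    }
  }
  # stages 2-3, cycled: isotropic then per-axis scale line searches (the
  # scale factors form a narrow diagonal valley that a fresh simplex cannot
  # enter by single-axis steps), a rigid re-fit at the new scale, and a
  # joint Nelder-Mead polish; repeat until the estimate stops moving
  val_prev <- obj1(best)
  for (round in 1:3) {
    prev <- best
    iso <- optimize(function(ls) obj1(c(best[1:6], best[7:9] + ls)),
                    interval = c(-0.08, 0.08), tol = 1e-5)
    best[7:9] <- best[7:9] + iso$minimum
    for (ax in 7:9) {
      ls <- optimize(function(v) { p <- best; p[ax] <- v; obj1(p) },
                     interval = best[ax] + c(-0.04, 0.04), tol = 1e-5)
      best[ax] <- ls$minimum
    }
    rigid <- function(p6) obj1(c(p6, best[7:9]))
    rf <- optim(best[1:6], rigid, method = "Nelder-Mead",
                control = list(maxit = 150, parscale = rep(1, 6),
                               reltol = 1e-9))
    best[1:6] <- rf$par
    jf <- optim(best, obj1, method = "Nelder-Mead",
                control = list(maxit = 200,
                               parscale = c(rep(0.5, 6), rep(0.005, 3)),
                               reltol = 1e-10))
    best <- jf$par
    if (val_prev - jf$value < 1e-5 && max(abs(best - prev)) < 1e-3) break
    val_prev <- jf$value
  }
  # one full refinement cycle at the fine stride, then the final polish
  iso <- optimize(function(ls) obj_fine(c(best[1:6], best[7:9] + ls)),
                  interval = c(-0.03, 0.03), tol = 1e-5)
  best[7:9] <- best[7:9] + iso$minimum
  for (ax in 7:9) {
    ls <- optimize(function(v) { p <- best; p[ax] <- v; obj_fine(p) },
                   interval = best[ax] + c(-0.02, 0.02), tol = 1e-5)
    best[ax] <- ls$minimum
  }
  rf <- optim(best[1:6], function(p6) obj_fine(c(p6, best[7:9])),
              method = "Nelder-Mead",
              control = list(maxit = 150, parscale = rep(0.5, 6),
                             reltol = 1e-10))
  best[1:6] <- rf$par
  fit <- optim(best, obj_fine, method = "Nelder-Mead",
               control = list(maxit = 200,
                              parscale = c(rep(0.2, 6), rep(0.002, 3)),
                              reltol = 1e-12))
  improved <- fit$value < obj_fine(p0) - 1e-12
  if (!improved) {
    warning("register_affine_nmi: optimizer did not improve on the initial transform")
    fit$par <- p0
    fit$value <- obj1(p0)
  }
  out <- affine_transform(rotation = fit$par[1:3], translation = fit$par[4:6],
                          scale = exp(fit$par[7:9]), center = ctr)
  attr(out, "nmi") <- -fit$value
  attr(out, "improved") <- improved
  out
}
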