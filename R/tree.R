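#' Grow a synthetic branching vascular tree
#'
#' Recursive bifurcation inside a binary domain: each root starts near the
#' domain boundary with a caliber of `root_radius` and marches inward in
#' segments of random length; at each tip the branch either bifurcates (two
#' children at randomized angles) or continues, and the radius decays by
#' `radius_decay` per generation (with jitter, clamped so a child is never
#' wider than its parent). Growth stops when the radius falls below
#' `min_radius` or the branch can no longer be kept inside the domain.
#' The defaults span calibers from `min_radius` to `root_radius` so every
#' diameter-pruning threshold between 1 and 4 mm bisects the tree.
#'
#' @param seed integer seed; the same (seed, domain, params) reproduces the
#'   tree exactly.
#' @param domain a `seeg_volume` binary mask the tree must stay inside.
#' @param n_roots number of root branches (0 gives an empty tree).
#' @param branch_params list overriding any of: `root_radius` (mm, 4.0),
#'   `radius_decay` (per generation, 0.75), `min_radius` (mm, 0.5),
#'   `seg_length` (mm range, c(6, 12)), `branch_prob` (0.75),
#'   `branch_angle` (deg range, c(20, 45)), `max_generation` (8),
#'   `max_retries` (20).
#' @return object of class `vascular_tree`: a data.frame `segments` with
#'   columns x0..z1, `radius` (mm), `parent` (0 for roots), `generation`,
#'   `branch` (branch id: consecutive segments of constant radius), plus the
#'   `roots` matrix.
#' @export
grow_vascular_tree <- function(seed, domain, n_roots = 2,
                               branch_params = list()) {
  p <- modifyList(list(root_radius = 4.0, radius_decay = 0.75,
                       min_radius = 0.5, seg_length = c(6, 12),
                       branch_prob = 0.65, branch_angle = c(20, 45),
                       max_generation = 7, max_retries = 20), branch_params)
  if (!any(as.logical(domain$data))) stop("grow_vascular_tree: empty domain")

  dom_pts <- voxel_centers(domain, as.logical(domain$data))
  centroid <- colMeans(dom_pts)
  inside <- function(pt) lookup_volume(domain, rbind(pt), outside = 0) > 0.5

  segs <- list()
  n_branch <- 0L

  rand_dir_near <- function(dir, max_deg) {
    # random unit vector within max_deg of dir
    dir <- dir / sqrt(sum(dir^2))
    ang <- runif(1, 0, max_deg) * pi / 180
    # orthonormal frame
    ref <- if (abs(dir[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    u <- ref - sum(ref * dir) * dir; u <- u / sqrt(sum(u^2))
    v <- c(dir[2] * u[3] - dir[3] * u[2],
           dir[3] * u[1] - dir[1] * u[3],
           dir[1] * u[2] - dir[2] * u[1])
    phi <- runif(1, 0, 2 * pi)
    cos(ang) * dir + sin(ang) * (cos(phi) * u + sin(phi) * v)
  }

  grow <- function(start, dir, radius, parent, generation, branch_id) {
    if (radius < p$min_radius || generation > p$max_generation) return(invisible())
    len <- runif(1, p$seg_length[1], p$seg_length[2])
    end <- NULL
    for (try in seq_len(p$max_retries)) {
      cand_dir <- if (try == 1) dir else rand_dir_near(dir, 60)
      cand <- start + len * cand_dir
      mid <- start + 0.5 * len * cand_dir
      if (inside(cand) && inside(mid)) { end <- cand; dir <- cand_dir; break }
      len <- len * 0.8
    }
    if (is.null(end)) return(invisible())
    seg <- data.frame(x0 = start[1], y0 = start[2], z0 = start[3],
                      x1 = end[1], y1 = end[2], z1 = end[3],
                      radius = radius, parent = parent,
                      generation = generation, branch = branch_id)
    segs[[length(segs) + 1L]] <<- seg
    my_id <- length(segs)

    branch <- runif(1) < p$branch_prob
    if (branch) {
      for (child in 1:2) {
        ang <- runif(1, p$branch_angle[1], p$branch_angle[2])
        cdir <- rand_dir_near(dir, ang)
        decay <- p$radius_decay * runif(1, 0.9, 1.1)
        cr <- min(radius, radius * decay)
        n_branch <<- n_branch + 1L
        grow(end, cdir, cr, my_id, generation + 1L, n_branch)
      }
    } else {
      # continue the same branch with a gentle bend, same caliber
      cdir <- rand_dir_near(dir, 15)
      grow(end, cdir, radius, my_id, generation, branch_id)
    }
    invisible()
  }

  roots <- matrix(numeric(0), 0, 3)
  with_seed(seed, {
    for (r in seq_len(n_roots)) {
      placed <- FALSE
      for (try in seq_len(200)) {
        pt <- dom_pts[sample.int(nrow(dom_pts), 1), ]
        # bias roots toward the domain periphery
        off <- pt - centroid
        rad <- sqrt(sum(off^2))
        if (rad < 0.5 * max(sqrt(rowSums(sweep(dom_pts, 2, centroid)^2))))
          next
        dir0 <- rand_dir_near(-off, 30)
        if (inside(pt + 2 * dir0)) {
          roots <- rbind(roots, pt)
          n_branch <- n_branch + 1L
          grow(pt, dir0, p$root_radius, 0L, 1L, n_branch)
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop(sprintf("grow_vascular_tree: could not confine root %d in the domain (seed %d)",
                     r, seed))
    }
  })

  segments <- if (length(segs)) do.call(rbind, segs) else
    data.frame(x0 = numeric(0), y0 = numeric(0), z0 = numeric(0),
               x1 = numeric(0), y1 = numeric(0), z1 = numeric(0),
               radius = numeric(0), parent = integer(0),
               generation = integer(0), branch = integer(0))
  rownames(segments) <- NULL
  structure(list(segments = segments, roots = roots, params = p, seed = seed),
            class = "vascular_tree")
}

#' @export
print.vascular_tree <- function(x, ...) {
  s <- x$segments
  cat("<vascular_tree> ", nrow(s), " segments, ", nrow(x$roots), " roots",
      if (nrow(s)) sprintf(", radii %.2f-%.2f mm", min(s$radius), max(s$radius)),
      "\n", sep = "")
  invisible(x)
}

#' Signed clearance of points from the tree's tube surfaces
#'
#' Minimum over segments of (distance to the segment axis minus the segment
#' radius); negative inside a vessel.
#'
#' @param pts n x 3 matrix of mm points.
#' @param tree a `vascular_tree`.
#' @return numeric vector (Inf for an empty tree).
#' @export
tree_surface_distance <- function(pts, tree) {
  pts <- rbind(pts)
  segs <- tree$segments
  best <- rep(Inf, nrow(pts))
  if (!nrow(segs)) return(best)
  for (s in seq_len(nrow(segs))) {
    p0 <- c(segs$x0[s], segs$y0[s], segs$z0[s])
    v <- c(segs$x1[s] - p0[1], segs$y1[s] - p0[2], segs$z1[s] - p0[3])
    vv <- sum(v^2)
    w1 <- pts[, 1] - p0[1]; w2 <- pts[, 2] - p0[2]; w3 <- pts[, 3] - p0[3]
    t <- if (vv > 0) pmin(1, pmax(0, (w1 * v[1] + w2 * v[2] + w3 * v[3]) / vv)) else 0
    d <- sqrt((w1 - t * v[1])^2 + (w2 - t * v[2])^2 + (w3 - t * v[3])^2) -
      segs$radius[s]
    best <- pmin(best, d)
  }
  best
}

#' Rasterize a vascular tree onto a grid
#'
#' Paints every tree segment with diameter at or above `min_diameter` as a
#' solid tube. Returns the tube mask together with per-voxel ground truth:
#' the generating segment index and its true diameter.
#'
#' @param tree a `vascular_tree`.
#' @param grid grid spec (list with `dim`, `voxdim`, `origin`).
#' @param min_diameter mm; segments with `2 * radius < min_diameter`
#'   contribute nothing.
#' @return list of `seeg_volume`s: `mask` (0/1), `segment` (index, 0 =
#'   background), `diameter` (mm, 0 = background).
#' @export
rasterize_tree <- function(tree, grid, min_diameter = 0) {
  d <- grid$dim
  mask <- array(FALSE, d)
  segid <- array(0L, d)
  diam <- array(0, d)
  segs <- tree$segments
  if (nrow(segs)) {
    ax <- lapply(1:3, function(a) grid$origin[a] + (seq_len(d[a]) - 1) * grid$voxdim[a])
    for (s in seq_len(nrow(segs))) {
      r <- segs$radius[s]
      if (2 * r < min_diameter) next
      p0 <- c(segs$x0[s], segs$y0[s], segs$z0[s])
      p1 <- c(segs$x1[s], segs$y1[s], segs$z1[s])
      lo <- pmin(p0, p1) - r - max(grid$voxdim)
      hi <- pmax(p0, p1) + r + max(grid$voxdim)
      ii <- which(ax[[1]] >= lo[1] & ax[[1]] <= hi[1])
      jj <- which(ax[[2]] >= lo[2] & ax[[2]] <= hi[2])
      kk <- which(ax[[3]] >= lo[3] & ax[[3]] <= hi[3])
      if (!length(ii) || !length(jj) || !length(kk)) next
      px <- ax[[1]][ii]; py <- ax[[2]][jj]; pz <- ax[[3]][kk]
      g <- expand.grid(x = px, y = py, z = pz)
      v <- p1 - p0
      vv <- sum(v^2)
      wx <- g$x - p0[1]; wy <- g$y - p0[2]; wz <- g$z - p0[3]
      t <- if (vv > 0) pmin(1, pmax(0, (wx * v[1] + wy * v[2] + wz * v[3]) / vv)) else 0
      dx <- wx - t * v[1]; dy <- wy - t * v[2]; dz <- wz - t * v[3]
      hit <- (dx * dx + dy * dy + dz * dz) <= r * r
      if (!any(hit)) next
      idx <- cbind(rep(ii, times = length(jj) * length(kk)),
                   rep(rep(jj, each = length(ii)), times = length(kk)),
                   rep(kk, each = length(ii) * length(jj)))[hit, , drop = FALSE]
      lin <- idx[, 1] + d[1] * (idx[, 2] - 1) + d[1] * d[2] * (idx[, 3] - 1)
      # larger vessels own contested voxels
      take <- diam[lin] < 2 * r
      lin <- lin[take]
      mask[lin] <- TRUE
      segid[lin] <- s
      diam[lin] <- 2 * r
    }
  }
  list(mask = new_volume(mask * 1, grid$voxdim, grid$origin),
       segment = new_volume(segid, grid$voxdim, grid$origin),
       diameter = new_volume(diam, grid$voxdim, grid$origin))
}

#' Serialize / deserialize a vascular tree as JSON
#' @param tree a `vascular_tree`.
#' @param path file path.
#' @export
write_tree_json <- function(tree, path) {
  jsonlite::write_json(list(segments = tree$segments,
                            roots = as.data.frame(tree$roots),
                            params = tree$params, seed = tree$seed),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_tree_json
#' @export
read_tree_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(segments = as.data.frame(x$segments),
                 roots = as.matrix(x$roots), params = x$params,
                 seed = x$seed),
            class = "vascular_tree")
}
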