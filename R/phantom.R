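#' Modality visibility profile
#'
#' Encodes what a vascular imaging modality resolves: vessels below
#' `min_visible_diameter` are invisible to it, and the rendered image carries
#' the stated blur and additive noise. The study's three defaults stand in
#' for catheter angiography (everything visible), MR angiography/venography
#' (>= 2 mm) and gadolinium-enhanced MR (>= 4 mm).
#'
#' @param name text label.
#' @param min_visible_diameter mm; vessels with smaller true diameter are not
#'   rendered.
#' @param blur_sigma mm Gaussian blur (partial-volume stand-in).
#' @param noise_sd additive Gaussian noise SD (intensity units).
#' @param contrast tube intensity before blur/noise.
#' @export
modality_profile <- function(name, min_visible_diameter = 0,
                             blur_sigma = 0.5, noise_sd = 0.05,
                             contrast = 1) {
  stopifnot(min_visible_diameter >= 0, blur_sigma >= 0, noise_sd >= 0)
  structure(list(name = name, min_visible_diameter = min_visible_diameter,
                 blur_sigma = blur_sigma, noise_sd = noise_sd,
                 contrast = contrast),
            class = "modality_profile")
}

#' Default modality profiles of the synthetic study
#' @param noise_sd noise level shared by the three profiles.
#' @return named list of three [modality_profile()]s: `gold` (delta = 0 mm),
#'   `mid` (delta = 2 mm), `low` (delta = 4 mm).
#' @export
default_profiles <- function(noise_sd = 0.05) {
  list(gold = modality_profile("gold", 0, noise_sd = noise_sd),
       mid = modality_profile("mid", 2, noise_sd = noise_sd),
       low = modality_profile("low", 4, noise_sd = noise_sd))
}

#' Render a vascular tree as a modality image
#'
#' Voxels inside any tube whose true diameter is at least the profile's
#' visibility cutoff receive the profile contrast; sub-threshold vessels
#' contribute nothing. Gaussian blur then additive Gaussian noise follow.
#' An optional known affine misalignment can be applied (the truth transform
#' is returned as an attribute so registration can be validated against it).
#'
#' @param tree a `vascular_tree`.
#' @param profile a [modality_profile()].
#' @param grid grid spec (list with `dim`, `voxdim`, `origin`).
#' @param seed integer seed for the noise (and misalignment draw).
#' @param misalign `NULL` (default, no misalignment), `TRUE` to draw a random
#'   small transform (translation up to 3 voxels, rotation up to 2 degrees),
#'   or an [affine_transform()] to apply as-is.
#' @return `seeg_volume`; when misaligned, the applied transform is attached
#'   as attribute `"true_transform"`.
#' @export
render_modality <- function(tree, profile, grid, seed = 1, misalign = NULL) {
  if (nrow(tree$segments) &&
      min(grid$voxdim) > 2 * min(tree$segments$radius))
    warning("voxel size exceeds the smallest rendered vessel radius")
  ras <- rasterize_tree(tree, grid, min_diameter = profile$min_visible_diameter)
  render_from_mask(ras$mask, profile, seed, misalign)
}

# blur/noise/misalignment stage shared by render_modality and make_phantom
# (which reuses its cached full-visibility rasterization)
render_from_mask <- function(mask, profile, seed, misalign = NULL) {
  grid <- vol_grid(mask)
  img <- mask
  img$data <- (mask$data > 0) * profile$contrast
  tr <- NULL
  with_seed(seed, {
    if (isTRUE(misalign)) {
      tr <- affine_transform(rotation = runif(3, -2, 2),
                             translation = runif(3, -3, 3) * grid$voxdim,
                             center = grid$origin + (grid$dim - 1) * grid$voxdim / 2)
    } else if (inherits(misalign, "affine_transform")) {
      tr <- misalign
    }
    if (!is.null(tr)) img <- resample_volume(img, tr, grid)
    if (profile$blur_sigma > 0) img <- gaussian_smooth(img, profile$blur_sigma)
    if (profile$noise_sd > 0)
      img$data <- img$data + array(rnorm(prod(grid$dim), 0, profile$noise_sd),
                                   grid$dim)
  })
  if (!is.null(tr)) attr(img, "true_transform") <- tr
  img
}

#' Subdivided icosahedron sphere mesh (deterministic)
#' @param center,radius sphere parameters (mm).
#' @param subdivisions icosahedron subdivision level (3 gives 5120 faces).
#' @export
icosphere <- function(center = c(0, 0, 0), radius = 1, subdivisions = 3) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    mid_cache <- new.env()
    nv <- nrow(v)
    newf <- matrix(0L, 0, 3)
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      if (!is.null(mid_cache[[key]])) return(mid_cache[[key]])
      m <- (v[a, ] + v[b, ]) / 2
      m <- m / sqrt(sum(m^2))
      v <<- rbind(v, m)
      mid_cache[[key]] <- nrow(v)
      nrow(v)
    }
    for (t in seq_len(nrow(f))) {
      a <- f[t, 1]; b <- f[t, 2]; cc <- f[t, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      newf <- rbind(newf, c(a, ab, ca), c(b, bc, ab), c(cc, ca, bc),
                    c(ab, bc, ca))
    }
    f <- newf
  }
  surface_mesh(sweep(v * radius, 2, center, "+"), f)
}

#' Phantom configuration
#'
#' Study conditions of the synthetic cohort: a spherical head with a
#' gray-matter ribbon carrying deep sulcal infoldings, a skull shell, deep
#' target regions, and one vascular tree imaged at three fidelities.
#'
#' @param n grid size per axis (voxels).
#' @param voxdim isotropic voxel size mm.
#' @param brain_radius intracranial sphere radius mm.
#' @param gm_thickness cortical ribbon thickness mm.
#' @param n_sulci number of sulcal infoldings.
#' @param sulcus_depth mm range of fold depths.
#' @param sulcus_width mm slab thickness of a fold.
#' @param skull_radius skull sphere radius mm.
#' @param n_target_rois number of deep target regions.
#' @param roi_radius mm target sphere radius.
#' @param roi_depth mm distance of ROI centers from the brain surface.
#' @param roi_clearance mm minimum clearance of an ROI center from vessel
#'   surfaces (targets are chosen where an avascular corridor can exist, as
#'   in clinical target selection).
#' @param roi_separation mm nominal spacing between ROI centers (achieved
#'   through a wide-angle direction set; used for validation).
#' @param tree_params passed to [grow_vascular_tree()].
#' @param n_roots roots of the vascular tree.
#' @param profiles named list of [modality_profile()]s.
#' @export
phantom_config <- function(n = 96, voxdim = 1, brain_radius = 40,
                           gm_thickness = 4, n_sulci = 6,
                           sulcus_depth = c(10, 16), sulcus_width = 3,
                           skull_radius = 44, n_target_rois = 8,
                           roi_radius = 5, roi_depth = 18,
                           roi_clearance = 4.5, roi_separation = 22,
                           tree_params = list(), n_roots = 2,
                           profiles = default_profiles()) {
  cfg <- list(n = n, voxdim = voxdim, brain_radius = brain_radius,
              gm_thickness = gm_thickness, n_sulci = n_sulci,
              sulcus_depth = sulcus_depth, sulcus_width = sulcus_width,
              skull_radius = skull_radius, n_target_rois = n_target_rois,
              roi_radius = roi_radius, roi_depth = roi_depth,
              roi_clearance = roi_clearance, roi_separation = roi_separation,
              tree_params = tree_params, n_roots = n_roots,
              profiles = profiles)
  bad <- character(0)
  if (cfg$n_target_rois < 1) bad <- c(bad, "n_target_rois")
  if (length(cfg$profiles) < 1 ||
      !all(vapply(cfg$profiles, inherits, TRUE, "modality_profile")))
    bad <- c(bad, "profiles")
  if (cfg$brain_radius >= cfg$skull_radius) bad <- c(bad, "brain_radius/skull_radius")
  if (cfg$skull_radius * 2 >= cfg$n * cfg$voxdim) bad <- c(bad, "skull_radius/n")
  if (length(bad)) stop("phantom_config: inconsistent fields: ",
                        paste(bad, collapse = ", "))
  cfg
}

rand_unit_vector <- function() {
  v <- rnorm(3)
  v / sqrt(sum(v^2))
}

# unit vectors roughly evenly spread (seeded)
spread_directions <- function(k) {
  # Fibonacci sphere with a random rotation already applied by caller's RNG
  i <- seq_len(k) - 0.5
  phi <- acos(1 - 2 * i / k)
  theta <- pi * (1 + sqrt(5)) * i + runif(1, 0, 2 * pi)
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# k directions with a guaranteed wide pairwise angle (randomly rotated
# octahedron / cube vertices for k <= 8, Fibonacci beyond), consuming the
# caller's RNG for the rotation
separated_directions <- function(k) {
  base <- if (k <= 6) {
    rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
          c(0, 0, 1), c(0, 0, -1))[seq_len(k), , drop = FALSE]
  } else if (k <= 8) {
    (as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1))) /
       sqrt(3))[seq_len(k), , drop = FALSE]
  } else {
    spread_directions(k)
  }
  rot <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(rot) < 0) rot[, 1] <- -rot[, 1]
  base %*% rot
}

#' Generate a complete seeded head phantom
#'
#' @param seed integer seed; all of tree growth, ROI placement, fold
#'   placement and image noise derive from it.
#' @param config a [phantom_config()].
#' @return object of class `seeg_phantom`: grid, `intracranial_mask`,
#'   `gm_mask`, `skull_mesh`, `target_rois` (label volume, 1..K),
#'   `sulci_dirs`, `tree`, `truth` (segment/diameter volumes from the
#'   full-visibility rasterization), and `modality_images` (named list).
#' @export
make_phantom <- function(seed, config = phantom_config()) {
  cfg <- config
  grid <- list(dim = rep(cfg$n, 3), voxdim = rep(cfg$voxdim, 3),
               origin = c(0, 0, 0))
  # center of the field of view (not of the voxel lattice), so the phantom
  # geometry is identical across grid resolutions
  ctr <- grid$dim * grid$voxdim / 2
  ax <- lapply(1:3, function(a) (seq_len(grid$dim[a]) - 1) * grid$voxdim[a])
  # radius field
  dx <- ax[[1]] - ctr[1]; dy <- ax[[2]] - ctr[2]; dz <- ax[[3]] - ctr[3]
  r2 <- outer(outer(dx^2, dy^2, "+"), dz^2, "+")
  rr <- sqrt(r2)
  icv <- rr <= cfg$brain_radius

  out <- with_seed(seed, {
    # gray matter: outer ribbon + sulcal slabs reaching inward
    gm <- icv & rr >= (cfg$brain_radius - cfg$gm_thickness)
    dirs <- spread_directions(max(cfg$n_sulci, 1))
    xs <- array(rep(dx, times = cfg$n^2), grid$dim)
    ys <- array(rep(rep(dy, each = cfg$n), times = cfg$n), grid$dim)
    zs <- array(rep(dz, each = cfg$n^2), grid$dim)
    if (cfg$n_sulci > 0) {
      for (s in seq_len(cfg$n_sulci)) {
        nrm <- dirs[s, ]
        depth <- runif(1, cfg$sulcus_depth[1], cfg$sulcus_depth[2])
        # slab through the fold axis, limited to the outer `depth` shell
        proj <- xs * nrm[1] + ys * nrm[2] + zs * nrm[3]
        lateral2 <- r2 - proj^2
        fold <- icv & proj > 0 & abs(sqrt(pmax(lateral2, 0))) <= cfg$sulcus_width / 2 &
          rr >= (cfg$brain_radius - depth)
        gm <- gm | fold
      }
    }

    # vascular tree confined to the brain interior; the growth domain is
    # rasterized at a fixed 1 mm resolution so the truth tree depends only
    # on the seed and the anatomy, never on the rendering grid
    dn <- as.integer(round(grid$dim * grid$voxdim))
    dax <- lapply(1:3, function(a) (seq_len(dn[a]) - 1) - ctr[a])
    drr <- sqrt(outer(outer(dax[[1]]^2, dax[[2]]^2, "+"), dax[[3]]^2, "+"))
    dom <- new_volume((drr <= cfg$brain_radius - 2) * 1, c(1, 1, 1),
                      grid$origin)
    tree <- grow_vascular_tree(seed + 1000L, dom, n_roots = cfg$n_roots,
                               branch_params = cfg$tree_params)
    truth <- rasterize_tree(tree, grid, min_diameter = 0)

    # deep target ROIs: placed, as in clinical target selection, where the
    # center keeps a vascular clearance; rejection-sample directions
    rois <- array(0L, grid$dim)
    roi_centers <- matrix(0, cfg$n_target_rois, 3)
    # ROI directions from a rotated wide-angle set, so centers stay
    # pairwise separated by construction; per-ROI jitter picks the
    # best-cleared nearby spot (as clinical target selection would)
    base_dirs <- separated_directions(cfg$n_target_rois)
    n_try <- 60L
    for (k in seq_len(cfg$n_target_rois)) {
      # escalate the jitter cone until a vascular-cleared center is found;
      # the widest cone still keeps centers pairwise separated well beyond
      # the trajectory-spacing floor
      cpt <- NULL; best_pt <- NULL; best_clear <- -Inf
      for (sd_j in c(0.07, 0.12, 0.2, 0.3)) {
        jit <- matrix(rnorm(3 * n_try, sd = sd_j), n_try, 3)
        dirs_k <- sweep(jit, 2, base_dirs[k, ], "+")
        dirs_k <- dirs_k / sqrt(rowSums(dirs_k^2))
        depths <- cfg$roi_depth + runif(n_try, -3, 3)
        cand_pts <- sweep(dirs_k * (cfg$brain_radius - depths), 2, ctr, "+")
        cand_clear <- tree_surface_distance(cand_pts, tree)
        if (max(cand_clear) > best_clear) {
          best_clear <- max(cand_clear)
          best_pt <- cand_pts[which.max(cand_clear), ]
        }
        if (any(cand_clear >= cfg$roi_clearance)) {
          cpt <- cand_pts[which(cand_clear >= cfg$roi_clearance)[1], ]
          break
        }
      }
      if (is.null(cpt)) cpt <- best_pt
      roi_centers[k, ] <- cpt
      ball <- ((xs - (cpt[1] - ctr[1]))^2 + (ys - (cpt[2] - ctr[2]))^2 +
                 (zs - (cpt[3] - ctr[3]))^2) <= cfg$roi_radius^2
      rois[ball & icv & rois == 0L] <- k
    }

    imgs <- list()
    for (nm in names(cfg$profiles)) {
      pr <- cfg$profiles[[nm]]
      vis <- truth$mask
      vis$data <- (truth$diameter$data >= pr$min_visible_diameter &
                     truth$mask$data > 0) * 1
      imgs[[nm]] <- render_from_mask(vis, pr,
                                     seed = seed + match(nm, names(cfg$profiles)))
    }

    list(gm = gm, rois = rois, roi_centers = roi_centers, tree = tree,
         truth = truth, imgs = imgs, sulci_dirs = dirs)
  })

  structure(list(
    grid = grid, seed = seed, config = cfg, center = ctr,
    intracranial_mask = new_volume(icv * 1, grid$voxdim, grid$origin),
    gm_mask = new_volume(out$gm * 1, grid$voxdim, grid$origin),
    skull_mesh = icosphere(ctr, cfg$skull_radius, subdivisions = 3),
    target_rois = new_volume(out$rois, grid$voxdim, grid$origin),
    roi_centers = out$roi_centers,
    tree = out$tree, truth = out$truth,
    modality_images = out$imgs, sulci_dirs = out$sulci_dirs),
    class = "seeg_phantom")
}

#' @export
print.seeg_phantom <- function(x, ...) {
  cat("<seeg_phantom> seed ", x$seed, ", grid ",
      paste(x$grid$dim, collapse = "x"), " @ ",
      signif(x$grid$voxdim[1], 3), " mm, ",
      nrow(x$tree$segments), " vessel segments, ",
      length(x$modality_images), " modality images\n", sep = "")
  invisible(x)
}
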