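test_that("isosurface of a ball recovers its radius and area", {
  vol <- sphere_volume(40, radius = 12)
  mesh <- smooth_surface(vol)
  ctr <- rep(19.5, 3)
  rad <- sqrt(rowSums(sweep(mesh$vertices, 2, ctr)^2))
  expect_true(all(abs(rad - 12) <= 1))
  expect_lt(abs(mesh_area(mesh) - 4 * pi * 12^2) / (4 * pi * 12^2), 0.15)
})

test_that("isosurface threshold handling: bounds and empty surfaces", {
  vol <- sphere_volume(40, radius = 12)
  expect_error(extract_vessel_surface(vol, 2), "outside image intensity")
  expect_error(extract_vessel_surface(vol, -1), "outside image intensity")
  # at the global max nothing exceeds the iso value: empty mesh, warning
  expect_warning(m <- extract_vessel_surface(vol, max(vol$data)), "empty")
  expect_equal(nrow(m$faces), 0)
})

test_that("tube isosurface has cylinder topology and area", {
  vol <- cylinder_volume(60, radius = 3)
  mesh <- smooth_surface(vol)
  comp <- mesh_components(mesh)
  expect_equal(max(comp), 1)
  # closed cylinder (capped at the volume boundary): Euler characteristic 2
  ne <- nrow(mesh$faces) * 3 / 2
  expect_equal(nrow(mesh$vertices) - ne + nrow(mesh$faces), 2)
  lateral <- 2 * pi * 3 * 60
  caps <- 2 * pi * 3^2
  expect_lt(abs(mesh_area(mesh) - (lateral + caps)) / lateral, 0.15)
})

test_that("small-component removal keeps exactly the large structures", {
  base <- cylinder_volume(60, radius = 3)
  # five specks well separated from the tube
  for (p in list(c(5, 5, 5), c(50, 8, 10), c(8, 50, 20), c(50, 50, 40),
                 c(10, 10, 55))) {
    sl <- lapply(p, function(x) x:(x + 1))
    base$data[sl[[1]], sl[[2]], sl[[3]]] <- 1
  }
  mesh <- smooth_surface(base)
  expect_gt(max(mesh_components(mesh)), 1)
  kept <- remove_small_components(mesh, 500)
  expect_equal(max(mesh_components(kept)), 1)
  # surviving geometry unchanged: every kept vertex existed before
  expect_true(all(kept$vertices %in% mesh$vertices))
  expect_identical(remove_small_components(mesh, 0)$vertices, mesh$vertices)
  expect_equal(nrow(remove_small_components(mesh, 1e6)$vertices), 0)
})

test_that("diameter pruning follows the strict-below convention", {
  tree <- three_branch_tree()   # diameters 1, 3, 5 mm
  ras <- rasterize_tree(tree, grid80())
  mesh <- smooth_surface(ras$mask)
  mesh$vertex_radius <- tree_vertex_radii(mesh, tree)
  branch_of <- function(m) {
    # branch id of each vertex by nearest tube axis x-position
    sapply(m$vertices[, 1], function(x) which.min(abs(c(20, 40, 60) - x)))
  }
  surviving <- function(th) sort(unique(branch_of(prune_by_diameter(mesh, th))))
  expect_identical(surviving(1), 1:3)      # diameter 1 survives at its own size
  expect_identical(surviving(2), 2:3)
  expect_identical(surviving(3), 2:3)      # diameter 3 survives at 3
  expect_identical(surviving(4), 3L)
  expect_identical(prune_by_diameter(mesh, 0), mesh)
  # uniformly thin tube vanishes above its diameter
  thin <- smooth_surface(rasterize_tree(two_tube_tree(radii = 0.5, x = 40),
                                        grid80())$mask)
  thin$vertex_radius <- rep(0.5, nrow(thin$vertices))
  expect_equal(nrow(prune_by_diameter(thin, 2)$vertices), 0)
  expect_error(prune_by_diameter(smooth_surface(ras$mask), 2), "vertex_radius")
})

test_that("pruned vertex sets nest with increasing threshold", {
  ph <- cached_phantom()
  gold <- truth_vessel_model(ph)
  keyset <- function(m) paste(m$vertices[, 1], m$vertices[, 2], m$vertices[, 3])
  prev <- keyset(gold)
  for (th in c(1, 2, 3, 4)) {
    cur <- keyset(prune_by_diameter(gold, th))
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("centerline radii recover cylinder truth within half a voxel", {
  for (r0 in c(1.5, 2, 3, 4)) {
    vol <- cylinder_volume(40, cx = 20, cy = 20, radius = r0)
    mesh <- smooth_surface(vol)
    est <- extract_centerline_radii(mesh, vol_grid(vol))
    expect_lt(abs(median(est$vertex_radius) - r0), 0.5)
    expect_true(all(est$vertex_radius > 0))
  }
})

test_that("sphere centerline degenerates to the center", {
  vol <- sphere_volume(40, radius = 10)
  mesh <- smooth_surface(vol)
  est <- extract_centerline_radii(mesh, vol_grid(vol))
  expect_lt(abs(median(est$vertex_radius) - 10), 1)
  expect_gt(min(est$vertex_radius), 8)
})

test_that("two-cylinder trees preserve the radius ordering per branch", {
  tree <- two_tube_tree(radii = c(1, 3), x = c(20, 55), len = c(10, 70))
  ras <- rasterize_tree(tree, grid80())
  mesh <- smooth_surface(ras$mask)
  est <- extract_centerline_radii(mesh, grid80())
  b <- ifelse(est$vertices[, 1] < 37, 1, 2)
  m1 <- median(est$vertex_radius[b == 1])
  m2 <- median(est$vertex_radius[b == 2])
  expect_lt(m1, m2)
  expect_lt(abs(m1 - 1), 0.6)
  expect_lt(abs(m2 - 3), 0.6)
})

test_that("sulcal model keeps only gray matter deeper than the erosion", {
  ph <- cached_phantom()
  # voxel-level oracle: GM AND eroded intracranial mask
  er <- erode_mask(ph$intracranial_mask, 5)
  oracle <- as.logical(ph$gm_mask$data) & as.logical(er$data)
  msk <- sulcal_mask(ph$gm_mask, ph$intracranial_mask, 5)
  expect_identical(as.logical(msk$data), oracle)
  mesh <- extract_sulcal_model(ph$gm_mask, ph$intracranial_mask, 5)
  expect_gt(nrow(mesh$vertices), 0)
  # every sulcal vertex is near the oracle mask and far from the outer ribbon
  d_out <- distance_map(new_volume((ph$intracranial_mask$data <= 0) * 1,
                                   ph$grid$voxdim, ph$grid$origin))
  expect_gt(min(sample_volume(d_out, mesh$vertices)), 3.5)
  # erosion deeper than any fold removes everything
  expect_warning(m2 <- extract_sulcal_model(ph$gm_mask, ph$intracranial_mask,
                                            30), "removed all")
  expect_equal(nrow(m2$faces), 0)
  # zero erosion keeps the full GM surface
  m0 <- extract_sulcal_model(ph$gm_mask, ph$intracranial_mask, 0)
  expect_gt(nrow(m0$vertices), nrow(mesh$vertices))
})

test_that("noiseless phantom segmentation reaches full recall on thick vessels", {
  ph <- cached_phantom()
  profiles <- list(gold = modality_profile("gold", 0, noise_sd = 0))
  img <- render_modality(ph$tree, profiles$gold, ph$grid, seed = 1)
  mesh <- segment_vessel_model(img, ph$intracranial_mask)
  segs <- ph$tree$segments
  thick <- segs[2 * segs$radius >= 2, ]
  mids <- cbind((thick$x0 + thick$x1) / 2, (thick$y0 + thick$y1) / 2,
                (thick$z0 + thick$z1) / 2)
  d <- point_mesh_distance(mids, mesh)
  # every thick segment's midpoint lies within its radius + 1 voxel of the
  # extracted surface
  expect_true(all(d <= thick$radius + 1))
})
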