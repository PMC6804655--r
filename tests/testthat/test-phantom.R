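test_that("default phantom has the advertised structure", {
  ph <- cached_phantom()
  expect_s3_class(ph, "seeg_phantom")
  expect_equal(ph$grid$dim, rep(96, 3))
  expect_equal(ph$grid$voxdim, rep(1, 3))
  expect_length(ph$modality_images, 3)
  expect_true(all(vapply(ph$modality_images, function(v)
    identical(dim(v$data), rep(96L, 3)), logical(1))))
  # gm is inside the intracranial mask; ROIs are inside the brain
  expect_true(all(ph$intracranial_mask$data[ph$gm_mask$data > 0] > 0))
  expect_true(all(ph$intracranial_mask$data[ph$target_rois$data > 0] > 0))
  expect_equal(max(ph$target_rois$data), 8)
  # deep sulcal folds exist: gm voxels well below the outer ribbon
  depth <- distance_map(new_volume((ph$intracranial_mask$data <= 0) * 1,
                                   ph$grid$voxdim, ph$grid$origin))
  expect_gt(sum(ph$gm_mask$data > 0 & depth$data > 8), 0)
})

test_that("phantom generation is deterministic and seed-isolated", {
  cfg <- phantom_config(n = 48, voxdim = 2, n_target_rois = 4,
                        skull_radius = 44)
  a <- make_phantom(3, cfg)
  b <- make_phantom(3, cfg)
  c <- make_phantom(4, cfg)
  expect_identical(a$tree$segments, b$tree$segments)
  expect_identical(a$modality_images$gold$data, b$modality_images$gold$data)
  expect_false(identical(a$tree$segments, c$tree$segments))
  # mask construction parameters shared across seeds
  expect_identical(dim(a$intracranial_mask$data), dim(c$intracranial_mask$data))
  expect_equal(sum(a$intracranial_mask$data), sum(c$intracranial_mask$data))
})

test_that("a coarser grid preserves the underlying truth tree", {
  cfg1 <- phantom_config(n = 48, voxdim = 2, n_target_rois = 4)
  a <- make_phantom(3, cfg1)
  expect_equal(a$grid$voxdim, rep(2, 3))
  # truth tree identical to the fine-grid phantom of the same seed
  cfg2 <- phantom_config(n = 96, voxdim = 1, n_target_rois = 4)
  b <- make_phantom(3, cfg2)
  expect_identical(a$tree$segments, b$tree$segments)
})

test_that("config inconsistencies are reported by field", {
  expect_error(phantom_config(n_target_rois = 0), "n_target_rois")
  expect_error(phantom_config(brain_radius = 50, skull_radius = 44),
               "brain_radius")
  expect_error(phantom_config(profiles = list(1, 2)), "profiles")
})

test_that("modality rendering honors the visibility cutoff", {
  g <- grid80()
  # a single 3 mm-diameter tube is invisible to a 4 mm profile
  tube <- two_tube_tree(radii = 1.5, x = 40, len = c(10, 70))
  prof4 <- modality_profile("low", 4, blur_sigma = 0, noise_sd = 0.05)
  img <- render_modality(tube, prof4, g, seed = 1)
  expect_lt(max(abs(img$data)), 5 * 0.05 * 1.2)   # pure noise level
  expect_equal(mean(img$data), 0, tolerance = 0.01)
  # noiseless blur-free rendering is exactly the contrast on the tube
  prof0 <- modality_profile("gold", 0, blur_sigma = 0, noise_sd = 0)
  img0 <- render_modality(tube, prof0, g, seed = 1)
  expect_setequal(unique(as.numeric(img0$data)), c(0, 1))
  expect_equal(img0$data[41, 41, 41], 1)
  # both tubes of a 2/6 mm pair are present at a 2 mm cutoff
  pair <- two_tube_tree(radii = c(1, 3), x = c(20, 55), len = c(10, 70))
  prof2 <- modality_profile("mid", 2, blur_sigma = 0.5, noise_sd = 0.05)
  img2 <- render_modality(pair, prof2, g, seed = 2)
  axis_a <- cbind(20, 40, 15:65)
  axis_b <- cbind(55, 40, 15:65)
  expect_gt(mean(sample_volume(img2, axis_a)), 5 * 0.05)
  expect_gt(mean(sample_volume(img2, axis_b)), 5 * 0.05)
})

test_that("rendered vessel sets nest with decreasing visibility", {
  ph <- cached_phantom()
  segs <- ph$tree$segments
  vis <- function(delta) which(2 * segs$radius >= delta)
  expect_true(all(vis(4) %in% vis(2)))
  expect_true(all(vis(2) %in% vis(0)))
  # and the rendered images reflect it: the low image has no signal where
  # only thin vessels run
  thin_only <- ph$truth$diameter$data > 0 & ph$truth$diameter$data < 2
  img_low <- ph$modality_images$low
  expect_lt(mean(img_low$data[thin_only]), 0.5)
})

test_that("misaligned rendering stores the recoverable truth transform", {
  tube <- two_tube_tree(radii = c(1, 3), x = c(30, 50), len = c(15, 65))
  prof <- modality_profile("gold", 0, noise_sd = 0)
  img <- render_modality(tube, prof, grid80(), seed = 9, misalign = TRUE)
  tr <- attr(img, "true_transform")
  expect_s3_class(tr, "affine_transform")
  expect_true(all(abs(tr$translation) <= 3))
  expect_true(all(abs(tr$rotation) <= 2))
  # applying the inverse restores the aligned rendering (up to resampling)
  aligned <- render_modality(tube, prof, grid80(), seed = 9)
  back <- resample_volume(img, inverse_transform(tr), grid80())
  inside <- aligned$data > 0.5
  expect_gt(mean(back$data[inside]), 0.5)
})
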