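test_that("NMI is maximal at self-alignment and near 1 for noise", {
  img <- reg_image()
  self <- normalized_mutual_information(img, img)
  g <- vol_grid(img)
  for (tvec in list(c(3, 0, 0), c(0, -4, 2), c(6, 6, 0))) {
    sh <- resample_volume(img, affine_transform(translation = tvec), g,
                          outside = NA)
    expect_lt(normalized_mutual_information(img, sh), self)
  }
  # bijective intensity remapping leaves the score unchanged
  inv <- img
  inv$data <- max(img$data) - img$data
  expect_equal(normalized_mutual_information(img, inv), self,
               tolerance = 1e-10)
  # independent noise: score near the independence floor of 1
  noise <- new_volume(array(with_seed(4, rnorm(80^3)), rep(80, 3)))
  expect_lt(normalized_mutual_information(img, noise), 1.05)
  expect_gte(normalized_mutual_information(img, noise), 1)
  expect_error(normalized_mutual_information(img, new_volume(
    array(NA_real_, rep(80, 3)))), "empty overlap")
})

test_that("transforms compose, invert and scale mesh radii correctly", {
  t <- affine_transform(rotation = c(4, -3, 2), translation = c(5, -2, 1),
                        scale = c(1.02, 0.98, 1.05), center = c(40, 40, 40))
  m <- icosphere(c(40, 40, 40), 10, 2)
  m$vertex_radius <- rep(1, nrow(m$vertices))
  # identity and pure translation
  expect_equal(transform_mesh(m, affine_transform())$vertices, m$vertices)
  tt <- affine_transform(translation = c(2, 3, -1))
  expect_equal(transform_mesh(m, tt)$vertices,
               sweep(m$vertices, 2, c(2, 3, -1), "+"))
  # doubling scale doubles centroid distances and vertex radii
  ts <- affine_transform(scale = c(2, 2, 2), center = c(40, 40, 40))
  ms <- transform_mesh(m, ts)
  expect_equal(sqrt(rowSums(sweep(ms$vertices, 2, c(40, 40, 40))^2)),
               2 * sqrt(rowSums(sweep(m$vertices, 2, c(40, 40, 40))^2)))
  expect_equal(ms$vertex_radius, rep(2, nrow(m$vertices)))
  # round trip through the inverse
  mr <- transform_mesh(transform_mesh(m, t), inverse_transform(t))
  expect_lt(max(abs(mr$vertices - m$vertices)), 1e-6)
  # radii scale by the mean factor, so anisotropic round trips are only
  # approximate (mean(s) * mean(1/s) != 1)
  expect_lt(max(abs(mr$vertex_radius - m$vertex_radius)), 1e-2)
  expect_error(affine_transform(scale = c(1, -1, 1)), "positive")
})

test_that("identity and known affines are recovered from noiseless images", {
  img <- reg_image()
  g <- vol_grid(img)
  # moving = fixed: identity within tolerance
  t0 <- suppressWarnings(register_affine_nmi(img, img, n_starts = 1))
  expect_lt(max(abs(t0$translation)), 0.5)
  expect_lt(max(abs(t0$rotation)), 0.5)
  expect_lt(max(abs(t0$scale - 1)), 0.01)

  # translation by (3, -2, 1) voxels
  tr <- affine_transform(translation = c(3, -2, 1), center = c(39.5, 39.5, 39.5))
  mov <- resample_volume(img, inverse_transform(tr), g)
  fit <- register_affine_nmi(img, mov, seed = 1)
  expect_lt(max(abs(fit$translation - c(3, -2, 1))), 0.5)

  # isotropic scale 1.05 recovered within 1%
  ts <- affine_transform(scale = rep(1.05, 3), center = c(39.5, 39.5, 39.5))
  mov2 <- resample_volume(img, inverse_transform(ts), g)
  fit2 <- register_affine_nmi(img, mov2, seed = 1)
  expect_lt(max(abs(fit2$scale - 1.05)), 0.01)
})
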