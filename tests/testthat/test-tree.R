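domain40 <- sphere_volume(n = 84, center = c(41.5, 41.5, 41.5), radius = 40)

test_that("generated trees satisfy their structural contract", {
  tree <- grow_vascular_tree(1, domain40, n_roots = 2)
  s <- tree$segments
  expect_gte(nrow(s), 20)
  expect_equal(max(s$radius), 4.0)
  expect_lte(min(s$radius), 1.0)   # thin calibers present for pruning sweeps
  expect_true(all(s$radius > 0))
  # child radius never exceeds the parent's
  for (i in seq_len(nrow(s))) {
    p <- s$parent[i]
    if (p > 0) expect_lte(s$radius[i], s$radius[p] + 1e-12)
  }
  # forest: parents precede children, so no cycles are possible
  expect_true(all(s$parent < seq_len(nrow(s))))
  # endpoints stay inside the domain
  ends <- rbind(as.matrix(s[, c("x0", "y0", "z0")]),
                as.matrix(s[, c("x1", "y1", "z1")]))
  expect_true(all(lookup_volume(domain40, ends) > 0))
})

test_that("tree generation is deterministic and seed-sensitive", {
  t1 <- grow_vascular_tree(5, domain40)
  t2 <- grow_vascular_tree(5, domain40)
  t3 <- grow_vascular_tree(6, domain40)
  expect_identical(t1$segments, t2$segments)
  expect_false(identical(t1$segments, t3$segments))
})

test_that("edge cases: no roots, empty domain", {
  t0 <- grow_vascular_tree(1, domain40, n_roots = 0)
  expect_equal(nrow(t0$segments), 0)
  empty <- domain40
  empty$data[] <- 0
  expect_error(grow_vascular_tree(1, empty), "empty domain")
})

test_that("tree JSON serialization round-trips", {
  tree <- grow_vascular_tree(3, domain40)
  path <- tempfile(fileext = ".json")
  write_tree_json(tree, path)
  back <- read_tree_json(path)
  expect_equal(back$segments$radius, tree$segments$radius)
  expect_equal(back$segments$x1, tree$segments$x1)
  unlink(path)
})

test_that("rasterization recovers per-voxel ground truth", {
  tree <- two_tube_tree(radii = c(1, 3), x = c(20, 55), len = c(10, 70))
  ras <- rasterize_tree(tree, grid80())
  # voxel at the center of each tube belongs to it, with its true diameter
  expect_equal(ras$segment$data[21, 41, 41], 1)
  expect_equal(ras$diameter$data[21, 41, 41], 2)
  expect_equal(ras$segment$data[56, 41, 41], 2)
  expect_equal(ras$diameter$data[56, 41, 41], 6)
  expect_equal(ras$diameter$data[5, 5, 5], 0)
  # visibility filter drops the thin tube entirely
  ras2 <- rasterize_tree(tree, grid80(), min_diameter = 4)
  expect_true(all(ras2$segment$data != 1))
  expect_true(any(ras2$segment$data == 2))
})
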