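test_that("constant images give an identically zero response", {
  v <- new_volume(array(3, c(20, 20, 20)))
  resp <- sato_vesselness(v, vesselness_params(scales = c(1, 2)))
  expect_true(all(resp$data == 0))
  expect_error(sato_vesselness(list(data = matrix(0, 4, 4))), "3-D")
  expect_error(vesselness_params(scales = numeric(0)), "scales")
})

test_that("tubes outscore balls of the same radius and contrast", {
  tube <- gaussian_smooth(cylinder_volume(40, radius = 2), 0.5)
  ball <- gaussian_smooth(sphere_volume(40, radius = 2), 0.5)
  p <- vesselness_params(scales = c(1, 2, 3))
  rt <- sato_vesselness(tube, p)
  rb <- sato_vesselness(ball, p)
  axis_resp <- max(sample_volume(rt, cbind(19.5, 19.5, 10:30)))
  ball_resp <- sample_volume(rb, rbind(c(19.5, 19.5, 19.5)))
  expect_gt(axis_resp, ball_resp)
  expect_true(all(rt$data >= 0))
})

test_that("single-scale response peaks near the tube radius", {
  # Gaussian-profile tube of sigma 2 mm
  ax <- 0:39
  lat <- outer((ax - 19.5)^2, (ax - 19.5)^2, "+")
  prof <- exp(-lat / (2 * 2^2))
  vol <- new_volume(array(rep(prof, 40), c(40, 40, 40)))
  resp_at <- vapply(c(0.5, 1, 2, 4, 8), function(sg) {
    r <- sato_vesselness(vol, vesselness_params(scales = sg))
    max(sample_volume(r, cbind(19.5, 19.5, 15:25)))
  }, numeric(1))
  expect_equal(c(0.5, 1, 2, 4, 8)[which.max(resp_at)], 2)
})

test_that("response is covariant under joint rescaling of tube and scales", {
  gtube <- function(n, sg) {
    ax <- 0:(n - 1); c0 <- (n - 1) / 2
    lat <- outer((ax - c0)^2, (ax - c0)^2, "+")
    new_volume(array(rep(exp(-lat / (2 * sg^2)), n), c(n, n, n)))
  }
  r1 <- sato_vesselness(gtube(40, 2), vesselness_params(scales = c(1.5, 2, 3)))
  r2 <- sato_vesselness(gtube(80, 4), vesselness_params(scales = c(3, 4, 6)))
  p1 <- max(sample_volume(r1, cbind(19.5, 19.5, 10:30)))
  p2 <- max(sample_volume(r2, cbind(39.5, 39.5, 20:60)))
  expect_lt(abs(p1 - p2) / p1, 0.10)
})

test_that("intracranial masking zeroes exactly the excluded region", {
  v <- new_volume(array(runif(8000), c(20, 20, 20)))
  ones <- new_volume(array(1, c(20, 20, 20)))
  zeros <- new_volume(array(0, c(20, 20, 20)))
  half <- new_volume(array(rep(c(1, 0), each = 10 * 20 * 20) * 1,
                           c(20, 20, 20)))
  expect_equal(apply_intracranial_mask(v, ones)$data, v$data)
  expect_true(all(apply_intracranial_mask(v, zeros)$data == 0))
  hm <- apply_intracranial_mask(new_volume(array(1, c(20, 20, 20))), half)
  expect_equal(sum(hm$data), 10 * 20 * 20)
  # idempotence
  expect_equal(apply_intracranial_mask(apply_intracranial_mask(v, half), half)$data,
               apply_intracranial_mask(v, half)$data)
  bad <- new_volume(array(1, c(10, 10, 10)))
  expect_error(apply_intracranial_mask(v, bad), "grids differ")
})
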