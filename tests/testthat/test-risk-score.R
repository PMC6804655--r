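cfg128 <- risk_config()

test_that("risk score hits its anchor values", {
  n <- cfg128$n_nodes
  expect_equal(risk_score(rep(10, n), cfg128), 0)
  expect_equal(risk_score(rep(15, n), cfg128), 0)   # clamped at 10
  expect_equal(risk_score(rep(3, n), cfg128), 1)
  expect_equal(risk_score(rep(0, n), cfg128), 2)
  # hand evaluation, N = 4: one touching node switches to the risky regime
  cfg4 <- risk_config(n_nodes = 4)
  expect_equal(risk_score(c(10, 10, 10, 0), cfg4), 1 + 3 / (3 * 4))
  expect_error(risk_score(rep(5, 10), cfg128), "expected 128")
})

test_that("risk score is continuous at the 3 mm margin", {
  n <- cfg128$n_nodes
  eps <- 1e-4
  lo <- risk_score(rep(3 - eps, n), cfg128)
  hi <- risk_score(rep(3 + eps, n), cfg128)
  expect_lt(abs(lo - hi), 1e-3)
  expect_lt(abs(risk_score(rep(3 - 1e-9, n), cfg128) -
                  risk_score(rep(3 + 1e-9, n), cfg128)), 1e-6)
})

test_that("risk score is monotone under random distance perturbations", {
  n <- cfg128$n_nodes
  bad <- with_seed(99, {
    viol <- 0L
    for (rep in seq_len(10000)) {
      d <- runif(n, 0, 12)
      i <- sample.int(n, 1)
      d2 <- d
      d2[i] <- d[i] * runif(1)     # strictly decrease one node distance
      r1 <- risk_score(d, cfg128)
      r2 <- risk_score(d2, cfg128)
      if (r2 < r1 - 1e-12) viol <- viol + 1L
      if (r1 < 0 || r1 > 2 || r2 < 0 || r2 > 2) viol <- viol + 1L
    }
    viol
  })
  expect_identical(bad, 0L)
})

test_that("min distance reduces node distances correctly", {
  expect_equal(min_distance(c(4, 3, 7)), 3)
  expect_equal(min_distance(rep(Inf, 5)), Inf)
  expect_error(min_distance(numeric(0)), "empty")
})

test_that("node distances subtract the electrode radius and floor at zero", {
  # one distant triangle; brute-force distance oracle over its vertices/plane
  tri <- surface_mesh(rbind(c(0, -1, -1), c(0, 1, -1), c(0, 0, 1.5)),
                      rbind(1:3))
  es <- electrode_spec(diameter = 1.3)
  t1 <- trajectory(c(5, 0, 0), c(9, 0, 0), es, n_nodes = 8)
  d <- node_distances(t1, list(tri))
  expect_equal(d[1], 5 - 0.65)   # nearest point is on the triangle interior
  expect_equal(attr(d, "raw")[1], 5 - 0.65)
  # node on the surface floors at 0
  t2 <- trajectory(c(0, 0, 0), c(4, 0, 0), es, n_nodes = 8)
  d2 <- node_distances(t2, list(tri))
  expect_equal(d2[1], 0)
  expect_equal(attr(d2, "raw")[1], -0.65)
  # empty critical set: all infinite, risk 0 downstream
  d3 <- node_distances(trajectory(c(0, 0, 0), c(1, 0, 0), es, 128), list())
  expect_true(all(is.infinite(d3)))
  expect_equal(risk_score(as.numeric(d3), risk_config()), 0)
})
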