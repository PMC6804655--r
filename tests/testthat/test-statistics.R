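test_that("normality gate separates normal from skewed samples", {
  res <- with_seed(1, {
    norm_hits <- vapply(1:50, function(i)
      identical(as.character(normality_gate(rnorm(100))), "normal"),
      logical(1))
    exp_hits <- vapply(1:50, function(i)
      identical(as.character(normality_gate(rexp(100))), "non-normal"),
      logical(1))
    c(mean(norm_hits), mean(exp_hits))
  })
  expect_gte(res[1], 0.9)
  expect_gte(res[2], 0.9)
})

test_that("degenerate constant vectors are flagged non-normal", {
  expect_warning(g <- normality_gate(rep(1, 3)), "constant")
  expect_identical(as.character(g), "non-normal")
  expect_error(normality_gate(c(1, 2)), "at least 3")
})

test_that("paired comparison applies the Bonferroni-adjusted threshold", {
  cmp <- paired_compare(1:10, 1:10)
  expect_false(cmp$significant)
  expect_equal(cmp$p, 1)
  expect_true(cmp$all_zero)

  cmp2 <- with_seed(3, paired_compare(rnorm(30), rnorm(30) + 5,
                                      alpha_family = 0.05, n_comparisons = 3))
  expect_equal(cmp2$adjusted_alpha, 0.05 / 3)
  # truncating the adjusted alpha to three decimals gives the working 0.016
  expect_equal(floor(cmp2$adjusted_alpha * 1000) / 1000, 0.016)
  expect_equal(cmp2$adjusted_alpha * 3, 0.05)
  expect_true(cmp2$significant)
})

test_that("a one-SD paired shift at n = 80 is nearly always detected", {
  hits <- with_seed(11, vapply(1:40, function(i) {
    a <- rnorm(80)
    b <- a + rnorm(80, mean = 1, sd = 0.5)
    paired_compare(a, b)$significant
  }, logical(1)))
  expect_gte(mean(hits), 0.95)
})

test_that("squared Pearson correlation matches closed form", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson_r2(x, 2 * x + 1), 1.0)
  # hand evaluation for a 4-point set
  y <- c(2, 1, 4, 3)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson_r2(x, y), r^2)
  yy <- with_seed(5, rnorm(1000))
  xx <- with_seed(6, rnorm(1000))
  expect_lt(pearson_r2(xx, yy), 0.02)
  expect_error(pearson_r2(rep(1, 5), 1:5), "zero variance")
})

test_that("wilcoxon choice is invariant under positive affine scaling", {
  a <- with_seed(8, rexp(25)); b <- with_seed(9, rexp(25))
  p1 <- paired_compare(a, b)
  p2 <- paired_compare(10 * a + 3, 10 * b + 3)
  expect_identical(p1$test_used, p2$test_used)
  if (p1$test_used == "wilcoxon") expect_equal(p1$p, p2$p)
})
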