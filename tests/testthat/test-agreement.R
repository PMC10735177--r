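test_that("Bland-Altman reduces to closed forms", {
  ident <- bland_altman(1:3, 1:3)
  expect_equal(ident$bias, 0)
  expect_equal(ident$loa_low, 0)
  expect_equal(ident$loa_high, 0)
  # differences {1, -1}: sd = sqrt(2), limits at +/- 1.96 * sqrt(2)
  ba <- bland_altman(c(2, 1), c(1, 2))
  expect_equal(ba$bias, 0, tolerance = 1e-15)
  expect_equal(ba$loa_high, 1.96 * sqrt(2), tolerance = 1e-12)
  expect_equal(ba$loa_low, -1.96 * sqrt(2), tolerance = 1e-12)
  expect_error(bland_altman(1, 1), "two complete pairs")
})

test_that("adding a constant shifts the bias but not the limit width", {
  set.seed(7)
  a <- rnorm(50, 10)
  b <- rnorm(50, 10)
  ba <- bland_altman(a, b)
  ba_c <- bland_altman(a + 3, b)
  expect_equal(ba_c$bias, ba$bias + 3)
  expect_equal(ba_c$loa_high - ba_c$loa_low, ba$loa_high - ba$loa_low)
})

test_that("limits of agreement cover ~95% of normal differences", {
  set.seed(8)
  n <- 10000
  b <- rnorm(n, 100, 10)
  a <- b + rnorm(n, 0, 5)
  ba <- bland_altman(a, b)
  inside <- mean(ba$points$diff >= ba$loa_low & ba$points$diff <= ba$loa_high)
  expect_equal(inside, 0.95, tolerance = 0.01)
})

test_that("percent agreement follows the ratio definition and the fold", {
  expect_equal(percent_agreement(c(5, 8), c(5, 8))$raw, 100)
  expect_equal(percent_agreement(c(4, 8), c(5, 10))$raw, 80)
  mix <- percent_agreement(c(0.9, 1.1), c(1, 1))
  expect_equal(mix$raw, 100)
  expect_equal(mix$symmetrized, 90)
  # scale invariance
  set.seed(9)
  a <- runif(20, 50, 100)
  b <- runif(20, 50, 100)
  expect_equal(
    percent_agreement(a, b)$symmetrized,
    percent_agreement(3.7 * a, 3.7 * b)$symmetrized
  )
  expect_warning(percent_agreement(c(1, 2), c(0, 2)), "zero")
})

test_that("paired tests handle identical data and select by normality", {
  same <- paired_tests(1:5, 1:5)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  set.seed(101)
  b <- rnorm(60)
  d <- rnorm(60, 0.1, 0.5)
  stopifnot(stats::shapiro.test(d)$p.value > 0.2) # clearly normal fixture
  norm_choice <- paired_tests(b + d, b)
  expect_equal(norm_choice$method, "t")
  skewed <- paired_tests(b + rexp(60)^3, b)
  expect_equal(skewed$method, "wilcoxon")
  forced <- paired_tests(b + 1, b, method = "wilcoxon")
  expect_equal(forced$method, "wilcoxon")
  expect_lt(forced$p_value, 0.001)
})

test_that("a paired shift of one SD at n = 30 is reliably detected", {
  set.seed(11)
  rej <- mean(replicate(200, {
    b <- rnorm(30)
    paired_tests(b + rnorm(30, 1, 1), b)$p_value < 0.05
  }))
  expect_gt(rej, 0.9) # power far above the 5% level
})

test_that("Spearman rho is rank-invariant and signals constant input", {
  a <- c(3, 1, 4, 1.5, 9, 2.6)
  mono <- spearman_rho(exp(a), a)
  expect_equal(mono$rho, 1)
  rev <- spearman_rho(-a, a)
  expect_equal(rev$rho, -1)
  set.seed(12)
  indep <- spearman_rho(runif(1000), runif(1000))
  expect_lt(abs(indep$rho), 0.1)
  flat <- spearman_rho(rep(1, 5), 1:5)
  expect_false(flat$defined)
})

test_that("agreement statistics ignore the order of the pairs", {
  set.seed(13)
  a <- rnorm(40, 20, 4)
  b <- rnorm(40, 20, 4)
  perm <- sample(40)
  s1 <- agreement_summary(a, b)
  s2 <- agreement_summary(a[perm], b[perm])
  expect_equal(s1$bias, s2$bias)
  expect_equal(s1$loa_low, s2$loa_low)
  expect_equal(s1$rho, s2$rho)
  expect_equal(s1$pct_agreement_sym, s2$pct_agreement_sym)
  expect_equal(s1$p_value, s2$p_value)
})
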