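sim_data <- function(n = 200, seed = 1) {
  set.seed(seed)
  data.frame(
    sex = sample(c("female", "male"), n, replace = TRUE),
    age = rnorm(n, 58, 7),
    wear_h = rnorm(n, 14.5, 1),
    x = rnorm(n), y = rnorm(n), z1 = rnorm(n), z2 = rnorm(n)
  )
}

test_that("standardized beta equals Pearson r without covariates", {
  d <- sim_data(150, 2)
  d$y <- 0.5 * d$x + rnorm(150)
  r <- cor(d$x, d$y)
  expect_equal(standardized_beta("y", "x", character(0), d,
                                 transform = "never")$std_beta,
               r, tolerance = 1e-10)
  # identity: exposure == outcome
  d$y2 <- d$x
  res <- suppressWarnings(  # summary.lm flags the intentionally perfect fit
    standardized_beta("y2", "x", character(0), d, transform = "never"))
  expect_equal(res$std_beta, 1, tolerance = 1e-12)
  expect_lt(res$p, 1e-100)
})

test_that("planted effect is recovered and CI brackets it at large n", {
  set.seed(3)
  n <- 500
  d <- sim_data(n, 3)
  d$y <- -0.41 * d$x + sqrt(1 - 0.41^2) * rnorm(n)
  res <- standardized_beta("y", "x", c("sex", "age"), d, transform = "never")
  expect_equal(res$std_beta, -0.41, tolerance = 0.05)
  expect_lt(res$ci_low, res$std_beta)
  expect_gt(res$ci_high, res$std_beta)
  expect_equal(res$n, n)
})

test_that("type-I error is calibrated at the 5% level", {
  rej <- vapply(1:500, function(s) {
    d <- sim_data(64, 1000 + s)
    standardized_beta("y", "x", c("sex", "age"), d, transform = "never")$p < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)
})

test_that("errors are classed for small n and collinearity", {
  d <- sim_data(8, 4)
  expect_error(standardized_beta("y", "x", character(0), d),
               class = "metflexr_insufficient_n")
  d2 <- sim_data(50, 5)
  d2$x2 <- d2$x
  expect_error(standardized_beta("y", "x", "x2", d2, transform = "never"),
               class = "metflexr_collinearity")
})

test_that("log10 transform rule fires on skewed residuals only", {
  set.seed(6)
  expect_false(transform_rule(rnorm(200)))
  expect_true(transform_rule(rlnorm(200, 0, 1)))
  d <- sim_data(200, 7)
  d$y <- 10^(0.4 * d$x + rnorm(200, 0, 0.5))  # log-normal outcome
  res <- standardized_beta("y", "x", character(0), d, transform = "auto")
  expect_true(res$transformed)
  # idempotence: the transformed fit is what "always" would give
  res2 <- standardized_beta("y", "x", character(0), d, transform = "always")
  expect_equal(res$std_beta, res2$std_beta)
})

test_that("total-PA sensitivity refit behaves under orthogonality and collinearity", {
  set.seed(8)
  n <- 300
  d <- sim_data(n, 8)
  d$total_pa_h <- rnorm(n)  # orthogonal to x by construction
  d$y <- 0.4 * d$x + rnorm(n, 0, 0.8)
  out <- sensitivity_adjust_total_pa("y", "x", c("sex", "age"), d,
                                     transform = "never")
  expect_equal(out$base$std_beta, out$adjusted$std_beta, tolerance = 0.05)
  expect_true(all(is.finite(out$vif$vif)))
  # collinear plant: adjusting for total PA attenuates the exposure
  d2 <- d
  d2$total_pa_h <- -d2$x + rnorm(n, 0, 0.15)
  out2 <- sensitivity_adjust_total_pa("y", "x", c("sex", "age"), d2,
                                      transform = "never")
  expect_lt(abs(out2$adjusted$std_beta - out2$base$std_beta), 1)
  expect_gt(max(out2$vif$vif), 5)
  expect_true(any(out2$vif$flagged))
})

test_that("partial correlation matches the matrix-inversion oracle", {
  set.seed(9)
  for (i in 1:25) {
    n <- 60
    Z <- matrix(rnorm(n * 3), n)
    x <- 0.5 * Z[, 1] + rnorm(n)
    y <- -0.3 * Z[, 1] + 0.4 * x + rnorm(n)
    d <- data.frame(x = x, y = y, z1 = Z[, 1], z2 = Z[, 2], z3 = Z[, 3])
    got <- partial_pearson("x", "y", c("z1", "z2", "z3"), d)
    expect_equal(got$r, oracle_partial_r(x, y, Z), tolerance = 1e-10)
  }
  # y = x with no covariates gives r = 1
  d <- data.frame(x = rnorm(30)); d$y <- d$x
  expect_equal(partial_pearson("x", "y", character(0), d)$r, 1)
  # independence given covariates: small residual correlation at n = 1000
  set.seed(10)
  d2 <- data.frame(z = rnorm(1000))
  d2$x <- d2$z + rnorm(1000); d2$y <- d2$z + rnorm(1000)
  expect_lt(abs(partial_pearson("x", "y", "z", d2)$r), 0.08)
})

test_that("paired and median-split tests behave at their boundary cases", {
  v <- rnorm(20)
  same <- paired_change_test(v, v)
  expect_equal(same$mean_delta, 0)
  expect_equal(same$p, 1)
  set.seed(11)
  # planted 0.18 shift with SD 0.30 at n = 64: near-certain detection
  pw <- vapply(1:100, function(s) {
    b <- rnorm(64, 1.0, 0.4)
    paired_change_test(b, b + rnorm(64, 0.18, 0.30))$p < 0.05
  }, logical(1))
  expect_gte(mean(pw), 0.99)
  b <- rnorm(30); a <- b + rnorm(30, 0.3, 0.2)
  flip <- paired_change_test(-b, -a)
  expect_equal(flip$mean_delta, -paired_change_test(b, a)$mean_delta)
  expect_equal(flip$p, paired_change_test(b, a)$p)

  d <- data.frame(sed = c(rep(9, 16), rep(11, 16)),
                  y = c(rnorm(16, 0.01, 0.02), rnorm(16, -0.03, 0.02)))
  ms <- median_split_compare("sed", "y", d, threshold = 10)
  expect_equal(ms$groups$n, c(16L, 16L))
  expect_lt(ms$p, 0.05)
  expect_error(median_split_compare("sed", "y", d, threshold = min(d$sed) - 1),
               class = "metflexr_split_error")
})

test_that("VIF matches the auxiliary-regression oracle and flags collinearity", {
  set.seed(12)
  d <- data.frame(a = rnorm(100), b = rnorm(100), c = rnorm(100))
  v <- vif_check(d)
  for (j in 1:3) expect_equal(v$vif[j], oracle_vif(d, j), tolerance = 1e-10)
  expect_true(all(v$vif < 2))
  d$d <- d$a + rnorm(100, 0, 0.01)
  v2 <- vif_check(d)
  expect_gt(max(v2$vif), 5)
  expect_true(any(v2$flagged))
})
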