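# Bespoke statistics: two-proportion z, circular descriptives, Watson's U2.

test_that("two-proportion z reproduces direct arithmetic in both variants", {
  # frozen from the unpooled formula: p1 = 3/238, p2 = 12/218
  expect_equal(two_proportion_z(3, 238, 12, 218, "unpooled")$statistic,
               2.4884, tolerance = 1e-4)
  expect_equal(two_proportion_z(5, 100, 5, 100, "pooled")$statistic, 0)
  expect_equal(two_proportion_z(5, 100, 5, 100, "unpooled")$statistic, 0)
  # frozen from the pooled formula with a zero count in the first arm
  expect_equal(two_proportion_z(0, 48, 28, 80, "pooled")$statistic,
               4.6374, tolerance = 1e-4)

  res <- two_proportion_z(10, 50, 20, 60, "pooled")
  expect_equal(res$p.value, 2 * pnorm(-abs(res$statistic)))
  expect_s3_class(tidy(res), "tbl_df")
  expect_equal(tidy(res)$statistic, res$statistic)
})

test_that("two-proportion z is antisymmetric and rejects degenerate input", {
  set.seed(71)
  for (i in 1:10) {
    n1 <- sample(10:200, 1)
    n2 <- sample(10:200, 1)
    x1 <- sample(0:n1, 1)
    x2 <- sample(0:n2, 1)
    for (variant in c("pooled", "unpooled")) {
      ok <- !(variant == "unpooled" && x1 %in% c(0, n1) && x2 %in% c(0, n2)) &&
        !(variant == "pooled" && x1 + x2 %in% c(0, n1 + n2))
      if (!ok) next
      z_ab <- two_proportion_z(x1, n1, x2, n2, variant)$statistic
      z_ba <- two_proportion_z(x2, n2, x1, n1, variant)$statistic
      expect_equal(z_ab, -z_ba)
    }
  }
  expect_error(two_proportion_z(0, 50, 0, 60, "pooled"), "zero variance")
  expect_error(two_proportion_z(0, 50, 60, 60, "unpooled"), "zero variance")
  expect_error(two_proportion_z(-1, 50, 3, 60), "negative")
  expect_error(two_proportion_z(51, 50, 3, 60), "exceed")
})

test_that("pooled test holds its nominal type-I error under the null", {
  set.seed(1234)
  n <- 200
  p <- 0.3
  nsim <- 5000
  x1 <- rbinom(nsim, n, p)
  x2 <- rbinom(nsim, n, p)
  keep <- (x1 + x2) > 0 & (x1 + x2) < 2 * n
  z <- vapply(which(keep), function(i) {
    two_proportion_z(x1[i], n, x2[i], n, "pooled")$statistic
  }, numeric(1))
  rate <- mean(abs(z) > qnorm(0.975))
  # 3 binomial MC SEs around 0.05
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / nsim) + 0.003)
})

test_that("circular summary matches component-sum arithmetic", {
  all_half <- circular_summary(rep(0.5, 7))
  expect_equal(all_half$mean_direction, 0.5)
  expect_equal(all_half$R, 1)
  expect_equal(all_half$circular_sd, 0)

  # frozen: cos/sin sums at 144 and 216 degrees
  cs <- circular_summary(c(0.4, 0.6))
  expect_equal(cs$mean_direction, 0.5, tolerance = 1e-9)
  expect_equal(cs$R, 0.80902, tolerance = 1e-4)
  expect_equal(cs$circular_sd, 0.10362, tolerance = 1e-4)

  # rotation equivariance: mean shifts, R and sd unchanged
  set.seed(9)
  ph <- runif(40, 0.3, 0.7)
  base <- circular_summary(ph)
  rot <- circular_summary((ph + 0.3) %% 1)
  expect_equal(rot$mean_direction, (base$mean_direction + 0.3) %% 1,
               tolerance = 1e-10)
  expect_equal(rot$R, base$R, tolerance = 1e-12)
  expect_equal(rot$circular_sd, base$circular_sd, tolerance = 1e-12)

  # antipodal pair: zero resultant, undefined mean, no error
  degenerate <- circular_summary(c(0.1, 0.6))
  expect_false(degenerate$mean_defined)
  expect_true(is.na(degenerate$mean_direction))
})

test_that("circular and linear SD agree for tightly concentrated samples", {
  set.seed(21)
  ph <- 0.5 + runif(200, -0.02, 0.02)
  expect_equal(circular_summary(ph)$circular_sd, sd(ph), tolerance = 0.01)
})

test_that("Watson's U2 equals the brute-force oracle", {
  s1 <- c(0.10, 0.20, 0.30, 0.40)
  s2 <- c(0.60, 0.70, 0.80, 0.90)
  expect_equal(suppressWarnings(watson_u2(s1, s2))$u2,
               watson_u2_oracle(s1, s2), tolerance = 1e-12)

  set.seed(33)
  for (i in 1:50) {
    n1 <- sample(4:8, 1)
    n2 <- sample(4:8, 1)
    a <- runif(n1)
    b <- runif(n2)
    expect_equal(suppressWarnings(watson_u2(a, b))$u2,
                 watson_u2_oracle(a, b), tolerance = 1e-12)
  }
})

test_that("Watson's U2 is symmetric, rotation invariant, and null on equal samples", {
  set.seed(41)
  a <- runif(20)
  b <- runif(15)
  u_ab <- suppressWarnings(watson_u2(a, b))$u2
  expect_equal(u_ab, suppressWarnings(watson_u2(b, a))$u2, tolerance = 1e-12)
  for (delta in c(0.1, 0.37, 0.9)) {
    expect_equal(suppressWarnings(watson_u2((a + delta) %% 1,
                                            (b + delta) %% 1))$u2,
                 u_ab, tolerance = 1e-10)
  }
  # identical multisets: tie-averaged statistic collapses to its minimum
  u_same <- watson_u2(a, a)$u2
  expect_lt(u_same, 0.05)
  expect_equal(u_same, 0, tolerance = 1e-12)
})

test_that("the Monte-Carlo null quantile is seeded and ordered in level", {
  q1 <- u2_null_quantile(20, 20, n_replicates = 1000, seed = 5)
  q2 <- u2_null_quantile(20, 20, n_replicates = 1000, seed = 5)
  expect_equal(q1$quantile, q2$quantile)
  q90 <- u2_null_quantile(20, 20, n_replicates = 1000, seed = 5, level = 0.90)
  expect_lte(q90$quantile, q1$quantile)
  expect_error(u2_null_quantile(20, 20, n_replicates = 50), "at least 100")
})
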