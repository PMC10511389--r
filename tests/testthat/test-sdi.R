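test_that("strain distribution indices match hand-computed values", {
  s1 <- compute_sdi(c(1, 1, 1))
  expect_equal(s1$mean, 1)
  expect_equal(s1$maximum, 1)
  expect_equal(s1$coefficient_of_variation, 0)
  expect_equal(s1$skewness, 0)

  s2 <- compute_sdi(c(0, 0, 0, 1))
  expect_equal(s2$mean, 0.25)
  expect_equal(s2$maximum, 1)
  expect_equal(s2$coefficient_of_variation, 2, tolerance = 1e-12)
  expect_equal(s2$skewness, 2, tolerance = 1e-12)

  ln <- with_seed(3, exp(rnorm(10000, 0, 0.8)))
  expect_gt(compute_sdi(ln)$skewness, 0)

  expect_error(compute_sdi(c(1, 2)), "at least 3")
})

test_that("SDIs transform as expected under permutation and scaling", {
  x <- with_seed(5, exp(rnorm(500, -2, 0.5)))
  a <- compute_sdi(x)
  b <- compute_sdi(sample(x))
  expect_equal(a$mean, b$mean)
  expect_equal(a$skewness, b$skewness)
  cs <- compute_sdi(3 * x)
  expect_equal(cs$mean, 3 * a$mean)
  expect_equal(cs$maximum, 3 * a$maximum)
  expect_equal(cs$coefficient_of_variation, a$coefficient_of_variation)
  expect_equal(cs$skewness, a$skewness)
})

test_that("group comparison screens normality and picks the right branch", {
  x <- with_seed(1, rnorm(5, 0.1, 0.005))
  same <- compare_groups_sdi(x, x)
  expect_false(same$reject)
  expect_gt(same$p_value, 0.9)

  ## well-separated Gaussian groups: t branch, matches the closed-form
  ## pooled-variance t statistic
  a <- with_seed(2, rnorm(5, 0.10, 0.005))
  b <- with_seed(3, rnorm(3, 0.12, 0.005))
  out <- compare_groups_sdi(a, b)
  expect_equal(out$branch, "t")
  expect_true(out$reject)
  sp <- sqrt(((5 - 1) * var(a) + (3 - 1) * var(b)) / (5 + 3 - 2))
  t_oracle <- (mean(a) - mean(b)) / (sp * sqrt(1 / 5 + 1 / 3))
  expect_equal(out$statistic, t_oracle, tolerance = 1e-12)

  ## grossly non-normal data routes to the rank branch
  h1 <- with_seed(4, exp(rnorm(20, 0, 1))^3)
  h2 <- with_seed(5, exp(rnorm(20, 0, 1))^3)
  expect_equal(compare_groups_sdi(h1, h2)$branch, "rank")

  expect_error(compare_groups_sdi(rep(1, 4), c(1, 2, 3)), "zero variance")
})

test_that("pairwise region tests use Mann-Whitney U with Bonferroni", {
  mk_rs <- function(samples) {
    structure(list(samples = samples,
                   counts = vapply(samples, length, integer(1)),
                   case_id = NA, position = NA), class = "region_strains")
  }
  ## complete separation: U = 0
  rs0 <- mk_rs(list(A1 = c(1, 2), A4 = c(3, 4), A5 = c(3, 4)))
  out0 <- suppressWarnings(pairwise_region_tests(rs0, pairs = list(c("A1", "A4"))))
  expect_equal(out0$U, 0)

  ## exhaustive U oracle at small n
  x <- c(0.11, 0.05, 0.21, 0.08)
  y <- c(0.04, 0.17, 0.02)
  u_oracle <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  rs1 <- mk_rs(list(A1 = x, A3 = y))
  out1 <- pairwise_region_tests(rs1, pairs = list(c("A1", "A3")))
  expect_equal(out1$U, u_oracle, tolerance = 1e-12)

  ## identical distributions: nothing significant after correction
  z <- with_seed(6, rnorm(200, 0.1, 0.02))
  rs2 <- mk_rs(list(A1 = z, A2 = z, A3 = z, A4 = z, A5 = z))
  out2 <- pairwise_region_tests(rs2)
  expect_false(any(out2$significant))
  expect_equal(attr(out2, "bonferroni_divisor"), 6L)

  ## a clear shift is detected after correction
  rs3 <- mk_rs(list(A1 = z + 0.05, A2 = z, A3 = z, A4 = z, A5 = z))
  out3 <- pairwise_region_tests(rs3)
  expect_true(out3$significant[out3$region_a == "A1" & out3$region_b == "A3"])

  ## missing regions are skipped with a warning
  rs4 <- mk_rs(list(A1 = z, A3 = z))
  expect_warning(out4 <- pairwise_region_tests(rs4), "skipping")
  expect_equal(nrow(out4), 1L)
  expect_equal(attr(out4, "bonferroni_divisor"), 1L)
})

test_that("Bonferroni significance is monotone in the number of pairs", {
  z <- with_seed(7, rnorm(150, 0.1, 0.02))
  mk_rs <- function(samples) {
    structure(list(samples = samples,
                   counts = vapply(samples, length, integer(1)),
                   case_id = NA, position = NA), class = "region_strains")
  }
  rs <- mk_rs(list(A1 = z + 0.03, A2 = z, A3 = z, A4 = z, A5 = z))
  many <- pairwise_region_tests(rs)
  few <- pairwise_region_tests(rs, pairs = list(c("A1", "A2")))
  sig_many <- many[many$region_a == "A1" & many$region_b == "A2", "significant"]
  expect_true(!sig_many || few$significant[1])
})

test_that("mean-strain versus proportion fit matches the normal equations", {
  expect_equal(suppressWarnings(
    fit_mean_strain_vs_proportion(c(0.1, 0.2, 0.3), c(1, 2, 3)))$R_squared, 1)

  xy <- with_seed(8, list(x = runif(1000), y = rnorm(1000)))
  expect_lt(fit_mean_strain_vs_proportion(xy$x, xy$y)$R_squared, 0.01)

  x <- c(0.05, 0.12, 0.22, 0.31, 0.44)
  y <- c(0.091, 0.082, 0.071, 0.066, 0.052)
  fit <- fit_mean_strain_vs_proportion(x, y)
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)       # normal-equations oracle
  res <- y - X %*% beta
  r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
  expect_equal(fit$slope, beta[2], tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(fit$R_squared, r2, tolerance = 1e-12)

  expect_error(fit_mean_strain_vs_proportion(rep(0.2, 4), 1:4), "constant")
})
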