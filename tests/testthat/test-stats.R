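test_that("pearson correlation matches the direct formula and handles exact linearity", {
  x <- 1:10
  expect_equal(pearson_r(x, 2 * x + 1)$r, 1, tolerance = 1e-12)
  expect_equal(pearson_r(x, -x)$r, -1, tolerance = 1e-12)

  # fixed 10-point pair against the covariance / (sd sd) oracle
  xf <- c(2.1, 3.4, 1.7, 5.2, 4.8, 3.3, 2.9, 6.1, 4.4, 3.8)
  yf <- c(12.0, 14.5, 10.9, 18.2, 16.1, 13.8, 13.1, 19.5, 15.2, 15.0)
  n <- length(xf)
  r_oracle <- sum((xf - mean(xf)) * (yf - mean(yf))) /
    sqrt(sum((xf - mean(xf))^2) * sum((yf - mean(yf))^2))
  t_oracle <- r_oracle * sqrt((n - 2) / (1 - r_oracle^2))
  p_oracle <- 2 * stats::pt(-abs(t_oracle), n - 2)
  res <- pearson_r(xf, yf)
  expect_equal(res$r, r_oracle, tolerance = 1e-12)
  expect_equal(res$p, p_oracle, tolerance = 1e-12)
  expect_identical(res$n, n)

  expect_error(pearson_r(rep(1, 5), 1:5), "zero variance")
  expect_error(pearson_r(1:2, 1:2), "at least 3")
})

test_that("correlation matrices are symmetric with unit diagonal and rescaling-invariant", {
  set.seed(31)
  ds <- data.frame(red = rnorm(40), green = rnorm(40), blue = rnorm(40))
  ds$L <- ds$red + rnorm(40, sd = 0.3)
  ds$A <- rnorm(40)
  ds$B <- ds$A # exact equality
  cm <- correlation_matrix(ds)
  expect_equal(cm$r, t(cm$r))
  expect_equal(diag(cm$r), rep(1, 6), ignore_attr = TRUE)
  expect_equal(cm$r["A", "B"], 1, tolerance = 1e-12)

  # affine rescaling of one parameter: |r| unchanged, sign flips with scale
  ds2 <- ds
  ds2$L <- -3 * ds$L + 7
  cm2 <- correlation_matrix(ds2)
  expect_equal(cm2$r["L", "red"], -cm$r["L", "red"], tolerance = 1e-12)
  expect_equal(abs(cm2$r), abs(cm$r), tolerance = 1e-12)

  expect_error(correlation_matrix(ds, c("red", "nope")), "missing columns")
})

test_that("single-predictor standardized beta, part correlation and Pearson r coincide", {
  set.seed(32)
  ds <- data.frame(temperature = runif(60, 20, 900))
  ds$B <- 15 - 0.01 * ds$temperature + rnorm(60, sd = 2)
  fit <- standardized_mlr(ds, "B", "temperature")
  r <- pearson_r(ds$temperature, ds$B)$r
  expect_equal(fit$coefficients$beta, r, tolerance = 1e-10)
  expect_equal(fit$coefficients$part, r, tolerance = 1e-10)
  expect_equal(unname(coef(fit)), r, tolerance = 1e-10)
})

test_that("orthogonal predictors give beta equal to the marginal correlation", {
  # exactly orthogonal, mean-centred design
  x1 <- rep(c(-1, 1), each = 8)
  x2 <- rep(c(-1, 1, 1, -1), 4)
  stopifnot(sum(x1 * x2) == 0)
  set.seed(33)
  ds <- data.frame(temperature = x1, duration = x2)
  ds$L <- 50 + 4 * x1 - 2 * x2 + rnorm(16, sd = 1)
  fit <- standardized_mlr(ds, "L", c("temperature", "duration"))
  r1 <- pearson_r(x1, ds$L)$r
  r2 <- pearson_r(x2, ds$L)$r
  expect_equal(fit$coefficients$beta, c(r1, r2), tolerance = 1e-10)
  expect_equal(fit$coefficients$part, fit$coefficients$beta, tolerance = 1e-10)
})

test_that("part correlations match the residualised-predictor oracle", {
  set.seed(34)
  n <- 80
  ds <- data.frame(temperature = runif(n, 20, 900),
                   duration = runif(n, 5, 50))
  ds$B <- 15 - 0.01 * ds$temperature - 0.02 * ds$duration + rnorm(n, sd = 1.5)
  fit <- standardized_mlr(ds, "B", c("temperature", "duration"))
  # oracle: correlation of the response with each predictor's residual on the
  # other predictors, scaled by the residual's share of the predictor's sd
  for (j in 1:2) {
    other <- ds[[c("temperature", "duration")[-j]]]
    xj <- ds[[c("temperature", "duration")[j]]]
    resid_j <- stats::resid(stats::lm(xj ~ other))
    sr <- stats::cor(ds$B, resid_j) # semi-partial correlation
    expect_equal(fit$coefficients$part[j], sr, tolerance = 1e-10)
  }
})

test_that("standardized coefficients are invariant to linear rescaling", {
  set.seed(35)
  n <- 50
  ds <- data.frame(temperature = runif(n, 20, 900),
                   duration = runif(n, 5, 50))
  ds$L <- 30 + 0.03 * ds$temperature - 0.1 * ds$duration + rnorm(n)
  f1 <- standardized_mlr(ds, "L", c("temperature", "duration"))
  ds2 <- transform(ds, temperature = temperature / 100,
                   duration = duration * 60, L = 10 * L + 3)
  f2 <- standardized_mlr(ds2, "L", c("temperature", "duration"))
  expect_equal(f2$coefficients$beta, f1$coefficients$beta, tolerance = 1e-10)
  expect_equal(f2$coefficients$part, f1$coefficients$part, tolerance = 1e-10)
  expect_equal(f2$coefficients$p, f1$coefficients$p, tolerance = 1e-9)
})

test_that("categorical codings and degenerate designs are handled", {
  set.seed(36)
  n <- 60
  ds <- data.frame(temperature = runif(n, 20, 450),
                   medium = sample(c("air", "adipose"), n, replace = TRUE),
                   age_group = sample(c("<60", "60-80", ">80"), n, replace = TRUE))
  ds$L <- 60 - 0.05 * ds$temperature + 2 * (ds$medium == "adipose") + rnorm(n)
  fit <- standardized_mlr(ds, "L", c("temperature", "medium", "age_group"))
  expect_identical(fit$coefficients$predictor,
                   c("temperature", "medium", "age_60_80", "age_over_80"))
  expect_gt(fit$coefficients$beta[2], 0) # adipose coded 1 raises L

  ds$dup <- ds$temperature * 2
  expect_error(standardized_mlr(ds, "L", c("temperature", "dup")), "collinear")
  expect_error(standardized_mlr(ds[1:3, ], "L", c("temperature", "medium")),
               "too few")
})

test_that("empirical cluster ranges reflect the true temperatures of members", {
  # all records in one cluster: range is the min/max of the set
  ds <- data.frame(temperature = c(700, 760, 900), L = c(85, 86, 84),
                   B = c(1, 1.2, 0.8))
  cr <- cluster_temperature_ranges(ds)
  expect_identical(cr$n[6], 3L)
  expect_equal(cr$t_min_obs[6], 700)
  expect_equal(cr$t_max_obs[6], 900)
  expect_false(any(cr$present[-6]))

  # synthetic learning-set analogue: observed minima ascend with cluster id
  ds2 <- generate_dataset(design_spec(seed = 101))
  cr2 <- cluster_temperature_ranges(ds2)
  mins <- cr2$t_min_obs[cr2$present]
  expect_true(all(diff(mins) >= 0))
})
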