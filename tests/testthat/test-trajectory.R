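test_that("default fits carry five non-crossing percentile curves", {
  set.seed(1)
  age <- runif(300, 8, 83)
  y <- 1 + 0.03 * age + rnorm(300, sd = 0.5)
  fit <- fitTrajectory(age, y)
  expect_equal(fit@percentiles, c(10, 25, 50, 75, 90))
  expect_equal(nrow(trajectoryCurves(fit)), 5L)
  # non-crossing at every grid age, for several random datasets
  for (s in 2:5) {
    set.seed(s)
    ys <- rnorm(200, sd = exp(0.3 * scale(age[1:200])))
    f <- fitTrajectory(age[1:200], ys)
    expect_true(all(apply(f@curves, 2, function(col) all(diff(col) > 0))))
  }
})

test_that("the median curve matches a least-squares oracle for Gaussian data", {
  set.seed(6)
  n <- 500
  age <- runif(n, 8, 83)
  ac <- age - mean(age)
  y <- 2 + 0.1 * ac + rnorm(n)
  fit <- fitTrajectory(age, y)
  ols <- lm(y ~ ac + I(ac^2))
  grid <- fit@ageGrid - mean(age)
  pred <- predict(ols, newdata = data.frame(ac = grid),
                  interval = "confidence", level = 0.954)
  p50 <- trajectoryCurves(fit)["p50", ]
  expect_true(all(p50 > pred[, "lwr"] & p50 < pred[, "upr"]))
})

test_that("the backfitting fitter matches the mgcv location-scale oracle", {
  skip_if_not_installed("mgcv")
  set.seed(7)
  n <- 400
  age <- runif(n, 8, 83)
  ac <- age - mean(age)
  y <- 1 + 0.05 * ac - 3e-4 * ac^2 +
    rnorm(n, sd = exp(-0.5 + 0.01 * ac))
  fit <- fitTrajectory(age, y)
  g <- mgcv::gam(list(y ~ ac + I(ac^2), ~ ac + I(ac^2)),
                 family = mgcv::gaulss(b = 1e-8))
  mu <- drop(cbind(1, ac, ac^2) %*% fit@muCoefficients)
  sig <- exp(drop(cbind(1, ac, ac^2) %*% fit@sigmaCoefficients))
  fv <- mgcv::predict.gam(g, type = "response")
  expect_lt(max(abs(mu - fv[, 1])), 1e-3)
  # gaulss column 2 is 1/sigma (plus the small b offset)
  expect_lt(max(abs(sig - 1 / fv[, 2])) / mean(sig), 1e-2)
})

test_that("empirical coverage sits near nominal levels at large n", {
  set.seed(8)
  n <- 2000
  age <- runif(n, 8, 83)
  y <- 2 + 0.1 * (age - mean(age)) + rnorm(n)
  fit <- fitTrajectory(age, y)
  cov <- trajectoryCoverage(fit)
  expect_lt(abs(cov[["p10"]] - 10), 1.5)
  expect_lt(abs(cov[["p90"]] - 90), 1.5)
  expect_lt(abs(cov[["p50"]] - 50), 2.5)
})

test_that("the Box-Cox Cole-Green family reduces to the Gaussian at nu = 1", {
  set.seed(9)
  n <- 300
  age <- runif(n, 8, 83)
  y <- 10 + 0.05 * (age - mean(age)) + rnorm(n, sd = 0.8)
  g <- fitTrajectory(age, y, family = "gaussian_ls")
  b <- fitTrajectory(age, y, family = "box_cox_cole_green", nu = 1)
  expect_lt(max(abs(g@curves - b@curves)), 1e-4)
  expect_error(fitTrajectory(age, y - 20, family = "box_cox_cole_green"),
               "positive")
})

test_that("BCCG with a free power fits skewed positive data coherently", {
  set.seed(10)
  n <- 400
  age <- runif(n, 8, 83)
  y <- exp(rnorm(n, mean = 1 + 0.004 * (age - 45), sd = 0.25))
  fit <- fitTrajectory(age, y, family = "box_cox_cole_green")
  expect_true(fit@converged)
  expect_true(all(apply(fit@curves, 2, function(col) all(diff(col) > 0))))
  cov <- trajectoryCoverage(fit)
  expect_lt(abs(cov[["p50"]] - 50), 5)
})

test_that("shape classification recovers planted generating shapes", {
  # majority over replicates: any single draw can contain a spurious
  # BIC-winning term, but the planted shape must dominate
  n <- 316
  gens <- list(
    linear_increasing = function(ac) 1 + 0.1 * ac,
    linear_decreasing = function(ac) 1 - 0.1 * ac,
    concave_inverted_U = function(ac) 1 - 0.02 * ac^2,
    convex_U = function(ac) 1 + 0.02 * ac^2)
  for (shape in names(gens)) {
    hits <- vapply(1:10, function(r) {
      set.seed(100 * match(shape, names(gens)) + r)
      age <- runif(n, 8, 83)
      ac <- age - mean(age)
      y <- gens[[shape]](ac) + rnorm(n, sd = 0.6)
      classifyShape(fitTrajectory(age, y)) == shape
    }, TRUE)
    expect_gte(sum(hits), 8)
  }
})

test_that("pure noise is labeled flat in at least 90 percent of replicates", {
  set.seed(12)
  age <- runif(316, 8, 83)
  flat <- vapply(1:100, function(r) {
    classifyShape(fitTrajectory(age, rnorm(316))) == "flat"
  }, TRUE)
  expect_gte(mean(flat), 0.9)
})

test_that("sex-stratified location models produce per-sex curves", {
  set.seed(13)
  n <- 400
  age <- runif(n, 8, 83)
  sex <- rep(c("male", "female"), n / 2)
  s <- ifelse(sex == "male", 0.5, -0.5)
  y <- 1 + s * 2 + rnorm(n, sd = 0.5)
  fit <- fitTrajectory(age, y, sex = sex, sexInMu = TRUE)
  m <- trajectoryCurves(fit, sex = "male")["p50", ]
  f <- trajectoryCurves(fit, sex = "female")["p50", ]
  expect_true(all(m > f))
  expect_error(trajectoryCurves(fitTrajectory(age, y), sex = "male"),
               "per-sex")
})

test_that("trajectory fitting validates its inputs", {
  expect_error(fitTrajectory(1:20, rnorm(20)), "30 observations")
  expect_error(fitTrajectory(rep(5, 40), rnorm(40)), "constant")
  expect_error(fitTrajectory(runif(40, 8, 83), rnorm(40), sexInMu = TRUE),
               "sex vector")
})
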