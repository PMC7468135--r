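test_that("increment log-likelihood matches closed forms", {
  # iid increments, no observation error
  ll <- increment_loglik(1:3, c(0, 0.5, 1.0), mu = 0.5, sigma2 = 0.01,
                         tau2 = 0)
  expect_equal(ll, 2 * dnorm(0.5, 0.5, 0.1, log = TRUE), tolerance = 1e-10)
  # a survey gap doubles the process-noise variance of that increment
  ll_gap <- increment_loglik(c(1, 3), c(0, 1), mu = 0.3, sigma2 = 0.05,
                             tau2 = 0)
  expect_equal(ll_gap, dnorm(1, 0.6, sqrt(2 * 0.05), log = TRUE),
               tolerance = 1e-10)
  expect_error(increment_loglik(1, 0.5, 0, 1, 1), "at least 2")
})

test_that("increment log-likelihood equals the dense MVN oracle", {
  set.seed(101)
  for (r in 1:60) {
    n <- sample(3:10, 1)
    years <- cumsum(c(2000, sample(1:3, n - 1, replace = TRUE)))
    values <- rnorm(n)
    mu <- rnorm(1, 0, 0.2)
    sigma2 <- runif(1, 1e-4, 0.5)
    tau2 <- runif(1, 0, 0.5)
    expect_equal(
      increment_loglik(years, values, mu, sigma2, tau2),
      mvn_increment_oracle(years, values, mu, sigma2, tau2),
      tolerance = 1e-8)
  }
})

test_that("with tau2 = 0 the MLE is the closed-form increment summary", {
  set.seed(5)
  years <- 2000:2019
  values <- cumsum(c(0.4, rnorm(19, 0.05, 0.1)))
  d <- diff(values)
  mu_cf <- mean(d)
  s2_cf <- mean((d - mu_cf)^2)
  obj <- function(p) -increment_loglik(years, values, p[1], p[2], 0)
  fit <- optim(c(0, 0.01), obj, lower = c(-1, 1e-8), upper = c(1, 1),
               method = "L-BFGS-B",
               control = list(factr = 10, pgtol = 1e-12,
                              ndeps = c(1e-7, 1e-7)))
  expect_equal(fit$par[1], mu_cf, tolerance = 1e-6)
  expect_equal(fit$par[2], s2_cf, tolerance = 1e-4)
})

test_that("exact linear series give a perfect deterministic fit", {
  f <- fit_state_space(0:10, 0.1 * (0:10))
  expect_equal(f$mu, 0.1)
  expect_equal(f$sigma2, 0)
  expect_equal(f$tau2, 0)
  expect_equal(f$classification, "increase")
  k <- fit_state_space(1:6, rep(0.5, 6), constant = TRUE)
  expect_equal(k$mu, 0)
  expect_equal(k$classification, "no_net_change")
})

test_that("fits are invariant to a constant year offset and seed-stable", {
  ser <- simulate_series(0.01, 4e-4, 2e-4, 1990:2014, seed = 33)
  f1 <- fit_state_space(ser$year, ser$abundance, seed = 4)
  f2 <- fit_state_space(ser$year + 1000, ser$abundance, seed = 4)
  expect_equal(f1$mu, f2$mu, tolerance = 1e-8)
  expect_equal(f1$sigma2, f2$sigma2, tolerance = 1e-8)
  f3 <- fit_state_space(ser$year, ser$abundance, seed = 4)
  expect_identical(f1$mu, f3$mu)
})

test_that("trend classification follows the interval-versus-zero rule", {
  expect_equal(classify_trend(-0.02, -0.005), "decline")
  expect_equal(classify_trend(-0.01, 0.02), "no_net_change")
  expect_equal(classify_trend(0.002, 0.018), "increase")
  expect_equal(classify_trend(c(-1, 0.1), c(-0.1, 0.2)),
               c("decline", "increase"))
})

test_that("profile interval brackets the Wald midpoint", {
  ser <- simulate_series(0.02, 9e-4, 4e-4, 1981:2010, seed = 12)
  f <- fit_state_space(ser$year, ser$abundance, ci_method = "profile")
  w <- fit_state_space(ser$year, ser$abundance, ci_method = "wald")
  mid <- (w$ci_lo + w$ci_hi) / 2
  expect_true(f$ci_lo <= mid && mid <= f$ci_hi)
  expect_true(f$ci_lo <= f$mu && f$mu <= f$ci_hi)
})

test_that("drift interval coverage is near nominal on simulated series", {
  hits <- logical(1000)
  for (i in seq_len(1000)) {
    ser <- simulate_series(0.02, 9e-4, 4e-4, 1981:2010, seed = 5000 + i)
    f <- fit_state_space(ser$year, ser$abundance, seed = i)
    hits[i] <- f$ci_lo <= 0.02 && f$ci_hi >= 0.02
  }
  expect_gte(mean(hits), 0.90)
  expect_lte(mean(hits), 0.98)
})

test_that("null series classify symmetrically at near-nominal rates", {
  cls <- character(400)
  for (i in seq_len(400)) {
    ser <- simulate_series(0, 9e-4, 4e-4, 1981:2010, seed = 9000 + i)
    cls[i] <- fit_state_space(ser$year, ser$abundance, seed = i)$classification
  }
  p_dec <- mean(cls == "decline")
  p_inc <- mean(cls == "increase")
  # each tail near alpha/2 = 2.5% (binomial 3 se at n = 400 is ~2.3 pp)
  expect_gte(p_dec, 0.005); expect_lte(p_dec, 0.06)
  expect_gte(p_inc, 0.005); expect_lte(p_inc, 0.06)
  # two-sided symmetry
  expect_lt(abs(p_dec - p_inc), 0.035)
})

test_that("linear trends match least squares and flip with year order", {
  lt <- fit_linear_trend(1:5, c(0, 0.25, 0.5, 0.75, 1))
  expect_equal(lt$slope, 0.25)
  expect_equal(lt$se, 0)
  set.seed(8)
  y <- rnorm(12)
  yr <- 2001:2012
  lt2 <- fit_linear_trend(yr, y)
  cf <- summary(lm(y ~ yr))$coefficients
  expect_equal(lt2$slope, cf[2, 1], tolerance = 1e-10)
  expect_equal(lt2$se, cf[2, 2], tolerance = 1e-10)
  expect_equal(lt2$p, cf[2, 4], tolerance = 1e-10)
  lt3 <- fit_linear_trend(rev(yr), y)
  expect_equal(lt3$slope, -lt2$slope, tolerance = 1e-10)
  expect_error(fit_linear_trend(2000, 1), "at least 2")
})

test_that("fluctuation metrics degrade coherently", {
  years <- 1:8
  exact <- 0.1 * years
  f <- fit_state_space(years, exact)
  m <- fluctuation_metrics(years, exact, f)
  expect_equal(unname(m[c("se_slope", "half_ci", "sigma2")]), c(0, 0, 0))
  # tau2 = 0 makes the weighted interval equal the plain one
  expect_equal(unname(m["half_ci_weighted"]), unname(m["half_ci"]))
  expect_equal(unname(fluctuation_metrics(1:3, c(0, 0.5, 1), f)["sd_raw"]),
               0.5)
})

test_that("percent change matches the worked abundance examples", {
  expect_equal(round(percent_change(606, 194)), -68)
  expect_equal(round(percent_change(89, 328)), 269)
  expect_equal(percent_change(42, 42), 0)
  expect_error(percent_change(0, 5), "undefined")
})
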