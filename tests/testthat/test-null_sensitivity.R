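small_collection <- function(n_series = 10, len = 8, seed = 2) {
  meta <- tibble::tibble(series_id = sprintf("s%02d", seq_len(n_series)))
  obs <- dplyr::bind_rows(lapply(seq_len(n_series), function(i) {
    ser <- simulate_series(0.05, 1e-3, 0, 2000 + seq_len(len),
                           seed = seed * 100 + i, x0 = 5)
    tibble::tibble(series_id = meta$series_id[i], year = ser$year,
                   abundance = ser$abundance)
  }))
  pop_collection(meta, obs)
}

test_that("randomization permutes within series and is seed-stable", {
  x <- small_collection()
  r1 <- randomize_dataset(x, seed = 4)
  r2 <- randomize_dataset(x, seed = 4)
  r3 <- randomize_dataset(x, seed = 5)
  expect_identical(r1$obs, r2$obs)
  expect_false(identical(r1$obs$abundance, r3$obs$abundance))
  # multiset of values and the year grid preserved per series
  for (id in x$meta$series_id) {
    a <- get_series(x, id)
    b <- get_series(r1, id)
    expect_equal(sort(a$values), sort(b$values))
    expect_equal(a$years, b$years)
  }
  # a singleton series passes through unchanged
  one <- pop_collection(tibble::tibble(series_id = "z"),
                        tibble::tibble(series_id = "z", year = 2000,
                                       abundance = 3))
  expect_equal(randomize_dataset(one, 1)$obs$abundance, 3)
})

test_that("significance rates hit the degenerate limits", {
  x <- small_collection(n_series = 12, len = 10)
  # deterministic strong trends: everything significantly positive
  det <- x
  det$obs$abundance <- rep(seq_len(10), 12) * 2
  r <- significance_rates(det)
  expect_equal(r$pct_sig_positive, 100)
  expect_equal(r$pct_sig_negative, 0)
  # alpha = 1 calls every non-tied slope significant
  r2 <- significance_rates(x, alpha = 1)
  expect_equal(r2$pct_sig_negative + r2$pct_sig_positive, 100)
  expect_error(significance_rates(
    pop_collection(tibble::tibble(series_id = "a"),
                   tibble::tibble(series_id = "a", year = 1:2,
                                  abundance = c(1, 2)))),
    "at least 3")
})

test_that("permuted null series trigger at close to the nominal rate", {
  r <- null_trend_rates(n_series = 1500, seed = 7)
  # each tail ~ alpha/2; generous binomial band at n = 1500
  expect_gt(r$pct_sig_negative, 1.0)
  expect_lt(r$pct_sig_negative, 4.0)
  expect_gt(r$pct_sig_positive, 1.0)
  expect_lt(r$pct_sig_positive, 4.0)
  expect_lt(abs(r$pct_sig_positive - r$pct_sig_negative), 1.6)
})

test_that("truncation drops the stated observations and composes with the filter", {
  x <- small_collection(n_series = 2, len = 12)
  t1 <- truncate_series(x, drop_first = 5)
  expect_equal(nrow(t1$obs), 2 * 7)
  expect_equal(get_series(t1, "s01")$years, 2006:2012)
  t2 <- truncate_series(x, drop_first = 0, drop_last = 0)
  expect_equal(t2$obs, x$obs)
  # 9 observations minus 5 leaves 4, which the k = 5 filter then removes
  y <- small_collection(n_series = 3, len = 9)
  t3 <- truncate_series(y, drop_first = 5)
  expect_message(f <- filter_min_points(t3, 5), "removed 3 of 3")
  expect_equal(nrow(f$meta), 0)
})

test_that("truncating a noise-free linear series leaves its slope unchanged", {
  years <- 2000:2014
  vals <- 3 + 0.2 * (years - 2000)
  full <- fit_linear_trend(years, vals)
  left <- fit_linear_trend(years[-(1:5)], vals[-(1:5)])
  right <- fit_linear_trend(head(years, 10), head(vals, 10))
  expect_equal(left$slope, full$slope, tolerance = 1e-12)
  expect_equal(right$slope, full$slope, tolerance = 1e-12)
})

test_that("dip statistic honours its analytic envelope", {
  set.seed(61)
  for (r in 1:60) {
    n <- sample(4:60, 1)
    D <- dip_statistic(rnorm(n))$D
    expect_gte(D, 1 / (2 * n))
    expect_lte(D, 0.25)
  }
  # two balanced well-separated point masses approach the maximum
  expect_equal(dip_statistic(c(rep(0, 50), rep(1, 50)))$D, 0.25)
  expect_equal(dip_statistic(c(0, 0, 1, 1))$D, 0.25)
  expect_error(dip_statistic(c(1, 2, 3)), "at least 4")
})

test_that("dip matches the brute-force LP oracle on random small samples", {
  set.seed(62)
  samples <- lapply(1:40, function(r) {
    n <- sample(4:12, 1)
    switch(sample(3, 1),
           rnorm(n),
           c(rnorm(ceiling(n / 2), -3, 0.1), rnorm(floor(n / 2), 3, 0.1)),
           round(runif(n), 1))
  })
  oracle <- dip_oracle_batch(samples)
  for (i in seq_along(samples)) {
    n <- length(samples[[i]])
    expect_equal(dip_statistic(samples[[i]], tol = 1e-10)$D,
                 min(max(oracle[i], 1 / (2 * n)), 0.25),
                 tolerance = 1e-6)
  }
})

test_that("a large uniform sample is unimodal by the dip", {
  D <- withr::with_seed(63, dip_statistic(runif(1000))$D)
  expect_lt(D, 0.02)
})

test_that("dip p-values are calibrated and reproducible", {
  # null median should sit near p = 0.5
  null_D <- vapply(1:120, function(i) {
    withr::with_seed(700 + i, dip_statistic(runif(60))$D)
  }, numeric(1))
  med <- median(null_D)
  p_med <- dip_pvalue(med, n = 60, n_boot = 400, seed = 3)
  expect_gt(p_med$p, 0.35)
  expect_lt(p_med$p, 0.65)
  expect_equal(dip_pvalue(0.2, 60, n_boot = 200, seed = 9)$p, 0)
  p1 <- dip_pvalue(0.05, 60, n_boot = 200, seed = 5)
  p2 <- dip_pvalue(0.05, 60, n_boot = 200, seed = 5)
  expect_identical(p1$p, p2$p)
})

test_that("a clearly bimodal trend distribution is detected", {
  x <- withr::with_seed(64,
                        c(rnorm(300, -0.025, 0.008), rnorm(300, 0.025, 0.008)))
  D <- dip_statistic(x)$D
  expect_gt(D, 0.03)
  expect_lt(dip_pvalue(D, length(x), n_boot = 300, seed = 2)$p, 0.01)
})

test_that("the duration model matches through-origin least squares", {
  # two exact points: posterior centres on the through-origin slope, with
  # wide Monte-Carlo noise because the residual variance is barely informed
  expect_equal(duration_model(c(0.1, 0.2), c(10, 20), iterations = 8000,
                              burnin = 2000, thin = 2, seed = 4)$slope,
               0.01, tolerance = 0.2)
  z <- duration_model(rep(0, 20), seq(5, 24), iterations = 3000,
                      burnin = 500, thin = 2)
  expect_equal(z$slope, 0, tolerance = 1e-3)
  set.seed(65)
  dur <- runif(80, 5, 40)
  tr <- 0.002 * dur + rnorm(80, 0, 0.02)
  d <- duration_model(tr, dur, iterations = 4000, burnin = 1000, thin = 2)
  ols <- sum(tr * dur) / sum(dur^2)
  expect_equal(d$slope, ols, tolerance = 2e-3)
  expect_true(d$lo <= d$slope && d$slope <= d$hi)
})
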