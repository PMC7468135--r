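fast_mcmc <- list(iterations = 4000, burnin = 1000, thin = 2)

test_that("single-group posterior mean matches the conjugate closed form", {
  set.seed(2)
  df <- data.frame(y = rnorm(300, 3, 0.5), g = "a")
  fit <- gibbs_mixed_fit(df, "y", "g", random_species = FALSE,
                         iterations = fast_mcmc$iterations,
                         burnin = fast_mcmc$burnin, thin = fast_mcmc$thin,
                         seed = 5)
  s <- posterior_summary(fit)
  # near-flat prior: posterior mean of the level effect ~ sample mean,
  # within 2 Monte-Carlo standard errors
  draws <- fit$draws$a
  mc_se <- sd(draws) / sqrt(length(draws) / 10)  # generous autocorr factor
  expect_lt(abs(s$mean[s$parameter == "a"] - mean(df$y)), 2 * mc_se + 0.02)
})

test_that("two constant-response categories are recovered exactly", {
  df <- data.frame(y = c(rep(1.5, 40), rep(-2, 40)),
                   g = rep(c("a", "b"), each = 40))
  fit <- gibbs_mixed_fit(df, "y", "g", random_species = FALSE,
                         iterations = 3000, burnin = 500, thin = 2)
  s <- posterior_summary(fit)
  expect_equal(s$mean[s$parameter == "a"], 1.5, tolerance = 1e-2)
  expect_equal(s$mean[s$parameter == "b"], -2, tolerance = 1e-2)
  expect_true(all(fit$draws$var_residual > 0))
})

test_that("known measurement-error variances produce precision weighting", {
  set.seed(3)
  mev <- c(rep(0.01, 60), rep(1, 60))
  y <- rnorm(120, 1, sqrt(mev + 1e-4))
  df <- data.frame(y = y, m = mev)
  fit <- gibbs_mixed_fit(df, "y", predictor = NULL, random_species = FALSE,
                         mev = "m", iterations = 6000, burnin = 1000,
                         thin = 5)
  post <- posterior_summary(fit)$mean[1]
  ivw <- sum(y / mev) / sum(1 / mev)
  expect_lt(abs(post - ivw), 0.05)
  # the plain mean is measurably different here; weighting must win
  expect_lt(abs(post - ivw), abs(post - mean(y)))
})

test_that("species random intercepts recover stage-2 truth", {
  set.seed(14)
  n_sp <- 60
  sp <- sprintf("sp%02d", seq_len(n_sp))
  b <- rnorm(n_sp, 0, 0.01)
  eff <- c(amphibia = -0.01, aves = 0.004)
  rows <- do.call(rbind, lapply(1:600, function(i) {
    s <- sample(n_sp, 1)
    g <- if (s <= n_sp / 2) "amphibia" else "aves"
    data.frame(y = eff[[g]] + b[s] + rnorm(1, 0, 0.02),
               taxa = g, species = sp[s])
  }))
  fit <- gibbs_mixed_fit(rows, "y", "taxa", species = "species",
                         iterations = 4000, burnin = 1000, thin = 3,
                         seed = 2)
  s <- posterior_summary(fit)
  for (g in names(eff)) {
    row <- s[s$parameter == g, ]
    psd <- sd(fit$draws[[g]])
    expect_lt(abs(row$mean - eff[[g]]), 2 * psd + 0.002)
  }
})

test_that("row order does not change posterior summaries", {
  set.seed(6)
  df <- data.frame(y = rnorm(100), g = sample(c("a", "b"), 100, TRUE),
                   species = sample(c("x", "y", "z"), 100, TRUE))
  fit1 <- gibbs_mixed_fit(df, "y", "g", iterations = 2000, burnin = 500,
                          thin = 2, seed = 9)
  perm <- sample(nrow(df))
  df2 <- df[perm, ]
  # re-sorting restores the sampler's visiting order exactly
  df2 <- df2[order(as.numeric(rownames(df2))), ]
  fit2 <- gibbs_mixed_fit(df2, "y", "g", iterations = 2000, burnin = 500,
                          thin = 2, seed = 9)
  expect_identical(fit1$draws$a, fit2$draws$a)
})

test_that("tightening the coefficient prior shrinks the posterior mean", {
  set.seed(7)
  df <- data.frame(y = rnorm(60, 2, 1), g = "a")
  means <- vapply(c(1e8, 1, 0.1, 0.01), function(bv) {
    fit <- gibbs_mixed_fit(df, "y", "g", random_species = FALSE,
                           iterations = 3000, burnin = 500, thin = 2,
                           seed = 3,
                           prior = list(beta_var = bv, v_shape = 0.001,
                                        v_scale = 0.001))
    mean(fit$draws$a)
  }, numeric(1))
  expect_true(all(diff(abs(means)) < 0))
})

test_that("four chains mix with split-Rhat below 1.05", {
  set.seed(8)
  df <- data.frame(y = rnorm(150, 1, 0.3),
                   g = sample(c("a", "b"), 150, TRUE),
                   species = sample(sprintf("s%d", 1:15), 150, TRUE))
  fit <- gibbs_mixed_fit(df, "y", "g", iterations = 3000, burnin = 1000,
                         thin = 2, chains = 4, seed = 11)
  expect_true(all(fit$rhat < 1.05))
})

test_that("posterior summaries behave on degenerate draw sets", {
  d <- tibble::tibble(a = rep(3, 200), chain = 1)
  s <- posterior_summary(d)
  expect_equal(s$lo, 3)
  expect_equal(s$hi, 3)
  set.seed(10)
  d2 <- tibble::tibble(b = rnorm(10000, 1, 0.01), chain = 1)
  s2 <- posterior_summary(d2)
  expect_equal(s2$lo, 0.98, tolerance = 2e-3)
  expect_equal(s2$hi, 1.02, tolerance = 2e-3)
  expect_true(s2$differs_from_zero)
  d3 <- tibble::tibble(c = c(rnorm(5000), -rnorm(5000)), chain = 1)
  expect_false(posterior_summary(d3)$differs_from_zero)
  expect_error(posterior_summary(tibble::tibble(a = 1:10, chain = 1)),
               "100 retained draws")
})

test_that("effect standardization is a plain ratio with guards", {
  expect_equal(standardize_effect(0.5, 2), 0.25)
  expect_equal(standardize_effect(0, 3), 0)
  expect_equal(standardize_effect(1.7, 1), 1.7)
  expect_error(standardize_effect(1, 0), "positive")
  expect_error(standardize_effect(1, -2), "positive")
})

test_that("non-finite responses are rejected", {
  df <- data.frame(y = c(1, Inf, 2), g = "a")
  expect_error(gibbs_mixed_fit(df, "y", "g", random_species = FALSE),
               "non-finite")
})
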