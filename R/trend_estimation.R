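#' Increment log-likelihood of the drift + observation-error model
#'
#' The latent abundance follows a random walk with drift,
#' `X_t = X_{t-1} + mu + eps_t`, `eps_t ~ N(0, sigma2)`, observed with error
#' `Y_t = X_t + F_t`, `F_t ~ N(0, tau2)`. Differencing removes the latent
#' state: `Y_t - Y_{t-1} = mu + eps_t + F_t - F_{t-1}`, so the vector of
#' observed increments is multivariate normal with mean `mu * delta_i`
#' (`delta_i` = years between surveys), variance `sigma2 * delta_i + 2 *
#' tau2` and covariance `-tau2` between increments sharing a survey (an
#' MA(1) structure). The likelihood conditions on the first observation.
#'
#' @param years Integer survey years, strictly increasing.
#' @param values Observed (scaled) abundances, same length.
#' @param mu Drift per year.
#' @param sigma2 Process-noise variance (>= 0).
#' @param tau2 Observation-error variance (>= 0).
#' @return Log-density of the increment vector (a scalar).
#' @export
increment_loglik <- function(years, values, mu, sigma2, tau2) {
  n <- length(values)
  if (n < 2) stop("need at least 2 observations", call. = FALSE)
  stopifnot(length(years) == n, all(diff(years) >= 1),
            sigma2 >= 0, tau2 >= 0)
  d <- diff(values)
  delta <- diff(years)
  m <- length(d)
  S <- diag(sigma2 * delta + 2 * tau2, m)
  if (m > 1) {
    idx <- cbind(seq_len(m - 1), seq_len(m - 1) + 1)
    S[idx] <- -tau2
    S[idx[, 2:1, drop = FALSE]] <- -tau2
  }
  r <- d - mu * delta
  ch <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  z <- backsolve(ch, r, transpose = TRUE)
  -0.5 * (m * log(2 * pi) + 2 * sum(log(diag(ch))) + sum(z^2))
}

# Profile out mu: given variances, the GLS estimate of mu and the maximized
# loglik. Used by the optimizer (2-parameter search over variances).
.ss_profile_mu <- function(years, values, sigma2, tau2) {
  d <- diff(values)
  delta <- diff(years)
  m <- length(d)
  S <- diag(sigma2 * delta + 2 * tau2, m)
  if (m > 1) {
    idx <- cbind(seq_len(m - 1), seq_len(m - 1) + 1)
    S[idx] <- -tau2
    S[idx[, 2:1, drop = FALSE]] <- -tau2
  }
  ch <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(ch)) return(list(mu = NA_real_, loglik = -Inf))
  zd <- backsolve(ch, d, transpose = TRUE)
  zx <- backsolve(ch, delta, transpose = TRUE)
  mu <- sum(zx * zd) / sum(zx * zx)
  r <- zd - mu * zx
  list(mu = mu,
       loglik = -0.5 * (m * log(2 * pi) + 2 * sum(log(diag(ch))) +
                          sum(r^2)))
}

#' Fit the state-space trend model to one series by maximum likelihood
#'
#' Maximizes [increment_loglik()] over `(mu, sigma2, tau2)` subject to
#' non-negative variances, using multiple jittered starting points to guard
#' against local optima (the increment likelihood can be multimodal in the
#' variance split). The drift is profiled out in closed form (generalized
#' least squares), so the numerical search is over the two variances only.
#' The default 95% interval for `mu` is an integrated-likelihood interval:
#' the Gaussian interval for the drift conditional on the variance pair is
#' averaged over restricted-likelihood weights on a grid of variance
#' pairs. This propagates the weakly identified process-noise /
#' observation-error split into the drift interval; on short series a
#' profile or Wald interval conditions on the fitted split and becomes
#' anti-conservative whenever a variance estimate hits the zero boundary.
#' Profile-likelihood (chi-squared(1) cutoff) and Wald intervals remain
#' available through `ci_method`.
#'
#' @param years Integer survey years.
#' @param values Scaled abundances.
#' @param n_starts Number of optimizer starts (default 8).
#' @param ci Compute the 95% interval for `mu` (default TRUE).
#' @param ci_method `"integrated"` (default), `"profile"` or `"wald"`.
#' @param seed Integer seed for start jitter (default 1); fits are
#'   deterministic given the seed.
#' @param constant Flag from scaling: constant series short-circuit to a
#'   zero trend with zero variances.
#' @return List of class `ss_fit`: `mu`, `sigma2`, `tau2`, `loglik`,
#'   `ci_lo`, `ci_hi`, `half_ci`, `classification`, `converged`,
#'   `ci_method`.
#' @export
fit_state_space <- function(years, values, n_starts = 8, ci = TRUE,
                            ci_method = c("integrated", "profile", "wald"),
                            seed = 1, constant = FALSE) {
  ci_method <- match.arg(ci_method)
  n <- length(values)
  if (n < 2) stop("need at least 2 observations", call. = FALSE)
  if (constant || diff(range(values)) == 0) {
    return(structure(list(mu = 0, sigma2 = 0, tau2 = 0, loglik = Inf,
                          ci_lo = 0, ci_hi = 0, half_ci = 0,
                          classification = "no_net_change",
                          converged = TRUE, ci_method = "degenerate"),
                     class = "ss_fit"))
  }
  d <- diff(values)
  delta <- diff(years)
  inc_rate <- d / delta
  v0 <- stats::var(inc_rate) * (length(d) - 1) / length(d)
  if (!is.finite(v0) || v0 <= 0) v0 <- 1e-4
  # exactly linear series: increments constant, ML degenerates to a perfect fit
  if (v0 < 1e-12 && length(unique(delta)) == 1) {
    mu <- mean(inc_rate)
    return(structure(list(mu = mu, sigma2 = 0, tau2 = 0, loglik = Inf,
                          ci_lo = mu, ci_hi = mu, half_ci = 0,
                          classification = classify_trend(mu, mu),
                          converged = TRUE, ci_method = "degenerate"),
                     class = "ss_fit"))
  }
  floor_v <- 1e-10
  obj <- function(p) {
    -.ss_profile_mu(years, values, exp(p[1]), exp(p[2]))$loglik
  }
  rs <- .local_rng(seed)
  starts <- rbind(
    c(log(v0), log(floor_v)),          # all variance as process noise
    c(log(floor_v), log(v0 / 2)),      # all as observation error
    c(log(v0 / 2), log(v0 / 4)),       # an even split
    matrix(log(v0) + rs$rnorm(2 * max(0, n_starts - 3), 0, 2),
           ncol = 2)
  )[seq_len(max(3, n_starts)), , drop = FALSE]
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::optim(starts[i, ], obj, method = "Nelder-Mead",
                   control = list(maxit = 500, reltol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) {
      best <- fit
    }
  }
  if (is.null(best) || !is.finite(best$value)) {
    return(structure(list(mu = NA_real_, sigma2 = NA_real_, tau2 = NA_real_,
                          loglik = NA_real_, ci_lo = NA_real_,
                          ci_hi = NA_real_, half_ci = NA_real_,
                          classification = NA_character_,
                          converged = FALSE, ci_method = "none"),
                     class = "ss_fit"))
  }
  sigma2 <- exp(best$par[1])
  tau2 <- exp(best$par[2])
  # snap boundary estimates to exact zero
  if (sigma2 < 1e-8) sigma2 <- 0
  if (tau2 < 1e-8) tau2 <- 0
  prof <- .ss_profile_mu(years, values, sigma2, tau2)
  out <- list(mu = prof$mu, sigma2 = sigma2, tau2 = tau2,
              loglik = prof$loglik, converged = TRUE)
  if (ci) {
    ival <- switch(ci_method,
      integrated = .ss_integrated_ci(years, values),
      profile = .ss_profile_ci(years, values, out$mu, sigma2, tau2,
                               prof$loglik),
      wald = {
        se <- .ss_wald_se(years, values, out$mu, sigma2, tau2)
        list(lo = out$mu - 1.96 * se, hi = out$mu + 1.96 * se,
             method = "wald")
      })
    out$ci_lo <- ival$lo
    out$ci_hi <- ival$hi
    out$ci_method <- ival$method
    out$half_ci <- (ival$hi - ival$lo) / 2
    out$classification <- classify_trend(ival$lo, ival$hi)
  } else {
    out$ci_lo <- NA_real_
    out$ci_hi <- NA_real_
    out$ci_method <- "none"
    out$half_ci <- NA_real_
    out$classification <- NA_character_
  }
  structure(out, class = "ss_fit")
}

#' @export
print.ss_fit <- function(x, ...) {
  cat(sprintf(
    "state-space fit: mu = %.4g (95%% CI %.4g to %.4g), sigma2 = %.4g, tau2 = %.4g\n",
    x$mu, x$ci_lo, x$ci_hi, x$sigma2, x$tau2))
  cat(sprintf("  classification: %s (CI: %s)\n", x$classification,
              x$ci_method))
  invisible(x)
}

# Integrated-likelihood CI for mu: mixture over a log-spaced grid of
# (sigma2, tau2), weighted by the restricted likelihood (drift removed by
# generalized least squares, with the standard REML determinant term).
# The mixture CDF of mu is a weighted sum of Gaussians; interval endpoints
# come from root-finding on it.
.ss_integrated_ci <- function(years, values, ngrid = 25, level = 0.95) {
  d <- diff(values)
  delta <- diff(years)
  m <- length(d)
  vtot <- stats::var(d / delta)
  if (!is.finite(vtot) || vtot <= 0) vtot <- 1e-6
  lsig <- seq(log(vtot * 1e-4), log(vtot * 4), length.out = ngrid)
  ltau <- seq(log(vtot * 1e-4), log(vtot * 2), length.out = ngrid)
  mus <- ses <- ll <- matrix(NA_real_, ngrid, ngrid)
  idx <- if (m > 1) cbind(seq_len(m - 1), seq_len(m - 1) + 1) else NULL
  for (i in seq_len(ngrid)) {
    for (j in seq_len(ngrid)) {
      s2 <- exp(lsig[i])
      t2 <- exp(ltau[j])
      S <- diag(s2 * delta + 2 * t2, m)
      if (!is.null(idx)) {
        S[idx] <- -t2
        S[idx[, 2:1, drop = FALSE]] <- -t2
      }
      ch <- tryCatch(chol(S), error = function(e) NULL)
      if (is.null(ch)) next
      zd <- backsolve(ch, d, transpose = TRUE)
      zx <- backsolve(ch, delta, transpose = TRUE)
      sxx <- sum(zx^2)
      mu <- sum(zx * zd) / sxx
      r <- zd - mu * zx
      ll[i, j] <- -sum(log(diag(ch))) - 0.5 * sum(r^2) - 0.5 * log(sxx)
      mus[i, j] <- mu
      ses[i, j] <- sqrt(1 / sxx)
    }
  }
  if (all(is.na(ll))) return(list(lo = NA_real_, hi = NA_real_,
                                  method = "none"))
  w <- exp(ll - max(ll, na.rm = TRUE))
  w[is.na(w)] <- 0
  w <- w / sum(w)
  a <- (1 - level) / 2
  lim <- c(min(mus - 6 * ses, na.rm = TRUE),
           max(mus + 6 * ses, na.rm = TRUE))
  cdf <- function(t) sum(w * stats::pnorm((t - mus) / ses), na.rm = TRUE)
  lo <- stats::uniroot(function(t) cdf(t) - a, lim, tol = 1e-9)$root
  hi <- stats::uniroot(function(t) cdf(t) - (1 - a), lim, tol = 1e-9)$root
  list(lo = lo, hi = hi, method = "integrated")
}

# Profile-likelihood CI for mu at the chisq(1) 95% cutoff. For fixed mu the
# variances are re-optimized (2-parameter inner search started at the MLE).
.ss_profile_ci <- function(years, values, mu_hat, sigma2, tau2, loglik_hat) {
  cutoff <- loglik_hat - stats::qchisq(0.95, df = 1) / 2
  lp_start <- log(pmax(c(sigma2, tau2), 1e-10))
  prof_ll <- function(mu) {
    obj <- function(p) {
      -increment_loglik(years, values, mu, exp(p[1]), exp(p[2]))
    }
    fit <- tryCatch(
      stats::optim(lp_start, obj, method = "Nelder-Mead",
                   control = list(maxit = 300, reltol = 1e-10)),
      error = function(e) NULL)
    if (is.null(fit)) -Inf else -fit$value
  }
  se0 <- .ss_wald_se(years, values, mu_hat, sigma2, tau2)
  step <- if (is.finite(se0) && se0 > 0) se0 else
    max(abs(mu_hat), 0.01) / 2 + 0.01
  root_for <- function(dir) {
    lo_mu <- mu_hat
    hi_mu <- mu_hat + dir * step
    for (i in 1:40) {
      if (prof_ll(hi_mu) < cutoff) break
      lo_mu <- hi_mu
      hi_mu <- mu_hat + dir * step * 2^i
    }
    if (prof_ll(hi_mu) >= cutoff) return(NA_real_)
    stats::uniroot(function(m) prof_ll(m) - cutoff,
                   lower = min(lo_mu, hi_mu), upper = max(lo_mu, hi_mu),
                   tol = 1e-7)$root
  }
  lo <- tryCatch(root_for(-1), error = function(e) NA_real_)
  hi <- tryCatch(root_for(+1), error = function(e) NA_real_)
  if (is.na(lo) || is.na(hi)) {
    if (is.finite(se0) && se0 > 0) {
      return(list(lo = mu_hat - 1.96 * se0, hi = mu_hat + 1.96 * se0,
                  method = "wald"))
    }
    return(list(lo = NA_real_, hi = NA_real_, method = "none"))
  }
  list(lo = lo, hi = hi, method = "profile")
}

# Wald SE of mu from the analytic GLS variance at fixed variances
.ss_wald_se <- function(years, values, mu, sigma2, tau2) {
  delta <- diff(years)
  m <- length(delta)
  S <- diag(sigma2 * delta + 2 * tau2, m)
  if (m > 1) {
    idx <- cbind(seq_len(m - 1), seq_len(m - 1) + 1)
    S[idx] <- -tau2
    S[idx[, 2:1, drop = FALSE]] <- -tau2
  }
  ch <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(ch)) return(NA_real_)
  zx <- backsolve(ch, delta, transpose = TRUE)
  sqrt(1 / sum(zx^2))
}

#' Classify a trend by its 95% interval
#'
#' A population is declining when the whole interval is below zero,
#' increasing when it is above zero, and otherwise shows no net change.
#'
#' @param lo,hi Interval endpoints.
#' @return `"decline"`, `"increase"` or `"no_net_change"`.
#' @export
classify_trend <- function(lo, hi) {
  stopifnot(all(lo <= hi | is.na(lo) | is.na(hi)))
  out <- rep("no_net_change", length(lo))
  out[hi < 0] <- "decline"
  out[lo > 0] <- "increase"
  out[is.na(lo) | is.na(hi)] <- NA_character_
  out
}

#' Ordinary least-squares trend of abundance on year
#'
#' The comparison estimator: slope, standard error and two-sided p-value of
#' a straight-line fit of (scaled) abundance against calendar year.
#'
#' @param years Survey years.
#' @param values Abundances (any scaling).
#' @return List with `slope`, `se`, `p`.
#' @export
fit_linear_trend <- function(years, values) {
  n <- length(values)
  if (n < 2) stop("need at least 2 observations", call. = FALSE)
  xc <- years - mean(years)
  sxx <- sum(xc^2)
  slope <- sum(xc * values) / sxx
  if (n == 2) {
    return(list(slope = slope, se = NA_real_, p = NA_real_))
  }
  fitted <- mean(values) + slope * xc
  rss <- sum((values - fitted)^2)
  se <- sqrt(rss / (n - 2) / sxx)
  tstat <- if (se > 0) slope / se else Inf * sign(slope)
  p <- if (se > 0) 2 * stats::pt(-abs(tstat), df = n - 2) else 0
  list(slope = slope, se = se, p = p)
}

#' Five per-series fluctuation metrics
#'
#' Alternative measures of population variability, later z-scaled across a
#' dataset before second-stage modelling: (1) the standard error of the
#' linear-model slope, (2) half the 95% interval around the drift, (3) the
#' same half-interval weighted by the observation-error variance, (4) the
#' process noise `sigma2`, (5) the standard deviation of the scaled data.
#'
#' @param years,values The series the fit was computed on.
#' @param fit An `ss_fit` from [fit_state_space()].
#' @return Named numeric vector of the five metrics.
#' @export
fluctuation_metrics <- function(years, values, fit) {
  stopifnot(inherits(fit, "ss_fit"))
  lt <- fit_linear_trend(years, values)
  half <- fit$half_ci
  c(se_slope = lt$se,
    half_ci = half,
    half_ci_weighted = half * (1 + fit$tau2),
    sigma2 = fit$sigma2,
    sd_raw = stats::sd(values))
}

#' Percent change between two abundances
#'
#' @param first Abundance at the start (> 0).
#' @param last Abundance at the end.
#' @return Percent change, `100 * (last - first) / first`; negative values
#'   are declines.
#' @export
percent_change <- function(first, last) {
  if (any(first == 0)) stop("percent change undefined for first = 0",
                            call. = FALSE)
  100 * (last - first) / first
}

#' Stage-1 driver: fit every series in a collection
#'
#' Aggregates within-year replicates, applies the minimum-points filter,
#' scales each series and fits the state-space and linear-trend models,
#' returning one row per retained series.
#'
#' @param x A [pop_collection()].
#' @param scaling `"minmax01"` (default) or `"zscore"`.
#' @param min_points Minimum surveys per series (default 5).
#' @param ci Compute profile intervals (default TRUE).
#' @param seed Seed for optimizer start jitter.
#' @return Tibble with columns `series_id`, `species`, `taxon_class`,
#'   `realm`, `biome`, `latitude`, `n_obs`, `duration`, `mu`, `sigma2`,
#'   `tau2`, `ci_lo`, `ci_hi`, `half_ci`, `classification`, `slope_lm`,
#'   `se_slope`, `p_slope`, `sd_raw`, `loglik`, `converged`.
#' @export
fit_trends <- function(x, scaling = "minmax01", min_points = 5, ci = TRUE,
                       ci_method = "integrated", seed = 1) {
  stopifnot(inherits(x, "pop_collection"))
  x <- aggregate_within_year(x)
  x <- filter_min_points(x, k = min_points)
  if (nrow(x$meta) == 0) return(tibble::tibble())
  x <- scale_abundance(x, method = scaling)
  ids <- x$meta$series_id
  rows <- vector("list", length(ids))
  obs_split <- split(x$obs[c("year", "scaled")], x$obs$series_id)
  for (i in seq_along(ids)) {
    id <- ids[i]
    o <- obs_split[[id]]
    fit <- fit_state_space(o$year, o$scaled, ci = ci,
                           ci_method = ci_method, seed = seed,
                           constant = x$meta$constant_flag[i])
    lt <- fit_linear_trend(o$year, o$scaled)
    rows[[i]] <- tibble::tibble(
      series_id = id,
      n_obs = nrow(o),
      duration = diff(range(o$year)) + 1L,
      mu = fit$mu, sigma2 = fit$sigma2, tau2 = fit$tau2,
      ci_lo = fit$ci_lo, ci_hi = fit$ci_hi, half_ci = fit$half_ci,
      classification = fit$classification,
      slope_lm = lt$slope, se_slope = lt$se, p_slope = lt$p,
      sd_raw = stats::sd(o$scaled), loglik = fit$loglik,
      converged = fit$converged
    )
  }
  out <- dplyr::bind_rows(rows)
  meta_keep <- x$meta[c("series_id", "species", "taxon_class", "realm",
                        "biome", "latitude", "unit", "iucn_category")]
  dplyr::left_join(meta_keep, out, by = "series_id")
}

# Seed-local RNG helpers: draw reproducibly without touching the global
# .Random.seed (callers' RNG state is left intact).
.local_rng <- function(seed) {
  env <- new.env()
  env$state <- local({
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    } else NULL
    set.seed(seed)
    s <- get(".Random.seed", globalenv())
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
    s
  })
  draw <- function(fn, ...) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    } else NULL
    assign(".Random.seed", env$state, envir = globalenv())
    out <- fn(...)
    env$state <- get(".Random.seed", globalenv())
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
    out
  }
  list(
    rnorm = function(...) draw(stats::rnorm, ...),
    runif = function(...) draw(stats::runif, ...),
    rpois = function(...) draw(stats::rpois, ...),
    rgamma = function(...) draw(stats::rgamma, ...),
    sample = function(...) draw(base::sample, ...),
    draw = draw
  )
}
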