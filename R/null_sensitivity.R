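#' Randomize a dataset while preserving its structure
#'
#' Builds a null dataset with the same shape as the input: within each
#' series, abundance values are randomly permuted across its survey years,
#' so every series keeps its exact value distribution, length, year grid
#' and metadata, but any temporal trend is destroyed.
#'
#' @param x A [pop_collection()].
#' @param seed Integer seed; the permutation is reproducible.
#' @return A [pop_collection()] of permuted series.
#' @export
randomize_dataset <- function(x, seed = 1) {
  stopifnot(inherits(x, "pop_collection"))
  rs <- .local_rng(seed)
  obs <- x$obs
  for (ii in split(seq_len(nrow(obs)), obs$series_id)) {
    if (length(ii) > 1) {
      obs$abundance[ii] <- obs$abundance[ii[rs$sample(length(ii))]]
    }
  }
  pop_collection(x$meta, obs)
}

#' Share of significant linear trends
#'
#' Fits an ordinary least-squares slope of abundance on year to every
#' series and reports the percentage of series with a significantly
#' negative and significantly positive slope (two-sided t-test at
#' `alpha`). Applied to randomized data this measures the null
#' expectation against which observed decline/increase rates are judged.
#'
#' @param x A [pop_collection()]; every series needs >= 3 observations.
#' @param alpha Significance level (default 0.05).
#' @return List of class `null_result`: `pct_sig_negative`,
#'   `pct_sig_positive`, `n_series`, `alpha`.
#' @export
significance_rates <- function(x, alpha = 0.05) {
  stopifnot(inherits(x, "pop_collection"))
  counts <- table(x$obs$series_id)
  if (any(counts < 3)) {
    stop("all series need at least 3 observations", call. = FALSE)
  }
  obs_split <- split(x$obs[c("year", "abundance")], x$obs$series_id)
  neg <- 0L
  pos <- 0L
  for (o in obs_split) {
    lt <- fit_linear_trend(o$year, o$abundance)
    if (!is.na(lt$p) && lt$p < alpha) {
      if (lt$slope < 0) neg <- neg + 1L else pos <- pos + 1L
    }
  }
  n <- length(obs_split)
  structure(list(pct_sig_negative = 100 * neg / n,
                 pct_sig_positive = 100 * pos / n,
                 n_series = n, alpha = alpha),
            class = "null_result")
}

#' @export
print.null_result <- function(x, ...) {
  cat(sprintf(
    "null rates over %d series (alpha = %g): %.2f%% declining, %.2f%% increasing\n",
    x$n_series, x$alpha, x$pct_sig_negative, x$pct_sig_positive))
  invisible(x)
}

#' Left/right-truncate every series
#'
#' Site-selection bias check: monitoring often starts when density is
#' unusually high (or, for rare species, low), so trends are re-estimated
#' after dropping the first and/or last surveys of every series. The
#' minimum-points filter is expected to be re-applied downstream.
#'
#' @param x A [pop_collection()].
#' @param drop_first,drop_last Number of observations to remove from each
#'   end (defaults 5 and 0).
#' @return A [pop_collection()]; series whose observations are exhausted
#'   are removed entirely.
#' @export
truncate_series <- function(x, drop_first = 5, drop_last = 0) {
  stopifnot(inherits(x, "pop_collection"), drop_first >= 0, drop_last >= 0)
  obs <- dplyr::bind_rows(lapply(split(x$obs, x$obs$series_id), function(o) {
    n <- nrow(o)
    keep <- seq_len(n) > drop_first & seq_len(n) <= n - drop_last
    o[keep, , drop = FALSE]
  }))
  meta <- x$meta[x$meta$series_id %in% obs$series_id, , drop = FALSE]
  if (nrow(meta) == 0) {
    return(structure(list(meta = meta, obs = obs,
                          has_duplicate_years = FALSE),
                     class = "pop_collection"))
  }
  pop_collection(meta, obs)
}

# Greatest-convex-minorant feasibility sweep used by the dip statistic.
# Points (w_i, bands [l_i, u_i]) are processed left to right, maintaining
# the lower convex hull of the upper bounds; a prefix 1..k admits a convex
# nondecreasing function inside its bands iff that hull stays above every
# lower bound. Returns:
#   kmax  - longest plainly feasible prefix
#   kmax_relaxed - longest prefix feasible when the final point's own
#                  lower bound is waived (mode-with-atom splits)
.gcm_prefix_feasible <- function(w, l, u) {
  K <- length(w)
  hull <- integer(K)   # indices of hull vertices
  nh <- 0L
  kmax <- 0L
  kmax_relaxed <- 0L
  for (k in seq_len(K)) {
    # pop vertices that stop being convex once (w_k, u_k) is added
    while (nh >= 2) {
      a <- hull[nh - 1L]; b <- hull[nh]
      # b above segment a->k  => pop
      cr <- (u[k] - u[a]) * (w[b] - w[a]) - (u[b] - u[a]) * (w[k] - w[a])
      if (cr >= 0) break
      nh <- nh - 1L
    }
    ok_interior <- TRUE
    if (nh >= 1) {
      a <- hull[nh]
      span <- if (k - a > 1L) (a + 1L):(k - 1L) else integer(0)
      if (length(span) > 0) {
        line <- u[a] + (u[k] - u[a]) * (w[span] - w[a]) / (w[k] - w[a])
        ok_interior <- all(line >= l[span] - 1e-12)
      }
    }
    ok_own <- u[k] >= l[k] - 1e-12
    if (ok_interior) kmax_relaxed <- k
    if (ok_interior && ok_own) {
      kmax <- k
      nh <- nh + 1L
      hull[nh] <- k
    } else {
      break
    }
  }
  list(kmax = kmax, kmax_relaxed = kmax_relaxed)
}

# Convexity forces a prefix's end value above every chord from an upper
# bound (w_i, u_i) through a lower bound (w_j, l_j), extrapolated
# forward; the tightest such bound is attained (verified against exact
# linear programs). `shat[j]` is the steepest forced slope into knot j.
.forced_slopes <- function(w, l, u, kmax) {
  if (kmax <= 1) return(numeric(kmax))
  # steepest chord from any earlier upper bound up to each lower bound
  kk <- seq_len(kmax)
  r <- outer(l[kk], u[kk], "-") / outer(w[kk], w[kk], "-")
  r[upper.tri(r, diag = TRUE)] <- -Inf
  r[1, 1] <- 0
  pmax(0, r[cbind(kk, max.col(r, ties.method = "first"))])
}


# Band feasibility of a unimodal cdf at half-width rho. The mode may fall
# between two distinct data values (both parts band-constrained) or carry
# an atom at a data value (that value's inner constraint waived on each
# side). Concave suffixes are checked by the reflection
# g(t) = 1 - h(-t), which maps them onto convex prefixes. At a candidate
# mode the rising flank's minimal end value must not exceed the falling
# flank's maximal start value (the CDF is nondecreasing through the
# mode); with `coupling = FALSE` that junction condition is skipped,
# giving a cheap relaxation used to bracket the bisection.
.dip_feasible <- function(w, cum, n, rho, coupling = TRUE) {
  if (!coupling) {
    !is.null(.dip_sides(w, cum, n, rho))
  } else {
    v <- .dip_violation(w, cum, n, rho)
    v <= 1e-12
  }
}

# Flank feasibility bookkeeping at half-width rho; NULL when even the
# junction-free relaxation fails.
.dip_sides <- function(w, cum, n, rho) {
  K <- length(w)
  l <- pmax(cum / n - rho, 0)
  u <- pmin(c(0, cum[-K]) / n + rho, 1)
  pre <- .gcm_prefix_feasible(w, l, u)
  # reflection g(t) = 1 - h(-t): same bands, reversed and complemented
  wr <- -rev(w)
  lr <- 1 - rev(u)
  ur <- 1 - rev(l)
  suf <- .gcm_prefix_feasible(wr, lr, ur)
  if (pre$kmax >= K || suf$kmax >= K) {
    return(list(single_flank = TRUE))
  }
  gap_ok <- pre$kmax + suf$kmax >= K
  knot_ok <- pre$kmax_relaxed + suf$kmax_relaxed >= K + 1
  if (!gap_ok && !knot_ok) return(NULL)
  list(single_flank = FALSE, K = K, l = l, u = u, wr = wr, lr = lr,
       pre = pre, suf = suf, gap_ok = gap_ok, knot_ok = knot_ok)
}

# Minimal junction violation (rising flank's lowest end value minus the
# falling flank's highest start value) over all admissible mode
# positions: <= 0 means a unimodal cdf fits the band. +Inf when the
# relaxation already fails, -Inf when one flank spans the whole sample.
# Increasing rho by delta lowers every minimum, raises every maximum and
# loosens every flank by at least delta, so the violation falls at rate
# of at least 2 in rho: from an infeasible rho, rho + violation/2 is
# always feasible, which the bisection exploits.
.dip_violation <- function(w, cum, n, rho) {
  s <- .dip_sides(w, cum, n, rho)
  if (is.null(s)) return(Inf)
  if (s$single_flank) return(-Inf)
  K <- s$K
  kp <- min(s$pre$kmax_relaxed, K)
  ks <- min(s$suf$kmax_relaxed, K)
  shat_pre <- .forced_slopes(w, s$l, s$u, kp)
  shat_suf <- .forced_slopes(s$wr, s$lr, 1 - rev(s$l), ks)
  env <- function(l_, w_, shat_, k) {
    if (k <= 1) return(-Inf)
    j <- seq_len(k - 1)
    max(l_[j] + shat_[j] * (w_[k] - w_[j]))
  }
  viol <- Inf
  # suffix starting at knot j = reflected prefix of length K - j + 1;
  # its maximal start value is 1 - (reflected minimal end value)
  if (s$gap_ok) {
    for (k in max(1, K - s$suf$kmax):min(s$pre$kmax, K - 1)) {
      gmin <- max(s$l[k], env(s$l, w, shat_pre, k))
      hmax <- 1 - max(s$lr[K - k], env(s$lr, s$wr, shat_suf, K - k))
      viol <- min(viol, gmin - hmax)
      if (viol <= 0) return(viol)
    }
  }
  if (s$knot_ok) {
    for (m in max(1, K - s$suf$kmax_relaxed + 1):min(s$pre$kmax_relaxed, K)) {
      gmin <- env(s$l, w, shat_pre, m)   # own lower bound waived
      hmax <- 1 - env(s$lr, s$wr, shat_suf, K - m + 1)
      viol <- min(viol, gmin - hmax)
      if (viol <= 0) return(viol)
    }
  }
  viol
}

#' Hartigan's dip statistic
#'
#' The dip is the smallest sup-norm distance between the empirical CDF
#' and any unimodal CDF: large values indicate at least two modes. It is
#' computed by bisection on the band half-width `rho`, where feasibility
#' of a unimodal CDF within the band `[F_n - rho, F_n + rho]` is decided
#' with a greatest-convex-minorant sweep from the left (rising, convex
#' flank) and a least-concave-majorant sweep from the right (falling
#' flank), over every admissible mode position. The reported value is
#' clamped to the known envelope `[1/(2n), 1/4]`.
#'
#' @param x Numeric sample, `n >= 4`.
#' @param tol Bisection tolerance (default 1e-9).
#' @return List of class `dip_result` with `D` and `n`.
#' @export
dip_statistic <- function(x, tol = 1e-9) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 4) stop("need at least 4 observations", call. = FALSE)
  sx <- sort(x)
  w <- unique(sx)
  cum <- cumsum(tabulate(match(sx, w), length(w)))
  # phase 1: cheap bisection without the mode-junction condition (a
  # relaxation, so it brackets the dip from below); phase 2: resume with
  # the full check from the relaxed solution upward. In the common case
  # the junction never binds and phase 2 costs one feasibility check.
  lo <- 0
  hi <- 0.5
  if (.dip_feasible(w, cum, n, lo, coupling = FALSE)) {
    hi <- 0
  } else {
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (.dip_feasible(w, cum, n, mid, coupling = FALSE)) hi <- mid
      else lo <- mid
    }
  }
  lo_full <- lo
  v <- .dip_violation(w, cum, n, hi)
  if (v > 1e-12) {
    # junction binds: rho + v/2 is guaranteed feasible (violation falls
    # at rate >= 2 in rho), then violation-guided bisection
    lo <- hi
    hi <- min(hi + v / 2 + tol, 0.5)
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      v <- .dip_violation(w, cum, n, mid)
      if (v <= 1e-12) {
        hi <- mid
      } else {
        lo <- mid
        hi <- min(hi, mid + v / 2 + tol)
      }
    }
  } else {
    lo <- lo_full
  }
  D <- min(max((lo + hi) / 2, 1 / (2 * n)), 0.25)
  structure(list(D = D, n = n), class = "dip_result")
}

#' @export
print.dip_result <- function(x, ...) {
  cat(sprintf("Hartigan dip: D = %.4f (n = %d)", x$D, x$n))
  if (!is.null(x$p)) cat(sprintf(", p = %.4g (%d bootstraps)", x$p, x$n_boot))
  cat("\n")
  invisible(x)
}

#' Monte-Carlo p-value for the dip statistic
#'
#' The null reference distribution is the dip of uniform(0, 1) samples of
#' the same size (the uniform is the least favourable unimodal null).
#'
#' @param D Observed dip statistic.
#' @param n Sample size it was computed from.
#' @param n_boot Number of Monte-Carlo draws (default 2000).
#' @param seed Integer seed.
#' @return List of class `dip_result` with `D`, `p`, `n`, `n_boot`.
#' @export
dip_pvalue <- function(D, n, n_boot = 2000, seed = 1) {
  stopifnot(n >= 4, n_boot >= 1)
  rs <- .local_rng(seed)
  null_D <- vapply(seq_len(n_boot), function(i) {
    dip_statistic(rs$runif(n), tol = 1e-7)$D
  }, numeric(1))
  structure(list(D = D, p = mean(null_D >= D), n = n, n_boot = n_boot),
            class = "dip_result")
}

#' Trend-versus-duration model through the origin
#'
#' Regresses per-series trend estimates on monitoring duration with the
#' intercept suppressed: a series monitored for zero years cannot have
#' changed, so the line is forced through the origin. Fitted with the
#' same Gibbs machinery as the other second-stage models.
#'
#' @param trends Numeric vector of trend estimates.
#' @param durations Numeric vector of durations (> 0), same length.
#' @param species Optional species labels for a random intercept.
#' @param iterations,burnin,thin,seed MCMC settings (desk-scale defaults).
#' @return Tibble row: posterior mean `slope`, `lo`, `hi`.
#' @export
duration_model <- function(trends, durations, species = NULL,
                           iterations = 6000, burnin = 1000, thin = 5,
                           seed = 1) {
  stopifnot(length(trends) == length(durations), all(durations > 0))
  df <- tibble::tibble(trend = trends, duration = durations)
  if (!is.null(species)) df$species <- species
  fit <- gibbs_mixed_fit(df, response = "trend", predictor = "duration",
                         random_species = !is.null(species),
                         zero_intercept = TRUE,
                         iterations = iterations, burnin = burnin,
                         thin = thin, seed = seed)
  s <- posterior_summary(fit)
  s <- s[s$parameter == "duration", ]
  tibble::tibble(slope = s$mean, lo = s$lo, hi = s$hi)
}
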