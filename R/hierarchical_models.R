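#' Bayesian Gaussian mixed model by blocked Gibbs sampling
#'
#' Second-stage model of per-population estimates (trends or fluctuation
#' metrics) across a predictor, with an optional species random intercept
#' and optional known per-observation measurement-error variances:
#'
#' `y_i = x_i' beta + b_species(i) + m_i + e_i`,
#' `b_j ~ N(0, var_species)`, `m_i ~ N(0, mev_i)` (known), `e_i ~ N(0,
#' var_residual)`.
#'
#' Categorical predictors are fitted with a zero intercept (one
#' coefficient per level, no reference category) so each level's net trend
#' is tested directly against zero; continuous predictors get a global
#' intercept unless `zero_intercept = TRUE` (used by the
#' monitoring-duration model, where zero duration must imply zero change).
#' Coefficients have N(0, 1e8) priors; variances have inverse-gamma
#' priors. All conditional updates are conjugate (normal for location
#' blocks, inverse-gamma for variances).
#'
#' @param data Data frame holding the response, predictor, species labels
#'   and (optionally) measurement-error variances.
#' @param response Name of the response column.
#' @param predictor Name of the predictor column, or `NULL` for an
#'   intercept-only model.
#' @param species Name of the species column (random intercept); set
#'   `random_species = FALSE` to drop the random effect.
#' @param random_species Include the species random intercept?
#' @param zero_intercept Drop the global intercept. Defaults to `TRUE` for
#'   categorical predictors (factor/character), `FALSE` otherwise.
#' @param mev Name of a column of known per-observation measurement-error
#'   variances (>= 0), or `NULL` for none.
#' @param iterations,burnin,thin MCMC settings; defaults follow the
#'   production configuration (120000 / 20000 / 10). Use smaller values
#'   for desk-scale runs.
#' @param chains Number of independent chains (default 1). With more than
#'   one chain, split-Rhat is computed per parameter.
#' @param seed Integer seed; chain `c` uses `seed + c - 1`.
#' @param prior List with `beta_var` (coefficient prior variance),
#'   `v_shape`, `v_scale` (inverse-gamma shape/scale for variances).
#' @return Object of class `hier_fit`: `draws` (tibble of retained draws,
#'   one column per parameter plus `chain`), `parameters`, `rhat` (when
#'   `chains > 1`), `sd_response`, `sd_predictor`, and the call settings.
#' @export
gibbs_mixed_fit <- function(data, response, predictor = NULL,
                            species = "species", random_species = TRUE,
                            zero_intercept = NULL, mev = NULL,
                            iterations = 120000, burnin = 20000,
                            thin = 10, chains = 1, seed = 1,
                            prior = list(beta_var = 1e8, v_shape = 0.001,
                                         v_scale = 0.001)) {
  stopifnot(iterations > burnin, thin >= 1, chains >= 1)
  df <- as.data.frame(data)
  y <- df[[response]]
  if (is.null(y)) stop("no column '", response, "' in data", call. = FALSE)
  keep <- is.finite(y)
  if (!is.null(predictor)) keep <- keep & !is.na(df[[predictor]])
  if (random_species) keep <- keep & !is.na(df[[species]])
  if (!all(keep[!is.na(df[[response]])])) {
    # non-finite responses among otherwise-complete rows are a data error
    bad <- !is.finite(df[[response]]) & !is.na(df[[response]])
    if (any(bad)) stop("non-finite response values", call. = FALSE)
  }
  df <- df[keep, , drop = FALSE]
  y <- df[[response]]
  n <- length(y)
  if (n < 2) stop("need at least 2 usable rows", call. = FALSE)

  # fixed-effect design
  if (is.null(predictor)) {
    X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
    categorical <- FALSE
  } else {
    p_raw <- df[[predictor]]
    categorical <- is.character(p_raw) || is.factor(p_raw)
    if (is.null(zero_intercept)) zero_intercept <- categorical
    if (categorical) {
      f <- factor(p_raw)
      X <- vapply(levels(f), function(L) as.numeric(f == L),
                  numeric(n))
      if (!zero_intercept && nlevels(f) > 1) {
        X <- cbind("(Intercept)" = 1, X[, -1, drop = FALSE])
      }
    } else {
      X <- if (zero_intercept) {
        matrix(p_raw, n, 1, dimnames = list(NULL, predictor))
      } else {
        cbind("(Intercept)" = 1, stats::setNames(p_raw, NULL))
      }
      if (!zero_intercept) colnames(X)[2] <- predictor
    }
  }
  p <- ncol(X)

  sp <- if (random_species) factor(df[[species]]) else NULL
  m_lev <- if (random_species) nlevels(sp) else 0L
  sp_i <- if (random_species) as.integer(sp) else NULL

  mev_v <- if (is.null(mev)) rep(0, n) else {
    v <- df[[mev]]
    stopifnot(all(is.finite(v)), all(v >= 0))
    v
  }
  has_mev <- mev_v > 0

  bv <- prior$beta_var
  vs <- prior$v_shape
  vr <- prior$v_scale
  XtX <- crossprod(X)

  run_chain <- function(chain_seed) {
    rs <- .local_rng(chain_seed)
    # initial values from least squares
    beta <- tryCatch(stats::coef(stats::lm.fit(X, y)),
                     error = function(e) rep(0, p))
    beta[!is.finite(beta)] <- 0
    b <- rep(0, m_lev)
    mlat <- rep(0, n)
    var_sp <- stats::var(y) / 4 + 1e-6
    var_e <- stats::var(y) / 2 + 1e-6
    n_keep <- floor((iterations - burnin) / thin)
    cols <- p + (if (random_species) 1L else 0L) + 1L
    out <- matrix(NA_real_, n_keep, cols)
    kept <- 0L
    for (it in seq_len(iterations)) {
      resid_b <- if (random_species) b[sp_i] else 0
      # beta | rest
      r <- y - resid_b - mlat
      Vinv <- XtX / var_e + diag(1 / bv, p)
      ch <- chol(Vinv)
      mu_b <- backsolve(ch, backsolve(ch, crossprod(X, r) / var_e,
                                      transpose = TRUE))
      beta <- as.vector(mu_b + backsolve(ch, rs$rnorm(p)))
      xb <- as.vector(X %*% beta)
      # species intercepts | rest
      if (random_species) {
        r <- y - xb - mlat
        sums <- rowsum(r, sp_i, reorder = TRUE)[, 1]
        nj <- tabulate(sp_i, m_lev)
        prec <- nj / var_e + 1 / var_sp
        b <- rs$rnorm(m_lev, (sums / var_e) / prec, sqrt(1 / prec))
        var_sp <- 1 / rs$rgamma(1, vs + m_lev / 2,
                                rate = vr + sum(b^2) / 2)
        resid_b <- b[sp_i]
      }
      # latent measurement-error terms (known variances) | rest
      if (any(has_mev)) {
        r <- y - xb - resid_b
        prec <- 1 / mev_v[has_mev] + 1 / var_e
        mlat[has_mev] <- rs$rnorm(sum(has_mev),
                                  (r[has_mev] / var_e) / prec,
                                  sqrt(1 / prec))
      }
      # residual variance | rest
      rr <- y - xb - resid_b - mlat
      var_e <- 1 / rs$rgamma(1, vs + n / 2, rate = vr + sum(rr^2) / 2)
      if (it > burnin && (it - burnin) %% thin == 0) {
        kept <- kept + 1L
        out[kept, ] <- c(beta,
                         if (random_species) var_sp,
                         var_e)
      }
    }
    colnames(out) <- c(colnames(X),
                       if (random_species) "var_species",
                       "var_residual")
    out
  }

  draws_list <- lapply(seq_len(chains),
                       function(cc) run_chain(seed + cc - 1))
  draws <- do.call(rbind, draws_list)
  draws <- tibble::as_tibble(draws)
  draws$chain <- rep(seq_len(chains), each = nrow(draws_list[[1]]))

  rhat <- if (chains > 1) {
    vapply(setdiff(names(draws), "chain"), function(par) {
      .split_rhat(matrix(draws[[par]], ncol = chains))
    }, numeric(1))
  } else NULL

  structure(
    list(draws = draws,
         parameters = setdiff(names(draws), "chain"),
         fixed_names = colnames(X),
         rhat = rhat,
         sd_response = stats::sd(y),
         sd_predictor = if (!is.null(predictor) && !categorical) {
           stats::sd(df[[predictor]])
         } else NA_real_,
         categorical = if (is.null(predictor)) NA else categorical,
         response = response, predictor = predictor,
         n = n, n_species = m_lev,
         settings = list(iterations = iterations, burnin = burnin,
                         thin = thin, chains = chains, seed = seed)),
    class = "hier_fit")
}

# split-Rhat: each chain halved, between/within variance ratio
.split_rhat <- function(mat) {
  half <- floor(nrow(mat) / 2)
  splits <- do.call(cbind, lapply(seq_len(ncol(mat)), function(j) {
    cbind(mat[seq_len(half), j], mat[half + seq_len(half), j])
  }))
  m <- ncol(splits)
  n <- nrow(splits)
  means <- colMeans(splits)
  vars <- apply(splits, 2, stats::var)
  B <- n * stats::var(means)
  W <- mean(vars)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' @export
print.hier_fit <- function(x, ...) {
  cat(sprintf("<hier_fit> %d rows, %d species, %d chain(s), %d draws\n",
              x$n, x$n_species, x$settings$chains, nrow(x$draws)))
  print(posterior_summary(x))
  invisible(x)
}

#' Posterior means and credible intervals
#'
#' Summarises retained draws: posterior mean, central credible interval,
#' and a flag for whether the interval excludes zero (mirroring the
#' stage-1 trend classification logic).
#'
#' @param fit A `hier_fit` (or any data frame of draws with a `chain`
#'   column).
#' @param level Credible level (default 0.95).
#' @return Tibble with `parameter`, `mean`, `lo`, `hi`,
#'   `differs_from_zero`.
#' @export
posterior_summary <- function(fit, level = 0.95) {
  draws <- if (inherits(fit, "hier_fit")) fit$draws else
    tibble::as_tibble(fit)
  pars <- setdiff(names(draws), "chain")
  if (nrow(draws) < 100) {
    stop("need at least 100 retained draws", call. = FALSE)
  }
  a <- (1 - level) / 2
  out <- lapply(pars, function(p) {
    v <- draws[[p]]
    q <- unname(stats::quantile(v, c(a, 1 - a), type = 7))
    tibble::tibble(parameter = p, mean = mean(v), lo = q[1], hi = q[2],
                   differs_from_zero = q[1] > 0 | q[2] < 0)
  })
  dplyr::bind_rows(out)
}

#' Standardize an effect size
#'
#' Effect sizes are made comparable across models by dividing by the
#' standard deviation of the corresponding input data.
#'
#' @param effect Effect size (posterior mean or slope).
#' @param input_sd Standard deviation of the input variable (> 0).
#' @return `effect / input_sd`.
#' @export
standardize_effect <- function(effect, input_sd) {
  if (any(!is.finite(input_sd)) || any(input_sd <= 0)) {
    stop("input_sd must be positive", call. = FALSE)
  }
  effect / input_sd
}
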