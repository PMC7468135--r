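#' Read Newick trees and sample a subset
#'
#' Reads one or many Newick trees from a file, normalizes tip labels
#' (underscores become spaces) so they match binomial species names, and
#' samples `k` trees without replacement, reproducibly from the seed. This
#' mirrors the practice of downloading a pool of candidate trees from a
#' tree repository and analysing a random sample of them to propagate
#' phylogenetic uncertainty.
#'
#' @param path Newick file (one tree per line or a multi-tree file).
#' @param k Number of trees to sample (default 10).
#' @param seed Integer seed for the sample.
#' @return List of `ape::phylo` trees, length `k`.
#' @export
read_newick_trees <- function(path, k = 10, seed = 1) {
  trees <- tryCatch(ape::read.tree(path),
                    error = function(e) {
                      stop("failed to parse Newick file '", path, "': ",
                           conditionMessage(e), call. = FALSE)
                    })
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (length(trees) == 0) stop("no trees in '", path, "'", call. = FALSE)
  if (k > length(trees)) {
    stop(sprintf("requested %d trees but file holds %d", k, length(trees)),
         call. = FALSE)
  }
  rs <- .local_rng(seed)
  idx <- sort(rs$sample(length(trees), k))
  lapply(trees[idx], function(tr) {
    tr$tip.label <- gsub("_", " ", tr$tip.label)
    tr
  })
}

#' Brownian-motion correlation matrix from a tree
#'
#' Under Brownian motion the covariance between two species is the shared
#' root-to-tip path length; dividing by the tree depth turns this into a
#' correlation with unit diagonal (non-ultrametric trees are scaled by
#' their maximum depth, so diagonals are forced to 1).
#'
#' @param tree An `ape::phylo` with branch lengths.
#' @param species Species to keep (must all be tips; underscores and
#'   spaces in labels are interchangeable).
#' @return List of class `phylo_corr` with `species` and `matrix` (a
#'   positive semi-definite correlation matrix).
#' @export
tree_to_correlation <- function(tree, species) {
  stopifnot(inherits(tree, "phylo"))
  tips <- gsub("_", " ", tree$tip.label)
  species_n <- gsub("_", " ", species)
  missing <- setdiff(species_n, tips)
  if (length(missing) > 0) {
    stop("species not in tree: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  tree$tip.label <- tips
  if (length(tips) > length(species_n)) {
    tree <- ape::keep.tip(tree, species_n)
  }
  V <- ape::vcv(tree)
  d <- diag(V)
  if (any(d <= 0)) stop("tree has zero root-to-tip depth", call. = FALSE)
  C <- V / max(d)
  diag(C) <- 1
  C <- C[species_n, species_n, drop = FALSE]
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) stop("correlation matrix not PSD", call. = FALSE)
  structure(list(species = species_n, matrix = C), class = "phylo_corr")
}

#' Intercept-only mixed model with phylogenetic and species random effects
#'
#' Decomposes the between-series variance of a trait (trend or fluctuation
#' estimate) into a phylogenetically structured species component
#' (covariance proportional to the Brownian-motion correlation from one
#' tree), an unstructured species component, and residual variance:
#'
#' `y_i = beta0 + u_phylo(species(i)) + u_species(i) + e_i`,
#' `u_phylo ~ N(0, var_phylo * C)`, `u_species ~ N(0, var_species * I)`.
#'
#' Fitted by Gibbs sampling with parameter expansion: each random-effect
#' block carries a redundant working scale `alpha ~ N(0, 1)` multiplying
#' latent effects with an inverse-gamma(1/2, 1/2) working variance, so the
#' implied prior on each effect's standard deviation is half-Cauchy-like
#' and the sampler does not stick at zero variance.
#'
#' @param response Numeric vector of per-series estimates.
#' @param species Character vector of species labels, same length.
#' @param corr A `phylo_corr` covering all species present.
#' @param iterations,burnin,thin MCMC settings (test-scale default 20000 /
#'   5000 / 10; production settings of 120000 / 20000 / 10 available).
#' @param seed Integer seed; identical seeds give identical draws.
#' @param prior List with `beta_var` and the parameter-expansion working
#'   prior `alpha_var`, `v_shape`, `v_scale`.
#' @return Object of class `phylo_fit` with `draws` (tibble: `intercept`,
#'   `var_phylo`, `var_species`, `var_residual`) and bookkeeping fields.
#' @export
fit_phylo_mixed <- function(response, species, corr,
                            iterations = 20000, burnin = 5000, thin = 10,
                            seed = 1,
                            prior = list(beta_var = 1e8, alpha_var = 1,
                                         v_shape = 0.5, v_scale = 0.5)) {
  stopifnot(inherits(corr, "phylo_corr"), length(response) == length(species),
            iterations > burnin)
  species <- gsub("_", " ", species)
  miss <- setdiff(unique(species), corr$species)
  if (length(miss) > 0) {
    stop("species missing from correlation matrix: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  keep <- is.finite(response)
  response <- response[keep]
  species <- species[keep]
  n <- length(response)
  sp_lev <- intersect(corr$species, unique(species))
  if (length(sp_lev) < 2) stop("need at least 2 species", call. = FALSE)
  m <- length(sp_lev)
  sp_i <- match(species, sp_lev)
  C <- corr$matrix[sp_lev, sp_lev, drop = FALSE]
  Cinv <- tryCatch(chol2inv(chol(C)), error = function(e) {
    message("fit_phylo_mixed: singular correlation, adding 1e-8 jitter")
    chol2inv(chol(C + diag(1e-8, m)))
  })
  nj <- tabulate(sp_i, m)

  rs <- .local_rng(seed)
  y <- response
  beta0 <- mean(y)
  v <- rep(0, m)      # latent phylo effects (working scale)
  z <- rep(0, m)      # latent iid species effects (working scale)
  a_p <- 0.1
  a_s <- 0.1
  s2_v <- 1
  s2_z <- 1
  var_e <- stats::var(y) + 1e-8
  bv <- prior$beta_var
  av <- prior$alpha_var
  vs <- prior$v_shape
  vr <- prior$v_scale
  n_keep <- floor((iterations - burnin) / thin)
  out <- matrix(NA_real_, n_keep, 4,
                dimnames = list(NULL, c("intercept", "var_phylo",
                                        "var_species", "var_residual")))
  kept <- 0L
  for (it in seq_len(iterations)) {
    u_p <- a_p * v
    u_s <- a_s * z
    # intercept
    r <- y - u_p[sp_i] - u_s[sp_i]
    prec0 <- n / var_e + 1 / bv
    beta0 <- rs$rnorm(1, (sum(r) / var_e) / prec0, sqrt(1 / prec0))
    # phylo block (latent v), correlated prior
    r <- y - beta0 - u_s[sp_i]
    rsum <- rowsum(r, sp_i, reorder = TRUE)[, 1]
    rsums <- rep(0, m); rsums[sort(unique(sp_i))] <- rsum
    P <- diag(nj * a_p^2 / var_e, m) + Cinv / s2_v
    ch <- chol(P)
    mu_v <- backsolve(ch, backsolve(ch, a_p * rsums / var_e,
                                    transpose = TRUE))
    v <- as.vector(mu_v + backsolve(ch, rs$rnorm(m)))
    # working scale alpha_p
    pv <- v[sp_i]
    prec_a <- sum(nj * v^2) / var_e + 1 / av
    a_p <- rs$rnorm(1, (sum(pv * r) / var_e) / prec_a, sqrt(1 / prec_a))
    # working variance of v
    qf <- as.numeric(t(v) %*% Cinv %*% v)
    s2_v <- 1 / rs$rgamma(1, vs + m / 2, rate = vr + qf / 2)
    u_p <- a_p * v
    # iid species block (latent z)
    r <- y - beta0 - u_p[sp_i]
    rsum <- rowsum(r, sp_i, reorder = TRUE)[, 1]
    rsums <- rep(0, m); rsums[sort(unique(sp_i))] <- rsum
    prec_z <- nj * a_s^2 / var_e + 1 / s2_z
    z <- rs$rnorm(m, (a_s * rsums / var_e) / prec_z, sqrt(1 / prec_z))
    zv <- z[sp_i]
    prec_a <- sum(nj * z^2) / var_e + 1 / av
    a_s <- rs$rnorm(1, (sum(zv * r) / var_e) / prec_a, sqrt(1 / prec_a))
    s2_z <- 1 / rs$rgamma(1, vs + m / 2, rate = vr + sum(z^2) / 2)
    u_s <- a_s * z
    # residual variance
    rr <- y - beta0 - u_p[sp_i] - u_s[sp_i]
    var_e <- 1 / rs$rgamma(1, vs + n / 2, rate = vr + sum(rr^2) / 2)
    if (it > burnin && (it - burnin) %% thin == 0) {
      kept <- kept + 1L
      out[kept, ] <- c(beta0, a_p^2 * s2_v, a_s^2 * s2_z, var_e)
    }
  }
  structure(
    list(draws = tibble::as_tibble(out), n = n, n_species = m,
         species = sp_lev,
         settings = list(iterations = iterations, burnin = burnin,
                         thin = thin, seed = seed)),
    class = "phylo_fit")
}

#' @export
print.phylo_fit <- function(x, ...) {
  cat(sprintf("<phylo_fit> %d series, %d species, %d draws\n",
              x$n, x$n_species, nrow(x$draws)))
  print(colMeans(as.matrix(x$draws)))
  invisible(x)
}

#' Summarise variance decompositions across trees
#'
#' Combines per-tree fits into the across-tree mean and range of each
#' variance component, plus a "pushed against zero" assessment per
#' component: a posterior distribution of a variance concentrated at zero
#' indicates lack of the corresponding effect. The operational rule (the
#' published criterion is visual) is that the lower `prob` fraction of
#' posterior mass lies below `threshold` times the total variance.
#'
#' @param fits List of `phylo_fit` objects (one per tree).
#' @param threshold,prob Parameters of the pushed-against-zero rule
#'   (defaults 0.05 and 0.15).
#' @return Object of class `phylo_decomposition`: tibble `per_tree`
#'   (tree, component, mean, lo, hi), tibble `across_trees` (component,
#'   mean, range_lo, range_hi, pushed_against_zero).
#' @export
multi_tree_summary <- function(fits, threshold = 0.05, prob = 0.15) {
  stopifnot(length(fits) >= 1,
            all(vapply(fits, inherits, logical(1), "phylo_fit")))
  comps <- c("var_phylo", "var_species", "var_residual")
  per_tree <- dplyr::bind_rows(lapply(seq_along(fits), function(i) {
    d <- fits[[i]]$draws
    dplyr::bind_rows(lapply(comps, function(cmp) {
      q <- unname(stats::quantile(d[[cmp]], c(0.025, 0.975)))
      tibble::tibble(tree = i, component = cmp, mean = mean(d[[cmp]]),
                     lo = q[1], hi = q[2])
    }))
  }))
  pushed <- vapply(comps, function(cmp) {
    frac <- mean(vapply(fits, function(f) {
      d <- f$draws
      total <- d$var_phylo + d$var_species + d$var_residual
      mean(d[[cmp]] < threshold * total)
    }, numeric(1)))
    frac > prob
  }, logical(1))
  across <- per_tree |>
    dplyr::summarise(range_lo = min(.data$mean), range_hi = max(.data$mean),
                     mean = mean(.data$mean), .by = "component")
  across$pushed_against_zero <- unname(pushed[across$component])
  structure(list(per_tree = per_tree,
                 across_trees = across[c("component", "mean", "range_lo",
                                         "range_hi",
                                         "pushed_against_zero")]),
            class = "phylo_decomposition")
}

#' @export
print.phylo_decomposition <- function(x, ...) {
  cat("<phylo_decomposition> across", length(unique(x$per_tree$tree)),
      "tree(s)\n")
  print(x$across_trees)
  invisible(x)
}
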